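# Type-restricted negative sampling, the two losses with L2
# regularization, and the Adagrad mini-batch trainer combining the KG loss
# with the optional text-alignment penalty.

#' Load the bundled hyper-parameter search grid
#'
#' Reads the YAML search space shipped with the package (regularization,
#' alignment and learning-rate sweeps plus the fixed dimension, batch
#' size and epoch count, and the per-scorer loss convention).
#'
#' @param path YAML file; defaults to the bundled grid.
#' @return Nested list with `fixed`, `grid` and `loss_by_scorer`.
#' @export
load_hyperparameter_grid <- function(path = system.file(
  "config", "hyperparameter_grid.yaml", package = "pharmakg")) {
  yaml::read_yaml(path)
}

#' Training configuration
#'
#' Collects every knob of the embedding trainer. The loss defaults follow
#' the convention of the original scorer papers: margin ranking loss for
#' TransE/DistMult, logistic loss for ComplEx/SimplE.
#'
#' @param scorer Scoring function the config targets (fixes the loss
#'   default).
#' @param loss `"logistic"` or `"margin"`; `NULL` picks the scorer
#'   default.
#' @param margin_gamma Margin \eqn{\gamma} of the ranking loss.
#' @param reg_lambda L2 regularization coefficient \eqn{\lambda}.
#' @param align_lambda Alignment coefficient \eqn{\lambda_a}; 0 disables
#'   the text-alignment penalty.
#' @param lr_alpha0 Initial Adagrad learning rate \eqn{\alpha_0}.
#' @param dim Embedding dimension (default 768, the width of a BERT-style
#'   sentence encoder so text vectors can seed the tables directly).
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training triples.
#' @param negatives_per_positive Corruptions sampled per positive triple,
#'   alternating head- and tail-side.
#' @param type_filtering Restrict corruptions to entities whose type the
#'   relation admits on the corrupted side.
#' @param optimizer `"adagrad"` (per-parameter adaptive rates) or `"sgd"`.
#' @param text_method One of `"none"`, `"initialization"`, `"alignment"`,
#'   `"augmentation"` (recorded for harness bookkeeping; the trainer only
#'   acts on `align_lambda`/`text_vectors`).
#' @param text_field Text field the text method draws on.
#' @param strict_eq5 Use the literally-printed logistic sign
#'   `log(1+exp(+y f))` instead of the standard `log(1+exp(-y f))`.
#' @param seed Integer seed for shuffling and sampling.
#' @return A `train_config` list.
#' @export
train_config <- function(scorer = c("transe", "distmult", "complex",
                                    "simple"),
                         loss = NULL, margin_gamma = 12, reg_lambda = 1e-6,
                         align_lambda = 0, lr_alpha0 = 0.1, dim = 768L,
                         batch_size = 4096L, epochs = 100L,
                         negatives_per_positive = 64L,
                         type_filtering = TRUE,
                         optimizer = c("adagrad", "sgd"),
                         text_method = c("none", "initialization",
                                         "alignment", "augmentation"),
                         text_field = "name", strict_eq5 = FALSE,
                         seed = 1L) {
  scorer <- match.arg(scorer)
  if (is.null(loss)) {
    loss <- if (scorer %in% c("transe", "distmult")) "margin" else "logistic"
  }
  loss <- match.arg(loss, c("logistic", "margin"))
  stopifnot(margin_gamma >= 0, reg_lambda >= 0, align_lambda >= 0,
            lr_alpha0 > 0, dim >= 1, batch_size >= 1, epochs >= 0,
            negatives_per_positive >= 1)
  structure(list(scorer = scorer, loss = loss, margin_gamma = margin_gamma,
                 reg_lambda = reg_lambda, align_lambda = align_lambda,
                 lr_alpha0 = lr_alpha0, dim = as.integer(dim),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 negatives_per_positive = as.integer(negatives_per_positive),
                 type_filtering = isTRUE(type_filtering),
                 optimizer = match.arg(optimizer),
                 text_method = match.arg(text_method),
                 text_field = text_field,
                 strict_eq5 = isTRUE(strict_eq5),
                 seed = as.integer(seed)),
            class = "train_config")
}

# per relation+side pools of admissible replacement entity ids
.corruption_pools <- function(kg, type_filtering) {
  rel <- kg$relations
  pools <- list()
  for (i in seq_len(nrow(rel))) {
    if (type_filtering) {
      hp <- kg$entities$id[kg$entities$etype %in% rel$head_types[[i]]]
      tp <- kg$entities$id[kg$entities$etype %in% rel$tail_types[[i]]]
    } else {
      hp <- tp <- kg$entities$id
    }
    pools[[rel$relation[i]]] <- list(head = hp, tail = tp)
  }
  pools
}

#' Corrupt one triple for negative sampling
#'
#' Replaces the head or the tail with a different entity, optionally
#' restricted to entities whose type the relation admits on that side
#' (type filtering); with filtering off, any other entity may be drawn,
#' so e.g. a drug-interact-category corruption becomes possible.
#'
#' @param triple One-row tibble (or list) with `head`, `relation`, `tail`.
#' @param kg A `typed_kg` supplying the candidate entities.
#' @param side `"head"` or `"tail"`.
#' @param type_filtering Restrict replacements to type-admissible
#'   entities.
#' @return One-row tibble: the corrupted triple (differs from the input
#'   on exactly the chosen side).
#' @export
corrupt_triple <- function(triple, kg, side = c("head", "tail"),
                           type_filtering = TRUE) {
  side <- match.arg(side)
  pools <- .corruption_pools(kg, type_filtering)
  pl <- pools[[triple$relation]]
  if (is.null(pl)) abort(paste0("Unknown relation: ", triple$relation))
  cand <- setdiff(pl[[side]], triple[[side]])
  if (length(cand) == 0) {
    abort(paste0("No candidate entity to corrupt the ", side, " of a ",
                 triple$relation, " triple."))
  }
  out <- tibble(head = triple$head, relation = triple$relation,
                tail = triple$tail)
  out[[side]] <- cand[sample.int(length(cand), 1L)]
  out
}

#' Sample a batch of type-restricted negatives
#'
#' Vectorized corruption of `k` negatives per positive triple; corruption
#' sides alternate head/tail per negative index. Negatives always differ
#' from their source triple on the corrupted side; they are *not*
#' guaranteed to avoid other registered (or unregistered true) triples.
#'
#' @param triples Positive triples (tibble `head`, `relation`, `tail`).
#' @param kg A `typed_kg`.
#' @param k Negatives per positive.
#' @param type_filtering Restrict replacements by entity type.
#' @return Tibble of `k * nrow(triples)` corrupted triples with an extra
#'   `source` column giving the row of the positive each came from.
#' @export
sample_negatives <- function(triples, kg, k = 1L, type_filtering = TRUE) {
  pools <- .corruption_pools(kg, type_filtering)
  n <- nrow(triples)
  out <- vector("list", k)
  for (j in seq_len(k)) {
    side <- if (j %% 2L == 1L) "head" else "tail"
    repl <- character(n)
    for (r in unique(triples$relation)) {
      sel <- which(triples$relation == r)
      pool <- pools[[r]][[side]]
      orig <- triples[[side]][sel]
      pick <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
      # redraw collisions with the original entity
      bad <- which(pick == orig)
      guard <- 0L
      while (length(bad) > 0 && guard < 100L) {
        pick[bad] <- pool[sample.int(length(pool), length(bad),
                                     replace = TRUE)]
        bad <- bad[pick[bad] == orig[bad]]
        guard <- guard + 1L
      }
      if (length(bad) > 0) {
        for (b in bad) {
          cand <- setdiff(pool, orig[b])
          if (length(cand) == 0) {
            abort(paste0("No candidate entity to corrupt the ", side,
                         " of relation ", r))
          }
          pick[b] <- cand[sample.int(length(cand), 1L)]
        }
      }
      repl[sel] <- pick
    }
    neg <- tibble(head = triples$head, relation = triples$relation,
                  tail = triples$tail, source = seq_len(n))
    neg[[side]] <- repl
    out[[j]] <- neg
  }
  bind_rows(out)
}

#' Logistic loss
#'
#' \eqn{\sum_i \log(1 + \exp(-y_i f_i)) + \lambda \lVert\Theta\rVert_2^2}
#' over labeled triples (\eqn{y = +1} positive, \eqn{-1} negative).
#' Positives are rewarded for high scores. `strict_eq5 = TRUE` flips the
#' sign inside the exponential to the literally-printed form, under which
#' the loss *increases* with positive scores.
#'
#' @param y Vector of labels \eqn{\pm 1}.
#' @param scores Vector of triple scores, same length.
#' @param reg_lambda L2 coefficient \eqn{\lambda}.
#' @param params_norm_sq \eqn{\lVert\Theta\rVert_2^2} of the model
#'   parameters.
#' @param strict_eq5 Use the printed sign convention.
#' @return The scalar loss.
#' @export
#' @examples
#' logistic_loss(1, 0) # log(2)
logistic_loss <- function(y, scores, reg_lambda = 0, params_norm_sq = 0,
                          strict_eq5 = FALSE) {
  if (length(y) != length(scores)) abort("y and scores length mismatch")
  s <- if (strict_eq5) 1 else -1
  sum(.softplus(s * y * scores)) + reg_lambda * params_norm_sq
}

#' Margin-based pairwise ranking loss
#'
#' \eqn{\sum_i \max(0, \gamma - f^+_i + f^-_i) + \lambda
#' \lVert\Theta\rVert_2^2} over paired positive/negative scores; zero (up
#' to the regularizer) once every positive beats its negative by at least
#' the margin.
#'
#' @param pos_scores,neg_scores Paired score vectors of equal length.
#' @param margin_gamma Margin \eqn{\gamma}.
#' @param reg_lambda,params_norm_sq As in [logistic_loss()].
#' @return The scalar loss.
#' @export
#' @examples
#' margin_ranking_loss(2, 0, margin_gamma = 1) # 0
margin_ranking_loss <- function(pos_scores, neg_scores, margin_gamma = 12,
                                reg_lambda = 0, params_norm_sq = 0) {
  if (length(pos_scores) != length(neg_scores)) {
    abort("pos_scores and neg_scores length mismatch")
  }
  sum(pmax(0, margin_gamma - pos_scores + neg_scores)) +
    reg_lambda * params_norm_sq
}

# numerically stable log(1 + exp(x))
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# squared L2 norm of all parameter tables
.params_norm_sq <- function(model) {
  sum(vapply(model$tables, function(m) sum(m^2), numeric(1)))
}

# ---- gradients ---------------------------------------------------------

# Per-triple score gradients, multiplied by the per-triple loss
# coefficient `coef` (= dL/df), returned as (table name -> list(idx, g))
# contribution lists ready for rowsum aggregation.
.grad_contribs <- function(model, hi, ri, ti, coef) {
  tb <- model$tables
  switch(model$scorer,
    transe = {
      delta <- tb$ent[hi, , drop = FALSE] + tb$rel[ri, , drop = FALSE] -
        tb$ent[ti, , drop = FALSE]
      nrm <- sqrt(rowSums(delta^2))
      u <- delta / pmax(nrm, 1e-12)  # unit direction; 0/0 guarded
      g <- u * (-coef)
      list(ent = list(idx = c(hi, ti), g = rbind(g, -g)),
           rel = list(idx = ri, g = g))
    },
    distmult = {
      H <- tb$ent[hi, , drop = FALSE]; R <- tb$rel[ri, , drop = FALSE]
      T_ <- tb$ent[ti, , drop = FALSE]
      list(ent = list(idx = c(hi, ti), g = rbind(R * T_ * coef,
                                                 H * R * coef)),
           rel = list(idx = ri, g = H * T_ * coef))
    },
    complex = {
      Hr <- tb$ent_re[hi, , drop = FALSE]; Hi <- tb$ent_im[hi, , drop = FALSE]
      Rr <- tb$rel_re[ri, , drop = FALSE]; Ri <- tb$rel_im[ri, , drop = FALSE]
      Tr <- tb$ent_re[ti, , drop = FALSE]; Ti <- tb$ent_im[ti, , drop = FALSE]
      # f = sum(Hr Rr Tr - Hi Ri Tr + Hr Ri Ti + Hi Rr Ti)
      list(
        ent_re = list(idx = c(hi, ti),
                      g = rbind((Rr * Tr + Ri * Ti) * coef,
                                (Hr * Rr - Hi * Ri) * coef)),
        ent_im = list(idx = c(hi, ti),
                      g = rbind((-Ri * Tr + Rr * Ti) * coef,
                                (Hr * Ri + Hi * Rr) * coef)),
        rel_re = list(idx = ri, g = (Hr * Tr + Hi * Ti) * coef),
        rel_im = list(idx = ri, g = (-Hi * Tr + Hr * Ti) * coef))
    },
    simple = {
      Hh <- tb$ent_h[hi, , drop = FALSE]; Ht <- tb$ent_t[hi, , drop = FALSE]
      Th <- tb$ent_h[ti, , drop = FALSE]; Tt <- tb$ent_t[ti, , drop = FALSE]
      Vf <- tb$rel_fwd[ri, , drop = FALSE]; Vi <- tb$rel_inv[ri, , drop = FALSE]
      # f = 0.5 (sum(Hh Vf Tt) + sum(Ht Vi Th))
      list(
        ent_h = list(idx = c(hi, ti),
                     g = rbind(0.5 * Vf * Tt * coef,
                               0.5 * Ht * Vi * coef)),
        ent_t = list(idx = c(hi, ti),
                     g = rbind(0.5 * Vi * Th * coef,
                               0.5 * Hh * Vf * coef)),
        rel_fwd = list(idx = ri, g = 0.5 * Hh * Tt * coef),
        rel_inv = list(idx = ri, g = 0.5 * Ht * Th * coef))
    })
}

# Adagrad / SGD update of one table given raw (idx, g) contributions
.apply_update <- function(table, state, idx, g, lr, optimizer) {
  agg <- rowsum(g, group = idx)
  rows <- as.integer(rownames(agg))
  if (optimizer == "adagrad") {
    state[rows, ] <- state[rows, , drop = FALSE] + agg^2
    step <- agg / sqrt(state[rows, , drop = FALSE] + 1e-10)
  } else {
    step <- agg
  }
  table[rows, ] <- table[rows, , drop = FALSE] - lr * step
  list(table = table, state = state)
}

#' Train a knowledge-graph embedding model
#'
#' Minimizes \eqn{L = L_{KG} + L_a} by mini-batch gradient descent with
#' per-parameter adaptive learning rates (Adagrad). Per positive triple,
#' `negatives_per_positive` type-restricted corruptions are drawn
#' (alternating head/tail side). The L2 and alignment penalties are
#' applied lazily to the rows each batch touches; the recorded loss trace
#' uses the exact full-table penalty values at the end of each epoch.
#'
#' @param model A `kge_model` (its scorer must match `config$scorer`).
#' @param kg A `typed_kg` supplying type pools for corruption.
#' @param split A `kg_split`; only `split$train` is used.
#' @param config A [train_config()].
#' @param text_vectors A text-vector table (see [build_text_vectors()]);
#'   required when `config$align_lambda > 0`.
#' @return A `kge_fit`: list with the trained `model`, the `config` and a
#'   per-epoch `trace` tibble (`epoch`, `loss_kg`, `loss_align`, `total`).
#' @export
train_kge <- function(model, kg, split, config, text_vectors = NULL) {
  stopifnot(inherits(model, "kge_model"), inherits(config, "train_config"))
  if (model$scorer != config$scorer) {
    abort("model$scorer and config$scorer disagree")
  }
  if (config$align_lambda > 0 && is.null(text_vectors)) {
    abort("align_lambda > 0 requires text_vectors")
  }
  train <- split$train
  missing_e <- setdiff(unique(c(train$head, train$tail)), model$entity_ids)
  if (length(missing_e) > 0) {
    abort(paste0("Training triples reference entities outside the model ",
                 "vocabulary: ", paste(head(missing_e, 5), collapse = ", ")))
  }
  Vt <- NULL
  ent_tables <- intersect(names(model$tables),
                          c("ent", "ent_re", "ent_im", "ent_h", "ent_t"))
  if (!is.null(text_vectors)) {
    Vt <- .text_matrix(text_vectors, model$entity_ids, model$dim)
  }
  trace <- tibble(epoch = integer(), loss_kg = numeric(),
                  loss_align = numeric(), total = numeric())
  fit <- structure(list(model = model, config = config, trace = trace),
                   class = "kge_fit")
  if (config$epochs == 0L || nrow(train) == 0L) return(fit)

  hi0 <- .row_idx(train$head, model$entity_ids, "entity")
  ti0 <- .row_idx(train$tail, model$entity_ids, "entity")
  ri0 <- .row_idx(train$relation, model$relation_ids, "relation")
  pools <- .corruption_pools(kg, config$type_filtering)
  pool_idx <- lapply(pools, function(p) {
    list(head = .row_idx(p$head, model$entity_ids, "entity"),
         tail = .row_idx(p$tail, model$entity_ids, "entity"))
  })
  rel_of <- train$relation
  k <- config$negatives_per_positive
  n <- nrow(train)
  states <- lapply(model$tables, function(m) {
    matrix(0, nrow(m), ncol(m))
  })

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    loss_kg <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      rows <- ord[start:min(start + config$batch_size - 1L, n)]
      bh <- hi0[rows]; br <- ri0[rows]; bt <- ti0[rows]
      m <- length(rows)

      # negatives: k per positive, alternating corruption side
      neg_h <- integer(0); neg_r <- integer(0); neg_t <- integer(0)
      src <- integer(0)
      for (j in seq_len(k)) {
        side <- if (j %% 2L == 1L) "head" else "tail"
        repl <- integer(m)
        for (r in unique(rel_of[rows])) {
          sel <- which(rel_of[rows] == r)
          pool <- pool_idx[[r]][[side]]
          orig <- if (side == "head") bh[sel] else bt[sel]
          if (length(pool) < 2 && all(pool %in% orig)) {
            abort(paste0("No candidate entity to corrupt relation ", r))
          }
          pick <- pool[sample.int(length(pool), length(sel),
                                  replace = TRUE)]
          bad <- which(pick == orig); guard <- 0L
          while (length(bad) > 0 && guard < 100L) {
            pick[bad] <- pool[sample.int(length(pool), length(bad),
                                         replace = TRUE)]
            bad <- bad[pick[bad] == orig[bad]]
            guard <- guard + 1L
          }
          repl[sel] <- pick
        }
        if (side == "head") {
          neg_h <- c(neg_h, repl); neg_t <- c(neg_t, bt)
        } else {
          neg_h <- c(neg_h, bh); neg_t <- c(neg_t, repl)
        }
        neg_r <- c(neg_r, br); src <- c(src, seq_len(m))
      }

      f_pos <- .score_idx(model, bh, br, bt)
      f_neg <- .score_idx(model, neg_h, neg_r, neg_t)

      if (config$loss == "logistic") {
        sgn <- if (config$strict_eq5) 1 else -1
        # d/df log(1+exp(s*y*f)) = s*y*sigmoid(s*y*f)
        coef_pos <- sgn * stats::plogis(sgn * f_pos)
        coef_neg <- -sgn * stats::plogis(-sgn * f_neg)
        loss_kg <- loss_kg + sum(.softplus(sgn * f_pos)) +
          sum(.softplus(-sgn * f_neg))
        all_h <- c(bh, neg_h); all_r <- c(br, neg_r); all_t <- c(bt, neg_t)
        coef <- c(coef_pos, coef_neg)
      } else {
        viol <- config$margin_gamma - f_pos[src] + f_neg
        active <- viol > 0
        loss_kg <- loss_kg + sum(viol[active])
        # positives: -1 per active pair they appear in; negatives: +1
        pos_coef <- as.numeric(rowsum(-as.numeric(active), group = src))
        keep <- which(active)
        all_h <- c(bh, neg_h[keep]); all_r <- c(br, neg_r[keep])
        all_t <- c(bt, neg_t[keep])
        coef <- c(pos_coef, rep(1, length(keep)))
      }
      nz <- which(coef != 0)
      if (length(nz) == 0) next
      contribs <- .grad_contribs(model, all_h[nz], all_r[nz], all_t[nz],
                                 coef[nz])
      for (tn in names(contribs)) {
        idx <- contribs[[tn]]$idx
        g <- contribs[[tn]]$g
        if (config$reg_lambda > 0) {
          g <- g + 2 * config$reg_lambda *
            model$tables[[tn]][idx, , drop = FALSE]
        }
        if (!is.null(Vt) && config$align_lambda > 0 &&
            tn %in% ent_tables) {
          g <- g + 2 * config$align_lambda *
            (model$tables[[tn]][idx, , drop = FALSE] -
               Vt[idx, , drop = FALSE])
        }
        upd <- .apply_update(model$tables[[tn]], states[[tn]], idx, g,
                             config$lr_alpha0, config$optimizer)
        model$tables[[tn]] <- upd$table
        states[[tn]] <- upd$state
      }
    }
    reg_val <- config$reg_lambda * .params_norm_sq(model)
    la <- if (!is.null(Vt) && config$align_lambda > 0) {
      sum(vapply(ent_tables,
                 function(tn) sum((model$tables[[tn]] - Vt)^2),
                 numeric(1))) * config$align_lambda
    } else 0
    total <- loss_kg + reg_val + la
    if (!is.finite(total)) {
      abort(paste0("Non-finite loss at epoch ", ep,
                   " (loss_kg=", loss_kg, ", align=", la, "); try a ",
                   "smaller learning rate."))
    }
    trace <- bind_rows(trace, tibble(epoch = ep,
                                     loss_kg = loss_kg + reg_val,
                                     loss_align = la, total = total))
  }
  structure(list(model = model, config = config, trace = trace),
            class = "kge_fit")
}

#' @export
print.kge_fit <- function(x, ...) {
  cat("<kge_fit> scorer=", x$model$scorer, " loss=", x$config$loss,
      " epochs=", nrow(x$trace), sep = "")
  if (nrow(x$trace) > 0) {
    cat(" | final total loss ", signif(tail(x$trace$total, 1), 5), sep = "")
  }
  cat("\n")
  invisible(x)
}
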