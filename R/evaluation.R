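# Filtered, type-aware link-prediction ranking; per-relation, macro- and
# micro-averaged MRR; grid/ablation harness.

#' Candidate entities for ranking one side of a triple
#'
#' For the chosen side of an evaluation triple, the candidate set starts
#' from all entities except the triple's other endpoint (no self-pairing),
#' then drops entities of types the relation does not admit on that side
#' (`type_filtered`), then drops entities that would re-create a triple
#' registered anywhere in the KG other than the evaluated one itself
#' (`filtered` — the standard filtered setting). The true entity is always
#' a candidate.
#'
#' @param kg A `typed_kg` whose `triples` hold *all* splits (the filter
#'   set).
#' @param triple One-row tibble/list with `head`, `relation`, `tail`.
#' @param side Which side is being replaced: `"head"` or `"tail"`.
#' @param filtered Apply the known-true-triple filter.
#' @param type_filtered Apply the entity-type filter.
#' @return Character vector of candidate entity ids (including the true
#'   one).
#' @export
candidate_set <- function(kg, triple, side = c("tail", "head"),
                          filtered = TRUE, type_filtered = TRUE) {
  side <- match.arg(side)
  rel_row <- kg$relations[kg$relations$relation == triple$relation, ]
  if (nrow(rel_row) == 0) {
    abort(paste0("Unknown relation: ", triple$relation))
  }
  other <- if (side == "tail") triple$head else triple$tail
  true_ent <- if (side == "tail") triple$tail else triple$head
  cand <- kg$entities$id
  if (type_filtered) {
    allowed <- if (side == "tail") rel_row$tail_types[[1]] else
      rel_row$head_types[[1]]
    cand <- cand[kg$entities$etype %in% allowed]
  }
  cand <- setdiff(cand, other)
  if (filtered) {
    tr <- kg$triples[kg$triples$relation == triple$relation, , drop = FALSE]
    known <- if (side == "tail") tr$tail[tr$head == triple$head] else
      tr$head[tr$tail == triple$tail]
    cand <- setdiff(cand, setdiff(known, true_ent))
  }
  union(cand, true_ent)
}

#' Rank of the true entity among candidates
#'
#' Scores every candidate completion of the triple on the chosen side and
#' returns the rank of the true entity under the mean-rank tie policy:
#' \deqn{rank = 1 + \#\{f_c > f_{true}\} + \tfrac12\#\{c \ne true : f_c =
#' f_{true}\}.} A constant (e.g. untrained) scorer therefore yields the
#' expected mid rank \eqn{(n+1)/2}, not an optimistic 1.
#'
#' @param model A `kge_model`.
#' @param triple One-row tibble/list with `head`, `relation`, `tail`.
#' @param side `"head"` or `"tail"`.
#' @param candidates Character vector of candidate ids; must contain the
#'   true entity.
#' @return The (possibly fractional) rank, \eqn{\ge 1}.
#' @export
rank_of <- function(model, triple, side = c("tail", "head"), candidates) {
  side <- match.arg(side)
  if (length(candidates) == 0) abort("Empty candidate set")
  true_ent <- if (side == "tail") triple$tail else triple$head
  if (!true_ent %in% candidates) {
    abort("True entity is not among the candidates")
  }
  cand_triples <- if (side == "tail") {
    tibble(head = triple$head, relation = triple$relation,
           tail = candidates)
  } else {
    tibble(head = candidates, relation = triple$relation,
           tail = triple$tail)
  }
  f <- score_triples(model, cand_triples)
  f_true <- f[match(true_ent, candidates)]
  others <- candidates != true_ent
  1 + sum(f[others] > f_true) + 0.5 * sum(f[others] == f_true)
}

#' Evaluate link prediction on a split partition
#'
#' Computes, for every evaluation-included triple of the chosen
#' partition, the rank of the true head and of the true tail among the
#' (optionally filtered and type-filtered) candidates, then aggregates
#' mean reciprocal rank per relation, macro (unweighted mean over
#' relations) and micro (mean over all rank observations).
#'
#' @param model A `kge_model`.
#' @param kg The full `typed_kg` (all splits; supplies the filter set and
#'   entity types).
#' @param split A `kg_split`.
#' @param part `"valid"` or `"test"`.
#' @param filtered,type_filtered See [candidate_set()].
#' @return A `kge_ranking`: list with `observations` (tibble `head`,
#'   `relation`, `tail`, `side`, `rank`), `by_relation` (tibble
#'   `relation`, `mrr`, `n`), `macro_mrr`, `micro_mrr` and the evaluation
#'   settings.
#' @export
evaluate_ranking <- function(model, kg, split, part = c("test", "valid"),
                             filtered = TRUE, type_filtered = TRUE) {
  part <- match.arg(part)
  triples <- split[[part]]
  eval_rel <- kg$relations$relation[kg$relations$eval_included]
  triples <- triples[triples$relation %in% eval_rel, , drop = FALSE]
  if (nrow(triples) == 0) abort(paste0("Empty ", part, " partition."))

  etype <- setNames(kg$entities$etype, kg$entities$id)
  ent_idx <- .row_idx(kg$entities$id, model$entity_ids, "entity")
  names(ent_idx) <- kg$entities$id

  obs <- vector("list", 2L * nrow(triples))
  o <- 0L
  for (side in c("head", "tail")) {
    for (i in seq_len(nrow(triples))) {
      trp <- triples[i, ]
      cand <- candidate_set(kg, trp, side = side, filtered = filtered,
                            type_filtered = type_filtered)
      rk <- .rank_idx(model, trp, side, cand, ent_idx)
      o <- o + 1L
      obs[[o]] <- tibble(head = trp$head, relation = trp$relation,
                         tail = trp$tail, side = side, rank = rk)
    }
  }
  agg <- aggregate_ranking(bind_rows(obs))
  structure(
    c(agg,
      list(part = part, filtered = filtered,
           type_filtered = type_filtered)),
    class = "kge_ranking")
}

#' Aggregate rank observations into per-relation and averaged MRR
#'
#' Per-relation MRR pools head- and tail-side observations; the macro
#' average weights every relation equally while the micro average weights
#' every observation equally, so a relation with many observations (like
#' `interact` in realistic graphs) dominates micro but not macro.
#'
#' @param observations Tibble with at least `relation` and `rank`
#'   columns.
#' @return List with `observations`, `by_relation` (tibble `relation`,
#'   `mrr`, `n`), `macro_mrr`, `micro_mrr`.
#' @export
#' @examples
#' obs <- tibble::tibble(relation = c("a", "a", "b"), rank = c(1, 2, 4))
#' aggregate_ranking(obs)$macro_mrr
aggregate_ranking <- function(observations) {
  by_relation <- observations |>
    group_by(relation = .data$relation) |>
    summarise(mrr = mean(1 / .data$rank), n = n(), .groups = "drop") |>
    arrange(.data$relation)
  list(observations = observations, by_relation = by_relation,
       macro_mrr = mean(by_relation$mrr),
       micro_mrr = mean(1 / observations$rank))
}

# index-based rank (avoids repeated id->row matching inside the loop)
.rank_idx <- function(model, trp, side, cand, ent_idx) {
  ci <- ent_idx[cand]
  ri <- match(trp$relation, model$relation_ids)
  if (side == "tail") {
    hi <- rep(ent_idx[[trp$head]], length(ci)); ti <- ci
    true_ent <- trp$tail
  } else {
    ti <- rep(ent_idx[[trp$tail]], length(ci)); hi <- ci
    true_ent <- trp$head
  }
  f <- .score_idx(model, hi, rep(ri, length(ci)), ti)
  f_true <- f[match(true_ent, cand)]
  others <- cand != true_ent
  1 + sum(f[others] > f_true) + 0.5 * sum(f[others] == f_true)
}

#' Aggregate mean reciprocal rank
#'
#' @param ranks Numeric vector of ranks (\eqn{\ge 1}).
#' @return Mean of `1/ranks`.
#' @export
#' @examples
#' mrr(c(1, 2, 4)) # 0.58333...
mrr <- function(ranks) mean(1 / ranks)

#' @export
print.kge_ranking <- function(x, ...) {
  cat("<kge_ranking> ", x$part, " | filtered=", x$filtered,
      " type_filtered=", x$type_filtered, "\n", sep = "")
  cat("  macro MRR ", signif(x$macro_mrr, 4), ", micro MRR ",
      signif(x$micro_mrr, 4), " over ", nrow(x$observations),
      " observations\n", sep = "")
  print(x$by_relation)
  invisible(x)
}

#' Train/evaluate a grid of method combinations
#'
#' Runs one training per grid row (scorer x text method x text field x
#' hyper-parameters), evaluates validation and test macro-MRR, and
#' returns one result row per combination; the row with the best
#' validation macro-MRR is flagged. This is the engine behind
#' scorer/method comparison and augmentation-ablation tables at
#' synthetic scale.
#'
#' @param kg A `typed_kg`.
#' @param split A `kg_split` of `kg`.
#' @param grid Tibble of combinations; recognised columns are the
#'   [train_config()] fields (`scorer`, `loss`, `text_method`,
#'   `text_field`, `lr_alpha0`, `reg_lambda`, `align_lambda`, ...) plus
#'   optional `aug_fields` (list column of field sets for augmentation
#'   rows).
#' @param encoder A `text_encoder` (required when any row uses a text
#'   method).
#' @param dim,epochs,... Defaults forwarded to [train_config()] for
#'   columns the grid omits.
#' @param filtered,type_filtered Evaluation setting.
#' @return Tibble: the grid columns plus `valid_macro_mrr`,
#'   `test_macro_mrr`, `best` and a `by_relation` list column of test
#'   per-relation MRR tibbles.
#' @export
run_grid <- function(kg, split, grid, encoder = NULL, dim = 16L,
                     epochs = 50L, filtered = TRUE, type_filtered = TRUE,
                     ...) {
  stopifnot(nrow(grid) > 0)
  defaults <- list(...)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- as.list(grid[i, , drop = FALSE])
    g <- lapply(g, function(v) if (is.list(v)) v[[1]] else v)
    cfg_args <- g[intersect(names(g),
                            names(formals(train_config)))]
    cfg_args <- c(cfg_args, defaults[setdiff(names(defaults),
                                             names(cfg_args))])
    cfg_args$dim <- cfg_args$dim %||% dim
    cfg_args$epochs <- cfg_args$epochs %||% epochs
    config <- do.call(train_config, cfg_args)

    kg_i <- kg; split_i <- split; tv <- NULL
    if (config$text_method == "augmentation") {
      if (is.null(encoder)) abort("augmentation rows need an encoder")
      aug <- augment_graph(kg, g$aug_fields %||%
                             setdiff(text_fields(), "name"), encoder)
      kg_i <- aug$kg
      extra <- kg_i$triples |>
        anti_join(bind_rows(split$train, split$valid, split$test),
                  by = c("head", "relation", "tail"))
      split_i$train <- bind_rows(split$train, extra)
      tv <- aug$text_vectors
    } else if (config$text_method %in% c("initialization", "alignment")) {
      if (is.null(encoder)) abort("text rows need an encoder")
      tv <- build_text_vectors(kg_i, encoder, field = config$text_field)
    }
    model <- init_embeddings(kg_i, config$scorer, config$dim,
                             init_spec(seed = config$seed))
    if (config$text_method %in% c("initialization", "augmentation")) {
      model <- initialize_from_text(model, tv)
    }
    fit <- train_kge(model, kg_i, split_i, config,
                     text_vectors = if (config$align_lambda > 0) tv)
    ev_valid <- evaluate_ranking(fit$model, kg_i, split_i, "valid",
                                 filtered = filtered,
                                 type_filtered = type_filtered)
    ev_test <- evaluate_ranking(fit$model, kg_i, split_i, "test",
                                filtered = filtered,
                                type_filtered = type_filtered)
    rows[[i]] <- dplyr::bind_cols(
      as_tibble(grid[i, , drop = FALSE]),
      tibble(valid_macro_mrr = ev_valid$macro_mrr,
             test_macro_mrr = ev_test$macro_mrr,
             by_relation = list(ev_test$by_relation)))
  }
  out <- bind_rows(rows)
  out$best <- seq_len(nrow(out)) == which.max(out$valid_macro_mrr)
  out
}
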