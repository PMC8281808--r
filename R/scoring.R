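# The four triple-scoring functions and their embedding parameter tables.
#
# TransE and DistMult keep one vector per entity and per relation; ComplEx
# keeps real+imaginary pairs; SimplE keeps head-role/tail-role entity
# vectors and forward/inverse relation vectors.

.scorers <- c("transe", "distmult", "complex", "simple")

# names of the parameter tables per scorer
.table_names <- function(scorer) {
  switch(scorer,
         transe = ,
         distmult = list(entity = "ent", relation = "rel"),
         complex = list(entity = c("ent_re", "ent_im"),
                        relation = c("rel_re", "rel_im")),
         simple = list(entity = c("ent_h", "ent_t"),
                       relation = c("rel_fwd", "rel_inv")))
}

#' TransE triple score
#'
#' The translational-distance score \eqn{f(h,r,t) = -\lVert h + r - t
#' \rVert_2}. The maximum value 0 is attained exactly when the relation
#' vector translates the head onto the tail.
#'
#' @param h,r,t Numeric vectors of equal length.
#' @return A single real score (always \eqn{\le 0}).
#' @export
#' @examples
#' score_transe(c(1, 0), c(0, 1), c(1, 1)) # 0: exact translation
score_transe <- function(h, r, t) {
  .check_len(h, r, t)
  -sqrt(sum((h + r - t)^2))
}

#' DistMult triple score
#'
#' The diagonal bilinear score \eqn{f(h,r,t) = \sum_i h_i r_i t_i}. It is
#' symmetric in head and tail, so it cannot distinguish the direction of
#' asymmetric relations.
#'
#' @inheritParams score_transe
#' @return A single real score.
#' @export
score_distmult <- function(h, r, t) {
  .check_len(h, r, t)
  sum(h * r * t)
}

#' ComplEx triple score
#'
#' The complex bilinear score \eqn{f(h,r,t) =
#' \mathrm{Re}(\sum_i h_i r_i \bar{t}_i)} with the tail conjugated, the
#' form that models both symmetric and asymmetric relations. With
#' `conjugate_tail = FALSE` the tail is not conjugated; that variant is
#' symmetric in head and tail (it coincides with DistMult on real vectors
#' in either mode).
#'
#' @param h,r,t Complex (or numeric) vectors of equal length.
#' @param conjugate_tail Conjugate the tail vector (the standard form).
#' @return A single real score.
#' @export
#' @examples
#' score_complex(complex(real = 1, imaginary = 1), 1i, 1 + 0i) # -1
score_complex <- function(h, r, t, conjugate_tail = TRUE) {
  .check_len(h, r, t)
  tt <- if (conjugate_tail) Conj(as.complex(t)) else as.complex(t)
  Re(sum(as.complex(h) * as.complex(r) * tt))
}

#' SimplE triple score
#'
#' \eqn{f(h,r,t) = \tfrac12(\langle h^{head}, v_r, t^{tail}\rangle +
#' \langle h^{tail}, v_{r^{-1}}, t^{head}\rangle)} where
#' \eqn{\langle a,b,c\rangle = \sum_i a_i b_i c_i}; each entity carries a
#' head-role and a tail-role vector, each relation a forward and an
#' inverse vector.
#'
#' @param h_head,h_tail Head entity's head-role / tail-role vectors.
#' @param v_r,v_r_inv Relation forward / inverse vectors.
#' @param t_head,t_tail Tail entity's head-role / tail-role vectors.
#' @return A single real score.
#' @export
score_simple <- function(h_head, h_tail, v_r, v_r_inv, t_head, t_tail) {
  .check_len(h_head, h_tail, v_r, v_r_inv, t_head, t_tail)
  0.5 * (sum(h_head * v_r * t_tail) + sum(h_tail * v_r_inv * t_head))
}

.check_len <- function(...) {
  ln <- lengths(list(...))
  if (length(unique(ln)) != 1) {
    abort(paste0("Vector length mismatch: ", paste(ln, collapse = ", ")))
  }
  invisible(NULL)
}

#' Uniform initialization specification
#'
#' Embedding coordinates are drawn i.i.d. uniform on \eqn{[-b, b]} with
#' \eqn{b = (\gamma + \epsilon)/d}; the defaults \eqn{\gamma = 12},
#' \eqn{\epsilon = 2} give \eqn{b \approx 0.018} at \eqn{d = 768}.
#'
#' @param gamma_init,epsilon_init Bound parameters \eqn{\gamma},
#'   \eqn{\epsilon}.
#' @param seed Integer seed.
#' @return An `init_spec` list.
#' @export
init_spec <- function(gamma_init = 12, epsilon_init = 2, seed = 1L) {
  structure(list(gamma_init = gamma_init, epsilon_init = epsilon_init,
                 seed = as.integer(seed)),
            class = "init_spec")
}

#' Initialize an embedding model
#'
#' Allocates the parameter tables a scorer needs (one or two vectors per
#' entity/relation) and fills every coordinate with i.i.d. uniform draws
#' on \eqn{[-(\gamma+\epsilon)/d, +(\gamma+\epsilon)/d]}, reproducibly
#' under the spec's seed. Only evaluable relation vocabulary comes from
#' the KG's relation table; entities from its entity table.
#'
#' @param kg A `typed_kg`.
#' @param scorer One of `"transe"`, `"distmult"`, `"complex"`, `"simple"`.
#' @param dim Embedding dimension \eqn{d \ge 1}.
#' @param spec An [init_spec()].
#' @return A `kge_model`: list with `scorer`, `dim`, `entity_ids`,
#'   `relation_ids` and named parameter matrices in `$tables` (rows =
#'   vocabulary, columns = dimensions).
#' @export
init_embeddings <- function(kg, scorer = .scorers, dim = 768L,
                            spec = init_spec()) {
  scorer <- match.arg(scorer)
  if (dim < 1) abort("dim must be a positive integer")
  entity_ids <- sort(kg$entities$id)
  relation_ids <- sort(kg$relations$relation)
  b <- (spec$gamma_init + spec$epsilon_init) / dim
  if (b <= 0) abort("Uniform bound (gamma+epsilon)/d must be positive")
  nm <- .table_names(scorer)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(spec$seed)
  mk <- function(ids) {
    m <- matrix(runif(length(ids) * dim, -b, b), nrow = length(ids),
                ncol = dim, dimnames = list(ids, NULL))
    m
  }
  tables <- c(
    setNames(lapply(nm$entity, function(x) mk(entity_ids)), nm$entity),
    setNames(lapply(nm$relation, function(x) mk(relation_ids)), nm$relation)
  )
  structure(list(scorer = scorer, dim = as.integer(dim),
                 entity_ids = entity_ids, relation_ids = relation_ids,
                 tables = tables, init = spec),
            class = "kge_model")
}

#' @export
print.kge_model <- function(x, ...) {
  cat("<kge_model> scorer=", x$scorer, " d=", x$dim, " | ",
      length(x$entity_ids), " entities, ", length(x$relation_ids),
      " relations\n", sep = "")
  invisible(x)
}

# row indices of ids in a table, with an informative error
.row_idx <- function(ids, vocab, what) {
  idx <- match(ids, vocab)
  if (anyNA(idx)) {
    abort(paste0("Unknown ", what, " id(s): ",
                 paste(unique(ids[is.na(idx)]), collapse = ", ")))
  }
  idx
}

# vectorized scoring over index vectors; used by both score_triples and
# the trainer/evaluator
.score_idx <- function(model, hi, ri, ti, conjugate_tail = TRUE) {
  tb <- model$tables
  switch(model$scorer,
    transe = {
      delta <- tb$ent[hi, , drop = FALSE] + tb$rel[ri, , drop = FALSE] -
        tb$ent[ti, , drop = FALSE]
      -sqrt(rowSums(delta^2))
    },
    distmult = {
      rowSums(tb$ent[hi, , drop = FALSE] * tb$rel[ri, , drop = FALSE] *
                tb$ent[ti, , drop = FALSE])
    },
    complex = {
      hr <- tb$ent_re[hi, , drop = FALSE]; hi_ <- tb$ent_im[hi, , drop = FALSE]
      rr <- tb$rel_re[ri, , drop = FALSE]; ri_ <- tb$rel_im[ri, , drop = FALSE]
      tr <- tb$ent_re[ti, , drop = FALSE]; ti_ <- tb$ent_im[ti, , drop = FALSE]
      if (conjugate_tail) {
        rowSums(hr * rr * tr - hi_ * ri_ * tr + hr * ri_ * ti_ +
                  hi_ * rr * ti_)
      } else {
        rowSums(hr * rr * tr - hi_ * ri_ * tr - hr * ri_ * ti_ -
                  hi_ * rr * ti_)
      }
    },
    simple = {
      0.5 * (rowSums(tb$ent_h[hi, , drop = FALSE] *
                       tb$rel_fwd[ri, , drop = FALSE] *
                       tb$ent_t[ti, , drop = FALSE]) +
               rowSums(tb$ent_t[hi, , drop = FALSE] *
                         tb$rel_inv[ri, , drop = FALSE] *
                         tb$ent_h[ti, , drop = FALSE]))
    })
}

#' Score a batch of triples
#'
#' Vectorized scoring of a triple table under a model; elementwise equal
#' to the corresponding single-triple scoring function.
#'
#' @param model A `kge_model`.
#' @param triples Tibble (or data frame) with columns `head`, `relation`,
#'   `tail`; all ids must be in the model vocabulary.
#' @param conjugate_tail For the ComplEx scorer, conjugate the tail.
#' @return Numeric vector of scores, one per row of `triples`.
#' @export
score_triples <- function(model, triples, conjugate_tail = TRUE) {
  stopifnot(inherits(model, "kge_model"))
  if (nrow(triples) == 0) return(numeric(0))
  hi <- .row_idx(triples$head, model$entity_ids, "entity")
  ti <- .row_idx(triples$tail, model$entity_ids, "entity")
  ri <- .row_idx(triples$relation, model$relation_ids, "relation")
  .score_idx(model, hi, ri, ti, conjugate_tail = conjugate_tail)
}
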