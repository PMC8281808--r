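# Typed heterogeneous KG container, validation, symmetric closure,
# splitting and degree statistics.

#' Construct a typed knowledge graph
#'
#' Bundles entities, relation types and triples into a `typed_kg` object.
#' By default the symmetric closure is materialized at construction time,
#' so that every `interact` edge is present in both directions.
#'
#' @param entities Tibble with columns `id`, `etype`.
#' @param triples Tibble with columns `head`, `relation`, `tail`.
#' @param relations Relation-type table as returned by [pharma_schema()].
#' @param texts Text-attribute tibble with columns `entity_id`, `field`,
#'   `item_index`, `text`, or `NULL` to derive a `name` row per entity from
#'   its id (every entity must carry a name; pass an explicit empty tibble
#'   to opt out and surface the violations via [validate_kg()]).
#' @param close_symmetric Apply [symmetric_closure()] on construction.
#' @return A `typed_kg` object: a list of tibbles `entities`, `relations`,
#'   `triples`, `texts`.
#' @export
#' @examples
#' kg <- typed_kg(
#'   entities = tibble::tibble(id = c("d1", "d2"), etype = "drug"),
#'   triples = tibble::tibble(head = "d1", relation = "interact", tail = "d2")
#' )
#' kg$triples
typed_kg <- function(entities, triples,
                     relations = pharma_schema(),
                     texts = NULL,
                     close_symmetric = TRUE) {
  entities <- as_tibble(entities)
  triples <- as_tibble(triples)
  stopifnot(all(c("id", "etype") %in% names(entities)),
            all(c("head", "relation", "tail") %in% names(triples)))
  if (anyDuplicated(entities$id)) {
    abort("Entity ids must be unique within a KG.")
  }
  bad_type <- setdiff(unique(entities$etype), entity_types())
  if (length(bad_type) > 0) {
    abort(paste0("Unknown entity type(s): ", paste(bad_type, collapse = ", ")))
  }
  if (is.null(texts)) {
    texts <- tibble(entity_id = entities$id, field = "name",
                    item_index = 0L, text = entities$id)
  }
  texts <- as_tibble(texts)
  kg <- structure(
    list(entities = entities[c("id", "etype")],
         relations = as_tibble(relations),
         triples = distinct(triples[c("head", "relation", "tail")]),
         texts = texts),
    class = "typed_kg"
  )
  if (close_symmetric) kg <- symmetric_closure(kg, validate = FALSE)
  kg
}

#' @export
print.typed_kg <- function(x, ...) {
  cat("<typed_kg> ", nrow(x$entities), " entities, ",
      nrow(x$triples), " triples, ",
      nrow(x$relations), " relation types\n", sep = "")
  tb <- count(x$triples, .data$relation)
  et <- count(x$entities, .data$etype)
  cat("  entities: ",
      paste0(et$etype, "=", et$n, collapse = ", "), "\n", sep = "")
  cat("  triples:  ",
      paste0(tb$relation, "=", tb$n, collapse = ", "), "\n", sep = "")
  invisible(x)
}

is_typed_kg <- function(x) inherits(x, "typed_kg")

#' Validate a typed knowledge graph
#'
#' Checks every triple against its relation's head/tail type constraints,
#' reports references to entities that do not exist, triples with unknown
#' relation types, and entities lacking a non-empty `name` text. Never
#' raises: a well-formed KG yields a zero-row tibble.
#'
#' @param kg A `typed_kg`.
#' @return Tibble of violations with columns `kind` (one of
#'   `type_violation`, `dangling_reference`, `unknown_relation`,
#'   `missing_name`), `head`, `relation`, `tail`, `entity`, `detail`.
#' @export
validate_kg <- function(kg) {
  stopifnot(is_typed_kg(kg))
  viol <- list()
  blank <- tibble(kind = character(), head = character(),
                  relation = character(), tail = character(),
                  entity = character(), detail = character())
  etype <- setNames(kg$entities$etype, kg$entities$id)
  tr <- kg$triples

  unknown_rel <- !(tr$relation %in% kg$relations$relation)
  if (any(unknown_rel)) {
    bad <- tr[unknown_rel, ]
    viol$unknown <- tibble(kind = "unknown_relation", head = bad$head,
                           relation = bad$relation, tail = bad$tail,
                           entity = NA_character_,
                           detail = "relation not in schema")
  }
  dang_h <- !(tr$head %in% kg$entities$id)
  dang_t <- !(tr$tail %in% kg$entities$id)
  if (any(dang_h | dang_t)) {
    bad <- tr[dang_h | dang_t, ]
    who <- ifelse(!(bad$head %in% kg$entities$id), bad$head, bad$tail)
    viol$dangling <- tibble(kind = "dangling_reference", head = bad$head,
                            relation = bad$relation, tail = bad$tail,
                            entity = who,
                            detail = "triple references unknown entity id")
  }
  ok <- !unknown_rel & !dang_h & !dang_t
  if (any(ok)) {
    chk <- tr[ok, ]
    rel <- kg$relations
    ht_ok <- rep(TRUE, nrow(chk))
    for (i in seq_len(nrow(rel))) {
      sel <- chk$relation == rel$relation[i]
      if (!any(sel)) next
      ht_ok[sel] <- etype[chk$head[sel]] %in% rel$head_types[[i]] &
        etype[chk$tail[sel]] %in% rel$tail_types[[i]]
    }
    if (any(!ht_ok)) {
      bad <- chk[!ht_ok, ]
      viol$type <- tibble(
        kind = "type_violation", head = bad$head, relation = bad$relation,
        tail = bad$tail, entity = NA_character_,
        detail = paste0(etype[bad$head], " -[", bad$relation, "]-> ",
                        etype[bad$tail], " violates type constraint"))
    }
  }
  named <- kg$texts |>
    filter(.data$field == "name", !is.na(.data$text),
           nchar(.data$text) > 0) |>
    pull(.data$entity_id)
  unnamed <- setdiff(kg$entities$id, named)
  if (length(unnamed) > 0) {
    viol$name <- tibble(kind = "missing_name", head = NA_character_,
                        relation = NA_character_, tail = NA_character_,
                        entity = unnamed,
                        detail = "entity has no non-empty name text")
  }
  if (length(viol) == 0) blank else bind_rows(blank, bind_rows(viol))
}

#' Symmetric closure of a knowledge graph
#'
#' For every triple of a symmetric relation (only `interact` in the
#' pharmaceutical schema) adds the reverse triple. Asymmetric relations are
#' untouched and the operation is idempotent.
#'
#' @param kg A `typed_kg`.
#' @param validate Raise if the KG has violations before closing.
#' @return The closed `typed_kg`.
#' @export
symmetric_closure <- function(kg, validate = TRUE) {
  stopifnot(is_typed_kg(kg))
  if (validate) {
    v <- validate_kg(kg)
    if (nrow(v) > 0) {
      abort(paste0("Cannot close an invalid KG (", nrow(v), " violations)."))
    }
  }
  sym <- kg$relations$relation[kg$relations$symmetric]
  fwd <- kg$triples
  rev <- fwd |>
    filter(.data$relation %in% sym) |>
    rename(head = "tail", tail = "head") |>
    select("head", "relation", "tail")
  kg$triples <- distinct(bind_rows(fwd, rev))
  kg
}

#' Split triples into train/validation/test sets
#'
#' Splits the evaluation-included triples uniformly at random, stratified
#' per relation type so that every relation is represented in each
#' partition at the global ratio. Triples of relations excluded from
#' evaluation (`atc_hypernym` and the `has_<field>` augmentation edges) go
#' to the training set unconditionally. Both directions of a symmetric
#' pair are assigned to the same partition, preventing leakage of an
#' `interact` fact from train into test via its mirror image.
#'
#' @param kg A `typed_kg`.
#' @param ratios Numeric length-3 vector (train, valid, test) summing to 1.
#' @param seed Integer seed; the split is reproducible under it.
#' @return A `kg_split` object: list of tibbles `train`, `valid`, `test`
#'   plus the `seed` and `ratios` used.
#' @export
split_triples <- function(kg, ratios = c(0.90, 0.05, 0.05), seed = 1L) {
  stopifnot(is_typed_kg(kg), length(ratios) == 3)
  if (abs(sum(ratios) - 1) > 1e-8) abort("ratios must sum to 1")
  if (nrow(kg$triples) == 0) abort("Cannot split an empty KG.")
  rel <- kg$relations
  eval_rel <- rel$relation[rel$eval_included]
  sym_rel <- rel$relation[rel$symmetric]
  tr <- kg$triples
  train_only <- filter(tr, !(.data$relation %in% eval_rel))
  splittable <- filter(tr, .data$relation %in% eval_rel)

  parts <- list(train = list(train_only), valid = list(), test = list())
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  for (r in sort(unique(splittable$relation))) {
    sub <- filter(splittable, .data$relation == r)
    if (r %in% sym_rel) {
      # split at the level of unordered pairs, then re-expand
      key <- ifelse(sub$head <= sub$tail,
                    paste(sub$head, sub$tail, sep = "\r"),
                    paste(sub$tail, sub$head, sep = "\r"))
      units <- sort(unique(key))
      lab <- .assign_partitions(length(units), ratios)
      unit_lab <- setNames(lab, units)
      grp <- unit_lab[key]
    } else {
      grp <- .assign_partitions(nrow(sub), ratios)
    }
    parts$train <- c(parts$train, list(sub[grp == 1L, ]))
    parts$valid <- c(parts$valid, list(sub[grp == 2L, ]))
    parts$test <- c(parts$test, list(sub[grp == 3L, ]))
  }
  structure(
    list(train = bind_rows(parts$train),
         valid = bind_rows(parts$valid),
         test = bind_rows(parts$test),
         seed = seed, ratios = ratios),
    class = "kg_split")
}

# partition n units into 1/2/3 at the given ratios, random order;
# valid/test counts rounded to nearest, remainder to train
.assign_partitions <- function(n, ratios) {
  n_valid <- round(n * ratios[2])
  n_test <- round(n * ratios[3])
  n_train <- n - n_valid - n_test
  lab <- rep.int(c(1L, 2L, 3L), c(n_train, n_valid, n_test))
  sample(lab, n)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.kg_split <- function(x, ...) {
  cat("<kg_split> seed=", x$seed, " train/valid/test = ",
      nrow(x$train), "/", nrow(x$valid), "/", nrow(x$test), "\n", sep = "")
  invisible(x)
}

#' Per-entity degree histogram of one relation
#'
#' Counts, for one relation, how many triples each entity participates in
#' on the chosen side. The category-side histogram of the `category`
#' relation is heavily imbalanced in realistic pharmaceutical graphs: a
#' few broad categories absorb most memberships.
#'
#' @param kg A `typed_kg`.
#' @param relation Relation name.
#' @param side `"head"` or `"tail"`.
#' @return Tibble with columns `id`, `n`, sorted by decreasing `n`.
#' @export
relation_degree_histogram <- function(kg, relation, side = c("tail", "head")) {
  stopifnot(is_typed_kg(kg))
  side <- match.arg(side)
  if (!relation %in% kg$relations$relation) {
    abort(paste0("Unknown relation: ", relation))
  }
  rel <- relation
  kg$triples |>
    filter(.data$relation == rel) |>
    count(id = .data[[side]]) |>
    arrange(dplyr::desc(.data$n), .data$id)
}
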