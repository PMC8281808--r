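# Text resolution and encoding, plus the three schemes injecting text into
# embedding learning: initialization, alignment, augmentation.

#' Join multi-item text fields
#'
#' Multiple registered items (e.g. the synonyms "Acenol", "APAP",
#' "Paracetamol") are connected with a comma into one encoder input.
#'
#' @param items Character vector.
#' @return Single string; empty input gives `""`.
#' @export
#' @examples
#' join_text_items(c("Acenol", "APAP", "Paracetamol"))
join_text_items <- function(items) {
  if (length(items) == 0) return("")
  paste(items, collapse = ", ")
}

#' Resolve the text of an entity for a given field
#'
#' Returns the comma-joined text of `field` when the entity carries it;
#' otherwise falls back to the entity's name (name coverage is total, so
#' the fallback always succeeds — ATC codes, for instance, have no
#' description and resolve to their name).
#'
#' @param kg A `typed_kg`.
#' @param entity_id Entity id.
#' @param field One of [text_fields()].
#' @return Single string.
#' @export
resolve_text <- function(kg, entity_id, field = "name") {
  stopifnot(field %in% text_fields())
  tx <- kg$texts[kg$texts$entity_id == entity_id, , drop = FALSE]
  name_items <- tx$text[tx$field == "name" & nchar(tx$text) > 0]
  if (length(name_items) == 0) {
    abort(paste0("Entity ", entity_id, " has no name text."))
  }
  sel <- tx$field == field & nchar(tx$text) > 0
  items <- tx$text[sel][order(tx$item_index[sel])]
  if (length(items) == 0) items <- name_items
  join_text_items(items)
}

# ---- hashed text encoder ----------------------------------------------

# stable 31-ary rolling hash of a string into [0, 2^31 - 2]
.string_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483646
  as.integer(h)
}

# independent second hash (base 131) for content-addressed ids
.string_hash2 <- function(s) {
  h <- 7
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483629
  as.integer(h)
}

.tokenize <- function(text, budget = 512L) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nchar(toks) > 0]
  head(toks, budget)
}

#' Deterministic hashed text encoder
#'
#' A lightweight bag-of-tokens encoder with the same contract as a
#' transformer sentence encoder (fixed output width, deterministic,
#' truncation at a token budget): each token maps, via a stable hash
#' seeded by `seed`, to a pseudo-random unit vector, and a text is encoded
#' as the L2-normalized mean of its token vectors. Texts sharing tokens
#' therefore land near each other, which is exactly the lexical-overlap
#' signal the text-injection methods exploit. An external transformer
#' encoder can be dropped in anywhere a `text_encoder` is accepted, as
#' long as it exposes the same `dim`/`encode` contract.
#'
#' @param dim Output dimension.
#' @param seed Integer seed defining the token vocabulary embedding.
#' @param token_budget Maximum number of leading tokens encoded (the
#'   remainder of longer texts is ignored).
#' @return A `text_encoder`: list with `dim` and `encode(text)`.
#' @export
#' @examples
#' enc <- hashed_encoder(8, seed = 1)
#' all.equal(enc$encode("aspirin tablet"), enc$encode("aspirin tablet"))
hashed_encoder <- function(dim, seed = 1L, token_budget = 512L) {
  stopifnot(dim >= 1)
  cache <- new.env(parent = emptyenv())
  token_vec <- function(tok) {
    if (!is.null(cache[[tok]])) return(cache[[tok]])
    old <- .Random.seed_get()
    set.seed((.string_hash(tok) + as.integer(seed) * 7919L) %% 2147483646)
    v <- rnorm(dim)
    .Random.seed_set(old)
    v <- v / sqrt(sum(v^2))
    cache[[tok]] <- v
    v
  }
  encode <- function(text) {
    toks <- .tokenize(text, token_budget)
    if (length(toks) == 0) return(rep(0, dim))
    v <- rowSums(vapply(toks, token_vec, numeric(dim))) / length(toks)
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  }
  structure(list(dim = as.integer(dim), encode = encode,
                 token_budget = as.integer(token_budget),
                 seed = as.integer(seed)),
            class = "text_encoder")
}

#' Build the text-vector table of a KG
#'
#' Encodes `resolve_text(entity, field)` for every entity; the name
#' fallback guarantees 100% coverage.
#'
#' @param kg A `typed_kg`.
#' @param encoder A `text_encoder` whose `dim` matches the model.
#' @param field Text field to draw on.
#' @return A tibble with columns `entity_id` and `vector` (list column of
#'   length-`dim` numeric vectors); class `text_vectors`.
#' @export
build_text_vectors <- function(kg, encoder, field = "name") {
  stopifnot(inherits(encoder, "text_encoder"))
  ids <- kg$entities$id
  # resolve in bulk rather than per entity for speed
  tx <- kg$texts |>
    filter(nchar(.data$text) > 0) |>
    arrange(.data$entity_id, .data$field, .data$item_index)
  joined <- tx |>
    group_by(.data$entity_id, .data$field) |>
    summarise(text = join_text_items(.data$text), .groups = "drop")
  nm <- setNames(joined$text[joined$field == "name"],
                 joined$entity_id[joined$field == "name"])
  fl <- setNames(joined$text[joined$field == field],
                 joined$entity_id[joined$field == field])
  if (!all(ids %in% names(nm))) {
    abort(paste0("Entities without name text: ",
                 paste(head(setdiff(ids, names(nm)), 5), collapse = ", ")))
  }
  resolved <- ifelse(ids %in% names(fl), fl[ids], nm[ids])
  # identical resolved strings encode once
  uniq <- unique(resolved)
  enc <- lapply(uniq, encoder$encode)
  names(enc) <- uniq
  structure(tibble(entity_id = ids, vector = unname(enc[resolved])),
            class = c("text_vectors", class(tibble())))
}

# text_vectors tibble -> matrix aligned with a row-id vocabulary
.text_matrix <- function(text_vectors, ids, dim) {
  idx <- match(ids, text_vectors$entity_id)
  if (anyNA(idx)) {
    abort(paste0("text_vectors missing entities: ",
                 paste(head(ids[is.na(idx)], 5), collapse = ", ")))
  }
  m <- do.call(rbind, text_vectors$vector[idx])
  if (ncol(m) != dim) {
    abort(paste0("text vector dimension ", ncol(m),
                 " does not match model dimension ", dim))
  }
  rownames(m) <- ids
  m
}

#' Initialize entity embeddings from text vectors
#'
#' Overwrites every entity vector of the model with the entity's text
#' vector; for two-vector scorers (ComplEx real/imaginary, SimplE
#' head/tail roles) *both* vectors are set to the same text vector.
#' Relation vectors keep their random initialization.
#'
#' @param model A `kge_model`.
#' @param text_vectors A `text_vectors` table covering the model's
#'   entities.
#' @return The updated `kge_model`.
#' @export
initialize_from_text <- function(model, text_vectors) {
  stopifnot(inherits(model, "kge_model"))
  Vt <- .text_matrix(text_vectors, model$entity_ids, model$dim)
  for (tn in intersect(names(model$tables),
                       c("ent", "ent_re", "ent_im", "ent_h", "ent_t"))) {
    model$tables[[tn]] <- Vt
  }
  model
}

#' Alignment penalty between KG and text embeddings
#'
#' \eqn{L_a = \lambda_a \lVert V_{KG} - V_{text} \rVert^2} — the squared
#' Frobenius distance between the entity embedding table(s) and the
#' frozen text-vector table, summed over both vectors for two-vector
#' scorers.
#'
#' @param model A `kge_model`.
#' @param text_vectors A `text_vectors` table.
#' @param align_lambda Coefficient \eqn{\lambda_a}.
#' @return Scalar penalty value (\eqn{\ge 0}).
#' @export
alignment_penalty <- function(model, text_vectors, align_lambda = 1) {
  Vt <- .text_matrix(text_vectors, model$entity_ids, model$dim)
  tot <- 0
  for (tn in intersect(names(model$tables),
                       c("ent", "ent_re", "ent_im", "ent_h", "ent_t"))) {
    tot <- tot + sum((model$tables[[tn]] - Vt)^2)
  }
  align_lambda * tot
}

#' Augment a KG with textual nodes
#'
#' For each entity and each requested field the entity *natively* carries
#' (no name fallback here), adds one `text_node` entity and a
#' `has_<field>` triple from the entity to it. Text nodes are deduplicated
#' by `(field, exact joined text)`, so a synonym string shared between
#' two drugs yields one shared node — multiple text items of one entity
#' are thereby considered at once. The `has_<field>` relations are
#' excluded from evaluation, so all added triples are train-only. The
#' returned vector table initializes every original entity with its
#' *name* text vector and every text node with the encoding of its text.
#'
#' @param kg A `typed_kg`.
#' @param fields Character vector of fields from [text_fields()]
#'   (excluding `name`).
#' @param encoder A `text_encoder`.
#' @return List with `kg` (the augmented `typed_kg`) and `text_vectors`
#'   (covering originals and text nodes).
#' @export
augment_graph <- function(kg, fields, encoder) {
  stopifnot(length(fields) > 0, all(fields %in% text_fields()))
  fields <- setdiff(fields, "name")
  base <- kg$entities[kg$entities$etype != "text_node", , drop = FALSE]
  tx <- kg$texts |>
    filter(.data$entity_id %in% base$id, .data$field %in% fields,
           nchar(.data$text) > 0) |>
    arrange(.data$entity_id, .data$field, .data$item_index) |>
    group_by(.data$entity_id, .data$field) |>
    summarise(text = join_text_items(.data$text), .groups = "drop")

  node_key <- paste0(tx$field, "\r", tx$text)
  uniq <- !duplicated(node_key)
  # content-addressed node ids (two independent rolling hashes) so that a
  # node's id depends only on (field, text): ablation of one field leaves
  # the other fields' nodes byte-identical
  content_id <- function(field, text) {
    paste0("text:", field, ":",
           vapply(text, .string_hash, integer(1)), "-",
           vapply(text, .string_hash2, integer(1)))
  }
  node_id <- setNames(content_id(tx$field[uniq], tx$text[uniq]),
                      node_key[uniq])
  tx$node <- node_id[node_key]

  new_nodes <- tibble(id = unname(node_id), etype = "text_node")
  new_triples <- tibble(head = tx$entity_id,
                        relation = paste0("has_", tx$field),
                        tail = tx$node)
  node_texts <- tibble(entity_id = tx$node[uniq], field = "name",
                       item_index = 0L, text = tx$text[uniq])

  relations <- kg$relations |>
    filter(!grepl("^has_", .data$relation)) |>
    bind_rows(augmentation_relations(fields))
  aug <- typed_kg(
    entities = distinct(bind_rows(base, new_nodes)),
    triples = distinct(bind_rows(
      kg$triples[!grepl("^has_", kg$triples$relation), , drop = FALSE] |>
        filter(!(.data$head %in%
                   kg$entities$id[kg$entities$etype == "text_node"]),
               !(.data$tail %in%
                   kg$entities$id[kg$entities$etype == "text_node"])),
      new_triples)),
    relations = relations,
    texts = distinct(bind_rows(
      kg$texts[kg$texts$entity_id %in% base$id, , drop = FALSE],
      node_texts))
  )

  name_vecs <- build_text_vectors(
    typed_kg(base, tibble(head = character(), relation = character(),
                          tail = character()),
             relations = kg$relations,
             texts = kg$texts[kg$texts$entity_id %in% base$id, ,
                              drop = FALSE]),
    encoder, field = "name")
  node_enc <- lapply(tx$text[uniq], encoder$encode)
  node_vecs <- tibble(entity_id = tx$node[uniq], vector = node_enc)
  tv <- bind_rows(name_vecs, node_vecs)
  list(kg = aug,
       text_vectors = structure(tv,
                                class = c("text_vectors",
                                          class(tibble()))))
}
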