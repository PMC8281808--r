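# Model and text-vector checkpoints: a JSON header plus one TSV matrix
# per parameter table. Text on disk, diff-able, round-trip exact.

.vocab_hash <- function(ids) .string_hash(paste(ids, collapse = "\n"))

.write_matrix <- function(m, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(seq_len(nrow(m)), function(i) {
    paste(formatC(m[i, ], format = "g", digits = 17), collapse = "\t")
  }, character(1)), con)
  invisible(path)
}

.read_matrix <- function(path, ids) {
  lines <- readLines(path)
  m <- do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE),
                             as.numeric))
  rownames(m) <- ids
  m
}

#' Save / load an embedding model checkpoint
#'
#' A checkpoint directory holds `header.json` (scorer, dimension,
#' vocabularies and their hashes) and one TSV file per parameter table.
#' The loader validates the header hashes against the stored
#' vocabularies and reproduces the model exactly.
#'
#' @param model A `kge_model`.
#' @param dir Checkpoint directory (created if missing).
#' @return `write_kge_model()`: the directory, invisibly;
#'   `read_kge_model()`: the `kge_model`.
#' @export
write_kge_model <- function(model, dir) {
  stopifnot(inherits(model, "kge_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- list(scorer = model$scorer, dim = model$dim,
                 entity_ids = model$entity_ids,
                 relation_ids = model$relation_ids,
                 entity_hash = .vocab_hash(model$entity_ids),
                 relation_hash = .vocab_hash(model$relation_ids),
                 tables = names(model$tables))
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  for (tn in names(model$tables)) {
    .write_matrix(model$tables[[tn]], file.path(dir, paste0(tn, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_kge_model
#' @export
read_kge_model <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "header.json"),
                                simplifyVector = TRUE)
  if (.vocab_hash(header$entity_ids) != header$entity_hash ||
      .vocab_hash(header$relation_ids) != header$relation_hash) {
    abort("Checkpoint header hash mismatch: vocabulary corrupted.")
  }
  tables <- setNames(lapply(header$tables, function(tn) {
    ids <- if (grepl("^ent", tn)) header$entity_ids else
      header$relation_ids
    .read_matrix(file.path(dir, paste0(tn, ".tsv")), ids)
  }), header$tables)
  structure(list(scorer = header$scorer, dim = as.integer(header$dim),
                 entity_ids = header$entity_ids,
                 relation_ids = header$relation_ids,
                 tables = tables),
            class = "kge_model")
}

#' Save / load a text-vector table
#'
#' Written in the same directory layout as model checkpoints: a JSON
#' header plus one TSV matrix.
#'
#' @param text_vectors A `text_vectors` tibble.
#' @param dir Directory.
#' @return The directory (write) or the `text_vectors` tibble (read).
#' @export
write_text_vectors <- function(text_vectors, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- do.call(rbind, text_vectors$vector)
  header <- list(entity_ids = text_vectors$entity_id, dim = ncol(m),
                 entity_hash = .vocab_hash(text_vectors$entity_id))
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_matrix(m, file.path(dir, "vectors.tsv"))
  invisible(dir)
}

#' @rdname write_text_vectors
#' @export
read_text_vectors <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "header.json"),
                                simplifyVector = TRUE)
  m <- .read_matrix(file.path(dir, "vectors.tsv"), NULL)
  structure(tibble(entity_id = header$entity_ids,
                   vector = lapply(seq_len(nrow(m)), function(i) m[i, ])),
            class = c("text_vectors", class(tibble())))
}
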