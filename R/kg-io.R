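# Readers/writers for triple and text tables, ATC hierarchy expansion and
# the fixture-scale DrugBank-like XML parser.

#' Read / write triple TSV files
#'
#' Triple files are UTF-8 TSV with exactly three columns
#' `head_id<TAB>relation<TAB>tail_id` and no header. Reading a file written
#' by [write_triples()] returns the identical triple set.
#'
#' @param path File path.
#' @return `read_triples()`: tibble with columns `head`, `relation`,
#'   `tail`. `write_triples()`: the path, invisibly.
#' @export
read_triples <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nchar(lines) > 0]
  if (length(lines) == 0) {
    return(tibble(head = character(), relation = character(),
                  tail = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    bad <- which(nf != 3)[1]
    abort(paste0("Malformed triple line ", bad, " in ", path, ": expected 3 ",
                 "tab-separated columns, got ", nf[bad]))
  }
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  tibble(head = m[, 1], relation = m[, 2], tail = m[, 3])
}

#' @param x A `typed_kg` or a tibble of triples.
#' @rdname read_triples
#' @export
write_triples <- function(x, path) {
  tr <- if (is_typed_kg(x)) x$triples else as_tibble(x)
  writeLines(paste(tr$head, tr$relation, tr$tail, sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read / write entity tables
#'
#' Entity tables are two-column TSV `entity_id<TAB>entity_type`, no header.
#'
#' @param path File path.
#' @return Tibble with columns `id`, `etype`.
#' @export
read_entities <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nchar(lines) > 0]
  if (length(lines) == 0) return(tibble(id = character(), etype = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort(paste0("Malformed entity line ", which(lengths(parts) != 2)[1],
                 " in ", path))
  }
  m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  tibble(id = m[, 1], etype = m[, 2])
}

#' @param entities Tibble with columns `id`, `etype`.
#' @rdname read_entities
#' @export
write_entities <- function(entities, path) {
  writeLines(paste(entities$id, entities$etype, sep = "\t"), path,
             useBytes = TRUE)
  invisible(path)
}

# tabs and newlines inside free text are escaped so the TSV stays 4-column
.escape_text <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}
.unescape_text <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    res <- ""
    while (nchar(s) > 0) {
      k <- regexpr("\\", s, fixed = TRUE)
      if (k < 0) { res <- paste0(res, s); break }
      res <- paste0(res, substr(s, 1, k - 1))
      code <- substr(s, k + 1, k + 1)
      res <- paste0(res, switch(code, "t" = "\t", "n" = "\n", code))
      s <- substr(s, k + 2, nchar(s))
    }
    out[i] <- res
  }
  out
}

#' Read / write text-attribute tables
#'
#' Text tables are 4-column TSV `entity_id<TAB>field<TAB>item_index<TAB>text`
#' without header; `item_index` is 0-based and orders multi-item fields
#' such as synonyms. Tabs/newlines inside the text are backslash-escaped.
#' The key `(entity_id, field, item_index)` must be unique.
#'
#' @param path File path.
#' @return Tibble with columns `entity_id`, `field`, `item_index`, `text`.
#' @export
read_text_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nchar(lines) > 0]
  if (length(lines) == 0) {
    return(tibble(entity_id = character(), field = character(),
                  item_index = integer(), text = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4)) {
    abort(paste0("Malformed text-table line ",
                 which(lengths(parts) != 4)[1], " in ", path))
  }
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  out <- tibble(entity_id = m[, 1], field = m[, 2],
                item_index = as.integer(m[, 3]),
                text = .unescape_text(m[, 4]))
  if (anyDuplicated(out[c("entity_id", "field", "item_index")])) {
    abort(paste0("Duplicate (entity_id, field, item_index) key in ", path))
  }
  arrange(out, .data$entity_id, .data$field, .data$item_index)
}

#' @param texts Text-attribute tibble.
#' @rdname read_text_table
#' @export
write_text_table <- function(texts, path) {
  if (anyDuplicated(texts[c("entity_id", "field", "item_index")])) {
    abort("Duplicate (entity_id, field, item_index) key.")
  }
  writeLines(paste(texts$entity_id, texts$field, texts$item_index,
                   .escape_text(texts$text), sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Write / read a train-valid-test split
#'
#' Writes three triple TSVs (`train.tsv`, `valid.tsv`, `test.tsv`) plus a
#' `manifest.json` carrying seed, ratios and counts.
#'
#' @param split A `kg_split`.
#' @param dir Directory (created if missing).
#' @return The directory (write) or a `kg_split` (read).
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in c("train", "valid", "test")) {
    write_triples(split[[p]], file.path(dir, paste0(p, ".tsv")))
  }
  manifest <- list(seed = split$seed, ratios = split$ratios,
                   counts = list(train = nrow(split$train),
                                 valid = nrow(split$valid),
                                 test = nrow(split$test)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_split
#' @export
read_split <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structure(
    list(train = read_triples(file.path(dir, "train.tsv")),
         valid = read_triples(file.path(dir, "valid.tsv")),
         test = read_triples(file.path(dir, "test.tsv")),
         seed = manifest$seed,
         ratios = unlist(manifest$ratios)),
    class = "kg_split")
}

# ---- ATC codes ---------------------------------------------------------

# the five ATC levels are prefixes of length 1, 3, 4, 5, 7
.atc_levels <- c(1L, 3L, 4L, 5L, 7L)

.check_atc <- function(code) {
  ok <- grepl("^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$", code) &
    nchar(code) %in% .atc_levels
  if (any(!ok)) {
    abort(paste0("Malformed ATC code(s): ",
                 paste(code[!ok], collapse = ", ")))
  }
  invisible(code)
}

#' Ancestors of an ATC code
#'
#' @param code Character vector of ATC codes.
#' @return For `atc_ancestors()`, a list of character vectors of strictly
#'   higher-level prefixes, nearest first (e.g. `"A10BA02"` yields
#'   `"A10BA"`, `"A10B"`, `"A10"`, `"A"`).
#' @export
atc_ancestors <- function(code) {
  .check_atc(code)
  lapply(code, function(cd) {
    lv <- .atc_levels[.atc_levels < nchar(cd)]
    rev(vapply(lv, function(k) substr(cd, 1, k), character(1)))
  })
}

#' Expand an ATC code set into its hypernym hierarchy
#'
#' The ATC classification has five levels whose codes are nested prefixes
#' (lengths 1, 3, 4, 5, 7). Each code is linked to its next-higher level by
#' an `atc_hypernym` triple (`A10BA -> A10B`, `N02 -> N`), and every
#' intermediate ancestor code is materialized as an `atc` entity. The
#' result is a forest: each non-root code has exactly one parent.
#'
#' @param codes Character vector of syntactically valid ATC codes.
#' @return List with `entities` (tibble `id`, `etype`) covering the codes
#'   and all their ancestors, and `triples` (tibble of `atc_hypernym`
#'   edges child -> parent), both duplicate-free.
#' @export
#' @examples
#' expand_atc_hierarchy("A10BA02")$triples
expand_atc_hierarchy <- function(codes) {
  codes <- unique(codes)
  .check_atc(codes)
  anc <- atc_ancestors(codes)
  all_codes <- sort(unique(c(codes, unlist(anc))))
  parent_of <- function(cd) {
    lv <- .atc_levels[.atc_levels < nchar(cd)]
    if (length(lv) == 0) return(NA_character_)
    substr(cd, 1, max(lv))
  }
  parents <- vapply(all_codes, parent_of, character(1))
  keep <- !is.na(parents)
  list(
    entities = tibble(id = all_codes, etype = "atc"),
    triples = tibble(head = all_codes[keep], relation = "atc_hypernym",
                     tail = unname(parents[keep]))
  )
}

# ---- DrugBank-like XML -------------------------------------------------

#' Parse a DrugBank-like XML file
#'
#' Parses the minimal XML dialect documented in
#' `inst/extdata/README-drugbank-dialect.md`: `<drug>` elements carrying a
#' `<drugbank-id>`, text fields (`name`, `description`, `indication`,
#' `pharmacodynamics`, `mechanism-of-action`, `metabolism`, `synonyms`),
#' `<categories>` (MeSH ids), `<atc-codes>`, `<pathways>` (SMPDB ids),
#' `<drug-interactions>` and protein links (`targets`, `enzymes`,
#' `carriers`, `transporters` with UniProt ids). One drug entity is
#' emitted per element; category/ATC/pathway/interaction/protein links
#' become triples with the matching relation names. ATC links are emitted
#' for the leaf code and every ancestor level, and the code hierarchy is
#' expanded into `atc_hypernym` triples.
#'
#' @param path Path to the XML file.
#' @return A `typed_kg` (symmetric closure applied), whose `texts` slot
#'   holds the captured text rows.
#' @export
parse_drugbank_xml <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  doc <- xml2::read_xml(path)
  drugs <- xml2::xml_find_all(doc, ".//drug[drugbank-id]")

  ents <- list(); trips <- list(); texts <- list()
  txt1 <- function(node, xp) {
    n <- xml2::xml_find_first(node, xp)
    if (inherits(n, "xml_missing")) NA_character_ else
      stringr::str_squish(xml2::xml_text(n))
  }
  add_text <- function(id, field, items) {
    items <- items[!is.na(items) & nchar(items) > 0]
    if (length(items) == 0) return(NULL)
    tibble(entity_id = id, field = field,
           item_index = seq_along(items) - 1L, text = items)
  }

  atc_seen <- character()
  for (d in drugs) {
    id <- txt1(d, "./drugbank-id")
    ents[[length(ents) + 1L]] <- tibble(id = id, etype = "drug")
    texts[[length(texts) + 1L]] <- add_text(id, "name", txt1(d, "./name"))
    for (f in c("description", "indication", "pharmacodynamics",
                "mechanism-of-action", "metabolism")) {
      texts[[length(texts) + 1L]] <-
        add_text(id, normalize_text_field(f), txt1(d, paste0("./", f)))
    }
    syn <- xml2::xml_text(xml2::xml_find_all(d, "./synonyms/synonym"))
    texts[[length(texts) + 1L]] <- add_text(id, "synonyms",
                                            stringr::str_squish(syn))

    for (cat in xml2::xml_find_all(d, "./categories/category")) {
      mesh <- txt1(cat, "./mesh-id")
      if (is.na(mesh) || nchar(mesh) == 0) next
      ents[[length(ents) + 1L]] <- tibble(id = mesh, etype = "category")
      nm <- txt1(cat, "./category")
      texts[[length(texts) + 1L]] <-
        add_text(mesh, "name", if (is.na(nm)) mesh else nm)
      trips[[length(trips) + 1L]] <-
        tibble(head = id, relation = "category", tail = mesh)
    }

    codes <- xml2::xml_attr(xml2::xml_find_all(d, "./atc-codes/atc-code"),
                            "code")
    codes <- codes[!is.na(codes)]
    if (length(codes) > 0) {
      .check_atc(codes)
      # the drug is linked to the leaf code and to all ancestor levels
      lvls <- unique(c(codes, unlist(atc_ancestors(codes))))
      trips[[length(trips) + 1L]] <-
        tibble(head = id, relation = "atc", tail = lvls)
      atc_seen <- c(atc_seen, codes)
    }

    for (pw in xml2::xml_find_all(d, "./pathways/pathway")) {
      smpdb <- txt1(pw, "./smpdb-id")
      if (is.na(smpdb)) next
      ents[[length(ents) + 1L]] <- tibble(id = smpdb, etype = "pathway")
      nm <- txt1(pw, "./name")
      texts[[length(texts) + 1L]] <-
        add_text(smpdb, "name", if (is.na(nm)) smpdb else nm)
      dsc <- txt1(pw, "./description")
      texts[[length(texts) + 1L]] <- add_text(smpdb, "description", dsc)
      trips[[length(trips) + 1L]] <-
        tibble(head = id, relation = "pathway", tail = smpdb)
    }

    di <- xml2::xml_find_all(d, "./drug-interactions/drug-interaction")
    for (x in di) {
      other <- txt1(x, "./drugbank-id")
      if (is.na(other)) next
      ents[[length(ents) + 1L]] <- tibble(id = other, etype = "drug")
      nm <- txt1(x, "./name")
      texts[[length(texts) + 1L]] <-
        add_text(other, "name", if (is.na(nm)) other else nm)
      trips[[length(trips) + 1L]] <-
        tibble(head = id, relation = "interact", tail = other)
    }

    grp_map <- c(target = "targets", enzyme = "enzymes",
                 carrier = "carriers", transporter = "transporters")
    for (rel in names(grp_map)) {
      pps <- xml2::xml_find_all(d, paste0("./", grp_map[[rel]],
                                          "/*/polypeptide"))
      for (pp in pps) {
        uid <- xml2::xml_attr(pp, "id")
        if (is.na(uid)) next
        ents[[length(ents) + 1L]] <- tibble(id = uid, etype = "protein")
        nm <- txt1(pp, "./name")
        texts[[length(texts) + 1L]] <-
          add_text(uid, "name", if (is.na(nm)) uid else nm)
        texts[[length(texts) + 1L]] <-
          add_text(uid, "description", txt1(pp, "./general-function"))
        texts[[length(texts) + 1L]] <-
          add_text(uid, "gene_name", txt1(pp, "./gene-name"))
        syn <- xml2::xml_text(xml2::xml_find_all(pp, "./synonyms/synonym"))
        texts[[length(texts) + 1L]] <-
          add_text(uid, "synonyms", stringr::str_squish(syn))
        trips[[length(trips) + 1L]] <-
          tibble(head = id, relation = rel, tail = uid)
      }
    }

    known <- c("drugbank-id", "name", "description", "indication",
               "pharmacodynamics", "mechanism-of-action", "metabolism",
               "synonyms", "categories", "atc-codes", "pathways",
               "drug-interactions", "targets", "enzymes", "carriers",
               "transporters")
    extra <- setdiff(xml2::xml_name(xml2::xml_children(d)), known)
    if (length(extra) > 0) {
      warn(paste0("Skipping unknown element(s) in drug ", id, ": ",
                  paste(extra, collapse = ", ")))
    }
  }

  atc <- expand_atc_hierarchy(unique(atc_seen))
  entities <- distinct(bind_rows(c(ents, list(atc$entities))))
  if (anyDuplicated(entities$id)) {
    abort("Conflicting entity types for a shared id in XML input.")
  }
  atc_names <- tibble(entity_id = atc$entities$id, field = "name",
                      item_index = 0L, text = atc$entities$id)
  texts <- bind_rows(texts) |>
    bind_rows(atc_names) |>
    distinct(.data$entity_id, .data$field, .data$item_index,
             .keep_all = TRUE)
  typed_kg(entities,
           distinct(bind_rows(c(trips, list(atc$triples)))),
           texts = texts)
}
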