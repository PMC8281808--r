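#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join anti_join semi_join bind_rows distinct count n rename across
#'   all_of row_number pull slice
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_chr map_dbl map_int map_lgl map2 pmap imap
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head tail
NULL

# ---- closed vocabularies -----------------------------------------------

#' Entity types of the pharmaceutical knowledge graph
#'
#' The five heterogeneous entity types (drug, protein, pathway, category,
#' ATC code) plus `text_node`, which only appears in graphs augmented with
#' textual nodes.
#'
#' @return Character vector of valid entity type names.
#' @export
entity_types <- function() {
  c("drug", "protein", "pathway", "category", "atc", "text_node")
}

#' Text fields attached to entities
#'
#' The closed set of text attributes an entity may carry. Source-specific
#' labels are normalized onto this set by [normalize_text_field()]:
#' protein "functions" map to `description`, protein "alternative names"
#' to `synonyms`, MeSH "ScopeNote" to `description` and MeSH "Entry terms"
#' to `synonyms`.
#'
#' @return Character vector of valid text field names.
#' @export
text_fields <- function() {
  c("name", "description", "synonyms", "indication", "pharmacodynamics",
    "mechanism_of_action", "metabolism", "gene_name")
}

#' Normalize a source-specific text field label
#'
#' @param field Character vector of raw field labels.
#' @return Character vector of canonical field names from [text_fields()].
#' @export
#' @examples
#' normalize_text_field(c("functions", "ScopeNote", "Entry terms", "name"))
normalize_text_field <- function(field) {
  mapping <- c(
    "functions" = "description",
    "general-function" = "description",
    "alternative names" = "synonyms",
    "alternative-names" = "synonyms",
    "ScopeNote" = "description",
    "scope-note" = "description",
    "Entry terms" = "synonyms",
    "entry-terms" = "synonyms",
    "mechanism-of-action" = "mechanism_of_action",
    "gene-name" = "gene_name"
  )
  out <- ifelse(field %in% names(mapping), mapping[field], field)
  bad <- setdiff(unique(out), text_fields())
  if (length(bad) > 0) {
    abort(paste0("Unknown text field(s): ", paste(bad, collapse = ", ")))
  }
  unname(out)
}

# ---- relation schema ---------------------------------------------------

#' The pharmaceutical relation schema
#'
#' Returns the relation-type table of the heterogeneous pharmaceutical KG:
#' eight evaluated relations (`category`, `atc`, `pathway`, `interact`,
#' `target`, `enzyme`, `carrier`, `transporter`) plus the structural
#' `atc_hypernym` relation linking each ATC code to its next-higher level.
#' Only `interact` is symmetric. `atc_hypernym` is excluded from link
#' prediction because the hierarchy is apparent from the code strings; the
#' `has_<field>` relations added by [augment_graph()] are likewise
#' train-only.
#'
#' @return A tibble with columns `relation`, `head_types` (list column of
#'   allowed head entity types), `tail_types`, `symmetric`, `eval_included`.
#' @export
#' @examples
#' pharma_schema()
pharma_schema <- function() {
  tibble(
    relation = c("category", "atc", "pathway", "interact", "target",
                 "enzyme", "carrier", "transporter", "atc_hypernym"),
    head_types = list("drug", "drug", c("drug", "protein"), "drug", "drug",
                      "drug", "drug", "drug", "atc"),
    tail_types = list("category", "atc", "pathway", "drug", "protein",
                      "protein", "protein", "protein", "atc"),
    symmetric = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                  FALSE),
    eval_included = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

# relation rows for text-augmentation edges: any concrete entity type may
# point at a text node
augmentation_relations <- function(fields) {
  tibble(
    relation = paste0("has_", fields),
    head_types = rep(list(setdiff(entity_types(), "text_node")),
                     length(fields)),
    tail_types = rep(list("text_node"), length(fields)),
    symmetric = FALSE,
    eval_included = FALSE
  )
}
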