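# Schema-faithful synthetic KG generators: a planted-embedding graph for
# parameter-recovery experiments and a lexical-overlap graph whose drug
# descriptions share tokens with their categories' names.

#' Synthetic KG specification
#'
#' Defaults describe a small but structurally faithful instance of the
#' pharmaceutical schema: 200 entities over the five types, an
#' interact-heavy triple budget of roughly two thousand edges after
#' symmetric closure, and a heavy-tailed category degree distribution.
#'
#' @param n_drug,n_protein,n_pathway,n_category,n_atc_leaf Entity counts
#'   per type (ATC count is the number of *leaf* codes; ancestors are
#'   derived).
#' @param latent_dim Dimension of the planted ground-truth embeddings.
#' @param triples_per_relation Named integer vector of triple budgets;
#'   `interact` counts unordered drug pairs (closure doubles them).
#' @param category_degree_exponent Power-law exponent of category
#'   popularity; larger = more imbalanced.
#' @param text_signal Probability, per drug-category link, that the
#'   drug's description contains the category's name tokens.
#' @param noise_triples_frac Fraction of additional uniformly random
#'   (type-valid) triples mixed into a planted KG.
#' @param top_m Number of top-scoring tails declared true per sampled
#'   (head, relation) pair when planting.
#' @param n_clusters Number of latent clusters the planted ground-truth
#'   entity vectors are drawn around (per entity type). Clustered truth
#'   keeps the effective rank of the planted relation matrices well below
#'   the nominal dimension, so that the few observed edges per head
#'   suffice to recover the held-out ones — without it, recovery from a
#'   sparse split is information-theoretically hopeless.
#' @param cluster_noise Within-cluster spread relative to the centroid
#'   scale; 0 collapses each cluster onto its centroid.
#' @param seed Integer seed.
#' @return A `synthetic_kg_spec` list.
#' @export
synthetic_kg_spec <- function(n_drug = 100L, n_protein = 40L,
                              n_pathway = 20L, n_category = 25L,
                              n_atc_leaf = 15L, latent_dim = 16L,
                              triples_per_relation = c(
                                category = 250L, atc = 200L,
                                pathway = 150L, interact = 500L,
                                target = 200L, enzyme = 100L,
                                carrier = 50L, transporter = 80L),
                              category_degree_exponent = 1.2,
                              text_signal = 0.9,
                              noise_triples_frac = 0,
                              top_m = 5L, n_clusters = 6L,
                              cluster_noise = 0.1, seed = 1L) {
  stopifnot(n_drug >= 1, n_protein >= 1, n_pathway >= 1, n_category >= 1,
            n_atc_leaf >= 1, latent_dim >= 1,
            text_signal >= 0, text_signal <= 1,
            noise_triples_frac >= 0, noise_triples_frac <= 1, top_m >= 1,
            n_clusters >= 1, cluster_noise >= 0)
  structure(list(n_drug = n_drug, n_protein = n_protein,
                 n_pathway = n_pathway, n_category = n_category,
                 n_atc_leaf = n_atc_leaf, latent_dim = latent_dim,
                 triples_per_relation = triples_per_relation,
                 category_degree_exponent = category_degree_exponent,
                 text_signal = text_signal,
                 noise_triples_frac = noise_triples_frac,
                 top_m = as.integer(top_m),
                 n_clusters = as.integer(n_clusters),
                 cluster_noise = cluster_noise, seed = as.integer(seed)),
            class = "synthetic_kg_spec")
}

# entity frame for a spec, with 5-level ATC-like leaf codes
.synthetic_entities <- function(spec) {
  pad <- function(n, w) formatC(seq_len(n), width = w, flag = "0")
  leaves <- .synthetic_atc_leaves(spec$n_atc_leaf)
  atc <- expand_atc_hierarchy(leaves)
  list(
    entities = bind_rows(
      tibble(id = paste0("DB", pad(spec$n_drug, 5)), etype = "drug"),
      tibble(id = paste0("P", pad(spec$n_protein, 5)), etype = "protein"),
      tibble(id = paste0("SMP", pad(spec$n_pathway, 5)),
             etype = "pathway"),
      tibble(id = paste0("D", pad(spec$n_category, 6)),
             etype = "category"),
      atc$entities),
    atc_leaves = leaves,
    atc_hypernym = atc$triples)
}

# deterministic spread of n leaf codes over the 5-level ATC grammar
.synthetic_atc_leaves <- function(n) {
  l1 <- LETTERS[((seq_len(n) - 1L) %/% 4L) %% 26L + 1L]
  l2 <- formatC(((seq_len(n) - 1L) %% 4L) * 3L + 1L, width = 2, flag = "0")
  l3 <- LETTERS[(seq_len(n) - 1L) %% 26L + 1L]
  l4 <- LETTERS[(seq_len(n) * 7L) %% 26L + 1L]
  l5 <- formatC((seq_len(n) %% 20L) + 1L, width = 2, flag = "0")
  unique(paste0(l1, l2, l3, l4, l5))
}

#' Generate a planted-embedding knowledge graph
#'
#' Samples a ground-truth embedding model for the chosen scorer, then for
#' each relation repeatedly picks a type-valid head and declares its
#' `top_m` highest-scoring type-valid tails true, until the relation's
#' triple budget is met. Interact edges are closed symmetrically. Because
#' the facts are generated *by* a scorer of the same family, recovering
#' them from a train split is information-theoretically possible — the
#' construction every parameter-recovery test relies on. A configurable
#' fraction of uniformly random type-valid noise triples can be mixed in.
#'
#' @param spec A [synthetic_kg_spec()].
#' @param scorer Scorer family of the ground truth.
#' @return List with `kg` (a `typed_kg` with name texts) and
#'   `truth` (the generating `kge_model`).
#' @export
generate_planted_kg <- function(spec,
                                scorer = c("distmult", "transe",
                                           "complex", "simple")) {
  scorer <- match.arg(scorer)
  stopifnot(inherits(spec, "synthetic_kg_spec"))
  ef <- .synthetic_entities(spec)
  entities <- ef$entities
  relations <- pharma_schema()
  shell <- typed_kg(entities,
                    tibble(head = character(), relation = character(),
                           tail = character()),
                    relations = relations)
  # ground-truth vectors on a wider uniform range than the training init
  # so planted scores separate cleanly
  truth <- init_embeddings(shell, scorer, spec$latent_dim,
                           init_spec(gamma_init = spec$latent_dim,
                                     epsilon_init = spec$latent_dim,
                                     seed = spec$seed))
  etype <- setNames(entities$etype, entities$id)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(spec$seed + 1L)
  truth <- .cluster_truth(truth, etype, spec)

  triples <- list()
  for (r in names(spec$triples_per_relation)) {
    quota <- spec$triples_per_relation[[r]]
    rel_row <- relations[relations$relation == r, ]
    heads <- entities$id[etype[entities$id] %in% rel_row$head_types[[1]]]
    tails <- entities$id[etype[entities$id] %in% rel_row$tail_types[[1]]]
    ri <- match(r, truth$relation_ids)
    ti_all <- .row_idx(tails, truth$entity_ids, "entity")
    feasible <- length(heads) * (length(tails) - as.integer(r == "interact"))
    if (quota > feasible) {
      abort(paste0("Spec requests more ", r, " triples than type-valid ",
                   "pairs allow."))
    }
    # per-relation planting depth: every head contributes its full top-m_r
    # tail set, so the registered triples are exactly the planted truth
    # (an unregistered-but-true pair would compete unfiltered at
    # evaluation time and put a hard ceiling on attainable MRR)
    m_r <- max(1L, min(as.integer(round(quota / length(heads))),
                       spec$top_m))
    per_head <- lapply(heads, function(h) {
      hi <- match(h, truth$entity_ids)
      cand_ti <- ti_all
      if (r == "interact") cand_ti <- cand_ti[tails != h]
      f <- .score_idx(truth, rep(hi, length(cand_ti)),
                      rep(ri, length(cand_ti)), cand_ti)
      top <- order(f, decreasing = TRUE)[seq_len(min(m_r,
                                                     length(cand_ti)))]
      tibble(head = h, relation = r,
             tail = truth$entity_ids[cand_ti[top]])
    })
    got <- bind_rows(per_head)
    if (spec$noise_triples_frac > 0) {
      n_noise <- round(nrow(got) * spec$noise_triples_frac)
      if (n_noise > 0) {
        noise <- tibble(
          head = heads[sample.int(length(heads), n_noise, replace = TRUE)],
          relation = r,
          tail = tails[sample.int(length(tails), n_noise, replace = TRUE)])
        noise <- noise[noise$head != noise$tail | r != "interact", ]
        got <- distinct(bind_rows(got, noise))
      }
    }
    triples[[r]] <- got
  }
  all_triples <- bind_rows(c(unname(triples),
                             list(tibble(head = ef$atc_hypernym$head,
                                         relation = "atc_hypernym",
                                         tail = ef$atc_hypernym$tail))))
  kg <- typed_kg(entities, all_triples, relations = relations)
  list(kg = kg, truth = truth)
}

# Redraw the truth's entity vectors around per-type cluster centroids:
# entity = centroid[cluster] + cluster_noise * spread. One cluster
# assignment per entity is shared across both tables of 2-vector scorers.
.cluster_truth <- function(truth, etype, spec) {
  b <- 2  # centroid scale, matching the wide uniform truth init
  d <- truth$dim
  assign <- integer(length(truth$entity_ids))
  names(assign) <- truth$entity_ids
  for (ty in unique(etype)) {
    ids <- truth$entity_ids[etype[truth$entity_ids] == ty]
    assign[ids] <- sample.int(spec$n_clusters, length(ids),
                              replace = TRUE)
  }
  ent_tables <- intersect(names(truth$tables),
                          c("ent", "ent_re", "ent_im", "ent_h", "ent_t"))
  for (tn in ent_tables) {
    for (ty in unique(etype)) {
      ids <- truth$entity_ids[etype[truth$entity_ids] == ty]
      centroids <- matrix(runif(spec$n_clusters * d, -b, b),
                          spec$n_clusters, d)
      noise <- matrix(runif(length(ids) * d, -b, b), length(ids), d)
      truth$tables[[tn]][ids, ] <- centroids[assign[ids], , drop = FALSE] +
        spec$cluster_noise * noise
    }
  }
  truth
}

# small synthetic token vocabulary; indices pick tokens
.synth_token <- function(i, prefix = "tok") paste0(prefix, i)

#' Generate a lexical-overlap knowledge graph
#'
#' Builds a KG in which textual signal, not graph structure, carries the
#' category information: every category (and ATC code) owns a distinct
#' bundle of name tokens, each drug's description contains the name
#' tokens of its linked categories with probability `text_signal` (and
#' random filler tokens otherwise), and synonyms are name variants
#' sharing tokens with the name. Category membership degrees follow the
#' configured power law, mimicking the extreme imbalance of real category
#' nodes, while `interact` partners are drawn near-uniformly.
#'
#' @param spec A [synthetic_kg_spec()].
#' @return List with `kg` (a `typed_kg`; its `texts` slot holds the
#'   generated name/description/synonym rows).
#' @export
generate_lexical_kg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_kg_spec"))
  ef <- .synthetic_entities(spec)
  entities <- ef$entities
  relations <- pharma_schema()
  etype <- setNames(entities$etype, entities$id)
  drugs <- entities$id[entities$etype == "drug"]
  cats <- entities$id[entities$etype == "category"]
  atcs <- entities$id[entities$etype == "atc"]
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(spec$seed)

  # distinct 2-token name bundles per category / ATC code, 1-token drug names
  cat_tokens <- lapply(seq_along(cats), function(i) {
    c(.synth_token(2 * i, "cat"), .synth_token(2 * i + 1, "cat"))
  })
  names(cat_tokens) <- cats
  atc_tokens <- lapply(seq_along(atcs), function(i) .synth_token(i, "atc"))
  names(atc_tokens) <- atcs
  drug_tokens <- lapply(seq_along(drugs), function(i) .synth_token(i, "drg"))
  names(drug_tokens) <- drugs

  texts <- list()
  add <- function(id, field, items) {
    items <- items[nchar(items) > 0]
    if (length(items) == 0) return(NULL)
    tibble(entity_id = id, field = field,
           item_index = seq_along(items) - 1L, text = items)
  }
  for (id in entities$id) {
    nm <- switch(etype[[id]],
                 drug = paste(drug_tokens[[id]], collapse = " "),
                 category = paste(cat_tokens[[id]], collapse = " "),
                 atc = paste(atc_tokens[[id]], collapse = " "),
                 id)
    texts[[length(texts) + 1L]] <- add(id, "name", nm)
  }
  # category synonyms: name variants sharing the first token
  for (id in cats) {
    texts[[length(texts) + 1L]] <-
      add(id, "synonyms", c(paste(cat_tokens[[id]][1], "variant"),
                            paste(cat_tokens[[id]][2])))
  }

  # power-law category popularity
  w <- (seq_along(cats))^(-spec$category_degree_exponent)
  quota <- spec$triples_per_relation
  n_cat <- quota[["category"]] %||% 0L
  cat_tr <- tibble(head = character(), tail = character())
  guard <- 0L
  while (nrow(cat_tr) < n_cat && guard < 50L) {
    need <- n_cat - nrow(cat_tr)
    batch <- tibble(
      head = drugs[sample.int(length(drugs), 3L * need, replace = TRUE)],
      tail = sample(cats, 3L * need, replace = TRUE, prob = w))
    cat_tr <- head(distinct(bind_rows(cat_tr, batch)), n_cat)
    guard <- guard + 1L
  }

  # every drug links one leaf code plus its ancestors
  leaf_of <- ef$atc_leaves[(seq_along(drugs) - 1L) %%
                             length(ef$atc_leaves) + 1L]
  atc_tr <- bind_rows(lapply(seq_along(drugs), function(i) {
    lv <- c(leaf_of[i], atc_ancestors(leaf_of[i])[[1]])
    tibble(head = drugs[i], tail = lv)
  }))
  atc_tr <- head(distinct(atc_tr), quota[["atc"]] %||% nrow(atc_tr))

  # near-uniform interact pairs
  n_int <- quota[["interact"]] %||% 0L
  int_tr <- tibble(head = character(), tail = character())
  guard <- 0L
  while (nrow(int_tr) < n_int && guard < 50L) {
    need <- n_int - nrow(int_tr)
    a <- drugs[sample.int(length(drugs), 3L * need, replace = TRUE)]
    b <- drugs[sample.int(length(drugs), 3L * need, replace = TRUE)]
    keep <- a != b
    int_tr <- head(distinct(bind_rows(
      int_tr, tibble(head = a[keep], tail = b[keep]))), n_int)
    guard <- guard + 1L
  }

  # drug descriptions: category name tokens with prob text_signal,
  # filler tokens otherwise
  drug_cats <- split(cat_tr$tail, cat_tr$head)
  filler_i <- 0L
  for (d in drugs) {
    toks <- character(0)
    for (ct in (drug_cats[[d]] %||% character(0))) {
      if (runif(1) < spec$text_signal) {
        toks <- c(toks, cat_tokens[[ct]])
      } else {
        filler_i <- filler_i + 2L
        toks <- c(toks, .synth_token(filler_i, "flr"),
                  .synth_token(filler_i + 1L, "flr"))
      }
    }
    filler_i <- filler_i + 2L
    toks <- c(toks, .synth_token(filler_i, "flr"))
    texts[[length(texts) + 1L]] <-
      add(d, "description", paste(sample(toks), collapse = " "))
    # drug synonyms share the drug's own name token
    texts[[length(texts) + 1L]] <-
      add(d, "synonyms", paste(drug_tokens[[d]], "syn"))
  }

  triples <- bind_rows(
    mutate(cat_tr, relation = "category"),
    mutate(atc_tr, relation = "atc"),
    mutate(int_tr, relation = "interact"),
    tibble(head = ef$atc_hypernym$head, relation = "atc_hypernym",
           tail = ef$atc_hypernym$tail)) |>
    select("head", "relation", "tail")
  kg <- typed_kg(entities, triples, relations = relations,
                 texts = bind_rows(texts))
  list(kg = kg)
}

#' Gini coefficient of a degree histogram
#'
#' Summary of imbalance used to compare e.g. the category-side degree
#' distribution of `category` against the drug-side distribution of
#' `interact`; 0 = perfectly even, 1 = maximally concentrated.
#'
#' @param counts Numeric vector of per-entity counts.
#' @return The Gini coefficient in `[0, 1)`.
#' @export
gini <- function(counts) {
  x <- sort(as.numeric(counts))
  n <- length(x)
  if (n == 0 || sum(x) == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}
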