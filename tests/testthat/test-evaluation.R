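test_that("candidate sets apply type and known-triple filters", {
  kg <- typed_kg(
    entities = tibble::tibble(id = c("A", "B", "C", "K"),
                              etype = c("drug", "drug", "drug",
                                        "category")),
    triples = tibble::tibble(head = c("A", "A"),
                             relation = c("interact", "interact"),
                             tail = c("B", "C")))
  trp <- list(head = "A", relation = "interact", tail = "B")
  expect_setequal(candidate_set(kg, trp, "tail", TRUE, TRUE), "B")
  expect_setequal(candidate_set(kg, trp, "tail", FALSE, FALSE),
                  c("B", "C", "K"))
  expect_setequal(candidate_set(kg, trp, "tail", FALSE, TRUE), c("B", "C"))
  expect_error(candidate_set(kg, list(head = "A", relation = "nope",
                                      tail = "B"), "tail"),
               "Unknown relation")
})

test_that("rank_of counts beats and splits ties evenly", {
  kg <- toy_kg()
  model <- init_embeddings(kg, "distmult", 4, init_spec(seed = 3))
  trp <- list(head = "A", relation = "interact", tail = "B")
  # craft tables so B scores strictly highest among candidates
  model$tables$ent["A", ] <- c(1, 0, 0, 0)
  model$tables$ent["B", ] <- c(5, 0, 0, 0)
  model$tables$ent["C", ] <- c(1, 0, 0, 0)
  model$tables$rel["interact", ] <- c(1, 0, 0, 0)
  expect_equal(rank_of(model, trp, "tail", c("B", "C", "A")), 1)

  # constant model: everything ties, mean-rank policy gives (n+1)/2
  model$tables$ent[] <- 1
  model$tables$rel[] <- 1
  expect_equal(rank_of(model, trp, "tail", c("B", "C", "A")), 2)
  expect_equal(rank_of(model, trp, "tail",
                       kg$entities$id), (5 + 1) / 2)
  expect_error(rank_of(model, trp, "tail", character()), "Empty")
})

test_that("evaluate matches the exhaustive brute-force oracle exactly", {
  spec <- synthetic_kg_spec(
    n_drug = 5L, n_protein = 2L, n_pathway = 1L, n_category = 2L,
    n_atc_leaf = 1L, latent_dim = 4L,
    triples_per_relation = c(category = 5L, interact = 8L, target = 5L),
    top_m = 2L, seed = 21)
  pl <- generate_planted_kg(spec, "transe")
  sp <- split_triples(pl$kg, ratios = c(0.6, 0.2, 0.2), seed = 4)
  model <- init_embeddings(pl$kg, "transe", 4, init_spec(seed = 8))
  for (filt in c(TRUE, FALSE)) for (tf in c(TRUE, FALSE)) {
    ev <- evaluate_ranking(model, pl$kg, sp, "test",
                           filtered = filt, type_filtered = tf)
    orc <- oracle_evaluate(model, pl$kg, sp, "test",
                           filtered = filt, type_filtered = tf)
    got <- dplyr::arrange(ev$observations, relation, side, rank)
    want <- dplyr::arrange(orc, relation, side, rank)
    expect_equal(got$rank, want$rank)
  }
})

test_that("MRR aggregation: worked examples and weighting laws", {
  expect_equal(mrr(c(1, 2, 4)), (1 + 0.5 + 0.25) / 3)
  agg <- aggregate_ranking(tibble::tibble(
    relation = c(rep("a", 100), "b"),
    rank = c(rep(5, 100), 1.25)))
  expect_equal(agg$by_relation$mrr, c(0.2, 0.8))
  expect_equal(agg$macro_mrr, 0.5)
  expect_equal(agg$micro_mrr, (100 * 0.2 + 0.8) / 101)
  # equal observation counts collapse macro onto micro
  agg2 <- aggregate_ranking(tibble::tibble(
    relation = rep(c("a", "b"), each = 3), rank = c(1, 2, 4, 1, 1, 2)))
  expect_equal(agg2$macro_mrr, agg2$micro_mrr)
})

test_that("filtering can only improve MRR", {
  pl <- tiny_planted(12)
  sp <- split_triples(pl$kg, seed = 5)
  model <- init_embeddings(pl$kg, "distmult", 8, init_spec(seed = 12))
  ev_f <- evaluate_ranking(model, pl$kg, sp, "test", filtered = TRUE)
  ev_u <- evaluate_ranking(model, pl$kg, sp, "test", filtered = FALSE)
  expect_gte(ev_f$micro_mrr, ev_u$micro_mrr)
  # ranks pairwise never worse
  expect_true(all(ev_f$observations$rank <= ev_u$observations$rank))
  expect_s3_class(glance(ev_f), "tbl_df")
  expect_identical(tidy(ev_f), ev_f$by_relation)
  expect_s3_class(ggplot2::autoplot(ev_f), "ggplot")
  expect_s3_class(
    plot_degree_histogram(
      relation_degree_histogram(pl$kg, "category", "tail")),
    "ggplot")
})

test_that("the grid harness trains, selects and reports per combination", {
  pl <- tiny_planted(14)
  sp <- split_triples(pl$kg, seed = 6)
  enc <- hashed_encoder(8, seed = 3)
  grid <- tibble::tibble(scorer = "distmult",
                         text_method = c("none", "initialization"),
                         text_field = "name")
  res <- run_grid(pl$kg, sp, grid, encoder = enc, dim = 8L, epochs = 5L,
                  batch_size = 256L, negatives_per_positive = 2L,
                  seed = 2L)
  expect_identical(nrow(res), 2L)
  expect_identical(sum(res$best), 1L)
  expect_true(all(c("valid_macro_mrr", "test_macro_mrr") %in% names(res)))
  expect_s3_class(res$by_relation[[1]], "tbl_df")

  # degenerate grid of one equals a direct train + evaluate
  res1 <- run_grid(pl$kg, sp, grid[1, ], dim = 8L, epochs = 5L,
                   batch_size = 256L, negatives_per_positive = 2L,
                   seed = 2L)
  cfg <- train_config("distmult", dim = 8, epochs = 5, batch_size = 256,
                      negatives_per_positive = 2, seed = 2)
  model <- init_embeddings(pl$kg, "distmult", 8, init_spec(seed = 2))
  fit <- train_kge(model, pl$kg, sp, cfg)
  ev <- evaluate_ranking(fit$model, pl$kg, sp, "test")
  expect_equal(res1$test_macro_mrr, ev$macro_mrr)
})
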