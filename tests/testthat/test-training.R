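test_that("type-filtered corruption only draws admissible entities", {
  kg <- typed_kg(
    entities = tibble::tibble(id = c("dA", "dB", "cK"),
                              etype = c("drug", "drug", "category")),
    triples = tibble::tibble(head = "dA", relation = "interact",
                             tail = "dB"))
  trp <- list(head = "dA", relation = "interact", tail = "dB")
  set.seed(1)
  for (i in 1:25) {
    neg <- corrupt_triple(trp, kg, "tail", type_filtering = TRUE)
    expect_identical(neg$head, "dA")
    expect_true(neg$tail %in% c("dA"))  # a drug, never the category
  }
  # filtering off: the category eventually appears as tail
  tails <- replicate(200, corrupt_triple(trp, kg, "tail",
                                         type_filtering = FALSE)$tail)
  expect_true("cK" %in% tails)
  expect_false("dB" %in% tails)  # never the original entity

  solo <- typed_kg(
    entities = tibble::tibble(id = "dA", etype = "drug"),
    triples = tibble::tibble(head = character(), relation = character(),
                             tail = character()))
  expect_error(
    corrupt_triple(list(head = "dA", relation = "interact", tail = "dA"),
                   solo, "tail"),
    "No candidate")
})

test_that("bulk negatives differ on exactly the corrupted side", {
  pl <- tiny_planted(4)
  set.seed(2)
  tr <- pl$kg$triples[pl$kg$triples$relation != "atc_hypernym", ][1:50, ]
  neg <- sample_negatives(tr, pl$kg, k = 4, type_filtering = TRUE)
  expect_identical(nrow(neg), 200L)
  src <- tr[neg$source, ]
  changed_head <- neg$head != src$head
  changed_tail <- neg$tail != src$tail
  expect_true(all(xor(changed_head, changed_tail)))
  # with type filtering every replacement respects the relation signature
  etype <- stats::setNames(pl$kg$entities$etype, pl$kg$entities$id)
  rel <- pl$kg$relations
  for (i in seq_len(nrow(rel))) {
    sel <- neg$relation == rel$relation[i]
    if (!any(sel)) next
    expect_true(all(etype[neg$head[sel]] %in% rel$head_types[[i]]))
    expect_true(all(etype[neg$tail[sel]] %in% rel$tail_types[[i]]))
  }
})

test_that("loss functions evaluate to their closed-form values", {
  expect_equal(logistic_loss(1, 0), log(2))
  expect_equal(logistic_loss(-1, 0), log(2))
  expect_lt(logistic_loss(1, 50), 1e-12)
  expect_equal(logistic_loss(-1, 2), log(1 + exp(2)))
  # printed-form flag flips the sign convention
  expect_equal(logistic_loss(1, 2, strict_eq5 = TRUE), log(1 + exp(2)))
  expect_equal(logistic_loss(1, 1, reg_lambda = 0.5, params_norm_sq = 4),
               log(1 + exp(-1)) + 2)

  expect_equal(margin_ranking_loss(2, 0, margin_gamma = 1), 0)
  expect_equal(margin_ranking_loss(0.5, 0.3, margin_gamma = 1), 0.8)
  expect_equal(margin_ranking_loss(1.3, 1.3, margin_gamma = 12), 12)
  expect_error(logistic_loss(c(1, -1), 0), "mismatch")
})

test_that("loss defaults follow the scorer convention", {
  expect_identical(train_config("transe")$loss, "margin")
  expect_identical(train_config("distmult")$loss, "margin")
  expect_identical(train_config("complex")$loss, "logistic")
  expect_identical(train_config("simple")$loss, "logistic")
})

test_that("the trainer reduces loss, respects epochs=0 and seeds", {
  pl <- tiny_planted(6)
  sp <- split_triples(pl$kg, seed = 2)
  cfg <- train_config("distmult", dim = 8, epochs = 30, batch_size = 256,
                      negatives_per_positive = 4, lr_alpha0 = 0.25,
                      seed = 9)
  model <- init_embeddings(pl$kg, "distmult", 8, init_spec(seed = 9))

  fit0 <- train_kge(model, pl$kg, sp,
                    train_config("distmult", dim = 8, epochs = 0, seed = 9))
  expect_identical(fit0$model$tables, model$tables)
  expect_identical(nrow(fit0$trace), 0L)

  fit <- train_kge(model, pl$kg, sp, cfg)
  expect_identical(nrow(fit$trace), 30L)
  expect_true(all(is.finite(fit$trace$total)))
  expect_lt(dplyr::last(fit$trace$total), fit$trace$total[1])

  # reproducible under the same seed
  fit2 <- train_kge(model, pl$kg, sp, cfg)
  expect_identical(fit$model$tables, fit2$model$tables)
  expect_identical(tidy(fit), fit$trace)
  expect_identical(glance(fit)$epochs, 30L)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("a zero alignment coefficient leaves the trajectory untouched", {
  pl <- tiny_planted(7)
  sp <- split_triples(pl$kg, seed = 2)
  model <- init_embeddings(pl$kg, "distmult", 8, init_spec(seed = 5))
  enc <- hashed_encoder(8, seed = 1)
  tv <- build_text_vectors(pl$kg, enc, "name")
  cfg_none <- train_config("distmult", dim = 8, epochs = 10,
                           batch_size = 256, negatives_per_positive = 4,
                           seed = 11)
  cfg_align0 <- train_config("distmult", dim = 8, epochs = 10,
                             batch_size = 256, negatives_per_positive = 4,
                             align_lambda = 0,
                             text_method = "alignment", seed = 11)
  f1 <- train_kge(model, pl$kg, sp, cfg_none)
  f2 <- train_kge(model, pl$kg, sp, cfg_align0, text_vectors = tv)
  expect_identical(f1$model$tables, f2$model$tables)
  expect_identical(f1$trace$total, f2$trace$total)
})
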