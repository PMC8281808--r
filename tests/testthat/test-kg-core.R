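test_that("validation accepts a well-formed KG and pinpoints defects", {
  expect_identical(nrow(validate_kg(toy_kg())), 0L)

  bad <- toy_kg()
  bad$triples <- dplyr::bind_rows(
    bad$triples,
    tibble::tibble(head = "A", relation = "interact", tail = "K"))
  v <- validate_kg(bad)
  expect_identical(v$kind, "type_violation")
  expect_identical(v$tail, "K")

  dang <- toy_kg()
  dang$triples <- dplyr::bind_rows(
    dang$triples,
    tibble::tibble(head = "X", relation = "interact", tail = "A"))
  v <- validate_kg(dang)
  expect_identical(v$kind, "dangling_reference")
  expect_identical(v$entity, "X")

  unnamed <- typed_kg(
    entities = tibble::tibble(id = "A", etype = "drug"),
    triples = tibble::tibble(head = character(), relation = character(),
                             tail = character()),
    texts = tibble::tibble(entity_id = character(), field = character(),
                           item_index = integer(), text = character()))
  expect_identical(validate_kg(unnamed)$kind, "missing_name")
})

test_that("symmetric closure mirrors interact, leaves the rest, idempotent", {
  kg <- toy_kg(close_symmetric = FALSE)
  closed <- symmetric_closure(kg)
  expect_true(nrow(dplyr::filter(closed$triples, head == "B",
                                 relation == "interact", tail == "A")) == 1)
  # asymmetric relations untouched: no reversed target edge
  expect_identical(
    nrow(dplyr::filter(closed$triples, relation == "target")), 1L)
  expect_identical(symmetric_closure(closed)$triples, closed$triples)
})

test_that("closure of any valid generated KG validates cleanly", {
  for (seed in 1:3) {
    kg <- tiny_planted(seed)$kg
    expect_identical(nrow(validate_kg(symmetric_closure(kg))), 0L)
  }
})

test_that("splitting hits 90/5/5, is seed-stable and exhaustive", {
  drugs <- sprintf("d%02d", 1:40)
  pairs <- t(combn(drugs, 2))[1:50, ]
  kg <- typed_kg(
    entities = tibble::tibble(id = drugs, etype = "drug"),
    triples = tibble::tibble(head = pairs[, 1], relation = "interact",
                             tail = pairs[, 2]))
  expect_identical(nrow(kg$triples), 100L)  # closure doubles 50 pairs
  sp <- split_triples(kg, seed = 7)
  # pairs travel together, so valid/test land within one triple of the
  # 5% target and train absorbs the remainder
  expect_lte(abs(nrow(sp$valid) - 5L), 1L)
  expect_lte(abs(nrow(sp$test) - 5L), 1L)
  expect_identical(nrow(sp$train) + nrow(sp$valid) + nrow(sp$test), 100L)
  sp2 <- split_triples(kg, seed = 7)
  expect_identical(sp, sp2)

  # both directions of a symmetric pair stay in one partition
  for (part in c("train", "valid", "test")) {
    tr <- sp[[part]]
    key <- paste(pmin(tr$head, tr$tail), pmax(tr$head, tr$tail))
    expect_true(all(table(key) == 2))
  }
})

test_that("eval-excluded relations go to train; split partitions exactly", {
  pl <- tiny_planted(11)
  sp <- split_triples(pl$kg, seed = 3)
  hyper <- dplyr::filter(pl$kg$triples, relation == "atc_hypernym")
  expect_identical(
    nrow(dplyr::semi_join(sp$train, hyper,
                          by = c("head", "relation", "tail"))),
    nrow(hyper))
  expect_identical(nrow(dplyr::intersect(sp$valid, sp$test)), 0L)
  expect_identical(nrow(dplyr::intersect(sp$train, sp$valid)), 0L)
  all_back <- dplyr::bind_rows(sp$train, sp$valid, sp$test)
  expect_identical(nrow(all_back), nrow(pl$kg$triples))
  expect_identical(
    nrow(dplyr::anti_join(pl$kg$triples, all_back,
                          by = c("head", "relation", "tail"))), 0L)

  # per-relation proportions within one triple of target for big relations
  for (r in unique(sp$valid$relation)) {
    n_r <- sum(pl$kg$triples$relation == r)
    if (n_r >= 20 && !(r %in% "interact")) {
      expect_lte(abs(sum(sp$valid$relation == r) - 0.05 * n_r), 1)
      expect_lte(abs(sum(sp$test$relation == r) - 0.05 * n_r), 1)
    }
  }
  expect_error(split_triples(typed_kg(
    entities = tibble::tibble(id = "A", etype = "drug"),
    triples = tibble::tibble(head = character(), relation = character(),
                             tail = character()))), "empty")
})

test_that("degree histograms count triples and conserve totals", {
  kg <- toy_kg()
  h <- relation_degree_histogram(kg, "category", "tail")
  expect_identical(h, tibble::tibble(id = "K", n = 2L))
  h2 <- relation_degree_histogram(kg, "category", "head")
  expect_identical(sort(h2$id), c("A", "B"))
  expect_true(all(h2$n == 1L))
  expect_identical(
    nrow(relation_degree_histogram(kg, "carrier", "tail")), 0L)
  expect_error(relation_degree_histogram(kg, "nope"), "Unknown relation")

  pl <- tiny_planted(5)$kg
  for (r in c("interact", "category", "target")) {
    expect_identical(
      sum(relation_degree_histogram(pl, r, "tail")$n),
      sum(pl$triples$relation == r))
  }
})
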