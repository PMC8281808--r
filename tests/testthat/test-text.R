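test_that("text items join with commas; resolution falls back to name", {
  expect_identical(join_text_items(c("Acenol", "APAP", "Paracetamol")),
                   "Acenol, APAP, Paracetamol")
  expect_identical(join_text_items("X"), "X")
  expect_identical(join_text_items(character()), "")

  kg <- typed_kg(
    entities = tibble::tibble(id = c("d1", "atcA"),
                              etype = c("drug", "atc")),
    triples = tibble::tibble(head = character(), relation = character(),
                             tail = character()),
    texts = tibble::tibble(
      entity_id = c("d1", "d1", "d1", "d1", "atcA"),
      field = c("name", "description", "synonyms", "synonyms", "name"),
      item_index = c(0L, 0L, 0L, 1L, 0L),
      text = c("Drug One", "a useful description", "SynA", "SynB",
               "Alimentary tract")))
  expect_identical(resolve_text(kg, "d1", "description"),
                   "a useful description")
  expect_identical(resolve_text(kg, "d1", "synonyms"), "SynA, SynB")
  # ATC codes carry no description: name comes back instead
  expect_identical(resolve_text(kg, "atcA", "description"),
                   "Alimentary tract")
  kg$texts <- kg$texts[kg$texts$entity_id != "d1", ]
  expect_error(resolve_text(kg, "d1", "name"), "no name")
})

test_that("the hashed encoder is deterministic, truncating and lexical", {
  enc <- hashed_encoder(32, seed = 3)
  expect_identical(enc$encode("abc def"), enc$encode("abc def"))
  expect_identical(length(enc$encode("anything")), 32L)
  expect_equal(sum(enc$encode("abc def")^2), 1)

  long <- paste(paste0("tok", 1:600), collapse = " ")
  first512 <- paste(paste0("tok", 1:512), collapse = " ")
  expect_identical(enc$encode(long), enc$encode(first512))

  # shared tokens pull texts together relative to disjoint vocab
  a <- enc$encode("alpha beta gamma delta")
  b <- enc$encode("alpha beta gamma epsilon")
  c <- enc$encode("zeta eta theta iota")
  expect_gt(sum(a * b), sum(a * c))
})

test_that("text vectors cover every entity with name fallback", {
  lex <- generate_lexical_kg(synthetic_kg_spec(
    n_drug = 15L, n_category = 6L, n_atc_leaf = 4L,
    triples_per_relation = c(category = 20L, atc = 30L, interact = 30L),
    seed = 8))
  enc <- hashed_encoder(16, seed = 2)
  tv <- build_text_vectors(lex$kg, enc, field = "description")
  expect_setequal(tv$entity_id, lex$kg$entities$id)
  # entities without a native description resolve to their name vector
  cat_id <- lex$kg$entities$id[lex$kg$entities$etype == "category"][1]
  nm <- resolve_text(lex$kg, cat_id, "name")
  expect_identical(tv$vector[[match(cat_id, tv$entity_id)]],
                   enc$encode(nm))
})

test_that("initialization copies text vectors into every entity table", {
  pl <- tiny_planted(9, "complex")
  enc <- hashed_encoder(8, seed = 4)
  tv <- build_text_vectors(pl$kg, enc, "name")
  model <- init_embeddings(pl$kg, "complex", 8, init_spec(seed = 2))
  rel_before <- model$tables$rel_re
  m2 <- initialize_from_text(model, tv)
  id <- model$entity_ids[5]
  v <- tv$vector[[match(id, tv$entity_id)]]
  expect_equal(unname(m2$tables$ent_re[id, ]), v)
  expect_equal(unname(m2$tables$ent_im[id, ]), v)
  expect_identical(m2$tables$rel_re, rel_before)
})

test_that("the alignment penalty is a squared Frobenius distance", {
  kg <- typed_kg(
    entities = tibble::tibble(id = "e1", etype = "drug"),
    triples = tibble::tibble(head = character(), relation = character(),
                             tail = character()))
  model <- init_embeddings(kg, "transe", 2, init_spec(seed = 1))
  tv <- structure(tibble::tibble(entity_id = "e1",
                                 vector = list(model$tables$ent["e1", ])),
                  class = c("text_vectors", class(tibble::tibble())))
  expect_equal(alignment_penalty(model, tv, 1), 0)

  tv$vector[[1]] <- model$tables$ent["e1", ] - c(3, 4)
  expect_equal(alignment_penalty(model, tv, 1), 25)
  expect_equal(alignment_penalty(model, tv, 2), 50)
})

test_that("augmentation adds deduplicated train-only text nodes", {
  kg <- typed_kg(
    entities = tibble::tibble(id = c("d1", "d2", "d3"), etype = "drug"),
    triples = tibble::tibble(head = c("d1", "d2"), relation = "interact",
                             tail = c("d2", "d3")),
    texts = tibble::tibble(
      entity_id = c("d1", "d2", "d3", "d1", "d1", "d1", "d2"),
      field = c("name", "name", "name", "description", "synonyms",
                "synonyms", "description"),
      item_index = c(0L, 0L, 0L, 0L, 0L, 1L, 0L),
      text = c("one", "two", "three", "shared words", "synA", "synB",
               "shared words")))
  enc <- hashed_encoder(8, seed = 1)
  aug <- augment_graph(kg, c("description", "synonyms"), enc)

  expect_identical(nrow(validate_kg(aug$kg)), 0L)
  nodes <- aug$kg$entities[aug$kg$entities$etype == "text_node", ]
  # identical descriptions of d1/d2 share one node; d1 adds a synonyms node
  expect_identical(nrow(nodes), 2L)
  has_tr <- aug$kg$triples[grepl("^has_", aug$kg$triples$relation), ]
  expect_identical(nrow(has_tr), 3L)
  expect_false(any(
    aug$kg$relations$eval_included[grepl("^has_",
                                         aug$kg$relations$relation)]))
  # train-only: a split sends every has_* triple to train
  sp <- split_triples(aug$kg, seed = 1)
  expect_false(any(grepl("^has_", c(sp$valid$relation, sp$test$relation))))
  # text vectors cover originals (by name) and nodes (by their text)
  expect_setequal(aug$text_vectors$entity_id, aug$kg$entities$id)
  nid <- has_tr$tail[has_tr$head == "d1" &
                       has_tr$relation == "has_description"]
  expect_equal(
    aug$text_vectors$vector[[match(nid, aug$text_vectors$entity_id)]],
    enc$encode("shared words"))

  # idempotence and exact field ablation
  re_aug <- augment_graph(aug$kg, c("description", "synonyms"), enc)
  expect_setequal(re_aug$kg$entities$id, aug$kg$entities$id)
  expect_identical(dplyr::arrange(re_aug$kg$triples, head, relation, tail),
                   dplyr::arrange(aug$kg$triples, head, relation, tail))
  abl <- augment_graph(kg, "description", enc)
  dropped <- dplyr::setdiff(aug$kg$triples, abl$kg$triples)
  expect_true(all(dropped$relation == "has_synonyms"))
  expect_identical(
    dplyr::setdiff(aug$kg$entities$id, abl$kg$entities$id),
    setdiff(has_tr$tail[has_tr$relation == "has_synonyms"], character()))
})
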