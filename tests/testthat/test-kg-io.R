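test_that("triple TSV round-trips and flags malformed lines", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tr <- tiny_planted(2)$kg$triples[1:10, ]
  write_triples(tr, tmp)
  back <- read_triples(tmp)
  expect_identical(dplyr::arrange(back, head, relation, tail),
                   dplyr::arrange(tr, head, relation, tail))

  writeLines(c("a\tinteract\tb", "only\ttwo"), tmp)
  expect_error(read_triples(tmp), "line 2")
  writeLines(character(), tmp)
  expect_identical(nrow(read_triples(tmp)), 0L)
  expect_error(read_triples(file.path(tempdir(), "absent.tsv")),
               "No such file")
})

test_that("text tables round-trip with escaping and reject duplicate keys", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tx <- tibble::tibble(
    entity_id = c("d1", "d1", "d1", "d2"),
    field = c("name", "synonyms", "synonyms", "name"),
    item_index = c(0L, 0L, 1L, 0L),
    text = c("Drug one", "syn\twith tab", "syn\nwith newline", "Drug two"))
  write_text_table(tx, tmp)
  expect_identical(read_text_table(tmp),
                   dplyr::arrange(tx, entity_id, field, item_index))

  dup <- tx; dup$item_index <- c(0L, 0L, 0L, 0L)
  expect_error(write_text_table(dup, tmp), "Duplicate")
})

test_that("ATC hierarchy expansion builds the exact prefix chains", {
  ex <- expand_atc_hierarchy("A10BA02")
  expect_setequal(
    paste(ex$triples$head, ex$triples$tail),
    c("A10BA02 A10BA", "A10BA A10B", "A10B A10", "A10 A"))
  expect_setequal(ex$entities$id, c("A10BA02", "A10BA", "A10B", "A10", "A"))

  expect_identical(expand_atc_hierarchy("N02")$triples$tail, "N")
  expect_identical(nrow(expand_atc_hierarchy("A")$triples), 0L)
  expect_error(expand_atc_hierarchy("A1"), "Malformed ATC")
})

test_that("ATC expansion is a forest: one parent per non-root, no cycles", {
  codes <- pharmakg:::.synthetic_atc_leaves(12)
  ex <- expand_atc_hierarchy(codes)
  expect_identical(anyDuplicated(ex$triples$head), 0L)
  # walking up from any node terminates at a root
  parent <- stats::setNames(ex$triples$tail, ex$triples$head)
  for (cd in ex$entities$id) {
    seen <- character(); cur <- cd
    while (cur %in% names(parent)) {
      expect_false(cur %in% seen)
      seen <- c(seen, cur); cur <- parent[[cur]]
    }
    expect_identical(nchar(cur), 1L)
  }
})

test_that("the DrugBank-like parser reproduces the fixture's link pattern", {
  path <- system.file("extdata", "synthetic_drugbank.xml",
                      package = "pharmakg")
  kg <- parse_drugbank_xml(path)
  expect_identical(nrow(validate_kg(kg)), 0L)

  # the morphine-style drug links all four leaf codes plus every ancestor
  atc <- dplyr::filter(kg$triples, relation == "atc", head == "DB00295")
  expect_true(all(c("A07DA52", "N02AA51", "N02AA01", "N02AG01",
                    "A07DA", "N02AA", "N02AG", "N02", "N", "A") %in%
                    atc$tail))
  expect_setequal(
    dplyr::filter(kg$triples, relation == "category")$tail,
    c("D000470", "D018681"))
  # interact closed symmetrically
  expect_true(all(c("DB00813", "DB00295") %in%
                    dplyr::filter(kg$triples,
                                  relation == "interact")$head))
  # drug without a description: name row present, no description rows
  f_texts <- dplyr::filter(kg$texts, entity_id == "DB00813")
  expect_true("name" %in% f_texts$field)
  expect_false("description" %in% f_texts$field)
  # protein general-function lands in the normalized description field
  expect_true("description" %in%
                dplyr::filter(kg$texts, entity_id == "P35372")$field)
})

test_that("model and text-vector checkpoints round-trip exactly", {
  dir <- withr::local_tempdir()
  pl <- tiny_planted(4, "simple")
  model <- init_embeddings(pl$kg, "simple", 8, init_spec(seed = 6))
  write_kge_model(model, file.path(dir, "ckpt"))
  back <- read_kge_model(file.path(dir, "ckpt"))
  expect_identical(back$scorer, "simple")
  expect_equal(back$tables, model$tables)
  # corrupting the stored vocabulary trips the header hash
  hdr <- jsonlite::read_json(file.path(dir, "ckpt", "header.json"),
                             simplifyVector = TRUE)
  hdr$entity_ids[1] <- "tampered"
  jsonlite::write_json(hdr, file.path(dir, "ckpt", "header.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_kge_model(file.path(dir, "ckpt")), "hash mismatch")

  enc <- hashed_encoder(8, seed = 2)
  tv <- build_text_vectors(pl$kg, enc, "name")
  write_text_vectors(tv, file.path(dir, "tv"))
  tv2 <- read_text_vectors(file.path(dir, "tv"))
  expect_identical(tv2$entity_id, tv$entity_id)
  expect_equal(tv2$vector, lapply(tv$vector, unname))
})

test_that("split directories round-trip with their manifest", {
  dir <- withr::local_tempdir()
  sp <- split_triples(tiny_planted(3)$kg, seed = 13)
  write_split(sp, dir)
  back <- read_split(dir)
  for (p in c("train", "valid", "test")) {
    expect_identical(dplyr::arrange(back[[p]], head, relation, tail),
                     dplyr::arrange(sp[[p]], head, relation, tail))
  }
  expect_identical(back$seed, 13L)
})
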