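# Toy fixtures built in code.

# three drugs, one category, one protein; named after their ids
toy_kg <- function(close_symmetric = TRUE) {
  typed_kg(
    entities = tibble::tibble(
      id = c("A", "B", "C", "K", "P1"),
      etype = c("drug", "drug", "drug", "category", "protein")),
    triples = tibble::tibble(
      head = c("A", "A", "A", "B"),
      relation = c("interact", "category", "target", "category"),
      tail = c("B", "K", "P1", "K")),
    close_symmetric = close_symmetric)
}

# a minimal planted instance small enough for fast unit tests
tiny_planted <- function(seed = 1, scorer = "distmult") {
  spec <- synthetic_kg_spec(
    n_drug = 20L, n_protein = 8L, n_pathway = 4L, n_category = 6L,
    n_atc_leaf = 4L, latent_dim = 8L,
    triples_per_relation = c(category = 40L, atc = 20L, pathway = 20L,
                             interact = 60L, target = 40L, enzyme = 20L,
                             carrier = 20L, transporter = 20L),
    top_m = 3L, seed = seed)
  generate_planted_kg(spec, scorer)
}

# score one triple straight from the model tables with the exported
# single-triple scorers: the naive per-triple oracle
oracle_score <- function(model, h, r, t) {
  tb <- model$tables
  switch(model$scorer,
    transe = score_transe(tb$ent[h, ], tb$rel[r, ], tb$ent[t, ]),
    distmult = score_distmult(tb$ent[h, ], tb$rel[r, ], tb$ent[t, ]),
    complex = score_complex(
      complex(real = tb$ent_re[h, ], imaginary = tb$ent_im[h, ]),
      complex(real = tb$rel_re[r, ], imaginary = tb$rel_im[r, ]),
      complex(real = tb$ent_re[t, ], imaginary = tb$ent_im[t, ])),
    simple = score_simple(tb$ent_h[h, ], tb$ent_t[h, ],
                          tb$rel_fwd[r, ], tb$rel_inv[r, ],
                          tb$ent_h[t, ], tb$ent_t[t, ]))
}

# exhaustive brute-force ranking oracle: explicit set algebra for the
# candidates, base-R rank() (ties = "average") for the rank
oracle_evaluate <- function(model, kg, split, part,
                            filtered = TRUE, type_filtered = TRUE) {
  eval_rel <- kg$relations$relation[kg$relations$eval_included]
  triples <- split[[part]]
  triples <- triples[triples$relation %in% eval_rel, , drop = FALSE]
  etype <- stats::setNames(kg$entities$etype, kg$entities$id)
  rows <- list()
  for (i in seq_len(nrow(triples))) {
    trp <- triples[i, ]
    rel_row <- kg$relations[kg$relations$relation == trp$relation, ]
    for (side in c("head", "tail")) {
      true_ent <- if (side == "tail") trp$tail else trp$head
      other <- if (side == "tail") trp$head else trp$tail
      cand <- kg$entities$id
      if (type_filtered) {
        allowed <- if (side == "tail") rel_row$tail_types[[1]] else
          rel_row$head_types[[1]]
        cand <- cand[etype[cand] %in% allowed]
      }
      cand <- setdiff(cand, other)
      if (filtered) {
        for (j in seq_len(nrow(kg$triples))) {
          kt <- kg$triples[j, ]
          if (kt$relation != trp$relation) next
          if (side == "tail" && kt$head == trp$head &&
              kt$tail != true_ent) cand <- setdiff(cand, kt$tail)
          if (side == "head" && kt$tail == trp$tail &&
              kt$head != true_ent) cand <- setdiff(cand, kt$head)
        }
      }
      cand <- union(cand, true_ent)
      ct <- if (side == "tail") {
        tibble::tibble(head = trp$head, relation = trp$relation,
                       tail = cand)
      } else {
        tibble::tibble(head = cand, relation = trp$relation,
                       tail = trp$tail)
      }
      f <- vapply(seq_along(cand), function(k) {
        oracle_score(model, ct$head[k], ct$relation[k], ct$tail[k])
      }, numeric(1))
      rk <- rank(-f, ties.method = "average")[match(true_ent, cand)]
      rows[[length(rows) + 1L]] <-
        tibble::tibble(relation = trp$relation, side = side, rank = rk)
    }
  }
  dplyr::bind_rows(rows)
}
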