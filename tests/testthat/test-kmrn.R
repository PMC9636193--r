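imp <- function() tibble::tibble(node_id = "IMP", formula = "C10H13N4O8P",
                                 monoisotopic_mass = formula_mass("C10H13N4O8P"),
                                 inchikey14 = "AAAAAAAAAAAAAA",
                                 smiles = NA_character_, origin = "known")

test_that("rule application produces mass-consistent products with paths", {
  rules <- default_rules()
  prods <- apply_rules(imp(), rules, max_steps = 2)
  # step 1: dephosphorylation gives the inosine formula/mass
  p1 <- prods[prods$steps == 1 & purrr::map_chr(prods$path, 1) == "-HPO3", ]
  expect_equal(p1$formula, "C10H12N4O5")
  expect_equal(p1$monoisotopic_mass, 268.08077, tolerance = 1e-5)
  # step 2: sulfation of that product (inosine sulfate analog)
  p2 <- prods[prods$steps == 2 &
                purrr::map_lgl(prods$path, ~ identical(.x, c("-HPO3", "+SO3"))), ]
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$monoisotopic_mass, 348.03759, tolerance = 1e-5)
  # every product mass equals substrate mass plus the signed delta sum
  deltas <- purrr::map_dbl(prods$path, ~ sum(rules$mass_delta[match(.x, rules$label)]))
  expect_equal(prods$monoisotopic_mass, imp()$monoisotopic_mass + deltas,
               tolerance = 1e-9)
})

test_that("infeasible deltas are skipped, not errors", {
  sub <- tibble::tibble(node_id = "acetate", formula = "C2H4O2",
                        monoisotopic_mass = formula_mass("C2H4O2"),
                        inchikey14 = NA_character_, smiles = NA_character_,
                        origin = "known")
  big_loss <- tibble::tibble(label = "-C6H8O6", formula_delta = "-C6H8O6",
                             mass_delta = -formula_mass("C6H8O6"),
                             structural_rule = NA_character_,
                             enzyme = NA_character_)
  expect_equal(nrow(apply_rules(sub, big_loss, max_steps = 1)), 0L)
})

test_that("the Tanimoto filter is strict at 0.7", {
  expect_true(filter_pair(list(), list(), tanimoto = 0.75)$kept)
  expect_false(filter_pair(list(), list(), tanimoto = 0.70)$kept)
  expect_false(filter_pair(list(), list(), tanimoto = 0.65)$kept)
  # structureless pairs need the explicit flag
  expect_false(filter_pair(list(smiles = NA), list(smiles = NA))$kept)
  expect_true(filter_pair(list(smiles = NA), list(smiles = NA),
                          structureless_ok = TRUE)$kept)
})

test_that("structure-based Tanimoto works through the fingerprint backend", {
  glc <- "OCC1OC(O)C(O)C(O)C1O"
  expect_equal(tanimoto_smiles(glc, glc), 1)
  t_dis <- tanimoto_smiles(glc, "CCO")
  expect_lt(t_dis, 0.7)
  expect_true(filter_pair(list(smiles = glc), list(smiles = glc))$kept)
})

test_that("stereoisomers merge on the first InChIKey block", {
  nodes <- metabolite_nodes(
    node_id = c("n2", "n1", "n3"),
    formula = c("C6H12O6", "C6H12O6", "C5H10O5"),
    inchikey = c("BAWFJGJZGIEFAR-NNYOXOHSSA-N", "BAWFJGJZGIEFAR-UHFFFAOYSA-N",
                 "ZZZZZZZZZZZZZZ-UHFFFAOYSA-N"),
    origin = c("known", "predicted", "known")
  )
  merged <- merge_stereoisomers(nodes)
  expect_equal(nrow(merged), 2L)
  kept <- merged[merged$inchikey14 == "BAWFJGJZGIEFAR", ]
  expect_equal(kept$node_id, "n1")        # lexicographically smallest id
  expect_equal(kept$origin, "known")      # known wins over predicted
  # distinct blocks stay distinct
  expect_equal(nrow(merge_stereoisomers(nodes[c(1, 3), ])), 2L)
  # edges rewired to the kept id
  res <- merge_stereoisomers(nodes, tibble::tibble(
    node_a = "n2", node_b = "n3", label = "+H2"))
  expect_equal(res$edges$node_a, "n1")
})

test_that("network building links the purine-seed chain and drops unpaired nodes", {
  rules <- default_rules()[default_rules()$label %in%
                             c("-HPO3", "+SO3", "+C6H8O6", "-H2O"), ]
  g <- build_kmrn(imp(), rules = rules, max_steps = 2, structureless_ok = TRUE)
  # the subnetwork contains the dephosphorylated product and its sulfate,
  # connected substrate -> intermediate -> 2-step product
  ino <- g$nodes$node_id[abs(g$nodes$monoisotopic_mass - 268.08077) < 1e-4]
  sulf_mass <- 348.03759
  two_step <- g$edges[g$edges$steps == 2 & g$edges$label == "-HPO3++SO3", ]
  expect_gte(nrow(two_step), 1L)
  expect_true(any(abs(g$nodes$monoisotopic_mass[match(two_step$node_b, g$nodes$node_id)] -
                        sulf_mass) < 1e-4))
  one_step <- kmrn_neighbors(g, ino[1])
  expect_true("IMP" %in% one_step$neighbor)
  expect_true(any(g$edges$node_a == ino[1] & g$edges$label == "+SO3"))
  # predicted nodes all have degree >= 1
  pred <- g$nodes$node_id[g$nodes$origin == "predicted"]
  expect_true(all(pred %in% c(g$edges$node_a, g$edges$node_b)))
})

test_that("network building is deterministic, mass-consistent, and identity on empty rules", {
  fx <- make_toy_kmrn(fixture_config(n_seeds = 8, rng_seed = 3))
  known <- fx$kmrn$nodes[fx$kmrn$nodes$origin == "known", ]
  pairs <- tibble::tibble(node_a = known$node_id[1], node_b = known$node_id[2],
                          label = "known_rp")
  g0 <- build_kmrn(known, pairs, rules = default_rules()[0, ],
                   structureless_ok = TRUE)
  expect_equal(nrow(g0$edges), 1L)
  expect_equal(nrow(g0$nodes), nrow(known))

  g1 <- build_kmrn(known, pairs, structureless_ok = TRUE)
  g2 <- build_kmrn(known, pairs, structureless_ok = TRUE)
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$edges, g2$edges)
  # single-step edge mass consistency within 1e-4 Da
  e1 <- g1$edges[g1$edges$steps == 1 & g1$edges$provenance != "known_pair", ]
  dm <- g1$nodes$monoisotopic_mass[match(e1$node_b, g1$nodes$node_id)] -
    g1$nodes$monoisotopic_mass[match(e1$node_a, g1$nodes$node_id)]
  expect_true(all(abs(abs(dm) - abs(e1$mass_delta)) < 1e-4))
  # CHONPS restriction on predicted nodes
  pred <- g1$nodes[g1$nodes$origin == "predicted", ]
  els <- unique(unlist(purrr::map(pred$formula, ~ names(parse_formula(.x)))))
  expect_true(all(els %in% c("C", "H", "O", "N", "P", "S")))
  expect_error(build_kmrn(known, tibble::tibble(node_a = "nope", node_b = known$node_id[1],
                                                label = "x")),
               "missing nodes")
})

test_that("rule tables round-trip through TSV and validate mass deltas", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(default_rules(), path)
  back <- read_rules(path)
  expect_equal(back$label, default_rules()$label)
  bad <- default_rules()
  bad$mass_delta[1] <- bad$mass_delta[1] + 1
  readr::write_tsv(bad, path)
  expect_error(read_rules(path), "inconsistent")
})
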