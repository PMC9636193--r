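test_that("annotations propagate along the two-step chain in rounds 1 and 2", {
  fx <- chain_fixture()
  seeds <- annotate_seeds(fx$features, fx$library)
  expect_equal(seeds$feature_id, "F_seed")
  res <- propagate(seeds, fx$kmrn, fx$features)
  ann <- res$annotations
  u1 <- ann[!is.na(ann$node_id) & ann$node_id == "u1", ]
  u2 <- ann[!is.na(ann$node_id) & ann$node_id == "u2", ]
  expect_equal(u1$feature_id, "F_u1")
  expect_equal(u1$round, 1L)
  expect_equal(u1$label, "-HPO3")
  expect_equal(u1$level, 3.2)
  expect_equal(u2$feature_id, "F_u2")
  expect_equal(u2$round, 2L)
  expect_equal(u2$label, "+SO3")
  # two productive rounds, then the fixed point
  expect_equal(res$n_rounds, 3L)
  # similarity-network edges carry the biotransformation labels
  expect_setequal(res$network$edges$biotransformation, c("-HPO3", "+SO3"))
})

test_that("candidates failing both MS2 clauses are rejected; n_matched rescues", {
  fx <- chain_fixture(share_frag = FALSE) # no shared fragments at all
  seeds <- annotate_seeds(fx$features, fx$library)
  res <- propagate(seeds, fx$kmrn, fx$features)
  expect_equal(sum(res$annotations$origin == "propagated"), 0L)

  # five shared fragments with discordant intensities: score < 0.5 but
  # n_matched = 5 accepts (the "more than 4 fragments" clause)
  fx2 <- chain_fixture()
  frag <- fx2$features$ms2[[1]]$peaks$mz # the seed's five fragments
  weak <- spec_of(c(frag, 180.5, 220.7, 240.1, 260.3),
                  c(1, 1, 1, 1, 1, 100, 100, 100, 100),
                  precursor = fx2$features$mz[2])
  fx2$features$ms2[[2]] <- weak
  seeds2 <- annotate_seeds(fx2$features, fx2$library)
  res2 <- propagate(seeds2, fx2$kmrn, fx2$features)
  u1 <- res2$annotations[!is.na(res2$annotations$node_id) &
                           res2$annotations$node_id == "u1", ]
  expect_equal(nrow(u1), 1L)
  expect_lt(u1$ms2_score, 0.5)
  expect_gte(u1$n_matched, 5L)
})

test_that("a cyclic reaction network terminates with finite annotations", {
  fx <- chain_fixture()
  kmrn <- fx$kmrn
  kmrn$edges <- dplyr::bind_rows(
    kmrn$edges,
    tibble::tibble(node_a = "u2", node_b = "seed", label = "-SO3+HPO3",
                   mass_delta = 0, steps = 1L,
                   provenance = "in_silico_structureless",
                   tanimoto = NA_real_)
  )
  seeds <- annotate_seeds(fx$features, fx$library)
  res <- propagate(seeds, kmrn, fx$features)
  expect_lte(res$n_rounds, nrow(fx$features) + 1L)
  expect_lte(nrow(res$annotations), 20L)
})

test_that("no qualifying neighbor leaves the seed set unchanged after one round", {
  fx <- chain_fixture()
  feat <- fx$features[1, ] # only the seed feature present
  seeds <- annotate_seeds(feat, fx$library)
  res <- propagate(seeds, fx$kmrn, feat)
  expect_equal(sum(res$annotations$origin == "propagated"), 0L)
  expect_equal(res$n_rounds, 1L)
})

test_that("every emitted annotation satisfies the four constraints on audit", {
  fx <- make_toy_kmrn(fixture_config(n_seeds = 25, rng_seed = 13))
  sim <- simulate_dataset(fx)
  seeds <- annotate_seeds(sim$features, fx$library)
  rtm <- train_rt_model(
    dplyr::inner_join(
      dplyr::mutate(dplyr::distinct(seeds, .data$feature_id, .data$inchikey14),
                    rt = sim$features$rt[match(.data$feature_id,
                                               sim$features$feature_id)]),
      fx$descriptors, by = "inchikey14"),
    "hilic", seed_rng = 3L)
  res <- propagate(seeds, fx$kmrn, sim$features, rt_model = rtm,
                   descriptors = fx$descriptors)
  prop <- res$annotations[res$annotations$origin == "propagated", ]
  expect_gt(nrow(prop), 0L)
  cfg <- propagation_config()
  for (i in seq_len(nrow(prop))) {
    p <- prop[i, ]
    # constraint 1: reaction pairing with the parent's node
    parent <- res$annotations[res$annotations$annotation_id == p$parent_id, ]
    nb <- kmrn_neighbors(fx$kmrn, parent$node_id)
    expect_true(p$node_id %in% nb$neighbor)
    # constraint 2: m/z within 15 ppm of the candidate adduct
    node <- fx$kmrn$nodes[match(p$node_id, fx$kmrn$nodes$node_id), ]
    mz_t <- candidate_mz(node$monoisotopic_mass, p$adduct)
    fmz <- sim$features$mz[match(p$feature_id, sim$features$feature_id)]
    expect_lte(abs(ppm_error(fmz, mz_t)), cfg$tol_ppm)
    # constraint 3: RT within the relative window when predicted
    if (!is.na(p$rt_dev_rel)) expect_lte(p$rt_dev_rel, cfg$rt_tol_rel)
    # constraint 4: similarity or matched-fragment acceptance
    expect_true(p$ms2_score > cfg$ms2_threshold ||
                  p$n_matched >= cfg$min_matched)
  }
  # child round = parent round + 1, tracing to a seed
  parents <- match(prop$parent_id, res$annotations$annotation_id)
  expect_equal(prop$round, res$annotations$round[parents] + 1L)
})

test_that("knowledge guidance prunes the similarity network and reruns are identical", {
  fx <- make_toy_kmrn(fixture_config(n_seeds = 12, rng_seed = 19))
  sim <- simulate_dataset(fx)
  seeds <- annotate_seeds(sim$features, fx$library)
  res1 <- propagate(seeds, fx$kmrn, sim$features)
  res2 <- propagate(seeds, fx$kmrn, sim$features)
  expect_identical(res1$annotations, res2$annotations)
  unconstrained <- ms2_similarity_graph(sim$features, threshold = 0.5,
                                        min_matched = 5L)
  expect_lte(nrow(res1$network$edges), nrow(unconstrained))
})
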