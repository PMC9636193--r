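same_intensity <- function(n = 6, v = 1e5) {
  rep(list(stats::setNames(rep(v, n), paste0("s", seq_len(n)))), 1)
}

test_that("co-elution grouping uses an inclusive 3-second window", {
  ft <- make_features(mz = c(100, 101, 102, 103, 104),
                      rt = c(300, 301.5, 303.0, 304.0, 297.0),
                      intensities = rep(same_intensity(), 5))
  g <- group_coeluting(ft, "f01")
  expect_setequal(g$feature_id, c("f02", "f03", "f05")) # 303 and 297 inclusive
  alone <- make_features(mz = 100, rt = 10, intensities = same_intensity())
  expect_equal(nrow(group_coeluting(alone, "f01")), 0L)
})

test_that("isotope recognition applies the spacing and ratio-deviation rules", {
  mk <- function(iso_rel) make_features(
    mz = c(200.0000, 200.0000 + 1.003355), rt = c(100, 100),
    intensities = list(c(s1 = 1e6, s2 = 1e6, s3 = 1e6, s4 = 1e6),
                       c(s1 = 1e6, s2 = 1e6, s3 = 1e6, s4 = 1e6) * iso_rel))
  # C10 hint: theoretical ratio ~10.8%; experimental 30% -> deviation ~177%
  ft <- mk(0.30)
  iso <- find_isotopes(ft[1, ], ft[2, ], formula_hint = "C10H16O4")
  expect_equal(nrow(iso), 1L)
  expect_equal(iso$N, 1L)
  expect_lt(abs(iso$ppm), 1e-6)
  expect_lte(iso$delta_ratio, 500)
  # experimental 70% vs ~10.8% -> deviation > 500% -> rejected
  ft_bad <- mk(0.70)
  expect_equal(nrow(find_isotopes(ft_bad[1, ], ft_bad[2, ],
                                  formula_hint = "C10H16O4")), 0L)
  # direct Eq-style arithmetic: |30-10|/10*100 = 200 <= 500 retains,
  # |70-10|/10*100 = 600 rejects (ratio hint via a ~C9 m/z estimate)
  expect_equal(abs(30 - 10) / 10 * 100, 200)
  expect_equal(abs(70 - 10) / 10 * 100, 600)
})

test_that("adduct/neutral-loss recognition combines mass and correlation evidence", {
  glc <- formula_mass("C6H12O6")
  base_mz <- candidate_mz(glc, "[M+H]+")
  corr <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4, s5 = 5)
  ft <- make_features(
    mz = c(base_mz, candidate_mz(glc, "[M+Na]+"), candidate_mz(glc, "[M-H2O+H]+")),
    rt = c(100, 100, 100),
    intensities = list(corr * 1e5, corr * 4e4, rev(corr) * 3e4))
  hits <- find_adducts_neutral_losses(ft[1, ], ft[2:3, ], "[M+H]+", "positive")
  expect_equal(nrow(hits), 1L) # anticorrelated water-loss candidate rejected
  expect_equal(hits$qualifier, "[M+Na]+")
  expect_lt(abs(hits$ppm), 1e-6)
  expect_gt(hits$pearson_r, 0.3)
  # with the correlation fixed, the water loss appears as [M-H2O+H]+ (adduct
  # table entry) at ~0 ppm
  ft$intensities[[3]] <- corr * 3e4
  hits2 <- find_adducts_neutral_losses(ft[1, ], ft[2:3, ], "[M+H]+", "positive")
  expect_setequal(hits2$qualifier, c("[M+Na]+", "[M-H2O+H]+"))
  # fewer than 4 samples: the filter is skipped with a notice
  ft3 <- ft
  ft3$intensities <- purrr::map(ft3$intensities, ~ .x[1:3])
  expect_message(
    hits3 <- find_adducts_neutral_losses(ft3[1, ], ft3[2:3, ], "[M+H]+",
                                         "positive"),
    "fewer than 4 samples")
  expect_equal(nrow(hits3), 2L)
})

test_that("ISF recognition is limited to the five most intense fragments", {
  ms2 <- spec_of(c(110, 120, 130, 140, 150, 153.0398),
                 c(100, 90, 80, 70, 60, 50), precursor = 285.081)
  ft <- make_features(
    mz = c(285.0810, 153.0398, 150.0000), rt = c(555, 555, 555),
    intensities = rep(same_intensity(), 3),
    ms2 = list(ms2, NULL, NULL))
  hits <- find_isf(ft[1, ], ft[2:3, ])
  # 150 (rank 5) matches; 153.0398 is rank 6 and must not be assigned
  expect_equal(hits$feature_id, "f03")
  no_ms2 <- make_features(mz = 285, rt = 555, intensities = same_intensity())
  expect_equal(nrow(find_isf(no_ms2, ft[2:3, ])), 0L)
})

test_that("a smaller subnetwork whose base is an ISF of a larger one is removed", {
  # xanthosine-like scenario: base A (m/z 285.0810) with its ISF at 153.0398
  # also annotated as an independent base B
  corr <- stats::setNames(c(1, 2, 3, 4, 5, 6) * 1e5, paste0("s", 1:6))
  ids <- c("A", "A_iso", "A_na", "B", "B_iso", "B_na", "C")
  glcA <- 284.0737 # neutral mass hypothesis for A under [M+H]+
  mzA <- glcA + 1.00727646
  mzB <- 153.0398
  ft <- make_features(
    mz = c(mzA, mzA + 1.003355, glcA + 22.98922,
           mzB, mzB + 1.003355, 152.0325 + 22.98922, 400.2),
    rt = rep(555, 7), ids = ids,
    intensities = list(corr, corr * 0.12, corr * 0.4,
                       corr * 0.2, corr * 0.024, corr * 0.08, corr),
    ms2 = list(spec_of(c(110.03, 135.03, 153.0398), c(40, 30, 100),
                       precursor = mzA),
               NULL, NULL,
               spec_of(c(110.03, 135.03), c(40, 100), precursor = mzB),
               NULL, NULL, NULL))
  ann <- tibble::tibble(feature_id = c("A", "B"), adduct = "[M+H]+",
                        node_id = c("metA", "metB"))
  sn <- build_subnetworks(ft, ann)
  expect_equal(nrow(sn), 2L)
  sizeA <- sn$size[sn$base_feature_id == "A"]
  sizeB <- sn$size[sn$base_feature_id == "B"]
  expect_gt(sizeA, sizeB)
  # A's subnetwork contains B as an ISF member
  expect_true("B" %in% sn$members[[which(sn$base_feature_id == "A")]]$feature_id)
  opt <- optimize_subnetworks(sn, ft)
  expect_equal(opt$retained$base_feature_id, "A")
  expect_equal(opt$removed$base_feature_id, "B")
  expect_equal(opt$removed$step, 3L)
  expect_match(opt$removed$reason, "ion form of a larger")
  # B keeps a role (ISF of A) even though its own annotation is gone
  roles <- role_assignments(opt$retained)
  expect_equal(roles$role[roles$feature_id == "B"], "isf")
})

test_that("the same base with two adduct hypotheses keeps the larger subnetwork", {
  corr <- stats::setNames(c(5, 1, 4, 2, 3) * 1e5, paste0("s", 1:5))
  M <- 180.06339
  ft <- make_features(
    mz = c(candidate_mz(M, "[M+H]+"), candidate_mz(M, "[M+Na]+"),
           candidate_mz(M, "[M+H]+") + 1.003355, candidate_mz(M, "[M+K]+")),
    rt = rep(200, 4), ids = c("X", "X_na", "X_iso", "X_k"),
    intensities = list(corr, corr * 0.3, corr * 0.07, corr * 0.2))
  # two hypotheses for X: the correct [M+H]+ (explains Na, K, isotope) and a
  # wrong [M-H2O+H]+ (explains little)
  ann <- tibble::tibble(feature_id = c("X", "X"),
                        adduct = c("[M+H]+", "[M-H2O+H]+"),
                        node_id = c("met1", "met2"))
  sn <- build_subnetworks(ft, ann)
  opt <- optimize_subnetworks(sn, ft)
  expect_equal(nrow(opt$retained), 1L)
  expect_equal(opt$retained$adduct, "[M+H]+")
  expect_true(any(opt$removed$step == 2))
})

test_that("a multimer base without monomer evidence is removed by rule check", {
  corr <- stats::setNames(c(1, 2, 3, 4) * 1e5, paste0("s", 1:4))
  M <- 174.0528
  ft <- make_features(
    mz = c(2 * M + 1.00727646, 2 * M + 1.00727646 + 1.003355),
    rt = c(462, 462), ids = c("D", "D_iso"),
    intensities = list(corr, corr * 0.09))
  ann <- tibble::tibble(feature_id = "D", adduct = "[2M+H]+",
                        node_id = "metD")
  sn <- build_subnetworks(ft, ann)
  opt <- optimize_subnetworks(sn, ft)
  expect_equal(nrow(opt$retained), 0L)
  expect_equal(opt$removed$step, 1L)
  expect_match(opt$removed$reason, "monomer")
})

test_that("greedy conflict resolution agrees with the brute-force oracle", {
  set.seed(101)
  mismatches <- 0L
  for (rep in 1:100) {
    fx <- random_subnetwork_fixture(n_features = sample(5:10, 1),
                                    n_subnetworks = sample(2:4, 1))
    opt <- optimize_subnetworks(fx$subnetworks, fx$features)
    oracle <- oracle_optimize(fx$subnetworks)
    same_sets <- setequal(opt$retained$subnetwork_id, oracle$subnetwork_id)
    same_assign <- TRUE
    if (same_sets) {
      for (id in oracle$subnetwork_id) {
        got <- opt$retained$members[[match(id, opt$retained$subnetwork_id)]]$feature_id
        want <- oracle$members[[match(id, oracle$subnetwork_id)]]
        if (!setequal(got, want)) same_assign <- FALSE
      }
    }
    if (!same_sets || !same_assign) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("retained subnetworks give every feature at most one role", {
  fx <- make_toy_kmrn(fixture_config(n_seeds = 30, rng_seed = 23))
  sim <- simulate_dataset(fx)
  seeds <- annotate_seeds(sim$features, fx$library)
  res <- propagate(seeds, fx$kmrn, sim$features)
  sn <- build_subnetworks(sim$features, res$annotations, kmrn = fx$kmrn)
  opt <- optimize_subnetworks(sn, sim$features)
  roles <- role_assignments(opt$retained)
  expect_equal(anyDuplicated(roles$feature_id), 0L)
  # coverage amplification: members recognized >= 2x the annotated bases
  expect_gte(nrow(roles), 2 * nrow(opt$retained))
})
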