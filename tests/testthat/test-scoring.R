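ann_row <- function(level, ppm = 0, rt_err_s = NA, rt_dev_rel = NA,
                    ms2 = 1, id = "c1", fid = "F1") {
  tibble::tibble(feature_id = fid, candidate = id, node_id = id, level = level,
                 ppm = ppm, rt_err_s = rt_err_s, rt_dev_rel = rt_dev_rel,
                 ms2_score = ms2, inchikey14 = paste0("KEY", id))
}

test_that("identification, confidence and total scores follow the weighting", {
  # perfect level-1 seed: all sub-scores 1 -> S_iden 1, S_total 4
  s1 <- compute_scores(ann_row(1, ppm = 0, rt_err_s = 0, ms2 = 1))
  expect_equal(s1$s_iden, 1.0)
  expect_equal(s1$s_confidence, 3)
  expect_equal(s1$s_total, 4.0)
  # level-3.1 propagated with S_iden 0.8 -> S_total 1.8
  s31 <- compute_scores(ann_row(3.1, ppm = 0, rt_dev_rel = 0, ms2 = 0.6))
  expect_equal(s31$s_iden, 0.8)
  expect_equal(s31$s_total, 1.8)
  # level-2 with s_mz = 1, s_rt = 0 (missing RT), s_msms = 1 -> 0.75 + 2
  s2 <- compute_scores(ann_row(2, ppm = 0, ms2 = 1))
  expect_equal(s2$s_iden, 0.75)
  expect_equal(s2$s_total, 2.75)
  expect_equal(s2$missing_component, "rt")
  # sub-scores shrink linearly with the tolerance-normalized deviation
  mid <- compute_scores(ann_row(1, ppm = 7.5, rt_err_s = 10, ms2 = 0.9))
  expect_equal(mid$s_mz, 0.5)
  expect_equal(mid$s_rt, 0.5)
})

test_that("weights must be a convex combination", {
  expect_error(scoring_config(w_mz = 0.5, w_rt = 0.5, w_msms = 0.5))
  cfg <- scoring_config()
  expect_equal(cfg$w_mz + cfg$w_rt + cfg$w_msms, 1)
})

test_that("reporting keeps only the best confidence tier, top 10, ties resolved", {
  anns <- dplyr::bind_rows(
    ann_row(1, ms2 = 0.9, id = "lib1"),
    ann_row(3.1, ms2 = 0.99, id = "n1"),
    ann_row(3.1, ms2 = 0.98, id = "n2"),
    ann_row(3.1, ms2 = 0.97, id = "n3")
  )
  rep1 <- rank_and_report(compute_scores(anns |>
                                           dplyr::mutate(rt_err_s = 0)))
  expect_equal(rep1$candidate, "lib1") # level 1 dominates regardless of score
  # 12 same-tier candidates truncate at 10
  many <- dplyr::bind_rows(purrr::map(1:12, function(i) {
    ann_row(3.2, ms2 = 1 - i / 100, id = sprintf("m%02d", i))
  }))
  rep2 <- rank_and_report(compute_scores(many))
  expect_equal(nrow(rep2), 10L)
  expect_equal(rep2$rank, 1:10)
  expect_equal(rep2$candidate[1], "m01") # highest ms2 first
  # unannotated features are listed
  rep3 <- rank_and_report(compute_scores(ann_row(1, rt_err_s = 0)),
                          all_feature_ids = c("F1", "F_empty"))
  expect_true("F_empty" %in% rep3$feature_id)
  expect_true(is.na(rep3$candidate[rep3$feature_id == "F_empty"]))
})

test_that("improving one sub-score never lowers the rank within a tier", {
  base <- dplyr::bind_rows(
    ann_row(3.1, ppm = 5, ms2 = 0.7, id = "a"),
    ann_row(3.1, ppm = 5, ms2 = 0.6, id = "b")
  ) |> dplyr::mutate(rt_dev_rel = 0.1)
  r1 <- rank_and_report(compute_scores(base))
  better <- base
  better$ms2_score[better$candidate == "b"] <- 0.95
  r2 <- rank_and_report(compute_scores(better))
  rank_b1 <- r1$rank[r1$candidate == "b"]
  rank_b2 <- r2$rank[r2$candidate == "b"]
  expect_lte(rank_b2, rank_b1)
})

test_that("removal of a subnetwork drops its (feature, adduct) annotations", {
  anns <- dplyr::bind_rows(
    ann_row(3.1, id = "a") |> dplyr::mutate(adduct = "[M+H]+"),
    ann_row(3.1, id = "b", fid = "F2") |> dplyr::mutate(adduct = "[M+H]+")
  )
  removed <- tibble::tibble(base_feature_id = "F2", adduct = "[M+H]+")
  out <- apply_removals(anns, removed)
  expect_equal(out$feature_id, "F1")
  expect_equal(nrow(apply_removals(anns, removed[0, ])), 2L)
})

test_that("top-n evaluation classifies correct, error and unannotated features", {
  report <- tibble::tibble(
    feature_id = c(rep("F1", 4), "F2"),
    candidate = c("a", "b", "c", "d", "x"),
    inchikey14 = c("K_a", "K_truth", "K_c", "K_d", "K_other"),
    rank = c(1:4, 1)
  )
  truth <- tibble::tibble(feature_id = c("F1", "F2", "F3"),
                          inchikey14 = c("K_truth", "K_truth2", "K3"))
  ev <- evaluate_top_n(report, truth, n = 3)
  expect_equal(unname(ev$counts), c(1, 1, 1)) # rank 2 correct; F2 error; F3 unannotated
  # the truth key at rank 4 does not count at n = 3
  truth4 <- tibble::tibble(feature_id = "F1", inchikey14 = "K_d")
  expect_equal(unname(evaluate_top_n(report, truth4, n = 3)$counts["error"]), 1)
  expect_equal(unname(evaluate_top_n(report, truth4, n = 4)$counts["correct"]), 1)
})

test_that("role evaluation matches role class plus isotope/adduct qualifiers", {
  roles <- tibble::tibble(
    feature_id = c("f1", "f2", "f3", "f4"),
    role = c("base", "isotope", "adduct", "isf"),
    qualifier = c("[M+H]+", "1", "[M+Na]+", "153.04"),
    parent_feature_id = c(NA, "f1", "f1", "f1"),
    subnetwork_id = "f1_[M+H]+", base_feature_id = "f1"
  )
  truth <- tibble::tibble(
    feature_id = c("f1", "f2", "f3", "f4", "f5"),
    role = c("base", "isotope", "adduct", "isf", "adduct"),
    qualifier = c("[M+H]+", "1", "[M+K]+", "160.1", "[M+Na]+")
  )
  ev <- evaluate_roles(roles, truth)
  # f3 wrong qualifier; f4 correct (isf compares class only); f5 unassigned
  expect_equal(unname(ev$counts), c(3, 1, 1))
  expect_equal(ev$accuracy, 3 / 5)
})
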