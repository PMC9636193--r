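## Candidate scoring and reporting. Each candidate gets an identification
## score (weighted m/z, RT, MS/MS sub-scores), a confidence score from its
## MSI-style level, and a total score = identification + confidence. Per
## feature only the best confidence tier is reported, ranked by total score.

#' Scoring configuration
#'
#' @param w_mz,w_rt,w_msms Sub-score weights (default 0.25 / 0.25 / 0.5;
#'   must sum to 1).
#' @param tol_ppm MS1 tolerance used to normalize the m/z sub-score (ppm).
#' @param tol_rt_seed_s Seed RT tolerance (seconds) normalizing level-1 RT
#'   sub-scores.
#' @param tol_rt_rel Relative RT tolerance normalizing propagated RT
#'   sub-scores.
#' @param confidence Named confidence scores per level tier.
#' @return A list of settings.
#' @export
scoring_config <- function(w_mz = 0.25, w_rt = 0.25, w_msms = 0.5,
                           tol_ppm = 15, tol_rt_seed_s = 20, tol_rt_rel = 0.30,
                           confidence = c(`1` = 3, `2` = 2, `3.1` = 1, `3.2` = 1)) {
  stopifnot(abs(w_mz + w_rt + w_msms - 1) < 1e-9, w_mz >= 0, w_rt >= 0, w_msms >= 0)
  list(w_mz = w_mz, w_rt = w_rt, w_msms = w_msms, tol_ppm = tol_ppm,
       tol_rt_seed_s = tol_rt_seed_s, tol_rt_rel = tol_rt_rel,
       confidence = confidence)
}

#' Score annotation candidates
#'
#' Sub-scores are linear tolerance-normalized: `s_mz = max(0, 1 -
#' |ppm|/tol_ppm)`; `s_rt = max(0, 1 - |RT deviation|/tol)` using the seed RT
#' tolerance (seconds) for seed annotations and the relative propagation
#' tolerance otherwise; `s_msms` is the square-root dot product already
#' carried by the annotation. A missing component scores 0 and is flagged in
#' `missing_component`. Then `s_iden = w_mz*s_mz + w_rt*s_rt + w_msms*s_msms`
#' and `s_total = s_iden + s_confidence`.
#'
#' @param annotations Annotation tibble (seed rows have `rt_err_s` via
#'   seed provenance; propagated rows have `rt_dev_rel`).
#' @param config [scoring_config()].
#' @return The annotations with `s_mz`, `s_rt`, `s_msms`, `s_iden`,
#'   `s_confidence`, `s_total`, `missing_component` columns.
#' @export
compute_scores <- function(annotations, config = scoring_config()) {
  a <- annotations
  n <- nrow(a)
  s_mz <- pmax(0, 1 - abs(a$ppm) / config$tol_ppm)
  rt_dev <- rep(NA_real_, n)
  rt_tol <- rep(NA_real_, n)
  if ("rt_err_s" %in% names(a)) {
    seed_rt <- !is.na(a$rt_err_s)
    rt_dev[seed_rt] <- abs(a$rt_err_s[seed_rt])
    rt_tol[seed_rt] <- config$tol_rt_seed_s
  }
  if ("rt_dev_rel" %in% names(a)) {
    prop_rt <- is.na(rt_dev) & !is.na(a$rt_dev_rel)
    rt_dev[prop_rt] <- a$rt_dev_rel[prop_rt]
    rt_tol[prop_rt] <- config$tol_rt_rel
  }
  s_rt <- ifelse(is.na(rt_dev), 0, pmax(0, 1 - rt_dev / rt_tol))
  s_msms <- tidyr::replace_na(a$ms2_score, 0)
  missing <- dplyr::case_when(
    is.na(rt_dev) & is.na(a$ms2_score) ~ "rt,msms",
    is.na(rt_dev) ~ "rt",
    is.na(a$ms2_score) ~ "msms",
    TRUE ~ ""
  )
  lvl <- as.character(a$level)
  s_conf <- unname(config$confidence[lvl])
  if (any(is.na(s_conf))) stop("unknown confidence level: ",
                               paste(unique(lvl[is.na(s_conf)]), collapse = ", "),
                               call. = FALSE)
  dplyr::mutate(a,
                s_mz = s_mz, s_rt = s_rt, s_msms = s_msms,
                s_iden = config$w_mz * s_mz + config$w_rt * s_rt +
                  config$w_msms * s_msms,
                s_confidence = s_conf,
                s_total = .data$s_iden + .data$s_confidence,
                missing_component = missing)
}

#' Drop annotations removed during subnetwork optimization
#'
#' Subnetwork removal eliminates the `(feature, adduct)` annotation
#' hypotheses of the removed base peaks.
#'
#' @param annotations Annotation tibble.
#' @param removed Removal tibble from [optimize_subnetworks()].
#' @return Filtered annotations.
#' @export
apply_removals <- function(annotations, removed) {
  if (is.null(removed) || nrow(removed) == 0L) return(annotations)
  key <- paste(annotations$feature_id, annotations$adduct)
  drop_key <- paste(removed$base_feature_id, removed$adduct)
  annotations[!(key %in% drop_key), , drop = FALSE]
}

#' Rank scored candidates and build the report table
#'
#' Per feature, only candidates at the best available confidence tier are
#' kept; within the tier, candidates are ranked by total score (descending),
#' ties broken by higher MS/MS sub-score then candidate id, and truncated at
#' `top_n`. Features listed in `all_feature_ids` but holding no candidate
#' appear as unannotated rows.
#'
#' @param scored Scored annotation tibble ([compute_scores()]), with a
#'   `candidate` id column (`node_id` or library name).
#' @param top_n Candidates kept per feature (default 10).
#' @param all_feature_ids Optional universe of feature ids.
#' @return Report tibble with `rank` per feature; unannotated features have
#'   `NA` candidates.
#' @export
rank_and_report <- function(scored, top_n = 10, all_feature_ids = NULL) {
  if (!"candidate" %in% names(scored)) {
    scored$candidate <- dplyr::coalesce(scored$node_id,
                                        scored[["library_name"]] %||%
                                          NA_character_)
  }
  report <- scored |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::filter(.data$s_confidence == max(.data$s_confidence)) |>
    dplyr::arrange(dplyr::desc(.data$s_total), dplyr::desc(.data$s_msms),
                   .data$candidate, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank <= top_n) |>
    dplyr::ungroup()
  if (!is.null(all_feature_ids)) {
    missing <- setdiff(all_feature_ids, report$feature_id)
    if (length(missing) > 0L) {
      report <- dplyr::bind_rows(
        report,
        tibble::tibble(feature_id = missing, candidate = NA_character_,
                       rank = NA_integer_)
      )
    }
  }
  dplyr::arrange(report, .data$feature_id, .data$rank)
}

#' Top-n annotation accuracy against a truth table
#'
#' A feature counts correct when any of its top-`n` reported candidates
#' carries the truth's first InChIKey block; features in the truth but
#' absent from the report (or reported without candidates) count
#' unannotated; the rest count errors.
#'
#' @param report Report tibble ([rank_and_report()]) with a candidate
#'   `inchikey14` column.
#' @param truth Tibble `feature_id`, `inchikey14` (rows with `NA` key are
#'   ignored).
#' @param n Candidate depth, default 3.
#' @return List with `counts` (correct / error / unannotated), `rates`
#'   (same names, proportions of truth features), and per-feature `detail`.
#' @export
evaluate_top_n <- function(report, truth, n = 3) {
  truth <- truth[!is.na(truth$inchikey14), , drop = FALSE]
  detail <- purrr::map(seq_len(nrow(truth)), function(i) {
    fid <- truth$feature_id[i]
    cand <- report[report$feature_id == fid & !is.na(report$rank) &
                     report$rank <= n, , drop = FALSE]
    status <- if (nrow(cand) == 0L) "unannotated"
      else if (truth$inchikey14[i] %in% cand$inchikey14) "correct"
      else "error"
    tibble::tibble(feature_id = fid, truth_key = truth$inchikey14[i],
                   status = status)
  }) |> dplyr::bind_rows()
  counts <- c(correct = sum(detail$status == "correct"),
              error = sum(detail$status == "error"),
              unannotated = sum(detail$status == "unannotated"))
  list(counts = counts, rates = counts / nrow(truth), detail = detail)
}

#' Ion-form role accuracy against a truth table
#'
#' A feature's assigned role is correct when its role class matches the
#' truth and, for isotopes (isotope index) and adducts (adduct label), the
#' qualifier matches too. Truth features with no assigned role count as
#' unassigned.
#'
#' @param roles Role tibble ([role_assignments()]).
#' @param truth Tibble `feature_id`, `role`, optional `qualifier`.
#' @return List with `counts` (`correct`, `wrong`, `unassigned`),
#'   `accuracy` (correct / truth rows), and per-feature `detail`.
#' @export
evaluate_roles <- function(roles, truth) {
  idx <- match(truth$feature_id, roles$feature_id)
  assigned_role <- roles$role[idx]
  assigned_qual <- roles$qualifier[idx]
  need_qual <- truth$role %in% c("isotope", "adduct")
  qual_target <- if ("qualifier" %in% names(truth)) truth$qualifier else
    rep(NA_character_, nrow(truth))
  qual_ok <- !need_qual |
    (!is.na(assigned_qual) &
       (is.na(qual_target) | assigned_qual == qual_target))
  correct <- !is.na(assigned_role) & assigned_role == truth$role & qual_ok
  unassigned <- is.na(assigned_role)
  detail <- tibble::tibble(
    feature_id = truth$feature_id, truth_role = truth$role,
    assigned_role = assigned_role, assigned_qualifier = assigned_qual,
    status = dplyr::case_when(correct ~ "correct", unassigned ~ "unassigned",
                              TRUE ~ "wrong")
  )
  counts <- c(correct = sum(correct), wrong = sum(!correct & !unassigned),
              unassigned = sum(unassigned))
  list(counts = counts, accuracy = unname(counts["correct"] / nrow(truth)),
       detail = detail)
}
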