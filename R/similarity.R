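## MS/MS similarity primitives: spectrum cleaning, greedy fragment matching,
## and the square-root-weighted dot product used for seed matching, annotation
## propagation, and edge scoring.

#' Clean an MS2 spectrum before similarity scoring
#'
#' Removes fragments above `precursor_mz + 0.5` Th, drops peaks below a
#' relative-intensity floor, and renormalizes the base peak to 100.
#'
#' @param s A `fragment_spectrum`.
#' @param precursor_mz Precursor m/z; defaults to the spectrum's own.
#' @param min_rel_intensity Relative floor as a fraction of the base peak
#'   (default 0.001, i.e. 0.1%).
#' @return A cleaned `fragment_spectrum`, or `NULL` when no peaks survive.
#' @export
clean_spectrum <- function(s, precursor_mz = NULL, min_rel_intensity = 0.001) {
  stopifnot(inherits(s, "fragment_spectrum"))
  precursor_mz <- precursor_mz %||% s$precursor_mz
  pk <- s$peaks
  if (!is.null(precursor_mz) && !is.na(precursor_mz)) {
    pk <- pk[pk$mz <= precursor_mz + 0.5, , drop = FALSE]
  }
  if (nrow(pk) == 0L) return(NULL)
  pk <- pk[pk$intensity >= min_rel_intensity * max(pk$intensity), , drop = FALSE]
  if (nrow(pk) == 0L) return(NULL)
  pk$intensity <- pk$intensity / max(pk$intensity) * 100
  new_spectrum(precursor_mz, pk, c(s$metadata, list(CLEANED = TRUE)))
}

#' Match fragments between two spectra
#'
#' One-to-one greedy pairing: candidate pairs within tolerance are taken in
#' order of increasing ppm distance, each peak used at most once. The
#' tolerance is `max(tol_ppm * mz * 1e-6, tol_abs)` so low-m/z fragments keep
#' a small absolute window.
#'
#' @param a,b `fragment_spectrum` objects (cleaned).
#' @param tol_ppm Match tolerance in ppm (default 25).
#' @param tol_abs Absolute floor in Th (default 0.004).
#' @return Tibble with columns `i`, `j` (peak row indices in `a`, `b`),
#'   `mz_a`, `mz_b`, `ppm`.
#' @export
match_fragments <- function(a, b, tol_ppm = 25, tol_abs = 0.004) {
  empty <- tibble::tibble(i = integer(), j = integer(), mz_a = numeric(),
                          mz_b = numeric(), ppm = numeric())
  if (is.null(a) || is.null(b)) return(empty)
  pa <- a$peaks
  pb <- b$peaks
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(empty)
  cand <- tidyr::expand_grid(i = seq_len(nrow(pa)), j = seq_len(nrow(pb))) |>
    dplyr::mutate(
      mz_a = pa$mz[.data$i], mz_b = pb$mz[.data$j],
      dmz = abs(.data$mz_a - .data$mz_b),
      tol = pmax(tol_ppm * 1e-6 * pmax(.data$mz_a, .data$mz_b), tol_abs),
      ppm = .data$dmz / pmax(.data$mz_a, .data$mz_b) * 1e6
    ) |>
    dplyr::filter(.data$dmz <= .data$tol) |>
    dplyr::arrange(.data$ppm, .data$mz_a)
  used_i <- logical(nrow(pa))
  used_j <- logical(nrow(pb))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_i[i] && !used_j[j]) {
      keep[k] <- TRUE
      used_i[i] <- TRUE
      used_j[j] <- TRUE
    }
  }
  dplyr::select(cand[keep, ], "i", "j", "mz_a", "mz_b", "ppm")
}

#' Square-root-weighted dot product between two spectra
#'
#' Fragment intensities are replaced by their square roots and the score is
#' the cosine between the resulting intensity vectors aligned by
#' [match_fragments()]:
#' `score = sum(sqrt(Ia * Ib)) / sqrt(sum(Ia) * sum(Ib))`
#' over matched pairs, with the denominators running over all peaks of each
#' spectrum. Symmetric in its arguments and invariant to rescaling either
#' spectrum.
#'
#' @inheritParams match_fragments
#' @return A list with `score` in `[0, 1]` and `n_matched`.
#' @examples
#' a <- new_spectrum(300, tibble::tibble(mz = c(100, 200), intensity = c(100, 100)))
#' b <- new_spectrum(300, tibble::tibble(mz = 100, intensity = 100))
#' sqrt_dot_product(a, b)$score # 0.7071
#' @export
sqrt_dot_product <- function(a, b, tol_ppm = 25, tol_abs = 0.004) {
  if (is.null(a) || is.null(b) || nrow(a$peaks) == 0L || nrow(b$peaks) == 0L) {
    return(list(score = 0, n_matched = 0L))
  }
  pairs <- match_fragments(a, b, tol_ppm = tol_ppm, tol_abs = tol_abs)
  if (nrow(pairs) == 0L) return(list(score = 0, n_matched = 0L))
  ia <- sqrt(a$peaks$intensity[pairs$i])
  ib <- sqrt(b$peaks$intensity[pairs$j])
  score <- sum(ia * ib) / sqrt(sum(a$peaks$intensity) * sum(b$peaks$intensity))
  list(score = min(1, score), n_matched = nrow(pairs))
}
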