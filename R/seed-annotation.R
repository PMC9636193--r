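## Seed annotation: features matched against the standard library on MS1 m/z,
## (optionally) retention time, and MS/MS similarity. Seeds initiate the
## annotation propagation over the reaction network.

#' Read a standard library from an MSP file
#'
#' Records need `NAME`, `FORMULA` and `INCHIKEY` fields; `RT` (seconds) and
#' `SMILES` are optional. Multiple records with the same name (e.g. different
#' collision energies) contribute multiple spectra to one library entry.
#'
#' @param path MSP file.
#' @return Tibble with `name`, `formula`, `monoisotopic_mass`, `inchikey`,
#'   `inchikey14`, `smiles`, `rt`, and list-column `spectra`.
#' @export
read_library <- function(path) {
  sp <- read_spectra(path, format = "msp")
  meta <- purrr::map(sp$spectrum, "metadata")
  get <- function(key) purrr::map_chr(meta, ~ as.character(.x[[key]] %||% NA))
  df <- tibble::tibble(
    name = sp$spectrum_id,
    formula = get("FORMULA"),
    inchikey = get("INCHIKEY"),
    smiles = get("SMILES"),
    rt = suppressWarnings(as.numeric(get("RT"))),
    spectrum = sp$spectrum
  )
  if (any(is.na(df$formula)) || any(is.na(df$inchikey))) {
    stop("library records must carry FORMULA and INCHIKEY", call. = FALSE)
  }
  df |>
    dplyr::group_by(.data$name, .data$formula, .data$inchikey, .data$smiles) |>
    dplyr::summarise(rt = dplyr::first(.data$rt[!is.na(.data$rt)], default = NA_real_),
                     spectra = list(.data$spectrum), .groups = "drop") |>
    dplyr::mutate(
      monoisotopic_mass = purrr::map_dbl(.data$formula, formula_mass),
      inchikey14 = substr(.data$inchikey, 1L, 14L)
    ) |>
    dplyr::select("name", "formula", "monoisotopic_mass", "inchikey",
                  "inchikey14", "smiles", "rt", "spectra")
}

#' Annotate seed metabolites against the standard library
#'
#' A feature/library candidate is accepted when the protonated (positive
#' mode) or deprotonated (negative mode) theoretical m/z matches within
#' `tol_ppm` and the best MS/MS score across the record's spectra is at least
#' `tol_ms2`. Level 1 additionally requires an observed library RT within
#' `tol_rt_s`; records without RT yield level 2. All tolerances are
#' inclusive. Features without MS2 never become seeds.
#'
#' @param features Feature tibble with `ms2` list-column ([link_spectra()]).
#' @param library Library tibble ([read_library()]).
#' @param polarity `"positive"` or `"negative"`; defaults to the table's.
#' @param tol_ppm MS1 tolerance (ppm), default 15.
#' @param tol_rt_s RT tolerance (seconds), default 20.
#' @param tol_ms2 Minimum MS/MS score, default 0.8.
#' @param ms2_tol_ppm Fragment-match tolerance (ppm), default 25.
#' @return Tibble of seed annotations: `feature_id`, `library_name`,
#'   `inchikey14`, `adduct`, `ppm`, `rt_err_s`, `ms2_score`, `n_matched`,
#'   `level` (1 or 2).
#' @export
annotate_seeds <- function(features, library, polarity = NULL,
                           tol_ppm = 15, tol_rt_s = 20, tol_ms2 = 0.8,
                           ms2_tol_ppm = 25) {
  polarity <- polarity %||% features$polarity[1]
  adduct <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
  atab <- adduct_table(polarity, "ionform")
  empty <- tibble::tibble(
    feature_id = character(), library_name = character(),
    inchikey14 = character(), adduct = character(), ppm = numeric(),
    rt_err_s = numeric(), ms2_score = numeric(), n_matched = integer(),
    level = numeric()
  )
  if (nrow(library) == 0L || nrow(features) == 0L) return(empty)
  lib_mz <- candidate_mz(library$monoisotopic_mass, adduct, atab)
  out <- list()
  for (i in seq_len(nrow(features))) {
    f_ms2 <- features$ms2[[i]]
    if (is.null(f_ms2)) next
    f_clean <- clean_spectrum(f_ms2, precursor_mz = features$mz[i])
    if (is.null(f_clean)) next
    dppm <- ppm_error(features$mz[i], lib_mz)
    cand <- which(abs(dppm) <= tol_ppm)
    for (j in cand) {
      sims <- purrr::map(library$spectra[[j]], function(s) {
        sc <- clean_spectrum(s)
        sqrt_dot_product(f_clean, sc, tol_ppm = ms2_tol_ppm)
      })
      scores <- purrr::map_dbl(sims, "score")
      best <- which.max(scores)
      if (scores[best] < tol_ms2) next
      rt_err <- if (!is.na(library$rt[j])) features$rt[i] - library$rt[j] else NA_real_
      level <- if (!is.na(rt_err) && abs(rt_err) <= tol_rt_s) 1 else
        if (is.na(rt_err)) 2 else NA_real_
      if (is.na(level)) next # library RT present but outside tolerance
      out[[length(out) + 1L]] <- tibble::tibble(
        feature_id = features$feature_id[i],
        library_name = library$name[j],
        inchikey14 = library$inchikey14[j],
        adduct = adduct, ppm = dppm[j], rt_err_s = rt_err,
        ms2_score = scores[best],
        n_matched = as.integer(sims[[best]]$n_matched),
        level = level
      )
    }
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out) |> dplyr::arrange(.data$feature_id, .data$level)
}
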