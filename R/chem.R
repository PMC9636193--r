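#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Monoisotopic atomic masses (Da). CHONPS plus the halogens/metals needed for
## adduct arithmetic. Electron mass included for charged-species m/z.
MONO_MASS <- c(
  C = 12.0, H = 1.00782503207, O = 15.9949146196, N = 14.0030740048,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809, K = 38.96370668,
  Cl = 34.96885268, F = 18.99840322, Br = 78.9183371, I = 126.904473,
  Si = 27.97692653, Se = 79.9165213
)

ELECTRON_MASS <- 0.00054857990
PROTON_MASS <- MONO_MASS[["H"]] - ELECTRON_MASS # 1.00727645
ISOTOPE_SPACING <- 1.003355 # Da per 13C-like isotope step
CHONPS <- c("C", "H", "O", "N", "P", "S")

#' Parse an elemental formula into named element counts
#'
#' Accepts Hill-style formulas such as `"C10H13N4O8P"`. An optional leading
#' `+`/`-` sign multiplies all counts by +1/-1, which is how signed
#' biotransformation deltas (e.g. `"-HPO3"`) are written.
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts (possibly negative for
#'   signed deltas).
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("-HPO3")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  f <- stringr::str_trim(formula)
  sign <- 1L
  if (stringr::str_starts(f, "[+-]")) {
    sign <- if (stringr::str_starts(f, "-")) -1L else 1L
    f <- stringr::str_sub(f, 2L)
  }
  if (!nzchar(f)) return(stats::setNames(integer(0), character(0)))
  m <- stringr::str_match_all(f, "([A-Z][a-z]?)(\\d*)")[[1]]
  m <- m[nzchar(m[, 1]), , drop = FALSE]
  if (sum(nchar(m[, 1])) != nchar(f)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  counts <- ifelse(nzchar(m[, 3]), suppressWarnings(as.integer(m[, 3])), 1L)
  out <- tapply(sign * counts, m[, 2], sum)
  out <- out[out != 0L]
  stats::setNames(as.integer(out), names(out))
}

#' Combine two element-count vectors
#'
#' @param a,b Named integer vectors as returned by [parse_formula()].
#' @return Named integer vector; zero-count elements are dropped.
#' @export
combine_counts <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out[out != 0L]
}

#' Write element counts back to a Hill-order formula string
#' @param counts Named integer vector of element counts.
#' @return Formula string (C first, H second, then alphabetical).
#' @export
counts_to_formula <- function(counts) {
  if (length(counts) == 0L) return("")
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' @param formula Formula string or named count vector.
#' @return Mass in Da (signed if counts are signed).
#' @examples
#' formula_mass("C10H13N4O8P") # IMP, 348.0471 Da
#' @export
formula_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  unknown <- setdiff(names(counts), names(MONO_MASS))
  if (length(unknown) > 0L) {
    stop("no monoisotopic mass for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(MONO_MASS[names(counts)] * counts)
}

#' Parts-per-million difference between an observed and a theoretical m/z
#' @param observed,theoretical m/z values (Th).
#' @return Signed ppm error.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

#' Theoretical relative isotope intensity from carbon content
#'
#' Relative intensity (percent of the monoisotopic peak) of the N-th isotope
#' peak under a binomial 13C model: `choose(nC, N) * (p13/p12)^N * 100` with
#' natural 13C abundance 1.07%. When only an m/z is known the carbon count is
#' estimated as `mz / 17` (a CH2O-ish average composition), which the wide
#' 500% ratio tolerance downstream is robust to.
#'
#' @param n_carbon Integer carbon count, or `NA` to estimate from `mz`.
#' @param N Isotope index (1..3).
#' @param mz Optional m/z used when `n_carbon` is missing.
#' @return Theoretical relative intensity in percent.
#' @export
isotope_ratio_theoretical <- function(n_carbon, N, mz = NULL) {
  stopifnot(N >= 1L, N <= 3L)
  if (is.na(n_carbon) || is.null(n_carbon)) {
    stopifnot(!is.null(mz))
    n_carbon <- max(1L, round(mz / 17))
  }
  p <- 0.0107 / (1 - 0.0107)
  choose(n_carbon, N) * p^N * 100
}

## ---- adduct and neutral-loss tables -----------------------------------------

#' Default adduct table
#'
#' The adducts considered in annotation propagation (11 positive, 8 negative)
#' and, with `scope = "ionform"`, the extended table used for ion-form
#' recognition in the peak correlation network. Columns: `label`, `polarity`,
#' `multimer` (1 or 2), `delta` (Da added to `multimer * M` before division by
#' unit charge), `charge`.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param scope `"propagation"` (default) or `"ionform"`.
#' @return A tibble, one row per adduct.
#' @export
adduct_table <- function(polarity = c("positive", "negative"),
                         scope = c("propagation", "ionform")) {
  polarity <- match.arg(polarity)
  scope <- match.arg(scope)
  p <- PROTON_MASS
  pos <- tibble::tribble(
    ~label,            ~multimer, ~delta,
    "[M+H]+",          1L, p,
    "[M+NH4]+",        1L, formula_mass("NH4") - ELECTRON_MASS,
    "[M+Na]+",         1L, MONO_MASS[["Na"]] - ELECTRON_MASS,
    "[M+K]+",          1L, MONO_MASS[["K"]] - ELECTRON_MASS,
    "[M-H2O+H]+",      1L, p - formula_mass("H2O"),
    "[M-2H2O+H]+",     1L, p - 2 * formula_mass("H2O"),
    "[M+CH3CN+H]+",    1L, p + formula_mass("C2H3N"),
    "[M+CH3OH+H]+",    1L, p + formula_mass("CH4O"),
    "[2M+H]+",         2L, p,
    "[2M+Na]+",        2L, MONO_MASS[["Na"]] - ELECTRON_MASS,
    "[2M+NH4]+",       2L, formula_mass("NH4") - ELECTRON_MASS
  )
  neg <- tibble::tribble(
    ~label,            ~multimer, ~delta,
    "[M-H]-",          1L, -p,
    "[M-H2O-H]-",      1L, -p - formula_mass("H2O"),
    "[M+Cl]-",         1L, MONO_MASS[["Cl"]] + ELECTRON_MASS,
    "[M+HCOO]-",       1L, formula_mass("CH2O2") - p,
    "[M+CH3COO]-",     1L, formula_mass("C2H4O2") - p,
    "[M-2H+Na]-",      1L, MONO_MASS[["Na"]] - 2 * MONO_MASS[["H"]] + ELECTRON_MASS,
    "[2M-H]-",         2L, -p,
    "[2M+HCOO]-",      2L, formula_mass("CH2O2") - p
  )
  tab <- if (polarity == "positive") pos else neg
  if (scope == "ionform") {
    extra_pos <- tibble::tribble(
      ~label,        ~multimer, ~delta,
      "[M+2Na-H]+",  1L, 2 * MONO_MASS[["Na"]] - MONO_MASS[["H"]] - ELECTRON_MASS,
      "[2M+K]+",     2L, MONO_MASS[["K"]] - ELECTRON_MASS
    )
    extra_neg <- tibble::tribble(
      ~label,        ~multimer, ~delta,
      "[2M+CH3COO]-", 2L, formula_mass("C2H4O2") - p
    )
    tab <- dplyr::bind_rows(tab, if (polarity == "positive") extra_pos else extra_neg)
  }
  dplyr::mutate(tab, polarity = polarity, charge = 1L, .after = "label")
}

#' Default neutral-loss table for ion-form recognition
#'
#' Neutral losses searched below an annotated base peak in its co-elution
#' group. Columns: `label`, `formula`, `mass` (Da, positive = lost).
#' Editable; loaded tables with the same columns may be substituted anywhere
#' a neutral-loss table is accepted.
#'
#' @return A tibble.
#' @export
neutral_loss_table <- function() {
  tibble::tribble(
    ~label,        ~formula,
    "-H2O",        "H2O",
    "-2H2O",       "H4O2",
    "-NH3",        "NH3",
    "-CO",         "CO",
    "-CO2",        "CO2",
    "-HCOOH",      "CH2O2",
    "-CH3OH",      "CH4O",
    "-C2H4O2",     "C2H4O2",
    "-SO3",        "SO3",
    "-HPO3",       "HPO3",
    "-H3PO4",      "H3PO4",
    "-C6H10O5",    "C6H10O5",
    "-C6H8O6",     "C6H8O6"
  ) |>
    dplyr::mutate(mass = purrr::map_dbl(.data$formula, formula_mass))
}

#' Theoretical m/z of a metabolite under an adduct
#'
#' `mz = (multimer * M + delta) / charge` with the delta/multimer taken from
#' the adduct table of the polarity implied by the label.
#'
#' @param node A list or one-row data frame with `monoisotopic_mass`, or a
#'   bare numeric mass.
#' @param adduct Adduct label, e.g. `"[M+H]+"`.
#' @param adducts Optional adduct table; defaults to the union of both
#'   polarities' ion-form tables.
#' @return Theoretical m/z (Th).
#' @examples
#' candidate_mz(268.08077, "[M+H]+") # inosine -> 269.08805
#' @export
candidate_mz <- function(node, adduct, adducts = NULL) {
  mass <- if (is.numeric(node)) node else node$monoisotopic_mass
  stopifnot(is.numeric(mass), length(mass) >= 1L)
  if (is.null(adducts)) {
    adducts <- dplyr::bind_rows(
      adduct_table("positive", "ionform"),
      adduct_table("negative", "ionform")
    )
  }
  row <- adducts[adducts$label == adduct, ]
  if (nrow(row) == 0L) stop("unknown adduct label: ", adduct, call. = FALSE)
  row <- row[1L, ]
  (row$multimer * mass + row$delta) / row$charge
}

#' Neutral mass implied by an observed m/z and adduct
#'
#' Inverse of [candidate_mz()].
#' @inheritParams candidate_mz
#' @param mz Observed m/z (Th).
#' @return Neutral monoisotopic mass (Da).
#' @export
mass_from_mz <- function(mz, adduct, adducts = NULL) {
  if (is.null(adducts)) {
    adducts <- dplyr::bind_rows(
      adduct_table("positive", "ionform"),
      adduct_table("negative", "ionform")
    )
  }
  row <- adducts[adducts$label == adduct, ]
  if (nrow(row) == 0L) stop("unknown adduct label: ", adduct, call. = FALSE)
  row <- row[1L, ]
  (mz * row$charge - row$delta) / row$multimer
}
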