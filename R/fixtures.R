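## Deterministic truth-labeled synthetic data: a toy metabolic reaction
## network (known seeds spawning predicted unknowns through biotransformation
## rules), a standard library with RTs and spectra for the knowns, and a
## simulated LC-MS/MS dataset in which every metabolite emits a base feature
## plus ion forms (isotopes at theoretical ratios, adducts, in-source
## fragments) with correlated per-sample intensities and measurement noise.

#' Configuration of the synthetic fixture generator
#'
#' Defaults define the standard simulated study: 100 known seed metabolites
#' each spawning one predicted unknown (200 metabolites total), adduct /
#' isotope / ISF planting rates typical of electrospray data, 10 samples,
#' 5 ppm m/z jitter, 2 s retention-time jitter, 20% multiplicative intensity
#' noise, reaction pairs sharing 60% of their fragments, and 30% decoy
#' features.
#'
#' @param n_seeds Number of known seed metabolites.
#' @param n_unknown_per_seed Predicted unknowns chained off each seed
#'   (unknown k is one biotransformation step from unknown k-1).
#' @param adduct_rates Named plant probabilities for extra adducts of each
#'   metabolite (labels from the polarity's adduct table).
#' @param isotope_rates Named plant probabilities for isotope peaks N = 1..3.
#' @param isf_rate Probability that a metabolite's most intense fragment
#'   appears as a co-eluting in-source-fragment feature.
#' @param n_samples Number of samples (>= 1).
#' @param ppm_sigma m/z jitter (ppm, Gaussian).
#' @param rt_sigma_s Metabolite-level RT jitter (s, Gaussian); ion forms of
#'   one metabolite share it and add only `within_rt_sd` of their own.
#' @param within_rt_sd Within-peak-group RT jitter (s).
#' @param intensity_cv Multiplicative intensity noise (lognormal sdlog).
#' @param fragment_share Fraction of fragments shared between reaction pairs.
#' @param n_fragments Fragments per planted MS2 spectrum.
#' @param decoy_rate Decoy features added, as a fraction of planted features.
#' @param polarity Ionization mode of the simulated table.
#' @param chromatography Chromatography of the RT generating model.
#' @param rng_seed RNG seed recorded in the outputs.
#' @return A validated config list.
#' @export
fixture_config <- function(n_seeds = 100, n_unknown_per_seed = 1,
                           adduct_rates = c("[M+Na]+" = 0.4, "[M+NH4]+" = 0.3,
                                            "[M-H2O+H]+" = 0.3),
                           isotope_rates = c(`1` = 0.9, `2` = 0.4, `3` = 0.1),
                           isf_rate = 0.3, n_samples = 10,
                           ppm_sigma = 5, rt_sigma_s = 2, within_rt_sd = 0.3,
                           intensity_cv = 0.2, fragment_share = 0.6,
                           n_fragments = 10, decoy_rate = 0.3,
                           polarity = "positive", chromatography = "hilic",
                           rng_seed = 1L) {
  stopifnot(all(adduct_rates >= 0), all(adduct_rates <= 1),
            all(isotope_rates >= 0), all(isotope_rates <= 1),
            isf_rate >= 0, isf_rate <= 1, decoy_rate >= 0, decoy_rate <= 1,
            fragment_share >= 0, fragment_share <= 1, n_samples >= 1,
            ppm_sigma >= 0, rt_sigma_s >= 0, intensity_cv >= 0)
  as.list(environment())
}

synthetic_inchikey14 <- function(n, offset = 0L) {
  ## deterministic letter blocks; bijective base-26 encoding of the index
  vapply(seq_len(n) + offset, function(i) {
    digits <- integer(14)
    x <- i
    for (k in 14:1) {
      digits[k] <- x %% 26L
      x <- x %/% 26L
    }
    paste0(LETTERS[digits + 1L], collapse = "")
  }, character(1))
}

random_known_formula <- function() {
  nc <- sample(6:20, 1)
  nh <- sample(max(4, nc):(2 * nc + 2), 1)
  nn <- sample(0:4, 1)
  no <- sample(2:8, 1)
  np <- stats::rbinom(1, 1, 0.15)
  ns <- stats::rbinom(1, 1, 0.1)
  counts <- c(C = nc, H = nh, N = nn, O = no, P = np, S = ns)
  counts_to_formula(counts[counts > 0])
}

#' Generate the toy reaction network, rules, library and descriptor cache
#'
#' Known seed metabolites receive random CHONPS formulas, synthetic InChIKey
#' first blocks, descriptor vectors, and retention times from a linear
#' descriptor model (`rt = 120 + 30 d1 + 8 d2 + 4 d3`, descriptors uniform
#' on [0, 10]). Each seed spawns a chain of predicted unknowns by feasible
#' rules from [default_rules()]; unknowns inherit perturbed descriptors
#' (structural similarity implies similar RT) and share
#' `fragment_share` of their fragments with their reaction partner. Library
#' records (with RT and spectra) exist for knowns only.
#'
#' @param config [fixture_config()].
#' @return List with `kmrn` (a `kmrn` object whose predicted nodes carry
#'   synthetic InChIKey blocks), `rules`, `library`, `descriptors`,
#'   `metabolites` (per-node truth: `node_id`, `inchikey14`, `origin`,
#'   `true_rt`, `monoisotopic_mass`, list-column `fragments`), and `config`.
#' @export
make_toy_kmrn <- function(config = fixture_config()) {
  set.seed(config$rng_seed)
  rules <- default_rules()
  desc_names <- default_descriptors(config$chromatography)
  n <- config$n_seeds

  seed_ids <- sprintf("K%03d", seq_len(n))
  seeds <- tibble::tibble(
    node_id = seed_ids,
    formula = replicate(n, random_known_formula()),
    inchikey14 = synthetic_inchikey14(n),
    origin = "known"
  )
  seeds$monoisotopic_mass <- purrr::map_dbl(seeds$formula, formula_mass)

  ## descriptors and true RT
  desc <- matrix(stats::runif(n * length(desc_names), 0, 10), nrow = n,
                 dimnames = list(NULL, desc_names))
  true_rt <- 120 + 30 * desc[, 1] + 8 * desc[, 2] + 4 * desc[, 3]

  nodes <- seeds
  edges <- list()
  desc_all <- list(tibble::as_tibble(desc) |>
                     dplyr::mutate(node_id = seed_ids,
                                   inchikey14 = seeds$inchikey14,
                                   .before = 1))
  rt_all <- stats::setNames(true_rt, seed_ids)
  frag_alphabet_max <- 1200
  fragments <- purrr::map(seq_len(n), function(i) {
    pmz <- seeds$monoisotopic_mass[i] + PROTON_MASS
    k <- config$n_fragments
    tibble::tibble(mz = sort(stats::runif(k, 50, max(60, pmz - 20))),
                   intensity = stats::runif(k, 10, 100))
  })
  names(fragments) <- seed_ids

  key_offset <- n
  for (i in seq_len(n)) {
    parent_id <- seed_ids[i]
    parent_formula <- seeds$formula[i]
    for (step in seq_len(config$n_unknown_per_seed)) {
      parent_counts <- parse_formula(nodes$formula[nodes$node_id == parent_id])
      feasible <- purrr::keep(seq_len(nrow(rules)), function(r) {
        out <- apply_one_rule(parent_counts, parse_formula(rules$formula_delta[r]))
        !is.null(out) && all(names(out) %in% CHONPS)
      })
      if (length(feasible) == 0L) break
      r <- feasible[sample.int(length(feasible), 1)]
      child_counts <- apply_one_rule(parent_counts, parse_formula(rules$formula_delta[r]))
      child_id <- sprintf("%s_U%d", seed_ids[i], step)
      key_offset <- key_offset + 1L
      child_key <- synthetic_inchikey14(1, offset = key_offset + 700000L)
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        node_id = child_id, formula = counts_to_formula(child_counts),
        inchikey14 = child_key, origin = "predicted",
        monoisotopic_mass = formula_mass(child_counts)
      ))
      edges[[length(edges) + 1L]] <- tibble::tibble(
        node_a = parent_id, node_b = child_id, label = rules$label[r],
        mass_delta = rules$mass_delta[r], steps = 1L,
        provenance = "in_silico_structureless", tanimoto = NA_real_
      )
      ## descriptors / RT: perturbed copy of the parent's
      pidx <- match(parent_id, desc_all[[1]]$node_id)
      pdesc <- if (!is.na(pidx)) unlist(desc_all[[1]][pidx, desc_names]) else {
        prev <- dplyr::bind_rows(desc_all)
        unlist(prev[match(parent_id, prev$node_id), desc_names])
      }
      cdesc <- stats::setNames(pmax(0, pdesc + stats::rnorm(length(pdesc), 0, 0.4)),
                               desc_names)
      desc_all[[length(desc_all) + 1L]] <- tibble::as_tibble(as.list(cdesc)) |>
        dplyr::mutate(node_id = child_id, inchikey14 = child_key, .before = 1)
      rt_all[child_id] <- 120 + 30 * cdesc[1] + 8 * cdesc[2] + 4 * cdesc[3]
      ## fragments: share a fixed fraction with the reaction partner
      pfr <- fragments[[parent_id]]
      n_share <- round(config$fragment_share * config$n_fragments)
      share_idx <- sample.int(nrow(pfr), n_share)
      cmz_max <- max(60, formula_mass(child_counts) + PROTON_MASS - 20)
      new_fr <- tibble::tibble(
        mz = stats::runif(config$n_fragments - n_share, 50, cmz_max),
        intensity = stats::runif(config$n_fragments - n_share, 10, 100)
      )
      fr <- dplyr::bind_rows(pfr[share_idx, ], new_fr) |> dplyr::arrange(mz)
      fragments[[child_id]] <- fr
      parent_id <- child_id
    }
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(node_a = character(), node_b = character(),
                   label = character(), mass_delta = numeric(),
                   steps = integer(), provenance = character(),
                   tanimoto = numeric())
  nodes$smiles <- NA_character_
  nodes$klass <- ifelse(nodes$origin == "known", "known-known", "unknown-unknown")
  kmrn <- structure(list(nodes = nodes, edges = edges), class = "kmrn")

  library <- tibble::tibble(
    name = seeds$node_id,
    formula = seeds$formula,
    monoisotopic_mass = seeds$monoisotopic_mass,
    inchikey = paste0(seeds$inchikey14, "-UHFFFAOYSA-N"),
    inchikey14 = seeds$inchikey14,
    smiles = NA_character_,
    rt = unname(true_rt),
    spectra = purrr::map(seed_ids, function(id) {
      pmz <- nodes$monoisotopic_mass[match(id, nodes$node_id)] + PROTON_MASS
      list(new_spectrum(pmz, fragments[[id]], list(NAME = id)))
    })
  )
  metabolites <- nodes |>
    dplyr::select("node_id", "inchikey14", "origin", "monoisotopic_mass",
                  "formula") |>
    dplyr::mutate(true_rt = unname(rt_all[.data$node_id]),
                  fragments = unname(fragments[.data$node_id]))
  list(kmrn = kmrn, rules = rules, library = library,
       descriptors = dplyr::bind_rows(desc_all), metabolites = metabolites,
       config = config)
}

jitter_ppm <- function(mz, sigma) mz * (1 + stats::rnorm(length(mz), 0, sigma) * 1e-6)

#' Simulate the LC-MS/MS dataset from a toy reaction network
#'
#' Every metabolite emits a protonated (positive mode) or deprotonated
#' (negative mode) base feature carrying its planted MS2 spectrum, plus ion
#' forms at the configured rates: isotope peaks at
#' `mz + 1.003355 N` with per-sample intensities at exactly the theoretical
#' ratio, adducts at exact mass deltas, and an ISF feature mirroring the
#' most intense fragment. Per-sample intensities share a metabolite-level
#' lognormal factor so same-metabolite ions correlate across samples;
#' measurement noise adds ppm jitter, shared metabolite-level RT jitter
#' (plus a small within-group term), and multiplicative intensity noise.
#' Unlabeled decoy features (a configurable fraction, half with random MS2)
#' are appended.
#'
#' @param fixture Output of [make_toy_kmrn()].
#' @param config [fixture_config()]; defaults to the fixture's own.
#' @return List with `features` (tibble with `intensities` and `ms2`
#'   list-columns), `truth` (tibble `feature_id`, `node_id`, `inchikey14`,
#'   `role`, `qualifier`, `adduct`), and `config`.
#' @export
simulate_dataset <- function(fixture, config = fixture$config) {
  set.seed(config$rng_seed + 1000003L)
  met <- fixture$metabolites
  polarity <- config$polarity
  base_adduct <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
  atab <- adduct_table(polarity, "ionform")
  ns <- config$n_samples
  sample_names <- sprintf("s%02d", seq_len(ns))

  rows <- list()
  add_row <- function(mz, rt, intens, node_id, key, role, qualifier, adduct,
                      ms2 = NULL) {
    rows[[length(rows) + 1L]] <<- list(
      mz = mz, rt = rt, intensities = stats::setNames(intens, sample_names),
      node_id = node_id, inchikey14 = key, role = role, qualifier = qualifier,
      adduct = adduct, ms2 = ms2
    )
  }

  for (i in seq_len(nrow(met))) {
    m <- met[i, ]
    base_mz_t <- candidate_mz(m$monoisotopic_mass, base_adduct, atab)
    rt_m <- m$true_rt + stats::rnorm(1, 0, config$rt_sigma_s)
    base_abund <- stats::rlnorm(1, log(1e6), 0.8)
    shared <- exp(stats::rnorm(ns, 0, 0.5)) # metabolite-level sample factor
    noise <- function() exp(stats::rnorm(ns, 0, config$intensity_cv))
    base_int <- base_abund * shared * noise()
    frag <- m$fragments[[1]]
    obs_frag <- frag
    obs_frag$mz <- jitter_ppm(frag$mz, config$ppm_sigma)
    obs_frag$intensity <- frag$intensity * exp(stats::rnorm(nrow(frag), 0, config$intensity_cv))
    base_ms2 <- new_spectrum(base_mz_t, obs_frag)
    add_row(jitter_ppm(base_mz_t, config$ppm_sigma),
            rt_m + stats::rnorm(1, 0, config$within_rt_sd),
            base_int, m$node_id, m$inchikey14, "base", base_adduct,
            base_adduct, ms2 = base_ms2)
    n_carbon <- as.integer(parse_formula(m$formula)["C"])
    for (N in names(config$isotope_rates)) {
      if (stats::runif(1) > config$isotope_rates[[N]]) next
      Ni <- as.integer(N)
      ratio <- isotope_ratio_theoretical(n_carbon, Ni) / 100
      add_row(jitter_ppm(base_mz_t + ISOTOPE_SPACING * Ni, config$ppm_sigma),
              rt_m + stats::rnorm(1, 0, config$within_rt_sd),
              base_int * ratio, m$node_id, m$inchikey14, "isotope",
              as.character(Ni), base_adduct)
    }
    for (lab in names(config$adduct_rates)) {
      if (stats::runif(1) > config$adduct_rates[[lab]]) next
      mz_t <- candidate_mz(m$monoisotopic_mass, lab, atab)
      rel <- stats::runif(1, 0.1, 0.5)
      add_row(jitter_ppm(mz_t, config$ppm_sigma),
              rt_m + stats::rnorm(1, 0, config$within_rt_sd),
              base_abund * rel * shared * noise(),
              m$node_id, m$inchikey14, "adduct", lab, base_adduct)
    }
    if (stats::runif(1) <= config$isf_rate) {
      top_mz <- frag$mz[which.max(frag$intensity)]
      rel <- stats::runif(1, 0.05, 0.3)
      add_row(jitter_ppm(top_mz, config$ppm_sigma),
              rt_m + stats::rnorm(1, 0, config$within_rt_sd),
              base_abund * rel * shared * noise(),
              m$node_id, m$inchikey14, "isf",
              format(top_mz, digits = 8, trim = TRUE), base_adduct)
    }
  }
  n_planted <- length(rows)
  n_decoys <- round(config$decoy_rate * n_planted)
  rt_range <- range(purrr::map_dbl(rows, "rt"))
  for (d in seq_len(n_decoys)) {
    ms2 <- NULL
    mz <- stats::runif(1, 80, 900)
    if (d %% 2L == 0L) {
      k <- sample(4:8, 1)
      ms2 <- new_spectrum(mz, tibble::tibble(
        mz = sort(stats::runif(k, 50, max(60, mz - 10))),
        intensity = stats::runif(k, 10, 100)
      ))
    }
    add_row(mz, stats::runif(1, rt_range[1], rt_range[2]),
            stats::rlnorm(ns, log(2e5), 0.7),
            NA_character_, NA_character_, NA_character_, NA_character_,
            NA_character_, ms2 = ms2)
  }

  mzs <- purrr::map_dbl(rows, "mz")
  rts <- purrr::map_dbl(rows, "rt")
  ids <- make_feature_id(mzs, rts)
  features <- tibble::tibble(
    feature_id = ids, mz = mzs, rt = rts, polarity = polarity,
    intensities = purrr::map(rows, "intensities"),
    ms2 = purrr::map(rows, "ms2")
  )
  truth <- tibble::tibble(
    feature_id = ids,
    node_id = purrr::map_chr(rows, "node_id"),
    inchikey14 = purrr::map_chr(rows, "inchikey14"),
    role = purrr::map_chr(rows, "role"),
    qualifier = purrr::map_chr(rows, "qualifier"),
    adduct = purrr::map_chr(rows, "adduct")
  )
  list(features = features, truth = truth, config = config)
}

#' Write a simulated fixture to disk in the pipeline's external formats
#'
#' Emits `features.csv` (generic dialect), `spectra.mgf` (titles = feature
#' ids), `library.msp` (NAME/FORMULA/INCHIKEY/RT records), `rules.tsv`,
#' `descriptors.tsv` and `truth.tsv` under `dir`.
#'
#' @param fixture Output of [make_toy_kmrn()].
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(fixture, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    features = file.path(dir, "features.csv"),
    spectra = file.path(dir, "spectra.mgf"),
    library = file.path(dir, "library.msp"),
    rules = file.path(dir, "rules.tsv"),
    descriptors = file.path(dir, "descriptors.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  ft <- sim$features
  intens <- do.call(rbind, ft$intensities)
  readr::write_csv(
    dplyr::bind_cols(
      tibble::tibble(feature_id = ft$feature_id, mz = ft$mz, rt = ft$rt),
      tibble::as_tibble(intens)
    ),
    paths["features"]
  )
  write_mgf(ft, paths["spectra"])
  lib <- fixture$library
  con <- file(paths["library"], "wt", encoding = "UTF-8")
  for (i in seq_len(nrow(lib))) {
    for (s in lib$spectra[[i]]) {
      writeLines(c(
        paste0("NAME: ", lib$name[i]),
        paste0("FORMULA: ", lib$formula[i]),
        paste0("INCHIKEY: ", lib$inchikey[i]),
        paste0("RT: ", format(lib$rt[i], digits = 8)),
        paste0("PRECURSORMZ: ", format(s$precursor_mz, digits = 10)),
        paste0("Num Peaks: ", nrow(s$peaks)),
        paste(format(s$peaks$mz, digits = 10, trim = TRUE),
              format(s$peaks$intensity, digits = 8, trim = TRUE)),
        ""
      ), con)
    }
  }
  close(con)
  readr::write_tsv(fixture$rules, paths["rules"])
  readr::write_tsv(fixture$descriptors, paths["descriptors"])
  readr::write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
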