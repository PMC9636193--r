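# Shared builders for tiny in-code fixtures.

spec_of <- function(mz, intensity, precursor = max(mz) + 1) {
  new_spectrum(precursor, tibble::tibble(mz = mz, intensity = intensity))
}

# A three-metabolite chain modeled on a purine nucleotide seed losing a
# phosphate and gaining a sulfate: seed (IMP-like) -> u1 (inosine-like, -HPO3)
# -> u2 (sulfate conjugate, +SO3), with planted shared fragments, used by the
# propagation tests.
chain_fixture <- function(share_frag = TRUE) {
  rules <- default_rules()
  nodes <- metabolite_nodes(
    node_id = c("seed", "u1", "u2"),
    formula = c("C10H13N4O8P", "C10H12N4O5", "C10H12N4O8S"),
    inchikey = c("AAAAAAAAAAAAAA", "BBBBBBBBBBBBBB", "CCCCCCCCCCCCCC"),
    origin = c("known", "predicted", "predicted")
  )
  edges <- tibble::tibble(
    node_a = c("seed", "u1"), node_b = c("u1", "u2"),
    label = c("-HPO3", "+SO3"),
    mass_delta = rules$mass_delta[match(c("-HPO3", "+SO3"), rules$label)],
    steps = 1L, provenance = "in_silico_structureless", tanimoto = NA_real_
  )
  kmrn <- structure(list(nodes = nodes, edges = edges), class = "kmrn")

  frag_seed <- c(92.0243, 110.0351, 135.0301, 137.0458, 153.0407)
  frag_u1 <- if (share_frag) c(frag_seed, 194.1035)
    else c(71.01, 83.02, 95.03, 107.04, 119.05)
  frag_u2 <- if (share_frag) c(frag_seed, 96.9601)
    else c(72.01, 84.02, 96.03, 108.04, 121.05)
  mzs <- candidate_mz(nodes$monoisotopic_mass, "[M+H]+")
  mk <- function(frag, pm) spec_of(frag, rep(100, length(frag)), precursor = pm)
  features <- tibble::tibble(
    feature_id = c("F_seed", "F_u1", "F_u2"),
    mz = mzs, rt = c(300, 310, 320), polarity = "positive",
    intensities = rep(list(c(s1 = 1e6, s2 = 9e5, s3 = 1.1e6, s4 = 1e6)), 3),
    ms2 = list(mk(frag_seed, mzs[1]), mk(frag_u1, mzs[2]), mk(frag_u2, mzs[3]))
  )
  library <- tibble::tibble(
    name = "seed_std", formula = "C10H13N4O8P",
    monoisotopic_mass = nodes$monoisotopic_mass[1],
    inchikey = "AAAAAAAAAAAAAA-UHFFFAOYSA-N", inchikey14 = "AAAAAAAAAAAAAA",
    smiles = NA_character_, rt = 298,
    spectra = list(list(mk(frag_seed, mzs[1])))
  )
  list(kmrn = kmrn, features = features, library = library, rules = rules)
}

# Simple feature-table builder for peak-correlation tests.
make_features <- function(mz, rt, intensities, ids = NULL, ms2 = NULL,
                          polarity = "positive") {
  n <- length(mz)
  tibble::tibble(
    feature_id = ids %||% sprintf("f%02d", seq_len(n)),
    mz = mz, rt = rt, polarity = polarity,
    intensities = intensities,
    ms2 = ms2 %||% rep(list(NULL), n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force oracle for subnetwork conflict resolution: enumerate every
# subset of subnetworks and every assignment of multiply claimed features,
# require each retained subnetwork to hold its own base, and pick the outcome
# whose retained (size, base intensity, id) tuples -- sorted by size desc,
# intensity desc, id asc -- are lexicographically maximal (longer prefix wins
# on ties). Returns the retained assignment table.
oracle_optimize <- function(subnetworks) {
  n <- nrow(subnetworks)
  members <- lapply(subnetworks$members, function(m) m$feature_id)
  best <- NULL
  best_key <- NULL
  outcome_key <- function(sizes, idx) {
    ord <- order(-sizes, -subnetworks$base_intensity[idx],
                 subnetworks$subnetwork_id[idx])
    list(size = sizes[ord], int = subnetworks$base_intensity[idx][ord],
         id = subnetworks$subnetwork_id[idx][ord])
  }
  key_better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    la <- length(a$size); lb <- length(b$size)
    for (k in seq_len(max(la, lb))) {
      if (k > la) return(FALSE)
      if (k > lb) return(TRUE)
      if (a$size[k] != b$size[k]) return(a$size[k] > b$size[k])
      if (a$int[k] != b$int[k]) return(a$int[k] > b$int[k])
      if (a$id[k] != b$id[k]) return(a$id[k] < b$id[k])
    }
    FALSE
  }
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) == 0L) next
    bases <- subnetworks$base_feature_id[idx]
    if (anyDuplicated(bases)) next
    claim <- table(unlist(members[idx]))
    shared <- names(claim)[claim > 1]
    forced <- stats::setNames(seq_along(idx), bases) # base -> position in idx
    free <- setdiff(shared, bases)
    choices <- lapply(free, function(f) {
      which(vapply(members[idx], function(mm) f %in% mm, logical(1)))
    })
    grids <- if (length(free) == 0L) list(integer(0)) else
      asplit(as.matrix(do.call(expand.grid, choices)), 1)
    for (g in grids) {
      assign_to <- integer(0)
      sizes <- vapply(seq_along(idx), function(pos) {
        mm <- members[idx][[pos]]
        keep <- vapply(mm, function(f) {
          if (f %in% bases) return(unname(forced[f]) == pos)
          if (f %in% free) return(g[[match(f, free)]] == pos)
          TRUE
        }, logical(1))
        sum(keep)
      }, integer(1))
      key <- outcome_key(sizes, idx)
      if (key_better(key, best_key)) {
        best_key <- key
        assignment <- lapply(seq_along(idx), function(pos) {
          mm <- members[idx][[pos]]
          mm[vapply(mm, function(f) {
            if (f %in% bases) return(unname(forced[f]) == pos)
            if (f %in% free) return(g[[match(f, free)]] == pos)
            TRUE
          }, logical(1))]
        })
        best <- list(idx = idx, sizes = sizes, assignment = assignment)
      }
    }
  }
  tibble::tibble(
    subnetwork_id = subnetworks$subnetwork_id[best$idx],
    size = best$sizes,
    members = best$assignment
  ) |> dplyr::filter(.data$size > 0)
}

# Random subnetwork fixture over <= n_features co-eluting features for the
# oracle-agreement test. Roles are ISF-like so no empirical rule fires.
random_subnetwork_fixture <- function(n_features = 8, n_subnetworks = 3) {
  fids <- sprintf("f%02d", seq_len(n_features))
  intens <- lapply(seq_len(n_features), function(i) {
    stats::setNames(stats::runif(4, 1e4, 1e6), paste0("s", 1:4))
  })
  features <- make_features(
    mz = stats::runif(n_features, 100, 600),
    rt = rep(100, n_features), intensities = intens, ids = fids
  )
  bases <- sample(fids, n_subnetworks)
  sn <- lapply(seq_len(n_subnetworks), function(k) {
    others <- sample(setdiff(fids, bases[k]),
                     sample.int(min(5, n_features - 1), 1))
    members <- tibble::tibble(
      feature_id = c(bases[k], others),
      role = c("base", rep("isf", length(others))),
      qualifier = c("[M+H]+", sprintf("%.4f", stats::runif(length(others), 50, 300))),
      parent_feature_id = c(NA_character_, rep(bases[k], length(others))),
      ppm = 0, pearson_r = NA_real_, delta_ratio = NA_real_
    )
    tibble::tibble(
      subnetwork_id = paste0(bases[k], "_[M+H]+"),
      base_feature_id = bases[k], adduct = "[M+H]+",
      base_intensity = mean(intens[[match(bases[k], fids)]]),
      size = nrow(members), members = list(members)
    )
  })
  list(features = features, subnetworks = dplyr::bind_rows(sn))
}
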