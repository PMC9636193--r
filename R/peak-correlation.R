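## Network 3: the global peak correlation network. For every annotated base
## peak, co-eluting features are screened as isotopes, adducts, neutral
## losses and in-source fragments (ISF); the resulting subnetworks are then
## optimized in three steps (empirical rules, same-base conflicts, global
## consolidation) so that every feature ends up with at most one role.

feature_mean_intensity <- function(features) {
  purrr::map_dbl(features$intensities, function(v) {
    if (length(v) == 0L) 0 else mean(v)
  })
}

#' Co-eluting peak group of a base feature
#'
#' All features within the RT grouping window of the base (inclusive),
#' excluding the base itself. No intensity filtering.
#'
#' @param features Feature tibble.
#' @param base_feature_id Id of the base feature.
#' @param window RT window in seconds (default 3).
#' @return Tibble of grouped features.
#' @export
group_coeluting <- function(features, base_feature_id, window = 3) {
  i <- match(base_feature_id, features$feature_id)
  if (is.na(i)) stop("base feature not in table: ", base_feature_id, call. = FALSE)
  rt0 <- features$rt[i]
  features[abs(features$rt - rt0) <= window &
             features$feature_id != base_feature_id, , drop = FALSE]
}

#' Recognize isotope peaks of a parent ion within its peak group
#'
#' Candidates sit at `mz_parent + 1.003355 * N` (N = 1..3) within `tol_ppm`.
#' A candidate is retained when the deviation of its relative intensity from
#' the theoretical isotope ratio, `|Int_E - Int_T| / Int_T * 100`, does not
#' exceed `max_ratio_dev` percent. The theoretical ratio comes from the
#' candidate formula's carbon count when `formula_hint` is given, otherwise
#' from an m/z-scaled carbon estimate.
#'
#' @param base One-row feature tibble (the parent ion).
#' @param group Co-eluting features ([group_coeluting()]).
#' @param formula_hint Optional elemental formula of the annotated candidate.
#' @param tol_ppm Mass tolerance (ppm), default 25.
#' @param max_ratio_dev Maximum ratio deviation (percent), default 500.
#' @return Tibble: `feature_id`, `N`, `mz`, `ppm`, `int_e`, `int_t`,
#'   `delta_ratio`.
#' @export
find_isotopes <- function(base, group, formula_hint = NULL, tol_ppm = 25,
                          max_ratio_dev = 500) {
  base_int <- feature_mean_intensity(base)
  empty <- tibble::tibble(feature_id = character(), N = integer(),
                          mz = numeric(), ppm = numeric(), int_e = numeric(),
                          int_t = numeric(), delta_ratio = numeric())
  if (nrow(group) == 0L || base_int <= 0) return(empty)
  n_carbon <- if (!is.null(formula_hint) && !is.na(formula_hint)) {
    cnt <- parse_formula(formula_hint)
    as.integer(cnt["C"] %||% NA)
  } else NA_integer_
  g_int <- feature_mean_intensity(group)
  out <- list()
  for (N in 1:3) {
    mz_t <- base$mz + ISOTOPE_SPACING * N
    dppm <- ppm_error(group$mz, mz_t)
    hits <- which(abs(dppm) <= tol_ppm)
    for (h in hits) {
      int_e <- g_int[h] / base_int * 100
      int_t <- isotope_ratio_theoretical(n_carbon, N, mz = base$mz)
      dev <- abs(int_e - int_t) / int_t * 100
      if (dev > max_ratio_dev) next
      out[[length(out) + 1L]] <- tibble::tibble(
        feature_id = group$feature_id[h], N = N, mz = group$mz[h],
        ppm = dppm[h], int_e = int_e, int_t = int_t, delta_ratio = dev
      )
    }
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out)
}

pearson_with_base <- function(base, group_rows) {
  v0 <- base$intensities[[1]]
  purrr::map_dbl(group_rows$intensities, function(v) {
    if (length(v0) < 4L || length(v) != length(v0)) return(NA_real_)
    if (stats::sd(v0) == 0 || stats::sd(v) == 0) return(NA_real_)
    stats::cor(v0, v)
  })
}

#' Recognize adduct and neutral-loss peaks of an annotated base
#'
#' The base's annotation fixes its adduct, hence the neutral mass; the
#' theoretical m/z of every other adduct (and of the base m/z minus each
#' neutral loss) is matched in the peak group within `tol_ppm`. Matches are
#' retained when their across-sample Pearson correlation with the base
#' exceeds `r_min`; with fewer than 4 samples the correlation cannot be
#' estimated and the filter is skipped (a notice is emitted).
#'
#' @param base One-row feature tibble.
#' @param group Co-eluting features.
#' @param base_adduct Adduct label of the base annotation.
#' @param polarity `"positive"` or `"negative"`.
#' @param tol_ppm Mass tolerance (ppm), default 25.
#' @param r_min Pearson threshold (strictly greater), default 0.3.
#' @param adducts,neutral_losses Optional override tables.
#' @return Tibble: `feature_id`, `role` (`"adduct"`/`"neutral_loss"`),
#'   `qualifier` (label), `mz`, `ppm`, `pearson_r`.
#' @export
find_adducts_neutral_losses <- function(base, group, base_adduct, polarity,
                                        tol_ppm = 25, r_min = 0.3,
                                        adducts = NULL, neutral_losses = NULL) {
  adducts <- adducts %||% adduct_table(polarity, "ionform")
  neutral_losses <- neutral_losses %||% neutral_loss_table()
  empty <- tibble::tibble(feature_id = character(), role = character(),
                          qualifier = character(), mz = numeric(),
                          ppm = numeric(), pearson_r = numeric())
  if (nrow(group) == 0L) return(empty)
  M <- mass_from_mz(base$mz, base_adduct, adducts)
  targets <- dplyr::bind_rows(
    adducts |>
      dplyr::filter(.data$label != base_adduct) |>
      dplyr::transmute(role = "adduct", qualifier = .data$label,
                       mz_t = (.data$multimer * M + .data$delta) / .data$charge),
    neutral_losses |>
      dplyr::transmute(role = "neutral_loss", qualifier = .data$label,
                       mz_t = base$mz - .data$mass)
  ) |>
    dplyr::filter(.data$mz_t > 0)
  r <- pearson_with_base(base, group)
  n_samples <- length(base$intensities[[1]])
  few <- n_samples < 4L
  if (few) message("fewer than 4 samples: Pearson filter skipped")
  out <- list()
  for (t in seq_len(nrow(targets))) {
    dppm <- ppm_error(group$mz, targets$mz_t[t])
    hits <- which(abs(dppm) <= tol_ppm)
    for (h in hits) {
      if (!few && !is.na(r[h]) && r[h] <= r_min) next
      out[[length(out) + 1L]] <- tibble::tibble(
        feature_id = group$feature_id[h], role = targets$role[t],
        qualifier = targets$qualifier[t], mz = group$mz[h],
        ppm = dppm[h], pearson_r = r[h]
      )
    }
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out) |> dplyr::distinct(.data$feature_id, .keep_all = TRUE)
}

#' Recognize in-source fragment peaks of a base
#'
#' The five most intense fragments of the base's MS2 spectrum are matched
#' against the MS1 m/z of the co-eluting group within `tol_ppm`.
#'
#' @param base One-row feature tibble (must carry `ms2`).
#' @param group Co-eluting features.
#' @param tol_ppm Mass tolerance (ppm), default 25.
#' @param top_n Number of most intense fragments considered, default 5.
#' @return Tibble: `feature_id`, `fragment_mz`, `mz`, `ppm`.
#' @export
find_isf <- function(base, group, tol_ppm = 25, top_n = 5) {
  empty <- tibble::tibble(feature_id = character(), fragment_mz = numeric(),
                          mz = numeric(), ppm = numeric())
  s <- base$ms2[[1]]
  if (is.null(s) || nrow(group) == 0L) return(empty)
  pk <- s$peaks[order(-s$peaks$intensity), , drop = FALSE]
  pk <- utils::head(pk, top_n)
  out <- list()
  for (t in seq_len(nrow(pk))) {
    dppm <- ppm_error(group$mz, pk$mz[t])
    hits <- which(abs(dppm) <= tol_ppm)
    for (h in hits) {
      out[[length(out) + 1L]] <- tibble::tibble(
        feature_id = group$feature_id[h], fragment_mz = pk$mz[t],
        mz = group$mz[h], ppm = dppm[h]
      )
    }
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out) |> dplyr::distinct(.data$feature_id, .keep_all = TRUE)
}

#' Build ion-form subnetworks for every annotated base peak
#'
#' One subnetwork is built per distinct `(feature, adduct)` annotation
#' hypothesis: the base plus its recognized isotopes, adducts, neutral
#' losses, ISF peaks, and the isotopes of each retained ion. Within a
#' subnetwork a feature takes at most one role (isotopes of the base first,
#' then adducts, neutral losses, ISF, then isotopes of members).
#'
#' @param features Feature tibble (with `ms2`, `intensities`).
#' @param annotations Annotation tibble (seed + propagated), needing
#'   `feature_id`, `adduct`, and optionally `node_id`.
#' @param kmrn Optional `kmrn` supplying candidate formulas for isotope
#'   ratio hints.
#' @param window RT grouping window (s), default 3.
#' @param tol_ppm Ion-form mass tolerance (ppm), default 25.
#' @param r_min Pearson threshold, default 0.3.
#' @param max_ratio_dev Isotope ratio tolerance (percent), default 500.
#' @param adducts,neutral_losses Optional override tables.
#' @return Tibble of subnetworks: `subnetwork_id`, `base_feature_id`,
#'   `adduct`, `base_intensity`, `size`, and list-column `members`
#'   (`feature_id`, `role`, `qualifier`, `parent_feature_id`, `ppm`,
#'   `pearson_r`, `delta_ratio`).
#' @export
build_subnetworks <- function(features, annotations, kmrn = NULL, window = 3,
                              tol_ppm = 25, r_min = 0.3, max_ratio_dev = 500,
                              adducts = NULL, neutral_losses = NULL) {
  polarity <- features$polarity[1]
  adducts <- adducts %||% adduct_table(polarity, "ionform")
  neutral_losses <- neutral_losses %||% neutral_loss_table()
  bases <- dplyr::distinct(annotations, .data$feature_id, .data$adduct)
  out <- list()
  for (b in seq_len(nrow(bases))) {
    fid <- bases$feature_id[b]
    adduct <- bases$adduct[b]
    i <- match(fid, features$feature_id)
    if (is.na(i)) next
    base <- features[i, ]
    group <- group_coeluting(features, fid, window = window)
    ## formula hint: any annotated candidate's formula for this base
    hint <- NA_character_
    if (!is.null(kmrn)) {
      nids <- annotations$node_id[annotations$feature_id == fid &
                                    annotations$adduct == adduct]
      nids <- nids[!is.na(nids)]
      if (length(nids) > 0L) {
        hint <- kmrn$nodes$formula[match(nids[1L], kmrn$nodes$node_id)]
      }
    }
    members <- tibble::tibble(
      feature_id = fid, role = "base", qualifier = adduct,
      parent_feature_id = NA_character_, ppm = 0, pearson_r = NA_real_,
      delta_ratio = NA_real_
    )
    taken <- fid
    add_members <- function(df) {
      df <- df[!(df$feature_id %in% taken), , drop = FALSE]
      taken <<- c(taken, df$feature_id)
      members <<- dplyr::bind_rows(members, df)
      df
    }
    iso <- find_isotopes(base, group, formula_hint = hint, tol_ppm = tol_ppm,
                         max_ratio_dev = max_ratio_dev)
    add_members(tibble::tibble(
      feature_id = iso$feature_id, role = "isotope",
      qualifier = as.character(iso$N), parent_feature_id = fid,
      ppm = iso$ppm, pearson_r = NA_real_, delta_ratio = iso$delta_ratio
    ))
    anl <- find_adducts_neutral_losses(base, group, adduct, polarity,
                                       tol_ppm = tol_ppm, r_min = r_min,
                                       adducts = adducts,
                                       neutral_losses = neutral_losses)
    anl_kept <- add_members(tibble::tibble(
      feature_id = anl$feature_id, role = anl$role, qualifier = anl$qualifier,
      parent_feature_id = fid, ppm = anl$ppm, pearson_r = anl$pearson_r,
      delta_ratio = NA_real_
    ))
    isf <- find_isf(base, group, tol_ppm = tol_ppm)
    isf_kept <- add_members(tibble::tibble(
      feature_id = isf$feature_id, role = "isf",
      qualifier = format(isf$fragment_mz, digits = 8, trim = TRUE),
      parent_feature_id = fid, ppm = isf$ppm, pearson_r = NA_real_,
      delta_ratio = NA_real_
    ))
    ## isotopes of retained member ions
    for (pid in c(anl_kept$feature_id, isf_kept$feature_id)) {
      pj <- match(pid, features$feature_id)
      iso_m <- find_isotopes(features[pj, ], group, tol_ppm = tol_ppm,
                             max_ratio_dev = max_ratio_dev)
      add_members(tibble::tibble(
        feature_id = iso_m$feature_id, role = "isotope",
        qualifier = as.character(iso_m$N), parent_feature_id = pid,
        ppm = iso_m$ppm, pearson_r = NA_real_, delta_ratio = iso_m$delta_ratio
      ))
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      subnetwork_id = paste0(fid, "_", adduct),
      base_feature_id = fid, adduct = adduct,
      base_intensity = feature_mean_intensity(base),
      size = nrow(members), members = list(members)
    )
  }
  if (length(out) == 0L) {
    return(tibble::tibble(subnetwork_id = character(),
                          base_feature_id = character(), adduct = character(),
                          base_intensity = numeric(), size = integer(),
                          members = list()))
  }
  dplyr::bind_rows(out)
}

#' Default empirical rules applied before conflict resolution
#'
#' A rule table the subnetwork check is driven by. Shipped defaults:
#' `multimer_needs_monomer` (a `[2M...]` base requires an in-group monomer
#' adduct; removes the subnetwork), `isotope_below_parent` (an N=1 isotope
#' may not exceed its parent's intensity; removes the member),
#' `nl_intensity_cap` (a neutral-loss ion may not exceed `factor` times the
#' base intensity; removes the member), `base_present` (a subnetwork must
#' contain its base; removes the subnetwork).
#'
#' @return Tibble `rule`, `action`, `factor`.
#' @export
empirical_rules <- function() {
  tibble::tribble(
    ~rule,                     ~action,             ~factor,
    "multimer_needs_monomer",  "remove_subnetwork", NA_real_,
    "isotope_below_parent",    "remove_member",     NA_real_,
    "nl_intensity_cap",        "remove_member",     10,
    "base_present",            "remove_subnetwork", NA_real_
  )
}

apply_empirical_rules <- function(subnetworks, features, adducts, rules) {
  f_int <- stats::setNames(feature_mean_intensity(features), features$feature_id)
  removed <- list()
  keep <- rep(TRUE, nrow(subnetworks))
  active <- function(rule) rule %in% rules$rule
  for (s in seq_len(nrow(subnetworks))) {
    m <- subnetworks$members[[s]]
    if (active("base_present") &&
        !subnetworks$base_feature_id[s] %in% m$feature_id[m$role == "base"]) {
      keep[s] <- FALSE
      removed[[length(removed) + 1L]] <- tibble::tibble(
        subnetwork_id = subnetworks$subnetwork_id[s],
        base_feature_id = subnetworks$base_feature_id[s],
        adduct = subnetworks$adduct[s],
        reason = "subnetwork lacks its base peak", step = 1L
      )
      next
    }
    if (active("multimer_needs_monomer")) {
      mult <- adducts$multimer[match(subnetworks$adduct[s], adducts$label)]
      if (!is.na(mult) && mult > 1L) {
        monomer_labels <- adducts$label[adducts$multimer == 1L]
        has_monomer <- any(m$role == "adduct" & m$qualifier %in% monomer_labels)
        if (!has_monomer) {
          keep[s] <- FALSE
          removed[[length(removed) + 1L]] <- tibble::tibble(
            subnetwork_id = subnetworks$subnetwork_id[s],
            base_feature_id = subnetworks$base_feature_id[s],
            adduct = subnetworks$adduct[s],
            reason = "multimer base without monomer evidence in group",
            step = 1L
          )
          next
        }
      }
    }
    drop <- rep(FALSE, nrow(m))
    if (active("isotope_below_parent")) {
      iso1 <- which(m$role == "isotope" & m$qualifier == "1")
      for (k in iso1) {
        if (f_int[m$feature_id[k]] > f_int[m$parent_feature_id[k]]) drop[k] <- TRUE
      }
    }
    if (active("nl_intensity_cap")) {
      fac <- rules$factor[rules$rule == "nl_intensity_cap"][1]
      nls <- which(m$role == "neutral_loss")
      base_int <- subnetworks$base_intensity[s]
      for (k in nls) {
        if (f_int[m$feature_id[k]] > fac * base_int) drop[k] <- TRUE
      }
    }
    ## cascade: members whose parent was dropped fall with it
    repeat {
      orphan <- !drop & !is.na(m$parent_feature_id) &
        m$parent_feature_id %in% m$feature_id[drop]
      if (!any(orphan)) break
      drop <- drop | orphan
    }
    if (any(drop)) {
      subnetworks$members[[s]] <- m[!drop, , drop = FALSE]
      subnetworks$size[s] <- sum(!drop)
    }
  }
  list(subnetworks = subnetworks[keep, , drop = FALSE],
       removed = if (length(removed)) dplyr::bind_rows(removed) else NULL)
}

#' Optimize ion-form subnetworks (three-step conflict resolution)
#'
#' Step 1 applies the empirical rules ([empirical_rules()]). Step 2 resolves
#' one base peak carrying different adduct annotations by keeping the larger
#' subnetwork. Step 3 consolidates globally: subnetworks claim features in
#' decreasing order of current size (ties: higher base intensity, then id);
#' a subnetwork whose base peak has already been claimed as an ion form of a
#' larger subnetwork is removed together with its annotations, and a
#' conflicted non-base member stays with the larger subnetwork only. After
#' optimization no feature holds two roles across retained subnetworks.
#'
#' @param subnetworks Tibble from [build_subnetworks()].
#' @param features Feature tibble.
#' @param adducts Adduct table (for multimer lookup); defaults to both
#'   polarities' ion-form tables.
#' @param rules Empirical rule table, default [empirical_rules()].
#' @return List with `retained` (subnetwork tibble, members pruned to the
#'   final assignment) and `removed` (tibble `subnetwork_id`,
#'   `base_feature_id`, `adduct`, `reason`, `step`).
#' @export
optimize_subnetworks <- function(subnetworks, features, adducts = NULL,
                                 rules = empirical_rules()) {
  adducts <- adducts %||% dplyr::bind_rows(adduct_table("positive", "ionform"),
                                           adduct_table("negative", "ionform"))
  step1 <- apply_empirical_rules(subnetworks, features, adducts, rules)
  sn <- step1$subnetworks
  removed <- list(step1$removed)

  ## step 2: same base, different adduct annotation -> keep larger
  if (nrow(sn) > 0L) {
    ord <- order(-sn$size, -sn$base_intensity, sn$subnetwork_id)
    sn <- sn[ord, , drop = FALSE]
    dup <- duplicated(sn$base_feature_id)
    if (any(dup)) {
      removed[[length(removed) + 1L]] <- tibble::tibble(
        subnetwork_id = sn$subnetwork_id[dup],
        base_feature_id = sn$base_feature_id[dup],
        adduct = sn$adduct[dup],
        reason = "conflicting ion-form annotation on the same base peak; smaller subnetwork removed",
        step = 2L
      )
      sn <- sn[!dup, , drop = FALSE]
    }
  }

  ## step 3: global consolidation by decreasing current size
  assigned <- character(0) # feature ids already holding a role
  kept <- list()
  pending <- sn
  while (nrow(pending) > 0L) {
    cur_size <- purrr::map_int(pending$members, ~ sum(!(.x$feature_id %in% assigned)))
    ## drop pending subnetworks whose base is already claimed
    base_claimed <- pending$base_feature_id %in% assigned
    if (any(base_claimed)) {
      removed[[length(removed) + 1L]] <- tibble::tibble(
        subnetwork_id = pending$subnetwork_id[base_claimed],
        base_feature_id = pending$base_feature_id[base_claimed],
        adduct = pending$adduct[base_claimed],
        reason = "base peak explained as an ion form of a larger subnetwork",
        step = 3L
      )
      pending <- pending[!base_claimed, , drop = FALSE]
      next
    }
    ord <- order(-cur_size, -pending$base_intensity, pending$subnetwork_id)
    pick <- ord[1L]
    m <- pending$members[[pick]]
    m <- m[!(m$feature_id %in% assigned), , drop = FALSE]
    row <- pending[pick, , drop = FALSE]
    row$members <- list(m)
    row$size <- nrow(m)
    kept[[length(kept) + 1L]] <- row
    assigned <- c(assigned, m$feature_id)
    pending <- pending[-pick, , drop = FALSE]
  }
  retained <- if (length(kept)) dplyr::bind_rows(kept) else sn[0, ]
  removed <- purrr::compact(removed)
  removed <- if (length(removed)) dplyr::bind_rows(removed) else
    tibble::tibble(subnetwork_id = character(), base_feature_id = character(),
                   adduct = character(), reason = character(), step = integer())
  list(retained = retained, removed = removed)
}

#' Flatten retained subnetworks into one role table
#' @param retained Retained subnetwork tibble from [optimize_subnetworks()].
#' @return Tibble `feature_id`, `role`, `qualifier`, `parent_feature_id`,
#'   `subnetwork_id`, `base_feature_id`.
#' @export
role_assignments <- function(retained) {
  if (nrow(retained) == 0L) {
    return(tibble::tibble(feature_id = character(), role = character(),
                          qualifier = character(),
                          parent_feature_id = character(),
                          subnetwork_id = character(),
                          base_feature_id = character()))
  }
  purrr::map2(retained$members, seq_len(nrow(retained)), function(m, i) {
    dplyr::mutate(m, subnetwork_id = retained$subnetwork_id[i],
                  base_feature_id = retained$base_feature_id[i])
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("feature_id", "role", "qualifier", "parent_feature_id",
                  "subnetwork_id", "base_feature_id")
}

#' Export the peak correlation network via [write_network()]
#' @param retained Retained subnetworks.
#' @param features Feature tibble.
#' @inheritParams write_network
#' @return Invisibly, the written path(s).
#' @export
write_peak_network <- function(retained, features, path, format = "graphml") {
  roles <- role_assignments(retained)
  nodes <- tibble::tibble(id = unique(roles$feature_id)) |>
    dplyr::left_join(dplyr::select(roles, id = "feature_id", "role", "qualifier"),
                     by = "id") |>
    dplyr::distinct(.data$id, .keep_all = TRUE) |>
    dplyr::mutate(mz = features$mz[match(.data$id, features$feature_id)],
                  rt = features$rt[match(.data$id, features$feature_id)])
  edges <- roles |>
    dplyr::filter(.data$role != "base") |>
    dplyr::transmute(from = .data$parent_feature_id, to = .data$feature_id,
                     role = .data$role, qualifier = .data$qualifier)
  write_network(nodes, edges, path, format)
}
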