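## Network 2: the knowledge-guided MS/MS similarity network. Annotations are
## propagated recursively from seeds to reaction-paired neighbor metabolites
## under four constraints: (1) reaction pairing in the metabolic network,
## (2) MS1 m/z match over the polarity's adduct list, (3) predicted RT match,
## (4) MS/MS similarity against the seed's experimental spectrum used as a
## surrogate reference.

#' Default propagation configuration
#'
#' @param tol_ppm MS1 match tolerance (ppm), default 15.
#' @param rt_tol_rel Relative RT tolerance vs the predicted RT, default 0.30.
#' @param ms2_threshold Surrogate-spectrum score acceptance (strictly
#'   greater), default 0.5.
#' @param min_matched Alternative acceptance: matched fragments at least this
#'   many, default 5 (the "more than 4" rule).
#' @param ms2_tol_ppm Fragment-match tolerance (ppm), default 25.
#' @param max_rounds Safety cap on propagation rounds.
#' @return A list of settings.
#' @export
propagation_config <- function(tol_ppm = 15, rt_tol_rel = 0.30,
                               ms2_threshold = 0.5, min_matched = 5L,
                               ms2_tol_ppm = 25, max_rounds = 50L) {
  list(tol_ppm = tol_ppm, rt_tol_rel = rt_tol_rel,
       ms2_threshold = ms2_threshold, min_matched = as.integer(min_matched),
       ms2_tol_ppm = ms2_tol_ppm, max_rounds = as.integer(max_rounds))
}

empty_annotations <- function() {
  tibble::tibble(
    annotation_id = character(), feature_id = character(),
    node_id = character(), adduct = character(), level = numeric(),
    inchikey14 = character(),
    parent_id = character(), label = character(), round = integer(),
    ms2_score = numeric(), n_matched = integer(), ppm = numeric(),
    rt_ok = logical(), rt_dev_rel = numeric(), origin = character()
  )
}

## map seed annotations (library hits) onto reaction-network nodes via the
## first InChIKey block; seeds absent from the network cannot propagate but
## remain reported annotations (node_id = NA).
seed_to_annotations <- function(seeds, kmrn) {
  node_idx <- match(seeds$inchikey14, kmrn$nodes$inchikey14)
  tibble::tibble(
    annotation_id = paste0("seed_", seeds$feature_id, "_", seeds$library_name,
                           "_", seeds$adduct),
    feature_id = seeds$feature_id,
    node_id = kmrn$nodes$node_id[node_idx],
    adduct = seeds$adduct,
    level = seeds$level,
    inchikey14 = seeds$inchikey14,
    parent_id = NA_character_, label = NA_character_, round = 0L,
    ms2_score = seeds$ms2_score, n_matched = seeds$n_matched,
    ppm = seeds$ppm, rt_ok = !is.na(seeds$rt_err_s),
    rt_dev_rel = NA_real_,
    origin = "seed"
  )
}

node_predicted_rt <- function(kmrn, rt_model, descriptors) {
  pred <- rep(NA_real_, nrow(kmrn$nodes))
  if (is.null(rt_model) || isTRUE(rt_model$fallback) || is.null(descriptors)) {
    return(pred)
  }
  key <- if ("node_id" %in% names(descriptors)) "node_id" else "inchikey14"
  idx <- match(kmrn$nodes[[key]], descriptors[[key]])
  ok <- !is.na(idx)
  if (any(ok)) {
    pred[ok] <- predict(rt_model, descriptors[idx[ok], , drop = FALSE])
  }
  pred
}

#' One propagation round
#'
#' For every current seed annotation, reaction-paired neighbor metabolites
#' are searched in the feature table over the polarity's adduct list
#' (`<= tol_ppm`), RT-filtered against the model-predicted RT, and accepted
#' when their spectrum scores `> ms2_threshold` against the seed feature's
#' spectrum or shares at least `min_matched` fragments with it. Features
#' without MS2 are skipped. Candidate `(feature, node, adduct)` triples
#' already annotated are not re-annotated.
#'
#' @param current_seeds Annotation tibble rows acting as seeds this round.
#' @param kmrn A `kmrn` object.
#' @param features Feature tibble with `ms2` list-column.
#' @param node_rt Predicted RT per `kmrn$nodes` row (`NA` disables the RT
#'   check for that node).
#' @param cleaned Named list of cleaned `fragment_spectrum` per feature id.
#' @param existing_keys Character keys `feature|node|adduct` already taken.
#' @param adducts Adduct tibble for the polarity.
#' @param config [propagation_config()].
#' @param round Round number assigned to new annotations.
#' @return Tibble of new annotations (possibly empty).
#' @export
propagate_once <- function(current_seeds, kmrn, features, node_rt, cleaned,
                           existing_keys, adducts, config, round) {
  new_rows <- list()
  ord <- order(current_seeds$feature_id, current_seeds$node_id,
               current_seeds$adduct)
  current_seeds <- current_seeds[ord, , drop = FALSE]
  for (s in seq_len(nrow(current_seeds))) {
    seed <- current_seeds[s, ]
    if (is.na(seed$node_id)) next
    seed_spec <- cleaned[[seed$feature_id]]
    if (is.null(seed_spec)) next
    nb <- kmrn_neighbors(kmrn, seed$node_id)
    if (nrow(nb) == 0L) next
    for (e in seq_len(nrow(nb))) {
      n_idx <- match(nb$neighbor[e], kmrn$nodes$node_id)
      node <- kmrn$nodes[n_idx, ]
      pred_rt <- node_rt[n_idx]
      for (a in seq_len(nrow(adducts))) {
        mz_t <- (adducts$multimer[a] * node$monoisotopic_mass +
                   adducts$delta[a]) / adducts$charge[a]
        dppm <- ppm_error(features$mz, mz_t)
        hits <- which(abs(dppm) <= config$tol_ppm)
        for (fi in hits) {
          fid <- features$feature_id[fi]
          if (fid == seed$feature_id) next
          key <- paste(fid, node$node_id, adducts$label[a], sep = "|")
          if (key %in% existing_keys) next
          spec <- cleaned[[fid]]
          if (is.null(spec)) next
          rt_dev <- if (is.na(pred_rt)) NA_real_ else
            abs(features$rt[fi] - pred_rt) / pred_rt
          if (!is.na(rt_dev) && rt_dev > config$rt_tol_rel) next
          sim <- sqrt_dot_product(spec, seed_spec, tol_ppm = config$ms2_tol_ppm)
          if (!(sim$score > config$ms2_threshold ||
                sim$n_matched >= config$min_matched)) next
          existing_keys <- c(existing_keys, key)
          new_rows[[length(new_rows) + 1L]] <- tibble::tibble(
            annotation_id = paste0("prop_", fid, "_", node$node_id, "_",
                                   adducts$label[a]),
            feature_id = fid, node_id = node$node_id,
            adduct = adducts$label[a],
            level = if (node$origin == "known") 3.1 else 3.2,
            inchikey14 = node$inchikey14,
            parent_id = seed$annotation_id, label = nb$label[e],
            round = as.integer(round),
            ms2_score = sim$score, n_matched = as.integer(sim$n_matched),
            ppm = dppm[fi], rt_ok = !is.na(rt_dev), rt_dev_rel = rt_dev,
            origin = "propagated"
          )
        }
      }
    }
  }
  if (length(new_rows) == 0L) return(empty_annotations())
  dplyr::bind_rows(new_rows)
}

#' Propagate annotations from seeds to a fixed point
#'
#' Repeats [propagate_once()], feeding newly annotated features back into the
#' seed pool, until a round yields no new annotation. Cycles in the reaction
#' network terminate because a `(feature, node, adduct)` triple is annotated
#' at most once (first round wins). Also emits the MS/MS-similarity network
#' whose nodes are features and whose edges carry the similarity score,
#' matched-fragment count, biotransformation label and round.
#'
#' @param seeds Seed annotation tibble from [annotate_seeds()].
#' @param kmrn A `kmrn` object.
#' @param features Feature tibble with `ms2` list-column.
#' @param rt_model Optional `rt_model`; `NULL` or a fallback model disables
#'   the RT constraint.
#' @param descriptors Optional descriptor table (`node_id` or `inchikey14`
#'   plus the model's descriptor columns).
#' @param config [propagation_config()].
#' @param adducts Optional adduct table; defaults to the polarity's
#'   propagation list.
#' @return Object of class `propagation_result`: list with `annotations`
#'   (seeds at round 0 plus propagated rows), `network` (`nodes`, `edges`
#'   tibbles), `n_rounds`.
#' @export
propagate <- function(seeds, kmrn, features, rt_model = NULL,
                      descriptors = NULL, config = propagation_config(),
                      adducts = NULL) {
  stopifnot(nrow(seeds) >= 1L)
  polarity <- features$polarity[1]
  adducts <- adducts %||% adduct_table(polarity, "propagation")
  cleaned <- stats::setNames(
    purrr::map2(features$ms2, features$mz, function(s, mz) {
      if (is.null(s)) NULL else clean_spectrum(s, precursor_mz = mz)
    }),
    features$feature_id
  )
  node_rt <- node_predicted_rt(kmrn, rt_model, descriptors)
  ann <- seed_to_annotations(seeds, kmrn)
  keys <- paste(ann$feature_id, ann$node_id, ann$adduct, sep = "|")
  active <- ann
  round <- 0L
  while (nrow(active) > 0L && round < config$max_rounds) {
    round <- round + 1L
    new_ann <- propagate_once(active, kmrn, features, node_rt, cleaned,
                              keys, adducts, config, round)
    if (nrow(new_ann) > 0L) {
      ann <- dplyr::bind_rows(ann, new_ann)
      keys <- c(keys, paste(new_ann$feature_id, new_ann$node_id,
                            new_ann$adduct, sep = "|"))
    }
    active <- new_ann
  }
  edges <- ann |>
    dplyr::filter(.data$origin == "propagated") |>
    dplyr::mutate(
      from = ann$feature_id[match(.data$parent_id, ann$annotation_id)],
      to = .data$feature_id
    ) |>
    dplyr::select("from", "to", ms2_score = "ms2_score",
                  n_matched = "n_matched", biotransformation = "label",
                  round = "round") |>
    dplyr::distinct()
  node_ids <- unique(c(ann$feature_id))
  nodes <- tibble::tibble(
    id = node_ids,
    mz = features$mz[match(node_ids, features$feature_id)],
    rt = features$rt[match(node_ids, features$feature_id)],
    is_seed = node_ids %in% ann$feature_id[ann$origin == "seed"]
  )
  structure(list(annotations = ann, network = list(nodes = nodes, edges = edges),
                 n_rounds = round),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  a <- x$annotations
  cat("<propagation_result>", sum(a$origin == "seed"), "seed +",
      sum(a$origin == "propagated"), "propagated annotations on",
      dplyr::n_distinct(a$feature_id), "features;", x$n_rounds, "rounds\n")
  invisible(x)
}

#' Unconstrained MS/MS similarity network at a score threshold
#'
#' Builds the all-pairs spectral-similarity graph over features with MS2,
#' keeping edges whose score exceeds `threshold`. Used to quantify how much
#' the knowledge guidance (reaction pairing + m/z + RT constraints) prunes
#' the similarity network.
#'
#' @param features Feature tibble with `ms2` list-column.
#' @param threshold Score threshold (strictly greater), default 0.5.
#' @param min_matched Optional matched-fragment acceptance (>= this many)
#'   mirroring the propagation rule; 0 disables it.
#' @param ms2_tol_ppm Fragment tolerance (ppm), default 25.
#' @return Edge tibble `from`, `to`, `ms2_score`, `n_matched`.
#' @export
ms2_similarity_graph <- function(features, threshold = 0.5, min_matched = 0L,
                                 ms2_tol_ppm = 25) {
  has <- which(!vapply(features$ms2, is.null, logical(1)))
  cleaned <- purrr::map(has, function(i) {
    clean_spectrum(features$ms2[[i]], precursor_mz = features$mz[i])
  })
  out <- list()
  for (ii in seq_along(has)) {
    for (jj in seq_len(ii - 1L)) {
      sim <- sqrt_dot_product(cleaned[[ii]], cleaned[[jj]],
                              tol_ppm = ms2_tol_ppm)
      if (sim$score > threshold ||
          (min_matched > 0L && sim$n_matched >= min_matched)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          from = features$feature_id[has[jj]],
          to = features$feature_id[has[ii]],
          ms2_score = sim$score, n_matched = as.integer(sim$n_matched)
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(from = character(), to = character(),
                          ms2_score = numeric(), n_matched = integer()))
  }
  dplyr::bind_rows(out)
}
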