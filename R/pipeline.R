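## End-to-end pipeline: seed annotation -> RT model -> propagation ->
## peak-correlation deconvolution -> scoring -> report, with all exports.

#' Assemble a pipeline configuration
#'
#' Inputs may be in-memory objects (tibbles, `kmrn`) or file paths; paths
#' are loaded with the package readers. All tolerances default to the
#' method's standard values: 15 ppm / 20 s / 0.8 for seed annotation,
#' 15 ppm / 30% / (0.5 or >= 5 fragments) for propagation, +/-3 s grouping,
#' 25 ppm ion forms, 500% isotope ratio, 0.3 Pearson, score weights
#' 0.25/0.25/0.5.
#'
#' @param features Feature tibble or path to a delimited feature table.
#' @param library Library tibble or path to an MSP library.
#' @param kmrn A `kmrn` object, or `NULL` to build one from `known_nodes`,
#'   `known_pairs`, `rules`.
#' @param spectra Optional spectra tibble or MGF/MSP path (linked to
#'   features when the feature table has no `ms2` column).
#' @param descriptors Optional descriptor tibble or TSV path.
#' @param known_nodes,known_pairs,rules Used when `kmrn` is `NULL`.
#' @param dialect Feature-table dialect for path input.
#' @param polarity `"positive"` or `"negative"`.
#' @param chromatography `"hilic"` or `"rp"`.
#' @param seed_tol List of seed tolerances `tol_ppm`, `tol_rt_s`, `tol_ms2`.
#' @param prop_config [propagation_config()].
#' @param score_config [scoring_config()].
#' @param group_window,ionform_tol_ppm,pearson_min,isotope_ratio_dev
#'   Peak-correlation settings.
#' @param top_n Candidates reported per feature.
#' @param truth Optional truth tibble enabling evaluation.
#' @param out_dir Optional directory for exports.
#' @param seed RNG seed recorded in the run log and used for model training.
#' @return A config list for [run_pipeline()].
#' @export
pipeline_config <- function(features, library, kmrn = NULL, spectra = NULL,
                            descriptors = NULL, known_nodes = NULL,
                            known_pairs = NULL, rules = default_rules(),
                            dialect = "generic",
                            polarity = c("positive", "negative"),
                            chromatography = c("hilic", "rp"),
                            seed_tol = list(tol_ppm = 15, tol_rt_s = 20,
                                            tol_ms2 = 0.8),
                            prop_config = propagation_config(),
                            score_config = scoring_config(),
                            group_window = 3, ionform_tol_ppm = 25,
                            pearson_min = 0.3, isotope_ratio_dev = 500,
                            top_n = 10, truth = NULL, out_dir = NULL,
                            seed = 42L) {
  polarity <- match.arg(polarity)
  chromatography <- match.arg(chromatography)
  cfg <- as.list(environment())
  if (is.null(cfg$features)) stop("config is missing `features`", call. = FALSE)
  if (is.null(cfg$library)) stop("config is missing `library`", call. = FALSE)
  if (is.character(cfg$features) && !file.exists(cfg$features)) {
    stop("feature table not found: ", cfg$features, call. = FALSE)
  }
  if (is.character(cfg$library) && !file.exists(cfg$library)) {
    stop("library not found: ", cfg$library, call. = FALSE)
  }
  if (is.character(cfg$spectra) && !file.exists(cfg$spectra)) {
    stop("spectra not found: ", cfg$spectra, call. = FALSE)
  }
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("metanno_stage_error", "error", "condition"),
                   list(message = paste0("stage '", name, "' failed: ",
                                         conditionMessage(e)),
                        call = NULL, stage = name)))
  })
}

#' Run the full annotation pipeline
#'
#' Executes seed annotation, RT-model training, annotation propagation,
#' peak-correlation deconvolution, scoring and reporting. With `out_dir`
#' set, writes the three network exports (reaction network, similarity
#' network, peak correlation network as GraphML), the annotation report and
#' removal report (TSV), and a YAML run log with parameters and seeds.
#'
#' @param config A [pipeline_config()] list.
#' @return Object of class `metanno_result`: list with `seeds`, `rt_model`,
#'   `propagation`, `subnetworks`, `retained`, `removed`, `roles`, `scored`,
#'   `report`, `evaluation` (when truth given), `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  features <- pipeline_stage("read_features", {
    if (is.character(cfg$features)) {
      read_feature_table(cfg$features, dialect = cfg$dialect,
                         polarity = cfg$polarity)
    } else cfg$features
  })
  if (!"ms2" %in% names(features)) {
    features <- pipeline_stage("link_spectra", {
      if (is.null(cfg$spectra)) stop("no MS2 spectra provided")
      sp <- if (is.character(cfg$spectra)) read_spectra(cfg$spectra) else cfg$spectra
      link_spectra(features, sp)
    })
  }
  library <- pipeline_stage("read_library", {
    if (is.character(cfg$library)) read_library(cfg$library) else cfg$library
  })
  kmrn <- pipeline_stage("build_network", {
    if (!is.null(cfg$kmrn)) cfg$kmrn else
      build_kmrn(cfg$known_nodes, cfg$known_pairs, cfg$rules,
                 structureless_ok = TRUE)
  })
  descriptors <- pipeline_stage("read_descriptors", {
    if (is.character(cfg$descriptors)) read_descriptor_cache(cfg$descriptors)
    else cfg$descriptors
  })

  seeds <- pipeline_stage("seed_annotation", {
    annotate_seeds(features, library, polarity = cfg$polarity,
                   tol_ppm = cfg$seed_tol$tol_ppm,
                   tol_rt_s = cfg$seed_tol$tol_rt_s,
                   tol_ms2 = cfg$seed_tol$tol_ms2)
  })

  rt_model <- pipeline_stage("rt_model", {
    if (is.null(descriptors)) NULL else {
      key <- if ("inchikey14" %in% names(descriptors)) "inchikey14" else "node_id"
      train_df <- seeds |>
        dplyr::filter(.data$level == 1) |>
        dplyr::distinct(.data$feature_id, .data$inchikey14) |>
        dplyr::mutate(rt = features$rt[match(.data$feature_id,
                                             features$feature_id)]) |>
        dplyr::inner_join(descriptors, by = stats::setNames(key, "inchikey14"))
      train_rt_model(train_df, chromatography = cfg$chromatography,
                     seed_rng = cfg$seed)
    }
  })

  prop <- pipeline_stage("propagation", {
    if (nrow(seeds) == 0L) stop("no seed annotations")
    propagate(seeds, kmrn, features, rt_model = rt_model,
              descriptors = descriptors, config = cfg$prop_config)
  })

  subnetworks <- pipeline_stage("peak_correlation", {
    build_subnetworks(features, prop$annotations, kmrn = kmrn,
                      window = cfg$group_window,
                      tol_ppm = cfg$ionform_tol_ppm,
                      r_min = cfg$pearson_min,
                      max_ratio_dev = cfg$isotope_ratio_dev)
  })
  opt <- pipeline_stage("subnetwork_optimization", {
    optimize_subnetworks(subnetworks, features,
                         adducts = adduct_table(cfg$polarity, "ionform"))
  })
  roles <- role_assignments(opt$retained)

  scored <- pipeline_stage("scoring", {
    prop$annotations |>
      apply_removals(opt$removed) |>
      compute_scores(cfg$score_config) |>
      dplyr::mutate(candidate = dplyr::coalesce(.data$node_id,
                                                .data$annotation_id))
  })
  report <- pipeline_stage("reporting", {
    rank_and_report(scored, top_n = cfg$top_n,
                    all_feature_ids = features$feature_id)
  })

  evaluation <- NULL
  if (!is.null(cfg$truth)) {
    evaluation <- pipeline_stage("evaluation", {
      base_truth <- cfg$truth[!is.na(cfg$truth$role) & cfg$truth$role == "base", ]
      list(
        metabolite = evaluate_top_n(report, base_truth, n = 3),
        role = evaluate_roles(roles,
                              cfg$truth[!is.na(cfg$truth$role), , drop = FALSE])
      )
    })
  }

  result <- structure(
    list(features = features, seeds = seeds, rt_model = rt_model,
         kmrn = kmrn, propagation = prop, subnetworks = subnetworks,
         retained = opt$retained, removed = opt$removed, roles = roles,
         scored = scored, report = report, evaluation = evaluation,
         config = cfg),
    class = "metanno_result"
  )
  if (!is.null(cfg$out_dir)) write_result(result, cfg$out_dir)
  result
}

#' Write all pipeline exports
#' @param result A `metanno_result`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_kmrn(result$kmrn, file.path(dir, "network1_reaction.graphml"))
  net2 <- result$propagation$network
  if (nrow(net2$nodes) > 0L) {
    write_network(net2$nodes,
                  dplyr::mutate(net2$edges,
                                biotransformation = tidyr::replace_na(.data$biotransformation, "")),
                  file.path(dir, "network2_ms2_similarity.graphml"))
  }
  if (nrow(result$retained) > 0L) {
    write_peak_network(result$retained, result$features,
                       file.path(dir, "network3_peak_correlation.graphml"))
  }
  report_flat <- dplyr::select(result$report,
                               !dplyr::any_of(c("intensities", "ms2")))
  readr::write_tsv(report_flat, file.path(dir, "annotations.tsv"))
  readr::write_tsv(result$removed, file.path(dir, "removals.tsv"))
  readr::write_tsv(result$roles, file.path(dir, "ion_form_roles.tsv"))
  log <- list(
    package = "metanno",
    version = as.character(utils::packageVersion("metanno")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = result$config$seed,
    polarity = result$config$polarity,
    tolerances = list(
      seed = result$config$seed_tol,
      propagation = result$config$prop_config[c("tol_ppm", "rt_tol_rel",
                                                "ms2_threshold", "min_matched")],
      grouping_window_s = result$config$group_window,
      ionform_tol_ppm = result$config$ionform_tol_ppm,
      isotope_ratio_dev_pct = result$config$isotope_ratio_dev,
      pearson_min = result$config$pearson_min
    )
  )
  yaml::write_yaml(log, file.path(dir, "run_log.yaml"))
  invisible(dir)
}

#' @export
print.metanno_result <- function(x, ...) {
  cat("<metanno_result>\n")
  cat("  features:          ", nrow(x$features), "\n")
  cat("  seed annotations:  ", nrow(x$seeds), "\n")
  a <- x$propagation$annotations
  cat("  propagated:        ", sum(a$origin == "propagated"), "in",
      x$propagation$n_rounds, "round(s)\n")
  cat("  retained subnets:  ", nrow(x$retained), "( removed:",
      nrow(x$removed), ")\n")
  cat("  features with role:", dplyr::n_distinct(x$roles$feature_id), "\n")
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x A `metanno_result`.
#' @param ... Unused.
#' @return Tibble of headline counts.
#' @export
glance.metanno_result <- function(x, ...) {
  a <- x$propagation$annotations
  tibble::tibble(
    n_features = nrow(x$features),
    n_seed_annotations = nrow(x$seeds),
    n_seed_features = dplyr::n_distinct(a$feature_id[a$origin == "seed"]),
    n_propagated = sum(a$origin == "propagated"),
    n_rounds = x$propagation$n_rounds,
    n_subnetworks = nrow(x$retained),
    n_removed = nrow(x$removed),
    n_features_with_role = dplyr::n_distinct(x$roles$feature_id)
  )
}

#' Tidy the per-feature report of a pipeline run
#' @param x A `metanno_result`.
#' @param ... Unused.
#' @return The report tibble.
#' @export
tidy.metanno_result <- function(x, ...) x$report
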