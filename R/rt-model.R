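## Retention-time prediction: a random-forest regressor trained on seed
## metabolites (molecular descriptors -> observed RT) supplies the predicted
## RTs that gate annotation propagation (constraint 3).

#' Default molecular-descriptor names per chromatography
#'
#' Eight descriptors for HILIC and five for reversed phase. The identities
#' are package defaults — any provider that fills a descriptor table with
#' these column names (or an overridden list) can be substituted, e.g. an
#' RDKit- or rcdk-based calculator or a precomputed cache.
#'
#' @param chromatography `"hilic"` or `"rp"`.
#' @return Character vector of descriptor names.
#' @export
default_descriptors <- function(chromatography = c("hilic", "rp")) {
  chromatography <- match.arg(chromatography)
  if (chromatography == "hilic") {
    c("xlogp", "tpsa", "hbd", "hba", "rotatable_bonds", "mw",
      "aromatic_rings", "charge_centers")
  } else {
    c("xlogp", "tpsa", "hbd", "hba", "mw")
  }
}

#' Read a descriptor cache (inchikey14 -> descriptor vector) from TSV
#' @param path TSV with column `inchikey14` plus one column per descriptor.
#' @return Tibble keyed by `inchikey14`.
#' @export
read_descriptor_cache <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot("inchikey14" %in% names(df))
  df
}

#' Train the retention-time random forest on seed metabolites
#'
#' Fits a random forest on descriptors -> observed RT with 10-fold
#' cross-validated selection of `mtry` and `min.node.size`. Duplicated seed
#' rows are collapsed before training. With fewer than `min_seeds` usable
#' seeds no model is trained: an object with `fallback = TRUE` is returned
#' and the RT constraint is disabled downstream (with a message).
#'
#' @param seeds Tibble with column `rt` (observed seconds) plus descriptor
#'   columns named in `descriptor_names`.
#' @param chromatography `"hilic"` or `"rp"` (sets the default descriptors).
#' @param descriptor_names Override of the descriptor column list.
#' @param min_seeds Training floor (default 20).
#' @param seed_rng RNG seed for fold assignment and forest growth.
#' @param num_trees Forest size, default 500.
#' @return An object of class `rt_model` with elements `fit`, `cv_stats`
#'   (per-fold RMSE/MAE), `descriptor_names`, `chromatography`, `fallback`.
#' @export
train_rt_model <- function(seeds, chromatography = c("hilic", "rp"),
                           descriptor_names = NULL, min_seeds = 20,
                           seed_rng = 42L, num_trees = 500) {
  chromatography <- match.arg(chromatography)
  descriptor_names <- descriptor_names %||% default_descriptors(chromatography)
  missing_cols <- setdiff(c("rt", descriptor_names), names(seeds))
  if (length(missing_cols) > 0L) {
    stop("seed table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::distinct(seeds[, c("rt", descriptor_names)])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < min_seeds) {
    message("only ", nrow(df), " usable seeds (< ", min_seeds,
            "): RT model not trained, RT constraint disabled")
    return(structure(list(fit = NULL, cv_stats = NULL,
                          descriptor_names = descriptor_names,
                          chromatography = chromatography, fallback = TRUE,
                          n_train = nrow(df)),
                     class = "rt_model"))
  }
  p <- length(descriptor_names)
  grid <- tidyr::expand_grid(
    mtry = unique(pmax(1L, round(p * c(1 / 3, 2 / 3, 1)))),
    min_node = c(2L, 5L)
  )
  set.seed(seed_rng)
  folds <- sample(rep_len(1:10, nrow(df)))
  cv <- purrr::pmap(grid, function(mtry, min_node) {
    errs <- purrr::map_dbl(1:10, function(k) {
      tr <- df[folds != k, , drop = FALSE]
      te <- df[folds == k, , drop = FALSE]
      if (nrow(te) == 0L) return(NA_real_)
      fit <- ranger::ranger(rt ~ ., data = tr, num.trees = num_trees,
                            mtry = min(mtry, p), min.node.size = min_node,
                            seed = seed_rng)
      pred <- stats::predict(fit, te)$predictions
      sqrt(mean((pred - te$rt)^2))
    })
    tibble::tibble(mtry = mtry, min_node = min_node,
                   rmse = mean(errs, na.rm = TRUE))
  }) |> dplyr::bind_rows()
  best <- cv[which.min(cv$rmse), ]
  fit <- ranger::ranger(rt ~ ., data = df, num.trees = num_trees,
                        mtry = min(best$mtry, p),
                        min.node.size = best$min_node, seed = seed_rng)
  ## held-out fold errors at the selected hyperparameters
  fold_stats <- purrr::map(1:10, function(k) {
    tr <- df[folds != k, , drop = FALSE]
    te <- df[folds == k, , drop = FALSE]
    if (nrow(te) == 0L) return(NULL)
    f <- ranger::ranger(rt ~ ., data = tr, num.trees = num_trees,
                        mtry = min(best$mtry, p),
                        min.node.size = best$min_node, seed = seed_rng)
    pred <- stats::predict(f, te)$predictions
    tibble::tibble(fold = k, n = nrow(te),
                   rmse = sqrt(mean((pred - te$rt)^2)),
                   mae = mean(abs(pred - te$rt)),
                   pred = list(pred), obs = list(te$rt))
  }) |> dplyr::bind_rows()
  structure(list(fit = fit, cv_stats = fold_stats, cv_grid = cv,
                 best = best, descriptor_names = descriptor_names,
                 chromatography = chromatography, fallback = FALSE,
                 n_train = nrow(df)),
            class = "rt_model")
}

#' Predict retention times for candidate metabolites
#'
#' @param object An `rt_model`.
#' @param newdata Tibble carrying the model's descriptor columns.
#' @param ... Unused.
#' @return Numeric vector of predicted RTs (seconds); all `NA` for a
#'   fallback model.
#' @export
predict.rt_model <- function(object, newdata, ...) {
  if (isTRUE(object$fallback)) return(rep(NA_real_, nrow(newdata)))
  nd <- newdata[, object$descriptor_names, drop = FALSE]
  pred <- rep(NA_real_, nrow(nd))
  ok <- stats::complete.cases(nd)
  if (any(ok)) {
    pred[ok] <- stats::predict(object$fit, nd[ok, , drop = FALSE])$predictions
  }
  pmax(pred, 1e-6)
}

#' @export
print.rt_model <- function(x, ...) {
  if (isTRUE(x$fallback)) {
    cat("<rt_model> fallback (", x$n_train, "seeds below floor ): RT constraint disabled\n")
  } else {
    cat("<rt_model>", x$chromatography, "random forest on",
        length(x$descriptor_names), "descriptors,", x$n_train, "seeds; CV RMSE",
        format(mean(x$cv_stats$rmse), digits = 4), "s\n")
  }
  invisible(x)
}

#' Tidy per-fold cross-validation errors of an RT model
#' @param x An `rt_model`.
#' @param ... Unused.
#' @return Tibble with one row per CV fold (`fold`, `n`, `rmse`, `mae`).
#' @export
tidy.rt_model <- function(x, ...) {
  if (isTRUE(x$fallback)) {
    return(tibble::tibble(fold = integer(), n = integer(),
                          rmse = numeric(), mae = numeric()))
  }
  dplyr::select(x$cv_stats, "fold", "n", "rmse", "mae")
}

#' One-row summary of an RT model
#' @param x An `rt_model`.
#' @param ... Unused.
#' @return Tibble with `n_train`, `n_descriptors`, `cv_rmse`, `cv_mae`,
#'   `cv_r_squared`, `fallback`.
#' @export
glance.rt_model <- function(x, ...) {
  if (isTRUE(x$fallback)) {
    return(tibble::tibble(n_train = x$n_train, n_descriptors = length(x$descriptor_names),
                          cv_rmse = NA_real_, cv_mae = NA_real_,
                          cv_r_squared = NA_real_, fallback = TRUE))
  }
  pred <- unlist(x$cv_stats$pred)
  obs <- unlist(x$cv_stats$obs)
  tibble::tibble(
    n_train = x$n_train, n_descriptors = length(x$descriptor_names),
    cv_rmse = sqrt(mean((pred - obs)^2)), cv_mae = mean(abs(pred - obs)),
    cv_r_squared = 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2),
    fallback = FALSE
  )
}

#' Relative retention-time match used during propagation
#'
#' True iff `|observed - predicted| / predicted <= tol` (default 30%,
#' inclusive). The predicted RT is the denominator.
#'
#' @param predicted_rt,observed_rt Positive RTs (seconds); vectorized.
#' @param tol Relative tolerance, default 0.30.
#' @return Logical vector.
#' @export
rt_match <- function(predicted_rt, observed_rt, tol = 0.30) {
  abs(observed_rt - predicted_rt) / predicted_rt <= tol
}
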