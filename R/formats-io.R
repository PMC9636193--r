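## Readers/writers for the external formats the pipeline touches. Retention
## time is seconds everywhere internally; dialects declare whether the source
## stores minutes.

#' Build canonical feature ids from m/z and retention time
#'
#' Ids follow the `M<nominal m/z>T<RT seconds>` convention, e.g. m/z 153.0398
#' at 555.4 s becomes `"M153T555"`. Rounding is round-half-even (R's
#' `round()`). Collisions within one call are resolved by appending `_1`,
#' `_2`, ... in input order.
#'
#' @param mz Numeric vector of m/z values (Th), all > 0.
#' @param rt Numeric vector of retention times (seconds), all >= 0.
#' @return Character vector of unique feature ids.
#' @examples
#' make_feature_id(c(153.0398, 285.0810), c(555.4, 555.0))
#' @export
make_feature_id <- function(mz, rt) {
  stopifnot(length(mz) == length(rt))
  if (any(!is.finite(mz)) || any(!is.finite(rt))) {
    stop("non-finite m/z or RT", call. = FALSE)
  }
  stopifnot(all(mz > 0), all(rt >= 0))
  ids <- paste0("M", round(mz), "T", round(rt))
  out <- ids
  dup <- duplicated(ids)
  if (any(dup)) {
    for (id in unique(ids[dup])) {
      idx <- which(ids == id)
      out[idx[-1L]] <- paste0(id, "_", seq_along(idx[-1L]))
    }
  }
  out
}

## Column maps for common feature-table exports. `rt_unit` declares how the
## source stores RT so it can be normalized to seconds.
DIALECTS <- list(
  generic = list(mz = c("mz", "m/z", "mzmed"), rt = c("rt", "rtmed", "rt_s"),
                 id = c("feature_id", "id", "name"), rt_unit = "seconds"),
  xcms    = list(mz = c("mzmed", "mz"), rt = c("rtmed", "rt"),
                 id = c("name", "feature_id"), rt_unit = "seconds"),
  msdial  = list(mz = c("average mz", "precursor m/z", "mz"),
                 rt = c("average rt(min)", "rt (min)", "rt"),
                 id = c("alignment id", "id"), rt_unit = "minutes"),
  mzmine  = list(mz = c("row m/z", "mz"), rt = c("row retention time", "rt"),
                 id = c("row id", "id"), rt_unit = "minutes")
)

pick_col <- function(cols, candidates) {
  hit <- match(candidates, tolower(cols))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Read a feature table exported from a peak-picking tool
#'
#' Reads delimited text (comma or tab, autodetected) with one row per LC-MS
#' feature. Sample-intensity columns are every numeric column not recognized
#' as m/z, RT, or id. RT is converted to seconds when the dialect stores
#' minutes. Missing feature ids are regenerated with [make_feature_id()].
#'
#' @param path File path.
#' @param dialect One of `"generic"`, `"xcms"`, `"msdial"`, `"mzmine"`.
#' @param polarity Ionization mode recorded on the table, `"positive"` or
#'   `"negative"`.
#' @return A tibble with columns `feature_id`, `mz`, `rt`, `polarity`, and a
#'   list-column `intensities` of named per-sample numeric vectors.
#' @export
read_feature_table <- function(path, dialect = "generic",
                               polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  dialect <- match.arg(dialect, names(DIALECTS))
  stopifnot(file.exists(path))
  map <- DIALECTS[[dialect]]
  header <- readLines(path, n = 1L)
  delim <- if (stringr::str_count(header, "\t") >=
               stringr::str_count(header, ",")) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  cols <- names(df)
  i_mz <- pick_col(cols, map$mz)
  i_rt <- pick_col(cols, map$rt)
  if (is.na(i_mz)) stop("feature table is missing an m/z column (looked for: ",
                        paste(map$mz, collapse = ", "), ")", call. = FALSE)
  if (is.na(i_rt)) stop("feature table is missing an RT column (looked for: ",
                        paste(map$rt, collapse = ", "), ")", call. = FALSE)
  i_id <- pick_col(cols, map$id)
  mz <- as.numeric(df[[i_mz]])
  rt <- as.numeric(df[[i_rt]])
  if (identical(map$rt_unit, "minutes")) rt <- rt * 60
  taken <- c(i_mz, i_rt, i_id)
  sample_cols <- setdiff(which(vapply(df, is.numeric, logical(1))), taken)
  ids <- if (!is.na(i_id)) as.character(df[[i_id]]) else make_feature_id(mz, rt)
  if (anyDuplicated(ids)) {
    stop("duplicated feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  intens <- purrr::pmap(df[sample_cols], function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), cols[sample_cols])
  })
  if (length(sample_cols) == 0L) intens <- rep(list(stats::setNames(numeric(0), character(0))), nrow(df))
  tibble::tibble(feature_id = ids, mz = mz, rt = rt,
                 polarity = polarity, intensities = intens)
}

## ---- spectra ----------------------------------------------------------------

#' Construct a fragment spectrum
#'
#' Peaks are sorted by ascending m/z and zero-intensity peaks dropped.
#'
#' @param precursor_mz Precursor m/z (Th), may be `NA`.
#' @param peaks Data frame with columns `mz` (> 0) and `intensity` (>= 0).
#' @param metadata Free-form named list.
#' @return A `fragment_spectrum` object.
#' @export
new_spectrum <- function(precursor_mz, peaks, metadata = list()) {
  peaks <- peaks[peaks$intensity > 0, , drop = FALSE]
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  stopifnot(all(peaks$mz > 0))
  structure(list(precursor_mz = precursor_mz,
                 peaks = tibble::as_tibble(peaks),
                 metadata = metadata),
            class = "fragment_spectrum")
}

#' @export
print.fragment_spectrum <- function(x, ...) {
  cat("<fragment_spectrum> precursor m/z", format(x$precursor_mz, digits = 8),
      "-", nrow(x$peaks), "peaks\n")
  invisible(x)
}

#' Read MS2 spectra from an MGF or MSP file
#'
#' Peaks are sorted by ascending m/z and zero-intensity peaks dropped. Blocks
#' that yield no peaks are skipped with a warning. Spectra can subsequently be
#' attached to a feature table with [link_spectra()].
#'
#' @param path File path.
#' @param format `"mgf"` or `"msp"`; inferred from the extension by default.
#' @return A tibble with columns `spectrum_id`, `precursor_mz`, `rt`
#'   (seconds, `NA` when absent), `title`, and list-column `spectrum` of
#'   `fragment_spectrum` objects.
#' @export
read_spectra <- function(path, format = NULL) {
  stopifnot(file.exists(path))
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(tolower(format), c("mgf", "msp"))
  lines <- readLines(path, warn = FALSE)
  if (format == "mgf") parse_mgf(lines) else parse_msp(lines)
}

empty_spectra_tbl <- function() {
  tibble::tibble(spectrum_id = character(), precursor_mz = numeric(),
                 rt = numeric(), title = character(), spectrum = list())
}

parse_peak_lines <- function(pl, where) {
  if (length(pl) == 0L) return(NULL)
  parts <- stringr::str_split(stringr::str_trim(pl), "[\\s,;]+")
  mz <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  int <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (any(is.na(mz)) || any(is.na(int))) {
    stop("unparseable peak line in ", where, call. = FALSE)
  }
  tibble::tibble(mz = mz, intensity = int)
}

parse_mgf <- function(lines) {
  begins <- which(stringr::str_detect(lines, "^BEGIN IONS"))
  ends <- which(stringr::str_detect(lines, "^END IONS"))
  if (length(begins) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN/END IONS", call. = FALSE)
  }
  out <- purrr::map(seq_along(begins), function(k) {
    body <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    body <- body[nzchar(stringr::str_trim(body))]
    is_kv <- stringr::str_detect(body, "^[A-Za-z][A-Za-z0-9_]*=")
    kv <- body[is_kv]
    keys <- toupper(stringr::str_extract(kv, "^[^=]+"))
    vals <- stringr::str_remove(kv, "^[^=]+=")
    meta <- stats::setNames(as.list(vals), keys)
    pmz <- suppressWarnings(as.numeric(stringr::str_split_i(meta$PEPMASS %||% NA, "\\s+", 1)))
    rt <- suppressWarnings(as.numeric(meta$RTINSECONDS %||% NA))
    peaks <- parse_peak_lines(body[!is_kv], paste0("MGF block ", k))
    if (is.null(peaks) || nrow(peaks[peaks$intensity > 0, ]) == 0L) {
      warning("MGF block ", k, " has no peaks; skipped", call. = FALSE)
      return(NULL)
    }
    tibble::tibble(
      spectrum_id = meta$TITLE %||% paste0("spectrum_", k),
      precursor_mz = pmz, rt = rt, title = meta$TITLE %||% NA_character_,
      spectrum = list(new_spectrum(pmz, peaks, meta))
    )
  })
  out <- purrr::compact(out)
  if (length(out) == 0L) return(empty_spectra_tbl())
  dplyr::bind_rows(out)
}

parse_msp <- function(lines) {
  lines <- lines[!stringr::str_starts(lines, "#")]
  starts <- which(stringr::str_detect(lines, stringr::regex("^name\\s*:", ignore_case = TRUE)))
  if (length(starts) == 0L) return(empty_spectra_tbl())
  bounds <- c(starts, length(lines) + 1L)
  out <- purrr::map(seq_along(starts), function(k) {
    body <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    body <- body[nzchar(stringr::str_trim(body))]
    is_kv <- stringr::str_detect(body, "^[A-Za-z][A-Za-z0-9_ /]*:")
    kv <- body[is_kv]
    keys <- toupper(stringr::str_trim(stringr::str_extract(kv, "^[^:]+")))
    vals <- stringr::str_trim(stringr::str_remove(kv, "^[^:]+:"))
    meta <- stats::setNames(as.list(vals), keys)
    npk <- suppressWarnings(as.integer(meta[["NUM PEAKS"]] %||% NA))
    peak_lines <- body[!is_kv]
    if (!is.na(npk) && length(peak_lines) != npk) {
      stop("MSP record ", k, " ('", meta$NAME %||% "?", "'): expected ", npk,
           " peaks, found ", length(peak_lines), call. = FALSE)
    }
    pmz <- suppressWarnings(as.numeric(meta$PRECURSORMZ %||% meta[["PRECURSOR M/Z"]] %||% NA))
    rt <- suppressWarnings(as.numeric(meta$RETENTIONTIME %||% meta$RT %||% NA))
    peaks <- parse_peak_lines(peak_lines, paste0("MSP record ", k))
    if (is.null(peaks) || nrow(peaks[peaks$intensity > 0, ]) == 0L) {
      warning("MSP record ", k, " has no peaks; skipped", call. = FALSE)
      return(NULL)
    }
    tibble::tibble(
      spectrum_id = meta$NAME %||% paste0("record_", k),
      precursor_mz = pmz, rt = rt, title = meta$NAME %||% NA_character_,
      spectrum = list(new_spectrum(pmz, peaks, meta))
    )
  })
  out <- purrr::compact(out)
  if (length(out) == 0L) return(empty_spectra_tbl())
  dplyr::bind_rows(out)
}

#' Attach MS2 spectra to a feature table
#'
#' Spectra whose title equals a feature id are linked by id; the rest are
#' linked by precursor m/z within `tol_ppm` and RT within `tol_rt_s` of the
#' feature (first match wins, ties broken by smallest ppm error). Spectra
#' without RT match on m/z alone.
#'
#' @param features Feature tibble from [read_feature_table()].
#' @param spectra Spectra tibble from [read_spectra()].
#' @param tol_ppm Precursor linking tolerance (ppm), default 10.
#' @param tol_rt_s RT linking tolerance (seconds), default 10.
#' @return `features` with an `ms2` list-column (`fragment_spectrum` or NULL).
#' @export
link_spectra <- function(features, spectra, tol_ppm = 10, tol_rt_s = 10) {
  ms2 <- rep(list(NULL), nrow(features))
  used <- logical(nrow(spectra))
  if (nrow(spectra) > 0) {
    by_id <- match(features$feature_id, spectra$title)
    hit <- which(!is.na(by_id))
    for (i in hit) {
      ms2[[i]] <- spectra$spectrum[[by_id[i]]]
      used[by_id[i]] <- TRUE
    }
    for (i in seq_len(nrow(features))) {
      if (!is.null(ms2[[i]])) next
      dppm <- abs(ppm_error(spectra$precursor_mz, features$mz[i]))
      ok <- !used & !is.na(dppm) & dppm <= tol_ppm
      has_rt <- !is.na(spectra$rt)
      ok[has_rt] <- ok[has_rt] & abs(spectra$rt[has_rt] - features$rt[i]) <= tol_rt_s
      if (any(ok)) {
        j <- which(ok)[which.min(dppm[ok])]
        ms2[[i]] <- spectra$spectrum[[j]]
        used[j] <- TRUE
      }
    }
  }
  features$ms2 <- ms2
  features
}

## ---- network export ---------------------------------------------------------

#' Write a node/edge network to GraphML or paired TSV tables
#'
#' Node and edge attributes round-trip: reading the files back reproduces the
#' node and edge sets and their attributes. Edge endpoint columns must be
#' named `from` and `to` and reference existing node ids.
#'
#' @param nodes Tibble with an `id` column (unique) plus attribute columns.
#' @param edges Tibble with `from`, `to` plus attribute columns.
#' @param path Output path; for `node_edge_tables` it is used as a prefix and
#'   `<path>_nodes.tsv` / `<path>_edges.tsv` are written.
#' @param format `"graphml"` or `"node_edge_tables"`.
#' @return Invisibly, the written file path(s).
#' @export
write_network <- function(nodes, edges, path,
                          format = c("graphml", "node_edge_tables")) {
  format <- match.arg(format)
  stopifnot(!anyDuplicated(nodes$id))
  dangling <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(dangling) > 0L) {
    bad <- edges[edges$from %in% dangling | edges$to %in% dangling, ][1L, ]
    stop("edge ", bad$from, " -> ", bad$to,
         " references a missing node", call. = FALSE)
  }
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(edges)) as.data.frame(edges) else
        data.frame(from = character(), to = character()),
      directed = FALSE,
      vertices = as.data.frame(dplyr::rename(nodes, name = "id"))
    )
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
  } else {
    paths <- paste0(path, c("_nodes.tsv", "_edges.tsv"))
    readr::write_tsv(nodes, paths[1])
    readr::write_tsv(edges, paths[2])
    invisible(paths)
  }
}

#' Read a network written by [write_network()]
#' @param path Path (or prefix for `node_edge_tables`).
#' @param format `"graphml"` or `"node_edge_tables"`.
#' @return List with tibbles `nodes` and `edges`.
#' @export
read_network <- function(path, format = c("graphml", "node_edge_tables")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble::as_tibble(igraph::as_data_frame(g, what = "vertices"))
    ## igraph surfaces the GraphML node key as an extra "id" attribute
    nodes <- dplyr::select(nodes, !dplyr::any_of("id")) |>
      dplyr::rename(id = "name")
    edges <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges"))
  } else {
    nodes <- readr::read_tsv(paste0(path, "_nodes.tsv"), show_col_types = FALSE)
    edges <- readr::read_tsv(paste0(path, "_edges.tsv"), show_col_types = FALSE)
  }
  list(nodes = nodes, edges = edges)
}

#' Export spectra to MGF (e.g. unannotated unknowns for external search)
#'
#' @param spectra Tibble like the output of [read_spectra()], or a feature
#'   table with `ms2` list-column (features without MS2 are skipped).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if ("ms2" %in% names(spectra)) {
    keep <- !vapply(spectra$ms2, is.null, logical(1))
    spectra <- tibble::tibble(
      spectrum_id = spectra$feature_id[keep],
      rt = spectra$rt[keep],
      spectrum = spectra$ms2[keep]
    )
  }
  for (i in seq_len(nrow(spectra))) {
    s <- spectra$spectrum[[i]]
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", spectra$spectrum_id[i]),
      paste0("PEPMASS=", format(s$precursor_mz, digits = 10)),
      if (!is.na(spectra$rt[i] %||% NA)) paste0("RTINSECONDS=", spectra$rt[i]),
      paste(format(s$peaks$mz, digits = 10, trim = TRUE),
            format(s$peaks$intensity, digits = 8, trim = TRUE)),
      "END IONS", ""
    ), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
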