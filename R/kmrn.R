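## Network 1: the knowledge-based metabolic reaction network. Known
## metabolites and their curated reaction pairs are expanded into predicted
## unknowns by applying biotransformation rules in silico (one or two steps),
## keeping pairs whose structures are Tanimoto-similar, and merging
## stereoisomers on the first InChIKey block.

#' Construct a metabolite node table
#'
#' @param node_id Unique id per node.
#' @param formula Elemental formula strings.
#' @param monoisotopic_mass Optional; computed from `formula` when missing.
#' @param inchikey First block (14 characters) or full InChIKey; truncated.
#' @param smiles Optional SMILES.
#' @param origin `"known"` or `"predicted"`.
#' @return Tibble of metabolite nodes.
#' @export
metabolite_nodes <- function(node_id, formula, monoisotopic_mass = NULL,
                             inchikey = NA_character_, smiles = NA_character_,
                             origin = "known") {
  if (is.null(monoisotopic_mass)) {
    monoisotopic_mass <- purrr::map_dbl(formula, formula_mass)
  }
  tibble::tibble(
    node_id = node_id, formula = formula,
    monoisotopic_mass = monoisotopic_mass,
    inchikey14 = substr(inchikey, 1L, 14L),
    smiles = smiles, origin = origin
  )
}

#' Default biotransformation rule table
#'
#' Signed formula deltas with their monoisotopic mass deltas. Covers common
#' phase I/II transformations (dephosphorylation, sulfation, glucuronidation,
#' dehydration, (de)hydrogenation, decarboxylation, (de)methylation). Any
#' table with the same columns (`label`, `formula_delta`, `mass_delta`,
#' `structural_rule`, `enzyme`) can be substituted, e.g. one imported from an
#' external biotransformation predictor.
#'
#' @return A tibble of transformation rules.
#' @export
default_rules <- function() {
  tibble::tribble(
    ~label,     ~formula_delta,
    "-HPO3",    "-HPO3",
    "+SO3",     "+SO3",
    "+C6H8O6",  "+C6H8O6",
    "-H2O",     "-H2O",
    "+H2",      "+H2",
    "-H2",      "-H2",
    "-CO2",     "-CO2",
    "+CH2",     "+CH2",
    "-CH2",     "-CH2"
  ) |>
    dplyr::mutate(
      mass_delta = purrr::map_dbl(.data$formula_delta, ~ formula_mass(parse_formula(.x))),
      structural_rule = NA_character_, enzyme = NA_character_
    )
}

#' Read a biotransformation rule table from TSV
#'
#' Expected columns: `label`, `formula_delta`; optional `mass_delta`
#' (recomputed and checked against the formula within 1e-4 Da),
#' `structural_rule`, `enzyme`.
#'
#' @param path TSV file path.
#' @return Rule tibble as from [default_rules()].
#' @export
read_rules <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("label", "formula_delta") %in% names(df)))
  if (anyDuplicated(df$label)) stop("duplicate rule labels", call. = FALSE)
  m <- purrr::map_dbl(df$formula_delta, ~ formula_mass(parse_formula(.x)))
  if ("mass_delta" %in% names(df)) {
    bad <- which(abs(df$mass_delta - m) > 1e-4)
    if (length(bad)) {
      stop("rule mass_delta inconsistent with formula_delta: ",
           paste(df$label[bad], collapse = ", "), call. = FALSE)
    }
  }
  df$mass_delta <- m
  if (!"structural_rule" %in% names(df)) df$structural_rule <- NA_character_
  if (!"enzyme" %in% names(df)) df$enzyme <- NA_character_
  df
}

apply_one_rule <- function(counts, rule_counts) {
  out <- combine_counts(counts, rule_counts)
  if (any(out < 0L)) return(NULL)
  if (!all(c("C", "H") %in% names(out))) return(NULL)
  out
}

#' Apply biotransformation rules to a substrate
#'
#' Generates candidate product metabolites by applying each rule to the
#' substrate's formula (and, for `max_steps = 2`, each rule again to every
#' step-1 product). Products with a negative element count are infeasible and
#' skipped; predicted products containing elements outside CHONPS are
#' dropped; products identical in formula to the substrate (e.g. `+H2` then
#' `-H2`) are dropped.
#'
#' @param substrate One-row tibble or list with `node_id`, `formula` (and
#'   optionally `smiles`).
#' @param rules Rule tibble ([default_rules()] layout).
#' @param max_steps 1 or 2 biotransformation steps.
#' @return Tibble of products: `node_id`, `formula`, `monoisotopic_mass`,
#'   `steps`, and list-column `path` of rule labels, plus `parent_id` of the
#'   step-1 intermediate (`NA` for 1-step products).
#' @export
apply_rules <- function(substrate, rules, max_steps = 2) {
  stopifnot(max_steps %in% c(1L, 2L))
  sub_counts <- parse_formula(substrate$formula)
  rule_counts <- purrr::map(rules$formula_delta, parse_formula)
  sub_formula <- counts_to_formula(sub_counts)

  step1 <- purrr::imap(rule_counts, function(rc, k) {
    out <- apply_one_rule(sub_counts, rc)
    if (is.null(out)) return(NULL)
    if (!all(names(out) %in% CHONPS)) return(NULL)
    f <- counts_to_formula(out)
    if (identical(f, sub_formula)) return(NULL)
    list(counts = out, formula = f, path = rules$label[k])
  })
  step1 <- purrr::compact(step1)

  mk_row <- function(formula, path, steps, parent_id) {
    tibble::tibble(
      node_id = paste0(substrate$node_id, "__", paste(path, collapse = "__")),
      formula = formula,
      monoisotopic_mass = formula_mass(formula),
      steps = steps, path = list(path), parent_id = parent_id
    )
  }
  out <- purrr::map(step1, ~ mk_row(.x$formula, .x$path, 1L, NA_character_))

  if (max_steps == 2L) {
    for (p1 in step1) {
      p1_id <- paste0(substrate$node_id, "__", p1$path)
      for (k in seq_along(rule_counts)) {
        out2 <- apply_one_rule(p1$counts, rule_counts[[k]])
        if (is.null(out2)) next
        if (!all(names(out2) %in% CHONPS)) next
        f2 <- counts_to_formula(out2)
        if (identical(f2, sub_formula)) next
        out <- c(out, list(mk_row(f2, c(p1$path, rules$label[k]), 2L, p1_id)))
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(node_id = character(), formula = character(),
                          monoisotopic_mass = numeric(), steps = integer(),
                          path = list(), parent_id = character()))
  }
  dplyr::bind_rows(out)
}

#' Tanimoto similarity between two SMILES (atom-pair 1024-bit fingerprints)
#'
#' Requires the ChemmineR package. Returns `NA` when either SMILES is missing
#' or fingerprinting fails.
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @return Tanimoto coefficient in `[0, 1]`, or `NA`.
#' @export
tanimoto_smiles <- function(smiles_a, smiles_b) {
  if (is.na(smiles_a) || is.na(smiles_b)) return(NA_real_)
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("ChemmineR is required for structure-based Tanimoto similarity",
         call. = FALSE)
  }
  res <- tryCatch({
    sdf <- suppressWarnings(
      ChemmineR::smiles2sdf(c(a = smiles_a, b = smiles_b))
    )
    ## desc2fp resolves its atom-pair dictionary via data(); load it for the
    ## unattached-namespace case
    fp_env <- new.env()
    utils::data("apfp", package = "ChemmineR", envir = fp_env)
    descnames <- as.character(fp_env$apfp$AP)[seq_len(1024)]
    fp <- ChemmineR::desc2fp(ChemmineR::sdf2ap(sdf), descnames = descnames)
    as.numeric(ChemmineR::fpSim(fp[1], fp[2], method = "Tanimoto"))
  }, error = function(e) NA_real_)
  res
}

#' Decide whether a substrate/product reaction pair is retained
#'
#' A pair is kept iff its Tanimoto structural similarity is strictly greater
#' than `threshold` (default 0.7). When structures are unavailable the pair
#' is kept only under `structureless_ok = TRUE` (recorded in provenance by
#' the caller); this supports rule tables that are purely formula-based.
#'
#' @param substrate,product Rows/lists with `smiles` (optional).
#' @param tanimoto Precomputed similarity; computed from SMILES when `NULL`.
#' @param threshold Strict retention threshold, default 0.7.
#' @param structureless_ok Keep pairs lacking structures.
#' @return List with `kept` (logical) and `tanimoto` (may be `NA`).
#' @export
filter_pair <- function(substrate, product, tanimoto = NULL, threshold = 0.7,
                        structureless_ok = FALSE) {
  if (is.null(tanimoto)) {
    sa <- substrate[["smiles"]] %||% NA_character_
    sb <- product[["smiles"]] %||% NA_character_
    tanimoto <- if (is.na(sa) || is.na(sb)) NA_real_ else tanimoto_smiles(sa, sb)
  }
  if (is.na(tanimoto)) {
    return(list(kept = isTRUE(structureless_ok), tanimoto = NA_real_))
  }
  list(kept = tanimoto > threshold, tanimoto = tanimoto)
}

#' Merge stereoisomeric nodes on the first InChIKey block
#'
#' Nodes sharing the first 14 InChIKey characters collapse into one node: the
#' lexicographically smallest `node_id` is kept, `known` origin wins over
#' `predicted`, and edges are rewired to the kept id (duplicates and
#' self-loops dropped). Nodes without an InChIKey are left untouched.
#'
#' @param nodes Node tibble ([metabolite_nodes()] layout).
#' @param edges Optional edge tibble with `node_a`, `node_b`.
#' @return If `edges` is `NULL`, the merged node tibble; otherwise a list
#'   with `nodes` and rewired `edges`.
#' @export
merge_stereoisomers <- function(nodes, edges = NULL) {
  keyed <- !is.na(nodes$inchikey14)
  mapping <- stats::setNames(nodes$node_id, nodes$node_id)
  if (any(keyed)) {
    groups <- split(which(keyed), nodes$inchikey14[keyed])
    for (idx in groups) {
      if (length(idx) < 2L) next
      ids <- nodes$node_id[idx]
      keep <- min(ids)
      mapping[ids] <- keep
      ki <- idx[ids == keep]
      if (any(nodes$origin[idx] == "known")) nodes$origin[ki] <- "known"
      sm <- nodes$smiles[idx]
      if (is.na(nodes$smiles[ki]) && any(!is.na(sm))) {
        nodes$smiles[ki] <- sm[!is.na(sm)][1L]
      }
    }
    nodes <- nodes[nodes$node_id == mapping[nodes$node_id], , drop = FALSE]
  }
  if (is.null(edges)) return(nodes)
  if (nrow(edges) > 0L) {
    edges$node_a <- unname(mapping[edges$node_a])
    edges$node_b <- unname(mapping[edges$node_b])
    edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
    key <- paste(pmin(edges$node_a, edges$node_b),
                 pmax(edges$node_a, edges$node_b), edges$label)
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  list(nodes = nodes, edges = edges)
}

#' Build the metabolic reaction network
#'
#' Expands every known metabolite through the rule table (up to two
#' biotransformation steps), retains substrate/product pairs that pass the
#' structural-similarity filter, merges stereoisomers, discards predicted
#' metabolites left without any edge, and classifies predicted nodes as
#' known-unknown (first InChIKey block present in `reference_keys`) or
#' unknown-unknown. Two-step products are linked both to the substrate
#' (2-step edge) and to the surviving intermediate (1-step edges).
#'
#' @param known_nodes Node tibble of known metabolites.
#' @param known_pairs Tibble `node_a`, `node_b`, `label` of curated reaction
#'   pairs between known nodes (may be empty).
#' @param rules Rule tibble; [default_rules()] by default.
#' @param max_steps Maximum in-silico steps (1 or 2).
#' @param tanimoto_threshold Strict retention threshold for in-silico pairs.
#' @param structureless_ok Keep pairs without structures (recorded in edge
#'   provenance as `in_silico_structureless`).
#' @param reference_keys Optional character vector of first InChIKey blocks
#'   used to classify predicted nodes.
#' @return An object of class `kmrn`: list with `nodes` and `edges` tibbles.
#' @export
build_kmrn <- function(known_nodes, known_pairs = NULL, rules = default_rules(),
                       max_steps = 2, tanimoto_threshold = 0.7,
                       structureless_ok = FALSE, reference_keys = NULL) {
  nodes <- dplyr::mutate(known_nodes, origin = "known")
  if (is.null(known_pairs)) {
    known_pairs <- tibble::tibble(node_a = character(), node_b = character(),
                                  label = character())
  }
  dangling <- setdiff(c(known_pairs$node_a, known_pairs$node_b), nodes$node_id)
  if (length(dangling) > 0L) {
    stop("known pairs reference missing nodes: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  edges <- known_pairs |>
    dplyr::mutate(
      mass_delta = nodes$monoisotopic_mass[match(.data$node_b, nodes$node_id)] -
        nodes$monoisotopic_mass[match(.data$node_a, nodes$node_id)],
      steps = 1L, provenance = "known_pair", tanimoto = NA_real_
    )

  pred_nodes <- list()
  pred_edges <- list()
  for (i in seq_len(nrow(known_nodes))) {
    sub <- known_nodes[i, ]
    prods <- apply_rules(sub, rules, max_steps = max_steps)
    if (nrow(prods) == 0L) next
    for (k in seq_len(nrow(prods))) {
      p <- prods[k, ]
      ## formula rules do not generate product structures, so the pair enters
      ## the similarity filter structureless; an adapter supplying product
      ## SMILES would flow through the same filter with a real Tanimoto value
      chk <- filter_pair(sub, list(smiles = p[["smiles"]] %||% NA_character_),
                         threshold = tanimoto_threshold,
                         structureless_ok = structureless_ok)
      if (!chk$kept) next
      prov <- if (is.na(chk$tanimoto)) "in_silico_structureless" else "in_silico"
      pred_nodes[[p$node_id]] <- tibble::tibble(
        node_id = p$node_id, formula = p$formula,
        monoisotopic_mass = p$monoisotopic_mass,
        inchikey14 = NA_character_, smiles = NA_character_,
        origin = "predicted"
      )
      path <- p$path[[1L]]
      if (p$steps == 1L) {
        pred_edges[[length(pred_edges) + 1L]] <- tibble::tibble(
          node_a = sub$node_id, node_b = p$node_id, label = path,
          mass_delta = rules$mass_delta[match(path, rules$label)],
          steps = 1L, provenance = prov, tanimoto = chk$tanimoto
        )
      } else {
        pred_edges[[length(pred_edges) + 1L]] <- tibble::tibble(
          node_a = sub$node_id, node_b = p$node_id,
          label = paste(path, collapse = "+"),
          mass_delta = sum(rules$mass_delta[match(path, rules$label)]),
          steps = 2L, provenance = prov, tanimoto = chk$tanimoto
        )
        if (p$parent_id %in% names(pred_nodes)) {
          pred_edges[[length(pred_edges) + 1L]] <- tibble::tibble(
            node_a = p$parent_id, node_b = p$node_id, label = path[2L],
            mass_delta = rules$mass_delta[match(path[2L], rules$label)],
            steps = 1L, provenance = prov, tanimoto = chk$tanimoto
          )
        }
      }
    }
  }
  if (length(pred_nodes) > 0L) nodes <- dplyr::bind_rows(nodes, dplyr::bind_rows(pred_nodes))
  if (length(pred_edges) > 0L) edges <- dplyr::bind_rows(edges, dplyr::bind_rows(pred_edges))

  merged <- merge_stereoisomers(nodes, edges)
  nodes <- merged$nodes
  edges <- merged$edges
  key <- paste(pmin(edges$node_a, edges$node_b),
               pmax(edges$node_a, edges$node_b), edges$label)
  edges <- edges[!duplicated(key), , drop = FALSE]

  deg_ids <- c(edges$node_a, edges$node_b)
  keep <- nodes$origin == "known" | nodes$node_id %in% deg_ids
  nodes <- nodes[keep, , drop = FALSE]
  edges <- edges[edges$node_a %in% nodes$node_id &
                   edges$node_b %in% nodes$node_id, , drop = FALSE]

  nodes$klass <- dplyr::case_when(
    nodes$origin == "known" ~ "known-known",
    !is.na(nodes$inchikey14) & nodes$inchikey14 %in% (reference_keys %||% character(0)) ~ "known-unknown",
    TRUE ~ "unknown-unknown"
  )
  structure(list(nodes = nodes, edges = dplyr::as_tibble(edges)), class = "kmrn")
}

#' @export
print.kmrn <- function(x, ...) {
  cat("<kmrn> metabolic reaction network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$origin == "known"), "known /",
      sum(x$nodes$origin == "predicted"), "predicted ),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Reaction-paired neighbors of a node
#' @param kmrn A `kmrn` object.
#' @param node_id Node id.
#' @return Tibble of edges incident to `node_id` with a `neighbor` column.
#' @export
kmrn_neighbors <- function(kmrn, node_id) {
  e <- kmrn$edges
  hit <- e$node_a == node_id | e$node_b == node_id
  e <- e[hit, , drop = FALSE]
  e$neighbor <- ifelse(e$node_a == node_id, e$node_b, e$node_a)
  e
}

#' Export a reaction network via [write_network()]
#' @param kmrn A `kmrn` object.
#' @inheritParams write_network
#' @return Invisibly, the written path(s).
#' @export
write_kmrn <- function(kmrn, path, format = "graphml") {
  nodes <- dplyr::rename(kmrn$nodes, id = "node_id") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.character), ~ tidyr::replace_na(.x, "")))
  edges <- dplyr::rename(kmrn$edges, from = "node_a", to = "node_b") |>
    dplyr::mutate(tanimoto = tidyr::replace_na(.data$tanimoto, -1))
  write_network(nodes, edges, path, format)
}
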