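# Readers and writers for the four text formats the pipeline touches.
# All files are UTF-8, tab-delimited; lines starting with '#' are ignored.

read_table_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' Read a gene-by-sample expression matrix
#'
#' Tab-separated text: first row holds sample IDs, first column gene IDs,
#' body numeric. Row and column order are preserved.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (genes x samples) passing [validate_expression()].
#' @export
read_expression <- function(path) {
  lines <- read_table_lines(path)
  if (length(lines) < 2) abort(sprintf("%s: expected a header plus gene rows", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  samples <- header[-1]
  body <- fields[-1]
  genes <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(genes)) {
    abort(sprintf("%s: duplicate gene ID '%s'", path, genes[duplicated(genes)][1]))
  }
  if (anyDuplicated(samples)) {
    abort(sprintf("%s: duplicate sample ID '%s'", path, samples[duplicated(samples)][1]))
  }
  n <- length(samples)
  vals <- matrix(NA_real_, nrow = length(body), ncol = n,
                 dimnames = list(genes, samples))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n + 1) {
      abort(sprintf("%s: row for gene '%s' has %d value(s), expected %d",
                    path, genes[i], length(row) - 1L, n))
    }
    x <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(x)) {
      j <- which(is.na(x))[1]
      abort(sprintf("%s: non-numeric cell '%s' at gene '%s', sample '%s'",
                    path, row[j + 1], genes[i], samples[j]))
    }
    vals[i, ] <- x
  }
  validate_expression(vals)
  vals
}

#' Write an expression matrix
#'
#' @param expr Numeric matrix, genes x samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  body <- apply(expr, 1, function(x) paste(format(x, trim = TRUE, digits = 15),
                                           collapse = "\t"))
  writeLines(paste(rownames(expr), body, sep = "\t"), con)
  invisible(path)
}

#' Default phenotype label aliases
#'
#' Maps field-typical label strings to the canonical `NORMAL`/`CASE` pair,
#' e.g. normal-glucose-tolerance (`NGT`) samples to `NORMAL` and diabetic
#' (`DM`, `T2DM`) samples to `CASE`. Matching is case-insensitive.
#'
#' @return Named character vector: alias -> canonical label.
#' @export
default_label_aliases <- function() {
  c(NGT = "NORMAL", control = "NORMAL", normal = "NORMAL",
    DM = "CASE", T2DM = "CASE", case = "CASE", disease = "CASE")
}

#' Read phenotype labels
#'
#' Two-column tab-separated text (`sample_id`, label). Labels are normalized
#' to `NORMAL`/`CASE` through `aliases`; anything unmapped is an error, so a
#' cohort with intermediate phenotypes (e.g. glucose-intolerant subjects)
#' must be filtered or aliased explicitly before analysis.
#'
#' @param path Path to a TSV file.
#' @param aliases Named character vector mapping label strings to
#'   `NORMAL`/`CASE`; see [default_label_aliases()].
#' @param expr Optional expression matrix to cross-check sample IDs.
#' @return A tibble with columns `sample_id`, `label`.
#' @export
read_phenotypes <- function(path, aliases = default_label_aliases(), expr = NULL) {
  lines <- read_table_lines(path)
  if (!length(lines)) abort(sprintf("%s: empty phenotype file", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad)) {
    abort(sprintf("%s: line %d has fewer than 2 columns", path, bad[1]))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  raw <- vapply(fields, `[[`, character(1), 2)
  lut <- c(aliases, stats::setNames(c("NORMAL", "CASE"), c("NORMAL", "CASE")))
  names(lut) <- toupper(names(lut))
  canon <- unname(lut[toupper(raw)])
  if (anyNA(canon)) {
    abort(sprintf("%s: unknown phenotype label '%s'; accepted: %s",
                  path, raw[is.na(canon)][1],
                  paste(names(lut), collapse = ", ")))
  }
  out <- phenotype_labels(ids, canon)
  if (!is.null(expr)) validate_phenotypes(out, expr)
  out
}

#' Write phenotype labels
#'
#' @param labels Tibble with columns `sample_id`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(labels, path) {
  validate_phenotypes(labels)
  writeLines(paste(labels$sample_id, labels$label, sep = "\t"), path)
  invisible(path)
}

#' Read an interaction network from a two-column edge list
#'
#' Self-loops are dropped and duplicate/reversed edges collapsed; a summary
#' of dropped records is messaged.
#'
#' @param path Path to a two-column TSV edge list of gene IDs.
#' @return An undirected simple [igraph::graph].
#' @export
read_network <- function(path) {
  lines <- read_table_lines(path)
  if (!length(lines)) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad)) {
    abort(sprintf("%s: line %d has fewer than 2 columns", path, bad[1]))
  }
  ppi_network(cbind(vapply(fields, `[[`, character(1), 1),
                    vapply(fields, `[[`, character(1), 2)))
}

#' Write a network as a two-column edge list
#'
#' Edges are written with lexicographically ordered endpoints and sorted,
#' so write-read round trips are canonical.
#'
#' @param net An [igraph::graph].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net)
  if (nrow(el)) {
    el <- t(apply(el, 1, sort))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  } else {
    writeLines(character(0), path)
  }
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One pathway per line: name, description, then member gene IDs, all
#' tab-separated.
#'
#' @param path Path to a GMT file.
#' @return A [pathway_collection()]: named list of gene-ID vectors with a
#'   `description` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- read_table_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    abort(sprintf("%s: line %d has no genes (GMT needs name, description, genes)",
                  path, bad[1]))
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort(sprintf("%s: duplicate pathway name '%s'", path, nm[duplicated(nm)][1]))
  }
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  pathway_collection(sets, descriptions = desc)
}

#' Write gene sets in GMT format
#'
#' @param sets A [pathway_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write discovered modules as JSON plus a TSV summary
#'
#' The JSON document is authoritative (it retains members and the growth
#' trace); the TSV is a flat summary (module_id, seed, size, disa and, when
#' present, score).
#'
#' @param modules Module tibble from [discover_modules()] or
#'   [score_modules()].
#' @param json_path,tsv_path Output paths; either may be `NULL` to skip.
#' @return The module tibble, invisibly.
#' @export
write_modules <- function(modules, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    recs <- purrr::pmap(modules, function(module_id, seed, members, disa, trace, ...) {
      extra <- list(...)
      c(list(module_id = module_id, seed = seed, members = members, disa = disa,
             trace = as.data.frame(trace)),
        extra[intersect(names(extra), c("score", "enriched_pathways"))])
    })
    jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    flat <- dplyr::mutate(
      dplyr::select(modules, dplyr::any_of(c("module_id", "seed", "disa", "score"))),
      size = lengths(modules$members), .after = "seed")
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(modules)
}
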