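# Greedy seed growth: starting from a differentially expressed seed gene,
# repeatedly add the network neighbour that minimizes the discriminative
# area of the enlarged module.

#' Discovery configuration
#'
#' @param delta Termination threshold: growth stops once the module's
#'   discriminative area falls below `delta`. Default 0.001.
#' @param disa_filter Modules with discriminative area above this value are
#'   discarded after growth. Default 0.2.
#' @param max_module_size Hard cap on module size. Default 50.
#' @param require_improvement Stop when the best neighbour no longer
#'   strictly lowers the discriminative area (default `TRUE`). Setting this
#'   `FALSE` together with a large `max_module_size` recovers growth ruled
#'   by `delta` alone.
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(delta = 0.001, disa_filter = 0.2,
                             max_module_size = 50, require_improvement = TRUE) {
  if (!(delta > 0 && delta < disa_filter && disa_filter <= 1)) {
    abort("Need 0 < delta < disa_filter <= 1.")
  }
  if (max_module_size < 1) abort("max_module_size must be a positive integer.")
  structure(list(delta = delta, disa_filter = disa_filter,
                 max_module_size = as.integer(max_module_size),
                 require_improvement = isTRUE(require_improvement)),
            class = "discovery_config")
}

# named list gene -> character vector of neighbours
adjacency_list <- function(net) {
  adj <- igraph::as_adj_list(net, mode = "all")
  lapply(adj, function(v) igraph::V(net)$name[as.integer(v)])
}

# group means and sample SDs of each row of a matrix of activity vectors
group_row_stats <- function(acts, cols) {
  m <- rowMeans(acts[, cols, drop = FALSE])
  s2 <- rowSums((acts[, cols, drop = FALSE] - m)^2) / (length(cols) - 1)
  list(mu = m, sigma = sqrt(s2))
}

#' Grow a discriminative module from a seed gene
#'
#' Starting from `M = {seed}`, each step evaluates the discriminative area
#' of `M + {g}` for every network neighbour `g` of the current members and
#' adds the minimizer. Growth stops when the area falls below
#' `cfg$delta`, when no neighbour remains, when the best neighbour no
#' longer strictly improves (if `cfg$require_improvement`), or at
#' `cfg$max_module_size`. Ties within 1e-12 break lexicographically on gene
#' ID, so growth is deterministic. Neighbours whose addition gives a
#' degenerate (zero within-group variance) fit are skipped.
#'
#' @param seed Seed gene ID (must be in the network and the matrix).
#' @param net An [igraph::graph] over gene IDs.
#' @param expr Numeric matrix, genes x samples (typically z-scored).
#' @param labels Phenotype tibble.
#' @param cfg A [discovery_config()].
#' @param adj Optional precomputed adjacency list (internal reuse).
#' @return An object of class `disa_module`: list with `seed`, `members`
#'   (in addition order), `disa`, and `trace` (tibble of accepted
#'   additions: `gene`, `disa` after the addition).
#' @export
grow_module <- function(seed, net, expr, labels, cfg = discovery_config(),
                        adj = NULL) {
  seed <- as.character(seed)
  if (!seed %in% igraph::V(net)$name) abort(paste0("Seed not in network: ", seed))
  if (!seed %in% rownames(expr)) abort(paste0("Seed not in expression matrix: ", seed))
  if (is.null(adj)) adj <- adjacency_list(net)
  grp <- split_samples(labels, expr)
  nn <- length(grp$normal); nc <- length(grp$case)

  members <- seed
  act_sum <- expr[seed, ]
  cur <- tryCatch(disa(expr, labels, members),
                  modisa_degenerate_fit = function(e) 1)
  seed_disa <- cur
  trace <- list()

  repeat {
    if (cur < cfg$delta) break
    if (length(members) >= cfg$max_module_size) break
    cands <- setdiff(unique(unlist(adj[members], use.names = FALSE)), members)
    cands <- cands[cands %in% rownames(expr)]
    if (!length(cands)) break
    k1 <- length(members) + 1
    acts <- sweep(expr[cands, , drop = FALSE], 2, act_sum, "+") / sqrt(k1)
    sn <- group_row_stats(acts, grp$normal)
    sc <- group_row_stats(acts, grp$case)
    ok <- sn$sigma > 0 & sc$sigma > 0
    if (!any(ok)) break
    vals <- rep(NA_real_, length(cands))
    vals[ok] <- gaussian_overlap(sn$mu[ok], sn$sigma[ok], sc$mu[ok], sc$sigma[ok])
    best_val <- min(vals, na.rm = TRUE)
    tied <- cands[!is.na(vals) & vals <= best_val + 1e-12]
    best <- sort(tied)[1]
    best_val <- vals[match(best, cands)]
    if (cfg$require_improvement && best_val >= cur) break
    members <- c(members, best)
    act_sum <- act_sum + expr[best, ]
    cur <- best_val
    trace[[length(trace) + 1]] <- list(gene = best, disa = best_val)
  }

  structure(
    list(seed = seed, members = members, disa = cur, seed_disa = seed_disa,
         trace = if (length(trace)) dplyr::bind_rows(lapply(trace, as_tibble))
                 else tibble(gene = character(), disa = numeric())),
    class = "disa_module")
}

#' @export
print.disa_module <- function(x, ...) {
  cat(sprintf("Discriminative module (seed %s): %d gene(s), disa = %.4g\n",
              x$seed, length(x$members), x$disa))
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Grow and filter modules for a set of seeds
#'
#' Grows one module per (deduplicated) seed, removes modules whose
#' discriminative area exceeds `cfg$disa_filter`, and sorts survivors by
#' ascending area (ties by seed ID).
#'
#' @param seeds Character vector of seed gene IDs.
#' @param net,expr,labels,cfg As in [grow_module()].
#' @return A tibble with one row per surviving module: `module_id`, `seed`,
#'   `size`, `disa`, plus list-columns `members` and `trace`.
#' @export
discover_modules <- function(seeds, net, expr, labels, cfg = discovery_config()) {
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) abort("`seeds` must be non-empty.")
  adj <- adjacency_list(net)
  mods <- purrr::map(seeds, grow_module, net = net, expr = expr,
                     labels = labels, cfg = cfg, adj = adj)
  out <- tibble(
    module_id = paste0("M_", seeds),
    seed = seeds,
    size = purrr::map_int(mods, ~ length(.x$members)),
    disa = purrr::map_dbl(mods, "disa"),
    members = purrr::map(mods, "members"),
    trace = purrr::map(mods, "trace")
  )
  out <- out[out$disa <= cfg$disa_filter, , drop = FALSE]
  out[order(out$disa, out$seed), , drop = FALSE]
}

#' Pearson correlations between module activity vectors
#'
#' Redundancy diagnostic: modules grown from different seeds often track
#' one another (activity correlation above 0.6 is typical for surviving
#' modules on strongly separated data), so high correlation flags
#' interchangeable candidates rather than independent signals.
#'
#' @param modules Module tibble from [discover_modules()].
#' @param expr Numeric matrix, genes x samples.
#' @return Symmetric correlation matrix (module_id x module_id); rows with
#'   zero-variance activity give `NA` off-diagonal entries with a warning.
#' @export
activity_correlations <- function(modules, expr) {
  if (!nrow(modules)) abort("Need at least one module.")
  acts <- t(vapply(modules$members, function(m) module_activity(expr, m),
                   numeric(ncol(expr))))
  rownames(acts) <- modules$module_id
  zero <- apply(acts, 1, function(v) var(v) == 0)
  cc <- suppressWarnings(cor(t(acts)))
  if (any(zero)) {
    warn(paste0("Zero-variance activity for module(s): ",
                paste(modules$module_id[zero], collapse = ", ")))
    cc[zero, ] <- NA_real_
    cc[, zero] <- NA_real_
  }
  diag(cc) <- 1
  cc
}
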