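# Independent oracles and small fixture builders shared across tests.
# Each oracle deliberately uses a different route than the implementation
# it checks.

# Overlap of two normal densities by numerical integration. Crossing points
# are isolated by a sign scan plus uniroot on the log-density difference
# (no closed-form root algebra), then each smooth segment is integrated
# adaptively.
overlap_oracle <- function(m1, s1, m2, s2) {
  lo <- min(m1 - 12 * s1, m2 - 12 * s2)
  hi <- max(m1 + 12 * s1, m2 + 12 * s2)
  g <- function(x) dnorm(x, m1, s1, log = TRUE) - dnorm(x, m2, s2, log = TRUE)
  grid <- seq(lo, hi, length.out = 4001)
  sg <- sign(g(grid))
  idx <- which(sg[-1] * sg[-length(sg)] < 0)
  roots <- vapply(idx, function(i)
    uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-14)$root, numeric(1))
  pts <- sort(unique(c(lo, roots, m1, m2, hi)))
  f <- function(x) pmin(dnorm(x, m1, s1), dnorm(x, m2, s2))
  sum(vapply(seq_len(length(pts) - 1), function(i)
    integrate(f, pts[i], pts[i + 1], rel.tol = 1e-11,
              subdivisions = 1000L, stop.on.error = FALSE)$value, numeric(1)))
}

# Benjamini-Hochberg step-up by direct definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (r in m:1) {
    running <- min(running, p[ord[r]] * m / r)
    adj[ord[r]] <- running
  }
  pmin(adj, 1)
}

# Upper-tail hypergeometric probability as the explicit combinatorial sum.
hyper_oracle <- function(n, n2, n1, s) {
  if (s == 0) return(1)
  i <- s:min(n1, n2)
  sum(choose(n2, i) * choose(n - n2, n1 - i)) / choose(n, n1)
}

# Bidirectional best-match average similarity, plain loops.
sim_oracle <- function(ps1, ps2) {
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  tot <- 0
  for (a in ps1) tot <- tot + max(vapply(ps2, jac, numeric(1), a = a))
  for (b in ps2) tot <- tot + max(vapply(ps1, jac, numeric(1), a = b))
  tot / (length(ps1) + length(ps2))
}

# random pathway collection over a gene alphabet
random_collection <- function(n_sets, genes, min_size = 2, max_size = 6) {
  sets <- lapply(seq_len(n_sets), function(i)
    sample(genes, sample(min_size:max_size, 1)))
  names(sets) <- paste0("S", seq_len(n_sets))
  pathway_collection(sets)
}

# tiny labelled two-group expression fixture
toy_dataset <- function(n_genes = 6, n_per_group = 5, shift_genes = character(),
                        shift = 0, seed = 42) {
  withr::with_seed(seed, {
    genes <- paste0("g", seq_len(n_genes))
    samples <- c(paste0("n", seq_len(n_per_group)),
                 paste0("c", seq_len(n_per_group)))
    expr <- matrix(rnorm(n_genes * 2 * n_per_group), nrow = n_genes,
                   dimnames = list(genes, samples))
    labels <- phenotype_labels(samples, rep(c("NORMAL", "CASE"),
                                            each = n_per_group))
    if (length(shift_genes)) {
      expr[shift_genes, labels$sample_id[labels$label == "CASE"]] <-
        expr[shift_genes, labels$sample_id[labels$label == "CASE"]] + shift
    }
    list(expr = expr, labels = labels)
  })
}
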