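# The discriminative-area statistic.
#
# A module's activity in each sample is the sum of its member genes'
# expression divided by sqrt(k). Under the working assumption that activity
# is Gaussian within each phenotype group, the module's discriminative area
# is the common area under the two fitted normal densities: 1 when the
# groups are indistinguishable, -> 0 as they separate.

#' Module activity vector
#'
#' Per-sample activity of a gene set: the sum of member expression values
#' divided by `sqrt(k)`, `k` the module size. The `1/sqrt(k)` scaling keeps
#' the variance of a sum of independent unit-variance genes at 1, so modules
#' of different sizes are comparable.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param members Character vector of member gene IDs (k >= 1).
#' @return Named numeric vector, one activity per sample.
#' @export
module_activity <- function(expr, members) {
  members <- as.character(members)
  missing <- setdiff(members, rownames(expr))
  if (length(missing)) {
    abort(paste0("Module member(s) absent from expression matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  if (!length(members)) abort("A module needs at least one member.")
  colSums(expr[members, , drop = FALSE]) / sqrt(length(members))
}

#' Fit per-group normal distributions to an activity vector
#'
#' @param activity Named numeric vector of per-sample activities.
#' @param labels Phenotype tibble (`sample_id`, `label`).
#' @return An object of class `normal_fit_pair`: list with `mu_n`,
#'   `sigma_n` (NORMAL group) and `mu_c`, `sigma_c` (CASE group), sample
#'   SDs with denominator n - 1.
#' @export
fit_group_normals <- function(activity, labels) {
  validate_phenotypes(labels)
  grp <- split_samples(labels)
  an <- activity[grp$normal]
  ac <- activity[grp$case]
  if (anyNA(an) || anyNA(ac)) {
    abort("Activity vector is missing values for some labelled samples.")
  }
  fit <- structure(
    list(mu_n = mean(an), sigma_n = sd(an), mu_c = mean(ac), sigma_c = sd(ac)),
    class = "normal_fit_pair")
  if (fit$sigma_n == 0 || fit$sigma_c == 0) {
    abort("Degenerate fit: zero activity variance within a group.",
          class = "modisa_degenerate_fit")
  }
  fit
}

#' @export
print.normal_fit_pair <- function(x, ...) {
  cat(sprintf("Group normal fits: NORMAL N(%.4g, %.4g), CASE N(%.4g, %.4g)\n",
              x$mu_n, x$sigma_n, x$mu_c, x$sigma_c))
  cat(sprintf("Overlap area: %.4g\n", overlap_area(x)))
  invisible(x)
}

#' Overlap area of two normal densities
#'
#' Computes `integral of min(phi(x; mu1, sd1), phi(x; mu2, sd2)) dx` in
#' closed form. With equal SDs the densities cross once at the midpoint and
#' the overlap is `2 * pnorm(-|mu1 - mu2| / (2 * sd))`. With unequal SDs the
#' log-density equality is a quadratic with two real roots; the overlap sums
#' Gaussian CDF segments taking the lower density on each interval.
#' Ill-conditioned root arithmetic falls back to adaptive quadrature.
#' Vectorized over all four parameters.
#'
#' @param mu1,sd1 Mean and SD of the first normal (SD > 0).
#' @param mu2,sd2 Mean and SD of the second normal (SD > 0).
#' @return Overlap area(s) in `[0, 1]`.
#' @export
gaussian_overlap <- function(mu1, sd1, mu2, sd2) {
  n <- max(length(mu1), length(sd1), length(mu2), length(sd2))
  mu1 <- rep_len(mu1, n); sd1 <- rep_len(sd1, n)
  mu2 <- rep_len(mu2, n); sd2 <- rep_len(sd2, n)
  if (any(sd1 <= 0) || any(sd2 <= 0)) abort("Standard deviations must be positive.")
  out <- numeric(n)
  eq <- abs(sd1 - sd2) < 1e-12
  if (any(eq)) {
    out[eq] <- 2 * pnorm(-abs(mu1[eq] - mu2[eq]) / (2 * sd1[eq]))
  }
  for (i in which(!eq)) {
    out[i] <- overlap_unequal(mu1[i], sd1[i], mu2[i], sd2[i])
  }
  pmin(pmax(out, 0), 1)
}

# closed-form overlap for sd1 != sd2: solve the log-density quadratic
overlap_unequal <- function(mu1, sd1, mu2, sd2) {
  a <- 1 / (2 * sd2^2) - 1 / (2 * sd1^2)
  b <- mu1 / sd1^2 - mu2 / sd2^2
  cc <- mu2^2 / (2 * sd2^2) - mu1^2 / (2 * sd1^2) + log(sd2 / sd1)
  disc <- b^2 - 4 * a * cc
  if (!is.finite(disc) || disc < 0) {
    return(overlap_quadrature(mu1, sd1, mu2, sd2))
  }
  r <- sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))
  mid <- mean(r)
  # whichever density is lower between the roots contributes its inner
  # mass; compare on the log scale (densities underflow when the roots are
  # far out in both tails)
  d1_lower <- dnorm(mid, mu1, sd1, log = TRUE) < dnorm(mid, mu2, sd2, log = TRUE)
  if (d1_lower) {
    inner <- pnorm(r[2], mu1, sd1) - pnorm(r[1], mu1, sd1)
    outer <- pnorm(r[1], mu2, sd2) + pnorm(r[2], mu2, sd2, lower.tail = FALSE)
  } else {
    inner <- pnorm(r[2], mu2, sd2) - pnorm(r[1], mu2, sd2)
    outer <- pnorm(r[1], mu1, sd1) + pnorm(r[2], mu1, sd1, lower.tail = FALSE)
  }
  inner + outer
}

# quadrature fallback; integrates piecewise with breaks at both means so
# narrow peaks are never skipped
overlap_quadrature <- function(mu1, sd1, mu2, sd2) {
  lo <- min(mu1 - 12 * sd1, mu2 - 12 * sd2)
  hi <- max(mu1 + 12 * sd1, mu2 + 12 * sd2)
  pts <- unique(sort(c(lo, mu1, mu2, hi)))
  f <- function(x) pmin(dnorm(x, mu1, sd1), dnorm(x, mu2, sd2))
  sum(vapply(seq_len(length(pts) - 1), function(i) {
    stats::integrate(f, pts[i], pts[i + 1], rel.tol = 1e-10,
                     subdivisions = 1000L)$value
  }, numeric(1)))
}

#' Overlap area of a fitted group pair
#'
#' @param fit A `normal_fit_pair` from [fit_group_normals()].
#' @return Overlap area in `[0, 1]`.
#' @export
overlap_area <- function(fit) {
  stopifnot(inherits(fit, "normal_fit_pair"))
  gaussian_overlap(fit$mu_n, fit$sigma_n, fit$mu_c, fit$sigma_c)
}

#' Discriminative area of a gene set
#'
#' Convenience composition: fit group normals to the module activity and
#' return their overlap area.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param labels Phenotype tibble.
#' @param members Character vector of member gene IDs.
#' @return Discriminative area in `[0, 1]`.
#' @export
disa <- function(expr, labels, members) {
  overlap_area(fit_group_normals(module_activity(expr, members), labels))
}
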