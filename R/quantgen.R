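# Heritability, transgressive segregation, normality and correlation
# structure of CLS phenotypes.

#' Environmental variance from parental replicates
#'
#' The parents of the cross are genetically uniform, so the spread of
#' their replicate measurements is purely environmental. V_E is the
#' degrees-of-freedom-weighted (pooled) within-parent sample variance.
#'
#' @param parent_replicates List of numeric vectors, one per parent, each
#'   with at least 2 replicate values.
#' @return Pooled environmental variance (numeric scalar).
#' @examples
#' pooled_parental_variance(list(c(1, 2, 3), c(4, 6, 8)))
#' @export
pooled_parental_variance <- function(parent_replicates) {
  if (!is.list(parent_replicates)) parent_replicates <- list(parent_replicates)
  ns <- lengths(parent_replicates)
  if (any(ns < 2L))
    stop("every parent needs at least 2 replicates", call. = FALSE)
  vars <- vapply(parent_replicates, stats::var, numeric(1))
  sum((ns - 1L) * vars) / sum(ns - 1L)
}

#' Broad-sense heritability
#'
#' `H2 = (V_P - V_E) / V_P`, with V_P the phenotypic variance among
#' segregants and V_E the environmental variance (e.g. from
#' [pooled_parental_variance()]). In a haploid cross analysed one
#' condition at a time there is no dominance and no gene-by-environment
#' term, so the genetic variance is additive plus epistatic. The
#' estimate is clipped to `[0, 1]`; the unclipped value is kept in the
#' `raw` attribute.
#'
#' @param segregant_values Numeric phenotypes of >= 10 segregants.
#' @param V_E Environmental variance (>= 0).
#' @return H2 in `[0, 1]` with attributes `raw`, `V_P`, `V_G`, `V_E`.
#' @export
broad_sense_h2 <- function(segregant_values, V_E) {
  segregant_values <- segregant_values[is.finite(segregant_values)]
  if (length(segregant_values) < 10L)
    stop("at least 10 segregants are required", call. = FALSE)
  .check_scalar_number(V_E, "V_E", lower = 0)
  V_P <- stats::var(segregant_values)
  if (V_P == 0) stop("segregant variance is zero", call. = FALSE)
  raw <- (V_P - V_E) / V_P
  h2 <- min(max(raw, 0), 1)
  structure(h2, raw = raw, V_P = V_P, V_G = V_P - V_E, V_E = V_E)
}

#' Narrow-sense heritability by parent-offspring regression
#'
#' Ordinary least-squares regression of the segregant-population mean on
#' the midparent value, pooling points across traits and conditions; the
#' slope estimates `h2 = V_A / V_P`, the additive fraction of phenotypic
#' variance.
#'
#' @param midparent Numeric vector of midparent values (one per
#'   trait x condition point).
#' @param offspring_mean Matching segregant-population means.
#' @return A `narrow_h2` list: `h2` (slope), `intercept`, `se`,
#'   `r_squared`, `n`, and the underlying `lm` fit.
#' @export
narrow_sense_h2 <- function(midparent, offspring_mean) {
  keep <- is.finite(midparent) & is.finite(offspring_mean)
  midparent <- midparent[keep]; offspring_mean <- offspring_mean[keep]
  if (length(midparent) < 3L)
    stop("at least 3 (midparent, offspring) points are required",
         call. = FALSE)
  if (stats::var(midparent) == 0)
    stop("midparent values have zero variance", call. = FALSE)
  fit <- stats::lm(offspring_mean ~ midparent)
  co <- summary(fit)$coefficients
  structure(list(h2 = unname(co["midparent", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 se = unname(co["midparent", "Std. Error"]),
                 r_squared = summary(fit)$r.squared,
                 n = length(midparent), fit = fit),
            class = "narrow_h2")
}

#' @export
print.narrow_h2 <- function(x, ...) {
  cat(sprintf("Parent-offspring regression: h2 = %.3f (SE %.3f), R^2 = %.3f, n = %d\n",
              x$h2, x$se, x$r_squared, x$n))
  invisible(x)
}

#' Heritability report for one trait and condition
#'
#' Convenience wrapper combining [pooled_parental_variance()] and
#' [broad_sense_h2()] into a variance-component table.
#'
#' @param segregant_values Numeric phenotypes of the segregants.
#' @param parent_replicates List of per-parent replicate vectors.
#' @return A `heritability_est` list with `V_P`, `V_E`, `V_G`, `H2`
#'   (clipped) and `H2_raw`.
#' @export
heritability <- function(segregant_values, parent_replicates) {
  V_E <- pooled_parental_variance(parent_replicates)
  h2 <- broad_sense_h2(segregant_values, V_E)
  structure(list(V_P = attr(h2, "V_P"), V_E = V_E, V_G = attr(h2, "V_G"),
                 H2 = as.numeric(h2), H2_raw = attr(h2, "raw")),
            class = "heritability_est")
}

#' @export
print.heritability_est <- function(x, ...) {
  cat(sprintf("V_P = %.4f, V_E = %.4f, V_G = %.4f, H2 = %.3f\n",
              x$V_P, x$V_E, x$V_G, x$H2))
  invisible(x)
}

#' Transgressive segregation summary
#'
#' Counts segregants whose phenotype exceeds the best parent by more than
#' `k` parental standard deviations (transgressive high) or falls below
#' the worst parent by the same margin (transgressive low).
#'
#' @param segregant_values Numeric segregant phenotypes.
#' @param parent_means Numeric vector of the two parental means.
#' @param parent_sd Parental (environmental) standard deviation (>= 0).
#' @param k SD multiplier defining the margin (default 2).
#' @return List with `n_high`, `n_low`, `frac_high`, `frac_low`, `n`,
#'   and the thresholds used.
#' @export
transgression_summary <- function(segregant_values, parent_means, parent_sd,
                                  k = 2) {
  .check_scalar_number(parent_sd, "parent_sd", lower = 0)
  .check_scalar_number(k, "k", lower = 0)
  x <- segregant_values[is.finite(segregant_values)]
  hi_thr <- max(parent_means) + k * parent_sd
  lo_thr <- min(parent_means) - k * parent_sd
  list(n_high = sum(x > hi_thr), n_low = sum(x < lo_thr),
       frac_high = mean(x > hi_thr), frac_low = mean(x < lo_thr),
       n = length(x), high_threshold = hi_thr, low_threshold = lo_thr)
}

#' Pairwise trait or condition correlations
#'
#' Complete-case Pearson correlation for every pair of columns, with the
#' number of complete pairs and the correlation-test p-value. Pairs in
#' which either vector is constant are reported as `NA` with a reason.
#'
#' @param mat Numeric matrix or data frame (strains x conditions/traits).
#' @return A `trait_correlations` list of matrices `r`, `n`, `p`, plus a
#'   long-format data frame `pairs` (including a `note` for degenerate
#'   pairs).
#' @export
trait_correlations <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 columns", call. = FALSE)
  k <- ncol(mat)
  nm <- colnames(mat)
  if (is.null(nm)) nm <- paste0("V", seq_len(k))
  r <- n <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1
  pairs <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- is.finite(mat[, i]) & is.finite(mat[, j])
    note <- NA_character_
    if (sum(ok) < 3L) {
      note <- "fewer than 3 complete pairs"
    } else if (stats::var(mat[ok, i]) == 0 || stats::var(mat[ok, j]) == 0) {
      note <- "constant vector; correlation undefined"
    } else {
      ct <- stats::cor.test(mat[ok, i], mat[ok, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
    n[i, j] <- n[j, i] <- sum(ok)
    pairs[[length(pairs) + 1L]] <- data.frame(
      a = nm[i], b = nm[j], r = r[i, j], n = sum(ok), p = p[i, j],
      note = note, stringsAsFactors = FALSE)
  }
  diag(n) <- colSums(is.finite(mat))
  structure(list(r = r, n = n, p = p, pairs = do.call(rbind, pairs)),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, ...) {
  cat("Pairwise Pearson correlations:\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Hierarchical clustering of conditions
#'
#' Agglomerative clustering (average linkage) of conditions using
#' `1 - R` as the dissimilarity, as is standard for grouping environments
#' by the similarity of the phenotypic response they elicit.
#'
#' @param R Symmetric correlation matrix with unit diagonal.
#' @param k Number of flat groups to report (default 2).
#' @param h Optional dissimilarity cut height (overrides `k`).
#' @return List with `hclust` (the merge tree) and `groups` (named
#'   integer vector of cluster memberships).
#' @export
cluster_conditions <- function(R, k = 2, h = NULL) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R)), na.rm = TRUE) > 1e-8)
    stop("'R' must be a symmetric correlation matrix", call. = FALSE)
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop("'R' must have a unit diagonal", call. = FALSE)
  d <- stats::as.dist(1 - R)
  hc <- stats::hclust(d, method = "average")
  groups <- if (is.null(h)) stats::cutree(hc, k = min(k, nrow(R)))
            else stats::cutree(hc, h = h)
  list(hclust = hc, groups = groups)
}

#' Shapiro-Wilk normality check
#'
#' Tests whether a phenotype distribution is consistent with normality.
#' With floor-censored Survival Integrals (a point mass at the assay
#' minimum) normality is typically rejected even when the underlying
#' trait is Gaussian.
#'
#' @param values Numeric vector, 3 to 5000 finite values.
#' @return List with `W` and `p_value`.
#' @export
normality_check <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires between 3 and 5000 values", call. = FALSE)
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p_value = ht$p.value)
}
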