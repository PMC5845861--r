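#' Describe the causal genetic architecture of a simulated cross
#'
#' Bundles the causal markers, their additive per-condition effects on the
#' Survival Integral, per-condition baselines and the residual
#' (environmental) standard deviation used by [simulate_phenotypes()].
#' Parent 1 carries allele 0 at every marker and parent 2 allele 1, so the
#' summed effects are the expected parent-2 minus parent-1 difference.
#'
#' @param effects Named numeric vector (one condition) or numeric matrix
#'   with causal markers as rows and conditions as columns. Effect units
#'   are SI days per allele-2 substitution.
#' @param baseline Mean SI of the allele-0 genotype, scalar or one value
#'   per condition.
#' @param env_sd Residual standard deviation (days), scalar or one value
#'   per condition; must be non-negative.
#' @return A `qtl_truth` object.
#' @examples
#' qtl_truth(c(c03_m005 = 0.8), baseline = 2, env_sd = 0.4)
#' @export
qtl_truth <- function(effects, baseline = 2, env_sd = 0.4) {
  if (is.null(dim(effects))) {
    if (is.null(names(effects)))
      stop("'effects' must be named by causal marker id", call. = FALSE)
    effects <- matrix(effects, ncol = 1,
                      dimnames = list(names(effects), "trait"))
  }
  if (is.null(rownames(effects)))
    stop("'effects' must have causal marker ids as rownames", call. = FALSE)
  n_cond <- ncol(effects)
  baseline <- rep_len(baseline, n_cond)
  env_sd <- rep_len(env_sd, n_cond)
  if (any(env_sd < 0)) stop("'env_sd' must be >= 0", call. = FALSE)
  structure(
    list(causal_markers = rownames(effects), effects = effects,
         baseline = stats::setNames(baseline, colnames(effects)),
         env_sd = stats::setNames(env_sd, colnames(effects))),
    class = "qtl_truth"
  )
}

#' Simulate haploid segregants from a biparental cross
#'
#' Generates parent-of-origin genotypes for haploid spores of a cross
#' between two homozygous parents, chromosome by chromosome. The first
#' marker of each chromosome is drawn Bernoulli(1/2); each subsequent
#' marker switches parental origin with the Haldane recombination fraction
#' implied by the map distance to the previous marker (no crossover
#' interference). Chromosomes assort independently.
#'
#' @param map A `marker_map` (see [make_marker_map()]).
#' @param n_segregants Number of haploid spores to simulate.
#' @param seed Optional integer seed for reproducibility.
#' @param missing_rate Fraction of genotype calls replaced by `NA`
#'   (default 0), emulating incomplete genotyping.
#' @return A `cls_cross` object: list with `genotypes` (integer matrix,
#'   segregants x markers, values 0/1/`NA`) and `map`.
#' @examples
#' cross <- simulate_cross(make_marker_map(2, 10, 10), 50, seed = 1)
#' dim(cross$genotypes)
#' @export
simulate_cross <- function(map, n_segregants, seed = NULL, missing_rate = 0) {
  map <- validate_marker_map(map)
  n_segregants <- .check_count(n_segregants, "n_segregants")
  .check_scalar_number(missing_rate, "missing_rate", lower = 0, upper = 1)
  .set_seed_if_given(seed)

  chroms <- unique(as.character(map$chrom))
  geno <- matrix(NA_integer_, nrow = n_segregants, ncol = nrow(map),
                 dimnames = list(sprintf("seg%04d", seq_len(n_segregants)),
                                 map$marker_id))
  for (ch in chroms) {
    idx <- which(as.character(map$chrom) == ch)
    m <- length(idx)
    cur <- as.integer(stats::runif(n_segregants) < 0.5)
    geno[, idx[1]] <- cur
    if (m > 1L) {
      r <- haldane_r(diff(map$pos_cm[idx]))
      for (j in seq_len(m - 1L)) {
        sw <- as.integer(stats::runif(n_segregants) < r[j])
        cur <- (cur + sw) %% 2L
        geno[, idx[j + 1L]] <- cur
      }
    }
  }
  if (missing_rate > 0) {
    drop <- stats::runif(length(geno)) < missing_rate
    geno[drop] <- NA_integer_
  }
  structure(list(genotypes = geno, map = map), class = "cls_cross")
}

#' @export
print.cls_cross <- function(x, ...) {
  g <- x$genotypes
  cat(sprintf("Simulated haploid cross: %d segregants x %d markers on %d chromosomes\n",
              nrow(g), ncol(g), length(unique(as.character(x$map$chrom)))))
  miss <- mean(is.na(g))
  cat(sprintf("  allele-2 frequency %.3f, missing %.1f%%\n",
              mean(g, na.rm = TRUE), 100 * miss))
  invisible(x)
}

#' Simulate additive phenotypes for a cross
#'
#' Generates per-segregant trait values under a purely additive model:
#' baseline + sum of causal-allele effects + Gaussian environmental noise.
#' Parental replicate values are generated from the same model (parent 1 =
#' baseline, parent 2 = baseline + summed effects) and are the raw
#' material for environmental-variance estimation. Values can optionally
#' be floored at the assay's minimum measurable Survival Integral.
#'
#' @param cross A `cls_cross`.
#' @param truth A `qtl_truth`.
#' @param n_parent_replicates Replicates per parent (default 3).
#' @param seed Optional integer seed.
#' @param si_floor Optional lower bound applied to every generated value
#'   (e.g. 0.5 days for daily sampling); `NULL` disables flooring.
#' @return A `cls_phenosim` list: `segregants` (matrix, segregants x
#'   conditions), `parents` (data frame parent/condition/replicate/value)
#'   and the `truth` used.
#' @export
simulate_phenotypes <- function(cross, truth, n_parent_replicates = 3,
                                seed = NULL, si_floor = NULL) {
  stopifnot(inherits(cross, "cls_cross"), inherits(truth, "qtl_truth"))
  n_parent_replicates <- .check_count(n_parent_replicates, "n_parent_replicates",
                                      min = 2L)
  unknown <- setdiff(truth$causal_markers, colnames(cross$genotypes))
  if (length(unknown))
    stop("causal marker(s) not present in genotypes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  .set_seed_if_given(seed)

  g <- cross$genotypes[, truth$causal_markers, drop = FALSE]
  if (anyNA(g))
    g[is.na(g)] <- 0L  # causal genotypes assumed observed; NA treated as allele 0
  n <- nrow(g)
  conds <- colnames(truth$effects)
  seg <- matrix(NA_real_, n, length(conds),
                dimnames = list(rownames(g), conds))
  for (k in seq_along(conds)) {
    genetic <- as.numeric(g %*% truth$effects[, k])
    seg[, k] <- truth$baseline[k] + genetic +
      stats::rnorm(n, 0, truth$env_sd[k])
  }

  par_grid <- expand.grid(parent = c("parent1", "parent2"), condition = conds,
                          replicate = seq_len(n_parent_replicates),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  par_mean <- ifelse(par_grid$parent == "parent1",
                     truth$baseline[par_grid$condition],
                     truth$baseline[par_grid$condition] +
                       colSums(truth$effects)[par_grid$condition])
  par_grid$value <- par_mean +
    stats::rnorm(nrow(par_grid), 0, truth$env_sd[par_grid$condition])

  if (!is.null(si_floor)) {
    seg <- pmax(seg, si_floor)
    par_grid$value <- pmax(par_grid$value, si_floor)
  }
  structure(list(segregants = seg, parents = par_grid, truth = truth),
            class = "cls_phenosim")
}
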