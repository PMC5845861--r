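# Shared fixture builders for the test suite.

# Small two-chromosome map with 10 markers each, 10 cM / 27 kb spacing.
small_map <- function(n_chrom = 2, markers_per_chrom = 10, spacing_cm = 10) {
  make_marker_map(n_chrom, markers_per_chrom, spacing_cm, 2700)
}

# Default study-scale map: 16 chromosomes x 19 markers at 5 cM (~300 markers).
study_map <- function() make_marker_map(16, 19, 5, 2700)

# Yeast-scale map for BSA (the G' null fit needs several markers per
# window and many linkage blocks per chromosome): 16 chromosomes x 100
# markers at 3 cM / ~8 kb spacing, ~4800 cM and ~13 Mb in total.
bsa_map <- function() make_marker_map(16, 100, 3, 2700)

# Effect size giving a QTL that explains `pve` of phenotypic variance in a
# balanced haploid cross with residual sd `sd`: V_A = a^2/4.
effect_for_pve <- function(pve, sd = 1) 2 * sd * sqrt(pve / (1 - pve))

# Dense-grid numerical integration of the piecewise-linear survival curve;
# independent oracle for the trapezoidal Survival Integral. Each between-day
# segment gets its own fine grid so the curve's kinks fall on grid points.
dense_si <- function(days, viability, n_per_segment = 2000) {
  f <- stats::approxfun(days, viability)
  total <- 0
  for (i in seq_len(length(days) - 1L)) {
    grid <- seq(days[i], days[i + 1L], length.out = n_per_segment)
    vals <- f(grid)
    h <- diff(grid)[1]
    total <- total + (sum(vals) - (vals[1] + vals[n_per_segment]) / 2) * h
  }
  total
}

# Brute-force LOD oracle from the genotype-phenotype Pearson correlation.
lod_oracle_cor <- function(g, y) {
  ok <- !is.na(g) & is.finite(y)
  r <- stats::cor(g[ok], y[ok])
  -(sum(ok) / 2) * log10(1 - r^2)
}

# Likelihood-ratio G oracle via loglin-style expected counts.
g_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  2 * sum(ifelse(tab == 0, 0, tab * log(tab / e)))
}
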