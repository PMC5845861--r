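test_that("hand-computed LOD example", {
  g <- cbind(m1 = c(0, 0, 0, 0, 1, 1, 1, 1))
  y <- c(0, 0, 0, 1, 1, 1, 1, 0)
  sc <- lod_scan(g, y)
  expect_equal(sc$lod, 4 * log10(2 / 1.5), tolerance = 1e-12)
  expect_equal(sc$lod, 0.4998, tolerance = 1e-4)
})

test_that("LOD equals the correlation-based oracle to 1e-9", {
  set.seed(51)
  cross <- simulate_cross(small_map(), 120, seed = 51)
  y <- rnorm(120) + cross$genotypes[, 4] * 0.8
  sc <- lod_scan(cross$genotypes, y)
  for (j in seq_len(ncol(cross$genotypes))) {
    expect_equal(sc$lod[j], lod_oracle_cor(cross$genotypes[, j], y),
                 tolerance = 1e-9)
  }
  # also with missing genotype data (complete-case per marker)
  g <- cross$genotypes
  g[sample(length(g), 300)] <- NA
  scm <- lod_scan(g, y)
  for (j in seq_len(ncol(g))) {
    if (is.na(scm$lod[j])) next
    expect_equal(scm$lod[j], lod_oracle_cor(g[, j], y), tolerance = 1e-9)
  }
})

test_that("LOD is invariant under affine phenotype transformation", {
  cross <- simulate_cross(small_map(), 100, seed = 52)
  y <- rnorm(100) + cross$genotypes[, 7]
  a <- lod_scan(cross$genotypes, y)$lod
  b <- lod_scan(cross$genotypes, 3.7 * y - 11)$lod
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("degenerate phenotypes and genotypes are handled as specified", {
  cross <- simulate_cross(small_map(), 60, seed = 53)
  # constant phenotype: all LOD zero, flagged
  sc <- lod_scan(cross$genotypes, rep(1, 60))
  expect_true(all(sc$lod == 0))
  expect_true(attr(sc, "constant_phenotype"))
  # monomorphic marker scores 0
  g <- cbind(cross$genotypes, mono = 0L)
  expect_equal(lod_scan(g, rnorm(60))$lod[ncol(g)], 0)
  # perfect fit is flagged infinite
  g1 <- cbind(m = rep(c(0L, 1L), each = 10))
  expect_true(is.infinite(lod_scan(g1, rep(c(0, 5), each = 10))$lod))
  # < 2 segregants in one allele group: skipped and recorded
  g2 <- cbind(cross$genotypes[, 1, drop = FALSE],
              thin = c(1L, rep(0L, 59)))
  sct <- lod_scan(g2, rnorm(60))
  expect_true(is.na(sct$lod[2]))
  expect_identical(attr(sct, "skipped"), "thin")
})

test_that("permutation threshold behaves as an empirical max-LOD quantile", {
  cross <- simulate_cross(small_map(), 100, seed = 54)
  y <- rnorm(100)
  thr <- permutation_threshold(cross$genotypes, y, n_perm = 200,
                               alpha = 0.05, seed = 55)
  maxima <- attr(thr, "maxima")
  expect_length(maxima, 200)
  expect_equal(as.numeric(thr), sort(maxima)[ceiling(0.95 * 200)])
  # alpha = 1 degenerates to the minimum of the permuted maxima
  thr1 <- permutation_threshold(cross$genotypes, y, n_perm = 100,
                                alpha = 1, seed = 56)
  expect_equal(as.numeric(thr1), min(attr(thr1, "maxima")))
  # threshold grows as alpha shrinks
  t10 <- permutation_threshold(cross$genotypes, y, n_perm = 300,
                               alpha = 0.10, seed = 57)
  t01 <- permutation_threshold(cross$genotypes, y, n_perm = 300,
                               alpha = 0.01, seed = 57)
  expect_gt(as.numeric(t01), as.numeric(t10))
  expect_error(permutation_threshold(cross$genotypes, y, n_perm = 100,
                                     alpha = 0), "alpha")
  # reproducible given the seed
  expect_equal(
    as.numeric(permutation_threshold(cross$genotypes, y, n_perm = 100,
                                     seed = 58)),
    as.numeric(permutation_threshold(cross$genotypes, y, n_perm = 100,
                                     seed = 58)))
})

test_that("vectorised permutation maxima equal scan-by-scan recomputation", {
  cross <- simulate_cross(small_map(), 80, seed = 59)
  y <- rnorm(80) + cross$genotypes[, 5]
  thr_fast <- permutation_threshold(cross$genotypes, y, n_perm = 100,
                                    seed = 60)
  set.seed(60)
  manual <- replicate(100, max(lod_scan(cross$genotypes,
                                        y[sample.int(80)])$lod))
  expect_equal(attr(thr_fast, "maxima"), manual, tolerance = 1e-9)
})

test_that("support intervals cover peaks and degenerate cases", {
  cross <- simulate_cross(small_map(), 200, seed = 61)
  tr <- qtl_truth(c(c01_m005 = 1.5), baseline = 2, env_sd = 0.5)
  ph <- simulate_phenotypes(cross, tr, seed = 62)
  fit <- isa_scan(cross, ph$segregants[, 1], n_perm = 200, seed = 63)
  expect_s3_class(fit$scan, "cls_scan")
  expect_gte(nrow(fit$intervals), 1)
  hit <- fit$intervals[fit$intervals$chrom == "I", ]
  pos <- cross$map$pos_bp[cross$map$marker_id == "c01_m005"]
  expect_true(any(hit$start_bp <= pos & hit$end_bp >= pos))

  # nothing significant -> empty intervals
  empty <- support_intervals(fit$scan, threshold = 1e6)
  expect_equal(nrow(empty), 0)
  # single isolated significant marker -> width 0
  sc <- fit$scan
  sc$lod <- rep(0, nrow(sc)); sc$lod[5] <- 10
  one <- support_intervals(sc, threshold = 5, lod_drop = 1.5)
  expect_equal(nrow(one), 1)
  expect_equal(one$width_kb, 0)
})

test_that("a strong QTL is detected with its causal marker in the interval", {
  # injected QTL explaining ~30% of variance in a 488-segregant cross
  map <- study_map()
  hits <- 0; covered <- 0; n_rep <- 25
  a <- effect_for_pve(0.30)
  for (i in seq_len(n_rep)) {
    cross <- simulate_cross(map, 488, seed = 700 + i)
    ph <- simulate_phenotypes(cross, qtl_truth(c(c07_m010 = a), env_sd = 1),
                              seed = 800 + i)
    fit <- isa_scan(cross, ph$segregants[, 1], n_perm = 150,
                    seed = 900 + i)
    pos <- map$pos_bp[map$marker_id == "c07_m010"]
    ii <- fit$intervals
    if (any(ii$chrom == "VII" & fit$scan$lod[match("c07_m010", fit$scan$marker)] >= fit$threshold))
      hits <- hits + 1
    if (any(ii$chrom == "VII" & ii$start_bp <= pos & ii$end_bp >= pos))
      covered <- covered + 1
  }
  expect_gte(hits / n_rep, 0.95)
  expect_gte(covered / n_rep, 0.95)
})
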