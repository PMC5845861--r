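test_that("bulk selection is deterministic with documented tie-breaking", {
  si <- setNames(c(5, 3, 4, 1, 2, 0.5), paste0("s", 1:6))
  b <- select_bulks(si, size = 2)
  expect_identical(b$high_bulk, c("s1", "s3"))
  expect_identical(b$low_bulk, c("s6", "s4"))
  expect_length(intersect(b$high_bulk, b$low_bulk), 0)

  # n = 2*size partitions the population
  si100 <- setNames(rnorm(100), sprintf("s%03d", 1:100))
  b100 <- select_bulks(si100, size = 50)
  expect_setequal(c(b100$high_bulk, b100$low_bulk), names(si100))

  # all-equal phenotypes: purely id-determined, still disjoint
  tied <- setNames(rep(1, 100), sprintf("s%03d", 1:100))
  bt <- select_bulks(tied, size = 50)
  expect_identical(bt$high_bulk, sort(names(tied), decreasing = TRUE)[1:50])
  expect_identical(bt$low_bulk, sort(names(tied))[1:50])

  expect_error(select_bulks(si, size = 4), "exceeds")
})

test_that("allele counting respects bulks and missing data", {
  g <- rbind(s1 = c(0L, 1L), s2 = c(0L, NA), s3 = c(1L, 1L), s4 = c(1L, 0L))
  colnames(g) <- c("mA", "mB")
  b <- list(high_bulk = c("s1", "s2"), low_bulk = c("s3", "s4"), size = 2)
  cnt <- allele_counts(g, b)
  expect_equal(cnt$n_high_allele1, c(2, 0))
  expect_equal(cnt$n_high_allele2, c(0, 1))  # NA excluded
  expect_equal(cnt$n_low_allele1, c(0, 1))
  expect_equal(cnt$n_low_allele2, c(2, 1))
  expect_error(allele_counts(g, list(high_bulk = "sX", low_bulk = "s1",
                                     size = 1)), "sX")
})

test_that("worked G-statistic values and oracle agreement", {
  expect_equal(g_statistic(25, 25, 25, 25), 0)
  expect_equal(g_statistic(40, 10, 10, 40), 38.549, tolerance = 1e-3)
  expect_equal(g_statistic(50, 0, 0, 50), 200 * log(2))
  expect_error(g_statistic(0, 0, 0, 0), "all-zero")

  set.seed(71)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 20), 2)
    expect_equal(g_statistic(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 g_oracle(tab), tolerance = 1e-9)
  }
})

test_that("G is invariant under simultaneously swapping bulks and alleles", {
  set.seed(72)
  for (i in 1:20) {
    n <- rpois(4, 15) + 1
    expect_equal(g_statistic(n[1], n[2], n[3], n[4]),
                 g_statistic(n[4], n[3], n[2], n[1]), tolerance = 1e-12)
  }
})

test_that("tricube smoothing matches hand-evaluated weights", {
  # constant G is a fixed point
  map3 <- validate_marker_map(data.frame(
    marker_id = c("a", "b", "c"), chrom = "I",
    pos_bp = c(1L, 12501L, 25001L), pos_cm = c(0, 5, 10)))
  expect_equal(smooth_gprime(rep(7, 3), map3, window_kb = 25), rep(7, 3))
  # three equidistant markers at half-window spacing, G = (0, 30, 0)
  w0 <- (1 - 0.5^3)^3
  gp <- smooth_gprime(c(0, 30, 0), map3, window_kb = 25)
  expect_equal(gp[2], 30 / (2 * w0 + 1), tolerance = 1e-12)
  expect_equal(gp[2], 12.823, tolerance = 1e-3)
  # isolated marker keeps its own G
  far <- validate_marker_map(data.frame(
    marker_id = c("a", "b"), chrom = "I",
    pos_bp = c(1L, 900001L), pos_cm = c(0, 300)))
  expect_equal(smooth_gprime(c(3, 9), far, window_kb = 25), c(3, 9))
})

test_that("log-normal null calibration controls the marker-level FDR", {
  set.seed(73)
  n_sig <- replicate(50, {
    gp <- exp(rnorm(300, mean = 1, sd = 0.3))
    sum(gprime_significance(gp, fdr_level = 0.05)$q_value <= 0.05)
  })
  # under a pure null most replicates call nothing
  expect_gte(mean(n_sig == 0), 0.9)

  # identical G' everywhere: all p identical, nothing significant
  same <- gprime_significance(rep(4, 100), fdr_level = 0.5)
  expect_equal(length(unique(same$p_value)), 1)
  expect_false(any(same$q_value <= 0.5))
  expect_error(gprime_significance(rep(1, 10)), "50 markers")
})

test_that("a strong QTL peaks at the causal position with enriched bulks", {
  map <- bsa_map()
  cross <- simulate_cross(map, 488, seed = 75)
  a <- effect_for_pve(0.4)
  ph <- simulate_phenotypes(cross, qtl_truth(c(c05_m025 = a), env_sd = 1),
                            seed = 76)
  y <- setNames(ph$segregants[, 1], rownames(ph$segregants))
  fit <- bsa_scan(cross, y, window_kb = 150)
  # high bulk enriched for the increasing allele
  cnt <- fit$counts[fit$counts$marker == "c05_m025", ]
  expect_gt(cnt$n_high_allele2 / 50, 0.7)
  expect_lt(cnt$n_low_allele2 / 50, 0.3)
  # q-value minimum at/near the causal marker
  best <- fit$scan$marker[which.min(fit$scan$q_value)]
  expect_equal(fit$scan$chrom[fit$scan$marker == best][1], "V")
  # significant region covers the causal marker
  pos <- map$pos_bp[map$marker_id == "c05_m025"]
  expect_true(any(fit$regions$chrom == "V" & fit$regions$start_bp <= pos &
                    fit$regions$end_bp >= pos))
})

test_that("unlinked markers stay near 50:50 in both bulks", {
  map <- small_map(n_chrom = 4, markers_per_chrom = 15)
  cross <- simulate_cross(map, 400, seed = 77)
  ph <- simulate_phenotypes(cross, qtl_truth(c(c01_m001 = 2), env_sd = 0.3),
                            seed = 78)
  y <- setNames(ph$segregants[, 1], rownames(ph$segregants))
  fit <- bsa_scan(cross, y, bulk_size = 100, window_kb = 20)
  # chromosome II is unlinked to the causal locus
  cnt <- fit$counts[grepl("^c02", fit$counts$marker), ]
  frac_hi <- cnt$n_high_allele2 / (cnt$n_high_allele1 + cnt$n_high_allele2)
  se <- sqrt(0.25 / 100)
  expect_true(all(abs(frac_hi - 0.5) < 4 * se))
})

test_that("significant regions merge runs and report widths", {
  scan <- data.frame(
    marker = paste0("m", 1:8), chrom = "IV",
    pos_bp = c(100000L, 103000L, 106000L, 110000L, 113000L, 150000L,
               153000L, 156000L),
    gprime = c(5, 30, 40, 35, 20, 3, 25, 24),
    q_value = c(0.2, 0.01, 0.001, 0.01, 0.04, 0.6, 0.02, 0.03),
    stringsAsFactors = FALSE)
  reg <- significant_regions(scan, fdr_level = 0.05)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start_bp[1], 103000)
  expect_equal(reg$end_bp[1], 113000)
  expect_equal(reg$width_kb[1], 10)
  expect_equal(reg$peak_marker[1], "m3")
  # one 13-kb run
  one <- scan[2:5, ]; one$pos_bp <- c(100000L, 104000L, 109000L, 113000L)
  r1 <- significant_regions(one, fdr_level = 0.05)
  expect_equal(r1$width_kb, 13)
  # nothing significant
  none <- scan; none$q_value <- 0.9
  expect_equal(nrow(significant_regions(none, 0.05)), 0)
})

test_that("gene overlap uses the inclusive convention", {
  ann <- data.frame(
    gene = paste0("G", 1:7), chrom = c(rep("VI", 6), "VII"),
    start_bp = c(1000, 3000, 5000, 9000, 12000, 20000, 4000),
    end_bp = c(2000, 4500, 8000, 11000, 13999, 22000, 6000),
    stringsAsFactors = FALSE)
  region <- list(chrom = "VI", start_bp = 2000, end_bp = 12000)
  hits <- genes_in_interval(region, ann)
  expect_setequal(hits, paste0("G", 1:5))  # G1 abuts, G5 starts at end
  # brute-force cross-check
  brute <- ann$gene[vapply(seq_len(nrow(ann)), function(i) {
    ann$chrom[i] == "VI" &&
      max(ann$start_bp[i], 2000) <= min(ann$end_bp[i], 12000)
  }, logical(1))]
  expect_setequal(hits, brute)
  expect_length(genes_in_interval(region, ann[0, ]), 0)
  # malformed rows skipped with a warning
  bad <- ann; bad$end_bp[2] <- NA; bad$start_bp[3] <- 99999
  expect_warning(res <- genes_in_interval(region, bad), "2 malformed")
  expect_false("G2" %in% res)
})
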