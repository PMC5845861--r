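test_that("pooled parental variance is the df-weighted within-parent variance", {
  expect_equal(pooled_parental_variance(list(c(2, 2, 2), c(5, 5))), 0)
  # parent A var 1 (n=3), parent B var 3 (n=3) -> pooled 2
  a <- c(0, 1, 2)                       # var 1
  b <- c(0, sqrt(3) * c(1, 2)) + 1      # shift irrelevant
  b <- c(1, 1 + sqrt(3), 1 + 2 * sqrt(3))
  expect_equal(var(b), 3)
  expect_equal(pooled_parental_variance(list(a, b)), 2)
  expect_error(pooled_parental_variance(list(c(1, 2), c(3))), "2 replicates")
  # sampling check: large n recovers sigma^2 within the chi-square interval
  set.seed(81)
  reps <- list(rnorm(400, 0, 1.5), rnorm(400, 5, 1.5))
  v <- pooled_parental_variance(reps)
  ci <- 798 * 1.5^2 / qchisq(c(0.9995, 0.0005), df = 798)
  expect_gt(v, ci[1]); expect_lt(v, ci[2])
})

test_that("broad-sense heritability follows (V_P - V_E)/V_P with clipping", {
  set.seed(82)
  x <- rnorm(50, 0, 2)
  expect_equal(as.numeric(broad_sense_h2(x, 0)), 1)
  y <- c(rep(0, 10), rep(2, 10))        # var = 40/19
  expect_equal(as.numeric(broad_sense_h2(y, var(y) / 4)), 0.75)
  # V_E above V_P clips to 0, raw kept
  h <- broad_sense_h2(x, var(x) * 2)
  expect_equal(as.numeric(h), 0)
  expect_equal(attr(h, "raw"), -1)
  expect_error(broad_sense_h2(rep(1, 20), 0.1), "zero")
  expect_error(broad_sense_h2(x[1:5], 0.1), "10 segregants")
})

test_that("H2 recovery on simulated crosses matches V_A/(V_A + V_E)", {
  map <- small_map(n_chrom = 4)
  a <- c(1, 0.7, 0.5)
  V_A <- sum(a^2) / 4   # causal loci on distinct chromosomes -> independent
  env_sd <- 0.5
  h2_true <- V_A / (V_A + env_sd^2)
  for (n in c(100, 488, 2000)) {
    cross <- simulate_cross(map, n, seed = 83 + n)
    tr <- qtl_truth(setNames(a, c("c01_m002", "c03_m008", "c02_m005")),
                    baseline = 2, env_sd = env_sd)
    ph <- simulate_phenotypes(cross, tr, n_parent_replicates = 50,
                              seed = 84 + n)
    reps <- split(ph$parents$value, ph$parents$parent)
    est <- heritability(ph$segregants[, 1], reps)
    tol <- 3 * sqrt(2 / n) # rough sampling scale for a variance ratio
    expect_lt(abs(est$H2 - h2_true), tol)
  }
})

test_that("parent-offspring regression recovers slopes", {
  # exact constructions
  mid <- c(1, 2, 3, 4)
  suppressWarnings({  # exact constructions trip lm's perfect-fit warning
    expect_equal(narrow_sense_h2(mid, mid)$h2, 1)
    expect_equal(narrow_sense_h2(mid, 0.5 * mid + 3)$h2, 0.5)
  })
  expect_error(narrow_sense_h2(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(narrow_sense_h2(c(1, 2), c(1, 2)), "3")
  # midparent symmetry: swapping the parents leaves the slope unchanged
  p1 <- c(1, 3, 2, 5); p2 <- c(2, 1, 4, 3); off <- c(1.4, 2.2, 3.1, 3.9)
  expect_equal(narrow_sense_h2((p1 + p2) / 2, off)$h2,
               narrow_sense_h2((p2 + p1) / 2, off)$h2)
})

test_that("purely additive crosses give h2 near 1 across conditions", {
  map <- small_map()
  cross <- simulate_cross(map, 488, seed = 85)
  eff <- cbind(SC = c(1, 0.4), CR = c(0.3, 1.2), Glu10 = c(0.8, 0.8),
               Gal = c(0.2, 1.6))
  rownames(eff) <- c("c01_m003", "c02_m007")
  tr <- qtl_truth(eff, baseline = c(2, 4, 1.5, 2.5), env_sd = 0.3)
  ph <- simulate_phenotypes(cross, tr, n_parent_replicates = 10, seed = 86)
  mid <- vapply(colnames(eff), function(cn) {
    v <- ph$parents$value[ph$parents$condition == cn]
    p <- ph$parents$parent[ph$parents$condition == cn]
    mean(tapply(v, p, mean))
  }, numeric(1))
  off <- colMeans(ph$segregants)
  fit <- narrow_sense_h2(mid, off)
  expect_equal(fit$h2, 1, tolerance = 0.12)
})

test_that("transgressive segregation is flagged beyond k parental SDs", {
  ts <- transgression_summary(c(2.5, 1.5, 0.4), parent_means = c(1, 2),
                              parent_sd = 0.1, k = 2)
  expect_equal(ts$n_high, 1)   # 2.5 > 2.2
  expect_equal(ts$n_low, 1)    # 0.4 < 0.8
  expect_equal(ts$frac_high, 1 / 3)
  # opposing-effect QTLs in the parents guarantee transgression
  # (enumeration of the four noise-free genotype classes)
  classes <- c(`00` = 0, `01` = -1, `10` = 1, `11` = 0) + 2
  parents <- c(2, 2)  # parent1 = 00, parent2 = 11
  ts2 <- transgression_summary(classes, parents, parent_sd = 0, k = 2)
  expect_gt(ts2$n_high, 0)
  expect_gt(ts2$n_low, 0)
})

test_that("trait correlations handle estimation, degeneracy and symmetry", {
  set.seed(87)
  x <- rnorm(40)
  m <- cbind(a = x, b = x, c = -x, d = rnorm(40))
  tc <- trait_correlations(m)
  expect_equal(tc$r["a", "b"], 1)
  expect_equal(tc$r["a", "c"], -1)
  expect_equal(tc$r, t(tc$r))
  expect_equal(unname(diag(tc$r)), rep(1, 4))
  # constant vector reported as missing with a reason
  mc <- cbind(a = x, k = rep(2, 40))
  tcc <- trait_correlations(mc)
  expect_true(is.na(tcc$r["a", "k"]))
  expect_match(tcc$pairs$note[1], "constant")
  # bivariate normal rho = 0.5, n = 58: inside the Fisher-z 95% CI
  rho <- 0.5; n <- 58
  z_ci <- atanh(rho) + c(-1, 1) * 1.96 / sqrt(n - 3)
  hits <- replicate(40, {
    u <- rnorm(n); v <- rho * u + sqrt(1 - rho^2) * rnorm(n)
    est <- trait_correlations(cbind(u, v))$r[1, 2]
    est > tanh(z_ci[1]) && est < tanh(z_ci[2])
  })
  expect_gte(mean(hits), 0.85)
})

test_that("condition clustering recovers planted block structure", {
  R <- matrix(0, 6, 6, dimnames = rep(list(paste0("c", 1:6)), 2))
  R[1:3, 1:3] <- 0.9; R[4:6, 4:6] <- 0.9; diag(R) <- 1
  cl <- cluster_conditions(R, k = 2)
  expect_equal(length(unique(cl$groups[1:3])), 1)
  expect_equal(length(unique(cl$groups[4:6])), 1)
  expect_false(cl$groups[1] == cl$groups[4])
  # all correlations 1: a single cluster at any positive cut
  R1 <- matrix(1, 3, 3, dimnames = rep(list(letters[1:3]), 2))
  expect_equal(length(unique(cluster_conditions(R1, h = 0.01)$groups)), 1)
  # two conditions: a single merge
  R2 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = rep(list(c("x", "y")), 2))
  expect_equal(nrow(cluster_conditions(R2)$hclust$merge), 1)
  # ordering invariance
  perm <- c(4, 1, 6, 2, 5, 3)
  cl2 <- cluster_conditions(R[perm, perm], k = 2)
  expect_equal(unname(cl2$groups[colnames(R)[1]] ==
                        cl2$groups[colnames(R)[2]]), TRUE)
  expect_error(cluster_conditions(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
})

test_that("normality checks behave on Gaussian and floor-censored samples", {
  set.seed(88)
  p_norm <- replicate(40, normality_check(rnorm(200))$p_value)
  expect_gte(mean(p_norm > 0.05), 0.9)
  # floor-censored SI distributions are rejected far more than 5%
  p_cens <- replicate(40, {
    x <- pmax(rnorm(200, 1, 0.8), 0.5)
    normality_check(x)$p_value
  })
  expect_gt(mean(p_cens < 0.05), 0.5)
  expect_error(normality_check(c(1, 2)), "between 3 and 5000")
})
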