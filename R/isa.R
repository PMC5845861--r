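# Individual Segregant Analysis: single-marker regression LOD scan with a
# permutation-derived genome-wide significance threshold.

# Core LOD computation for a genotype matrix with no missing values.
# RSS0: residual sum of squares around the grand mean; RSS1: around the
# two allele-group means. LOD = (n/2) log10(RSS0/RSS1). Vectorised over
# markers and over many phenotype vectors at once (columns of Y).
.lod_matrix <- function(geno, Y) {
  n <- nrow(geno)
  n1 <- colSums(geno)
  n0 <- n - n1
  S <- colSums(Y)                      # per-phenotype totals
  SS <- colSums(Y^2)
  s1 <- crossprod(geno, Y)             # markers x phenotypes
  rss0 <- matrix(SS - S^2 / n, nrow = length(n1), ncol = ncol(Y),
                 byrow = TRUE)
  ok <- n1 > 0L & n0 > 0L
  rss1 <- rss0
  if (any(ok)) {
    s1ok <- s1[ok, , drop = FALSE]
    Smat <- matrix(S, nrow = sum(ok), ncol = ncol(Y), byrow = TRUE)
    SSmat <- matrix(SS, nrow = sum(ok), ncol = ncol(Y), byrow = TRUE)
    rss1[ok, ] <- SSmat - s1ok^2 / n1[ok] - (Smat - s1ok)^2 / n0[ok]
  }
  lod <- matrix(0, nrow = length(n1), ncol = ncol(Y))
  pos <- rss0 > 0
  lod[pos] <- (n / 2) * log10(rss0[pos] / pmax(rss1[pos], 0))
  lod[pos & rss1 <= 0] <- Inf
  lod[!ok, ] <- 0                      # monomorphic markers carry no signal
  lod
}

#' Single-marker LOD scan
#'
#' Scores each marker for association with a quantitative phenotype by
#' comparing the residual sum of squares of a grand-mean model (RSS0)
#' with that of a two-allele-group-means model (RSS1):
#' `LOD = (n/2) * log10(RSS0 / RSS1)`, with `n` the complete cases at the
#' marker. Segregants with a missing allele are dropped marker-wise.
#' Monomorphic markers score 0; markers with fewer than 2 segregants per
#' allele group are skipped (`NA`, recorded in attribute `skipped`); a
#' perfect fit (RSS1 = 0) is reported as `Inf`.
#'
#' @param genotypes Integer matrix (segregants x markers, values 0/1/`NA`)
#'   or a `cls_cross`.
#' @param phenotype Numeric vector, one value per segregant.
#' @param map Optional `marker_map` used to attach `chrom` and `pos_bp`.
#' @return A `cls_scan` data frame: `marker`, `lod` (plus `chrom`,
#'   `pos_bp` when a map is given).
#' @examples
#' g <- cbind(m1 = c(0, 0, 0, 0, 1, 1, 1, 1))
#' lod_scan(g, c(0, 0, 0, 1, 1, 1, 1, 0))
#' @export
lod_scan <- function(genotypes, phenotype, map = NULL) {
  if (inherits(genotypes, "cls_cross")) {
    if (is.null(map)) map <- genotypes$map
    genotypes <- genotypes$genotypes
  }
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 2L)
    stop("at least 2 segregants are required", call. = FALSE)
  if (length(phenotype) != nrow(genotypes))
    stop("'phenotype' must have one value per segregant", call. = FALSE)
  keep_ph <- is.finite(phenotype)
  if (sum(keep_ph) < 4L)
    stop("phenotype present for fewer than 4 segregants", call. = FALSE)
  geno <- genotypes[keep_ph, , drop = FALSE]
  y <- phenotype[keep_ph]

  constant_phenotype <- stats::var(y) == 0
  m <- ncol(geno)
  lod <- numeric(m)
  skipped <- character(0)
  if (!constant_phenotype) {
    na_marker <- colSums(is.na(geno)) > 0L
    if (any(!na_marker)) {
      lod[!na_marker] <- .lod_matrix(geno[, !na_marker, drop = FALSE],
                                     matrix(y, ncol = 1))[, 1]
    }
    for (j in which(na_marker)) {
      ok <- !is.na(geno[, j])
      gj <- geno[ok, j]
      counts <- tabulate(gj + 1L, nbins = 2L)
      if (any(counts == 0L) || stats::var(y[ok]) == 0) { lod[j] <- 0; next }
      if (min(counts) < 2L) {
        lod[j] <- NA_real_
        skipped <- c(skipped, colnames(geno)[j])
        next
      }
      lod[j] <- .lod_matrix(cbind(gj), matrix(y[ok], ncol = 1))[1, 1]
    }
    # markers without NA but with < 2 per group (and both groups present)
    n1 <- colSums(geno == 1L, na.rm = TRUE)
    n0 <- colSums(geno == 0L, na.rm = TRUE)
    thin <- !na_marker & n1 > 0L & n0 > 0L & (n1 < 2L | n0 < 2L)
    if (any(thin)) {
      lod[thin] <- NA_real_
      skipped <- c(skipped, colnames(geno)[thin])
    }
  }
  out <- data.frame(marker = colnames(genotypes), lod = lod,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    idx <- match(out$marker, map$marker_id)
    out$chrom <- as.character(map$chrom)[idx]
    out$pos_bp <- map$pos_bp[idx]
    out <- out[, c("marker", "chrom", "pos_bp", "lod")]
  }
  attr(out, "skipped") <- unique(skipped)
  attr(out, "constant_phenotype") <- constant_phenotype
  class(out) <- c("cls_scan", "data.frame")
  out
}

#' Permutation-derived genome-wide LOD threshold
#'
#' Permutes the phenotype labels `n_perm` times, records the maximum LOD
#' of each permuted genome scan, and returns the empirical `1 - alpha`
#' quantile (nearest rank) of those maxima — the genome-wide threshold at
#' significance level `alpha`. Infinite permuted LODs are excluded from
#' the quantile.
#'
#' @inheritParams lod_scan
#' @param n_perm Number of permutations (>= 100, default 1000).
#' @param alpha Genome-wide significance level in `(0, 1]` (default 0.05).
#' @param seed Optional integer seed.
#' @return Threshold LOD (numeric scalar) with attributes `maxima`,
#'   `n_perm`, `alpha`.
#' @export
permutation_threshold <- function(genotypes, phenotype, n_perm = 1000,
                                  alpha = 0.05, seed = NULL) {
  if (inherits(genotypes, "cls_cross")) genotypes <- genotypes$genotypes
  genotypes <- as.matrix(genotypes)
  n_perm <- .check_count(n_perm, "n_perm", min = 100L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  .set_seed_if_given(seed)

  keep <- is.finite(phenotype)
  geno <- genotypes[keep, , drop = FALSE]
  y <- phenotype[keep]
  n <- length(y)
  if (!anyNA(geno)) {
    # vectorised path: all permutations in one cross-product
    poly <- colSums(geno) > 0L & colSums(geno) < n
    Y <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
    lod <- .lod_matrix(geno[, poly, drop = FALSE], Y)
    maxima <- apply(lod, 2, function(z) {
      z <- z[is.finite(z)]
      if (length(z)) max(z) else 0
    })
  } else {
    maxima <- vapply(seq_len(n_perm), function(i) {
      sc <- lod_scan(geno, y[sample.int(n)])
      z <- sc$lod[is.finite(sc$lod)]
      if (length(z)) max(z) else 0
    }, numeric(1))
  }
  thr <- .nearest_rank_quantile(maxima, 1 - alpha)
  attr(thr, "maxima") <- maxima
  attr(thr, "n_perm") <- n_perm
  attr(thr, "alpha") <- alpha
  thr
}

#' LOD support intervals around significant peaks
#'
#' For each contiguous run of markers at or above the threshold, takes
#' the run's peak marker and extends left and right along the chromosome
#' while the LOD stays within `lod_drop` of the peak, yielding the
#' classical LOD-drop support interval.
#'
#' @param scan A `cls_scan` with `chrom` and `pos_bp` columns.
#' @param threshold Genome-wide LOD threshold.
#' @param lod_drop LOD units to drop from the peak (default 1.5).
#' @return Data frame `chrom`, `start_bp`, `end_bp`, `peak_marker`,
#'   `peak_lod`, `width_kb`; zero rows when nothing is significant.
#' @export
support_intervals <- function(scan, threshold, lod_drop = 1.5) {
  if (!all(c("chrom", "pos_bp") %in% names(scan)))
    stop("scan must carry 'chrom' and 'pos_bp' (pass a marker map to lod_scan)",
         call. = FALSE)
  out <- list()
  for (ch in unique(scan$chrom)) {
    sub <- scan[scan$chrom == ch, ]
    sub <- sub[order(sub$pos_bp), ]
    lod <- ifelse(is.na(sub$lod), -Inf, sub$lod)
    sig <- lod >= threshold
    if (!any(sig)) next
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      run <- starts[k]:ends[k]
      peak <- run[which.max(lod[run])]
      lo <- peak
      while (lo > 1L && is.finite(lod[lo - 1L]) &&
             lod[lo - 1L] >= lod[peak] - lod_drop) lo <- lo - 1L
      hi <- peak
      while (hi < nrow(sub) && is.finite(lod[hi + 1L]) &&
             lod[hi + 1L] >= lod[peak] - lod_drop) hi <- hi + 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = sub$pos_bp[lo], end_bp = sub$pos_bp[hi],
        peak_marker = sub$marker[peak], peak_lod = lod[peak],
        width_kb = (sub$pos_bp[hi] - sub$pos_bp[lo]) / 1000,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), peak_marker = character(),
                      peak_lod = numeric(), width_kb = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Individual Segregant Analysis scan
#'
#' One-call ISA: LOD scan, permutation genome-wide threshold and LOD-drop
#' support intervals.
#'
#' @inheritParams lod_scan
#' @inheritParams permutation_threshold
#' @param lod_drop Support-interval LOD drop (default 1.5).
#' @return A `cls_isa` object: `scan` (cls_scan), `threshold`, `alpha`,
#'   `n_perm`, `intervals`.
#' @examples
#' cross <- simulate_cross(make_marker_map(4, 12, 10), 150, seed = 2)
#' ph <- simulate_phenotypes(cross, qtl_truth(c(c02_m006 = 1.2)), seed = 3)
#' fit <- isa_scan(cross, ph$segregants[, 1], n_perm = 100, seed = 4)
#' summary(fit)
#' @export
isa_scan <- function(genotypes, phenotype, map = NULL, n_perm = 1000,
                     alpha = 0.05, lod_drop = 1.5, seed = NULL) {
  if (inherits(genotypes, "cls_cross")) {
    if (is.null(map)) map <- genotypes$map
    genotypes <- genotypes$genotypes
  }
  scan <- lod_scan(genotypes, phenotype, map = map)
  thr <- permutation_threshold(genotypes, phenotype, n_perm = n_perm,
                               alpha = alpha, seed = seed)
  intervals <- if (!is.null(map)) support_intervals(scan, as.numeric(thr),
                                                    lod_drop = lod_drop)
               else NULL
  structure(list(scan = scan, threshold = as.numeric(thr), alpha = alpha,
                 n_perm = attr(thr, "n_perm"), lod_drop = lod_drop,
                 intervals = intervals, perm_maxima = attr(thr, "maxima")),
            class = "cls_isa")
}

#' @export
print.cls_isa <- function(x, ...) {
  cat(sprintf("ISA scan: %d markers, genome-wide LOD threshold %.2f (alpha = %g, %d permutations)\n",
              nrow(x$scan), x$threshold, x$alpha, x$n_perm))
  n_sig <- if (is.null(x$intervals)) sum(x$scan$lod >= x$threshold, na.rm = TRUE)
           else nrow(x$intervals)
  if (!is.null(x$intervals) && nrow(x$intervals)) {
    cat("Significant QTL intervals:\n")
    print(x$intervals, row.names = FALSE)
  } else {
    cat("No marker exceeds the threshold\n")
  }
  invisible(x)
}

#' @export
summary.cls_isa <- function(object, ...) {
  top <- object$scan[order(-ifelse(is.na(object$scan$lod), -Inf,
                                   object$scan$lod)), ][1, ]
  cat(sprintf("Peak LOD %.2f at %s; threshold %.2f; %d interval(s)\n",
              top$lod, top$marker, object$threshold,
              if (is.null(object$intervals)) NA_integer_
              else nrow(object$intervals)))
  invisible(object)
}

#' @export
plot.cls_isa <- function(x, ...) {
  scan <- x$scan
  if (!"pos_bp" %in% names(scan)) {
    graphics::plot(seq_len(nrow(scan)), scan$lod, type = "h",
                   xlab = "marker index", ylab = "LOD", ...)
  } else {
    chroms <- unique(scan$chrom)
    offs <- c(0, cumsum(vapply(chroms, function(ch)
      max(scan$pos_bp[scan$chrom == ch]), numeric(1))))
    xpos <- scan$pos_bp + offs[match(scan$chrom, chroms)]
    graphics::plot(xpos / 1e3, scan$lod, type = "l",
                   xlab = "genome position (kb)", ylab = "LOD", ...)
  }
  graphics::abline(h = x$threshold, lty = 2, col = "red")
  invisible(x)
}
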