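# End-to-end in-silico study: simulate a cross, generate phenotypes
# (optionally through the plate-reader assay), map QTLs by ISA and BSA in
# every condition, and summarise heritability, transgression and the
# correlation structure across conditions.

#' Build a study configuration
#'
#' Assembles and validates the configuration consumed by [run_study()].
#' Defaults mirror the reference cross design: 488 haploid segregants,
#' 16 chromosomes, permutation level 0.05 for ISA, bulks of 50 and FDR
#' 0.05 for BSA.
#'
#' @param seed Master integer seed; every stochastic stage draws from a
#'   sub-seed derived from it.
#' @param n_segregants Number of haploid segregants (default 488).
#' @param map Marker-map parameters passed to [make_marker_map()].
#' @param conditions Named list; each element is a list with `baseline`
#'   (mean SI, days), `env_sd` (days) and `qtls`, itself a list of
#'   `list(marker =, effect =)` entries (possibly empty).
#' @param assay List: `mode` ("direct" takes simulated SI values as the
#'   phenotype; "outgrowth" pushes them through plate-curve simulation
#'   and re-quantification), `days`, `times`, `noise_sd`, `si_floor`.
#' @param isa List: `n_perm`, `alpha`, `lod_drop`.
#' @param bsa List: `bulk_size`, `window_kb`, `fdr`. The default smoothing
#'   window (200 kb) is matched to the signal-containment scale of a
#'   biparental cross: the expected linked allele-frequency signal of a
#'   detectable QTL falls below the genome-wide significance threshold at
#'   roughly 70 cM, i.e. ~190 kb at the simulated 2.7 kb/cM. This also
#'   lets each window pool enough markers for a stable G' null fit; for
#'   dense real marker data a much narrower window (see [bsa_scan()]) is
#'   appropriate.
#' @param n_parent_replicates Parental replicates per condition.
#' @param outdir Optional directory; when given, every intermediate table
#'   is persisted there.
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1,
                         n_segregants = 488,
                         map = list(n_chrom = 16, markers_per_chrom = 19,
                                    spacing_cm = 5, bp_per_cm = 2700),
                         conditions = list(
                           SC = list(baseline = 2, env_sd = 0.4,
                                     qtls = list())),
                         assay = list(mode = "direct", days = 1:10,
                                      times = seq(0, 24, 0.25),
                                      noise_sd = 0, si_floor = NULL),
                         isa = list(n_perm = 1000, alpha = 0.05,
                                    lod_drop = 1.5),
                         bsa = list(bulk_size = 50, window_kb = 200,
                                    fdr = 0.05),
                         n_parent_replicates = 3,
                         outdir = NULL) {
  .check_count(seed, "seed", min = 0L)
  .check_count(n_segregants, "n_segregants")
  defaults <- formals(study_config)
  assay <- utils::modifyList(eval(defaults$assay), assay)
  isa <- utils::modifyList(eval(defaults$isa), isa)
  bsa <- utils::modifyList(eval(defaults$bsa), bsa)
  map <- utils::modifyList(eval(defaults$map), map)
  assay$mode <- match.arg(assay$mode, c("direct", "outgrowth"))
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("'conditions' must be a named list", call. = FALSE)
  for (cn in names(conditions)) {
    cond <- conditions[[cn]]
    if (is.null(cond$baseline) || is.null(cond$env_sd))
      stop(sprintf("condition '%s' needs 'baseline' and 'env_sd'", cn),
           call. = FALSE)
    if (cond$env_sd < 0)
      stop(sprintf("condition '%s': env_sd must be >= 0", cn), call. = FALSE)
    if (is.null(cond$qtls)) conditions[[cn]]$qtls <- list()
  }
  structure(list(seed = as.integer(seed), n_segregants = n_segregants,
                 map = map, conditions = conditions, assay = assay,
                 isa = isa, bsa = bsa,
                 n_parent_replicates = n_parent_replicates, outdir = outdir),
            class = "study_config")
}

#' Read / write a study configuration as YAML
#'
#' @param path File path.
#' @param config A `study_config`.
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Effects matrix (markers x conditions) implied by a config.
.config_truth <- function(config) {
  conds <- names(config$conditions)
  markers <- unique(unlist(lapply(config$conditions, function(cond)
    vapply(cond$qtls, `[[`, character(1), "marker"))))
  if (!length(markers)) markers <- character(0)
  eff <- matrix(0, nrow = length(markers), ncol = length(conds),
                dimnames = list(markers, conds))
  for (cn in conds) for (q in config$conditions[[cn]]$qtls)
    eff[q$marker, cn] <- q$effect
  baseline <- vapply(config$conditions, `[[`, numeric(1), "baseline")
  env_sd <- vapply(config$conditions, `[[`, numeric(1), "env_sd")
  if (!length(markers)) {
    # no causal loci: keep a placeholder architecture with zero effect
    return(list(truth = NULL, baseline = baseline, env_sd = env_sd))
  }
  list(truth = qtl_truth(eff, baseline = baseline, env_sd = env_sd),
       baseline = baseline, env_sd = env_sd)
}

# Push simulated SI values through the outgrowth assay and re-quantify.
.assay_phenotypes <- function(si_matrix, assay, seed) {
  conds <- colnames(si_matrix)
  out <- si_matrix
  params <- growth_params()
  counter <- 0L
  for (cn in conds) {
    plates <- vector("list", nrow(si_matrix))
    for (i in seq_len(nrow(si_matrix))) {
      counter <- counter + 1L
      v <- viability_schedule(si_matrix[i, cn], days = assay$days)
      plates[[i]] <- simulate_outgrowth(
        v, params = params, times = assay$times, noise_sd = assay$noise_sd,
        seed = if (assay$noise_sd > 0) .derive_seed(seed, counter) else NULL,
        strain_id = rownames(si_matrix)[i], condition = cn)
    }
    plate <- do.call(rbind, plates)
    ph <- quantify_plate(plate)
    out[ph$strain, cn] <- ph$si
  }
  out
}

#' Run the full in-silico CLS QTL study
#'
#' Executes the complete pipeline implied by a [study_config()]:
#' simulate the cross, generate additive phenotypes per condition
#' (optionally via outgrowth-curve simulation and re-quantification),
#' run ISA and BSA scans per condition, estimate heritability and
#' transgression, compute the condition correlation matrix and
#' dendrogram, and compare detected intervals against the configured
#' truth. Fully deterministic for a fixed seed.
#'
#' @param config A `study_config` (or a path to its YAML form).
#' @return A `cls_study` object.
#' @examples
#' cfg <- study_config(seed = 7, n_segregants = 120,
#'   map = list(n_chrom = 4, markers_per_chrom = 10),
#'   conditions = list(SC = list(baseline = 2, env_sd = 0.4,
#'     qtls = list(list(marker = "c02_m005", effect = 1)))),
#'   isa = list(n_perm = 100), bsa = list(bulk_size = 25))
#' st <- run_study(cfg)
#' print(st)
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  stage <- "simulate-cross"
  res <- tryCatch({
    map <- do.call(make_marker_map, config$map)
    cross <- simulate_cross(map, config$n_segregants,
                            seed = .derive_seed(config$seed, 1L))
    arch <- .config_truth(config)
    stage <- "simulate-phenotypes"
    if (is.null(arch$truth)) {
      conds <- names(config$conditions)
      seed_ph <- .derive_seed(config$seed, 2L)
      set.seed(seed_ph)
      seg <- vapply(conds, function(cn)
        arch$baseline[cn] + stats::rnorm(config$n_segregants, 0,
                                         arch$env_sd[cn]),
        numeric(config$n_segregants))
      rownames(seg) <- rownames(cross$genotypes)
      parents <- expand.grid(parent = c("parent1", "parent2"),
                             condition = conds,
                             replicate = seq_len(config$n_parent_replicates),
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      parents$value <- arch$baseline[parents$condition] +
        stats::rnorm(nrow(parents), 0, arch$env_sd[parents$condition])
      phen <- list(segregants = seg, parents = parents, truth = NULL)
    } else {
      phen <- simulate_phenotypes(cross, arch$truth,
                                  n_parent_replicates = config$n_parent_replicates,
                                  seed = .derive_seed(config$seed, 2L),
                                  si_floor = config$assay$si_floor)
    }
    si <- phen$segregants
    if (config$assay$mode == "outgrowth") {
      stage <- "quantify-outgrowth"
      si <- .assay_phenotypes(si, config$assay,
                              seed = .derive_seed(config$seed, 3L))
    }

    conds <- colnames(si)
    isa <- bsa <- herit <- transgression <- stats::setNames(
      vector("list", length(conds)), conds)
    for (k in seq_along(conds)) {
      cn <- conds[k]
      stage <- paste0("scan-isa:", cn)
      isa[[cn]] <- isa_scan(cross, si[, cn],
                            n_perm = config$isa$n_perm,
                            alpha = config$isa$alpha,
                            lod_drop = config$isa$lod_drop,
                            seed = .derive_seed(config$seed, 100L + k))
      stage <- paste0("scan-bsa:", cn)
      bsa[[cn]] <- bsa_scan(cross, si[, cn],
                            bulk_size = config$bsa$bulk_size,
                            window_kb = config$bsa$window_kb,
                            fdr_level = config$bsa$fdr)
      stage <- paste0("heritability:", cn)
      reps <- split(phen$parents$value[phen$parents$condition == cn],
                    phen$parents$parent[phen$parents$condition == cn])
      herit[[cn]] <- heritability(si[, cn], reps)
      pm <- vapply(reps, mean, numeric(1))
      transgression[[cn]] <- transgression_summary(
        si[, cn], pm, sqrt(herit[[cn]]$V_E))
    }

    stage <- "correlations"
    correlations <- if (length(conds) >= 2L) trait_correlations(si) else NULL
    clustering <- if (length(conds) >= 3L)
      cluster_conditions(correlations$r) else NULL

    stage <- "narrow-sense-h2"
    narrow <- NULL
    if (length(conds) >= 3L) {
      mid <- vapply(conds, function(cn) {
        reps <- split(phen$parents$value[phen$parents$condition == cn],
                      phen$parents$parent[phen$parents$condition == cn])
        mean(vapply(reps, mean, numeric(1)))
      }, numeric(1))
      off <- colMeans(si)
      narrow <- tryCatch(narrow_sense_h2(mid, off), error = function(e) NULL)
    }

    stage <- "report"
    detection <- .detection_report(config, map, isa, bsa)
    structure(list(config = config, map = map, cross = cross,
                   phenotypes = si, parents = phen$parents,
                   truth = arch$truth, isa = isa, bsa = bsa,
                   heritability = herit, transgression = transgression,
                   correlations = correlations, clustering = clustering,
                   narrow_h2 = narrow, detection = detection),
              class = "cls_study")
  }, error = function(e) {
    stop(sprintf("study failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(config$outdir)) .persist_study(res, config$outdir)
  res
}

# Truth-vs-detected table: a configured QTL counts as detected by ISA/BSA
# when a significant interval/region on its chromosome contains it.
.detection_report <- function(config, map, isa, bsa) {
  rows <- list()
  for (cn in names(isa)) {
    qtls <- config$conditions[[cn]]$qtls
    if (!length(qtls)) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cn, marker = NA_character_, effect = 0,
        detected_isa = nrow(isa[[cn]]$intervals) > 0,
        detected_bsa = nrow(bsa[[cn]]$regions) > 0,
        stringsAsFactors = FALSE)
      next
    }
    for (q in qtls) {
      idx <- match(q$marker, map$marker_id)
      ch <- as.character(map$chrom[idx]); pos <- map$pos_bp[idx]
      ii <- isa[[cn]]$intervals
      bi <- bsa[[cn]]$regions
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cn, marker = q$marker, effect = q$effect,
        detected_isa = any(ii$chrom == ch & ii$start_bp <= pos &
                             ii$end_bp >= pos),
        detected_bsa = any(bi$chrom == ch & bi$start_bp <= pos &
                             bi$end_bp >= pos),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.persist_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_marker_map(study$map, file.path(outdir, "marker_map.tsv"))
  write_genotypes(study$cross, file.path(outdir, "genotypes.tsv"))
  ph <- data.frame(strain = rep(rownames(study$phenotypes),
                                ncol(study$phenotypes)),
                   condition = rep(colnames(study$phenotypes),
                                   each = nrow(study$phenotypes)),
                   si = as.vector(study$phenotypes),
                   stringsAsFactors = FALSE)
  write_phenotypes(ph, file.path(outdir, "phenotypes.tsv"))
  if (!is.null(study$truth))
    write_truth(study$truth, file.path(outdir, "truth.yaml"))
  for (cn in names(study$isa)) {
    utils::write.table(study$isa[[cn]]$scan,
                       file.path(outdir, paste0("isa_scan_", cn, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(study$isa[[cn]]$intervals))
      write_bed(study$isa[[cn]]$intervals,
                file.path(outdir, paste0("isa_intervals_", cn, ".bed")))
    utils::write.table(study$bsa[[cn]]$scan,
                       file.path(outdir, paste0("bsa_scan_", cn, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(study$bsa[[cn]]$regions))
      write_bed(study$bsa[[cn]]$regions,
                file.path(outdir, paste0("bsa_regions_", cn, ".bed")))
  }
  hr <- do.call(rbind, lapply(names(study$heritability), function(cn) {
    h <- study$heritability[[cn]]
    data.frame(condition = cn, V_P = h$V_P, V_E = h$V_E, V_G = h$V_G,
               H2 = h$H2, stringsAsFactors = FALSE)
  }))
  utils::write.table(hr, file.path(outdir, "heritability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(study$correlations))
    utils::write.csv(study$correlations$r,
                     file.path(outdir, "condition_correlations.csv"))
  if (!is.null(study$clustering) && requireNamespace("ape", quietly = TRUE))
    write_dendrogram(study$clustering$hclust,
                     file.path(outdir, "condition_dendrogram.nwk"))
  utils::write.table(study$detection, file.path(outdir, "detection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @export
print.cls_study <- function(x, ...) {
  cat(sprintf("CLS QTL study: %d segregants, %d markers, %d condition(s) [seed %d]\n",
              nrow(x$phenotypes), nrow(x$map), ncol(x$phenotypes),
              x$config$seed))
  cat("\nHeritability (broad sense):\n")
  for (cn in names(x$heritability))
    cat(sprintf("  %-8s H2 = %.3f (V_P %.3f, V_E %.3f)\n", cn,
                x$heritability[[cn]]$H2, x$heritability[[cn]]$V_P,
                x$heritability[[cn]]$V_E))
  if (!is.null(x$narrow_h2))
    cat(sprintf("Narrow-sense h2 (parent-offspring regression): %.3f\n",
                x$narrow_h2$h2))
  cat("\nQTL detection (truth vs scans):\n")
  print(x$detection, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cls_study <- function(object, ...) {
  print(object, ...)
  invisible(object)
}
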