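# Tabular I/O. Genotypes, marker maps and phenotypes travel as TSV, plate
# data as long-format CSV, QTL intervals as BED (0-based half-open),
# configs and simulation truth as YAML.

#' Write / read a genotype matrix as TSV
#'
#' Rows are segregants, columns markers; cells are 0 (parent-1 allele),
#' 1 (parent-2 allele) or NA.
#'
#' @param genotypes Segregants x markers matrix or a `cls_cross`.
#' @param path File path.
#' @return `read_genotypes` returns an integer matrix with segregant
#'   rownames and marker colnames.
#' @export
write_genotypes <- function(genotypes, path) {
  if (inherits(genotypes, "cls_cross")) genotypes <- genotypes$genotypes
  df <- data.frame(segregant_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "segregant_id")
    stop("genotype TSV must start with a 'segregant_id' column", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(is.na(m) | m == 0 | m == 1), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid genotype value '%s' at line %d (segregant %s, marker %s)",
                 m[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L,
                 df$segregant_id[bad[1, 1]], colnames(m)[bad[1, 2]]),
         call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- df$segregant_id
  m
}

#' Write / read a marker map as TSV
#'
#' @param map A `marker_map`.
#' @param path File path.
#' @return `read_marker_map` returns a validated `marker_map`.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  validate_marker_map(df)
}

#' Write / read phenotype tables as TSV
#'
#' Long-format phenotypes: one row per strain x condition with Survival
#' Integral and growth parameters.
#'
#' @param phenotypes Data frame with at least `strain`, `condition`, `si`.
#' @param path File path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(as.data.frame(phenotypes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("strain", "condition", "si")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("phenotype TSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Write / read plate-reader data as long-format CSV
#'
#' Columns: `strain`, `condition`, `aging_day`, `time_h`, `od`.
#'
#' @param plate A `plate_data` data frame.
#' @param path File path.
#' @export
write_plate <- function(plate, path) {
  utils::write.csv(as.data.frame(plate), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("strain", "condition", "aging_day", "time_h", "od")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("plate CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(df$od < 0, na.rm = TRUE) || any(df$time_h < 0, na.rm = TRUE))
    stop("plate CSV contains negative time or OD values", call. = FALSE)
  class(df) <- c("plate_data", "data.frame")
  df
}

#' Export QTL intervals as BED
#'
#' Writes regions in BED convention: 0-based half-open coordinates, with
#' the peak marker as the feature name and the peak statistic as score.
#'
#' @param intervals Data frame from [support_intervals()] or a `cls_bsa`
#'   `regions` table (columns `chrom`, `start_bp`, `end_bp`,
#'   `peak_marker`, and a peak statistic).
#' @param path File path.
#' @export
write_bed <- function(intervals, path) {
  score_col <- intersect(c("peak_lod", "peak_gprime"), names(intervals))
  score <- if (length(score_col)) intervals[[score_col[1]]]
           else rep(0, nrow(intervals))
  bed <- data.frame(chrom = intervals$chrom,
                    start = intervals$start_bp - 1L,
                    end = intervals$end_bp,
                    name = intervals$peak_marker,
                    score = round(score, 3))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Accepts a TSV with columns `gene`, `chrom`, `start_bp`, `end_bp`
#' (1-based inclusive) or a GFF3 file (gene features; requires the
#' rtracklayer package).
#'
#' @param path File path (`.gff`/`.gff3` triggers GFF3 parsing).
#' @return Data frame `gene`, `chrom`, `start_bp`, `end_bp`.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the 'rtracklayer' package", call. = FALSE)
    gr <- as.data.frame(rtracklayer::import(path))
    gr <- gr[gr$type == "gene", ]
    nm <- if (!is.null(gr$Name)) gr$Name else gr$ID
    return(data.frame(gene = as.character(nm),
                      chrom = as.character(gr$seqnames),
                      start_bp = gr$start, end_bp = gr$end,
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("gene", "chrom", "start_bp", "end_bp")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

#' Write / read the simulation truth sidecar
#'
#' Persists a `qtl_truth` as YAML so a simulated dataset carries its own
#' generating architecture.
#'
#' @param truth A `qtl_truth`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  obj <- list(causal_markers = truth$causal_markers,
              conditions = colnames(truth$effects),
              effects = as.list(as.data.frame(truth$effects)),
              baseline = as.list(truth$baseline),
              env_sd = as.list(truth$env_sd))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  eff <- do.call(cbind, lapply(obj$effects, unlist))
  rownames(eff) <- obj$causal_markers
  colnames(eff) <- obj$conditions
  qtl_truth(eff, baseline = unlist(obj$baseline), env_sd = unlist(obj$env_sd))
}

#' Load and validate a set of study tables
#'
#' Reads whichever of the genotype/map/phenotype/plate files are given,
#' validates their schemas and cross-checks that genotype markers match
#' the map.
#'
#' @param genotypes,map,phenotypes,plate Optional file paths.
#' @return Named list of the loaded, validated objects.
#' @export
load_tables <- function(genotypes = NULL, map = NULL, phenotypes = NULL,
                        plate = NULL) {
  out <- list()
  if (!is.null(map)) out$map <- read_marker_map(map)
  if (!is.null(genotypes)) {
    out$genotypes <- read_genotypes(genotypes)
    if (!is.null(out$map) &&
        !setequal(colnames(out$genotypes), out$map$marker_id))
      stop("genotype markers do not match the marker map", call. = FALSE)
  }
  if (!is.null(phenotypes)) out$phenotypes <- read_phenotypes(phenotypes)
  if (!is.null(plate)) out$plate <- read_plate(plate)
  out
}

#' Export a condition dendrogram as Newick
#'
#' @param hc An `hclust` tree (e.g. from [cluster_conditions()]).
#' @param path File path.
#' @export
write_dendrogram <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export requires the 'ape' package", call. = FALSE)
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
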