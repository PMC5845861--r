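#' Haldane map function
#'
#' Converts a genetic map distance into a recombination fraction assuming
#' crossovers occur as a Poisson process with no interference:
#' \eqn{r = (1 - e^{-2d}) / 2} with \eqn{d} in Morgans.
#'
#' @param d_cm Map distance in centimorgans (non-negative, vectorised).
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_r(c(0, 1, 10, 50, Inf))
#' @export
haldane_r <- function(d_cm) {
  if (any(d_cm < 0, na.rm = TRUE))
    stop("map distances must be non-negative", call. = FALSE)
  0.5 * (1 - exp(-2 * d_cm / 100))
}

#' Build an evenly spaced marker map
#'
#' Deterministically lays out `markers_per_chrom` markers on each of
#' `n_chrom` chromosomes at a constant genetic spacing, with physical
#' positions obtained from a constant bp-per-cM ratio. The first marker of
#' every chromosome sits at 0 cM and 1 bp.
#'
#' @param n_chrom Number of chromosomes (yeast: 16).
#' @param markers_per_chrom Markers per chromosome.
#' @param spacing_cm Genetic distance between adjacent markers (cM).
#' @param bp_per_cm Physical distance corresponding to 1 cM (bp).
#' @return A `marker_map` data frame with columns `marker_id`, `chrom`
#'   (Roman-numeral labels), `pos_bp` (1-based) and `pos_cm`.
#' @examples
#' make_marker_map(2, 5, 10, 2700)
#' @export
make_marker_map <- function(n_chrom = 16, markers_per_chrom = 19,
                            spacing_cm = 5, bp_per_cm = 2700) {
  n_chrom <- .check_count(n_chrom, "n_chrom")
  markers_per_chrom <- .check_count(markers_per_chrom, "markers_per_chrom")
  .check_scalar_number(spacing_cm, "spacing_cm", lower = 0, strict_lower = TRUE)
  .check_scalar_number(bp_per_cm, "bp_per_cm", lower = 0, strict_lower = TRUE)

  chrom_labels <- as.character(utils::as.roman(seq_len(n_chrom)))
  pos_cm <- (seq_len(markers_per_chrom) - 1) * spacing_cm
  map <- data.frame(
    marker_id = paste0(
      "c", rep(sprintf("%02d", seq_len(n_chrom)), each = markers_per_chrom),
      "_m", rep(sprintf("%03d", seq_len(markers_per_chrom)), n_chrom)
    ),
    chrom = factor(rep(chrom_labels, each = markers_per_chrom),
                   levels = chrom_labels),
    pos_bp = rep(round(pos_cm * bp_per_cm) + 1L, n_chrom),
    pos_cm = rep(pos_cm, n_chrom),
    stringsAsFactors = FALSE
  )
  class(map) <- c("marker_map", "data.frame")
  validate_marker_map(map)
}

#' Validate a marker map
#'
#' Checks the structural invariants of a marker map: unique marker ids,
#' strictly increasing physical positions and non-decreasing genetic
#' positions within each chromosome.
#'
#' @param map A data frame with columns `marker_id`, `chrom`, `pos_bp`,
#'   `pos_cm`.
#' @return The validated map (invisibly classed as `marker_map`).
#' @export
validate_marker_map <- function(map) {
  required <- c("marker_id", "chrom", "pos_bp", "pos_cm")
  missing <- setdiff(required, names(map))
  if (length(missing))
    stop("marker map is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(map$marker_id))
    stop("marker ids must be unique", call. = FALSE)
  for (ch in unique(as.character(map$chrom))) {
    sub <- map[as.character(map$chrom) == ch, ]
    if (is.unsorted(sub$pos_bp, strictly = TRUE))
      stop(sprintf("pos_bp not strictly increasing on chromosome %s", ch),
           call. = FALSE)
    if (is.unsorted(sub$pos_cm))
      stop(sprintf("pos_cm not non-decreasing on chromosome %s", ch),
           call. = FALSE)
  }
  if (!inherits(map, "marker_map")) class(map) <- c("marker_map", "data.frame")
  map
}
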