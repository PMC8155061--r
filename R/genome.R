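#' Reference genome build for C. elegans
#'
#' Chromosome names and physical lengths used for all genome-wide ordering,
#' binning and interval arithmetic. Defaults to the six nuclear chromosomes of
#' the WBcel235 assembly (just over 100 Mb in total). Coordinates throughout
#' the package are 1-based; interval arithmetic is half-open internally and
#' rendered 1-based inclusive in reports.
#'
#' @param chroms Character vector of chromosome names in genome order.
#' @param lengths_bp Integer vector of chromosome lengths in bp.
#' @return A tibble with columns `chrom` (factor, levels in genome order) and
#'   `length_bp`.
#' @examples
#' ce_genome()
#' @export
ce_genome <- function(chroms = c("I", "II", "III", "IV", "V", "X"),
                      lengths_bp = c(15072434L, 15279421L, 13783801L,
                                     17493829L, 20924180L, 17718942L)) {
  stopifnot(length(chroms) == length(lengths_bp), !anyDuplicated(chroms),
            all(lengths_bp > 0))
  tibble::tibble(
    chrom = factor(chroms, levels = chroms),
    length_bp = as.integer(lengths_bp)
  )
}

#' @keywords internal
chrom_levels <- function(build) levels(build$chrom)

#' Coerce a chromosome vector to the build's factor ordering
#' @keywords internal
as_chrom <- function(x, build) {
  factor(as.character(x), levels = chrom_levels(build))
}

#' Order a table of loci in genome order
#'
#' Sorts by chromosome (in the order given by the build), then position, then
#' any further tie-break columns.
#'
#' @param df A data frame with `chrom` and `pos_bp` columns.
#' @param build Genome build tibble, see [ce_genome()].
#' @param ... Additional tie-break columns passed to [dplyr::arrange()].
#' @return The input as a tibble, sorted in genome order.
#' @export
arrange_genome <- function(df, build = ce_genome(), ...) {
  df <- tibble::as_tibble(df)
  df$chrom <- as_chrom(df$chrom, build)
  dplyr::arrange(df, .data$chrom, .data$pos_bp, ...)
}

#' Fixed 1-Mb (or other) windows over a genome build
#'
#' Non-overlapping fixed windows per chromosome; the terminal partial window
#' counts as a full interval. Bin indices are 0-based: position p falls in bin
#' `floor((p - 1) / bin_size)`.
#'
#' @param build Genome build tibble.
#' @param bin_size_bp Window size in bp (default 1 Mb).
#' @return Tibble with `chrom`, `bin`, `start_bp`, `end_bp` (1-based inclusive).
#' @export
genome_bins <- function(build = ce_genome(), bin_size_bp = 1e6) {
  stopifnot(bin_size_bp > 0)
  purrr::pmap_dfr(build, function(chrom, length_bp) {
    n <- ceiling(length_bp / bin_size_bp)
    tibble::tibble(
      chrom = chrom,
      bin = seq_len(n) - 1L,
      start_bp = as.integer((seq_len(n) - 1L) * bin_size_bp + 1),
      end_bp = as.integer(pmin(seq_len(n) * bin_size_bp, length_bp))
    )
  }) |>
    dplyr::mutate(chrom = as_chrom(.data$chrom, build))
}

#' Default genetic map for the N2 x CB4856 cross
#'
#' Piecewise-linear genetic map anchors (physical bp vs genetic cM position)
#' per chromosome. Genetic positions are signed: loci on the left arm carry
#' negative cM values and the chromosome center sits near 0 cM, following the
#' standard worm convention. The default map gives each chromosome ~50 cM
#' (~300 cM genome-wide) with the outer thirds (the recombination-rich arms)
#' at about twice the central rate, the well-known pattern for this species.
#'
#' @param build Genome build tibble.
#' @param arm_cM Genetic length of each arm-plus-tip side (cM); each chromosome
#'   spans `[-arm_cM, +arm_cM]`.
#' @param center_cM Genetic span of the central third (cM).
#' @return Tibble of anchors with `chrom`, `pos_bp`, `pos_cM`, strictly
#'   increasing in both coordinates within each chromosome.
#' @export
ce_genetic_map <- function(build = ce_genome(), arm_cM = 25, center_cM = 10) {
  stopifnot(arm_cM > center_cM / 2, center_cM > 0)
  purrr::pmap_dfr(build, function(chrom, length_bp) {
    tibble::tibble(
      chrom = chrom,
      pos_bp = as.numeric(c(1, round(length_bp / 3), round(2 * length_bp / 3),
                            length_bp)),
      pos_cM = c(-arm_cM, -center_cM / 2, center_cM / 2, arm_cM)
    )
  }) |>
    dplyr::mutate(chrom = as_chrom(.data$chrom, build))
}

#' @keywords internal
check_genetic_map <- function(map) {
  by_chr <- split(map, map$chrom, drop = TRUE)
  for (m in by_chr) {
    if (nrow(m) < 2) stop("genetic map needs >= 2 anchors per chromosome")
    if (is.unsorted(m$pos_bp, strictly = TRUE) ||
        is.unsorted(m$pos_cM, strictly = TRUE)) {
      stop("genetic map anchors must be strictly increasing in bp and cM")
    }
  }
  invisible(map)
}

#' Interpolate genetic position (cM) at physical loci
#'
#' Linear interpolation between flanking anchors; outside the anchored range
#' the value is clamped to the terminal anchor's cM.
#'
#' @param map Genetic map anchor tibble, see [ce_genetic_map()].
#' @param chrom Chromosome name (scalar or vector recycled against `pos_bp`).
#' @param pos_bp Physical positions (bp).
#' @return Numeric vector of genetic positions in cM.
#' @export
cm_at <- function(map, chrom, pos_bp) {
  check_genetic_map(map)
  n <- max(length(chrom), length(pos_bp))
  chrom <- rep_len(as.character(chrom), n)
  pos_bp <- rep_len(pos_bp, n)
  out <- numeric(n)
  for (ch in unique(chrom)) {
    m <- map[as.character(map$chrom) == ch, ]
    if (nrow(m) == 0) stop("chromosome not in genetic map: ", ch)
    i <- chrom == ch
    out[i] <- stats::approx(m$pos_bp, m$pos_cM, xout = pos_bp[i],
                            rule = 2, ties = "ordered")$y
  }
  out
}

#' Interpolate physical position (bp) at genetic loci
#'
#' Inverse of [cm_at()]: linear interpolation of bp against cM anchors, clamped
#' to terminal anchors outside the range.
#'
#' @inheritParams cm_at
#' @param pos_cM Genetic positions in cM.
#' @return Numeric vector of physical positions (bp).
#' @export
bp_at <- function(map, chrom, pos_cM) {
  check_genetic_map(map)
  n <- max(length(chrom), length(pos_cM))
  chrom <- rep_len(as.character(chrom), n)
  pos_cM <- rep_len(pos_cM, n)
  out <- numeric(n)
  for (ch in unique(chrom)) {
    m <- map[as.character(map$chrom) == ch, ]
    if (nrow(m) == 0) stop("chromosome not in genetic map: ", ch)
    i <- chrom == ch
    out[i] <- stats::approx(m$pos_cM, m$pos_bp, xout = pos_cM[i],
                            rule = 2, ties = "ordered")$y
  }
  out
}
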