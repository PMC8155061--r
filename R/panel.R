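# Unified nearest-neighbor duplex parameters (dH kcal/mol, dS cal/(mol K))
# for Watson-Crick dinucleotide steps, plus terminal initiation terms.
nn_dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
nn_dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
init_dH <- c(GC = 0.1, AT = 2.3)
init_dS <- c(GC = -2.8, AT = 4.1)

#' @keywords internal
revcomp <- function(seq) {
  chartr("ACGT", "TGCA", vapply(strsplit(seq, NULL), function(x) {
    paste(rev(x), collapse = "")
  }, character(1)))
}

#' Nearest-neighbor primer melting temperature
#'
#' Duplex melting temperature from the unified nearest-neighbor
#' thermodynamic parameter set with an entropy-based monovalent-salt
#' correction (`dS + 0.368 * (N - 1) * ln[mono]`, `N` the primer length) and
#' terminal A.T / G.C initiation terms. Assumes the primer anneals to its
#' exact complement in excess template, so the effective strand concentration
#' is the primer concentration divided by 4.
#'
#' @param seq Character vector of primer sequences (uppercase ACGT).
#' @param monovalent_mM Total monovalent cation concentration (mM, default 50).
#' @param primer_uM Primer concentration (micromolar, default 0.25).
#' @return Numeric vector of melting temperatures in degrees C.
#' @examples
#' estimate_tm("AGCGTACGTTAGCCTAGGCA")
#' @export
estimate_tm <- function(seq, monovalent_mM = 50, primer_uM = 0.25) {
  stopifnot(monovalent_mM > 0, primer_uM > 0)
  vapply(seq, function(s) {
    s <- toupper(s)
    chars <- strsplit(s, NULL)[[1]]
    if (length(chars) < 8) stop("primer must be at least 8 nt")
    if (!all(chars %in% c("A", "C", "G", "T"))) {
      stop("primer contains non-ACGT characters: ", s)
    }
    steps <- paste0(chars[-length(chars)], chars[-1])
    ends <- ifelse(chars[c(1, length(chars))] %in% c("G", "C"), "GC", "AT")
    dH <- sum(nn_dH[steps]) + sum(init_dH[ends])          # kcal/mol
    dS <- sum(nn_dS[steps]) + sum(init_dS[ends])          # cal/(mol K)
    dS <- dS + 0.368 * (length(chars) - 1) * log(monovalent_mM / 1000)
    ct <- primer_uM * 1e-6 / 4
    dH * 1000 / (dS + 1.987 * log(ct)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

marker_violation_codes <- c("N2_SIZE", "CB_SIZE", "ORIENTATION", "SIZE_MISMATCH",
                            "TM_FWD", "TM_REV", "SMALL_CHANGE")

#' Validate marker loci against the panel design constraints
#'
#' Checks each marker row against the design rules of the 96-well panel:
#' N2 product size within 500-1500 bp (`N2_SIZE`), CB4856 product within
#' 400-1300 bp (`CB_SIZE`), CB4856 product strictly smaller than the N2
#' product (`ORIENTATION`; CB products are designed smaller so the mutant
#' pool's missing band is always the lower one), product size difference
#' equal to the indel length change when both are present (`SIZE_MISMATCH`),
#' primer melting temperatures within `tm_target +/- tm_tol`
#' (`TM_FWD`/`TM_REV`), and - as a warning-level code only - a length change
#' of 100 bp or less (`SMALL_CHANGE`) when `flag_small_change` is set, since
#' small changes separate poorly on gel but a few are kept deliberately to
#' cover Mb intervals with no larger indel.
#'
#' @param markers Marker tibble as produced by [synthetic_marker_table()]
#'   (columns `marker_id`, `n2_product_bp`, `cb_product_bp`, and optionally
#'   `size_change_bp`, `tm_fwd`, `tm_rev`).
#' @param tm_target Target melting temperature (degrees C, default 60).
#' @param tm_tol Allowed deviation from the target (degrees C, default 2).
#' @param flag_small_change Emit the `SMALL_CHANGE` warning code for length
#'   changes <= 100 bp (default TRUE).
#' @return A long tibble with `marker_id`, `code`, `severity`
#'   (`"violation"` or `"warning"`); zero rows when every marker passes.
#'   Validation never errors on content.
#' @export
validate_markers <- function(markers, tm_target = 60, tm_tol = 2,
                             flag_small_change = TRUE) {
  markers <- tibble::as_tibble(markers)
  out <- list()
  emit <- function(mask, code, severity = "violation") {
    mask[is.na(mask)] <- FALSE
    if (any(mask)) {
      out[[length(out) + 1]] <<- tibble::tibble(
        marker_id = markers$marker_id[mask], code = code, severity = severity)
    }
  }
  emit(markers$n2_product_bp < 500 | markers$n2_product_bp > 1500, "N2_SIZE")
  emit(markers$cb_product_bp < 400 | markers$cb_product_bp > 1300, "CB_SIZE")
  emit(markers$cb_product_bp >= markers$n2_product_bp, "ORIENTATION")
  if ("size_change_bp" %in% names(markers)) {
    emit(markers$n2_product_bp - markers$cb_product_bp != markers$size_change_bp,
         "SIZE_MISMATCH")
    if (flag_small_change) {
      emit(markers$size_change_bp <= 100, "SMALL_CHANGE", "warning")
    }
  }
  if ("tm_fwd" %in% names(markers)) {
    emit(abs(markers$tm_fwd - tm_target) > tm_tol, "TM_FWD")
  }
  if ("tm_rev" %in% names(markers)) {
    emit(abs(markers$tm_rev - tm_target) > tm_tol, "TM_REV")
  }
  if (length(out) == 0) {
    return(tibble::tibble(marker_id = character(), code = character(),
                          severity = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$marker_id, .data$code)
}

#' Select a genome-covering marker panel
#'
#' Greedy maximisation of the number of distinct 1-Mb windows covered: at
#' each step the candidate covering the most not-yet-covered windows is
#' added; ties (including the steps after every coverable window is taken)
#' prefer higher CB4856-band success at 1:9 dilution (`p_dilute`), then
#' larger indel length change, then the lower genome coordinate. Selection
#' stops at `target_size` markers or when candidates run out.
#'
#' @param candidates Marker tibble with `marker_id`, `chrom`, `pos_bp` and
#'   optionally `p_dilute`, `size_change_bp`.
#' @param build Genome build tibble.
#' @param target_size Panel size (default 96).
#' @param bin_size_bp Window size for coverage (default 1 Mb).
#' @return The selected markers in genome order.
#' @export
select_panel <- function(candidates, build = ce_genome(), target_size = 96,
                         bin_size_bp = 1e6) {
  candidates <- tibble::as_tibble(candidates)
  if (nrow(candidates) == 0) stop("no candidate markers supplied")
  cand <- candidates
  cand$.chrom_i <- as.integer(as_chrom(cand$chrom, build))
  cand$.bin <- paste0(cand$.chrom_i, ":", floor((cand$pos_bp - 1) / bin_size_bp))
  cand$.p_dilute <- if ("p_dilute" %in% names(cand)) cand$p_dilute else 0
  cand$.size <- if ("size_change_bp" %in% names(cand)) cand$size_change_bp else 0L
  picked <- logical(nrow(cand))
  covered <- character(0)
  for (step in seq_len(min(target_size, nrow(cand)))) {
    gain <- ifelse(picked, -1L, as.integer(!(cand$.bin %in% covered)))
    best <- order(-gain, -cand$.p_dilute, -cand$.size,
                  cand$.chrom_i, cand$pos_bp)[1]
    if (picked[best]) break
    picked[best] <- TRUE
    covered <- union(covered, cand$.bin[best])
  }
  out <- candidates[picked, ]
  arrange_genome(out, build)
}

#' @keywords internal
plate_wells <- function(n) {
  stopifnot(n <= 96)
  paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))[seq_len(n)]
}

#' Assign 96-well plate positions in genome order
#'
#' Markers are laid out row-major (A1..A12, B1..B12, ... H12) following
#' genome order from the left end of chromosome I to the right end of X, so
#' neighbouring wells hold neighbouring loci and a linked region reads as a
#' block of lanes without the lower CB4856 band.
#'
#' @param panel Marker tibble with `chrom` and `pos_bp` (at most 96 rows).
#' @param build Genome build tibble.
#' @return The panel in genome order with a `well` column.
#' @export
assign_wells <- function(panel, build = ce_genome()) {
  panel <- tibble::as_tibble(panel)
  if (nrow(panel) > 96) stop("a plate holds at most 96 markers, got ", nrow(panel))
  panel <- arrange_genome(panel, build)
  panel$well <- plate_wells(nrow(panel))
  panel
}
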