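#' Call the mutation-containing interval from pooled band observations
#'
#' Scans genome-ordered marker observations for the signature of linkage in a
#' pool of phenotype-selected mutants: a maximal consecutive same-chromosome
#' stretch of markers whose N2-sized band is present but whose CB4856-sized
#' band is absent. Failed reactions (neither band) are non-informative and do
#' not break a run. The winning run is the longest by marker count, ties
#' resolved by larger physical span, then genome order. The reported interval
#' runs from the nearest CB4856-positive marker left of the run (or bp 1) to
#' the nearest CB4856-positive marker right of it (or the chromosome end).
#' A best run of a single marker is reported with status `"hint"` (its
#' interval is still given); with no CB4856-negative informative marker at
#' all the status is `"no_linkage"`. Both are results, not errors.
#'
#' @param observations Tibble with `marker_id`, `chrom`, `pos_bp`, `cb_band`,
#'   `n2_band` (logical band presence).
#' @param build Genome build tibble (for ordering and chromosome ends).
#' @param min_run Minimum run length for a `"linked"` call (default 2).
#' @return A `mapping_result` object: a list with `status` (`"linked"`,
#'   `"hint"` or `"no_linkage"`), `chrom`, `lo_bp`, `hi_bp`,
#'   `supporting_markers`, `flanking_markers`, `n_markers_in_run`,
#'   `inconsistent`, and the full `runs` table.
#' @export
call_pooled <- function(observations, build = ce_genome(), min_run = 2L) {
  obs <- tibble::as_tibble(observations)
  stopifnot(all(c("marker_id", "cb_band", "n2_band") %in% names(obs)))
  chrom_i <- as.integer(as_chrom(obs$chrom, build))
  if (anyNA(chrom_i)) stop("observation chromosomes must be in the build")
  obs <- obs[order(chrom_i, obs$pos_bp, obs$marker_id), ]
  obs$chrom <- as.character(obs$chrom)
  # informative markers only; FAIL (no band at all) does not break runs
  inf <- obs[obs$cb_band | obs$n2_band, ]
  inf$negative <- inf$n2_band & !inf$cb_band
  runs <- enumerate_runs(inf, build)
  if (nrow(runs) == 0) {
    return(new_mapping_result(status = "no_linkage", runs = runs))
  }
  runs <- runs[order(-runs$n_markers, -runs$span_bp,
                     runs$chrom_i, runs$start_bp), ]
  best <- runs[1, ]
  chrom <- best$chrom
  on_chr <- inf[as.character(inf$chrom) == chrom, ]
  pos_cb <- on_chr$pos_bp[!on_chr$negative]
  left_flank <- pos_cb[pos_cb < best$start_bp]
  right_flank <- pos_cb[pos_cb > best$end_bp]
  chrom_len <- build$length_bp[as.character(build$chrom) == chrom]
  lo <- if (length(left_flank) > 0) max(left_flank) else 1
  hi <- if (length(right_flank) > 0) min(right_flank) else chrom_len
  run_markers <- on_chr$marker_id[on_chr$negative &
                                    on_chr$pos_bp >= best$start_bp &
                                    on_chr$pos_bp <= best$end_bp]
  flank_ids <- c(
    if (length(left_flank) > 0)
      on_chr$marker_id[on_chr$pos_bp == max(left_flank) & !on_chr$negative][1]
    else "chrom_start",
    if (length(right_flank) > 0)
      on_chr$marker_id[on_chr$pos_bp == min(right_flank) & !on_chr$negative][1]
    else "chrom_end"
  )
  new_mapping_result(
    status = if (best$n_markers >= min_run) "linked" else "hint",
    chrom = chrom, lo_bp = lo, hi_bp = hi,
    supporting_markers = run_markers,
    flanking_markers = flank_ids,
    n_markers_in_run = best$n_markers,
    runs = runs
  )
}

#' @keywords internal
enumerate_runs <- function(inf, build) {
  # maximal stretches of consecutive negative informative markers per chromosome
  empty <- tibble::tibble(chrom = character(), chrom_i = integer(),
                          start_bp = numeric(), end_bp = numeric(),
                          n_markers = integer(), span_bp = numeric())
  if (nrow(inf) == 0 || !any(inf$negative)) return(empty)
  chrom_i <- as.integer(as_chrom(inf$chrom, build))
  grp <- cumsum(c(TRUE, diff(chrom_i) != 0 |
                    diff(as.integer(inf$negative)) != 0))
  keep <- inf$negative
  g <- grp[keep]
  first <- !duplicated(g)
  last <- !duplicated(g, fromLast = TRUE)
  pos <- inf$pos_bp[keep]
  tibble::tibble(
    chrom = as.character(inf$chrom)[keep][first],
    chrom_i = chrom_i[keep][first],
    start_bp = pos[first],
    end_bp = pos[last],
    n_markers = as.integer(tabulate(match(g, unique(g)))),
    span_bp = pos[last] - pos[first]
  )
}

#' @keywords internal
new_mapping_result <- function(status, chrom = NA_character_, lo_bp = NA_real_,
                               hi_bp = NA_real_, supporting_markers = character(),
                               flanking_markers = character(),
                               n_markers_in_run = 0L, inconsistent = FALSE,
                               runs = NULL) {
  structure(
    list(status = status, chrom = chrom, lo_bp = lo_bp, hi_bp = hi_bp,
         supporting_markers = supporting_markers,
         flanking_markers = flanking_markers,
         n_markers_in_run = as.integer(n_markers_in_run),
         inconsistent = inconsistent, runs = runs),
    class = "mapping_result"
  )
}

#' @export
print.mapping_result <- function(x, ...) {
  cat("<mapping_result>\n")
  if (x$status == "no_linkage") {
    cat("  no linkage detected (no CB4856-negative marker run)\n")
  } else {
    cat(sprintf("  status: %s%s\n", x$status,
                if (x$inconsistent) " (inconsistent with individual genotypes)" else ""))
    cat(sprintf("  interval: %s:%s-%s (%.2f Mb)\n", x$chrom,
                format(x$lo_bp, big.mark = ","), format(x$hi_bp, big.mark = ","),
                (x$hi_bp - x$lo_bp) / 1e6))
    cat(sprintf("  supporting markers (%d): %s\n", x$n_markers_in_run,
                paste(x$supporting_markers, collapse = ", ")))
    cat(sprintf("  flanking markers: %s\n",
                paste(x$flanking_markers, collapse = ", ")))
  }
  invisible(x)
}

#' Tidy a mapping result
#'
#' @param x A `mapping_result`.
#' @param ... Unused.
#' @return One row per supporting marker with the interval coordinates, or a
#'   single status row for a no-linkage result.
#' @method tidy mapping_result
#' @export
tidy.mapping_result <- function(x, ...) {
  if (x$status == "no_linkage" || length(x$supporting_markers) == 0) {
    return(tibble::tibble(marker_id = character(), chrom = character(),
                          lo_bp = numeric(), hi_bp = numeric()))
  }
  tibble::tibble(marker_id = x$supporting_markers, chrom = x$chrom,
                 lo_bp = x$lo_bp, hi_bp = x$hi_bp)
}

#' One-row summary of a mapping result
#'
#' @inheritParams tidy.mapping_result
#' @return A one-row tibble with status, interval, width and run size.
#' @method glance mapping_result
#' @export
glance.mapping_result <- function(x, ...) {
  tibble::tibble(
    status = x$status, chrom = x$chrom, lo_bp = x$lo_bp, hi_bp = x$hi_bp,
    width_mb = (x$hi_bp - x$lo_bp) / 1e6,
    n_markers_in_run = x$n_markers_in_run,
    inconsistent = x$inconsistent
  )
}

#' Refine a pooled mapping interval with individual F2 genotypes
#'
#' In phenotype-selected (assumed homozygous mutant) worms, any marker where
#' at least one worm shows a CB4856 allele (`NC` or `CC` call) lies outside
#' the mutation-containing region; markers called `NN` in every worm (with
#' `FAIL` calls non-informative) remain candidates. The refined interval is
#' the region strictly between the innermost CB4856-allele-bearing markers
#' that flank the best all-NN marker stretch inside the pooled interval,
#' intersected with the pooled interval so refinement never widens it. If no
#' all-NN marker exists inside the pooled interval the pooled result is
#' returned flagged `inconsistent`.
#'
#' @param genotypes Long tibble with `individual`, `marker_id`, `call`
#'   (`"NN"`, `"NC"`, `"CC"`, `"FAIL"`), e.g. from
#'   [simulate_individual_bands()].
#' @param markers Marker positions: `marker_id`, `chrom`, `pos_bp`.
#' @param pooled_result A `mapping_result` from [call_pooled()].
#' @param build Genome build tibble.
#' @return A `mapping_result` with the refined interval.
#' @export
refine_with_individuals <- function(genotypes, markers, pooled_result,
                                    build = ce_genome()) {
  stopifnot(inherits(pooled_result, "mapping_result"))
  if (pooled_result$status == "no_linkage") {
    stop("cannot refine a no-linkage result")
  }
  markers <- arrange_genome(tibble::as_tibble(markers), build, .data$marker_id)
  on_chr <- markers[as.character(markers$chrom) == pooled_result$chrom, ]
  gt <- tibble::as_tibble(genotypes)
  gt <- gt[gt$marker_id %in% on_chr$marker_id, ]
  if (nrow(gt) == 0) {
    stop("no genotypes on the mapped chromosome ", pooled_result$chrom)
  }
  status <- gt |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(
      has_cb = any(.data$call %in% c("NC", "CC")),
      all_nn = all(.data$call %in% c("NN", "FAIL")) & any(.data$call == "NN")
    )
  m <- dplyr::left_join(on_chr, status, by = "marker_id")
  m$has_cb[is.na(m$has_cb)] <- FALSE
  m$all_nn[is.na(m$all_nn)] <- FALSE
  inside <- m$pos_bp >= pooled_result$lo_bp & m$pos_bp <= pooled_result$hi_bp
  cand <- m[inside & m$all_nn, ]
  if (nrow(cand) == 0) {
    out <- pooled_result
    out$inconsistent <- TRUE
    return(out)
  }
  # best all-NN stretch inside the pooled interval: longest, then wider span,
  # then leftmost (same tie-breaks as the pooled caller)
  mm <- m[m$has_cb | m$all_nn, ]  # genotype-informative markers
  grp <- cumsum(c(TRUE, diff(as.integer(mm$all_nn)) != 0))
  stretches <- mm |>
    dplyr::mutate(grp = grp) |>
    dplyr::filter(.data$all_nn,
                  .data$pos_bp >= pooled_result$lo_bp,
                  .data$pos_bp <= pooled_result$hi_bp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(start_bp = min(.data$pos_bp), end_bp = max(.data$pos_bp),
                     n = dplyr::n(),
                     ids = list(.data$marker_id)) |>
    dplyr::arrange(dplyr::desc(.data$n),
                   dplyr::desc(.data$end_bp - .data$start_bp), .data$start_bp)
  best <- stretches[1, ]
  cb_pos <- m$pos_bp[m$has_cb]
  left <- cb_pos[cb_pos < best$start_bp]
  right <- cb_pos[cb_pos > best$end_bp]
  lo <- max(c(pooled_result$lo_bp, left))
  hi <- min(c(pooled_result$hi_bp, right))
  flank <- c(
    if (length(left) > 0 && max(left) >= pooled_result$lo_bp)
      m$marker_id[m$pos_bp == max(left) & m$has_cb][1]
    else pooled_result$flanking_markers[1],
    if (length(right) > 0 && min(right) <= pooled_result$hi_bp)
      m$marker_id[m$pos_bp == min(right) & m$has_cb][1]
    else pooled_result$flanking_markers[2]
  )
  new_mapping_result(
    status = pooled_result$status,
    chrom = pooled_result$chrom, lo_bp = lo, hi_bp = hi,
    supporting_markers = best$ids[[1]],
    flanking_markers = flank,
    n_markers_in_run = best$n,
    runs = pooled_result$runs
  )
}

#' Report genes and genetic coordinates for a mapped interval
#'
#' @param result A `mapping_result`.
#' @param catalog Catalog tibble with nearest-gene annotation.
#' @param map Genetic map anchors (for the interval's cM coordinates).
#' @return Tibble of the distinct annotated genes falling inside the
#'   interval, in coordinate order, with the physical and genetic interval
#'   bounds attached as columns; a no-linkage result yields a single status
#'   row with no genes.
#' @export
map_report <- function(result, catalog, map = ce_genetic_map()) {
  stopifnot(inherits(result, "mapping_result"))
  if (result$status == "no_linkage") {
    return(tibble::tibble(status = "no_linkage", chrom = NA_character_,
                          gene_id = NA_character_, gene_pos_bp = NA_real_))
  }
  inside <- catalog[as.character(catalog$chrom) == result$chrom &
                      !is.na(catalog$gene_id) &
                      catalog$gene_pos_bp >= result$lo_bp &
                      catalog$gene_pos_bp <= result$hi_bp, ]
  genes <- dplyr::distinct(inside[, c("gene_id", "gene_pos_bp", "gene_pos_cM")]) |>
    dplyr::arrange(.data$gene_pos_bp)
  cm <- cm_at(map, result$chrom, c(result$lo_bp, result$hi_bp))
  tibble::tibble(
    status = result$status, chrom = result$chrom,
    lo_bp = result$lo_bp, hi_bp = result$hi_bp,
    lo_cM = cm[1], hi_cM = cm[2],
    gene_id = if (nrow(genes)) genes$gene_id else NA_character_,
    gene_pos_bp = if (nrow(genes)) genes$gene_pos_bp else NA_real_,
    gene_pos_cM = if (nrow(genes)) genes$gene_pos_cM else NA_real_
  )
}
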