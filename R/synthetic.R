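#' Synthetic indel catalog with arm-enriched density
#'
#' Draws a catalog whose per-region variant counts are Poisson at the stated
#' densities, emulating the real pattern in which autosome centers carry far
#' fewer large indels than the recombination-rich arms. Arms are the outer
#' thirds of each autosome; the X chromosome is treated uniformly at the arm
#' density. Length changes are uniform on [40, 699]; positions uniform within
#' their region; each variant is assigned a carrier set drawn from the isolate
#' universe (one isolate, plus extras with probability `p_shared`).
#'
#' @param build Genome build tibble.
#' @param arm_density,center_density Expected indels per Mb on autosome arms
#'   (and the whole X) and autosome centers.
#' @param isolates Character vector of isolate names to draw carriers from.
#' @param p_shared Probability a variant is carried by more than one isolate.
#' @param seed Integer seed; the same seed reproduces the same catalog.
#' @return A catalog tibble, see [as_indel_catalog()].
#' @export
make_synthetic_catalog <- function(build = ce_genome(),
                                   arm_density = 10, center_density = 1,
                                   isolates = c("CB4856", "JU258", "MY2"),
                                   p_shared = 0.3, seed = 1L) {
  if (arm_density < 0 || center_density < 0) stop("densities must be >= 0")
  withr::local_seed(seed)
  regions <- purrr::pmap_dfr(build, function(chrom, length_bp) {
    if (identical(as.character(chrom), "X")) {
      tibble::tibble(chrom = chrom, start = 1, end = length_bp,
                     density = arm_density)
    } else {
      b1 <- round(length_bp / 3); b2 <- round(2 * length_bp / 3)
      tibble::tibble(
        chrom = chrom,
        start = c(1, b1 + 1, b2 + 1),
        end = c(b1, b2, length_bp),
        density = c(arm_density, center_density, arm_density)
      )
    }
  })
  rows <- purrr::pmap_dfr(regions, function(chrom, start, end, density) {
    n <- stats::rpois(1, density * (end - start + 1) / 1e6)
    if (n == 0) return(NULL)
    tibble::tibble(
      chrom = as.character(chrom),
      pos_bp = sort(sample.int(end - start + 1L, n, replace = TRUE)) + start - 1
    )
  })
  if (nrow(rows) == 0) {
    return(as_indel_catalog(
      tibble::tibble(variant_id = character(), chrom = character(),
                     pos_bp = numeric(), size_change_bp = integer()),
      build
    ))
  }
  rows$size_change_bp <- sample(40:699, nrow(rows), replace = TRUE)
  rows$longer_allele <- sample(c("N2", "isolate"), nrow(rows), replace = TRUE)
  rows$isolates <- draw_carrier_sets(nrow(rows), isolates, p_shared)
  rows <- arrange_genome(rows, build)
  rows$variant_id <- sprintf("SYNVar%05d", seq_len(nrow(rows)))
  out <- as_indel_catalog(rows, build)
  attr(out, "isolate_universe") <- isolates
  out
}

#' @keywords internal
draw_carrier_sets <- function(n, isolates, p_shared) {
  first <- sample(isolates, n, replace = TRUE)
  if (length(isolates) == 1L) return(first)
  extra <- stats::runif(n) < p_shared
  vapply(seq_len(n), function(i) {
    if (!extra[i]) return(first[i])
    k <- sample.int(length(isolates) - 1L, 1)
    paste(c(first[i], sample(setdiff(isolates, first[i]), k)), collapse = ";")
  }, character(1))
}

#' Synthetic wild-isolate natural variant catalog
#'
#' Generates a full 40-isolate indel catalog at the study conditions of the
#' real WormBase-derived data: 11,556 indels of 40-699 bp in total across the
#' 40 wild isolates; CB4856 carrying about 1,660 of them with at least one in
#' every 1 Mb interval; two further well-covered isolates (JU258, JU775) and a
#' closely related trio (JU1171, MY2, MY14) sharing most of their indels; and
#' 34 sparse isolates whose indels sit mostly on chromosome arms, leaving many
#' empty 1 Mb intervals. Carrier sets, positions within regions and indel
#' sizes are random under the seed; the headline counts are fixed by
#' construction. Names other than the six isolates discussed above are
#' synthetic placeholders (`WI07`..`WI40`).
#'
#' @param seed Integer seed.
#' @param build Genome build tibble.
#' @param n_total Total number of catalog records (default 11556).
#' @param n_cb4856 Number of records carried by CB4856 (default 1664).
#' @return A catalog tibble with the 40-isolate universe attached; nearest
#'   genes are annotated against [synthetic_gene_table()].
#' @export
synthetic_natural_variants <- function(seed = 1L, build = ce_genome(),
                                       n_total = 11556L, n_cb4856 = 1664L) {
  withr::local_seed(seed)
  sparse <- sprintf("WI%02d", 7:40)
  universe <- c("CB4856", "JU258", "JU775", "JU1171", "MY2", "MY14", sparse)
  bins <- genome_bins(build)

  # CB4856: one indel per 1 Mb bin guaranteed, remainder arm-weighted;
  # ~60% unique to CB4856, the rest shared with random other isolates.
  guaranteed <- bins |>
    dplyr::mutate(pos_bp = .data$start_bp +
                    floor(stats::runif(dplyr::n()) * (.data$end_bp - .data$start_bp + 1)))
  extra_n <- n_cb4856 - nrow(guaranteed)
  cb_extra <- sample_arm_positions(build, extra_n, arm_weight = 4)
  cb <- dplyr::bind_rows(
    dplyr::mutate(dplyr::select(guaranteed, "chrom", "pos_bp"),
                  chrom = as.character(.data$chrom)),
    cb_extra
  )
  cb$isolates <- ifelse(
    stats::runif(nrow(cb)) < 0.6, "CB4856",
    vapply(seq_len(nrow(cb)), function(i) {
      paste(c("CB4856", sample(setdiff(universe, "CB4856"),
                               sample.int(4, 1))), collapse = ";")
    }, character(1))
  )

  # Closely related trio: a large common core plus small private sets.
  core <- sample_arm_positions(build, 1000L, arm_weight = 3)
  core$isolates <- vapply(seq_len(nrow(core)), function(i) {
    extra <- if (stats::runif(1) < 0.15)
      sample(sparse, sample.int(2, 1)) else character()
    paste(c("JU1171", "MY2", "MY14", extra), collapse = ";")
  }, character(1))
  trio_private <- sample_arm_positions(build, 450L, arm_weight = 3)
  trio_private$isolates <- sample(c("JU1171", "MY2", "MY14"), 450L, replace = TRUE)

  # JU258, JU775: well covered but with a few deliberately empty intervals.
  covered <- purrr::map_dfr(c("JU258", "JU775"), function(iso) {
    gap_bins <- dplyr::slice_sample(bins, n = 5)
    pos <- sample_arm_positions(build, 1100L, arm_weight = 2)
    pos <- dplyr::anti_join(
      dplyr::mutate(pos, bin = floor((.data$pos_bp - 1) / 1e6)),
      dplyr::mutate(dplyr::select(gap_bins, "chrom", "bin"),
                    chrom = as.character(.data$chrom)),
      by = c("chrom", "bin")
    )
    pos$isolates <- ifelse(stats::runif(nrow(pos)) < 0.8, iso,
                           paste(iso, sample(sparse, nrow(pos), replace = TRUE),
                                 sep = ";"))
    dplyr::select(pos, "chrom", "pos_bp", "isolates")
  })

  # 34 sparse isolates: small, strongly arm-biased private sets.
  n_so_far <- nrow(cb) + nrow(core) + nrow(trio_private) + nrow(covered)
  n_sparse <- n_total - n_so_far
  sp <- sample_arm_positions(build, n_sparse, arm_weight = 12)
  sp$isolates <- vapply(seq_len(n_sparse), function(i) {
    paste(sample(sparse, sample(1:3, 1, prob = c(0.7, 0.2, 0.1))),
          collapse = ";")
  }, character(1))

  rows <- dplyr::bind_rows(dplyr::select(cb, "chrom", "pos_bp", "isolates"),
                           core, trio_private, covered, sp)
  stopifnot(nrow(rows) == n_total)
  rows$chrom <- as.character(rows$chrom)
  rows$size_change_bp <- sample(40:699, n_total, replace = TRUE)
  rows$longer_allele <- sample(c("N2", "isolate"), n_total, replace = TRUE)
  rows <- arrange_genome(rows, build)
  rows$variant_id <- sprintf("SYNVar%05d", seq_len(n_total))
  out <- as_indel_catalog(rows, build)
  attr(out, "isolate_universe") <- universe
  out <- annotate_nearest_gene(out, synthetic_gene_table(build, seed = seed))
  attr(out, "isolate_universe") <- universe
  attr(out, "build") <- build
  out
}

#' @keywords internal
sample_arm_positions <- function(build, n, arm_weight = 4) {
  # Regions: autosome arms (outer thirds) weighted arm_weight : 1 vs centers;
  # X uniform at weight 1.
  regions <- purrr::pmap_dfr(build, function(chrom, length_bp) {
    if (identical(as.character(chrom), "X")) {
      tibble::tibble(chrom = as.character(chrom), start = 1, end = length_bp, w = 1)
    } else {
      b1 <- round(length_bp / 3); b2 <- round(2 * length_bp / 3)
      tibble::tibble(chrom = as.character(chrom),
                     start = c(1, b1 + 1, b2 + 1), end = c(b1, b2, length_bp),
                     w = c(arm_weight, 1, arm_weight))
    }
  })
  wt <- regions$w * (regions$end - regions$start + 1)
  idx <- sample.int(nrow(regions), n, replace = TRUE, prob = wt)
  tibble::tibble(
    chrom = regions$chrom[idx],
    pos_bp = regions$start[idx] +
      floor(stats::runif(n) * (regions$end[idx] - regions$start[idx] + 1))
  )
}

#' Synthetic gene table
#'
#' Evenly spaced synthetic gene records (one per ~50 kb, jittered) with
#' genetic positions interpolated from [ce_genetic_map()], for nearest-gene
#' annotation of synthetic catalogs.
#'
#' @param build Genome build tibble.
#' @param spacing_bp Mean spacing between genes.
#' @param seed Integer seed.
#' @return Tibble with `gene_id`, `chrom`, `pos_bp`, `pos_cM`.
#' @export
synthetic_gene_table <- function(build = ce_genome(), spacing_bp = 5e4,
                                 seed = 1L) {
  withr::local_seed(seed + 101L)
  map <- ce_genetic_map(build)
  genes <- purrr::pmap_dfr(build, function(chrom, length_bp) {
    pos <- seq(spacing_bp / 2, length_bp, by = spacing_bp)
    pos <- pmin(pmax(1, round(pos + stats::rnorm(length(pos), 0, spacing_bp / 10))),
                length_bp)
    tibble::tibble(chrom = as.character(chrom), pos_bp = sort(pos))
  })
  genes$gene_id <- sprintf("syngene-%05d", seq_len(nrow(genes)))
  genes$pos_cM <- cm_at(map, genes$chrom, genes$pos_bp)
  genes[, c("gene_id", "chrom", "pos_bp", "pos_cM")]
}

#' Synthetic 96-well marker/primer table
#'
#' Emulates the toolkit's marker table: 102 indel marker loci spread at about
#' one per Mb across the genome, each with a primer pair (20-mers accepted at
#' an estimated melting temperature of 60 +/- `tm_tol` degrees C), expected N2
#' and CB4856 product sizes inside the design windows (N2 500-1500 bp, CB4856
#' 400-1300 bp, N2 always larger by the indel size), PCR success rates under
#' the two template conditions, and a plate well. By construction 95 of the
#' 102 pairs exceed 90% success with full (0.1 adult) template, 82 reach at
#' least 75% CB4856-band success with 1:9 CB4856:N2 template, and about half
#' of those are at 100%; the 96 best loci fill wells A1..H12 in genome order
#' and the rest are marked `NU` (not in the oft-used plate).
#'
#' @param seed Integer seed.
#' @param build Genome build tibble.
#' @param n_loci Number of marker loci (default 102).
#' @param tm_tol Acceptance half-width around the 60 degree Tm target when
#'   drawing primer sequences.
#' @return Tibble with columns `marker_id`, `chrom`, `pos_bp`,
#'   `size_change_bp`, `fwd_seq`, `rev_seq`, `tm_fwd`, `tm_rev`,
#'   `n2_product_bp`, `cb_product_bp`, `p_full`, `p_dilute`, `well`.
#' @export
synthetic_marker_table <- function(seed = 1L, build = ce_genome(),
                                   n_loci = 102L, tm_tol = 2) {
  withr::local_seed(seed + 202L)
  bins <- genome_bins(build)
  # ~1 marker/Mb: sample n_loci distinct bins spread over the genome, one
  # marker near the middle of each.
  chosen <- dplyr::slice_sample(bins, n = min(n_loci, nrow(bins)))
  chosen <- dplyr::bind_rows(
    chosen,
    dplyr::slice_sample(bins, n = n_loci - nrow(chosen))
  )
  loci <- chosen |>
    dplyr::mutate(pos_bp = .data$start_bp +
                    floor(stats::runif(n_loci) * (.data$end_bp - .data$start_bp + 1))) |>
    dplyr::select("chrom", "pos_bp")
  loci <- arrange_genome(loci, build)
  loci$marker_id <- sprintf("im%03d", seq_len(n_loci))

  # mostly >100 bp length changes, a few smaller ones kept for coverage
  small <- stats::runif(n_loci) < 0.1
  loci$size_change_bp <- ifelse(small, sample(40:100, n_loci, replace = TRUE),
                                sample(101:699, n_loci, replace = TRUE))
  lo <- pmax(400, 500 - loci$size_change_bp)
  hi <- pmin(1300, 1500 - loci$size_change_bp)
  loci$cb_product_bp <- lo + floor(stats::runif(n_loci) * (hi - lo + 1))
  loci$n2_product_bp <- loci$cb_product_bp + loci$size_change_bp

  # success-rate structure at the two template conditions
  n_hi_full <- 95L; n_hi_dil <- 82L; n_perfect <- 50L
  p_full <- c(stats::runif(n_hi_full, 0.905, 1),
              stats::runif(n_loci - n_hi_full, 0.5, 0.9))
  p_dilute <- numeric(n_loci)
  hi_dil <- sample(seq_len(n_hi_full), n_hi_dil)  # high-dilute pairs among high-full
  perfect <- sample(hi_dil, n_perfect)
  p_dilute[hi_dil] <- stats::runif(n_hi_dil, 0.75, 0.95)
  p_dilute[perfect] <- 1
  p_full[perfect] <- 1
  rest <- setdiff(seq_len(n_loci), hi_dil)
  p_dilute[rest] <- stats::runif(length(rest), 0.2, 0.745)
  p_dilute <- pmin(p_dilute, p_full)
  ord <- sample.int(n_loci)  # decouple rate structure from genome order
  loci$p_full <- round(p_full[ord], 3)
  loci$p_dilute <- round(p_dilute[ord], 3)

  primers <- purrr::map(seq_len(n_loci), function(i) {
    c(draw_primer(tm_target = 60, tm_tol = tm_tol),
      draw_primer(tm_target = 60, tm_tol = tm_tol))
  })
  loci$fwd_seq <- purrr::map_chr(primers, 1)
  loci$rev_seq <- purrr::map_chr(primers, 2)
  loci$tm_fwd <- round(estimate_tm(loci$fwd_seq), 2)
  loci$tm_rev <- round(estimate_tm(loci$rev_seq), 2)

  # 96 plate wells in genome order; extra loci (lowest p_dilute) are NU
  nu <- integer(0)
  if (n_loci > 96L) nu <- order(loci$p_dilute, loci$p_full)[seq_len(n_loci - 96L)]
  loci$well <- "NU"
  in_plate <- setdiff(seq_len(n_loci), nu)
  loci$well[in_plate] <- plate_wells(length(in_plate))
  loci[, c("marker_id", "chrom", "pos_bp", "size_change_bp",
           "fwd_seq", "rev_seq", "tm_fwd", "tm_rev",
           "n2_product_bp", "cb_product_bp", "p_full", "p_dilute", "well")]
}

#' @keywords internal
draw_primer <- function(len = 20L, tm_target = 60, tm_tol = 2, max_tries = 500L) {
  for (i in seq_len(max_tries)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = c(0.22, 0.28, 0.28, 0.22)), collapse = "")
    tm <- estimate_tm(s)
    if (abs(tm - tm_target) <= tm_tol) return(s)
  }
  stop("could not draw a primer near the target Tm")  # nocov
}

#' Synthetic mutagenesis burden table
#'
#' Per-strain mutation counts emulating the Million Mutation Project
#' mutagenesis summaries: 656 strains mutagenised with 50 mM EMS (total
#' mutations per strain drawn around 376 +/- 100, predicted-effect mutations
#' around 86 +/- 24) and 943 strains with 50 mM EMS + 1 mM ENU (545 +/- 149
#' total, 123 +/- 34 with predicted effect). Counts are truncated at zero and
#' effect counts never exceed totals.
#'
#' @param seed Integer seed.
#' @return Tibble with `strain`, `method`, `n_total`, `n_effect`.
#' @export
synthetic_mutagenesis_table <- function(seed = 1L) {
  withr::local_seed(seed + 303L)
  spec <- tibble::tibble(
    method = c("50 mM EMS", "50 mM EMS + 1 mM ENU"),
    n = c(656L, 943L),
    mean_total = c(376, 545), sd_total = c(100, 149),
    mean_effect = c(86, 123), sd_effect = c(24, 34)
  )
  purrr::pmap_dfr(spec, function(method, n, mean_total, sd_total,
                                 mean_effect, sd_effect) {
    total <- pmax(0L, round(stats::rnorm(n, mean_total, sd_total)))
    effect <- pmax(0L, pmin(total, round(stats::rnorm(n, mean_effect, sd_effect))))
    tibble::tibble(
      strain = sprintf("SYN%s-%04d", ifelse(method == "50 mM EMS", "EMS", "EMSENU"),
                       seq_len(n)),
      method = method, n_total = as.integer(total), n_effect = as.integer(effect)
    )
  })
}
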