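single_chrom_build <- function(n = 12, spacing = 1e6) {
  ce_genome(chroms = "I", lengths_bp = n * spacing + 1e6)
}

obs_from_pattern <- function(cb, n2 = rep(TRUE, length(cb)), spacing = 1e6) {
  tibble::tibble(marker_id = sprintf("m%02d", seq_along(cb)), chrom = "I",
                 pos_bp = spacing * seq_along(cb), cb_band = cb, n2_band = n2)
}

test_that("a clean interior run is bracketed by its flanking CB-positive markers", {
  cb <- rep(TRUE, 12); cb[4:7] <- FALSE
  r <- call_pooled(obs_from_pattern(cb), single_chrom_build())
  expect_equal(r$status, "linked")
  expect_equal(r$supporting_markers, sprintf("m%02d", 4:7))
  expect_equal(r$lo_bp, 3e6)
  expect_equal(r$hi_bp, 8e6)
  expect_equal(r$flanking_markers, c("m03", "m08"))
  expect_equal(r$n_markers_in_run, 4L)
})

test_that("CB bands everywhere yield a no-linkage result, not an error", {
  r <- call_pooled(obs_from_pattern(rep(TRUE, 12)), single_chrom_build())
  expect_equal(r$status, "no_linkage")
  expect_equal(nrow(tidy(r)), 0)
  expect_equal(glance(r)$status, "no_linkage")
})

test_that("runs at a chromosome end clip the interval to the end", {
  cb <- rep(TRUE, 12); cb[1:3] <- FALSE
  r <- call_pooled(obs_from_pattern(cb), single_chrom_build())
  expect_equal(r$lo_bp, 1)
  expect_equal(r$hi_bp, 4e6)
  cb2 <- rep(TRUE, 12); cb2[10:12] <- FALSE
  r2 <- call_pooled(obs_from_pattern(cb2), single_chrom_build())
  expect_equal(r2$lo_bp, 9e6)
  expect_equal(r2$hi_bp, 13e6)  # chromosome length
})

test_that("failed reactions are non-informative and do not break runs", {
  cb <- rep(TRUE, 12); cb[c(4, 6, 7)] <- FALSE
  n2 <- rep(TRUE, 12); n2[5] <- FALSE; cb[5] <- FALSE  # marker 5 FAILs
  r <- call_pooled(obs_from_pattern(cb, n2), single_chrom_build())
  expect_equal(r$status, "linked")
  expect_equal(r$supporting_markers, sprintf("m%02d", c(4, 6, 7)))
  expect_equal(r$lo_bp, 3e6)
  expect_equal(r$hi_bp, 8e6)
})

test_that("a lone CB-negative marker is a hint, not a linkage call", {
  cb <- rep(TRUE, 12); cb[6] <- FALSE
  r <- call_pooled(obs_from_pattern(cb), single_chrom_build())
  expect_equal(r$status, "hint")
  expect_equal(r$n_markers_in_run, 1L)
  expect_equal(c(r$lo_bp, r$hi_bp), c(5e6, 7e6))
})

test_that("pooled calls agree with exhaustive run enumeration over 2^10 patterns", {
  build <- single_chrom_build(10)
  obs <- obs_from_pattern(rep(TRUE, 10))
  for (code in 0:1023) {
    cb <- as.logical(bitwAnd(code, 2^(0:9)))
    obs$cb_band <- cb
    got <- call_pooled(obs, build)
    want <- oracle_call_pooled(cb, obs$pos_bp, build$length_bp[1])
    expect_equal(got$status, want$status, info = paste("pattern", code))
    if (want$status != "no_linkage") {
      expect_equal(got$lo_bp, want$lo, info = paste("pattern", code))
      expect_equal(got$hi_bp, want$hi, info = paste("pattern", code))
      expect_equal(got$supporting_markers, obs$marker_id[want$support],
                   info = paste("pattern", code))
    }
  }
})

test_that("tie-breaks prefer the physically wider run, then genome order", {
  # two 2-marker runs; second spans more bp because of uneven spacing
  pos <- c(1, 2, 3, 4.0, 6.5, 9) * 1e6
  cb <- c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  obs <- tibble::tibble(marker_id = sprintf("m%d", 1:6), chrom = "I",
                        pos_bp = pos, cb_band = cb, n2_band = TRUE)
  r <- call_pooled(obs, single_chrom_build(12))
  expect_equal(r$supporting_markers, c("m5", "m6"))
  # equal span -> leftmost wins
  cb2 <- c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE)
  obs2 <- obs_from_pattern(cb2)
  r2 <- call_pooled(obs2, single_chrom_build(12))
  expect_equal(r2$supporting_markers, c("m01", "m02"))
})

test_that("individual genotypes refine the pooled interval to recombinant breakpoints", {
  mk <- toy_markers(6)
  pooled <- call_pooled(
    obs_from_pattern(c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)),
    single_chrom_build(6)
  )
  gt <- tidyr::crossing(individual = 1:10, marker_id = mk$marker_id) |>
    dplyr::mutate(call = "NN")
  gt$call[gt$individual == 1 & gt$marker_id == "m02"] <- "NC"
  gt$call[gt$individual == 2 & gt$marker_id == "m05"] <- "NC"
  r <- refine_with_individuals(gt, mk, pooled, single_chrom_build(6))
  expect_equal(c(r$lo_bp, r$hi_bp), c(2e6, 5e6))
  expect_equal(r$supporting_markers, c("m03", "m04"))
  expect_false(r$inconsistent)
})

test_that("all-NN genotypes leave the pooled interval unchanged", {
  mk <- toy_markers(6)
  pooled <- call_pooled(
    obs_from_pattern(c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)),
    single_chrom_build(6)
  )
  gt <- tidyr::crossing(individual = 1:10, marker_id = mk$marker_id) |>
    dplyr::mutate(call = "NN")
  r <- refine_with_individuals(gt, mk, pooled, single_chrom_build(6))
  expect_equal(c(r$lo_bp, r$hi_bp), c(pooled$lo_bp, pooled$hi_bp))
})

test_that("contradictory genotypes flag the result as inconsistent", {
  mk <- toy_markers(6)
  pooled <- call_pooled(
    obs_from_pattern(c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)),
    single_chrom_build(6)
  )
  gt <- tidyr::crossing(individual = 1:3, marker_id = mk$marker_id) |>
    dplyr::mutate(call = ifelse(individual == 1, "CC", "NN"))
  r <- refine_with_individuals(gt, mk, pooled, single_chrom_build(6))
  expect_true(r$inconsistent)
  expect_equal(c(r$lo_bp, r$hi_bp), c(pooled$lo_bp, pooled$hi_bp))
  expect_error(
    refine_with_individuals(gt[0, ], mk, pooled, single_chrom_build(6)),
    "no genotypes"
  )
})

test_that("refinement never widens an interval (random genotype tables)", {
  withr::local_seed(47)
  build <- single_chrom_build(8)
  mk <- toy_markers(8)
  pooled <- call_pooled(
    obs_from_pattern(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
                     spacing = 1e6),
    build
  )
  for (i in 1:30) {
    gt <- tidyr::crossing(individual = 1:6, marker_id = mk$marker_id) |>
      dplyr::mutate(call = sample(c("NN", "NC", "FAIL"), 48, replace = TRUE,
                                  prob = c(0.7, 0.15, 0.15)))
    r <- refine_with_individuals(gt, mk, pooled, build)
    expect_gte(r$lo_bp, pooled$lo_bp)
    expect_lte(r$hi_bp, pooled$hi_bp)
  }
})

test_that("map_report lists interval genes in coordinate order", {
  build <- single_chrom_build(6)
  cat <- toy_catalog(tibble::tibble(chrom = "I", pos_bp = c(2.5e6, 3.5e6, 9e6),
                                    size_change_bp = 100L), build)
  genes <- tibble::tibble(gene_id = c("gA", "gB", "gC"), chrom = "I",
                          pos_bp = c(2.4e6, 3.6e6, 9.1e6))
  cat <- annotate_nearest_gene(cat, genes)
  pooled <- call_pooled(
    obs_from_pattern(c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)),
    build
  )
  map <- tibble::tibble(chrom = factor("I"), pos_bp = c(1, 7e6),
                        pos_cM = c(-10, 10))
  rpt <- map_report(pooled, cat, map)
  expect_equal(rpt$gene_id, c("gA", "gB"))
  expect_true(all(diff(rpt$gene_pos_bp) > 0))
  nl <- call_pooled(obs_from_pattern(rep(TRUE, 6)), build)
  rep_nl <- map_report(nl, cat, map)
  expect_equal(rep_nl$status, "no_linkage")
  expect_true(is.na(rep_nl$gene_id))
})
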