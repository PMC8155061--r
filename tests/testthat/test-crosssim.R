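test_that("genetic-map interpolation hits anchors, midpoints and clamps ends", {
  build <- ce_genome(chroms = "I", lengths_bp = 10e6)
  map <- tibble::tibble(chrom = factor("I"), pos_bp = c(1, 4e6, 10e6),
                        pos_cM = c(0, 10, 30))
  expect_equal(cm_at(map, "I", 4e6), 10)
  expect_equal(cm_at(map, "I", 2e6 + 0.5), 5, tolerance = 1e-6)
  expect_equal(cm_at(map, "I", 1), 0)        # left of/at first anchor clamps
  expect_equal(cm_at(map, "I", 1e7 + 5e6), 30)
  expect_equal(bp_at(map, "I", 10), 4e6)
  expect_error(cm_at(map, "II", 1), "not in")
})

test_that("gametes are reproducible and respect chromosome structure", {
  map <- ce_genetic_map()
  g1 <- make_gametes(20, map, seed = 4)
  g2 <- make_gametes(20, map, seed = 4)
  expect_identical(g1, g2)
  # segments sorted, contiguous, within bounds, alternating origin
  build <- ce_genome()
  for (ch in c("I", "X")) {
    len <- build$length_bp[build$chrom == ch]
    segs <- g1[as.character(g1$chrom) == ch, ]
    for (gam in unique(segs$gamete)) {
      s <- segs[segs$gamete == gam, ]
      expect_equal(s$start_bp[1], 1)
      expect_equal(s$end_bp[nrow(s)], len + 1)
      if (nrow(s) > 1) {
        expect_equal(s$start_bp[-1], s$end_bp[-nrow(s)])
        expect_true(all(diff(s$start_bp) >= 0))
        alt <- s$origin[s$start_bp < s$end_bp]  # drop zero-length segments
        expect_true(all(alt[-1] != alt[-length(alt)]))
      }
    }
  }
})

test_that("a zero-length genetic map yields no crossovers", {
  build <- ce_genome(chroms = "I", lengths_bp = 1e6)
  map <- tibble::tibble(chrom = factor("I"), pos_bp = c(1, 1e6),
                        pos_cM = c(0, 1e-9))
  g <- make_gametes(200, map, build, seed = 1)
  expect_equal(nrow(g), 200L)  # one segment per gamete
})

test_that("crossover counts follow the Poisson map-length expectation", {
  build <- ce_genome(chroms = "I", lengths_bp = 10e6)
  map <- tibble::tibble(chrom = factor("I"), pos_bp = c(1, 10e6),
                        pos_cM = c(0, 100))  # 1 Morgan
  g <- make_gametes(1e4, map, build, seed = 8)
  xo <- tabulate(g$gamete, nbins = 1e4) - 1L
  se <- sqrt(1 / 1e4)  # Poisson(1) mean has SE sqrt(lambda/n)
  expect_lt(abs(mean(xo) - 1), 3 * se)
})

test_that("unselected F2 segregate 1:2:1 at every tested locus", {
  pop <- make_f2_population(1e4, seed = 13)
  for (locus in list(c("I", 2e6), c("III", 7e6), c("X", 12e6))) {
    gt <- genotype_at(pop, locus[1], as.numeric(locus[2]))
    counts <- table(factor(gt$genotype, levels = c("NN", "NC", "CC")))
    p <- stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
    expect_gt(p, 0.001)
  }
})

test_that("phenotype selection keeps the Mendelian quarter, scaled by penetrance", {
  pop <- make_f2_population(1e4, seed = 17)
  locus <- c("II", 7.5e6)
  sel <- select_homozygous_mutants(pop, locus[1], as.numeric(locus[2]))
  frac <- length(unique(sel$individual)) / 1e4
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 1e4))
  # all selected individuals are homozygous N2 at the locus
  gt <- genotype_at(sel, locus[1], as.numeric(locus[2]))
  expect_true(all(gt$genotype == "NN"))
  half <- select_homozygous_mutants(pop, locus[1], as.numeric(locus[2]),
                                    penetrance = 0.5, seed = 2)
  frac_half <- length(unique(half$individual)) / 1e4
  expect_lt(abs(frac_half - 0.125), 3 * sqrt(0.125 * 0.875 / 1e4))
  expect_error(select_homozygous_mutants(pop, "II", 7.5e6, penetrance = 0))
})

test_that("CB4856 allele fraction is 0 at the selected locus and ~0.5 unlinked", {
  pop <- make_f2_population(2000, seed = 19)
  sel <- select_homozygous_mutants(pop, "II", 7.5e6)
  n_hap <- 2 * length(unique(sel$individual))
  expect_equal(cb_allele_fraction(sel, "II", 7.5e6), 0)
  f <- cb_allele_fraction(sel, "V", 10e6)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n_hap))
  expect_error(cb_allele_fraction(pop[0, ], "I", 1), "empty")
})

test_that("Haldane closed form behaves at its anchors", {
  expect_equal(expected_cb_fraction_selected(0), 0)
  expect_equal(expected_cb_fraction_selected(1e4), 0.5, tolerance = 1e-12)
  expect_equal(expected_cb_fraction_selected(50), (1 - exp(-1)) / 2)
  d <- seq(0, 200, by = 5)
  expect_true(all(diff(expected_cb_fraction_selected(d)) > 0))
  expect_error(expected_cb_fraction_selected(-1), ">= 0")
})

test_that("marker CB fraction among selected mutants tracks the Haldane fraction", {
  build <- ce_genome()
  map <- ce_genetic_map(build)
  # mutation at the left telomere of V (-25 cM) leaves 50 cM of room rightward
  mut_bp <- 1
  withr::local_seed(23)
  pop <- make_f2_population(4100, map, build)
  sel <- select_homozygous_mutants(pop, "V", mut_bp)
  n_hap <- 2 * length(unique(sel$individual))
  expect_gte(n_hap, 2 * 1000)
  for (d in c(0, 5, 10, 20, 50)) {
    mk_bp <- bp_at(map, "V", -25 + d)
    f <- cb_allele_fraction(sel, "V", mk_bp)
    th <- expected_cb_fraction_selected(d)
    se <- sqrt(th * (1 - th) / n_hap)
    expect_lte(abs(f - th), max(3 * se, 1e-12))
  }
})
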