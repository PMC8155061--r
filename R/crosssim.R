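#' Expected CB4856 allele fraction among phenotype-selected mutants
#'
#' Among F2 animals selected to be homozygous for the (N2-background)
#' mutation, each haplotype carries the CB4856 allele at a marker `d` cM away
#' with probability equal to the Haldane recombination fraction
#' `r(d) = (1 - exp(-2 d / 100)) / 2`: monotone increasing from 0 at the
#' mutation itself to 0.5 for unlinked markers.
#'
#' @param d_cM Non-negative map distance(s) in cM.
#' @return Expected per-haplotype CB4856 allele fraction in `[0, 0.5)`.
#' @examples
#' expected_cb_fraction_selected(c(0, 5, 50))
#' @export
expected_cb_fraction_selected <- function(d_cM) {
  if (any(d_cM < 0)) stop("map distance must be >= 0")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Simulate meiotic gametes of the N2/CB4856 F1 heterozygote
#'
#' Haldane (no-interference) meiosis: per chromosome the crossover count is
#' Poisson with mean equal to the map length in Morgans, crossover positions
#' are uniform on the cM scale (converted to bp by inverse interpolation of
#' the genetic map), and the starting parental origin is a fair coin. Each
#' gamete is returned as a mosaic of half-open `[start_bp, end_bp)` segments
#' of `"N2"` or `"CB"` origin.
#'
#' @param n Number of gametes.
#' @param map Genetic map anchors, see [ce_genetic_map()].
#' @param build Genome build tibble.
#' @param seed Optional integer seed; omit to draw from the current RNG
#'   stream (e.g. inside a seeded caller).
#' @return Tibble with `gamete`, `chrom`, `start_bp`, `end_bp`, `origin`;
#'   segments are sorted and contiguous, origins alternate across breakpoints.
#' @export
make_gametes <- function(n, map = ce_genetic_map(), build = ce_genome(),
                         seed = NULL) {
  check_genetic_map(map)
  if (!is.null(seed)) withr::local_seed(seed)
  purrr::pmap_dfr(build, function(chrom, length_bp) {
    ch <- as.character(chrom)
    m <- map[as.character(map$chrom) == ch, ]
    if (nrow(m) == 0) stop("chromosome not in genetic map: ", ch)
    len_morgan <- (max(m$pos_cM) - min(m$pos_cM)) / 100
    k <- stats::rpois(n, len_morgan)
    start_cb <- stats::runif(n) < 0.5
    xo_cm <- stats::runif(sum(k), min(m$pos_cM), max(m$pos_cM))
    xo_bp <- if (length(xo_cm) > 0) round(bp_at(map, ch, xo_cm)) else numeric(0)
    gam <- rep.int(seq_len(n), k)
    # breakpoints sorted within gamete; duplicates (same bp twice) cancel out
    # as zero-length segments and are harmless for origin queries
    ord <- order(gam, xo_bp)
    gam <- gam[ord]; xo_bp <- xo_bp[ord]
    seg_n <- k + 1L
    g_idx <- rep.int(seq_len(n), seg_n)
    starts <- numeric(sum(seg_n)); ends <- numeric(sum(seg_n))
    first <- cumsum(seg_n) - seg_n + 1L
    starts[first] <- 1
    ends[first + seg_n - 1L] <- length_bp + 1
    if (length(xo_bp) > 0) {
      # crossover j of gamete g ends segment (first[g] + j - 1)
      j_within <- sequence(k)
      idx <- first[gam] + j_within - 1L
      ends[idx] <- xo_bp
      starts[idx + 1L] <- xo_bp
    }
    seg_par <- (rep.int(as.integer(start_cb), seg_n) +
                  (sequence(seg_n) - 1L)) %% 2L
    tibble::tibble(
      gamete = g_idx, chrom = ch,
      start_bp = starts, end_bp = ends,
      origin = ifelse(seg_par == 1L, "CB", "N2")
    )
  }) |>
    dplyr::mutate(chrom = as_chrom(.data$chrom, build))
}

#' Simulate an F2 mapping population by F1 selfing
#'
#' Forms `n_f2` F2 individuals, each from two independent gametes of the F1
#' CB4856/N2 heterozygote (self-fertilisation of the F1 hermaphrodite).
#'
#' @param n_f2 Number of F2 individuals.
#' @param map Genetic map anchors.
#' @param build Genome build tibble.
#' @param seed Optional integer seed.
#' @return Segment tibble as in [make_gametes()] with `individual` and `hap`
#'   (1 or 2) columns replacing `gamete`.
#' @export
make_f2_population <- function(n_f2, map = ce_genetic_map(),
                               build = ce_genome(), seed = NULL) {
  stopifnot(n_f2 > 0)
  g <- make_gametes(2 * n_f2, map, build, seed)
  g$individual <- (g$gamete + 1L) %/% 2L
  g$hap <- ifelse(g$gamete %% 2L == 1L, 1L, 2L)
  dplyr::select(g, "individual", "hap", "chrom", "start_bp", "end_bp", "origin")
}

#' Parental origin of every haplotype at a locus
#'
#' @param pop Population segment tibble from [make_f2_population()] (or a
#'   gamete tibble from [make_gametes()]).
#' @param chrom Chromosome of the locus.
#' @param pos_bp Physical position of the locus.
#' @return Tibble with one row per haplotype: the identifier columns of `pop`
#'   plus `origin` at the locus.
#' @export
origin_at <- function(pop, chrom, pos_bp) {
  hit <- pop[as.character(pop$chrom) == as.character(chrom) &
               pop$start_bp <= pos_bp & pos_bp < pop$end_bp &
               pop$start_bp < pop$end_bp, ]
  id_cols <- intersect(c("individual", "hap", "gamete"), names(pop))
  dplyr::select(hit, dplyr::all_of(c(id_cols, "origin")))
}

#' Genotype every individual at a locus
#'
#' @inheritParams origin_at
#' @return Tibble with `individual`, `n_cb` (number of CB4856-origin
#'   haplotypes, 0/1/2) and `genotype` (`"NN"`, `"NC"`, `"CC"`).
#' @export
genotype_at <- function(pop, chrom, pos_bp) {
  origin_at(pop, chrom, pos_bp) |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(n_cb = sum(.data$origin == "CB")) |>
    dplyr::mutate(genotype = c("NN", "NC", "CC")[.data$n_cb + 1L]) |>
    dplyr::ungroup()
}

#' Select phenotype-positive homozygous mutants from an F2 population
#'
#' The causal mutation sits on the N2 background, so phenotype selection
#' retains individuals homozygous N2 at the mutation locus; each such
#' individual is kept with probability `penetrance` (incomplete penetrance
#' loses true mutants but never admits non-mutants).
#'
#' @param pop Population segment tibble.
#' @param chrom,pos_bp Mutation locus.
#' @param penetrance Probability a homozygous mutant shows the phenotype
#'   (default 1).
#' @param seed Optional integer seed for the penetrance draw.
#' @return The segment rows of the selected individuals.
#' @export
select_homozygous_mutants <- function(pop, chrom, pos_bp, penetrance = 1,
                                      seed = NULL) {
  stopifnot(penetrance > 0, penetrance <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  geno <- genotype_at(pop, chrom, pos_bp)
  mutants <- geno$individual[geno$n_cb == 0L]
  if (penetrance < 1) {
    mutants <- mutants[stats::runif(length(mutants)) < penetrance]
  }
  pop[pop$individual %in% mutants, ]
}

#' CB4856 allele fraction at a marker in a (selected) population
#'
#' The fraction of haplotypes carrying the CB4856 allele at the marker:
#' `(# CB-origin haplotypes) / (2 x # individuals)`. In a pool of selected
#' mutants this is the template fraction feeding the CB4856-sized PCR band.
#'
#' @inheritParams origin_at
#' @return A single fraction in `[0, 1]`.
#' @export
cb_allele_fraction <- function(pop, chrom, pos_bp) {
  if (nrow(pop) == 0) stop("empty population")
  o <- origin_at(pop, chrom, pos_bp)
  mean(o$origin == "CB")
}

#' CB4856 allele fractions at a set of markers
#'
#' @param pop Population segment tibble.
#' @param markers Marker tibble with `marker_id`, `chrom`, `pos_bp`.
#' @return `markers` with an `f_cb` column.
#' @export
cb_allele_fractions <- function(pop, markers) {
  if (nrow(pop) == 0) stop("empty population")
  markers <- tibble::as_tibble(markers)
  markers$f_cb <- purrr::map2_dbl(as.character(markers$chrom), markers$pos_bp,
                                  function(ch, p) cb_allele_fraction(pop, ch, p))
  markers
}

#' True genotypes of each individual at a set of markers
#'
#' @inheritParams cb_allele_fractions
#' @return Long tibble with `individual`, `marker_id`, `n_cb`, `genotype`.
#' @export
genotype_markers <- function(pop, markers) {
  markers <- tibble::as_tibble(markers)
  purrr::pmap_dfr(
    markers[, c("marker_id", "chrom", "pos_bp")],
    function(marker_id, chrom, pos_bp) {
      g <- genotype_at(pop, as.character(chrom), pos_bp)
      g$marker_id <- marker_id
      g
    }
  ) |>
    dplyr::select("individual", "marker_id", "n_cb", "genotype")
}
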