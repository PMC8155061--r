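#' Band detection probability as a function of allele template fraction
#'
#' Maps the fraction of pooled template carrying an allele to the probability
#' that its PCR band is observed, anchored at the two measured conditions of
#' the marker table: `p(0.5) = p_full` (equal-mix template) and
#' `p(0.1) = p_dilute` (1:9 CB4856:N2 template). Between the anchors the
#' curve is log-linear in the fraction; above 0.5 it is constant at
#' `p_full`; below 0.1 it decays geometrically, `p_dilute^(0.1 / f)`, so the
#' success probability falls with the number of template copies and a
#' perfectly reliable marker (`p_dilute = 1`) stays detectable at any
#' non-zero fraction; `p(0) = 0` exactly. The curve is monotone
#' non-decreasing provided `p_full >= p_dilute`, which the model requires
#' (more template never hurts).
#'
#' @param f Allele template fraction(s) in `[0, 1]`.
#' @param p_full Detection probability at fraction 0.5.
#' @param p_dilute Detection probability at fraction 0.1; must not exceed
#'   `p_full`.
#' @return Detection probabilities, clamped to `[0, 1]`.
#' @export
detection_prob <- function(f, p_full, p_dilute) {
  if (any(f < 0 | f > 1)) stop("allele fraction must be in [0, 1]")
  if (any(p_full < 0 | p_full > 1 | p_dilute < 0 | p_dilute > 1)) {
    stop("detection probabilities must be in [0, 1]")
  }
  if (any(p_dilute > p_full)) {
    stop("p_dilute must not exceed p_full (detection cannot fall with more template)")
  }
  n <- max(length(f), length(p_full), length(p_dilute))
  f <- rep_len(f, n); p_full <- rep_len(p_full, n); p_dilute <- rep_len(p_dilute, n)
  p <- numeric(n)
  hi <- f >= 0.5
  p[hi] <- p_full[hi]
  mid <- f >= 0.1 & f < 0.5
  # log-linear between the anchors; a zero anchor pins the whole segment to 0
  pm <- ifelse(p_dilute[mid] == 0 | p_full[mid] == 0,
               ifelse(f[mid] >= 0.5, p_full[mid], 0),
               exp(log(p_dilute[mid]) +
                     (log(p_full[mid]) - log(p_dilute[mid])) * (f[mid] - 0.1) / 0.4))
  p[mid] <- pm
  lo <- f > 0 & f < 0.1
  p[lo] <- p_dilute[lo]^(0.1 / f[lo])
  pmin(pmax(p, 0), 1)
}

#' Simulate PCR band observations for a pooled template
#'
#' For each marker, the CB4856-sized and N2-sized bands are independent
#' Bernoulli draws with probabilities `detection_prob(f_cb, ...)` and
#' `detection_prob(1 - f_cb, ...)` under that marker's success-rate anchors.
#' Optionally a spurious-band rate adds false positives (off-target products
#' at very low template are not modelled beyond this).
#'
#' @param fractions Tibble with `marker_id`, `chrom`, `pos_bp`, `f_cb`
#'   (CB4856 allele fraction of the pool), e.g. from [cb_allele_fractions()].
#' @param model Tibble with `marker_id`, `p_full`, `p_dilute`; defaults to
#'   those columns of `fractions` if present.
#' @param seed Optional integer seed.
#' @param fp_rate Per-band false-positive probability (default 0).
#' @return `fractions` with logical `cb_band` and `n2_band` columns.
#' @export
simulate_pool_bands <- function(fractions, model = NULL, seed = NULL,
                                fp_rate = 0) {
  fractions <- tibble::as_tibble(fractions)
  if (is.null(model)) {
    stopifnot(all(c("p_full", "p_dilute") %in% names(fractions)))
    model <- fractions[, c("marker_id", "p_full", "p_dilute")]
  }
  m <- dplyr::left_join(fractions,
                        tibble::as_tibble(model)[, c("marker_id", "p_full", "p_dilute")],
                        by = "marker_id", suffix = c(".x", ""))
  if (!is.null(seed)) withr::local_seed(seed)
  p_cb <- detection_prob(m$f_cb, m$p_full, m$p_dilute)
  p_n2 <- detection_prob(1 - m$f_cb, m$p_full, m$p_dilute)
  n <- nrow(m)
  fractions$cb_band <- stats::runif(n) < p_cb | stats::runif(n) < fp_rate
  fractions$n2_band <- stats::runif(n) < p_n2 | stats::runif(n) < fp_rate
  fractions
}

#' Simulate per-worm band observations and genotype calls
#'
#' Individual lysates have allele fractions 0, 0.5 or 1 by genotype; bands
#' are drawn as in [simulate_pool_bands()] and converted to calls with
#' [genotype_call()].
#'
#' @param genotypes Long tibble with `individual`, `marker_id`, `genotype`
#'   (`"NN"`, `"NC"`, `"CC"`), e.g. from [genotype_markers()].
#' @param model Tibble with `marker_id`, `p_full`, `p_dilute`.
#' @param seed Optional integer seed.
#' @return `genotypes` with `cb_band`, `n2_band` and observed `call` columns
#'   (`"NN"`, `"NC"`, `"CC"`, `"FAIL"`).
#' @export
simulate_individual_bands <- function(genotypes, model, seed = NULL) {
  genotypes <- tibble::as_tibble(genotypes)
  m <- dplyr::left_join(genotypes,
                        tibble::as_tibble(model)[, c("marker_id", "p_full", "p_dilute")],
                        by = "marker_id")
  if (!is.null(seed)) withr::local_seed(seed)
  f_cb <- c(NN = 0, NC = 0.5, CC = 1)[m$genotype]
  p_cb <- detection_prob(f_cb, m$p_full, m$p_dilute)
  p_n2 <- detection_prob(1 - f_cb, m$p_full, m$p_dilute)
  n <- nrow(m)
  genotypes$cb_band <- stats::runif(n) < p_cb
  genotypes$n2_band <- stats::runif(n) < p_n2
  genotypes$call <- genotype_call(genotypes$n2_band, genotypes$cb_band)
  genotypes
}

#' Genotype call from a pair of band observations
#'
#' N2 band only is homozygous N2 (`NN`), CB4856 band only homozygous CB4856
#' (`CC`), both bands heterozygous (`NC`), neither a failed reaction
#' (`FAIL`).
#'
#' @param n2_present,cb_present Logical vectors.
#' @return Character vector of calls.
#' @export
genotype_call <- function(n2_present, cb_present) {
  dplyr::case_when(
    n2_present & cb_present ~ "NC",
    n2_present & !cb_present ~ "NN",
    !n2_present & cb_present ~ "CC",
    .default = "FAIL"
  )
}
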