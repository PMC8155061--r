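#' Summarise per-strain mutation counts for one mutagenesis method
#'
#' Arithmetic mean and sample (n-1 denominator) standard deviation of total
#' and predicted-effect mutation counts per mutagenised strain.
#'
#' @param total Integer vector of total mutation counts per strain (>= 2
#'   strains, otherwise the s.d. is undefined and an error is raised).
#' @param effect Optional vector of predicted-effect mutation counts,
#'   parallel to `total`.
#' @param method Label for the mutagenesis method.
#' @return One-row tibble with `method`, `n_strains`, `mean_total`,
#'   `sd_total` and (when `effect` is given) `mean_effect`, `sd_effect`.
#' @export
summarize_counts <- function(total, effect = NULL, method = "unspecified") {
  if (length(total) < 2) stop("need >= 2 strains to compute a standard deviation")
  if (any(total < 0)) stop("counts must be non-negative")
  out <- tibble::tibble(
    method = method, n_strains = length(total),
    mean_total = mean(total), sd_total = stats::sd(total)
  )
  if (!is.null(effect)) {
    stopifnot(length(effect) == length(total))
    out$mean_effect <- mean(effect)
    out$sd_effect <- stats::sd(effect)
  }
  out
}

#' Summarise a mutagenesis table by method
#'
#' Tidy wrapper over [summarize_counts()] for tables with one row per strain
#' (`strain`, `method`, `n_total`, `n_effect`), as produced by
#' [synthetic_mutagenesis_table()].
#'
#' @param df Per-strain count tibble.
#' @return One row per method with mean/s.d. of total and effect counts.
#' @export
summarize_mutagenesis <- function(df) {
  df <- tibble::as_tibble(df)
  df |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(d, key) {
      summarize_counts(d$n_total, d$n_effect)[-1]
    }) |>
    dplyr::ungroup()
}

#' Expected candidate mutations in a mapped interval
#'
#' Laboratory-induced mutations are close to uniformly distributed along the
#' genome, so the number of predicted-effect mutations falling in a mapped
#' interval is modelled as Poisson with mean
#' `lambda = mean_effect * interval_mb / genome_mb`. Reports lambda and the
#' Poisson probabilities of 0, exactly 1, and at most 1 candidate mutation.
#'
#' @param interval_mb Mapped interval width (Mb).
#' @param mean_effect Mean predicted-effect mutations per strain (e.g. the
#'   `mean_effect` column of [summarize_counts()]).
#' @param genome_mb Genome size in Mb (default 100.3, the worm nuclear
#'   genome of just over 100 Mb).
#' @return One-row tibble with `lambda`, `p0`, `p1`, `p_le_1`.
#' @export
expected_candidates <- function(interval_mb, mean_effect, genome_mb = 100.3) {
  if (genome_mb <= 0) stop("genome size must be positive")
  if (interval_mb < 0 || interval_mb > genome_mb) {
    stop("interval must be between 0 and the genome size")
  }
  if (mean_effect < 0) stop("mean_effect must be >= 0")
  lambda <- mean_effect * interval_mb / genome_mb
  tibble::tibble(
    lambda = lambda,
    p0 = stats::dpois(0, lambda),
    p1 = stats::dpois(1, lambda),
    p_le_1 = stats::ppois(1, lambda)
  )
}
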