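#' Per-Mb indel distribution bar plot for one isolate
#'
#' Bar-per-window rendering of an isolate's indel density across the six
#' chromosomes, with indels unique to the isolate (within the catalog's
#' universe) stacked in a second colour.
#'
#' @param catalog Catalog tibble.
#' @param isolate Isolate name.
#' @param build Genome build tibble.
#' @param bin_size_bp Window size (default 1 Mb).
#' @return A ggplot object, faceted by chromosome.
#' @export
plot_indel_distribution <- function(catalog, isolate, build = NULL,
                                    bin_size_bp = 1e6) {
  build <- catalog_build(catalog, build)
  sets <- split_isolates(catalog$isolates)
  carried <- purrr::map_lgl(sets, function(x) isolate %in% x)
  df <- catalog[carried, ]
  df$class <- ifelse(lengths(sets)[carried] == 1L, "unique", "shared")
  df$bin <- floor((df$pos_bp - 1) / bin_size_bp)
  counts <- dplyr::count(df, .data$chrom, .data$bin, .data$class)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$bin + 0.5, y = .data$n,
                               fill = .data$class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~chrom, ncol = 1, strip.position = "right") +
    ggplot2::scale_fill_manual(values = c(shared = "#c0392b", unique = "#f1c40f")) +
    ggplot2::labs(x = "position (Mb)", y = "indels per window",
                  title = paste0("i40-699 indel distribution: ", isolate),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a mapping result along its chromosome
#'
#' Marker band states along the mapped chromosome with the called interval
#' shaded; pooled observations show which markers lost the CB4856 band.
#'
#' @param object A `mapping_result`.
#' @param observations The observation tibble given to [call_pooled()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mapping_result
#' @export
autoplot.mapping_result <- function(object, observations, ...) {
  obs <- tibble::as_tibble(observations)
  obs <- obs[as.character(obs$chrom) == object$chrom, ]
  obs$state <- dplyr::case_when(
    !obs$n2_band & !obs$cb_band ~ "failed",
    obs$cb_band ~ "CB4856 band present",
    .default = "CB4856 band absent"
  )
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$pos_bp / 1e6, y = 0))
  if (object$status != "no_linkage") {
    p <- p + ggplot2::annotate("rect", xmin = object$lo_bp / 1e6,
                               xmax = object$hi_bp / 1e6,
                               ymin = -0.5, ymax = 0.5,
                               fill = "#2980b9", alpha = 0.2)
  }
  p +
    ggplot2::geom_point(ggplot2::aes(shape = .data$state, colour = .data$state),
                        size = 3) +
    ggplot2::scale_colour_manual(values = c(
      "CB4856 band absent" = "#2c3e50", "CB4856 band present" = "#c0392b",
      failed = "grey60")) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(-1, 1)) +
    ggplot2::labs(x = paste0("chromosome ", object$chrom, " (Mb)"),
                  colour = NULL, shape = NULL,
                  title = sprintf("Pooled mapping call: %s", object$status)) +
    ggplot2::theme_minimal()
}
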