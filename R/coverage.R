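#' Bin one isolate's indels into fixed genome windows
#'
#' Counts catalog variants carried by the isolate per fixed window (default
#' 1 Mb): position p falls in bin `floor((p - 1) / bin_size)`; the terminal
#' partial window counts as a full interval.
#'
#' @param catalog Catalog tibble.
#' @param isolate Isolate name (must be in the catalog's isolate universe).
#' @param build Genome build tibble.
#' @param bin_size_bp Window size (default 1 Mb).
#' @return Tibble with `isolate`, `chrom`, `bin`, `start_bp`, `end_bp`, `n`.
#' @export
bin_indels <- function(catalog, isolate, build = NULL, bin_size_bp = 1e6) {
  build <- catalog_build(catalog, build)
  universe <- isolate_universe(catalog)
  if (!isolate %in% universe) {
    stop("unknown isolate '", isolate, "'; known isolates: ",
         paste(universe, collapse = ", "))
  }
  carried <- catalog[purrr::map_lgl(split_isolates(catalog$isolates),
                                    function(x) isolate %in% x), ]
  bins <- genome_bins(build, bin_size_bp)
  counts <- carried |>
    dplyr::mutate(bin = floor((.data$pos_bp - 1) / bin_size_bp)) |>
    dplyr::count(.data$chrom, .data$bin)
  bins |>
    dplyr::left_join(counts, by = c("chrom", "bin")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L), isolate = isolate) |>
    dplyr::select("isolate", "chrom", "bin", "start_bp", "end_bp", "n")
}

#' Windows with no indel for an isolate
#'
#' @param bc Bin count tibble from [bin_indels()].
#' @return The zero-count rows (`chrom`, `bin`, `start_bp`, `end_bp`), in
#'   genome order. An isolate usable for whole-genome mapping should leave
#'   this empty or nearly so.
#' @export
empty_bins <- function(bc) {
  dplyr::select(bc[bc$n == 0L, ], "chrom", "bin", "start_bp", "end_bp")
}

#' Score and rank wild isolates for mapping suitability
#'
#' For every isolate in the catalog's universe: total indel count and the
#' number of empty windows. Isolates are ranked by ascending empty-window
#' count (fewest gaps first), ties by descending indel count, then name;
#' `passes` marks those with at most `max_empty_bins` gaps. The threshold for
#' "too many" empty intervals is a caller decision, not a library constant.
#'
#' @param catalog Catalog tibble.
#' @param max_empty_bins Pass threshold on the number of empty windows.
#' @param build Genome build tibble.
#' @param bin_size_bp Window size (default 1 Mb).
#' @return Tibble with `isolate`, `n_indels`, `n_empty_bins`, `passes`,
#'   ranked best first.
#' @export
score_isolates <- function(catalog, max_empty_bins, build = NULL,
                           bin_size_bp = 1e6) {
  stopifnot(max_empty_bins >= 0)
  build <- catalog_build(catalog, build)
  universe <- isolate_universe(catalog)
  scores <- purrr::map_dfr(universe, function(iso) {
    bc <- bin_indels(catalog, iso, build, bin_size_bp)
    tibble::tibble(isolate = iso, n_indels = sum(bc$n),
                   n_empty_bins = sum(bc$n == 0L))
  })
  scores$passes <- scores$n_empty_bins <= max_empty_bins
  dplyr::arrange(scores, .data$n_empty_bins, dplyr::desc(.data$n_indels),
                 .data$isolate)
}

#' Pairwise Jaccard similarity of isolate indel sets
#'
#' `J(a, b) = |A intersect B| / |A union B|` over the sets of catalog
#' variants each isolate carries. Diagonal entries are 1 for isolates with at
#' least one indel; an isolate with none gets a zero row/column (off the
#' diagonal) and a warning.
#'
#' @param catalog Catalog tibble.
#' @return Symmetric numeric matrix with isolate names as dimnames.
#' @export
sharing_matrix <- function(catalog) {
  universe <- isolate_universe(catalog)
  if (length(universe) < 2) stop("need at least two isolates")
  sets <- split_isolates(catalog$isolates)
  membership <- vapply(universe, function(iso) {
    purrr::map_lgl(sets, function(x) iso %in% x)
  }, logical(nrow(catalog)))
  if (nrow(catalog) == 0) {
    membership <- matrix(FALSE, 0, length(universe),
                         dimnames = list(NULL, universe))
  }
  sizes <- colSums(membership)
  if (any(sizes == 0)) {
    warning("isolate(s) with zero indels: ",
            paste(universe[sizes == 0], collapse = ", "))
  }
  inter <- crossprod(membership)
  un <- outer(sizes, sizes, "+") - inter
  J <- ifelse(un > 0, inter / un, 0)
  diag(J) <- ifelse(sizes > 0, 1, 0)
  J
}

#' Cluster isolates by indel sharing
#'
#' Single-linkage clusters of isolates whose pairwise Jaccard similarity
#' reaches the threshold, used to spot groups of closely related isolates
#' (which likely share phenotypes and are redundant as mapping partners).
#'
#' @param J Jaccard matrix from [sharing_matrix()].
#' @param threshold Minimum similarity to link two isolates (default 0.5).
#' @return Tibble with `isolate` and `cluster` id.
#' @export
isolate_clusters <- function(J, threshold = 0.5) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J))
  hc <- stats::hclust(stats::as.dist(1 - J), method = "single")
  tibble::tibble(
    isolate = rownames(J),
    cluster = unname(stats::cutree(hc, h = 1 - threshold))
  )
}
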