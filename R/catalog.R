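#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
NULL

catalog_cols <- c("variant_id", "chrom", "pos_bp", "size_change_bp",
                  "longer_allele", "isolates", "n_isolates",
                  "gene_id", "gene_pos_bp", "gene_pos_cM")

#' Validate and normalise an indel catalog tibble
#'
#' A catalog is a tibble of indel variants with one row per variant:
#' `variant_id`, `chrom`, `pos_bp` (1-based leftmost affected base),
#' `size_change_bp` (absolute allele length difference), `longer_allele`
#' (`"N2"` or `"isolate"`), `isolates` (semicolon-joined names of wild
#' isolates carrying the non-N2 allele), `n_isolates`, and nearest-gene
#' annotation columns (`gene_id`, `gene_pos_bp`, `gene_pos_cM`, `NA` until
#' annotated). Rows are kept sorted by (chromosome order, position,
#' variant id). Variants with an empty isolate list are retained but can be
#' identified by `n_isolates == 0`.
#'
#' @param df Data frame with at least `variant_id`, `chrom`, `pos_bp`,
#'   `size_change_bp`; missing optional columns are added.
#' @param build Genome build tibble, see [ce_genome()]. Rows on chromosomes
#'   not present in the build are dropped with a warning.
#' @return A genome-sorted catalog tibble; the build is attached as the
#'   `"build"` attribute and the isolate universe (if supplied) as
#'   `"isolate_universe"`.
#' @export
as_indel_catalog <- function(df, build = ce_genome()) {
  df <- tibble::as_tibble(df)
  for (col in setdiff(catalog_cols, names(df))) {
    df[[col]] <- switch(col,
      longer_allele = NA_character_, isolates = "",
      n_isolates = NA_integer_, gene_id = NA_character_,
      gene_pos_bp = NA_real_, gene_pos_cM = NA_real_,
      NA
    )
  }
  bad <- !(as.character(df$chrom) %in% chrom_levels(build))
  if (any(bad)) {
    warning(sum(bad), " variant(s) on chromosomes not in the build were dropped: ",
            paste(unique(df$chrom[bad]), collapse = ", "))
    df <- df[!bad, ]
  }
  if (nrow(df) > 0 && (any(is.na(df$pos_bp)) || any(df$pos_bp < 1))) {
    stop("variant positions must be 1-based positive integers")
  }
  df$pos_bp <- as.numeric(df$pos_bp)
  df$size_change_bp <- as.integer(df$size_change_bp)
  if (nrow(df) > 0 && any(df$size_change_bp < 1)) {
    stop("size_change_bp must be >= 1")
  }
  df$isolates <- ifelse(is.na(df$isolates), "", df$isolates)
  df$n_isolates <- count_isolates(df$isolates)
  df <- arrange_genome(df[catalog_cols], build, .data$variant_id)
  attr(df, "build") <- build
  df
}

#' @keywords internal
count_isolates <- function(isolates) {
  lengths(split_isolates(isolates))
}

#' @keywords internal
split_isolates <- function(isolates) {
  out <- stringr::str_split(isolates, stringr::fixed(";"))
  purrr::map(out, function(x) x[nzchar(x)])
}

#' @keywords internal
catalog_build <- function(catalog, build = NULL) {
  build %||% attr(catalog, "build") %||% ce_genome()
}

#' Isolate universe of a catalog
#'
#' The set of wild isolate names a catalog is scored against: the
#' `"isolate_universe"` attribute when set, otherwise all names appearing in
#' the `isolates` column.
#'
#' @param catalog Catalog tibble.
#' @return Character vector of isolate names.
#' @export
isolate_universe <- function(catalog) {
  attr(catalog, "isolate_universe") %||%
    sort(unique(unlist(split_isolates(catalog$isolates))))
}

#' Read an indel variant catalog from the package's TSV dialect
#'
#' The dialect is UTF-8, tab-separated with a header row and columns
#' `variant_id`, `chrom`, `pos_bp`, `size_change_bp`, `longer_allele`,
#' `isolates` (semicolon-joined), `gene_id`, `gene_pos_bp`, `gene_pos_cM`
#' (the last three optional). This mirrors one row per annotated indel with
#' its size, carriers among the wild isolates, and nearest-gene annotation.
#'
#' @param path Path to the TSV file.
#' @param build Genome build tibble.
#' @return A catalog tibble, see [as_indel_catalog()].
#' @export
read_indel_tsv <- function(path, build = ce_genome()) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          chrom = readr::col_character(),
                          isolates = readr::col_character(),
                          .default = readr::col_guess()
                        ))
  if (!all(c("variant_id", "chrom", "pos_bp", "size_change_bp") %in% names(df))) {
    stop("TSV must contain variant_id, chrom, pos_bp, size_change_bp columns")
  }
  bad_pos <- which(is.na(suppressWarnings(as.numeric(df$pos_bp))) |
                     as.numeric(df$pos_bp) < 1)
  if (length(bad_pos) > 0) {
    stop("malformed pos_bp at line ", bad_pos[1] + 1L, " of ", path)
  }
  as_indel_catalog(df, build)
}

#' Write a catalog in the package's TSV dialect
#'
#' @param catalog Catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indel_tsv <- function(catalog, path) {
  readr::write_tsv(catalog, path)
  invisible(path)
}

#' Read an indel catalog from a minimal VCF
#'
#' Uses CHROM, POS, REF and ALT to compute the absolute allele length change,
#' and sample genotype columns to list carriers: any sample with a
#' non-reference, non-missing genotype is recorded as carrying the non-N2
#' allele. Multi-allelic records take the first ALT allele.
#'
#' @param path Path to a VCF file (plain text).
#' @param build Genome build tibble.
#' @return A catalog tibble.
#' @export
read_indel_vcf <- function(path, build = ce_genome()) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  alt1 <- stringr::str_split_i(fix$ALT, stringr::fixed(","), 1)
  carriers <- rep("", nrow(fix))
  if (ncol(v@gt) > 1) {
    gt <- vcfR::extract.gt(v)
    has_alt <- !is.na(gt) & stringr::str_detect(gt, "[1-9]")
    carriers <- apply(has_alt, 1, function(x) {
      paste(colnames(gt)[x], collapse = ";")
    })
  }
  df <- tibble::tibble(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM,
    pos_bp = as.numeric(fix$POS),
    size_change_bp = abs(nchar(fix$REF) - nchar(alt1)),
    longer_allele = ifelse(nchar(fix$REF) >= nchar(alt1), "N2", "isolate"),
    isolates = unname(carriers)
  )
  df <- df[df$size_change_bp >= 1, ]
  as_indel_catalog(df, build)
}

#' Filter a catalog to indels with 40-699 bp length change
#'
#' Retains exactly the variants whose absolute allele length difference lies
#' in the closed interval `[min_bp, max_bp]`. These are the indels large
#' enough to score as a band-size shift on a standard agarose gel yet small
#' enough to amplify reliably, the marker class this toolkit is built around.
#' The filter is idempotent.
#'
#' @param catalog Catalog tibble.
#' @param min_bp,max_bp Closed bounds on the length change (default 40 and 699).
#' @return The filtered catalog tibble.
#' @export
filter_i40_699 <- function(catalog, min_bp = 40, max_bp = 699) {
  if (min_bp > max_bp) stop("min_bp must be <= max_bp")
  out <- dplyr::filter(catalog, .data$size_change_bp >= min_bp,
                       .data$size_change_bp <= max_bp)
  attributes(out)[c("build", "isolate_universe")] <-
    attributes(catalog)[c("build", "isolate_universe")]
  out
}

#' Annotate each variant with its nearest gene
#'
#' For every variant, finds the same-chromosome gene minimising the absolute
#' physical distance `|gene pos - variant pos|`; equidistant ties resolve to
#' the gene at the lower coordinate. Chromosomes carrying variants but no
#' genes are annotated `NA` with a warning.
#'
#' @param catalog Catalog tibble.
#' @param genes Tibble of gene records with `gene_id`, `chrom`, `pos_bp` and
#'   optionally `pos_cM` (signed genetic position, left arm negative).
#' @return The catalog with `gene_id`, `gene_pos_bp`, `gene_pos_cM` filled in.
#' @export
annotate_nearest_gene <- function(catalog, genes) {
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("gene_id", "chrom", "pos_bp") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  if (!"pos_cM" %in% names(genes)) genes$pos_cM <- NA_real_
  out <- catalog
  for (ch in unique(as.character(catalog$chrom))) {
    vi <- which(as.character(catalog$chrom) == ch)
    g <- genes[as.character(genes$chrom) == ch, ]
    if (nrow(g) == 0) {
      warning("no genes on chromosome ", ch, "; variants there left unannotated")
      out$gene_id[vi] <- NA_character_
      next
    }
    # sort genes; ties between equidistant genes resolve to lower coordinate
    g <- g[order(g$pos_bp, g$gene_id), ]
    pos <- catalog$pos_bp[vi]
    right <- findInterval(pos, g$pos_bp) + 1L  # first gene at coordinate > pos (or == handled below)
    left <- findInterval(pos, g$pos_bp)        # last gene at coordinate <= pos
    left[left < 1L] <- NA_integer_
    right[right > nrow(g)] <- NA_integer_
    d_left <- ifelse(is.na(left), Inf, abs(pos - g$pos_bp[pmax(left, 1L)]))
    d_right <- ifelse(is.na(right), Inf, abs(g$pos_bp[pmin(right, nrow(g))] - pos))
    pick <- ifelse(d_left <= d_right, left, right)  # tie -> lower coordinate
    out$gene_id[vi] <- g$gene_id[pick]
    out$gene_pos_bp[vi] <- g$pos_bp[pick]
    out$gene_pos_cM[vi] <- g$pos_cM[pick]
  }
  out
}

#' Per-isolate indel counts and unique-indel counts
#'
#' For each isolate in the catalog's isolate universe: `n_indels`, the number
#' of catalog variants the isolate carries, and `n_unique`, the number carried
#' by that isolate alone among the universe (the "yellow bar" class when the
#' distribution is plotted per Mb).
#'
#' @param catalog Catalog tibble.
#' @param universe Character vector of isolate names; defaults to
#'   [isolate_universe()] of the catalog.
#' @return Tibble with `isolate`, `n_indels`, `n_unique`, sorted by descending
#'   `n_indels`.
#' @export
presence_summary <- function(catalog, universe = isolate_universe(catalog)) {
  sets <- split_isolates(catalog$isolates)
  long <- tibble::tibble(
    isolate = unlist(sets),
    unique = rep(lengths(sets) == 1L, lengths(sets))
  )
  long <- long[long$isolate %in% universe, ]
  out <- long |>
    dplyr::group_by(.data$isolate) |>
    dplyr::summarise(n_indels = dplyr::n(), n_unique = sum(.data$unique)) |>
    dplyr::ungroup()
  missing <- setdiff(universe, out$isolate)
  if (length(missing) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(isolate = missing,
                                                n_indels = 0L, n_unique = 0L))
  }
  dplyr::arrange(out, dplyr::desc(.data$n_indels), .data$isolate)
}
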