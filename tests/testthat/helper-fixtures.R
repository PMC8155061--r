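# Small fixture builders and independent oracles used across the test files.

toy_build <- function(chroms = c("I", "X"), lengths_bp = c(12e6, 8e6)) {
  ce_genome(chroms = chroms, lengths_bp = lengths_bp)
}

toy_catalog <- function(df, build = toy_build()) {
  pick <- function(col, default) {
    if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
  }
  base <- tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(nrow(df))),
    chrom = df[["chrom"]], pos_bp = df[["pos_bp"]],
    size_change_bp = pick("size_change_bp", 100L),
    isolates = pick("isolates", "A")
  )
  as_indel_catalog(base, build)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive nearest-gene scan: for every variant, check all same-chromosome
# genes and pick the minimum distance, ties to the lower coordinate.
oracle_nearest_gene <- function(variants, genes) {
  vapply(seq_len(nrow(variants)), function(i) {
    g <- genes[as.character(genes$chrom) == as.character(variants$chrom[i]), ]
    if (nrow(g) == 0) return(NA_character_)
    d <- abs(g$pos_bp - variants$pos_bp[i])
    cand <- which(d == min(d))
    g$gene_id[cand[which.min(g$pos_bp[cand])]]
  }, character(1))
}

# Brute-force pooled-run caller for a single chromosome with all N2 bands
# present: enumerate every maximal run of CB-negative markers, apply the
# longest / widest-span / leftmost tie-breaks, and bracket with the flanking
# CB-positive markers (or chromosome ends).
oracle_call_pooled <- function(cb_present, pos_bp, chrom_len) {
  neg <- !cb_present
  n <- length(neg)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (neg[i]) {
      j <- i
      while (j < n && neg[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(runs) == 0) return(list(status = "no_linkage"))
  best <- NULL
  for (r in runs) {
    cand <- list(n = r[2] - r[1] + 1L, span = pos_bp[r[2]] - pos_bp[r[1]],
                 start = pos_bp[r[1]], idx = r[1]:r[2])
    better <- is.null(best) || cand$n > best$n ||
      (cand$n == best$n && cand$span > best$span) ||
      (cand$n == best$n && cand$span == best$span && cand$start < best$start)
    if (better) best <- cand
  }
  list(
    status = if (best$n >= 2L) "linked" else "hint",
    lo = if (best$idx[1] > 1L) pos_bp[best$idx[1] - 1L] else 1,
    hi = if (best$idx[length(best$idx)] < n) pos_bp[best$idx[length(best$idx)] + 1L]
         else chrom_len,
    support = best$idx
  )
}

# Evenly spaced single-chromosome marker table for mapping tests.
toy_markers <- function(n = 12, chrom = "I", spacing = 1e6,
                        p_full = 1, p_dilute = 1) {
  tibble::tibble(
    marker_id = sprintf("m%02d", seq_len(n)), chrom = chrom,
    pos_bp = spacing * seq_len(n), p_full = p_full, p_dilute = p_dilute
  )
}
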