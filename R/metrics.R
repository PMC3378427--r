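## Assembly summary metrics, the pairwise assembly-overlap statistic,
## per-gene parameter profiles across the (k, cutoff) grid, and the
## expression-vs-parameter correlation analysis.

#' Length-based assembly metrics
#'
#' N50 (N90) is the length of the smallest contig such that contigs of that
#' length and larger contain at least 50% (90%) of the assembled bases.
#' Length classes use upper-inclusive boundaries (100,200], (200,500],
#' (500,1000], (1000, Inf).
#'
#' @param contigs contigs data.frame (or an `assembly_result`), or a numeric
#'   vector of lengths.
#' @return list: n_contigs, total_bases, longest, class_counts (named
#'   integer), n50, n90. For an empty contig set all values are `NA`
#'   (absent), not zero.
#' @export
length_metrics <- function(contigs) {
  len <- if (is.numeric(contigs)) {
    as.integer(contigs)
  } else if (inherits(contigs, "assembly_result")) {
    contigs$contigs$length
  } else {
    contigs$length
  }
  if (!length(len)) {
    return(list(n_contigs = NA_integer_, total_bases = NA_integer_,
                longest = NA_integer_,
                class_counts = c(`(100,200]` = NA_integer_,
                                 `(200,500]` = NA_integer_,
                                 `(500,1000]` = NA_integer_,
                                 `(1000,Inf]` = NA_integer_),
                n50 = NA_integer_, n90 = NA_integer_))
  }
  total <- sum(len)
  s <- sort(len, decreasing = TRUE)
  cum <- cumsum(s)
  n50 <- s[which(cum >= 0.5 * total)[1L]]
  n90 <- s[which(cum >= 0.9 * total)[1L]]
  cls <- cut(len, breaks = c(100, 200, 500, 1000, Inf), right = TRUE)
  cc <- as.integer(table(cls))
  names(cc) <- c("(100,200]", "(200,500]", "(500,1000]", "(1000,Inf]")
  list(n_contigs = length(len), total_bases = total, longest = max(len),
       class_counts = cc, n50 = n50, n90 = n90)
}

#' Percentage of reads included in an assembly
#'
#' A read is included when it has at least one valid end-to-end placement
#' (at most `max_mismatches` substitutions, either strand) on any contig.
#'
#' @param reads a `read_set` or named character vector.
#' @param contigs contigs data.frame, `assembly_result` or character vector.
#' @param max_mismatches placement mismatch allowance (default 3).
#' @return percent in \[0, 100\] (0 when the contig set is empty).
#' @export
read_inclusion <- function(reads, contigs, max_mismatches = 3L) {
  targets <- as_named_seqs(contigs)
  qs <- if (is.character(reads)) reads else read_sequences(reads)
  if (!length(qs)) stop("no reads")
  if (!length(targets)) return(0)
  mc <- map_reads(qs, targets, max_mismatches = max_mismatches)
  100 * mc$n_reads_mapped / length(qs)
}

#' Normalized overlap between two complete-transcript sets
#'
#' The number of complete transcripts common to both assemblies divided by
#' the total summed across both, divided by 0.5: 1 for identical sets, 0 for
#' disjoint ones. Undefined (NA) when both sets are empty.
#'
#' @param complete_a,complete_b character vectors of complete-transcript
#'   identifiers.
#' @return fraction in \[0, 1\], or `NA` for the empty-vs-empty case.
#' @export
overlap_statistic <- function(complete_a, complete_b) {
  a <- unique(complete_a)
  b <- unique(complete_b)
  tot <- length(a) + length(b)
  if (tot == 0L) return(NA_real_)
  length(intersect(a, b)) / tot / 0.5
}

#' Pairwise overlap matrix across a sweep's completeness calls
#'
#' @param complete_sets named list of complete-transcript id vectors, one
#'   per grid cell.
#' @return symmetric numeric matrix of [overlap_statistic()] values.
#' @export
overlap_matrix <- function(complete_sets) {
  n <- length(complete_sets)
  m <- matrix(NA_real_, n, n,
              dimnames = list(names(complete_sets), names(complete_sets)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- overlap_statistic(complete_sets[[i]], complete_sets[[j]])
    }
  }
  m
}

#' Per-gene parameter profiles across the grid
#'
#' For each gene, the set of (k, cutoff) cells in which it was assembled
#' complete, and the derived counts: number of distinct k values (`n_k`),
#' distinct cutoffs (`n_c`) and cells (`n_cells`).
#'
#' @param calls data.frame with columns gene, k, cutoff -- one row per
#'   (gene, grid cell) completeness call.
#' @return data.frame: gene, n_k, n_c, n_cells.
#' @export
parameter_profiles <- function(calls) {
  stopifnot(all(c("gene", "k", "cutoff") %in% names(calls)))
  dt <- unique(as.data.table(calls)[, .(gene, k, cutoff)])
  out <- dt[, .(n_k = length(unique(k)),
                n_c = length(unique(cutoff)),
                n_cells = .N), by = gene]
  setorder(out, gene)
  as.data.frame(out)
}

#' Expression level versus breadth of assembly success
#'
#' Genes are binned by the number of k-mer sizes (and, separately, coverage
#' cutoffs) under which they were assembled complete; the mean RPKM of each
#' nonempty bin is computed after excluding genes with RPKM strictly above
#' `exclude_above`; and the Pearson correlation between bin index and bin
#' mean is reported. With fewer than 3 nonempty bins, or zero variance of
#' the bin means, the correlation is reported as `NA`.
#'
#' @param profiles output of [parameter_profiles()].
#' @param expression data.frame with columns gene, rpkm (e.g.
#'   [rpkm_table()] renamed).
#' @param exclude_above RPKM exclusion threshold (strict; default 1000).
#' @return list: by_k / by_cutoff (data.frame bin, n_genes, mean_rpkm),
#'   r_k, r_cutoff, n_excluded.
#' @export
expression_correlation <- function(profiles, expression,
                                   exclude_above = 1000) {
  stopifnot(all(c("gene", "rpkm") %in% names(expression)))
  d <- merge(profiles, expression[, c("gene", "rpkm")], by = "gene")
  excl <- d$rpkm > exclude_above
  d <- d[!excl, , drop = FALSE]
  bin_summary <- function(idx) {
    dt <- as.data.table(data.frame(bin = idx, rpkm = d$rpkm))
    out <- dt[, .(n_genes = .N, mean_rpkm = mean(rpkm)), by = bin]
    setorder(out, bin)
    as.data.frame(out)
  }
  safe_cor <- function(bs) {
    if (nrow(bs) < 2L) return(NA_real_)
    if (stats::sd(bs$mean_rpkm) == 0 || stats::sd(bs$bin) == 0) return(NA_real_)
    cor(bs$bin, bs$mean_rpkm)
  }
  by_k <- bin_summary(d$n_k)
  by_c <- bin_summary(d$n_c)
  list(by_k = by_k, by_cutoff = by_c,
       r_k = safe_cor(by_k), r_cutoff = safe_cor(by_c),
       n_excluded = sum(excl))
}
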