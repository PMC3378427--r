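## Read container + quality trimming / pairing rules.
##
## Reads live in a single data.frame with a `pool` column ("paired" or
## "single") and pairing metadata, plus an optional truth table (source
## coordinates, synthetic runs only) and a provenance tally that must always
## sum to the number of input reads.

empty_reads_df <- function() {
  data.frame(read_id = character(0), sequence = character(0),
             quality = character(0), pool = character(0),
             pair_id = character(0), mate = integer(0),
             stringsAsFactors = FALSE)
}

empty_read_truth_df <- function() {
  data.frame(read_id = character(0), gene_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a read set
#'
#' @param reads data.frame with columns read_id, sequence, quality, pool
#'   ("paired"/"single"), pair_id, mate.
#' @param truth optional per-read source table (read_id, gene_id, start, end,
#'   strand; 1-based closed coordinates).
#' @param provenance named list of bookkeeping counts.
#' @return a `read_set` object.
#' @export
read_set <- function(reads, truth = NULL, provenance = list(input = nrow(reads))) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "quality", "pool") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("sequence and quality lengths differ")
  }
  if (anyDuplicated(reads$read_id)) stop("duplicated read ids")
  structure(list(reads = reads, truth = truth, provenance = provenance),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  r <- x$reads
  cat("read_set:", nrow(r), "reads (",
      sum(r$pool == "paired"), "paired /", sum(r$pool == "single"),
      "single )\n")
  if (nrow(r)) cat("  lengths:", min(nchar(r$sequence)), "-",
                   max(nchar(r$sequence)), "bp\n")
  if (length(x$provenance)) {
    cat("  provenance:",
        paste(names(x$provenance), unlist(x$provenance),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

## Phred scores (integer vector) of one quality string, Sanger offset 33
phred_scores <- function(qual) {
  if (!nchar(qual)) return(integer(0))
  as.integer(charToRaw(qual)) - 33L
}

## leftmost longest run of TRUE in a logical vector; returns c(start, end)
## or c(0, -1) when empty
longest_true_run <- function(ok) {
  if (!length(ok) || !any(ok)) return(c(0L, -1L))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])] # which.max -> leftmost tie-break
  c(starts[best], ends[best])
}

#' Quality-trim reads to the longest contiguous high-quality segment
#'
#' Each read is trimmed to the longest window in which every base has a
#' Phred quality of at least `min_quality` (inclusive comparison; ties
#' between equal-length windows are broken leftmost). A read with no
#' qualifying base becomes empty. Trimming never alters a base: outputs are
#' substrings of the inputs, and trimming is idempotent.
#'
#' @param reads a `read_set` (or data.frame in the same layout).
#' @param min_quality Phred threshold, default 20 (one error per 100 bases).
#' @return a `read_set` with trimmed sequences/qualities; provenance gains a
#'   `trimmed_bases` count.
#' @export
trim_reads <- function(reads, min_quality = 20L) {
  rs <- as_read_set(reads)
  df <- rs$reads
  if (!nrow(df)) return(rs)
  ## windows depend only on the quality string; compute once per distinct one
  uq <- unique(df$quality)
  win <- vapply(uq, function(q) {
    longest_true_run(phred_scores(q) >= min_quality)
  }, integer(2))
  idx <- match(df$quality, uq)
  start <- win[1L, idx]
  end <- win[2L, idx]
  in_bases <- sum(nchar(df$sequence))
  df$sequence <- substring(df$sequence, start, end)
  df$quality <- substring(df$quality, start, end)
  prov <- rs$provenance
  prov$trimmed_bases <- in_bases - sum(nchar(df$sequence))
  read_set(df, truth = rs$truth, provenance = prov)
}

#' Filter trimmed reads by length and demote orphaned mates
#'
#' Reads shorter than `min_length` are discarded. Pairs in which both mates
#' pass remain paired; pairs in which exactly one mate passes contribute that
#' mate to the single-end pool (demotion). Provenance counts
#' (`kept_paired + demoted + kept_single + discarded`) always sum to the
#' input count.
#'
#' @param reads a `read_set`.
#' @param min_length minimum retained read length (inclusive), default 30.
#' @return filtered `read_set`.
#' @export
filter_and_pair <- function(reads, min_length = 30L) {
  rs <- as_read_set(reads)
  df <- rs$reads
  n_in <- nrow(df)
  pass <- nchar(df$sequence) >= min_length
  paired <- df$pool == "paired" & !is.na(df$pair_id)
  ## per-pair pass counts
  demote <- rep(FALSE, n_in)
  if (any(paired)) {
    tab <- tapply(pass[paired], df$pair_id[paired], sum)
    n_pass <- as.integer(tab[df$pair_id[paired]])
    demote[paired] <- pass[paired] & n_pass == 1L
  }
  keep_paired <- paired & pass & !demote
  keep_single <- (!paired & pass)
  out <- df[keep_paired | keep_single | demote, , drop = FALSE]
  dem_ids <- df$read_id[demote]
  out$pool[out$read_id %in% dem_ids] <- "single"
  out$pair_id[out$read_id %in% dem_ids] <- NA_character_
  rownames(out) <- NULL
  prov <- rs$provenance
  prov$kept_paired <- sum(keep_paired)
  prov$demoted <- sum(demote)
  prov$kept_single <- sum(keep_single)
  prov$discarded <- n_in - sum(keep_paired) - sum(demote) - sum(keep_single)
  truth <- rs$truth
  if (!is.null(truth)) truth <- truth[truth$read_id %in% out$read_id, , drop = FALSE]
  read_set(out, truth = truth, provenance = prov)
}

as_read_set <- function(x) {
  if (inherits(x, "read_set")) return(x)
  if (is.data.frame(x)) return(read_set(x))
  stop("expected a read_set or data.frame")
}

## named character vector of read sequences (drops empty reads)
read_sequences <- function(reads) {
  rs <- as_read_set(reads)
  s <- rs$reads$sequence
  names(s) <- rs$reads$read_id
  s[nchar(s) > 0L]
}
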