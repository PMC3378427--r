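## Independent oracles used to validate the package's own implementations.
## Each oracle is written without reusing the code path it checks: brute
## force scans, naive tallies, and the full dynamic-programming aligner from
## Biostrings.

## reverse complement, independent of the package implementation
oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

## full Needleman-Wunsch global alignment identity (matches / columns)
oracle_alignment_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1
  )
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / cols
}

## naive canonical k-mer tally: nested loops, no vectorised shortcuts
oracle_kmer_tally <- function(seqs, k) {
  tal <- new.env(parent = emptyenv())
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      r <- oracle_rc(w)
      key <- if (w <= r) w else r
      tal[[key]] <- (if (is.null(tal[[key]])) 0L else tal[[key]]) + 1L
    }
  }
  counts <- vapply(ls(tal), function(x) tal[[x]], integer(1))
  counts[order(names(counts))]
}

## exhaustive longest all-above-threshold quality window: scans all O(n^2)
## substrings, leftmost tie-break
oracle_trim_window <- function(q, threshold) {
  n <- length(q)
  best <- c(0L, -1L)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(q[i:j] >= threshold)) {
        if ((j - i) > (best[2] - best[1])) best <- c(i, j)
      }
    }
  }
  best
}

## exhaustive Hamming scan: minimum mismatches of `read` over all end-to-end
## placements on `target`, both strands; Inf when the read does not fit
oracle_min_mismatches <- function(read, target) {
  L <- nchar(read)
  n <- nchar(target)
  if (L > n) return(Inf)
  rc <- oracle_rc(read)
  best <- Inf
  rch <- strsplit(read, "", fixed = TRUE)[[1L]]
  cch <- strsplit(rc, "", fixed = TRUE)[[1L]]
  tch <- strsplit(target, "", fixed = TRUE)[[1L]]
  for (i in seq_len(n - L + 1L)) {
    w <- tch[i:(i + L - 1L)]
    best <- min(best, sum(w != rch), sum(w != cch))
  }
  best
}

## brute-force N-statistic: sort descending, accumulate
oracle_nstat <- function(lengths, frac) {
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= frac * sum(s))[1L]]
}

## Hamming identity of two equal-length strings, character by character
oracle_hamming_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(ca == cb)
}
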