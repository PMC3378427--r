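## Low-level sequence helpers shared across modules. Sequences are plain
## upper-case character strings over {A,C,G,T}; Biostrings is used for the
## reverse complement so strand handling has a single authoritative code path.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  out <- rep.int("", length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

## canonical form: lexicographic minimum of a sequence and its reverse
## complement (the standard strand-neutral k-mer representative)
canonical_form <- function(x) {
  r <- revcomp(x)
  ifelse(x <= r, x, r)
}

#' Generate a random DNA sequence
#'
#' @param n sequence length in bases.
#' @return a single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Hamming distance between paired equal-length strings, vectorised by
## grouping on length and comparing raw bytes of the concatenation.
hamming_pairs <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!length(a)) return(integer(0))
  na <- nchar(a)
  if (!all(na == nchar(b))) stop("hamming_pairs() requires equal-length pairs")
  out <- integer(length(a))
  for (len in unique(na)) {
    i <- which(na == len)
    if (len == 0L) next
    ra <- charToRaw(paste0(a[i], collapse = ""))
    rb <- charToRaw(paste0(b[i], collapse = ""))
    out[i] <- as.integer(rowSums(matrix(ra != rb,
                                        nrow = length(i), ncol = len,
                                        byrow = TRUE)))
  }
  out
}

## substitute bases of `seq` at 1-based `positions`, never reproducing the
## original base; draws use the current RNG stream
substitute_bases <- function(seq, positions) {
  if (!length(positions)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

## all k-mers of a set of sequences (one row per position); sequences
## shorter than k contribute nothing
extract_kmers <- function(seqs, k) {
  len <- nchar(seqs)
  keep <- len >= k
  seqs <- seqs[keep]
  len <- len[keep]
  if (!length(seqs)) return(character(0))
  nk <- len - k + 1L
  starts <- sequence(nk)
  substring(rep.int(seqs, nk), starts, starts + k - 1L)
}

## positions table of all s-mers of named sequences:
## data.table(id, pos (1-based), kmer)
kmer_positions <- function(seqs, s) {
  stopifnot(!is.null(names(seqs)))
  len <- nchar(seqs)
  keep <- len >= s
  seqs <- seqs[keep]
  len <- len[keep]
  if (!length(seqs)) {
    return(data.table(id = character(0), pos = integer(0),
                      kmer = character(0)))
  }
  nk <- len - s + 1L
  starts <- sequence(nk)
  data.table(
    id   = rep.int(names(seqs), nk),
    pos  = starts,
    kmer = substring(rep.int(unname(seqs), nk), starts, starts + s - 1L)
  )
}

## deterministic seed derivation for independent simulation stages
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}
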