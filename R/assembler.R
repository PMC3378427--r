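## Minimal canonical-k-mer de Bruijn assembler.
##
## A k-mer is a node; two k-mers are linked when they overlap by k-1 bases.
## K-mers are stored in canonical form (lexicographic minimum of the k-mer
## and its reverse complement) so both strands collapse onto one graph.
## Contigs are maximal unambiguous paths: a node is extended only while it
## has exactly one surviving successor and that successor has exactly one
## surviving predecessor, in orientation-aware form. Traversal therefore
## stops at every branch -- the conservative behaviour that prevents chimeric
## joins between near-identical homeologous copies, at the price of
## fragmentation wherever two transcripts share a stretch of >= k bases.

#' Build a canonical k-mer multiplicity graph from reads
#'
#' Every position of every read contributes one count to the canonical form
#' of its k-mer; reads shorter than k are skipped (with a warning if none is
#' long enough).
#'
#' @param reads a `read_set`, data.frame, or character vector of sequences.
#' @param k odd k-mer size >= 15.
#' @param chunk_size reads tallied per batch; bounds the transient
#'   per-position k-mer vector for large libraries.
#' @return a `kmer_graph` with sorted `kmers` and integer `counts`.
#' @export
build_kmer_graph <- function(reads, k, chunk_size = 200000L) {
  k <- as.integer(k)
  stopifnot(k >= 15L, k %% 2L == 1L)
  seqs <- if (is.character(reads)) reads else as_read_set(reads)$reads$sequence
  seqs <- seqs[nchar(seqs) >= k]
  if (!length(seqs)) {
    warning("k exceeds every read length; empty graph")
    return(new_kmer_graph(k, character(0), integer(0)))
  }
  ## tally in chunks so the transient per-position k-mer vector stays small
  chunks <- split(seqs, ceiling(seq_along(seqs) / chunk_size))
  parts <- lapply(chunks, function(ss) {
    dt <- data.table(kmer = extract_kmers(ss, k))[, .N, by = kmer]
    dt[, kmer := canonical_form(kmer)]
    dt[, .(count = sum(N)), by = kmer]
  })
  dt <- rbindlist(parts)[, .(count = sum(count)), by = kmer]
  setorder(dt, kmer)
  new_kmer_graph(k, dt$kmer, as.integer(dt$count))
}

new_kmer_graph <- function(k, kmers, counts) {
  structure(list(k = k, kmers = kmers, counts = counts),
            class = "kmer_graph")
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat("kmer_graph: k =", x$k, ",", length(x$kmers), "canonical k-mers\n")
  if (length(x$counts)) {
    cat("  multiplicity: median", median(x$counts),
        ", max", max(x$counts), "\n")
  }
  invisible(x)
}

#' Remove k-mers below a coverage cutoff
#'
#' @param graph a `kmer_graph`.
#' @param c integer cutoff >= 1; k-mers with multiplicity < c are dropped.
#' @return the filtered `kmer_graph`.
#' @export
apply_coverage_cutoff <- function(graph, c) {
  stopifnot(inherits(graph, "kmer_graph"), c >= 1)
  keep <- graph$counts >= c
  new_kmer_graph(graph$k, graph$kmers[keep], graph$counts[keep])
}

#' Automatic coverage cutoff from the k-mer multiplicity spectrum
#'
#' Returns `max(2, round(sqrt(median multiplicity of k-mers seen at least
#' twice)))`; if no k-mer is seen twice the floor of 2 is returned. The
#' formula is monotone in coverage depth, tracks the dominant coverage mode
#' of a single deeply covered gene, and collapses towards the floor as soon
#' as low-coverage material dominates the median -- the qualitative behaviour
#' observed when reads from many genes are assembled jointly.
#'
#' @param graph a `kmer_graph`.
#' @return integer cutoff >= 2.
#' @export
auto_cutoff <- function(graph) {
  stopifnot(inherits(graph, "kmer_graph"))
  m <- graph$counts[graph$counts >= 2L]
  if (!length(m)) return(2L)
  max(2L, as.integer(round(sqrt(median(m)))))
}

#' Traverse unambiguous paths of the graph into contigs
#'
#' Contigs are maximal chains of simple edges: an edge is followed only when
#' its source node has exactly one surviving successor and its target exactly
#' one surviving predecessor (computed orientation-aware; the in-degree of a
#' node equals the out-degree of its reverse complement). Each k-mer
#' contributes to at most one contig. Contigs not longer than `min_length`
#' bases are discarded; survivors are reported in canonical orientation,
#' sorted, with their mean k-mer multiplicity.
#'
#' @param graph a `kmer_graph` (typically after [apply_coverage_cutoff()]).
#' @param min_length retention threshold; contigs must be strictly longer
#'   (default 100 bp).
#' @return data.frame: contig_id, sequence, length, mean_kmer_coverage.
#' @export
traverse_contigs <- function(graph, min_length = 100L) {
  k <- graph$k
  kmers <- graph$kmers
  n <- length(kmers)
  if (!n) return(empty_contigs_df())
  rcs <- revcomp(kmers)
  seq_or <- list(kmers, rcs)            # oriented node sequences: F, R
  last_or <- list(substring(kmers, k, k), substring(rcs, k, k))

  ## successor candidates per orientation: suffix(k-1) + base
  succ_id <- succ_or <- list()
  outdeg <- list()
  for (o in 1:2) {
    suf <- substring(seq_or[[o]], 2L, k)
    ids <- matrix(NA_integer_, n, 4L)
    ors <- matrix(NA_integer_, n, 4L)
    for (b in 1:4) {
      cand <- paste0(suf, DNA_BASES[b])
      crc <- revcomp(cand)
      canon <- ifelse(cand <= crc, cand, crc)
      ids[, b] <- match(canon, kmers)
      ors[, b] <- ifelse(cand <= crc, 1L, 2L)
    }
    present <- !is.na(ids)
    outdeg[[o]] <- rowSums(present)
    first <- max.col(present, ties.method = "first")
    any_p <- outdeg[[o]] > 0L
    sid <- rep(NA_integer_, n)
    sor <- rep(NA_integer_, n)
    sid[any_p] <- ids[cbind(which(any_p), first[any_p])]
    sor[any_p] <- ors[cbind(which(any_p), first[any_p])]
    succ_id[[o]] <- sid
    succ_or[[o]] <- sor
  }
  od <- cbind(outdeg[[1]], outdeg[[2]])
  sid <- cbind(succ_id[[1]], succ_id[[2]])
  sor <- cbind(succ_or[[1]], succ_or[[2]])
  flip <- function(o) 3L - o

  ## simple out-edge from (i,o): unique successor whose in-degree is 1
  simple_out <- matrix(FALSE, n, 2L)
  for (o in 1:2) {
    cand <- od[, o] == 1L
    w <- which(cand)
    tgt <- sid[w, o]
    tor <- sor[w, o]
    simple_out[w, o] <- od[cbind(tgt, flip(tor))] == 1L
  }
  ## simple in-edge of (i,o) == simple out-edge of (i, flip(o)) reversed
  simple_in <- simple_out[, 2:1, drop = FALSE]

  visited <- logical(n)
  walk_from <- function(i, o) {
    path <- integer(256L)
    bases <- character(256L)
    len <- 0L
    repeat {
      len <- len + 1L
      if (len > length(path)) {
        length(path) <- 2L * length(path)
        length(bases) <- 2L * length(bases)
      }
      path[len] <- i
      bases[len] <- last_or[[o]][i]
      visited[i] <<- TRUE
      if (!simple_out[i, o]) break
      ni <- sid[i, o]
      no <- sor[i, o]
      if (visited[ni]) break
      i <- ni
      o <- no
    }
    list(path = path[seq_len(len)], bases = bases[seq_len(len)])
  }

  res_seq <- character(0)
  res_cov <- numeric(0)
  emit <- function(start_i, start_o) {
    w <- walk_from(start_i, start_o)
    first <- w$path[1L]
    seq0 <- paste0(seq_or[[start_o]][first],
                   paste(w$bases[-1L], collapse = ""))
    res_seq[length(res_seq) + 1L] <<- seq0
    res_cov[length(res_cov) + 1L] <<- mean(graph$counts[w$path])
  }
  for (o in 1:2) {
    starts <- which(!simple_in[, o])
    for (i in starts) {
      if (!visited[i]) emit(i, o)
    }
  }
  ## leftover perfect cycles: start anywhere
  for (i in which(!visited)) {
    if (!visited[i]) emit(i, 1L)
  }

  keep <- nchar(res_seq) > min_length
  if (!any(keep)) return(empty_contigs_df())
  seqs <- canonical_form(res_seq[keep])
  cov <- res_cov[keep]
  o <- order(seqs)
  seqs <- seqs[o]
  cov <- cov[o]
  data.frame(
    contig_id = sprintf("ctg%05d", seq_along(seqs)),
    sequence = seqs,
    length = nchar(seqs),
    mean_kmer_coverage = cov,
    stringsAsFactors = FALSE
  )
}

empty_contigs_df <- function() {
  data.frame(contig_id = character(0), sequence = character(0),
             length = integer(0), mean_kmer_coverage = numeric(0),
             stringsAsFactors = FALSE)
}

#' Assemble reads at one (k, coverage cutoff) grid point
#'
#' Composition of [build_kmer_graph()], [auto_cutoff()] /
#' [apply_coverage_cutoff()] and [traverse_contigs()].
#'
#' @param reads a `read_set` or character vector of sequences.
#' @param k k-mer size.
#' @param coverage_cutoff integer cutoff, or `"auto"` for the automatic mode.
#' @param min_length contig retention threshold (strictly greater), 100 bp.
#' @return an `assembly_result`: list(k, coverage_cutoff, resolved_cutoff,
#'   contigs).
#' @export
assemble <- function(reads, k, coverage_cutoff = 2L, min_length = 100L) {
  g <- build_kmer_graph(reads, k)
  assemble_graph(g, coverage_cutoff, min_length)
}

assemble_graph <- function(graph, coverage_cutoff, min_length = 100L) {
  resolved <- if (identical(coverage_cutoff, "auto")) {
    auto_cutoff(graph)
  } else {
    as.integer(coverage_cutoff)
  }
  contigs <- traverse_contigs(apply_coverage_cutoff(graph, resolved),
                              min_length = min_length)
  structure(list(k = graph$k, coverage_cutoff = coverage_cutoff,
                 resolved_cutoff = resolved, contigs = contigs),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("assembly_result: k =", x$k, ", cutoff =", x$resolved_cutoff,
      if (identical(x$coverage_cutoff, "auto")) "(auto)" else "",
      "\n  ", nrow(x$contigs), "contigs,",
      sum(x$contigs$length), "bases\n")
  invisible(x)
}

#' Sweep a grid of (k, coverage cutoff) assemblies
#'
#' Builds each k-mer graph once and applies every cutoff to it; each grid
#' cell is identical to an independent [assemble()] call.
#'
#' @param reads a `read_set` or character vector.
#' @param k_values,cutoff_values nonempty vectors defining the grid.
#' @param min_length contig retention threshold.
#' @return an `assembly_sweep`: list of `assembly_result` (named
#'   `k{K}_c{C}`) plus a `manifest` data.frame (k, cutoff, resolved_cutoff,
#'   n_contigs, total_bases).
#' @export
sweep_assemblies <- function(reads, k_values, cutoff_values,
                             min_length = 100L) {
  stopifnot(length(k_values) >= 1L, length(cutoff_values) >= 1L)
  results <- list()
  for (k in k_values) {
    g <- build_kmer_graph(reads, k)
    for (cc in cutoff_values) {
      res <- assemble_graph(g, cc, min_length)
      results[[sprintf("k%d_c%s", k, as.character(cc))]] <- res
    }
  }
  manifest <- do.call(rbind, lapply(results, function(r) {
    data.frame(k = r$k,
               cutoff = as.character(r$coverage_cutoff),
               resolved_cutoff = r$resolved_cutoff,
               n_contigs = nrow(r$contigs),
               total_bases = sum(r$contigs$length),
               stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL
  structure(list(results = results, manifest = manifest),
            class = "assembly_sweep")
}

#' @export
print.assembly_sweep <- function(x, ...) {
  cat("assembly_sweep:", nrow(x$manifest), "grid cells (",
      length(unique(x$manifest$k)), "k-values x",
      length(unique(x$manifest$cutoff)), "cutoffs )\n")
  print(head(x$manifest, 10))
  invisible(x)
}
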