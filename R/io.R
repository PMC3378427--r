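## External interfaces: FASTA/FASTQ via Biostrings, tab-separated truth /
## manifest / hits / expression tables. TSV coordinates are 0-based
## half-open; the in-memory API is 1-based closed.

#' Write a transcriptome (or any named sequences) as FASTA
#'
#' @param x a `transcriptome_truth`, contigs data.frame, `assembly_result`,
#'   or named character vector.
#' @param path output file.
#' @param species optional species filter for `transcriptome_truth` input.
#' @return invisibly, the path.
#' @export
write_fasta <- function(x, path, species = NULL) {
  seqs <- if (inherits(x, "transcriptome_truth")) {
    g <- x$genes
    if (!is.null(species)) g <- g[g$species == species, , drop = FALSE]
    setNames(g$sequence, g$gene_id)
  } else {
    as_named_seqs(x)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a read set as FASTQ
#'
#' Paired reads go to `<prefix>_1.fastq` / `<prefix>_2.fastq`, single reads
#' to `<prefix>_single.fastq` (Sanger Phred+33 qualities).
#'
#' @param reads a `read_set`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix, default "reads".
#' @return invisibly, the character vector of files written.
#' @export
write_fastq <- function(reads, dir, prefix = "reads") {
  rs <- as_read_set(reads)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- rs$reads
  written <- character(0)
  emit <- function(sub, file) {
    x <- Biostrings::DNAStringSet(sub$sequence)
    names(x) <- sub$read_id
    Biostrings::writeXStringSet(
      x, file, format = "fastq",
      qualities = Biostrings::BStringSet(sub$quality)
    )
    file
  }
  paired <- df[df$pool == "paired", , drop = FALSE]
  if (nrow(paired)) {
    for (m in 1:2) {
      sub <- paired[paired$mate == m, , drop = FALSE]
      sub <- sub[order(sub$pair_id), , drop = FALSE]
      written <- c(written,
                   emit(sub, file.path(dir, sprintf("%s_%d.fastq", prefix, m))))
    }
  }
  single <- df[df$pool == "single", , drop = FALSE]
  f <- file.path(dir, paste0(prefix, "_single.fastq"))
  ## always write the single-end file so an empty read set still yields
  ## valid (empty) FASTQ output
  x <- Biostrings::DNAStringSet(single$sequence)
  names(x) <- single$read_id
  Biostrings::writeXStringSet(x, f, format = "fastq",
                              qualities = Biostrings::BStringSet(single$quality))
  written <- c(written, f)
  invisible(written)
}

#' Read FASTQ files into a read set
#'
#' @param single path to a single-end FASTQ (or NULL).
#' @param mate1,mate2 paths to the two paired-end FASTQ files (or NULL).
#' @return a `read_set`.
#' @export
read_fastq <- function(single = NULL, mate1 = NULL, mate2 = NULL) {
  load1 <- function(path, pool, mate) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    if (!length(x)) return(empty_reads_df())
    ids <- sub("\\s.*$", "", names(x))
    data.frame(read_id = ids,
               sequence = as.character(x),
               quality = as.character(S4Vectors::mcols(x)$qualities),
               pool = pool,
               pair_id = if (pool == "paired") sub("/[12]$", "", ids) else NA_character_,
               mate = mate,
               stringsAsFactors = FALSE)
  }
  parts <- list()
  if (!is.null(mate1)) parts$m1 <- load1(mate1, "paired", 1L)
  if (!is.null(mate2)) parts$m2 <- load1(mate2, "paired", 2L)
  if (!is.null(single)) parts$s <- load1(single, "single", NA_integer_)
  df <- if (length(parts)) do.call(rbind, parts) else empty_reads_df()
  rownames(df) <- NULL
  read_set(df)
}

#' Write the simulation truth tables as TSV
#'
#' `genes.tsv`: gene_id, family_id, copy_label, species, length,
#' expression_weight. `reads.tsv`: read_id, gene_id, start, end, strand with
#' 0-based half-open coordinates. `shared_regions.tsv`: family_id, start
#' (0-based), length.
#'
#' @param truth a `transcriptome_truth`.
#' @param reads optional `read_set` carrying a read truth table.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_truth_tables <- function(truth, reads = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  g <- truth$genes[, c("gene_id", "family_id", "copy_label", "species",
                       "length", "expression_weight")]
  f <- file.path(dir, "genes.tsv")
  write.table(g, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- f
  sr <- truth$shared_regions
  if (nrow(sr)) {
    sr$start <- sr$start - 1L # 0-based half-open
    f <- file.path(dir, "shared_regions.tsv")
    write.table(sr, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(reads) && !is.null(reads$truth)) {
    rt <- reads$truth
    rt$start <- rt$start - 1L # end stays: 1-based closed == 0-based half-open
    f <- file.path(dir, "reads.tsv")
    write.table(rt, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Write a sweep to disk: per-cell contig FASTA plus manifest TSV
#'
#' Each grid cell is written as `asm_k{K}_c{C}.fasta`; the sweep manifest
#' (k, cutoff, resolved_cutoff, n_contigs, total_bases) goes to
#' `manifest.tsv`.
#'
#' @param sweep an `assembly_sweep` from [sweep_assemblies()].
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "assembly_sweep"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (r in sweep$results) {
    f <- file.path(dir, sprintf("asm_k%d_c%s.fasta", r$k,
                                as.character(r$resolved_cutoff)))
    write_fasta(r, f)
    files <- c(files, f)
  }
  mf <- file.path(dir, "manifest.tsv")
  write.table(sweep$manifest, mf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(files, mf))
}

#' Write a sweep manifest / hits / expression table as TSV
#'
#' Generic TSV writer used for the manifest of [sweep_assemblies()], hit
#' tables of [map_contigs()] (coordinates converted to 0-based half-open),
#' and expression tables.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param zero_base_cols columns holding 1-based starts to convert.
#' @return invisibly, the path.
#' @export
write_tsv <- function(df, path, zero_base_cols = character(0)) {
  for (col in zero_base_cols) df[[col]] <- df[[col]] - 1L
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
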