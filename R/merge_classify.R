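## Pooling, CAP3-style greedy overlap merging, homeologue / orthologue /
## paralogue classification and the truth-based chimera audit.
##
## Contigs annotated to the same reference gene across all grid assemblies
## are pooled (strictly > 55% reference coverage), then merged greedily:
## at each step the pair with the longest suffix-prefix (or containment)
## overlap of at least 40 bp at >= 98% identity is joined, consensus by
## majority with the first-seen member winning ties, until no joinable pair
## remains. The thresholds mirror an overlap assembler run with 98% overlap
## identity and 40 bp minimum overlap; the deterministic ordering rule makes
## the output invariant under input permutation.

#' Pool contigs per reference gene
#'
#' A contig enters the pool of a reference gene iff its best-hit reference
#' coverage is strictly greater than `min_coverage`. References are
#' collapsed to gene families through `family` (e.g. so hits to either
#' reference species' orthologue land in one pool).
#'
#' @param hits best-hit table ([best_hits()]) over the union of all grid
#'   assemblies; contig ids must be unique across assemblies.
#' @param min_coverage strict pooling threshold, default 0.55.
#' @param family optional named character vector mapping reference_id to
#'   family id; defaults to the reference id itself.
#' @return data.frame: family, reference_id, contig_id, ref_coverage.
#' @export
pool_candidates <- function(hits, min_coverage = 0.55, family = NULL) {
  h <- hits[hits$ref_coverage > min_coverage, , drop = FALSE]
  fam <- if (is.null(family)) {
    h$reference_id
  } else {
    unname(family[h$reference_id])
  }
  out <- data.frame(family = fam, reference_id = h$reference_id,
                    contig_id = h$contig_id, ref_coverage = h$ref_coverage,
                    stringsAsFactors = FALSE)
  out[order(out$family, out$contig_id), , drop = FALSE]
}

## best candidate join between oriented sequences x (left/first-seen) and y:
## seeds nominate diagonals (y position t aligns x position t + d); the
## longest overlap with identity >= min_identity and length >= min_overlap
## wins. Returns list(ov, d, mm) or NULL.
best_join <- function(x, y, min_overlap, min_identity, seed_length = 15L) {
  lx <- nchar(x); ly <- nchar(y)
  if (lx < seed_length || ly < seed_length) return(NULL)
  xi <- kmer_positions(c(x = x), seed_length)
  yi <- kmer_positions(c(y = y), seed_length)
  j <- xi[yi, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(j)) return(NULL)
  ds <- sort(unique(j$pos - j$i.pos)) # x pos - y pos
  best <- NULL
  for (d in ds) {
    x1 <- max(1L, 1L + d); x2 <- min(lx, ly + d)
    ov <- x2 - x1 + 1L
    if (ov < min_overlap) next
    mm <- hamming_pairs(substr(x, x1, x2), substr(y, x1 - d, x2 - d))
    if ((ov - mm) / ov < min_identity) next
    if (is.null(best) || ov > best$ov || (ov == best$ov && mm < best$mm)) {
      best <- list(ov = ov, d = d, mm = mm)
    }
  }
  best
}

## merged sequence for a join: overlap consensus takes the bases of x
## (first-seen); y contributes only its non-overlapping overhangs
merge_join <- function(x, y, d) {
  lx <- nchar(x); ly <- nchar(y)
  left <- if (d < 0L) substr(y, 1L, -d) else ""
  right <- if (ly + d > lx) substr(y, lx - d + 1L, ly) else ""
  paste0(left, x, right)
}

#' Greedy overlap merging of pooled contigs
#'
#' Repeatedly joins the pair of sequences (either orientation of the second)
#' with the longest overlap of at least `min_overlap` bases at
#' `min_identity` or better, until no joinable pair remains; containments
#' are absorbed. Members are kept in a deterministic order (decreasing
#' length, then sequence), which fixes the first-seen consensus tie-break
#' and makes the result independent of input order.
#'
#' @param contigs named character vector of pooled contig sequences.
#' @param min_identity overlap identity threshold (default 0.98).
#' @param min_overlap minimum overlap length in bases (default 40).
#' @return data.frame: supercontig_id, sequence, length, n_members, members
#'   (comma-separated input names).
#' @export
overlap_merge <- function(contigs, min_identity = 0.98, min_overlap = 40L) {
  if (!length(contigs)) {
    return(data.frame(supercontig_id = character(0), sequence = character(0),
                      length = integer(0), n_members = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  if (is.null(names(contigs))) names(contigs) <- sprintf("m%04d", seq_along(contigs))
  mem <- data.frame(sequence = unname(contigs),
                    members = names(contigs), stringsAsFactors = FALSE)
  reorder <- function(m) m[order(-nchar(m$sequence), m$sequence, m$members), ,
                           drop = FALSE]
  mem <- reorder(mem)
  repeat {
    n <- nrow(mem)
    if (n < 2L) break
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        for (ori in c("F", "R")) {
          y <- if (ori == "F") mem$sequence[j] else revcomp(mem$sequence[j])
          cand <- best_join(mem$sequence[i], y, min_overlap, min_identity)
          if (!is.null(cand) &&
              (is.null(best) || cand$ov > best$ov)) {
            best <- c(cand, list(i = i, j = j, ori = ori))
          }
        }
      }
    }
    if (is.null(best)) break
    y <- if (best$ori == "F") mem$sequence[best$j] else revcomp(mem$sequence[best$j])
    merged <- merge_join(mem$sequence[best$i], y, best$d)
    newrow <- data.frame(
      sequence = merged,
      members = paste(mem$members[best$i], mem$members[best$j], sep = ","),
      stringsAsFactors = FALSE
    )
    mem <- reorder(rbind(mem[-c(best$i, best$j), , drop = FALSE], newrow))
  }
  rownames(mem) <- NULL
  data.frame(
    supercontig_id = sprintf("sc%04d", seq_len(nrow(mem))),
    sequence = mem$sequence,
    length = nchar(mem$sequence),
    n_members = lengths(strsplit(mem$members, ",", fixed = TRUE)),
    members = mem$members,
    stringsAsFactors = FALSE
  )
}

#' Classify copy number from merged supercontigs
#'
#' One supercontig per gene and species is a single copy; exactly two are a
#' candidate homeologous pair; more than two are flagged (possible chimera
#' or unannotated recent duplication) and excluded from pair counts.
#'
#' @param n_supercontigs integer vector (per gene/species).
#' @return character vector: "single", "pair" or "flagged" ("absent" for 0).
#' @export
classify_copies <- function(n_supercontigs) {
  ifelse(n_supercontigs == 0L, "absent",
         ifelse(n_supercontigs == 1L, "single",
                ifelse(n_supercontigs == 2L, "pair", "flagged")))
}

#' Classify a cross-species gene relationship
#'
#' Sequences called for the same gene family in the two species are
#' orthologues when their identity is strictly greater than `threshold`
#' (default 0.95) and likely paralogues (copy one in one species, copy two
#' in the other) otherwise. The call is symmetric in species order: the
#' arguments are ordered canonically before alignment.
#'
#' @param seq_sp1,seq_sp2 DNA strings.
#' @param threshold identity threshold, default 0.95.
#' @return "orthologue", "paralogue", or `NA` when the pair does not align.
#' @export
classify_cross_species <- function(seq_sp1, seq_sp2, threshold = 0.95) {
  ## canonical argument order -> symmetric call
  a <- seq_sp1; b <- seq_sp2
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  h <- align_pair(b, a)
  if (is.null(h)) return(NA_character_)
  if (h$identity > threshold) "orthologue" else "paralogue"
}

#' Audit supercontigs for chimeric joins against the simulation truth
#'
#' At every position where the two true homeologous copies of a family
#' differ (a copy-discriminating position), an aligned supercontig base
#' matches copy A, copy B, or neither. A supercontig is chimeric iff it
#' matches copy A at one or more discriminating positions and copy B at one
#' or more others.
#'
#' @param supercontigs data.frame with columns supercontig_id, sequence,
#'   family_id, species.
#' @param truth a `transcriptome_truth`.
#' @return list: `report` (per supercontig: family_id, species,
#'   supercontig_id, n_disc_covered, n_match_a, n_match_b, chimeric) and
#'   `rate` (fraction of auditable supercontigs flagged chimeric).
#' @export
audit_chimeras <- function(supercontigs, truth) {
  if (!inherits(truth, "transcriptome_truth")) stop("truth missing")
  g <- truth$genes
  rows <- vector("list", nrow(supercontigs))
  for (i in seq_len(nrow(supercontigs))) {
    sc <- supercontigs[i, ]
    fam <- g[g$family_id == sc$family_id & g$species == sc$species, ,
             drop = FALSE]
    if (nrow(fam) < 2L) {
      rows[[i]] <- data.frame(family_id = sc$family_id, species = sc$species,
                              supercontig_id = sc$supercontig_id,
                              n_disc_covered = NA_integer_,
                              n_match_a = NA_integer_, n_match_b = NA_integer_,
                              chimeric = NA, stringsAsFactors = FALSE)
      next
    }
    a <- fam$sequence[fam$copy_label == "A"]
    b <- fam$sequence[fam$copy_label == "B"]
    ca <- strsplit(a, "")[[1L]]
    cb <- strsplit(b, "")[[1L]]
    disc <- which(ca != cb)
    h <- align_pair(sc$sequence, a)
    if (is.null(h)) h <- align_pair(sc$sequence, b)
    if (is.null(h)) {
      rows[[i]] <- data.frame(family_id = sc$family_id, species = sc$species,
                              supercontig_id = sc$supercontig_id,
                              n_disc_covered = 0L, n_match_a = 0L,
                              n_match_b = 0L, chimeric = NA,
                              stringsAsFactors = FALSE)
      next
    }
    qo <- if (h$strand == "+") sc$sequence else revcomp(sc$sequence)
    cov_disc <- disc[disc >= h$ref_start & disc <= h$ref_end]
    qpos <- h$q_start + (cov_disc - h$ref_start)
    qb <- substring(qo, qpos, qpos)
    n_a <- sum(qb == ca[cov_disc])
    n_b <- sum(qb == cb[cov_disc])
    rows[[i]] <- data.frame(family_id = sc$family_id, species = sc$species,
                            supercontig_id = sc$supercontig_id,
                            n_disc_covered = length(cov_disc),
                            n_match_a = n_a, n_match_b = n_b,
                            chimeric = n_a >= 1L && n_b >= 1L,
                            stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  auditable <- !is.na(report$chimeric)
  rate <- if (any(auditable)) mean(report$chimeric[auditable]) else NA_real_
  list(report = report, rate = rate)
}
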