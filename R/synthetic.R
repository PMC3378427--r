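## Synthetic allopolyploid transcriptome + Illumina-like read simulator.
##
## The generator emulates the structure of an allopolyploid transcriptome:
## gene families carrying two homeologous copies per species (copies A and B,
## derived from the two parental subgenomes) at a controlled within-species
## identity, orthologous copies across two species at high identity, heavily
## skewed (log-normal) expression with a configurable very-high-expression
## band, and 75 bp reads whose per-cycle error rate rises sharply after a
## "knee" cycle. All divergence is substitution-only, so percent identity has
## a single unambiguous (Hamming) definition.

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_transcriptome()] and [simulate_reads()]. Defaults encode the
#' study conditions: homeologues at 85-95% identity, orthologues at ~98%
#' (floor 0.95), 75 bp reads, quality knee at cycle 45 (paired-end) or 60
#' (single-end), and a log-normal expression distribution with a small
#' fraction of genes forced above the RPKM-1000 band.
#'
#' @param n_families number of gene families to simulate.
#' @param homeologue_identity_range length-2 numeric interval within
#'   \[0.85, 0.95\] (by default) from which each family's within-species
#'   homeologue identity target is drawn. Any sub-interval of \[0, 1\] is
#'   accepted so lower-divergence scenarios can be explored.
#' @param orthologue_identity cross-species identity of orthologous copies
#'   (default 0.98).
#' @param orthologue_identity_min asserted floor for orthologue identity
#'   (default 0.95).
#' @param singleton_fraction fraction of families carrying a single copy per
#'   species (no homeologue), e.g. plastid-like genes.
#' @param length_log_mean,length_log_sd,length_min,length_max log-normal
#'   coding-sequence length model (bases); lengths are clamped to
#'   \[length_min, length_max\] and never below 200.
#' @param expression_log_mean,expression_log_sd log-normal expression weight
#'   model (relative transcript abundance, per gene copy).
#' @param high_expression_fraction fraction of genes (per species) rescaled
#'   so that their implied RPKM exceeds `rpkm_high_threshold`.
#' @param rpkm_high_threshold RPKM value defining the very-high-expression
#'   band (default 1000).
#' @param shared_region_fraction fraction of two-copy families in which
#'   identical windows are planted between the homeologues.
#' @param shared_region_count number of planted windows per such family.
#' @param shared_region_length_range window length interval in bases
#'   (default 35-47).
#' @param max_identical_run optional upper bound (bases) on the length of any
#'   identical run between the two homeologues of a family outside planted
#'   windows; `Inf` disables the constraint.
#' @param read_length read length in bases (>= 31).
#' @param n_reads total number of reads produced by [simulate_reads()].
#' @param paired_fraction fraction of reads that are paired-end.
#' @param insert_mean,insert_sd paired-end insert size model (bases).
#' @param error_knee_pe,error_knee_se last high-quality cycle for paired-end
#'   and single-end reads.
#' @param pre_knee_error,post_knee_error per-base substitution probabilities
#'   before (inclusive) and after the knee cycle; both in \[0, 0.5\].
#' @param seed integer seed; identical configurations give byte-identical
#'   outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_families = 100L,
                       homeologue_identity_range = c(0.85, 0.95),
                       orthologue_identity = 0.98,
                       orthologue_identity_min = 0.95,
                       singleton_fraction = 0.2,
                       length_log_mean = log(900),
                       length_log_sd = 0.45,
                       length_min = 250L,
                       length_max = 3000L,
                       expression_log_mean = 0,
                       expression_log_sd = 2.2,
                       high_expression_fraction = 0.03,
                       rpkm_high_threshold = 1000,
                       shared_region_fraction = 0,
                       shared_region_count = 8L,
                       shared_region_length_range = c(35L, 47L),
                       max_identical_run = Inf,
                       read_length = 75L,
                       n_reads = 100000L,
                       paired_fraction = 0.25,
                       insert_mean = 300,
                       insert_sd = 30,
                       error_knee_pe = 45L,
                       error_knee_se = 60L,
                       pre_knee_error = 0.004,
                       post_knee_error = 0.12,
                       seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families),
    homeologue_identity_range = as.numeric(homeologue_identity_range),
    orthologue_identity = orthologue_identity,
    orthologue_identity_min = orthologue_identity_min,
    singleton_fraction = singleton_fraction,
    length_log_mean = length_log_mean,
    length_log_sd = length_log_sd,
    length_min = as.integer(length_min),
    length_max = as.integer(length_max),
    expression_log_mean = expression_log_mean,
    expression_log_sd = expression_log_sd,
    high_expression_fraction = high_expression_fraction,
    rpkm_high_threshold = rpkm_high_threshold,
    shared_region_fraction = shared_region_fraction,
    shared_region_count = as.integer(shared_region_count),
    shared_region_length_range = as.integer(shared_region_length_range),
    max_identical_run = max_identical_run,
    read_length = as.integer(read_length),
    n_reads = as.integer(n_reads),
    paired_fraction = paired_fraction,
    insert_mean = insert_mean,
    insert_sd = insert_sd,
    error_knee_pe = as.integer(error_knee_pe),
    error_knee_se = as.integer(error_knee_se),
    pre_knee_error = pre_knee_error,
    post_knee_error = post_knee_error,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_families >= 1L,
    length(cfg$homeologue_identity_range) == 2L,
    cfg$homeologue_identity_range[1] <= cfg$homeologue_identity_range[2],
    all(cfg$homeologue_identity_range >= 0),
    all(cfg$homeologue_identity_range <= 1),
    cfg$orthologue_identity > 0, cfg$orthologue_identity <= 1,
    cfg$orthologue_identity >= cfg$orthologue_identity_min,
    cfg$singleton_fraction >= 0, cfg$singleton_fraction <= 1,
    cfg$high_expression_fraction >= 0, cfg$high_expression_fraction <= 1,
    cfg$shared_region_fraction >= 0, cfg$shared_region_fraction <= 1,
    cfg$paired_fraction >= 0, cfg$paired_fraction <= 1,
    cfg$read_length >= 31L,
    cfg$pre_knee_error >= 0, cfg$pre_knee_error <= 0.5,
    cfg$post_knee_error >= 0, cfg$post_knee_error <= 0.5,
    cfg$length_min >= 200L
  )
  invisible(cfg)
}

#' Mutate a sequence to a target identity
#'
#' Applies substitution-only divergence so that the returned sequence matches
#' the input at `round(n * target_identity)` positions; a substituted base is
#' never equal to the original base.
#'
#' @param sequence DNA string (non-empty).
#' @param target_identity fraction in (0, 1].
#' @param seed integer seed making the call deterministic.
#' @return the diverged DNA string.
#' @export
mutate_to_identity <- function(sequence, target_identity, seed = 1L) {
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  if (!(target_identity > 0 && target_identity <= 1)) {
    stop("target_identity must be in (0, 1]")
  }
  n_mut <- as.integer(round(n * (1 - target_identity)))
  if (n_mut == 0L) return(sequence)
  withr::with_seed(seed, {
    pos <- sample.int(n, n_mut)
    substitute_bases(sequence, pos)
  })
}

#' Plant identical windows between two homeologous copies
#'
#' Copies the bases of `copy_a` into `copy_b` over each region so that the
#' two sequences are byte-identical within every window and untouched
#' elsewhere. This reproduces the situation where two homeologues share short
#' identical stretches (35-47 bp in the motivating case) that defeat
#' assembly at k-mer sizes not exceeding the window length.
#'
#' @param copy_a,copy_b equal-length DNA strings.
#' @param regions data.frame (or matrix) with columns `start` (1-based) and
#'   `length`; regions must lie within the sequences and not overlap.
#' @return list with elements `copy_a`, `copy_b`.
#' @export
plant_shared_regions <- function(copy_a, copy_b, regions) {
  n <- nchar(copy_a)
  if (nchar(copy_b) != n) stop("copies must have equal length")
  regions <- as.data.frame(regions)
  if (nrow(regions) == 0L) return(list(copy_a = copy_a, copy_b = copy_b))
  stopifnot(all(c("start", "length") %in% names(regions)))
  st <- as.integer(regions$start)
  ln <- as.integer(regions$length)
  en <- st + ln - 1L
  if (any(st < 1L) || any(en > n) || any(ln < 1L)) {
    stop("regions out of range")
  }
  o <- order(st)
  if (any(st[o][-1L] <= en[o][-length(o)])) stop("regions overlap")
  for (i in seq_along(st)) {
    substr(copy_b, st[i], en[i]) <- substr(copy_a, st[i], en[i])
  }
  list(copy_a = copy_a, copy_b = copy_b)
}

## Sample n distinct positions from `eligible`, then (if finite maxrun)
## relocate positions until no gap between consecutive chosen positions
## (within 1..L) exceeds maxrun. Used for the homeologue-divergence set so
## that "no identical window of >= maxrun+1 bases" can be guaranteed.
sample_positions_maxrun <- function(eligible, n, L, maxrun = Inf) {
  pos <- sort(sample(eligible, n))
  if (!is.finite(maxrun)) return(pos)
  repeat {
    bounds <- c(0L, pos, L + 1L)
    gaps <- diff(bounds) - 1L
    worst <- which.max(gaps)
    if (gaps[worst] <= maxrun) break
    ## midpoint of the worst gap, snapped to the nearest eligible unused pos
    lo <- bounds[worst] + 1L
    hi <- bounds[worst + 1L] - 1L
    mid <- as.integer((lo + hi) %/% 2L)
    cand <- setdiff(eligible[eligible >= lo & eligible <= hi], pos)
    if (!length(cand)) stop("max_identical_run unreachable: no eligible position in gap")
    newpos <- cand[which.min(abs(cand - mid))]
    ## drop the position bordering the smallest gap to keep the count fixed
    inner <- seq_along(pos)
    small <- inner[which.min(gaps[inner] + gaps[inner + 1L])]
    pos <- sort(c(pos[-small], newpos))
  }
  pos
}

#' Simulate an allopolyploid transcriptome with known truth
#'
#' For each gene family an ancestral coding sequence is generated; the two
#' parental subgenomes diverge at a family-specific set of positions so that
#' the two homeologous copies within each species match the drawn identity
#' target exactly, while orthologous copies across the two species (`sp1`,
#' `sp2`) retain identity `orthologue_identity`. All mutated position sets
#' are disjoint, making every pairwise identity an exact, auditable count.
#' Optionally, identical windows are planted between the homeologues of a
#' fraction of families, and the longest identical run between copies can be
#' bounded.
#'
#' @param config a [sim_config()] object.
#' @return a `transcriptome_truth` list with elements `genes` (data.frame:
#'   gene_id, family_id, copy_label, species, length, identity_target,
#'   expression_weight, sequence), `shared_regions` (data.frame: family_id,
#'   start, length; 1-based starts) and `config`.
#' @export
simulate_transcriptome <- function(config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, 1L), {
    r_sp <- (1 - config$orthologue_identity) / 2
    rows <- vector("list", config$n_families)
    shared <- vector("list", config$n_families)
    for (f in seq_len(config$n_families)) {
      fam <- sprintf("fam%04d", f)
      L <- as.integer(round(rlnorm(1, config$length_log_mean,
                                   config$length_log_sd)))
      L <- max(config$length_min, min(config$length_max, L))
      anc <- random_dna(L)
      singleton <- runif(1) < config$singleton_fraction
      m_s <- as.integer(round(L * r_sp))

      windows <- NULL
      eligible <- seq_len(L)
      if (!singleton && config$shared_region_fraction > 0 &&
          runif(1) < config$shared_region_fraction) {
        windows <- draw_windows(L, config$shared_region_count,
                                config$shared_region_length_range)
        if (nrow(windows)) {
          covered <- unlist(mapply(seq, windows$start,
                                   windows$start + windows$length - 1L,
                                   SIMPLIFY = FALSE))
          eligible <- setdiff(eligible, covered)
          shared[[f]] <- cbind(family_id = fam, windows)
        }
      }

      if (singleton) {
        need <- 2L * m_s
        if (need > length(eligible)) stop("identity targets unreachable for family ", fam)
        pos <- sample(eligible, need)
        s1 <- pos[seq_len(m_s)]
        s2 <- pos[m_s + seq_len(m_s)]
        seq1 <- substitute_bases(anc, s1)
        seq2 <- substitute_bases(anc, s2)
        rows[[f]] <- data.frame(
          gene_id = paste0(fam, "_", c("sp1", "sp2"), "_s"),
          family_id = fam,
          copy_label = "singleton",
          species = c("sp1", "sp2"),
          length = L,
          identity_target = NA_real_,
          sequence = c(seq1, seq2),
          stringsAsFactors = FALSE
        )
      } else {
        t_id <- runif(1, config$homeologue_identity_range[1],
                      config$homeologue_identity_range[2])
        n_diff <- as.integer(round(L * (1 - t_id)))
        nH <- n_diff - 2L * m_s
        if (nH < 0L) {
          stop("identity targets unreachable for family ", fam,
               ": homeologue target ", signif(t_id, 3),
               " exceeds 1 - 2 * species divergence")
        }
        if (nH + 4L * m_s > length(eligible)) {
          stop("identity targets unreachable for family ", fam,
               ": not enough mutable positions")
        }
        ## H positions drive the homeologue divergence; optionally bounded
        ## so no identical run between copies reaches max_identical_run + 1.
        ## Species-specific positions also separate copies, so the run bound
        ## enforced on H alone is conservative only up to those; enforce on
        ## the union afterwards by construction: draw H with the bound, then
        ## species positions freely (they can only shorten runs).
        H <- sample_positions_maxrun(eligible, nH, L,
                                     maxrun = config$max_identical_run)
        rest <- setdiff(eligible, H)
        pos <- sample(rest, 4L * m_s)
        sA1 <- pos[seq_len(m_s)]
        sB1 <- pos[m_s + seq_len(m_s)]
        sA2 <- pos[2L * m_s + seq_len(m_s)]
        sB2 <- pos[3L * m_s + seq_len(m_s)]
        B0 <- substitute_bases(anc, H)
        seqs <- c(
          substitute_bases(anc, sA1), # sp1 copy A
          substitute_bases(B0, sB1),  # sp1 copy B
          substitute_bases(anc, sA2), # sp2 copy A
          substitute_bases(B0, sB2)   # sp2 copy B
        )
        rows[[f]] <- data.frame(
          gene_id = paste0(fam, "_", rep(c("sp1", "sp2"), each = 2L),
                           "_", c("A", "B")),
          family_id = fam,
          copy_label = rep(c("A", "B"), 2L),
          species = rep(c("sp1", "sp2"), each = 2L),
          length = L,
          identity_target = t_id,
          sequence = seqs,
          stringsAsFactors = FALSE
        )
      }
    }
    genes <- do.call(rbind, rows)
    rownames(genes) <- NULL
    genes$expression_weight <- rlnorm(nrow(genes), config$expression_log_mean,
                                      config$expression_log_sd)
    for (sp in c("sp1", "sp2")) {
      idx <- which(genes$species == sp)
      genes$expression_weight[idx] <- force_high_expression(
        genes$expression_weight[idx], genes$length[idx],
        config$high_expression_fraction, config$rpkm_high_threshold
      )
    }
    shared_df <- if (length(sr <- Filter(Negate(is.null), shared))) {
      do.call(rbind, sr)
    } else {
      data.frame(family_id = character(0), start = integer(0),
                 length = integer(0))
    }
    rownames(shared_df) <- NULL
    structure(list(genes = genes, shared_regions = shared_df,
                   config = config),
              class = "transcriptome_truth")
  })
}

## non-overlapping windows of lengths drawn from `range`, uniform placement
draw_windows <- function(L, count, range) {
  lens <- sample(seq(range[1], range[2]), count, replace = TRUE)
  starts <- integer(0)
  taken <- integer(0)
  kept <- integer(0)
  for (i in seq_along(lens)) {
    ok <- FALSE
    for (try in 1:50) {
      s <- sample.int(L - lens[i] + 1L, 1L)
      span <- s:(s + lens[i] - 1L)
      if (!any(span %in% taken)) {
        taken <- c(taken, span)
        starts <- c(starts, s)
        kept <- c(kept, lens[i])
        ok <- TRUE
        break
      }
    }
    if (!ok) break # sequence too crowded; keep what fits
  }
  data.frame(start = starts, length = kept)
}

## scale the top-weight genes until their implied RPKM clears the threshold
force_high_expression <- function(w, len, fraction, threshold) {
  n_hi <- as.integer(round(fraction * length(w)))
  if (n_hi == 0L) return(w)
  hi <- order(w, decreasing = TRUE)[seq_len(n_hi)]
  for (iter in 1:100) {
    implied <- 1e9 * w / sum(w * len)
    if (all(implied[hi] > threshold)) break
    w[hi] <- w[hi] * 1.5
  }
  w
}

#' @export
print.transcriptome_truth <- function(x, ...) {
  g <- x$genes
  cat("transcriptome_truth:", length(unique(g$family_id)), "families,",
      nrow(g), "gene copies\n")
  cat("  species:", paste(sort(unique(g$species)), collapse = ", "), "\n")
  cat("  copy labels:", paste(names(table(g$copy_label)),
                              table(g$copy_label), collapse = "; "), "\n")
  cat("  lengths:", min(g$length), "-", max(g$length), "bp\n")
  if (nrow(x$shared_regions)) {
    cat("  planted shared windows in",
        length(unique(x$shared_regions$family_id)), "families\n")
  }
  invisible(x)
}

#' Simulate Illumina-like reads from a transcriptome truth
#'
#' Reads are drawn from the gene copies of one species with probability
#' proportional to `expression_weight * length`, from a uniformly placed
#' position and a uniformly random strand. Substitution errors are applied
#' per cycle at `pre_knee_error` up to the knee cycle and `post_knee_error`
#' beyond it; Phred qualities (Sanger offset 33) encode the error
#' probability of each cycle. Paired-end fragments use a normal insert-size
#' model; mates are the two fragment ends, the second read on the opposite
#' strand. The returned truth table records the source coordinates of every
#' read (1-based closed internally; TSV export is 0-based half-open).
#'
#' @param truth a `transcriptome_truth` object.
#' @param config a [sim_config()]; defaults to `truth$config`.
#' @param species which species' transcriptome to sequence.
#' @return a `read_set` (see [read_set()]).
#' @export
simulate_reads <- function(truth, config = truth$config, species = "sp1") {
  validate_sim_config(config)
  genes <- truth$genes[truth$genes$species == species, , drop = FALSE]
  if (!nrow(genes)) stop("no genes for species ", species)
  rl <- config$read_length
  if (any(genes$length < rl)) stop("gene shorter than read length")
  n <- config$n_reads
  if (n == 0L) {
    return(read_set(empty_reads_df(), empty_read_truth_df(),
                    provenance = list(input = 0L)))
  }
  withr::with_seed(derive_seed(config$seed, 2L), {
    n_pairs <- as.integer(round(n * config$paired_fraction / 2))
    n_se <- n - 2L * n_pairs
    prob <- genes$expression_weight * genes$length

    ## ---- single-end ----
    se <- NULL
    if (n_se > 0L) {
      gi <- sample.int(nrow(genes), n_se, replace = TRUE, prob = prob)
      glen <- genes$length[gi]
      start <- 1L + as.integer(floor(runif(n_se) * (glen - rl + 1L)))
      strand <- ifelse(runif(n_se) < 0.5, "+", "-")
      raw <- substring(genes$sequence[gi], start, start + rl - 1L)
      raw[strand == "-"] <- revcomp(raw[strand == "-"])
      seqs <- apply_cycle_errors(raw, rl, config$error_knee_se,
                                 config$pre_knee_error, config$post_knee_error)
      se <- list(
        reads = data.frame(
          read_id = sprintf("se%07d", seq_len(n_se)),
          sequence = seqs,
          quality = quality_string(rl, config$error_knee_se,
                                   config$pre_knee_error,
                                   config$post_knee_error),
          pool = "single", pair_id = NA_character_, mate = NA_integer_,
          stringsAsFactors = FALSE
        ),
        truth = data.frame(
          read_id = sprintf("se%07d", seq_len(n_se)),
          gene_id = genes$gene_id[gi],
          start = start, end = start + rl - 1L, strand = strand,
          stringsAsFactors = FALSE
        )
      )
    }

    ## ---- paired-end ----
    pe <- NULL
    if (n_pairs > 0L) {
      gi <- sample.int(nrow(genes), n_pairs, replace = TRUE, prob = prob)
      glen <- genes$length[gi]
      ins <- as.integer(round(rnorm(n_pairs, config$insert_mean,
                                    config$insert_sd)))
      ins <- pmax(rl, pmin(ins, glen))
      fstart <- 1L + as.integer(floor(runif(n_pairs) * (glen - ins + 1L)))
      fstrand <- ifelse(runif(n_pairs) < 0.5, "+", "-")
      ## read 1 = 5' fragment end on fragment strand; read 2 = other end,
      ## opposite strand. Coordinates always on the gene's forward strand.
      r1_start <- ifelse(fstrand == "+", fstart, fstart + ins - rl)
      r2_start <- ifelse(fstrand == "+", fstart + ins - rl, fstart)
      r1_strand <- fstrand
      r2_strand <- ifelse(fstrand == "+", "-", "+")
      raw1 <- substring(genes$sequence[gi], r1_start, r1_start + rl - 1L)
      raw2 <- substring(genes$sequence[gi], r2_start, r2_start + rl - 1L)
      raw1[r1_strand == "-"] <- revcomp(raw1[r1_strand == "-"])
      raw2[r2_strand == "-"] <- revcomp(raw2[r2_strand == "-"])
      seq1 <- apply_cycle_errors(raw1, rl, config$error_knee_pe,
                                 config$pre_knee_error, config$post_knee_error)
      seq2 <- apply_cycle_errors(raw2, rl, config$error_knee_pe,
                                 config$pre_knee_error, config$post_knee_error)
      pid <- sprintf("pe%07d", seq_len(n_pairs))
      qual <- quality_string(rl, config$error_knee_pe,
                             config$pre_knee_error, config$post_knee_error)
      pe <- list(
        reads = data.frame(
          read_id = c(paste0(pid, "/1"), paste0(pid, "/2")),
          sequence = c(seq1, seq2),
          quality = qual,
          pool = "paired",
          pair_id = c(pid, pid),
          mate = rep(1:2, each = n_pairs),
          stringsAsFactors = FALSE
        ),
        truth = data.frame(
          read_id = c(paste0(pid, "/1"), paste0(pid, "/2")),
          gene_id = genes$gene_id[c(gi, gi)],
          start = c(r1_start, r2_start),
          end = c(r1_start, r2_start) + rl - 1L,
          strand = c(r1_strand, r2_strand),
          stringsAsFactors = FALSE
        )
      )
    }

    reads <- rbind(if (!is.null(pe)) pe$reads, if (!is.null(se)) se$reads)
    truth_df <- rbind(if (!is.null(pe)) pe$truth, if (!is.null(se)) se$truth)
    rownames(reads) <- rownames(truth_df) <- NULL
    read_set(reads, truth_df, provenance = list(input = nrow(reads)))
  })
}

## per-cycle substitution errors applied to a block of equal-length reads,
## operating on the raw bytes of the concatenation
apply_cycle_errors <- function(seqs, rl, knee, pre, post) {
  if (!length(seqs) || (pre == 0 && post == 0)) return(seqs)
  p_cycle <- ifelse(seq_len(rl) <= knee, pre, post)
  n <- length(seqs)
  raw <- charToRaw(paste0(seqs, collapse = ""))
  p_all <- rep(p_cycle, times = n)
  err <- which(runif(length(raw)) < p_all)
  if (length(err)) {
    codes <- charToRaw(paste(DNA_BASES, collapse = ""))
    ## for each base the three alternative codes
    alt <- sapply(codes, function(b) codes[codes != b]) # 3 x 4 raw matrix
    colnames(alt) <- rawToChar(codes, multiple = TRUE)
    cur <- rawToChar(raw[err], multiple = TRUE)
    pick <- sample.int(3L, length(err), replace = TRUE)
    raw[err] <- alt[cbind(pick, match(cur, colnames(alt)))]
  }
  starts <- seq.int(1L, by = rl, length.out = n)
  substring(rawToChar(raw), starts, starts + rl - 1L)
}

## constant Sanger-encoded quality string implied by the two-level error model
quality_string <- function(rl, knee, pre, post) {
  q <- ifelse(seq_len(rl) <= knee,
              phred_from_error(pre), phred_from_error(post))
  rawToChar(as.raw(33L + q))
}

phred_from_error <- function(p) {
  if (p <= 0) return(40L) # error-free cycles written as Q40
  as.integer(round(-10 * log10(p)))
}
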