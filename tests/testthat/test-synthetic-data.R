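test_that("mutate_to_identity hits the forced substitution count exactly", {
  expect_identical(mutate_to_identity("ACGTACGTAC", 1.0, seed = 99),
                   "ACGTACGTAC")
  m <- mutate_to_identity(strrep("A", 100), 0.90, seed = 7)
  expect_equal(sum(strsplit(m, "")[[1]] != "A"), 10)
  ## substituted bases never equal the original
  expect_false(any(strsplit(m, "")[[1]][strsplit(m, "")[[1]] != "A"] == "A"))
  ## Hamming oracle on random 500-mers at target 0.93 -> 35 mismatches
  for (s in 1:5) {
    x <- rand_seq(500, seed = s)
    y <- mutate_to_identity(x, 0.93, seed = s + 100)
    expect_equal(500 - round(500 * oracle_hamming_identity(x, y)), 35)
  }
  expect_error(mutate_to_identity("", 0.9), "empty")
  expect_error(mutate_to_identity("ACGT", 0), "target_identity")
})

test_that("plant_shared_regions copies windows and leaves the rest intact", {
  a <- rand_seq(300, seed = 1)
  b <- mutate_to_identity(a, 0.9, seed = 2)
  ## empty region list: unchanged
  out <- plant_shared_regions(a, b, data.frame(start = integer(0),
                                               length = integer(0)))
  expect_identical(out$copy_b, b)
  ## full-length region: outputs identical
  out <- plant_shared_regions(a, b, data.frame(start = 1, length = 300))
  expect_identical(out$copy_a, out$copy_b)
  ## two windows of 35 and 47: windows equal, identity strictly increases
  reg <- data.frame(start = c(20, 150), length = c(35, 47))
  out <- plant_shared_regions(a, b, reg)
  for (i in 1:2) {
    expect_identical(substr(out$copy_a, reg$start[i], reg$start[i] + reg$length[i] - 1),
                     substr(out$copy_b, reg$start[i], reg$start[i] + reg$length[i] - 1))
  }
  expect_gt(oracle_hamming_identity(out$copy_a, out$copy_b),
            oracle_hamming_identity(a, b))
  ## bases outside the windows untouched
  outside <- setdiff(1:300, c(20:54, 150:196))
  expect_identical(substring(out$copy_b, outside, outside),
                   substring(b, outside, outside))
  ## invalid regions rejected
  expect_error(plant_shared_regions(a, b, data.frame(start = 290, length = 20)),
               "range")
  expect_error(plant_shared_regions(a, b, data.frame(start = c(10, 30),
                                                     length = c(25, 10))),
               "overlap")
})

test_that("simulated homeologue and orthologue identities match their targets", {
  cfg <- sim_config(n_families = 6, singleton_fraction = 0,
                    homeologue_identity_range = c(0.90, 0.90),
                    length_log_mean = log(1000), length_log_sd = 0,
                    seed = 3)
  tr <- simulate_transcriptome(cfg)
  g <- tr$genes
  for (fam in unique(g$family_id)) {
    for (sp in c("sp1", "sp2")) {
      pair <- g[g$family_id == fam & g$species == sp, ]
      ## independent global-alignment oracle: identity 0.90 +/- 0.005
      expect_equal(oracle_alignment_identity(pair$sequence[1], pair$sequence[2]),
                   0.90, tolerance = 0.005)
    }
    ## orthologues across species at >= the configured floor
    for (lab in c("A", "B")) {
      orth <- g[g$family_id == fam & g$copy_label == lab, ]
      expect_gte(oracle_alignment_identity(orth$sequence[1], orth$sequence[2]),
                 cfg$orthologue_identity_min)
    }
  }
})

test_that("zero-divergence configuration yields byte-identical homeologues", {
  cfg <- sim_config(n_families = 3, singleton_fraction = 0,
                    homeologue_identity_range = c(1, 1),
                    orthologue_identity = 1, orthologue_identity_min = 1,
                    seed = 5)
  tr <- simulate_transcriptome(cfg)
  g <- tr$genes
  for (fam in unique(g$family_id)) {
    pair <- g[g$family_id == fam & g$species == "sp1", ]
    expect_identical(pair$sequence[1], pair$sequence[2])
  }
})

test_that("the simulator is deterministic for a fixed seed", {
  cfg <- sim_config(n_families = 4, n_reads = 500, seed = 11)
  t1 <- simulate_transcriptome(cfg)
  t2 <- simulate_transcriptome(cfg)
  expect_identical(t1, t2)
  r1 <- simulate_reads(t1, species = "sp1")
  r2 <- simulate_reads(t2, species = "sp1")
  expect_identical(r1$reads, r2$reads)
  ## byte-identical FASTQ/FASTA output
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fastq(r1, d1); write_fastq(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("planted shared windows are byte-identical between copies", {
  cfg <- sim_config(n_families = 8, singleton_fraction = 0,
                    shared_region_fraction = 1, shared_region_count = 4,
                    length_log_mean = log(1200), length_log_sd = 0,
                    seed = 9)
  tr <- simulate_transcriptome(cfg)
  expect_gt(nrow(tr$shared_regions), 0)
  g <- tr$genes
  for (i in seq_len(nrow(tr$shared_regions))) {
    sr <- tr$shared_regions[i, ]
    for (sp in c("sp1", "sp2")) {
      pair <- g[g$family_id == sr$family_id & g$species == sp, ]
      expect_identical(
        substr(pair$sequence[1], sr$start, sr$start + sr$length - 1),
        substr(pair$sequence[2], sr$start, sr$start + sr$length - 1)
      )
    }
  }
  expect_true(all(tr$shared_regions$length >= 35 &
                    tr$shared_regions$length <= 47))
})

test_that("error-free reads are exact substrings of their recorded source", {
  cfg <- sim_config(n_families = 3, n_reads = 400,
                    pre_knee_error = 0, post_knee_error = 0, seed = 13)
  tr <- simulate_transcriptome(cfg)
  rs <- simulate_reads(tr, species = "sp1")
  g <- setNames(tr$genes$sequence, tr$genes$gene_id)
  tt <- rs$truth
  src <- substring(g[tt$gene_id], tt$start, tt$end)
  src[tt$strand == "-"] <- revcomp(src[tt$strand == "-"])
  expect_identical(rs$reads$sequence[match(tt$read_id, rs$reads$read_id)],
                   unname(src))
})

test_that("read sampling follows expression weight x length", {
  ## two genes, equal length, weights 9:1 -> 9000:1000 of 10,000 within
  ## binomial 99% bounds
  cfg <- sim_config(n_families = 1, n_reads = 10000, paired_fraction = 0,
                    pre_knee_error = 0, post_knee_error = 0,
                    singleton_fraction = 0,
                    length_log_mean = log(800), length_log_sd = 0, seed = 17)
  tr <- simulate_transcriptome(cfg)
  tr$genes$expression_weight <- c(9, 1, 9, 1)
  rs <- simulate_reads(tr, species = "sp1")
  n_a <- sum(rs$truth$gene_id == tr$genes$gene_id[1])
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.9)
  expect_gte(n_a, bounds[1])
  expect_lte(n_a, bounds[2])
})

test_that("post-knee cycles carry the configured error rate", {
  cfg <- sim_config(n_families = 2, n_reads = 3000, paired_fraction = 1,
                    error_knee_pe = 45, pre_knee_error = 0,
                    post_knee_error = 0.1, singleton_fraction = 0, seed = 19)
  tr <- simulate_transcriptome(cfg)
  rs <- simulate_reads(tr, species = "sp1")
  g <- setNames(tr$genes$sequence, tr$genes$gene_id)
  tt <- rs$truth
  src <- substring(g[tt$gene_id], tt$start, tt$end)
  src[tt$strand == "-"] <- revcomp(src[tt$strand == "-"])
  obs <- rs$reads$sequence[match(tt$read_id, rs$reads$read_id)]
  tail_mm <- mapply(function(o, s) {
    sum(strsplit(substr(o, 46, 75), "")[[1]] != strsplit(substr(s, 46, 75), "")[[1]])
  }, obs, src)
  rate <- sum(tail_mm) / (length(obs) * 30)
  expect_equal(rate, 0.1, tolerance = 0.01)
  ## error substitutions never reproduce the original base, so the raw
  ## mismatch rate *is* the error rate
  head_mm <- mapply(function(o, s) {
    sum(strsplit(substr(o, 1, 45), "")[[1]] != strsplit(substr(s, 1, 45), "")[[1]])
  }, obs, src)
  expect_identical(sum(head_mm), 0L)
})

test_that("max_identical_run bounds identical stretches between copies", {
  cfg <- sim_config(n_families = 5, singleton_fraction = 0,
                    homeologue_identity_range = c(0.88, 0.94),
                    max_identical_run = 39,
                    length_log_mean = log(900), length_log_sd = 0, seed = 23)
  tr <- simulate_transcriptome(cfg)
  g <- tr$genes
  for (fam in unique(g$family_id)) {
    pair <- g[g$family_id == fam & g$species == "sp1", ]
    same <- strsplit(pair$sequence[1], "")[[1]] ==
      strsplit(pair$sequence[2], "")[[1]]
    runs <- rle(same)
    expect_lte(max(runs$lengths[runs$values]), 39)
  }
})

test_that("n_reads = 0 yields an empty but valid read set and FASTQ", {
  cfg <- sim_config(n_families = 2, n_reads = 0, seed = 29)
  tr <- simulate_transcriptome(cfg)
  rs <- simulate_reads(tr, species = "sp1")
  expect_identical(nrow(rs$reads), 0L)
  d <- withr::local_tempdir()
  files <- write_fastq(rs, d)
  f <- file.path(d, "reads_single.fastq")
  expect_true(file.exists(f))
  expect_identical(length(readLines(f)), 0L)
})
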