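test_that("align_pair recovers identity and coverage on exact cases", {
  ref <- rand_seq(600, seed = 20)
  h <- align_pair(ref, ref)
  expect_equal(h$identity, 1.0)
  expect_equal(h$ref_coverage, 1.0)
  ## first 570 of 600 bases: coverage 0.95 exactly
  h <- align_pair(substr(ref, 1, 570), ref)
  expect_equal(h$ref_coverage, 0.95)
  expect_equal(h$identity, 1.0)
  ## reverse complement query found on the minus strand
  h <- align_pair(revcomp(ref), ref)
  expect_equal(h$identity, 1.0)
  expect_identical(h$strand, "-")
  ## unrelated sequences: no seed -> no hit, distinct from zero identity
  expect_null(align_pair(rand_seq(100, seed = 21), rand_seq(300, seed = 22)))
})

test_that("align_pair identity agrees with the full DP alignment oracle", {
  withr::local_seed(23)
  for (i in 1:50) {
    n <- sample(120:300, 1)
    a <- rand_seq(n)
    b <- mutate_to_identity(a, runif(1, 0.85, 0.99), seed = i)
    if (i %% 2 == 0) b <- revcomp(b)
    h <- align_pair(a, b)
    expect_false(is.null(h))
    oracle <- max(oracle_alignment_identity(a, b),
                  oracle_alignment_identity(oracle_rc(a), b))
    expect_equal(h$identity, oracle, tolerance = 0.01)
  }
})

test_that("best_hits keeps the longest qualifying hit with stable ties", {
  refA <- rand_seq(400, seed = 24)
  refB <- rand_seq(300, seed = 25)
  ## contig = 300 bases of refA + unrelated tail; matches refA over 300 and
  ## refB over 200
  contig <- paste0(substr(refA, 1, 300), rand_seq(50, seed = 26))
  refs <- c(refA = refA, refB = refB)
  refs["refB"] <- paste0(substr(contig, 101, 300), rand_seq(100, seed = 27))
  hits <- map_contigs(c(ctg = contig), refs)
  bh <- best_hits(hits)
  expect_identical(bh$reference_id, "refA")
  ## identity floor: hits below 0.80 identity are dropped
  noisy <- mutate_to_identity(substr(refA, 1, 300), 0.70, seed = 28)
  bh2 <- best_hits(map_contigs(c(x = noisy), c(refA = refA)))
  expect_identical(nrow(bh2), 0L)
  ## determinism under input reordering
  h1 <- best_hits(map_contigs(c(a = contig, b = noisy), refs))
  h2 <- best_hits(map_contigs(c(b = noisy, a = contig), refs))
  expect_identical(h1[order(h1$contig_id), ], h2[order(h2$contig_id), ])
})

test_that("complete-transcript calling is inclusive at the boundary", {
  h <- data.frame(contig_id = c("c1", "c2", "c3"),
                  reference_id = c("g1", "g2", "g3"),
                  ref_coverage = c(0.95, 0.949, 1.0))
  expect_setequal(call_complete(h), c("g1", "g3"))
  expect_identical(call_complete(allosweep:::empty_hits_df()), character(0))
})

test_that("read mapping counts match the exhaustive Hamming scan", {
  withr::local_seed(29)
  targets <- setNames(replicate(3, rand_seq(200)), c("t1", "t2", "t3"))
  ## constructed reads: exact, 2-substitution, unrelated
  exact <- substr(targets[1], 50, 89)
  two <- allosweep:::substitute_bases(substr(targets[2], 10, 49), c(5, 20))
  reads <- c(exact = exact, two = two, junk = rand_seq(40))
  mc <- map_reads(reads, targets, max_mismatches = 3)
  cnt <- mc$counts
  expect_identical(cnt$mm0[cnt$target == "t1"], 1L)
  expect_identical(cnt$mm0[cnt$target == "t2"], 0L)
  expect_identical(cnt$mm1[cnt$target == "t2"], 0L)
  expect_identical(cnt$mm2[cnt$target == "t2"], 1L)
  expect_identical(cnt$mm3[cnt$target == "t2"], 1L)
  ## randomized instances against the oracle, including reverse-complement
  ## placements and multi-target reads
  for (i in 1:20) {
    rd <- if (i %% 3 == 0) {
      revcomp(substr(targets[[1 + i %% 3]], i, i + 35))
    } else {
      allosweep:::substitute_bases(substr(targets[[1 + i %% 3]], i, i + 35),
                                   sample(36, i %% 4))
    }
    mc1 <- map_reads(c(r = rd), targets, max_mismatches = 3)
    for (tn in names(targets)) {
      o <- oracle_min_mismatches(rd, targets[[tn]])
      for (m in 0:3) {
        expect_identical(mc1$counts[[paste0("mm", m)]][mc1$counts$target == tn],
                         as.integer(o <= m))
      }
    }
  }
})

test_that("mapping counts are non-decreasing in the mismatch allowance", {
  withr::local_seed(30)
  tx <- setNames(replicate(4, rand_seq(300)), paste0("g", 1:4))
  reads <- unlist(lapply(tx, function(s) {
    starts <- sample(1:(300 - 50), 30, replace = TRUE)
    vapply(starts, function(st) {
      allosweep:::substitute_bases(substr(s, st, st + 49),
                                   sample(50, sample(0:3, 1)))
    }, character(1))
  }))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  mc <- map_reads(reads, tx, 3)
  expect_true(all(mc$counts$mm0 <= mc$counts$mm1))
  expect_true(all(mc$counts$mm1 <= mc$counts$mm2))
  expect_true(all(mc$counts$mm2 <= mc$counts$mm3))
})

test_that("percent increase reproduces the worked mapped-read examples", {
  expect_identical(percent_increase(215536, 276132), 28L)
  expect_identical(percent_increase(1854, 6111), 229L)
  expect_identical(percent_increase(10937, 12521), 14L)
  expect_identical(percent_increase(8903, 9823), 10L)
  ## 17576/195295 = 8.9997%: truncation gives 8; the value quoted in prose
  ## as "about 9%" is the rounded exact ratio
  expect_identical(percent_increase(195295, 212871), 8L)
  expect_identical(round(100 * (212871 - 195295) / 195295), 9)
  expect_identical(percent_increase(5, 5), 0L)
  expect_warning(out <- percent_increase(0, 10), "undefined")
  expect_true(is.na(out))
})

test_that("RPKM follows the formula and is depth-invariant", {
  counts <- data.frame(target = c("x", "y"), length = c(1000L, 2000L),
                       mm3 = c(10L, 999990L))
  tab <- rpkm_table(counts, 3)
  ## M_X = 10, M_A = 1e6, L = 1 kb -> RPKM 10
  expect_equal(tab$rpkm[tab$gene == "x"], 10)
  ## zero-count gene -> RPKM 0
  counts0 <- data.frame(target = c("x", "y"), length = c(1000L, 500L),
                        mm3 = c(0L, 50L))
  expect_equal(rpkm_table(counts0, 3)$rpkm[1], 0)
  ## doubling every read leaves RPKM unchanged
  doubled <- counts; doubled$mm3 <- 2L * doubled$mm3
  expect_equal(rpkm_table(doubled, 3)$rpkm, tab$rpkm)
  ## no mapped reads: error
  none <- data.frame(target = "x", length = 100L, mm3 = 0L)
  expect_error(rpkm_table(none, 3), "undefined")
})

test_that("recovered RPKM rank-correlates with the true expression weights", {
  ## homeologues at the low end of the identity range so that reads do not
  ## cross-map between copies within 3 mismatches (the shared-read
  ## phenomenon, tested elsewhere) and RPKM isolates the estimator itself
  cfg <- sim_config(n_families = 50, singleton_fraction = 0.5,
                    homeologue_identity_range = c(0.85, 0.88),
                    paired_fraction = 0, n_reads = 40000,
                    expression_log_sd = 1,
                    length_log_mean = log(500), length_log_sd = 0.2,
                    length_max = 900, seed = 31)
  tr <- simulate_transcriptome(cfg)
  rs <- filter_and_pair(trim_reads(simulate_reads(tr, species = "sp1")))
  g <- tr$genes[tr$genes$species == "sp1", ]
  targets <- setNames(g$sequence, g$gene_id)
  mc <- map_reads(rs, targets, 3)
  tab <- rpkm_table(mc, 3)
  truth_w <- g$expression_weight[match(tab$gene, g$gene_id)]
  expect_gt(cor(tab$rpkm, truth_w, method = "spearman"), 0.95)
})
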