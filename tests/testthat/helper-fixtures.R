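## Fixture builders shared across test files. All randomness is locally
## seeded so every test is reproducible in isolation.

rand_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

## error-free reads tiling a transcript at every `step` positions on both
## strands, wrapped as a read_set with uniform Q35 qualities
tiling_reads <- function(transcript, read_length = 75L, step = 1L,
                         depth_rounds = 1L) {
  n <- nchar(transcript)
  starts <- seq(1L, n - read_length + 1L, by = step)
  fwd <- substring(transcript, starts, starts + read_length - 1L)
  seqs <- rep(c(fwd, revcomp(fwd)), depth_rounds)
  as_test_read_set(seqs)
}

## wrap bare sequences as a single-end read_set with uniform high quality
as_test_read_set <- function(seqs, quality_char = "D") { # "D" = Q35
  read_set(data.frame(
    read_id = sprintf("t%06d", seq_along(seqs)),
    sequence = seqs,
    quality = strrep(quality_char, nchar(seqs)),
    pool = "single",
    pair_id = NA_character_,
    mate = NA_integer_,
    stringsAsFactors = FALSE
  ))
}

## a homeologue pair with one substitution every `spacing` bases and a
## planted identical window; flanks of the window are forced to differ so
## the window length is exactly the planted one
spaced_homeologue_pair <- function(n = 600L, spacing = 25L,
                                   window_start = 271L, window_len = 60L,
                                   seed = 42L) {
  withr::with_seed(seed, {
    a <- rand_seq(n)
    pos <- seq(spacing, n, by = spacing)
    pos <- union(pos, c(window_start - 1L, window_start + window_len))
    pos <- pos[pos >= 1L & pos <= n]
    pos <- setdiff(pos, seq(window_start, window_start + window_len - 1L))
    b <- allosweep:::substitute_bases(a, pos)
    pl <- plant_shared_regions(a, b, data.frame(start = window_start,
                                                length = window_len))
    list(a = pl$copy_a, b = pl$copy_b,
         window = c(window_start, window_len))
  })
}
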