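---
title: "Methods: simulating and sweeping allopolyploid transcriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and sweeping allopolyploid transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Allopolyploid plant species carry two diverged parental subgenomes, so most
genes are present as two *homeologous* copies that are typically 85--95%
identical within a species, while *orthologous* copies across closely
related species remain ~98% identical. De novo transcriptome assembly from
short reads must thread a needle: the de Bruijn graph k-mer size `k` has to
be large enough that near-identical homeologues do not share graph nodes
(any identical stretch of at least `k` bases creates a shared path, which a
conservative assembler refuses to cross, fragmenting both copies), yet small
enough that weakly expressed genes still have overlapping k-mers. The k-mer
coverage cutoff `c` interacts with the same trade-off through expression
level: raising `c` denoises highly expressed genes but erases weakly
expressed ones entirely.

`allosweep` implements this study end to end on synthetic data with known
truth: a transcriptome and read simulator, quality control, a minimal
assembler swept over a (k, c) grid, reference-based evaluation, CAP3-style
merging with homeologue/orthologue classification, a chimera audit, and the
comparison metrics (N50/N90, assembly-overlap statistic, per-gene parameter
profiles, expression correlation).

## The simulator

`simulate_transcriptome()` builds gene families from an ancestral coding
sequence. Divergence is **substitution only** (no indels), a deliberate
design choice: percent identity then has a single unambiguous definition
(matching positions / length), homeologue classification thresholds are
exact, and the chimera audit can reason about *discriminating positions* --
positions where the two true copies differ -- without alignment ambiguity.
An indel mode is out of scope.

Identities are constructed, not merely sampled. For each two-copy family a
homeologue identity target `t` is drawn from `homeologue_identity_range`
(default \[0.85, 0.95\], the within-species similarity regime of
allopolyploids of this age; the literature also reports wider 70--90%
ranges, which is why the range is a parameter rather than a constant).
Mutation *positions* are then drawn as disjoint sets: a shared
subgenome-divergence set `H`, plus small species-specific sets for each copy
(rate `(1 - orthologue_identity)/2` per copy, default giving orthologues at
exactly 98% identity). Because the sets are disjoint, the realized
homeologue identity equals `t` exactly (to the nearest achievable count) and
orthologue identity equals its target exactly; the test suite verifies both
against an independent Needleman--Wunsch oracle. The optional
`max_identical_run` constraint relocates `H` positions until no identical
stretch between the copies exceeds the bound, which is how "no identical
window of >= 40 bp" scenarios are realized exactly rather than
probabilistically. Identical windows (default lengths 35--47 bp, the
empirically troublesome size class) can also be planted explicitly with
`plant_shared_regions()`; planted windows are excluded from every mutation
set, so they are byte-identical between copies while the family still meets
its overall identity target.

Expression weights are log-normal with `sdlog = 2.2` by default. That gives
roughly four orders of magnitude of dynamic range, which is what leaf
transcriptomes show (the most extreme genes reach RPKM of tens of
thousands); a configurable fraction of genes is additionally rescaled above
the RPKM-1000 band to guarantee a "very high expression" regime exists.
Reads (default 75 bp) are drawn with probability proportional to
`expression_weight * length`, from a uniform position and strand; the
per-cycle substitution error rate is `pre_knee_error` (default 0.004, ~Q24)
up to the knee cycle and `post_knee_error` (default 0.12, ~Q9) beyond it,
with the knee at cycle 45 for paired-end and 60 for single-end reads --
the empirical "quality cliff" of the sequencing chemistry being emulated.
Phred qualities written to FASTQ encode exactly these error probabilities,
so trimming at Q20 reproduces the intended effective read lengths. Error
substitutions never reproduce the original base; with the two-level model
the raw mismatch rate against the recorded source coordinates *is* the
error rate, which the tests exploit.

What the simulator does **not** emulate: indel sequencing errors, quality
recalibration structure, coverage biases (GC, positional), alternative
splicing, and genes shorter than the read length. Passing tests therefore
demonstrate the parameter-interaction logic of assembly, not robustness to
every artefact of real libraries.

## Quality control

`trim_reads()` keeps the longest contiguous window in which every base has
Phred quality >= 20 (inclusive comparison -- Q20 means one expected error
per 100 bases and is kept; ties between equal-length windows go to the
leftmost). `filter_and_pair()` then discards reads shorter than 30 bases
(inclusive: exactly 30 is kept; the length rule is configurable because the
two natural readings, "at least 30" and "more than 30", differ at the
boundary), keeps pairs in which both mates pass, and demotes the surviving
mate of a broken pair to the single-end pool. Provenance counts
(kept + demoted + discarded) always reconcile with the input count.

## The assembler

`build_kmer_graph()` counts canonical k-mers (lexicographic minimum of
k-mer and reverse complement; `k` must be odd so no k-mer is its own
reverse complement). `apply_coverage_cutoff()` removes k-mers with
multiplicity below `c` *before* traversal -- applying the cutoff at the
k-mer stage is the simplest testable choice and reproduces the qualitative
behaviour of coverage-cutoff assemblers. `traverse_contigs()` emits maximal
unambiguous paths: an edge is followed only when its source has exactly one
surviving successor and its target exactly one surviving predecessor
(orientation-aware; the in-degree of a node equals the out-degree of its
reverse complement). There is no tip clipping, bubble popping, or
paired-end linkage. This conservatism is the point: traversal provably
stops at every branch, so a contig can never walk from one homeologue's
private sequence through a shared stretch into the other's -- the
chimera-safety property the tests audit against truth. The cost is
fragmentation wherever two transcripts share >= k identical bases, which is
precisely the phenomenon the sweep quantifies. Contigs must be strictly
longer than 100 bp to be retained, are reported in canonical orientation
and sorted for determinism.

`auto_cutoff()` implements the automatic coverage-cutoff mode as
`max(2, round(sqrt(median multiplicity of k-mers seen at least twice)))`,
with a floor of 2 when nothing repeats. The formula is this package's own:
it is monotone in coverage depth, tracks the dominant coverage mode when one
gene's reads are assembled alone, and collapses to the floor as soon as
reads from many genes of different depths are pooled -- the observed
behaviour of automatic cutoffs under joint assembly. No claim is made that
it matches any specific assembler's internal rule.

`sweep_assemblies()` evaluates the full grid, building each k-mer graph
once; every cell is bit-identical to an independent `assemble()` call.

## Reference mapping and quantification

`map_contigs()`/`align_pair()` use exact 15-mer seeds to nominate
(reference, strand, diagonal) candidates and score each candidate over the
whole overlap on that diagonal: identity = matches / alignment columns,
reference coverage = overlap / reference length. Because simulated
divergence is substitution-only, the alignment band degenerates to a single
diagonal, so no gapped extension is needed; the test suite checks the
identity against a full dynamic-programming aligner on hundreds of pairs.
"No shared seed" is reported as *no hit*, distinct from a zero-identity
hit. `best_hits()` keeps, per contig, the hit with the longest aligned
region among those at >= 80% identity (ties: higher identity, then
lexicographic reference id), and `call_complete()` declares a reference
complete when some contig covers at least 95% of it (inclusive boundary).

`map_reads()` finds, for every read, all end-to-end placements with at most
`max_mismatches` (0--3) substitutions on either strand, by the pigeonhole
principle: the read is cut into `max_mismatches + 1` disjoint seed pieces,
one of which must match exactly; every seeded diagonal is verified by
direct Hamming comparison. A read may count for several targets
(multi-mapping reads are counted once per target, no fractional
allocation); counts are non-decreasing in the allowance by construction,
and the tests compare small instances against an exhaustive scan.
`rpkm_table()` computes `RPKM_X = 1e6 * M_X / (M_A * L_X)` with `L_X` in
kilobases and `M_A` the total mapped-read count. `percent_increase()`
reports the mapped-count increase between mismatch levels 0 and 3 as an
integer percent truncated toward zero -- the rounding that reproduces the
exactly-printed worked-example values; one value quoted in prose as "about
9%" is in fact 8.9997%, i.e. truncation gives 8 and ordinary rounding the
quoted 9.

## Merging and classification

Contigs from *all* grid assemblies whose best hit covers **more than 55%**
of a reference (strict boundary) are pooled per gene family; two such
contigs necessarily share at least 10% of the reference
(2 x 55% - 100%), which is the overlap bound this package asserts.
`overlap_merge()` then joins them greedily: at each step the pair (either
orientation) with the longest suffix-prefix or containment overlap of at
least 40 bp at >= 98% identity is merged, consensus by majority with the
first-seen member winning ties. Members are kept in a content-based order
(length, then sequence), so the result is invariant under input
permutation. These thresholds make cross-copy merging essentially
impossible when homeologues share no identical window of >= 40 bp: a 40--49
bp overlap at 98% must be error-free, i.e. an identical window.

Per gene and species, one supercontig is a single copy, exactly two are a
candidate homeologous pair, and more than two are flagged and excluded from
pair counts. Cross-species calls use the strict 95% identity threshold:
above it the two species' sequences are putative orthologues, below it
likely paralogues (copy one in one species, copy two in the other); the
call is symmetric because arguments are ordered canonically before
alignment. Which supercontig is "copy 1" is decided by descending RPKM --
an arbitrary but reproducible labelling, since assigning copies to parental
lineages is out of scope.

`audit_chimeras()` operationalizes chimerism on synthetic runs: a
supercontig is chimeric iff, at positions where the two true copies differ,
it matches copy A at some covered position *and* copy B at another. This is
a definition of convenience -- the hazard is usually named but not defined
-- and it is exact under substitution-only truth.

## Metrics and the correlation analysis

`length_metrics()` computes N50/N90 by the accumulation definition
(smallest contig length such that contigs that long or longer hold >= 50% /
90% of assembled bases) and length-class counts with upper-inclusive
boundaries. Empty contig sets report absent values, not zeros.
`overlap_statistic()` is `|A ∩ B| / (|A| + |B|) / 0.5` over
complete-transcript identifier sets -- 1 for identical sets, 0 for disjoint,
undefined for empty-vs-empty; on synthetic data the identifier is the
annotated reference id, which is the deterministic equivalent of matching
sequences at 100% identity. `parameter_profiles()` turns per-cell
completeness calls into per-gene counts of distinct successful k values,
cutoffs, and cells. `expression_correlation()` bins genes by those counts,
averages RPKM per bin after excluding genes with RPKM strictly above 1000,
and reports the Pearson correlation between bin index and bin mean (bin
means rather than per-gene values, following the described procedure). The
correlation is reported whenever at least two nonempty bins with nonzero
variance exist; with exactly two bins it is trivially ±1.

## Numerical and degenerate-input choices

* Coordinates are 1-based closed in the R API and 0-based half-open in all
  TSV outputs.
* Boundary semantics collected in one place: trimming keeps quality >= 20;
  length filter keeps >= 30; contig retention keeps length > 100;
  completeness keeps coverage >= 0.95; pooling keeps coverage > 0.55;
  orthologue calls require identity > 0.95; RPKM exclusion removes > 1000.
* Determinism: all randomness flows through a single integer seed
  (sub-seeds are derived per stage); equal configurations give
  byte-identical FASTA/FASTQ. Assembler output is sorted and canonicalized;
  merge tie-breaks are content-based; `best_hits()` is stable under input
  reordering.
* `k` must be odd and >= 15; empty graphs, empty read sets and empty contig
  sets propagate as valid empty results (with warnings where the cause is
  likely a mistake, e.g. `k` longer than every read).

## Study problem sizes

The packaged analyses run at deliberately desk-sized scales, chosen once:

* **Chimera-safety run**: 50 homeologue pairs at 88--94% identity with
  `max_identical_run = 39` (so no identical window reaches 40 bp), 40,000
  single-end reads, grid {25, 31} x {3, 5}. The audit must find zero
  chimeric supercontigs.
* **Correlation-recovery run**: 100 families x 2 homeologous copies (200
  genes, mean length ~600 bp), 1.5 million single-end 75 bp reads, grid
  {25, 31, 41, 51} x {2, 4, 7, 12, 20}. The library size is not arbitrary:
  with `M_A` mapped reads, a gene at the RPKM-1000 exclusion boundary has
  read depth `6e-8 * 1000 * M_A`; 1.5 M reads place that boundary at ~90x,
  so genes *retained* by the exclusion (RPKM <= 1000) span the whole range
  from unassemblable to comfortably assemblable depth, which is what makes
  the binned correlation informative. At much smaller library sizes the
  arithmetic of RPKM (with 200 genes, mean RPKM is necessarily
  `1e6 / sum(L_kb)` ~ 8000) pushes every assemblable gene above the
  exclusion threshold and the analysis degenerates.
* The correlation property is stochastic. Across seeds, the cutoff-binned
  correlation is consistently ~0.95--1.0 while the k-binned correlation is
  weaker and noisier (~0.5--0.8) -- the same ordering the full-scale study
  shows (0.95 vs 0.82), driven by the fact that k-range success also
  depends on each family's identity draw, not only on expression.

## Known limitations

* Substitution-only divergence and error model; no indels anywhere.
* The aligner is diagonal-only and will under-report identity for inputs
  with real indels; it is matched to the simulator, not a general aligner.
* The merger is a greedy stand-in for an overlap-layout-consensus
  assembler: thresholds are honoured exactly, but consensus behaviour in
  many-member pools is first-seen-greedy, not globally optimal.
* `auto_cutoff()` is a plausible monotone rule, not a reimplementation of
  any published assembler's automatic mode.
* Paired-end information is used only for pairing bookkeeping; there is no
  scaffolding.
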