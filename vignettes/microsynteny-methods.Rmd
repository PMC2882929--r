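---
title: "Methods: template-guided microsynteny analysis of a polyploid genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-guided microsynteny analysis of a polyploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Autopolyploid crop genomes such as sugarcane (~12x, >100 chromosomes) resist
conventional assembly: there is no dense genetic map, no physical map, and
every locus is present in many near-identical allelic copies. A practical
route to their gene space is to sequence large-insert (BAC) clones sampled
one per chromosome arm and to lean on a sequenced diploid relative — sorghum,
in the system this package models — as an ordering template. `polysynt`
implements that full analysis as a tested pipeline: clone selection from
hybridization screens, pooled-read deconvolution, local-alignment anchoring,
template-guided contig ordering with AGP output, micro-rearrangement
classification, repeat and microsatellite accounting, and molecular-clock
dating from synonymous divergence. Because the original raw data are not
required, a first-class simulator generates template genomes and diverged
clones with complete ground truth, and every downstream stage is validated
against that truth.

# Coordinate convention

All coordinates — in memory and on disk — are 1-based inclusive. This is the
native convention of IRanges, GFF3 and AGP, and using it uniformly removes
the half-open/closed conversion layer an R implementation would otherwise
carry. Gap arithmetic is therefore `gap = next_start - prev_end - 1`.

# The synthetic study system

`sim_config()` freezes the study conditions; its defaults are the conditions
of the modelled study, not tuning knobs:

* 10 chromosomes, one clone per arm (20 clones in a 4 x 5 pooling grid),
  insert sizes 40-165 kb, 64x pooled shotgun coverage. The source
  description states the grid once as 4 horizontal x 5 vertical and once as
  5 x 4; the grid is therefore a configuration value, with 4 rows x 5
  columns as default (9 pools either way).
* gene density one gene per 10.1 kb (multi-exon genes with valid ORFs,
  GT/AG introns, both strands);
* repeat fractions 27.6% (template) and 25.5% (clones), realized by
  implanting diverged, often 5'-truncated copies from a labelled consensus
  library over ten fixed families, with a Gypsy-rich mix in the template
  and a Copia-rich mix in the clones;
* target synonymous divergence Ks = 0.10 between clone genes and their
  template orthologs;
* a rearrangement spectrum of 7 translocations, 4 inverted translocations,
  3 inversions, 26 clone-side duplications and 14 template-side
  duplications with per-class mean sizes 275/392/281/467/328 bp.

## Substitutions: why omega = 0.35

The two calibration targets — synonymous divergence 0.10 and ~95.2% exon
identity — cannot both hold under neutral uniform substitution: with ~25% of
coding sites synonymous, Ks = 0.10 under neutrality forces exon identity
near 90.5%. The generator therefore applies purifying selection:
substitution proposals (transition:transversion 2:1) are always accepted at
synonymous sites, accepted with probability `omega` at nonsynonymous sites,
and rejected if they create a stop codon. Writing the raw per-site
divergence for Ks = 0.10 as `p = (3/4)(1 - exp(-(4/3) * 0.10)) = 0.094` and
the synonymous site fraction as `fS = 0.25`,

```
1 - identity = p * (fS + (1 - fS) * omega)
```

gives `omega = 0.35` for 95.2% identity. The realized per-site proposal rate
is then found by closed-loop calibration
(`calibrate_substitution_rate()`): root-finding on the package's own NG86
estimator applied to a large mutated test CDS, so the generator is
calibrated against the same statistic the pipeline later measures.

## Rearrangement implants

Event lengths are drawn as `150 + Geometric` with the per-class means above.
The floor is a generator condition, chosen up front: the analysis filters
alignments at bit score > 200, which with the default scoring corresponds to
roughly 110 bp of aligned sequence, so a pure geometric with mean 275 bp
would make about a third of the implanted events undetectable *by the
analysis rule itself* rather than by any algorithmic failure.

Clone-side events are edited into the clone: inversions reverse-complement a
backbone block in place; translocations (plain and inverted) copy a diverged
block in from a distant chromosome; clone duplications insert a tandem copy
of a local block. Template-side duplications cannot be created by editing
the clone alone: the template must carry two near-identical copies where the
clone has one. `simulate_template()` therefore plants tandem donor pairs
(second copy at 2% divergence) near the arm centers, and
`simulate_polyploid_clones()` collapses them to a single copy in the clone.
Small indels (rate 2e-4/bp, geometric lengths, mean 3 bp) are restricted to
intergenic, non-event sequence so gene models stay in frame — consistent
with an analysis that treats indels as "too numerous to count" and never
calls them as events.

## Repeat expansion

The template-vs-clone repeat excess is controlled by `expansion_bias`: bp of
inherited repeat copies deleted from the clone per kb of insert (default
120), partially compensated by clone-specific insertions up to the 25.5%
query target. The three published ratios (25.5%, 27.6%, 20.7% expansion)
mix BAC-wide and aligned-extent denominators and are not jointly satisfiable
by any single closed accounting, so the generator targets the two repeat
fractions and reports whatever expansion the alignments then show.

# Anchor alignment

`seed_extend_align()` is a classic seed-and-extend local aligner: exact
13-mer seeds (both strands, canonical lookups), greedy diagonal clustering
(seeds join a cluster while the query gap is <= 300 bp and the diagonal
drift <= 60 bp), and a banded affine-gap Smith-Waterman over each cluster's
diagonal band, tracking the alignment start, matched columns and length
through the DP so no traceback matrix is needed. Scores are match +1,
mismatch -2, gap `5 + 2L`; bit scores follow Karlin-Altschul,
`bit = (lambda * raw - ln K) / ln 2` with `lambda = 1.28`, `K = 0.46`
matched to that score system. The published analysis filtered at
"bit value > 200" from an unnamed external scorer; the threshold is kept,
but equivalence of the two score systems cannot be asserted, only declared.
Soft-masked (lower-case) bases are excluded from seeding but available to
extension, mirroring mask-then-align practice; tests verify reported raw
scores against an independent full Smith-Waterman rescoring
(`Biostrings::pairwiseAlignment`) of the reported interval pairs.

Chaining (`chain_anchors()`) finds the maximum-bit-weight collinear chain
per (chromosome, strand) by LIS-style dynamic programming. Adjacent chained
anchors may overlap on one genome — that is exactly the signature a tandem
duplication leaves when the extension runs straight through both copies —
so overlaps are permitted in the chain and interpreted later.

# Ordering, gaps and summaries

Contigs are first deduplicated (`dedupe_contigs()`: drop a contig when >= 90%
of it is covered, identity-weighted, by a single longer contig). Each
remaining contig's dominant chain places it; a contig whose best and
second-best template loci differ by less than a factor 2 in chain weight is
left unplaced as `multi_locus` (the published analysis likewise refused to
order contigs projecting to several super-contigs), and overlapping
projections are resolved by trimming the weaker projection, never the
sequence. Gaps between adjacent placed contigs are the template distance
between their projections; negative estimates are flagged
`overlap_suspected` and gaps strictly below 2 kb `closable` (the size class
the wet-lab protocol closed by PCR). `summarize_layouts()` computes the
headline fractions (ordered, aligned, expansion); fed the published
per-clone totals it reproduces 78.2% / 53.1% / 20.7% exactly, and the
ordered/aligned denominator can be switched from insert size to
unambiguous-contig total, since the published 78.2% is resolvable by
arithmetic to the insert denominator (1451/1855).

# Rearrangement classification

The main chain defines the syntenic frame. Two complementary signals are
read off (`classify_rearrangements()`):

* **chain-adjacency overlaps** — adjacent chained anchors overlapping >= 100
  bp on the query with disjoint template intervals mean the template carries
  two copies of that query stretch (`duplication_template`); the mirrored
  case is `duplication_query`;
* **off-chain anchors** — an anchor whose query interval is already >= 50%
  covered by the frame is the extra copy of a template-side duplication
  (template coverage, query-side); an opposite-strand anchor lying where
  the frame's interpolated query-template map expects it (within 20 kb) is
  an `inversion`; same-strand anchors at unexpected template positions are
  `translocation`s, opposite-strand ones `inverted_translocation`s.
  Off-chain anchors that fit the frame within tolerance are collinear
  leftovers and yield no event, which keeps precision high.

Each off-chain anchor contributes to at most one class. Polarity is reported
relative to the template; without an outgroup the genome of origin of an
inversion cannot be inferred, and the report says so rather than guessing.
On the default spectrum the pipeline recovers the implanted events with
precision and recall above 0.9 (measured against simulator truth).

# Pooled-read deconvolution

The original clone-array pooled shotgun data were deconvolved by vendor
software whose procedure is unpublished; the package substitutes a
transparent criterion. Reads and pools are reduced to canonical minimizers
(k = 21, window w = 11; 2-bit codes, strand-symmetric). A row-pool read is
assigned to column c iff it shares >= 3 distinct minimizers with exactly one
column pool c; several qualifying columns make it ambiguous, none make it
unassigned, and the three categories provably partition the input.
Ambiguous reads are excluded from the per-clone bins rather than
multi-assigned, mirroring the original exclusion of ambiguous sequences.
With clone-unique sequence the assignment is error-free at 64x; with ~10%
shared repeat content the repeat reads turn ambiguous while non-ambiguous
assignments stay >= 99% correct.

# Repeats and SSRs

`mask_repeats()` aligns the labelled consensus library against the target
(threshold 50 bits, permissive enough for 5-15% diverged copies), soft-masks
hits, resolves family claims by bit score, and tallies bp per family of the
frozen ten-family taxonomy plus perfect simple repeats and low-complexity
sequence (Shannon entropy < 1.5 bits/base over 64-bp windows — a declared
definition, not one inherited from any database). Masking is idempotent.
Only the accounting scheme of the published repeat tables is reproduced;
their percentages depend on RepBase/TIGR database versions and are out of
desk-scale reach. `detect_ssrs()` reports maximal perfect tandem runs of
primitive 1-6 bp motifs (thresholds mono >= 12, di >= 6, tri >= 4,
tetra-hexa >= 3 copies), resolves overlaps to the longest run then the
shortest motif, canonicalizes motifs over rotations and strands, and
extracts 200 bp flanks for primer design. Imperfect (mismatch-tolerant)
runs are deliberately out of scope.

# Ka/Ks and dating

Ortholog CDS pairs are aligned at the protein level (global
Needleman-Wunsch via `Biostrings::pairwiseAlignment` with BLOSUM62, gap
open 10 / extend 1) and the protein alignment is expanded back to codon
space, PAL2NAL-style. Pairs with internal stops, fewer than 50 aligned
residues, or under 50% protein identity are discarded as unreliable
(declared thresholds). `ng86()` implements classic Nei-Gojobori counting:
per-position synonymous site fractions averaged between the two sequences
(changes to stop codons count as nonsynonymous), multi-hit codons averaged
uniformly over substitution orderings with pathways through stop codons
excluded (codon pairs with no valid pathway are excluded entirely), and
Jukes-Cantor correction of both proportions. A test-side oracle enumerates
every pathway explicitly and must agree to 1e-9. Dating uses
`T = Ks / (2r)` with the grass synonymous rate `r = 6.5e-9`/site/year
(exposed as a parameter) and the **lower** median for even pair counts — the
source states only that the median was taken, so the convention is declared
here. Median Ks 0.10 gives 7.7 million years.

# Problem sizes and numerical choices

The test-suite and acceptance runs use reduced problem sizes chosen to
exercise every code path while keeping the whole suite in minutes: templates
of 2-5 chromosomes of 100-400 kb, 4-10 clones, coverage 8-64x, 500 ortholog
pairs for divergence recovery, 1000 codon-pair alignments for the NG86
oracle. These sizes are the package's own choices for a reproducible desk
run; all thresholds above (bit 200, 50-bit repeats, k=21/w=11/3 shared
minimizers, containment 0.9, locus-ambiguity ratio 2, 2 kb closable gaps,
20 kb collinear tolerance, 100 bp minimum event, 0.5 coverage fraction)
are defaults of the corresponding functions and can be varied.

Degenerate inputs are defined behavior: empty hit lists classify to empty
event sets, empty probe tables filter to empty id lists, an all-gap codon
alignment or an empty Ks list raises an informative error, saturation
(pS >= 3/4) is an error rather than a number, and ties in chaining and clone
selection break deterministically (leftmost template coordinate; most probe
support, smallest distance, lexicographic id).

# What passing tests do and do not show

The simulator emulates substitution divergence under purifying selection,
indels, family-structured repeats, differential repeat expansion, tandem
and dispersed rearrangements, pooled shotgun sampling and hybridization
screens. It does not emulate 454 homopolymer errors, chimeric reads,
assembly artifacts, heterozygosity within the template, nested/fragmented
repeat structures, or real repeat-database taxonomies. Recovery results on
synthetic data therefore validate the algorithms and their bookkeeping, not
performance on raw 454 BAC data; the published quantities that depend on
those data (absolute repeat percentages, EST validation counts, the exact
95.2% exon identity of the real clones) are represented by calibration
targets and property tests, not claimed as reproduced measurements.
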