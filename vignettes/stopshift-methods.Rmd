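---
title: "Methods: analysing genomes with all three stop codons reassigned"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing genomes with all three stop codons reassigned}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

*Blastocrithidia* species translate UGA as tryptophan and UAG as glutamate,
and give UAA a dual meaning: glutamate when in-frame, terminator when it is
the final triplet of a CDS. stopshift encodes this as a `genetic_code`
object with three parts: the 64-triplet table, a set of `terminal_stops`
(solely UAA for the reassigned variant), and an `internal_reassignments`
map applied to in-frame triplets. The operational rule for the dual meaning
is strict: **only the final triplet of a 3'-complete CDS terminates**; every
other UAA, UAG or UGA is translated as its reassigned amino acid. The
canonical variant has three terminators and no internal reassignments, and
reproduces the standard table exactly.

All sequence handling uses the DNA alphabet (T rather than U) because the
inputs are genome assemblies; prose uses U when discussing codon identities.
Genomic coordinates are 0-based half-open internally; GFF3 and BED I/O
convert to and from each format's convention. Codons containing any
non-ACGT symbol are excluded from every codon statistic and tallied in a
diagnostics channel — including them would bias denominators, and the data
give no principled way to assign them.

## Gene models from homology

The annotation stage reimplements a homology-guided procedure for genomes
in which ordinary gene finders fail (an in-frame "stop" is usually a sense
codon). Its inputs are TBLASTN-style HSP tables, the genome, and optionally
spliced-leader (SL) addition sites; its thresholds (e ≤ 1e-10 for model
building, e ≤ 1e-5 with read coverage ≥ 10 for transcript-region rescue,
10 nt tolerated overlap, 30 aa minimum protein, SL sequence
AGTTTCTGTACTTTATTG with ≥ 6 nt matches) are all exposed in
`gene_model_config()` with these defaults.

Per query/target pair, HSPs sharing the strand and frame of the
highest-scoring HSP are merged to a candidate range spanning their extreme
coordinates. The range is then extended: the start is the in-frame ATG
*nearest* the 5' boundary, searched upstream first (never across an
in-frame terminator, which marks the upstream ORF limit; search capped at
3,000 nt), falling back to the first in-frame ATG downstream inside the
homology region; the stop is the first in-frame UAA at or after the 3'
boundary. Models that cannot reach an ATG or a terminator are flagged
incomplete rather than dropped, so the exclusion log stays interpretable.

The SL rule deserves its own paragraph because the design was genuinely
open. Trans-splicing attaches the SL to the mature mRNA at the SL site, so
no start codon upstream of an SL site can be real. We therefore scan a 5'
candidate window (default 500 nt, `sl_search_window`) upstream of the
homology boundary; if SL sites are found there, the start is relocated to
the first in-frame ATG downstream of the most 3' site, and the model is
flagged `sl_supported`. Deliberately, this window is **not** limited by the
upstream in-frame-terminator barrier that limits the ATG search: the mature
5' leader may freely contain in-frame UAA triplets, and tying the SL window
to the ORF limit would make the rule miss exactly the cases it exists for
(decoy ATGs upstream of the SL site, and starts mis-snapped onto internal
Met codons when the alignment boundary is eroded). SL sites found inside a
model's coding span or just downstream of its stop are anomalous for that
model and are ignored with a warning.

Overlap reduction keeps, among models overlapping by more than 10 genomic
nucleotides (strand-agnostic; the 10-nt rule's strandedness is not
specified anywhere, and measuring on genomic nucleotides is the
conservative reading), only the longest; ties break to the leftmost start
and then lexicographic id, making the operation deterministic and
idempotent. Candidate ranges from different queries hitting one locus are
reduced jointly in this step.

## Genuine stops and stop context

The genuine stop of a gene is identified operationally: the in-frame
triplet immediately 3' of a high-confidence alignment (e ≤ 1e-20) that
covers the query protein through its final residue. Terminator usage is
tabulated over 3'-complete CDSs, with non-UAA terminators reported as
anomalies under the reassigned code.

Downstream stop-context profiles count, for each of 25 triplet positions
after the terminator and each of three frames (frame 1 = the protein's
frame; frames 2 and 3 its +1/+2 nt shifts), the genes whose triplet at that
slot belongs to the code's "true stop" set — UAA only for the reassigned
code, all three stops for the canonical one. We count *genes* per cell (at
most one per gene per cell), not occurrences; with 25 distinct positions
the two conventions coincide unless a gene had two stops in one slot, which
is impossible, so the choice only matters for aggregations over positions.
Genes with short flanks contribute only to the positions they cover;
per-cell denominators are reported and nothing is imputed. The upstream
profile does the same over the last 25 in-frame codons before the
terminator.

The "filtered" 3'UTR set contains genes with at least one additional
in-frame putative stop within 30 codons of the genuine stop, with GC
averaged over the first 120 downstream nucleotides. The zig-zag A/U
patterning of 3'UTRs is shown but never quantified in the literature, so
the alternation score is this package's own formalisation: the mean over
interior positions p of |f(p) − (f(p−1)+f(p+1))/2| for A and for T,
averaged; it is 0 for any smooth positional profile and 1 for a strict
period-2 pattern.

## Enrichment statistics

Motif logos are background-normalised: per position and nucleotide, the
observed probability across sites divided by the genome-wide CDS nucleotide
frequency. Significance uses an exact two-sided binomial test per cell on
40 iterations of 200 randomly subsampled motifs, the per-cell p-values
averaged across iterations and then Bonferroni-corrected. Two details are
configuration rather than fact, because no authority pins them down: the
averaging order (we average, then correct; `correct_then_average` exposes
the alternative) and the Bonferroni family, which we take as window
positions × 4 nucleotides. The default flank is 6 nt per side of the
anchor codon. With one iteration spanning all sites the averaged p-value
collapses to the plain exact binomial p-value, which the tests assert.

Sample sizing uses Cohen's effect size for proportions,
h = 2·asin√(p₀+δ) − 2·asin√p₀, with the two-tailed Z approximation
n = ⌈((z₁₋α/₂ + z_power)/h)²⌉. For p₀ = 0.25, δ = 0.10, power 0.9 and
α = 0.05 this gives n = 220. The sizing is for the one-sample setting —
a sampled motif proportion tested against the *known* CDS background — and
a Monte-Carlo simulation of that Z-test at n = 220 reproduces ≈ 0.9 power;
the corresponding two-sample test would need twice the n, which is one
reason the resampling n of 200 is paired with an exact test rather than
the approximation.

## Somy

Scaffold copy number comes from read depth alone: the median of 1-kb
window mean depths (MOM) per scaffold, divided by the median genome
coverage over the 100 largest scaffolds (all scaffolds, flagged, when
fewer exist), assuming a disomic majority. The published bin notation is
internally inconsistent ("0.25 ≥ R < 0.75" and the like), so the bins are
regularised around centres at k/2: R < 0.25 sub-monosomic (made explicit
rather than silently dropped), [0.25, 0.75) monosomic, [0.75, 1.25]
disomic, (1.25, 1.75] trisomic, (1.75, 2.25] tetrasomic, > 2.25 pentasomic
or higher. The exact ownership of edges like 1.25 cannot be recovered from
the notation; the chosen closure is documented here and the classes are
scale-invariant by construction.

## Conservation and GC

GC is reported over all counted CDS nucleotides (`gc_orf`) and at third
positions of 4-fold degenerate codons (`gc_4fds`), the neutral proxy. The
eight 4-fold families are determined from the canonical code for every
taxon — the reassignments touch only stop/Glu/Trp, none of which is
4-fold — and the tests re-derive the family list by enumeration over an
independent code table. Conserved-site ifRC proportions use alignment
columns in which **every** taxon shows the target amino acid with no gaps
or missing data; Glu conservation is assessed on the translated symbol, so
UAR codons in reassigned-code taxa still count as conserved Glu, which is
what makes the cross-genus comparison possible. `gc_orf` can be computed
either from a full CDS set or from the aligned back-mapped subset
(`conservation_summary()` uses the latter, keeping numerator and
denominator on the same gene set); both modes are available because the
choice is ambiguous in the source material. Correlations are Pearson on
untransformed proportions, with the small-n setting (a handful of species)
preserved in the tests.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions the rest of the package assumes:

* 2,000 genes of mean length 400 codons, drawn i.i.d. from a codon-usage
  vector built on an independent-base model at ORF GC 0.38 with the three
  ifRC fractions pinned at 2.2% (UAA), 1.5% (UAG) and 0.8% (UGA) — the
  middles of the observed ranges;
* intergenic and UTR sequence i.i.d. at GC 0.25 (observed 23–26%);
* 3'UTRs with in-frame UAA enriched 3-fold over background for codons 1–14
  (the overrepresentation fades at the 13th–15th codon), alternating A/U
  bias of amplitude 0.1, and the final coding codon's third base pinned so
  that G at −1 is 2-fold enriched over the CDS background;
* SL sites for 80% of genes, 15–60 nt upstream of the ATG, with the mature
  leader kept free of in-frame ATGs (a scanning ribosome would otherwise
  initiate there);
* terminators drawn from the code's terminal set — always UAA for the
  reassigned code, and 20/50/30% UAA/UAG/UGA for canonical-code genomes,
  echoing UAG-preferring termination in the sister genus;
* HSP boundaries eroded inward by a capped geometric number of codons
  (p = 0.6, mean ≈ 0.7 codons, cap `trim_max`): local alignments lose at
  most a residue or two at their edges, not uniform chunks; fragmentation
  splits a gene's alignment in two with a short unaligned gap; decoy rows
  with above-threshold e-values are spiked in so threshold logic is always
  exercised, while genuine rows carry placeholder e-values far below every
  threshold;
* coverage windows Normal(median·somy/2, cv·mean) truncated at zero;
  ortholog alignments with exact numbers of gap-free conserved Glu/Trp
  columns (defaults 1,066 and 202) and per-taxon Bernoulli codon choice;
  abundances exp(a − slope·ifRC + ε).

What the generator does **not** emulate: repeats and assembly artifacts,
read-level sequencing (SL detection is consumed as a site table; a helper
scans read 5' ends for ≥ 6-nt SL suffix matches), codon autocorrelation
along genes, selection heterogeneity among sites, and real alignment noise
beyond boundary erosion. Passing tests therefore demonstrate that the
estimators recover what was planted under these idealised conditions — they
bound implementation error, not biological misspecification. One visible
consequence: with an i.i.d. AT-rich UTR the background rate of an extra
in-frame UAA within 30 codons is already ≈ 0.80, so adding the planted
early-UAA enrichment lifts the filtered-set fraction to ≈ 0.95, above the
observed 79–81%; real UTRs evidently combine the tandem-stop signal with a
less UAA-prone background than i.i.d. composition implies.

## Numerical choices and conventions

* Terminal stop codons are excluded from all codon-count denominators, so
  Glu1/Glu2/Trp fractions are comparable between codes.
* Partial (5'-incomplete) CDSs cannot be framed reliably and are excluded
  from codon statistics, listed in the exclusion log.
* Unobserved codons in a CAI reference receive w = 0.5/(count of the
  family's most frequent codon), the classic pseudo-count convention;
  single-codon families (Met; Trp under the canonical code) are excluded
  from the geometric mean. Note the pseudo-count makes w for *unobserved*
  codons scale with reference depth; scale-invariance holds exactly for
  observed codons and for CAI of sequences composed of them.
* Reference selection for w exposes both published rules — abundance
  > 0.1 A.U. and top-k = 290 — since they describe the same set.
* The expression regressions default to the raw response; a log-response
  flag exists because abundance distributions are skewed, but it is not
  the default since the published fits do not state a transform.
* The 40-gene category subsample is drawn once per pair under the run
  seed (redrawing per pair, not per category); genes with several category
  letters count once per letter.
* Pipeline stages derive child seeds by stable hashing of the stage name
  (`stage_seed()`), so any stage re-run alone reproduces its slice of a
  full run; all derived seeds stay below 2^31.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
codon-statistic equivalence on 50 small seeded sets; parameter recovery on
a 2,000-gene genome; gene-model recovery on 300 genes with trim ≤ 10
codons and 30% fragmentation; enrichment calibration on 200 null
replicates of 400 windows (40 × 200 resampling) and 20 planted-boost
replicates of 2,000 sites; somy on 100 scaffolds of 20 kb at 50× and
cv = 0.1; conservation on a 9-taxon alignment with 1,066 + 202 conserved
columns. These sizes give the binomial standard errors the assertions are
written against while keeping a full run in minutes on a single core.

## Known limitations

Start choice among several in-frame ATGs without SL support follows the
nearest-upstream rule and can mistake an internal Met for the start when
homology boundaries erode; SL evidence corrects this, which is visible in
the recovery tests. The dual-meaning rule cannot represent C-terminal
extensions read through a genuine UAA, selenocysteine-style context
dependence, or UGA/Sec homonymy. Somy calls inherit the disomic-majority
assumption and 1-kb window granularity. The enrichment test treats sites
as independent; overlapping or paralogous motif windows violate that.
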