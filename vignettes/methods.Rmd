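---
title: "Methods: comparative cassette-exon response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative cassette-exon response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassex)
```

## The model

`cassex` asks which cassette exons respond to a splicing-modulator
compound, and why, by comparing two species. The underlying quantities:

**Percent spliced in.** For a cassette event with upstream-inclusion,
downstream-inclusion and skip junction counts $(j_{up}, j_{down},
j_{skip})$,

$$\psi = \frac{j_{up} + j_{down}}{j_{up} + j_{down} + 2\, j_{skip}}.$$

The factor 2 reflects that one inclusion isoform molecule produces two
junction reads' worth of evidence while one skipping molecule produces
one; this is the standard junction-balance estimator. `compute_psi()`
returns `NA` when all three counts are zero — an undefined $\psi$ is never
coerced to 0, because "no expression" and "fully skipped" are different
observations. $\Delta\psi = \psi_{treatment} - \psi_{control}$ is computed
per replicate. One point deserves note: the between-replicate baseline
statistic is defined as
$(\psi_{C1} - \psi_{C2} + \psi_{T1} - \psi_{T2})/2$, a pure within-condition
fluctuation measure, and the treatment contrast always uses the
per-replicate convention above; mixed-sign variants of the averaged
contrast are not used anywhere.

**Response classes.** With two replicates, an event is `skip` when
$\Delta\psi \le -0.05$ in either replicate and $< 0$ in the other,
`inclusion` symmetrically, `no_change` when both replicates sit inside
$(-0.05, 0.05)$, and otherwise one of three `others` classes evaluated
first, in order: `no_expression` (any replicate $\Delta\psi$ undefined),
`psi_too_low` (all four $\psi < 0.05$), `inconsistent` (one replicate
crosses a cutoff while the other has the opposite sign). Evaluating the
degenerate classes first makes the classification a total function — every
input receives exactly one class, which the suite verifies by property
test.

**Strict skip-enhancement.** The headline set uses a harder rule:
replicate-mean $\Delta\psi \le -0.25$ *and* a two-sided, pooled-variance
two-sample t test on the replicate $\psi$ values at $p < 0.05$. With n = 2
per condition the pooled (Student) variance is the only stable choice; the
test has 2 degrees of freedom. When both groups have zero variance the t
statistic is degenerate and we take $p = 0$ if the means differ, 1
otherwise. The $-0.25$ threshold is applied to the replicate-mean
$\Delta\psi$ since a single threshold with two replicates admits no other
symmetric reading.

**Expression filter.** Expression is measured in RPK30M — reads per
kilobase per 30 million mapped reads, i.e. RPKM rescaled for resolution.
An event is excluded when its gene is below 16 RPK30M in *all* replicates,
or when the total of its three junctions falls below 4 RPK30M in *any*
single replicate of either condition. The second clause admits a laxer
grammatical reading ("in at least one condition" could bind to "all
replicates of"); we implement the strictest reading and expose both
cutoffs (`gene_min_rpk30m`, `junction_min_rpk30m`) so the parse is
auditable and overridable. Gene expression may be supplied precomputed;
the pipeline's default approximates it from the gene's total junction
reads over its genomic span, which is exact for the synthetic data and a
documented approximation otherwise.

## Event extraction

From GTF gene models (converted internally to 0-based half-open
coordinates), every internal exon of every transcript is tested: it is a
cassette exon iff some *other* transcript of the *same* gene has an intron
running exactly from the 5′ end of the exon's upstream intron to the 3′
end of its downstream intron. Events are deduplicated on the
(gene, 4-coordinate) tuple — multiple supporting transcript pairs still
yield one event — and coordinate coincidences across overlapping genes are
never merged, because the definition iterates within a gene. Minus-strand
genes are processed in genomic coordinates throughout; strand matters only
at feature extraction, which avoids double reverse-complementing. The
implementation is checked against an exhaustive enumerator over all
(internal exon, other-transcript intron) pairs on hundreds of random toy
genes.

## Homologous exon pairing

Candidate partners for a species-A cassette exon are the internal exons of
the species-B genes linked in the input homology table (ID conversion is
out of scope; the table is data). Pairing uses Smith–Waterman local
alignment with blastn-like scoring (match +2, mismatch −3, gap open −5,
gap extend −2; all configurable), implemented on Biostrings'
`pairwiseAlignment`; a brute-force affine-gap dynamic program in the test
suite serves as the independent oracle. Percent identity is computed over
aligned columns with gaps counted as mismatches (the BLAST convention) and
coverage divides the aligned span by the full annotated exon length on
each side. Accepted pairs need identity strictly above 70 % and coverage
strictly above 0.9 on both sides; among those the winner maximises
(identity, coverage sum) lexicographically — the two criteria are stated
without an order in the source method, so we fixed one and added a final
genomic-coordinate tie-break for determinism. Alignments scoring below 20
(ten matched bases) are treated as no hit. A species-B exon may serve as
partner for several species-A exons. When the annotation offers several
flanking-exon pairs for the chosen exon, the pair whose three event
junctions carry the highest total read count across all samples defines
the B-side event, with a coordinate tie-break.

## Sequence features

Per event we compute: exon length; ESE and ESS counts (all occurrences of
all motifs, overlapping occurrences included — "presence" is ambiguous, so
we count everything, deterministically); donor and acceptor splice-site
scores; branch-point and PPT scores; intron lengths; and the outer sites
(upstream exon's donor, downstream exon's acceptor). Window conventions
are the standard ones of the cited scorers: the donor 9-mer is 3 exonic +
6 intronic nt, the acceptor 23-mer is 20 intronic + 3 exonic nt, and the
branch/PPT input is the 100 intronic nt immediately preceding the cassette
acceptor. Windows shortened by a short intron or a contig edge are
truncated and flagged, never padded.

**Splice-site scoring** is a pluggable position-weight model:
$\mathrm{score}(k\text{-mer}) = \sum_i \log_2(p_i(b_i)/0.25)$. The
shipped default is a first-order PWM trained on the annotation at hand
(pseudocount 0.5); published maximum-entropy tables can be loaded from the
same plain-text format. Scores are only ever compared within one model,
and the pipeline deliberately applies the species-A models to both species
so that cross-species score differences reflect sequence, not scorer.

**Branch point.** A heuristic replaces the SVM-based predictor: all
heptamers with an adenosine at position 6 are scored against a
yUnAy-consensus PWM; the best scorer wins and ties go to the 3′-most
candidate (the analogue of taking the prediction with the highest SVM
score). Adenosines inside the final 3 nt (the acceptor AG region) are not
candidates. Windows without any candidate yield missing branch and PPT
scores, and such events are excluded from PPT-based analyses and from
binning.

**PPT score.** Defined here as (number of pyrimidines) + (longest
uninterrupted pyrimidine run) over the bases strictly between the branch
adenosine and the final 3 nt. This is a stand-in on a scale commensurate
with the published bin edges (0–9 / 10–19 / 20–29 / ≥30): it grows with
both tract length and purity, is monotone under purine→pyrimidine
substitution (property-tested), and is trivially auditable. The original
SVM's tract score formula is unpublished, so the synthetic generator and
the bin edges are calibrated against *this* scale; users substituting real
SVM outputs should recalibrate the edges (they are configurable).

## Inference

The four-way comparison takes: A = skip-enhanced species-A exons vs their
paired insensitive ("no change") species-B homologs; B = the control pairs
(both sides $\Delta\psi = 0$ in both replicates, exactly — with integer
junction counts exact zeros are attainable and the natural control
definition); C and D = within-species contrasts of those groups. Each
feature is compared by two-sided Wilcoxon rank-sum (exact enumeration when
there are no ties and min(n, m) ≤ 8, normal approximation with tie
correction otherwise), reported with raw p-values and significance stars
at 0.05/0.01/0.001 plus a Benjamini–Hochberg-adjusted column for
transparency — the display mirrors raw values because that is how such
panels are conventionally read, but the adjusted values travel with them.

The nine-category table cross-tabulates the per-species classes
(skip / no effect / inclusion) of homologous pairs; expected counts come
from the marginal products under independence (no cross-species
conservation of the effect) and a Pearson chi-square with 4 df tests the
difference, without continuity correction. Zero expected cells flag the
statistic unreliable rather than failing. The set-overlap test compares an
observed overlap against $|A||B|/N$ with a df-1 chi-square on the 2×2
membership table.

The enrichment analysis strata are exon length (0–64 / ≥65 nt), ESE count
(0–4 / 5–15 / ≥16), ESS count (0–19 / ≥20) and PPT score (0–9 / 10–19 /
20–29 / ≥30): 48 bins. Two printed edge sets in the source method are
internally inconsistent ("1–19" would leave 0-ESS exons unbinnable;
"10–29" would overlap the second PPT bin); we resolve both as the unique
partitioning reading (0–19 and 20–29), and the edges are configurable.
Each bin's enrichment is (hits/size) divided by the dataset baseline
(total hits / total binned events), so the size-weighted mean enrichment
is exactly 1 — asserted as an invariant. P-values are upper-tail
hypergeometric (enrichment direction only), and bins need at least 3 hits
to be reportable. The decision-tree report nests length → ESS → ESE → PPT
and surfaces "region a" (short, low-ESS, low/mid-ESE bins ordered by PPT,
where the weak-tract trend is expected) and "region b" (short, high-ESS
bins, where strong-tract enrichment has been observed but no rule is
modelled — it is surfaced, not interpreted).

## The synthetic generator

`generate_dataset()` emulates the study design: two species, two
conditions, two replicates; one cassette event per gene with an annotated
inclusion and skipping transcript; alternating strands to exercise strand
handling. Sensitivity is *generated from features*: sensitive species-A
exons are short (45–63 nt), carry few ESEs (< 5) and ESSs, and have PPT
targets in [10, 20); their species-B homologs are insensitive with strong
tracts (≥ 25) — the divergent-pair biology. Insensitive exons span the
other strata. Exon sequences are composed so that motif counts are exact
(motifs all contain G, fillers are G-free, single-C spacers prevent
boundary artefacts), and upstream-intron windows carry a planted branch
heptamer with an adenosine-free remainder so the branch-point scan lands
on the planted site and the PPT score equals its target — both verified
in tests against the feature extractor.

Junction counts are multinomial draws per gene with weights
$(\psi, \psi, 1-\psi)$, matching the estimator's denominator weighting, at
a per-gene depth of `library_size / n_genes`. Replicate noise acts on
$\mathrm{logit}(\psi)$ with sd `replicate_noise_sd`, clipped to
(0.001, 0.999). One deliberate exception: a ~30 % fraction of insensitive
events is constitutively included ($\psi = 1$ exactly, no noise, zero skip
reads) — these model exons that are alternative in the annotation but
constitutive in the assayed cell type, and they are what makes the exact
$\Delta\psi = 0$ control set non-empty, as it is in real data.

Defaults are the study conditions: `n_genes = 500`,
`frac_sensitive = 0.05`, `effect_size_skip = -0.3`,
`identity_target = 0.936` (the observed exonic similarity level between
the species), `library_size = 3e7` (a typical bulk RNA-seq depth, and the
RPK30M reference scale), and `replicate_noise_sd = 0.1`. The noise level
is not stated by the source; 0.1 on the logit scale keeps the
between-replicate baseline $|\Delta\psi|$ within ±0.05 for the large
majority of events (~98 % in the default runs), matching the narrow
baseline histogram the method assumes. Homolog divergence is pure point
substitution (exact identity by construction, same length).

**What the generator does not emulate:** indels and exon boundary drift
between species (coverage is near 1 for true pairs; real orthologs shed
more pairs at the 0.9 coverage cutoff); overlapping genes and shared
junctions; gene-expression variation beyond uniform allocation;
intron-length variation (fixed flank architecture); read-level artefacts
(counts are drawn, not aligned — the SAM anchor-filter path is exercised
by separate fixtures); and branch-point ambiguity (windows are built to
have a unique candidate). Passing tests therefore demonstrate correctness
of the pipeline's logic and calibration on its own scale, not performance
on real genomes.

## Numerical and degenerate-input choices

- Undefined $\psi$ (0/0) propagates as `NA`; events with any undefined
  replicate become `others:no_expression`.
- Zero-variance t tests: $p \in \{0, 1\}$ as above.
- Wilcoxon with ties never uses the exact path; identical groups give
  $p = 1$.
- Chi-square with zero expected cells: statistic computed over positive
  cells, flagged unreliable.
- Enrichment with zero total hits: all enrichments undefined and flagged.
- Local alignments below score 20 are no-hits; empty candidate sets yield
  no pair, with the reason logged.
- All tie-breaks (homolog choice, flanking pairs, branch-point candidates)
  are deterministic and documented at the function level.

## Problem sizes

The test suite runs the full pipeline at 40 genes and the acceptance
script at the default 500 genes (about one minute end to end); oracle
equivalence suites use 200 random toy genes for event extraction and
n ≤ 8 groups for exact-test enumeration. These sizes give stable
statistics for every check while keeping runs reproducible on a laptop.

## Limitations

The splice-site and branch-point scorers are deliberately simple,
interface-compatible stand-ins for published maximum-entropy and SVM
models; absolute scores are not comparable to those tools, only contrasts
within one model are meaningful. The PPT scale is package-specific, so bin
edges must be recalibrated if an external tract score is injected. The
nine-category and overlap tests assume independent pairs; paralogous
many-to-one pairings (explicitly allowed) mildly violate that. Gene
expression from junction reads underestimates genes with few introns. The
pipeline analyses exactly one event type — cassette exons; alternative
5′/3′ sites, retained introns and mutually exclusive exons are out of
scope.
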