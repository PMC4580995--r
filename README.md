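# cassex

Comparative transcriptomics of cassette-exon responses to a
splicing-modulator compound.

## The problem

Small molecules that inhibit CLK kinases (and thereby SR-protein
phosphorylation) enhance skipping of some cassette exons but not others.
Which sequence features make an exon responsive? `cassex` implements a
two-species comparative pipeline that answers this from RNA-seq junction
counts and genome annotation:

1. **Event extraction** — annotated exon-skipping events are pulled from
   gene models: an internal exon is a cassette exon when another transcript
   of the same gene joins its flanking exons directly. Each event is
   described by four genomic coordinates (upstream-intron 5′ end, exon
   start, exon end, downstream-intron 3′ end).
2. **Quantification** — junction reads (8-nt minimum anchor into each
   flanking exon) give the percent spliced in per sample,

   ψ = (j_up + j_down) / (j_up + j_down + 2·j_skip),

   and Δψ = ψ_treatment − ψ_control per replicate. Expression is
   normalised as RPK30M (reads per kilobase per 30 million mapped reads);
   events on weakly expressed genes (< 16 RPK30M in all replicates) or with
   weak junction support (three-junction total < 4 RPK30M in any replicate)
   are dropped. Events are classed as skip / inclusion / no-change /
   others, and a strict skip-enhanced set requires Δψ ≤ −0.25 plus a
   two-sample t test at p < 0.05.
3. **Homology** — each cassette exon of species A is paired with its best
   internal exon in the homologous species-B gene by Smith–Waterman local
   alignment (blastn-like scoring), requiring identity > 70 % and coverage
   > 0.9 on both sides; ties resolve by identity, then coverage sum.
   Flanking exons are chosen by junction-read support.
4. **Sequence features** — exon length, ESE/ESS motif counts (signed-score
   motif table, SpliceAid-style), donor 9-mer and acceptor 23-mer
   splice-site scores under position-weight models, branch-point
   prediction in the 100-nt upstream-intron window, and a polypyrimidine
   tract (PPT) score = pyrimidine count + longest pyrimidine run between
   the branch adenosine and the acceptor AG.
5. **Inference** — four-way Wilcoxon feature comparisons (skip-enhanced vs
   paired insensitive homologs, plus control pairs with Δψ = 0),
   a nine-category cross-species conservation table with a chi-square test
   against independence, a set-overlap independence test, and a 48-bin
   (2 length × 3 ESE × 2 ESS × 4 PPT) hypergeometric enrichment analysis of
   strongly skip-enhanced exons.

A synthetic two-species generator (`generate_dataset()`) builds toy
genomes, annotations, junction counts and ground-truth labels in which
sensitivity is driven by short exon length, few splicing-factor motifs and
a weak PPT — the signal the pipeline is designed to detect — so everything
is testable end to end without downloads.

## Worked example

```r
library(cassex)

bundle <- generate_dataset(sim_config(n_genes = 60, frac_sensitive = 0.15,
                                      seed = 3), "sim")
cfg <- pipeline_config_from_sim(bundle, "run")
res <- run_full(cfg)
print(res)
```

```
Comparative cassette-exon run
Filtering cascade:
  annotated_events             60
  expressed                    60
  strict_skip_enhanced          9
  with_homolog                  9
  divergent_pairs               8
Top enriched bin: len0-64|ESS0-19|ESE0-4|PPT10-19 (5.00x, p = 1.49e-08)
```

Sixty annotated events survive the expression filter; nine pass the strict
skip-enhancement call (Δψ ≤ −0.25, t test p < 0.05); all nine find a
homologous species-B exon, and eight of those homologs are insensitive
(divergent pairs — the interesting set). The enrichment table ranks the
short/few-motif/weak-PPT stratum (length < 65 nt, ESS < 20, ESE < 5, PPT
10–19) first at five-fold over baseline. The four-way comparison shows the
same picture feature-wise:

```r
res$comparisons[res$comparisons$feature == "ppt_score",
                c("h_skip_median", "m_paired_median", "p_A", "p_B")]
#   h_skip_median m_paired_median          p_A p_B
#              14            32.5 0.0006345689   1
```

PPT scores of skip-enhanced exons (median 14) are much weaker than those
of their insensitive homologs (median 32.5, comparison A significant),
while the control pairs show no cross-species difference (comparison B) —
the signature of a feature that determines the response rather than a
species effect.

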