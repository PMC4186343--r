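---
title: "Models and methods behind hlagdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hlagdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hlagdiv` studies the haplotype diversity of the *HLA-G* locus from
low-coverage sequencing data. This vignette explains the models the package
implements, the conventions and tunable parameters behind them, what the
synthetic-data generator does and does not emulate, and the numerical
choices a maintainer should know about.

## The gene model and its coordinate system

The locus is modeled as fifteen ordered segments (eight exons, seven
introns) totalling 4144 nt. Coordinates are anchored on the coding
sequence: the adenine of the main translation-start ATG is position +1,
the base before it is −1, and there is no position 0. With exon 2
contributing its last 73 nt to the CDS, cumulative segment lengths fix
every boundary (exon 2 spans −112..+73, intron 2 +74..+202, exon 3
+203..+472, …, exon 8 +2924..+3278); the 5′UTR is 178 nt
(exon 1 + non-coding exon 2), the CDS 1017 nt, and the 3′UTR 383 nt
(post-stop exon 7 + exon 8). The constructor re-derives all of these from
the segment lengths and aborts if any invariant fails, so the bundled
constants cannot silently drift.

Two conventions deserve emphasis:

* **Mature-protein codons.** HLA proteins are numbered after cleavage of
  the 24-residue leader peptide, so the package reports both the CDS codon
  (`ceiling(cds_pos / 3)`) and the mature codon (CDS codon − 24). The
  anchors +292 → codon 31, +755 → codon 110, +1799 → codon 258 and the
  frameshift "around codon 130" at +813 all follow from the same 73-nt
  exon-2 contribution, which is why the model derives rather than stores
  them.
* **The 14-bp insertion.** The 14-bp insertion/deletion in the 3′UTR
  (rs371194629) is treated as ancestral and *counted in the gene
  numbering*, but it is absent from hg19. Gene positions beyond +2974 are
  therefore 14 larger than their hg19 offset (e.g. +3003 ↔ 29798610), and
  the inserted positions +2961..+2974 have no hg19 coordinate at all.
  `gene_to_genomic()` / `genomic_to_gene()` implement the piecewise map
  and round-trip exactly; the test suite checks all 133 bundled site pairs.
  The anchor 29795622 for +1 is not stated anywhere as a single constant;
  it is derived from the paired position columns of the bundled site lists
  and validated by those same 133 checks.

Effect classification is deliberately single-locus: intronic positions in
the terminal dinucleotides of an intron are splice acceptor/donor sites
(the canonical AG/GT window of 2 nt, which reproduces the one labelled
acceptor site at +201); coding indels whose length difference is not a
multiple of 3 are frameshifts; coding SNVs are resolved to
synonymous / non-synonymous / stop-gained only when a 1017-nt CDS sequence
is supplied, and degrade to `indeterminate` otherwise. Everything upstream
of the CDS is reported as regulatory (`utr`), following the convention of
treating all upstream variants as promoter-region variants even though
positions −800..−113 lie structurally in intron 1.

## Genotype refinement from allele depths

Low-coverage data make naive genotype calls unreliable in two ways: a true
heterozygote may show only one allele at low depth, and miss-mapped reads
from related loci inject spurious alternates. The refinement stage
re-calls every sample × site from its per-allele read counts:

1. one observed allele: homozygous if depth ≥ 7 (`min_hom_depth`),
   otherwise fully missing;
2. minor allele proportion < 5% (`low_prop`, strict) **and** depth ≥ 20
   (`high_depth_threshold`): the minor allele is discarded and the call is
   homozygous for the major allele;
3. minor proportion in [5%, 20%] (inclusive on both ends, a literal
   reading of "between 5 and 20%"): a half call — the major allele plus an
   explicit missing allele, to be resolved at imputation;
4. minor proportion > 20% (strict): heterozygous for the two
   best-supported alleles.

With ≥ 3 observed alleles each non-major allele is banded independently
and the strongest surviving allele joins the call, which is what makes the
triallelic promoter site −725 C/T/G workable. Ties for the major allele
break by count then allele string, so runs are deterministic. Zero depth
is a missing genotype, not an error. Note that rule 2 is vacuous below
depth 20 with integer counts (one read out of ≤ 19 is already > 5%); the
suite asserts this. Indel alleles are ordinary strings — the insertion
allele is simply 15 characters long.

After refinement, sites that became monomorphic and sites whose minor
allele survives exactly once (singletons) are removed, with a reasoned
report. The depth-7 homozygosity rule corresponds to a balanced-binomial
non-sampling probability of at most 2·0.5⁷ ≈ 0.016 per genotype; the
threshold itself, not any particular probability convention, is what the
package implements.

## The synthetic cohort generator

The generator defines the study conditions for all stochastic tests.
Diplotypes are random unions of gametes (Hardy–Weinberg) drawn from a
bundled haplotype frequency table — either the pooled worldwide
frequencies or the per-population tables. Residual mass not covered by the
named rows ("others") is spread uniformly over a small number of unnamed
pseudo-haplotypes generated by single random edits of the most frequent
haplotype; this keeps frequencies summing to one while exercising the
`new`-haplotype nomenclature path, and the pseudo-haplotypes are flagged
as unnamed throughout.

Observations then emulate 1000Genomes-like low coverage: depth per
sample × site is Poisson(λ) (default λ = 4, typical of low-coverage
whole-genome data); each read copies one of the two true alleles with
equal probability and is corrupted to a uniformly chosen *other* allele of
the site's panel dictionary with probability ε (default 0.005);
independently, Poisson(ρ) contaminant reads (default ρ = 0.1) carry a
uniformly random panel allele, emulating miss-mapping from related HLA
loci. Expected site depth is therefore λ + ρ, which the suite asserts.
Corruption targets panel alleles only — refinement operates on called
alternates, not raw base space, so a finite observation alphabet loses
nothing. The published data come with no error or contamination rates;
these defaults are plausibility choices, swept in tests, and no claim is
made that they match the real data. The generator does not simulate reads,
base qualities, mapping qualities, or linkage to flanking loci.

Under clean high coverage (λ = 30, ε = ρ = 0) every refinement rule
resolves correctly by construction, giving the exact-recovery integration
tests their baseline.

## Phasing: EM with partition-ligation

The original analyses used a coalescent-guided Bayesian phaser. The
package deliberately replaces it with an Excoffier–Slatkin-style EM
estimator plus partition-ligation: it is desk-scale, dependency-free,
deterministic under a seed, and the downstream surface consumes haplotype
frequency tables, not phaser-specific output. Consequences of this choice:
no recombination model guides rare-haplotype reconstruction, and the
published phasing-quality numbers (mean pair probability, share of samples
above 0.9) are reported by `phasing_summary()` but are data-dependent and
never asserted numerically.

Mechanics: each sample's genotypes over a window expand into the set of
unordered haplotype pairs consistent with its calls — half calls and
missing genotypes expand over the site's allele dictionary — and EM
iterates the standard E step (pair weights `f(h1)·f(h2)`, doubled for
heterozygous pairs) and M step (expected haplotype counts over 2N
chromosomes). The log-likelihood is non-decreasing at every iteration
(asserted in tests); iteration stops when the gain falls below `tol`
(1e−8) or at `max_iter` (500), with non-convergence reported rather than
fatal. Windows default to 8 sites; adjacent blocks are ligated by
composing each sample's pair lists across blocks (both orientations) and
re-running EM on the composed candidates; the top 50 haplotypes per block
are retained, always keeping enough pairs for every sample to stay
consistent. Pools are pruned at `1/(10·2N)` and renormalized, and EM runs
3 restarts (uniform plus random Dirichlet starts) keeping the best
likelihood. A sample whose expansion exceeds the cap (4096 states) or that
loses all pairs falls back to a maximum-likelihood completion restricted
to the final pool and is flagged. Best pairs maximize
`f(h1)·f(h2)·(2 − δ)`; the reported posterior is that weight normalized
over the sample's consistent pairs, and missing alleles are imputed from
the best pair.

## Nomenclature

Haplotype naming follows the regional conventions: exact allele-vector
matches take the reference name; a vector at Hamming distance exactly 1
from a unique nearest reference is `<name>-Like` ("a single nucleotide
modification"); anything else is `new`, with deterministic identifiers
assigned by first occurrence. Distance counts sites, not nucleotides, so
the 14-bp allele is one mismatch here even though it weighs 14 in
diversity. Distance-1 ties break by higher reference global frequency,
then name order, and the output records that a tie occurred. The promoter
table includes the coding-region site +15 because the reference table
lists it — nomenclature site lists are definitions, not coordinate cuts.
Extended haplotypes are slash-joined component names; lineages are looked
up from the bundled extended table, which also accepts the short-form
promoter aliases (`0104a` for `010104a`) that the extended table prints.

## Population-genetics estimators

All estimators treat haplotypes as alleles of a single locus, matching an
analysis "based on haplotype frequencies":

* **Gene / haplotype diversity**: unbiased expected heterozygosity
  `(2n/(2n−1))(1 − Σp²)`, per variation site (averaged, with SD) or over
  haplotype frequencies. Residual rare-haplotype mass is treated as
  negligible unless its sum of squares is supplied — many rare distinct
  haplotypes contribute essentially nothing to Σp².
* **Nucleotide diversity**: the frequency form
  `k = (2n/(2n−1))·Σ_s w_s (1 − Σ_a p²_{s,a})`, which equals the
  frequency-weighted pairwise Hamming average exactly (linearity over
  sites); the suite checks the identity against a brute-force pairwise
  oracle at 1e−10. The 14-bp indel takes weight 14 — with the bundled
  3′UTR frequencies this uniquely reproduces the worked value of 8.19 mean
  pairwise differences, whereas weight 1 gives ≈ 2.80 — and region length
  defaults to the span between first and last analyzed site inclusive
  (3′UTR: 2942..3227 → 286 bp). Elsewhere (nomenclature distance, gene
  diversity) the indel counts as one site.
* **Hardy–Weinberg**: a Markov-chain exact test in the Guo–Thompson frame.
  The chain proposes allele swaps between two genotype cells chosen
  uniformly (same cell allowed, so two like heterozygotes can become two
  homozygotes); a 1/2-per-heterozygote proposal asymmetry is corrected in
  the acceptance ratio, where it cancels the 2^H term of the conditional
  distribution analytically. The p-value is the fraction of visited states
  no more probable than the observed one, with a batch-means Monte-Carlo
  standard error; defaults are 100 000 steps after 10 000 dememorization
  steps. Biallelic cases are verified against full enumeration within
  3 MC SE. Monomorphic input returns p = 1, flagged.
* **Differentiation**: pairwise θ is the among-population fraction of the
  haploid variance decomposition on haplotype identity distances (the
  two-population AMOVA special case; small negative estimates are
  legitimate and retained), with p-values from chromosome-label
  permutations. The exact test of differentiation uses the Fisher
  probability-mass criterion on the haplotype × population table: full
  enumeration for 2×2, otherwise Monte Carlo via Patefield's algorithm
  (`stats::r2dtable`), which samples the conditional null directly.
  Reynolds distance is the linearization −ln(1 − θ) with θ clamped to
  [0, 1 − 1e−12]. No molecular distance between haplotypes enters θ —
  pure frequency differentiation, the conservative reading when the
  variant used upstream is unstated.
* **AMOVA**: two- or three-level sums of squares on identity distances
  with the standard coefficient equations; percentages always sum to 100
  (components may dip negative on flat designs, as usual for
  unbiased estimators), and the two-population two-level result equals
  pairwise θ exactly. P-values use the three standard schemes: whole
  populations among groups (F_CT), chromosomes among populations within
  groups (F_SC), chromosomes among all populations (F_ST). When every
  group holds one population the design collapses to two levels and F_SC
  is reported absent.
* **MDS**: classical Torgerson scaling via `stats::cmdscale`, with
  negative eigenvalues clipped under a warning (Reynolds matrices are
  routinely non-Euclidean) and output centered; recovery of planted planar
  configurations is tested to Procrustes residual < 1e−8.
* **Bonferroni**: `alpha/m` with the conventional one-significant-figure
  reporting (0.05/91 → 0.0005) alongside the raw value.

## Problem sizes and test budgets

The suite exercises the full pipeline at deliberately desk-scale sizes:
recovery tests use the 9-site 3′UTR panel with 250–500 individuals at
λ = 30 (frequency RMSE < 0.01, switch error < 5%), exhaustive rule-table
agreement runs over all two-allele compositions to depth 40, and chain
tests use 60 000-step runs. These sizes were chosen so properties are
sharp while the whole suite stays in minutes; they are not the scale of
the original cohort.

## Known limitations

* Population-level results printed for the real 1076-sample cohort
  (missing-allele percentage, 200-haplotype count, per-population
  diversity tables, F_ST/differentiation matrices) depend on the actual
  reads and are not reproducible from bundled tables; the package asserts
  only in-table arithmetic and parameter-recovery properties on synthetic
  cohorts.
* Averaging unbiased per-site heterozygosity over the 17 bundled 3′UTR
  sites gives ≈ 0.165, not the published pooled gene diversity of 0.2730;
  the original software's averaging convention is unclear, so gene
  diversity totals are computed but never asserted against published
  values.
* The phaser is frequency-based EM: no recombination awareness, no
  reference-panel imputation, and no compatibility with coalescent-phaser
  output formats.
* The effect annotator is single-locus by design; splice-isoform
  consequences (the seven HLA-G isoforms) are documented, not modeled.
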