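---
title: "Inferring lncRNA-miRNA-mRNA ceRNA networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA-miRNA-mRNA ceRNA networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

Competing endogenous RNA (ceRNA) inference asks whether a long non-coding
RNA (lncRNA) acts as a sponge that titrates shared microRNAs away from a
messenger RNA, de-repressing it. `spongenet` implements the standard
two-condition RNA-seq recipe for this question, here phrased for a
blind-side hypermelanosis contrast in a flatfish (condition `BH`,
hypermelanotic skin, versus `BN`, normal skin, three replicates each — but
nothing in the code is specific to that system):

1. **Differential expression** per RNA class (mRNA, lncRNA, miRNA) with the
   fixed published thresholds: FDR < 0.05 and |log2 fold change| > 1, both
   strict.
2. **lncRNA annotation**: novel-transcript filtering (spliced length
   > 200 nt, multi-exonic) and positional classification into sense,
   antisense, intronic, bidirectional and intergenic classes relative to
   protein-coding genes.
3. **Target prediction** by canonical seed match (6mer core, 7mer-A1,
   7mer-m8, 8mer) of differentially expressed miRNAs against DE mRNA
   3'UTRs and DE lncRNA transcripts.
4. **Correlation filtering** across the six pooled samples: predicted
   miRNA-target pairs are kept when Spearman rho < -0.7 (repression-like),
   and DE lncRNA x DE mRNA pairs when Pearson r > 0.9 (co-expression).
5. **Sponge test**: for each co-expressed (lncRNA, mRNA) pair sharing at
   least one miRNA, the overlap of their miRNA regulator sets is tested
   with the upper-tail hypergeometric distribution; pairs with p < 0.05
   form the ceRNA network, exported in Cytoscape's SIF format.
6. **Enrichment** of network mRNAs against a term-to-gene map with the same
   hypergeometric kernel (BH-adjusted p < 0.05 for GO-style output, raw
   p < 0.05 for KEGG-style output).

## The sponge test

For one candidate ceRNA pair, let `N` be the number of eligible miRNAs,
`K` of which target the lncRNA and `n` the mRNA, with `k` shared. Under
the null that the two regulator sets are independent draws,
`k ~ Hypergeometric(N, K, n)` and the reported p-value is

$$p = \sum_{j=k}^{\min(K,n)} \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}}.$$

Two choices here were genuinely open:

* **The universe `N`.** We default to the distinct miRNAs participating in
  at least one retained negative pair — the pool actually eligible to be
  shared — and allow an explicit universe (e.g. all DE miRNAs) to be
  passed. A larger universe makes any given overlap look more surprising,
  so the default is the conservative choice.
* **No multiple-testing correction** is applied to sponge p-values (the
  published procedure uses raw p < 0.05); `bh_adjust()` is available if a
  corrected variant is wanted.

Note a structural consequence of the test: a pair sharing a *single*
miRNA (`k = K = n = 1`) has `p = n/N`, which cannot fall below 0.05 unless
the universe holds more than 20 eligible miRNAs. Detectable planted triads
must therefore share several miRNAs; the generator groups its planted
triads into ceRNA pairs sharing four miRNAs each by default.

## The differential-expression stand-in

The original analysis delegates DE calling to well-known external tools.
Re-implementing their internals is explicitly out of scope here; instead
the pipeline uses a transparent stand-in: per-sample total-count scaling to
the mean depth, Welch's unequal-variance t-test per feature on
`log2(normalized + 1)`, Benjamini-Hochberg adjustment, and the strict
printed thresholds. Fold changes use a pseudocount of 1 on the normalized
scale so zero counts are stable.

The stand-in's operating characteristics are *measured, not assumed*: the
acceptance suite checks a type-I error in [0.03, 0.07] at nominal 0.05 on
200 x 2000 simulated null features (it runs slightly conservative,
~0.035), and >= 80% sensitivity for planted |log2FC| = 2 at the 3v3
design. Two honest limitations follow from Welch at n = 3:

* Power drops quickly as the negative-binomial dispersion grows; the
  sensitivity property holds at the generator's default dispersion (0.01,
  see below) but not at 0.05, where moderated-variance methods would be
  needed.
* Total-count normalization suffers composition bias when DE features
  dominate a class's library; the generator therefore keeps planted
  structures a minority of each class, as in any realistic transcriptome.

## What the generator emulates — and what it does not

`sim_config()` states the synthetic world once:

| parameter | default | why |
|---|---|---|
| `n_mrna`, `n_lncrna`, `n_mirna` | 80 / 40 / 48 | large enough that DE features are a minority (the study found 610 DEGs of ~20k genes, 226 of 971 miRNAs), small enough for seconds-scale runs |
| `n_replicates_per_group` | 3 | the BH-1..3 / BN-1..3 design |
| `nb_dispersion` | 0.01 | each replicate is a pool of three individuals; pooling shrinks biological variance toward the low end of RNA-seq gene-wise dispersion |
| `base_mean_log_range` | log2 means 6-10 | expressed-gene coverage (64-1024 expected counts) so Poisson noise does not drown the planted signal |
| `planted_de_lfc` | 2.0 | comfortably beyond the printed \|log2FC\| > 1 cut |
| `mirnas_per_cerna_pair` | 4 | makes planted sponge overlaps detectable (see above) |
| `latent_sd` | 0.25 | within-group co-expression signal; small enough that triad members remain callable as DE at n = 3 |
| `library_size_cv` | 0.2 | realistic but controlled depth variation to exercise normalization |

Counts are negative binomial around condition means
`mu = 2^(u + s + z) * lib`: `u` the base mean, `s` the DE half-shift, `z`
a per-sample latent factor shared within each planted structure (added for
the lncRNA and mRNA, subtracted for their miRNAs, scaled by
`triad_correlation_strength`), and `lib` the log-normal depth factor.
Decoy structures make each filter individually falsifiable: miRNA-mRNA
pairs with a seed site but co-directional expression (the Spearman filter
must reject them), co-expressed lncRNA-mRNA pairs with no shared site (the
>= 1-shared-miRNA rule must reject them), and miRNA-mRNA-only negative
pairs that enlarge the sponge universe without sharing miRNAs.

Sequences are generated so that target prediction is exactly scorable:
every planted (miRNA, target) pair carries one exact 8mer site at a
recorded position, and backgrounds are rejection-sampled to be free of
7mer-or-better sites for every non-planted pair. miRNA seed regions are
drawn pairwise non-conflicting (distinct cores, and no miRNA may match
inside another's fixed site string) because such collisions cannot be
fixed by resampling the background.

The generator does **not** emulate: read-level error or mapping artifacts
(counts are drawn directly), isoform structure beyond a fixed exon layout,
coding-potential ambiguity (biotypes are given), conservation, or any
free-energy component of miRNA targeting. A green end-to-end test
establishes that the pipeline's logic recovers a planted signal of stated
strength under stated noise — not that the thresholds are biologically
optimal.

One spec-level tension is worth recording: planted triad members must be
differentially expressed with coherent directions (lncRNA and mRNA up
together when their miRNAs are down), and those coherent group shifts
alone induce pooled-sample correlations. Setting
`triad_correlation_strength` to zero therefore does *not* push recovery to
the permutation-null level. The enforceable negative control — permuting
the miRNA matrix's sample labels with a partition-breaking permutation —
is what the acceptance suite uses, and it does collapse recovery to zero.

## lncRNA classification choices

The five positional categories are assigned by first matching rule:
sense (same-strand exonic overlap), antisense (opposite-strand span
overlap), intronic (same-strand containment in a single intron),
bidirectional (no overlap, divergent TSSs within 1000 nt), intergenic
(otherwise). The precedence — physical overlap beats proximity, strand
disambiguates overlap — and the 1 kb window are conventions, both
configurable. Antisense is tested against the gene *span* so that
intronic-antisense transcripts fall under antisense, matching common
classifiers. The novel-transcript exon rule is read as >= 2 exons (the
usual multi-exon convention) with `min_exons = 3` available for the
literal "above 2" reading.

The small-RNA cascade annotates a tag with the first matching track in the
fixed order rRNA-like > existing miRNA > existing miRNA edit > known miRNA
> repeat > exon > novel miRNA > intron, else "unannotated". An "edit" is
operationalized as at most one internal substitution against a known
mature sequence with length within +/- 2 nt; the original pipeline does
not define the term, so this is documented rather than inferred.

## Numerical conventions

* All threshold comparisons are strict, exactly as printed: values equal
  to -0.7, 0.9, 1.0 or 0.05 are excluded.
* Constant expression vectors make a correlation undefined; such pairs are
  excluded and listed in an `excluded` attribute rather than given a
  coefficient.
* Spearman uses tie-aware average ranks; at n = 6 its attainable values
  below -0.7 start at -0.714..., so the filter effectively demands
  near-perfect anti-monotonicity in this design.
* A feature with zero variance in both groups gets p = 1 when the group
  means agree (and p = 0 otherwise) by convention.
* BH adjustment computes `(m/i) * p` with the ratio first, so the largest
  p-value maps to itself exactly in floating point.
* Fixtures are byte-deterministic: each generator stage seeds its own RNG
  stream from the master seed, so identical seeds give identical files
  regardless of call order.

## Known limitations

* The Welch stand-in is conservative and underpowered at n = 3 relative to
  moderated-variance DE callers; end-to-end triad recovery (~0.82 at the
  stated low-dispersion world) is limited almost entirely by single
  members of a planted pair narrowly missing the BH cut.
* Correlations over six pooled samples are noisy by construction; the
  -0.7/0.9 thresholds plus n = 6 mean single-sample flukes can drop an
  edge. This mirrors the real design's limitation, not a defect of the
  implementation.
* Enrichment uses the plain hypergeometric test without any length-bias
  correction, and the synthetic term map is a shape fixture, not a real
  ontology.
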