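---
title: "Methods: inferring regulatory shifts from chromatin, expression and GWAS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring regulatory shifts from chromatin, expression and GWAS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A cell population is exposed to a stimulus (the motivating system is primary
human aortic endothelial cells exposed to oxidised LDL) and responds with a
transcriptional program even though bulk chromatin accessibility barely
changes. The working model is that transcription factors (TFs) redistribute
*within* already-open chromatin. `regshift` implements the inference chain
that follows from this model:

1. score how much open chromatin plausibly regulates each gene
   (**regulatory potential**, RP);
2. delete a TF's binding sites from the chromatin landscape *in silico*
   (**ISD**) and ask whether the differentially expressed (DE) genes lose
   more RP than background genes — if so, the TF is a candidate regulator;
3. confirm a specific altered binding-site set against an
   **expression-matched empirical null**;
4. find the individual motif occurrences whose transposase **footprint**
   deepens or vanishes with treatment (**dynamic binding sites**, DBSs);
5. compare the stimulus expression signature to an in-vivo disease signature
   with **rank–rank hypergeometric overlap** (RRHO);
6. intersect GWAS risk variants — pruned and pooled by linkage
   disequilibrium (LD) — with the DBSs to prioritise candidate causal
   variants.

Every stage is exercised end-to-end on a seeded synthetic dataset whose
generator is itself part of the package, so all statistical claims made by
the test suite are reproducible without any external download.

# Regulatory potential and in-silico deletion

For gene $g$ with transcription start site (TSS) $t_g$, the regulatory
potential is a distance-decay-weighted sum of accessibility signal $s(b)$
over bins $b$ with centers $c_b$:

$$\mathrm{RP}_g = \sum_{|c_b - t_g| \le W} s(b)\, 2^{-|c_b - t_g|/\delta},$$

with half-decay $\delta$ = 10 kb (the "enhanced 10k" convention: the weight
halves every 10 kb), window $W$ = 100 kb and 1 kb bins
(`rp_params()`). The model is TSS-anchored; signal over the gene body
carries no extra weight. The exact decay kernel of the reference ISD
framework is not published, so the package fixes the natural half-decay
form above; RP is linear in the signal and reduces to per-base summation at
`bin_size = 1`, which the tests exploit as a brute-force oracle.

ISD masks a TF's binding sites and recomputes RP. Two granularities matter:

- `insilico_delete()` zeroes exactly the bases covered by the supplied
  intervals — the primitive operation;
- `isd_delta_rp()` and `targeted_isd()` widen each site by
  `delete_pad = 500` bp before masking. This emulates the removal of all
  sequencing *fragments* overlapping a site: a cut-site track only records
  fragment ends, and deleting a naked 15 bp motif span would remove a
  trivially small signal share. The ~1 kb deletion window matches the
  deletion granularity of ISD frameworks in this field.

The fractional loss $\Delta\mathrm{RP}_g = (\mathrm{RP}^{\mathrm{before}}_g -
\mathrm{RP}^{\mathrm{after}}_g)/\mathrm{RP}^{\mathrm{before}}_g$ lies in
$[0,1]$; genes with zero prior RP report 0. Masking can only remove signal,
and `delta_rp()` treats any increase as a programming error.

**Regulator ranking** (`rank_regulators()`): per TF, a one-sided Wilcoxon
rank-sum test compares $\Delta$RP of DE genes against a single seeded random
sample of background genes (default 500; at the synthetic scale of 200
genes the tests use 150), with Benjamini–Hochberg FDR across TFs. TFs whose
deletion changes nothing (all $\Delta$RP equal) are assigned p = 1 rather
than the rank-sum's vacuous 0.5, so silent TFs sort to the bottom.

**Targeted ISD** (`targeted_isd()`): the observed statistic is the number
of DE genes with $\Delta\mathrm{RP} > 0.1$ (strict inequality — a gene at
exactly 10% is not disrupted). The null replays the same count on 1,000
background gene sets matched to the DE set's expression profile:
`match_background_genes()` stratifies all genes into expression deciles
(ties broken by gene id), and each null set reproduces the DE set's
per-decile composition, sampling without replacement within a set. The
empirical p-value uses the add-one estimator
$(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(N+1)$ and is therefore never
zero. Because the statistic is an integer count, ties with the null make
the p-value slightly conservative near 1; the calibration test accounts for
this by testing uniformity at the 1% level and separately checking that
small p-values are not over-produced.

# Differential footprinting

A bound TF shields its motif from transposase insertion, leaving a local
dip in the cut-count track. The footprint score of a site is

$$\max\!\left(0,\ \overline{s}_{\mathrm{flanks}} - \overline{s}_{\mathrm{motif}}\right)$$

with two 30 bp flanks (`footprint_params()`). Scores are computed on
depth-normalized (`normalize_cpm()`), bias-corrected tracks.

**Bias model.** Transposases prefer some sequence contexts; the package
divides the signal at each base by the relative cut rate of the k-mer
starting there (default dinucleotides) and rescales to the original library
size (`correct_bias()`). This is intentionally simpler than hexamer
regression models: the synthetic generator plants exactly this bias from a
recorded lookup, closing the loop so the correction is testable (the
high-/low-bias position ratio returns to within 5% of 1 after correction).
K-mers missing from the table fall back to rate 1 with a counted warning.

**DBS calling** (`call_dbs()`): per site
$\Delta = \log_2\frac{s_T + \varepsilon}{s_C + \varepsilon}$ with
$\varepsilon = 0.01$; a site is dynamic when $|\Delta| \ge 1$ (the two-fold
rule on $\varepsilon$-stabilized scores), *activated* when $\Delta > 0$.
The calling is exactly antisymmetric under swapping the two tracks.

**Per-TF differential** (`tf_differential()`): scores of all sites of all
TFs are min–max scaled to $[0,1]$ jointly over both conditions; a TF's
effect is the mean per-site scaled change. Significance comes from
size-matched random site draws from the pooled universe (two-sided
empirical p with the add-one estimator, BH across TFs), and the
significance flag additionally requires $|\Delta\mathrm{score}| > 0.1$.
The effect-size gate matters: a strongly shifted TF inflates the pooled
mean, which can make unmoved TFs statistically "different from the pool"
even though their effect is ~0.

# Rank–rank hypergeometric overlap

Genes are ranked by the signed significance
$\mathrm{sign}(\mathrm{logFC}) \cdot (-\log_{10} p)$, so strong induction
sits at one end and strong repression at the other (p-values of 0 must be
floored by the caller; ties break by gene id). For each threshold pair
$(i \cdot \mathrm{step},\ j \cdot \mathrm{step})$ the overlap of the two
list heads is tested with the exact hypergeometric upper tail; the full
grid is BH-adjusted and reported as $-\log_{10}\mathrm{FDR}$
(`rrho_map()`). The default step $\max(1, \lfloor N/100\rfloor)$ caps the
map at 100×100. The map is one-sided and concordant: it detects shared
ordering, and a perfectly reversed partner list produces no signal rather
than an "anti-corner" (discordance testing is a quadrant-split variant this
package does not implement). `fisher_overlap()` supplies the companion flat
one-sided Fisher test of two DE gene sets over a finite universe.

# Variant prioritization

From GWAS summary statistics and a haplotype panel (0/1 matrix, haplotypes
× variants — a stand-in for a reference LD panel):

1. `filter_variants()`: keep $p < 5\times10^{-8}$ and MAF $> 1\%$ (both
   strict);
2. `ld_prune()`: greedy by ascending p, keep a variant iff $r^2 \le 0.1$
   with every kept variant on the same chromosome (PLINK-style clumping;
   ties on p break by rsid so the result is input-order invariant);
3. `ld_pool()`: re-expand each index variant to all same-chromosome
   proxies with $r^2 > 0.8$ (strict); contested proxies join the
   smaller-p index, so pools are disjoint;
4. `overlap_dbs_variants()`: extend each DBS by 500 bp per side (the same
   convention used for DBS annotation), keep pooled variants whose 1-based
   position falls inside an extended DBS, and group rows by hosting DBS as
   `locus_id`;
5. `annotate_variant()`: gene-body containment, reported as
   "`<gene> intron`" — a deliberate proxy, since exon structure is not
   modelled — otherwise "Intergenic region".

$r^2$ is the squared allelic correlation from haplotype frequencies.
`allelic_imbalance()` is the exact two-sided binomial test of
allele-specific read counts against 0.5, used to corroborate a prioritized
heterozygous site with allele-specific accessibility.

A worked example ships with the package
(`inst/extdata/prioritized_variants.tsv`, the printed eight-variant report
this pipeline emulates): parsing it, converting the printed 1-based
positions against the BED-style half-open DBS intervals, and grouping by
interval yields 5 distinct loci with every variant inside its DBS.

# The synthetic dataset

`sim_config()` fixes the study conditions; the defaults are the package's
desk-scale choices and are deliberately not tuned per test:

| parameter | default | what it encodes |
|---|---|---|
| genome | 2 × 1 Mb | two chromosomes, enough room for 100 kb RP windows |
| genes | 200 | log-normal baseline expression (log2 mean 5, sd 1.5) |
| TFs × sites | 5 × 200 | 15 bp motif sites, non-overlapping within a TF |
| `frac_altered_sites` | 0.5 | TF1's condition-specific sites, each within 10 kb of a target gene TSS |
| `peak_height` / `background_rate` | 2.0 / 0.05 cuts/bp | accessible peaks (±200 bp of a site) over sparse background |
| `footprint_depth` | 0.5 | fractional motif-span depletion when bound (recovery tests run at 0.8) |
| `regulator_effect` | 2 | log2 fold-change planted on 25 target genes |
| replicates | 3 per condition | log2 replicate noise sd 0.4, pooled t-test |
| panel | 500 × 2,000 | LD blocks of 20 variants, copy-with-mutation (2% flip) |
| causal loci | 4 | causal variant repositioned inside an altered site, p ∈ [1e-12, 1e-9] |

Design points worth knowing:

- **Poisson counts, not negative binomial.** Downstream statistics are
  ratio- or rank-based; over-dispersion would change power, not
  correctness, and Poisson keeps the generator analytically checkable
  (site-free region means match the recorded expected rates within
  Monte-Carlo error).
- **One master seed, fixed stage offsets.** Each stage seeds at
  `seed + k`, so adding a stage never perturbs earlier draws and every
  output is bit-reproducible.
- **The planted dinucleotide bias** multiplies every expected rate and is
  recorded in the annotation, giving `correct_bias()` a ground truth.
- **The plaque-like second signature** is built in signed z space:
  $z_2 = \rho z_1 + \sqrt{1-\rho^2}\,\eta$ with $z_1$ the signed probit of
  the first signature's p-value. Under the null $z_2 \sim N(0,1)$, so the
  second table's p-values are honestly uniform; at $\rho = 1$ the two
  ranked lists are identical.
- **What is not emulated:** donor/batch covariate structure, fragment-length
  mixtures, nucleosome positioning, copy number, sequencing error,
  multi-allelic sites, and realistic motif redundancy across TFs. Passing
  tests therefore demonstrate the *inference chain* is correct under its
  stated model, not that the model captures every property of real
  ATAC-seq.

# Numerical and testing choices

- Internal coordinates are 1-based closed (`GRanges`); BED/bedGraph on disk
  keep their native 0-based half-open semantics, converted at the I/O
  boundary. Variant positions stay 1-based as printed in GWAS tables.
- Problem sizes in the test suite: recovery runs use 20 seeds at the
  default scale; null calibrations use 200 seeds of a reduced
  single-chromosome configuration (240 genes, 120 sites) for the targeted
  ISD, 50 seed pairs of 500-gene lists for RRHO, and 500 balanced binomial
  draws for allelic imbalance. These sizes give each check stable
  Monte-Carlo margins while keeping the whole suite in minutes on one CPU.
- Discrete-statistic calibration is tested two-sidedly where the statistic
  is rich enough (χ² on the targeted-ISD p) and one-sidedly
  (no excess small p) plus an exact-achievable-level check where the
  statistic is strongly discrete (binomial allelic imbalance): an exact
  discrete test can never be uniform at its point masses, and pretending
  otherwise would reject correct code.
- The empirical-FDR of DBS calling depends on `footprint_depth`: deep
  footprints (0.8) separate cleanly (sensitivity ≳ 0.98, FDR ≲ 0.01);
  at the default 0.5 the score noise pushes the empirical FDR to ~0.15 —
  a property of the condition, not of the caller.

# Limitations

- The RP kernel is a fixed choice among plausible decay forms; no gene-body
  integration is attempted.
- The bias model is order-k division, not a learned insertion model; on
  real data a dedicated correction tool should be run upstream and its
  output fed in as the track.
- LD operations assume the supplied panel represents the GWAS population;
  pooling/pruning thresholds are exposed but default to the conventional
  0.8 / 0.1.
- "Intron" annotation is gene-body containment; supply exon-aware
  annotations downstream if the distinction matters.
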