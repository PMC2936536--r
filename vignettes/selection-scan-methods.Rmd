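---
title: "Multi-statistic selection scans with altsweep: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-statistic selection scans with altsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altsweep)
```

## The problem

A recent, strong episode of positive selection in one population leaves a
cluster of footprints around the selected locus: allele frequencies diverge
from related populations, local diversity collapses, the site frequency
spectrum shifts toward rare variants, and one haplotype stays unusually long
for its frequency. No single statistic captures all of these, and each can
be mimicked by demography, so the scan implemented here combines four
complementary statistics for a *focal* population contrasted with two
*reference* populations, and assesses each against its own genome-wide
empirical distribution rather than a model-based null.

* **LSBL** (locus-specific branch length). Per marker, the three pairwise
  Weir--Cockerham $\hat\theta$ values are triangulated into
  population-specific branch lengths, $d_A = (\theta_{AB} + \theta_{AC} -
  \theta_{BC})/2$ and cyclic permutations. The focal branch isolates
  allele-frequency change on the focal lineage; with three populations it is
  equivalent to a population-specific $F_{ST}$. Upper tail = candidate.
* **lnRH**: $\ln(H_{focal}/H_{ref})$ with $H$ the window-averaged unbiased
  expected heterozygosity, over 100-kb windows sliding by 25 kb. Strongly
  negative values mark focal-specific diversity loss.
* **Standardized difference of Tajima's D**: per window
  $\Delta_i = D_{focal,i} - D_{ref,i}$, standardized by the mean and sample
  SD of the defined $\Delta$. Negative tail = focal-specific rare-variant
  excess.
* **Long-range haplotype (REHH) test**: core haplotypes on non-overlapping
  7-marker spans; EHH at 500 kb is the probability that two carrier
  chromosomes are identical out to that distance; REHH divides the core's
  EHH by the carrier-weighted average of the other cores on the span. REHH
  values are tested against a gamma null fitted by maximum likelihood
  within core-frequency bins, with Benjamini--Hochberg FDR control, and the
  reported significant set is restricted to cores carrying a derived allele
  at frequency strictly above 0.85.

Downstream, significant markers/windows are clustered into 1-Mb
non-overlapping regions via the upper hypergeometric tail (Bonferroni over
the tested regions; corrected $p \le 0.004$ by default), regions jointly
significant for the standardized difference of D plus LSBL or lnRH are
nominated (adjacent nominations merge into runs), genes are scored by their
most extreme statistic within a 50-kb-flanked span against a per-gene
extreme-value null, and pathway enrichment uses a one-sided
Kolmogorov--Smirnov test.

## Empirical significance: the two arithmetic rules

Two small arithmetic conventions matter for reproducing published scan
tables, and both are frozen into this package after checking them against
printed worked examples:

* **Empirical p-value**: $P_E = (\mathrm{rank} - 1)/N$ -- the fraction of
  the genome-wide distribution *strictly more* extreme. This is the only
  rule among the natural candidates (rank/$N$, rank/$(N{+}1)$,
  (rank$-$1)/$N$, ...) that reproduces every published rank/total/$P_E$
  triple we checked at 4-decimal rounding; rank/$N$ fails exactly at a
  borderline half-rounding case. Consequence: the top-ranked value has
  $P_E = 0$.
* **Tail counts**: the number of significant values at level $\alpha$ is
  $\mathrm{round\_half\_up}(\alpha N)$, the unique rule consistent with all
  published count/total pairs we checked (e.g. $0.05 \times 856{,}231 =
  42{,}811.55 \to 42{,}812$). Significance flags are therefore count-based
  (rank within the $\alpha$ prefix), not $P_E$-threshold-based; ties share
  their block-maximum rank and enter or leave the prefix as a block.

Autosomes and the X chromosome are ranked separately throughout; Y and
mitochondrial markers are dropped on ingest.

## Numerical and convention choices

* Coordinates are 1-based inclusive internally (VCF convention); BED is
  converted on read and on write. Missing genotypes are a sentinel (`NA`),
  never imputed; the only default QC is the "95% or greater" per-population
  call-rate filter, applied before any statistic.
* Weir--Cockerham $\hat\theta$ uses the full genotype-level estimator with
  the observed-heterozygosity term; a haploid allele-count variant is
  available (`variant = "haploid"`) as a sensitivity check. Negative
  $\hat\theta$ is reported raw and floored at zero only on entry to the
  triangulation, so $d_A + d_B = \max(\theta_{AB}, 0)$ holds exactly.
* **Monomorphic pairs.** A pair of populations monomorphic for the same
  allele has $\hat\theta = 0/0$, and `wc_fst()` flags it undefined. Inside
  `lsbl_scan()`, however, such a pair at a marker that is still polymorphic
  across the triangulation contributes $\theta = 0$ (no differentiation)
  instead of dropping the locus. The alternative -- propagating undefined --
  silently removes precisely the loci the scan targets: a completed focal
  sweep with both references fixed for the ancestral allele. Markers
  monomorphic in all three panels stay undefined.
* Tajima's D uses constants at the full panel size $n = 2 \times$ samples;
  per-window $S$ counts segregating markers and $\pi$ sums per-site
  unbiased heterozygosity with per-site called chromosome counts. $S = 0$
  windows are undefined, not zero. Standardization uses the sample SD over
  defined windows; a zero-variance track standardizes to zeros with a
  warning.
* Windows anchor at position 1 of each chromosome and are emitted only
  while they fit entirely on the chromosome. By default every defined
  window enters the lower-tail ranking (`tail_only`); the `two_stage` mode
  restricts eligibility to windows with negative standardized focal D, for
  scans that screen on the focal spectrum first. `tail_only` is the default
  because published per-statistic significant-window counts equal exact
  alpha-fractions of *all* windows, implying no pre-filter on the counted
  distribution.
* The gamma MLE solves the profile score equation
  $\log k - \psi(k) = \log\bar x - \overline{\log x}$ by Newton iteration
  (relative tolerance $10^{-8}$) started from the standard closed-form
  approximation; constant input is an error. Frequency bins (width 0.05)
  with fewer than 30 REHH values fall back to a fit pooled over all cores
  rather than an unstable bin fit.
* The hypergeometric tail is exact (`phyper`); the region-level threshold
  0.004 is a configuration value taken from practice, applied to
  Bonferroni-corrected p-values over the tested (non-empty) regions only.
* The one-sided K-S statistic is $D^+ = \sup_x[F_{bg}(x) - F_{path}(x)]$,
  oriented to detect a pathway shifted toward *high* values, with the
  asymptotic p-value $\exp(-2 D^2 nm/(n+m))$ capped at 1. A pathway sample
  wholly below the background gives $D = 0$, $p = 1$ by construction.

## The synthetic world

`simulate_three_populations()` is a discrete-generation Wright--Fisher
simulator on a fixed marker lattice (about one marker per 3 kb), with
recombination, producing phased haplotypes, diploid genotypes, marker maps
with known ancestral states, gene annotations with pathway tags, and truth
labels. Its defaults *are* the package's stated validation conditions:

| parameter | default | why |
|---|---|---|
| $N_e$ per population | 500 (diploid) | desk-scale rescaling of a human-like panmictic size |
| splits $t_1$, $t_2$ | 300, 150 generations | highland--lowland drift $F_{ST} = 1-(1-\tfrac{1}{2N_e})^{t_2} \approx 0.14$, in the realistic 0.05--0.15 band; $t_1 = 2t_2$ |
| recombination | $2\times10^{-7}$/bp/gen | preserves the human population-scaled rate $4N_e r \approx 4\times10^{-4}$/bp after rescaling $N_e$ down ~20x; the literal per-meiosis human rate would make the whole chromosome one hitchhiking block |
| selection $s$ | 0 (sweeps: 0.05) | additive fitnesses $1, 1+s, 1+2s$ in the highland branch only |
| sweep origin | standing variant at root frequency 0.05--0.10 | rare in the root and hence in the outgroup, so the signal is genuinely highland-specific; lost alleles trigger bounded re-draws of the highland branch |
| samples | 50/50/50 diploids | typical array-panel sizes |
| missing rate | 0.02 | exercises the 0.95 call-rate filter without dominating it |
| root frequencies | $\propto 1/x$ on [0.05, 0.95] | neutral-spectrum-shaped, truncated to mimic array-ascertained common variants; an optional MAF floor (`ascertain_maf`) re-ascertains on the final sample |

What the generator emulates: two population splits, drift-scaled
differentiation, linkage disequilibrium built by a 100-generation burn-in
and maintained by tight linkage, a highland-restricted sweep with
hitchhiking, high call rates, known ancestral states, and a gene/pathway
annotation with one true target gene. What it does **not** emulate: new
mutations (the lattice is standing variation only), realistic human
demography (bottlenecks, growth, migration), X-specific effective size (an
"X" chromosome is simulated like an autosome and exercises the separate-X
code path), genotyping error beyond missingness, and CNV biology (biallelic
CNPs are coded markers). A green simulation-based test therefore
establishes internal consistency of the statistics and the detectability of
a planted sweep under drift -- not calibration against real human data.

One visible consequence: raw window Tajima's D in this world sits around
+2, not 0, because an ascertained common-variant lattice has no
rare-variant supply. Real array data shows the same upward shift, which is
exactly why the method ranks *standardized* D and the standardized
difference of D rather than raw values. The neutral-centering checks in the
test suite therefore assert that lnRH and the focal-minus-reference D
difference are centered, not raw D.

The per-generation loop is compiled (Rcpp) and uses R's RNG, so a seed
fully determines every output file; `write_fixture_set()` emits a manifest
with MD5 checksums to make that checkable.

## Known limitations

* The LSBL empirical distribution includes hitchhiking markers; in ~15-20%
  of simulated sweeps a linked neighbor gene outranks the true target at
  the per-gene 1% cutoff (the criterion we validate against tolerates
  this). Interpreting the top gene as *the* target is not supported --
  nominated regions are the right unit.
* The REHH gamma null is fitted to the observed REHH distribution itself;
  under widespread selection this is conservative.
* Phasing of real unphased data is out of scope; the haplotype stage
  requires phased input (the simulator provides it).
* The K-S p-value is asymptotic; for pathway sets smaller than ~100 items
  an exact or permutation p is preferable.
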