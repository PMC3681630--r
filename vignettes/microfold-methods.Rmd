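---
title: "Methods: replicated-probe microarray analysis with microfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicated-probe microarray analysis with microfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microfold)
library(dplyr)
```

## The analysis problem

`microfold` implements the processing chain for single-channel spotted
expression microarrays in which every gene is printed as several identical
replicate spots and each biological condition is hybridized to one array
from a pooled sample. This design — common in bacterial stress-response
studies, for example solventogenic *Clostridium* cultures challenged with
the lignocellulose-derived inhibitor furfural during their acidogenic and
solventogenic growth phases — trades array-level replication for
within-array probe replication. The default simulated design carries 5,003
genes at five replicate spots each, with one control and one treatment
array per growth phase.

With a single array per condition there is no within-contrast variance
estimate, so the pipeline is deliberately simple and fully deterministic:

1. **Scale-factor normalization.** Each array is summarized by the
   arithmetic mean of its spot median intensities, $\mu$. The treatment
   array is put on the control array's scale by the single multiplicative
   factor
   $$\mathrm{SF} = \mu_{\mathrm{control}} / \mu_{\mathrm{treatment}},$$
   applied to every treatment spot. After application the two array means
   agree to floating-point accuracy (a tested post-condition, relative
   $10^{-12}$).
2. **Trimmed-mean summarization.** Within each (gene, array) replicate
   group of *adjusted* signals, exactly one occurrence of the maximum and
   one of the minimum are discarded and the remaining values averaged.
   With the five-replicate design this averages the middle three spots,
   giving robustness to one aberrant spot in either direction. Order
   matters: trimming runs after scaling, so the discarded extremes are
   chosen on the adjusted values.
3. **Ratios and signed fold changes.** Per gene, the expression ratio is
   the treatment summary divided by the control summary. Ratios at or
   above one are reported as-is; ratios below one are reported as the
   negated reciprocal ($r \mapsto -1/r$), so down-regulation reads as
   $-k$-fold and no fold change falls in $(-1, 1)$. The log2 ratio makes
   the distribution symmetric for export and heatmaps.
4. **Threshold DE calls.** Genes with $|\mathrm{fold}| > 3$ (strict by
   default, reflecting "more than 3-fold"; an inclusive $\geq$ mode is
   provided) are called up- or down-regulated. No p-value is attached —
   none is estimable from pooled single arrays — so the threshold *is* the
   decision rule.
5. **Term over-representation.** The DE list is tested against a
   gene-to-term annotation with the one-sided upper-tail hypergeometric
   test, $P(X \geq k)$ for an overlap of $k$ DE genes in a term of size
   $K$, a DE list of size $n$ and a universe of size $N$; the EASE variant
   ($k - 1$ in place of $k$, floored at zero) is available as the more
   conservative option used by popular annotation servers. P-values are
   Benjamini–Hochberg adjusted. The default universe is the set of genes
   with a defined expression ratio — genes removed by QC cannot be called
   DE, so leaving them in the background would inflate enrichment — with
   the full array available as an option.
6. **qPCR validation.** Cycle-threshold plates are analyzed by the
   comparative-CT method: well replicates are averaged, the reference
   gene's mean CT is subtracted per condition ($\Delta C_T$), control is
   subtracted from treatment ($\Delta\Delta C_T$), and relative expression
   is $2^{-\Delta\Delta C_T}$, assuming doubling per cycle. A
   reference-stability check reports the largest between-condition shift
   in the reference gene's mean CT against a tolerance (default 0.5
   cycles, a conventional bound for calling a reference "constant"; 16S
   rRNA plays this role in the bacterial setting). Cross-platform
   concordance is the Pearson R between matched signed fold changes (the
   scale of the usual validation scatter), with a log2 mode because
   Pearson on signed folds is scale-sensitive.

## The synthetic-data generator

Real deposited arrays are not required anywhere: `simulate_experiment()`
generates spot-level data with known truth. A spot's signal is

$$\mathrm{signal}(g, r, a) = s_a \cdot 2^{\,b_g + f_g [a\ \mathrm{treated}]
 + \alpha_{g,r} + \varepsilon_{g,r,a}},$$

with per-array scale $s_a$, gene baseline $b_g \sim N(10, 1.5^2)$ in log2
intensity units, spiked log2 fold change $f_g$, probe affinity
$\alpha_{g,r} \sim N(0, 0.15^2)$ fixed across arrays (the same probe
sequence is printed on every array), and per-spot noise $\varepsilon \sim
N(0, 0.2^2)$. With probability 0.01 a spot is an outlier, shifted $\pm 4$
log2 units with random sign — large enough to be fatal to a plain mean and
therefore to exercise the trimmed mean in both directions. Signals are
clamped at a positive floor (1 intensity unit) so downstream ratios stay
defined; floor hits are counted and reported. Noise is multiplicative
(log-normal) because intensities are positive and scanner noise classically
scales with signal; none of these magnitudes is estimated from real data —
they are conventions chosen once to give realistic intensity spreads
(medians near $2^{10}$, spot CVs near 15%).

Defaults mirror the emulated study design: two phases ("acidogenic",
"solventogenic"), DE fractions $111/5003$ and $721/5003$ split evenly
between directions, spiked $|$fold$|$ drawn uniformly (in log2) from 3 up
to 16-fold in the first phase and 54-fold in the second, per-array scales
$(1, 1.2, 1, 0.85)$, and per-phase qPCR panels of 19 and 23 genes drawn
across up-, down- and non-regulated strata with triplicate wells and a
constant-CT reference gene.

Two structural choices make the noise-free limit exactly recoverable, and
both are worth understanding because they state the assumption under which
global-mean normalization is *correct* rather than merely convenient:

* **DE sets are disjoint across phases**, so each phase's balance
  constraint involves only its own genes.
* **Spiked regulation conserves total signal.** A single global scale
  factor can only recover fold changes exactly if differential expression
  does not move the array mean. The generator therefore shifts the
  baselines of up- and down-spiked genes by equal and opposite log2
  amounts chosen so the treatment array's expected mean equals the
  control's. The shift cancels in every treatment/control ratio, so no
  gene's true fold change is altered; it only removes the global bias that
  unbalanced spiking would otherwise put into SF. A phase spiked in only
  one direction cannot be balanced and is left unbalanced — in that regime
  SF normalization is biased by construction, which is a property of the
  method, not of the simulator.

What the simulator does **not** emulate: spatial artifacts and gradients
within the slide, intensity-dependent (nonlinear) dye response,
background/foreground segmentation, cross-hybridization between related
probes, and array-to-array variance beyond a scalar intensity factor.
Passing tests therefore demonstrate the pipeline's algebra, robustness and
calibration under the stated model — not that a single scale factor is
sufficient normalization for any real slide.

## Numerical choices and degenerate inputs

* Trimming removes exactly one occurrence of each extreme, ties included
  (`{5,5,5,5,5}` keeps three fives; `{1,1,1,1,10}` summarizes to 1).
  Groups of four drop both extremes and average two; groups of three are
  averaged untrimmed (never average fewer than two values); groups under
  three are excluded with a warning. The implementation sorts each group
  and averages the interior in ascending order, which makes it *exactly*
  equal to the sort-and-average oracle, not merely within tolerance.
* The signed-fold map is discontinuous at ratio 1 (+1 vs −1). Exactness
  checks on noise-free data are therefore run on the continuous log2
  scale; on the fold scale they are asserted away from the jump.
* A control summary at or below the signal floor leaves that gene's ratio
  undefined (excluded, logged); a treatment summary at or below the floor
  is computed against the floor and flagged.
* Scale factors with non-positive treatment means, DE genes absent from
  the enrichment universe, CT tables missing the reference in a condition,
  and concordance inputs with fewer than three shared genes or zero
  variance are all hard, named errors — never silent coercion.
* All randomness flows from the single config seed (the qPCR plate uses a
  fixed offset of it), so identical configurations reproduce output trees
  byte for byte; the TSV writers emit shortest round-trip representations
  of doubles, and the results writer uses fixed 6-decimal formatting.

## Problem sizes used in the shipped checks

The test suite exercises the full 5,003-gene design where the property
depends on scale (noise-free recovery; noisy recovery at spot noise 0.2
log2 units, 2% DE at $\geq$4-fold, averaged over ten seeds — sensitivity
$\geq 0.99$, FPR $\leq 0.01$) and reduced designs (60–400 genes) where it
does not (tie handling, I/O round-trips, determinism). The hypergeometric
implementation is checked against exhaustive combinatorial enumeration for
every universe size up to 30 and against one-sided Fisher tests;
super-uniformity of the null p-value is checked with 10,000 random DE
draws. Concordance degradation is measured at qPCR noise 0.1/0.3/0.6
cycles with 50 replicates each on a 150-gene single-phase design.

## A worked run

```{r run}
run <- run_pipeline(sim_config(seed = 1))
run$summary
```

Under the study-like defaults this calls on the order of 113 and 714 DE
genes in the two phases (the configured fractions spike 112 and 720; a few
boundary spikes near 3-fold land under the strict threshold and a few
noisy non-DE genes land above it), and the microarray and qPCR fold
changes correlate near R = 0.97–0.99 — higher than typical published
validations because the simulated platforms share none of the biological
and protocol differences that separate real ones.

```{r views, fig.width = 6, fig.height = 3.5}
autoplot(run)
glance(run$concordance$acidogenic)
head(tidy(run))
```

## Known limitations

* One array per condition: no variance estimation, no moderated
  statistics; the 3-fold rule is a decision threshold, not a test.
* Global-mean normalization assumes total-signal conservation; strongly
  unbalanced regulation biases every ratio by a common factor.
* The enrichment step implements the statistic only; it knows nothing of
  ontology structure (no parent-term propagation) and ships no annotation
  content.
* Comparative CT assumes amplification efficiency 2 for every assay; no
  standard-curve calibration is provided.
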