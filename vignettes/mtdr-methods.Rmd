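---
title: "Estimating typical codon decoding rates from ribosome profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating typical codon decoding rates from ribosome profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtdr)
```

## The problem

Ribosome profiling (Ribo-seq) counts, for every codon position of every
mRNA, how many ribosome-protected footprints mapped there. Because a
ribosome that dwells longer at a position leaves more footprints, these
counts carry information about how fast each codon is decoded. The catch is
that raw footprint counts confound the quantity of interest (per-codon
dwell time) with everything else: mRNA abundance, initiation rate,
sequencing depth, the initiation-proximal density ramp, and rare long
pauses such as ribosomal traffic jams.

`mtdr` separates these effects. It estimates, per codon type, a *typical*
(pause-free) decoding time, and summarizes any open reading frame by the
geometric mean of its codons' typical decoding rates — the MTDR index, a
condition- and tissue-specific translation elongation efficiency score that
can be computed for any sequence, including lowly expressed or newly
engineered genes that have no reliable expression measurements of their
own.

## From footprint counts to NFC distributions

The preprocessing chain (`buildNfcTable()`) applies, in this fixed order:

1. **Gene filter.** Only genes whose median footprint count over the full
   profile strictly exceeds 1 are analyzed (`geneStat = "median"`,
   `geneThreshold = 1`). Mostly-zero profiles are dominated by mapping
   noise. The mean variant is available via `geneStat = "mean"` because
   both summaries are in circulation for this filter.
2. **End trimming.** The first and last 20 codons are removed
   (`trimStart`, `trimEnd`). Ribosome density is systematically elevated
   near the start (the 5' ramp) and, in some organisms, the end of the
   ORF; the trim removes these artifacts rather than modeling them.
3. **Position filter.** Positions with fewer than 1 footprint count are
   excluded (`codonMinFc`): single stray reads are unreliable.
4. **Normalization.** Surviving counts are divided by the gene's average
   count, giving normalized footprint counts (NFC) that are comparable
   across genes with different mRNA levels and initiation rates.

The denominator in step 4 is, by default, the mean over the same positions
that yield samples (trimmed positions passing `codonMinFc`). This makes the
normalization self-consistent: the mean NFC of a gene's contributing
positions is exactly 1, so an NFC value is interpretable as "time spent at
this codon relative to the other analyzed codons of the same gene". The
alternative — the mean over all trimmed positions including sub-threshold
ones — is available as `denominator = "all_trimmed"`; with zero-inflated
data it deflates the denominator and shifts all NFC values up by a
gene-dependent factor.

Pooling the NFC values of every surviving position, keyed by the codon at
that position, yields one empirical distribution per sense codon (61
buckets; stop codons are not decoded and never enter the table).

## The exponentially modified Gaussian model

Each codon's NFC distribution is modeled as the sum of two independent
components:

* a **normal** component, mean $\mu$ and s.d. $\sigma$ — the typical,
  pause-free decoding time of the codon (in NFC units);
* an **exponential** component with rate $\lambda$ — occasional long
  dwells from translational pauses and ribosomal traffic jams, which add a
  heavy right tail. Its mean contribution is $1/\lambda$.

Their sum has the exponentially modified Gaussian (EMG) density

$$
f(x;\mu,\sigma,\lambda) = \frac{\lambda}{2}
\exp\!\Big(\frac{\lambda}{2}(2\mu + \lambda\sigma^2 - 2x)\Big)
\,\mathrm{erfc}\!\Big(\frac{\mu + \lambda\sigma^2 - x}{\sqrt{2}\,\sigma}\Big).
$$

$\lambda$ is parameterized as the exponential *rate* (the standard EMG
convention); output tables also report $1/\lambda$ to avoid ambiguity.

**Numerical evaluation.** The naive form overflows or underflows whenever
$\lambda\sigma$ is large (the near-Gaussian regime). `demg()` evaluates

$$
\log f = \log\frac{\lambda}{2} - \frac{(x-\mu)^2}{2\sigma^2}
+ \log\,\mathrm{erfcx}(u), \qquad
u = \frac{\mu + \lambda\sigma^2 - x}{\sqrt{2}\,\sigma},
$$

with a range-guarded $\log\,\mathrm{erfcx}$: the library function for
$|u| < 25$, the asymptotic series
$\mathrm{erfcx}(u) \sim (u\sqrt{\pi})^{-1}(1 - \tfrac{1}{2u^2} + \dots)$
for $u \ge 25$ (relative error below $10^{-10}$ at the boundary), and
$u^2 + \log 2$ for $u \le -25$. This keeps the density finite and accurate
over the entire parameter range, verified by quadrature (the density
integrates to 1 and reproduces the closed-form moments
$E[X] = \mu + 1/\lambda$, $\mathrm{Var}[X] = \sigma^2 + 1/\lambda^2$).

**Fitting.** `fitEmg()` maximizes the log-likelihood with L-BFGS-B in
$(\mu, \log\sigma, \log\lambda)$ — the log-parameterization enforces
positivity without constraint machinery — using analytic gradients and a
method-of-moments start (skewness-matching, with the skewness clamped to
$[0.02, 1.96]$ so symmetric or negatively skewed inputs get a near-Gaussian
start instead of failing). If the first start does not converge, five
deterministically perturbed restarts are tried; the best log-likelihood
wins, ties going to the smaller $\lambda$. Convergence requires both a
clean optimizer termination and a per-sample gradient sup-norm below
`gradTol = 1e-3` — at the curvature of these likelihoods
($\partial^2\ell/\partial\mu^2 \approx n/\sigma^2$) that bounds the
parameter displacement from the true optimum by roughly $10^{-6}$, which is
what the location/scale equivariance checks in the test suite demand. A
line-search abort at a stationary point (a known L-BFGS-B behavior with
tight `factr`) is accepted as convergence if and only if the gradient check
passes.

Codons with fewer than `minSamples = 200` NFC samples are reported as
*unfit* rather than fitted: below this the decomposition into normal and
exponential parts is unstable. Fits with $\hat\mu \le 0$ are flagged
*atypical* and excluded from rate tables, since a decoding time must be
positive. Both exclusions propagate to scoring via the missing-codon
policy rather than aborting a run.

One modeling caveat is inherited from the estimation protocol: the
position filter truncates each gene's NFC sample at a gene-dependent lower
bound, and the EMG is fitted to the surviving samples without a truncation
correction. A truncated-likelihood variant would remove the resulting mild
upward bias at low-$\mu$ codons; it is noted as future work.

## The MTDR index

The typical decoding *rate* of a codon is $1/\hat\mu$ — the reciprocal is
the only dimensionally consistent conversion from a time. The MTDR index
of an ORF is the geometric mean of its codons' rates:

$$
\mathrm{MTDR} = \exp\Big(\frac{1}{L}\sum_{i=1}^{L} \log r_{c_i}\Big).
$$

Scoring uses **all** sense codons of the target ORF: the 20-codon trim is
an estimation-side artifact filter, not part of the index (the trimmed
variant is available via `trimEnds = TRUE`). A terminal stop codon is never
scored; codons lacking a fitted rate are skipped and counted
(`policy = "skip"`) or raise an error (`policy = "strict"`). The index is
exactly invariant to codon order, strictly increasing when a codon is
replaced by a faster one, and scales linearly when all rates are scaled.

## Comparison indexes: CAI and tAI

For benchmarking, the package includes reference implementations of the
two standard sequence-only indexes. CAI weights are within-family
frequency ratios in a highly expressed reference set (Sharp–Li), with a
0.5 pseudo-count so absent codons keep a positive weight, and ATG/TGG
excluded from scoring by default. tAI weights follow the dos Reis wobble
box scheme over tRNA gene copy numbers with the published selective
constraints $s = (0,0,0,0,0.41,0.28,0.9999,0.68,0.89)$, the methionine
special case, an optional prokaryotic ATA rule, and zero weights replaced
by the geometric mean of the nonzero ones. Their decoding-time transforms
(`decodingTimeTransform()`) are reciprocals of the weights by default —
the simplest monotone time proxy; since only *rank* agreement with fitted
$\hat\mu$ values is ever asserted, any strictly decreasing transform gives
identical conclusions (a log variant is provided).

## Validation statistics

* `spearmanCor()` is Pearson correlation on average ranks with a
  two-sided t-approximation p-value — deliberately implemented as its
  definition so tests can check it against an independent brute-force
  oracle and against `stats::cor.test`.
* `partialSpearman()` is the first-order partial Pearson formula on
  ranks, equivalent to correlating residuals-of-ranks; degenerate cases
  (a variable perfectly rank-correlated with the conditioning variable)
  are flagged rather than returned as numbers.
* `fitPaRegression()` fits $PA = c + w_1\,\mathrm{MTDR} + w_2\,\mathrm{tAI}
  + w_3\,\mathrm{CAI}$ by OLS and reports 95% t-based confidence
  intervals; a coefficient whose interval excludes zero contributes
  significantly. Rank-deficient designs are an error with a condition
  number report.
* `ribosomalLoadValidation()` implements the held-out protocol: a seeded
  50/50 split of the genes passing the coverage filter (this package's
  operationalization of "highly expressed genes" — the estimation
  population itself, since no separate threshold is standard), decoding
  times estimated on one half, MTDR scored on the other half, and
  correlated with observed mean footprint counts. The split is random
  under `splitSeed` and recorded in the output.
* `conditionComparison()` compares two conditions by per-gene MTDR and
  load ratios: Spearman of the ratio vectors, plus t and Wilcoxon
  rank-sum tests of the MTDR ratios in the top vs bottom 30% of genes by
  load ratio. Raw p-values are reported throughout (an optional
  Benjamini–Hochberg helper is provided but not applied by default).

## What the synthetic generator emulates

`simConfig()` / `simulateOrfs()` / `simulateProfiles()` generate data with
exactly the statistical structure the estimator assumes, so every pipeline
stage is testable without external downloads. Per gene: a sequencing depth
$d$ from a log-normal (most genes in real libraries are shallow); per
codon position, a count $d \times$ a positive EMG draw under the codon's
true parameters; a multiplicative excess over the first 20 codons (the 5'
ramp — present only so tests can verify that trimming removes it); and
dropout, each position zeroed with probability $e^{-d/d_0}$, reproducing
depth-dependent sparsity.

Two features model *translational selection*, without which synthetic
data could not reproduce the positive MTDR/ribosomal-load association
seen in real organisms (mechanically, a gene's mean footprint count is
depth × mean dwell, and mean dwell *anti*-correlates with MTDR; the
positive association in real data comes from highly translated genes
being selected for fast codons):

* `usageBias`: each gene draws $b \sim U(0, 1)$ and samples codons with
  probability $\propto$ usage $\times\, (1/\mu_c)^b$ — gene-to-gene codon
  usage bias, the very signal CAI measures;
* `loadCoupling`: depth is multiplied by
  $\exp(2 \cdot (\log \mathrm{MTDR}_g - \overline{\log \mathrm{MTDR}}))$,
  chosen against the measured dwell elasticity ($\approx -0.5$) so that
  selection dominates and the generative Spearman between true MTDR and
  mean count is $\approx 0.35$ — inside the 0.2–0.6 range reported for
  real organisms under standard growth conditions.

Reference conditions (the defaults): 200 genes of 200–400 codons, 61
distinct true decoding times equally spaced on $[0.1, 1.0]$ NFC units,
$\sigma_c = 0.25\,\mu_c$ (a realistic 25% coefficient of variation),
common pause rate $\lambda = 3$ (mean pause contribution $1/3$, i.e.
pauses comparable to typical dwells, which is what makes the
decomposition non-trivial), depth log-normal with median 10 and
$\mathrm{sdlog} = 1$, dropout scale $d_0 = 4$, ramp factor 1.3. All
outputs are pure functions of (config, seed).

Because the EMG has support on the whole real line but counts cannot be
negative, negative draws are rejected and redrawn. This truncation mildly
biases the lowest-$\mu$ codons upward — together with the position-filter
truncation it is why end-to-end checks assert *rank* recovery (Spearman
> 0.9 between true and estimated times) rather than unbiasedness.

What the generator does **not** emulate: mechanistic ribosome flow
(traffic jams arise only statistically through the exponential tail, not
from a TASEP-style model), sequencing biases (ligation, nuclease footprint
size), isoform structure, and position-dependent rates. Passing tests
therefore demonstrate correctness of the estimation machinery under the
model's own assumptions, not robustness to every artifact of real
libraries.

## Problem sizes used by the checks

The package's own benchmark (`endToEndRecovery()`) runs the default
200-gene configuration and scores 100 held-out ORFs; at these sizes each
codon accumulates roughly 500–900 NFC samples and the whole run takes a
few seconds. The held-out load protocol is exercised at 300 genes: with a
selection effect of $\rho \approx 0.3$, roughly 140 held-out genes are
needed for one-sided $p < 0.01$, mirroring the hundreds-to-thousands of
genes per organism the protocol is designed for. Maximum-likelihood
recovery is checked over 20 replicates of 5000 draws from
EMG(0.2, 0.05, 5), where the median absolute error of $\hat\mu$ is well
under 0.005.

## Degenerate inputs and tie-breaks

* Profiles shorter than `trimStart + trimEnd + minLenAfterTrim`, genes
  whose every position fails `codonMinFc`, and genes absent from the
  FASTA (or with mismatched length) are excluded and recorded in the
  per-gene report with a reason; they are never silent.
* Constant vectors make rank correlations undefined; the result is
  flagged (`ok = FALSE`), not an error, so batch reports stay complete.
* Multi-start ties in the EMG fit (log-likelihoods within $10^{-9}$) are
  broken toward the smaller $\hat\lambda$, i.e. the more-Gaussian
  explanation.
* `computeMtdr` on an ORF none of whose codons has a rate is an error
  under both policies; in batch scoring it degrades to an NA row with the
  reason in `note`.

## Known limitations

* NFC units are relative to each gene's own mean, so $\hat\mu$ values are
  not comparable across data sets with different filtering, and absolute
  times from any particular organism/condition cannot be reproduced
  without that data set.
* No truncated-likelihood correction for the position filter (see above).
* The per-codon fits assume pooled NFC samples are i.i.d.; residual
  gene-level structure (e.g. gene-specific elongation regimes) fattens
  the fitted $\sigma$ rather than being modeled.
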