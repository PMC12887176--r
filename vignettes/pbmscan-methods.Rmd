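---
title: "Quantitative TF binding models from protein binding microarrays"
author: "pbmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative TF binding models from protein binding microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbmscan)
```

## The model

A protein binding microarray (PBM) measures the fluorescence of a tagged
transcription factor bound to ~15,000 double-stranded 60-nt probes whose
variable regions tile a de Bruijn sequence, so that every short word
occurs in a known number of probes. `pbmscan` turns such an experiment
into a quantitative sequence-to-affinity model in three steps, wrapped by
the fitting function `pbm_fit()`:

1. **Spatial detrending** (`spatial_detrend()`). Each probe's intensity is
   divided by the median intensity of the probes in the $(2r+1)^2$ block
   centered on its array position ($r = 7$ by default, a 15×15 block), then
   rescaled so the global median is exactly preserved. The block *median*
   is used because it ignores isolated bright-spot artifacts; the final
   rescale is explicit because division by local medians preserves the
   global median only for flat fields.

2. **Per-k-mer affinity z-scores** (`kmer_stats()`). For every canonical
   7-mer $m$ (the lexicographic minimum of the word and its reverse
   complement — probes are double stranded, so strands are indistinguishable),
   the statistic is the median log-intensity over the probes whose
   variable region contains $m$ on either strand,

   $$z(m) = \frac{s(m) - \overline{s}}{\mathrm{sd}(s)},\qquad
     s(m) = \mathrm{median}\{\log I_p : m \in p\},$$

   standardized across the $4^7/2 = 8192$ canonical 7-mers. The z-scores
   are the model: scanning a sequence assigns each window the z of its
   canonical 7-mer. For visualization the z-scale is mapped to a linear
   relative-affinity scale by $2^z$, which turns the standard score into a
   fold-like quantity with $z=0 \mapsto 1$.

3. **Seed-and-wobble PWM** (`seed_and_wobble()`). The seed is the
   canonical 7-mer with the highest rank-based enrichment E-score
   ($U/(n_{fg} n_{bg}) - 1/2 \in [-0.5, 0.5]$, invariant under monotone
   intensity transforms). For each position and base, the energy of the
   single substitution is the difference in median log-intensity between
   probes carrying the substituted word and probes carrying the seed; seed
   bases sit at the zero reference energy. A single wobble pass is
   performed — no iterative seed extension — to keep the estimator
   auditable. Exponentiating each energy column and normalizing
   (a Boltzmann softmax) gives the column-stochastic probabilities of the
   energy-normalized logo (`energy_logo()`), with letter heights equal to
   the column's information content in bits.

### Assumptions

* Log-intensity is approximately additive in (best-window binding energy +
  noise); the *maximum* over windows, not the sum, carries the signal —
  appropriate below scanner saturation.
* Chromatin accessibility is not modeled: a promoter scan predicts
  *intrinsic* binding potential, not occupancy in a particular cell state.
* Medians and rank statistics are used throughout, so the model is robust
  to heavy-tailed intensity noise and to monotone rescaling between arrays.

## Promoter scanning and tracks

`extract_promoters()` takes windows of 1000 bases upstream and 500 bases
downstream of the TSS, adjusted for gene orientation. With a 1-based TSS
$t$, the 0-based half-open interval is $[t-1-1000,\, t-1+500)$ on the `+`
strand and $[t-500,\, t+1000)$ on the `-` strand; the TSS sits at offset
1000 of the returned sequence in both cases. All internal coordinates are
0-based half-open (the bedGraph/BED convention); `to_one_based()` /
`to_zero_based()` convert to the 1-based inclusive convention used in
print. Note that a 1-based inclusive span of a 1500-base window prints as
1499 when the end coordinate is quoted inclusively; both conversions are
provided rather than forcing one reading.

`score_sequence()` anchors each 7-mer's z at its **start** offset (a
deliberate, documented choice — visual comparisons against center-anchored
displays can shift by $\lfloor k/2 \rfloor = 3$). Windows containing `N`
score the missing-k-mer default (0 = background z) so track length stays
predictable at $L - k + 1$. Because the table is canonical, scanning a
sequence and its reverse complement yields mirror-image tracks.

`call_sites()` reports maximal runs with $z \ge z_{\min}$ (default 2.0,
roughly the top 2.3% of k-mers under normality of the z distribution —
the threshold is a package default, not a published value). Runs are
split only when start offsets are at least $\max(\text{merge\_gap}, k)$
apart: the gap rule alone (default 5 < $k$) could emit sites sharing
covered bases, and disjointness is the more useful contract.

## Scrambled-site variant design

`design_knockout_panel()` reproduces the wild-type / first-site-scrambled
(Ps1) / second-site (Ps2) / both-sites (Ps1+2) design. "Scrambled" is
operationalized as a seeded uniform permutation of the site's bases with
**rejection**: a candidate is redrawn while any k-mer window overlapping
the scrambled interval still scores $z \ge z_{\text{ceiling}}$ (default =
the calling threshold). Rejection is essential — a naive single
permutation recreates a high-affinity word by chance often enough to
defeat the design intent of eliminating predicted binding; the residual
max z of the accepted variant is reported so the elimination is
verifiable. Composition preservation (exact base multiset inside the
interval, identity outside) holds by construction. Sites are ranked by
peak z with ties broken by leftmost start, making the Ps1/Ps2 labels
reproducible.

## ChIP-seq comparison

`window_correlation()` computes the Spearman correlation between per-base
predicted linear affinities and per-base coverage inside a promoter
window, with a permutation p-value from circular shifts of the predicted
track: $p = (1 + \#\{\rho_{\text{shift}} \ge \rho\})/(1 + n_{\text{perm}})$.
Circular shifting preserves the autocorrelation of the affinity profile,
which base-level shuffling would destroy; Spearman is used because
coverage is depth-scaled and heavy-tailed. Two calibration facts shaped
the test suite's study design:

* For a *single fixed* window, shift p-values are not exactly
  exchangeable: simulated coverage kernels have a window-edge profile, so
  the conditional null is biased for windows whose sites sit near an
  edge. The null-calibration suite therefore draws an independent
  prediction window per run, which restores uniformity.
* Per-base rank correlation between a spiky 7-mer track and ~200-bp
  fragment kernels is geometry-limited: shifts that land a spike anywhere
  on a kernel flank compete with the true alignment. The matched-case
  check therefore summarises the median p over five windows with four
  planted sites each, scanned with a site-level (consensus-only) table.

## DEG filtering, clustering, Venn analysis

`filter_degs()` applies three thresholds jointly: adjusted $p \le 0.05$
(missing values fail), $|\log_2 FC| \ge 2$ *in at least one condition*
(inclusive bounds; the any-condition reading reproduces a union gene set
for heatmap inclusion), and base mean $> 5$. `ward_cluster()` runs
agglomerative clustering with Ward's minimum-variance criterion on
Euclidean distances of the log2 fold-change profiles (fold-change space,
no row standardization — configurable by passing any matrix) and cuts at
four flat clusters; per-cluster medians, IQRs and sample SDs annotate the
result, with singleton clusters reporting IQR = SD = 0 under a flag so
annotations stay total. `venn_sets()` returns the seven exclusive region
cardinalities, which always sum to the union size.

## What the generators emulate — and what they do not

`gen_probeset()` mirrors the array design: a de Bruijn order-7 tile pool
(~566 probes) guarantees every canonical 7-mer at least one probe, the
remainder are uniform random variable regions, all followed by a constant
3' primer region excluded from k-mer statistics. Log-intensities are
baseline + best-window PWM energy + Gaussian noise (default sd 0.1
log-units) + an optional row/column gradient for detrending tests. Not
emulated: scanner physics, dye chemistry, probe secondary structure,
position-on-probe effects, and inter-array normalization.

`gen_promoters()` plants PWM-sampled (or verbatim) sites on random strands
in uniform-ACGT backgrounds. Real promoters are GC- and CpG-structured;
passing tests here demonstrates algorithmic correctness, not performance
on genomic base composition. One consequence worth knowing: the chance
probability that a *specific* 7-mer occurs somewhere in a 1500-base random
window (either strand) is $1 - e^{-1494 \cdot 2/4^7} \approx 17\%$, so
"no planted sites" does not mean "no high-affinity words" — the
zero-site calibration test asserts that unplanted windows stay below
planted-site affinity, which holds ~83% of the time, not a 95% absence of
threshold crossings, which no standardized complete table can deliver
(a mean-0, sd-1 distribution over 8192 words always puts ~2% of them
above $z = 2$).

`gen_chip_coverage()` sums triangular kernels (width = fragment length,
default 200 bp; peak height = depth, default 50) at true site centers
plus a half-normal noise floor — fragment pileup shape, not read-level
simulation. `gen_deg_table()` draws cluster-mean log2 fold changes over
five conditions emulating four regulatory classes (up-everywhere,
down-everywhere, OE-only, IFN-only) plus null genes.

## Numerical and design choices

* **Canonicalization** by lexicographic minimum; deterministic and
  standard in k-mer counting. A=0 < C=1 < G=2 < T=3 encoding makes numeric
  index order equal string order, so scanning is a pair of rolling
  polynomial evaluations.
* **Conflicting duplicate table rows raise** rather than average — a
  malformed input should surface, not blend in.
* **Zero-spread degeneracy**: if all k-mer medians are equal, all z are
  set to 0 (with a message) rather than dividing by zero.
* **Uncovered substitutions** in the wobble step take a configurable
  floor energy (default −5 log-units) and are logged; with the de Bruijn
  pool this path is rarely taken.
* **k is a parameter** (default 7 everywhere); the table word length and
  the wobble word length are the same parameter by default and are not
  assumed to match any particular array's design order.
* **Ties** in site ranking break to the leftmost start; `which.max`
  conventions make peak positions leftmost-on-tie as well.
* **Problem sizes** used by the test suite and acceptance script: the
  full array scale (15,000 probes) for headline motif recovery — at a few
  thousand probes each 7-mer is covered by only ~2–7 probes and a shifted
  neighbor that co-occurs with the consensus can tie its median, making
  the argmax ill-defined; 2,000 probes or fewer for structural unit
  tests; 100 seeded promoters for knockout monotonicity; 200 runs ×
  100 shifts for null calibration. These sizes were chosen to make the
  statistical properties they test well-defined.

## Limitations

* The model is intrinsically 7-mer local: no dinucleotide dependencies,
  no flanking-sequence or shape features, and no $k \ne 7$ interactions
  beyond what the single parameter `k` provides.
* Promoter scans assume accessibility and ignore isoform-specific TSS
  choice.
* The ChIP comparison consumes coverage tracks as given; it does not
  align, deduplicate, or call peaks.
* The scramble designer guarantees *predicted* elimination under its own
  table; it cannot guarantee that a scramble does not create a binding
  site for some other factor.
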