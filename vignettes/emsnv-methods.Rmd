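---
title: "Methods: EM ensemble genotyping and decision-tree variant filtering"
author: "emsnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EM ensemble genotyping and decision-tree variant filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsnv)
```

## The calling problem as unsupervised ensemble classification

At each reference position of a diploid genome, the genotype is one of ten
unordered allele pairs over {A,C,G,T}:

```
AA CC GG TT AC AG AT CG CT GT
```

(four homozygous classes, then six heterozygous, in this fixed canonical
order). Every aligned read base covering a locus is a noisy vote for that
locus's genotype. `emsnv` treats these votes as coming from an *ensemble of
learners*: read observations are stratified by Phred base quality into bins
(default Q0–9, Q10–19, Q20–29, Q30+), and each bin is modeled as one
annotator whose reliability is unknown. This is a Dawid–Skene-style model:
each learner $j$ has a class-conditional emission ("confusion") matrix

$$\theta_{j}(b \mid k) = P(\text{learner } j \text{ emits base } b \mid
\text{true genotype } k), \qquad b \in \{A,C,G,T\},\ k \in 1..10,$$

and the model carries genotype priors $\pi_r(k)$ *conditioned on the
reference base* $r$ at the locus. Conditioning on $r$ matters: an
unconditional 10-class prior would be dominated by reference composition
and systematically bias calls; conditioning makes "homozygous reference"
the high-prior class at every locus regardless of which base the reference
shows.

Let $n_{ijb}$ be the number of reads of learner $j$ showing base $b$ at
locus $i$. With reads conditionally independent given the genotype, the
posterior over classes at locus $i$ is

$$q_i(k) \;\propto\; \pi_{r_i}(k) \prod_j \prod_b
\theta_j(b \mid k)^{\,n_{ijb}} .$$

The decided genotype is the posterior argmax (ties broken deterministically
toward the lowest canonical class index), and a locus becomes an **SNV
candidate** exactly when the decided genotype differs from the homozygous
reference pair in at least one allele — both heterozygous (`ref→AC`) and
homozygous-alternate (`ref→CC`) calls qualify.

## EM fitting

Neither $\theta$ nor $\pi$ is known, and no labeled data is assumed: both
are estimated by expectation–maximization.

* **E step.** Compute $q_i(\cdot)$ above, in log space, for all loci.
  A zero-depth locus receives the prior row itself.
* **M step.** Posterior-weighted re-estimation with symmetric Dirichlet
  smoothing (pseudocount $c$, default 0.1):
  $$\hat\theta_j(b \mid k) = \frac{c + \sum_i q_i(k)\, n_{ijb}}
  {4c + \sum_i q_i(k) \sum_b n_{ijb}}, \qquad
  \hat\pi_r(k) = \frac{c + \sum_{i: r_i = r} q_i(k)}
  {10c + \sum_{i: r_i = r} 1}.$$
  The pseudocount keeps every probability strictly positive. A learner
  with no observations at all retains its previous emission rows.

Because the M step maximizes a Dirichlet-penalized expected log-likelihood,
the quantity this EM provably increases each iteration is the **MAP
objective** — observed-data log-likelihood plus
$c\sum \log \theta + c\sum \log \pi$ — not the raw likelihood alone, whose
monotonicity is exact only in the vanishing-smoothing limit. `run_em()`
therefore records both per iteration and uses the relative change of the
MAP objective as its stopping rule (default tolerance $10^{-6}$, at most
50 iterations). The test suite asserts monotonicity of the MAP objective
at the default pseudocount and of the raw log-likelihood at a negligible
pseudocount, on 100 seeded random instances each.

**Initialization** is structured rather than random: under a homozygous
class $(x,x)$ the matching base starts at $1-\varepsilon$ (default
$\varepsilon = 0.05$) with the remainder spread over the other three
bases; under a heterozygous $(x,y)$ each allele starts at
$(1-\varepsilon)/2$; priors start at $p_0 = 0.998$ on the
homozygous-reference class. With this initialization the class labels are
anchored to their intended meanings from iteration one, so the label
switching that plagues unconstrained mixture EM does not arise in
practice.

**Windowing and aggregation.** The EM is fitted per contig in windows
(default 1 Mb). Within a window, loci with identical (reference base,
count pattern) are collapsed into one weighted pattern; the likelihood is
algebraically identical and the collapse is typically a 10–50× speedup on
deep data. Exactness of the collapse is asserted by a test. Because each
window refits its own $\theta, \pi$, genuinely marginal loci (posterior
mass split between two classes) can be decided differently under different
window sizes; confidently decided loci are invariant, and the suite checks
exactly that.

## Numerical choices

* All likelihood products are sums of logs; normalization uses the
  max-shift (log-sum-exp) trick.
* In the zero-probability limit ($\theta = 0$ exactly, which can only be
  user-supplied — fitted models are floored by the pseudocount) the code
  clamps $\log 0$ to $-10^{300}$ so that a zero count contributes exactly
  0 and a positive count annihilates the class, rather than producing
  `0 · (−∞) = NaN`.
* Posterior argmax uses an absolute tolerance of $10^{-12}$ when detecting
  ties, so exact symmetric ties (e.g. counts `{G:1, T:1}` making CG and CT
  equally likely) resolve to the lowest class index regardless of
  floating-point summation order.
* Posterior entropy is Shannon entropy in **bits** (base 2, with
  $0\log 0 = 0$), ranging over $[0, \log_2 10 \approx 3.32]$; a base must
  be fixed for the filter feature to be portable across runs.

## The candidate filter

The EM step is intentionally sensitive; a second step removes untrue
candidates. Each candidate carries four features:

| feature | meaning | encoding |
|---|---|---|
| genotype | the decided class | canonical code 0–9 plus an `is_het` flag |
| depth | reads mapped to the locus | integer |
| alt fraction | share of reads with a non-reference base | real in [0,1] |
| entropy | Shannon entropy of the 10-class posterior | bits; lower = more confident |

A CART decision tree (Gini impurity, balanced class weights, fixed seed)
of **depth at most 5** is trained on labeled candidates: a candidate is
labeled true iff a truth variant exists at the same position *with the
identical genotype*. The shallow depth is a deliberate overfitting guard;
more expressive models are intentionally avoided. On the packaged
synthetic regimes, posterior entropy and alternate-base fraction carry
almost all of the split importance, with depth and genotype marginal —
the pattern one expects, since the spiked/untrue candidates differ from
true ones precisely in confidence, not in coverage.

The package does not ship a pre-trained model file; `default_filter_model()`
deterministically trains one at first use from a documented simulated
regime (seed 20240601: a 50 kb, 30× run whose candidates are labeled
against the planted truth and augmented with 150 spiked low-confidence
false candidates). Users calling variants on real data should train on
their own truth set via `run_train_filter()`.

## Evaluation semantics

`evaluate_calls()` compares SNV records at identical (chrom, pos):
a true positive requires the *identical unordered genotype*; a call at a
truth locus with the wrong genotype counts as one false positive **and**
one false negative; precision $= TP/(TP+FP)$, recall $= TP/(TP+FN)$, F1 is
their harmonic mean. An empty call set has undefined precision; it is
reported as 1.0 together with an explicit `zero_calls` flag so the case
cannot be misread silently. Evaluation can be restricted to confident
regions given as a BED mask. This is genotype-aware matching in the style
of the standard benchmarking pipelines for isolated SNVs; haplotype-level
normalization of complex/adjacent variants is out of scope.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates: an i.i.d. uniform reference; SNVs planted
at a fixed per-base rate (default $10^{-3}$), heterozygous with
probability 0.67 (the roughly 2:1 het:hom ratio typical of human SNVs),
alternate allele uniform over the three non-reference bases; reads of
fixed length placed uniformly, each drawn whole from one of the two
haplotypes (a read is a physical molecule from one chromosome);
substitution errors at a per-learner rate, uniform over the three wrong
bases, with the base-quality string encoding the learner bin (defaults:
rates 0.01/0.005/0.002/0.001 at Q7/Q15/Q25/Q37, equal mixture weights);
reads emitted pre-aligned (perfect placement, all-match CIGAR) in
coordinate-sorted SAM, since alignment is an upstream preprocessing step
for this caller. Everything is reproducible bit-for-bit from the seed.

Two deliberate design choices: SNVs are planted only in the *interior* of
the contig, at least one read length from each end, because the coverage
ramp at contig edges would otherwise leave some planted sites trivially
undersampled and make exact-recovery properties meaningless; and note that
the default caller filters (`min_baseq = 13`) discard the Q7 stratum
entirely — low-quality evidence is dropped by design, as in mainstream
callers — so harnesses that study *all* learner strata (e.g. confusion
recovery) lower `min_baseq` to 0.

The simulator deliberately omits: INDELs and structural variants (the
caller is SNV-only), alignment and mapping error, quality-by-cycle and GC
bias, PCR duplicates, and mate-pair fragment structure (each read is
independent, so overlapping mates — which the pileup intentionally does
not deduplicate — occur only by chance). Consequently, passing tests
demonstrate correctness of the inference machinery and calibrated
behavior under the stated noise model; they do not demonstrate accuracy
on real data, where alignment artifacts and correlated errors dominate
the residual error of any caller.

## Problem sizes and fixed parameters used by the packaged checks

The packaged property checks run, as the package's chosen study scale:
confusion-matrix recovery on a 50,000 bp genome at 30× (~50k loci, error
rates spanning 0.001–0.05, compared against a 5,000 bp run under the same
seed); end-to-end genotype recovery on a 100,000 bp genome at 30× with
per-base error ≤ 1% (bar: F1 ≥ 0.99) and, with zero error at 50×, exact
recovery (F1 = 1.0); the oracle-equivalence check enumerates every
single-learner count vector of depth ≤ 4 at every reference base plus 60
random two-learner instances, against an independent probability-space
Bayes enumeration at $10^{-10}$. All seeds are fixed constants.

## Known limitations

* Diploid, SNV-only; no INDELs, no ploidy ≠ 2, single-sample.
* Overlapping mate pairs are counted twice; on real paired-end data with
  short fragments this slightly overstates evidence at overlapped loci.
* The learner construction (base-quality bins) is one defensible choice
  of ensemble; other stratifications (by strand, by cycle) would slot
  into the same model but are not implemented.
* Per-window EM refitting means marginal-locus decisions can depend on
  window boundaries.
* Genotype-aware exact matching diverges from haplotype-resolution
  benchmarking tools on adjacent or complex variants; for isolated SNVs
  the two agree.
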