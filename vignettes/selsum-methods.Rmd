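---
title: "Methods: SUMSTAT enrichment for polygenic selection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SUMSTAT enrichment for polygenic selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selsum)
```

## The model and its assumptions

The branch-site test contrasts, per gene and per phylogenetic branch,
a codon model with a site class allowed dN/dS > 1 (H1) against one
without (H0), yielding the likelihood-ratio statistic
$\Delta lnL = 2(\ln L_{H1} - \ln L_{H0})$. `selsum` treats these
statistics as given and asks a set-level question: does a pathway show
a *distribution shift* toward positive selection, rather than one or
two outlier genes?

The pipeline assumes:

1. **Scores are exchangeable within a branch.** All comparisons are
   against random gene sets drawn from the same branch's score table,
   so any branch-wide inflation (branch length, alignment quality)
   cancels. Nothing is compared across branches.
2. **Genes in sets differ from genes outside sets.** In-set genes are
   more conserved on average, so the null samples only from genes
   belonging to at least one set (`background_mode = "in_sets"`). With
   an all-genes background the null would be dominated by high
   out-of-set scores and P values would be biased upward; the package
   exposes `background_mode = "all_scored"` only for that comparison,
   and a directional unit test documents the effect.
3. **The fourth root is the right variance-stabilizer.** $\Delta lnL^{1/4}$
   brings the nonzero scores close to normality and bounds the
   leverage of any single gene; the top-gene-removal pass handles the
   residual outlier risk.

## Score preparation rules

* **Replicate reconciliation.** Optimizers fail to converge; with
  $k \ge 1$ replicate runs per hypothesis the score is
  $2(\max_i \ln L_{H1,i} - \max_i \ln L_{H0,i})$, clamped at zero
  (negative values mean all H1 runs failed). The replicate count is not
  fixed at any particular number — it is an operational detail of the
  compute setup that produced the likelihoods.
* **Duplicate branch labels.** Gene trees may label several nested
  branches identically; the oldest (minimal node depth) is kept. When
  depths tie — a case for which no principled ordering exists — the row
  with the larger score wins, deterministically, with a warning.
* **Missing sequences.** A branch merged with its downstream neighbour
  carries one "average" score for both; that score is copied unweighted
  to every tested branch the merged edge spans. Down-weighting was
  considered and rejected: the score is a likelihood ratio for the whole
  merged path, and halving it would have no likelihood interpretation.
* **Paralogs.** Branches that precede a duplication are reported
  redundantly for each paralog; members of a set sharing an
  `ancestral_group_id` therefore contribute once to SUMSTAT (the group
  maximum, which is a no-op on well-formed inputs where the redundant
  scores are identical). Random null sets apply the same rule, so
  observed and null statistics stay comparable.
* **ID mapping.** Cross-database candidate tables are merged into a
  pair multiset and reduced greedily — per source id keep the
  highest-count target, then per target id the highest-count source —
  giving a one-to-one mapping. Count ties break to the lexically
  smallest candidate: a random choice would be equally defensible
  statistically but would break replay-exactness.

## Set preparation

Sets are restricted to scored genes, sets with fewer than `min_size`
(default 10) members are dropped (the test has little power below
that), and near-identical sets are merged. "Share 95% or more of their
genes" is implemented as the overlap coefficient
$|A \cap B| / \min(|A|,|B|)$ at threshold 0.95, with transitive
(connected-component) closure, because groups of nearly identical sets
should collapse to one union set; both the coefficient (`overlap` vs
`jaccard`) and the threshold are configuration. Merged sets keep the
identity of their largest constituent with the name suffixed `*`.

## The empirical null and the sequential sampler

SUMSTAT significance for a set of size $k$ is the tail probability of
its score among random $k$-subsets of the background, estimated as
$P = (1 + \#\{null \ge obs\}) / (1 + n)$. The pseudo-count keeps P
strictly positive — required by the q-value machinery — and is the only
estimator choice here that never returns zero.

Sampling is sequential: every set first sees a block of 10,000 random
sets; at iteration $i$ only sets with current $P < (1/2)^i$ receive
another block, until nothing continues or a set reaches 1,000,000
samples. Null ensembles are shared between sets of identical size
within a run — draws are i.i.d., so this is statistically identical to
per-set sampling and substantially cheaper; a frozen set keeps the P
value computed from the samples it had seen. A validation test checks
that sequential P values agree with a one-shot full-size null within a
simultaneous three-standard-error Monte-Carlo band.

## Top-gene removal and candidates

Each set is re-tested with its maximum member score removed, against
null sets that each drop their own maximum. A set whose signal is one
extreme gene loses significance here by construction. Candidates for
polygenic selection must reach q < `alpha` (default 0.2, a 20% FDR) in
both passes.

## Multiple testing

Storey q-values with the bootstrap $\pi_0$ estimator over
$\lambda = 0.05, \ldots, 0.95$; `pi0_method = "fixed1"` fixes
$\pi_0 = 1$ and reduces exactly to Benjamini–Hochberg. The per-lambda
estimate uses a +1 pseudo-count, $(W_\lambda + 1)/(m(1-\lambda))$:
on families of ~100 sets the upper tail window can be empty by chance,
and an unregularized estimate of zero would declare everything
significant. At pathway-collection sizes (~1,400 sets) the
regularization is negligible.

## Pruning and the permutation FDR

Pruning repeats: test, record the most significant set (ties at the
Monte-Carlo floor break by higher SUMSTAT, then lexically), delete its
genes from all remaining sets, drop sets under `prune_min_size`
(default 10, consistent with preparation), recompute the background,
repeat until no set remains. P values produced this way are selection-
biased, so FDR is estimated by rerunning the entire pruning on data
whose $\Delta lnL^4$ scores were permuted among in-set genes
(membership fixed), $N = 300$ times by default:
$\widehat{FDR}(P^*) = \pi_0 \hat V(P^*) / R(P^*)$ with $\pi_0 = 1$
(conservative), $\hat V$ the mean *count* of permuted records at or
below $P^*$ — the count interpretation keeps the numerator and the
denominator $R$ in the same units; a `v_scale = "proportion"` switch
provides the per-replicate-proportion reading — and
$q(P^*) = \min_{P \ge P^*} \widehat{FDR}(P)$, clipped at 1. Replicate
pruning runs use a reduced null cap (default 100,000) to bound cost;
the ratio is insensitive to this because observed and permuted records
use the same test configuration. The top-gene-removal pass is applied
to the final pruned candidates only, not inside every pruning
iteration (a configuration flag on the caller's side, since the
records carry all inputs needed to re-run it).

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated:

* **Null scores**: exact zero with probability `zero_prop = 0.72`
  (real branch-site data show 70–75% zeros, well above the asymptotic
  50%), otherwise central $\chi^2_1$.
* **Signal genes** (a `signal_gene_frac` fraction of each planted
  set's members): noncentral $\chi^2_1(\text{ncp})$, not
  zero-inflated — a gene under episodic positive selection produces a
  positive likelihood ratio. At ncp 0 the nonzero score distribution
  collapses onto the null's $\chi^2_1$.
* **Set structure**: sizes uniform on 10–50, consecutive sets sharing
  `overlap_factor = 0.2` of the smaller set (sliding window), which is
  enough redundancy to exercise pruning; at `overlap_factor = 0` sets
  are pairwise disjoint, at $\ge 0.95$ a near-duplicate pair is planted
  for the merge step.
* **Tree bookkeeping**: 3% of genes paired into paralogs sharing an
  ancestral group and score; 5% of rows marked as merged branches.

What the generator does *not* emulate: sequence-length and
branch-length covariates of the score, GC effects, the dependence of
zero-inflation on alignment quality, and the specific nested structure
of real pathway databases. Passing tests therefore demonstrate the
statistical machinery (calibration, power, robustness, determinism) on
data with the right marginal shape, not biological validity on any
particular database release.

## Numerical choices

* `delta_lnl4` is validated against `delta_lnl^(1/4)` at relative
  1e-12.
* Empirical P values are never zero (pseudo-count estimator).
* All character orderings use byte (radix) order, so outputs are
  locale-independent and byte-identical under a fixed seed.
* One master seed; each stage (main pass, no-top pass, each pruning
  iteration, each permutation replicate) derives its own child stream,
  so stages are replay-exact independently of each other.
* Validation problem sizes: universes of 2,000 genes and 100 sets
  (50 for the sequential-vs-one-shot comparison), null blocks of
  2,000–5,000 samples capped at 8,000–50,000, 300 permutation
  replicates in production but 4–30 in the test suite. These sizes give
  Monte-Carlo error well inside every asserted tolerance while keeping
  the suite fast.
* In power studies on overlapping collections, a "false discovery" is
  a candidate set containing *no* injected signal gene: neighbouring
  sets genuinely absorb signal genes through overlap, and calling them
  false would conflate the generator's overlap design with a failure of
  the test.

## Known limitations

* The test is blind to selection signals that express as many exact
  zeros (e.g. purifying-selection shifts); it is one-sided toward high
  scores.
* Permutation FDR assumes score exchangeability among in-set genes
  under the null; gene-level covariates (length, tree size) that
  correlate with scores would violate this and are not modelled.
* The bootstrap $\pi_0$ is unstable below a few dozen sets; for very
  small collections use `pi0_method = "fixed1"`.
* Pruning is greedy: a set pruned early absorbs shared genes entirely,
  and no credit assignment between overlapping winners is attempted.
```{r session}
sessionInfo()
```
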