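# selsum

Gene set enrichment for **polygenic positive selection** on ancestral
phylogenetic branches.

Branch-site codon-model tests score individual genes for episodic
positive selection, but have low power on short internal branches: very
few genes survive genome-wide multiple-testing correction. `selsum`
aggregates the per-gene evidence over biological pathways, so that many
genes with weak-to-moderate signals can jointly reveal selection on a
function even when no single gene is significant. It is aimed at
molecular evolution researchers who have per-gene, per-branch
likelihood-ratio results (e.g. from codeml-style branch-site tests) and
a pathway collection in GMT format.

## The statistic

For gene `g` on a tested branch, with replicate maximum-likelihood runs
of the branch-site models H1 (positive selection allowed) and H0 (not
allowed):

    ΔlnL_g = 2 ( max_i lnL_H1,i − max_i lnL_H0,i ),   clamped at 0

Negative values indicate optimizer non-convergence and are set to zero.
The per-gene selection score is the fourth root, `ΔlnL4_g`, which
approximately normalizes the nonzero scores and damps outliers. A gene
set `s` is scored by

    SUMSTAT_s = Σ_{g ∈ s} ΔlnL4_g

with paralogs that share a pre-duplication ancestral branch counted
once. Significance comes from an empirical null of random same-size
gene sets drawn from the genes belonging to at least one set (in-set
genes are systematically more conserved, so an all-genes null would be
miscalibrated). The null is grown by sequential Monte-Carlo sampling —
blocks of 10,000 random sets, continuing at iteration *i* only for sets
with P < (1/2)^i, up to 1,000,000 — so precision is spent where it
matters. Robustness and multiplicity handling:

* **top-gene-removal pass** — each set (and each null set) is re-scored
  after dropping its maximum-scoring gene; sets driven by a single
  outlier lose significance. Candidates must score q < 0.2 in both
  passes (Storey q-values, bootstrap π0).
* **pruning** — overlapping collections are decomposed by iteratively
  removing the most significant set's genes from all others and
  re-testing; the FDR of the pruned records is estimated empirically
  from whole-pipeline reruns on score-permuted data,
  FDR(P*) = π0·V̂(P*)/R(P*) with π0 = 1.

A synthetic-data generator produces score tables with the observed
statistical shape (≈72% exact zeros, χ²(1) tails, optional noncentral
χ²(1) signal genes, paralog pairs, merged branches) and overlapping set
collections with known ground truth.

## Worked example

```r
library(selsum)

cfg <- sim_config(n_genes = 2000, n_sets = 60, signal_sets = 3,
                  signal_gene_frac = 0.3, signal_ncp = 8, seed = 11)
u <- simulate_universe(cfg)

sets <- filter_min_size(restrict_to_scored(u$collection, u$table), 10)
fit <- sumstat_test(sets, u$table, block = 5000, max_n = 50000, seed = 7)
summary(fit)
```

```
SUMSTAT enrichment test
  sets tested:      60
  background genes: 1150
  candidates (q < 0.2, both passes): 7

Top sets:
 set_id  name size sumstat n_null p_value q_value sumstat_notop p_notop
  s0006 s0006   47   34.81  50000 0.00002 0.00020         32.75 0.00002
  s0017 s0017   42   31.05  50000 0.00002 0.00020         28.80 0.00002
  s0056 s0056   30   21.57  50000 0.00006 0.00040         19.16 0.00010
  s0048 s0048   29   15.29  35000 0.01380 0.06900         13.19 0.01600
  ...
```

The three planted signal sets (`s0006`, `s0017`, `s0056`) head the
table: their SUMSTAT beat all (or nearly all) of 50,000 random
same-size sets (`p_value` = 1/50001 is the Monte-Carlo floor), and they
stay significant after their top gene is removed (`q_notop`), so they
are flagged `is_candidate`. Sets further down reach q < 0.2 because
they absorbed signal genes through overlap; pruning separates those:

```r
pruned <- permutation_fdr(sets, u$table, n_perm = 300, seed = 7)
summary(pruned)
```

which reports, per pruning iteration, the winning set with its
post-pruning SUMSTAT, size, P value and empirical FDR q.

Real data enter through `read_likelihood_table()` +
`prepare_scores()` (replicate reconciliation, oldest-branch resolution
of duplicate labels, merged-branch propagation), `read_gmt()`, and
optionally `map_ids()` for cross-database gene identifiers; the
`run_prepare()` / `run_test()` / `run_prune()` functions (or the
`inst/cli/selsum` script) orchestrate the same steps around on-disk
TSV/GMT artifacts.

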