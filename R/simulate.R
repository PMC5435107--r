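#' Configuration for the synthetic score/set generator
#'
#' The generator emulates the statistical shape of branch-site test
#' results: per-gene \eqn{\Delta lnL} scores that are an exact zero with
#' probability \code{zero_prop} (real branches show 70-75% zeros, well
#' above the 50% asymptotic expectation) and otherwise follow a
#' chi-square(1) right tail; overlapping gene-set structure with a
#' sliding-window sharing scheme; and tree bookkeeping (paralog pairs
#' sharing an ancestral group, merged-branch spans). Genes under positive
#' selection draw their nonzero part from a noncentral chi-square(1),
#' whose ncp -> 0 limit recovers the null.
#'
#' @param n_genes genes in the pool.
#' @param n_sets gene sets.
#' @param set_size_range integer pair, sizes drawn uniformly in range.
#' @param overlap_factor expected shared-gene proportion (of the smaller
#'   set) between neighboring sets; at >= 0.95 a near-duplicate pair is
#'   planted to exercise [merge_similar()].
#' @param zero_prop probability of an exact-zero score (default 0.72).
#' @param signal_sets number of sets carrying injected signal.
#' @param signal_gene_frac fraction of each signal set's members that are
#'   signal genes.
#' @param signal_ncp noncentrality of the signal genes' chi-square(1).
#' @param dup_frac fraction of genes given a paralog partner sharing an
#'   ancestral group (and score), emulating pre-duplication branches.
#' @param missing_frac fraction of scores marked as covering two tested
#'   branches (merged edge after a missing sequence).
#' @param branches two branch labels; scores are generated for the first,
#'   merged spans cover both.
#' @param seed master integer seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000L, n_sets = 100L,
                       set_size_range = c(10L, 50L),
                       overlap_factor = 0.2, zero_prop = 0.72,
                       signal_sets = 0L, signal_gene_frac = 0.3,
                       signal_ncp = 8, dup_frac = 0.03,
                       missing_frac = 0.05,
                       branches = c("branch1", "branch2"), seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
              set_size_range = as.integer(set_size_range),
              overlap_factor = overlap_factor, zero_prop = zero_prop,
              signal_sets = as.integer(signal_sets),
              signal_gene_frac = signal_gene_frac,
              signal_ncp = signal_ncp, dup_frac = dup_frac,
              missing_frac = missing_frac, branches = branches,
              seed = as.integer(seed))
  fr <- c(cfg$overlap_factor, cfg$zero_prop, cfg$signal_gene_frac,
          cfg$dup_frac, cfg$missing_frac)
  stopifnot(all(fr >= 0 & fr <= 1), cfg$signal_sets <= cfg$n_sets,
            cfg$signal_ncp >= 0, length(cfg$set_size_range) == 2L,
            cfg$set_size_range[1L] >= 1L,
              cfg$set_size_range[2L] <= cfg$n_genes,
            length(cfg$branches) == 2L)
  class(cfg) <- "sim_config"
  cfg
}

gene_pool <- function(config) sprintf("g%05d", seq_len(config$n_genes))

#' Simulate an overlapping gene set collection
#'
#' Set sizes are uniform in \code{set_size_range}. Consecutive sets share
#' approximately \code{overlap_factor} of the smaller set's genes
#' (sliding-window scheme), emulating the redundancy of aggregated
#' pathway databases. When \code{overlap_factor >= 0.95} the last set is
#' replaced by a near-duplicate of the first so that [merge_similar()]
#' has something to collapse.
#'
#' @param config a [sim_config()].
#' @return a [gene_set_collection()].
#' @export
simulate_sets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 11L))
  pool <- gene_pool(config)
  szr <- config$set_size_range
  sets <- vector("list", config$n_sets)
  prev <- character(0)
  used <- character(0)
  for (i in seq_len(config$n_sets)) {
    sz <- if (szr[1L] == szr[2L]) szr[1L] else
      sample(seq(szr[1L], szr[2L]), 1L)
    k <- if (i == 1L) 0L else
      min(round(config$overlap_factor * min(sz, length(prev))), sz)
    shared <- if (k > 0L) sample(prev, k) else character(0)
    # at overlap 0 the sets are pairwise disjoint; otherwise only the
    # previous set is excluded so older sets can overlap by chance
    excl <- if (config$overlap_factor == 0) used else union(prev, shared)
    avail <- setdiff(pool, excl)
    if (length(avail) < sz - k)
      stop("gene pool too small for disjoint sets of this size")
    fresh <- sample(avail, sz - k)
    sets[[i]] <- c(shared, fresh)
    prev <- sets[[i]]
    used <- union(used, prev)
  }
  names(sets) <- sprintf("s%04d", seq_len(config$n_sets))
  if (config$overlap_factor >= 0.95 && config$n_sets >= 2L &&
      length(sets[[1L]]) >= 2L) {
    dup <- sets[[1L]][-1L]  # overlap coefficient with set 1 is exactly 1
    sets[[config$n_sets]] <- dup
  }
  gene_set_collection(sets)
}

#' Simulate a score table with known truth
#'
#' Null genes draw \eqn{\Delta lnL = 0} with probability
#' \code{zero_prop}, otherwise a central chi-square(1) value. Signal
#' genes (a \code{signal_gene_frac} fraction of each signal set's
#' members) draw from a noncentral chi-square(1) with ncp
#' \code{signal_ncp} and are not zero-inflated: a gene under episodic
#' positive selection yields a positive likelihood-ratio statistic. At
#' \code{signal_ncp = 0} the nonzero score distribution coincides with
#' the null's chi-square(1).
#'
#' @param config a [sim_config()].
#' @param collection the set collection signal sets are drawn from;
#'   defaults to [simulate_sets()] under the same config.
#' @return list with \code{table} (a [score_table()] for the first
#'   configured branch) and \code{truth} (list: signal_set_ids,
#'   signal_gene_ids, config).
#' @export
simulate_scores <- function(config, collection = simulate_sets(config)) {
  stopifnot(inherits(config, "sim_config"))
  pool <- gene_pool(config)
  set.seed(derive_seed(config$seed, 12L))
  signal_set_ids <- if (config$signal_sets > 0L)
    sort(sample(names(collection$sets), config$signal_sets),
         method = "radix") else character(0)
  signal_gene_ids <- character(0)
  for (sid in signal_set_ids) {
    m <- collection$sets[[sid]]
    n_sig <- max(1L, round(config$signal_gene_frac * length(m)))
    signal_gene_ids <- union(signal_gene_ids, sample(m, n_sig))
  }
  signal_gene_ids <- sort(signal_gene_ids, method = "radix")

  set.seed(derive_seed(config$seed, 13L))
  n <- config$n_genes
  nonzero <- stats::rbinom(n, 1L, 1 - config$zero_prop) == 1L
  d <- numeric(n)
  is_sig <- pool %in% signal_gene_ids
  d[nonzero & !is_sig] <- stats::rchisq(sum(nonzero & !is_sig), df = 1)
  d[is_sig] <- stats::rchisq(sum(is_sig), df = 1, ncp = config$signal_ncp)
  tab <- data.frame(gene_id = pool, delta_lnl = d, delta_lnl4 = d^0.25,
                    tree_id = paste0("t_", pool),
                    ancestral_group_id = NA_character_,
                    was_clamped = FALSE, stringsAsFactors = FALSE)
  list(table = score_table(tab, config$branches[1L]),
       truth = list(signal_set_ids = signal_set_ids,
                    signal_gene_ids = signal_gene_ids,
                    config = config))
}

#' Overlay tree bookkeeping on a simulated score table
#'
#' Emits the raw per-branch likelihood-table dialect consumed by
#' [prepare_scores()], with two structures overlaid: \code{dup_frac} of
#' the genes are paired into paralog partners sharing an
#' \code{ancestral_group_id} and the (redundant, pre-duplication) score
#' of the first partner; \code{missing_frac} of the rows get a
#' \code{merged_span} covering both configured branches, emulating a
#' branch merged with its downstream neighbor after a missing sequence.
#' Genes listed in \code{protect} (e.g. signal genes) are never selected
#' as the score-overwritten second partner.
#'
#' @param table a [score_table()].
#' @param config a [sim_config()].
#' @param protect gene ids whose scores must not be overwritten.
#' @return data.frame in the raw likelihood-table format (columns
#'   gene_id, branch, tree_id, node_depth, ancestral_group_id,
#'   merged_span, delta_lnl).
#' @export
inject_tree_structure <- function(table, config, protect = character(0)) {
  stopifnot(inherits(table, "score_table"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 14L))
  raw <- data.frame(gene_id = table$gene_id,
                    branch = attr(table, "branch"),
                    tree_id = table$tree_id,
                    node_depth = 1L,
                    ancestral_group_id = table$ancestral_group_id,
                    merged_span = NA_character_,
                    delta_lnl = table$delta_lnl,
                    stringsAsFactors = FALSE)
  n <- nrow(raw)
  n_dup <- 2L * (round(config$dup_frac * n) %/% 2L)
  if (n_dup >= 2L) {
    eligible <- which(!(raw$gene_id %in% protect))
    n_dup <- min(n_dup, 2L * (length(eligible) %/% 2L))
    picked <- sample(eligible, n_dup)
    first <- picked[seq(1L, n_dup, by = 2L)]
    second <- picked[seq(2L, n_dup, by = 2L)]
    gid <- sprintf("ag%04d", seq_along(first))
    raw$ancestral_group_id[first] <- gid
    raw$ancestral_group_id[second] <- gid
    raw$delta_lnl[second] <- raw$delta_lnl[first]
    raw$tree_id[second] <- raw$tree_id[first]
  }
  n_miss <- round(config$missing_frac * n)
  if (n_miss > 0L) {
    span <- paste(config$branches, collapse = ",")
    raw$merged_span[sample(n, n_miss)] <- span
  }
  raw
}

#' Simulate a complete synthetic universe
#'
#' Orchestrates [simulate_sets()], [simulate_scores()] and
#' [inject_tree_structure()], then runs the raw table through
#' [prepare_scores()] so that the returned score table has passed the
#' same preparation path as real data.
#'
#' @param config a [sim_config()].
#' @return list with \code{raw} (likelihood-table data.frame),
#'   \code{table} (prepared [score_table()] for the first branch),
#'   \code{collection} (a [gene_set_collection()]), \code{truth}.
#' @export
simulate_universe <- function(config) {
  collection <- simulate_sets(config)
  sc <- simulate_scores(config, collection)
  raw <- inject_tree_structure(sc$table, config,
                               protect = sc$truth$signal_gene_ids)
  tables <- prepare_scores(raw, branches = config$branches)
  list(raw = raw, table = tables[[config$branches[1L]]],
       collection = collection, truth = sc$truth)
}
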