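#' SUMSTAT score of a gene set
#'
#' Sum of the members' fourth-root selection scores:
#' \deqn{SUMSTAT_s = \sum_{g \in s} \Delta lnL^4_g}
#' Paralogous members that descend from the same duplication carry a
#' shared \code{ancestral_group_id}; on branches preceding the
#' duplication their (redundant) score contributes exactly once.
#'
#' @param members character vector of member gene ids; all must be
#'   present in \code{table}.
#' @param table a [score_table()].
#' @return nonnegative SUMSTAT value.
#' @export
sumstat <- function(members, table) {
  i <- match(unique(members), table$gene_id)
  if (anyNA(i))
    stop("set member(s) absent from the score table: ",
         paste(utils::head(setdiff(members, table$gene_id), 5L),
               collapse = ", "))
  sum(dedup_scores(table$delta_lnl4[i], table$ancestral_group_id[i]))
}

# Statistic of a drawn/observed member index vector.
# drop_top: remove the single highest score after group de-duplication
# (top-gene-removal robustness pass).
set_stat <- function(idx, scores, groups, drop_top = FALSE) {
  s <- dedup_scores(scores[idx], if (is.null(groups)) NULL else groups[idx])
  if (drop_top) sum(s) - max(s) else sum(s)
}

# m random sets of size k from the background (without replacement inside
# a set), returning the SUMSTAT-type statistic of each. Fast path when no
# ancestral groups exist in the background.
draw_stats <- function(m, k, scores, groups, drop_top = FALSE) {
  B <- length(scores)
  has_groups <- !is.null(groups) && any(!is.na(groups) & nzchar(groups))
  if (!has_groups) {
    idx <- vapply(seq_len(m), function(i) sample.int(B, k), integer(k))
    sm <- matrix(scores[idx], nrow = k)
    tot <- colSums(sm)
    if (!drop_top) return(tot)
    tm <- t(sm)
    mx <- tm[cbind(seq_len(m), max.col(tm, ties.method = "first"))]
    return(tot - mx)
  }
  out <- numeric(m)
  for (j in seq_len(m))
    out[j] <- set_stat(sample.int(B, k), scores, groups, drop_top)
  out
}

#' Null ensemble of random same-size gene sets
#'
#' Draws \code{n} random sets of \code{set_size} distinct genes uniformly
#' from the background and computes their SUMSTAT (with the same
#' ancestral-group de-duplication as the observed statistic). The
#' background is, by default, every scored gene belonging to at least one
#' set: genes inside sets are systematically more conserved than genes
#' outside any set, so an all-genes background would overstate
#' significance.
#'
#' @param set_size number of genes per random set.
#' @param n number of random sets.
#' @param table a [score_table()].
#' @param background character vector of gene ids to sample from; must
#'   all be present in \code{table}.
#' @param seed integer seed (NULL = use current RNG state).
#' @param drop_top if TRUE each random set drops its own maximum score
#'   before summing (null for the top-gene-removal pass).
#' @return list with \code{set_size}, \code{samples}, \code{n_samples},
#'   \code{seed}.
#' @export
draw_null <- function(set_size, n, table, background = table$gene_id,
                      seed = NULL, drop_top = FALSE) {
  i <- match(unique(background), table$gene_id)
  if (anyNA(i)) stop("background gene(s) absent from the score table")
  if (set_size > length(i))
    stop("set_size (", set_size, ") exceeds background size (",
         length(i), ")")
  if (!is.null(seed)) set.seed(seed)
  samples <- draw_stats(n, set_size, table$delta_lnl4[i],
                        table$ancestral_group_id[i], drop_top = drop_top)
  list(set_size = set_size, samples = samples, n_samples = n, seed = seed)
}

#' Empirical P value against a null ensemble
#'
#' \eqn{P = (1 + \#\{null \ge observed\}) / (1 + n)}. The pseudo-count
#' keeps P strictly positive, which downstream q-value estimation
#' requires.
#'
#' @param observed observed statistic.
#' @param ensemble numeric vector of null samples, or a list with a
#'   \code{samples} element as returned by [draw_null()].
#' @return P value in (0, 1].
#' @export
empirical_p <- function(observed, ensemble) {
  samples <- if (is.list(ensemble)) ensemble$samples else ensemble
  n <- length(samples)
  if (n == 0L) stop("empty null ensemble")
  (1 + sum(samples >= observed)) / (1 + n)
}

# Sequential Monte-Carlo empirical null engine.
#
# Every set is first tested against `block` random sets. At iteration i
# (i = 1, 2, ...) only sets whose current P value is below (1/2)^i receive
# another `block` samples, until no set continues or a set's total reaches
# max_n. Null ensembles are shared between sets of identical size (draws
# are i.i.d., so this is statistically identical to per-set sampling);
# a frozen set keeps the P value computed from the samples it had seen.
#
# obs: observed statistics; sizes: set sizes; bg_scores/bg_groups:
# background score and ancestral-group vectors.
# Returns list(p, n_used).
seq_engine <- function(obs, sizes, bg_scores, bg_groups,
                       block = 10000L, max_n = 1000000L,
                       seed = NULL, drop_top = FALSE) {
  stopifnot(length(obs) == length(sizes), block >= 1L, max_n >= block)
  if (!is.null(seed)) set.seed(seed)
  usz <- sort(unique(sizes))
  ens <- vector("list", length(usz))
  names(ens) <- as.character(usz)
  for (s in usz)
    ens[[as.character(s)]] <- draw_stats(block, s, bg_scores, bg_groups,
                                         drop_top)
  n_used <- rep(block, length(obs))
  p <- vapply(seq_along(obs), function(j)
    empirical_p(obs[j], ens[[as.character(sizes[j])]]), numeric(1L))
  i <- 1L
  repeat {
    active <- p < 0.5^i & n_used < max_n
    if (!any(active)) break
    for (s in unique(sizes[active])) {
      key <- as.character(s)
      have <- length(ens[[key]])
      need <- min(max(n_used[active & sizes == s]) + block, max_n)
      if (need > have)
        ens[[key]] <- c(ens[[key]],
                        draw_stats(need - have, s, bg_scores, bg_groups,
                                   drop_top))
    }
    for (j in which(active)) {
      n_used[j] <- min(n_used[j] + block, max_n)
      p[j] <- empirical_p(obs[j],
                          ens[[as.character(sizes[j])]][seq_len(n_used[j])])
    }
    i <- i + 1L
  }
  list(p = p, n_used = n_used)
}

#' Sequentially sampled empirical P values for a collection
#'
#' Runs the sequential Monte-Carlo null on every set of a collection:
#' all sets are first compared with \code{block} random same-size sets;
#' at iteration i only sets with current P < (1/2)^i are extended by
#' another \code{block} samples, up to \code{max_n} per set. This spends
#' the large nulls only on promising sets, while final P values agree
#' with a one-shot null of the same total size to Monte-Carlo error.
#'
#' @param collection a \code{gene_set_collection}; all members must be
#'   scored.
#' @param table a [score_table()].
#' @param background background gene ids (default: the collection's
#'   in-set background).
#' @param block samples added per iteration (default 10000).
#' @param max_n per-set sample cap (default 1e6).
#' @param seed integer seed.
#' @param drop_top compute the top-gene-removal variant of the statistic
#'   (observed and null sets drop their maximum member score).
#' @return data.frame: set_id, size, sumstat, n_null, p_value.
#' @export
sequential_test <- function(collection, table,
                            background = set_background(collection),
                            block = 10000L, max_n = 1000000L,
                            seed = NULL, drop_top = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sizes <- lengths(collection$sets)
  if (drop_top && any(sizes < 2L))
    stop("top-gene removal needs sets of size >= 2")
  i <- match(unique(background), table$gene_id)
  if (anyNA(i)) stop("background gene(s) absent from the score table")
  bg_scores <- table$delta_lnl4[i]
  bg_groups <- table$ancestral_group_id[i]
  obs <- vapply(collection$sets, function(m) {
    mi <- match(m, table$gene_id)
    if (anyNA(mi)) stop("set member(s) absent from the score table")
    set_stat(mi, table$delta_lnl4, table$ancestral_group_id, drop_top)
  }, numeric(1L))
  res <- seq_engine(unname(obs), unname(sizes), bg_scores, bg_groups,
                    block = block, max_n = max_n, seed = seed,
                    drop_top = drop_top)
  data.frame(set_id = collection$info$set_id,
             size = unname(sizes),
             sumstat = unname(obs),
             n_null = res$n_used,
             p_value = res$p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the proportion of true nulls
#' \eqn{\pi_0} estimated by the bootstrap method over the grid
#' \eqn{\lambda = 0.05, 0.10, \ldots, 0.95}:
#' \eqn{q_i = \min_{P_j \ge P_i} \pi_0 m P_j / rank(P_j)}, clipped at 1.
#' With \code{pi0_method = "fixed1"} (\eqn{\pi_0 = 1}) this reduces to
#' Benjamini-Hochberg adjusted P values.
#'
#' @param p P values in (0, 1].
#' @param pi0_method \code{"bootstrap"} (default) or \code{"fixed1"}.
#' @param lambda grid for the pi0 estimate.
#' @return q-values, same length/order as \code{p}.
#' @export
qvalues <- function(p, pi0_method = c("bootstrap", "fixed1"),
                    lambda = seq(0.05, 0.95, 0.05)) {
  pi0_method <- match.arg(pi0_method)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p values must lie in (0, 1]")
  pi0 <- if (pi0_method == "fixed1") 1 else estimate_pi0(p, lambda)
  o <- order(p, decreasing = TRUE)
  qo <- pmin(1, cummin(pi0 * m * p[o] / seq(m, 1L)))
  q <- numeric(m)
  q[o] <- qo
  q
}

# Bootstrap pi0 estimator (Storey, Taylor & Siegmund 2004): candidate
# pi0(lambda) = #{p >= lambda} / (m (1 - lambda)); pick the lambda whose
# bootstrap MSE against min pi0 is smallest (closed form). The +1
# pseudo-count keeps the estimate strictly positive: on small families a
# tail window can be empty by chance, and a pi0 of zero would declare
# every hypothesis significant. The regularization is negligible at the
# family sizes pathway collections have.
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  m <- length(p)
  W <- vapply(lambda, function(l) sum(p >= l), numeric(1L))
  pi0l <- (W + 1) / (m * (1 - lambda))
  minpi0 <- min(pi0l)
  mse <- (W / (m^2 * (1 - lambda)^2)) * (1 - W / m) + (pi0l - minpi0)^2
  pi0 <- min(pi0l[mse == min(mse)])
  min(pi0, 1)
}

#' Monte-Carlo P value under the parametric zero-inflated chi-square null
#'
#' Asymptotic theory puts the branch-site lnL ratio, under the null, at a
#' mixture of 50% zeros and 50% chi-square with one degree of freedom; in
#' real data the zero fraction is substantially larger (around 70-75%).
#' This samples set-level sums of fourth-root scores under the mixture
#' (gene score = 0 with probability \code{zero_prop}, else a chi-square(1)
#' draw to the power 1/4) for comparison with the empirical null; the main
#' pipeline does not use it.
#'
#' @param observed observed SUMSTAT.
#' @param set_size genes per set.
#' @param zero_prop probability of an exact-zero gene score.
#' @param n_mc Monte-Carlo replicates.
#' @param seed integer seed.
#' @return P value in (0, 1].
#' @export
parametric_null_p <- function(observed, set_size, zero_prop = 0.5,
                              n_mc = 10000L, seed = NULL) {
  stopifnot(zero_prop >= 0, zero_prop <= 1, set_size >= 1L, n_mc >= 1L)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rchisq(set_size * n_mc, df = 1)^0.25
  nz <- stats::rbinom(set_size * n_mc, 1L, prob = 1 - zero_prop)
  sums <- colSums(matrix(x * nz, nrow = set_size))
  empirical_p(observed, sums)
}
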