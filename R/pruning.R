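#' Iterative pruning of overlapping gene sets
#'
#' Pathway collections are redundant: overlapping sets become significant
#' together because they share high-scoring genes. Pruning decomposes the
#' collection into independent signals: the enrichment test is run, the
#' most significant set is recorded and its genes are removed from every
#' remaining set, sets falling below \code{min_size} are dropped, the
#' background is recomputed, and the procedure repeats until no set is
#' left. Ties on the lowest P value (common at the Monte-Carlo floor) go
#' to the higher SUMSTAT, then to the lexically smallest set id.
#'
#' @param collection a [gene_set_collection()], members all scored.
#' @param table a [score_table()].
#' @param min_size sets shrinking below this size are dropped (default
#'   10, matching the preparation filter).
#' @param block,max_n sequential null parameters, see [sequential_test()].
#' @param seed master integer seed; each iteration derives its own
#'   stream.
#' @return data.frame of pruning records: iteration, set_id, name,
#'   size_pre, sumstat_pre, size_post, sumstat_post, n_null, p_post.
#' @export
prune_sets <- function(collection, table, min_size = 10L,
                       block = 10000L, max_n = 1000000L, seed = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  pre_sizes <- lengths(collection$sets)
  pre_sum <- vapply(collection$sets, sumstat, numeric(1L), table = table)
  names(pre_sizes) <- names(pre_sum) <- collection$info$set_id
  cur <- collection
  records <- list()
  iter <- 0L
  while (length(cur$sets) > 0L) {
    iter <- iter + 1L
    st <- sequential_test(cur, table,
                          background = intersect(set_background(cur),
                                                 table$gene_id),
                          block = block, max_n = max_n,
                          seed = if (is.null(seed)) NULL
                                 else derive_seed(seed, 100L + iter))
    win <- st[order(st$p_value, -st$sumstat, st$set_id,
                    method = "radix"), , drop = FALSE][1L, ]
    records[[iter]] <- data.frame(
      iteration = iter,
      set_id = win$set_id,
      name = cur$info$name[match(win$set_id, cur$info$set_id)],
      size_pre = unname(pre_sizes[win$set_id]),
      sumstat_pre = unname(pre_sum[win$set_id]),
      size_post = win$size,
      sumstat_post = win$sumstat,
      n_null = win$n_null,
      p_post = win$p_value,
      stringsAsFactors = FALSE)
    winners_genes <- cur$sets[[win$set_id]]
    keep <- setdiff(names(cur$sets), win$set_id)
    sets <- lapply(cur$sets[keep], function(m) setdiff(m, winners_genes))
    big <- lengths(sets) >= min_size
    if (!any(big)) break
    cur <- gene_set_collection(sets[big],
                               cur$info[match(names(sets)[big],
                                              cur$info$set_id), ,
                                        drop = FALSE])
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Empirical FDR for pruned results by whole-pipeline permutation
#'
#' P values produced inside the pruning loop are not independent and are
#' biased low (only high-scoring residual sets survive), so their FDR is
#' estimated empirically: the \eqn{\Delta lnL^4} scores are permuted among
#' the genes belonging to at least one set (set membership fixed), the
#' full pruning procedure is rerun on each of \code{n_perm} permuted data
#' sets, and for each observed P value threshold \eqn{P^*}
#' \deqn{\widehat{FDR}(P^*) = \pi_0 \hat V(P^*) / R(P^*)}
#' where \eqn{\hat V} is the mean number of pruning records with
#' \eqn{P \le P^*} across permutation replicates, \eqn{R} the observed
#' count, and \eqn{\pi_0 = 1} conservatively. The q-value at \eqn{P^*} is
#' the minimum estimated FDR over all observed \eqn{P \ge P^*}.
#'
#' @param collection,table,min_size,block,max_n as in [prune_sets()];
#'   \code{max_n} defaults lower here (1e5) to bound the cost of the
#'   replicate pruning runs — the FDR ratio is robust to this because
#'   observed and permuted P values use the same test configuration.
#' @param records observed pruning records from [prune_sets()] run with
#'   the same configuration; if NULL they are computed.
#' @param n_perm number of permutation replicates (default 300).
#' @param v_scale \code{"count"} (default): \eqn{\hat V} is the mean
#'   number of sub-threshold records per replicate; \code{"proportion"}:
#'   mean per-replicate proportion rescaled by the observed record count.
#' @param seed master integer seed.
#' @return object of class \code{sumstat_prune}: list with
#'   \code{records} (observed records plus \code{fdr_q}), \code{fdr}
#'   (grid of FdrEstimate rows: p_star, V_hat, R, pi0, fdr, q),
#'   \code{n_perm}.
#' @export
permutation_fdr <- function(collection, table, records = NULL,
                            n_perm = 300L, min_size = 10L,
                            block = 10000L, max_n = 100000L,
                            v_scale = c("count", "proportion"),
                            seed = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"), n_perm >= 1L)
  v_scale <- match.arg(v_scale)
  if (is.null(records))
    records <- prune_sets(collection, table, min_size = min_size,
                          block = block, max_n = max_n,
                          seed = if (is.null(seed)) NULL
                                 else derive_seed(seed, 7L))
  bg <- intersect(set_background(collection), table$gene_id)
  bi <- match(bg, table$gene_id)
  perm_p <- vector("list", n_perm)
  for (r in seq_len(n_perm)) {
    rs <- if (is.null(seed)) NULL else derive_seed(seed, 1000L + r)
    if (!is.null(rs)) set.seed(rs)
    perm <- table
    sh <- sample(length(bi))
    perm$delta_lnl4[bi] <- table$delta_lnl4[bi][sh]
    perm$delta_lnl[bi] <- table$delta_lnl[bi][sh]
    pr <- prune_sets(collection, perm, min_size = min_size,
                     block = block, max_n = max_n,
                     seed = if (is.null(rs)) NULL
                            else derive_seed(rs, 8L))
    perm_p[[r]] <- if (is.null(pr)) numeric(0) else pr$p_post
  }
  fdr <- fdr_from_permutations(records$p_post, perm_p, pi0 = 1,
                               v_scale = v_scale)
  records$fdr_q <- fdr$q[match(records$p_post, fdr$p_star)]
  structure(list(records = records, fdr = fdr, n_perm = n_perm,
                 v_scale = v_scale),
            class = "sumstat_prune")
}

#' Empirical FDR and q-values from permutation-replicate P values
#'
#' The estimator behind [permutation_fdr()], exposed for reuse and
#' testing: given the observed pruning P values and the per-replicate
#' lists of permuted-data P values, computes, at every observed threshold
#' \eqn{P^*}, \eqn{\hat V(P^*)} (mean sub-threshold count per replicate),
#' \eqn{R(P^*)} (observed sub-threshold count),
#' \eqn{FDR = \pi_0 \hat V / R}, and the min-smoothed q-value.
#'
#' @param observed_p observed P values.
#' @param perm_p list of numeric vectors, one per permutation replicate.
#' @param pi0 proportion of true nulls; conservatively 1.
#' @param v_scale see [permutation_fdr()].
#' @return data.frame: p_star (sorted unique observed P), V_hat, R, pi0,
#'   fdr, q (q clipped at 1, nonincreasing in decreasing p_star).
#' @export
fdr_from_permutations <- function(observed_p, perm_p, pi0 = 1,
                                  v_scale = c("count", "proportion")) {
  v_scale <- match.arg(v_scale)
  stopifnot(length(observed_p) > 0L, is.list(perm_p), length(perm_p) >= 1L)
  p_star <- sort(unique(observed_p))
  R <- vapply(p_star, function(ps) sum(observed_p <= ps), numeric(1L))
  counts <- vapply(p_star, function(ps)
    mean(vapply(perm_p, function(pp) sum(pp <= ps), numeric(1L))),
    numeric(1L))
  V <- if (v_scale == "count") counts else {
    prop <- vapply(p_star, function(ps)
      mean(vapply(perm_p, function(pp)
        if (length(pp)) sum(pp <= ps) / length(pp) else 0, numeric(1L))),
      numeric(1L))
    prop * length(observed_p)
  }
  fdr <- pi0 * V / R
  q <- pmin(rev(cummin(rev(fdr))), 1)
  data.frame(p_star = p_star, V_hat = V, R = R, pi0 = pi0,
             fdr = fdr, q = q, row.names = NULL)
}

#' @export
print.sumstat_prune <- function(x, ...) {
  cat("Pruned SUMSTAT enrichment (", nrow(x$records), " iterations, ",
      x$n_perm, " permutation replicates)\n", sep = "")
  r <- x$records
  r$sumstat_post <- round(r$sumstat_post, 2)
  r$sumstat_pre <- round(r$sumstat_pre, 2)
  print.data.frame(utils::head(
    r[, c("iteration", "set_id", "name", "sumstat_post", "size_post",
          "p_post", "fdr_q")], 12L), row.names = FALSE, digits = 4)
  if (nrow(r) > 12L) cat("... (", nrow(r) - 12L, " more)\n", sep = "")
  invisible(x)
}

#' @export
summary.sumstat_prune <- function(object, alpha = 0.2, ...) {
  print(object)
  cat("\nRecords with FDR q < ", alpha, ": ",
      sum(object$records$fdr_q < alpha, na.rm = TRUE), "\n", sep = "")
  invisible(object)
}
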