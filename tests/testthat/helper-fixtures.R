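# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Score table from a named vector of delta_lnl values (names = gene ids);
# optional named ancestral group assignment.
toy_table <- function(delta_lnl, groups = NULL, branch = "b1") {
  ids <- names(delta_lnl)
  stopifnot(!is.null(ids))
  g <- rep(NA_character_, length(ids))
  if (!is.null(groups)) g[match(names(groups), ids)] <- unname(groups)
  score_table(data.frame(gene_id = ids,
                         delta_lnl = unname(delta_lnl),
                         delta_lnl4 = unname(delta_lnl)^0.25,
                         tree_id = paste0("t", seq_along(ids)),
                         ancestral_group_id = g,
                         was_clamped = FALSE,
                         stringsAsFactors = FALSE),
              branch)
}

# Zero-inflated chi-square background table: n genes, P(zero) = zero_prop.
random_table <- function(n, zero_prop = 0.72, seed = NULL,
                         branch = "b1") {
  if (!is.null(seed)) set.seed(seed)
  d <- ifelse(stats::runif(n) < zero_prop, 0, stats::rchisq(n, 1))
  names(d) <- sprintf("g%05d", seq_len(n))
  toy_table(d, branch = branch)
}

# Collection from a plain named list of member vectors.
toy_collection <- function(sets) gene_set_collection(sets)

# Independent connected-components oracle (no igraph): repeated
# neighborhood expansion over an adjacency matrix.
brute_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any))
      nb <- nb[is.na(comp[nb])]
      comp[nb] <- cid
      frontier <- nb
    }
  }
  comp
}

# Independent two-sided Fisher oracle: enumeration of the hypergeometric
# support, same relative-error tie rule as stats::fisher.test.
fisher_oracle <- function(a, b, c_, d) {
  K <- a + b; n <- a + c_; N <- a + b + c_ + d
  lo <- max(0L, K + n - N); hi <- min(K, n)
  supp <- lo:hi
  dens <- stats::dhyper(supp, n, N - n, K)
  sum(dens[dens <= dens[supp == a] * (1 + 1e-7)])
}
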