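#' Reconcile replicate likelihood runs into a single branch-site score
#'
#' The branch-site test for positive selection contrasts a codon model with
#' a class of sites with dN/dS > 1 (H1) against one without (H0). Numerical
#' optimization of either model can fail to converge, so the test is run
#' several times and, per hypothesis, the best (highest) log-likelihood
#' across runs is kept:
#' \deqn{\Delta lnL = 2\,(\max_i lnL^{H1}_i - \max_i lnL^{H0}_i)}
#' A negative value indicates that all H1 runs failed to converge and is
#' clamped to zero. The fourth root of the clamped statistic
#' (\code{delta_lnl4}) is the per-gene selection score summed by SUMSTAT:
#' it approximately normalizes the nonzero score distribution and damps
#' outlier genes.
#'
#' @param lnl_h1 numeric vector of replicate log-likelihoods under the
#'   model with positive selection (any number >= 1 of runs).
#' @param lnl_h0 numeric vector of replicate log-likelihoods under the
#'   null model; same length as \code{lnl_h1}.
#' @return list with \code{delta_lnl} (clamped, >= 0), \code{delta_lnl4}
#'   (its fourth root) and \code{was_clamped} (TRUE iff the raw value was
#'   negative).
#' @examples
#' reconcile_runs(c(-1000.0, -999.5, -999.8), c(-1000.2, -1000.1, -1000.4))
#' @export
reconcile_runs <- function(lnl_h1, lnl_h0) {
  if (length(lnl_h1) == 0L || length(lnl_h0) == 0L)
    stop("empty replicate run list")
  if (length(lnl_h1) != length(lnl_h0))
    stop("lnl_h1 and lnl_h0 must have the same number of replicate runs")
  if (anyNA(lnl_h1) || anyNA(lnl_h0))
    stop("missing log-likelihood values")
  raw <- 2 * (max(lnl_h1) - max(lnl_h0))
  clamped <- raw < 0
  d <- if (clamped) 0 else raw
  list(delta_lnl = d, delta_lnl4 = d^0.25, was_clamped = clamped)
}

#' Resolve multiple rows carrying the same branch label for one gene
#'
#' Gene trees can annotate nested branches with the same label (e.g. both
#' the true Homininae branch and the Hominini branch below it). Only one
#' score per gene per tested branch may enter the enrichment test; the
#' oldest branch (closest to the root, minimal \code{node_depth}) is kept.
#' When depths tie the row with the larger \code{delta_lnl} wins, with a
#' warning, since no principled ordering exists for that degenerate case.
#'
#' @param rows data.frame of candidate rows for one gene and one branch
#'   label, with columns \code{node_depth} and \code{delta_lnl}.
#' @return single-row data.frame.
#' @export
resolve_oldest_branch <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  if (nrow(rows) == 1L) return(rows)
  dmin <- min(rows$node_depth)
  cand <- rows[rows$node_depth == dmin, , drop = FALSE]
  if (nrow(cand) > 1L) {
    warning("tie in node_depth for gene '", cand$gene_id[1L],
            "'; keeping the row with the larger delta_lnl")
    cand <- cand[order(-cand$delta_lnl), , drop = FALSE]
  }
  cand[1L, , drop = FALSE]
}

#' Copy a merged-branch score onto every branch it covers
#'
#' When a species' sequence is missing or was excluded, its branch in the
#' gene tree is merged with the downstream branch and the reported lnL
#' ratio is an "average" over both. That single score is used as input for
#' each tested branch the merged edge spans.
#'
#' @param score single-row data.frame (one gene-branch score) whose
#'   \code{merged_span} field names the covered branch labels
#'   (comma-joined).
#' @param tested_branches character vector of valid branch labels.
#' @return data.frame with one row per covered branch, identical score.
#' @export
propagate_merged <- function(score, tested_branches) {
  stopifnot(is.data.frame(score), nrow(score) == 1L)
  span <- score$merged_span[1L]
  labs <- if (is.na(span) || !nzchar(span)) character(0)
          else strsplit(span, ",", fixed = TRUE)[[1L]]
  labs <- trimws(labs)
  if (length(labs) == 0L) stop("empty merged_span")
  unknown <- setdiff(labs, tested_branches)
  if (length(unknown))
    stop("merged_span names unknown branch label(s): ",
         paste(unknown, collapse = ", "))
  out <- score[rep(1L, length(labs)), , drop = FALSE]
  out$branch <- labs
  rownames(out) <- NULL
  out
}

#' Assemble a per-branch score table
#'
#' One row per gene for one tested branch. Paralogous genes are retained
#' as separate rows carrying a shared \code{ancestral_group_id}; their
#' de-duplication happens at SUMSTAT time, not here. Two rows for the same
#' gene with conflicting scores violate the preparation contract and
#' raise an error.
#'
#' @param scores data.frame with columns \code{gene_id}, \code{delta_lnl},
#'   \code{delta_lnl4}, \code{tree_id}, \code{ancestral_group_id},
#'   \code{was_clamped} (and optionally \code{branch}).
#' @param branch branch label for the table.
#' @return a \code{score_table}: data.frame keyed by \code{gene_id} with a
#'   \code{branch} attribute.
#' @export
score_table <- function(scores, branch) {
  cols <- c("gene_id", "delta_lnl", "delta_lnl4", "tree_id",
            "ancestral_group_id", "was_clamped")
  missing_cols <- setdiff(cols, names(scores))
  if (length(missing_cols))
    stop("missing score column(s): ", paste(missing_cols, collapse = ", "))
  scores <- scores[, cols, drop = FALSE]
  if (anyDuplicated(scores$gene_id)) {
    dup <- unique(scores$gene_id[duplicated(scores$gene_id)])
    sub <- scores[scores$gene_id %in% dup, , drop = FALSE]
    agg <- tapply(sub$delta_lnl, sub$gene_id, function(x) length(unique(x)))
    if (any(agg > 1L))
      stop("conflicting scores for gene(s): ",
           paste(names(agg)[agg > 1L], collapse = ", "))
    scores <- scores[!duplicated(scores$gene_id), , drop = FALSE]
  }
  scores <- scores[radix_order(scores$gene_id), , drop = FALSE]
  rownames(scores) <- NULL
  attr(scores, "branch") <- branch
  class(scores) <- c("score_table", "data.frame")
  scores
}

#' @export
print.score_table <- function(x, ...) {
  cat("Score table for branch '", attr(x, "branch"), "': ",
      nrow(x), " genes, ", sum(x$delta_lnl == 0), " zero scores (",
      round(100 * mean(x$delta_lnl == 0), 1), "%)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

#' Prepare per-branch score tables from a raw likelihood table
#'
#' Applies, in order: replicate reconciliation (or pass-through of a
#' precomputed \code{delta_lnl} column), oldest-branch resolution of
#' duplicated branch labels, propagation of merged-branch scores, and
#' table assembly per tested branch.
#'
#' @param raw data.frame as returned by [read_likelihood_table()]: columns
#'   \code{gene_id}, \code{branch}, \code{tree_id}, \code{node_depth},
#'   \code{ancestral_group_id}, \code{merged_span}, then either a
#'   \code{delta_lnl} column or replicate columns \code{lnl_h0_1..k} and
#'   \code{lnl_h1_1..k}.
#' @param branches branch labels to build tables for; default all labels
#'   present in \code{raw} plus any named in merged spans.
#' @return named list of [score_table()] objects, one per branch.
#' @export
prepare_scores <- function(raw, branches = NULL) {
  stopifnot(is.data.frame(raw))
  need <- c("gene_id", "branch", "tree_id", "node_depth")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing input column(s): ", paste(missing_cols, collapse = ", "))
  if (!"ancestral_group_id" %in% names(raw)) raw$ancestral_group_id <- NA_character_
  if (!"merged_span" %in% names(raw)) raw$merged_span <- NA_character_

  h0 <- grep("^lnl_h0_[0-9]+$", names(raw), value = TRUE)
  h1 <- grep("^lnl_h1_[0-9]+$", names(raw), value = TRUE)
  if ("delta_lnl" %in% names(raw)) {
    if (any(raw$delta_lnl < 0, na.rm = TRUE))
      stop("precomputed delta_lnl must be nonnegative")
    raw$was_clamped <- FALSE
  } else {
    if (length(h0) == 0L || length(h0) != length(h1))
      stop("need either a delta_lnl column or matched lnl_h0_*/lnl_h1_* columns")
    h0 <- h0[radix_order(h0)]; h1 <- h1[radix_order(h1)]
    m0 <- do.call(pmax, c(raw[h0], na.rm = TRUE))
    m1 <- do.call(pmax, c(raw[h1], na.rm = TRUE))
    rawd <- 2 * (m1 - m0)
    raw$was_clamped <- rawd < 0
    raw$delta_lnl <- pmax(rawd, 0)
  }
  raw$delta_lnl4 <- raw$delta_lnl^0.25

  span_labs <- unlist(strsplit(raw$merged_span[!is.na(raw$merged_span) &
                                                 nzchar(raw$merged_span)],
                               ",", fixed = TRUE))
  known_branches <- sort(unique(c(raw$branch, trimws(span_labs))),
                         method = "radix")
  out_branches <- branches %||% known_branches

  # oldest-branch rule per gene x branch label
  key <- paste(raw$gene_id, raw$branch, sep = "\r")
  if (anyDuplicated(key)) {
    pieces <- split(seq_len(nrow(raw)), key)
    keep <- vapply(pieces, function(ii) {
      if (length(ii) == 1L) return(ii)
      rows <- raw[ii, , drop = FALSE]
      win <- resolve_oldest_branch(rows)
      ii[which(rows$node_depth == win$node_depth &
                 rows$delta_lnl == win$delta_lnl)[1L]]
    }, integer(1L))
    raw <- raw[sort(keep), , drop = FALSE]
  }

  # merged-branch propagation
  has_span <- !is.na(raw$merged_span) & nzchar(raw$merged_span)
  if (any(has_span)) {
    prop <- do.call(rbind, lapply(which(has_span), function(i)
      propagate_merged(raw[i, , drop = FALSE], known_branches)))
    raw <- rbind(raw[!has_span, , drop = FALSE], prop)
  }

  out <- lapply(out_branches, function(b)
    score_table(raw[raw$branch == b, , drop = FALSE], b))
  names(out) <- out_branches
  out[vapply(out, nrow, integer(1L)) > 0L]
}

#' Build a one-to-one ID mapping from candidate pair tables
#'
#' Cross-database gene identifier conversion (e.g. Ensembl to Entrez) from
#' one or more two-column candidate tables that may contain one-to-many or
#' many-to-many pairs. The tables are merged into a pair multiset; for
#' each source id the target with the highest pair count is kept, then the
#' same greedy rule is applied per target id, so the result is one-to-one.
#' Count ties are broken toward the lexically smallest candidate, making
#' the mapping deterministic. Unmapped source ids are dropped (reported in
#' the \code{"dropped"} attribute).
#'
#' @param source_ids character vector of ids to map.
#' @param candidate_maps list of two-column data.frames (source, target).
#' @return named character vector: names are mapped source ids, values the
#'   target ids; attribute \code{"dropped"} lists unmapped source ids.
#' @export
map_ids <- function(source_ids, candidate_maps) {
  stopifnot(is.character(source_ids))
  if (is.data.frame(candidate_maps)) candidate_maps <- list(candidate_maps)
  pairs <- do.call(rbind, lapply(candidate_maps, function(m) {
    stopifnot(ncol(m) >= 2L)
    data.frame(src = as.character(m[[1L]]), tgt = as.character(m[[2L]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    warning("no candidate pairs; empty mapping")
    out <- character(0)
    attr(out, "dropped") <- unique(source_ids)
    return(out)
  }
  pairs <- pairs[pairs$src %in% source_ids, , drop = FALSE]
  cnt <- stats::aggregate(list(n = rep(1L, nrow(pairs))),
                          by = list(src = pairs$src, tgt = pairs$tgt),
                          FUN = sum)
  # greedy per source, then per target; lexical tie-break
  cnt <- cnt[radix_order(cnt$src, -cnt$n, cnt$tgt), , drop = FALSE]
  cnt <- cnt[!duplicated(cnt$src), , drop = FALSE]
  cnt <- cnt[radix_order(cnt$tgt, -cnt$n, cnt$src), , drop = FALSE]
  cnt <- cnt[!duplicated(cnt$tgt), , drop = FALSE]
  out <- cnt$tgt
  names(out) <- cnt$src
  out <- out[radix_order(names(out))]
  dropped <- setdiff(unique(source_ids), names(out))
  if (length(dropped) && length(out) == 0L)
    warning("no source id could be mapped")
  attr(out, "dropped") <- dropped
  out
}
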