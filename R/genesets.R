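#' Construct a gene set collection
#'
#' @param sets named list of character vectors (member gene ids), names
#'   are set ids.
#' @param info optional data.frame with columns \code{set_id},
#'   \code{name}, \code{source_db}, \code{merged_from}; defaults are
#'   filled from the set ids.
#' @return object of class \code{gene_set_collection}: list with elements
#'   \code{sets} (named list) and \code{info} (data.frame); the background
#'   (union of all members) is available via [set_background()].
#' @export
gene_set_collection <- function(sets, info = NULL) {
  stopifnot(is.list(sets))
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named by set_id")
  empty <- lengths(sets) == 0L
  if (any(empty)) stop("empty gene set(s): ",
                       paste(names(sets)[empty], collapse = ", "))
  sets <- lapply(sets, function(m) sort(unique(as.character(m)),
                                        method = "radix"))
  ids <- names(sets)
  if (is.null(info)) {
    info <- data.frame(set_id = ids, name = ids,
                       source_db = NA_character_,
                       merged_from = "", stringsAsFactors = FALSE)
  } else {
    stopifnot("set_id" %in% names(info))
    info <- info[match(ids, info$set_id), , drop = FALSE]
    if (is.null(info$name)) info$name <- ids
    if (is.null(info$source_db)) info$source_db <- NA_character_
    if (is.null(info$merged_from)) info$merged_from <- ""
    info <- info[, c("set_id", "name", "source_db", "merged_from")]
  }
  rownames(info) <- NULL
  structure(list(sets = sets, info = info), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat("Gene set collection: ", length(x$sets), " sets, ",
      length(set_background(x)), " distinct genes\n", sep = "")
  if (length(sz))
    cat("  set sizes: min ", min(sz), ", median ", stats::median(sz),
        ", max ", max(sz), "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Background of a collection: every gene belonging to at least one set
#' @param x a \code{gene_set_collection}.
#' @return character vector of gene ids.
#' @export
set_background <- function(x) {
  stopifnot(inherits(x, "gene_set_collection"))
  sort(unique(unlist(x$sets, use.names = FALSE)), method = "radix")
}

#' Restrict a collection to genes present in a score table
#'
#' Genes without a selection score on the tested branch cannot contribute
#' to SUMSTAT and are removed from every set; sets left empty are dropped.
#'
#' @param collection a \code{gene_set_collection}.
#' @param table a [score_table()].
#' @return filtered \code{gene_set_collection}.
#' @export
restrict_to_scored <- function(collection, table) {
  stopifnot(inherits(collection, "gene_set_collection"))
  scored <- table$gene_id
  sets <- lapply(collection$sets, function(m) m[m %in% scored])
  keep <- lengths(sets) > 0L
  if (!any(keep)) stop("no gene set retains any scored gene")
  gene_set_collection(sets[keep], collection$info[keep, , drop = FALSE])
}

#' Drop gene sets below a minimum size
#'
#' The enrichment test has low power for small sets; sets with fewer
#' members than \code{min_size} (default 10) are removed.
#'
#' @param collection a \code{gene_set_collection}.
#' @param min_size minimum number of members (>= 1).
#' @return filtered \code{gene_set_collection}.
#' @export
filter_min_size <- function(collection, min_size = 10L) {
  stopifnot(inherits(collection, "gene_set_collection"), min_size >= 1L)
  keep <- lengths(collection$sets) >= min_size
  if (!any(keep)) stop("no gene set of size >= ", min_size)
  gene_set_collection(collection$sets[keep],
                      collection$info[keep, , drop = FALSE])
}

#' Merge groups of nearly identical gene sets
#'
#' Pathway aggregations contain near-duplicate sets. Two sets are similar
#' when their similarity coefficient reaches \code{threshold} (default
#' 0.95); groups of similar sets (connected components of the similarity
#' graph, so merging is transitive) are replaced by a single set holding
#' the union of their members. The merged set keeps the id and name of
#' its largest constituent, with the name suffixed \code{"*"}, and records
#' the constituents in \code{merged_from}.
#'
#' @param collection a \code{gene_set_collection}.
#' @param threshold similarity needed to connect two sets, in (0, 1].
#' @param method \code{"overlap"} (default): |A intersect B| / min(|A|,|B|);
#'   \code{"jaccard"}: |A intersect B| / |A union B|.
#' @return \code{gene_set_collection} with merged sets.
#' @export
merge_similar <- function(collection, threshold = 0.95,
                          method = c("overlap", "jaccard")) {
  stopifnot(inherits(collection, "gene_set_collection"),
            threshold > 0, threshold <= 1)
  method <- match.arg(method)
  sets <- collection$sets
  n <- length(sets)
  if (n < 2L) return(collection)
  genes <- sort(unique(unlist(sets, use.names = FALSE)), method = "radix")
  M <- matrix(0L, length(genes), n)
  for (j in seq_len(n)) M[match(sets[[j]], genes), j] <- 1L
  inter <- crossprod(M)
  sz <- lengths(sets)
  denom <- if (method == "overlap") outer(sz, sz, pmin)
           else outer(sz, sz, `+`) - inter
  sim <- inter / denom
  adj <- sim >= threshold
  diag(adj) <- FALSE
  if (!any(adj)) return(collection)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  new_sets <- list(); new_info <- list()
  for (cid in sort(unique(comp))) {
    ii <- which(comp == cid)
    if (length(ii) == 1L) {
      i <- ii
      new_sets[[collection$info$set_id[i]]] <- sets[[i]]
      new_info[[length(new_info) + 1L]] <- collection$info[i, , drop = FALSE]
    } else {
      rep_i <- ii[radix_order(-sz[ii], collection$info$set_id[ii])][1L]
      members <- sort(unique(unlist(sets[ii], use.names = FALSE)),
                      method = "radix")
      id <- collection$info$set_id[rep_i]
      inf <- collection$info[rep_i, , drop = FALSE]
      inf$name <- paste0(inf$name, "*")
      inf$merged_from <- paste(sort(collection$info$set_id[ii],
                                    method = "radix"), collapse = ";")
      new_sets[[id]] <- members
      new_info[[length(new_info) + 1L]] <- inf
    }
  }
  info <- do.call(rbind, new_info)
  ord <- radix_order(info$set_id)
  gene_set_collection(new_sets[ord], info[ord, , drop = FALSE])
}

#' Exact over-representation test of a gene list in a set
#'
#' Two-sided Fisher exact test on the 2x2 table (in set vs not) x (hit vs
#' not) over a gene universe. Used both for classical enrichment of a
#' top-gene list and for checking whether sets are biased toward genes
#' filtered out of the score table.
#'
#' @param hit_genes character vector, subset of \code{universe}.
#' @param members character vector of set members, subset of
#'   \code{universe}.
#' @param universe character vector of all genes considered.
#' @return two-sided exact P value.
#' @export
overrep_test <- function(hit_genes, members, universe) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  hit_genes <- unique(hit_genes); members <- unique(members)
  if (!all(members %in% universe) || !all(hit_genes %in% universe))
    stop("hit_genes and members must be subsets of the universe")
  a <- sum(members %in% hit_genes)
  b <- length(members) - a
  c_ <- length(hit_genes) - a
  d <- length(universe) - a - b - c_
  stats::fisher.test(matrix(c(a, b, c_, d), 2L, 2L))$p.value
}

#' Over-representation across a collection, with q-values
#'
#' Applies [overrep_test()] to every set of a collection and corrects the
#' P values with Storey q-values (see [qvalues()]).
#'
#' @inheritParams overrep_test
#' @param collection a \code{gene_set_collection}.
#' @param pi0_method passed to [qvalues()].
#' @return data.frame with set_id, name, size, n_hit, p_value, q_value.
#' @export
overrep_collection <- function(collection, hit_genes, universe,
                               pi0_method = "bootstrap") {
  stopifnot(inherits(collection, "gene_set_collection"))
  p <- vapply(collection$sets, overrep_test,
              numeric(1L), hit_genes = hit_genes, universe = universe)
  data.frame(set_id = collection$info$set_id,
             name = collection$info$name,
             size = lengths(collection$sets),
             n_hit = vapply(collection$sets,
                            function(m) sum(m %in% hit_genes), integer(1L)),
             p_value = unname(p),
             q_value = qvalues(unname(p), pi0_method = pi0_method),
             stringsAsFactors = FALSE, row.names = NULL)
}
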