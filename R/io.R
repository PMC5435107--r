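# Readers and writers for the package's plain-text dialects:
# raw likelihood tables (TSV), per-branch score tables (TSV), gene set
# collections (GMT), id-mapping pair tables (TSV), truth tables (TSV).

read_tsv_base <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    check.names = FALSE)
}

write_tsv_base <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a raw per-branch likelihood table
#'
#' Tab-separated with header columns \code{gene_id}, \code{branch},
#' \code{tree_id}, \code{node_depth}, \code{ancestral_group_id} (may be
#' empty), \code{merged_span} (comma-joined branch labels, may be empty),
#' and then either a precomputed \code{delta_lnl} column or replicate
#' log-likelihood columns \code{lnl_h0_1..k} / \code{lnl_h1_1..k}.
#'
#' @param path file path.
#' @return data.frame suitable for [prepare_scores()].
#' @export
read_likelihood_table <- function(path) {
  x <- read_tsv_base(path)
  need <- c("gene_id", "branch", "tree_id", "node_depth")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  x
}

#' Write a raw per-branch likelihood table
#' @param x data.frame in the raw dialect.
#' @param path file path.
#' @export
write_likelihood_table <- function(x, path) write_tsv_base(x, path)

#' Write a per-branch score table
#'
#' TSV with columns gene_id, delta_lnl, delta_lnl4, tree_id,
#' ancestral_group_id, was_clamped, branch.
#'
#' @param table a [score_table()].
#' @param path file path.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  out <- as.data.frame(table)
  out$branch <- attr(table, "branch")
  write_tsv_base(out, path)
}

#' Read a per-branch score table written by [write_score_table()]
#' @param path file path.
#' @return a [score_table()].
#' @export
read_score_table <- function(path) {
  x <- read_tsv_base(path)
  branch <- if ("branch" %in% names(x)) x$branch[1L] else NA_character_
  x$was_clamped <- as.logical(x$was_clamped)
  if (!"ancestral_group_id" %in% names(x))
    x$ancestral_group_id <- NA_character_
  x$ancestral_group_id <- as.character(x$ancestral_group_id)
  score_table(x, branch)
}

#' Read a gene set collection from a GMT file
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated. Descriptions written by [write_gmt()] encode
#' \code{source_db|name|merged_from}; plain descriptions are taken as the
#' set name.
#'
#' @param path file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(path, ": empty gene set file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop(path, ": line(s) without members: ",
         paste(which(bad), collapse = ", "))
  ids <- vapply(parts, `[[`, character(1L), 1L)
  desc <- vapply(parts, `[[`, character(1L), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  meta <- strsplit(desc, "|", fixed = TRUE)
  info <- data.frame(
    set_id = ids,
    name = vapply(meta, function(m)
      if (length(m) >= 2L) m[2L] else m[1L], character(1L)),
    source_db = vapply(meta, function(m)
      if (length(m) >= 2L && nzchar(m[1L]) && m[1L] != "NA") m[1L]
      else NA_character_, character(1L)),
    merged_from = vapply(meta, function(m)
      if (length(m) >= 3L) m[3L] else "", character(1L)),
    stringsAsFactors = FALSE)
  gene_set_collection(sets, info)
}

#' Write a gene set collection to a GMT file
#'
#' The description field encodes \code{source_db|name|merged_from} so
#' that merge annotations survive a round trip.
#'
#' @param collection a [gene_set_collection()].
#' @param path file path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  info <- collection$info
  desc <- paste(ifelse(is.na(info$source_db), "NA", info$source_db),
                info$name, info$merged_from, sep = "|")
  desc <- sub("\\|$", "", desc)  # omit trailing empty merged_from
  lines <- vapply(seq_along(collection$sets), function(i)
    paste(c(info$set_id[i], desc[i], collection$sets[[i]]),
          collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read two-column id-mapping pair tables
#' @param paths one or more TSV paths (header optional: detected when the
#'   first line's second field is not a value-like token is NOT attempted;
#'   files must carry a header line).
#' @return list of two-column data.frames for [map_ids()].
#' @export
read_id_maps <- function(paths) {
  lapply(paths, function(p) {
    x <- read_tsv_base(p)
    if (ncol(x) < 2L) stop(p, ": id map needs two columns")
    x[, 1:2]
  })
}

#' Write the synthetic truth table
#' @param truth truth list from [simulate_scores()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  df <- rbind(
    if (length(truth$signal_set_ids))
      data.frame(kind = "signal_set", id = truth$signal_set_ids),
    if (length(truth$signal_gene_ids))
      data.frame(kind = "signal_gene", id = truth$signal_gene_ids))
  if (is.null(df)) df <- data.frame(kind = character(0), id = character(0))
  write_tsv_base(df, path)
}

#' Read a synthetic truth table
#' @param path file path.
#' @return list with signal_set_ids and signal_gene_ids.
#' @export
read_truth <- function(path) {
  x <- read_tsv_base(path)
  list(signal_set_ids = x$id[x$kind == "signal_set"],
       signal_gene_ids = x$id[x$kind == "signal_gene"])
}
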