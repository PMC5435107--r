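#' Assemble a pipeline run configuration
#'
#' Defaults follow the analysis as published: minimum set size 10,
#' 95% overlap-coefficient merging, sequential null with blocks of
#' 10,000 up to 1,000,000 samples, in-set background, bootstrap pi0,
#' candidate threshold q < 0.2 on both passes, 300 FDR permutations with
#' a reduced per-replicate null cap.
#'
#' @param ... overrides for any configuration key.
#' @param file optional YAML file of key-value overrides (values in
#'   \code{...} win).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list(
    scores = NULL, sets = NULL, maps = NULL, out_dir = ".",
    branches = NULL,
    alpha = 0.2, min_size = 10L, merge_threshold = 0.95,
    merge_method = "overlap",
    block_size = 10000L, max_null = 1000000L,
    background_mode = "in_sets", pi0_method = "bootstrap",
    n_perm = 300L, prune_min_size = 10L, perm_null_cap = 100000L,
    seed = 1L, sim = NULL)
  if (!is.null(file)) {
    over <- yaml::read_yaml(file)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$alpha > 0, cfg$alpha < 1)
  class(cfg) <- "run_config"
  cfg
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Generate and write a synthetic fixture bundle
#'
#' Wraps the synthetic-data generator: writes \code{scores.tsv} (raw
#' likelihood-table dialect), \code{sets.gmt} and \code{truth.tsv} into
#' \code{out_dir}.
#'
#' @param config a [run_config()] whose \code{sim} entry is a
#'   [sim_config()] (or a list of [sim_config()] arguments).
#' @return invisibly, the written file paths.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  if (is.null(sim)) sim <- sim_config(seed = config$seed)
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  out <- ensure_dir(config$out_dir)
  u <- simulate_universe(sim)
  paths <- c(scores = file.path(out, "scores.tsv"),
             sets = file.path(out, "sets.gmt"),
             truth = file.path(out, "truth.tsv"))
  write_likelihood_table(u$raw, paths[["scores"]])
  write_gmt(u$collection, paths[["sets"]])
  write_truth(u$truth, paths[["truth"]])
  invisible(paths)
}

#' Prepare per-branch score tables and set collections
#'
#' Reads the raw likelihood table and the GMT collection, optionally
#' applies a one-to-one id mapping to the score gene ids, then per
#' branch: restricts sets to scored genes, filters small sets, merges
#' near-identical sets. Writes \code{scores_<branch>.tsv},
#' \code{sets_<branch>.gmt} and a \code{prep_report.tsv} with per-branch
#' gene and set counts.
#'
#' @param config a [run_config()] with \code{scores}, \code{sets} (and
#'   optionally \code{maps}) paths set.
#' @return invisibly, a list of per-branch lists (table, collection).
#' @export
run_prepare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$scores) || is.null(config$sets))
    stop("config needs 'scores' and 'sets' paths")
  raw <- read_likelihood_table(config$scores)
  collection <- read_gmt(config$sets)
  tables <- prepare_scores(raw, branches = config$branches)
  if (length(tables) == 0L) stop("no branch yielded any score")
  maps <- if (!is.null(config$maps)) read_id_maps(config$maps) else NULL
  out <- ensure_dir(config$out_dir)
  prepared <- list()
  report <- list()
  for (b in names(tables)) {
    tab <- tables[[b]]
    if (!is.null(maps)) {
      mp <- map_ids(tab$gene_id, maps)
      keep <- tab$gene_id %in% names(mp)
      tab <- tab[keep, , drop = FALSE]
      tab$gene_id <- unname(mp[tab$gene_id])
      tab <- score_table(as.data.frame(tab), b)
    }
    coll <- restrict_to_scored(collection, tab)
    coll <- filter_min_size(coll, config$min_size)
    coll <- merge_similar(coll, config$merge_threshold,
                          config$merge_method)
    write_score_table(tab, file.path(out, paste0("scores_", b, ".tsv")))
    write_gmt(coll, file.path(out, paste0("sets_", b, ".gmt")))
    prepared[[b]] <- list(table = tab, collection = coll)
    report[[b]] <- data.frame(
      branch = b, n_genes = nrow(tab),
      n_sets_in = length(collection$sets),
      n_sets_prepared = length(coll$sets),
      n_merged = sum(nzchar(coll$info$merged_from)),
      stringsAsFactors = FALSE)
  }
  write_tsv_base(do.call(rbind, report), file.path(out, "prep_report.tsv"))
  invisible(prepared)
}

read_prepared <- function(config) {
  out <- config$out_dir
  score_files <- list.files(out, "^scores_.*\\.tsv$", full.names = TRUE)
  if (length(score_files) == 0L)
    stop("no prepared inputs in ", out, "; run run_prepare() first")
  branches <- sub("^scores_(.*)\\.tsv$", "\\1", basename(score_files))
  branches <- sort(branches, method = "radix")
  if (!is.null(config$branches))
    branches <- intersect(branches, config$branches)
  out_list <- lapply(branches, function(b) {
    list(table = read_score_table(file.path(out,
                                            paste0("scores_", b, ".tsv"))),
         collection = read_gmt(file.path(out, paste0("sets_", b, ".gmt"))))
  })
  names(out_list) <- branches
  out_list
}

#' Run the enrichment test on prepared inputs
#'
#' Per branch: [sumstat_test()] (main + top-gene-removal pass, q-values,
#' candidate flags) written to \code{results_<branch>.tsv}.
#'
#' @param config a [run_config()] whose \code{out_dir} holds the outputs
#'   of [run_prepare()].
#' @return invisibly, named list of \code{sumstat_fit} objects.
#' @export
run_test <- function(config) {
  stopifnot(inherits(config, "run_config"))
  prepared <- read_prepared(config)
  fits <- list()
  for (b in names(prepared)) {
    fit <- sumstat_test(prepared[[b]]$collection, prepared[[b]]$table,
                        alpha = config$alpha,
                        block = config$block_size, max_n = config$max_null,
                        pi0_method = config$pi0_method,
                        background_mode = config$background_mode,
                        seed = derive_seed(config$seed,
                                           match(b, names(prepared))))
    write_tsv_base(fit$results,
                   file.path(config$out_dir,
                             paste0("results_", b, ".tsv")))
    fits[[b]] <- fit
  }
  invisible(fits)
}

#' Prune overlapping sets and estimate the permutation FDR
#'
#' Per branch: [prune_sets()] followed by [permutation_fdr()]; pruning
#' records (mirroring the post-pruning SUMSTAT/size/P columns, with
#' pre-pruning values alongside) go to \code{pruned_<branch>.tsv}, the
#' FDR grid to \code{fdr_<branch>.tsv}.
#'
#' @param config a [run_config()] whose \code{out_dir} holds the outputs
#'   of [run_prepare()].
#' @return invisibly, named list of \code{sumstat_prune} objects.
#' @export
run_prune <- function(config) {
  stopifnot(inherits(config, "run_config"))
  prepared <- read_prepared(config)
  prunes <- list()
  for (b in names(prepared)) {
    bseed <- derive_seed(config$seed, 50L + match(b, names(prepared)))
    if (config$n_perm < 10L)
      message("n_perm = ", config$n_perm,
              ": FDR estimates will be low-precision")
    pr <- permutation_fdr(prepared[[b]]$collection, prepared[[b]]$table,
                          n_perm = config$n_perm,
                          min_size = config$prune_min_size,
                          block = config$block_size,
                          max_n = config$perm_null_cap,
                          seed = bseed)
    write_tsv_base(pr$records,
                   file.path(config$out_dir, paste0("pruned_", b, ".tsv")))
    write_tsv_base(pr$fdr,
                   file.path(config$out_dir, paste0("fdr_", b, ".tsv")))
    prunes[[b]] <- pr
  }
  invisible(prunes)
}

#' Summarize pipeline outputs
#'
#' Collects per-branch counts from the result and pruning tables in
#' \code{out_dir} into \code{report.tsv}.
#'
#' @param config a [run_config()].
#' @return the report data.frame, invisibly.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  res_files <- list.files(out, "^results_.*\\.tsv$", full.names = TRUE)
  rows <- lapply(res_files, function(f) {
    b <- sub("^results_(.*)\\.tsv$", "\\1", basename(f))
    r <- read_tsv_base(f)
    pf <- file.path(out, paste0("pruned_", b, ".tsv"))
    pruned <- if (file.exists(pf)) read_tsv_base(pf) else NULL
    data.frame(branch = b, n_sets = nrow(r),
               n_candidates = sum(r$is_candidate),
               n_significant_main = sum(r$q_value < config$alpha),
               n_pruned_records =
                 if (is.null(pruned)) NA_integer_ else nrow(pruned),
               n_pruned_significant =
                 if (is.null(pruned)) NA_integer_
                 else sum(pruned$fdr_q < config$alpha, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  write_tsv_base(report, file.path(out, "report.tsv"))
  invisible(report)
}

#' Run the full pipeline
#'
#' simulate (only when \code{config$sim} is set and no scores path is
#' given) -> prepare -> test -> prune -> report.
#'
#' @param config a [run_config()].
#' @return invisibly, list with \code{fits}, \code{prunes},
#'   \code{report}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$scores) && !is.null(config$sim)) {
    paths <- run_simulate(config)
    config$scores <- paths[["scores"]]
    config$sets <- paths[["sets"]]
  }
  run_prepare(config)
  fits <- run_test(config)
  prunes <- run_prune(config)
  report <- run_report(config)
  invisible(list(fits = fits, prunes = prunes, report = report))
}
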