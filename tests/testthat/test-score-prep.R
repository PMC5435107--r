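test_that("replicate reconciliation follows the best-run lnL ratio with zero clamping", {
  r <- reconcile_runs(c(-1000.0, -999.5, -999.8), c(-1000.2, -1000.1, -1000.4))
  expect_equal(r$delta_lnl, 1.2)
  expect_false(r$was_clamped)
  expect_equal(r$delta_lnl4, 1.2^0.25, tolerance = 1e-12)

  r <- reconcile_runs(-500.3, -500.1)
  expect_equal(r$delta_lnl, 0)
  expect_true(r$was_clamped)

  expect_equal(reconcile_runs(-92, -100)$delta_lnl4, 2)  # delta_lnl = 16

  expect_error(reconcile_runs(numeric(0), numeric(0)), "empty")
  expect_error(reconcile_runs(c(-1, -2), -1), "same number")
})

test_that("reconciliation is invariant to replicate order and monotone in each run", {
  set.seed(11)
  for (k in c(1L, 2L, 3L, 5L)) {
    h1 <- -1000 + rnorm(k); h0 <- -1000 + rnorm(k)
    base <- reconcile_runs(h1, h0)
    expect_equal(reconcile_runs(h1[sample(k)], h0[sample(k)]), base)
    # raising any H1 replicate never lowers the statistic; raising H0 never raises it
    i <- sample(k, 1L)
    up <- h1; up[i] <- up[i] + 0.5
    expect_gte(reconcile_runs(up, h0)$delta_lnl, base$delta_lnl)
    up0 <- h0; up0[i] <- up0[i] + 0.5
    expect_lte(reconcile_runs(h1, up0)$delta_lnl, base$delta_lnl)
  }
})

test_that("multiple same-label branches resolve to the oldest, ties to larger delta_lnl", {
  rows <- data.frame(gene_id = "g1", node_depth = c(3L, 2L),
                     delta_lnl = c(5, 1))
  expect_equal(resolve_oldest_branch(rows)$node_depth, 2L)
  one <- rows[1L, , drop = FALSE]
  expect_identical(resolve_oldest_branch(one), one)
  tie <- data.frame(gene_id = "g1", node_depth = c(2L, 2L),
                    delta_lnl = c(1, 4))
  expect_warning(win <- resolve_oldest_branch(tie), "tie")
  expect_equal(win$delta_lnl, 4)
})

test_that("merged-branch scores are copied once onto every covered branch", {
  sc <- data.frame(gene_id = "g1", branch = "Hominoidae", delta_lnl = 3.2,
                   merged_span = "Hominoidae,Catarrhini")
  out <- propagate_merged(sc, c("Hominoidae", "Catarrhini"))
  expect_equal(nrow(out), 2L)
  expect_setequal(out$branch, c("Hominoidae", "Catarrhini"))
  expect_equal(unique(out$delta_lnl), 3.2)

  sc$merged_span <- "Hominoidae"
  expect_equal(nrow(propagate_merged(sc, c("Hominoidae", "Catarrhini"))), 1L)
  sc$merged_span <- ""
  expect_error(propagate_merged(sc, "Hominoidae"), "empty")
  sc$merged_span <- "NotABranch"
  expect_error(propagate_merged(sc, "Hominoidae"), "unknown branch")
})

test_that("score tables keep one row per gene, retain paralogs, reject conflicts", {
  df <- data.frame(gene_id = c("g1", "g2", "g3"),
                   delta_lnl = c(1, 2, 3), delta_lnl4 = c(1, 2, 3)^0.25,
                   tree_id = "t", ancestral_group_id = NA_character_,
                   was_clamped = FALSE)
  expect_equal(nrow(score_table(df, "b")), 3L)

  df$ancestral_group_id <- c("d7", "d7", NA)
  tab <- score_table(df, "b")
  expect_equal(sum(tab$ancestral_group_id == "d7", na.rm = TRUE), 2L)

  conflict <- rbind(df, data.frame(gene_id = "g1", delta_lnl = 9,
                                   delta_lnl4 = 9^0.25, tree_id = "t",
                                   ancestral_group_id = NA, was_clamped = FALSE))
  expect_error(score_table(conflict, "b"), "conflicting")
})

test_that("prepare_scores gives identical tables from lnL runs and precomputed delta_lnl", {
  set.seed(21)
  n <- 40L
  h1 <- matrix(-1000 + rnorm(3 * n), n)
  h0 <- h1 - matrix(runif(3 * n, -0.5, 2), n)  # some negatives after max
  raw1 <- data.frame(gene_id = sprintf("g%03d", 1:n), branch = "bA",
                     tree_id = "t", node_depth = 1L,
                     lnl_h0_1 = h0[, 1], lnl_h0_2 = h0[, 2], lnl_h0_3 = h0[, 3],
                     lnl_h1_1 = h1[, 1], lnl_h1_2 = h1[, 2], lnl_h1_3 = h1[, 3])
  t1 <- prepare_scores(raw1)[["bA"]]
  d <- pmax(2 * (apply(h1, 1, max) - apply(h0, 1, max)), 0)
  raw2 <- data.frame(gene_id = sprintf("g%03d", 1:n), branch = "bA",
                     tree_id = "t", node_depth = 1L, delta_lnl = d)
  t2 <- prepare_scores(raw2)[["bA"]]
  expect_equal(t1$delta_lnl, t2$delta_lnl)
  expect_equal(t1$delta_lnl4, t2$delta_lnl4)
  expect_true(any(t1$was_clamped))
  # clamped rows are exactly zero
  expect_true(all(t1$delta_lnl[t1$was_clamped] == 0))
})

test_that("prepare_scores applies oldest-branch resolution and span propagation", {
  raw <- data.frame(
    gene_id = c("g1", "g1", "g2"),
    branch = c("bA", "bA", "bA"),
    tree_id = "t", node_depth = c(2L, 3L, 1L),
    ancestral_group_id = NA_character_,
    merged_span = c(NA, NA, "bA,bB"),
    delta_lnl = c(4, 9, 2.5))
  tabs <- prepare_scores(raw)
  expect_equal(tabs$bA$delta_lnl[tabs$bA$gene_id == "g1"], 4)  # oldest kept
  expect_equal(tabs$bB$gene_id, "g2")
  expect_equal(tabs$bB$delta_lnl, 2.5)
  expect_equal(tabs$bA$delta_lnl[tabs$bA$gene_id == "g2"], 2.5)
})

test_that("id mapping is greedy by pair count and strictly one-to-one", {
  maps <- list(data.frame(src = c("a", "a", "a", "a", "b", "b"),
                          tgt = c("1", "1", "1", "2", "2", "2")))
  m <- map_ids(c("a", "b"), maps)
  expect_equal(unname(m[c("a", "b")]), c("1", "2"))

  m2 <- map_ids(c("a", "b"), list(data.frame(src = c("a", "b"), tgt = c("1", "1"))))
  expect_equal(length(m2), 1L)
  expect_equal(as.character(m2), "1")
  expect_equal(length(attr(m2, "dropped")), 1L)

  expect_warning(m3 <- map_ids("a", list(data.frame(src = character(0),
                                                    tgt = character(0)))),
                 "empty|no candidate")
  expect_equal(length(m3), 0L)
})

test_that("id mappings are bijective on their domain", {
  set.seed(31)
  for (rep in 1:5) {
    src <- sprintf("e%03d", 1:30)
    pairs <- data.frame(src = sample(src, 120, replace = TRUE),
                        tgt = sprintf("n%03d", sample(25, 120, replace = TRUE)))
    m <- map_ids(src, list(pairs))
    expect_false(anyDuplicated(names(m)) > 0)
    expect_false(anyDuplicated(m) > 0)
    # forward then inverse is the identity on the mapped domain
    inv <- names(m); names(inv) <- unname(m)
    expect_identical(unname(inv[unname(m[names(m)])]), names(m))
  }
})

test_that("likelihood and score tables round-trip through their TSV dialects", {
  tmp <- withr::local_tempdir()
  u <- simulate_universe(sim_config(n_genes = 120, n_sets = 6,
                                    set_size_range = c(5L, 10L), seed = 5))
  f <- file.path(tmp, "raw.tsv")
  write_likelihood_table(u$raw, f)
  back <- read_likelihood_table(f)
  expect_equal(back$delta_lnl, u$raw$delta_lnl)
  expect_equal(back$merged_span, u$raw$merged_span)

  f2 <- file.path(tmp, "scores.tsv")
  write_score_table(u$table, f2)
  t2 <- read_score_table(f2)
  expect_equal(as.data.frame(t2), as.data.frame(u$table))
  expect_equal(attr(t2, "branch"), attr(u$table, "branch"))
})
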