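test_that("SUMSTAT sums fourth-root scores, counting ancestral groups once", {
  tab <- toy_table(c(g1 = 16, g2 = 81, g3 = 0))
  expect_equal(sumstat(c("g1", "g2", "g3"), tab), 5)  # 2 + 3 + 0

  # paralogs g1,g2 share a duplication group with score 2; third gene 1
  tab2 <- toy_table(c(g1 = 16, g2 = 16, g3 = 1),
                    groups = c(g1 = "d7", g2 = "d7"))
  expect_equal(sumstat(c("g1", "g2", "g3"), tab2), 3)

  tab3 <- toy_table(c(g1 = 0, g2 = 0), groups = c(g1 = "d1", g2 = "d1"))
  expect_equal(sumstat(c("g1", "g2"), tab3), 0)

  expect_error(sumstat(c("g1", "nope"), tab), "absent")
})

test_that("unequal paralog scores contribute their group maximum once", {
  tab <- toy_table(c(g1 = 16, g2 = 81), groups = c(g1 = "d1", g2 = "d1"))
  expect_equal(sumstat(c("g1", "g2"), tab), 3)
})

test_that("SUMSTAT is additive over disjoint sets without shared groups", {
  set.seed(61)
  tab <- random_table(100, seed = 61)
  a <- sample(tab$gene_id, 15)
  b <- sample(setdiff(tab$gene_id, a), 20)
  expect_equal(sumstat(c(a, b), tab), sumstat(a, tab) + sumstat(b, tab))
})

test_that("null ensembles have the uniform-draw expectation and are seed-reproducible", {
  tab <- toy_table(stats::setNames(rep(16, 50), sprintf("g%02d", 1:50)))
  e <- draw_null(5L, 100L, tab, seed = 1)
  expect_true(all(e$samples == 10))  # every sample = 5 * 16^(1/4)

  tab2 <- random_table(400, seed = 62)
  k <- 20L; n <- 4000L
  e2 <- draw_null(k, n, tab2, seed = 2)
  mu <- k * mean(tab2$delta_lnl4)
  # variance of a without-replacement sum, finite-population corrected
  v <- k * stats::var(tab2$delta_lnl4) * (1 - (k - 1) / (nrow(tab2) - 1))
  expect_lt(abs(mean(e2$samples) - mu), 3 * sqrt(v / n))

  e3 <- draw_null(k, 200L, tab2, seed = 3)
  e4 <- draw_null(k, 200L, tab2, seed = 3)
  expect_identical(e3$samples, e4$samples)

  expect_error(draw_null(500L, 10L, tab2), "exceeds")
})

test_that("empirical P follows the pseudo-count formula exactly", {
  expect_equal(empirical_p(10, rep(1, 10000)), 1 / 10001)
  expect_equal(empirical_p(0.5, rep(1, 100)), 1)
  med <- stats::qnorm(seq(0.001, 0.999, length.out = 999))
  expect_equal(empirical_p(med[500], med), (1 + 500) / 1000)
  samples <- c(1, 2, 2, 3)
  expect_equal(empirical_p(2, samples), (1 + 3) / 5)  # ties counted as >=
  expect_error(empirical_p(1, numeric(0)), "empty")
})

test_that("q-values reduce to Benjamini-Hochberg under fixed pi0 = 1", {
  expect_equal(qvalues(c(0.01, 0.02, 1.0), pi0_method = "fixed1"),
               c(0.03, 0.03, 1.0))
  expect_equal(qvalues(rep(1, 5)), rep(1, 5))
  expect_identical(qvalues(numeric(0)), numeric(0))
  expect_error(qvalues(c(0, 0.5)), "\\(0, 1\\]")

  set.seed(63)
  p <- runif(200)
  q <- qvalues(p, pi0_method = "bootstrap")
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  expect_true(all(q <= 1) && all(q > 0))
  # bootstrap pi0 <= 1 makes q no larger than BH
  expect_true(all(q <= qvalues(p, pi0_method = "fixed1") + 1e-12))
})

test_that("sequential testing freezes dull sets early and expands promising ones", {
  set.seed(64)
  tab <- random_table(600, seed = 64)
  ids <- tab$gene_id
  strong <- sample(ids[tab$delta_lnl4 > quantile(tab$delta_lnl4, 0.8)], 12)
  dull <- sample(ids[tab$delta_lnl4 <= quantile(tab$delta_lnl4, 0.5)], 12)
  coll <- toy_collection(list(strong = strong, dull = dull))
  st <- sequential_test(coll, tab, background = ids,
                        block = 1000L, max_n = 8000L, seed = 9)
  expect_equal(st$n_null[st$set_id == "dull"], 1000L)   # frozen after block 1
  expect_equal(st$n_null[st$set_id == "strong"], 8000L) # escalated to cap
  expect_equal(st$p_value[st$set_id == "strong"], 1 / 8001)
})

test_that("top-gene-removal statistic drops the maximum after group de-duplication", {
  tab <- toy_table(stats::setNames(c(81, 16, 1, rep(0, 20)),
                                   c("a", "b", "c", sprintf("z%02d", 1:20))))
  coll <- toy_collection(list(S = c("a", "b", "c")))
  st <- sequential_test(coll, tab, background = tab$gene_id,
                        block = 500L, max_n = 500L, seed = 1, drop_top = TRUE)
  expect_equal(st$sumstat, 3)  # {3,2,1} minus max 3

  all_eq <- toy_table(stats::setNames(rep(16, 30), sprintf("e%02d", 1:30)))
  st2 <- sequential_test(toy_collection(list(S = sprintf("e%02d", 1:6))),
                         all_eq, block = 200L, max_n = 200L, seed = 1,
                         drop_top = TRUE)
  expect_equal(st2$sumstat, 5 * 2)  # (k-1) * c

  expect_error(sequential_test(toy_collection(list(S = "a")), tab,
                               drop_top = TRUE, block = 10L, max_n = 10L),
               "size >= 2")
})

test_that("raising a member's score never lowers SUMSTAT nor raises its empirical P", {
  set.seed(65)
  tab <- random_table(200, seed = 65)
  members <- sample(tab$gene_id, 10)
  ens <- draw_null(10L, 2000L, tab, seed = 66)
  s0 <- sumstat(members, tab)
  p0 <- empirical_p(s0, ens)
  for (bump in c(0.5, 2, 10)) {
    tab2 <- tab
    i <- match(members[1L], tab2$gene_id)
    tab2$delta_lnl[i] <- tab2$delta_lnl[i] + bump
    tab2$delta_lnl4[i] <- tab2$delta_lnl[i]^0.25
    s1 <- sumstat(members, tab2)
    expect_gte(s1, s0)
    expect_lte(empirical_p(s1, ens), p0)
  }
})

test_that("in-set backgrounds remove the conservativeness of an all-genes null", {
  # in-set genes score low, out-of-set genes high: an all-genes null is
  # dominated by high out-of-set draws, pushing P toward 1; the in-set
  # null is the calibrated comparison and yields smaller P
  set.seed(67)
  lo <- stats::setNames(rchisq(150, 1) * 0.3, sprintf("in%03d", 1:150))
  hi <- stats::setNames(rchisq(150, 1) * 3, sprintf("out%03d", 1:150))
  tab <- toy_table(c(lo, hi))
  coll <- toy_collection(list(S = sample(names(lo), 20),
                              T2 = sample(names(lo), 30)))
  p_inset <- sequential_test(coll, tab, background = names(lo),
                             block = 3000L, max_n = 3000L, seed = 7)$p_value
  p_all <- sequential_test(coll, tab, background = tab$gene_id,
                           block = 3000L, max_n = 3000L, seed = 7)$p_value
  expect_true(all(p_inset <= p_all))
  expect_true(any(p_inset < p_all))
})

test_that("the parametric zero-inflated chi-square null behaves at its edges", {
  expect_equal(parametric_null_p(0.5, 5L, zero_prop = 1, n_mc = 1000L,
                                 seed = 1), 1 / 1001)
  p <- parametric_null_p(stats::qchisq(0.95, 1)^0.25, 1L, zero_prop = 0,
                         n_mc = 40000L, seed = 2)
  expect_lt(abs(p - 0.05), 3 * sqrt(0.05 * 0.95 / 40000))
  # gene-level zero fraction under the default mixture
  set.seed(3)
  x <- stats::rchisq(10000, 1)^0.25 * stats::rbinom(10000, 1, 0.5)
  expect_lt(abs(mean(x == 0) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("the fitted test object flags both-pass candidates and prints", {
  u <- simulate_universe(sim_config(n_genes = 600, n_sets = 20,
                                    signal_sets = 2, signal_ncp = 12,
                                    seed = 17))
  sets <- filter_min_size(restrict_to_scored(u$collection, u$table), 5L)
  fit <- sumstat_test(sets, u$table, block = 1000L, max_n = 8000L, seed = 2)
  r <- fit$results
  expect_identical(r$is_candidate, r$q_value < 0.2 & r$q_notop < 0.2)
  expect_true(all(r$p_value > 0 & r$p_value <= 1))
  expect_output(print(fit), "candidates")
  expect_s3_class(candidates(fit), "data.frame")

  fit0 <- sumstat_test(sets, u$table, alpha = 0, block = 500L,
                       max_n = 500L, seed = 2)
  expect_equal(sum(fit0$results$is_candidate), 0L)
})
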