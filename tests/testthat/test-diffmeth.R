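test_that("fisher_site reproduces hand-verified published tables", {
  # promoter rows with reconstructible 2x2 tables: Dmrtc2 (5,5 vs 0,5),
  # Cartpt (both consistent tables), Speer6-ps1 (6,6 vs 1,5)
  expect_equal(fisher_site(5, 5, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(round(fisher_site(5, 5, 0, 5), 2), 0.01)
  expect_equal(fisher_site(5, 5, 1, 5), 12 / 252, tolerance = 1e-12)
  expect_equal(fisher_site(4, 5, 0, 5), 12 / 252, tolerance = 1e-12)
  expect_equal(round(fisher_site(5, 5, 1, 5), 2), 0.05)
  expect_equal(fisher_site(6, 6, 1, 5), 7 / 462, tolerance = 1e-12)
  expect_equal(round(fisher_site(6, 6, 1, 5), 2), 0.02)
})

test_that("fisher_site equals enumeration oracle on the full n<=12 grid", {
  for (n1 in 1:12) for (n2 in 1:12) {
    for (x1 in 0:n1) for (x2 in 0:n2) {
      p <- fisher_site(x1, n1, x2, n2)
      expect_equal(p, oracle_fisher(x1, n1, x2, n2), tolerance = 1e-12)
    }
  }
})

test_that("fisher_site matches stats::fisher.test on random large tables", {
  set.seed(8)
  for (i in 1:50) {
    n1 <- sample(5:400, 1); n2 <- sample(5:400, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    m <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2)
    expect_equal(fisher_site(x1, n1, x2, n2),
                 stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("fisher_site is invariant under group swap", {
  set.seed(12)
  for (i in 1:30) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    expect_equal(fisher_site(x1, n1, x2, n2), fisher_site(x2, n2, x1, n1),
                 tolerance = 1e-12)
  }
  expect_error(fisher_site(6, 5, 0, 5), "x_i <= n_i")
})

test_that("ttest_site handles degenerate and separated inputs", {
  d <- ttest_site(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  s <- ttest_site(c(0, 0, 0), c(1, 1, 1))
  expect_true(s$degenerate)
  expect_equal(s$p_value, 0)
  eps <- 1e-6
  j <- ttest_site(c(0, eps, -eps), c(1, 1 + eps, 1 - eps))
  expect_lt(j$p_value, 1e-6)
  expect_false(j$degenerate)
  expect_error(ttest_site(0.5, c(0.4, 0.6)), "replicates")
})

test_that("ttest_site holds its nominal type-I error under the null", {
  set.seed(202)
  n_sim <- 10000
  rej <- 0L
  # 5 replicates per group: enough for the Welch-Satterthwaite
  # approximation to hold its nominal size (n = 3 is known to run a
  # little liberal)
  for (i in seq_len(n_sim)) {
    if (ttest_site(rnorm(5), rnorm(5))$p_value < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / n_sim - 0.05), 0.01)
})

test_that("reconstruct_table inverts published totals and differences", {
  r <- reconstruct_table(5, 5, 1.0)
  expect_true(r$unique)
  expect_equal(r$candidates$x1, 5L)
  expect_equal(r$candidates$x2, 0L)

  r <- reconstruct_table(6, 5, 0.8)
  expect_true(r$unique)
  expect_equal(unlist(r$candidates[, c("x1", "x2")], use.names = FALSE),
               c(6L, 1L))

  r <- reconstruct_table(5, 5, 0.8)
  expect_false(r$unique)
  expect_equal(nrow(r$candidates), 2L)
  key <- paste(r$candidates$x1, r$candidates$x2)
  expect_setequal(key, c("5 1", "4 0"))
  # both candidates share the Fisher p (column-complement symmetry)
  ps <- mapply(fisher_site, r$candidates$x1, 5, r$candidates$x2, 5)
  expect_equal(ps[1], ps[2], tolerance = 1e-12)
})

make_calls <- function(cov, xc, start = seq_along(cov)) {
  data.frame(contig = "c", start = start, end = start + 1L, strand = "+",
             context = "CpG", count_C = xc, count_T = cov - xc,
             coverage = cov, level = xc / cov)
}

test_that("run_comparison filters, labels and swaps correctly", {
  g1 <- make_calls(c(4L, 10L, 8L), c(0L, 9L, 1L))
  g2 <- make_calls(c(9L, 10L, 8L), c(9L, 1L, 1L))
  dm <- run_comparison(g1, g2, diff_config(), labels = c("L", "H"))
  # site 1 has coverage 4 < 5 in group 1: excluded
  expect_equal(dm$start, c(2L, 3L))
  expect_equal(dm$total_L, c(10L, 8L))
  expect_equal(dm$diff, c(0.1 - 0.9, 0))
  expect_equal(dm$direction, c("hypo", "none"))
  expect_equal(dm$p_value[1], fisher_site(9, 10, 1, 10))
  # swapping groups negates diff, keeps p
  sw <- run_comparison(g2, g1, diff_config(), labels = c("H", "L"))
  expect_equal(sw$diff, -dm$diff)
  expect_equal(sw$p_value, dm$p_value)
})

test_that("identical groups yield no signal beyond the alpha level", {
  set.seed(91)
  cov <- sample(5:20, 400, replace = TRUE)
  xc <- rbinom(400, cov, 0.5)
  g <- make_calls(cov, xc)
  dm <- run_comparison(g, g, diff_config())
  expect_true(all(dm$diff == 0))
  expect_equal(attr(dm, "summary")$n_significant, 0L)
})

test_that("replicate-level t-test route works with Fisher fallback", {
  set.seed(14)
  reps1 <- lapply(1:3, function(i) make_calls(rep(10L, 6), rep(1L, 6)))
  reps2 <- lapply(1:3, function(i) make_calls(rep(10L, 6), rep(9L, 6)))
  # starve one site of replicate coverage in group 2
  reps2[[1]]$coverage[1] <- 2L; reps2[[1]]$count_T[1] <- 1L
  reps2[[2]]$coverage[1] <- 2L; reps2[[2]]$count_T[1] <- 1L
  dm <- suppressMessages(
    run_comparison(reps1, reps2, diff_config(test = "ttest")))
  expect_true("ttest" %in% dm$test_used)
  expect_true("fisher" %in% dm$test_used)
  expect_true(all(dm$p_value[dm$test_used == "ttest"] < 0.05 |
                    dm$p_value[dm$test_used == "ttest"] == 0))
})

test_that("planted differential sites are detected end to end", {
  cfg <- sim_config(genome_length = 12000, seed = 44, enzyme_site_rate = 6,
                    island_count = 4, island_length = 300,
                    dm_fraction = 0.2, dm_effect = 1,
                    coverage_target = 12, replicates_per_group = 1)
  sim <- simulate_rrbs(cfg)
  refdb <- build_reference(sim$fragments, sim$simg$genome)
  calls <- lapply(sim$reads, function(r)
    pileup(align_reads(r, refdb), r, refdb, sim$simg$genome))
  dm <- run_comparison(calls$LMFA_1, calls$HMFA_1,
                       labels = cfg$group_labels)
  planted <- sim$truth[sim$truth$is_dm, ]
  key <- paste(dm$contig, dm$start, dm$strand)
  hit <- dm[match(paste(planted$contig, planted$pos, planted$strand), key), ]
  tested <- !is.na(hit$p_value)
  expect_gt(mean(tested), 0.8)
  expect_gt(mean(hit$significant[tested]), 0.9)
  # empirical FDR among significant calls stays moderate
  sig <- dm[dm$significant, ]
  truly <- paste(planted$contig, planted$pos, planted$strand)
  fdr <- mean(!(paste(sig$contig, sig$start, sig$strand) %in% truly))
  expect_lt(fdr, 0.3)
})
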