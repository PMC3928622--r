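test_that("sim_config validates its stated world", {
  expect_s3_class(tiny_sim(), "sim_config")
  expect_error(sim_config(genome_length = 0), "genome_length")
  expect_error(sim_config(dm_fraction = 1.5), "fractions")
  expect_error(sim_config(group_labels = "one"), "two group labels")
  expect_error(sim_config(replicates_per_group = 0), "replicates")
})

test_that("genome generation is byte-deterministic under a fixed seed", {
  cfg <- tiny_sim(seed = 7, len = 10000)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(g1$genome, f1); write_fasta(g2$genome, f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(g1$genes, g2$genes)
  unlink(c(f1, f2))
})

test_that("degenerate configurations are refused", {
  expect_error(generate_genome(tiny_sim(enzyme_site_rate = 0)),
               "no digestible fragments")
})

test_that("generated genomes yield size-selected fragments", {
  simg <- generate_genome(sim_config(genome_length = 50000, seed = 3))
  frags <- digest_genome(simg$genome)
  expect_gt(sum(frags$selected), 0L)
  expect_true(all(frags$length[frags$selected] >= 40L &
                    frags$length[frags$selected] <= 350L))
  # digest cuts equal the substring-scan oracle
  expect_equal(sort(unique(c(frags$start, frags$end))),
               sort(unique(c(0L, oracle_cuts(simg$genome[[1]]),
                             nchar(simg$genome[[1]])))))
})

test_that("methylation assignment honours dm_fraction and dm_effect", {
  simg <- generate_genome(tiny_sim(seed = 9, len = 20000))

  t0 <- assign_methylation(simg, tiny_sim(seed = 9, len = 20000,
                                          dm_fraction = 0))
  expect_equal(t0$p_LMFA, t0$p_HMFA)
  expect_false(any(t0$is_dm))

  t1 <- assign_methylation(simg, tiny_sim(seed = 9, len = 20000,
                                          dm_effect = 1))
  dm <- t1[t1$is_dm, ]
  expect_gt(nrow(dm), 0)
  expect_true(all(dm$p_LMFA %in% c(0, 1)))
  expect_true(all(dm$p_HMFA %in% c(0, 1)))
  expect_true(all(dm$p_LMFA != dm$p_HMFA))
  expect_true(all(dm$context == "CpG"))
  expect_true(all(dm$assayable))
  # non-selected sites identical across groups
  rest <- t1[!t1$is_dm, ]
  expect_equal(rest$p_LMFA, rest$p_HMFA)
})

test_that("flagged fraction matches dm_fraction within binomial error", {
  cfg <- sim_config(genome_length = 60000, seed = 21, dm_fraction = 0.16)
  simg <- generate_genome(cfg)
  truth <- assign_methylation(simg, cfg)
  n_elig <- sum(truth$eligible)
  expect_gt(n_elig, 500)
  frac <- sum(truth$is_dm) / n_elig
  se <- sqrt(0.16 * 0.84 / n_elig)
  expect_lt(abs(frac - 0.16), 4 * se)
})

test_that("fully unmethylated world with perfect conversion emits no C", {
  cfg <- tiny_sim(seed = 13, conversion_efficiency = 1,
                  sequencing_error_rate = 0, replicates_per_group = 1,
                  coverage_target = 4)
  simg <- generate_genome(cfg)
  truth <- assign_methylation(simg, cfg)
  truth$p_LMFA <- 0; truth$p_HMFA <- 0
  sim <- simulate_reads(simg, truth, cfg)
  seqs <- unlist(lapply(sim$reads, `[[`, "seq"))
  expect_gt(length(seqs), 0)
  expect_false(any(grepl("C", seqs)))
})

test_that("fully methylated error-free reads equal the raw template", {
  cfg <- tiny_sim(seed = 14, sequencing_error_rate = 0,
                  replicates_per_group = 1, coverage_target = 4)
  simg <- generate_genome(cfg)
  truth <- assign_methylation(simg, cfg)
  truth$p_LMFA <- 1; truth$p_HMFA <- 1
  sim <- simulate_reads(simg, truth, cfg)
  g <- simg$genome[[1]]
  for (key in names(sim$reads)) {
    reads <- sim$reads[[key]]
    tr <- sim$read_truth[sim$read_truth$group ==
                           sub("_.*", "", key), ]
    tr <- tr[tr$replicate == as.integer(sub(".*_", "", key)), ]
    idx <- match(reads$id, tr$read_id)
    for (j in seq_len(nrow(reads))) {
      t <- tr[idx[j], ]
      tmpl <- if (t$strand == "+") {
        substr(g, t$start + 1, t$start + t$length)
      } else {
        rc <- substr(g, t$start - t$length + 2, t$start + 1)
        chartr("ACGT", "TGCA",
               paste(rev(strsplit(rc, "")[[1]]), collapse = ""))
      }
      expect_identical(reads$seq[j], tmpl)
    }
  }
})

test_that("per-site C fraction in reads follows the true probability", {
  cfg <- sim_config(genome_length = 4000, seed = 31, enzyme_site_rate = 8,
                    island_count = 2, island_length = 300,
                    conversion_efficiency = 1, sequencing_error_rate = 0,
                    replicates_per_group = 1, coverage_target = 200)
  simg <- generate_genome(cfg)
  truth <- assign_methylation(simg, cfg)
  truth$p_LMFA <- 0.75; truth$p_HMFA <- 0.75
  sim <- simulate_reads(simg, truth, cfg)
  reads <- sim$reads[[1]]
  tr <- sim$read_truth[sim$read_truth$group == cfg$group_labels[1] &
                         sim$read_truth$replicate == 1, ]
  # pick one assayable CpG site on the top strand and count directly
  site <- truth[truth$eligible & truth$strand == "+", ][1, ]
  idx <- match(reads$id, tr$read_id)
  nC <- 0L; nT <- 0L
  for (j in seq_len(nrow(reads))) {
    t <- tr[idx[j], ]
    if (t$strand != "+") next
    rel <- site$pos - t$start
    if (rel < 0 || rel >= t$length) next
    b <- substr(reads$seq[j], rel + 1, rel + 1)
    if (b == "C") nC <- nC + 1L else if (b == "T") nT <- nT + 1L
  }
  cov <- nC + nT
  expect_gt(cov, 50)
  expect_lt(abs(nC / cov - 0.75), 3 * sqrt(0.75 * 0.25 / cov))
})

test_that("simulator runs are reproducible end to end", {
  cfg <- tiny_sim(seed = 5, len = 4000, coverage_target = 3,
                  replicates_per_group = 1)
  s1 <- simulate_rrbs(cfg)
  s2 <- simulate_rrbs(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_simdata(s1, d1); write_simdata(s2, d2)
  m1 <- tools::md5sum(list.files(d1, full.names = TRUE))
  m2 <- tools::md5sum(list.files(d2, full.names = TRUE))
  expect_equal(unname(m1), unname(m2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("every read traces to a selected fragment end", {
  cfg <- tiny_sim(seed = 6, len = 4000, coverage_target = 2,
                  replicates_per_group = 1)
  sim <- simulate_rrbs(cfg)
  sel <- sim$fragments[sim$fragments$selected, ]
  tr <- sim$read_truth
  expect_true(all(tr$fragment_id %in% sel$fragment_id))
  i <- match(tr$fragment_id, sel$fragment_id)
  ok <- ifelse(tr$strand == "+",
               tr$start >= sel$start[i] & tr$start < sel$end[i],
               tr$start < sel$end[i] & tr$start >= sel$start[i])
  expect_true(all(ok))
})
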