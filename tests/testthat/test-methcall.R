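test_that("context classification follows the CpG/CHG/CHH rules", {
  expect_equal(classify_context("CGA", 0, "+"), "CpG")
  expect_equal(classify_context("CTG", 0, "+"), "CHG")
  expect_equal(classify_context("CTT", 0, "+"), "CHH")
  expect_equal(classify_context("ACG", 1, "+"), "CpG")
  # bottom strand: G in genome is the cytosine; neighbours read leftward
  expect_equal(classify_context("CGA", 1, "-"), "CpG")
  expect_equal(classify_context("ACAG", 3, "-"), "CHG")
  expect_equal(classify_context("TTG", 2, "-"), "CHH")
  # context windows leaving the contig or touching N are NA
  expect_true(is.na(classify_context("CT", 0, "+")))
  expect_true(is.na(classify_context("CNG", 0, "+")))
  expect_error(classify_context("AGT", 0, "+"), "not a cytosine")
})

test_that("cytosine_sites partitions every site into one context", {
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  sites <- cytosine_sites(s, "chr")
  expect_true(all(sites$context %in% c("CpG", "CHG", "CHH")))
  chars <- strsplit(s, "")[[1]]
  expect_true(all(chars[sites$pos[sites$strand == "+"] + 1] == "C"))
  expect_true(all(chars[sites$pos[sites$strand == "-"] + 1] == "G"))
  # CpG sites come in strand pairs at adjacent positions
  cpg_top <- sites$pos[sites$strand == "+" & sites$context == "CpG"]
  cpg_bot <- sites$pos[sites$strand == "-" & sites$context == "CpG"]
  expect_setequal(cpg_top + 1L, cpg_bot)
})

# one controlled fragment: 10A CCGG <body> TCGA 10A, so a single
# size-selected fragment whose top-strand 5' end we cover with synthetic
# reads
crafted_world <- function(body) {
  g <- c(chr = paste0(strrep("A", 10), "CCGG", body, "TCGA", strrep("A", 10)))
  frags <- digest_genome(g, digest_config(1, 350))
  refdb <- build_reference(frags, g, digest_config(1, 350))
  list(genome = g, refdb = refdb,
       top5 = refdb$entries$entry_id[refdb$entries$strand == "+" &
                                       refdb$entries$which_end == "5prime"])
}

test_that("pileup implements m = C / (C + T) with the C-or-T rule", {
  w <- crafted_world("ACGTAAT")
  # top-strand 5' entry raw: fragment runs from the MspI cut (inside
  # CCGG) to the TaqI cut (inside TCGA)
  entry <- w$refdb$raw[match(w$top5, w$refdb$entries$entry_id)]
  expect_equal(entry, "CGGACGTAATT")
  # site of interest: the C of ACGT inside the body (entry position 5)
  reads <- data.frame(
    id = as.character(1:5),
    seq = c("TGGATGTAAT",   # converted everywhere (T at site)
            "TGGACGTAAT",   # methylated at site (C)
            "TGGACGTAAT",
            "TGGACGTAAT",
            "TGGAGGTAAT"))  # sequencing error G at site
  aln <- align_reads(reads, w$refdb)
  expect_true(all(aln$verdict == "unique"))
  calls <- pileup(aln, reads, w$refdb, w$genome)
  site <- calls[calls$strand == "+" & calls$context == "CpG" &
                  calls$count_C == 3, ]
  expect_equal(nrow(site), 1L)
  expect_equal(site$count_T, 1L)      # G read excluded from coverage
  expect_equal(site$coverage, 4L)
  expect_equal(site$level, 0.75)
  expect_equal(site$end, site$start + 1L)
})

test_that("pileup conserves read-base observations", {
  cfg <- tiny_sim(seed = 19, len = 4000, replicates_per_group = 1,
                  coverage_target = 4)
  sim <- simulate_rrbs(cfg)
  refdb <- build_reference(sim$fragments, sim$simg$genome)
  reads <- sim$reads[[1]]
  aln <- align_reads(reads, refdb)
  calls <- pileup(aln, reads, refdb, sim$simg$genome)
  # independent recount of C/T observations over reference cytosines
  kept <- aln[aln$verdict == "unique", ]
  total <- 0L
  for (j in seq_len(nrow(kept))) {
    e <- match(kept$entry_id[j], refdb$entries$entry_id)
    ech <- strsplit(refdb$raw[e], "")[[1]]
    rch <- strsplit(reads$seq[match(kept$read_id[j], reads$id)], "")[[1]]
    span <- (kept$offset[j] + 1):(kept$offset[j] + length(rch))
    cpos <- which(ech[span] == "C")
    gp <- refdb$offsets[[e]][span[cpos]]
    ctx_ok <- !is.na(classify_context(sim$simg$genome[[1]], gp,
                                      rep(refdb$entries$strand[e],
                                          length(gp))))
    total <- total + sum(rch[cpos] %in% c("C", "T") & ctx_ok)
  }
  expect_equal(sum(calls$coverage), total)
})

test_that("methylation estimates recover the truth binomially", {
  cfg <- sim_config(genome_length = 4000, seed = 37, enzyme_site_rate = 8,
                    island_count = 2, island_length = 250,
                    conversion_efficiency = 1, sequencing_error_rate = 0,
                    replicates_per_group = 1, coverage_target = 300)
  simg <- generate_genome(cfg)
  truth <- assign_methylation(simg, cfg)
  truth$p_LMFA <- 0.6; truth$p_HMFA <- 0.6
  sim <- simulate_reads(simg, truth, cfg)
  refdb <- build_reference(sim$fragments, simg$genome)
  reads <- sim$reads[[1]]
  aln <- align_reads(reads, refdb)
  calls <- pileup(aln, reads, refdb, simg$genome)
  big <- calls[calls$coverage >= 200, ]
  expect_gt(nrow(big), 20)
  ok <- abs(big$level - 0.6) <= 3 * sqrt(0.6 * 0.4 / big$coverage)
  expect_gt(mean(ok), 0.97)
})

test_that("exported tracks round-trip and validate", {
  w <- crafted_world("ACGTTACGAAT")
  reads <- data.frame(id = "1", seq = substr(w$refdb$raw[1], 1, 14))
  aln <- align_reads(reads, w$refdb)
  calls <- pileup(aln, reads, w$refdb, w$genome)
  prefix <- tempfile()
  paths <- export_tracks(calls, prefix)
  back <- read_calls(paths["tsv"])
  expect_equal(back, calls)
  bg <- read_bedgraph(paths["bedGraph"])
  expect_true(all(bg$start < bg$end))
  expect_false(is.unsorted(bg$start))
  # empty call set still writes valid files
  empty <- calls[0, ]
  p2 <- export_tracks(empty, tempfile())
  expect_equal(nrow(read_calls(p2["tsv"])), 0L)
  expect_equal(nrow(read_bedgraph(p2["bedGraph"])), 0L)
  unlink(c(paths, p2))
})

test_that("pooling replicates sums counts and recomputes levels", {
  a <- data.frame(contig = "c", start = c(0L, 5L), end = c(1L, 6L),
                  strand = "+", context = "CpG",
                  count_C = c(2L, 0L), count_T = c(1L, 4L),
                  coverage = c(3L, 4L), level = c(2 / 3, 0))
  b <- data.frame(contig = "c", start = 0L, end = 1L, strand = "+",
                  context = "CpG", count_C = 1L, count_T = 2L,
                  coverage = 3L, level = 1 / 3)
  pooled <- pool_calls(list(a, b))
  expect_equal(pooled$count_C[pooled$start == 0], 3L)
  expect_equal(pooled$coverage[pooled$start == 0], 6L)
  expect_equal(pooled$level[pooled$start == 0], 0.5)
  expect_equal(pooled$coverage[pooled$start == 5], 4L)
})
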