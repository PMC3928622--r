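# Synthetic RRBS world: toy genomes with planted CpG islands and
# restriction sites, a ground-truth methylome, and bisulfite reads with
# per-cytosine conversion records.

#' Simulation configuration
#'
#' Stated world for the synthetic RRBS experiment: a two-group (LMFA vs
#' HMFA maternal folic acid), three-replicate design sequenced to roughly
#' 12x per-site depth with 50-bp single-end reads from MspI/TaqI fragment
#' ends, a 16% differentially methylated CpG fraction and tables-scale
#' effect sizes (|delta m| around 0.8).
#'
#' @param genome_length Contig length in bases.
#' @param gc_content Background GC fraction.
#' @param island_count,island_length Number and length of planted
#'   CpG-dense, GC-rich segments.
#' @param enzyme_site_rate Expected planted recognition sites per kb, for
#'   each enzyme.
#' @param group_labels Two group names; the second is the "treatment"
#'   whose methylation difference is reported as `m2 - m1`.
#' @param replicates_per_group Biological replicates per group.
#' @param mean_context_methylation Named fractions giving the mean true
#'   methylation probability per context.
#' @param dm_fraction Fraction of eligible (assayable CpG) strand-sites
#'   planted as differential.
#' @param dm_effect Absolute between-group probability difference at
#'   planted sites; the two group probabilities are
#'   `(1 - dm_effect)/2` and `(1 + dm_effect)/2` (so `dm_effect = 1`
#'   yields probabilities 0 and 1).
#' @param coverage_target Mean per-group read depth at a sequenced
#'   strand-site.
#' @param conversion_efficiency Probability an unmethylated cytosine is
#'   read as T (methylated cytosines always stay C).
#' @param sequencing_error_rate Per-base substitution error probability.
#' @param read_length Read length in bases.
#' @param end_trim Fixed number of bases trimmed from each read start
#'   (mitigation knob for end-repair artifacts, which are not modelled).
#' @param n_genes Number of toy gene models to emit (`NULL`: scaled to
#'   genome length).
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 50000L,
                       gc_content = 0.42,
                       island_count = 8L,
                       island_length = 600L,
                       enzyme_site_rate = 4,
                       group_labels = c("LMFA", "HMFA"),
                       replicates_per_group = 3L,
                       mean_context_methylation = c(CpG = 0.75, CHG = 0.02,
                                                    CHH = 0.02),
                       dm_fraction = 0.16,
                       dm_effect = 0.8,
                       coverage_target = 12,
                       conversion_efficiency = 0.995,
                       sequencing_error_rate = 0.001,
                       read_length = 50L,
                       end_trim = 0L,
                       n_genes = NULL,
                       seed = 1L) {
  frac_ok <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (genome_length <= 0) stop("genome_length must be positive")
  if (!frac_ok(gc_content) || !frac_ok(dm_fraction) || !frac_ok(dm_effect) ||
      !frac_ok(conversion_efficiency) || !frac_ok(sequencing_error_rate) ||
      !frac_ok(mean_context_methylation)) {
    stop("all fractions must lie in [0, 1]")
  }
  if (!setequal(names(mean_context_methylation), c("CpG", "CHG", "CHH"))) {
    stop("mean_context_methylation must name CpG, CHG and CHH")
  }
  if (length(group_labels) != 2L) stop("exactly two group labels required")
  if (replicates_per_group < 1L) stop("replicates_per_group must be >= 1")
  if (read_length <= 0L) stop("read_length must be positive")
  if (enzyme_site_rate < 0) stop("enzyme_site_rate must be non-negative")
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content,
                 island_count = as.integer(island_count),
                 island_length = as.integer(island_length),
                 enzyme_site_rate = enzyme_site_rate,
                 group_labels = as.character(group_labels),
                 replicates_per_group = as.integer(replicates_per_group),
                 mean_context_methylation = mean_context_methylation,
                 dm_fraction = dm_fraction,
                 dm_effect = dm_effect,
                 coverage_target = coverage_target,
                 conversion_efficiency = conversion_efficiency,
                 sequencing_error_rate = sequencing_error_rate,
                 read_length = as.integer(read_length),
                 end_trim = as.integer(end_trim),
                 n_genes = n_genes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a toy genome with planted islands, sites and gene models
#'
#' Background sequence is drawn at `gc_content`; CpG islands are planted
#' as GC-rich segments with forced CG dinucleotides (>= 3x background CpG
#' frequency); MspI (`CCGG`) and TaqI (`TCGA`) recognition sites are
#' planted at `enzyme_site_rate` per kb each so that the digest yields
#' fragments in the 40-350 bp analysis window. Toy gene models (spans,
#' exons) are laid out for the annotation stage.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `rrbs_simgenome`: list with `genome` (named
#'   character), `genes`, `exons`, `islands` (0-based half-open data
#'   frames) and `cfg`.
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$enzyme_site_rate == 0) {
    stop("no digestible fragments: enzyme_site_rate is 0")
  }
  set.seed(cfg$seed)
  n <- cfg$genome_length
  gc <- cfg$gc_content
  bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  # plant non-overlapping CpG islands
  islands <- data.frame(contig = character(), start = integer(),
                        end = integer())
  if (cfg$island_count > 0L && cfg$island_length < n) {
    slots <- floor(n / max(cfg$island_length * 3L, 1L))
    k <- min(cfg$island_count, slots)
    if (k > 0L) {
      slot_ids <- sort(sample.int(slots, k))
      starts <- (slot_ids - 1L) * cfg$island_length * 3L +
        cfg$island_length %/% 2L
      for (s in starts) {
        idx <- (s + 1L):(s + cfg$island_length)
        bases[idx] <- sample(c("A", "C", "G", "T"), cfg$island_length,
                             replace = TRUE,
                             prob = c(0.175, 0.325, 0.325, 0.175))
        # force CG dinucleotides every 7 bp: island CpG freq ~0.14/dinuc,
        # well above 3x the ~0.04 background
        cg_at <- seq(s + 1L, s + cfg$island_length - 1L, by = 7L)
        bases[cg_at] <- "C"
        bases[cg_at + 1L] <- "G"
      }
      islands <- data.frame(contig = "chrS", start = starts,
                            end = starts + cfg$island_length)
    }
  }

  # plant restriction sites (uniform positions, Poisson counts)
  for (site in c("CCGG", "TCGA")) {
    k <- stats::rpois(1L, cfg$enzyme_site_rate * n / 1000)
    if (k > 0L) {
      pos <- sample.int(n - 4L, min(k, n - 4L))
      for (j in 1:4) bases[pos + j - 1L] <- substr(site, j, j)
    }
  }
  seq <- paste(bases, collapse = "")

  # toy gene models: evenly spaced spans with 2-4 exons each
  n_genes <- if (is.null(cfg$n_genes)) max(4L, n %/% 5000L) else
    as.integer(cfg$n_genes)
  pitch <- n %/% (n_genes + 1L)
  gene_len <- max(200L, min(2000L, pitch %/% 2L))
  gstart <- pitch * seq_len(n_genes) - gene_len %/% 2L
  gstart <- pmax(0L, pmin(gstart, n - gene_len))
  genes <- data.frame(contig = "chrS", start = gstart,
                      end = gstart + gene_len,
                      name = sprintf("gene%03d", seq_len(n_genes)),
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    k <- sample(2:4, 1L)
    w <- gene_len %/% (2L * k)
    es <- genes$start[i] + (0:(k - 1L)) * 2L * w
    data.frame(contig = "chrS", start = es, end = es + w,
               name = genes$name[i], strand = genes$strand[i],
               stringsAsFactors = FALSE)
  }))

  genome <- c(chrS = seq)
  frags <- digest_genome(genome)
  if (!any(frags$selected)) {
    stop("no digestible fragments in the size-selection window; ",
         "increase genome_length or enzyme_site_rate")
  }
  structure(list(genome = genome, genes = genes, exons = exons,
                 islands = islands, cfg = cfg),
            class = "rrbs_simgenome")
}

# strand-sites reachable by sequencing: within read_length of the
# sequencing start of a selected fragment (top strand: left edge; bottom
# strand: right edge)
#' @keywords internal
assayable_mask <- function(sites, fragments, cfg) {
  sel <- fragments[fragments$selected, , drop = FALSE]
  ok <- rep(FALSE, nrow(sites))
  L <- cfg$read_length
  for (i in seq_len(nrow(sel))) {
    fr <- sel[i, ]
    w <- min(L, fr$length)
    top <- sites$strand == "+" & sites$contig == fr$contig &
      sites$pos >= fr$start & sites$pos < fr$start + w
    bot <- sites$strand == "-" & sites$contig == fr$contig &
      sites$pos >= fr$end - w & sites$pos < fr$end
    ok <- ok | top | bot
  }
  ok
}

#' Assign a ground-truth methylome
#'
#' Every cytosine on both strands receives a true methylation probability
#' per group, drawn from a context-specific Beta distribution around
#' `mean_context_methylation`. A `dm_fraction` Bernoulli subset of the
#' eligible sites (CpG strand-sites inside the sequenced portion of
#' size-selected fragments, i.e. the RRBS-assayable territory) is made
#' differential: group probabilities `(1 - dm_effect)/2` and
#' `(1 + dm_effect)/2`, direction random. All other sites are identical
#' across groups.
#'
#' @param simg An `rrbs_simgenome` from [generate_genome()].
#' @param cfg A [sim_config()] (normally the one inside `simg`).
#' @return `data.frame` truth table with one row per strand-site:
#'   `contig`, `pos` (0-based), `strand`, `context`, `assayable`,
#'   `eligible`, `is_dm`, `direction` and one `p_<group>` column per group.
#' @export
assign_methylation <- function(simg, cfg = simg$cfg) {
  stopifnot(inherits(simg, "rrbs_simgenome"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  sites <- do.call(rbind, lapply(names(simg$genome), function(ctg) {
    cytosine_sites(simg$genome[[ctg]], ctg)
  }))
  frags <- digest_genome(simg$genome)
  sites$assayable <- assayable_mask(sites, frags, cfg)
  sites$eligible <- sites$assayable & sites$context == "CpG"

  m <- cfg$mean_context_methylation[sites$context]
  conc <- 2  # broad Beta: bimodal-ish CpG landscape, near-zero non-CpG
  base <- stats::rbeta(nrow(sites), pmax(m * conc, 1e-3),
                       pmax((1 - m) * conc, 1e-3))
  sites$is_dm <- sites$eligible & stats::runif(nrow(sites)) < cfg$dm_fraction
  sites$direction <- ifelse(sites$is_dm,
                            ifelse(stats::runif(nrow(sites)) < 0.5,
                                   "hyper", "hypo"),
                            "none")
  p_lo <- (1 - cfg$dm_effect) / 2
  p_hi <- (1 + cfg$dm_effect) / 2
  g1 <- ifelse(sites$is_dm, ifelse(sites$direction == "hyper", p_lo, p_hi),
               base)
  g2 <- ifelse(sites$is_dm, ifelse(sites$direction == "hyper", p_hi, p_lo),
               base)
  sites[[paste0("p_", cfg$group_labels[1])]] <- g1
  sites[[paste0("p_", cfg$group_labels[2])]] <- g2
  rownames(sites) <- NULL
  sites
}

#' Simulate bisulfite reads from fragment ends
#'
#' Reads are the first `min(read_length, fragment_length)` bases of a
#' size-selected fragment on one original strand (both strands
#' equiprobable; the sequenced molecules are the two C-poor
#' post-conversion strands). Each cytosine is emitted as C when the site
#' is methylated for that molecule, otherwise as T with probability
#' `conversion_efficiency`; independent per-base substitution errors are
#' then applied. Read names carry no truth; provenance lives in the
#' returned read table.
#'
#' @param simg An `rrbs_simgenome`.
#' @param truth Truth table from [assign_methylation()].
#' @param cfg A [sim_config()].
#' @return List with `reads` (per group/replicate list of `data.frame`s
#'   with `id`, `seq`, `qual`), `read_truth` (provenance: `read_id`,
#'   `group`, `replicate`, `fragment_id`, `strand`, `start`, `length`) and
#'   `fragments` (the digest table used).
#' @export
simulate_reads <- function(simg, truth, cfg = simg$cfg) {
  stopifnot(inherits(simg, "rrbs_simgenome"))
  set.seed(cfg$seed + 2L)
  frags <- digest_genome(simg$genome)
  sel <- frags[frags$selected, , drop = FALSE]
  if (!nrow(sel)) stop("no fragments pass size selection")

  groups <- cfg$group_labels
  reps <- seq_len(cfg$replicates_per_group)
  p_cols <- paste0("p_", groups)
  truth_key <- paste(truth$contig, truth$pos, truth$strand)

  out_reads <- list()
  truth_rows <- list()
  counters <- list()
  rate <- cfg$coverage_target / cfg$replicates_per_group
  err <- cfg$sequencing_error_rate
  eff <- cfg$conversion_efficiency
  other <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))

  for (i in seq_len(nrow(sel))) {
    fr <- sel[i, ]
    L <- min(cfg$read_length, fr$length)
    seq <- simg$genome[[fr$contig]]
    for (strand in c("+", "-")) {
      if (strand == "+") {
        tmpl <- substr(seq, fr$start + 1L, fr$start + L)
        gpos <- fr$start:(fr$start + L - 1L)
      } else {
        tmpl <- revcomp(substr(seq, fr$end - L + 1L, fr$end))
        gpos <- (fr$end - 1L):(fr$end - L)
      }
      tchars <- strsplit(tmpl, "")[[1]]
      cidx <- which(tchars == "C")
      pidx <- match(paste(fr$contig, gpos[cidx], strand), truth_key)
      for (g in seq_along(groups)) {
        pvec <- truth[[p_cols[g]]][pidx]
        pvec[is.na(pvec)] <- 0
        for (r in reps) {
          nr <- stats::rpois(1L, rate)
          if (nr == 0L) next
          mat <- matrix(tchars, nrow = L, ncol = nr)
          if (length(cidx)) {
            meth <- matrix(stats::runif(length(cidx) * nr) < pvec,
                           nrow = length(cidx))
            conv <- matrix(stats::runif(length(cidx) * nr) < eff,
                           nrow = length(cidx))
            asT <- !meth & conv
            for (ci in seq_along(cidx)) {
              mat[cidx[ci], asT[ci, ]] <- "T"
            }
          }
          if (err > 0) {
            hits <- which(stats::runif(L * nr) < err)
            for (h in hits) {
              mat[h] <- sample(other[[mat[h]]], 1L)
            }
          }
          if (cfg$end_trim > 0L && cfg$end_trim < L) {
            mat <- mat[-(seq_len(cfg$end_trim)), , drop = FALSE]
          }
          key <- paste(groups[g], r, sep = "_")
          cnt <- counters[[key]] %||% 0L
          ids <- sprintf("r%07d", cnt + seq_len(nr))
          counters[[key]] <- cnt + nr
          seqs <- apply(mat, 2L, paste, collapse = "")
          out_reads[[key]] <- c(out_reads[[key]], list(
            data.frame(id = ids, seq = seqs,
                       qual = strrep("I", nrow(mat)),
                       stringsAsFactors = FALSE)))
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            read_id = ids, group = groups[g], replicate = r,
            fragment_id = fr$fragment_id, strand = strand,
            start = if (strand == "+") fr$start + cfg$end_trim
                    else fr$end - 1L - cfg$end_trim,
            length = nrow(mat), stringsAsFactors = FALSE)
        }
      }
    }
  }
  reads <- lapply(out_reads, function(lst) do.call(rbind, lst))
  list(reads = reads,
       read_truth = do.call(rbind, truth_rows),
       fragments = frags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulator under one configuration
#'
#' Convenience wrapper calling [generate_genome()],
#' [assign_methylation()] and [simulate_reads()] in order. Identical
#' configurations (including seed) give identical results.
#'
#' @param cfg A [sim_config()].
#' @return List with `simg`, `truth` and the [simulate_reads()] output.
#' @export
simulate_rrbs <- function(cfg) {
  simg <- generate_genome(cfg)
  truth <- assign_methylation(simg, cfg)
  sim <- simulate_reads(simg, truth, cfg)
  list(simg = simg, truth = truth, reads = sim$reads,
       read_truth = sim$read_truth, fragments = sim$fragments)
}

#' Write simulator outputs to disk
#'
#' Emits the genome FASTA, gene/exon/island BED6 files, per
#' group/replicate FASTQ files and TSV truth tables.
#'
#' @param sim Output of [simulate_rrbs()].
#' @param dir Output directory.
#' @return Named character vector of paths written, invisibly.
#' @export
write_simdata <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.bed"),
             exons = file.path(dir, "exons.bed"),
             islands = file.path(dir, "islands.bed"),
             site_truth = file.path(dir, "site_truth.tsv"),
             read_truth = file.path(dir, "read_truth.tsv"))
  write_fasta(sim$simg$genome, paths["genome"])
  write_bed(sim$simg$genes, paths["genes"])
  write_bed(sim$simg$exons, paths["exons"])
  write_bed(sim$simg$islands, paths["islands"])
  write_tsv(sim$truth, paths["site_truth"])
  write_tsv(sim$read_truth, paths["read_truth"])
  for (key in names(sim$reads)) {
    p <- file.path(dir, sprintf("reads_%s.fastq", key))
    write_fastq(sim$reads[[key]], p)
    paths[paste0("fastq_", key)] <- p
  }
  invisible(paths)
}
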