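# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration via lchoose, exhaustive substring
# scans, naive interval membership.

# two-sided Fisher p by explicit enumeration of all tables with the same
# margins, summing probabilities <= observed (same 1+1e-7 tie tolerance
# as the implementation, computed through lchoose instead of dhyper)
oracle_fisher <- function(x1, n1, x2, n2) {
  k <- x1 + x2
  logp_table <- function(a) {
    lchoose(n1, a) + lchoose(n2, k - a) - lchoose(n1 + n2, k)
  }
  support <- max(0, k - n2):min(n1, k)
  lp <- vapply(support, logp_table, numeric(1))
  obs <- logp_table(x1)
  min(1, sum(exp(lp[lp <= obs + log(1 + 1e-7)])))
}

# exhaustive substring-scan digest oracle: every CCGG / TCGA occurrence
# by brute-force windowing, cuts at site start + 1
oracle_cuts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  cuts <- integer()
  if (n >= 4) {
    for (i in 1:(n - 3)) {
      w <- paste(chars[i:(i + 3)], collapse = "")
      if (w == "CCGG" || w == "TCGA") cuts <- c(cuts, i)  # 0-based i-1+1
    }
  }
  sort(cuts)
}

# per-read exhaustive Hamming alignment oracle over every entry and
# offset: converted-space filter, bisulfite-aware recount, margin rule
oracle_align_one <- function(raw_read, refdb, max_mm = 3L, margin = 2L) {
  conv <- chartr("C", "T", raw_read)
  rc <- strsplit(conv, "")[[1]]
  rr <- strsplit(raw_read, "")[[1]]
  L <- length(rc)
  hits <- list()
  for (e in seq_along(refdb$raw)) {
    ec <- strsplit(refdb$conv[e], "")[[1]]
    er <- strsplit(refdb$raw[e], "")[[1]]
    if (length(ec) < L) next
    for (off in 0:(length(ec) - L)) {
      seg <- ec[(off + 1):(off + L)]
      mmc <- sum(rc != seg | rc == "N" | seg == "N")
      if (mmc <= max_mm) {
        segr <- er[(off + 1):(off + L)]
        bs <- sum((rr != segr | rr == "N" | segr == "N") &
                    !(rr == "T" & segr == "C"))
        hits[[length(hits) + 1]] <- list(entry = e, off = off, bs = bs)
      }
    }
  }
  if (!length(hits)) return(list(verdict = "unaligned"))
  bs <- vapply(hits, `[[`, 0, "bs")
  o <- order(bs)
  if (length(bs) > 1 && bs[o[2]] - bs[o[1]] < margin) {
    return(list(verdict = "multi"))
  }
  h <- hits[[o[1]]]
  list(verdict = "unique", entry_id = refdb$entries$entry_id[h$entry],
       offset = h$off, bs = h$bs)
}

# vectorised full-scan oracle for many reads (same semantics as
# oracle_align_one; integer matrices instead of per-read loops so the
# acceptance-scale comparison stays in budget)
oracle_align_bulk <- function(raw_reads, refdb, max_mm = 3L, margin = 2L) {
  code <- function(ch, n_code) {
    m <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = n_code)
    unname(m[ch])
  }
  lens <- nchar(raw_reads)
  n <- length(raw_reads)
  best <- rep(Inf, n); second <- rep(Inf, n)
  best_entry <- rep(NA_character_, n); best_off <- rep(NA_integer_, n)
  ent_raw <- lapply(refdb$raw, function(s) code(strsplit(s, "")[[1]], 6L))
  ent_conv <- lapply(ent_raw, function(v) ifelse(v == 2L, 4L, v))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    rawm <- vapply(strsplit(raw_reads[idx], ""), code, integer(L),
                   n_code = 5L)
    rawm <- matrix(rawm, nrow = L)
    convm <- ifelse(rawm == 2L, 4L, rawm)
    for (e in seq_along(ent_raw)) {
      eL <- length(ent_raw[[e]])
      if (eL < L) next
      for (off in 0:(eL - L)) {
        segc <- ent_conv[[e]][(off + 1):(off + L)]
        mmc <- colSums(convm != segc)
        cand <- which(mmc <= max_mm)
        if (!length(cand)) next
        segr <- ent_raw[[e]][(off + 1):(off + L)]
        sub <- rawm[, cand, drop = FALSE]
        bs <- colSums(sub != segr & !(sub == 4L & segr == 2L))
        gi <- idx[cand]
        better <- bs < best[gi]
        second[gi] <- ifelse(better, best[gi], pmin(second[gi], bs))
        best[gi[better]] <- bs[better]
        best_entry[gi[better]] <- refdb$entries$entry_id[e]
        best_off[gi[better]] <- off
      }
    }
  }
  verdict <- ifelse(!is.finite(best), "unaligned",
                    ifelse(second - best >= margin, "unique", "multi"))
  data.frame(verdict = verdict,
             entry_id = ifelse(verdict == "unique", best_entry, NA),
             offset = ifelse(verdict == "unique", best_off, NA))
}

# naive interval-membership feature oracle (no GRanges)
oracle_feature <- function(pos, contig, genes, exons, promoters) {
  inside <- function(df) {
    any(df$contig == contig & pos >= df$start & pos < df$end)
  }
  if (inside(promoters)) "promoter"
  else if (!is.null(exons) && inside(exons)) "exon"
  else if (inside(genes)) "intron"
  else "intergenic"
}

# small simulated world shared by several test files; ... overrides any
# default (including the tiny-world ones)
tiny_sim <- function(seed = 42, len = 6000, ...) {
  args <- utils::modifyList(
    list(genome_length = len, seed = seed, enzyme_site_rate = 6,
         island_count = 3L, island_length = 300L),
    list(...))
  do.call(sim_config, args)
}
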