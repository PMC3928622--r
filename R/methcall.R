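# Per-cytosine methylation calling: pile up uniquely placed reads through
# the entry offset maps, estimate m = C / (C + T), classify CpG/CHG/CHH
# context from the unconverted reference genome.

#' Classify cytosine sequence context
#'
#' Context is computed from the unconverted reference, never from reads:
#' a cytosine followed by G is CpG; otherwise, G two bases downstream
#' gives CHG, anything else CHH (H = A, C or T). For the bottom strand
#' the downstream direction runs toward lower genome coordinates on the
#' complement. Sites whose context window leaves the contig or touches an
#' N are returned as `NA`.
#'
#' @param seq Contig sequence (character scalar).
#' @param pos 0-based genome position(s) of the cytosine (must be `C` on
#'   `+`, `G` on `-`).
#' @param strand `"+"` or `"-"` (recycled).
#' @return Character vector in `{"CpG","CHG","CHH", NA}`.
#' @export
classify_context <- function(seq, pos, strand) {
  seq <- toupper(seq)
  n <- nchar(seq)
  k <- max(length(pos), length(strand))
  pos <- rep_len(pos, k); strand <- rep_len(strand, k)
  chars <- strsplit(seq, "")[[1]]
  at <- function(p) {
    r <- rep("N", length(p))
    ok <- p >= 0L & p < n
    r[ok] <- chars[p[ok] + 1L]
    r
  }
  base0 <- at(pos)
  ok_base <- ifelse(strand == "+", base0 == "C", base0 == "G")
  if (any(!ok_base)) {
    stop("classify_context: reference base is not a cytosine on the ",
         "requested strand")
  }
  b1 <- ifelse(strand == "+", at(pos + 1L), at(pos - 1L))
  b2 <- ifelse(strand == "+", at(pos + 2L), at(pos - 2L))
  # on the bottom strand the complement of genome C is G etc.
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  b1 <- ifelse(strand == "+", b1, comp[b1])
  b2 <- ifelse(strand == "+", b2, comp[b2])
  out <- ifelse(b1 == "G", "CpG", ifelse(b2 == "G", "CHG", "CHH"))
  out[b1 == "N" | (b1 != "G" & b2 == "N")] <- NA_character_
  unname(out)
}

#' Enumerate all cytosine strand-sites of a contig
#'
#' @param seq Contig sequence.
#' @param contig Contig name for the output table.
#' @return `data.frame` with `contig`, `pos` (0-based), `strand`,
#'   `context`; sites with undeterminable context are dropped.
#' @export
cytosine_sites <- function(seq, contig = "contig1") {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  top <- which(chars == "C") - 1L
  bot <- which(chars == "G") - 1L
  df <- data.frame(contig = contig,
                   pos = c(top, bot),
                   strand = rep(c("+", "-"), c(length(top), length(bot))),
                   stringsAsFactors = FALSE)
  if (!nrow(df)) {
    df$context <- character(0)
    return(df)
  }
  df$context <- classify_context(seq, df$pos, df$strand)
  df <- df[!is.na(df$context), , drop = FALSE]
  df <- df[order(df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Pile up kept alignments into per-cytosine calls
#'
#' For every reference cytosine covered by at least one uniquely placed
#' read, counts reads reporting C and reads reporting T (any other base,
#' e.g. a sequencing error to G, is excluded from coverage) and reports
#' the methylation level `m = count_C / (count_C + count_T)` at genome
#' coordinates via the entry offset maps.
#'
#' @param aln Alignment table from [align_reads()].
#' @param reads The read table that was aligned (`id`, `seq`).
#' @param refdb The `rrbs_refdb` used for alignment.
#' @param genome Genome the reference was built from (context source).
#' @return `data.frame` of calls: `contig`, `start` (0-based), `end`
#'   (`start + 1`), `strand`, `context`, `count_C`, `count_T`,
#'   `coverage`, `level`.
#' @export
pileup <- function(aln, reads, refdb, genome) {
  stopifnot(inherits(refdb, "rrbs_refdb"))
  genome <- as_genome_chr(genome)
  kept <- aln[aln$verdict == "unique", , drop = FALSE]
  entry_idx <- match(kept$entry_id, refdb$entries$entry_id)
  seqs <- reads$seq[match(kept$read_id, reads$id)]
  entry_chars <- lapply(refdb$raw, function(s) strsplit(s, "")[[1]])

  pos_l <- list(); strand_l <- list(); base_l <- list(); ctg_l <- list()
  for (i in seq_len(nrow(kept))) {
    e <- entry_idx[i]
    ech <- entry_chars[[e]]
    off <- kept$offset[i]
    rch <- strsplit(seqs[i], "")[[1]]
    span <- (off + 1L):(off + length(rch))
    cpos <- which(ech[span] == "C")
    if (!length(cpos)) next
    rb <- rch[cpos]
    keep <- rb %in% c("C", "T")
    if (!any(keep)) next
    pos_l[[length(pos_l) + 1L]] <- refdb$offsets[[e]][span[cpos[keep]]]
    strand_l[[length(strand_l) + 1L]] <-
      rep(refdb$entries$strand[e], sum(keep))
    base_l[[length(base_l) + 1L]] <- rb[keep]
    ctg_l[[length(ctg_l) + 1L]] <- rep(refdb$entries$contig[e], sum(keep))
  }
  if (!length(pos_l)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      context = character(), count_C = integer(),
                      count_T = integer(), coverage = integer(),
                      level = numeric()))
  }
  obs <- data.frame(contig = unlist(ctg_l), pos = unlist(pos_l),
                    strand = unlist(strand_l), base = unlist(base_l),
                    stringsAsFactors = FALSE)
  key <- paste(obs$contig, obs$pos, obs$strand, sep = "\r")
  cC <- tapply(obs$base == "C", key, sum)
  cT <- tapply(obs$base == "T", key, sum)
  parts <- strsplit(names(cC), "\r", fixed = TRUE)
  calls <- data.frame(contig = vapply(parts, `[`, "", 1L),
                      start = as.integer(vapply(parts, `[`, "", 2L)),
                      strand = vapply(parts, `[`, "", 3L),
                      count_C = as.integer(cC), count_T = as.integer(cT),
                      stringsAsFactors = FALSE)
  ctx <- rep(NA_character_, nrow(calls))
  for (ctg in unique(calls$contig)) {
    sel <- calls$contig == ctg
    ctx[sel] <- classify_context(genome[[ctg]], calls$start[sel],
                                 calls$strand[sel])
  }
  calls$context <- ctx
  skipped <- sum(is.na(ctx))
  if (skipped) {
    message("pileup: skipped ", skipped,
            " site(s) with undeterminable context (contig edge or N)")
  }
  calls <- calls[!is.na(calls$context), , drop = FALSE]
  calls$end <- calls$start + 1L
  calls$coverage <- calls$count_C + calls$count_T
  calls$level <- calls$count_C / calls$coverage
  calls <- calls[order(calls$contig, calls$start, calls$strand), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls[, c("contig", "start", "end", "strand", "context",
            "count_C", "count_T", "coverage", "level")]
}

#' Pool replicate call tables into group-level calls
#'
#' Counts are summed per site; the level is recomputed from the pooled
#' counts.
#'
#' @param call_list List of call `data.frame`s from [pileup()].
#' @return Pooled call `data.frame` in the same layout.
#' @export
pool_calls <- function(call_list) {
  stopifnot(length(call_list) >= 1L)
  all <- do.call(rbind, call_list)
  key <- paste(all$contig, all$start, all$strand, sep = "\r")
  first <- !duplicated(key)
  out <- all[first, c("contig", "start", "end", "strand", "context"),
             drop = FALSE]
  out$count_C <- as.integer(tapply(all$count_C, key, sum)[key[first]])
  out$count_T <- as.integer(tapply(all$count_T, key, sum)[key[first]])
  out$coverage <- out$count_C + out$count_T
  out$level <- out$count_C / out$coverage
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export calls as bedGraph and TSV
#'
#' bedGraph carries one `[start, start + 1)` interval per site with the
#' methylation level as value; the TSV keeps all fields and round-trips
#' through [read_calls()] exactly.
#'
#' @param calls Call table from [pileup()] or [pool_calls()].
#' @param prefix Output path prefix; writes `<prefix>.bedGraph` and
#'   `<prefix>.tsv`.
#' @return Character vector of paths written, invisibly.
#' @export
export_tracks <- function(calls, prefix) {
  bg <- file.path(paste0(prefix, ".bedGraph"))
  tsv <- file.path(paste0(prefix, ".tsv"))
  write_bedgraph(data.frame(contig = calls$contig, start = calls$start,
                            end = calls$end, value = calls$level),
                 bg, track_name = basename(prefix))
  write_tsv(calls, tsv)
  invisible(c(bedGraph = bg, tsv = tsv))
}

#' Re-read an exported call TSV
#'
#' @param path Path written by [export_tracks()].
#' @return Call `data.frame`.
#' @export
read_calls <- function(path) {
  df <- read_tsv(path)
  need <- c("contig", "start", "end", "strand", "context", "count_C",
            "count_T", "coverage", "level")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("call table missing columns: ",
                         paste(miss, collapse = ", "))
  df
}
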