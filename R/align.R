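# Three-letter bisulfite alignment: search in fully C->T-converted space,
# recount mismatches bisulfite-aware on the unconverted sequences, then
# apply the best-vs-second-best uniqueness margin.

#' Alignment configuration
#'
#' @param max_mismatches Maximum converted-space mismatches for a
#'   candidate placement.
#' @param uniqueness_margin Minimum mismatch gap between best and
#'   second-best placement for a read to be kept ("two more mismatches").
#' @param seed_length Index seed length; retained as a tuning knob for
#'   interface compatibility. The search used here is exhaustive (exact up
#'   to `max_mismatches`) regardless, so no read ever falls outside the
#'   guarantee.
#' @return Object of class `align_config`.
#' @export
align_config <- function(max_mismatches = 3L, uniqueness_margin = 2L,
                         seed_length = 20L) {
  if (uniqueness_margin < 1L) stop("uniqueness_margin must be >= 1")
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0")
  structure(list(max_mismatches = as.integer(max_mismatches),
                 uniqueness_margin = as.integer(uniqueness_margin),
                 seed_length = as.integer(seed_length)),
            class = "align_config")
}

#' Convert a read to three-letter space
#'
#' Replaces every C by T, recording where the conversions happened so the
#' original read can be re-scored after placement.
#'
#' @param seq Read sequence (A/C/G/T/N).
#' @return List with `raw`, `conv` and `converted_positions` (1-based
#'   indices of the Cs in `raw`).
#' @export
convert_read <- function(seq) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  list(raw = seq, conv = convert_ct(seq),
       converted_positions = which(chars == "C"))
}

# mismatch count with N-as-mismatch, plain letter equality
#' @keywords internal
mm_plain <- function(a, b) {
  sum(a != b | a == "N" | b == "N")
}

# bisulfite-aware mismatch count: read-T over reference-C is not a
# mismatch; the reverse (read C over reference T) is; N always mismatches
#' @keywords internal
mm_bisulfite <- function(read, ref) {
  sum((read != ref | read == "N" | ref == "N") &
        !(read == "T" & ref == "C"))
}

#' Enumerate candidate placements in converted space
#'
#' Finds every placement of the converted read inside any reference entry
#' with at most `max_mismatches` converted-space mismatches. The search
#' is exact: \code{Biostrings::vmatchPattern} performs the exhaustive
#' Hamming scan (its N handling can only under-count mismatches, so its
#' hit set is a superset of ours), after which mismatch counts are
#' recomputed under the N-always-mismatches rule and re-filtered.
#'
#' @param conv_read A [convert_read()] result (or a plain converted
#'   sequence).
#' @param refdb An `rrbs_refdb` from [build_reference()].
#' @param cfg An [align_config()].
#' @return `data.frame` with one row per placement: `entry` (index into
#'   `refdb$entries`), `entry_id`, `offset` (0-based within the entry),
#'   `strand`, `conv_mismatches`.
#' @export
candidate_hits <- function(conv_read, refdb, cfg = align_config()) {
  stopifnot(inherits(refdb, "rrbs_refdb"))
  conv <- if (is.list(conv_read)) conv_read$conv else convert_ct(conv_read)
  empty <- data.frame(entry = integer(), entry_id = character(),
                      offset = integer(), strand = character(),
                      conv_mismatches = integer())
  if (!length(refdb$raw) || nchar(conv) == 0L) return(empty)
  subject <- refdb$conv_dss %||% Biostrings::DNAStringSet(refdb$conv)
  m <- Biostrings::vmatchPattern(conv, subject,
                                 max.mismatch = cfg$max_mismatches,
                                 fixed = TRUE)
  starts <- Biostrings::startIndex(m)
  hits <- list()
  rchars <- strsplit(conv, "")[[1]]
  for (e in seq_along(starts)) {
    st <- starts[[e]]
    if (is.null(st) || !length(st)) next
    echars <- strsplit(refdb$conv[e], "")[[1]]
    for (s in st) {
      if (s < 1L || s + length(rchars) - 1L > length(echars)) next
      mm <- mm_plain(rchars, echars[s:(s + length(rchars) - 1L)])
      if (mm <= cfg$max_mismatches) {
        hits[[length(hits) + 1L]] <- data.frame(
          entry = e, entry_id = refdb$entries$entry_id[e],
          offset = s - 1L, strand = refdb$entries$strand[e],
          conv_mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty)
  do.call(rbind, hits)
}

#' Bisulfite-aware mismatch recount
#'
#' Re-scores converted-space placements on the unconverted read and
#' reference: positions where the read shows T over a reference C are
#' ignored (possible unmethylated cytosine), while a read C over a
#' reference T still counts.
#'
#' @param hits Output of [candidate_hits()].
#' @param raw_read Unconverted read sequence.
#' @param refdb The reference database.
#' @return `hits` with an extra `bs_mismatches` column.
#' @export
recount_bisulfite <- function(hits, raw_read, refdb) {
  rchars <- strsplit(toupper(raw_read), "")[[1]]
  hits$bs_mismatches <- vapply(seq_len(nrow(hits)), function(i) {
    echars <- strsplit(refdb$raw[hits$entry[i]], "")[[1]]
    s <- hits$offset[i] + 1L
    mm_bisulfite(rchars, echars[s:(s + length(rchars) - 1L)])
  }, integer(1))
  hits
}

#' Resolve the uniqueness of a read's placements
#'
#' Orders placements by bisulfite-aware mismatches and keeps the best iff
#' it has no competitor within `uniqueness_margin` mismatches (ties at the
#' best count are always discarded).
#'
#' @param hits Placements with a `bs_mismatches` column.
#' @param cfg An [align_config()].
#' @return List with `verdict` (`"unique"`, `"multi"` or `"unaligned"`)
#'   and `hit` (the kept row, or `NULL`).
#' @export
resolve_unique <- function(hits, cfg = align_config()) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(verdict = "unaligned", hit = NULL))
  }
  ord <- order(hits$bs_mismatches)
  best <- hits[ord[1L], , drop = FALSE]
  if (nrow(hits) == 1L) return(list(verdict = "unique", hit = best))
  second <- hits$bs_mismatches[ord[2L]]
  if (second - best$bs_mismatches >= cfg$uniqueness_margin) {
    list(verdict = "unique", hit = best)
  } else {
    list(verdict = "multi", hit = NULL)
  }
}

#' Align a set of reads to the converted reference
#'
#' Full three-letter pipeline per read: conversion, exhaustive
#' converted-space candidate search, bisulfite-aware recount, uniqueness
#' resolution. Reads with identical sequences are processed once and the
#' verdict reused.
#'
#' @param reads `data.frame` with columns `id` and `seq`.
#' @param refdb An `rrbs_refdb`.
#' @param cfg An [align_config()].
#' @return `data.frame` with one row per read: `read_id`, `entry_id`,
#'   `offset`, `strand`, `bs_mismatches` (NA unless kept) and `verdict`.
#' @export
align_reads <- function(reads, refdb, cfg = align_config()) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  useqs <- unique(reads$seq)
  res <- vector("list", length(useqs))
  # converted-space candidates can be shared across raw reads with the
  # same converted form
  conv_all <- convert_ct(useqs)
  conv_cache <- new.env(parent = emptyenv())
  for (i in seq_along(useqs)) {
    conv <- conv_all[i]
    cand <- get0(conv, envir = conv_cache, ifnotfound = NULL)
    if (is.null(cand)) {
      cand <- candidate_hits(conv, refdb, cfg)
      assign(conv, cand, envir = conv_cache)
    }
    if (nrow(cand)) {
      cand <- recount_bisulfite(cand, useqs[i], refdb)
    }
    v <- resolve_unique(cand, cfg)
    res[[i]] <- if (v$verdict == "unique") {
      data.frame(entry_id = v$hit$entry_id, offset = v$hit$offset,
                 strand = v$hit$strand, bs_mismatches = v$hit$bs_mismatches,
                 verdict = "unique", stringsAsFactors = FALSE)
    } else {
      data.frame(entry_id = NA_character_, offset = NA_integer_,
                 strand = NA_character_, bs_mismatches = NA_integer_,
                 verdict = v$verdict, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, res)
  idx <- match(reads$seq, useqs)
  out <- tab[idx, , drop = FALSE]
  out <- cbind(data.frame(read_id = reads$id, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
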