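# Genomic feature annotation of differential sites: promoter / exon /
# intron / intergenic with a fixed precedence, CpG-island membership, and
# the category-distribution summaries. CpG-island detection implements
# the Gardiner-Garden & Frommer criteria as a fallback when no island
# annotation is supplied.

#' Build a feature model from gene / exon / island tables
#'
#' Promoters are derived deterministically from the TSS and strand:
#' `[TSS - upstream, TSS + downstream]` in transcription orientation
#' (a conventional window; clipped at contig start).
#'
#' @param genes `data.frame` with `contig`, `start`, `end`, `name`,
#'   `strand` (0-based half-open).
#' @param exons Optional exon `data.frame` in the same layout (`name`
#'   ties an exon to its gene).
#' @param islands Optional island `data.frame` with `contig`, `start`,
#'   `end`.
#' @param promoter_upstream,promoter_downstream Promoter window half
#'   widths in bases relative to the TSS.
#' @return Object of class `feature_model` wrapping `GRanges` for
#'   promoters, exons, gene spans and islands.
#' @export
feature_model <- function(genes, exons = NULL, islands = NULL,
                          promoter_upstream = 1000L,
                          promoter_downstream = 500L) {
  stopifnot(all(c("contig", "start", "end", "strand") %in% names(genes)))
  as_gr <- function(df) {
    if (is.null(df) || !nrow(df)) {
      return(GenomicRanges::GRanges())
    }
    GenomicRanges::GRanges(df$contig,
                           IRanges::IRanges(start = df$start + 1L,
                                            end = df$end))
  }
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  prom <- data.frame(
    contig = genes$contig,
    start = pmax(0L, as.integer(ifelse(genes$strand == "+",
                                       tss - promoter_upstream,
                                       tss - promoter_downstream))),
    end = as.integer(ifelse(genes$strand == "+",
                            tss + promoter_downstream + 1L,
                            tss + promoter_upstream + 1L)))
  structure(list(promoters = as_gr(prom),
                 exons = as_gr(exons),
                 genes = as_gr(genes),
                 islands = as_gr(islands),
                 contigs = unique(genes$contig),
                 promoter_upstream = as.integer(promoter_upstream),
                 promoter_downstream = as.integer(promoter_downstream)),
            class = "feature_model")
}

#' Assign genomic feature categories to sites
#'
#' Categories are mutually exclusive with precedence
#' promoter > exon > intron > intergenic; CpG-island membership is an
#' independent flag. Sites on contigs absent from the model are
#' intergenic (with a warning).
#'
#' @param sites `data.frame` with `contig` and a 0-based position column
#'   (`start` or `pos`).
#' @param model A [feature_model()].
#' @return `sites` with added `feature` and `island` columns.
#' @export
assign_feature <- function(sites, model) {
  stopifnot(inherits(model, "feature_model"))
  pos <- if ("start" %in% names(sites)) sites$start else sites$pos
  if (is.null(pos)) stop("sites need a 'start' or 'pos' column")
  unknown <- setdiff(unique(sites$contig), model$contigs)
  if (length(unknown)) {
    warning("contig(s) absent from feature model, treated as intergenic: ",
            paste(unknown, collapse = ", "))
  }
  q <- GenomicRanges::GRanges(sites$contig,
                              IRanges::IRanges(start = pos + 1L, width = 1L))
  hits <- function(gr) {
    if (!length(gr)) return(rep(FALSE, length(q)))
    # unknown contigs are handled above; silence seqlevel-union notes
    suppressWarnings(IRanges::overlapsAny(q, gr))
  }
  in_prom <- hits(model$promoters)
  in_exon <- hits(model$exons)
  in_gene <- hits(model$genes)
  sites$feature <- ifelse(in_prom, "promoter",
                          ifelse(in_exon, "exon",
                                 ifelse(in_gene, "intron", "intergenic")))
  sites$island <- hits(model$islands)
  sites
}

#' Category distribution of differential sites
#'
#' Fractions of promoter/exon/intron/intergenic sites, split by island
#' membership and by context class (CpG vs non-CpG), mirroring the usual
#' DMR-distribution summaries.
#'
#' @param sites Annotated sites ([assign_feature()] output) with a
#'   `context` column.
#' @return `data.frame` with `split`, `category`, `count`, `fraction`
#'   (fractions sum to 1 within each non-empty split; `NaN` when a split
#'   is empty).
#' @export
category_distribution <- function(sites) {
  cats <- c("promoter", "exon", "intron", "intergenic")
  splits <- list(
    island = sites$island,
    non_island = !sites$island,
    CpG = sites$context == "CpG",
    nonCpG = sites$context %in% c("CHG", "CHH"))
  out <- do.call(rbind, lapply(names(splits), function(s) {
    sub <- sites$feature[splits[[s]]]
    cnt <- vapply(cats, function(cc) sum(sub == cc), integer(1))
    data.frame(split = s, category = cats, count = cnt,
               fraction = cnt / sum(cnt), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Detect CpG islands (Gardiner-Garden & Frommer criteria)
#'
#' Sliding 200-bp window scan retaining maximal merged regions of length
#' >= `min_length` with GC fraction >= `min_gc` and observed/expected
#' CpG ratio >= `min_oe` (expected = nC * nG / length). Merged regions
#' are re-checked against all three criteria before being reported, so
#' every emitted interval satisfies them.
#'
#' @param seq Contig sequence (character scalar).
#' @param contig Contig name.
#' @param min_length Minimum island length.
#' @param min_gc Minimum GC fraction.
#' @param min_oe Minimum observed/expected CpG ratio.
#' @return `data.frame` with `contig`, `start`, `end` (0-based half-open),
#'   `gc`, `obs_exp`.
#' @export
detect_cpg_islands <- function(seq, contig = "contig1", min_length = 200L,
                               min_gc = 0.5, min_oe = 0.6) {
  seq <- toupper(seq)
  n <- nchar(seq)
  w <- as.integer(min_length)
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), gc = numeric(), obs_exp = numeric())
  if (n < w) return(empty)
  chars <- strsplit(seq, "")[[1]]
  isC <- chars == "C"; isG <- chars == "G"
  cpg <- isC[-n] & isG[-1L]          # CG dinucleotide starting at i
  cumC <- cumsum(isC); cumG <- cumsum(isG); cumCpG <- cumsum(c(cpg, FALSE))
  rng <- function(cs, a, b) cs[b] - if (a > 1L) cs[a - 1L] else 0
  region_stats <- function(a, b) {   # 1-based inclusive
    len <- b - a + 1L
    nC <- rng(cumC, a, b); nG <- rng(cumG, a, b)
    # CpGs fully inside the region: dinucleotide starts in [a, b-1]
    ncpg <- if (b > a) rng(cumCpG, a, b - 1L) else 0
    gc <- (nC + nG) / len
    exp_cpg <- nC * nG / len
    list(gc = gc, oe = if (exp_cpg > 0) ncpg / exp_cpg else 0)
  }
  starts <- 1:(n - w + 1L)
  gc_w <- (cumC[starts + w - 1L] - c(0, cumC)[starts] +
             cumG[starts + w - 1L] - c(0, cumG)[starts]) / w
  nC_w <- cumC[starts + w - 1L] - c(0, cumC)[starts]
  nG_w <- cumG[starts + w - 1L] - c(0, cumG)[starts]
  cpg_w <- cumCpG[starts + w - 2L] - c(0, cumCpG)[starts]
  exp_w <- nC_w * nG_w / w
  ok <- gc_w >= min_gc & exp_w > 0 & cpg_w / exp_w >= min_oe
  if (!any(ok)) return(empty)
  ir <- IRanges::reduce(IRanges::IRanges(start = starts[ok], width = w))
  res <- lapply(seq_along(ir), function(i) {
    a <- IRanges::start(ir)[i]; b <- IRanges::end(ir)[i]
    st <- region_stats(a, b)
    if ((b - a + 1L) >= min_length && st$gc >= min_gc && st$oe >= min_oe) {
      data.frame(contig = contig, start = a - 1L, end = b,
                 gc = st$gc, obs_exp = st$oe, stringsAsFactors = FALSE)
    } else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
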