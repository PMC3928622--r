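# In-silico sequential restriction digest and converted fragment-end
# reference construction for MspI/TaqI RRBS libraries.

# Enzyme definitions: recognition site and cut offset within the site.
# MspI cuts C^CGG, TaqI cuts T^CGA: both leave the cut one base into the
# recognition sequence.
.rrbs_enzymes <- list(
  MspI = list(site = "CCGG", cut_offset = 1L),
  TaqI = list(site = "TCGA", cut_offset = 1L)
)

#' Digest configuration
#'
#' Size-selection window and fragment-end length for reference
#' construction. Defaults follow the standard MspI-TaqI RRBS analysis
#' window: fragments of 40-350 bp, 50-bp ends.
#'
#' @param size_min,size_max Retained fragment length window in bp.
#' @param end_length Length of each fragment end entered into the
#'   alignment reference (fragments shorter than this contribute their
#'   whole sequence).
#' @return Object of class `digest_config`.
#' @export
digest_config <- function(size_min = 40L, size_max = 350L, end_length = 50L) {
  size_min <- as.integer(size_min)
  size_max <- as.integer(size_max)
  end_length <- as.integer(end_length)
  if (!(size_min > 0L && size_min < size_max)) {
    stop("require 0 < size_min < size_max")
  }
  if (end_length <= 0L) stop("end_length must be positive")
  structure(list(size_min = size_min, size_max = size_max,
                 end_length = end_length),
            class = "digest_config")
}

#' Find restriction cut positions in a sequence
#'
#' Scans one contig for every occurrence of an enzyme's recognition
#' sequence (overlapping occurrences included; `N` never matches) and
#' returns the 0-based cut coordinates (site start + cut offset).
#'
#' @param seq A single sequence (character scalar or `DNAString`).
#' @param enzyme `"MspI"` or `"TaqI"`.
#' @return Sorted integer vector of 0-based cut coordinates.
#' @examples
#' find_sites("CCGG", "MspI")  # 1
#' find_sites("TCGA", "MspI")  # integer(0)
#' @export
find_sites <- function(seq, enzyme = c("MspI", "TaqI")) {
  enzyme <- match.arg(enzyme)
  ez <- .rrbs_enzymes[[enzyme]]
  s <- if (methods::is(seq, "DNAString")) seq else
    Biostrings::DNAString(toupper(as.character(seq)))
  m <- Biostrings::matchPattern(ez$site, s, fixed = TRUE)
  sort(Biostrings::start(m) - 1L + ez$cut_offset)
}

#' In-silico sequential digest with size selection
#'
#' Models sequential TaqI + MspI digestion as the union of both enzymes'
#' cut sites (order-independent); fragments are the maximal intervals
#' between consecutive cuts. A fragment passes size selection iff its
#' length lies in `[size_min, size_max]` and both of its ends are
#' enzyme cuts (fragments abutting contig ends are never retained).
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param cfg A [digest_config()].
#' @return `data.frame` of all fragments (0-based half-open `start`/`end`)
#'   with columns `fragment_id`, `contig`, `start`, `end`, `length`,
#'   `left_enzyme`, `right_enzyme`, `selected`.
#' @export
digest_genome <- function(genome, cfg = digest_config()) {
  stopifnot(inherits(cfg, "digest_config"))
  genome <- as_genome_chr(genome)
  res <- lapply(names(genome), function(ctg) {
    seq <- genome[[ctg]]
    len <- nchar(seq)
    cuts_by_enzyme <- lapply(names(.rrbs_enzymes), function(e) {
      find_sites(seq, e)
    })
    names(cuts_by_enzyme) <- names(.rrbs_enzymes)
    cut_pos <- sort(unique(unlist(cuts_by_enzyme, use.names = FALSE)))
    cut_lab <- vapply(cut_pos, function(p) {
      labs <- names(cuts_by_enzyme)[vapply(cuts_by_enzyme,
                                           function(v) p %in% v, logical(1))]
      paste(labs, collapse = "+")  # cut shared by both enzymes is impossible
    }, character(1))
    bounds <- c(0L, cut_pos, len)
    labels <- c("contig_end", cut_lab, "contig_end")
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L]
    keep <- ends > starts  # drop empty interval when a cut sits at 0 or len
    data.frame(contig = ctg,
               start = starts[keep], end = ends[keep],
               length = (ends - starts)[keep],
               left_enzyme = labels[-length(labels)][keep],
               right_enzyme = labels[-1L][keep],
               stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, res)
  frags$selected <- frags$length >= cfg$size_min &
    frags$length <= cfg$size_max &
    frags$left_enzyme != "contig_end" & frags$right_enzyme != "contig_end"
  frags <- frags[, c("contig", "start", "end", "length",
                     "left_enzyme", "right_enzyme", "selected")]
  frags$fragment_id <- sprintf("frag%06d", seq_len(nrow(frags)))
  frags
}

#' Build the converted fragment-end reference database
#'
#' For each size-selected fragment, up to four entries are produced
#' (5'/3' end x top/bottom strand), each holding the raw end sequence,
#' its fully C-to-T-converted form, and a per-base genome-offset map.
#' Ends shorter than `end_length` use the whole fragment; when the two
#' ends of a strand coincide (fragment length <= `end_length`) the entry
#' is stored once so pileups are never double counted.
#'
#' @param fragments Output of [digest_genome()].
#' @param genome The same genome the fragments were derived from.
#' @param cfg A [digest_config()].
#' @return Object of class `rrbs_refdb`: list with `entries`
#'   (`data.frame`), `raw` and `conv` (character vectors indexed like
#'   `entries`), `offsets` (list of 0-based genome-coordinate vectors)
#'   and `cfg`.
#' @export
build_reference <- function(fragments, genome, cfg = digest_config()) {
  stopifnot(inherits(cfg, "digest_config"))
  genome <- as_genome_chr(genome)
  sel <- fragments[fragments$selected, , drop = FALSE]
  rows <- list(); raws <- list(); offs <- list()
  for (i in seq_len(nrow(sel))) {
    fr <- sel[i, ]
    seq <- genome[[fr$contig]]
    L <- min(cfg$end_length, fr$length)
    whole <- fr$length <= cfg$end_length  # 5' and 3' ends coincide
    ends <- if (whole) "5prime" else c("5prime", "3prime")
    for (strand in c("+", "-")) {
      for (we in ends) {
        if (strand == "+") {
          span <- if (we == "5prime") c(fr$start, fr$start + L)
                  else c(fr$end - L, fr$end)
          raw <- substr(seq, span[1] + 1L, span[2])
          off <- span[1]:(span[2] - 1L)
        } else {
          # bottom strand reads 5'->3' from the fragment's right edge
          span <- if (we == "5prime") c(fr$end - L, fr$end)
                  else c(fr$start, fr$start + L)
          raw <- revcomp(substr(seq, span[1] + 1L, span[2]))
          off <- (span[2] - 1L):span[1]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          entry_id = sprintf("%s:%s:%s", fr$fragment_id, we, strand),
          fragment_id = fr$fragment_id, contig = fr$contig,
          which_end = we, strand = strand,
          length = L, stringsAsFactors = FALSE)
        raws[[length(raws) + 1L]] <- raw
        offs[[length(offs) + 1L]] <- off
      }
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entry_id = character(), fragment_id = character(),
               contig = character(), which_end = character(),
               strand = character(), length = integer())
  raw <- unlist(raws, use.names = FALSE)
  if (is.null(raw)) raw <- character()
  conv <- convert_ct(raw)
  structure(list(entries = entries,
                 raw = raw,
                 conv = conv,
                 conv_dss = Biostrings::DNAStringSet(conv),
                 offsets = offs,
                 cfg = cfg),
            class = "rrbs_refdb")
}

#' Full C-to-T conversion of sequences
#'
#' @param seqs Character vector.
#' @return `seqs` with every `C` replaced by `T` (idempotent).
#' @export
convert_ct <- function(seqs) chartr("C", "T", seqs)

#' Serialize a reference database
#'
#' Writes the converted entries as FASTA (headers carry the entry id)
#' plus a TSV side table of per-base genome offsets.
#'
#' @param refdb An `rrbs_refdb`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_reference <- function(refdb, dir) {
  stopifnot(inherits(refdb, "rrbs_refdb"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference_converted.fa")
  conv <- refdb$conv
  names(conv) <- refdb$entries$entry_id
  write_fasta(conv, fa)
  off <- do.call(rbind, lapply(seq_along(refdb$offsets), function(i) {
    data.frame(entry_id = refdb$entries$entry_id[i],
               base_index = seq_along(refdb$offsets[[i]]) - 1L,
               genome_pos = refdb$offsets[[i]])
  }))
  tsv <- file.path(dir, "reference_offsets.tsv")
  write_tsv(off, tsv)
  invisible(c(fa, tsv))
}
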