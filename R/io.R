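#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; sequences are
#' uppercased and names truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per contig.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Strict 4-line-record parser. Malformed records (missing `@`/`+`
#' markers, sequence/quality length disagreement, truncated file) raise
#' errors that report the offending line number.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("FASTQ parse error at line ", n + 1L,
         ": truncated record (line count not a multiple of 4) in ", path)
  }
  if (n == 0L) return(data.frame(id = character(), seq = character(),
                                 qual = character(), stringsAsFactors = FALSE))
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("FASTQ parse error at line ", idx[bad[1L]],
         ": record header must start with '@'")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("FASTQ parse error at line ", idx[bad[1L]] + 2L,
         ": separator line must start with '+'")
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("FASTQ parse error at line ", idx[bad[1L]] + 3L,
         ": quality length (", nchar(qual[bad[1L]]),
         ") does not match sequence length (", nchar(seqs[bad[1L]]), ")")
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hdr)),
             seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads `data.frame` with columns `id`, `seq` and optionally `qual`
#'   (constant `"I"` quality is filled in when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  qual <- if ("qual" %in% names(reads)) reads$qual else
    vapply(nchar(reads$seq), function(w) strrep("I", w), character(1))
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    out[seq(1L, length(out), 4L)] <- paste0("@", reads$id)
    out[seq(2L, length(out), 4L)] <- reads$seq
    out[seq(3L, length(out), 4L)] <- "+"
    out[seq(4L, length(out), 4L)] <- qual
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path Path to a BED file (3 to 6 columns, tab-separated, no header).
#' @return `data.frame` with columns `contig`, `start`, `end`, `name`,
#'   `score`, `strand` (0-based half-open coordinates, BED native).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("contig", "start", "end", "name",
                                         "score", "strand")[1:6],
                           fill = TRUE, comment.char = "#")
  if (ncol(raw) < 3L) stop("BED parse error: fewer than 3 columns in ", path)
  if (is.null(raw$name)) raw$name <- "."
  if (is.null(raw$score) || all(is.na(raw$score))) raw$score <- 0
  if (is.null(raw$strand) || all(is.na(raw$strand)) || all(raw$strand == ""))
    raw$strand <- "*"
  bad <- which(!(raw$end > raw$start))
  if (length(bad)) {
    stop("BED parse error at data line ", bad[1L], ": end <= start")
  }
  raw[, c("contig", "start", "end", "name", "score", "strand")]
}

#' Write a BED6 file
#'
#' @param df `data.frame` with at least `contig`, `start`, `end`; `name`,
#'   `score`, `strand` filled with defaults when missing.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("contig", "start", "end") %in% names(df)))
  out <- data.frame(contig = df$contig,
                    start = as.integer(df$start),
                    end = as.integer(df$end),
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0,
                    strand = if ("strand" %in% names(df)) df$strand else "*")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bedGraph track
#'
#' Intervals are sorted by contig and start before writing, as required by
#' genome-browser loaders.
#'
#' @param df `data.frame` with columns `contig`, `start`, `end`, `value`.
#' @param path Output path.
#' @param track_name Optional name for the `track` header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, path, track_name = "methylation") {
  stopifnot(all(c("contig", "start", "end", "value") %in% names(df)))
  if (nrow(df) && any(df$end <= df$start)) {
    stop("bedGraph intervals must satisfy start < end")
  }
  df <- df[order(df$contig, df$start), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  if (nrow(df)) {
    writeLines(sprintf("%s\t%d\t%d\t%g", df$contig, as.integer(df$start),
                       as.integer(df$end), df$value), con)
  }
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path Path written by [write_bedgraph()] (or any 4-column bedGraph).
#' @return `data.frame` with columns `contig`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  df <- utils::read.table(text = lines, sep = "\t",
                          col.names = c("contig", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  bad <- which(df$end <= df$start)
  if (length(bad)) stop("bedGraph parse error at data line ", bad[1L],
                        ": start >= end")
  df
}

#' Read gene models from a GFF3 file
#'
#' Extracts `gene` and `exon` records via \pkg{rtracklayer} (Suggests) into
#' the plain data frames [feature_model()] consumes. BED6 input does not
#' need this helper.
#'
#' @param path Path to a GFF3 file.
#' @return List with `genes` and `exons` data frames (0-based half-open).
#' @export
read_gff3_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gff3_genes requires the 'rtracklayer' package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  as_df <- function(g, name_col) {
    data.frame(contig = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g) - 1L,
               end = GenomicRanges::end(g),
               name = as.character(S4Vectors::mcols(g)[[name_col]]),
               strand = as.character(GenomicRanges::strand(g)),
               stringsAsFactors = FALSE)
  }
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  name_col <- if ("Name" %in% names(S4Vectors::mcols(genes))) "Name" else "ID"
  list(genes = as_df(genes, name_col),
       exons = as_df(exons, if ("Parent" %in%
                                names(S4Vectors::mcols(exons))) "Parent"
                     else name_col))
}

#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
read_tsv <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

# coerce a genome argument (DNAStringSet / named character) to named character
#' @keywords internal
as_genome_chr <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(toupper(out))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      if (length(genome) != 1L) stop("unnamed multi-contig genome")
      names(genome) <- "contig1"
    }
    return(toupper(genome))
  }
  stop("genome must be a DNAStringSet or a named character vector")
}

#' @keywords internal
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}
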