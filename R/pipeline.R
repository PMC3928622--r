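# Orchestration: one reproducible run from (simulated or supplied) reads
# to annotated differential sites, with a checksum manifest.

#' Pipeline run configuration
#'
#' Either `sim` (a [sim_config()], in which case inputs are simulated) or
#' `genome_fasta` + `reads_fastq` must be supplied. Referenced files are
#' checked before any stage runs.
#'
#' @param out_dir Output directory.
#' @param sim Optional [sim_config()] for simulated input.
#' @param genome_fasta,reads_fastq Paths for real input; `reads_fastq` is
#'   a named list `list(group1 = c(...paths...), group2 = c(...))`.
#' @param genes_bed,exons_bed,islands_bed Optional annotation paths
#'   (simulated runs default to the simulator's own annotations).
#' @param digest A [digest_config()].
#' @param align A [align_config()].
#' @param diff A [diff_config()].
#' @param promoter_upstream,promoter_downstream Promoter window.
#' @param group_labels Two group names (simulated runs inherit the
#'   simulator's labels).
#' @param seed RNG seed recorded in the manifest.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       sim = NULL,
                       genome_fasta = NULL, reads_fastq = NULL,
                       genes_bed = NULL, exons_bed = NULL,
                       islands_bed = NULL,
                       digest = digest_config(),
                       align = align_config(),
                       diff = diff_config(),
                       promoter_upstream = 1000L,
                       promoter_downstream = 500L,
                       group_labels = c("LMFA", "HMFA"),
                       seed = 1L) {
  if (is.null(sim)) {
    if (is.null(genome_fasta) || is.null(reads_fastq)) {
      stop("configuration error: supply either 'sim' or both ",
           "'genome_fasta' and 'reads_fastq'")
    }
    paths <- c(genome_fasta, unlist(reads_fastq),
               genes_bed, exons_bed, islands_bed)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("configuration error: missing input file(s): ",
           paste(missing, collapse = ", "))
    }
    if (length(reads_fastq) != 2L || is.null(names(reads_fastq))) {
      stop("configuration error: reads_fastq must be a named 2-group list")
    }
    group_labels <- names(reads_fastq)
  } else {
    stopifnot(inherits(sim, "sim_config"))
    group_labels <- sim$group_labels
  }
  structure(list(out_dir = out_dir, sim = sim,
                 genome_fasta = genome_fasta, reads_fastq = reads_fastq,
                 genes_bed = genes_bed, exons_bed = exons_bed,
                 islands_bed = islands_bed,
                 digest = digest, align = align, diff = diff,
                 promoter_upstream = as.integer(promoter_upstream),
                 promoter_downstream = as.integer(promoter_downstream),
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full RRBS pipeline
#'
#' Executes simulate (optional) -> digest -> align -> call -> diff ->
#' annotate, writing every intermediate to `out_dir` together with a
#' manifest listing each file's md5 checksum. Identical configurations
#' (including seed) produce identical manifests. Stage failures abort
#' with the stage name; partial outputs are left in place.
#'
#' @param cfg A [run_config()].
#' @return List with `diff` (annotated differential table), `calls`
#'   (per-group pooled calls), `distribution` (category summary),
#'   `manifest` (`data.frame`), and `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "configure"
  written <- character()
  emit <- function(path) written <<- c(written, path)
  tryCatch({
    cfg_json <- file.path(cfg$out_dir, "run_config.json")
    ser <- cfg
    ser$out_dir <- NULL  # implied by file location; keeps manifests
                         # comparable across output directories
    ser$sim <- if (is.null(cfg$sim)) NULL else unclass(cfg$sim)
    ser$digest <- unclass(cfg$digest); ser$align <- unclass(cfg$align)
    ser$diff <- unclass(cfg$diff)
    jsonlite::write_json(unclass(ser), cfg_json, auto_unbox = TRUE,
                         null = "null", pretty = TRUE)
    emit(cfg_json)

    stage <- "simulate"
    if (!is.null(cfg$sim)) {
      sim <- simulate_rrbs(cfg$sim)
      sim_dir <- file.path(cfg$out_dir, "simdata")
      emit(write_simdata(sim, sim_dir))
      genome <- sim$simg$genome
      reads_by_group <- lapply(cfg$group_labels, function(g) {
        keys <- grep(paste0("^", g, "_"), names(sim$reads), value = TRUE)
        sim$reads[keys]
      })
      genes <- sim$simg$genes; exons <- sim$simg$exons
      islands <- sim$simg$islands
    } else {
      genome <- read_fasta(cfg$genome_fasta)
      reads_by_group <- lapply(cfg$reads_fastq, function(paths) {
        lapply(paths, read_fastq)
      })
      genes <- if (!is.null(cfg$genes_bed)) {
        b <- read_bed(cfg$genes_bed); b
      } else NULL
      exons <- if (!is.null(cfg$exons_bed)) read_bed(cfg$exons_bed) else NULL
      islands <- if (!is.null(cfg$islands_bed)) read_bed(cfg$islands_bed)
        else NULL
    }
    names(reads_by_group) <- cfg$group_labels

    stage <- "digest"
    frags <- digest_genome(genome, cfg$digest)
    ftsv <- file.path(cfg$out_dir, "fragments.tsv")
    write_tsv(frags, ftsv); emit(ftsv)
    refdb <- build_reference(frags, genome, cfg$digest)
    emit(write_reference(refdb, file.path(cfg$out_dir, "refdb")))

    stage <- "align"
    aln_by_group <- lapply(reads_by_group, function(reps) {
      lapply(reps, function(r) align_reads(r, refdb, cfg$align))
    })
    for (g in cfg$group_labels) {
      for (i in seq_along(aln_by_group[[g]])) {
        p <- file.path(cfg$out_dir, sprintf("aln_%s_%d.tsv", g, i))
        write_tsv(aln_by_group[[g]][[i]], p); emit(p)
      }
    }

    stage <- "call"
    calls_by_group <- lapply(cfg$group_labels, function(g) {
      reps <- lapply(seq_along(aln_by_group[[g]]), function(i) {
        pileup(aln_by_group[[g]][[i]], reads_by_group[[g]][[i]],
               refdb, genome)
      })
      pooled <- pool_calls(reps)
      emit(export_tracks(pooled, file.path(cfg$out_dir,
                                           paste0("calls_", g))))
      list(reps = reps, pooled = pooled)
    })
    names(calls_by_group) <- cfg$group_labels

    stage <- "diff"
    dm <- run_comparison(calls_by_group[[1]]$pooled,
                         calls_by_group[[2]]$pooled,
                         cfg$diff, labels = cfg$group_labels)

    stage <- "annotate"
    if (!is.null(genes) && nrow(genes)) {
      model <- feature_model(genes, exons, islands,
                             cfg$promoter_upstream, cfg$promoter_downstream)
      dm <- assign_feature(dm, model)
      dist <- category_distribution(dm[dm$significant, , drop = FALSE])
      dtsv <- file.path(cfg$out_dir, "category_distribution.tsv")
      write_tsv(dist, dtsv); emit(dtsv)
    } else {
      dist <- NULL
    }
    dmtsv <- file.path(cfg$out_dir, "differential_sites.tsv")
    write_tsv(dm, dmtsv); emit(dmtsv)
    for (ctx in names(split_by_context(dm))) {
      p <- file.path(cfg$out_dir, sprintf("differential_%s.tsv", ctx))
      write_tsv(split_by_context(dm)[[ctx]], p); emit(p)
    }

    stage <- "manifest"
    manifest <- data.frame(path = sub(paste0("^", cfg$out_dir, "/?"), "",
                                      written),
                           md5 = unname(tools::md5sum(written)),
                           stringsAsFactors = FALSE)
    manifest <- manifest[order(manifest$path), , drop = FALSE]
    rownames(manifest) <- NULL
    write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))

    list(diff = dm,
         calls = lapply(calls_by_group, `[[`, "pooled"),
         distribution = dist,
         manifest = manifest,
         out_dir = cfg$out_dir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `digest`, `align`, `call`, `diff`, `annotate`,
#' `expr` and `run` subcommands (see `inst/cli/rrbskit.R` for the
#' executable wrapper). Returns an exit code: 0 success, 2 configuration
#' error, 3 data error.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
rrbs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rrbskit <simulate|digest|align|call|diff|annotate|expr|run>",
    "[options]")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1L]; rest <- args[-1L]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) && i[1L] < length(rest)) rest[i[1L] + 1L] else default
  }
  code <- tryCatch({
    switch(cmd,
      simulate = {
        out <- opt("--out", "simdata")
        cfg <- sim_config(seed = as.integer(opt("--seed", "1")))
        write_simdata(simulate_rrbs(cfg), out)
        0L
      },
      digest = {
        genome <- read_fasta(opt("--fasta"))
        cfg <- digest_config(as.integer(opt("--min", "40")),
                             as.integer(opt("--max", "350")),
                             as.integer(opt("--end-length", "50")))
        frags <- digest_genome(genome, cfg)
        refdb <- build_reference(frags, genome, cfg)
        out <- opt("--out", "refdb")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_tsv(frags, file.path(out, "fragments.tsv"))
        write_reference(refdb, out)
        0L
      },
      expr = {
        ct <- read_tsv(opt("--ct"))
        rep <- expression_report(ct)
        write_tsv(rep, opt("--out", "expression_report.tsv"))
        0L
      },
      run = {
        cfg <- run_config(out_dir = opt("--out", "rrbs_run"),
                          sim = sim_config(
                            seed = as.integer(opt("--seed", "1"))))
        run_pipeline(cfg)
        0L
      },
      { message("unknown subcommand: ", cmd); message(usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("configuration error", conditionMessage(e))) 2L else 3L
  })
  invisible(code)
}
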