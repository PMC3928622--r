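# Per-site differential methylation: Fisher exact test on pooled C/T
# counts (minimum-likelihood two-sided tail) or Welch t-test on replicate
# levels, with the >= 5-reads-per-group coverage filter, effect sizes,
# direction labels and table reconstruction utilities.

#' Differential-testing configuration
#'
#' @param min_coverage Minimum reads per group for a site to be tested.
#' @param alpha Significance level for the `significant` flag.
#' @param test `"fisher"` (pooled counts), `"ttest"` (replicate levels,
#'   falling back to Fisher where replicates are insufficient) or
#'   `"auto"` (Fisher on pooled counts).
#' @param min_abs_difference Reporting threshold on `|m2 - m1|`.
#' @param rounding Decimals used for the reported difference and p value
#'   columns mirroring published tables.
#' @return Object of class `diff_config`.
#' @export
diff_config <- function(min_coverage = 5L, alpha = 0.05,
                        test = c("auto", "fisher", "ttest"),
                        min_abs_difference = 0, rounding = 2L) {
  test <- match.arg(test)
  if (min_coverage < 1L) stop("min_coverage must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(list(min_coverage = as.integer(min_coverage), alpha = alpha,
                 test = test, min_abs_difference = min_abs_difference,
                 rounding = as.integer(rounding)),
            class = "diff_config")
}

#' Two-sided Fisher exact test for one site
#'
#' Exact two-sided p for the 2x2 table `(x1, n1 - x1; x2, n2 - x2)`
#' using the minimum-likelihood tail: all hypergeometric tables with
#' probability not exceeding that of the observed table (up to a
#' `1 + 1e-7` relative tie tolerance, matching common practice) are
#' summed. Probabilities are evaluated in log space.
#'
#' @param x1,n1 Methylated count and coverage in group 1.
#' @param x2,n2 Methylated count and coverage in group 2.
#' @return p value in `[0, 1]`.
#' @examples
#' fisher_site(5, 5, 0, 5)   # 2/252
#' fisher_site(6, 6, 1, 5)   # 7/462
#' @export
fisher_site <- function(x1, n1, x2, n2) {
  if (any(c(n1, n2) < 1L) || any(c(x1, x2) < 0L) || x1 > n1 || x2 > n2) {
    stop("require n_i >= 1 and 0 <= x_i <= n_i")
  }
  k <- x1 + x2
  support <- max(0L, k - n2):min(n1, k)
  logd <- stats::dhyper(support, n1, n2, k, log = TRUE)
  logobs <- stats::dhyper(x1, n1, n2, k, log = TRUE)
  p <- sum(exp(logd[logd <= logobs + log1p(1e-7)]))
  min(1, p)
}

#' Welch t-test on replicate methylation levels
#'
#' Two-sided Welch test comparing per-replicate methylation levels.
#' Degenerate inputs (zero variance in both groups) return `p = 1` when
#' the group means agree and `p = 0` otherwise, flagged as degenerate.
#'
#' @param levels1,levels2 Numeric vectors of replicate methylation levels
#'   (>= 2 values each).
#' @return List with `p_value`, `df` (Welch degrees of freedom, `NA` when
#'   degenerate) and `degenerate`.
#' @export
ttest_site <- function(levels1, levels2) {
  if (length(levels1) < 2L || length(levels2) < 2L) {
    stop("ttest_site requires >= 2 replicates per group")
  }
  v1 <- stats::var(levels1); v2 <- stats::var(levels2)
  if (v1 == 0 && v2 == 0) {
    same <- isTRUE(all.equal(mean(levels1), mean(levels2)))
    return(list(p_value = if (same) 1 else 0, df = NA_real_,
                degenerate = TRUE))
  }
  tt <- stats::t.test(levels1, levels2, var.equal = FALSE)
  list(p_value = unname(tt$p.value), df = unname(tt$parameter),
       degenerate = FALSE)
}

# inner join of two call tables on (contig, start, strand)
#' @keywords internal
join_calls <- function(c1, c2) {
  k1 <- paste(c1$contig, c1$start, c1$strand, sep = "\r")
  k2 <- paste(c2$contig, c2$start, c2$strand, sep = "\r")
  i <- match(k1, k2)
  keep <- !is.na(i)
  list(a = c1[keep, , drop = FALSE], b = c2[i[keep], , drop = FALSE])
}

#' Per-site differential methylation between two groups
#'
#' Sites covered by at least `min_coverage` reads in each group are
#' tested; the methylation difference is `m2 - m1` (group 2 minus group
#' 1), direction `hyper`/`hypo` from its sign, Benjamini-Hochberg
#' q-values are added but the `significant` flag uses the raw p, as in
#' raw-P reporting.
#'
#' @param group1,group2 Either one pooled call table each ([pileup()] /
#'   [pool_calls()] layout) or a list of replicate call tables.
#' @param cfg A [diff_config()].
#' @param labels Group names for reporting.
#' @return `data.frame` with one row per tested site (`contig`, `start`,
#'   `end`, `strand`, `context`, `n1`, `n2`, `x1`, `x2`, `m1`, `m2`,
#'   `diff`, `p_value`, `q_value`, `test_used`, `significant`,
#'   `direction`, plus rounded reporting columns); a `summary` attribute
#'   carries tested/significant counts per context.
#' @export
run_comparison <- function(group1, group2, cfg = diff_config(),
                           labels = c("group1", "group2")) {
  stopifnot(inherits(cfg, "diff_config"))
  is_reps <- function(x) is.list(x) && !is.data.frame(x)
  reps1 <- if (is_reps(group1)) group1 else list(group1)
  reps2 <- if (is_reps(group2)) group2 else list(group2)
  pooled1 <- pool_calls(reps1)
  pooled2 <- pool_calls(reps2)
  j <- join_calls(pooled1, pooled2)
  a <- j$a; b <- j$b
  if (!nrow(a)) {
    warning("no overlapping sites between groups")
  }
  keep <- a$coverage >= cfg$min_coverage & b$coverage >= cfg$min_coverage
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  n <- nrow(a)
  out <- data.frame(contig = a$contig, start = a$start, end = a$end,
                    strand = a$strand, context = a$context,
                    n1 = a$coverage, n2 = b$coverage,
                    x1 = a$count_C, x2 = b$count_C,
                    m1 = a$level, m2 = b$level,
                    stringsAsFactors = FALSE)
  out$diff <- out$m2 - out$m1

  use_ttest <- rep(FALSE, n)
  p <- numeric(n)
  test_used <- rep("fisher", n)
  if (cfg$test == "ttest" && (length(reps1) >= 2L && length(reps2) >= 2L)) {
    key <- paste(out$contig, out$start, out$strand, sep = "\r")
    lev <- function(reps) {
      vapply(reps, function(r) {
        k <- paste(r$contig, r$start, r$strand, sep = "\r")
        i <- match(key, k)
        ok <- !is.na(i) & r$coverage[i] >= cfg$min_coverage
        ifelse(ok, r$level[i], NA_real_)
      }, numeric(n))
    }
    l1 <- lev(reps1); l2 <- lev(reps2)
    n_ok1 <- rowSums(!is.na(l1)); n_ok2 <- rowSums(!is.na(l2))
    use_ttest <- n_ok1 >= 2L & n_ok2 >= 2L
    for (i in which(use_ttest)) {
      p[i] <- ttest_site(l1[i, !is.na(l1[i, ])],
                         l2[i, !is.na(l2[i, ])])$p_value
      test_used[i] <- "ttest"
    }
    if (any(!use_ttest)) {
      message("run_comparison: ", sum(!use_ttest),
              " site(s) lacked replicate coverage; fell back to Fisher")
    }
  }
  fish <- which(!use_ttest)
  if (length(fish)) {
    p[fish] <- mapply(fisher_site, out$x1[fish], out$n1[fish],
                      out$x2[fish], out$n2[fish])
  }
  out$p_value <- p
  out$q_value <- stats::p.adjust(p, method = "BH")
  out$test_used <- test_used
  out$significant <- out$p_value < cfg$alpha &
    abs(out$diff) >= cfg$min_abs_difference
  out$direction <- ifelse(out$diff > 0, "hyper",
                          ifelse(out$diff < 0, "hypo", "none"))
  out$diff_reported <- round(out$diff, cfg$rounding)
  out$p_reported <- round(out$p_value, cfg$rounding)
  names(out)[names(out) %in% c("n1", "n2")] <-
    c(paste0("total_", labels[1]), paste0("total_", labels[2]))
  # keep canonical aliases too
  out$n1 <- out[[paste0("total_", labels[1])]]
  out$n2 <- out[[paste0("total_", labels[2])]]
  summ <- list(
    n_tested = n,
    n_significant = sum(out$significant),
    frac_significant = if (n) sum(out$significant) / n else NA_real_,
    by_context = if (n) table(out$context, out$significant) else NULL)
  attr(out, "summary") <- summ
  rownames(out) <- NULL
  out
}

#' Split a differential table by context class
#'
#' @param diff_table Output of [run_comparison()].
#' @return Named list of sub-tables for `CpG`, `CHG`, `CHH`.
#' @export
split_by_context <- function(diff_table) {
  lapply(stats::setNames(nm = c("CpG", "CHG", "CHH")), function(ctx) {
    diff_table[diff_table$context == ctx, , drop = FALSE]
  })
}

#' Reconstruct 2x2 tables from published totals and |difference|
#'
#' Enumerates all integer `(x1, x2)` with `0 <= x_i <= n_i` whose
#' absolute methylation-level difference equals `abs_difference` after
#' rounding to table precision. Candidates are canonicalised under the
#' C/T column-complement map `(x1, x2) -> (n1 - x1, n2 - x2)` (which
#' preserves both `|difference|` and the Fisher p), keeping the
#' representative with `m1 >= m2`.
#'
#' @param n1,n2 Published per-group read totals.
#' @param abs_difference Published absolute methylation difference.
#' @param decimals Table rounding precision (default 2).
#' @return List with `candidates` (`data.frame` of `x1`, `x2`, `m1`,
#'   `m2`) and `unique` (`TRUE` iff exactly one canonical candidate).
#' @export
reconstruct_table <- function(n1, n2, abs_difference, decimals = 2L) {
  stopifnot(n1 >= 1L, n2 >= 1L, abs_difference >= 0, abs_difference <= 1)
  grid <- expand.grid(x1 = 0:n1, x2 = 0:n2)
  d <- abs(grid$x1 / n1 - grid$x2 / n2)
  hit <- grid[round(d, decimals) == round(abs_difference, decimals), ,
              drop = FALSE]
  if (!nrow(hit)) {
    return(list(candidates = data.frame(x1 = integer(), x2 = integer(),
                                        m1 = numeric(), m2 = numeric()),
                unique = FALSE))
  }
  # canonical form: complement both columns if m1 < m2
  m1 <- hit$x1 / n1; m2 <- hit$x2 / n2
  flip <- m1 < m2
  cx1 <- ifelse(flip, n1 - hit$x1, hit$x1)
  cx2 <- ifelse(flip, n2 - hit$x2, hit$x2)
  key <- paste(cx1, cx2)
  first <- !duplicated(key)
  cand <- data.frame(x1 = cx1[first], x2 = cx2[first])
  cand$m1 <- cand$x1 / n1
  cand$m2 <- cand$x2 / n2
  cand <- cand[order(-cand$m1, -cand$m2), , drop = FALSE]
  rownames(cand) <- NULL
  list(candidates = cand, unique = nrow(cand) == 1L)
}
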