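# Efficiency-corrected relative qRT-PCR quantification (Pfaffl method)
# used to validate methylation-driven expression changes.

#' Pfaffl relative expression ratio
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref`, where each dCt is
#' `Ct(control) - Ct(treated)` and E is the amplification efficiency in
#' fold per cycle (2 = perfect doubling; the classic `2^-ddCt` is the
#' `E = 2` special case).
#'
#' @param e_target,e_ref Amplification efficiencies in `(1, 2]`
#'   (default 2, logged via message when filled in).
#' @param dct_target,dct_ref Cycle-threshold differences
#'   (control - treated) for target and reference gene.
#' @return Relative expression ratio (always > 0). Vectorised.
#' @examples
#' pfaffl_ratio(2, 0, 2, 0)  # 1
#' pfaffl_ratio(2, 1, 2, 0)  # 2
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  if (missing(e_target)) e_target <- NA_real_
  if (missing(e_ref)) e_ref <- NA_real_
  if (anyNA(e_target)) {
    message("pfaffl_ratio: target efficiency missing, defaulting to 2")
    e_target[is.na(e_target)] <- 2
  }
  if (anyNA(e_ref)) {
    message("pfaffl_ratio: reference efficiency missing, defaulting to 2")
    e_ref[is.na(e_ref)] <- 2
  }
  if (any(e_target <= 1) || any(e_ref <= 1) ||
      any(e_target > 2) || any(e_ref > 2)) {
    stop("amplification efficiencies must lie in (1, 2]")
  }
  if (any(!is.finite(dct_target)) || any(!is.finite(dct_ref))) {
    stop("Ct differences must be finite")
  }
  e_target^dct_target / e_ref^dct_ref
}

#' Summarize replicate expression ratios
#'
#' Mean and SD across replicate ratios plus a two-sided one-sample t-test
#' against the no-change ratio of 1, with the conventional star coding
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001). With fewer than two
#' replicates only the mean is returned; zero-variance input is flagged
#' degenerate and earns no stars.
#'
#' @param ratios Numeric vector of replicate expression ratios.
#' @return List with `mean`, `sd`, `n`, `p_value`, `stars`, `degenerate`.
#' @export
summarize_replicates <- function(ratios) {
  stopifnot(is.numeric(ratios), length(ratios) >= 1L)
  n <- length(ratios)
  if (n < 2L) {
    return(list(mean = mean(ratios), sd = NA_real_, n = n,
                p_value = NA_real_, stars = "", degenerate = FALSE))
  }
  s <- stats::sd(ratios)
  if (s == 0) {
    return(list(mean = mean(ratios), sd = 0, n = n, p_value = NA_real_,
                stars = "", degenerate = TRUE))
  }
  p <- stats::t.test(ratios, mu = 1)$p.value
  list(mean = mean(ratios), sd = s, n = n, p_value = unname(p),
       stars = star_code(p), degenerate = FALSE)
}

#' @keywords internal
star_code <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}

#' Relative expression from a Ct table
#'
#' Applies the Pfaffl calculation per target gene and replicate batch,
#' then summarises across batches. Expected columns: `gene`, `batch`,
#' `dct_target`, `dct_ref` and optionally `e_target`, `e_ref`.
#'
#' @param ct `data.frame` of Ct differences and efficiencies.
#' @return `data.frame` with per-gene `mean`, `sd`, `n`, `p_value`,
#'   `stars`.
#' @export
expression_report <- function(ct) {
  need <- c("gene", "dct_target", "dct_ref")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("Ct table missing columns: ",
                         paste(miss, collapse = ", "))
  et <- if ("e_target" %in% names(ct)) ct$e_target else rep(NA_real_, nrow(ct))
  er <- if ("e_ref" %in% names(ct)) ct$e_ref else rep(NA_real_, nrow(ct))
  ratios <- pfaffl_ratio(et, ct$dct_target, er, ct$dct_ref)
  out <- do.call(rbind, lapply(split(seq_len(nrow(ct)), ct$gene),
                               function(idx) {
    s <- summarize_replicates(ratios[idx])
    data.frame(gene = ct$gene[idx[1L]], mean = s$mean, sd = s$sd, n = s$n,
               p_value = s$p_value, stars = s$stars,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
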