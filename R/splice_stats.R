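#' Pearson correlation with R-squared and two-sided p
#'
#' Product-moment correlation between paired per-cell observations (e.g.
#' nuclear intron-retaining count versus total nuclear transcript count),
#' reported as `r`, `R2 = r^2` and the two-sided p-value from
#' `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.  Returning
#' `r` alongside `R2` preserves the correlation's sign.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, finite.
#' @return List: `r`, `R2`, `p`, `n`, `df`, and `defined` (`FALSE`, with
#'   `NA` statistics, when either variable has zero variance).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, R2 = NA_real_, p = NA_real_,
                n = length(x), df = length(x) - 2L, defined = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, R2 = r^2, p = ct$p.value, n = length(x),
       df = unname(ct$parameter), defined = TRUE)
}

#' Unpaired two-tailed equal-variance t test
#'
#' Pooled-variance Student t with `n_a + n_b - 2` degrees of freedom, the
#' group comparison used for all mean contrasts (e.g. transcript counts per
#' cell between interphase and mitosis, or control versus treated).
#'
#' @param a,b Numeric samples, each with at least 2 observations.
#' @return List: `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
ttest_equal_var <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stopf("each sample needs n >= 2")
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_a = mean(a), mean_b = mean(b))
}

#' Fold change between two means
#'
#' Symmetric fold change `max(m1, m2) / min(m1, m2)` with a direction flag
#' (increase/decrease going from the reference to the alternative mean),
#' rounded to one decimal in `fold_rounded` to match the conventional
#' "~x.x-fold" reporting.
#'
#' @param mean_ref,mean_alt Positive means (reference and alternative
#'   condition).
#' @return List: `fold`, `fold_rounded`, `direction` (`"increase"`,
#'   `"decrease"` or `"none"`), `defined`.
#' @examples
#' fold_change(29, 12)  # 2.4-fold decrease
#' fold_change(21, 38)  # 1.8-fold increase
#' @export
fold_change <- function(mean_ref, mean_alt) {
  if (is.na(mean_ref) || is.na(mean_alt) || mean_ref <= 0 || mean_alt <= 0)
    return(list(fold = NA_real_, fold_rounded = NA_real_,
                direction = NA_character_, defined = FALSE))
  fold <- max(mean_ref, mean_alt) / min(mean_ref, mean_alt)
  dir <- if (mean_alt > mean_ref) "increase"
  else if (mean_alt < mean_ref) "decrease" else "none"
  list(fold = fold, fold_rounded = round(fold, 1L), direction = dir,
       defined = TRUE)
}

#' Nuclear enrichment percentage
#'
#' Percentage of a transcript's detected molecules located in the nucleus:
#' `100 * nuclear / (nuclear + cytoplasmic)`.
#'
#' @param nuclear,cytoplasmic Non-negative molecule counts with a positive
#'   sum.
#' @return Percent in `[0, 100]`.
#' @export
nuclear_enrichment <- function(nuclear, cytoplasmic) {
  if (any(nuclear < 0) || any(cytoplasmic < 0)) stopf("counts must be >= 0")
  tot <- nuclear + cytoplasmic
  if (any(tot <= 0)) stopf("nuclear + cytoplasmic must be > 0")
  100 * nuclear / tot
}

#' Relative expression time series by the 2^-ddCt method
#'
#' For each timepoint, `dCt = Ct_target - Ct_reference`; `ddCt` is `dCt`
#' minus the calibrator timepoint's `dCt`; relative expression is
#' `2^-ddCt`, so the calibrator equals exactly 1 and one extra cycle of
#' `ddCt` halves the value.  Technical replicate Ct values are averaged per
#' timepoint before differencing.  Used for transcription-shutoff (e.g.
#' actinomycin D) decay series against a stable housekeeping reference.
#'
#' @param time Timepoints (h).
#' @param ct_target,ct_ref Ct values of the target and reference gene per
#'   timepoint; matrices or lists give replicate values to average.
#' @param calibrator Which timepoint is the calibrator (default the first).
#' @return Data.frame: `time`, `dct`, `ddct`, `rel_expr`.
#' @export
relative_expression_series <- function(time, ct_target, ct_ref,
                                       calibrator = time[1L]) {
  avg <- function(x) {
    if (is.matrix(x)) rowMeans(x)
    else if (is.list(x)) vapply(x, mean, numeric(1L))
    else x
  }
  ct_target <- avg(ct_target); ct_ref <- avg(ct_ref)
  if (length(ct_target) != length(time) || length(ct_ref) != length(time))
    stopf("need one (mean) Ct per timepoint for target and reference")
  ci <- match(calibrator, time)
  if (is.na(ci)) stopf("calibrator timepoint not among timepoints")
  dct <- ct_target - ct_ref
  ddct <- dct - dct[ci]
  data.frame(time = time, dct = dct, ddct = ddct, rel_expr = 2^(-ddct))
}

#' Transcripts per million from counts and effective lengths
#'
#' @param counts Non-negative read counts per gene.
#' @param lengths Effective lengths (bp) per gene.
#' @return TPM values summing to 1e6.
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stopf("lengths must be positive")
  rate <- counts / lengths
  rate / sum(rate) * 1e6
}

#' Relative abundance of a gene across subcellular compartments
#'
#' For each gene, the fraction of its expression in each compartment:
#' `TPM_c / sum_c TPM_c` over e.g. chromatin, nucleoplasm and cytoplasm.
#' When `x` holds raw counts, per-compartment TPMs are computed first from
#' `lengths` by the standard per-million normalization.
#'
#' @param x Numeric matrix, genes x compartments, of TPMs (default) or
#'   counts.
#' @param lengths Effective gene lengths; supplying them treats `x` as
#'   counts.
#' @return Matrix of the same shape; rows with any expression sum to 1.
#' @export
compartment_fraction <- function(x, lengths = NULL) {
  x <- as.matrix(x)
  if (any(x < 0)) stopf("expression values must be >= 0")
  if (!is.null(lengths)) x <- apply(x, 2L, tpm, lengths = lengths)
  tot <- rowSums(x)
  if (all(tot == 0)) stopf("not all genes may be zero in all compartments")
  sweep(x, 1L, ifelse(tot > 0, tot, NA_real_), "/")
}
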