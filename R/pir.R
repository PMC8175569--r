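#' Estimate percent intron retention from junction counts
#'
#' PIR is the percentage of junction-read evidence supporting retention over
#' retention plus splicing.  In the default two-junction mode the retention
#' evidence is the mean of the upstream (EI) and downstream (IE) junction
#' counts:
#' \deqn{PIR = 100 \cdot \frac{(EI+IE)/2}{(EI+IE)/2 + EE}}
#' Two quality filters apply.  Events with fewer than `min_total` reads of
#' evidence are reported as `low_coverage` with undefined PIR, and events
#' whose EI/IE balance fails a two-sided exact binomial test at level `alpha`
#' (a hallmark of alternative splice sites inside the intron) are reported as
#' `imbalanced`, again with undefined PIR.  Such introns can be re-estimated
#' from one junction only via the single-junction modes, where
#' \eqn{PIR = 100\, IE/(IE+EE)} (downstream) or \eqn{100\, EI/(EI+EE)}
#' (upstream); the coverage filter is then applied to the reduced evidence
#' total and the balance test is moot.
#'
#' Undefined PIR propagates as `NA`, never as 0 or 100.
#'
#' @param counts Data.frame of junction counts (from
#'   [count_junction_reads()] or a TSV) with columns `intron_id`, `EI`,
#'   `IE`, `EE`; extra columns are carried through.
#' @param min_total Minimum reads of evidence per event (default 15).
#' @param alpha Level of the junction-balance filter (default 0.05).
#' @param mode `"two_junction"` (default), `"single_junction_upstream"` or
#'   `"single_junction_downstream"`.
#' @return A data.frame with columns `intron_id`, `pir`, `n_total`,
#'   `balance_p`, `status` (one of `ok`, `low_coverage`, `imbalanced`,
#'   `single_junction_upstream`, `single_junction_downstream`).
#' @examples
#' estimate_pir(data.frame(intron_id = "i1", EI = 30, IE = 30, EE = 70))
#' @export
estimate_pir <- function(counts, min_total = 15L, alpha = 0.05,
                         mode = c("two_junction", "single_junction_upstream",
                                  "single_junction_downstream")) {
  mode <- match.arg(mode)
  need <- c("intron_id", "EI", "IE", "EE")
  if (!all(need %in% names(counts)))
    stopf("counts must have columns %s", paste(need, collapse = ", "))
  if (any(counts$EI < 0 | counts$IE < 0 | counts$EE < 0))
    stopf("counts must be non-negative")
  n <- nrow(counts)
  pir <- rep(NA_real_, n); status <- character(n); bp <- rep(NA_real_, n)
  n_total <- switch(mode,
    two_junction = counts$EI + counts$IE + counts$EE,
    single_junction_upstream = counts$EI + counts$EE,
    single_junction_downstream = counts$IE + counts$EE)
  for (i in seq_len(n)) {
    if (n_total[i] < min_total) { status[i] <- "low_coverage"; next }
    if (mode == "two_junction") {
      bp[i] <- balance_test(counts$EI[i], counts$IE[i])
      if (bp[i] < alpha) { status[i] <- "imbalanced"; next }
      ret <- (counts$EI[i] + counts$IE[i]) / 2
      pir[i] <- 100 * ret / (ret + counts$EE[i])
      status[i] <- "ok"
    } else if (mode == "single_junction_upstream") {
      pir[i] <- 100 * counts$EI[i] / (counts$EI[i] + counts$EE[i])
      status[i] <- mode
    } else {
      pir[i] <- 100 * counts$IE[i] / (counts$IE[i] + counts$EE[i])
      status[i] <- mode
    }
  }
  data.frame(intron_id = counts$intron_id, pir = pir, n_total = n_total,
             balance_p = bp, status = status)
}

#' Re-estimate PIR from a single junction
#'
#' For introns whose two-junction estimate is rejected by the balance filter
#' (alternative donors or acceptors inside the intron make one boundary
#' uncountable), PIR is recalculated from the clean boundary alone.
#'
#' @param counts As in [estimate_pir()].
#' @param side `"upstream"` (use EI) or `"downstream"` (use IE).
#' @inheritParams estimate_pir
#' @return As [estimate_pir()], with status recording the side used.
#' @export
recalc_single_junction <- function(counts, side = c("upstream", "downstream"),
                                   min_total = 15L) {
  side <- match.arg(side)
  estimate_pir(counts, min_total = min_total,
               mode = paste0("single_junction_", side))
}

#' Fit per-intron PIR from junction read evidence
#'
#' The front door of the junction module: takes aligned reads (or
#' pre-tabulated junction counts), counts junction evidence per intron and
#' estimates PIR with the coverage and balance filters.  Selected introns can
#' be routed to single-junction recalculation, as is needed for introns
#' harbouring alternative splice sites.
#'
#' @param x A `junction_alignments` object, a SAM/BAM path, or a junction
#'   count data.frame with columns `intron_id`, `EI`, `IE`, `EE` (and
#'   optionally `gene_id`, `biotype`, `mid_intron`).
#' @param model A [gene_model()]; required when `x` is reads.
#' @param min_total,alpha,min_anchor Filter and counting parameters; see
#'   [estimate_pir()] and [count_junction_reads()].
#' @param single_junction Optional named character vector mapping
#'   `intron_id` to `"upstream"` or `"downstream"` for single-junction
#'   recalculation of those introns.
#' @return An object of class `pir_fit` with components `estimates` (the
#'   per-intron PIR table), `counts`, and `params`.  Methods: `print`,
#'   `summary` (per-gene max/min PIR), `coef` (named PIR vector), `plot`
#'   (cumulative distribution of per-gene maximum PIR), `simulate`
#'   (parametric resampling of junction counts at the fitted PIR).
#' @examples
#' m <- gen_gene_model(3, seed = 1)
#' aln <- simulate_junction_reads(m, rho = 0.3, depth = 20000, seed = 1)
#' fit <- pir_fit(aln, m)
#' coef(fit)
#' @export
pir_fit <- function(x, model = NULL, min_total = 15L, alpha = 0.05,
                    min_anchor = 8L, single_junction = NULL) {
  if (is.character(x) || inherits(x, "junction_alignments")) {
    if (is.null(model)) stopf("`model` is required when `x` is reads")
    counts <- count_junction_reads(x, model, min_anchor = min_anchor)
    if (!is.null(model)) counts$biotype <- model$biotype
  } else {
    counts <- as.data.frame(x)
    if (is.null(counts$gene_id)) counts$gene_id <- "gene"
  }
  est <- estimate_pir(counts, min_total = min_total, alpha = alpha)
  if (!is.null(single_junction)) {
    for (id in names(single_junction)) {
      i <- which(counts$intron_id == id)
      if (!length(i)) stopf("single_junction names unknown intron '%s'", id)
      est[i, ] <- recalc_single_junction(counts[i, , drop = FALSE],
                                         side = single_junction[[id]],
                                         min_total = min_total)
    }
  }
  est$gene_id <- counts$gene_id
  est$biotype <- counts$biotype %||% "coding"
  structure(list(estimates = est, counts = counts,
                 params = list(min_total = min_total, alpha = alpha,
                               min_anchor = min_anchor,
                               single_junction = single_junction),
                 call = match.call()),
            class = "pir_fit")
}

#' @export
print.pir_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("PIR fit: %d introns, %d with defined PIR\n",
              nrow(e), sum(!is.na(e$pir))))
  df <- e[, c("intron_id", "pir", "n_total", "balance_p", "status")]
  df$pir <- round(df$pir, 1)
  df$balance_p <- signif(df$balance_p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pir_fit <- function(object, ...) {
  stats::setNames(object$estimates$pir, object$estimates$intron_id)
}

#' @export
summary.pir_fit <- function(object, ...) {
  out <- gene_pir_extremes(object$estimates)
  class(out) <- c("summary.pir_fit", class(out))
  out
}

#' @export
print.summary.pir_fit <- function(x, ...) {
  cat("Per-gene PIR extremes (defined estimates only):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pir_fit <- function(x, ...) {
  s <- gene_pir_extremes(x$estimates)
  if (nrow(s) == 0L) stopf("no gene has a defined PIR")
  plot(stats::ecdf(s$max_pir), xlab = "maximum PIR per gene (%)",
       ylab = "cumulative fraction of genes",
       main = "Cumulative distribution of per-gene maximum PIR", ...)
  invisible(x)
}

#' @export
simulate.pir_fit <- function(object, nsim = 1, seed = NULL, ...) {
  e <- object$estimates; cts <- object$counts
  with_seed(seed, {
    lapply(seq_len(nsim), function(j) {
      out <- cts
      for (i in seq_len(nrow(e))) {
        p <- e$pir[i]
        if (is.na(p)) next
        tot <- round((cts$EI[i] + cts$IE[i]) / 2 + cts$EE[i])
        r <- stats::rbinom(1L, tot, p / 100)
        ei <- stats::rbinom(1L, 2L * r, 0.5)
        out$EI[i] <- ei; out$IE[i] <- 2L * r - ei; out$EE[i] <- tot - r
      }
      out
    })
  })
}

#' Per-gene maximum and minimum PIR
#'
#' Summarizes a per-intron PIR table into one row per gene with the maximum
#' and minimum over introns with defined PIR; genes with no defined PIR are
#' omitted.  The per-gene maximum is the quantity whose cumulative
#' distribution separates coding from lncRNA retention behaviour.
#'
#' @param estimates Data.frame with columns `gene_id`, `pir` and optionally
#'   `biotype`.
#' @return Data.frame: `gene_id`, `biotype`, `max_pir`, `min_pir`,
#'   `n_evaluable_introns`.
#' @export
gene_pir_extremes <- function(estimates) {
  if (is.null(estimates$biotype)) estimates$biotype <- "coding"
  def <- estimates[!is.na(estimates$pir), , drop = FALSE]
  if (nrow(def) == 0L)
    return(data.frame(gene_id = character(0), biotype = character(0),
                      max_pir = numeric(0), min_pir = numeric(0),
                      n_evaluable_introns = integer(0)))
  sp <- split(def, def$gene_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(gene_id = d$gene_id[1L], biotype = d$biotype[1L],
               max_pir = max(d$pir), min_pir = min(d$pir),
               n_evaluable_introns = nrow(d))
  }))
  rownames(out) <- NULL
  out
}

#' Empirical cumulative distribution of per-gene maximum PIR
#'
#' Computes, within each biotype class, the ECDF value of every gene's
#' maximum PIR (fraction of genes in the class with max PIR less than or
#' equal to this gene's), keeping the paired minimum alongside for plotting.
#'
#' @param gene_summary Output of [gene_pir_extremes()].
#' @return The input with an `ecdf_max` column appended, sorted by biotype
#'   then max PIR.
#' @export
pir_ecdf_table <- function(gene_summary) {
  sp <- split(gene_summary, gene_summary$biotype)
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$max_pir, d$gene_id), , drop = FALSE]
    d$ecdf_max <- stats::ecdf(d$max_pir)(d$max_pir)
    d
  }))
  rownames(out) <- NULL
  out
}

#' Percentile rank of a PIR value within a population
#'
#' The percentile is `100 * (# population values <= value) / N`, ties
#' counting as below-or-equal.  Used to place a gene's retained introns among
#' all retention events of its biotype class (e.g. "among the top 20%").
#'
#' @param value PIR value(s) to rank.
#' @param population Non-empty numeric vector of reference values.
#' @return Percentile(s) in `[0, 100]`.
#' @examples
#' percentile_rank(31.4, c(1, 5, 10, 20, 31.4))  # 100
#' @export
percentile_rank <- function(value, population) {
  population <- population[!is.na(population)]
  if (!length(population)) stopf("population must be non-empty")
  vapply(value, function(v) 100 * sum(population <= v) / length(population),
         numeric(1L))
}
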