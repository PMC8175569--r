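#' Count junction reads per intron
#'
#' Tallies, for every intron of a gene model, the four evidence classes the
#' PIR estimator uses:
#' \describe{
#'   \item{EI}{reads aligning contiguously across the transcript-upstream
#'     exon-intron boundary with at least `min_anchor` bp on each side;}
#'   \item{IE}{the same at the downstream intron-exon boundary;}
#'   \item{EE}{spliced reads with an alignment gap whose genomic span equals
#'     the intron exactly, flanked by at least `min_anchor` matched bp;}
#'   \item{mid_intron}{reads aligned fully within the intron body, at least
#'     `min_anchor` bp away from both boundaries.}
#' }
#' A read may count for several introns but at most once per class per
#' intron.  On the `-` strand the upstream (EI) boundary is the intron's
#' genomic end, so strand affects only the labelling, never the arithmetic.
#'
#' @param aln A `junction_alignments` object (from [simulate_junction_reads()]
#'   or [read_sam()]), or a path to a SAM/BAM file.
#' @param model A [gene_model()].
#' @param min_anchor Minimum matched bp on each side of a junction (default 8).
#' @return A data.frame with one row per intron: `intron_id`, `gene_id`,
#'   `intron_start`, `intron_end`, `EI`, `IE`, `EE`, `mid_intron`,
#'   `min_anchor`.  Rows are in transcript orientation.
#' @export
count_junction_reads <- function(aln, model, min_anchor = 8L) {
  if (is.character(aln)) aln <- read_sam(aln)
  stopifnot(inherits(aln, "junction_alignments"), inherits(model, "gene_model"))
  a <- as.integer(min_anchor)
  if (a < 1L) stopf("min_anchor must be >= 1")
  int <- model$introns
  n <- nrow(int)
  b <- aln$blocks; g <- aln$gaps
  # per-read reference span for the mid-intron test
  span_s <- tapply(b$start, b$read, min)
  span_e <- tapply(b$end, b$read, max)
  has_gap <- names(span_s) %in% as.character(unique(g$read))

  EI_g <- IE_g <- EE <- MID <- integer(n)
  for (i in seq_len(n)) {
    s <- int[i, "start"]; e <- int[i, "end"]
    # contiguous crossing of the genomic-left boundary (exon|intron)
    left <- b$start <= s - a & b$end >= s + a
    right <- b$start <= e - a & b$end >= e + a
    EI_g[i] <- length(unique(b$read[left]))
    IE_g[i] <- length(unique(b$read[right]))
    if (nrow(g)) {
      ee <- g$start == s & g$end == e & g$lflank >= a & g$rflank >= a
      EE[i] <- length(unique(g$read[ee]))
    }
    MID[i] <- sum(span_s >= s + a & span_e <= e - a & !has_gap)
  }
  if (model$strand == "+") { EI <- EI_g; IE <- IE_g } else { EI <- IE_g; IE <- EI_g }
  out <- data.frame(intron_id = intron_ids(model),
                    gene_id = model$gene_id,
                    intron_start = int[, "start"],
                    intron_end = int[, "end"],
                    EI = EI, IE = IE, EE = EE,
                    mid_intron = MID, min_anchor = a)
  out <- out[order(transcript_intron_order(model)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-sided exact binomial test of junction balance
#'
#' Under the null that a retained intron's upstream and downstream boundaries
#' are sequenced at equal rates, `ei` is Binomial(`ei + ie`, 0.5).  A small
#' p-value flags an imbalanced event, typically caused by an alternative
#' splice site inside the intron.  Returns 1 when there are no junction reads.
#'
#' @param ei,ie Non-negative junction read counts.
#' @return Two-sided exact p-value.
#' @examples
#' balance_test(10, 0)  # 2 * 0.5^10
#' @export
balance_test <- function(ei, ie) {
  if (ei < 0 || ie < 0) stopf("counts must be non-negative")
  n <- ei + ie
  if (n == 0) return(1)
  stats::binom.test(ei, n, p = 0.5)$p.value
}
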