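#' Gene model: exon/intron structure of a single transcript
#'
#' A `gene_model` records the exon coordinates of one transcript on one
#' chromosome, strand-aware, in 0-based half-open genomic coordinates.
#' Introns are derived as the gaps between consecutive exons.  The structure
#' mirrors what an annotation row (GTF/BED12) carries for a single
#' transcript; it is the coordinate frame against which junction reads are
#' counted and intron windows are built.
#'
#' @param gene_id Character scalar, gene identifier.
#' @param exons Two-column matrix or data.frame of exon `start`/`end`
#'   (0-based half-open), rows in ascending genomic order.
#' @param strand `"+"` or `"-"`.  Strand affects only the transcript-level
#'   labelling of junctions and windows, never the stored coordinates.
#' @param chrom Chromosome name.
#' @param biotype One of `"coding"`, `"lncRNA"`, `"other"`.
#'
#' @return An object of class `gene_model`: a list with elements `gene_id`,
#'   `biotype`, `strand`, `chrom`, `exons` (matrix with columns
#'   `start`, `end`) and `introns` (matrix, same layout; 0 rows when the
#'   model has a single exon).
#'
#' @examples
#' m <- gene_model("g1", cbind(c(0, 600), c(100, 700)))
#' m$introns  # one 500-bp intron [100, 600)
#' @export
gene_model <- function(gene_id, exons, strand = "+", chrom = "chr1",
                       biotype = c("coding", "lncRNA", "other")) {
  biotype <- match.arg(biotype)
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-', got '%s'", strand)
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stopf("`exons` must have two columns (start, end)")
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, "end"] <= exons[, "start"]))
    stopf("every exon must have end > start")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, "start"], strictly = TRUE))
      stopf("exons must be sorted by ascending start")
    gaps <- exons[-1L, "start"] - exons[-nrow(exons), "end"]
    if (any(gaps < 1L))
      stopf("exons overlap or abut: every intron must be >= 1 bp")
    introns <- cbind(start = exons[-nrow(exons), "end"],
                     end   = exons[-1L, "start"])
  } else {
    introns <- cbind(start = integer(0), end = integer(0))
  }
  structure(
    list(gene_id = as.character(gene_id), biotype = biotype,
         strand = strand, chrom = as.character(chrom),
         exons = exons, introns = introns),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s' (%s, %s strand, %s): %d exons, %d introns\n",
              x$gene_id, x$biotype, x$strand, x$chrom,
              nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

# Per-intron identifiers, numbered in transcript orientation (intron 1 is
# nearest the transcript 5' end, so on '-' strand it is the last genomic gap).
intron_ids <- function(model) {
  n <- nrow(model$introns)
  if (n == 0L) return(character(0))
  idx <- if (model$strand == "+") seq_len(n) else rev(seq_len(n))
  paste0(model$gene_id, ".I", idx)
}

#' Generate a random gene model
#'
#' Draws exon and intron lengths uniformly from the given ranges and lays
#' the exons out left to right from position `origin`.  Deterministic for a
#' fixed seed.
#'
#' @param n_exons Number of exons (>= 2, so at least one intron exists).
#' @param exon_len_range,intron_len_range Integer length-2 vectors giving
#'   inclusive bp ranges to draw lengths from.
#' @param biotype,strand,chrom,gene_id Passed through to [gene_model()].
#' @param origin Genomic start of the first exon.
#' @param seed Integer seed; identical seeds give identical models.
#'
#' @return A [gene_model()].
#' @examples
#' gen_gene_model(16, seed = 1)  # 16 exons, 15 introns
#' @export
gen_gene_model <- function(n_exons, exon_len_range = c(80L, 300L),
                           intron_len_range = c(200L, 2000L),
                           biotype = "coding", strand = "+", chrom = "chr1",
                           gene_id = "gene1", origin = 1000L, seed = NULL) {
  if (n_exons < 2L) stopf("n_exons must be >= 2 (no introns possible otherwise)")
  if (any(exon_len_range < 1L) || any(intron_len_range < 1L))
    stopf("length ranges must be positive")
  with_seed(seed, {
    er <- exon_len_range[1]:exon_len_range[2]
    ir <- intron_len_range[1]:intron_len_range[2]
    elen <- er[sample.int(length(er), n_exons, replace = TRUE)]
    ilen <- ir[sample.int(length(ir), n_exons - 1L, replace = TRUE)]
    starts <- origin + c(0L, cumsum(elen[-n_exons] + ilen))
    gene_model(gene_id, cbind(starts, starts + elen), strand = strand,
               chrom = chrom, biotype = biotype)
  })
}

# Transcript-orientation index of each genomic intron (1 = 5'-most).
transcript_intron_order <- function(model) {
  n <- nrow(model$introns)
  if (model$strand == "+") seq_len(n) else rev(seq_len(n))
}
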