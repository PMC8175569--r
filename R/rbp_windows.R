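#' Splice-site-anchored windows over an intron
#'
#' Partitions the neighbourhood of one intron into nine windows in
#' transcript orientation: a 40-bp exonic and intronic flank on each side of
#' the two splice sites, plus the remaining intron interior split into
#' `n_tiles` near-equal tiles.  Tile lengths differ by at most 1 bp, with
#' the remainder going to the transcript-5'-most tiles.  On the `-` strand
#' the roles are assigned in transcript orientation (tile1 abuts the
#' transcript 5' splice site, i.e. the higher genomic coordinate) while the
#' stored intervals stay genomic.  Dropping the two exonic flanks gives the
#' seven-window intron-only variant.
#'
#' @param intron_start,intron_end Intron interval, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param flank Flank width in bp (default 40).
#' @param n_tiles Number of interior tiles (default 5).
#' @param intron_id,chrom Identifiers carried into the output.
#' @return Data.frame in transcript orientation: `intron_id`, `chrom`,
#'   `role` (`exonic_5flank`, `intronic_5flank`, `tile1`..`tileN`,
#'   `intronic_3flank`, `exonic_3flank`), `start`, `end`, `width`.
#' @examples
#' w <- build_intron_windows(1000, 2000)   # five 184-bp tiles
#' subset(w, role == "tile1")
#' @export
build_intron_windows <- function(intron_start, intron_end, strand = "+",
                                 flank = 40L, n_tiles = 5L,
                                 intron_id = "intron", chrom = "chr1") {
  s <- as.integer(intron_start); e <- as.integer(intron_end)
  flank <- as.integer(flank); n_tiles <- as.integer(n_tiles)
  len <- e - s
  interior <- len - 2L * flank
  if (interior < n_tiles)
    stopf("intron '%s' too short (%d bp) for %d-bp flanks and %d tiles",
          intron_id, len, flank, n_tiles)
  base <- interior %/% n_tiles; rem <- interior %% n_tiles
  # tile widths in transcript orientation: remainder to the first tiles
  tw_tx <- rep(base, n_tiles) + c(rep(1L, rem), rep(0L, n_tiles - rem))
  tw_gen <- if (strand == "+") tw_tx else rev(tw_tx)
  tile_bounds <- s + flank + c(0L, cumsum(tw_gen))
  gen <- data.frame(
    start = c(s - flank, s, tile_bounds[-length(tile_bounds)], e - flank, e),
    end   = c(s, s + flank, tile_bounds[-1L], e, e + flank))
  roles_tx <- c("exonic_5flank", "intronic_5flank", paste0("tile", seq_len(n_tiles)),
                "intronic_3flank", "exonic_3flank")
  gen$role <- if (strand == "+") roles_tx else rev(roles_tx)
  ord <- if (strand == "+") seq_len(nrow(gen)) else rev(seq_len(nrow(gen)))
  out <- data.frame(intron_id = intron_id, chrom = chrom,
                    role = gen$role[ord], start = gen$start[ord],
                    end = gen$end[ord])
  out$width <- out$end - out$start
  rownames(out) <- NULL
  out
}

#' Windows for every intron of a gene model
#'
#' @param model A [gene_model()].
#' @inheritParams build_intron_windows
#' @return Row-bound [build_intron_windows()] tables, one per intron,
#'   introns numbered in transcript orientation.
#' @export
model_intron_windows <- function(model, flank = 40L, n_tiles = 5L) {
  ids <- intron_ids(model)
  do.call(rbind, lapply(seq_len(nrow(model$introns)), function(i)
    build_intron_windows(model$introns[i, "start"], model$introns[i, "end"],
                         strand = model$strand, flank = flank,
                         n_tiles = n_tiles, intron_id = ids[i],
                         chrom = model$chrom)))
}

#' Merge peak intervals per RBP
#'
#' Unions the peak intervals of each RBP across experiments/cell lines,
#' coalescing overlapping or bookended intervals, so that coverage fractions
#' count each base at most once.  Idempotent: replicate files with identical
#' peaks merge to the same result as one file.
#'
#' @param peaks A named list (one element per RBP) of either BED6 file paths
#'   (several per RBP allowed) or data.frames with columns `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return Named list of merged data.frames (`chrom`, `start`, `end`),
#'   sorted, per RBP.
#' @export
merge_peaks <- function(peaks) {
  stopifnot(is.list(peaks), !is.null(names(peaks)))
  lapply(peaks, function(x) {
    if (is.character(x)) {
      grl <- lapply(x, rtracklayer::import, format = "BED")
      gr <- do.call(c, grl)
    } else {
      gr <- GenomicRanges::GRanges(
        x$chrom, IRanges::IRanges(start = x$start + 1L, end = x$end))
    }
    m <- GenomicRanges::reduce(GenomicRanges::sort(gr), ignore.strand = TRUE)
    data.frame(chrom = as.character(GenomicRanges::seqnames(m)),
               start = BiocGenerics::start(m) - 1L,
               end = BiocGenerics::end(m))
  })
}

#' Fraction of window base pairs covered by peaks
#'
#' @param windows A window table from [build_intron_windows()] (or any
#'   data.frame with `chrom`, `start`, `end`).
#' @param peaks Merged peak data.frame for one RBP (`chrom`, `start`, `end`,
#'   0-based half-open; disjoint after [merge_peaks()]).
#' @return The `windows` table with a `coverage` column in `[0, 1]`.
#' @export
window_coverage <- function(windows, peaks) {
  cov <- vapply(seq_len(nrow(windows)), function(i) {
    p <- peaks[peaks$chrom == windows$chrom[i], , drop = FALSE]
    if (nrow(p) == 0L) return(0)
    ov <- pmin(p$end, windows$end[i]) - pmax(p$start, windows$start[i])
    sum(pmax(ov, 0)) / (windows$end[i] - windows$start[i])
  }, numeric(1L))
  windows$coverage <- cov
  windows
}

#' Per-RBP per-window coverage matrix
#'
#' @param windows Window table covering one or more introns.
#' @param peaks_by_rbp Named list of merged peak data.frames (from
#'   [merge_peaks()]).
#' @return Numeric matrix, rows = RBPs, columns = windows (named
#'   `intron_id:role`; just `role` for a single intron), values = covered
#'   base-pair fractions.
#' @export
coverage_matrix <- function(windows, peaks_by_rbp) {
  cn <- if (length(unique(windows$intron_id)) > 1L)
    paste(windows$intron_id, windows$role, sep = ":") else windows$role
  m <- t(vapply(peaks_by_rbp, function(p) window_coverage(windows, p)$coverage,
                numeric(nrow(windows))))
  colnames(m) <- cn
  m
}

#' Hierarchically cluster introns (or RBPs) by binding profile
#'
#' Agglomerative clustering with Euclidean distance and average linkage on
#' the rows of a coverage (or motif-score) matrix.  `hclust` resolves
#' distance ties deterministically in favour of the earlier-formed cluster,
#' so the leaf order is reproducible.
#'
#' @param mat Numeric matrix, one row per object (>= 2 rows).
#' @param method Linkage (default `"average"`).
#' @return The `hclust` tree, with leaf order in `$order`.
#' @export
cluster_introns <- function(mat, method = "average") {
  if (nrow(mat) < 2L) stopf("need at least 2 profiles to cluster")
  stats::hclust(stats::dist(mat, method = "euclidean"), method = method)
}
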