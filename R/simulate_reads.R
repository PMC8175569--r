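#' Simulate junction reads from a mixture of retained and spliced molecules
#'
#' Emulates the poly(A)+ RNA-seq evidence the PIR estimator consumes.  Each
#' read is drawn from a source molecule in which every intron is independently
#' retained with its retention fraction `rho`; retained introns yield
#' contiguous alignments across exon-intron boundaries and within the intron
#' body, spliced introns yield alignments with an `N` gap exactly spanning
#' the intron.  Read start positions are uniform along the source isoform
#' and the total read count is Poisson at the requested depth.
#'
#' As in real RNA-seq, where uniform fragmentation makes a molecule
#' contribute reads in proportion to its length, each read's source isoform
#' is drawn length-weighted from the molecule pool: configuration `c` (the
#' set of retained introns) is sampled with probability proportional to
#' `P(c) * (len(c) - read_len + 1)`, then the start is uniform.  Under this
#' model every intron's expected EI, IE and EE junction-read rates are
#' proportional to `rho`, `rho` and `1 - rho` respectively, so the
#' junction-ratio PIR estimator is unbiased, and EI and IE rates are equal
#' by symmetry.
#'
#' @param model A [gene_model()].
#' @param rho True retention fraction(s) in `[0,1]`: a scalar applied to all
#'   introns or one value per intron in genomic order.
#' @param depth Expected total read count (Poisson mean).
#' @param read_len Read length in bp; must be at least `2 * min_anchor`.
#' @param min_anchor Minimum junction anchor the downstream counter will use;
#'   only validated here.
#' @param seed Integer seed; identical seeds give identical read sets.
#'
#' @return An object of class `junction_alignments`: a list with
#'   `blocks` (data.frame `read`, `start`, `end`: reference-space aligned
#'   segments, 0-based half-open), `gaps` (data.frame `read`, `start`, `end`,
#'   `lflank`, `rflank`: skipped regions with flanking matched lengths),
#'   `n_reads`, `read_len` and `chrom`.  Serialize with [write_sam()].
#' @seealso [count_junction_reads()], [pir_fit()]
#' @export
simulate_junction_reads <- function(model, rho, depth, read_len = 100L,
                                    min_anchor = 8L, seed = NULL) {
  stopifnot(inherits(model, "gene_model"))
  k <- nrow(model$introns)
  if (k == 0L) stopf("model has no introns")
  if (length(rho) == 1L) rho <- rep(rho, k)
  if (length(rho) != k) stopf("rho must be scalar or one value per intron")
  if (any(rho < 0 | rho > 1)) stopf("rho must lie in [0,1]")
  if (depth <= 0) stopf("depth must be positive")
  read_len <- as.integer(read_len)
  if (read_len < 2L * min_anchor)
    stopf("read_len (%d) must be >= 2 * min_anchor (%d)", read_len,
          2L * min_anchor)

  with_seed(seed, {
    n <- stats::rpois(1L, depth)
    if (n == 0L) {
      return(empty_alignments(model$chrom, read_len))
    }
    # Length-weighted configuration sampling via the exact mixture
    # decomposition of P(c) * w(c), where w(c) = spliced_len - L + 1 +
    # sum of retained intron lengths: pick a component (base, or intron j
    # forced retained) with probability proportional to its mass, then draw
    # the remaining indicators independently.
    ilen <- model$introns[, "end"] - model$introns[, "start"]
    base_w <- sum(model$exons[, "end"] - model$exons[, "start"]) - read_len + 1L
    if (base_w < 1L)
      stopf("spliced isoform shorter than the read length")
    comp <- sample.int(k + 1L, n, replace = TRUE,
                       prob = c(base_w, rho * ilen)) - 1L
    ind <- matrix(stats::rbinom(n * k, 1L, rep(rho, each = n)), n, k)
    forced <- comp > 0L
    if (any(forced)) ind[cbind(which(forced), comp[forced])] <- 1L
    key <- as.vector(ind %*% (2^(seq_len(k) - 1L)))

    blocks_l <- list(); gaps_l <- list(); offset <- 0L
    for (kk in sort(unique(key))) {
      rows <- which(key == kk)
      ret <- ind[rows[1L], ] == 1L
      piece <- isoform_reads(model, ret, length(rows), read_len, offset)
      blocks_l[[length(blocks_l) + 1L]] <- piece$blocks
      gaps_l[[length(gaps_l) + 1L]] <- piece$gaps
      offset <- offset + length(rows)
    }
    blocks <- do.call(rbind, blocks_l)
    gaps <- do.call(rbind, gaps_l)
    structure(list(blocks = blocks,
                   gaps = gaps %||% empty_gaps(),
                   n_reads = n, read_len = read_len, chrom = model$chrom),
              class = "junction_alignments")
  })
}

empty_gaps <- function() {
  data.frame(read = integer(0), start = integer(0), end = integer(0),
             lflank = integer(0), rflank = integer(0))
}

empty_alignments <- function(chrom, read_len) {
  structure(list(blocks = data.frame(read = integer(0), start = integer(0),
                                     end = integer(0)),
                 gaps = empty_gaps(), n_reads = 0L, read_len = read_len,
                 chrom = chrom),
            class = "junction_alignments")
}

#' @export
print.junction_alignments <- function(x, ...) {
  cat(sprintf("junction_alignments: %d reads (%d bp) on %s, %d gapped\n",
              x$n_reads, x$read_len, x$chrom,
              length(unique(x$gaps$read))))
  invisible(x)
}

# Draw n uniform reads from the isoform with retained-intron indicator `ret`
# and map them to reference-space blocks/gaps.  Vectorized over reads.
isoform_reads <- function(model, ret, n, read_len, read_offset) {
  ex <- model$exons; int <- model$introns
  m <- nrow(ex)
  # ordered isoform segments: exon 1, (intron 1?), exon 2, ...
  seg_s <- integer(0); seg_e <- integer(0)
  for (i in seq_len(m)) {
    seg_s <- c(seg_s, ex[i, "start"]); seg_e <- c(seg_e, ex[i, "end"])
    if (i < m && ret[i]) {
      seg_s <- c(seg_s, int[i, "start"]); seg_e <- c(seg_e, int[i, "end"])
    }
  }
  len <- seg_e - seg_s
  off <- c(0L, cumsum(len))           # isoform offsets, length nseg+1
  iso_len <- off[length(off)]
  if (iso_len < read_len)
    stopf("isoform (%d bp) shorter than read length %d", iso_len, read_len)
  s <- sample.int(iso_len - read_len + 1L, n, replace = TRUE) - 1L
  e <- s + read_len
  first <- findInterval(s, off, rightmost.closed = FALSE)        # segment of s
  last <- findInterval(e - 1L, off)                              # segment of e-1
  nseg_per_read <- last - first + 1L
  read_id <- rep(seq_len(n), nseg_per_read) + read_offset
  seg_idx <- sequence(nseg_per_read, from = first)
  rs <- rep(s, nseg_per_read); re <- rep(e, nseg_per_read)
  b_start <- seg_s[seg_idx] + pmax(0L, rs - off[seg_idx])
  b_end <- seg_s[seg_idx] + pmin(len[seg_idx], re - off[seg_idx])
  # merge blocks that are genomically contiguous (retained-intron joins)
  new_run <- c(TRUE, read_id[-1L] != read_id[-length(read_id)] |
                 b_start[-1L] != b_end[-length(b_end)])
  run <- cumsum(new_run)
  blocks <- data.frame(
    read = read_id[new_run],
    start = b_start[new_run],
    end = as.integer(tapply(b_end, run, function(v) v[length(v)])))
  # gaps between consecutive merged blocks of one read
  gi <- which(blocks$read[-1L] == blocks$read[-nrow(blocks)])
  gaps <- if (length(gi)) {
    data.frame(read = blocks$read[gi],
               start = blocks$end[gi], end = blocks$start[gi + 1L],
               lflank = blocks$end[gi] - blocks$start[gi],
               rflank = blocks$end[gi + 1L] - blocks$start[gi + 1L])
  } else empty_gaps()
  list(blocks = blocks, gaps = gaps)
}

#' Write simulated alignments as SAM
#'
#' Emits a minimal SAM file (header plus alignments with M/N-only CIGARs,
#' unmapped mates and `*` sequence) readable by any SAM-aware tool.
#'
#' @param aln A `junction_alignments` object.
#' @param path Output file path.
#' @param chrom_len Reference length for the `@SQ` line; defaults to just
#'   past the last aligned base.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, chrom_len = NULL) {
  stopifnot(inherits(aln, "junction_alignments"))
  chrom_len <- chrom_len %||% (max(c(1L, aln$blocks$end)) + 1000L)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", aln$chrom, chrom_len))
  if (aln$n_reads == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  b <- aln$blocks[order(aln$blocks$read, aln$blocks$start), ]
  cig <- vapply(split(seq_len(nrow(b)), b$read), function(ix) {
    w <- b$end[ix] - b$start[ix]
    if (length(ix) == 1L) return(sprintf("%dM", w))
    gaps <- b$start[ix][-1L] - b$end[ix][-length(ix)]
    paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
           w[length(w)], "M")
  }, character(1L))
  pos1 <- vapply(split(b$start, b$read), min, integer(1L)) + 1L
  ids <- names(pos1)
  rec <- sprintf("read%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                 ids, aln$chrom, pos1, cig)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read spliced alignments from SAM/BAM into the junction counting container
#'
#' Accepts SAM text or BAM.  Only `M` and `N` CIGAR operators are supported;
#' any other operator raises an error naming the offending read.
#'
#' @param path SAM or BAM file.
#' @return A `junction_alignments` object (coordinates 0-based half-open).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  sc <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "cigar"))
  x <- Rsamtools::scanBam(bam, param = sc)[[1L]]
  keep <- !is.na(x$pos)
  qname <- x$qname[keep]; pos <- x$pos[keep]; cigar <- x$cigar[keep]
  rname <- as.character(x$rname[keep])
  if (length(pos) == 0L) return(empty_alignments(rname[1] %||% "chr1", NA_integer_))
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  bad <- which(!vapply(ops, function(o) all(o %in% c("M", "N")), logical(1L)))
  if (length(bad))
    stopf("unsupported CIGAR operator in read '%s' (%s); only M/N supported",
          qname[bad[1L]], cigar[bad[1L]])
  mr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = "M")
  nr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = "N")
  nm <- S4Vectors::elementNROWS(mr)
  um <- unlist(mr, use.names = FALSE)
  blocks <- data.frame(read = rep(seq_along(cigar), nm),
                       start = BiocGenerics::start(um) - 1L,
                       end = BiocGenerics::end(um))
  ng <- S4Vectors::elementNROWS(nr)
  gaps <- if (sum(ng)) {
    un <- unlist(nr, use.names = FALSE)
    g <- data.frame(read = rep(seq_along(cigar), ng),
                    start = BiocGenerics::start(un) - 1L,
                    end = BiocGenerics::end(un))
    # flanking matched lengths from the neighbouring M blocks
    g$lflank <- g$rflank <- NA_integer_
    for (i in seq_len(nrow(g))) {
      rb <- blocks[blocks$read == g$read[i], ]
      g$lflank[i] <- rb$end[match(g$start[i], rb$end)] -
        rb$start[match(g$start[i], rb$end)]
      g$rflank[i] <- rb$end[match(g$end[i], rb$start)] -
        rb$start[match(g$end[i], rb$start)]
    }
    g
  } else empty_gaps()
  structure(list(blocks = blocks, gaps = gaps,
                 n_reads = length(cigar),
                 read_len = as.integer(stats::median(
                   tapply(blocks$end - blocks$start, blocks$read, sum))),
                 chrom = rname[1L]),
            class = "junction_alignments")
}
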