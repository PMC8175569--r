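#' Planted peak and motif fixtures over the introns of a gene model
#'
#' Generates, with known ground truth, the inputs of the RBP window
#' analysis: per-RBP peak sets planted preferentially in chosen window
#' roles (so enrichment there is recoverable), a PWM per RBP with a known
#' consensus, and random intron sequences with the consensus planted once
#' per intron at a recorded position.
#'
#' @param model A [gene_model()].
#' @param n_rbps Number of RBPs (>= 1).
#' @param planted_roles Window roles to enrich with peaks (default the two
#'   intronic splice-site flanks).
#' @param peak_prob Probability a planted-role window of an intron receives
#'   a peak.
#' @param bg_prob Probability any other window receives a (smaller)
#'   background peak.
#' @param motif_len Motif width.
#' @param consensus_only If `TRUE` (default) PWMs put probability 1 on the
#'   consensus base at every position, making motif recovery exactly
#'   checkable; otherwise probability 0.85 on the consensus and 0.05
#'   elsewhere.
#' @param flank,n_tiles Window geometry (see [build_intron_windows()]).
#' @param out_dir If non-`NULL`, also write BED6 files (one per RBP), a
#'   MEME motif file, a FASTA of intron sequences and truth TSVs there.
#' @param seed Integer seed.
#' @return List: `windows`, `peaks` (named list of data.frames), `pwms`,
#'   `sequences` (named character, one per intron), `offsets` (genomic
#'   0-based start per sequence), `truth` (list `peaks`, `motifs`).
#' @export
gen_peak_and_motif_fixtures <- function(model, n_rbps = 3L,
                                        planted_roles = c("intronic_5flank",
                                                          "intronic_3flank"),
                                        peak_prob = 0.9, bg_prob = 0.05,
                                        motif_len = 8L, consensus_only = TRUE,
                                        flank = 40L, n_tiles = 5L,
                                        out_dir = NULL, seed = NULL) {
  if (n_rbps < 1L) stopf("n_rbps must be >= 1")
  windows <- model_intron_windows(model, flank = flank, n_tiles = n_tiles)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    rbps <- sprintf("RBP%02d", seq_len(n_rbps))
    peaks <- list(); truth_peaks <- list()
    for (r in rbps) {
      rows <- list()
      for (i in seq_len(nrow(windows))) {
        w <- windows[i, ]
        planted <- w$role %in% planted_roles
        pr <- if (planted) peak_prob else bg_prob
        if (stats::runif(1) < pr) {
          wid <- max(4L, round(stats::runif(1, 0.4, 0.7) * w$width))
          s <- w$start + sample.int(max(1L, w$width - wid + 1L), 1L) - 1L
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = w$chrom, start = s, end = s + wid)
          truth_peaks[[length(truth_peaks) + 1L]] <- data.frame(
            rbp = r, intron_id = w$intron_id, role = w$role,
            start = s, end = s + wid, planted = planted)
        }
      }
      peaks[[r]] <- if (length(rows)) do.call(rbind, rows) else
        data.frame(chrom = character(0), start = integer(0), end = integer(0))
    }
    pwms <- lapply(rbps, function(r) {
      cons <- sample(4L, motif_len, replace = TRUE)
      m <- matrix(if (consensus_only) 0 else 0.05, motif_len, 4L)
      m[cbind(seq_len(motif_len), cons)] <- if (consensus_only) 1 else 0.85
      pwm(m, motif_id = paste0(r, ".m1"), rbp = r)
    })
    ids <- unique(windows$intron_id)
    introns <- model$introns[order(transcript_intron_order(model)), , drop = FALSE]
    offsets <- stats::setNames(introns[, "start"], ids)
    sequences <- character(length(ids)); names(sequences) <- ids
    truth_motifs <- list()
    for (k in seq_along(ids)) {
      len <- introns[k, "end"] - introns[k, "start"]
      sq <- sample(bases, len, replace = TRUE)
      for (p in pwms) {
        cons <- bases[apply(p$mat, 1L, which.max)]
        pos <- sample.int(len - motif_len + 1L, 1L)
        sq[pos:(pos + motif_len - 1L)] <- cons
        truth_motifs[[length(truth_motifs) + 1L]] <- data.frame(
          rbp = p$rbp, motif_id = p$motif_id, intron_id = ids[k],
          start_local = pos, start_genomic = offsets[[k]] + pos - 1L)
      }
      sequences[k] <- paste(sq, collapse = "")
    }
    truth <- list(peaks = do.call(rbind, truth_peaks),
                  motifs = do.call(rbind, truth_motifs))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (r in rbps) {
        p <- peaks[[r]]
        utils::write.table(
          data.frame(p$chrom, p$start, p$end, paste0(r, "_peak", seq_len(nrow(p))),
                     1000L, "."),
          file.path(out_dir, paste0(r, ".bed")), sep = "\t", quote = FALSE,
          row.names = FALSE, col.names = FALSE)
      }
      write_meme(pwms, file.path(out_dir, "motifs.meme"))
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences),
                                  file.path(out_dir, "introns.fa"))
      utils::write.table(truth$peaks, file.path(out_dir, "truth_peaks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(truth$motifs, file.path(out_dir, "truth_motifs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(windows = windows, peaks = peaks, pwms = pwms,
         sequences = sequences, offsets = offsets, truth = truth)
  })
}
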