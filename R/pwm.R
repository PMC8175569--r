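#' Position weight matrix
#'
#' Per-position base probabilities of a sequence motif over A, C, G, T,
#' scored as log-odds against a background distribution.
#'
#' @param mat Numeric matrix, one row per motif position, columns
#'   `A`, `C`, `G`, `T`; each row must sum to 1 (tolerance 1e-4).
#' @param motif_id Motif identifier.
#' @param rbp RBP the motif belongs to (several motifs may share an RBP).
#' @param bg Background base probabilities (length 4, sums to 1); default
#'   uniform.
#' @return Object of class `pwm`.
#' @export
pwm <- function(mat, motif_id = "motif", rbp = motif_id,
                bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) stopf("pwm matrix must have 4 columns (A,C,G,T)")
  colnames(mat) <- c("A", "C", "G", "T")
  if (any(abs(rowSums(mat) - 1) > 1e-4))
    stopf("every pwm row must sum to 1")
  if (abs(sum(bg) - 1) > 1e-6) stopf("background must sum to 1")
  if (any(mat < 0) || any(bg < 0)) stopf("probabilities must be non-negative")
  structure(list(mat = mat, motif_id = as.character(motif_id),
                 rbp = as.character(rbp), bg = unname(bg)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(colnames(x$mat)[apply(x$mat, 1L, which.max)], collapse = "")
  cat(sprintf("pwm '%s' (RBP %s): width %d, consensus %s\n",
              x$motif_id, x$rbp, nrow(x$mat), cons))
  invisible(x)
}

#' Read motifs from MEME-style minimal text
#'
#' Parses the MEME minimal motif format (version line, optional alphabet
#' and background lines, then `MOTIF id [altname]` blocks with a
#' `letter-probability matrix` each).  The motif's alternate name, when
#' present, is taken as its RBP.
#'
#' @param path MEME-format text file.
#' @return List of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(0.25, 0.25, 0.25, 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1L] + 1L]), "\\s+")[[1L]]
    bg <- as.numeric(toks[seq(2L, 8L, by = 2L)])
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stopf("no MOTIF blocks in %s", path)
  lapply(starts, function(i) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    id <- hdr[2L]; rbp <- if (length(hdr) >= 3L) hdr[3L] else id
    j <- i + which(grepl("^letter-probability matrix", lines[(i + 1L):length(lines)]))[1L]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1L):(j + w)]
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])))
    # renormalize parse-precision drift
    mat <- mat / rowSums(mat)
    pwm(mat, motif_id = id, rbp = rbp, bg = bg)
  })
}

#' Write motifs as MEME-style minimal text
#'
#' @param pwms List of [pwm()] objects (background taken from the first).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1L]]$bg
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
           "Background letter frequencies",
           sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
           "")
  for (p in pwms) {
    out <- c(out, sprintf("MOTIF %s %s", p$motif_id, p$rbp),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     nrow(p$mat)),
             apply(p$mat, 1L, function(r) paste(sprintf("%.6f", r), collapse = "  ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

# Discretized log-odds score matrix (integer units of `step` bits) and the
# exact null distribution of the total score under the background, computed
# by dynamic programming (position-wise convolution over the 4 letters).
pwm_score_table <- function(p, step = 0.01, pseudocount = 1e-4) {
  pr <- (p$mat + pseudocount)
  pr <- pr / rowSums(pr)
  bits <- log2(sweep(pr, 2L, p$bg, "/"))
  si <- round(bits / step)                      # integer scores, w x 4
  storage.mode(si) <- "integer"
  w <- nrow(si)
  # DP: start with point mass at 0, fold in one position at a time
  cur_lo <- 0L; cur <- 1
  for (i in seq_len(w)) {
    s_i <- si[i, ]
    new_lo <- cur_lo + min(s_i)
    new_hi <- cur_lo + length(cur) - 1L + max(s_i)
    new <- numeric(new_hi - new_lo + 1L)
    for (l in 1:4) {
      off <- cur_lo + s_i[l] - new_lo
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * p$bg[l]
    }
    cur <- new; cur_lo <- new_lo
  }
  # survival function: P(total integer score >= s)
  surv <- rev(cumsum(rev(cur)))
  list(si = si, step = step, lo = cur_lo, surv = surv)
}

# P(null score >= s_int) from a pwm_score_table
pwm_pvalue <- function(tab, s_int) {
  k <- s_int - tab$lo + 1L
  ifelse(k <= 0L, 1, ifelse(k > length(tab$surv), 0, tab$surv[pmax(k, 1L)]))
}

#' Scan a sequence for PWM matches with exact null p-values
#'
#' Scores the motif's log-odds (bits against the background) at every
#' position of the sequence, on both strands unless `rna = TRUE`, and keeps
#' hits whose exact p-value is below `p_threshold`.  The p-value
#' `P(null score >= observed)` is computed exactly by dynamic programming
#' over the discretized score distribution under the background (the same
#' construction FIMO uses); positions overlapping `N` are skipped.
#'
#' @param sequence Character string or `Biostrings::DNAString` over
#'   `A,C,G,T,N`.
#' @param p A [pwm()].
#' @param p_threshold Retain hits with p below this (default 1e-4).
#' @param rna If `TRUE`, scan the given strand only (single-stranded RNA).
#' @param step Score discretization in bits (default 0.01).
#' @param pseudocount Added to matrix probabilities before log-odds, so that
#'   zero entries score finitely.
#' @return Data.frame `motif_id`, `rbp`, `start` (1-based in the sequence),
#'   `strand`, `score` (bits), `p`.  Sequences shorter than the motif give
#'   an empty result.
#' @export
scan_pwm <- function(sequence, p, p_threshold = 1e-4, rna = FALSE,
                     step = 0.01, pseudocount = 1e-4) {
  stopifnot(inherits(p, "pwm"))
  seqc <- toupper(as.character(sequence))
  w <- nrow(p$mat); n <- nchar(seqc)
  empty <- data.frame(motif_id = character(0), rbp = character(0),
                      start = integer(0), strand = character(0),
                      score = numeric(0), p = numeric(0))
  if (n < w) return(empty)
  tab <- pwm_score_table(p, step = step, pseudocount = pseudocount)
  strands <- if (rna) "+" else c("+", "-")
  hits <- list()
  for (st in strands) {
    sq <- if (st == "+") seqc else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqc)))
    code <- match(strsplit(sq, "")[[1L]], c("A", "C", "G", "T"))
    ns <- n - w + 1L
    total <- integer(ns); valid <- rep(TRUE, ns)
    for (j in seq_len(w)) {
      cj <- code[j:(j + ns - 1L)]
      bad <- is.na(cj)
      valid <- valid & !bad
      cj[bad] <- 1L
      total <- total + tab$si[j, cj]
    }
    pv <- pwm_pvalue(tab, total)
    keep <- which(valid & pv < p_threshold)
    if (length(keep)) {
      start_fwd <- if (st == "+") keep else n - (keep + w - 1L) + 1L
      hits[[st]] <- data.frame(motif_id = p$motif_id, rbp = p$rbp,
                               start = start_fwd, strand = st,
                               score = total[keep] * step, p = pv[keep])
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many sequences with many motifs
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet` of
#'   intron sequences.
#' @param pwms List of [pwm()] objects.
#' @param ... Passed to [scan_pwm()].
#' @return Data.frame of hits with a `seq_id` column prepended.
#' @export
scan_pwm_set <- function(sequences, pwms, ...) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  seqs <- as.character(sequences)
  out <- list()
  for (i in seq_along(seqs)) for (p in pwms) {
    h <- scan_pwm(seqs[[i]], p, ...)
    if (nrow(h)) out[[length(out) + 1L]] <- cbind(seq_id = ids[i], h)
  }
  if (!length(out))
    return(data.frame(seq_id = character(0), motif_id = character(0),
                      rbp = character(0), start = integer(0),
                      strand = character(0), score = numeric(0),
                      p = numeric(0)))
  do.call(rbind, out)
}

#' Collate motif hits to per-RBP per-window maximum scores
#'
#' Maps each hit to the window containing its (genomic) start position and
#' keeps, per RBP and window, the maximum score across that RBP's motifs
#' and hits -- the motif analogue of the peak coverage matrix.  RBPs with no
#' hit anywhere keep their row, filled with `NA`.
#'
#' @param hits Hit table from [scan_pwm_set()]; positions are 1-based within
#'   each intron sequence.
#' @param windows Window table from [build_intron_windows()] (genomic,
#'   0-based half-open).
#' @param offsets Named integer vector: genomic start (0-based) of each
#'   scanned sequence, named by `seq_id`.
#' @param rbps Row universe (default: RBPs present in `hits`).
#' @return Numeric matrix, rows = RBPs, columns = windows
#'   (`intron_id:role` or `role`), values = max score or `NA`.
#' @export
collate_max_score <- function(hits, windows, offsets, rbps = NULL) {
  rbps <- rbps %||% sort(unique(hits$rbp))
  cn <- if (length(unique(windows$intron_id)) > 1L)
    paste(windows$intron_id, windows$role, sep = ":") else windows$role
  m <- matrix(NA_real_, length(rbps), nrow(windows),
              dimnames = list(rbps, cn))
  if (nrow(hits)) {
    pos0 <- offsets[hits$seq_id] + hits$start - 1L   # genomic, 0-based
    for (k in seq_len(nrow(hits))) {
      wi <- which(windows$start <= pos0[k] & pos0[k] < windows$end)
      for (w in wi) {
        cur <- m[hits$rbp[k], w]
        if (is.na(cur) || hits$score[k] > cur) m[hits$rbp[k], w] <- hits$score[k]
      }
    }
  }
  m
}
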