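# Shared fixtures and independent brute-force oracles used across tests.

intron_ids_for_test <- function(m) pirfish:::intron_ids(m)
transcript_intron_order <- function(m) pirfish:::transcript_intron_order(m)

# A minimal two-intron gene model with round coordinates:
# exons [0,100) [600,700) [1200,1300); introns [100,600) [700,1200).
tiny_model <- function(strand = "+") {
  gene_model("g", cbind(c(0L, 600L, 1200L), c(100L, 700L, 1300L)),
             strand = strand)
}

# Build a junction_alignments object by hand from (pos, cigar) pairs,
# 0-based start positions, M/N-only CIGARs.  Independent of the simulator.
manual_alignments <- function(pos, cigar, chrom = "chr1") {
  blocks <- list(); gaps <- list()
  for (r in seq_along(pos)) {
    ops <- regmatches(cigar[r], gregexpr("\\d+[MN]", cigar[r]))[[1]]
    len <- as.integer(sub("[MN]", "", ops))
    typ <- sub("\\d+", "", ops)
    at <- pos[r]
    prev_m <- NA_integer_
    for (k in seq_along(ops)) {
      if (typ[k] == "M") {
        blocks[[length(blocks) + 1]] <-
          data.frame(read = r, start = at, end = at + len[k])
        prev_m <- len[k]
      } else {
        gaps[[length(gaps) + 1]] <-
          data.frame(read = r, start = at, end = at + len[k],
                     lflank = prev_m, rflank = len[k + 1L])
      }
      at <- at + len[k]
    }
  }
  structure(list(blocks = do.call(rbind, blocks),
                 gaps = if (length(gaps)) do.call(rbind, gaps) else
                   data.frame(read = integer(0), start = integer(0),
                              end = integer(0), lflank = integer(0),
                              rflank = integer(0)),
                 n_reads = length(pos), read_len = NA_integer_, chrom = chrom),
            class = "junction_alignments")
}

# Brute-force junction counter: plain per-read, per-intron interval checks,
# written independently of the package's vectorized counting.
brute_force_counts <- function(aln, model, a = 8L) {
  int <- model$introns
  out <- data.frame(EI = integer(nrow(int)), IE = integer(nrow(int)),
                    EE = integer(nrow(int)), mid_intron = integer(nrow(int)))
  for (i in seq_len(nrow(int))) {
    s <- int[i, "start"]; e <- int[i, "end"]
    for (r in seq_len(aln$n_reads)) {
      b <- aln$blocks[aln$blocks$read == r, , drop = FALSE]
      g <- aln$gaps[aln$gaps$read == r, , drop = FALSE]
      if (any(b$start <= s - a & b$end >= s + a)) out$EI[i] <- out$EI[i] + 1L
      if (any(b$start <= e - a & b$end >= e + a)) out$IE[i] <- out$IE[i] + 1L
      if (nrow(g) && any(g$start == s & g$end == e & g$lflank >= a & g$rflank >= a))
        out$EE[i] <- out$EE[i] + 1L
      if (nrow(g) == 0 && min(b$start) >= s + a && max(b$end) <= e - a)
        out$mid_intron[i] <- out$mid_intron[i] + 1L
    }
  }
  if (model$strand == "-") { tmp <- out$EI; out$EI <- out$IE; out$IE <- tmp }
  out[order(transcript_intron_order(model)), , drop = FALSE]
}

# Brute-force maximum-cardinality bipartite matching (augmenting paths) on
# the adjacency graph of spot pairs within `radius`.
max_matching_size <- function(exon, intron, radius) {
  ne <- nrow(exon); ni <- nrow(intron)
  if (ne == 0 || ni == 0) return(0L)
  adj <- sqrt(outer(exon$y, intron$y, "-")^2 +
                outer(exon$x, intron$x, "-")^2) <= radius
  match_i <- rep(0L, ni)
  try_kuhn <- function(u, seen) {
    for (v in which(adj[u, ])) {
      if (!seen[v]) {
        seen[v] <- TRUE
        if (match_i[v] == 0L || Recall(match_i[v], seen)$ok) {
          match_i[v] <<- u
          return(list(ok = TRUE, seen = seen))
        }
      }
    }
    list(ok = FALSE, seen = seen)
  }
  n <- 0L
  for (u in seq_len(ne)) {
    if (try_kuhn(u, rep(FALSE, ni))$ok) n <- n + 1L
  }
  n
}

# Exhaustive-enumeration PWM p-value oracle: scores every length-w word with
# the same discretized integer scores and sums background probabilities of
# words scoring >= s.
enum_pvalue <- function(p, s_int, step = 0.01, pseudocount = 1e-4) {
  pr <- (p$mat + pseudocount); pr <- pr / rowSums(pr)
  si <- round(log2(sweep(pr, 2, p$bg, "/")) / step)
  w <- nrow(si)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  tot <- numeric(nrow(grid)); pb <- rep(1, nrow(grid))
  for (j in seq_len(w)) {
    tot <- tot + si[j, grid[, j]]
    pb <- pb * p$bg[grid[, j]]
  }
  sum(pb[tot >= s_int])
}
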