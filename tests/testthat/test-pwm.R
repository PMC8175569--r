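consensus_pwm <- function(word, id = "m", rbp = id) {
  code <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix(0, length(code), 4)
  m[cbind(seq_along(code), code)] <- 1
  pwm(m, motif_id = id, rbp = rbp)
}

test_that("pwm construction validates probabilities", {
  expect_s3_class(consensus_pwm("ACGT"), "pwm")
  expect_error(pwm(matrix(0.3, 4, 4)), "sum to 1")
  expect_error(pwm(matrix(0.25, 4, 3)), "4 columns")
  expect_error(pwm(matrix(0.25, 4, 4), bg = c(0.5, 0.5, 0.5, 0.5)),
               "ackground")
})

test_that("MEME text round-trips motifs and background", {
  p1 <- consensus_pwm("ACGTACGT", id = "mot1", rbp = "SRSF1")
  p2 <- pwm(matrix(c(0.7, 0.1, 0.1, 0.1,
                     0.1, 0.7, 0.1, 0.1,
                     0.25, 0.25, 0.25, 0.25), 3, 4, byrow = TRUE),
            motif_id = "mot2", rbp = "PTBP1")
  f <- tempfile(fileext = ".meme")
  write_meme(list(p1, p2), f)
  back <- read_meme(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$motif_id, "mot1")
  expect_equal(back[[1]]$rbp, "SRSF1")
  expect_equal(back[[2]]$mat, p2$mat, ignore_attr = TRUE, tolerance = 1e-5)
  expect_equal(back[[1]]$bg, p1$bg)
})

test_that("consensus match p-values follow the exact null", {
  # length-8 consensus: p = 4^-8 < 1e-4, retained
  p8 <- consensus_pwm("ACGTTGCA")
  seq8 <- paste0("TTTTT", "ACGTTGCA", "GGGGG")
  h <- scan_pwm(seq8, p8)
  fwd <- h[h$strand == "+", ]
  expect_equal(fwd$start, 6L)
  expect_equal(fwd$p, 0.25^8)
  # length-4 consensus: best possible p = 4^-4 > 1e-4, nothing survives
  p4 <- consensus_pwm("ACGT")
  expect_equal(nrow(scan_pwm(strrep("ACGT", 10), p4)), 0L)
  # sequences shorter than the motif give empty results, not errors
  expect_equal(nrow(scan_pwm("ACG", p8)), 0L)
  expect_equal(nrow(scan_pwm("", p8)), 0L)
})

test_that("reverse-strand hits are reported in forward coordinates", {
  p <- consensus_pwm("AAACCC")
  sq <- paste0("TTTT", "GGGTTT", "TTTT")   # revcomp of AAACCC at 5..10
  h <- scan_pwm(sq, p, p_threshold = 1)
  rc <- h[h$strand == "-" & h$p == min(h$p), ]
  expect_equal(rc$start, 5L)
  h_rna <- scan_pwm(sq, p, p_threshold = 1, rna = TRUE)
  expect_true(all(h_rna$strand == "+"))
})

test_that("positions overlapping N are excluded", {
  p <- consensus_pwm("ACGTACGT")
  expect_equal(nrow(scan_pwm("TTACGTNCGTTT", p, p_threshold = 1.1)), 0L)
  h <- scan_pwm("NNACGTACGTNN", p)
  expect_equal(h$start[h$strand == "+"], 3L)
})

test_that("DP p-values equal exhaustive enumeration for short motifs", {
  set.seed(31)
  for (w in c(3L, 5L, 8L)) {
    m <- matrix(stats::runif(w * 4), w, 4)
    m <- m / rowSums(m)
    p <- pwm(m, motif_id = paste0("w", w))
    tab <- pirfish:::pwm_score_table(p)
    # integer scores of 50 random words, plus the extremes
    scores <- unique(c(
      replicate(50, sum(tab$si[cbind(seq_len(w), sample(4, w, TRUE))])),
      sum(apply(tab$si, 1, min)), sum(apply(tab$si, 1, max))))
    for (s in scores) {
      expect_identical(pirfish:::pwm_pvalue(tab, s), enum_pvalue(p, s))
    }
  }
})

test_that("per-RBP per-window collation keeps the maximum score", {
  w <- build_intron_windows(1000, 2000, intron_id = "i1")
  hits <- data.frame(seq_id = "i1", motif_id = c("a.m1", "a.m2", "b.m1"),
                     rbp = c("RBPa", "RBPa", "RBPb"),
                     start = c(50, 60, 1), strand = "+",
                     score = c(5.2, 7.1, 3.0), p = 1e-5)
  m <- collate_max_score(hits, w, offsets = c(i1 = 1000L),
                         rbps = c("RBPa", "RBPb", "RBPc"))
  expect_equal(m["RBPa", "tile1"], 7.1)    # two motifs of one RBP: max wins
  expect_equal(m["RBPb", "intronic_5flank"], 3.0)
  expect_true(all(is.na(m["RBPc", ])))     # hit-free RBP keeps its row
  # boundary rule: a hit starting exactly at a window edge joins that window
  hb <- data.frame(seq_id = "i1", motif_id = "c", rbp = "RBPa",
                   start = 41 + 184, strand = "+", score = 9, p = 1e-6)
  mb <- collate_max_score(hb, w, offsets = c(i1 = 1000L))
  expect_equal(mb["RBPa", "tile2"], 9)
  expect_true(is.na(mb["RBPa", "tile1"]))
})

test_that("planted consensus sites are recovered at the exact positions", {
  mdl <- gen_gene_model(3, intron_len_range = c(500L, 800L), seed = 33)
  fx <- gen_peak_and_motif_fixtures(mdl, n_rbps = 2, seed = 34)
  hits <- scan_pwm_set(fx$sequences, fx$pwms)
  tm <- fx$truth$motifs
  for (k in seq_len(nrow(tm))) {
    expect_true(any(hits$rbp == tm$rbp[k] & hits$seq_id == tm$intron_id[k] &
                      hits$start == tm$start_local[k] & hits$strand == "+"))
  }
  expect_true(all(hits$p < 1e-4))
})
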