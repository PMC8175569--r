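test_that("a 1-kb intron with 40-bp flanks tiles into five 184-bp windows", {
  w <- build_intron_windows(1000, 2000, strand = "+", flank = 40, n_tiles = 5)
  expect_equal(nrow(w), 9L)
  expect_equal(w$role, c("exonic_5flank", "intronic_5flank",
                         paste0("tile", 1:5), "intronic_3flank",
                         "exonic_3flank"))
  tiles <- w[grepl("^tile", w$role), ]
  expect_equal(tiles$width, rep(184L, 5))          # 920 / 5
  expect_equal(tiles$start[1], 1040); expect_equal(tiles$end[5], 1960)
  expect_equal(w$start[w$role == "exonic_5flank"], 960)
  expect_equal(w$end[w$role == "exonic_3flank"], 2040)
})

test_that("remainders spread over the transcript-first tiles", {
  w <- build_intron_windows(0, 103, flank = 40, n_tiles = 5)   # interior 23
  expect_equal(w$width[grepl("^tile", w$role)], c(5L, 5L, 5L, 4L, 4L))
  # minus strand: transcript tile1 is the genomic-rightmost window
  wm <- build_intron_windows(0, 103, strand = "-", flank = 40, n_tiles = 5)
  expect_equal(wm$width[grepl("^tile", wm$role)], c(5L, 5L, 5L, 4L, 4L))
  t1 <- wm[wm$role == "tile1", ]
  expect_equal(t1$end, 63)   # abuts the intronic flank at the 5' splice site
  expect_equal(wm$role[1], "exonic_5flank")
  expect_equal(wm$start[1], 103)   # genomic-rightmost window comes first
})

test_that("windows partition the flanked intron exactly", {
  for (len in c(300L, 997L, 1001L)) for (st in c("+", "-")) {
    w <- build_intron_windows(5000, 5000 + len, strand = st)
    g <- w[order(w$start), ]
    expect_equal(g$start[-1], g$end[-nrow(g)])     # contiguous, no overlap
    expect_equal(g$start[1], 5000 - 40)
    expect_equal(g$end[nrow(g)], 5000 + len + 40)
    # exonic flanks extend the intron by one flank on each side
    expect_equal(sum(g$width), len + 80L)
  }
  expect_error(build_intron_windows(0, 84, flank = 40, n_tiles = 5),
               "too short")
})

test_that("peak merging unions intervals idempotently", {
  p <- list(R1 = data.frame(chrom = "chr1", start = c(10, 15), end = c(20, 30)))
  m <- merge_peaks(p)$R1
  expect_equal(m$start, 10); expect_equal(m$end, 30)

  d <- list(R1 = data.frame(chrom = "chr1", start = c(0, 10), end = c(5, 15)))
  expect_equal(nrow(merge_peaks(d)$R1), 2L)

  # replicate peak sets and shuffling do not change the merge
  pk <- data.frame(chrom = "chr1", start = c(100, 50, 120), end = c(130, 70, 160))
  once <- merge_peaks(list(R = pk))$R
  twice <- merge_peaks(list(R = rbind(pk, pk)))$R
  shuf <- merge_peaks(list(R = pk[c(3, 1, 2), ]))$R
  expect_equal(once, twice)
  expect_equal(once, shuf)
})

test_that("BED files round-trip through merging", {
  pk <- data.frame(chrom = "chr1", start = c(10, 15), end = c(20, 30))
  f <- tempfile(fileext = ".bed")
  write.table(cbind(pk, name = "p", score = 0, strand = "."), f, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  m <- merge_peaks(list(R = f))$R
  expect_equal(m, data.frame(chrom = "chr1", start = 10, end = 30),
               ignore_attr = TRUE)
})

test_that("coverage fractions are covered bp over window length", {
  w <- data.frame(intron_id = "i", chrom = "chr1", role = "tile1",
                  start = 0, end = 100)
  pk <- data.frame(chrom = "chr1", start = 10, end = 30)
  expect_equal(window_coverage(w, pk)$coverage, 0.2)
  expect_equal(window_coverage(w, pk[0, ])$coverage, 0.0)
  expect_equal(window_coverage(w, data.frame(chrom = "chr1", start = 0,
                                             end = 100))$coverage, 1.0)
  # peaks on another chromosome do not count
  expect_equal(window_coverage(w, data.frame(chrom = "chr2", start = 0,
                                             end = 100))$coverage, 0.0)
})

test_that("adding a peak never lowers coverage; strand flips only roles", {
  w <- build_intron_windows(1000, 2000)
  set.seed(5)
  pk <- data.frame(chrom = "chr1", start = s <- sort(sample(900:2100, 6)),
                   end = s + 25)
  base <- window_coverage(w, merge_peaks(list(R = pk))$R)$coverage
  more <- window_coverage(w, merge_peaks(list(R = rbind(pk,
    data.frame(chrom = "chr1", start = 1500, end = 1600))))$R)$coverage
  expect_true(all(more >= base))

  wm <- build_intron_windows(1000, 2000, strand = "-")
  cm <- window_coverage(wm, merge_peaks(list(R = pk))$R)
  cp <- window_coverage(w, merge_peaks(list(R = pk))$R)
  # same genomic interval keeps its coverage under either strand labelling
  expect_equal(cm$coverage[match(cp$start, cm$start)], cp$coverage)
  # in genomic order the role sequence reverses with the strand
  gp <- cp[order(cp$start), ]; gm <- cm[order(cm$start), ]
  expect_equal(gm$role, rev(gp$role))
})

test_that("profile clustering recovers planted blocks and brute-force distances", {
  m <- rbind(a = c(1, 0), b = c(1, 0.1), c = c(0, 1), d = c(0.1, 1))
  hc <- cluster_introns(m)
  # two planted blocks separate into the first split
  grp <- cutree(hc, 2)
  expect_equal(grp[["a"]], grp[["b"]])
  expect_equal(grp[["c"]], grp[["d"]])
  expect_false(grp[["a"]] == grp[["c"]])
  # identical profiles merge at height 0
  expect_equal(min(cluster_introns(rbind(x = c(1, 2), y = c(1, 2)))$height), 0)
  # distances equal brute-force pairwise Euclidean
  set.seed(2); mm <- matrix(runif(10 * 4), 10)
  D <- as.matrix(dist(mm))
  brute <- outer(seq_len(10), seq_len(10),
                 Vectorize(function(i, j) sqrt(sum((mm[i, ] - mm[j, ])^2))))
  expect_equal(D, brute, ignore_attr = TRUE)
  expect_error(cluster_introns(mm[1, , drop = FALSE]), "at least 2")
})

test_that("planted splice-site peaks yield flank-dominant coverage", {
  mdl <- gen_gene_model(4, intron_len_range = c(600L, 1000L), seed = 21)
  fx <- gen_peak_and_motif_fixtures(mdl, n_rbps = 3, seed = 22)
  cm <- coverage_matrix(fx$windows, merge_peaks(fx$peaks))
  flank_cols <- grepl("intronic_", colnames(cm))
  tile_cols <- grepl("tile", colnames(cm))
  expect_gt(mean(cm[, flank_cols]), mean(cm[, tile_cols]))
  # planted base pairs from the truth table reproduce the flank coverage sums
  tp <- fx$truth$peaks
  expect_equal(sum(tp$planted),
               sum(tp$role %in% c("intronic_5flank", "intronic_3flank")))
  # an RBP with an empty peak set gives an all-zero row
  cm0 <- coverage_matrix(fx$windows,
                         merge_peaks(list(E = data.frame(chrom = character(0),
                                                         start = integer(0),
                                                         end = integer(0)))))
  expect_true(all(cm0 == 0))
})
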