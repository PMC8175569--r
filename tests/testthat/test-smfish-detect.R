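test_that("project_max reduces stacks per pixel", {
  st <- array(5, dim = c(4, 4, 3))
  expect_equal(project_max(st), matrix(5, 4, 4))
  st[2, 3, 2] <- 99
  pm <- project_max(st)
  expect_equal(pm[2, 3], 99)
  expect_equal(sum(pm == 99), 1L)
  expect_equal(project_max(pm), pm)   # 2D passthrough
})

test_that("blank noise yields no detections and bad input errors", {
  set.seed(1)
  img <- matrix(rnorm(200 * 200, 100, 10), 200, 200)
  expect_equal(nrow(detect_spots(img)), 0L)
  img[5, 5] <- NA
  expect_error(detect_spots(img), "finite")
})

test_that("one planted spot is found within a pixel of its position", {
  tr <- smfish_truth(shape = c(8L, 128L, 128L), n_cells = 1L, n_signals = 1L,
                     class_probs = c(0, 1, 0), seed = 2)
  fld <- render_smfish_stack(tr, snr = 10, seed = 3)
  det <- detect_spots(fld$exon)
  expect_equal(nrow(det), 1L)
  expect_lt(sqrt((det$y - tr$signals$exon_y)^2 + (det$x - tr$signals$exon_x)^2),
            1)
})

test_that("detection at snr 5 reaches 95% recall and precision", {
  rec <- prec <- c()
  for (s in 1:2) {
    tr <- smfish_truth(n_signals = 50, seed = 20 + s)
    fld <- render_smfish_stack(tr, snr = 5, seed = 30 + s)
    for (ch in c("exon", "intron")) {
      det <- detect_spots(fld[[ch]])
      acc <- spot_accuracy(det, tr$signals[[paste0(ch, "_y")]],
                           tr$signals[[paste0(ch, "_x")]])
      rec <- c(rec, acc$recall); prec <- c(prec, acc$precision)
    }
  }
  expect_gte(min(rec), 0.95)
  expect_gte(min(prec), 0.95)
})

test_that("nuclei segment into the planted disks", {
  tr <- smfish_truth(shape = c(6L, 360L, 360L), n_cells = 3L, n_signals = 3L,
                     seed = 4)
  fld <- render_smfish_stack(tr, snr = 20, seed = 5)
  lab <- segment_nuclei(fld$dna)
  expect_equal(length(setdiff(unique(as.vector(lab)), 0L)), 3L)
  # areas within 10% of the truth disks
  for (l in 1:3) {
    a_true <- sum(tr$nucleus_mask == l)
    overlaps <- vapply(setdiff(unique(as.vector(lab)), 0L), function(k)
      sum(lab == k & tr$nucleus_mask == l), integer(1))
    a_seg <- sum(lab == setdiff(unique(as.vector(lab)), 0L)[which.max(overlaps)])
    expect_lt(abs(a_seg - a_true) / a_true, 0.1)
  }
  # empty image: no labels; provided label masks pass through untouched
  expect_equal(sum(segment_nuclei(matrix(0, 50, 50) + 0.0)), 0)
  expect_identical(segment_nuclei(tr$nucleus_mask), tr$nucleus_mask)
})

test_that("mutual-NN matching handles the radius and tie contracts", {
  ex <- data.frame(y = 10, x = 10)
  # within radius: one pair
  m1 <- match_spots(ex, data.frame(y = 11, x = 10), radius = 3)
  expect_equal(nrow(m1$pairs), 1L)
  # 10 px away: no pair, a solo intron
  m2 <- match_spots(ex, data.frame(y = 20, x = 10), radius = 3)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched_intron, 1L)
  # two exon spots equidistant from one intron: exactly one pair, smaller index
  m3 <- match_spots(data.frame(y = c(9, 11), x = c(10, 10)),
                    data.frame(y = 10, x = 10), radius = 3)
  expect_equal(nrow(m3$pairs), 1L)
  expect_equal(m3$pairs$exon, 1L)
  expect_error(match_spots(ex, ex, radius = -1), "radius")
})

test_that("matching conserves spots and grows monotonically with radius", {
  for (s in 1:6) {
    set.seed(s)
    ex <- data.frame(y = runif(15, 0, 50), x = runif(15, 0, 50))
    it <- data.frame(y = runif(12, 0, 50), x = runif(12, 0, 50))
    prev <- -1L
    for (r in c(0.5, 2, 5, 10, 30)) {
      mm <- match_spots(ex, it, radius = r)
      expect_equal(nrow(mm$pairs) + length(mm$unmatched_exon), nrow(ex))
      expect_equal(nrow(mm$pairs) + length(mm$unmatched_intron), nrow(it))
      expect_gte(nrow(mm$pairs), prev)
      prev <- nrow(mm$pairs)
    }
  }
})

test_that("mutual-NN pair counts equal maximum-cardinality matching", {
  # well-separated spot fields, as produced by the generator's density cap
  for (s in 1:8) {
    tr <- smfish_truth(shape = c(6L, 256L, 256L), n_cells = 2L,
                       n_signals = 18L, seed = 40 + s)
    sg <- tr$signals
    ex <- data.frame(y = sg$exon_y, x = sg$exon_x)
    it <- data.frame(y = sg$intron_y, x = sg$intron_x)
    ex <- ex[!is.na(ex$y), , drop = FALSE]; it <- it[!is.na(it$y), , drop = FALSE]
    mm <- match_spots(ex, it, radius = 3)
    expect_equal(nrow(mm$pairs), max_matching_size(ex, it, 3))
  }
})
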