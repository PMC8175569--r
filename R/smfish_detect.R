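#' Maximum-intensity projection over z
#'
#' @param stack Numeric array `[y, x, z]` (a 2D matrix is returned as is).
#' @return Matrix `[y, x]` of per-pixel maxima over z.
#' @export
project_max <- function(stack) {
  if (is.matrix(stack)) return(stack)
  stopifnot(length(dim(stack)) == 3L)
  apply(stack, c(1L, 2L), max)
}

#' Detect diffraction-limited spots
#'
#' Band-pass filters the image with a scale-normalized Laplacian-of-Gaussian
#' kernel matched to the spot scale, extracts strict local maxima of the
#' response above a threshold, and refines positions by local centroid of the
#' response.  The default threshold is `k_sd` robust standard deviations of
#' the filtered image (median absolute deviation about zero), which bounds
#' the per-field false-positive rate on pure noise while detecting spots
#' down to low signal-to-noise ratios.  Deterministic for fixed input.
#'
#' 3D stacks are first smoothed along z with a Gaussian matched to the
#' axial PSF extent (`z_sigma`), then detected on their maximum projection,
#' with the z coordinate recovered as the argmax along z at each detection.
#' The z-smoothing matters: max-projecting raw noise over many planes
#' produces a heavy-tailed background that mimics dim spots, whereas true
#' spots extend over several planes and survive the filter.
#'
#' @param image Matrix `[y, x]` or array `[y, x, z]`; all pixels finite.
#' @param scale Spot scale (Gaussian sigma, pixels).
#' @param threshold Absolute response threshold, or `NULL` to use the
#'   `k_sd`-based policy.
#' @param k_sd Threshold in robust SDs of the filtered response (default 6).
#' @param min_sep Minimum separation between detections (pixels); of two
#'   maxima closer than this, only the stronger is kept.  Default
#'   `2 * scale`.
#' @param z_sigma Axial Gaussian smoothing sigma (planes) applied to 3D
#'   input before projection (default 1.0; 0 disables).
#' @return Data.frame `y`, `x`, `z` (NA for 2D input), `intensity` (image
#'   value at the peak), `response` (filter response), sorted by decreasing
#'   response.
#' @export
detect_spots <- function(image, scale = 1.3, threshold = NULL, k_sd = 6,
                         min_sep = 2 * scale, z_sigma = 1.0) {
  if (!all(is.finite(image))) stopf("image contains non-finite pixels")
  stack <- NULL
  if (!is.matrix(image)) {
    stack <- image
    image <- project_max(smooth_z(image, z_sigma))
  }
  resp <- log_filter(image, scale)
  thr <- threshold %||% (k_sd * stats::mad(resp, center = 0))
  pk <- local_maxima(resp, thr)
  if (nrow(pk) > 1L && min_sep > 0) {
    ord <- order(-resp[pk])
    pk <- pk[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(pk))
    for (i in seq_len(nrow(pk))[-1L]) {
      prev <- which(keep[seq_len(i - 1L)])
      if (any((pk[prev, 1L] - pk[i, 1L])^2 + (pk[prev, 2L] - pk[i, 2L])^2 <
                min_sep^2)) keep[i] <- FALSE
    }
    pk <- pk[keep, , drop = FALSE]
  }
  if (nrow(pk) == 0L)
    return(data.frame(y = numeric(0), x = numeric(0), z = numeric(0),
                      intensity = numeric(0), response = numeric(0)))
  # sub-pixel refinement: centroid of the positive response in a 3x3 window
  ny <- nrow(image); nx <- ncol(image)
  ref <- t(apply(pk, 1L, function(p) {
    yr <- max(1L, p[1] - 1L):min(ny, p[1] + 1L)
    xr <- max(1L, p[2] - 1L):min(nx, p[2] + 1L)
    w <- pmax(resp[yr, xr, drop = FALSE], 0)
    sw <- sum(w)
    if (sw == 0) return(c(p[1], p[2]))
    c(sum(outer(yr, rep(1, length(xr))) * w) / sw,
      sum(outer(rep(1, length(yr)), xr) * w) / sw)
  }))
  z <- rep(NA_real_, nrow(pk))
  if (!is.null(stack)) {
    z <- vapply(seq_len(nrow(pk)), function(i)
      which.max(stack[pk[i, 1], pk[i, 2], ])[1L], integer(1L))
  }
  out <- data.frame(y = ref[, 1], x = ref[, 2], z = as.numeric(z),
                    intensity = image[pk],
                    response = resp[pk])
  out[order(-out$response), , drop = FALSE]
}

# Gaussian smoothing along z (replicated boundary), as a weighted sum of
# shifted planes.
smooth_z <- function(stack, sigma) {
  if (sigma <= 0) return(stack)
  nz <- dim(stack)[3]
  hw <- min(nz - 1L, ceiling(3 * sigma))
  w <- exp(-((-hw):hw)^2 / (2 * sigma^2)); w <- w / sum(w)
  out <- array(0, dim = dim(stack))
  for (k in seq_len(nz)) {
    for (j in (-hw):hw) {
      out[, , k] <- out[, , k] + w[j + hw + 1L] *
        stack[, , min(max(k + j, 1L), nz)]
    }
  }
  out
}

# Negated, scale-normalized LoG filter: bright blobs of sigma ~ scale give
# positive peaks.  Convolution via EBImage (FFT) with replicated borders.
log_filter <- function(image, sigma) {
  hw <- ceiling(4 * sigma)
  g <- seq(-hw, hw)
  G <- exp(-g^2 / (2 * sigma^2))
  r2 <- outer(g^2, g^2, "+")
  K <- outer(G, G) * (r2 - 2 * sigma^2) / sigma^2   # sigma^2-normalized LoG
  K <- -(K - mean(K))                               # zero-mean, spot-positive
  EBImage::filter2(image, K, boundary = "replicate")
}

# Strict local maxima (8-neighbourhood) above thr; returns [y, x] indices.
local_maxima <- function(resp, thr) {
  ny <- nrow(resp); nx <- ncol(resp)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- resp
  ok <- resp > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- pad[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx]
    ok <- ok & (resp > nb | (resp == nb & (dy > 0L | (dy == 0L & dx > 0L))))
  }
  which(ok, arr.ind = TRUE)
}

#' Segment nuclei from a DNA-stain image
#'
#' Otsu global threshold on the (projected) DNA channel, hole filling,
#' connected-component labelling and a minimum-area filter.  If `image` is
#' already an integer label matrix (a provided mask), it is returned
#' unchanged -- the pass-through used when segmentation was done elsewhere,
#' e.g. manually.
#'
#' @param image DNA channel, matrix or `[y, x, z]` array; or an integer
#'   label matrix.
#' @param min_area Minimum object area in pixels.
#' @return Integer label matrix `[y, x]` (0 = background).
#' @export
segment_nuclei <- function(image, min_area = 50L) {
  if (is.matrix(image) && is.integer(image)) return(image)
  img <- project_max(image)
  rng <- range(img)
  if (rng[2] <= rng[1]) return(matrix(0L, nrow(img), ncol(img)))
  norm <- (img - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm))
  bin <- EBImage::fillHull(norm > thr)
  lab <- EBImage::bwlabel(bin)
  m <- EBImage::imageData(lab)
  areas <- tabulate(m[m > 0])
  drop <- which(areas < min_area)
  if (length(drop)) m[m %in% drop] <- 0L
  # relabel compactly
  u <- sort(unique(m[m > 0]))
  out <- matrix(match(m, u, nomatch = 0L), nrow(m), ncol(m))
  storage.mode(out) <- "integer"
  out
}

#' Match exon and intron spots by mutual nearest neighbours
#'
#' Iterated mutual-nearest-neighbour matching within a radius: in each round
#' every unmatched exon spot and its nearest unmatched intron spot (and vice
#' versa) are paired when the choice is mutual and within `radius`; rounds
#' repeat until no pair is added.  Ties in distance are broken by smaller
#' spot index.  Matched pairs are intron-retained (unspliced) transcripts,
#' leftover exon spots spliced transcripts, leftover intron spots solo
#' introns.
#'
#' @param exon,intron Spot data.frames with columns `y`, `x` (from
#'   [detect_spots()]).
#' @param radius Co-localization radius in pixels (>= 0).
#' @return List with `pairs` (data.frame `exon`, `intron`, `dist`: row
#'   indices into the inputs), `unmatched_exon`, `unmatched_intron` (integer
#'   index vectors).
#' @export
match_spots <- function(exon, intron, radius = 3) {
  if (radius < 0) stopf("radius must be non-negative")
  ne <- nrow(exon); ni <- nrow(intron)
  if (ne == 0L || ni == 0L)
    return(list(pairs = data.frame(exon = integer(0), intron = integer(0),
                                   dist = numeric(0)),
                unmatched_exon = seq_len(ne), unmatched_intron = seq_len(ni)))
  D <- sqrt(outer(exon$y, intron$y, "-")^2 + outer(exon$x, intron$x, "-")^2)
  free_e <- rep(TRUE, ne); free_i <- rep(TRUE, ni)
  pe <- pi_ <- integer(0); pd <- numeric(0)
  repeat {
    added <- FALSE
    Dm <- D
    Dm[!free_e, ] <- Inf; Dm[, !free_i] <- Inf
    if (all(!is.finite(Dm))) break
    nn_e <- apply(Dm, 1L, function(r) if (all(!is.finite(r))) NA_integer_
                  else which.min(r))          # ties: smaller index (which.min)
    nn_i <- apply(Dm, 2L, function(cc) if (all(!is.finite(cc))) NA_integer_
                  else which.min(cc))
    for (i in which(free_e)) {
      j <- nn_e[i]
      if (!is.na(j) && free_i[j] && !is.na(nn_i[j]) && nn_i[j] == i &&
          D[i, j] <= radius) {
        pe <- c(pe, i); pi_ <- c(pi_, j); pd <- c(pd, D[i, j])
        free_e[i] <- FALSE; free_i[j] <- FALSE; added <- TRUE
      }
    }
    if (!added) break
  }
  list(pairs = data.frame(exon = pe, intron = pi_, dist = pd),
       unmatched_exon = which(free_e), unmatched_intron = which(free_i))
}
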