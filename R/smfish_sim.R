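#' Generate ground-truth signals, cells and masks for an smFISH field
#'
#' Lays out non-overlapping circular cells (each with a concentric nucleus,
#' except mitotic cells, which have no nuclear envelope) on a field and
#' plants fluorescent signals of three classes mirroring dual-probe smFISH:
#' `unspliced_pair` (co-localizing exon and intron spots, an intron-retained
#' transcript), `spliced_exon_only` (exon spot alone) and `solo_intron`
#' (intron spot alone, e.g. a stable excised intron).  Each signal is
#' assigned a compartment consistent with the masks; unspliced transcripts
#' are preferentially nuclear, as intron-retaining RNAs are in vivo.
#'
#' Signal anchors are placed with a minimum pairwise separation (the density
#' cap) and away from compartment boundaries, so that detection and
#' compartment assignment are well-posed on the rendered field.
#'
#' @param shape Stack shape `c(z, y, x)` in voxels.
#' @param n_cells Number of cells in the field.
#' @param n_signals Total signals to plant across cells.
#' @param class_probs Probabilities of `unspliced_pair`, `spliced_exon_only`,
#'   `solo_intron` (in that order; normalized internally).
#' @param p_nuclear Named numeric: probability that a signal of each class in
#'   an interphase cell is nuclear.
#' @param mitotic_frac Fraction of cells flagged mitotic (no nucleus; signal
#'   compartment is recorded as `"none"`).
#' @param pairing_radius Maximum lateral offset (pixels) between the exon and
#'   intron spot of an `unspliced_pair`.
#' @param min_sep Minimum separation between distinct signal anchors (pixels).
#' @param seed Integer seed.
#' @return An object of class `smfish_truth`: list with `signals` (data.frame
#'   `signal_id`, `class`, `cell`, `compartment`, `exon_z/y/x`,
#'   `intron_z/y/x`), `nucleus_mask` and `cell_mask` (integer label matrices,
#'   `[y, x]`, nucleus label equals its cell label), `mitotic` (named logical
#'   per cell), `shape`.
#' @export
smfish_truth <- function(shape = c(12L, 512L, 512L), n_cells = 4L,
                         n_signals = 50L,
                         class_probs = c(unspliced_pair = 0.45,
                                         spliced_exon_only = 0.45,
                                         solo_intron = 0.10),
                         p_nuclear = c(unspliced_pair = 0.9,
                                       spliced_exon_only = 0.3,
                                       solo_intron = 0.9),
                         mitotic_frac = 0, pairing_radius = 1.5,
                         min_sep = 9, seed = NULL) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  classes <- c("unspliced_pair", "spliced_exon_only", "solo_intron")
  class_probs <- class_probs / sum(class_probs)
  with_seed(seed, {
    grid <- ceiling(sqrt(n_cells))
    cw <- min(ny, nx) / grid
    cell_r <- cw / 2 - 4
    nuc_r <- 0.55 * cell_r
    if (cell_r < 4 * min_sep)
      stopf("field too small for %d cells at min_sep %.1f", n_cells, min_sep)
    cy <- cx <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      gy <- (i - 1L) %/% grid; gx <- (i - 1L) %% grid
      cy[i] <- gy * cw + cw / 2; cx[i] <- gx * cw + cw / 2
    }
    n_mit <- round(mitotic_frac * n_cells)
    mitotic <- stats::setNames(rep(FALSE, n_cells), seq_len(n_cells))
    if (n_mit > 0) mitotic[sample.int(n_cells, n_mit)] <- TRUE

    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    cell_mask <- matrix(0L, ny, nx); nucleus_mask <- matrix(0L, ny, nx)
    for (i in seq_len(n_cells)) {
      d2 <- (yy - cy[i])^2 + (xx - cx[i])^2
      cell_mask[d2 <= cell_r^2] <- i
      if (!mitotic[i]) nucleus_mask[d2 <= nuc_r^2] <- i
    }

    cls <- sample(classes, n_signals, replace = TRUE, prob = class_probs)
    cell <- sample.int(n_cells, n_signals, replace = TRUE)
    comp <- character(n_signals)
    ay <- ax <- az <- numeric(n_signals)
    margin <- 3
    for (s in seq_len(n_signals)) {
      i <- cell[s]
      if (mitotic[i]) {
        comp[s] <- "none"
        rmin <- 0; rmax <- cell_r - margin
      } else if (stats::runif(1) < p_nuclear[[cls[s]]]) {
        comp[s] <- "nuclear"; rmin <- 0; rmax <- nuc_r - margin
      } else {
        comp[s] <- "cytoplasmic"; rmin <- nuc_r + margin; rmax <- cell_r - margin
      }
      ok <- FALSE
      for (try in 1:400) {
        r <- sqrt(stats::runif(1, rmin^2, rmax^2)); th <- stats::runif(1, 0, 2 * pi)
        py <- cy[i] + r * sin(th); px <- cx[i] + r * cos(th)
        if (s == 1L || all((py - ay[seq_len(s - 1L)])^2 +
                             (px - ax[seq_len(s - 1L)])^2 >= min_sep^2)) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stopf("could not place signal %d: density cap exceeded (min_sep %.1f)",
              s, min_sep)
      ay[s] <- py; ax[s] <- px; az[s] <- stats::runif(1, 3, nz - 2)
    }
    # spot coordinates per channel
    ez <- iy <- ix <- iz <- rep(NA_real_, n_signals)
    ey <- ex <- rep(NA_real_, n_signals)
    for (s in seq_len(n_signals)) {
      if (cls[s] != "solo_intron") { ey[s] <- ay[s]; ex[s] <- ax[s]; ez[s] <- az[s] }
      if (cls[s] != "spliced_exon_only") {
        if (cls[s] == "unspliced_pair") {
          r <- stats::runif(1, 0.3, pairing_radius); th <- stats::runif(1, 0, 2 * pi)
          iy[s] <- ay[s] + r * sin(th); ix[s] <- ax[s] + r * cos(th)
        } else { iy[s] <- ay[s]; ix[s] <- ax[s] }
        iz[s] <- az[s]
      }
    }
    truth <- structure(
      list(signals = data.frame(signal_id = seq_len(n_signals), class = cls,
                                cell = cell, compartment = comp,
                                exon_z = ez, exon_y = ey, exon_x = ex,
                                intron_z = iz, intron_y = iy, intron_x = ix),
           nucleus_mask = nucleus_mask, cell_mask = cell_mask,
           mitotic = mitotic, shape = shape),
      class = "smfish_truth")
    validate_smfish_truth(truth, pairing_radius)
    truth
  })
}

# Invariants asserted on emission: class/coordinate presence, pairing radius,
# compartment agreement with the masks.
validate_smfish_truth <- function(truth, pairing_radius = 1.5) {
  s <- truth$signals
  stopifnot(all(s$class %in% c("unspliced_pair", "spliced_exon_only",
                               "solo_intron")))
  up <- s$class == "unspliced_pair"
  if (any(up)) {
    d <- sqrt((s$exon_y[up] - s$intron_y[up])^2 +
                (s$exon_x[up] - s$intron_x[up])^2)
    stopifnot(all(is.finite(d)), all(d <= pairing_radius + 1e-9))
  }
  stopifnot(all(is.na(s$intron_y[s$class == "spliced_exon_only"])),
            all(is.na(s$exon_y[s$class == "solo_intron"])))
  ry <- round(ifelse(is.na(s$exon_y), s$intron_y, s$exon_y))
  rx <- round(ifelse(is.na(s$exon_x), s$intron_x, s$exon_x))
  pos <- cbind(ry, rx)
  nuc <- truth$nucleus_mask[pos]; cel <- truth$cell_mask[pos]
  stopifnot(all(cel == s$cell))
  stopifnot(all(nuc[s$compartment == "nuclear"] == s$cell[s$compartment == "nuclear"]),
            all(nuc[s$compartment == "cytoplasmic"] == 0L))
  invisible(truth)
}

#' @export
print.smfish_truth <- function(x, ...) {
  cat(sprintf("smfish_truth: %d signals in %d cells (%d mitotic), field %s\n",
              nrow(x$signals), length(x$mitotic), sum(x$mitotic),
              paste(x$shape, collapse = "x")))
  print(table(x$signals$class))
  invisible(x)
}

#' Render an smFISH field as dual-channel image stacks
#'
#' Every spot becomes an anisotropic 3D Gaussian of the stated per-axis
#' sigma; a constant background plus noise is added such that the ratio of
#' Gaussian peak amplitude to noise standard deviation equals `snr`.  The DNA
#' channel renders nuclei (or whole mitotic cells, mimicking condensed
#' chromatin) as filled regions.  Deterministic for a fixed seed.
#'
#' @param truth An [smfish_truth()] object, or `NULL` to generate one from
#'   `...`.
#' @param psf_sigma Gaussian sigma per axis `c(z, y, x)` in voxels; the
#'   default `(1.0, 1.3, 1.3)` emulates the axial elongation of a widefield
#'   point-spread function.
#' @param snr Peak amplitude over noise standard deviation; must be > 0.
#' @param amplitude Spot peak amplitude in arbitrary units.
#' @param background Constant background level.
#' @param noise `"gaussian"` (default; additive, sd = amplitude/snr) or
#'   `"poisson"` (photon-limited; amplitude is rescaled so that the Poisson
#'   sd at background matches amplitude/snr).
#' @param seed Integer seed (noise only; the truth carries its own seed).
#' @param ... Passed to [smfish_truth()] when `truth` is `NULL`.
#' @return A list of class `smfish_field`: `exon`, `intron`, `dna` (numeric
#'   arrays `[y, x, z]`), `truth`, and `params`.
#' @export
render_smfish_stack <- function(truth = NULL, psf_sigma = c(1.0, 1.3, 1.3),
                                snr = 10, amplitude = 1000, background = 100,
                                noise = c("gaussian", "poisson"), seed = NULL,
                                ...) {
  noise <- match.arg(noise)
  if (snr <= 0) stopf("snr must be > 0")
  if (is.null(truth)) truth <- smfish_truth(seed = seed, ...)
  nz <- truth$shape[1]; ny <- truth$shape[2]; nx <- truth$shape[3]
  s <- truth$signals
  exon <- render_spots(cbind(s$exon_z, s$exon_y, s$exon_x), nz, ny, nx,
                       psf_sigma, amplitude)
  intron <- render_spots(cbind(s$intron_z, s$intron_y, s$intron_x), nz, ny, nx,
                         psf_sigma, amplitude)
  dna_plane <- (truth$nucleus_mask > 0) * amplitude / 2
  for (i in which(truth$mitotic)) {
    dna_plane[truth$cell_mask == i] <- amplitude / 2
  }
  dna <- array(rep(dna_plane, nz), dim = c(ny, nx, nz))
  with_seed(seed, {
    sd_n <- amplitude / snr
    add_noise <- function(a) {
      if (noise == "gaussian") {
        a + background + array(stats::rnorm(length(a), 0, sd_n), dim = dim(a))
      } else {
        # photon-limited: counts scaled so sd(background) = amplitude/snr
        scale <- background / sd_n^2
        array(stats::rpois(length(a), pmax(a + background, 0) * scale) / scale,
              dim = dim(a))
      }
    }
    structure(list(exon = add_noise(exon), intron = add_noise(intron),
                   dna = add_noise(dna), truth = truth,
                   params = list(psf_sigma = psf_sigma, snr = snr,
                                 amplitude = amplitude,
                                 background = background, noise = noise,
                                 seed = seed)),
              class = "smfish_field")
  })
}

render_spots <- function(zyx, nz, ny, nx, sigma, amplitude) {
  a <- array(0, dim = c(ny, nx, nz))
  zyx <- zyx[stats::complete.cases(zyx), , drop = FALSE]
  hw <- ceiling(4 * sigma)   # window half-widths per axis (z, y, x)
  for (i in seq_len(nrow(zyx))) {
    z0 <- zyx[i, 1]; y0 <- zyx[i, 2]; x0 <- zyx[i, 3]
    zr <- max(1L, floor(z0 - hw[1])):min(nz, ceiling(z0 + hw[1]))
    yr <- max(1L, floor(y0 - hw[2])):min(ny, ceiling(y0 + hw[2]))
    xr <- max(1L, floor(x0 - hw[3])):min(nx, ceiling(x0 + hw[3]))
    gz <- exp(-((zr - z0)^2) / (2 * sigma[1]^2))
    gy <- exp(-((yr - y0)^2) / (2 * sigma[2]^2))
    gx <- exp(-((xr - x0)^2) / (2 * sigma[3]^2))
    a[yr, xr, zr] <- a[yr, xr, zr] +
      amplitude * outer(outer(gy, gx), gz)
  }
  a
}

#' Write an smFISH field to 16-bit multi-page TIFF files
#'
#' One file per channel (`exon.tif`, `intron.tif`, `dna.tif`), one z-plane
#' per page, plus label masks (`nucleus_mask.tif`, `cell_mask.tif`), the
#' truth table (`truth.tsv`, with `mitotic` per cell in `cells.tsv`) and a
#' sidecar `params.json` recording the generating parameters.
#'
#' @param field An `smfish_field` from [render_smfish_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_smfish_tiff <- function(field, dir) {
  stopifnot(inherits(field, "smfish_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maxval <- 65535
  wr <- function(a, name) {
    pages <- lapply(seq_len(dim(a)[3]), function(z)
      pmin(pmax(a[, , z] / maxval, 0), 1))
    tiff::writeTIFF(pages, file.path(dir, name), bits.per.sample = 16L)
  }
  wr(field$exon, "exon.tif"); wr(field$intron, "intron.tif")
  wr(field$dna, "dna.tif")
  tiff::writeTIFF(field$truth$nucleus_mask / maxval,
                  file.path(dir, "nucleus_mask.tif"), bits.per.sample = 16L)
  tiff::writeTIFF(field$truth$cell_mask / maxval,
                  file.path(dir, "cell_mask.tif"), bits.per.sample = 16L)
  utils::write.table(field$truth$signals, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell_id = as.integer(names(field$truth$mitotic)),
               mitotic = unname(field$truth$mitotic)),
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(field$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a multi-page TIFF stack as a numeric array
#'
#' @param path TIFF file (one z-plane per page).
#' @param scale Multiply pixel values by this factor (default restores the
#'   16-bit integer scale written by [write_smfish_tiff()]).
#' @return Numeric array `[y, x, z]`.
#' @export
read_stack_tiff <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages))) * scale
}
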