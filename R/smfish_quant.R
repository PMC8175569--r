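#' Per-cell compartmentalized transcript counts from matched spots
#'
#' Assigns every spot to a cell (label at its rounded position in the cell
#' mask; spots on background are dropped and counted), decides its
#' compartment (nuclear iff the nucleus mask at the position carries the
#' cell's own label; the centre pixel decides, with no partial-overlap
#' logic), and tallies the smFISH transcript classes: matched exon-intron
#' pairs are unspliced transcripts, unmatched exon spots spliced
#' transcripts, unmatched intron spots solo introns.  Solo introns never
#' enter the transcript total.
#'
#' Derived per cell: nuclear PIR
#' (`100 * unspliced_nuclear / exon_nuclear`, the percentage of nuclear
#' transcripts that retain the intron) and nuclear enrichment
#' (`100 * exon_nuclear / exon_total`).  For mitotic cells there is no
#' nuclear envelope, so no compartment split is made and the derived
#' percentages are `NA`.
#'
#' @param exon,intron Spot data.frames (columns `y`, `x`).
#' @param matches Output of [match_spots()] on these spot sets.
#' @param nucleus_mask,cell_mask Integer label matrices `[y, x]`; a nucleus
#'   carries the label of its cell.
#' @param mitotic Optional logical vector named by cell label (default: all
#'   interphase).
#' @return Object of class `cell_quant`: a data.frame with one row per cell
#'   (`cell_id`, `mitotic`, `exon_total`, `exon_nuclear`, `exon_cytoplasmic`,
#'   `unspliced_nuclear`, `unspliced_cytoplasmic`, `spliced_nuclear`,
#'   `spliced_cytoplasmic`, `unspliced_total`, `spliced_total`,
#'   `solo_intron`, `nuclear_pir`, `nuclear_enrichment`), with the number of
#'   dropped (outside-cell) spots in `attr(, "dropped")`.
#' @export
quantify_cells <- function(exon, intron, matches, nucleus_mask, cell_mask,
                           mitotic = NULL) {
  lab_at <- function(df, mask) {
    if (nrow(df) == 0L) return(integer(0))
    ry <- pmin(pmax(round(df$y), 1L), nrow(mask))
    rx <- pmin(pmax(round(df$x), 1L), ncol(mask))
    mask[cbind(ry, rx)]
  }
  e_cell <- lab_at(exon, cell_mask); e_nuc <- lab_at(exon, nucleus_mask)
  i_cell <- lab_at(intron, cell_mask); i_nuc <- lab_at(intron, nucleus_mask)
  cells <- sort(unique(c(e_cell, i_cell, as.integer(names(mitotic %||% character(0))))))
  cells <- cells[cells > 0L]
  dropped <- sum(e_cell == 0L) + sum(i_cell == 0L)
  if (is.null(mitotic)) mitotic <- stats::setNames(rep(FALSE, length(cells)), cells)

  # transcript class per exon spot
  e_class <- rep("spliced", nrow(exon))
  e_class[matches$pairs$exon] <- "unspliced"
  rows <- lapply(cells, function(cl) {
    mit <- isTRUE(mitotic[[as.character(cl)]])
    in_cell <- which(e_cell == cl)
    nuc <- e_nuc[in_cell] == cl
    un <- e_class[in_cell] == "unspliced"
    solo <- sum(i_cell[matches$unmatched_intron] == cl)
    if (mit) {
      data.frame(cell_id = cl, mitotic = TRUE,
                 exon_total = length(in_cell),
                 exon_nuclear = NA_integer_, exon_cytoplasmic = NA_integer_,
                 unspliced_nuclear = NA_integer_,
                 unspliced_cytoplasmic = NA_integer_,
                 spliced_nuclear = NA_integer_, spliced_cytoplasmic = NA_integer_,
                 unspliced_total = sum(un), spliced_total = sum(!un),
                 solo_intron = solo,
                 nuclear_pir = NA_real_, nuclear_enrichment = NA_real_)
    } else {
      en <- sum(nuc)
      data.frame(cell_id = cl, mitotic = FALSE,
                 exon_total = length(in_cell),
                 exon_nuclear = en, exon_cytoplasmic = sum(!nuc),
                 unspliced_nuclear = sum(un & nuc),
                 unspliced_cytoplasmic = sum(un & !nuc),
                 spliced_nuclear = sum(!un & nuc),
                 spliced_cytoplasmic = sum(!un & !nuc),
                 unspliced_total = sum(un), spliced_total = sum(!un),
                 solo_intron = solo,
                 nuclear_pir = if (en > 0) 100 * sum(un & nuc) / en else NA_real_,
                 nuclear_enrichment = if (length(in_cell) > 0)
                   100 * en / length(in_cell) else NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "dropped") <- dropped
  class(out) <- c("cell_quant", class(out))
  out
}

#' @export
print.cell_quant <- function(x, ...) {
  cat(sprintf("cell_quant: %d cells (%d mitotic), %d spots outside cells dropped\n",
              nrow(x), sum(x$mitotic), attr(x, "dropped") %||% 0L))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Quantify one rendered smFISH field end to end
#'
#' Max-projects the exon and intron channels, detects spots in each, matches
#' them within `radius`, and tallies per-cell counts against the field's
#' masks (segmented from the DNA channel when not provided).
#'
#' @param field An `smfish_field` (from [render_smfish_stack()]) or a
#'   directory written by [write_smfish_tiff()].
#' @param radius Co-localization radius (pixels).
#' @param scale Spot scale for detection.
#' @param masks `"provided"` to use the field's truth masks (the default;
#'   stands in for the study's manual segmentation), `"auto"` to segment
#'   nuclei from the DNA channel and partition cells by nearest nucleus.
#' @param ... Passed to [detect_spots()].
#' @return A list: `cells` ([quantify_cells()] table), `exon_spots`,
#'   `intron_spots`, `matches`.
#' @export
quantify_field <- function(field, radius = 3, scale = 1.3,
                           masks = c("provided", "auto"), ...) {
  masks <- match.arg(masks)
  if (is.character(field)) field <- read_smfish_dir(field)
  ex <- detect_spots(field$exon, scale = scale, ...)
  it <- detect_spots(field$intron, scale = scale, ...)
  mm <- match_spots(ex, it, radius = radius)
  if (masks == "provided") {
    nuc <- field$truth$nucleus_mask; cel <- field$truth$cell_mask
    mit <- field$truth$mitotic
  } else {
    nuc <- segment_nuclei(field$dna)
    cel <- voronoi_cells(nuc)
    mit <- NULL
  }
  list(cells = quantify_cells(ex, it, mm, nuc, cel, mitotic = mit),
       exon_spots = ex, intron_spots = it, matches = mm)
}

# Nearest-nucleus partition of the field: a convenience fallback for manual
# cell outlines, labelled as such.  Every pixel joins its nearest nucleus.
voronoi_cells <- function(nucleus_mask) {
  labs <- sort(unique(nucleus_mask[nucleus_mask > 0]))
  if (!length(labs)) return(nucleus_mask)
  cy <- vapply(labs, function(l) mean(which(nucleus_mask == l, arr.ind = TRUE)[, 1]),
               numeric(1))
  cx <- vapply(labs, function(l) mean(which(nucleus_mask == l, arr.ind = TRUE)[, 2]),
               numeric(1))
  yy <- matrix(seq_len(nrow(nucleus_mask)), nrow(nucleus_mask), ncol(nucleus_mask))
  xx <- matrix(seq_len(ncol(nucleus_mask)), nrow(nucleus_mask),
               ncol(nucleus_mask), byrow = TRUE)
  best <- matrix(Inf, nrow(nucleus_mask), ncol(nucleus_mask))
  out <- matrix(0L, nrow(nucleus_mask), ncol(nucleus_mask))
  for (i in seq_along(labs)) {
    d2 <- (yy - cy[i])^2 + (xx - cx[i])^2
    upd <- d2 < best
    out[upd] <- labs[i]; best[upd] <- d2[upd]
  }
  out
}

read_smfish_dir <- function(dir) {
  rd <- function(f) read_stack_tiff(file.path(dir, f))
  msk <- function(f) {
    m <- tiff::readTIFF(file.path(dir, f)) * 65535
    storage.mode(m) <- "integer"
    m
  }
  sig <- utils::read.delim(file.path(dir, "truth.tsv"))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"))
  truth <- structure(list(signals = sig,
                          nucleus_mask = msk("nucleus_mask.tif"),
                          cell_mask = msk("cell_mask.tif"),
                          mitotic = stats::setNames(cells$mitotic, cells$cell_id),
                          shape = NULL),
                     class = "smfish_truth")
  ex <- rd("exon.tif")
  truth$shape <- c(dim(ex)[3], dim(ex)[1], dim(ex)[2])
  structure(list(exon = ex, intron = rd("intron.tif"), dna = rd("dna.tif"),
                 truth = truth,
                 params = jsonlite::read_json(file.path(dir, "params.json"))),
            class = "smfish_field")
}

#' Interphase versus mitosis transcript-class means
#'
#' Groups per-cell counts by cell-cycle stage and reports mean, SD and n of
#' unspliced transcripts, spliced transcripts and solo introns per cell --
#' the comparison that reveals splicing restricted to mitosis (unspliced
#' counts collapse while spliced and solo-intron counts rise).
#'
#' @param cells A [quantify_cells()] table (needs the `mitotic` flag).
#' @return Data.frame: `stage`, `class`, `mean`, `sd`, `n`.  Stages with no
#'   cells are omitted.
#' @export
mitosis_counts <- function(cells) {
  stopifnot(all(c("mitotic", "unspliced_total", "spliced_total",
                  "solo_intron") %in% names(cells)))
  out <- list()
  for (st in c("interphase", "mitosis")) {
    d <- cells[cells$mitotic == (st == "mitosis"), , drop = FALSE]
    if (nrow(d) == 0L) next
    for (cl in c("unspliced", "spliced", "solo_intron")) {
      v <- switch(cl, unspliced = d$unspliced_total,
                  spliced = d$spliced_total, solo_intron = d$solo_intron)
      out[[length(out) + 1L]] <- data.frame(
        stage = st, class = cl, mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else NA_real_, n = length(v))
    }
  }
  do.call(rbind, out)
}
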