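#' Validate and normalize a run configuration
#'
#' Fills defaults, checks types and ranges, and rejects unknown keys.
#' Normalization is idempotent: `validate_config(validate_config(x))` equals
#' `validate_config(x)`.
#'
#' @param config Path to a YAML key-value file, a named list, or `NULL`
#'   (all defaults).
#' @return A named list of class `run_config` with every parameter set.
#' @export
validate_config <- function(config = NULL) {
  defaults <- list(
    seed = 1L,
    # junction simulation / PIR
    n_exons = 6L, depth = 50000, read_len = 100L, min_anchor = 8L,
    rho = c(0.1, 0.3, 0.5, 0.9), n_replicates = 10L,
    min_total = 15L, alpha = 0.05,
    # smFISH
    fields = 2L, n_signals = 50L, n_cells = 4L, snr = 10, radius = 3,
    scale = 1.3, mitotic_frac = 0,
    # RBP windows / motifs
    flank = 40L, tiles = 5L, n_rbps = 3L, p_max = 1e-4)
  cfg <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config) %||% list()
  else if (inherits(config, "run_config") || is.list(config)) unclass(config)
  else stopf("config must be a path, a list, or NULL")
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  chk <- function(key, ok) if (!ok) stopf("invalid value for '%s'", key)
  chk("seed", is.numeric(out$seed) && length(out$seed) == 1L)
  for (k in c("n_exons", "depth", "read_len", "min_anchor", "n_replicates",
              "min_total", "fields", "n_signals", "n_cells", "snr",
              "flank", "tiles", "n_rbps"))
    chk(k, is.numeric(out[[k]]) && all(out[[k]] > 0))
  chk("rho", is.numeric(out$rho) && all(out$rho >= 0 & out$rho <= 1))
  chk("alpha", out$alpha > 0 && out$alpha < 1)
  chk("radius", is.numeric(out$radius) && out$radius >= 0)
  chk("scale", out$scale > 0)
  chk("mitotic_frac", out$mitotic_frac >= 0 && out$mitotic_frac <= 1)
  chk("p_max", out$p_max > 0 && out$p_max < 1)
  for (k in c("seed", "n_exons", "read_len", "min_anchor", "n_replicates",
              "min_total", "fields", "n_signals", "n_cells"))
    out[[k]] <- as.integer(out[[k]])
  structure(out, class = "run_config")
}

#' Detection accuracy of spots against ground truth
#'
#' Matches detections to true positions one-to-one (mutual nearest
#' neighbours within `radius`) and reports recall, precision and the match
#' count.
#'
#' @param detected Data.frame with `y`, `x` (from [detect_spots()]).
#' @param truth_y,truth_x True spot coordinates.
#' @param radius Matching radius in pixels (default 2).
#' @return List: `recall`, `precision`, `n_matched`, `n_true`, `n_detected`.
#' @export
spot_accuracy <- function(detected, truth_y, truth_x, radius = 2) {
  tr <- data.frame(y = truth_y, x = truth_x)
  tr <- tr[stats::complete.cases(tr), , drop = FALSE]
  mm <- match_spots(tr, detected, radius = radius)
  n <- nrow(mm$pairs)
  list(recall = if (nrow(tr)) n / nrow(tr) else NA_real_,
       precision = if (nrow(detected)) n / nrow(detected) else NA_real_,
       n_matched = n, n_true = nrow(tr), n_detected = nrow(detected))
}

#' Run the end-to-end synthetic benchmark
#'
#' Executes the configured stages on synthetic data with known truth --
#' junction-read simulation and PIR recovery over the `rho` grid, smFISH
#' field rendering, detection and per-cell quantification, planted
#' peak/motif recovery -- and writes recovery tables (TSV), a summary and a
#' manifest (JSON) into `out_dir`.  One log line per stage, with row
#' counts, goes to `run.log` and (optionally) stderr.  Outputs are
#' byte-identical across runs with the same config.
#'
#' @param config Anything [validate_config()] accepts.
#' @param out_dir Output directory.
#' @param quiet Suppress the stderr copy of the log.
#' @return Invisibly, a list with the stage results (`pir_recovery`,
#'   `fish_accuracy`, `cells`, `rbp`, `summary`).
#' @export
run_benchmark <- function(config = NULL, out_dir, quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  cat("", file = logfile)
  logln <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  logln("config: seed=%d depth=%g fields=%d", cfg$seed, cfg$depth, cfg$fields)

  # --- stage 1: PIR recovery over the rho grid -------------------------
  model <- gen_gene_model(cfg$n_exons, intron_len_range = c(400L, 1200L),
                          seed = cfg$seed)
  rows <- list()
  for (ri in seq_along(cfg$rho)) for (rep in seq_len(cfg$n_replicates)) {
    sd_ <- cfg$seed + 1000L * ri + rep
    aln <- simulate_junction_reads(model, cfg$rho[ri], cfg$depth,
                                   cfg$read_len, cfg$min_anchor, seed = sd_)
    fit <- pir_fit(aln, model, min_total = cfg$min_total, alpha = cfg$alpha,
                   min_anchor = cfg$min_anchor)
    est <- fit$estimates
    ok <- !is.na(est$pir)
    rows[[length(rows) + 1L]] <- data.frame(
      rho = cfg$rho[ri], replicate = rep, intron_id = est$intron_id,
      pir = est$pir, status = est$status,
      abs_err = abs(est$pir - 100 * cfg$rho[ri]))
  }
  pir_recovery <- do.call(rbind, rows)
  wtsv(pir_recovery, "pir_recovery.tsv")
  logln("stage pir: %d rho values x %d replicates -> %d rows",
        length(cfg$rho), cfg$n_replicates, nrow(pir_recovery))

  # --- stage 2: smFISH detection and per-cell quantification -----------
  facc <- list(); cell_rows <- list()
  for (f in seq_len(cfg$fields)) {
    fld <- render_smfish_stack(
      truth = smfish_truth(n_cells = cfg$n_cells, n_signals = cfg$n_signals,
                           mitotic_frac = cfg$mitotic_frac,
                           seed = cfg$seed + 500L + f),
      snr = cfg$snr, seed = cfg$seed + 900L + f)
    q <- quantify_field(fld, radius = cfg$radius, scale = cfg$scale)
    tr <- fld$truth$signals
    acc_e <- spot_accuracy(q$exon_spots, tr$exon_y, tr$exon_x)
    acc_i <- spot_accuracy(q$intron_spots, tr$intron_y, tr$intron_x)
    truth_cells <- truth_cell_quant(fld$truth)
    err <- merge(q$cells[, c("cell_id", "nuclear_pir")],
                 truth_cells[, c("cell_id", "nuclear_pir")],
                 by = "cell_id", suffixes = c("_est", "_true"))
    facc[[f]] <- data.frame(field = f,
                            exon_recall = acc_e$recall,
                            exon_precision = acc_e$precision,
                            intron_recall = acc_i$recall,
                            intron_precision = acc_i$precision,
                            mean_abs_pir_err = mean(abs(err$nuclear_pir_est -
                                                          err$nuclear_pir_true),
                                                    na.rm = TRUE))
    cell_rows[[f]] <- cbind(field = f, as.data.frame(q$cells))
  }
  fish_accuracy <- do.call(rbind, facc)
  cells <- do.call(rbind, cell_rows)
  wtsv(fish_accuracy, "fish_accuracy.tsv")
  wtsv(cells, "cells.tsv")
  logln("stage fish: %d fields -> %d cells", cfg$fields, nrow(cells))

  # --- stage 3: RBP windows, coverage, motifs --------------------------
  fx <- gen_peak_and_motif_fixtures(model, n_rbps = cfg$n_rbps,
                                    flank = cfg$flank, n_tiles = cfg$tiles,
                                    seed = cfg$seed + 7L)
  merged <- merge_peaks(fx$peaks)
  covm <- coverage_matrix(fx$windows, merged)
  hits <- scan_pwm_set(fx$sequences, fx$pwms, p_threshold = cfg$p_max)
  wtsv(data.frame(rbp = rownames(covm), covm, check.names = FALSE),
       "coverage_matrix.tsv")
  wtsv(hits, "motif_hits.tsv")
  logln("stage rbp: %d RBPs, %d windows, %d motif hits",
        cfg$n_rbps, nrow(fx$windows), nrow(hits))

  # --- stage 4: summary ------------------------------------------------
  ok_pir <- pir_recovery[pir_recovery$status == "ok", , drop = FALSE]
  flank_cov <- mean(covm[, grepl("intronic_", colnames(covm)), drop = FALSE])
  tile_cov <- mean(covm[, grepl("tile", colnames(covm)), drop = FALSE])
  summary <- list(
    pir_mean_abs_err = mean(ok_pir$abs_err),
    pir_frac_within_2pp = mean(ok_pir$abs_err <= 2),
    exon_recall = mean(fish_accuracy$exon_recall),
    exon_precision = mean(fish_accuracy$exon_precision),
    intron_recall = mean(fish_accuracy$intron_recall),
    intron_precision = mean(fish_accuracy$intron_precision),
    mean_abs_nuclear_pir_err = mean(fish_accuracy$mean_abs_pir_err),
    flank_coverage_mean = flank_cov,
    tile_coverage_mean = tile_cov,
    motif_planted_recovered = motif_recovery_rate(hits, fx))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config = unclass(cfg),
         config_hash = digest_config(cfg),
         outputs = c("pir_recovery.tsv", "fish_accuracy.tsv", "cells.tsv",
                     "coverage_matrix.tsv", "motif_hits.tsv", "summary.json")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  logln("stage summary: pir_frac_within_2pp=%.3f exon_recall=%.3f",
        summary$pir_frac_within_2pp, summary$exon_recall)
  invisible(list(pir_recovery = pir_recovery, fish_accuracy = fish_accuracy,
                 cells = cells,
                 rbp = list(coverage = covm, hits = hits, fixtures = fx),
                 summary = summary))
}

# fraction of planted motif instances recovered as forward-strand hits
motif_recovery_rate <- function(hits, fx) {
  tm <- fx$truth$motifs
  if (!nrow(tm)) return(NA_real_)
  found <- mapply(function(r, i, s) {
    any(hits$rbp == r & hits$seq_id == i & hits$start == s &
          hits$strand == "+")
  }, tm$rbp, tm$intron_id, tm$start_local)
  mean(found)
}

digest_config <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                character(1L)),
             sep = "=", collapse = ";")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1000000007
}

#' Per-cell ground-truth counts from an smFISH truth object
#'
#' Tallies the planted signals into the same per-cell table that
#' [quantify_cells()] produces from detections, for accuracy comparisons.
#'
#' @param truth An [smfish_truth()] object.
#' @return A `cell_quant` table computed from the truth.
#' @export
truth_cell_quant <- function(truth) {
  s <- truth$signals
  ex <- data.frame(y = s$exon_y, x = s$exon_x)
  it <- data.frame(y = s$intron_y, x = s$intron_x)
  e_idx <- which(!is.na(ex$y)); i_idx <- which(!is.na(it$y))
  ex <- ex[e_idx, , drop = FALSE]; it <- it[i_idx, , drop = FALSE]
  paired_sig <- which(s$class == "unspliced_pair")
  pairs <- data.frame(exon = match(paired_sig, e_idx),
                      intron = match(paired_sig, i_idx),
                      dist = numeric(length(paired_sig)))
  mm <- list(pairs = pairs,
             unmatched_exon = setdiff(seq_along(e_idx), pairs$exon),
             unmatched_intron = setdiff(seq_along(i_idx), pairs$intron))
  quantify_cells(ex, it, mm, truth$nucleus_mask, truth$cell_mask,
                 mitotic = truth$mitotic)
}
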