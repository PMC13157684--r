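# End-to-end pipeline: QC gates -> PPG analysis -> optional vessel
# segmentation -> per-ROI hypersampling -> spectra -> bandpower table.
# Every effective parameter and seed is written to the run log so a run is
# fully reconstructable from config + log.

#' Assemble a pipeline configuration
#'
#' @param fmri,sidecar,physio,motion input file paths (see the io module
#'   for formats). \code{motion} may be \code{NULL} to skip the motion
#'   gate.
#' @param masks named character vector of ROI mask paths.
#' @param search_masks named character vector of vessel search-region mask
#'   paths; when non-empty, data-driven vessel segmentation is run and the
#'   resulting masks are analysed alongside \code{masks}.
#' @param outdir output directory.
#' @param physio_fs_hz PPG sampling rate, Hz.
#' @param min_ppg_quality,max_motion_mm,max_motion_fraction QC thresholds.
#' @param r_threshold,n_phase_bins vessel-segmentation settings.
#' @param gap_policy hypersampling gap policy.
#' @param halfwidth_hz cardiac band half-width.
#' @param seed integer seed for all randomness (vessel split).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(fmri, sidecar, physio, masks, outdir,
                       motion = NULL, search_masks = character(0),
                       physio_fs_hz = 100,
                       min_ppg_quality = 0.3, max_motion_mm = 1.0,
                       max_motion_fraction = 0.15,
                       r_threshold = 0.5, n_phase_bins = 10,
                       gap_policy = "interpolate", halfwidth_hz = 0.15,
                       seed = 1L) {
  paths <- c(fmri = fmri, sidecar = sidecar, physio = physio,
             motion = motion, masks, search_masks)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline
#'
#' Order of operations: load inputs; motion and PPG gates; slice-timing
#' coverage gate per ROI; optional split-half vessel segmentation inside
#' the supplied search regions; hypersampling, periodogram and bandpower
#' per ROI; outputs written under \code{outdir}: \code{qc.json},
#' \code{run_log.json}, per-ROI hypersampled TSV and spectrum TSV,
#' segmented vessel masks, and \code{bandpower.tsv}.
#'
#' @param config a \code{\link{run_config}}.
#' @param force proceed past failing QC gates (default FALSE: a failing
#'   gate aborts with the gate named).
#' @return list with \code{qc}, \code{cardiac}, \code{bandpower} (data
#'   frame) and \code{files} (paths written), invisibly.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  scan <- load_fmri(config$fmri, config$sidecar)
  table <- build_timing_table(scan)
  ppg <- load_physio(config$physio, fs_hz = config$physio_fs_hz)
  cinfo <- cardiac_info(ppg, halfwidth_hz = config$halfwidth_hz)
  masks <- lapply(names(config$masks), function(nm)
    load_mask(config$masks[[nm]], scan, label = nm))
  names(masks) <- names(config$masks)

  motion_res <- if (!is.null(config$motion)) {
    qc_motion(load_motion(config$motion, scan = scan),
              config$max_motion_mm, config$max_motion_fraction)
  } else list(pass = TRUE, fraction = NA)
  ppg_res <- qc_ppg(cinfo, config$min_ppg_quality)
  cov_res <- lapply(masks, qc_coverage, table = table)
  qc <- qc_report(motion_res, ppg_res, cov_res)

  files <- character(0)
  qc_path <- file.path(config$outdir, "qc.json")
  jsonlite::write_json(qc, qc_path, auto_unbox = TRUE, digits = NA)
  files["qc"] <- qc_path
  if (!qc$overall_pass && !force) {
    failing <- c(if (!motion_res$pass) "motion",
                 if (!ppg_res$pass) "ppg",
                 names(cov_res)[!vapply(cov_res, `[[`, logical(1), "pass")])
    stop("QC failed (", paste(failing, collapse = ", "),
         "); rerun with force = TRUE to override")
  }

  # data-driven vessel segmentation inside each search region
  if (length(config$search_masks)) {
    for (nm in names(config$search_masks)) {
      sm <- load_mask(config$search_masks[[nm]], scan, label = nm)
      pmap <- split_half_pulsatility_map(scan, cinfo,
                                         n_phase_bins = config$n_phase_bins,
                                         seed = config$seed, mask = sm)
      vm <- segment_vessels(pmap, sm, r_threshold = config$r_threshold,
                            label = nm)
      mp <- file.path(config$outdir, paste0("mask-", nm, "_seg.nii.gz"))
      write_mask(vm, mp, scan = scan)
      files[paste0("segmask_", nm)] <- mp
      masks[[nm]] <- vm
    }
  }

  bands <- make_bands(cinfo$f_card_hz, config$halfwidth_hz)
  bp <- list()
  for (nm in names(masks)) {
    hs <- hypersample_roi(scan, masks[[nm]], table,
                          gap_policy = config$gap_policy)
    hp <- file.path(config$outdir, paste0("hyper_", nm, ".tsv"))
    write_hypersampled_tsv(hs, hp)
    ps <- periodogram_psd(hs$values, fs_hz = 1 / hs$dt_s, tr_s = scan$tr_s)
    sp <- file.path(config$outdir, paste0("spectrum_", nm, ".tsv"))
    write_spectrum_tsv(ps, sp)
    files[paste0("hyper_", nm)] <- hp
    files[paste0("spectrum_", nm)] <- sp
    bp[[nm]] <- band_table(nm, bands, ps, "hypersampled_roi")
  }
  bandpower_df <- do.call(rbind, bp)
  bp_path <- file.path(config$outdir, "bandpower.tsv")
  utils::write.table(bandpower_df, bp_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  files["bandpower"] <- bp_path

  log <- list(
    tr_s = scan$tr_s, n_volumes = scan$n_volumes,
    n_time = table$n_time, dt_s = table$dt_s,
    fs_hyper_hz = table$fs_hyper_hz,
    nyquist_original_hz = 1 / (2 * scan$tr_s),
    nyquist_hyper_hz = table$fs_hyper_hz / 2,
    f_card_hz = cinfo$f_card_hz, ppg_quality = cinfo$quality,
    bands = bands, band_overlap_warning = attr(bands, "overlap_warning"),
    thresholds = list(min_ppg_quality = config$min_ppg_quality,
                      max_motion_mm = config$max_motion_mm,
                      max_motion_fraction = config$max_motion_fraction,
                      r_threshold = config$r_threshold,
                      n_phase_bins = config$n_phase_bins),
    gap_policy = config$gap_policy, seed = config$seed)
  log_path <- file.path(config$outdir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA)
  files["log"] <- log_path

  invisible(list(qc = qc, cardiac = cinfo, bandpower = bandpower_df,
                 timing = table, files = files))
}

#' Write a ready-to-run synthetic dataset
#'
#' Generates a phantom for the named acquisition preset and writes the
#' complete file set (NIfTI + sidecar + PPG + masks + motion) consumed by
#' \code{\link{run_pipeline}}.
#'
#' @param preset \code{"hcp_like"}, \code{"local_like"} or
#'   \code{"propagation_demo"}.
#' @param seed integer seed.
#' @param outdir output directory.
#' @param ... further overrides for \code{\link{phantom_preset}}.
#' @return named character vector of files written.
#' @export
make_fixtures <- function(preset, seed, outdir, ...) {
  over <- list(...)
  if (is.null(over$compartments)) {
    base <- phantom_preset(preset)
    over$compartments <- default_compartments(8, 8, base$nz)
    over$nx <- 8; over$ny <- 8
  }
  spec <- do.call(phantom_preset,
                  c(list(preset = preset, seed = as.integer(seed)), over))
  write_phantom(generate_phantom(spec), outdir, prefix = preset)
}
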