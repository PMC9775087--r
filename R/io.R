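#' Read titration spectra from long-format CSV
#'
#' Expected columns: `label`, `lipid_conc_M`, `wavelength_nm`, `intensity`;
#' one [emission_spectrum()] is built per (label, lipid concentration)
#' pair. An optional paired-blank table (same layout, protein-free) is
#' subtracted wavelength-wise before construction.
#'
#' @param path CSV file path.
#' @param protein_conc Protein concentration, molar, attached to every
#'   spectrum.
#' @param blank_path Optional protein-free blank CSV for paired
#'   subtraction.
#' @return List of [emission_spectrum()] objects.
#' @export
read_spectra_csv <- function(path, protein_conc, blank_path = NULL) {
  d <- read.csv(path)
  need <- c("label", "lipid_conc_M", "wavelength_nm", "intensity")
  if (!all(need %in% names(d)))
    stopf("expected columns: %s", paste(need, collapse = ", "))
  if (!is.null(blank_path)) {
    b <- read.csv(blank_path)
    key <- function(x) paste(x$lipid_conc_M, x$wavelength_nm)
    idx <- match(key(d), key(b))
    if (anyNA(idx)) stopf("blank table does not cover all titration points")
    d$intensity <- d$intensity - b$intensity[idx]
  }
  split_keys <- interaction(d$label, d$lipid_conc_M, drop = TRUE)
  lapply(split(d, split_keys), function(g) {
    g <- g[order(g$wavelength_nm), ]
    emission_spectrum(g$wavelength_nm, g$intensity, g$lipid_conc_M[1],
                      protein_conc, as.character(g$label[1]))
  })
}

#' Write log-normal fits to CSV
#'
#' @param fits List of [lognormal_fit()] objects (optionally named).
#' @param path Output CSV path.
#' @return The written data.frame, invisibly.
#' @export
write_lognormal_fits_csv <- function(fits, path) {
  if (inherits(fits, "lognormal_fit")) fits <- list(fits)
  d <- do.call(rbind, lapply(fits, function(f)
    data.frame(Im = f$Im, nu_m = f$nu_m, rho = f$rho, H = f$H, a = f$a,
               lambda_max = f$lambda_max, residual_rms = f$residual_rms,
               converged = f$converged)))
  if (!is.null(names(fits))) d <- cbind(label = names(fits), d)
  write.csv(d, path, row.names = FALSE)
  invisible(d)
}

#' Read a residue peak-height table (TSV)
#'
#' Expected columns: `residue`, `height` (an `assignment` column is
#' tolerated and ignored).
#'
#' @param path TSV path.
#' @return data.frame with `residue`, `height`.
#' @export
read_peak_table <- function(path) {
  d <- read.delim(path)
  if (!all(c("residue", "height") %in% names(d)))
    stopf("expected columns residue, height")
  d[, c("residue", "height")]
}

#' Read a DEST intensity-ratio table (TSV)
#'
#' Expected columns: `residue`, `offset_hz`, `bandwidth_hz`,
#' `intensity_ratio` (returned renamed to `ratio`).
#'
#' @param path TSV path.
#' @return data.frame with `residue`, `offset_hz`, `bandwidth_hz`, `ratio`.
#' @export
read_dest_table <- function(path) {
  d <- read.delim(path)
  need <- c("residue", "offset_hz", "bandwidth_hz", "intensity_ratio")
  if (!all(need %in% names(d))) stopf("expected columns: %s", paste(need, collapse = ", "))
  data.frame(residue = d$residue, offset_hz = d$offset_hz,
             bandwidth_hz = d$bandwidth_hz, ratio = d$intensity_ratio)
}

#' Read an R2 table (TSV)
#'
#' Expected columns: `residue`, `r2_s` (1/s), optional `r2_err`,
#' `condition` (`free` / `with_vesicles`).
#'
#' @param path TSV path.
#' @return data.frame with `residue`, `r2`, and any extra columns kept.
#' @export
read_r2_table <- function(path) {
  d <- read.delim(path)
  if (!all(c("residue", "r2_s") %in% names(d)))
    stopf("expected columns residue, r2_s")
  names(d)[names(d) == "r2_s"] <- "r2"
  d
}

#' Write a residue profile to TSV
#'
#' @param profile A [residue_profile()].
#' @param path Output TSV path.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(profile, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(profile)
}

#' Read per-cell exocytosis traces from long CSV plus an events CSV
#'
#' Trace CSV columns: `cell_id`, `frame`, `time_s`, `intensity`; events
#' CSV columns: `cell_id`, `stim_frame`, `nh4cl_frame`, optional
#' `peak_frame`, `condition`.
#'
#' @param traces_path,events_path CSV paths.
#' @return List of [exo_trace()] objects.
#' @export
read_exo_traces_csv <- function(traces_path, events_path) {
  tr <- read.csv(traces_path)
  ev <- read.csv(events_path)
  lapply(split(tr, tr$cell_id), function(g) {
    g <- g[order(g$frame), ]
    e <- ev[ev$cell_id == g$cell_id[1], ]
    if (nrow(e) != 1) stopf("events row missing for cell %s", g$cell_id[1])
    exo_trace(g$time_s, g$intensity, e$stim_frame,
              if ("peak_frame" %in% names(e)) e$peak_frame else NA,
              e$nh4cl_frame, cell_id = as.character(g$cell_id[1]),
              condition = if ("condition" %in% names(e))
                as.character(e$condition) else "unknown")
  })
}

#' Read a single- or two-channel TIFF image as matrices
#'
#' Thin wrapper over the `tiff` package (suggested dependency); channel
#' planes are returned as numeric matrices.
#'
#' @param path TIFF path.
#' @return A list of matrices, one per channel/plane.
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("reading TIFF requires the 'tiff' package")
  img <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(img)) img <- list(img)
  lapply(img, function(p) if (length(dim(p)) == 3)
    apply(p, 3, identity, simplify = FALSE) else p)
}
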