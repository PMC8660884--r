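#' Write and read phase stacks as multi-page TIFF
#'
#' Stacks are written as 32-bit float multi-page TIFF, one page per phase
#' step in ascending step order, with a JSON sidecar (`<path>.json`)
#' holding the [instrument_config()] and the intensity scale: the TIFF
#' library stores floats normalized to `[0, 1]`, so counts are divided by
#' `scale = max(counts)` on write and restored on read (float32
#' round-trip, ~1e-7 relative precision).
#'
#' @param stack a [phase_stack()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `write_phase_stack()` returns `path` invisibly;
#'   `read_phase_stack()` returns a [phase_stack()].
#' @export
write_phase_stack <- function(stack, path) {
  stopifnot(inherits(stack, "phase_stack"))
  scale <- max(stack$frames, 1)
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(k) stack$frames[k, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  cfg <- unclass(stack$config)
  jsonlite::write_json(c(cfg, list(intensity_scale = scale)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_phase_stack
#' @export
read_phase_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) frames[k, , ] <- pages[[k]] *
      meta$intensity_scale
  cfg <- instrument_config(
    frequency_mhz = meta$frequency_mhz,
    n_phase_steps = meta$n_phase_steps,
    excitation_modulation_depth = meta$excitation_modulation_depth,
    detection_modulation_depth = meta$detection_modulation_depth,
    reference_name = meta$reference_name,
    reference_lifetime = meta$reference_lifetime)
  phase_stack(frames, cfg)
}

#' Write and read a float image map as single-page TIFF
#'
#' 32-bit float single-page TIFF with a JSON sidecar carrying the value
#' scale (and `NaN` positions as a mask), for concentration, phasor or
#' lifetime maps.
#'
#' @param map numeric matrix.
#' @param path TIFF file path.
#' @return `write_map_tiff()` returns `path` invisibly; `read_map_tiff()`
#'   the matrix.
#' @export
write_map_tiff <- function(map, path) {
  finite <- is.finite(map)
  lo <- if (any(finite)) min(map[finite]) else 0
  hi <- if (any(finite)) max(map[finite]) else 1
  span <- if (hi > lo) hi - lo else 1
  norm <- (map - lo) / span
  norm[!finite] <- 0
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(offset = lo, span = span,
                            nan_index = which(!finite)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  out <- m * meta$span + meta$offset
  if (length(meta$nan_index)) out[meta$nan_index] <- NaN
  out
}

#' Serialize a calibration result to JSON and back
#'
#' Stores anchors, both Hill fits (coefficients and diagnostics), the
#' detection range, R and the modulation frequency -- everything needed to
#' quantify later sessions without refitting.
#'
#' @param result a `"calibration_result"` from [calibrate_in_situ()] or
#'   [calibrate_wells()].
#' @param path JSON file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` a list with `anchors` ([two_state_anchors()]),
#'   `hill_on_F`, `hill_on_a` (coefficient lists usable as calibrations),
#'   `detection_range`, `R`, `frequency_mhz`.
#' @export
write_calibration <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  payload <- list(
    anchors = unclass(result$anchors),
    hill_on_F = as.list(coef(result$hill_on_F)),
    hill_on_a = as.list(coef(result$hill_on_a)),
    detection_range = result$detection_range[c("ca_low", "ca_high",
                                               "degenerate")],
    R = result$R,
    frequency_mhz = result$frequency_mhz)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$anchors <- two_state_anchors(
    g_min = p$anchors$g_min, s_min = p$anchors$s_min,
    g_max = p$anchors$g_max, s_max = p$anchors$s_max,
    intensity_ratio_R = p$anchors$intensity_ratio_R,
    frequency_mhz = p$anchors$frequency_mhz)
  p
}

#' Write and read a calibration dataset as CSV
#'
#' Long-format CSV with columns `conc_nM`, `replicate`, `time_s`, `G`,
#' `S`, `intensity`, `digitonin_time_s`; frequency and R metadata travel
#' in a JSON sidecar.
#'
#' @param dataset a `"calibration_dataset"` data frame.
#' @param path CSV file path.
#' @return `write_calibration_dataset()` returns `path` invisibly;
#'   `read_calibration_dataset()` the dataset with attributes restored.
#' @export
write_calibration_dataset <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE)
  jsonlite::write_json(
    list(frequency_mhz = attr(dataset, "frequency_mhz"),
         intensity_ratio_R = attr(dataset, "intensity_ratio_R")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_dataset
#' @export
read_calibration_dataset <- function(path) {
  out <- read.csv(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "frequency_mhz") <- meta$frequency_mhz
    attr(out, "intensity_ratio_R") <- meta$intensity_ratio_R
  }
  class(out) <- c("calibration_dataset", "data.frame")
  out
}
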