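#' Write a four-channel field as multi-page TIFF with a JSON sidecar
#'
#' One 16-bit page per channel in fixed order (Munc13-1, Cav, VGLUT1,
#' PSD-95), pixel size stored in the TIFF resolution tags (pixels per
#' cm) and echoed, together with metadata and any ground truth, in a
#' JSON sidecar next to the image.
#'
#' @param field A `sted_field` or `sted_image_set`.
#' @param path Output TIFF path; the sidecar is written to
#'   `sub("\\\\.tiff?$", ".json", path)`.
#' @param ground_truth Logical; include the generator annotations (if
#'   present) in the sidecar.
#' @return `path`, invisibly.
#' @export
write_sted_field <- function(field, path, ground_truth = TRUE) {
  chans <- c("munc13", "cav", "vglut1", "psd95")
  pages <- lapply(chans, function(nm)
    pmin(pmax(field$images[[nm]], 0), 65535) / 65535)
  res_ppcm <- 1e7 / field$pixel_nm  # pixels per cm
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none",
                  reduce = FALSE)
  meta <- list(channels = chans, pixel_nm = field$pixel_nm,
               condition = field$condition,
               animal_id = field$animal_id, field_id = field$field_id,
               resolution_px_per_cm = res_ppcm)
  if (ground_truth && !is.null(field$ground_truth)) {
    gt <- field$ground_truth
    gt$scene <- unclass(gt$scene)
    meta$ground_truth <- gt
  }
  jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a four-channel field written by [write_sted_field()]
#'
#' @param path TIFF path (JSON sidecar expected next to it).
#' @return A `sted_image_set` with integer counts restored.
#' @export
read_sted_field <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", path),
                              simplifyVector = TRUE)
  imgs <- lapply(pages, function(p) round(p * 65535))
  names(imgs) <- meta$channels
  sted_image_set(imgs$munc13, imgs$cav, imgs$vglut1, imgs$psd95,
                 pixel_nm = meta$pixel_nm, field_id = meta$field_id,
                 animal_id = meta$animal_id, genotype = meta$condition)
}

#' Write / read a current trace as CSV with a protocol JSON sidecar
#'
#' The CSV has columns `time_ms`, `I_pA`, `valid`; the stimulus protocol
#' is stored as JSON next to it.
#'
#' @param trace A [current_trace()].
#' @param protocol A [voltage_protocol()] (optional for writing).
#' @param path CSV path; sidecar at `sub("\\\\.csv$", ".json", path)`.
#' @return `path` invisibly (write); a list `trace`, `protocol` (read).
#' @export
write_trace_csv <- function(trace, path, protocol = NULL) {
  utils::write.csv(data.frame(time_ms = trace$t_ms, I_pA = trace$I_pA,
                              valid = trace$valid),
                   path, row.names = FALSE)
  if (!is.null(protocol))
    jsonlite::write_json(unclass(protocol),
                         sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  fs <- 1 / stats::median(diff(df$time_ms))
  tr <- current_trace(df$I_pA, fs = round(fs, 6), t0 = df$time_ms[1],
                      valid = df$valid)
  jpath <- sub("\\.csv$", ".json", path)
  proto <- NULL
  if (file.exists(jpath)) {
    pl <- jsonlite::read_json(jpath, simplifyVector = TRUE)
    proto <- do.call(voltage_protocol, pl[!vapply(pl, is.null, TRUE)])
  }
  list(trace = tr, protocol = proto)
}
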