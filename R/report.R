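#' Measurement report
#'
#' `measurementReport()` converts a [TMJMeasurement-class] (plus the
#' configuration used) into a plain named list;
#' `writeMeasurementReport()` serializes it as JSON. Running the same
#' volume with the same configuration and seed twice produces bytewise
#' identical reports.
#'
#' @param meas a [TMJMeasurement-class].
#' @param cfg the configuration used (echoed into the report).
#' @param path output JSON path.
#' @return `measurementReport()`: a named list;
#'   `writeMeasurementReport()`: the path, invisibly.
#' @export
measurementReport <- function(meas, cfg = tmjConfig()) {
  lm <- lapply(meas@landmarks, function(p) list(u_mm = p[1], v_mm = p[2]))
  list(
    laterality = meas@laterality,
    plane_azimuth_deg = meas@planeAzimuthDeg,
    section_length_mm = meas@sectionLengthMm,
    theta_T_dorsal_deg = meas@thetaTD,
    theta_T_frontal_deg = meas@thetaTF,
    r_C_mm = meas@rC,
    r_D_mm = meas@rD,
    r_F_mm = meas@rF,
    degenerate = as.list(meas@degenerate),
    landmarks = lm,
    config_echo = .flattenConfig(cfg))
}

#' @rdname measurementReport
#' @export
writeMeasurementReport <- function(meas, path, cfg = tmjConfig()) {
  jsonlite::write_json(measurementReport(meas, cfg), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
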