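#' Pipeline configuration
#'
#' Returns the full configuration list with the package defaults,
#' optionally overridden. Defaults: curvature-flow time step 0.01 with 10
#' iterations; 3 mixture components; tangent sweep from 0 to 50 degrees
#' in 5-degree coarse steps refined at 0.5 degrees; adaptive step
#' threshold (`NULL` = `max(1 mm, 3 x median increment)`); profile
#' sampling at half the in-plane voxel size.
#'
#' @param ... named overrides, either top-level groups
#'   (`denoise = list(iterations = 5)`) or flat dotted keys
#'   (`"denoise.iterations" = 5`), as used by the YAML config files of
#'   the command-line interface.
#' @return Nested configuration list with groups `denoise`,
#'   `segmentation`, `geometry`, `sweep`, `profile`.
#' @export
tmjConfig <- function(...) {
  cfg <- list(
    denoise = list(timeStep = 0.01, iterations = 10L),
    segmentation = list(components = 3L, seed = 42L, tol = 1e-4,
                        varFloor = 1),
    geometry = list(contactTolVoxels = 0.75),
    sweep = list(thetaMaxDeg = 50, coarseStepDeg = 5, fineStepDeg = 0.5,
                 stepThresholdMm = NULL),
    profile = list(stepFactor = 0.5, peakFrac = 0.25,
                   minOffsetSamples = 2L, peakFloor = 0.5))
  over <- list(...)
  for (nm in names(over)) {
    if (grepl("\\.", nm)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (!parts[1] %in% names(cfg) || length(parts) != 2L)
        stop(sprintf("unknown config key '%s'", nm))
      cfg[[parts[1]]][[parts[2]]] <- over[[nm]]
    } else {
      if (!nm %in% names(cfg)) stop(sprintf("unknown config group '%s'", nm))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    }
  }
  cfg
}

# Flatten/expand between nested config and dotted YAML keys.
.flattenConfig <- function(cfg) {
  out <- list()
  for (g in names(cfg)) for (k in names(cfg[[g]]))
    out[[paste(g, k, sep = ".")]] <- cfg[[g]][[k]]
  out
}
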