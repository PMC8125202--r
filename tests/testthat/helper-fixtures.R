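# Shared fixtures: a reduced phantom for unit tests (coarser grid than
# the acceptance phantom so each pipeline run stays fast) and hand-built
# reference slices for landmark edge cases.

smallPhantomSpec <- function(...) {
  phantomSpec(spacing = c(0.4, 0.4, 0.4), dims = c(80L, 80L, 64L), ...)
}

# Cache pipeline stages for the default small sphere phantom: several
# tests reuse them.
.fixtureCache <- new.env()

smallSphereRun <- function() {
  if (!is.null(.fixtureCache$sphere)) return(.fixtureCache$sphere)
  ph <- generatePhantom(smallPhantomSpec(seed = 11L))
  cropped <- cropVolume(ph$volume, ph$voi)
  den <- curvatureFlowDenoise(cropped)
  stack <- segmentTmjHead(den)
  sec <- longestSection(stack)
  plane <- referencePlane(sec)
  ref <- extractReferenceSlice(den, stack, plane, "right")
  .fixtureCache$sphere <- list(ph = ph, cropped = cropped, den = den,
                               stack = stack, sec = sec, plane = plane,
                               ref = ref)
  .fixtureCache$sphere
}

# A ReferenceSlice built directly from a matrix of values (mask from a
# midpoint threshold) for landmark tests.
refSliceFromValues <- function(vals, spacing = 0.3, mask = NULL,
                               boneThreshold = 60) {
  if (is.null(mask)) mask <- vals > boneThreshold
  new("ReferenceSlice", values = vals, mask = mask, du = spacing,
      dv = spacing, anchorU = (nrow(vals) - 1) * spacing / 2,
      dorsalSign = 1, laterality = "right", azimuthDeg = 0)
}
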