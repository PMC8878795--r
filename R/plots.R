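#' Plot an axial sensitivity profile
#' @param profile data.frame from \code{\link{axialSensitivityProfile}}.
#' @param ... passed to \code{plot}.
#' @export
plotAxialProfile <- function(profile, ...) {
  graphics::plot(profile$z, profile$sensitivity_pct, type = "b", pch = 19,
                 xlab = "axial position [mm]", ylab = "sensitivity [%]", ...)
}

#' Plot a NECR curve
#' @param curve data.frame from \code{\link{necrCurve}} (\code{$curve}).
#' @param ... passed to \code{plot}.
#' @export
plotNECRCurve <- function(curve, ...) {
  graphics::plot(curve$activity_mbq, curve$necr / 1000, type = "b", pch = 19,
                 log = "x", xlab = "activity [MBq]", ylab = "rate [kcps]",
                 ylim = c(0, max(curve$prompts) / 1000), ...)
  graphics::lines(curve$activity_mbq, curve$trues / 1000, col = 2, type = "b")
  graphics::lines(curve$activity_mbq, curve$scattered / 1000, col = 3, type = "b")
  graphics::lines(curve$activity_mbq, curve$randoms / 1000, col = 4, type = "b")
  graphics::legend("topleft", c("NECR", "trues", "scattered", "randoms"),
                   col = 1:4, lty = 1, bty = "n")
}
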