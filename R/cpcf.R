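## Confocal patch-clamp fluorometry: extraction of the bound-ligand
## fluorescence from two-channel images. The red channel reports the free dye
## only; after offset correction it is scaled to the green channel in the bath
## (where no binding occurs) and subtracted pixel-wise, leaving the signal of
## the bound fluorescent ligand. The patch-mask average gives F, normalised by
## F_max from designated saturating reference frames.

#' Extract bound fluorescence from a two-channel image
#'
#' @param green,red numeric matrices (same dimensions): pixel intensities.
#' @param bathMask,patchMask logical matrices: disjoint, non-empty regions of
#'   bath (free dye only) and free patch membrane.
#' @param borderMask optional logical matrix of signal-free pixels used to
#'   estimate the channel offsets; offsets default to 0 when absent.
#' @return list with scale, offsets, the bound-signal image and F (mean bound
#'   signal over the patch mask).
#' @export
extractBoundFluorescence <- function(green, red, bathMask, patchMask,
                                     borderMask = NULL) {
  stopifnot(identical(dim(green), dim(red)),
            identical(dim(green), dim(bathMask)),
            identical(dim(green), dim(patchMask)))
  if (!any(bathMask) || !any(patchMask))
    stop("bath and patch masks must be non-empty")
  if (any(bathMask & patchMask)) stop("bath and patch masks must be disjoint")
  offG <- if (!is.null(borderMask) && any(borderMask))
    mean(green[borderMask]) else 0
  offR <- if (!is.null(borderMask) && any(borderMask))
    mean(red[borderMask]) else 0
  g <- green - offG; r <- red - offR
  bathR <- mean(r[bathMask])
  if (abs(bathR) < 1e-12) stop("zero red-channel bath signal: cannot scale")
  scale <- mean(g[bathMask]) / bathR
  bound <- g - scale * r
  list(scale = scale, offsets = c(green = offG, red = offR),
       bound = bound, F = mean(bound[patchMask]))
}

#' Bound-fluorescence series with F/F_max normalisation
#'
#' Applies \code{\link{extractBoundFluorescence}} to each frame; F_max is the
#' mean F over the designated saturating reference frames.
#'
#' @param greenFrames,redFrames lists of matrices (one per frame).
#' @param bathMask,patchMask,borderMask masks as in
#'   \code{\link{extractBoundFluorescence}}.
#' @param referenceFrames indices of the saturating reference frames.
#' @return data.frame with frame, F and relF columns.
#' @export
boundFluorescenceSeries <- function(greenFrames, redFrames, bathMask,
                                    patchMask, referenceFrames,
                                    borderMask = NULL) {
  stopifnot(length(greenFrames) == length(redFrames))
  Fv <- vapply(seq_along(greenFrames), function(k)
    extractBoundFluorescence(greenFrames[[k]], redFrames[[k]], bathMask,
                             patchMask, borderMask)$F, numeric(1))
  Fmax <- mean(Fv[referenceFrames])
  data.frame(frame = seq_along(Fv), F = Fv, relF = Fv / Fmax)
}
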