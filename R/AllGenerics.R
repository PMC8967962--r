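#' @name maskVoxels
#' @title Accessors for MaskVolume objects
#'
#' @description `maskVoxels()` returns the 0/1 lattice, `voxelSpacing()`
#' the mm spacing `(sx, sy, sz)`, `sourcePath()` the provenance label,
#' `maskMetadata()` the annotation list and `foregroundCount()` the
#' number of foreground voxels.
#'
#' @param x a [MaskVolume-class] object.
#' @return See the individual descriptions.
#' @aliases voxelSpacing sourcePath maskMetadata foregroundCount
#' @examples
#' m <- makeEllipsoidMask(c(5, 4, 6), dim = c(24, 24, 8),
#'                        spacing = c(1, 1, 2))
#' voxelSpacing(m)
#' foregroundCount(m)
NULL

#' @rdname maskVoxels
#' @export
setGeneric("maskVoxels", function(x) standardGeneric("maskVoxels"))

#' @rdname maskVoxels
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname maskVoxels
#' @export
setGeneric("sourcePath", function(x) standardGeneric("sourcePath"))

#' @rdname maskVoxels
#' @export
setGeneric("maskMetadata", function(x) standardGeneric("maskMetadata"))

#' @rdname maskVoxels
#' @export
setGeneric("foregroundCount", function(x) standardGeneric("foregroundCount"))

#' @name gtvValue
#' @title Accessors for VolumeEstimate objects
#'
#' @description `gtvValue()` returns the estimated volume in mm^3,
#' `gtvMethod()` the estimator name, `gapContributions()` the per-gap
#' frustum volumes and `sliceRuns()` the contiguous slice ranges used.
#'
#' @param x a [VolumeEstimate-class] object.
#' @return See the individual descriptions.
#' @aliases gtvMethod gapContributions sliceRuns
NULL

#' @rdname gtvValue
#' @export
setGeneric("gtvValue", function(x) standardGeneric("gtvValue"))

#' @rdname gtvValue
#' @export
setGeneric("gtvMethod", function(x) standardGeneric("gtvMethod"))

#' @rdname gtvValue
#' @export
setGeneric("gapContributions", function(x) standardGeneric("gapContributions"))

#' @rdname gtvValue
#' @export
setGeneric("sliceRuns", function(x) standardGeneric("sliceRuns"))

#' @name metricValues
#' @title Extract all metrics of an OverlapReport as a named vector
#'
#' @param x an [OverlapReport-class] object.
#' @return Named numeric vector with elements `dsc`, `hd_mm`, `msd_mm`,
#'   `ci`, `di_pred_in_gt`, `di_gt_in_pred`, `lr_mm`, `ap_mm`, `cc_mm`,
#'   `mv_mm`.
NULL

#' @rdname metricValues
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))
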