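#' MaskVolume: a 3-D binary segmentation mask on a regular lattice
#'
#' The universal input container of the package: a 3-D lattice of 0/1
#' values together with the physical voxel spacing in mm. The lattice is
#' stored `[x, y, z]` with x = left-right (LR), y = anterior-posterior
#' (AP) and z = cranial-caudal (CC); axial slices are `voxels[, , k]`.
#' Voxel centers map to mm coordinates as `(index - 1) * spacing` per
#' axis (1-based indices), so the first voxel center sits at the origin.
#'
#' @slot voxels 3-D integer array of 0/1 values.
#' @slot spacing numeric length-3 vector `(sx, sy, sz)` in mm/voxel;
#'   `sz` is the axial slice thickness used as the integration step h.
#' @slot sourcePath character scalar; provenance label, possibly "".
#' @slot metadata list of free-form annotations (phantom generators
#'   store their analytic geometry here).
#'
#' @seealso [MaskVolume()] for construction, [readMask()], [writeMask()]
#' @export
setClass("MaskVolume",
    representation(
        voxels = "array",
        spacing = "numeric",
        sourcePath = "character",
        metadata = "list"
    ),
    prototype(
        voxels = array(0L, dim = c(1L, 1L, 1L)),
        spacing = c(1, 1, 1),
        sourcePath = "",
        metadata = list()
    )
)

setValidity("MaskVolume", function(object) {
    msg <- character()
    d <- dim(object@voxels)
    if (length(d) != 3L)
        msg <- c(msg, "voxels must be a 3-D array")
    if (any(d < 1L))
        msg <- c(msg, "lattice must have >= 1 voxel along every axis")
    if (length(object@spacing) != 3L ||
        !all(is.finite(object@spacing)) || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive finite mm values")
    v <- object@voxels
    if (!all(v == 0L | v == 1L))
        msg <- c(msg, "voxel values must be exactly 0 or 1")
    if (length(object@sourcePath) != 1L)
        msg <- c(msg, "sourcePath must be a single character string")
    if (length(msg)) msg else TRUE
})

#' VolumeEstimate: a gross tumor volume value with its provenance
#'
#' Result container for the two GTV estimators. For the frustum
#' integration method the per-gap truncated-cone contributions and the
#' contiguous slice runs they came from are retained, so the total can
#' always be audited as the sum of its parts.
#'
#' @slot method character, `"etecim"` or `"voxel_sum"`.
#' @slot volume numeric, GTV in mm^3.
#' @slot gapContributions data.frame with columns `lower`, `upper`
#'   (slice indices) and `volume` (mm^3); one row per inter-slice
#'   frustum, plus single-slice cylinder terms with `lower == upper`.
#' @slot runs data.frame with columns `start`, `end`: maximal contiguous
#'   slice ranges that contained foreground.
#' @export
setClass("VolumeEstimate",
    representation(
        method = "character",
        volume = "numeric",
        gapContributions = "data.frame",
        runs = "data.frame"
    )
)

setValidity("VolumeEstimate", function(object) {
    msg <- character()
    if (!object@method %in% c("etecim", "voxel_sum"))
        msg <- c(msg, "method must be 'etecim' or 'voxel_sum'")
    if (length(object@volume) != 1L || !is.finite(object@volume) ||
        object@volume < 0)
        msg <- c(msg, "volume must be a single finite non-negative number")
    if (object@method == "etecim") {
        tot <- sum(object@gapContributions$volume)
        if (abs(tot - object@volume) > 1e-6 * max(1, object@volume))
            msg <- c(msg, "volume must equal the sum of gap contributions")
        r <- object@runs
        if (nrow(r) > 1L && any(diff(r$start) <= 0))
            msg <- c(msg, "runs must be sorted and non-overlapping")
    }
    if (length(msg)) msg else TRUE
})

#' OverlapReport: all pairwise comparison metrics for one mask pair
#'
#' Aggregates the voxel-overlap, surface-distance and center-of-mass
#' metrics between a predicted and a ground-truth mask. Distances are in
#' mm; `lr`, `ap`, `cc` are signed components of the center-of-mass
#' displacement (predicted minus ground truth) and `mv` their Euclidean
#' norm. When the predicted mask is empty, overlap fractions are 0 and
#' the inclusion/distance fields are `NA` with `predEmpty = TRUE`.
#'
#' @slot dsc Dice similarity coefficient in `[0, 1]`.
#' @slot hd Hausdorff distance (full max-of-max), mm.
#' @slot msd symmetrized mean surface distance, mm.
#' @slot ci conformity index (intersection over union) in `[0, 1]`.
#' @slot diPredInGT,diGTInPred degrees of inclusion in `[0, 1]`.
#' @slot lr,ap,cc signed COM displacement components, mm.
#' @slot mv motion vector magnitude, mm.
#' @slot counts named integer vector with elements `TP`, `FP`, `FN`.
#' @slot predEmpty logical flag.
#' @export
setClass("OverlapReport",
    representation(
        dsc = "numeric", hd = "numeric", msd = "numeric",
        ci = "numeric", diPredInGT = "numeric", diGTInPred = "numeric",
        lr = "numeric", ap = "numeric", cc = "numeric", mv = "numeric",
        counts = "numeric", predEmpty = "logical"
    )
)

setValidity("OverlapReport", function(object) {
    msg <- character()
    if (!object@predEmpty) {
        if (abs(object@dsc - 2 * object@ci / (1 + object@ci)) > 1e-12)
            msg <- c(msg, "dsc must equal 2*ci/(1+ci)")
        if (object@hd < object@msd - 1e-12)
            msg <- c(msg, "hd must be >= msd")
        if (abs(object@mv -
                sqrt(object@lr^2 + object@ap^2 + object@cc^2)) > 1e-9)
            msg <- c(msg, "mv must be the Euclidean norm of (lr, ap, cc)")
    }
    if (length(msg)) msg else TRUE
})
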