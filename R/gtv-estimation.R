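#' Volume of a truncated elliptical cone between two slices
#'
#' The frustum bounded by the equivalent ellipses of two adjacent axial
#' slices a distance `h` apart has volume
#' \deqn{V = \frac{\pi h}{6}\left[2(a_1 b_1 + a_2 b_2) + a_1 b_2 +
#'       b_1 a_2\right].}
#' With circular cross-sections (a = b = R, r) this reduces to the
#' classical circular frustum `(pi h / 3)(R^2 + R r + r^2)`; with equal
#' ellipses it is the elliptical cylinder `pi a b h`; with one ellipse
#' shrunk to a point it is the elliptical cone `(pi h / 3) a b`.
#' Vectorized over all arguments.
#'
#' @param aLower,bLower half-axes of the lower ellipse, mm (>= 0).
#' @param aUpper,bUpper half-axes of the upper ellipse, mm (>= 0).
#' @param h inter-slice distance (axial resolution), mm (> 0).
#' @return Frustum volume(s) in mm^3.
#' @examples
#' frustumVolume(2, 2, 1, 1, 3)     # 7 * pi, circular frustum
#' frustumVolume(2, 1, 2, 1, 6)     # 12 * pi, elliptical cylinder
#' @export
frustumVolume <- function(aLower, bLower, aUpper, bUpper, h) {
    if (any(c(aLower, bLower, aUpper, bUpper) < 0))
        stop("half-axes must be non-negative")
    if (any(h <= 0))
        stop("slice distance h must be strictly positive")
    pi * h / 6 * (2 * (aLower * bLower + aUpper * bUpper) +
                  aLower * bUpper + bLower * aUpper)
}

#' Gross tumor volume by truncated elliptical cone integration
#'
#' Sums [frustumVolume()] over every adjacent pair of fitted slices:
#' \deqn{GTV = \sum_{i=m}^{n-1} \frac{\pi h}{6}\left[2(a_i b_i +
#'       a_{i+1} b_{i+1}) + a_i b_{i+1} + b_i a_{i+1}\right]}
#' from the cranial slice m to the caudal slice n. Fits are first
#' partitioned into maximal contiguous slice runs; masks with empty
#' intermediate slices are summed run by run (with a warning), no
#' interpolation across the gap. A run consisting of a single slice
#' contributes an elliptical cylinder `pi a b h`, so one-slice lesions
#' have nonzero volume. No end-cap is extrapolated beyond the outermost
#' slices.
#'
#' @param fits data.frame from [fitStack()] (columns `slice`, `a`, `b`),
#'   sorted by `slice`.
#' @param h axial slice spacing, mm.
#' @return A [VolumeEstimate-class] with `method = "etecim"`.
#' @export
etecimVolume <- function(fits, h) {
    if (is.null(fits) || nrow(fits) == 0L)
        stop("no slice fits supplied: mask has no foreground")
    if (h <= 0) stop("slice distance h must be strictly positive")
    if (is.unsorted(fits$slice, strictly = TRUE))
        stop("fits must be strictly sorted by slice index")
    runId <- cumsum(c(1L, diff(fits$slice) != 1L))
    if (max(runId) > 1L)
        warning("foreground spans ", max(runId), " disjoint slice runs; ",
                "summed independently without interpolation", call. = FALSE)
    gaps <- lapply(split(seq_len(nrow(fits)), runId), function(ii) {
        f <- fits[ii, ]
        if (nrow(f) == 1L) {
            data.frame(lower = f$slice, upper = f$slice,
                       volume = pi * f$a * f$b * h)
        } else {
            lo <- seq_len(nrow(f) - 1L)
            data.frame(lower = f$slice[lo], upper = f$slice[lo + 1L],
                       volume = frustumVolume(f$a[lo], f$b[lo],
                                              f$a[lo + 1L], f$b[lo + 1L], h))
        }
    })
    gaps <- do.call(rbind, c(gaps, list(make.row.names = FALSE)))
    runs <- data.frame(
        start = as.vector(tapply(fits$slice, runId, min)),
        end = as.vector(tapply(fits$slice, runId, max)))
    methods::new("VolumeEstimate", method = "etecim",
                 volume = sum(gaps$volume), gapContributions = gaps,
                 runs = runs)
}

#' Gross tumor volume by voxel summation
#'
#' The conventional baseline: foreground voxel count times the voxel
#' volume `sx * sy * sz`. Because boundary voxels are counted in full
#' even where the lesion only partly fills them, this estimator is
#' biased upward relative to the frustum integration for convex stacked
#' lesions (for an n-slice cylinder the ratio is n / (n - 1)).
#'
#' @param mask a [MaskVolume-class]; an empty mask yields volume 0.
#' @return A [VolumeEstimate-class] with `method = "voxel_sum"`.
#' @export
voxelSumVolume <- function(mask) {
    stopifnot(methods::is(mask, "MaskVolume"))
    vol <- sum(mask@voxels) * prod(mask@spacing)
    methods::new("VolumeEstimate", method = "voxel_sum", volume = vol,
                 gapContributions = data.frame(lower = integer(),
                                               upper = integer(),
                                               volume = numeric()),
                 runs = data.frame(start = integer(), end = integer()))
}

#' Estimate gross tumor volume from a mask
#'
#' Dispatcher over the two estimators: `"etecim"` fits the equivalent
#' ellipse of every populated slice ([fitStack()]) and integrates
#' truncated elliptical cones between adjacent slices
#' ([etecimVolume()]) with h taken from the axial spacing; `"voxel_sum"`
#' multiplies the foreground count by the voxel volume.
#'
#' @param mask a [MaskVolume-class].
#' @param method `"etecim"` (default) or `"voxel_sum"`.
#' @return A [VolumeEstimate-class].
#' @examples
#' tube <- makeTubePhantom(data.frame(slice = 1:11, a = 10, b = 10,
#'                                    phi = 0, cx = 20, cy = 20),
#'                         dim = c(41, 41, 11), spacing = c(1, 1, 5))
#' gtvValue(estimateGTV(tube, "etecim"))
#' gtvValue(estimateGTV(tube, "voxel_sum"))
#' @export
estimateGTV <- function(mask, method = c("etecim", "voxel_sum")) {
    method <- match.arg(method)
    if (method == "etecim") {
        etecimVolume(fitStack(mask), h = voxelSpacing(mask)[3])
    } else {
        voxelSumVolume(mask)
    }
}

#' @rdname gtvValue
#' @export
setMethod("gtvValue", "VolumeEstimate", function(x) x@volume)

#' @rdname gtvValue
#' @export
setMethod("gtvMethod", "VolumeEstimate", function(x) x@method)

#' @rdname gtvValue
#' @export
setMethod("gapContributions", "VolumeEstimate", function(x) x@gapContributions)

#' @rdname gtvValue
#' @export
setMethod("sliceRuns", "VolumeEstimate", function(x) x@runs)

setMethod("show", "VolumeEstimate", function(object) {
    cat("VolumeEstimate [", object@method, "]: ",
        format(object@volume, digits = 8), " mm^3\n", sep = "")
    if (nrow(object@runs))
        cat("  slice runs:",
            paste(object@runs$start, object@runs$end, sep = "-",
                  collapse = ", "), "\n")
})

#' RECIST-style diameters from fitted slice ellipses
#'
#' The longest diameter is the maximum over slices of the equivalent
#' ellipse's long axis (2a), the measurement RECIST 1.1 bases target
#' lesion assessment on; the shortest diameter is the minimum over
#' slices of the short axis (2b). Ties go to the lowest slice index.
#' Degenerate fits (b = 0) are included as printed; if every fit is
#' degenerate a warning is emitted and both diameters are 0.
#'
#' @param fits data.frame from [fitStack()].
#' @return list with `longest` (mm), `shortest` (mm), `sliceOfLongest`.
#' @export
recistDiameters <- function(fits) {
    if (is.null(fits) || nrow(fits) == 0L)
        stop("no slice fits supplied")
    if (all(fits$degenerate)) {
        warning("all slice fits are degenerate; diameters reported as 0",
                call. = FALSE)
        return(list(longest = 0, shortest = 0,
                    sliceOfLongest = fits$slice[1]))
    }
    iMax <- which.max(fits$a)  # which.max returns the first (lowest) index
    list(longest = 2 * fits$a[iMax],
         shortest = 2 * min(fits$b),
         sliceOfLongest = fits$slice[iMax])
}
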