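#' Second moments of one axial slice's foreground
#'
#' Treats the foreground pixels of slice `sliceIndex` as a system of N
#' unit point masses at their voxel-center mm positions and computes the
#' centroid and the central (centroid-relative) second moments:
#' `A = sum(x_i^2)`, `B = sum(y_i^2)`, `H = sum(x_i * y_i)` in mm^2,
#' unnormalized, plus the pixel area `M = N * sx * sy`.
#'
#' @param mask a [MaskVolume-class].
#' @param sliceIndex 1-based axial slice index.
#' @return A list of class `"SliceMoments"` with elements `slice`, `N`,
#'   `cx`, `cy` (mm), `A`, `B`, `H` (mm^2), `M` (mm^2).
#' @examples
#' arr <- array(0, dim = c(6, 6, 1)); arr[3:4, 3:4, 1] <- 1
#' m <- sliceMoments(MaskVolume(arr), 1)
#' m$A; m$B; m$H  # 1, 1, 0: a 2x2 square of unit pixels
#' @export
sliceMoments <- function(mask, sliceIndex) {
    stopifnot(methods::is(mask, "MaskVolume"))
    d <- dim(mask@voxels)
    if (sliceIndex < 1L || sliceIndex > d[3])
        stop("slice index ", sliceIndex, " outside lattice (1..", d[3], ")")
    sl <- mask@voxels[, , sliceIndex]
    idx <- which(sl == 1L, arr.ind = TRUE)
    if (nrow(idx) == 0L)
        stop("slice ", sliceIndex, " has no foreground pixels")
    sp <- mask@spacing
    xs <- (idx[, 1] - 1) * sp[1]
    ys <- (idx[, 2] - 1) * sp[2]
    n <- nrow(idx)
    cx <- mean(xs); cy <- mean(ys)
    dx <- xs - cx; dy <- ys - cy
    structure(list(slice = as.integer(sliceIndex), N = n, cx = cx, cy = cy,
                   A = sum(dx * dx), B = sum(dy * dy), H = sum(dx * dy),
                   M = n * sp[1] * sp[2]),
              class = "SliceMoments")
}

#' Fit the equivalent (inertia) ellipse from slice moments
#'
#' The equivalent ellipse is the ellipse whose second moments match
#' those of the foreground pixel set; its half-axes are
#' \deqn{a = \sqrt{2[(A+B) + \sqrt{(A-B)^2 + 4H^2}]/N}, \quad
#'       b = \sqrt{2[(A+B) - \sqrt{(A-B)^2 + 4H^2}]/N}}
#' with A, B, H the central second moments in mm^2 and N the pixel
#' count, so a uniform ideal ellipse returns its own semi-axes exactly
#' (its coordinate variances are a^2/4 and b^2/4). The long-axis angle
#' `phi1` is the principal eigen-direction, `0.5 * atan2(2H, A - B)`,
#' reported in degrees in (-90, 90] in the y-up mm frame; `phi2` is the
#' short-axis angle, `phi1` +/- 90 wrapped into the same range. For a
#' circle (A = B, H = 0) `phi1` is 0 by convention.
#'
#' @param moments a `"SliceMoments"` list from [sliceMoments()].
#' @return A one-row data.frame with columns `slice`, `cx`, `cy`, `a`,
#'   `b` (mm, `a >= b`), `phi1`, `phi2` (degrees), `area` (mm^2),
#'   `nPixels`, `degenerate` (`TRUE` when N < 3 or b = 0).
#' @seealso [fitStack()] to fit every populated slice of a mask.
#' @export
fitEquivalentEllipse <- function(moments) {
    stopifnot(inherits(moments, "SliceMoments"))
    A <- moments$A; B <- moments$B; H <- moments$H; n <- moments$N
    disc <- sqrt((A - B)^2 + 4 * H^2)
    a <- sqrt(max(2 * ((A + B) + disc) / n, 0))
    b <- sqrt(max(2 * ((A + B) - disc) / n, 0))
    if (disc <= 1e-12 * max(A + B, .Machine$double.eps)) {
        phi1 <- 0  # circle: orientation undefined, fixed at 0
    } else {
        phi1 <- 0.5 * atan2(2 * H, A - B) * 180 / pi
        if (phi1 <= -90) phi1 <- phi1 + 180
        if (phi1 > 90) phi1 <- phi1 - 180
    }
    phi2 <- if (phi1 > 0) phi1 - 90 else phi1 + 90
    degenerate <- n < 3L || b < 1e-9
    data.frame(slice = moments$slice, cx = moments$cx, cy = moments$cy,
               a = a, b = b, phi1 = phi1, phi2 = phi2,
               area = moments$M, nPixels = n, degenerate = degenerate)
}

#' Fit equivalent ellipses on every populated slice of a mask
#'
#' Runs [sliceMoments()] + [fitEquivalentEllipse()] on each axial slice
#' that contains foreground; empty slices are omitted (their indices
#' simply do not appear). A warning is emitted for slices whose
#' foreground splits into more than one 4-connected component; all
#' pixels are still pooled into a single mass-point system.
#'
#' @param mask a [MaskVolume-class] with at least one foreground voxel.
#' @return data.frame, one row per populated slice, sorted by `slice`
#'   (cranial to caudal); columns as in [fitEquivalentEllipse()].
#' @examples
#' tube <- makeTubePhantom(data.frame(slice = 1:5, a = 8, b = 5,
#'                                    phi = 0, cx = 15, cy = 15),
#'                         dim = c(32, 32, 5), spacing = c(1, 1, 5))
#' fits <- fitStack(tube)
#' fits[, c("slice", "a", "b", "phi1")]
#' @export
fitStack <- function(mask) {
    stopifnot(methods::is(mask, "MaskVolume"))
    counts <- apply(mask@voxels, 3L, sum)
    populated <- which(counts > 0)
    if (!length(populated))
        stop("mask has no foreground voxels")
    rows <- lapply(populated, function(k) {
        if (countComponents2D(mask@voxels[, , k]) > 1L)
            warning("slice ", k, " has multiple connected components; ",
                    "pixels pooled into one fit", call. = FALSE)
        fitEquivalentEllipse(sliceMoments(mask, k))
    })
    do.call(rbind, rows)
}

# number of 4-connected foreground components of a 2-D 0/1 matrix
# (flood fill over a label queue; slices are small so this is cheap)
countComponents2D <- function(sl) {
    fg <- which(sl == 1L)
    if (!length(fg)) return(0L)
    nr <- nrow(sl)
    nc <- ncol(sl)
    seen <- logical(length(sl))
    ncomp <- 0L
    for (start in fg) {
        if (seen[start]) next
        ncomp <- ncomp + 1L
        queue <- start
        seen[start] <- TRUE
        while (length(queue)) {
            cur <- queue[length(queue)]
            queue <- queue[-length(queue)]
            i <- ((cur - 1L) %% nr) + 1L
            j <- ((cur - 1L) %/% nr) + 1L
            nb <- c(if (i > 1L) cur - 1L, if (i < nr) cur + 1L,
                    if (j > 1L) cur - nr, if (j < nc) cur + nr)
            nb <- nb[!seen[nb] & sl[nb] == 1L]
            seen[nb] <- TRUE
            queue <- c(queue, nb)
        }
    }
    ncomp
}
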