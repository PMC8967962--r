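# evaluate expr with its own RNG stream, leaving the caller's untouched
withLocalSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Rasterize an ellipsoid phantom mask
#'
#' A voxel is foreground iff its center satisfies
#' `((x-cx)/a)^2 + ((y-cy)/b)^2 + ((z-cz)/c)^2 <= 1` in mm coordinates
#' (center-inclusion rasterization: unbiased to first order in the
#' spacing). Deterministic. The exact analytic volume `4/3 pi a b c`
#' and the geometry are retained in the mask metadata.
#'
#' @param semiAxes numeric length-3 `(a, b, c)` in mm, all > 0.
#' @param dim lattice dimensions `(nx, ny, nz)`.
#' @param spacing voxel spacing in mm; defaults to the CT-like
#'   `(0.98, 0.98, 5)`.
#' @param center mm position of the ellipsoid center; default is the
#'   lattice center `(dim - 1) / 2 * spacing`.
#' @return A [MaskVolume-class]; metadata holds `shape`, `semiAxes`,
#'   `center`, `analyticVolume`.
#' @examples
#' m <- makeEllipsoidMask(c(10, 10, 10), dim = c(25, 25, 25),
#'                        spacing = c(1, 1, 1))
#' foregroundCount(m) / (4 / 3 * pi * 1000)  # close to 1
#' @export
makeEllipsoidMask <- function(semiAxes, dim, spacing = c(0.98, 0.98, 5),
                              center = NULL) {
    stopifnot(length(semiAxes) == 3L, all(semiAxes > 0),
              length(dim) == 3L, all(dim >= 1))
    spacing <- as.numeric(spacing)
    extent <- (dim - 1) * spacing
    if (is.null(center)) center <- extent / 2
    if (any(center - semiAxes < -spacing / 2) ||
        any(center + semiAxes > extent + spacing / 2))
        stop("ellipsoid (center ", paste(format(center), collapse = ", "),
             "; semi-axes ", paste(format(semiAxes), collapse = ", "),
             " mm) exceeds the lattice extent")
    u2 <- function(n, s, c0, ax) (((seq_len(n) - 1) * s - c0) / ax)^2
    q <- outer(outer(u2(dim[1], spacing[1], center[1], semiAxes[1]),
                     u2(dim[2], spacing[2], center[2], semiAxes[2]), "+"),
               u2(dim[3], spacing[3], center[3], semiAxes[3]), "+")
    if (!any(q <= 1))
        stop("ellipsoid intersects no voxel center (degenerate phantom)")
    MaskVolume(q <= 1, spacing = spacing,
               metadata = list(shape = "ellipsoid", semiAxes = semiAxes,
                               center = center,
                               analyticVolume = 4 / 3 * pi * prod(semiAxes)))
}

# rasterize one rotated ellipse onto an (nx, ny) slice grid, mm frame
rasterEllipse2D <- function(nx, ny, sx, sy, a, b, phiDeg, cx, cy) {
    xs <- (seq_len(nx) - 1) * sx - cx
    ys <- (seq_len(ny) - 1) * sy - cy
    co <- cos(phiDeg * pi / 180)
    si <- sin(phiDeg * pi / 180)
    X <- matrix(xs, nx, ny)
    Y <- matrix(ys, nx, ny, byrow = TRUE)
    U <- X * co + Y * si
    V <- -X * si + Y * co
    (U / a)^2 + (V / b)^2 <= 1
}

#' Build a tube phantom from per-slice ellipse parameters
#'
#' Emulates an axial lesion stack: each listed slice gets a rasterized
#' ellipse (center-inclusion rule) with its own half-axes, orientation
#' and center, so taper and orientation drift across slices can be
#' prescribed exactly. The analytic per-slice parameters, including the
#' exact ellipse areas `pi a b`, are kept in the mask metadata for
#' ground-truth-aware tests.
#'
#' @param sliceParams data.frame with columns `slice` (1-based index),
#'   `a`, `b` (half-axes mm), `phi` (long-axis angle, degrees), `cx`,
#'   `cy` (center, mm).
#' @param dim lattice dimensions `(nx, ny, nz)`; `nz` defaults to
#'   `max(sliceParams$slice)`.
#' @param spacing voxel spacing mm.
#' @return A [MaskVolume-class]; metadata holds `shape`, `sliceParams`
#'   (with an added `analyticArea` column).
#' @export
makeTubePhantom <- function(sliceParams, dim = NULL,
                            spacing = c(0.98, 0.98, 5)) {
    need <- c("slice", "a", "b", "phi", "cx", "cy")
    stopifnot(all(need %in% names(sliceParams)), nrow(sliceParams) >= 1)
    spacing <- as.numeric(spacing)
    if (is.null(dim)) stop("lattice dimensions must be given")
    if (length(dim) == 2L) dim <- c(dim, max(sliceParams$slice))
    extent <- (dim[1:2] - 1) * spacing[1:2]
    v <- array(0L, dim = dim)
    for (i in seq_len(nrow(sliceParams))) {
        p <- sliceParams[i, ]
        if (p$slice < 1 || p$slice > dim[3])
            stop("slice index ", p$slice, " outside lattice (1..",
                 dim[3], ")")
        phiRad <- p$phi * pi / 180
        wx <- sqrt((p$a * cos(phiRad))^2 + (p$b * sin(phiRad))^2)
        wy <- sqrt((p$a * sin(phiRad))^2 + (p$b * cos(phiRad))^2)
        if (p$cx - wx < -spacing[1] / 2 || p$cx + wx > extent[1] + spacing[1] / 2 ||
            p$cy - wy < -spacing[2] / 2 || p$cy + wy > extent[2] + spacing[2] / 2)
            stop("ellipse on slice ", p$slice, " exceeds the slice bounds")
        v[, , p$slice] <- v[, , p$slice] |
            rasterEllipse2D(dim[1], dim[2], spacing[1], spacing[2],
                            p$a, p$b, p$phi, p$cx, p$cy)
    }
    sliceParams$analyticArea <- pi * sliceParams$a * sliceParams$b
    MaskVolume(v, spacing = spacing,
               metadata = list(shape = "tube", sliceParams = sliceParams))
}

# one 6-neighborhood morphological step; op is pmax (dilate) or pmin-ish
morphStep <- function(v, dilate = TRUE) {
    d <- dim(v)
    p <- array(if (dilate) 0L else 1L, d + 2L)
    p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
    core <- function(dx, dy, dz)
        p[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy, (2:(d[3] + 1)) + dz]
    nb <- list(core(-1, 0, 0), core(1, 0, 0), core(0, -1, 0),
               core(0, 1, 0), core(0, 0, -1), core(0, 0, 1))
    out <- v
    if (dilate) {
        for (x in nb) out <- pmax(out, x)
    } else {
        for (x in nb) out <- pmin(out, x)
    }
    array(as.integer(out), dim = d)
}

#' Perturb a mask to emulate segmentation error
#'
#' Applies, in order: an integer-voxel translation, `|dilateErode|`
#' iterations of 6-neighborhood morphological dilation (positive) or
#' erosion (negative), and independent boundary flips: each foreground
#' surface voxel is dropped and each background face-neighbor of the
#' surface is added, independently with probability `flipRate`, so both
#' false positives and false negatives are produced. The flip stage is
#' a pure function of `seed`; the caller's RNG state is untouched.
#'
#' @param mask a [MaskVolume-class].
#' @param translation integer voxel shifts `(dx, dy, dz)`.
#' @param dilateErode signed iteration count; 0 = none.
#' @param flipRate per-voxel flip probability in `[0, 1]`.
#' @param seed integer seed for the flip stage; required when
#'   `flipRate > 0`.
#' @return A perturbed [MaskVolume-class] on the same lattice.
#' @export
perturbMask <- function(mask, translation = c(0L, 0L, 0L),
                        dilateErode = 0L, flipRate = 0, seed = NULL) {
    stopifnot(methods::is(mask, "MaskVolume"),
              length(translation) == 3L,
              flipRate >= 0, flipRate <= 1)
    v <- mask@voxels
    d <- dim(v)
    tr <- as.integer(round(translation))
    if (any(tr != 0L)) {
        fg <- which(v == 1L, arr.ind = TRUE)
        shifted <- sweep(fg, 2L, tr, "+")
        if (any(shifted < 1L) || any(shifted[, 1] > d[1]) ||
            any(shifted[, 2] > d[2]) || any(shifted[, 3] > d[3]))
            stop("translation (", paste(tr, collapse = ", "),
                 ") pushes foreground outside the lattice")
        v <- array(0L, dim = d)
        v[shifted] <- 1L
    }
    if (dilateErode != 0L) {
        for (k in seq_len(abs(dilateErode)))
            v <- morphStep(v, dilate = dilateErode > 0L)
    }
    if (flipRate > 0) {
        if (is.null(seed))
            stop("a seed is required when flipRate > 0")
        inner <- which(v == 1L & !interiorVoxels(v))
        dil <- morphStep(v, dilate = TRUE)
        outer_ <- which(dil == 1L & v == 0L)
        withLocalSeed(seed, {
            drop <- inner[stats::runif(length(inner)) < flipRate]
            add <- outer_[stats::runif(length(outer_)) < flipRate]
        })
        v[drop] <- 0L
        v[add] <- 1L
    }
    MaskVolume(v, spacing = mask@spacing,
               metadata = c(mask@metadata,
                            list(perturbed = list(translation = tr,
                                                  dilateErode = dilateErode,
                                                  flipRate = flipRate,
                                                  seed = seed))))
}

#' Generate a synthetic cohort of mask pairs with a manifest
#'
#' Writes `n` ground-truth tube phantoms with randomized size, taper,
#' orientation drift and centerline wander (lesions spanning 3-15
#' slices at CT-like spacing, mimicking axial acquisitions with 5 mm
#' slice thickness), plus a perturbed prediction for each (random
#' translation, dilation/erosion and boundary flips), and a manifest
#' CSV with round-robin fold assignment. Everything is a pure function
#' of `seed`: reruns produce byte-identical files. Manifest paths are
#' relative to the manifest, so the cohort directory is relocatable.
#'
#' @param n number of patients (>= 1).
#' @param dir output directory (created if missing).
#' @param seed integer master seed.
#' @param nFolds number of cross-validation folds (default 4).
#' @param spacing voxel spacing mm (default `(0.98, 0.98, 5)`).
#' @param dim in-plane lattice size (default 96 x 96).
#' @param errorProfile list of perturbation ranges: `maxShiftXY`,
#'   `maxShiftZ` (voxels), `flipRateRange` (length 2), `dilateErodeSet`
#'   (integer choices).
#' @return Path to the manifest CSV, invisibly.
#' @examples
#' dir <- tempfile("cohort")
#' mf <- makeCohort(4, dir, seed = 42)
#' nrow(readManifest(mf))  # 4
#' @export
makeCohort <- function(n, dir, seed, nFolds = 4L,
                       spacing = c(0.98, 0.98, 5), dim = c(96L, 96L),
                       errorProfile = list(maxShiftXY = 2L, maxShiftZ = 1L,
                                           flipRateRange = c(0, 0.15),
                                           dilateErodeSet = c(-1L, 0L, 0L, 1L))) {
    stopifnot(n >= 1)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ep <- errorProfile
    center <- (dim - 1) * spacing[1:2] / 2
    rows <- withLocalSeed(seed, lapply(seq_len(n), function(i) {
        nSlices <- sample(3:15, 1L)
        aBase <- stats::runif(1, 6, 16)
        aspect <- stats::runif(1, 1.3, 2.5)
        phi0 <- stats::runif(1, -90, 90)
        drift <- stats::runif(1, -5, 5)         # degrees per slice
        taper <- stats::runif(1, 0.5, 1)        # end-to-end size factor
        wander <- stats::runif(2, -0.5, 0.5)    # mm centerline drift/slice
        k <- seq_len(nSlices)
        scale <- 1 - (1 - taper) * abs(k - (nSlices + 1) / 2) /
            ((nSlices - 1) / 2)
        sp <- data.frame(slice = k + 1L,
                         a = pmax(aBase * scale, 2),
                         b = pmax(aBase / aspect * scale, 1.2),
                         phi = phi0 + drift * (k - 1),
                         cx = center[1] + wander[1] * (k - 1),
                         cy = center[2] + wander[2] * (k - 1))
        gt <- makeTubePhantom(sp, dim = c(dim, nSlices + 2L),
                              spacing = spacing)
        pred <- perturbMask(
            gt,
            translation = c(sample(-ep$maxShiftXY:ep$maxShiftXY, 2L,
                                   replace = TRUE),
                            sample(-ep$maxShiftZ:ep$maxShiftZ, 1L)),
            dilateErode = sample(ep$dilateErodeSet, 1L),
            flipRate = stats::runif(1, ep$flipRateRange[1],
                                    ep$flipRateRange[2]),
            seed = sample.int(2^30, 1L))
        gtFile <- sprintf("gt_%04d.nii.gz", i)
        predFile <- sprintf("pred_%04d.nii.gz", i)
        writeMask(gt, file.path(dir, gtFile))
        writeMask(pred, file.path(dir, predFile))
        data.frame(patient_id = sprintf("P%04d", i),
                   predicted_mask_path = predFile,
                   ground_truth_mask_path = gtFile,
                   fold = ((i - 1L) %% nFolds) + 1L)
    }))
    manifest <- do.call(rbind, rows)
    manifestPath <- file.path(dir, "manifest.csv")
    utils::write.csv(manifest, manifestPath, row.names = FALSE,
                     quote = FALSE)
    invisible(manifestPath)
}
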