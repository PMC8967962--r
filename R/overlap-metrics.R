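checkSameGeometry <- function(pred, gt) {
    dp <- dim(pred@voxels); dg <- dim(gt@voxels)
    if (!identical(dp, dg))
        stop("lattice shapes differ: predicted ",
             paste(dp, collapse = "x"), " vs ground truth ",
             paste(dg, collapse = "x"))
    if (!isTRUE(all.equal(pred@spacing, gt@spacing)))
        stop("voxel spacings differ: predicted (",
             paste(format(pred@spacing), collapse = ", "),
             ") vs ground truth (",
             paste(format(gt@spacing), collapse = ", "), ")")
    invisible(TRUE)
}

#' Voxel-wise confusion counts between two masks
#'
#' @param pred,gt [MaskVolume-class] objects on identical lattices with
#'   identical spacing; `pred` is the prediction, `gt` the reference.
#' @return list of class `"ConfusionCounts"` with integer elements `TP`
#'   (voxels foreground in both), `FP` (predicted only), `FN` (reference
#'   only). TN is never needed by the downstream metrics.
#' @export
confusionCounts <- function(pred, gt) {
    checkSameGeometry(pred, gt)
    p <- pred@voxels; g <- gt@voxels
    tp <- sum(p == 1L & g == 1L)
    structure(list(TP = tp, FP = sum(p) - tp, FN = sum(g) - tp),
              class = "ConfusionCounts")
}

#' Dice similarity coefficient
#'
#' `DSC = 2 TP / (2 TP + FP + FN)`, the spatial overlap between
#' predicted and reference foreground, in `[0, 1]`.
#'
#' @param counts a `"ConfusionCounts"` list from [confusionCounts()].
#' @return DSC value. Both masks empty (TP = FP = FN = 0) is an error,
#'   never a silent 0.
#' @export
diceCoefficient <- function(counts) {
    stopifnot(inherits(counts, "ConfusionCounts"))
    denom <- 2 * counts$TP + counts$FP + counts$FN
    if (denom == 0)
        stop("DSC undefined: both masks are empty")
    2 * counts$TP / denom
}

#' Surface voxel centers of a mask
#'
#' A foreground voxel belongs to the surface when at least one of its
#' six face neighbors is background; voxels on the lattice border count
#' the outside as background. This is the contour set the Hausdorff and
#' mean surface distances are computed over.
#'
#' @param mask a nonempty [MaskVolume-class].
#' @return numeric matrix, one row per surface voxel, columns
#'   `x`, `y`, `z` in mm (voxel-center coordinates).
#' @export
surfacePoints <- function(mask) {
    stopifnot(methods::is(mask, "MaskVolume"))
    v <- mask@voxels
    if (sum(v) == 0L)
        stop("mask has no foreground voxels")
    idx <- which(v == 1L & !interiorVoxels(v), arr.ind = TRUE)
    pts <- voxelToMM(idx, mask@spacing)
    colnames(pts) <- c("x", "y", "z")
    pts
}

# logical array: foreground voxels all of whose 6 face neighbors are
# foreground (computed by shifting a zero-padded copy along each axis)
interiorVoxels <- function(v) {
    d <- dim(v)
    p <- array(0L, d + 2L)
    p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
    core <- function(dx, dy, dz)
        p[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy, (2:(d[3] + 1)) + dz]
    v == 1L &
        core(-1, 0, 0) & core(1, 0, 0) &
        core(0, -1, 0) & core(0, 1, 0) &
        core(0, 0, -1) & core(0, 0, 1)
}

# for each row of P, the minimum Euclidean distance to any row of G,
# computed blockwise from the |p|^2 + |g|^2 - 2 p.g expansion
minDistToSet <- function(P, G, block = 512L) {
    g2 <- rowSums(G * G)
    out <- numeric(nrow(P))
    for (start in seq(1L, nrow(P), by = block)) {
        ii <- start:min(start + block - 1L, nrow(P))
        Pb <- P[ii, , drop = FALSE]
        d2 <- outer(rowSums(Pb * Pb), g2, "+") - 2 * Pb %*% t(G)
        out[ii] <- sqrt(pmax(apply(d2, 1L, min), 0))
    }
    out
}

#' Hausdorff distance between two surface point sets
#'
#' The full (not 95th-percentile) symmetric Hausdorff distance: the
#' larger of the two directed maxima of point-to-set Euclidean
#' distances, in mm.
#'
#' @param P,G matrices of mm coordinates from [surfacePoints()], both
#'   nonempty.
#' @return Hausdorff distance in mm.
#' @export
hausdorffDistance <- function(P, G) {
    if (!nrow(P) || !nrow(G))
        stop("Hausdorff distance undefined for an empty surface set")
    max(max(minDistToSet(P, G)), max(minDistToSet(G, P)))
}

#' Mean surface distance between two surface point sets
#'
#' Symmetrized: half the sum of the two directed mean nearest-neighbor
#' distances,
#' `MSD = (mean_p min_g d(p, g) + mean_g min_p d(g, p)) / 2`, in mm.
#'
#' @inheritParams hausdorffDistance
#' @return Mean surface distance in mm.
#' @export
meanSurfaceDistance <- function(P, G) {
    if (!nrow(P) || !nrow(G))
        stop("mean surface distance undefined for an empty surface set")
    (mean(minDistToSet(P, G)) + mean(minDistToSet(G, P))) / 2
}

#' Conformity index (intersection over union)
#'
#' `CI = |A intersect B| / |A union B|`; 1 means complete agreement.
#'
#' @inheritParams confusionCounts
#' @return CI in `[0, 1]`. Both masks empty is an error.
#' @export
conformityIndex <- function(pred, gt) {
    cc <- confusionCounts(pred, gt)
    union <- cc$TP + cc$FP + cc$FN
    if (union == 0)
        stop("conformity index undefined: both masks are empty")
    cc$TP / union
}

#' Degree of inclusion in both directions
#'
#' `DI(A in B) = |A intersect B| / |A|`: the fraction of A contained in
#' B. With A the predicted and B the reference volume,
#' `1 - DI(pred in gt)` is the fraction of the plan that would be
#' unnecessarily irradiated and `1 - DI(gt in pred)` the fraction of
#' tumor the plan would miss.
#'
#' @inheritParams confusionCounts
#' @return list with `predInGT` and `gtInPred`, both in `[0, 1]`.
#' @export
degreeOfInclusion <- function(pred, gt) {
    cc <- confusionCounts(pred, gt)
    nPred <- cc$TP + cc$FP
    nGt <- cc$TP + cc$FN
    if (nPred == 0)
        stop("degree of inclusion undefined: predicted mask is empty")
    if (nGt == 0)
        stop("degree of inclusion undefined: ground-truth mask is empty")
    list(predInGT = cc$TP / nPred, gtInPred = cc$TP / nGt)
}

#' Center-of-mass displacement between two masks
#'
#' The center of mass is the unweighted mean of the foreground
#' voxel-center mm coordinates. Returns COM(pred) - COM(gt), signed,
#' decomposed into left-right (x), anterior-posterior (y) and
#' cranial-caudal (z) components.
#'
#' @inheritParams confusionCounts
#' @return Named numeric vector `(lr, ap, cc)` in mm.
#' @export
centerOfMassShift <- function(pred, gt) {
    checkSameGeometry(pred, gt)
    if (sum(pred@voxels) == 0L) stop("predicted mask has no foreground")
    if (sum(gt@voxels) == 0L) stop("ground-truth mask has no foreground")
    com <- function(m)
        colMeans(voxelToMM(which(m@voxels == 1L, arr.ind = TRUE), m@spacing))
    d <- com(pred) - com(gt)
    stats::setNames(as.numeric(d), c("lr", "ap", "cc"))
}

#' Motion vector magnitude
#'
#' `MV = sqrt(LR^2 + AP^2 + CC^2)`, the Euclidean norm of the
#' center-of-mass displacement.
#'
#' @param lr,ap,cc signed displacement components in mm.
#' @return MV in mm.
#' @examples
#' motionVector(2, 3, 6)  # 7
#' @export
motionVector <- function(lr, ap, cc) {
    stopifnot(is.finite(lr), is.finite(ap), is.finite(cc))
    sqrt(lr^2 + ap^2 + cc^2)
}

#' Compare a predicted mask against its ground truth
#'
#' Computes every pairwise metric for one mask pair: DSC, Hausdorff and
#' mean surface distance over 6-neighborhood boundary voxels,
#' conformity index, both degrees of inclusion, and the signed
#' center-of-mass displacement with its motion-vector norm. When the
#' predicted mask is empty the overlap fractions are 0 and the
#' inclusion/distance/displacement fields `NA` (flagged via
#' `predEmpty`), never silently zeroed.
#'
#' @param pred,gt [MaskVolume-class] objects on the same lattice;
#'   `gt` must be nonempty.
#' @return An [OverlapReport-class].
#' @examples
#' gt <- makeEllipsoidMask(c(8, 6, 10), dim = c(32, 32, 12),
#'                         spacing = c(1, 1, 2))
#' pred <- perturbMask(gt, translation = c(2, 0, 0))
#' metricValues(compareMasks(pred, gt))
#' @export
compareMasks <- function(pred, gt) {
    checkSameGeometry(pred, gt)
    if (sum(gt@voxels) == 0L)
        stop("ground-truth mask has no foreground voxels")
    cc <- confusionCounts(pred, gt)
    counts <- c(TP = cc$TP, FP = cc$FP, FN = cc$FN)
    if (sum(pred@voxels) == 0L) {
        return(methods::new("OverlapReport",
            dsc = 0, hd = NA_real_, msd = NA_real_, ci = 0,
            diPredInGT = NA_real_, diGTInPred = NA_real_,
            lr = NA_real_, ap = NA_real_, cc = NA_real_, mv = NA_real_,
            counts = counts, predEmpty = TRUE))
    }
    di <- degreeOfInclusion(pred, gt)
    P <- surfacePoints(pred)
    G <- surfacePoints(gt)
    shift <- centerOfMassShift(pred, gt)
    union <- cc$TP + cc$FP + cc$FN
    methods::new("OverlapReport",
        dsc = 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN),
        hd = hausdorffDistance(P, G),
        msd = meanSurfaceDistance(P, G),
        ci = cc$TP / union,
        diPredInGT = di$predInGT, diGTInPred = di$gtInPred,
        lr = shift[["lr"]], ap = shift[["ap"]], cc = shift[["cc"]],
        mv = motionVector(shift[["lr"]], shift[["ap"]], shift[["cc"]]),
        counts = counts, predEmpty = FALSE)
}

#' @rdname metricValues
#' @export
setMethod("metricValues", "OverlapReport", function(x) {
    c(dsc = x@dsc, hd_mm = x@hd, msd_mm = x@msd, ci = x@ci,
      di_pred_in_gt = x@diPredInGT, di_gt_in_pred = x@diGTInPred,
      lr_mm = x@lr, ap_mm = x@ap, cc_mm = x@cc, mv_mm = x@mv)
})

#' @describeIn metricValues one-row data.frame of the same metrics.
#' @param row.names,optional,... ignored; present for S3 compatibility.
#' @export
as.data.frame.OverlapReport <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
    as.data.frame(as.list(metricValues(x)))
}

setMethod("show", "OverlapReport", function(object) {
    v <- metricValues(object)
    cat("OverlapReport",
        if (object@predEmpty) "(predicted mask empty)", "\n")
    cat(sprintf("  DSC %.4f  CI %.4f  DI(pred in gt) %.4f  DI(gt in pred) %.4f\n",
                v["dsc"], v["ci"], v["di_pred_in_gt"], v["di_gt_in_pred"]))
    cat(sprintf("  HD %.3f mm  MSD %.3f mm  MV %.3f mm (LR %.2f, AP %.2f, CC %.2f)\n",
                v["hd_mm"], v["msd_mm"], v["mv_mm"],
                v["lr_mm"], v["ap_mm"], v["cc_mm"]))
})
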