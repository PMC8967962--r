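cube <- function(lo, hi, dim = c(10, 10, 10), spacing = c(1, 1, 1)) {
    v <- array(0L, dim = dim)
    v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
    MaskVolume(v, spacing = spacing)
}

test_that("confusion counts match exhaustive enumeration", {
    a <- cube(c(3, 3, 3), c(6, 6, 6))
    cc <- confusionCounts(a, a)
    expect_equal(c(cc$TP, cc$FP, cc$FN), c(64, 0, 0))

    b <- cube(c(4, 3, 3), c(7, 6, 6))  # same 4^3 cube shifted 1 in x
    cc2 <- confusionCounts(b, a)
    expect_equal(c(cc2$TP, cc2$FP, cc2$FN), c(48, 16, 16))
    want <- oracleCounts(maskVoxels(b), maskVoxels(a))
    expect_equal(cc2[c("TP", "FP", "FN")], want)

    disj <- confusionCounts(cube(c(1, 1, 1), c(2, 3, 5)),
                            cube(c(7, 7, 7), c(8, 8, 9)))
    expect_equal(c(disj$TP, disj$FP, disj$FN), c(0, 30, 12))

    expect_error(confusionCounts(a, cube(c(1, 1, 1), c(2, 2, 2),
                                         dim = c(8, 8, 8))),
                 "10x10x10.*8x8x8")
    expect_error(confusionCounts(a, cube(c(3, 3, 3), c(6, 6, 6),
                                         spacing = c(1, 1, 5))),
                 "spacing")
})

test_that("Dice follows 2TP/(2TP+FP+FN) and rejects the empty-empty case", {
    expect_equal(diceCoefficient(structure(list(TP = 50, FP = 10, FN = 10),
                                           class = "ConfusionCounts")),
                 50 / 60)
    a <- cube(c(3, 3, 3), c(6, 6, 6))
    expect_equal(diceCoefficient(confusionCounts(a, a)), 1)
    empty <- MaskVolume(array(0L, dim = c(10, 10, 10)))
    expect_equal(diceCoefficient(confusionCounts(empty, a)), 0)
    expect_error(diceCoefficient(confusionCounts(empty, empty)),
                 "both masks are empty")
})

test_that("surface extraction keeps 6-neighborhood boundary voxels", {
    v <- array(0L, dim = c(5, 5, 5)); v[3, 3, 3] <- 1L
    expect_equal(surfacePoints(MaskVolume(v)),
                 matrix(c(2, 2, 2), 1, dimnames = list(NULL,
                                                       c("x", "y", "z"))))
    # solid 3x3x3 cube: all but the center voxel are surface
    expect_equal(nrow(surfacePoints(cube(c(4, 4, 4), c(6, 6, 6)))), 26L)
    # 1-voxel-thick plate: every voxel is surface
    plate <- cube(c(2, 2, 5), c(9, 9, 5))
    expect_equal(nrow(surfacePoints(plate)), 64L)
    expect_error(surfacePoints(MaskVolume(array(0L, dim = c(3, 3, 3)))),
                 "no foreground")
})

test_that("surface distances match the all-pairs oracle", {
    P1 <- matrix(c(0, 0, 0), 1); G1 <- matrix(c(0, 0, 3), 1)
    expect_equal(hausdorffDistance(P1, G1), 3)
    expect_equal(meanSurfaceDistance(P1, G1), 3)
    expect_equal(hausdorffDistance(P1, P1), 0)

    # two 4^3 cubes offset 2 voxels in x at unit spacing
    a <- surfacePoints(cube(c(3, 3, 3), c(6, 6, 6)))
    b <- surfacePoints(cube(c(5, 3, 3), c(8, 6, 6)))
    expect_equal(hausdorffDistance(a, b), 2)
    expect_lt(abs(meanSurfaceDistance(a, b) - oracleMSD(a, b)), 1e-10)

    for (seed in c(11, 12)) {
        p <- surfacePoints(randomBlobMask(seed))
        g <- surfacePoints(randomBlobMask(seed + 50))
        expect_lt(abs(hausdorffDistance(p, g) - oracleHausdorff(p, g)),
                  1e-10)
        expect_lt(abs(meanSurfaceDistance(p, g) - oracleMSD(p, g)), 1e-10)
        # symmetry and the HD >= MSD bound
        expect_equal(hausdorffDistance(p, g), hausdorffDistance(g, p))
        expect_equal(meanSurfaceDistance(p, g), meanSurfaceDistance(g, p))
        expect_gte(hausdorffDistance(p, g), meanSurfaceDistance(p, g))
    }
})

test_that("overlap-fraction identities hold in exact count arithmetic", {
    a <- cube(c(3, 3, 3), c(6, 6, 6))
    expect_equal(conformityIndex(a, a), 1)
    expect_equal(conformityIndex(cube(c(1, 1, 1), c(2, 2, 2)),
                                 cube(c(7, 7, 7), c(8, 8, 8))), 0)

    # subset: pred inside gt
    inner <- cube(c(4, 4, 4), c(5, 5, 5))  # 8 voxels inside the 64 cube
    di <- degreeOfInclusion(inner, a)
    expect_equal(di$predInGT, 1)
    expect_equal(di$gtInPred, 8 / 64)

    for (seed in 21:25) {
        p <- randomBlobMask(seed)
        g <- randomBlobMask(seed + 100)
        ci <- conformityIndex(p, g)
        if (ci == 0) next
        dsc <- diceCoefficient(confusionCounts(p, g))
        di <- degreeOfInclusion(p, g)
        expect_equal(dsc, 2 * ci / (1 + ci), tolerance = 1e-12)
        expect_equal(1 / ci, 1 / di$predInGT + 1 / di$gtInPred - 1,
                     tolerance = 1e-12)
        # DI is transposed, CI symmetric, under swapping the pair
        rev <- degreeOfInclusion(g, p)
        expect_equal(di$predInGT, rev$gtInPred)
        expect_equal(conformityIndex(g, p), ci)
    }

    empty <- MaskVolume(array(0L, dim = c(10, 10, 10)))
    expect_error(conformityIndex(empty, empty), "both masks are empty")
    expect_error(degreeOfInclusion(empty, a), "predicted mask is empty")
    expect_error(degreeOfInclusion(a, empty), "ground-truth mask is empty")
})

test_that("center-of-mass shift is signed, spacing-aware and exact", {
    a <- cube(c(3, 3, 2), c(6, 6, 5), dim = c(10, 12, 14))
    expect_equal(centerOfMassShift(a, a), c(lr = 0, ap = 0, cc = 0))
    b <- perturbMask(a, translation = c(2, 3, 6))
    expect_equal(centerOfMassShift(b, a), c(lr = 2, ap = 3, cc = 6))
    # 1-voxel z shift at 5 mm slice thickness
    a5 <- cube(c(3, 3, 2), c(6, 6, 5), spacing = c(1, 1, 5))
    b5 <- perturbMask(a5, translation = c(0, 0, 1))
    expect_equal(centerOfMassShift(b5, a5), c(lr = 0, ap = 0, cc = 5))

    expect_equal(motionVector(0, 0, 0), 0)
    expect_equal(motionVector(2, 3, 6), 7)
    expect_equal(motionVector(-2, 3, -6), 7)
})

test_that("compareMasks aggregates all metrics consistently", {
    gt <- makeEllipsoidMask(c(8, 6, 8), dim = c(34, 34, 18),
                            spacing = c(1, 1, 2))
    same <- compareMasks(gt, gt)
    v <- metricValues(same)
    expect_equal(unname(v[c("dsc", "ci", "di_pred_in_gt",
                            "di_gt_in_pred")]), c(1, 1, 1, 1))
    expect_equal(unname(v[c("hd_mm", "msd_mm", "mv_mm")]), c(0, 0, 0))

    moved <- perturbMask(gt, translation = c(2, 1, 3))
    expect_equal(metricValues(compareMasks(moved, gt))[["mv_mm"]],
                 sqrt(2^2 + 1^2 + 6^2))

    # independent recomputation of every field on a perturbed pair
    pred <- perturbMask(gt, translation = c(1, -1, 0), dilateErode = 1L,
                        flipRate = 0.1, seed = 11)
    rep <- compareMasks(pred, gt)
    cc <- oracleCounts(maskVoxels(pred), maskVoxels(gt))
    P <- surfacePoints(pred); G <- surfacePoints(gt)
    expect_equal(rep@counts, c(TP = cc$TP, FP = cc$FP, FN = cc$FN))
    v <- metricValues(rep)
    expect_equal(v[["dsc"]], 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN))
    expect_equal(v[["ci"]], cc$TP / (cc$TP + cc$FP + cc$FN))
    expect_lt(abs(v[["hd_mm"]] - oracleHausdorff(P, G)), 1e-10)
    expect_lt(abs(v[["msd_mm"]] - oracleMSD(P, G)), 1e-10)
    expect_equal(v[["mv_mm"]],
                 sqrt(v[["lr_mm"]]^2 + v[["ap_mm"]]^2 + v[["cc_mm"]]^2))

    # empty prediction: flagged, not silently zeroed
    empty <- MaskVolume(array(0L, dim = dim(gt)), spacing = c(1, 1, 2))
    er <- compareMasks(empty, gt)
    expect_true(er@predEmpty)
    expect_equal(metricValues(er)[["dsc"]], 0)
    expect_true(is.na(metricValues(er)[["hd_mm"]]))
    expect_error(compareMasks(gt, empty), "ground-truth")
})
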