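test_that("Pearson correlation matches the textbook formula", {
    expect_equal(pearsonCorrelation(c(1, 2, 3), c(2, 4, 6))$r, 1)
    expect_equal(pearsonCorrelation(c(1, 2, 3), c(2, 4, 6))$rSquared, 1)
    expect_equal(pearsonCorrelation(c(1, 2, 3), c(3, 2, 1))$r, -1)

    set.seed(3)
    x <- runif(41, 100, 5000)
    y <- 0.9 * x + rnorm(41, sd = 0.1 * sd(x))
    got <- pearsonCorrelation(x, y)
    want <- oraclePearson(x, y)
    expect_lt(abs(got$r - want$r), 1e-10)
    expect_lt(abs(got$p - want$p), 1e-10)
    expect_equal(got$rSquared, got$r^2)

    expect_error(pearsonCorrelation(rep(2, 5), 1:5), "constant")
    expect_error(pearsonCorrelation(1:2, 2:3), "at least 3")
})

test_that("paired t-test works on differences, with zero-variance guard", {
    x <- c(10, 20, 30, 40)
    res <- pairedTTest(x, x + c(1, -1, 1, -1))
    expect_equal(res$t, 0)
    expect_equal(res$p, 1)
    expect_error(pairedTTest(x, x), "zero variance")

    set.seed(5)
    x <- rnorm(100, 50, 10)
    y <- x + 0.5 * sd(x) + rnorm(100, sd = 2)
    got <- pairedTTest(x, y)
    want <- oraclePairedT(x, y)
    expect_lt(abs(got$t - want$t), 1e-10)
    expect_lt(abs(got$p - want$p), 1e-10)
    expect_equal(got$df, 99)
})

test_that("one-sample t-test matches the closed form and the paired identity", {
    expect_equal(oneSampleTTest(c(1, -1, 1, -1), 0)$t, 0)
    expect_equal(oneSampleTTest(c(1, 2, 3), 2)$p, 1)
    expect_error(oneSampleTTest(rep(3, 10)), "zero variance")

    set.seed(9)
    v <- rnorm(41, 0.3, 1)
    got <- oneSampleTTest(v, 0)
    want <- oracleOneSampleT(v, 0)
    expect_lt(abs(got$t - want$t), 1e-10)
    expect_lt(abs(got$p - want$p), 1e-10)

    # paired_t(x, y) is identically one_sample_t(y - x, 0)
    set.seed(10)
    x <- rnorm(30); y <- x + rnorm(30, 0.2)
    expect_equal(pairedTTest(x, y)$t, oneSampleTTest(y - x, 0)$t,
                 tolerance = 1e-12)
})

test_that("summaries use sample SD and interpolated quartiles", {
    s <- summarizeValues(c(1, 2, 3, 4))
    expect_equal(s$mean, 2.5)
    expect_equal(s$median, 2.5)
    expect_equal(s$sd, sd(c(1, 2, 3, 4)))

    sc <- summarizeValues(rep(7, 5))
    expect_equal(sc$sd, 0)
    expect_equal(c(sc$q1, sc$median, sc$q3), c(7, 7, 7))

    set.seed(1)
    v <- runif(164)
    s <- summarizeValues(v)
    expect_lt(abs(s$q1 - oracleQuantile(v, 0.25)), 1e-12)
    expect_lt(abs(s$median - oracleQuantile(v, 0.5)), 1e-12)
    expect_lt(abs(s$q3 - oracleQuantile(v, 0.75)), 1e-12)
    expect_true(s$q1 <= s$median && s$median <= s$q3)
})

test_that("calibration line is OLS of predicted on reference and inverts", {
    line <- calibrateGTV(c(1, 2, 3, 4), c(2, 4, 6, 8))
    expect_equal(line$slope, 2, tolerance = 1e-12)
    expect_equal(line$intercept, 0, tolerance = 1e-12)
    expect_equal(invertCalibration(line, 10), 5)

    line2 <- calibrateGTV(c(1, 2, 5), c(4, 5, 8))  # y = x + 3
    expect_equal(line2$slope, 1, tolerance = 1e-12)
    expect_equal(invertCalibration(line2, 3), 0, tolerance = 1e-12)

    # exact round trip through an arbitrary point
    xStar <- 1234.5
    expect_equal(invertCalibration(line2, xStar + 3), xStar,
                 tolerance = 1e-9)

    set.seed(13)
    x <- runif(164, 500, 30000)
    y <- 0.95 * x + rnorm(164, sd = 1500)
    got <- calibrateGTV(x, y)
    want <- oracleOLS(x, y)
    expect_lt(abs(got$slope - want$slope), 1e-10)
    expect_lt(abs(got$intercept - want$intercept), 1e-8)
    expect_lt(abs(got$slope - 0.95), 3 * want$seSlope)

    expect_error(calibrateGTV(rep(1, 5), 1:5), "constant")
    expect_error(invertCalibration(structure(list(slope = 0, intercept = 1),
                                             class = "CalibrationLine"), 2),
                 "zero slope")
})

test_that("cohort report aggregates per-patient metrics faithfully", {
    dir <- withr::local_tempdir()
    mf <- readManifest(makeCohort(8, dir, seed = 42))
    rep <- suppressWarnings(cohortReport(mf))
    expect_equal(nrow(rep$perPatient), 8L)
    expect_equal(rep$nExcluded, 0L)

    # every pooled summary equals recomputation from the patient table
    pp <- rep$perPatient
    expect_equal(rep$overall$ci$median, median(pp$ci))
    expect_equal(rep$overall$dsc$mean, mean(pp$dsc))
    expect_equal(rep$overall$mv$sd, sd(pp$mv_mm))
    expect_equal(rep$overall$gtv_etecim$pearson$r,
                 cor(pp$gtv_gt_etecim, pp$gtv_pred_etecim))
    expect_equal(rep$overall$position$lr$t,
                 oracleOneSampleT(pp$lr_mm, 0)$t, tolerance = 1e-10)
    expect_equal(rep$overall$di$paired_t$t,
                 oraclePairedT(pp$di_pred_in_gt, pp$di_gt_in_pred)$t,
                 tolerance = 1e-10)
})

test_that("perfect-prediction cohorts flag degenerate tests, never fake them", {
    dir <- withr::local_tempdir()
    mf <- readManifest(makeCohort(4, dir, seed = 7,
                                  errorProfile = list(
                                      maxShiftXY = 0L, maxShiftZ = 0L,
                                      flipRateRange = c(0, 0),
                                      dilateErodeSet = 0L)))
    rep <- cohortReport(mf)
    expect_true(all(rep$perPatient$dsc == 1))
    expect_true(all(rep$perPatient$mv_mm == 0))
    # paired differences and displacements all zero: degenerate variance
    expect_false(is.null(rep$overall$gtv_etecim$paired_t$error))
    expect_false(is.null(rep$overall$position$lr$error))
})

test_that("unreadable rows are excluded and counted, not silently dropped", {
    dir <- withr::local_tempdir()
    mfPath <- makeCohort(3, dir, seed = 1)
    unlink(file.path(dir, "pred_0002.nii.gz"))
    rep <- suppressWarnings(cohortReport(readManifest(mfPath)))
    expect_equal(rep$nExcluded, 1L)
    expect_equal(rep$excluded$patient_id, "P0002")
    expect_match(rep$excluded$error, "does not exist")
    expect_equal(nrow(rep$perPatient), 2L)
})
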