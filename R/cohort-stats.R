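checkSeries <- function(x, y, minN = 3L) {
    if (length(x) != length(y))
        stop("series lengths differ: ", length(x), " vs ", length(y))
    if (length(x) < minN)
        stop("series too short: need at least ", minN, " pairs")
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("series contain non-finite values")
    invisible(TRUE)
}

#' Pearson correlation between paired series
#'
#' Sample Pearson r with its square (the decision coefficient R^2
#' reported for predicted-vs-reference GTV scatter) and the two-sided
#' p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, length >= 3, each non-constant.
#' @return list with `r`, `rSquared`, `p`, `n`.
#' @export
pearsonCorrelation <- function(x, y) {
    checkSeries(x, y, 3L)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("Pearson correlation undefined for a constant series")
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate)
    list(r = r, rSquared = r^2, p = ct$p.value, n = length(x))
}

#' Paired-sample t-test
#'
#' Student's t on the mean of the paired differences `y - x`, two-sided,
#' n - 1 degrees of freedom; used to compare predicted against reference
#' GTVs and the two degrees of inclusion.
#'
#' @param x,y paired numeric vectors, length >= 2; the differences must
#'   have nonzero variance.
#' @return list with `t`, `p`, `meanDiff`, `df`.
#' @export
pairedTTest <- function(x, y) {
    checkSeries(x, y, 2L)
    d <- y - x
    if (stats::sd(d) == 0)
        stop("paired t-test undefined: differences have zero variance")
    tt <- stats::t.test(y, x, paired = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value,
         meanDiff = mean(d), df = unname(tt$parameter))
}

#' One-sample t-test
#'
#' `t = (mean - mu0) / (sd / sqrt(n))`, two-sided, n - 1 degrees of
#' freedom; used to test the signed LR/AP/CC center-of-mass
#' displacements against 0.
#'
#' @param values numeric vector, length >= 2, nonzero variance.
#' @param mu0 null-hypothesis mean (default 0).
#' @return list with `t`, `p`, `mean`, `df`.
#' @export
oneSampleTTest <- function(values, mu0 = 0) {
    if (length(values) < 2L)
        stop("one-sample t-test needs at least 2 values")
    if (any(!is.finite(values)))
        stop("series contains non-finite values")
    if (stats::sd(values) == 0)
        stop("one-sample t-test undefined: values have zero variance")
    tt <- stats::t.test(values, mu = mu0)
    list(t = unname(tt$statistic), p = tt$p.value,
         mean = mean(values), df = unname(tt$parameter))
}

#' Descriptive summary: mean, SD and quartiles
#'
#' Mean, sample standard deviation (n - 1 denominator), median and the
#' lower/upper quartiles by linearly interpolated order statistics
#' (`quantile()` type 7). This is the M +/- SD / quartile layout used
#' for CI, DI and MV cohort tables.
#'
#' @param values numeric vector, length >= 1.
#' @return list with `mean`, `sd`, `median`, `q1`, `q3`, `n`.
#' @export
summarizeValues <- function(values) {
    if (!length(values)) stop("cannot summarize an empty series")
    if (any(!is.finite(values))) stop("series contains non-finite values")
    q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
    list(mean = mean(values),
         sd = if (length(values) > 1L) stats::sd(values) else 0,
         median = q[2], q1 = q[1], q3 = q[3], n = length(values))
}

#' Linear calibration of predicted on reference GTV
#'
#' Ordinary least squares of the predicted values (y) on the reference
#' values (x), matching the predicted-vs-manual scatter orientation.
#' Given a new predicted GTV, the reference value is recovered by
#' algebraic inversion of this line ([invertCalibration()]).
#'
#' @param x reference (ground-truth) values; must not be constant.
#' @param y predicted values, same length as `x` (>= 2).
#' @return list of class `"CalibrationLine"` with `slope`, `intercept`,
#'   `fitDirection = "y-on-x"`, `n`.
#' @export
calibrateGTV <- function(x, y) {
    checkSeries(x, y, 2L)
    if (stats::sd(x) == 0)
        stop("calibration undefined: reference series is constant")
    fit <- stats::lm(y ~ x)
    co <- unname(stats::coef(fit))
    structure(list(slope = co[2], intercept = co[1],
                   fitDirection = "y-on-x", n = length(x)),
              class = "CalibrationLine")
}

#' Recover the reference GTV from a predicted value
#'
#' Inverts the calibration line: `(predicted - intercept) / slope`.
#'
#' @param line a `"CalibrationLine"` from [calibrateGTV()].
#' @param predicted predicted GTV value(s), mm^3.
#' @return Recovered reference GTV value(s), mm^3.
#' @export
invertCalibration <- function(line, predicted) {
    stopifnot(inherits(line, "CalibrationLine"))
    if (line$slope == 0)
        stop("calibration line has zero slope and cannot be inverted")
    (predicted - line$intercept) / line$slope
}

# run one statistic, recording a degenerate/undefined input as a note
# instead of aborting the whole cohort table
tryStat <- function(expr) {
    tryCatch(expr, error = function(e)
        list(error = conditionMessage(e)))
}

statsBlock <- function(pp) {
    list(
        n = nrow(pp),
        gtv_etecim = list(
            pearson = tryStat(pearsonCorrelation(pp$gtv_gt_etecim,
                                                 pp$gtv_pred_etecim)),
            paired_t = tryStat(pairedTTest(pp$gtv_gt_etecim,
                                           pp$gtv_pred_etecim)),
            calibration = tryStat(unclass(
                calibrateGTV(pp$gtv_gt_etecim, pp$gtv_pred_etecim)))),
        gtv_voxel = list(
            pearson = tryStat(pearsonCorrelation(pp$gtv_gt_voxel,
                                                 pp$gtv_pred_voxel)),
            paired_t = tryStat(pairedTTest(pp$gtv_gt_voxel,
                                           pp$gtv_pred_voxel))),
        di = list(
            paired_t = tryStat(pairedTTest(pp$di_pred_in_gt,
                                           pp$di_gt_in_pred)),
            pred_in_gt = tryStat(summarizeValues(pp$di_pred_in_gt)),
            gt_in_pred = tryStat(summarizeValues(pp$di_gt_in_pred))),
        position = list(
            lr = tryStat(oneSampleTTest(pp$lr_mm, 0)),
            ap = tryStat(oneSampleTTest(pp$ap_mm, 0)),
            cc = tryStat(oneSampleTTest(pp$cc_mm, 0))),
        ci = tryStat(summarizeValues(pp$ci)),
        mv = tryStat(summarizeValues(pp$mv_mm)),
        dsc = tryStat(summarizeValues(pp$dsc)),
        hd = tryStat(summarizeValues(pp$hd_mm)),
        msd = tryStat(summarizeValues(pp$msd_mm)))
}

#' Full comparative assessment over a cohort of mask pairs
#'
#' Drives the complete per-patient pipeline over a manifest: loads each
#' predicted/reference pair, computes the overlap report
#' ([compareMasks()]) and both GTV estimates for both masks
#' ([estimateGTV()]), then aggregates per fold and pooled: Pearson
#' correlation and paired t-test of predicted vs reference GTV for both
#' estimators, the OLS calibration line, the paired t-test between the
#' two degrees of inclusion, one-sample t-tests of the signed LR/AP/CC
#' displacements against 0, and quartile summaries of CI, MV, DSC, HD
#' and MSD. Unreadable or geometry-incompatible rows are excluded with
#' their error recorded, never silently dropped; statistics whose
#' preconditions fail (e.g. zero-variance differences when every
#' prediction equals its reference) carry an `error` note instead of a
#' value. The report contains no file paths, so identical cohorts in
#' different directories produce identical reports.
#'
#' @param manifest data.frame from [readManifest()].
#' @return list with `perPatient` (data.frame: patient id, fold, all
#'   metrics, four GTV values), `excluded` (data.frame id/error),
#'   `overall` (stats block), `folds` (named list of stats blocks).
#' @seealso [writeCohortReport()] for JSON serialization.
#' @export
cohortReport <- function(manifest) {
    rows <- list()
    excluded <- list()
    for (i in seq_len(nrow(manifest))) {
        id <- manifest$patient_id[i]
        res <- tryCatch({
            pred <- readMask(manifest$predicted_mask_path[i])
            gt <- readMask(manifest$ground_truth_mask_path[i])
            rep <- compareMasks(pred, gt)
            cbind(data.frame(patient_id = id, fold = manifest$fold[i]),
                  as.data.frame(rep),
                  data.frame(
                      gtv_pred_etecim = gtvValue(estimateGTV(pred, "etecim")),
                      gtv_gt_etecim = gtvValue(estimateGTV(gt, "etecim")),
                      gtv_pred_voxel = gtvValue(estimateGTV(pred, "voxel_sum")),
                      gtv_gt_voxel = gtvValue(estimateGTV(gt, "voxel_sum"))))
        }, error = function(e)
            structure(conditionMessage(e), class = "rowError"))
        if (inherits(res, "rowError")) {
            excluded[[length(excluded) + 1L]] <-
                data.frame(patient_id = id, error = as.character(res))
        } else {
            rows[[length(rows) + 1L]] <- res
        }
    }
    perPatient <- if (length(rows)) do.call(rbind, rows) else
        data.frame(patient_id = character())
    excluded <- if (length(excluded)) do.call(rbind, excluded) else
        data.frame(patient_id = character(), error = character())
    folds <- list()
    if (nrow(perPatient) && any(!is.na(perPatient$fold))) {
        for (f in sort(unique(perPatient$fold))) {
            folds[[paste0("fold_", f)]] <-
                statsBlock(perPatient[perPatient$fold == f, , drop = FALSE])
        }
    }
    list(perPatient = perPatient, excluded = excluded,
         nExcluded = nrow(excluded),
         overall = if (nrow(perPatient)) statsBlock(perPatient) else NULL,
         folds = folds)
}

#' Serialize a cohort report to JSON
#'
#' Writes the full report (per-patient table, exclusions, per-fold and
#' pooled statistics) as pretty-printed JSON with full numeric
#' precision. Output is deterministic: identical reports serialize to
#' byte-identical files.
#'
#' @param report list from [cohortReport()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCohortReport <- function(report, path) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    invisible(path)
}
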