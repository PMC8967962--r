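# Independent brute-force oracles. These deliberately avoid the code
# paths of the package: plain double loops and textbook formulas only.

# central second moments of a 2-D 0/1 matrix by explicit double loop
oracleMoments <- function(sl, sx = 1, sy = 1) {
    xs <- c(); ys <- c()
    for (i in seq_len(nrow(sl)))
        for (j in seq_len(ncol(sl)))
            if (sl[i, j] == 1) {
                xs <- c(xs, (i - 1) * sx)
                ys <- c(ys, (j - 1) * sy)
            }
    cx <- mean(xs); cy <- mean(ys)
    list(N = length(xs), cx = cx, cy = cy,
         A = sum((xs - cx)^2), B = sum((ys - cy)^2),
         H = sum((xs - cx) * (ys - cy)))
}

# all-pairs quadratic-time directed min distances
oracleMinDists <- function(P, G) {
    vapply(seq_len(nrow(P)), function(i) {
        best <- Inf
        for (j in seq_len(nrow(G)))
            best <- min(best, sqrt(sum((P[i, ] - G[j, ])^2)))
        best
    }, numeric(1))
}

oracleHausdorff <- function(P, G)
    max(max(oracleMinDists(P, G)), max(oracleMinDists(G, P)))

oracleMSD <- function(P, G)
    (mean(oracleMinDists(P, G)) + mean(oracleMinDists(G, P))) / 2

# exhaustive voxel-set counts on two 0/1 arrays
oracleCounts <- function(p, g) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(p)) {
        if (p[i] == 1 && g[i] == 1) tp <- tp + 1L
        else if (p[i] == 1) fp <- fp + 1L
        else if (g[i] == 1) fn <- fn + 1L
    }
    list(TP = tp, FP = fp, FN = fn)
}

# textbook statistics (explicit formulas, no stats:: test functions)
oraclePearson <- function(x, y) {
    n <- length(x)
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

oracleOneSampleT <- function(v, mu0 = 0) {
    n <- length(v)
    s <- sqrt(sum((v - mean(v))^2) / (n - 1))
    t <- (mean(v) - mu0) / (s / sqrt(n))
    list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

oraclePairedT <- function(x, y) oracleOneSampleT(y - x, 0)

# linearly interpolated quantile from first principles (sort + lerp)
oracleQuantile <- function(v, p) {
    s <- sort(v)
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
}

# OLS slope/intercept and the slope's standard error, closed form
oracleOLS <- function(x, y) {
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(x)
    resid <- y - intercept - slope * x
    se <- sqrt(sum(resid^2) / (n - 2) / sxx)
    list(slope = slope, intercept = intercept, seSlope = se)
}

# smallest angular separation modulo 180 degrees
angDiff180 <- function(t1, t2) {
    d <- abs(t1 - t2) %% 180
    min(d, 180 - d)
}

# rasterize one rotated ellipse slice as a bare matrix (test-side copy,
# independent of the package generator)
rasterEllipseMatrix <- function(nx, ny, a, b, phiDeg, cx, cy,
                                sx = 1, sy = 1) {
    m <- matrix(0L, nx, ny)
    co <- cos(phiDeg * pi / 180); si <- sin(phiDeg * pi / 180)
    for (i in seq_len(nx))
        for (j in seq_len(ny)) {
            x <- (i - 1) * sx - cx; y <- (j - 1) * sy - cy
            u <- x * co + y * si; v <- -x * si + y * co
            if ((u / a)^2 + (v / b)^2 <= 1) m[i, j] <- 1L
        }
    m
}

# small random blob mask for round-trip and metric tests
randomBlobMask <- function(seed, dim = c(20, 20, 6), spacing = c(1, 1, 5)) {
    set.seed(seed)
    v <- array(0L, dim = dim)
    n <- sample(30:80, 1)
    idx <- cbind(sample(3:(dim[1] - 2), n, TRUE),
                 sample(3:(dim[2] - 2), n, TRUE),
                 sample(2:(dim[3] - 1), n, TRUE))
    v[idx] <- 1L
    MaskVolume(v, spacing = spacing)
}
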