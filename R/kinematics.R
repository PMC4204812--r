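# Rigid-body kinematics: parameter rows to transforms, scalar displacement
# series for complete and reduced parameter sets, d_avg sensitivity sweeps
# and translation/rotation sign-discordance counts.

# Composition order T * Rx * Ry * Rz (the order used by SPM's parameter
# files), with standard right-handed rotation matrices. Centralized here so
# one function defines the convention for the whole package.
rotation3 <- function(rx, ry, rz) {
    cx <- cos(rx); sx <- sin(rx)
    cy <- cos(ry); sy <- sin(ry)
    cz <- cos(rz); sz <- sin(rz)
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rx %*% Ry %*% Rz
}

#' Convert one 6-parameter row to a rigid-body transform
#'
#' Builds the homogeneous world-space transform
#' \code{M = Translate(tx, ty, tz) \%*\% Rx(rx) \%*\% Ry(ry) \%*\% Rz(rz)}.
#'
#' @param p length-6 numeric vector: translations (mm) then rotations
#'   (radians).
#' @return A \linkS4class{RigidTransform}.
#' @examples
#' transformMatrix(paramsToTransform(c(3, 0, 0, 0, 0, 0)))
#' @export
paramsToTransform <- function(p) {
    if (length(p) != 6L || !all(is.finite(p)))
        stop("parameter row must be 6 finite values")
    m <- diag(4)
    m[1:3, 1:3] <- rotation3(p[4L], p[5L], p[6L])
    m[1:3, 4L] <- p[1:3]
    new("RigidTransform", matrix = m)
}

# Inverse of paramsToTransform: recover (tx,ty,tz,rx,ry,rz) from a rigid
# transform built in T*Rx*Ry*Rz order.
decomposeTransform <- function(m) {
    if (is(m, "RigidTransform")) m <- m@matrix
    r <- m[1:3, 1:3]
    ry <- asin(max(-1, min(1, r[1L, 3L])))
    if (abs(cos(ry)) > 1e-9) {
        rx <- atan2(-r[2L, 3L], r[3L, 3L])
        rz <- atan2(-r[1L, 2L], r[1L, 1L])
    } else {
        # gimbal lock: fold rz into rx
        rx <- atan2(r[2L, 1L], r[2L, 2L])
        rz <- 0
    }
    c(m[1:3, 4L], rx, ry, rz)
}

#' Zero out the complementary half of a parameter set
#'
#' Returns a copy of the trajectory in which either the three rotations
#' (\code{translation_only}) or the three translations
#' (\code{rotation_only}) are set to exactly zero; the reduced parameter
#' sets used throughout for comparison against the complete assessment.
#'
#' @param params a \linkS4class{RealignmentParams}.
#' @param set "complete" (unchanged copy), "translation_only" or
#'   "rotation_only".
#' @return A new \linkS4class{RealignmentParams}; the input is untouched.
#' @export
reduceParams <- function(params, set = c("translation_only",
                                         "rotation_only", "complete")) {
    set <- match.arg(set)
    v <- params@values
    if (set == "translation_only") v[, 4:6] <- 0
    if (set == "rotation_only") v[, 1:3] <- 0
    new("RealignmentParams", values = v, sourceLabel = params@sourceLabel)
}

# Quasi-uniform points on the unit sphere (Fibonacci lattice); deterministic.
fibonacciSphere <- function(n) {
    i <- seq_len(n) - 0.5
    phi <- pi * (sqrt(5) + 1) * i
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(r * cos(phi), r * sin(phi), z)
}

# displacement of unit-sphere-sampled points (scaled to radius d) under the
# rigid transform of each parameter row; returns per-row mean
spherePointDisplacement <- function(rows, d, points) {
    p <- points * d
    vapply(seq_len(nrow(rows)), function(t) {
        m <- paramsToTransform(rows[t, ])@matrix
        moved <- p %*% t(m[1:3, 1:3]) # rotate
        moved <- sweep(moved, 2L, m[1:3, 4L], "+")
        mean(sqrt(rowSums((moved - p)^2)))
    }, numeric(1L))
}

rowDisplacement <- function(rows, dAvg, method, nSpherePoints,
                            referenceDirection) {
    switch(method,
        fig1_vector_sum = sqrt(rowSums(
            (rows[, 1:3, drop = FALSE] +
             dAvg * rows[, 4:6, drop = FALSE])^2)),
        sphere_mean = spherePointDisplacement(
            rows, dAvg, fibonacciSphere(nSpherePoints)),
        reference_point = {
            u <- referenceDirection / sqrt(sum(referenceDirection^2))
            p0 <- dAvg * u
            vapply(seq_len(nrow(rows)), function(t) {
                m <- paramsToTransform(rows[t, ])@matrix
                sqrt(sum((m[1:3, 1:3] %*% p0 + m[1:3, 4L] - p0)^2))
            }, numeric(1L))
        })
}

#' Total-displacement series from a realignment trajectory
#'
#' Collapses each volume's 6 rigid-body parameters into a scalar
#' displacement in mm at the reference cortical distance \code{dAvg}.
#' Absolute mode references the first volume (whose parameters are zero by
#' realignment convention); relative mode is scan-to-scan, computed by
#' row-wise parameter differencing (or, optionally, by transform
#' composition \code{M_t \%*\% solve(M_[t-1])}).
#'
#' Methods:
#' \describe{
#'   \item{fig1_vector_sum}{\code{||(tx,ty,tz) + dAvg*(rx,ry,rz)||}: each
#'     rotation angle is converted to an arc length at distance dAvg and
#'     paired with the same-axis translation (the default).}
#'   \item{sphere_mean}{mean displacement of points sampled quasi-uniformly
#'     on the sphere of radius dAvg under the full rigid transform; the
#'     geometrically exact reference.}
#'   \item{reference_point}{displacement of a single point at distance dAvg
#'     along \code{referenceDirection}.}
#' }
#'
#' @param params a \linkS4class{RealignmentParams}.
#' @param dAvg reference (average cortical) distance in mm; must be > 0.
#' @param mode "absolute" or "relative".
#' @param method see Details.
#' @param parameterSet reduce the trajectory first: "complete",
#'   "translation_only" or "rotation_only".
#' @param relativeMethod "diff" (parameter differencing, default) or
#'   "compose" (transform composition).
#' @param nSpherePoints number of sphere sample points for
#'   \code{sphere_mean}.
#' @param referenceDirection unit direction for \code{reference_point}.
#' @return A \linkS4class{DisplacementSeries}.
#' @examples
#' p <- RealignmentParams(rbind(rep(0, 6), c(3, 4, 0, 0, 0, 0)))
#' displacement(displacementSeries(p, dAvg = 65)) # 0, 5
#' @export
displacementSeries <- function(params, dAvg = 65,
                               mode = c("absolute", "relative"),
                               method = c("fig1_vector_sum", "sphere_mean",
                                          "reference_point"),
                               parameterSet = c("complete",
                                                "translation_only",
                                                "rotation_only"),
                               relativeMethod = c("diff", "compose"),
                               nSpherePoints = 500,
                               referenceDirection = c(1, 0, 0)) {
    mode <- match.arg(mode)
    method <- match.arg(method)
    parameterSet <- match.arg(parameterSet)
    relativeMethod <- match.arg(relativeMethod)
    if (!is.finite(dAvg) || dAvg <= 0)
        stop("dAvg must be a positive distance in mm")
    if (parameterSet != "complete")
        params <- reduceParams(params, parameterSet)
    v <- params@values
    tt <- nrow(v)
    if (mode == "absolute") {
        rows <- sweep(v, 2L, v[1L, ], "-")
        vals <- rowDisplacement(rows, dAvg, method, nSpherePoints,
                                referenceDirection)
    } else if (relativeMethod == "diff" || tt == 1L) {
        rows <- rbind(rep(0, 6L), diff(v))
        vals <- rowDisplacement(rows, dAvg, method, nSpherePoints,
                                referenceDirection)
    } else {
        rows <- t(vapply(2:tt, function(t) {
            m <- paramsToTransform(v[t, ])@matrix %*%
                solve(paramsToTransform(v[t - 1L, ])@matrix)
            decomposeTransform(m)
        }, numeric(6L)))
        rows <- rbind(rep(0, 6L), rows)
        vals <- rowDisplacement(rows, dAvg, method, nSpherePoints,
                                referenceDirection)
    }
    vals[1L] <- 0
    new("DisplacementSeries", values = as.numeric(vals), mode = mode,
        method = method, dAvg = dAvg, parameterSet = parameterSet)
}

#' Sensitivity of displacement to the reference cortical distance
#'
#' Recomputes the displacement series over a grid of d_avg values and
#' expresses the per-series median displacement as a percentage of the
#' median at the reference distance, for both absolute and relative motion.
#'
#' @param params a \linkS4class{RealignmentParams}.
#' @param dMin,dMax,step sweep range (mm); default 50 to 80 in 0.5 mm steps.
#' @param dRef reference distance (mm), default 65.
#' @param method displacement method passed on to
#'   \code{\link{displacementSeries}}.
#' @param parameterSet parameter set passed on.
#' @return data.frame with columns \code{d_avg}, \code{percent_absolute},
#'   \code{percent_relative}; the row at \code{dRef} is exactly 100.
#' @export
davgSensitivitySweep <- function(params, dMin = 50, dMax = 80, step = 0.5,
                                 dRef = 65, method = "fig1_vector_sum",
                                 parameterSet = "complete") {
    if (!(dMin < dRef && dRef < dMax) || step <= 0)
        stop("need dMin < dRef < dMax and step > 0")
    ds <- seq(dMin, dMax, by = step)
    if (!any(abs(ds - dRef) < 1e-9)) ds <- sort(c(ds, dRef))
    med <- function(mode, d) {
        median(displacement(displacementSeries(
            params, dAvg = d, mode = mode, method = method,
            parameterSet = parameterSet)))
    }
    refAbs <- med("absolute", dRef)
    refRel <- med("relative", dRef)
    pct <- function(x, ref) if (ref > 0) 100 * x / ref else NA_real_
    out <- data.frame(
        d_avg = ds,
        percent_absolute = vapply(ds, function(d)
            pct(med("absolute", d), refAbs), numeric(1L)),
        percent_relative = vapply(ds, function(d)
            pct(med("relative", d), refRel), numeric(1L)))
    iRef <- which(abs(ds - dRef) < 1e-9)
    if (is.finite(out$percent_absolute[iRef]))
        out$percent_absolute[iRef] <- 100
    if (is.finite(out$percent_relative[iRef]))
        out$percent_relative[iRef] <- 100
    out
}

#' Count volumes where translation and rotation signs disagree
#'
#' For each axis pair (tx, rx), (ty, ry), (tz, rz), counts the volumes
#' where the two values have strictly opposite signs (product < 0). Volumes
#' where either member is exactly zero count as concordant.
#'
#' @param params a \linkS4class{RealignmentParams}.
#' @return A \linkS4class{SignDiscordanceCount}.
#' @export
signDiscordance <- function(params) {
    v <- params@values
    counts <- vapply(1:3, function(a)
        sum(v[, a] * v[, a + 3L] < 0), numeric(1L))
    new("SignDiscordanceCount", perAxis = as.integer(counts),
        totalDatapoints = nrow(v))
}
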