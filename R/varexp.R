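# Motion-regressor design matrices (raw, reduced, Volterra-expanded,
# fingerprint) and voxel-wise GLM variance summaries.

lagShift <- function(x, lag = 1L) {
    # "shifted back in time": row t holds the value from t - lag, zero-padded
    x <- as.matrix(x)
    tt <- nrow(x)
    if (lag >= tt) return(x * 0)
    rbind(matrix(0, lag, ncol(x)),
          x[seq_len(tt - lag), , drop = FALSE])
}

#' Build a motion-regressor design matrix
#'
#' Supported sets: the 6 realignment parameters from the complete
#' (\code{rps_complete}) or reduced (\code{rps_to}, \code{rps_ro})
#' assessments, and the 24-regressor Volterra expansion
#' (\code{volterra24}): the 6 parameters, their one-volume-lagged copies
#' (zero-padded first row), and the squares of all twelve. All columns are
#' mean-centered; the intercept is appended at fit time.
#'
#' @param params a \linkS4class{RealignmentParams}.
#' @param set one of "rps_complete", "rps_to", "rps_ro", "volterra24".
#' @return A \linkS4class{MotionDesign}.
#' @export
buildDesign <- function(params, set = c("rps_complete", "rps_to", "rps_ro",
                                        "volterra24")) {
    set <- match.arg(set)
    v <- params@values
    tt <- nrow(v)
    x <- switch(set,
        rps_complete = v,
        rps_to = reduceParams(params, "translation_only")@values,
        rps_ro = reduceParams(params, "rotation_only")@values,
        volterra24 = {
            lagged <- lagShift(v)
            colnames(lagged) <- paste0(colnames(v), "_lag1")
            sq <- cbind(v, lagged)^2
            colnames(sq) <- paste0(c(colnames(v), colnames(lagged)), "_sq")
            cbind(v, lagged, sq)
        })
    k <- ncol(x)
    if (tt < k + 2L)
        stop("need at least ", k + 2L, " volumes for ", k, " regressors")
    x <- scale(x, center = TRUE, scale = FALSE)
    attr(x, "scaled:center") <- NULL
    if (all(apply(x, 2L, function(co) all(abs(co) < 1e-12))))
        warning("degenerate design: all centered columns are zero (",
                set, ")")
    new("MotionDesign", columns = x, setId = set,
        includesIntercept = FALSE)
}

seriesToVoxelMatrix <- function(series, mask = NULL) {
    d <- dim(series@data)
    flat <- matrix(series@data, nrow = prod(d[1:3]), ncol = d[4L])
    if (!is.null(mask)) {
        keep <- as.logical(if (is(mask, "VolumeGrid")) mask@data else mask)
        flat <- flat[keep, , drop = FALSE]
    }
    t(flat) # T x V
}

#' Fit voxel-wise GLMs and summarize variance explained
#'
#' Ordinary least squares of every (masked) voxel time course on the
#' design's mean-centered regressors plus an intercept. Reports per-voxel
#' R-squared and the omnibus F statistic
#' \code{F = (R2/K) / ((1 - R2)/(T - K - 1))} with K the effective
#' (post-rank-reduction) number of regressors, plus mean and median
#' R-squared over the mask. Rank-deficient designs are reduced via pivoted
#' QR and the effective K recorded in the degrees of freedom.
#'
#' @param series an \linkS4class{FmriSeries} or a T x V numeric matrix of
#'   voxel time courses.
#' @param design a \linkS4class{MotionDesign}.
#' @param mask optional binary \linkS4class{VolumeGrid} (or logical array)
#'   selecting analysis voxels when \code{series} is 4-D.
#' @return A \linkS4class{GlmResult}.
#' @export
fitGlm <- function(series, design, mask = NULL) {
    y <- if (is(series, "FmriSeries")) seriesToVoxelMatrix(series, mask)
         else as.matrix(series)
    x <- design@columns
    tt <- nrow(y)
    if (nrow(x) != tt) stop("design and data disagree on T")
    # pivoted rank reduction of the centered regressors
    qx <- qr(x)
    keff <- qx$rank
    if (keff == 0L) stop("degenerate design: rank 0 after centering")
    xr <- x[, qx$pivot[seq_len(keff)], drop = FALSE]
    xf <- cbind(intercept = 1, xr)
    qf <- qr(xf)
    fitted <- qr.fitted(qf, y)
    res <- y - fitted
    ybar <- colMeans(y)
    sst <- colSums(sweep(y, 2L, ybar, "-")^2)
    sse <- colSums(res^2)
    dfDen <- tt - keff - 1L
    if (dfDen < 1L) stop("not enough volumes for ", keff, " regressors")
    r2 <- ifelse(sst > 0, 1 - sse / sst, 0)
    r2 <- pmin(pmax(r2, 0), 1)
    ssm <- pmax(sst - sse, 0)
    fstat <- ifelse(sse > 0, (ssm / keff) / (sse / dfDen), Inf)
    fstat[!is.finite(fstat)] <- .Machine$double.xmax
    new("GlmResult", r2 = as.numeric(r2), fstat = as.numeric(fstat),
        dfNum = as.integer(keff), dfDen = as.integer(dfDen),
        meanR2 = mean(r2), medianR2 = median(r2), setId = design@setId)
}

#' Variance explained as percent of a reference fit
#'
#' 100 * meanR2(result) / meanR2(reference); by convention the reference is
#' the Volterra-expanded complete parameter set (= 100%). Undefined (NA)
#' when the reference explains no variance. With \code{summary = "median"}
#' the per-mask median R-squared is used in both numerator and denominator.
#'
#' @param result,reference \linkS4class{GlmResult}s fitted on the same data
#'   and mask.
#' @param summary "mean" (default) or "median".
#' @return percent as a single number, or NA.
#' @export
percentOfReference <- function(result, reference,
                               summary = c("mean", "median")) {
    summary <- match.arg(summary)
    if (length(result@r2) != length(reference@r2))
        stop("results were fitted on different masks")
    num <- if (summary == "mean") result@meanR2 else result@medianR2
    den <- if (summary == "mean") reference@meanR2 else reference@medianR2
    if (!is.finite(den) || den <= 0) {
        warning("reference explains no variance; percent undefined")
        return(NA_real_)
    }
    100 * num / den
}

#' Write a design matrix as TSV
#'
#' @param design a \linkS4class{MotionDesign}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDesign <- function(design, path) {
    df <- as.data.frame(design@columns)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
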