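# Phantom motion replay: replicate the first volume, re-apply each
# volume's rigid transform, extract 9 interface-ROI traces and score
# motion-induced signal change. Purely geometric: interactions of the
# moving head with the static field (motion x B0) are not modelled.

volume3 <- function(series, t) {
    VolumeGrid(series@data[, , , t, drop = TRUE], affine = series@affine)
}

#' Replay a motion trajectory in a motion-free phantom series
#'
#' Copies the first volume T times and applies each volume's rigid
#' transform (the inverted motion, i.e. the correcting transform that
#' realignment estimated) with B-spline resampling, so that the output
#' series contains exactly the geometric signal changes the motion would
#' induce in a static brain. Out-of-field voxels are filled with 0.
#'
#' @param series a \linkS4class{FmriSeries}; only its first volume is used.
#' @param params a \linkS4class{RealignmentParams} with one row per volume
#'   of \code{series}.
#' @param splineOrder interpolation order 0-7, default 7.
#' @return A \linkS4class{FmriSeries} of the same dimensions; metadata-free
#'   note: the replay is purely geometric (no motion x B0 modelling).
#' @export
buildPhantom <- function(series, params, splineOrder = 7) {
    stopifnot(is(series, "FmriSeries"))
    tt <- dim(series@data)[4L]
    if (nVolumes(params) != tt)
        stop("params has ", nVolumes(params), " rows but series has ",
             tt, " volumes")
    first <- volume3(series, 1L)
    if (!all(is.finite(first@data))) stop("first volume must be finite")
    out <- array(0, dim(series@data))
    v <- params@values
    for (t in seq_len(tt)) {
        if (all(v[t, ] == 0)) {
            out[, , , t] <- first@data
        } else {
            m <- paramsToTransform(v[t, ])
            out[, , , t] <- applyRigidTransform(first, m,
                                                splineOrder = splineOrder)@data
        }
    }
    FmriSeries(out, affine = series@affine,
               repetitionTime = series@repetitionTime)
}

sphereOffsets <- function(radius) {
    r <- ceiling(radius)
    g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
    g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE]
}

#' Derive the 9 interface regions of interest
#'
#' Automatically places 8 ROIs at the interface of brain and non-brain near
#' the 8 corners of the image volume plus one at the center of the brain.
#' Each corner ROI is found by walking the ray from the volume corner
#' towards the mask centroid until the first mask voxel, then taking a
#' sphere of \code{radiusVox} voxels intersected with a two-voxel-thick
#' shell straddling the exterior mask boundary. The 9th ROI is a sphere at
#' the mask centroid. ROIs are trimmed to disjointness with first-claim
#' priority (corners 1..8, then center).
#'
#' @param brainMask a binary 3-D \linkS4class{VolumeGrid}.
#' @param radiusVox ROI sphere radius in voxels, default 2.
#' @return A \linkS4class{RoiSet}.
#' @export
deriveRois <- function(brainMask, radiusVox = 2) {
    a <- maskArray(brainMask)
    d <- dim(a)
    if (sum(a) == 0) stop("mask is empty")
    if (any(d < 8L)) stop("volume too small to host 9 disjoint ROIs")
    idx <- which(a == 1, arr.ind = TRUE)
    centroid <- colMeans(idx)
    # interface shell: exterior surface voxels plus adjacent exterior bg
    surf <- outerSurfaceVoxels(brainMask)
    shell <- array(FALSE, d)
    shell[surf] <- TRUE
    ext <- array(cpp_exterior_background(as.logical(a), as.integer(d)), d)
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
        nb <- sweep(surf, 2L, s, "+")
        ok <- nb[, 1L] >= 1 & nb[, 1L] <= d[1L] &
              nb[, 2L] >= 1 & nb[, 2L] <= d[2L] &
              nb[, 3L] >= 1 & nb[, 3L] <= d[3L]
        nb <- nb[ok, , drop = FALSE]
        inExt <- ext[nb]
        shell[nb[inExt, , drop = FALSE]] <- TRUE
    }
    claimed <- array(FALSE, d)
    offs <- sphereOffsets(radiusVox)
    corners <- as.matrix(expand.grid(c(1, d[1L]), c(1, d[2L]),
                                     c(1, d[3L])))
    clampRound <- function(p) pmin(pmax(round(p), 1L), d)
    takeRoi <- function(center, restrict) {
        vox <- sweep(offs, 2L, as.integer(center), "+")
        ok <- vox[, 1L] >= 1 & vox[, 1L] <= d[1L] &
              vox[, 2L] >= 1 & vox[, 2L] <= d[2L] &
              vox[, 3L] >= 1 & vox[, 3L] <= d[3L]
        vox <- vox[ok, , drop = FALSE]
        keep <- restrict[vox] & !claimed[vox]
        vox[keep, , drop = FALSE]
    }
    rois <- vector("list", 9L)
    for (ci in 1:8) {
        start <- corners[ci, ]
        dir <- centroid - start
        len <- sqrt(sum(dir^2))
        if (len < 1e-9) stop("degenerate mask centroid")
        dir <- dir / len
        hit <- NULL
        for (s in seq(0, len, by = 0.5)) {
            p <- clampRound(start + s * dir)
            if (a[p[1L], p[2L], p[3L]] == 1) {
                hit <- p
                break
            }
        }
        if (is.null(hit))
            stop("no brain voxel found along corner ray ", ci)
        vox <- takeRoi(hit, shell)
        if (nrow(vox) == 0L)
            stop("corner ROI ", ci, " is empty; mask too small")
        claimed[vox] <- TRUE
        rois[[ci]] <- vox
    }
    inMask <- array(FALSE, d)
    inMask[idx] <- TRUE
    centerVox <- takeRoi(clampRound(centroid), inMask)
    if (nrow(centerVox) == 0L) stop("center ROI is empty")
    claimed[centerVox] <- TRUE
    rois[[9L]] <- centerVox
    new("RoiSet", voxels = rois,
        labels = c(paste0("corner_", 1:8), "center"))
}

#' Mean ROI intensity traces
#'
#' @param series a \linkS4class{FmriSeries}.
#' @param rois a \linkS4class{RoiSet} on the same grid.
#' @return 9 x T matrix; entry (r, t) is the mean intensity over ROI r at
#'   volume t.
#' @export
roiTraces <- function(series, rois) {
    d <- dim(series@data)
    nvox <- prod(d[1:3])
    tt <- d[4L]
    flat <- matrix(series@data, nrow = nvox, ncol = tt)
    out <- matrix(0, 9L, tt)
    for (r in 1:9) {
        v <- rois@voxels[[r]]
        if (any(v < 1L) || any(v[, 1L] > d[1L]) || any(v[, 2L] > d[2L]) ||
            any(v[, 3L] > d[3L]))
            stop("ROI ", r, " lies outside the image grid")
        lin <- (v[, 3L] - 1L) * d[1L] * d[2L] + (v[, 2L] - 1L) * d[1L] +
            v[, 1L]
        out[r, ] <- colMeans(flat[lin, , drop = FALSE])
    }
    rownames(out) <- rois@labels
    out
}

#' Score motion-induced signal change from ROI traces
#'
#' Converts each ROI trace to its absolute deviation from the first-volume
#' value (the replay's reference) and averages over the 9 ROIs and volumes
#' 2..T. With \code{baseline = "mean"} each ROI's mean is the reference
#' instead.
#'
#' @param traces 9 x T matrix from \code{\link{roiTraces}}.
#' @param parameterSet label carried through to the result.
#' @param baseline "first" (default) or "mean".
#' @return A \linkS4class{SignalChangeScore}.
#' @export
signalChangeScore <- function(traces, parameterSet = "complete",
                              baseline = c("first", "mean")) {
    baseline <- match.arg(baseline)
    if (ncol(traces) < 2L) stop("need at least 2 volumes")
    ref <- if (baseline == "first") traces[, 1L] else rowMeans(traces)
    dev <- abs(traces - ref)
    dev <- dev[, -1L, drop = FALSE]
    new("SignalChangeScore", traces = traces, score = mean(dev),
        perRoi = rowMeans(dev), parameterSet = parameterSet)
}

#' Motion-fingerprint regressor traces
#'
#' Derives nuisance-regressor columns from the 9 phantom-replay ROI traces:
#' with \code{k = 9} the mean-centered traces themselves, with \code{k = 3}
#' the first 3 principal-component scores of the centered traces. With
#' \code{includeShifted} each column is additionally appended shifted back
#' in time by one volume (first entry zero-padded), giving
#' \code{k * 2} columns.
#'
#' @param traces 9 x T matrix from \code{\link{roiTraces}}.
#' @param k 3 or 9.
#' @param includeShifted append one-volume-lagged copies, default TRUE.
#' @param setId set identity stored on the design (e.g. "mfp_complete").
#' @return A \linkS4class{MotionDesign} with \code{k * (1 + includeShifted)}
#'   columns.
#' @export
fingerprintTraces <- function(traces, k = 3, includeShifted = TRUE,
                              setId = "mfp_complete") {
    if (!k %in% c(3, 9)) stop("k must be 3 or 9")
    tt <- ncol(traces)
    if (tt < 3L) stop("need at least 3 volumes")
    x <- scale(t(traces), center = TRUE, scale = FALSE) # T x 9
    if (k == 3) {
        sv <- svd(x)
        x <- sv$u[, 1:3, drop = FALSE] %*% diag(sv$d[1:3], 3L)
        colnames(x) <- paste0("mfp_pc", 1:3)
    } else {
        colnames(x) <- paste0("mfp_roi", 1:9)
    }
    if (includeShifted) {
        lag <- rbind(0, x[-tt, , drop = FALSE])
        colnames(lag) <- paste0(colnames(x), "_lag1")
        x <- cbind(x, lag)
    }
    new("MotionDesign", columns = x, setId = setId,
        includesIntercept = FALSE)
}
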