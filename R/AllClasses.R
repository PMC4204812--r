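#' @import methods
#' @importFrom stats cor.test lm coef median rnorm runif sd setNames
#' @importFrom utils read.table write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib motionQC, .registration = TRUE
NULL

PARAMETER_SETS <- c("complete", "translation_only", "rotation_only")
DISPLACEMENT_MODES <- c("absolute", "relative")
DISPLACEMENT_METHODS <- c("fig1_vector_sum", "sphere_mean", "reference_point")

#' Rigid-body realignment parameter trajectory
#'
#' A T x 6 matrix of rigid-body motion parameters, one row per volume:
#' columns \code{tx, ty, tz} are translations in mm and \code{rx, ry, rz}
#' rotations in radians, the order written by SPM-style \code{rp_*.txt}
#' files. By realignment convention the first volume is the reference, so
#' its row is all zeros.
#'
#' @slot values numeric matrix, T x 6, all entries finite.
#' @slot sourceLabel free-text provenance label.
#' @export
setClass("RealignmentParams",
    representation(values = "matrix", sourceLabel = "character"),
    validity = function(object) {
        v <- object@values
        if (!is.numeric(v) || ncol(v) != 6L)
            return("values must be a numeric matrix with 6 columns")
        if (nrow(v) < 1L)
            return("at least one volume (row) is required")
        if (!all(is.finite(v)))
            return("all parameter values must be finite")
        TRUE
    })

#' Construct a RealignmentParams object
#'
#' @param values T x 6 numeric matrix (tx, ty, tz in mm; rx, ry, rz in
#'   radians) or a length-6 vector for a single volume.
#' @param sourceLabel free-text label recording where the series came from.
#' @return A \linkS4class{RealignmentParams} object.
#' @export
RealignmentParams <- function(values, sourceLabel = "") {
    if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    colnames(values) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    new("RealignmentParams", values = values, sourceLabel = sourceLabel)
}

#' Homogeneous rigid-body transform
#'
#' A 4 x 4 homogeneous world-space transform whose upper-left 3 x 3 block is
#' a proper rotation (orthonormal, determinant +1).
#'
#' @slot matrix 4 x 4 numeric matrix.
#' @export
setClass("RigidTransform",
    representation(matrix = "matrix"),
    validity = function(object) {
        m <- object@matrix
        if (!all(dim(m) == c(4L, 4L))) return("matrix must be 4 x 4")
        if (max(abs(m[4L, ] - c(0, 0, 0, 1))) > 1e-9)
            return("last row must be (0, 0, 0, 1)")
        r <- m[1:3, 1:3]
        if (max(abs(crossprod(r) - diag(3))) > 1e-9)
            return("rotation block must be orthonormal")
        if (abs(det(r) - 1) > 1e-9)
            return("rotation block must have determinant +1")
        TRUE
    })

#' Per-volume scalar displacement series
#'
#' Scalar displacement (mm) per volume, derived from a realignment
#' trajectory at a reference cortical distance. The first volume is its own
#' reference so its displacement is 0 in both modes.
#'
#' @slot values non-negative displacement in mm, one per volume.
#' @slot mode "absolute" (relative to first volume) or "relative"
#'   (scan-to-scan).
#' @slot method combination rule used to collapse the 6 parameters.
#' @slot dAvg reference cortical distance in mm.
#' @slot parameterSet "complete", "translation_only" or "rotation_only".
#' @export
setClass("DisplacementSeries",
    representation(values = "numeric", mode = "character",
                   method = "character", dAvg = "numeric",
                   parameterSet = "character"),
    validity = function(object) {
        if (length(object@values) < 1L) return("empty series")
        if (!all(is.finite(object@values)) || any(object@values < 0))
            return("displacements must be finite and non-negative")
        if (abs(object@values[1L]) > 1e-12)
            return("first volume must have zero displacement")
        if (!object@mode %in% DISPLACEMENT_MODES) return("unknown mode")
        if (!object@method %in% DISPLACEMENT_METHODS) return("unknown method")
        if (!object@parameterSet %in% PARAMETER_SETS)
            return("unknown parameter set")
        if (object@dAvg <= 0) return("dAvg must be positive")
        TRUE
    })

#' Translation/rotation sign-discordance counts
#'
#' For each axis pair (tx, rx), (ty, ry), (tz, rz), the number of volumes
#' where translation and rotation have strictly opposite signs.
#'
#' @slot perAxis integer counts for x, y, z.
#' @slot totalDatapoints number of volumes examined per axis.
#' @export
setClass("SignDiscordanceCount",
    representation(perAxis = "integer", totalDatapoints = "integer"),
    validity = function(object) {
        if (length(object@perAxis) != 3L) return("perAxis must have length 3")
        if (any(object@perAxis < 0L) ||
            any(object@perAxis > object@totalDatapoints))
            return("counts must lie in [0, totalDatapoints]")
        TRUE
    })

#' 3-D or 4-D image volume with affine geometry
#'
#' An image array together with a 4 x 4 affine mapping 0-based voxel indices
#' to world coordinates in mm (NIfTI convention; R's 1-based index (i,j,k)
#' maps through \code{affine \%*\% c(i-1, j-1, k-1, 1)}).
#'
#' @slot data 3-D or 4-D numeric array.
#' @slot affine invertible 4 x 4 voxel-to-world matrix.
#' @export
setClass("VolumeGrid",
    representation(data = "array", affine = "matrix"),
    validity = function(object) {
        nd <- length(dim(object@data))
        if (!nd %in% c(3L, 4L)) return("data must be a 3-D or 4-D array")
        if (!all(dim(object@affine) == c(4L, 4L)))
            return("affine must be 4 x 4")
        d <- tryCatch(det(object@affine[1:3, 1:3]), error = function(e) 0)
        if (!is.finite(d) || abs(d) < 1e-12)
            return("affine must be invertible")
        TRUE
    })

#' Construct a VolumeGrid
#'
#' @param data 3-D (or 4-D) numeric array.
#' @param affine 4 x 4 voxel(0-based)-to-world matrix; default identity
#'   scaled by \code{spacing}.
#' @param spacing voxel size in mm used when \code{affine} is missing.
#' @return A \linkS4class{VolumeGrid}.
#' @export
VolumeGrid <- function(data, affine = NULL, spacing = 1) {
    data <- as.array(data)
    if (is.null(affine)) {
        affine <- diag(c(rep(spacing, 3L), 1))
    }
    new("VolumeGrid", data = data, affine = affine)
}

#' 4-D fMRI series
#'
#' A \linkS4class{VolumeGrid} whose 4th dimension is time, with the
#' repetition time carried as metadata.
#'
#' @slot repetitionTime TR in seconds (metadata only).
#' @export
setClass("FmriSeries", contains = "VolumeGrid",
    representation(repetitionTime = "numeric"),
    validity = function(object) {
        if (length(dim(object@data)) != 4L)
            return("an fMRI series must be 4-D")
        TRUE
    })

#' Construct an FmriSeries
#'
#' @param data 4-D numeric array (x, y, z, time).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param repetitionTime TR in seconds.
#' @param spacing voxel size in mm used when \code{affine} is missing.
#' @return An \linkS4class{FmriSeries}.
#' @export
FmriSeries <- function(data, affine = NULL, repetitionTime = 2,
                       spacing = 1) {
    data <- as.array(data)
    if (is.null(affine)) affine <- diag(c(rep(spacing, 3L), 1))
    new("FmriSeries", data = data, affine = affine,
        repetitionTime = repetitionTime)
}

#' Average cortical distance result
#'
#' @slot dAvg mean Euclidean distance (mm) from the origin to the outer
#'   cortical surface voxels.
#' @slot surfaceVoxelCount number of outer-surface voxels.
#' @slot originWorld world-space origin (mm) the distances refer to.
#' @export
setClass("CorticalDistanceResult",
    representation(dAvg = "numeric", surfaceVoxelCount = "integer",
                   originWorld = "numeric"),
    validity = function(object) {
        if (object@surfaceVoxelCount < 1L)
            return("at least one surface voxel is required")
        if (!is.finite(object@dAvg) || object@dAvg <= 0)
            return("dAvg must be positive")
        TRUE
    })

#' Motion-censoring (scrubbing) result
#'
#' @slot mask logical per volume, TRUE = discarded.
#' @slot cutoffMm admissible-motion cutoff in mm.
#' @slot discardedCount number of TRUE entries.
#' @slot mode displacement mode the cutoff was applied to.
#' @slot parameterSet parameter-set label of the underlying series.
#' @export
setClass("CensorResult",
    representation(mask = "logical", cutoffMm = "numeric",
                   discardedCount = "integer", mode = "character",
                   parameterSet = "character"),
    validity = function(object) {
        if (object@cutoffMm <= 0) return("cutoff must be positive")
        if (object@discardedCount != sum(object@mask))
            return("discardedCount must equal the number of TRUE entries")
        TRUE
    })

#' Set of 9 interface regions of interest
#'
#' Eight ROIs at the brain/non-brain interface near the volume corners plus
#' one at the center of the brain; pairwise disjoint and non-empty.
#'
#' @slot voxels list of 9 integer matrices (n x 3, 1-based voxel indices).
#' @slot labels "corner_1".."corner_8", "center".
#' @export
setClass("RoiSet",
    representation(voxels = "list", labels = "character"),
    validity = function(object) {
        if (length(object@voxels) != 9L || length(object@labels) != 9L)
            return("exactly 9 ROIs are required")
        if (any(vapply(object@voxels, nrow, 1L) == 0L))
            return("each ROI must be non-empty")
        keys <- unlist(lapply(object@voxels, function(v)
            paste(v[, 1L], v[, 2L], v[, 3L])))
        if (anyDuplicated(keys)) return("ROIs must be pairwise disjoint")
        TRUE
    })

#' Motion-induced signal-change score
#'
#' @slot traces 9 x T ROI-mean intensity traces.
#' @slot score mean absolute deviation from each ROI's first-volume value,
#'   over ROIs and volumes 2..T.
#' @slot perRoi per-ROI mean absolute deviation.
#' @slot parameterSet parameter-set label of the replayed motion.
#' @export
setClass("SignalChangeScore",
    representation(traces = "matrix", score = "numeric",
                   perRoi = "numeric", parameterSet = "character"),
    validity = function(object) {
        if (object@score < 0) return("score must be non-negative")
        TRUE
    })

#' Motion-regressor design matrix
#'
#' @slot columns T x K matrix of mean-centered regressors.
#' @slot setId one of rps_complete, rps_to, rps_ro, volterra24,
#'   mfp_complete, mfp_to, mfp_ro, mfp9_shifted.
#' @slot includesIntercept whether an intercept column is present (the
#'   intercept is normally appended at fit time).
#' @export
setClass("MotionDesign",
    representation(columns = "matrix", setId = "character",
                   includesIntercept = "logical"))

#' Voxel-wise GLM variance summary
#'
#' @slot r2 per-voxel coefficient of determination.
#' @slot fstat per-voxel omnibus F statistic.
#' @slot dfNum numerator degrees of freedom (effective K).
#' @slot dfDen denominator degrees of freedom (T - K - 1).
#' @slot meanR2 mean R-squared over the analysis mask.
#' @slot medianR2 median R-squared over the analysis mask.
#' @slot setId design-set identity.
#' @export
setClass("GlmResult",
    representation(r2 = "numeric", fstat = "numeric", dfNum = "integer",
                   dfDen = "integer", meanR2 = "numeric",
                   medianR2 = "numeric", setId = "character"),
    validity = function(object) {
        if (any(object@r2 < -1e-10 | object@r2 > 1 + 1e-10))
            return("R-squared must lie in [0, 1]")
        if (any(object@fstat < -1e-10)) return("F must be non-negative")
        TRUE
    })
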