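#' @rdname nVolumes
#' @export
setMethod("nVolumes", "RealignmentParams", function(x) nrow(x@values))

#' @rdname nVolumes
#' @export
setMethod("nVolumes", "DisplacementSeries", function(x) length(x@values))

#' @rdname nVolumes
#' @export
setMethod("nVolumes", "FmriSeries", function(x) dim(x@data)[4L])

#' @rdname paramValues
#' @export
setMethod("paramValues", "RealignmentParams", function(x) x@values)

#' @rdname displacement
#' @export
setMethod("displacement", "DisplacementSeries", function(x) x@values)

#' @rdname dAvg
#' @export
setMethod("dAvg", "DisplacementSeries", function(x) x@dAvg)

#' @rdname dAvg
#' @export
setMethod("dAvg", "CorticalDistanceResult", function(x) x@dAvg)

#' @rdname gridData
#' @export
setMethod("gridData", "VolumeGrid", function(x) x@data)

#' @rdname gridAffine
#' @export
setMethod("gridAffine", "VolumeGrid", function(x) x@affine)

#' @rdname transformMatrix
#' @export
setMethod("transformMatrix", "RigidTransform", function(x) x@matrix)

#' @rdname censorMask
#' @export
setMethod("censorMask", "CensorResult", function(x) x@mask)

#' @rdname discardedCount
#' @export
setMethod("discardedCount", "CensorResult", function(x) x@discardedCount)

#' @rdname designMatrix
#' @export
setMethod("designMatrix", "MotionDesign", function(x) x@columns)

#' @rdname setId
#' @export
setMethod("setId", "MotionDesign", function(x) x@setId)

#' @rdname setId
#' @export
setMethod("setId", "GlmResult", function(x) x@setId)

#' @rdname meanR2
#' @export
setMethod("meanR2", "GlmResult", function(x) x@meanR2)

#' @rdname roiVoxels
#' @export
setMethod("roiVoxels", "RoiSet", function(x) x@voxels)

#' @rdname roiLabels
#' @export
setMethod("roiLabels", "RoiSet", function(x) x@labels)

setMethod("show", "RealignmentParams", function(object) {
    cat("RealignmentParams:", nrow(object@values), "volumes")
    if (nzchar(object@sourceLabel))
        cat(" [", object@sourceLabel, "]", sep = "")
    cat("\n  max |translation| =",
        format(max(abs(object@values[, 1:3])), digits = 4), "mm;",
        "max |rotation| =",
        format(max(abs(object@values[, 4:6])), digits = 4), "rad\n")
})

setMethod("show", "DisplacementSeries", function(object) {
    cat("DisplacementSeries (", object@mode, ", ", object@method, ", ",
        object@parameterSet, ", d_avg = ", object@dAvg, " mm): ",
        length(object@values), " volumes\n", sep = "")
    cat("  median =", format(median(object@values), digits = 4),
        "mm; max =", format(max(object@values), digits = 4), "mm\n")
})

setMethod("show", "VolumeGrid", function(object) {
    cat(class(object), ": ", paste(dim(object@data), collapse = " x "),
        " voxels; spacing ",
        paste(format(sqrt(colSums(object@affine[1:3, 1:3]^2)), digits = 3),
              collapse = " x "), " mm\n", sep = "")
})

setMethod("show", "CorticalDistanceResult", function(object) {
    cat("Average cortical distance d_avg =",
        format(object@dAvg, digits = 5), "mm over",
        object@surfaceVoxelCount, "outer-surface voxels\n")
})

setMethod("show", "CensorResult", function(object) {
    cat("CensorResult (", object@mode, ", ", object@parameterSet,
        ", cutoff ", object@cutoffMm, " mm): ", object@discardedCount,
        "/", length(object@mask), " volumes discarded\n", sep = "")
})

setMethod("show", "RoiSet", function(object) {
    sizes <- vapply(object@voxels, nrow, 1L)
    cat("RoiSet: 9 interface ROIs, sizes",
        paste(sizes, collapse = ", "), "voxels\n")
})

setMethod("show", "SignalChangeScore", function(object) {
    cat("SignalChangeScore (", object@parameterSet, "): ",
        format(object@score, digits = 5), "\n", sep = "")
})

setMethod("show", "MotionDesign", function(object) {
    cat("MotionDesign [", object@setId, "]: ",
        nrow(object@columns), " volumes x ", ncol(object@columns),
        " regressors\n", sep = "")
})

setMethod("show", "GlmResult", function(object) {
    cat("GlmResult [", object@setId, "]: mean R^2 = ",
        format(object@meanR2, digits = 4), " over ",
        length(object@r2), " voxels (df ", object@dfNum, ", ",
        object@dfDen, ")\n", sep = "")
})

setMethod("show", "SignDiscordanceCount", function(object) {
    cat("Sign discordance (x, y, z):",
        paste(object@perAxis, collapse = ", "), "of",
        object@totalDatapoints, "datapoints per axis\n")
})
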