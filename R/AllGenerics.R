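#' @describeIn RealignmentParams number of volumes (rows)
#' @param object,x an object of the documented class.
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' Parameter matrix accessor
#' @param x a \linkS4class{RealignmentParams}.
#' @return the T x 6 parameter matrix.
#' @export
setGeneric("paramValues", function(x) standardGeneric("paramValues"))

#' Displacement values accessor
#' @param x a \linkS4class{DisplacementSeries} or
#'   \linkS4class{SignalChangeScore}.
#' @return numeric vector of per-volume displacements (mm).
#' @export
setGeneric("displacement", function(x) standardGeneric("displacement"))

#' Reference cortical distance accessor
#' @param x an object carrying a d_avg value.
#' @return d_avg in mm.
#' @export
setGeneric("dAvg", function(x) standardGeneric("dAvg"))

#' Image data accessor
#' @param x a \linkS4class{VolumeGrid}.
#' @return the underlying array.
#' @export
setGeneric("gridData", function(x) standardGeneric("gridData"))

#' Affine accessor
#' @param x a \linkS4class{VolumeGrid}.
#' @return the 4 x 4 voxel(0-based)-to-world matrix.
#' @export
setGeneric("gridAffine", function(x) standardGeneric("gridAffine"))

#' Transform matrix accessor
#' @param x a \linkS4class{RigidTransform}.
#' @return the 4 x 4 homogeneous matrix.
#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))

#' Censor mask accessor
#' @param x a \linkS4class{CensorResult}.
#' @return logical vector, TRUE = discarded volume.
#' @export
setGeneric("censorMask", function(x) standardGeneric("censorMask"))

#' Discarded-volume count accessor
#' @param x a \linkS4class{CensorResult}.
#' @return integer count of discarded volumes.
#' @export
setGeneric("discardedCount", function(x) standardGeneric("discardedCount"))

#' Design matrix accessor
#' @param x a \linkS4class{MotionDesign}.
#' @return the T x K regressor matrix.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' Design/result set identity accessor
#' @param x a \linkS4class{MotionDesign} or \linkS4class{GlmResult}.
#' @return the set identifier string.
#' @export
setGeneric("setId", function(x) standardGeneric("setId"))

#' Mean R-squared accessor
#' @param x a \linkS4class{GlmResult}.
#' @return mean R-squared over the analysis mask.
#' @export
setGeneric("meanR2", function(x) standardGeneric("meanR2"))

#' ROI voxel-index accessor
#' @param x a \linkS4class{RoiSet}.
#' @return list of n x 3 integer matrices of 1-based voxel indices.
#' @export
setGeneric("roiVoxels", function(x) standardGeneric("roiVoxels"))

#' ROI label accessor
#' @param x a \linkS4class{RoiSet}.
#' @return character vector of ROI labels.
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
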