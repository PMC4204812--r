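# Readers and writers: SPM-style rp_*.txt parameter files, TSV series,
# and NIfTI volumes (via RNifti).

#' Read an SPM-style realignment parameter file
#'
#' Whitespace-delimited, 6 columns (tx ty tz rx ry rz), one row per volume,
#' no header. Rotations are assumed to be in radians (the SPM convention)
#' unless \code{degrees = TRUE} is given explicitly; no unit heuristics are
#' applied.
#'
#' @param path path to an rp_*.txt-style file.
#' @param degrees set TRUE if the file stores rotations in degrees.
#' @param sourceLabel provenance label, defaults to the file name.
#' @return A \linkS4class{RealignmentParams}.
#' @export
readRealignmentParams <- function(path, degrees = FALSE,
                                  sourceLabel = basename(path)) {
    m <- as.matrix(read.table(path, header = FALSE))
    if (ncol(m) != 6L)
        stop("expected 6 columns in ", path, ", found ", ncol(m))
    if (degrees) m[, 4:6] <- m[, 4:6] * pi / 180
    RealignmentParams(m, sourceLabel = sourceLabel)
}

#' Write a realignment parameter file
#'
#' @param params a \linkS4class{RealignmentParams}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRealignmentParams <- function(params, path) {
    write.table(format(params@values, digits = 10, scientific = FALSE,
                       trim = TRUE),
                path, quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a displacement series as TSV
#'
#' Columns: \code{volume_index}, \code{displacement_mm} and, when a censor
#' result is supplied, \code{censored} (0/1).
#'
#' @param series a \linkS4class{DisplacementSeries}.
#' @param path output path.
#' @param censor optional \linkS4class{CensorResult} for the same series.
#' @return \code{path}, invisibly.
#' @export
writeDisplacementSeries <- function(series, path, censor = NULL) {
    df <- data.frame(volume_index = seq_along(series@values),
                     displacement_mm = series@values)
    if (!is.null(censor)) {
        stopifnot(length(censor@mask) == length(series@values))
        df$censored <- as.integer(censor@mask)
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a NIfTI volume into a VolumeGrid
#'
#' @param path a .nii or .nii.gz file.
#' @param repetitionTime TR in seconds, used when the file is 4-D.
#' @return A \linkS4class{VolumeGrid} (3-D) or \linkS4class{FmriSeries}
#'   (4-D).
#' @export
readVolume <- function(path, repetitionTime = 2) {
    img <- RNifti::readNifti(path)
    aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
    aff <- matrix(as.numeric(aff), 4L, 4L)
    a <- array(as.numeric(img), dim = dim(img))
    if (length(dim(a)) == 4L)
        FmriSeries(a, affine = aff, repetitionTime = repetitionTime)
    else
        VolumeGrid(a, affine = aff)
}

#' Write a VolumeGrid as NIfTI
#'
#' @param vol a \linkS4class{VolumeGrid} or \linkS4class{FmriSeries}.
#' @param path output .nii or .nii.gz path.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
    img <- RNifti::asNifti(vol@data)
    img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Export a labelled ROI mask volume
#'
#' Writes the 9 ROIs as one integer-labelled volume (labels 1-9 in ROI
#' order, 0 elsewhere) on the grid of \code{reference}.
#'
#' @param rois a \linkS4class{RoiSet}.
#' @param reference a \linkS4class{VolumeGrid} supplying grid and affine.
#' @param path optional NIfTI output path.
#' @return The labelled \linkS4class{VolumeGrid}, invisibly if written.
#' @export
roiLabelVolume <- function(rois, reference, path = NULL) {
    d <- dim(reference@data)[1:3]
    lab <- array(0, d)
    for (i in seq_along(rois@voxels)) {
        v <- rois@voxels[[i]]
        lab[v] <- i
    }
    out <- VolumeGrid(lab, affine = reference@affine)
    if (!is.null(path)) {
        writeVolume(out, path)
        return(invisible(out))
    }
    out
}
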