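# Average cortical distance d_avg: outer-surface extraction from a
# gray-matter mask and mean Euclidean distance to the image origin.

maskArray <- function(mask) {
    a <- mask@data
    if (length(dim(a)) != 3L) stop("mask must be 3-D")
    if (!all(a %in% c(0, 1))) stop("mask must be binary (0/1)")
    a
}

#' Outer-surface voxels of a binary mask
#'
#' Identifies the voxels on the exterior surface of the mask: mask voxels
#' 6-adjacent to background that is flood-fill reachable from the volume
#' border. Interior cavities (e.g. ventricles enclosed by the mask) are
#' thereby excluded. With \code{naive = TRUE} every mask voxel adjacent to
#' any background voxel is returned instead (cavity walls included).
#'
#' @param mask a binary 3-D \linkS4class{VolumeGrid}.
#' @param naive use the naive boundary definition (see above).
#' @return n x 3 integer matrix of 1-based voxel indices.
#' @export
outerSurfaceVoxels <- function(mask, naive = FALSE) {
    a <- maskArray(mask)
    if (sum(a) == 0) stop("mask is empty")
    d <- dim(a)
    if (naive) {
        bg <- a == 0
    } else {
        bg <- array(cpp_exterior_background(as.logical(a), as.integer(d)), d)
    }
    # pad with TRUE: outside the volume counts as exterior background
    pad <- array(TRUE, d + 2L)
    pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- bg
    i1 <- 2:(d[1L] + 1L); i2 <- 2:(d[2L] + 1L); i3 <- 2:(d[3L] + 1L)
    nb <- pad[i1 - 1L, i2, i3] | pad[i1 + 1L, i2, i3] |
          pad[i1, i2 - 1L, i3] | pad[i1, i2 + 1L, i3] |
          pad[i1, i2, i3 - 1L] | pad[i1, i2, i3 + 1L]
    which(a == 1 & nb, arr.ind = TRUE)
}

#' Average cortical distance from a gray-matter mask
#'
#' Computes d_avg: the mean Euclidean distance (3-D Pythagoras) from the
#' world-space origin to every voxel on the outer cortical surface of the
#' mask. The origin defaults to the affine's world origin (0, 0, 0).
#'
#' @param mask a binary 3-D \linkS4class{VolumeGrid} (gray-matter mask,
#'   typically resliced to 1 mm isotropic first).
#' @param origin world-space reference point in mm.
#' @param naive passed to \code{\link{outerSurfaceVoxels}}.
#' @return A \linkS4class{CorticalDistanceResult}.
#' @export
averageCorticalDistance <- function(mask, origin = c(0, 0, 0),
                                    naive = FALSE) {
    surf <- outerSurfaceVoxels(mask, naive = naive)
    world <- t(mask@affine %*% t(cbind(surf - 1, 1)))[, 1:3, drop = FALSE]
    lo <- apply(world, 2L, min); hi <- apply(world, 2L, max)
    if (any(origin < lo - 1e-9) || any(origin > hi + 1e-9))
        warning("origin lies outside the mask's field of view")
    dists <- sqrt(rowSums(sweep(world, 2L, origin, "-")^2))
    new("CorticalDistanceResult", dAvg = mean(dists),
        surfaceVoxelCount = nrow(surf), originWorld = as.numeric(origin))
}

#' Age trend of the average cortical distance in a cohort
#'
#' Least-squares slope of d_avg against age, converted to mm/year, with
#' Spearman rank correlation; intended for parameter-recovery checks on
#' synthetic cohorts.
#'
#' @param cohort data.frame with columns \code{age_months} and \code{d_avg}.
#' @return list with \code{slope_mm_per_year}, \code{intercept},
#'   \code{rho}, \code{p_value}, \code{n}.
#' @export
cohortTrend <- function(cohort) {
    stopifnot(all(c("age_months", "d_avg") %in% names(cohort)))
    if (nrow(cohort) < 3L) stop("need at least 3 subjects")
    if (length(unique(cohort$age_months)) < 2L)
        stop("ages are constant; trend is undefined")
    fit <- lm(d_avg ~ age_months, data = cohort)
    ct <- suppressWarnings(
        cor.test(cohort$age_months, cohort$d_avg, method = "spearman"))
    list(slope_mm_per_year = unname(coef(fit)[2L]) * 12,
         intercept = unname(coef(fit)[1L]),
         rho = unname(ct$estimate), p_value = ct$p.value,
         n = nrow(cohort))
}
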