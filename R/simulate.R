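# Seed-deterministic synthetic data: motion trajectories with drift and
# spikes, ellipsoid brain phantoms with gray-matter shells, age-trended
# cohorts, and motion-corrupted 4-D series with ground truth.

withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    eval.parent(substitute(expr))
}

#' Simulate a realignment parameter trajectory
#'
#' Generates slow random-walk drift plus sparse, abrupt position shifts
#' ("spikes": step changes that persist, as when a subject settles into a
#' new position). The first row is all zeros (realignment convention).
#' The drift component of each rotation is coupled to the same-axis
#' translation sign through \code{signConcordance} c in [-1, 1]: the
#' rotation carries the translation's sign with probability (1 + c)/2,
#' independently per volume, so c = 1 gives full concordance, c = -1 full
#' discordance and c = 0 independent signs (making the per-volume
#' sign-discordance counts exactly binomial). Spikes add a same-sign
#' rotation step. Rotation magnitudes follow their own random walk, with
#' drift and spike sizes scaled by 1/\code{leverArm} so that rotations
#' contribute displacements commensurate with translations at the
#' reference cortical distance.
#'
#' @param nVolumes number of volumes T (>= 2).
#' @param driftSd random-walk innovation SD for translations, mm per step.
#' @param spikeProbability per-volume probability of a spike.
#' @param spikeAmplitude range (mm) the absolute spike size is drawn from.
#' @param signConcordance translation/rotation sign coupling in [-1, 1].
#' @param leverArm distance (mm) used to scale rotation amplitudes.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with \code{params} (a \linkS4class{RealignmentParams}) and
#'   \code{spikes} (data.frame: \code{volume}, \code{axis},
#'   \code{amplitude_mm}).
#' @export
simulateMotion <- function(nVolumes, driftSd = 0.05,
                           spikeProbability = 0.02,
                           spikeAmplitude = c(0.5, 3),
                           signConcordance = 0, leverArm = 65,
                           seed = NULL) {
    stopifnot(nVolumes >= 2, spikeProbability >= 0, spikeProbability <= 1,
              abs(signConcordance) <= 1, leverArm > 0)
    withSeed(seed, {
        tt <- nVolumes
        trans <- apply(matrix(rnorm(3L * (tt - 1L), 0, driftSd),
                              tt - 1L, 3L), 2L, cumsum)
        trans <- rbind(rep(0, 3L), matrix(trans, tt - 1L, 3L))
        rotMag <- apply(matrix(rnorm(3L * (tt - 1L), 0,
                                     driftSd / leverArm),
                               tt - 1L, 3L), 2L, cumsum)
        rotMag <- abs(rbind(rep(0, 3L), matrix(rotMag, tt - 1L, 3L)))
        # spikes: persistent steps on a random translation axis, with a
        # same-sign rotation step scaled by the lever arm (one abrupt
        # repositioning affects both parameter families)
        spikeAt <- which(runif(tt - 1L) < spikeProbability) + 1L
        spikes <- data.frame(volume = integer(0), axis = integer(0),
                             amplitude_mm = numeric(0))
        rotSpike <- matrix(0, tt, 3L)
        for (s in spikeAt) {
            ax <- sample.int(3L, 1L)
            amp <- sample(c(-1, 1), 1L) *
                runif(1L, spikeAmplitude[1L], spikeAmplitude[2L])
            trans[s:tt, ax] <- trans[s:tt, ax] + amp
            rotSpike[s:tt, ax] <- rotSpike[s:tt, ax] + amp / leverArm
            spikes <- rbind(spikes,
                            data.frame(volume = s, axis = ax,
                                       amplitude_mm = amp))
        }
        # per-volume sign coupling of the drift component
        pPlus <- (1 + signConcordance) / 2
        flip <- matrix(ifelse(runif(3L * tt) < pPlus, 1, -1), tt, 3L)
        tSign <- sign(trans)
        tSign[tSign == 0] <- 1
        rot <- rotMag * tSign * flip + rotSpike
        rot[1L, ] <- 0
        params <- RealignmentParams(cbind(trans, rot),
                                    sourceLabel = "simulateMotion")
        list(params = params, spikes = spikes)
    })
}

#' Synthetic ellipsoid brain phantom
#'
#' Generates an ellipsoidal "brain" with smooth internal intensity
#' gradients (so that motion produces edge signal), a binary brain mask,
#' and a gray-matter shell mask of the requested thickness. The affine
#' places the world origin at the ellipsoid center shifted by
#' \code{originOffset}.
#'
#' @param semiAxes ellipsoid semi-axes in mm (length 3, or one value for a
#'   sphere).
#' @param spacing isotropic voxel size in mm, default 1.
#' @param shellThickness gray-matter shell thickness in mm, default 4.
#' @param contrast peak tissue intensity (arbitrary units), default 100.
#' @param noiseSd additive white Gaussian noise SD on the brain volume.
#' @param originOffset world-origin offset from the ellipsoid center (mm).
#' @param margin background margin around the ellipsoid, in voxels.
#' @param seed seed for the noise.
#' @return list of \linkS4class{VolumeGrid}s: \code{brain}, \code{mask},
#'   \code{gmShell}.
#' @export
syntheticBrain <- function(semiAxes = c(70, 60, 50), spacing = 1,
                           shellThickness = 4, contrast = 100,
                           noiseSd = 0, originOffset = c(0, 0, 0),
                           margin = 3, seed = NULL) {
    if (length(semiAxes) == 1L) semiAxes <- rep(semiAxes, 3L)
    stopifnot(length(semiAxes) == 3L, all(semiAxes > 0))
    if (shellThickness >= min(semiAxes))
        stop("shell thickness must be smaller than the smallest semi-axis")
    d <- as.integer(2 * ceiling(semiAxes / spacing) + 2L * margin + 1L)
    aff <- diag(c(rep(spacing, 3L), 1))
    # ellipsoid center at mid-grid; world origin = center + originOffset
    aff[1:3, 4L] <- -spacing * (d - 1) / 2 + originOffset
    cx <- spacing * (seq_len(d[1L]) - 1) + aff[1L, 4L] - originOffset[1L]
    cy <- spacing * (seq_len(d[2L]) - 1) + aff[2L, 4L] - originOffset[2L]
    cz <- spacing * (seq_len(d[3L]) - 1) + aff[3L, 4L] - originOffset[3L]
    ex <- (cx / semiAxes[1L])^2
    ey <- (cy / semiAxes[2L])^2
    ez <- (cz / semiAxes[3L])^2
    e <- outer(outer(ex, ey, "+"), ez, "+")
    mask <- (e <= 1) * 1
    inner <- semiAxes - shellThickness
    ei <- outer(outer((cx / inner[1L])^2, (cy / inner[2L])^2, "+"),
                (cz / inner[3L])^2, "+")
    gmShell <- ((e <= 1) & (ei > 1)) * 1
    grad <- 1 + 0.15 * outer(outer(cos(pi * cx / semiAxes[1L]),
                                   cos(pi * cy / semiAxes[2L])),
                             rep(1, d[3L]))
    brain <- contrast * (1 - 0.4 * e) * grad * mask
    if (noiseSd > 0)
        brain <- brain + withSeed(seed, array(rnorm(prod(d), 0, noiseSd), d))
    list(brain = VolumeGrid(brain, affine = aff),
         mask = VolumeGrid(mask, affine = aff),
         gmShell = VolumeGrid(gmShell, affine = aff))
}

#' Simulate a cohort of gray-matter shells with an age trend
#'
#' Spherical gray-matter shells whose outer radius (and hence expected
#' average cortical distance) grows linearly with age at the given slope,
#' plus Gaussian radius noise; used for slope-recovery checks with
#' \code{\link{cohortTrend}}.
#'
#' @param n number of subjects (>= 3).
#' @param ageRangeYears sampled uniformly, default 4-18 years.
#' @param slope d_avg increase in mm per year of age, default 0.18.
#' @param noiseSd per-subject radius noise in mm.
#' @param baseDavg expected d_avg (mm) at \code{refAgeYears}.
#' @param refAgeYears age anchoring \code{baseDavg}, default 11.
#' @param spacing voxel size in mm.
#' @param shellThickness shell thickness in mm.
#' @param seed integer seed.
#' @return list with \code{subjects} (list of gmShell
#'   \linkS4class{VolumeGrid}s), \code{ages} (data.frame: age_months,
#'   true_radius_mm).
#' @export
simulateCohort <- function(n = 60, ageRangeYears = c(4, 18), slope = 0.18,
                           noiseSd = 0.5, baseDavg = 61.58,
                           refAgeYears = 11, spacing = 1,
                           shellThickness = 3, seed = NULL) {
    stopifnot(n >= 3)
    withSeed(seed, {
        ages <- runif(n, ageRangeYears[1L], ageRangeYears[2L])
        radius <- baseDavg + slope * (ages - refAgeYears) +
            rnorm(n, 0, noiseSd)
        subjects <- lapply(radius, function(r)
            syntheticBrain(semiAxes = rep(r, 3L), spacing = spacing,
                           shellThickness = shellThickness,
                           contrast = 0)$gmShell)
        list(subjects = subjects,
             ages = data.frame(age_months = ages * 12,
                               true_radius_mm = radius))
    })
}

#' Simulate a motion-corrupted fMRI series
#'
#' Forward model of the phantom replay: each volume is the brain resampled
#' through that volume's rigid transform (the same pull-back convention as
#' \code{\link{buildPhantom}}), plus white Gaussian noise. With zero
#' parameters and zero noise all volumes equal the input brain.
#'
#' @param brain a 3-D \linkS4class{VolumeGrid}.
#' @param params a \linkS4class{RealignmentParams}; one volume per row.
#' @param noiseSd white-noise SD, default 0.
#' @param splineOrder interpolation order, default 7.
#' @param repetitionTime TR in seconds (metadata).
#' @param seed seed for the noise.
#' @return An \linkS4class{FmriSeries}.
#' @export
simulateFmri <- function(brain, params, noiseSd = 0, splineOrder = 7,
                         repetitionTime = 2, seed = NULL) {
    stopifnot(is(brain, "VolumeGrid"), length(dim(brain@data)) == 3L)
    tt <- nVolumes(params)
    d <- c(dim(brain@data), tt)
    out <- array(0, d)
    v <- params@values
    for (t in seq_len(tt)) {
        if (all(v[t, ] == 0)) {
            out[, , , t] <- brain@data
        } else {
            m <- paramsToTransform(v[t, ])
            out[, , , t] <- applyRigidTransform(brain, m,
                                                splineOrder = splineOrder)@data
        }
    }
    if (noiseSd > 0)
        out <- out + withSeed(seed, array(rnorm(prod(d), 0, noiseSd), d))
    FmriSeries(out, affine = brain@affine,
               repetitionTime = repetitionTime)
}

#' Ground-truth JSON for a simulated dataset
#'
#' Writes the spike log, true d_avg (when known) and true slope of a
#' simulation so that downstream checks can run without the generator.
#'
#' @param path output JSON path.
#' @param spikes spike log from \code{\link{simulateMotion}}.
#' @param trueDavg true average cortical distance in mm, if applicable.
#' @param trueSlope true cohort slope in mm/year, if applicable.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(path, spikes = NULL, trueDavg = NULL,
                             trueSlope = NULL) {
    jsonlite::write_json(
        list(spikes = spikes, true_davg_mm = trueDavg,
             true_slope_mm_per_year = trueSlope),
        path, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
}
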