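test_that("zero motion replays to the first volume exactly", {
    ph <- phantomFixture()
    pr <- RealignmentParams(matrix(0, 6, 6))
    base <- simulateFmri(ph$brain, pr)
    out <- buildPhantom(base, pr)
    first <- gridData(base)[, , , 1]
    for (t in 2:6)
        expect_lt(max(abs(gridData(out)[, , , t] - first)) /
                  max(abs(first)), 1e-6)
    expect_error(buildPhantom(base, RealignmentParams(matrix(0, 4, 6))),
                 "rows")
})

test_that("replay of an integer-voxel translation equals an array roll", {
    a <- array(0, c(12, 12, 12, 3))
    block <- array(1:27, c(3, 3, 3))
    for (t in 1:3) a[5:7, 5:7, 5:7, t] <- block
    ser <- FmriSeries(a, spacing = 1)
    # translation of -1 voxel in the transform shifts content +1 along x
    par <- RealignmentParams(rbind(rep(0, 6), c(-1, 0, 0, 0, 0, 0),
                                   c(-2, 0, 0, 0, 0, 0)))
    out <- gridData(buildPhantom(ser, par))
    expected2 <- array(0, c(12, 12, 12)); expected2[6:8, 5:7, 5:7] <- block
    expected3 <- array(0, c(12, 12, 12)); expected3[7:9, 5:7, 5:7] <- block
    expect_lt(max(abs(out[, , , 2] - expected2)), 1e-9)
    expect_lt(max(abs(out[, , , 3] - expected3)), 1e-9)
})

test_that("ROI derivation yields 9 disjoint interface regions", {
    ph <- phantomFixture()
    rois <- deriveRois(ph$mask)
    expect_length(roiVoxels(rois), 9)
    expect_equal(roiLabels(rois)[9], "center")
    a <- gridData(ph$mask)
    surf <- outerSurfaceVoxels(ph$mask)
    surfKey <- paste(surf[, 1], surf[, 2], surf[, 3])
    near <- array(FALSE, dim(a))
    near[surf] <- TRUE
    for (ci in 1:8) {
        v <- roiVoxels(rois)[[ci]]
        # corner ROIs hug the boundary shell: every voxel is a surface
        # voxel or 6-adjacent to one
        for (r in seq_len(nrow(v))) {
            nb <- rbind(v[r, ], sweep(matrix(v[r, ], 6, 3, byrow = TRUE),
                                      2, 0, "+") +
                        rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
            keys <- paste(nb[, 1], nb[, 2], nb[, 3])
            expect_true(any(keys %in% surfKey))
        }
    }
    # center ROI strictly interior
    cv <- roiVoxels(rois)[[9]]
    expect_true(all(a[cv] == 1))
    expect_false(any(paste(cv[, 1], cv[, 2], cv[, 3]) %in% surfKey))
    expect_error(deriveRois(VolumeGrid(array(0, c(10, 10, 10)))), "empty")
})

test_that("corner ROIs of a sphere sit at the sphere radius", {
    R <- 16
    ph <- syntheticBrain(semiAxes = R, spacing = 2, shellThickness = 4)
    rois <- deriveRois(ph$mask)
    aff <- gridAffine(ph$mask)
    for (ci in 1:8) {
        v <- roiVoxels(rois)[[ci]]
        world <- t(aff %*% t(cbind(v - 1, 1)))[, 1:3, drop = FALSE]
        radii <- sqrt(rowSums(world^2))
        expect_lt(abs(mean(radii) - R), 2 * 2) # within one voxel (2 mm) x2
    }
})

test_that("ROI traces equal hand-computed voxel means", {
    a <- array(0, c(10, 10, 10, 4))
    a[2, 3, 4, ] <- c(1, 2, 3, 4)
    a[5, 5, 5, ] <- 10
    ser <- FmriSeries(a, spacing = 1)
    rois <- new("RoiSet",
                voxels = c(list(matrix(c(2, 3, 4), 1, 3)),
                           lapply(1:7, function(i) matrix(c(i, 1, 1), 1, 3)),
                           list(rbind(c(5, 5, 5), c(5, 5, 6)))),
                labels = c(paste0("corner_", 1:8), "center"))
    tr <- roiTraces(ser, rois)
    expect_equal(tr[1, ], c(1, 2, 3, 4)) # single-voxel ROI = its course
    expect_equal(tr[9, ], rep(5, 4)) # mean of 10 and 0
    expect_equal(tr[2, ], rep(0, 4))
    bad <- new("RoiSet",
               voxels = c(list(matrix(c(11, 1, 1), 1, 3)),
                          lapply(2:9, function(i) matrix(c(i, 1, 1), 1, 3))),
               labels = c(paste0("corner_", 1:8), "center"))
    expect_error(roiTraces(ser, bad), "outside")
})

test_that("signal-change scoring follows its arithmetic definition", {
    flat <- matrix(5, 9, 6)
    expect_equal(signalChangeScore(flat)@score, 0)
    step <- flat
    step[3, 2:6] <- 7 # one ROI steps by +2 at every t > 1
    expect_equal(signalChangeScore(step)@score, 2 / 9)
    expect_error(signalChangeScore(flat[, 1, drop = FALSE]), "2 volumes")
    # mean baseline flag
    sc <- signalChangeScore(step, baseline = "mean")
    expect_gt(sc@score, 0)
})

test_that("zero-motion pipeline score stays below the interpolation-noise bound", {
    ph <- phantomFixture()
    pr <- RealignmentParams(matrix(0, 5, 6))
    base <- simulateFmri(ph$brain, pr)
    rois <- deriveRois(ph$mask)
    sc <- signalChangeScore(roiTraces(buildPhantom(base, pr), rois))
    amplitude <- max(abs(gridData(ph$brain)))
    expect_lt(sc@score, 1e-3 * amplitude)
})

test_that("doubling the motion never decreases the replay score", {
    ph <- phantomFixture()
    sm <- simulateMotion(8, driftSd = 0.15, spikeProbability = 0.2,
                         seed = 81)
    base <- simulateFmri(ph$brain, RealignmentParams(matrix(0, 8, 6)))
    rois <- deriveRois(ph$mask)
    s1 <- signalChangeScore(roiTraces(buildPhantom(base, sm$params),
                                      rois))@score
    doubled <- RealignmentParams(2 * paramValues(sm$params))
    s2 <- signalChangeScore(roiTraces(buildPhantom(base, doubled),
                                      rois))@score
    expect_gte(s2, s1)
})

test_that("reduced-set replay scores fall on both sides of the complete score", {
    ph <- phantomFixture()
    rois <- deriveRois(ph$mask)
    score <- function(rows, set) {
        par <- RealignmentParams(rows)
        base <- simulateFmri(ph$brain,
                             RealignmentParams(matrix(0, nrow(rows), 6)))
        red <- reduceParams(par, set)
        signalChangeScore(roiTraces(buildPhantom(base, red), rois),
                          parameterSet = set)@score
    }
    # a large shift with a co-rotation that pulls part of the brain back:
    # dropping the rotation increases the apparent signal change
    over <- rbind(rep(0, 6), c(8, 0, 0, 0, 0, 0.35))
    expect_gt(score(over, "translation_only"), score(over, "complete"))
    # a counter-rotation that adds to the shift: dropping it undershoots
    under <- rbind(rep(0, 6), c(4, 0, 0, 0, 0, -0.5))
    expect_lt(score(under, "translation_only"), score(under, "complete"))
})

test_that("corner ROIs respond more strongly to rotation than the center", {
    R <- 16
    ph <- syntheticBrain(semiAxes = R, spacing = 2, shellThickness = 4)
    rois <- deriveRois(ph$mask)
    rot <- RealignmentParams(rbind(rep(0, 6),
                                   c(0, 0, 0, 0.06, 0, 0.06),
                                   c(0, 0, 0, -0.06, 0.06, 0)))
    base <- simulateFmri(ph$brain, RealignmentParams(matrix(0, 3, 6)))
    sc <- signalChangeScore(roiTraces(buildPhantom(base, rot), rois))
    expect_gt(mean(sc@perRoi[1:8]), sc@perRoi[9])
})

test_that("fingerprint designs have the contracted shape and PCA is faithful", {
    set.seed(82)
    traces <- matrix(rnorm(9 * 30), 9, 30)
    expect_equal(ncol(designMatrix(fingerprintTraces(traces, 3, TRUE))), 6)
    expect_equal(ncol(designMatrix(fingerprintTraces(traces, 9, TRUE))), 18)
    expect_equal(ncol(designMatrix(fingerprintTraces(traces, 3, FALSE))), 3)
    expect_error(fingerprintTraces(traces, 5), "3 or 9")
    # rank-1 traces: PC1 carries essentially all variance
    r1 <- outer(rnorm(9), rnorm(30))
    d <- designMatrix(fingerprintTraces(r1, 3, FALSE))
    vars <- apply(d, 2, var)
    expect_gt(vars[1] / sum(vars), 0.999)
    # PCA scores equal eigendecomposition of the 9 x 9 covariance, up to sign
    x <- scale(t(traces), center = TRUE, scale = FALSE)
    ev <- eigen(crossprod(x))
    scores <- x %*% ev$vectors[, 1:3]
    mine <- designMatrix(fingerprintTraces(traces, 3, FALSE))
    for (j in 1:3) {
        s <- sign(sum(scores[, j] * mine[, j]))
        expect_equal(unname(mine[, j]), unname(s * scores[, j]),
                     tolerance = 1e-8)
    }
    # lag columns are zero-padded single shifts
    d6 <- designMatrix(fingerprintTraces(traces, 3, TRUE))
    expect_equal(unname(d6[1, 4:6]), c(0, 0, 0))
    expect_equal(unname(d6[-1, 4]), unname(d6[-nrow(d6), 1]))
})
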