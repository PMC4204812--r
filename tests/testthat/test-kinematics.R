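test_that("parameter rows map to valid rigid transforms", {
    expect_equal(transformMatrix(paramsToTransform(rep(0, 6))), diag(4))
    m <- transformMatrix(paramsToTransform(c(3, 0, 0, 0, 0, 0)))
    expect_equal(m[, 4], c(3, 0, 0, 1))
    m <- transformMatrix(paramsToTransform(c(0, 0, 0, 0, 0, pi / 2)))
    expect_equal(as.numeric(m[1:3, 1:3] %*% c(1, 0, 0)), c(0, 1, 0),
                 tolerance = 1e-12)
    # orthonormality for random rows
    for (i in 1:5) {
        r <- randomParamRows(1, seed = i, rotSd = 0.3)
        mm <- transformMatrix(paramsToTransform(as.numeric(r)))
        expect_lt(max(abs(crossprod(mm[1:3, 1:3]) - diag(3))), 1e-12)
        expect_equal(det(mm[1:3, 1:3]), 1, tolerance = 1e-12)
    }
    expect_error(paramsToTransform(c(1, NA, 0, 0, 0, 0)), "finite")
})

test_that("transform decomposition inverts composition", {
    for (i in 1:10) {
        p <- as.numeric(randomParamRows(1, seed = 100 + i, rotSd = 0.2))
        m <- paramsToTransform(p)
        expect_equal(motionQC:::decomposeTransform(m), p,
                     tolerance = 1e-10)
    }
})

test_that("reduceParams zeroes the complementary columns and copies", {
    p <- RealignmentParams(c(1, 2, 3, .01, .02, .03))
    to <- reduceParams(p, "translation_only")
    ro <- reduceParams(p, "rotation_only")
    expect_equal(as.numeric(paramValues(to)), c(1, 2, 3, 0, 0, 0))
    expect_equal(as.numeric(paramValues(ro)), c(0, 0, 0, .01, .02, .03))
    expect_equal(as.numeric(paramValues(p)), c(1, 2, 3, .01, .02, .03))
    z <- RealignmentParams(rep(0, 6))
    expect_equal(paramValues(reduceParams(z, "translation_only")),
                 paramValues(z))
    expect_error(reduceParams(p, "bogus"))
})

test_that("displacement series match closed-form cases", {
    z <- RealignmentParams(matrix(0, 5, 6))
    for (method in c("fig1_vector_sum", "sphere_mean", "reference_point"))
        for (mode in c("absolute", "relative"))
            expect_equal(displacement(displacementSeries(
                z, 65, mode, method)), rep(0, 5))
    p <- RealignmentParams(rbind(rep(0, 6), c(3, 4, 0, 0, 0, 0)))
    expect_equal(displacement(displacementSeries(p, 65))[2], 5)
    p <- RealignmentParams(rbind(rep(0, 6), c(0, 0, 0, 0, 0, 0.01)))
    expect_equal(displacement(displacementSeries(p, 65))[2], 0.65)
    expect_error(displacementSeries(p, dAvg = -1), "positive")
})

test_that("pure translations are invariant to the reference distance", {
    rows <- randomParamRows(10, seed = 7)
    rows[, 4:6] <- 0
    rows[1, ] <- 0
    p <- RealignmentParams(rows)
    for (method in c("fig1_vector_sum", "sphere_mean", "reference_point")) {
        a <- displacement(displacementSeries(p, 50, method = method))
        b <- displacement(displacementSeries(p, 80, method = method))
        expect_equal(a, b, tolerance = 1e-12)
    }
})

test_that("sphere_mean agrees with a dense Monte-Carlo oracle", {
    rows <- randomParamRows(20, seed = 11)
    for (i in seq_len(nrow(rows))) {
        impl <- displacement(displacementSeries(
            RealignmentParams(rbind(rep(0, 6), rows[i, ])), 65,
            method = "sphere_mean"))[2]
        oracle <- bruteSphereDisplacement(rows[i, ], 65, 1e5, seed = i)
        expect_lt(abs(impl - oracle) / oracle, 0.005)
    }
})

test_that("sphere_mean matches the small-angle closed form", {
    for (phi in c(0.05, 0.02, 0.005)) {
        for (axis in 4:6) {
            row <- rep(0, 6)
            row[axis] <- phi
            impl <- displacement(displacementSeries(
                RealignmentParams(rbind(rep(0, 6), row)), 65,
                method = "sphere_mean"))[2]
            expected <- (pi / 4) * 2 * 65 * sin(phi / 2)
            expect_lt(abs(impl - expected) / expected, 0.01)
        }
    }
})

test_that("translation and rotation contributions can cancel", {
    # same-axis translation and rotation of opposite sign cancel under the
    # component-wise pairing, so the reduced set can exceed the complete set
    row <- c(1, 0, 0, -1 / 65, 0, 0)
    p <- RealignmentParams(rbind(rep(0, 6), row))
    tdComplete <- displacement(displacementSeries(p, 65))[2]
    tdTo <- displacement(displacementSeries(
        p, 65, parameterSet = "translation_only"))[2]
    expect_equal(tdComplete, 0)
    expect_gt(tdTo, tdComplete)
})

test_that("relative series of a constant trajectory is zero after t=1", {
    rows <- matrix(rep(c(1, 2, 3, .01, .02, .03), each = 6), 6, 6)
    p <- RealignmentParams(rows)
    for (rm in c("diff", "compose")) {
        rel <- displacement(displacementSeries(p, 65, mode = "relative",
                                               relativeMethod = rm))
        expect_equal(rel, rep(0, 6), tolerance = 1e-12)
    }
})

test_that("compositional relative motion agrees with differencing for pure translations", {
    rows <- randomParamRows(8, seed = 21)
    rows[, 4:6] <- 0
    rows[1, ] <- 0
    p <- RealignmentParams(rows)
    a <- displacement(displacementSeries(p, 65, mode = "relative"))
    b <- displacement(displacementSeries(p, 65, mode = "relative",
                                         relativeMethod = "compose"))
    expect_equal(a, b, tolerance = 1e-10)
})

test_that("d_avg sweep is flat for translations and linear for rotations", {
    rows <- randomParamRows(20, seed = 31)
    rows[1, ] <- 0
    pureT <- rows
    pureT[, 4:6] <- 0
    swT <- davgSensitivitySweep(RealignmentParams(pureT))
    expect_equal(nrow(swT), 61)
    expect_true(all(abs(swT$percent_absolute - 100) < 1e-9))
    expect_true(all(abs(swT$percent_relative - 100) < 1e-9))
    pureR <- rows
    pureR[, 1:3] <- 0
    swR <- davgSensitivitySweep(RealignmentParams(pureR))
    expect_equal(swR$percent_absolute, 100 * swR$d_avg / 65,
                 tolerance = 1e-9)
    expect_equal(swR$percent_absolute[swR$d_avg == 60], 100 * 60 / 65,
                 tolerance = 1e-9)
    expect_error(davgSensitivitySweep(RealignmentParams(pureR),
                                      dMin = 70), "dMin")
})

test_that("d_avg sweep matches direct recomputation on mixed motion", {
    rows <- randomParamRows(30, seed = 41)
    rows[1, ] <- 0
    p <- RealignmentParams(rows)
    sw <- davgSensitivitySweep(p)
    ref <- median(displacement(displacementSeries(p, 65)))
    for (d in c(52, 65, 71.5)) {
        direct <- 100 * median(displacement(displacementSeries(p, d))) / ref
        expect_equal(sw$percent_absolute[abs(sw$d_avg - d) < 1e-9], direct,
                     tolerance = 1e-9)
    }
})

test_that("sign discordance counts strict opposite-sign pairs", {
    same <- RealignmentParams(matrix(rep(c(1, 1, 1, .1, .1, .1), 4),
                                     4, 6, byrow = TRUE))
    expect_equal(signDiscordance(same)@perAxis, c(0L, 0L, 0L))
    opp <- RealignmentParams(matrix(rep(c(1, 1, 1, -.1, .1, -.1), 4),
                                    4, 6, byrow = TRUE))
    expect_equal(signDiscordance(opp)@perAxis, c(4L, 0L, 4L))
    # zeros are concordant
    zr <- RealignmentParams(rbind(c(1, 0, -1, 0, 0.1, 0)))
    expect_equal(zr |> signDiscordance() |> slot("perAxis"), c(0L, 0L, 0L))
    # independent fair coins: binomial oracle
    set.seed(5)
    n <- 1e4
    rows <- cbind(matrix(sample(c(-1, 1), 3 * n, TRUE), n, 3),
                  matrix(sample(c(-1, 1), 3 * n, TRUE), n, 3))
    cnt <- signDiscordance(RealignmentParams(rows))@perAxis
    sigma <- sqrt(n * 0.25)
    expect_true(all(abs(cnt - n / 2) < 3 * sigma))
})

test_that("rp files round-trip through read and write", {
    rows <- randomParamRows(12, seed = 51)
    p <- RealignmentParams(rows, sourceLabel = "fixture")
    f <- withr::local_tempfile(fileext = ".txt")
    writeRealignmentParams(p, f)
    back <- readRealignmentParams(f)
    expect_equal(unname(paramValues(back)), unname(rows),
                 tolerance = 1e-8)
    # degrees flag converts at read time
    f2 <- withr::local_tempfile(fileext = ".txt")
    rowsDeg <- rows
    rowsDeg[, 4:6] <- rowsDeg[, 4:6] * 180 / pi
    write.table(rowsDeg, f2, row.names = FALSE, col.names = FALSE)
    backDeg <- readRealignmentParams(f2, degrees = TRUE)
    expect_equal(unname(paramValues(backDeg)), unname(rows),
                 tolerance = 1e-8)
})
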