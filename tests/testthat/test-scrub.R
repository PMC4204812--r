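mkSeries <- function(vals, mode = "relative") {
    new("DisplacementSeries", values = vals, mode = mode,
        method = "fig1_vector_sum", dAvg = 65, parameterSet = "complete")
}

test_that("censoring uses a strict threshold and spares volume 1", {
    s <- mkSeries(c(0, .4, .6, 2.0))
    cr <- censorSeries(s, 0.5)
    expect_equal(discardedCount(cr), 2L)
    expect_equal(censorMask(cr), c(FALSE, FALSE, TRUE, TRUE))
    # ties at the cutoff are kept ("exceeding" is strict)
    expect_equal(discardedCount(censorSeries(mkSeries(c(0, 0.5)), 0.5)), 0L)
    expect_equal(discardedCount(censorSeries(s, 99)), 0L)
    expect_error(censorSeries(s, 0), "positive")
    expect_error(censorSeries(s, -1), "positive")
})

test_that("discarded counts are monotone non-increasing in the cutoff", {
    sm <- simulateMotion(300, driftSd = 0.1, spikeProbability = 0.05,
                         seed = 61)
    for (mode in c("absolute", "relative"))
        for (set in c("complete", "translation_only", "rotation_only")) {
            ser <- displacementSeries(sm$params, 65, mode = mode,
                                      parameterSet = set)
            counts <- vapply(c(0.5, 1, 1.5, 2, 2.5, 3), function(cu)
                discardedCount(censorSeries(ser, cu)), integer(1))
            expect_true(all(diff(counts) <= 0))
        }
})

test_that("injected supra-threshold steps are each censored once in relative mode", {
    sm <- simulateMotion(200, driftSd = 0, spikeProbability = 0.04,
                         spikeAmplitude = c(1.5, 3), seed = 62)
    k <- nrow(sm$spikes)
    expect_gt(k, 0)
    ser <- displacementSeries(sm$params, 65, mode = "relative")
    cr <- censorSeries(ser, 1)
    expect_equal(discardedCount(cr), k)
    expect_equal(which(censorMask(cr)), sort(sm$spikes$volume))
})

test_that("the scrub table matches independent censor calls cell by cell", {
    sm <- simulateMotion(150, driftSd = 0.15, spikeProbability = 0.05,
                         seed = 63)
    cutoffs <- c(0.5, 1, 2)
    tab <- scrubTable(sm$params, dAvg = 65, cutoffs = cutoffs)
    for (r in seq_len(nrow(tab))) {
        ser <- displacementSeries(sm$params, 65, mode = tab$mode[r],
                                  parameterSet = tab$parameter_set[r])
        expect_equal(tab$n_discarded[r],
                     discardedCount(censorSeries(ser, tab$cutoff_mm[r])))
        refSer <- displacementSeries(sm$params, 65, mode = tab$mode[r])
        refCount <- discardedCount(censorSeries(refSer, tab$cutoff_mm[r]))
        if (refCount == 0) {
            expect_true(is.na(tab$percent_of_complete[r]))
        } else {
            expect_equal(tab$percent_of_complete[r],
                         100 * tab$n_discarded[r] / refCount)
        }
    }
})

test_that("lossless reductions give 100% and empty reductions give zero", {
    rows <- randomParamRows(80, seed = 64, transSd = 0.8)
    rows[1, ] <- 0
    pureT <- rows; pureT[, 4:6] <- 0
    tab <- scrubTable(RealignmentParams(pureT), cutoffs = c(0.5, 1))
    to <- tab[tab$parameter_set == "translation_only", ]
    comp <- tab[tab$parameter_set == "complete", ]
    expect_equal(to$n_discarded, comp$n_discarded)
    expect_true(all(to$percent_of_complete[comp$n_discarded > 0] == 100))
    pureR <- rows * 0; pureR[, 4:6] <- rnorm(3 * 80, 0, 0.02)
    pureR[1, ] <- 0
    tabR <- scrubTable(RealignmentParams(pureR), cutoffs = c(0.5, 1))
    expect_true(all(tabR$n_discarded[
        tabR$parameter_set == "translation_only"] == 0))
})

test_that("reduced sets can discard both fewer and more volumes", {
    # cancellation: complete displacement small, translation-only large
    cancel <- rbind(rep(0, 6),
                    matrix(rep(c(2, 0, 0, -2 / 65, 0, 0), 10), 10, 6,
                           byrow = TRUE))
    tabC <- scrubTable(RealignmentParams(cancel), cutoffs = 1)
    nC <- function(tab, set, mode)
        tab$n_discarded[tab$parameter_set == set & tab$mode == mode]
    expect_gt(nC(tabC, "translation_only", "absolute"),
              nC(tabC, "complete", "absolute"))
    # additive: complete exceeds both reductions
    add <- rbind(rep(0, 6),
                 matrix(rep(c(0.8, 0, 0, 0.8 / 65, 0, 0), 10), 10, 6,
                        byrow = TRUE))
    tabA <- scrubTable(RealignmentParams(add), cutoffs = 1)
    expect_gt(nC(tabA, "complete", "absolute"),
              nC(tabA, "translation_only", "absolute"))
})

test_that("censored volumes satisfy the triangle-inequality bound", {
    sm <- simulateMotion(200, driftSd = 0.2, spikeProbability = 0.05,
                         seed = 65)
    ser <- displacementSeries(sm$params, 65, mode = "absolute")
    cutoff <- 1
    cr <- censorSeries(ser, cutoff)
    v <- paramValues(sm$params)
    tNorm <- sqrt(rowSums(v[, 1:3]^2))
    rNorm <- sqrt(rowSums(v[, 4:6]^2))
    expect_true(all((tNorm + 65 * rNorm)[censorMask(cr)] >= cutoff))
})

test_that("cohort tables support pooled and median aggregation", {
    cohort <- lapply(1:3, function(s)
        simulateMotion(60, driftSd = 0.2, spikeProbability = 0.1,
                       seed = 70 + s)$params)
    pooled <- scrubTable(cohort, cutoffs = c(0.5, 1))
    expect_equal(unique(pooled$n_total), sum(vapply(cohort, nVolumes, 1L)))
    med <- scrubTable(cohort, cutoffs = c(0.5, 1), aggregate = "median")
    expect_equal(pooled$n_discarded, med$n_discarded) # counts identical
    f <- withr::local_tempfile(fileext = ".tsv")
    writeScrubTable(pooled, f)
    txt <- readLines(f)
    expect_length(txt, 7) # header + 3 sets x 2 modes
})
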