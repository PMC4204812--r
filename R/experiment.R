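# Orchestration: reproducible experiment pipelines over synthetic (or
# supplied) inputs, with declarative config and TSV/JSON reports.

#' Build a run configuration
#'
#' Collects the tunable settings of the experiment pipelines with their
#' defaults: reference cortical distance 65 mm, the fig1_vector_sum
#' displacement method, scrubbing cutoffs 0.5-3 mm, all three parameter
#' sets, spline order 7. A config round-trips through its JSON file
#' representation.
#'
#' @param dAvg reference cortical distance in mm.
#' @param method displacement method.
#' @param cutoffs scrubbing cutoffs in mm.
#' @param parameterSets parameter sets to assess.
#' @param splineOrder B-spline interpolation order.
#' @param seed integer seed driving all randomness.
#' @param nSubjects synthetic cohort size for displacement/scrub/replay
#'   pipelines.
#' @param nVolumesPerSubject synthetic series length.
#' @param outputDir report directory.
#' @return A named list of class \code{runConfig}.
#' @export
runConfig <- function(dAvg = 65, method = "fig1_vector_sum",
                      cutoffs = c(0.5, 1, 1.5, 2, 2.5, 3),
                      parameterSets = c("complete", "translation_only",
                                        "rotation_only"),
                      splineOrder = 7, seed = 1, nSubjects = 12,
                      nVolumesPerSubject = 120, outputDir = tempdir()) {
    structure(list(dAvg = dAvg, method = method, cutoffs = cutoffs,
                   parameterSets = parameterSets,
                   splineOrder = splineOrder, seed = seed,
                   nSubjects = nSubjects,
                   nVolumesPerSubject = nVolumesPerSubject,
                   outputDir = outputDir),
              class = "runConfig")
}

#' Write / read a run configuration
#'
#' @param config a \code{runConfig} list.
#' @param path JSON path.
#' @return \code{readRunConfig} returns the \code{runConfig}.
#' @export
writeRunConfig <- function(config, path) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(runConfig, x)
}

simulateCohortMotion <- function(config) {
    lapply(seq_len(config$nSubjects), function(s)
        simulateMotion(config$nVolumesPerSubject,
                       seed = config$seed * 1000L + s)$params)
}

#' Run a named experiment pipeline
#'
#' Orchestrates the analysis pipelines on synthetic inputs generated from
#' the config seed, writing deterministic TSV/JSON reports to the output
#' directory:
#' \describe{
#'   \item{simulate}{writes rp_*.txt trajectories plus ground truth.}
#'   \item{davg}{sphere-phantom average cortical distance report.}
#'   \item{displacement}{reduced-set median displacement as percent of the
#'     complete set, plus the d_avg sensitivity sweep.}
#'   \item{scrub}{the cutoff table (counts and percent-of-complete).}
#'   \item{replay}{phantom-replay signal-change scores per parameter set.}
#'   \item{varexp}{variance explained per design set relative to
#'     volterra24.}
#'   \item{all}{every pipeline above.}
#' }
#' Percent-of-reference summaries are reported as median with min-max
#' range.
#'
#' @param name pipeline name, see Details.
#' @param config a \code{\link{runConfig}}.
#' @return named list of report file paths, invisibly.
#' @export
runExperiment <- function(name = c("all", "simulate", "davg",
                                   "displacement", "scrub", "replay",
                                   "varexp"),
                          config = runConfig()) {
    name <- match.arg(name)
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    out <- list()
    writeRunConfig(config, file.path(config$outputDir, "config.json"))
    if (name %in% c("simulate", "all")) {
        cohort <- simulateCohortMotion(config)
        for (s in seq_along(cohort)) {
            p <- file.path(config$outputDir,
                           sprintf("rp_subject%02d.txt", s))
            writeRealignmentParams(cohort[[s]], p)
        }
        out$simulate <- config$outputDir
    }
    if (name %in% c("davg", "all")) {
        phantom <- syntheticBrain(semiAxes = rep(config$dAvg, 3L),
                                  shellThickness = 3, contrast = 0)
        res <- averageCorticalDistance(phantom$gmShell)
        p <- file.path(config$outputDir, "davg.json")
        jsonlite::write_json(list(d_avg_mm = res@dAvg,
                                  surface_voxel_count =
                                      res@surfaceVoxelCount,
                                  origin_world = res@originWorld),
                             p, auto_unbox = TRUE, digits = NA)
        out$davg <- p
    }
    if (name %in% c("displacement", "scrub", "replay", "varexp", "all")) {
        cohort <- simulateCohortMotion(config)
    }
    if (name %in% c("displacement", "all")) {
        pct <- function(set, mode) vapply(cohort, function(par) {
            comp <- median(displacement(displacementSeries(
                par, config$dAvg, mode = mode, method = config$method)))
            red <- median(displacement(displacementSeries(
                par, config$dAvg, mode = mode, method = config$method,
                parameterSet = set)))
            if (comp > 0) 100 * red / comp else NA_real_
        }, numeric(1L))
        rows <- expand.grid(parameter_set = setdiff(config$parameterSets,
                                                    "complete"),
                            mode = DISPLACEMENT_MODES,
                            stringsAsFactors = FALSE)
        rows$median_percent <- NA_real_
        rows$min_percent <- NA_real_
        rows$max_percent <- NA_real_
        for (r in seq_len(nrow(rows))) {
            v <- pct(rows$parameter_set[r], rows$mode[r])
            rows$median_percent[r] <- median(v, na.rm = TRUE)
            rows$min_percent[r] <- min(v, na.rm = TRUE)
            rows$max_percent[r] <- max(v, na.rm = TRUE)
        }
        p <- file.path(config$outputDir, "displacement_percent.tsv")
        write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
        sweep <- davgSensitivitySweep(cohort[[1L]], dRef = config$dAvg,
                                      method = config$method)
        ps <- file.path(config$outputDir, "davg_sweep.tsv")
        write.table(sweep, ps, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        out$displacement <- p
        out$davg_sweep <- ps
    }
    if (name %in% c("scrub", "all")) {
        tab <- scrubTable(cohort, dAvg = config$dAvg,
                          cutoffs = config$cutoffs,
                          method = config$method)
        p <- file.path(config$outputDir, "scrub_table.tsv")
        writeScrubTable(tab, p)
        write.table(tab, file.path(config$outputDir, "scrub_long.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        out$scrub <- p
    }
    if (name %in% c("replay", "varexp", "all")) {
        brain <- syntheticBrain(semiAxes = c(22, 18, 16), spacing = 2,
                                shellThickness = 4)
        nRep <- min(length(cohort), 4L)
        scores <- lapply(seq_len(nRep), function(s) {
            par <- cohort[[s]]
            base <- simulateFmri(brain$brain, RealignmentParams(
                matrix(0, nVolumes(par), 6L)))
            rois <- deriveRois(brain$mask)
            vapply(config$parameterSets, function(set) {
                ph <- buildPhantom(base, reduceParams(par, set),
                                   splineOrder = config$splineOrder)
                signalChangeScore(roiTraces(ph, rois), set)@score
            }, numeric(1L))
        })
        scores <- do.call(rbind, scores)
    }
    if (name %in% c("replay", "all")) {
        ref <- scores[, "complete"]
        rows <- do.call(rbind, lapply(
            setdiff(config$parameterSets, "complete"), function(set) {
                v <- 100 * scores[, set] / ref
                data.frame(parameter_set = set,
                           median_percent = median(v),
                           min_percent = min(v), max_percent = max(v))
            }))
        p <- file.path(config$outputDir, "replay_scores.tsv")
        write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
        out$replay <- p
    }
    if (name %in% c("varexp", "all")) {
        par <- cohort[[1L]]
        series <- simulateFmri(brain$brain, par, noiseSd = 3,
                               splineOrder = config$splineOrder,
                               seed = config$seed)
        maskVox <- brain$mask
        ref <- fitGlm(series, buildDesign(par, "volterra24"), maskVox)
        sets <- c("rps_complete", "rps_to", "rps_ro")
        rows <- do.call(rbind, lapply(sets, function(s) {
            fit <- fitGlm(series, buildDesign(par, s), maskVox)
            data.frame(set = s, mean_r2 = fit@meanR2,
                       percent_of_reference =
                           percentOfReference(fit, ref))
        }))
        rows <- rbind(data.frame(set = "volterra24", mean_r2 = ref@meanR2,
                                 percent_of_reference = 100), rows)
        p <- file.path(config$outputDir, "varexp.tsv")
        write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
        out$varexp <- p
    }
    invisible(out)
}
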