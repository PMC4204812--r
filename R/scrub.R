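# Motion scrubbing: admissible-motion cutoffs on displacement series and
# the complete-vs-reduced summary table.

#' Censor volumes exceeding an admissible-motion cutoff
#'
#' Marks every volume whose displacement strictly exceeds the cutoff
#' ("exceeding": ties at exactly the cutoff are kept). Volume 1 has zero
#' displacement by convention and is never censored.
#'
#' @param series a \linkS4class{DisplacementSeries}.
#' @param cutoff admissible motion in mm; must be > 0.
#' @return A \linkS4class{CensorResult}.
#' @export
censorSeries <- function(series, cutoff) {
    if (!is.finite(cutoff) || cutoff <= 0)
        stop("cutoff must be a positive distance in mm")
    mask <- series@values > cutoff
    new("CensorResult", mask = mask, cutoffMm = cutoff,
        discardedCount = sum(mask), mode = series@mode,
        parameterSet = series@parameterSet)
}

#' Scrubbing summary over parameter sets, modes and cutoffs
#'
#' Counts discarded volumes for every combination of parameter set
#' (complete, translation_only, rotation_only), displacement mode
#' (absolute, relative) and cutoff, and relates each reduced-set count to
#' the complete-set count at the same mode and cutoff (complete = 100%).
#' When the complete-set count is 0 the percentage is undefined and
#' reported as NA.
#'
#' Accepts one trajectory or a list of trajectories (a cohort). With
#' \code{aggregate = "pooled"} datapoints are pooled across subjects before
#' percentages are formed (counts are summed, percentages computed from
#' the totals); with \code{"median"} percentages are computed per subject
#' and the median is reported alongside summed counts.
#'
#' @param params a \linkS4class{RealignmentParams} or list thereof.
#' @param dAvg reference cortical distance in mm.
#' @param cutoffs cutoff values in mm, default 0.5/1/1.5/2/2.5/3.
#' @param method displacement method.
#' @param aggregate cohort aggregation, "pooled" (default) or "median".
#' @return data.frame with columns \code{parameter_set}, \code{mode},
#'   \code{cutoff_mm}, \code{n_discarded}, \code{percent_of_complete},
#'   \code{n_total}.
#' @export
scrubTable <- function(params, dAvg = 65,
                       cutoffs = c(0.5, 1, 1.5, 2, 2.5, 3),
                       method = "fig1_vector_sum",
                       aggregate = c("pooled", "median")) {
    aggregate <- match.arg(aggregate)
    if (length(cutoffs) == 0 || any(cutoffs <= 0))
        stop("cutoffs must be positive and non-empty")
    if (is(params, "RealignmentParams")) params <- list(params)
    sets <- PARAMETER_SETS
    modes <- DISPLACEMENT_MODES
    nTotal <- sum(vapply(params, nVolumes, 1L))
    # per-subject counts: array [subject, set, mode, cutoff]
    cnt <- array(0L, c(length(params), length(sets), length(modes),
                       length(cutoffs)))
    for (s in seq_along(params))
        for (i in seq_along(sets))
            for (j in seq_along(modes)) {
                ser <- displacementSeries(params[[s]], dAvg = dAvg,
                                          mode = modes[j], method = method,
                                          parameterSet = sets[i])
                for (k in seq_along(cutoffs))
                    cnt[s, i, j, k] <-
                        discardedCount(censorSeries(ser, cutoffs[k]))
            }
    rows <- expand.grid(parameter_set = sets, mode = modes,
                        cutoff_mm = cutoffs, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    rows$n_discarded <- NA_integer_
    rows$percent_of_complete <- NA_real_
    rows$n_total <- nTotal
    for (r in seq_len(nrow(rows))) {
        i <- match(rows$parameter_set[r], sets)
        j <- match(rows$mode[r], modes)
        k <- match(rows$cutoff_mm[r], cutoffs)
        total <- sum(cnt[, i, j, k])
        totalRef <- sum(cnt[, 1L, j, k])
        rows$n_discarded[r] <- total
        if (aggregate == "pooled") {
            if (totalRef > 0)
                rows$percent_of_complete[r] <- 100 * total / totalRef
        } else {
            ref <- cnt[, 1L, j, k]
            ok <- ref > 0
            if (any(ok))
                rows$percent_of_complete[r] <-
                    median(100 * cnt[ok, i, j, k] / ref[ok])
        }
    }
    rows
}

#' Write a scrubbing table as TSV
#'
#' One row per parameter set x mode, cutoffs across the columns, each cell
#' "percent (n)"; undefined percentages are written as "-".
#'
#' @param tab output of \code{\link{scrubTable}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScrubTable <- function(tab, path) {
    cutoffs <- sort(unique(tab$cutoff_mm))
    combos <- unique(tab[, c("parameter_set", "mode")])
    out <- data.frame(parameter_set = combos$parameter_set,
                      mode = combos$mode, stringsAsFactors = FALSE)
    for (cu in cutoffs) {
        cell <- character(nrow(combos))
        for (r in seq_len(nrow(combos))) {
            row <- tab[tab$parameter_set == combos$parameter_set[r] &
                       tab$mode == combos$mode[r] &
                       tab$cutoff_mm == cu, ]
            pct <- if (is.na(row$percent_of_complete)) "-" else
                sprintf("%.1f%%", row$percent_of_complete)
            cell[r] <- sprintf("%s (%d)", pct, row$n_discarded)
        }
        out[[sprintf("cutoff_%gmm", cu)]] <- cell
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
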