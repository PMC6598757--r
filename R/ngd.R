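#' @title Cleavage-site and collision analyses
#' @name ngd_analysis
#' @description Peak calling on occupancy tracks, spacing statistics
#'   between cleavage points and stalled/collided ribosomes, windowed
#'   occupancy ratios normalized to the control transcript, and in vitro /
#'   in vivo cut-site concordance.
NULL

#' Call peaks on an occupancy track
#'
#' Positions that are local maxima within +-1 nt, carry at least
#' \code{minFraction} of the track sum and at least \code{minCount}
#' calls. Thresholds are package defaults (the analyses the package
#' reproduces display tracks without a stated peak rule) and are
#' configurable.
#'
#' @param track an \linkS4class{OccupancyTrack}.
#' @param minFraction minimum fraction of the track sum (default 0.05).
#' @param minCount minimum absolute count (default 5).
#' @return data.frame (a PeakSet): \code{position} (0-based),
#'   \code{count}, \code{fraction}, sorted by position.
#' @export
callPeaks <- function(track, minFraction = 0.05, minCount = 5L) {
    counts <- trackCounts(track)
    total <- sum(counts)
    empty <- data.frame(position = integer(), count = integer(),
                        fraction = numeric())
    if (total == 0L) return(empty)
    n <- length(counts)
    left <- c(0L, counts[-n])
    right <- c(counts[-1L], 0L)
    is_peak <- counts >= left & counts >= right & counts >= minCount &
        counts >= minFraction * total
    pos <- which(is_peak)
    if (!length(pos)) return(empty)
    data.frame(position = pos - 1L, count = counts[pos],
               fraction = counts[pos] / total)
}

#' Modal spacing between two peak sets
#'
#' For every ordered pair (upstream peak u, downstream peak d) with
#' \code{0 < d - u <= maxLag}, lag \code{d - u} receives weight
#' \code{min(count_u, count_d)}; the modal spacing is the lag with maximal
#' weight (ties resolve to the smaller lag with a warning). Comparing the
#' 16-class cut-point peaks to the 21-class A-site peaks measures the
#' cleavage-to-stall distance; 28-class vs 21-class measures the
#' collided-to-lead distance. Both are 30 nt under stacked-ribosome
#' geometry.
#'
#' @param upstream,downstream PeakSet data.frames from
#'   \code{\link{callPeaks}}.
#' @param maxLag maximum lag considered (default 60 nt).
#' @return list (a SpacingResult): \code{modal_spacing},
#'   \code{spacing_histogram} (named numeric, lag -> weight),
#'   \code{n_pairs}.
#' @export
peakSpacing <- function(upstream, downstream, maxLag = 60L) {
    if (nrow(upstream) == 0L || nrow(downstream) == 0L)
        stop("peak sets must be nonempty")
    lag <- outer(downstream$position, upstream$position, "-")
    wt <- outer(downstream$count, upstream$count, pmin)
    keep <- lag > 0L & lag <= maxLag
    if (!any(keep))
        stop("no peak pairs within maxLag = ", maxLag)
    hist <- tapply(wt[keep], lag[keep], sum)
    lags <- as.integer(names(hist))
    best <- which(hist == max(hist))
    if (length(best) > 1L)
        warning("tied modal spacings ", paste(lags[best], collapse = ", "),
                "; choosing the smallest")
    list(modal_spacing = lags[min(best)],
         spacing_histogram = setNames(as.numeric(hist), names(hist)),
         n_pairs = sum(keep))
}

#' Control-normalized windowed occupancy
#'
#' The combined 21- and 28-class occupancy density over a reporter window
#' divided by the same density over the control transcript's CDS:
#' \deqn{\frac{(\sum_{w} c_{21} + c_{28}) / |w|}{(\sum_{RFP} c_{21} +
#'   c_{28}) / |CDS_{RFP}|}.}
#' The canonical window runs from 300 nt upstream of the stall insert to
#' the insert's end (\code{\link{stallWindow}}).
#'
#' @param track21,track28 reporter \linkS4class{OccupancyTrack}s (21- and
#'   28-class A sites).
#' @param window integer(2), 0-based half-open reporter window.
#' @param rfpTrack21,rfpTrack28 control-transcript tracks.
#' @param rfpCds integer(2), 0-based half-open control CDS interval.
#' @return scalar normalized occupancy.
#' @export
windowedOccupancy <- function(track21, track28, window,
                              rfpTrack21, rfpTrack28, rfpCds) {
    stopifnot(window[2L] > window[1L], rfpCds[2L] > rfpCds[1L])
    win_idx <- seq.int(window[1L] + 1L, window[2L])
    if (max(win_idx) > length(trackCounts(track21)))
        stop("window extends beyond the transcript")
    num <- sum(trackCounts(track21)[win_idx]) +
        sum(trackCounts(track28)[win_idx])
    rfp_idx <- seq.int(rfpCds[1L] + 1L, rfpCds[2L])
    den <- sum(trackCounts(rfpTrack21)[rfp_idx]) +
        sum(trackCounts(rfpTrack28)[rfp_idx])
    if (den == 0L)
        stop("zero control-transcript counts; normalized occupancy undefined")
    (num / length(win_idx)) / (den / length(rfp_idx))
}

#' Concordance between in vitro and in vivo cut points
#'
#' Fraction of the in vitro cut-point track's weight lying within
#' \code{toleranceNt} of an in vivo cut position. In vivo cut positions
#' are track positions carrying at least \code{minCount} calls (default
#' 1, i.e. the occupied support); raise \code{minCount} on noisy in vivo
#' tracks.
#'
#' @param invitroTrack cut-point \linkS4class{OccupancyTrack} from
#'   in vitro cleavage fragments (3' ends of 60-65 nt reads).
#' @param invivoTrack cut-point track from the in vivo 16-class.
#' @param toleranceNt matching tolerance (default 1 nt).
#' @param minCount minimum in vivo count defining a cut position.
#' @return fraction in [0, 1].
#' @export
cutSiteConcordance <- function(invitroTrack, invivoTrack,
                               toleranceNt = 1L, minCount = 1L) {
    if (invitroTrack@transcript != invivoTrack@transcript)
        stop("tracks must be on the same transcript")
    vit <- trackCounts(invitroTrack)
    viv <- trackCounts(invivoTrack)
    total <- sum(vit)
    if (total == 0L)
        stop("empty in vitro track; concordance undefined")
    anchors <- which(viv >= minCount)
    if (!length(anchors)) return(0)
    near <- rep(FALSE, length(vit))
    for (d in seq.int(-toleranceNt, toleranceNt)) {
        idx <- anchors + d
        idx <- idx[idx >= 1L & idx <= length(vit)]
        near[idx] <- TRUE
    }
    sum(vit[near]) / total
}

#' Plot occupancy tracks around the stall
#'
#' A minimal stacked track panel: one horizontal panel per size class with
#' the stall insert shaded.
#'
#' @param tracks named list of \linkS4class{OccupancyTrack}s.
#' @param construct optional \linkS4class{ReporterConstruct} whose stall
#'   interval is shaded.
#' @param xlim optional transcript-coordinate window.
#' @export
plotTracks <- function(tracks, construct = NULL, xlim = NULL) {
    old <- graphics::par(mfrow = c(length(tracks), 1L),
                         mar = c(2.5, 4, 1.5, 1))
    on.exit(graphics::par(old))
    for (nm in names(tracks)) {
        counts <- trackCounts(tracks[[nm]])
        x <- seq_along(counts) - 1L
        if (is.null(xlim)) xlim <- range(x)
        plot(x, counts, type = "h", xlim = xlim, xlab = "", col = "grey25",
             ylab = "calls", main = nm, cex.main = 0.9)
        if (!is.null(construct) && hasStallInsert(construct)) {
            st <- stallInterval(construct)
            graphics::rect(st[1L], 0, st[2L], max(counts) * 1.05,
                           col = grDevices::adjustcolor("red", 0.15),
                           border = NA)
        }
    }
    invisible(NULL)
}
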