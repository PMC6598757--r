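#' @title Reporter-SGA screen scoring
#' @name screen_sga
#' @description Scores dual-reporter fluorescence colony-array screens:
#'   border/size filtering, replicate aggregation to per-strain
#'   log2(GFP/RFP), per-plate LOESS spatial normalization, Z-scores, and
#'   dual-reporter hit calling (|Z| > 2.5 on a stall reporter, |Z| < 2.5
#'   on the matched no-stall OPT reporter).
NULL

#' Remove border strains and colony-size outliers
#'
#' @param grid a \linkS4class{PlateGrid}.
#' @param sizeMin,sizeMax kept colony-size window in pixels (defaults
#'   1500 and 6000, boundaries kept).
#' @return list with \code{grid} (filtered \linkS4class{PlateGrid}) and
#'   \code{report} (named counts of removed colonies).
#' @export
filterColonies <- function(grid, sizeMin = 1500, sizeMax = 6000) {
    d <- plateData(grid)
    border <- d$is_border
    outlier <- !border & (d$size_px < sizeMin | d$size_px > sizeMax)
    kept <- d[!border & !outlier, , drop = FALSE]
    if (nrow(kept) == 0L)
        warning("no colonies survive filtering on plate ", plateId(grid))
    out <- new("PlateGrid", plateId = grid@plateId,
               reporter = grid@reporter, nrow = grid@nrow,
               ncol = grid@ncol, data = kept)
    list(grid = out,
         report = c(border = sum(border), size_outlier = sum(outlier),
                    kept = nrow(kept)))
}

#' Aggregate colonies to per-strain scores
#'
#' Median (default) GFP and RFP over a strain's surviving replicate
#' colonies, and the log2 intensity ratio. The aggregator is selectable
#' because the source protocol names both the median and the mean;
#' median is the robust default.
#'
#' @param grid a filtered \linkS4class{PlateGrid}.
#' @param aggregator \code{"median"} or \code{"mean"}.
#' @return data.frame (StrainScore rows): \code{strain}, \code{plate_id},
#'   \code{n_colonies_used}, \code{med_gfp}, \code{med_rfp},
#'   \code{log2_ratio}, \code{row}, \code{col} (mean colony position,
#'   used as the LOESS covariate). Strains with no surviving colonies are
#'   absent; strains with nonpositive aggregated intensity are omitted
#'   with a warning.
#' @export
scoreStrains <- function(grid, aggregator = c("median", "mean")) {
    aggregator <- match.arg(aggregator)
    f <- if (aggregator == "median") median else mean
    d <- plateData(grid)
    if (nrow(d) == 0L)
        return(data.frame(strain = character(), plate_id = character(),
                          n_colonies_used = integer(), med_gfp = numeric(),
                          med_rfp = numeric(), log2_ratio = numeric(),
                          row = numeric(), col = numeric(),
                          stringsAsFactors = FALSE))
    sp <- split(d, d$strain)
    out <- do.call(rbind, lapply(sp, function(x)
        data.frame(strain = x$strain[1L], plate_id = grid@plateId,
                   n_colonies_used = nrow(x), med_gfp = f(x$gfp),
                   med_rfp = f(x$rfp), row = mean(x$row),
                   col = mean(x$col), stringsAsFactors = FALSE)))
    bad <- out$med_gfp <= 0 | out$med_rfp <= 0
    if (any(bad)) {
        warning(sum(bad), " strain(s) with nonpositive aggregated ",
                "intensity omitted")
        out <- out[!bad, , drop = FALSE]
    }
    out$log2_ratio <- log2(out$med_gfp / out$med_rfp)
    rownames(out) <- NULL
    out[, c("strain", "plate_id", "n_colonies_used", "med_gfp", "med_rfp",
            "log2_ratio", "row", "col")]
}

#' LOESS spatial normalization of one plate's strain scores
#'
#' Sequentially fits a locally weighted regression of \code{log2_ratio}
#' against the strain's column position, subtracts the fit, then repeats
#' against the row position. Plates with fewer than 10 strains skip the
#' fit with a warning and are median-centred instead.
#'
#' @param scores data.frame from \code{\link{scoreStrains}} (one plate).
#' @param span LOESS span (default 0.5).
#' @return the data.frame with a \code{loess_adjusted} column appended.
#' @export
loessNormalize <- function(scores, span = 0.5) {
    if (nrow(scores) < 10L) {
        warning("fewer than 10 strains; LOESS skipped, median-centring")
        scores$loess_adjusted <- scores$log2_ratio -
            median(scores$log2_ratio)
        return(scores)
    }
    resid <- scores$log2_ratio
    for (covar in c("col", "row")) {
        fit <- loess(resid ~ x, data = data.frame(resid = resid,
                                                  x = scores[[covar]]),
                     span = span, degree = 2L,
                     family = "symmetric")
        resid <- resid - predict(fit)
    }
    scores$loess_adjusted <- resid
    scores
}

#' Per-plate Z-scores
#'
#' Standardizes the LOESS-adjusted values to mean 0 and (sample) standard
#' deviation 1 within the plate.
#'
#' @param scores data.frame with a \code{loess_adjusted} column.
#' @return the data.frame with a \code{z} column appended.
#' @export
zscorePlate <- function(scores) {
    s <- sd(scores$loess_adjusted)
    if (!is.finite(s) || s == 0)
        stop("plate standard deviation is zero; Z-scores undefined")
    scores$z <- (scores$loess_adjusted - mean(scores$loess_adjusted)) / s
    scores
}

#' Dual-reporter hit calling
#'
#' A strain is a hit when its Z-score on the stall (NGD) reporter exceeds
#' the cutoff in magnitude (strictly) while its Z-score on the matched
#' OPT reporter stays strictly inside the cutoff. Strains missing from
#' either plate are excluded and reported in
#' \code{attr(x, "excluded")}.
#'
#' @param zNgd,zOpt data.frames with \code{strain} and \code{z} (from
#'   \code{\link{zscorePlate}}).
#' @param cutoff Z threshold (default 2.5).
#' @return data.frame of hits: \code{strain}, \code{z_ngd}, \code{z_opt},
#'   \code{direction} (\code{"decreased"}/\code{"increased"} GFP).
#' @export
callHits <- function(zNgd, zOpt, cutoff = 2.5) {
    common <- intersect(zNgd$strain, zOpt$strain)
    if (!length(common))
        stop("no strains shared between the NGD and OPT score sets")
    excluded <- union(setdiff(zNgd$strain, common),
                      setdiff(zOpt$strain, common))
    zn <- zNgd$z[match(common, zNgd$strain)]
    zo <- zOpt$z[match(common, zOpt$strain)]
    hit <- abs(zn) > cutoff & zo > -cutoff & zo < cutoff
    out <- data.frame(strain = common[hit], z_ngd = zn[hit],
                      z_opt = zo[hit],
                      direction = ifelse(zn[hit] < 0, "decreased",
                                         "increased"),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "excluded") <- excluded
    out
}

#' Overlaps among per-reporter candidate sets
#'
#' @param hitSets named list of character vectors (hit strain ids per
#'   reporter).
#' @return named integer vector of set sizes, all pairwise intersections,
#'   and (for three sets) the triple intersection.
#' @export
candidateOverlaps <- function(hitSets) {
    nms <- names(hitSets)
    out <- vapply(hitSets, function(x) length(unique(x)), integer(1L))
    if (length(hitSets) >= 2L) {
        prs <- utils::combn(seq_along(hitSets), 2L, simplify = FALSE)
        for (p in prs) {
            out[paste(nms[p], collapse = "&")] <-
                length(intersect(hitSets[[p[1L]]], hitSets[[p[2L]]]))
        }
    }
    if (length(hitSets) >= 3L)
        out[paste(nms, collapse = "&")] <-
            length(Reduce(intersect, hitSets))
    out
}

#' Score a matched NGD/OPT plate pair end to end
#'
#' filter -> aggregate -> LOESS -> Z-score on each plate, then
#' dual-reporter hit calling.
#'
#' @param ngd,opt \linkS4class{PlateGrid}s for the stall and OPT
#'   reporter plates.
#' @param cutoff Z threshold.
#' @param span LOESS span.
#' @param aggregator \code{"median"} or \code{"mean"}.
#' @return list with \code{hits}, \code{ngdScores}, \code{optScores}.
#' @export
screenPipeline <- function(ngd, opt, cutoff = 2.5, span = 0.5,
                           aggregator = "median") {
    score_one <- function(grid) {
        filt <- filterColonies(grid)
        zscorePlate(loessNormalize(scoreStrains(filt$grid,
                                                aggregator = aggregator),
                                   span = span))
    }
    zn <- score_one(ngd)
    zo <- score_one(opt)
    list(hits = callHits(zn, zo, cutoff = cutoff),
         ngdScores = zn, optScores = zo)
}

#' Write/read plate grids as delimited tables
#'
#' Column layout: \code{plate_id,row,col,strain,gfp,rfp,size_px,is_border}.
#'
#' @param grid a \linkS4class{PlateGrid}.
#' @param path file path.
#' @export
writePlateGrid <- function(grid, path) {
    d <- plateData(grid)
    d <- cbind(plate_id = plateId(grid), d)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePlateGrid
#' @param reporter reporter label for the read grid.
#' @param nrow,ncol grid dimensions (default 1536 format).
#' @export
readPlateGrid <- function(path, reporter = "NGD-CGA", nrow = 32L,
                          ncol = 48L) {
    d <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    pid <- unique(d$plate_id)
    if (length(pid) != 1L) stop("plate file must contain a single plate")
    new("PlateGrid", plateId = as.character(pid), reporter = reporter,
        nrow = as.integer(nrow), ncol = as.integer(ncol),
        data = d[, c("row", "col", "strain", "gfp", "rfp", "size_px",
                     "is_border")])
}
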