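#' @title Size classes, A-site inference and offset calibration
#' @name asite
#' @description Footprint length reports ribosome state: ~28 nt footprints
#'   come from ribosomes with an occupied A site (collided, rotated state
#'   at a stall), ~21 nt footprints from ribosomes awaiting A-site tRNA
#'   (the stalled lead), and 15-17 nt fragments are the 5' products of
#'   endonucleolytic cleavage whose 3' ends mark cut points. This module
#'   classifies footprints, converts each to an inferred A-site codon
#'   start or cut point, and calibrates 5'-end offsets from start codons.
NULL

.DEFAULT_TABLES <- list(
    monosome = data.frame(
        size_class = c(rep("16", 3L), rep("21", 3L), rep("28", 6L)),
        length = c(15:17, 20:22, 27:32),
        rule = c(rep("threeprime_end", 3L), rep("fiveprime_offset", 9L)),
        offset = c(rep(NA_integer_, 3L), 16L, 17L, 17L,
                   16L, 16L, 17L, 17L, 17L, 17L),
        stringsAsFactors = FALSE),
    disome = data.frame(
        size_class = c(rep("46", 5L), rep("54", 4L), rep("60", 6L)),
        length = c(44:48, 51:54, 57:62),
        rule = c(rep("threeprime_end", 5L), rep("fiveprime_offset", 10L)),
        offset = c(rep(NA_integer_, 5L), rep(47L, 10L)),
        stringsAsFactors = FALSE),
    invitro = data.frame(
        size_class = rep("invitro", 6L),
        length = 60:65,
        rule = "threeprime_end",
        offset = NA_integer_,
        stringsAsFactors = FALSE))

#' Default offset tables
#'
#' The canonical length-to-rule mappings. Monosome mode: 16-class (15-17
#' nt, 3' ends are cut points), 21-class (20:16, 21:17, 22:17), 28-class
#' (27:16, 28:16, 29:17, 30:17, 31:17, 32:17). Disome mode: 60-class
#' (57-62 nt, offset 47), 54-class (51-54 nt, offset 47), 46-class (44-48
#' nt, 3' ends). In vitro cleavage mode: 60-65 nt, 3' ends. Monosome
#' lengths 18-19 and 23-26 nt fall between classes and are unclassified.
#'
#' @param mode \code{"monosome"}, \code{"disome"} or \code{"invitro"}.
#' @return an \linkS4class{OffsetTable}.
#' @export
defaultOffsetTable <- function(mode = c("monosome", "disome", "invitro")) {
    mode <- match.arg(mode)
    new("OffsetTable", mode = mode, rules = .DEFAULT_TABLES[[mode]])
}

#' Classify footprint lengths into size classes
#'
#' @param length integer vector of templated footprint lengths (nt).
#' @param table an \linkS4class{OffsetTable} (or a mode name).
#' @return character vector of size-class labels; \code{NA} where the
#'   length belongs to no class.
#' @export
classifyFootprint <- function(length, table = defaultOffsetTable("monosome")) {
    if (is.character(table)) table <- defaultOffsetTable(table)
    rules <- offsetRules(table)
    rules$size_class[match(length, rules$length)]
}

#' Infer A-site codon starts and cut points
#'
#' Applies the size-class rule to each classified footprint: 5'-offset
#' classes yield \code{position = start + offset(length)} of kind
#' \code{a_site_codon_start}; 3'-end classes yield the half-open end
#' coordinate (the first nucleotide beyond the protected fragment) of kind
#' \code{cut_point}. Unclassified footprints are omitted; inferred
#' positions beyond the transcript are dropped and counted in
#' \code{attr(x, "dropped_boundary")}.
#'
#' @param alignments aligned-footprint data.frame (aligned rows are used).
#' @param table an \linkS4class{OffsetTable}.
#' @param transcriptLengths named integer vector of transcript lengths
#'   (for the boundary check); optional.
#' @return data.frame of site calls: \code{read_id},
#'   \code{transcript_id}, \code{position}, \code{kind},
#'   \code{size_class}.
#' @export
inferSites <- function(alignments, table = defaultOffsetTable("monosome"),
                       transcriptLengths = NULL) {
    aln <- alignments[alignments$status == "aligned", , drop = FALSE]
    cls <- classifyFootprint(aln$length, table)
    keep <- !is.na(cls)
    aln <- aln[keep, , drop = FALSE]
    cls <- cls[keep]
    rules <- offsetRules(table)
    ri <- match(aln$length, rules$length)
    is5 <- rules$rule[ri] == "fiveprime_offset"
    pos <- ifelse(is5, aln$start + rules$offset[ri], aln$end)
    kind <- ifelse(is5, "a_site_codon_start", "cut_point")
    out <- data.frame(read_id = aln$read_id,
                      transcript_id = aln$transcript_id,
                      position = as.integer(pos), kind = kind,
                      size_class = cls, stringsAsFactors = FALSE)
    dropped <- 0L
    if (!is.null(transcriptLengths)) {
        lim <- transcriptLengths[out$transcript_id]
        bad <- !is.na(lim) & out$position > lim
        dropped <- sum(bad)
        out <- out[!bad, , drop = FALSE]
    }
    rownames(out) <- NULL
    attr(out, "dropped_boundary") <- dropped
    out
}

#' Calibrate 5'-end A-site offsets from start codons
#'
#' For each requested read length, builds the metagene histogram of 5'
#' ends relative to annotated start codons (window
#' \code{[start - 40, start + 20)}) and sets
#' \code{offset = (start + 3) - modal 5' position}: the dominant
#' initiation-proximal peak is taken to have AUG in the P site, hence its
#' A site at the second codon. Lengths with fewer than \code{minReads} 5'
#' ends in the window fall back to the default monosome table with a
#' warning; modal ties resolve to the smaller offset with a warning.
#'
#' @param alignments aligned-footprint data.frame.
#' @param cds data.frame with columns \code{transcript}, \code{start}
#'   (0-based CDS start), as produced by the simulators or
#'   \code{\link{writeReference}}.
#' @param lengths read lengths to calibrate (default: the monosome
#'   5'-offset lengths).
#' @param minReads minimum in-window 5' ends per length (default 100).
#' @param window metagene window relative to the CDS start, half-open.
#' @return an \linkS4class{OffsetTable} of mode \code{"monosome"} with one
#'   \code{fiveprime_offset} rule per length (size classes inherited from
#'   the default table where applicable).
#' @export
calibrateOffsets <- function(alignments, cds, lengths = c(20:22, 27:32),
                             minReads = 100L, window = c(-40L, 20L)) {
    aln <- alignments[alignments$status == "aligned", , drop = FALSE]
    if (nrow(aln) == 0L) stop("empty alignment set")
    cds_start <- setNames(cds$start, cds$transcript)
    rel <- aln$start - cds_start[aln$transcript_id]
    default <- offsetRules(defaultOffsetTable("monosome"))
    rows <- lapply(lengths, function(L) {
        sel <- !is.na(rel) & aln$length == L & rel >= window[1L] &
            rel < window[2L]
        n <- sum(sel)
        if (n < minReads) {
            fallback <- default$offset[default$length == L]
            if (length(fallback) == 0L || is.na(fallback))
                stop("length ", L, " has too few reads (", n,
                     ") and no default offset to fall back to")
            warning("length ", L, ": only ", n, " reads near start codons; ",
                    "falling back to default offset ", fallback)
            off <- fallback
        } else {
            tab <- table(rel[sel])
            modal <- as.integer(names(tab)[tab == max(tab)])
            if (length(modal) > 1L)
                warning("length ", L, ": tied modal 5' positions; ",
                        "choosing the smaller offset")
            off <- 3L - max(modal)   # larger modal position = smaller offset
            if (off < 0L)
                stop("length ", L, ": negative calibrated offset (modal 5' ",
                     "end downstream of the second codon)")
        }
        cls <- default$size_class[default$length == L]
        data.frame(size_class = if (length(cls)) cls else as.character(L),
                   length = L, rule = "fiveprime_offset", offset = off,
                   stringsAsFactors = FALSE)
    })
    new("OffsetTable", mode = "monosome", rules = do.call(rbind, rows))
}

#' Build an occupancy track from site calls
#'
#' @param calls site-call data.frame from \code{\link{inferSites}}
#'   (all rows must lie on one transcript).
#' @param transcript transcript identifier.
#' @param transcriptLength transcript length in nt.
#' @param sizeClass optional size-class filter; when given, only calls of
#'   that class contribute.
#' @return an \linkS4class{OccupancyTrack}; its sum equals the number of
#'   contributing calls with positions inside the transcript.
#' @export
buildTrack <- function(calls, transcript, transcriptLength,
                       sizeClass = NULL) {
    sub <- calls[calls$transcript_id == transcript, , drop = FALSE]
    if (!is.null(sizeClass))
        sub <- sub[sub$size_class == as.character(sizeClass), , drop = FALSE]
    counts <- integer(transcriptLength)
    kind <- if (nrow(sub)) sub$kind[1L] else "a_site_codon_start"
    if (nrow(sub)) {
        inside <- sub$position >= 0L & sub$position < transcriptLength
        tab <- tabulate(sub$position[inside] + 1L, nbins = transcriptLength)
        counts <- as.integer(tab)
    }
    new("OccupancyTrack", transcript = transcript,
        sizeClass = if (is.null(sizeClass)) {
            if (nrow(sub)) sub$size_class[1L] else NA_character_
        } else as.character(sizeClass),
        kind = kind, counts = counts)
}

#' Write an offset table as plain text
#' @param table an \linkS4class{OffsetTable}.
#' @param path output path.
#' @export
writeOffsetTable <- function(table, path) {
    r <- offsetRules(table)
    r$mode <- table@mode
    write.table(r[, c("mode", "size_class", "length", "rule", "offset")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read an offset table written by \code{writeOffsetTable}
#' @param path file path.
#' @return an \linkS4class{OffsetTable}.
#' @export
readOffsetTable <- function(path) {
    r <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(size_class = "character"))
    mode <- unique(r$mode)
    if (length(mode) != 1L) stop("offset table must have a single mode")
    r$offset <- as.integer(r$offset)
    r$length <- as.integer(r$length)
    new("OffsetTable", mode = mode,
        rules = r[, c("size_class", "length", "rule", "offset")])
}

#' Export an occupancy track as bedGraph
#'
#' Transcript-coordinate bedGraph (0-based half-open intervals).
#'
#' @param track an \linkS4class{OccupancyTrack}.
#' @param path output path.
#' @export
writeTrackBedGraph <- function(track, path) {
    counts <- trackCounts(track)
    nz <- which(counts > 0L)
    gr <- GenomicRanges::GRanges(
        seqnames = track@transcript,
        ranges = IRanges::IRanges(start = nz, width = 1L),
        score = counts[nz])
    GenomeInfoDb::seqlengths(gr) <-
        setNames(length(counts), track@transcript)
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}
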