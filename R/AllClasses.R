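#' @title Core S4 classes
#' @name NGDprofiler-classes
#' @description S4 containers for the central objects of the NGD footprint
#'   analysis: reporter transcript models, A-site offset tables,
#'   per-nucleotide occupancy tracks, and colony-array plate grids.
#'
#' All transcript intervals are 0-based half-open; 1-based coordinates
#' appear only in GFF3 and SAM output.
NULL

#' Reporter transcript model
#'
#' A stall-reporter transcript assembled from ordered coding segments
#' (GFP, a 2A self-cleaving peptide, FLAG, HIS3) with an optional stall
#' insert of repeated codons placed at a codon boundary inside HIS3.
#'
#' @slot name reporter label, e.g. \code{"OPT"} or \code{"NGD-CGA"}.
#' @slot segments named \linkS4class{DNAStringSet} of the coding segments in
#'   transcript order.
#' @slot stallCodon the repeated stall codon (3-nt character), or
#'   \code{NA_character_} when the construct carries no insert.
#' @slot stallRepeats integer number of repeats (0 when absent).
#' @slot stallAfterCodon insertion point, counted in HIS3 codons.
#' @slot transcript the full transcript as a \linkS4class{DNAString}.
#' @slot cds integer(2), 0-based half-open CDS interval.
#' @slot stall integer(2), 0-based half-open stall-insert interval
#'   (both \code{NA} when absent).
#' @exportClass ReporterConstruct
setClass("ReporterConstruct",
    representation(
        name           = "character",
        segments       = "DNAStringSet",
        stallCodon     = "character",
        stallRepeats   = "integer",
        stallAfterCodon = "integer",
        transcript     = "DNAString",
        cds            = "integer",
        stall          = "integer"
    )
)

setValidity("ReporterConstruct", function(object) {
    msg <- character()
    seglen <- sum(Biostrings::width(object@segments))
    ins <- 3L * object@stallRepeats
    if (length(object@transcript) != seglen + ins)
        msg <- c(msg, "transcript length must equal segment sum plus 3 x repeat_count")
    cds <- object@cds
    if ((cds[2L] - cds[1L]) %% 3L != 0L)
        msg <- c(msg, "CDS length must be a multiple of 3")
    if (hasStallInsert(object)) {
        st <- object@stall
        if (st[2L] - st[1L] != ins)
            msg <- c(msg, "stall interval length must equal 3 x repeat_count")
        if ((st[1L] - cds[1L]) %% 3L != 0L)
            msg <- c(msg, "stall interval must begin on a codon boundary")
        up <- Biostrings::subseq(object@transcript, cds[1L] + 1L, st[1L])
        if (.has_internal_stop(as.character(up)))
            msg <- c(msg, "internal stop codon upstream of the stall insert")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn ReporterConstruct-class does the construct carry a stall insert?
#' @param object,x a \code{ReporterConstruct}
#' @export
hasStallInsert <- function(object) {
    !is.na(object@stallCodon) && object@stallRepeats > 0L
}

#' @describeIn ReporterConstruct-class transcript sequence as \code{DNAString}
#' @export
transcriptSeq <- function(x) x@transcript

#' @describeIn ReporterConstruct-class 0-based half-open CDS interval
#' @export
cdsInterval <- function(x) x@cds

#' @describeIn ReporterConstruct-class 0-based half-open stall-insert interval
#' @export
stallInterval <- function(x) {
    if (!hasStallInsert(x)) stop("construct '", x@name, "' has no stall insert")
    x@stall
}

setMethod("show", "ReporterConstruct", function(object) {
    cat("ReporterConstruct '", object@name, "'\n", sep = "")
    cat("  transcript: ", length(object@transcript), " nt; CDS [",
        object@cds[1L], ", ", object@cds[2L], ")\n", sep = "")
    if (hasStallInsert(object)) {
        cat("  stall insert: (", object@stallCodon, ")x", object@stallRepeats,
            " after ", object@stallAfterCodon, " HIS3 codons, interval [",
            object@stall[1L], ", ", object@stall[2L], ")\n", sep = "")
    } else {
        cat("  no stall insert\n")
    }
})

#' A-site / cut-point offset table
#'
#' Maps footprint size classes to inference rules. A rule is either a
#' 5'-end offset per read length (the inferred A-site codon start is
#' \code{start + offset}) or the 3'-end rule (the footprint's half-open end
#' coordinate is reported as an endonucleolytic cut point).
#'
#' @slot mode one of \code{"monosome"}, \code{"disome"}, \code{"invitro"}.
#' @slot rules data.frame with columns \code{size_class}, \code{length},
#'   \code{rule} (\code{"fiveprime_offset"} or \code{"threeprime_end"}) and
#'   \code{offset} (nt; \code{NA} for 3'-end rules).
#' @exportClass OffsetTable
setClass("OffsetTable",
    representation(mode = "character", rules = "data.frame"))

setValidity("OffsetTable", function(object) {
    msg <- character()
    r <- object@rules
    need <- c("size_class", "length", "rule", "offset")
    if (!all(need %in% names(r)))
        return(paste("rules must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(r$length))
        msg <- c(msg, "length sets of size classes must be disjoint")
    off <- r$offset[r$rule == "fiveprime_offset"]
    if (any(is.na(off)) || any(off < 0))
        msg <- c(msg, "fiveprime offsets must be nonnegative and non-NA")
    if (!all(r$rule %in% c("fiveprime_offset", "threeprime_end")))
        msg <- c(msg, "unknown rule")
    if (length(msg)) msg else TRUE
})

#' @describeIn OffsetTable-class the rule table as a data.frame
#' @param x an \code{OffsetTable}
#' @export
offsetRules <- function(x) x@rules

setMethod("show", "OffsetTable", function(object) {
    cat("OffsetTable (", object@mode, " mode): ",
        length(unique(object@rules$size_class)), " size classes, lengths ",
        min(object@rules$length), "-", max(object@rules$length), " nt\n",
        sep = "")
    for (cl in unique(object@rules$size_class)) {
        sub <- object@rules[object@rules$size_class == cl, ]
        if (sub$rule[1L] == "threeprime_end") {
            cat("  ", cl, ": lengths {", paste(sub$length, collapse = ","),
                "} -> 3' end (cut point)\n", sep = "")
        } else {
            cat("  ", cl, ": ", paste(sub$length, ":", sub$offset,
                sep = "", collapse = " "), " (5' offsets)\n", sep = "")
        }
    }
})

#' Per-nucleotide occupancy track
#'
#' Integer counts of inferred A-site codon starts or cut points along one
#' transcript, for one footprint size class.
#'
#' @slot transcript transcript identifier.
#' @slot sizeClass size-class label (e.g. \code{"16"}, \code{"21"}).
#' @slot kind \code{"a_site_codon_start"} or \code{"cut_point"}.
#' @slot counts integer vector, one entry per transcript nucleotide
#'   (index i = transcript coordinate i - 1).
#' @exportClass OccupancyTrack
setClass("OccupancyTrack",
    representation(transcript = "character", sizeClass = "character",
                   kind = "character", counts = "integer"))

setValidity("OccupancyTrack", function(object) {
    if (any(object@counts < 0)) "counts must be nonnegative" else TRUE
})

#' @describeIn OccupancyTrack-class the count vector
#' @param x an \code{OccupancyTrack}
#' @export
trackCounts <- function(x) x@counts

#' @describeIn OccupancyTrack-class total number of contributing site calls
#' @export
trackSum <- function(x) sum(x@counts)

setMethod("show", "OccupancyTrack", function(object) {
    nz <- which(object@counts > 0L)
    cat("OccupancyTrack ", object@transcript, " [", object@sizeClass,
        "-class, ", object@kind, "]: ", length(object@counts),
        " nt, ", sum(object@counts), " calls at ", length(nz),
        " positions\n", sep = "")
})

#' Colony-array plate grid
#'
#' One 1536-format (32 x 48) fluorescence screen plate. Each position
#' carries a strain identifier, GFP and RFP intensities (arbitrary units),
#' a colony size in pixels, and a border flag; non-border strains occupy
#' four positions (a 2 x 2 colony block).
#'
#' @slot plateId plate identifier.
#' @slot reporter reporter label on this plate (OPT, NGD-CGA or NGD-AAA).
#' @slot nrow,ncol grid dimensions.
#' @slot data data.frame with columns \code{row}, \code{col}, \code{strain},
#'   \code{gfp}, \code{rfp}, \code{size_px}, \code{is_border}.
#' @exportClass PlateGrid
setClass("PlateGrid",
    representation(plateId = "character", reporter = "character",
                   nrow = "integer", ncol = "integer", data = "data.frame"))

setValidity("PlateGrid", function(object) {
    msg <- character()
    need <- c("row", "col", "strain", "gfp", "rfp", "size_px", "is_border")
    if (!all(need %in% names(object@data)))
        return(paste("plate data must have columns", paste(need, collapse = ", ")))
    d <- object@data
    if (nrow(d) && (max(d$row) > object@nrow || max(d$col) > object@ncol ||
                    min(d$row) < 1L || min(d$col) < 1L))
        msg <- c(msg, "positions outside the grid")
    if (nrow(d) && anyDuplicated(d[, c("row", "col")]))
        msg <- c(msg, "duplicated grid positions")
    if (length(msg)) msg else TRUE
})

#' @describeIn PlateGrid-class per-position table
#' @param x a \code{PlateGrid}
#' @export
plateData <- function(x) x@data

#' @describeIn PlateGrid-class plate identifier
#' @export
plateId <- function(x) x@plateId

setMethod("show", "PlateGrid", function(object) {
    d <- object@data
    cat("PlateGrid '", object@plateId, "' (", object@reporter, "): ",
        object@nrow, " x ", object@ncol, ", ", nrow(d), " colonies, ",
        length(unique(d$strain[!d$is_border])), " non-border strains\n",
        sep = "")
})

# -- internal helpers ---------------------------------------------------------

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.has_internal_stop <- function(seq) {
    n <- nchar(seq)
    if (n < 3L) return(FALSE)
    starts <- seq.int(1L, n - 2L, by = 3L)
    any(substring(seq, starts, starts + 2L) %in% .STOP_CODONS)
}

# run code with a temporary RNG state seeded from `seed`
.with_seed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}
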