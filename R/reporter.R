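#' @title Reporter transcript construction
#' @name reporter
#' @description Build the GFP-2A-FLAG-HIS3 stall-reporter transcripts used
#'   throughout the package. GFP is decoupled from the stall by the 2A
#'   self-cleaving peptide, so GFP output reports mRNA abundance; the stall
#'   insert (e.g. (CGA)x12) sits inside HIS3, downstream of GFP.
#'
#' The true reporter plasmid sequences are not redistributed here; the
#' package ships deterministic stand-in coding sequences of realistic
#' lengths (GFP 717 nt, 2A 60 nt, FLAG 24 nt, HIS3 660 nt incl. stop),
#' generated from a fixed seed with no internal stop codons, no in-frame
#' CGA codons, no CGACGA hexamers and no A-runs longer than 3 outside a
#' stall insert, so that A-site peaks, cut points and untemplated-A calls
#' are unambiguous. All analyses depend on the reporter geometry, not on
#' the true nucleotide sequence.
NULL

.SEGMENT_NT <- c(GFP = 717L, P2A = 60L, FLAG = 24L, HIS3 = 660L)
.REPORTER_SEED <- 20190426L

# deterministic coding sequence with composition guards:
# no in-frame stop except a terminal TAA when `stop_end`, no in-frame CGA,
# no CGACGA at any offset, A-runs capped at 3 nt
.make_cds <- function(n_nt, start_atg = FALSE, stop_end = FALSE) {
    stopifnot(n_nt %% 3L == 0L)
    bases <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    ok <- setdiff(codons, c(.STOP_CODONS, "CGA"))
    n_cod <- n_nt %/% 3L
    out <- character(n_cod)
    i <- 1L
    if (start_atg) { out[1L] <- "ATG"; i <- 2L }
    last <- n_cod
    if (stop_end) { out[n_cod] <- "TAA"; last <- n_cod - 1L }
    tail6 <- if (start_atg) "ATG" else ""
    while (i <= last) {
        cand <- sample(ok, 1L)
        joined <- paste0(tail6, cand)
        if (grepl("AAAA", joined) || grepl("CGACGA", joined)) next
        out[i] <- cand
        tail6 <- substring(joined, max(1L, nchar(joined) - 4L))
        i <- i + 1L
    }
    paste(out, collapse = "")
}

.reporter_segments <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cache <<- .with_seed(.REPORTER_SEED, {
                Biostrings::DNAStringSet(c(
                    GFP  = .make_cds(.SEGMENT_NT[["GFP"]], start_atg = TRUE),
                    P2A  = .make_cds(.SEGMENT_NT[["P2A"]]),
                    FLAG = .make_cds(.SEGMENT_NT[["FLAG"]]),
                    HIS3 = .make_cds(.SEGMENT_NT[["HIS3"]], stop_end = TRUE)))
            })
        }
        cache
    }
})

#' Build a stall-reporter construct
#'
#' Assembles a GFP-2A-FLAG-HIS3 reporter transcript, optionally inserting a
#' run of repeated codons at a codon boundary inside HIS3. The canonical
#' constructs are \code{"OPT"} (no insert), \code{"NGD-CGA"} ((CGA)x12
#' inserted after 90 HIS3 codons; CGA is decoded slowly by the low-copy
#' ICG-tRNA and stalls elongation) and \code{"NGD-AAA"} ((AAA)x12).
#'
#' @param kind reporter label: \code{"OPT"}, \code{"NGD-CGA"},
#'   \code{"NGD-AAA"} or \code{"custom"}.
#' @param insertCodon 3-nt sense codon to repeat (used for
#'   \code{kind = "custom"}; implied otherwise).
#' @param repeatCount number of codon repeats (default 12).
#' @param insertionCodonIndex the insert is placed after this many HIS3
#'   codons (default 90).
#' @return a \linkS4class{ReporterConstruct}.
#' @examples
#' rep <- buildReporter("NGD-CGA")
#' stallInterval(rep)   # 36 nt, starting after GFP+2A+FLAG+90 HIS3 codons
#' @export
buildReporter <- function(kind = c("OPT", "NGD-CGA", "NGD-AAA", "custom"),
                          insertCodon = NULL, repeatCount = 12L,
                          insertionCodonIndex = 90L) {
    kind <- match.arg(kind)
    segs <- .reporter_segments()
    if (kind == "OPT") {
        tx <- Biostrings::DNAString(paste(as.character(segs), collapse = ""))
        return(new("ReporterConstruct", name = "OPT", segments = segs,
                   stallCodon = NA_character_, stallRepeats = 0L,
                   stallAfterCodon = NA_integer_, transcript = tx,
                   cds = c(0L, length(tx)),
                   stall = c(NA_integer_, NA_integer_)))
    }
    codon <- switch(kind, "NGD-CGA" = "CGA", "NGD-AAA" = "AAA",
                    "custom" = insertCodon)
    if (is.null(codon) || nchar(codon) != 3L)
        stop("insertCodon must be a 3-nt codon")
    codon <- toupper(codon)
    if (codon %in% .STOP_CODONS)
        stop("stall insert must be a sense codon, got stop codon ", codon)
    repeatCount <- as.integer(repeatCount)
    insertionCodonIndex <- as.integer(insertionCodonIndex)
    his3_sense <- .SEGMENT_NT[["HIS3"]] %/% 3L - 1L   # exclude the stop codon
    if (insertionCodonIndex < 1L || insertionCodonIndex > his3_sense)
        stop("insertionCodonIndex must be in [1, ", his3_sense,
             "] (within HIS3)")
    pre <- sum(.SEGMENT_NT[c("GFP", "P2A", "FLAG")])
    stall_start <- pre + 3L * insertionCodonIndex
    insert <- strrep(codon, repeatCount)
    full <- paste(as.character(segs), collapse = "")
    tx <- Biostrings::DNAString(paste0(
        substr(full, 1L, stall_start), insert,
        substr(full, stall_start + 1L, nchar(full))))
    name <- if (kind == "custom")
        sprintf("NGD-%s", codon) else kind
    new("ReporterConstruct", name = name, segments = segs,
        stallCodon = codon, stallRepeats = repeatCount,
        stallAfterCodon = insertionCodonIndex, transcript = tx,
        cds = c(0L, length(tx)),
        stall = c(stall_start, stall_start + 3L * repeatCount))
}

#' Build a control transcript
#'
#' A plain single-ORF control transcript (by default RFP-like, 711 nt CDS
#' ending in a stop) used as the internal normalization control for
#' occupancy ratios and as an off-reporter alignment target.
#'
#' @param name transcript identifier (default \code{"RFP"}).
#' @param cdsLength CDS length in nt (multiple of 3).
#' @param seed deterministic sequence seed.
#' @return a \linkS4class{ReporterConstruct} with a single segment and no
#'   stall insert.
#' @export
buildControlTranscript <- function(name = "RFP", cdsLength = 711L, seed = 711L) {
    cdsLength <- as.integer(cdsLength)
    seq <- .with_seed(seed,
        .make_cds(cdsLength, start_atg = TRUE, stop_end = TRUE))
    segs <- Biostrings::DNAStringSet(setNames(seq, name))
    tx <- Biostrings::DNAString(seq)
    new("ReporterConstruct", name = name, segments = segs,
        stallCodon = NA_character_, stallRepeats = 0L,
        stallAfterCodon = NA_integer_, transcript = tx,
        cds = c(0L, cdsLength), stall = c(NA_integer_, NA_integer_))
}

#' Window upstream of and across the stall insert
#'
#' The occupancy-ratio window: from \code{upstreamNt} upstream of the stall
#' insert to the insert's end, clipped at the transcript start.
#'
#' @param construct a \linkS4class{ReporterConstruct} with a stall insert.
#' @param upstreamNt nonnegative extension upstream of the insert (nt);
#'   the canonical choice is 300.
#' @return integer(2), 0-based half-open transcript interval.
#' @export
stallWindow <- function(construct, upstreamNt = 300L) {
    if (!hasStallInsert(construct))
        stop("construct '", construct@name, "' has no stall insert")
    if (upstreamNt < 0) stop("upstreamNt must be >= 0")
    st <- stallInterval(construct)
    c(max(0L, st[1L] - as.integer(upstreamNt)), st[2L])
}

#' Write the reference transcriptome and annotation
#'
#' Writes construct and control transcripts as FASTA plus CDS/stall
#' annotation as BED (0-based half-open) and/or GFF3 (1-based closed).
#'
#' @param constructs list of \linkS4class{ReporterConstruct} (reporters and
#'   controls).
#' @param fasta path of the FASTA file to write.
#' @param bed,gff optional paths for BED / GFF3 annotation output.
#' @return invisibly, the annotation data.frame with columns
#'   \code{transcript}, \code{type} (\code{CDS} or \code{stall}),
#'   \code{start}, \code{end} (0-based half-open).
#' @export
writeReference <- function(constructs, fasta, bed = NULL, gff = NULL) {
    if (length(constructs) == 0L) stop("empty construct list")
    nms <- vapply(constructs, function(x) x@name, character(1L))
    if (anyDuplicated(nms)) stop("duplicate construct names: ",
                                 paste(unique(nms[duplicated(nms)]), collapse = ", "))
    seqs <- Biostrings::DNAStringSet(lapply(constructs, transcriptSeq))
    names(seqs) <- nms
    Biostrings::writeXStringSet(seqs, fasta)
    ann <- do.call(rbind, lapply(constructs, function(x) {
        rows <- data.frame(transcript = x@name, type = "CDS",
                           start = x@cds[1L], end = x@cds[2L],
                           stringsAsFactors = FALSE)
        if (hasStallInsert(x))
            rows <- rbind(rows, data.frame(transcript = x@name, type = "stall",
                                           start = x@stall[1L],
                                           end = x@stall[2L],
                                           stringsAsFactors = FALSE))
        rows
    }))
    if (!is.null(bed)) {
        bed_df <- data.frame(ann$transcript, ann$start, ann$end, ann$type)
        write.table(bed_df, bed, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    if (!is.null(gff)) {
        gr <- GenomicRanges::GRanges(
            seqnames = ann$transcript,
            ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
            type = ifelse(ann$type == "CDS", "CDS", "sequence_feature"),
            phase = ifelse(ann$type == "CDS", 0L, NA_integer_),
            ID = paste0(ann$transcript, ":", ann$type))
        GenomeInfoDb::seqlengths(gr) <-
            setNames(Biostrings::width(seqs), nms)[GenomeInfoDb::seqlevels(gr)]
        rtracklayer::export(gr, gff, format = "gff3")
    }
    invisible(ann)
}

#' Read a reference written by \code{writeReference}
#'
#' @param fasta FASTA path.
#' @param bed optional BED annotation path.
#' @return list with \code{seqs} (\code{DNAStringSet}) and \code{annotation}
#'   (data.frame as returned by \code{writeReference}, or NULL).
#' @export
readReference <- function(fasta, bed = NULL) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    ann <- NULL
    if (!is.null(bed)) {
        ann <- read.table(bed, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("transcript", "start", "end", "type"))
        ann <- ann[, c("transcript", "type", "start", "end")]
    }
    list(seqs = seqs, annotation = ann)
}
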