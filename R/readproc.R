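#' @title Read processing: trimming, contaminant filtering, placement
#' @name read_processing
#' @description Trims the library's adapter/UMI structure, removes
#'   contaminant (rRNA/ncRNA-like) reads, and places footprints on a small
#'   transcriptome by ungapped search with untemplated-poly(A) awareness.
#'   Real data aligned elsewhere enter through \code{\link{readSam}}.
#'
#' Every input read is accounted for exactly once across the categories
#' kept / no_adapter / too_short / too_long / contaminant / unaligned /
#' multimapped.
NULL

.TRIM_STATUS <- c("kept", "no_adapter", "too_short", "too_long")
.ALIGN_STATUS <- c("aligned", "unaligned", "multimapped")

#' Trim adapter and UMIs from raw reads
#'
#' Locates the constant 3' adapter \code{CACTCGGGCACCAAGGA} (leftmost
#' match, at most one mismatch, prefix matches at the read end allowed
#' with a minimum overlap of 5 nt), strips it together with the preceding
#' 6-nt UMI block, and removes the 4 leading random nucleotides.
#'
#' @param reads character vector of raw read sequences (or a named vector
#'   from \code{\link{readFastq}}).
#' @param minInsert,maxInsert kept-insert length window (defaults 15 and
#'   90 nt, the widest gel cut used for footprint libraries).
#' @param adapter constant adapter sequence.
#' @param minOverlap minimum adapter overlap at the read end.
#' @param maxMismatch maximum mismatches tolerated in the adapter match.
#' @return data.frame with columns \code{read_id}, \code{insert},
#'   \code{umi5}, \code{umi3}, \code{status} (one of kept, no_adapter,
#'   too_short, too_long).
#' @export
trimReads <- function(reads, minInsert = 15L, maxInsert = 90L,
                      adapter = .ADAPTER, minOverlap = 5L,
                      maxMismatch = 1L) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
    if (length(reads) == 0L)
        return(data.frame(read_id = character(), insert = character(),
                          umi5 = character(), umi3 = character(),
                          status = character(), stringsAsFactors = FALSE))
    if (any(!nzchar(reads))) stop("empty read sequence")
    res <- .trim_reads_cpp(as.character(reads), adapter,
                           as.integer(minOverlap), as.integer(maxMismatch),
                           .UMI5_LEN, .UMI3_LEN,
                           as.integer(minInsert), as.integer(maxInsert))
    data.frame(read_id = ids, insert = res$insert, umi5 = res$umi5,
               umi3 = res$umi3, status = .TRIM_STATUS[res$status + 1L],
               stringsAsFactors = FALSE)
}

#' Partition trimmed reads into kept and contaminant sets
#'
#' A read is a contaminant when it matches any contaminant sequence
#' ungapped with at most \code{maxMismatchFrac} mismatches over its full
#' length (emulating a permissive pre-alignment to rRNA/ncRNA).
#'
#' @param trimmed data.frame from \code{\link{trimReads}} (kept rows are
#'   examined; other rows pass through untouched).
#' @param contaminants \code{DNAStringSet} or character vector of
#'   contaminant sequences; may be empty.
#' @param maxMismatchFrac mismatch tolerance (default 0.1).
#' @return list with \code{kept} and \code{contaminant} data.frames.
#' @export
filterContaminants <- function(trimmed, contaminants,
                               maxMismatchFrac = 0.1) {
    keep_rows <- trimmed$status == "kept"
    if (length(contaminants) == 0L || !any(keep_rows))
        return(list(kept = trimmed,
                    contaminant = trimmed[FALSE, , drop = FALSE]))
    hits <- .align_reads_cpp(trimmed$insert[keep_rows],
                             as.character(contaminants),
                             maxMismatchFrac, 15L, FALSE)
    is_cont <- hits$status != 1L   # any placement (unique or not) matches
    cont_idx <- which(keep_rows)[is_cont]
    list(kept = trimmed[setdiff(seq_len(nrow(trimmed)), cont_idx), ,
                        drop = FALSE],
         contaminant = trimmed[cont_idx, , drop = FALSE])
}

#' Place footprints on the transcriptome
#'
#' Ungapped search of each insert against the reference transcripts. At
#' each candidate placement the maximal trailing run of read A's that
#' disagree with the reference is interpreted as an untemplated poly(A)
#' tail (A's matching the reference stay templated) provided the templated
#' prefix covers at least \code{minTemplated} nt; otherwise trailing
#' disagreements count as mismatches. Placements must satisfy
#' \code{mismatches <= floor(maxMismatchFrac * templated length)}; reads
#' with more than one best placement are flagged multimapped and dropped.
#'
#' @param trimmed data.frame from \code{\link{trimReads}} (or any
#'   data.frame with \code{read_id} and \code{insert}; only kept rows are
#'   aligned), or a character vector of insert sequences.
#' @param reference named \code{DNAStringSet} or character vector of
#'   transcript sequences.
#' @param maxMismatchFrac mismatch-rate ceiling over the templated portion.
#' @param minTemplated minimum templated prefix (default 15 nt).
#' @return data.frame of AlignedFootprint rows: \code{read_id},
#'   \code{transcript_id}, \code{start}, \code{end} (0-based half-open,
#'   templated portion), \code{length}, \code{untemplated_A},
#'   \code{mismatches}, \code{umi5}, \code{umi3}, \code{status} (aligned /
#'   unaligned / multimapped).
#' @export
alignFootprints <- function(trimmed, reference, maxMismatchFrac = 0.1,
                            minTemplated = 15L) {
    if (is.character(trimmed) && is.null(dim(trimmed))) {
        ids <- names(trimmed)
        if (is.null(ids)) ids <- sprintf("read%07d", seq_along(trimmed))
        trimmed <- data.frame(read_id = ids, insert = as.character(trimmed),
                              umi5 = "", umi3 = "", status = "kept",
                              stringsAsFactors = FALSE)
    }
    use <- if ("status" %in% names(trimmed))
        trimmed$status == "kept" else rep(TRUE, nrow(trimmed))
    sub <- trimmed[use, , drop = FALSE]
    tx_names <- names(reference)
    refs <- as.character(reference)
    if (is.null(tx_names)) tx_names <- sprintf("tx%03d", seq_along(refs))
    if (nrow(sub) == 0L)
        return(data.frame(read_id = character(), transcript_id = character(),
                          start = integer(), end = integer(),
                          length = integer(), untemplated_A = integer(),
                          mismatches = integer(), umi5 = character(),
                          umi3 = character(), status = character(),
                          stringsAsFactors = FALSE))
    res <- .align_reads_cpp(sub$insert, refs, maxMismatchFrac,
                            as.integer(minTemplated), TRUE)
    data.frame(read_id = sub$read_id,
               transcript_id = unname(tx_names[res$tx]),
               start = res$start, end = res$start + res$length,
               length = res$length, untemplated_A = res$untemplated_A,
               mismatches = res$mismatches,
               umi5 = if ("umi5" %in% names(sub)) sub$umi5 else "",
               umi3 = if ("umi3" %in% names(sub)) sub$umi3 else "",
               status = .ALIGN_STATUS[res$status + 1L],
               stringsAsFactors = FALSE)
}

#' Optional UMI deduplication
#'
#' Collapses alignments identical in (transcript, start, end, umi5, umi3).
#' Off by default in the pipeline: the library's random nucleotides are
#' described but no deduplication step is; this is the escape hatch.
#'
#' @param alignments aligned-footprint data.frame.
#' @return the data.frame with duplicate rows removed (first kept).
#' @export
dedupUmis <- function(alignments) {
    key <- paste(alignments$transcript_id, alignments$start,
                 alignments$end, alignments$umi5, alignments$umi3,
                 sep = "\r")
    alignments[!duplicated(key) | alignments$status != "aligned", ,
               drop = FALSE]
}

#' Per-category read accounting
#'
#' @param trimmed output of \code{\link{trimReads}}.
#' @param contaminant contaminant partition from
#'   \code{\link{filterContaminants}} (or NULL).
#' @param alignments output of \code{\link{alignFootprints}} (or NULL).
#' @return named integer vector over the terminal categories; sums to the
#'   number of input reads.
#' @export
readAccounting <- function(trimmed, contaminant = NULL, alignments = NULL) {
    out <- c(no_adapter = sum(trimmed$status == "no_adapter"),
             too_short = sum(trimmed$status == "too_short"),
             too_long = sum(trimmed$status == "too_long"))
    n_cont <- if (is.null(contaminant)) 0L else nrow(contaminant)
    out <- c(out, contaminant = n_cont)
    if (is.null(alignments)) {
        out <- c(out, kept = sum(trimmed$status == "kept") - n_cont)
    } else {
        out <- c(out,
                 aligned = sum(alignments$status == "aligned"),
                 unaligned = sum(alignments$status == "unaligned"),
                 multimapped = sum(alignments$status == "multimapped"))
    }
    out
}

#' Write alignments as SAM
#'
#' Untemplated poly(A) tails are encoded as 3' soft clips; the templated
#' interval maps to the POS/CIGAR match block; the mismatch count is
#' carried in the NM tag. Only aligned rows are written (forward strand;
#' the pipeline's footprints are sense-strand by construction).
#'
#' @param alignments aligned-footprint data.frame.
#' @param reference named \code{DNAStringSet}/character of transcript
#'   sequences (for the header and SEQ reconstruction).
#' @param path output SAM path.
#' @return invisibly, the path.
#' @export
writeSam <- function(alignments, reference, path) {
    refs <- setNames(as.character(reference), names(reference))
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)))
    aln <- alignments[alignments$status == "aligned", , drop = FALSE]
    if (nrow(aln) == 0L) {
        writeLines(header, path)
        return(invisible(path))
    }
    templ <- substring(refs[aln$transcript_id], aln$start + 1L, aln$end)
    seqs <- paste0(templ, strrep("A", aln$untemplated_A))
    cigar <- ifelse(aln$untemplated_A > 0L,
                    sprintf("%dM%dS", aln$length, aln$untemplated_A),
                    sprintf("%dM", aln$length))
    rec <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                   aln$read_id, aln$transcript_id, aln$start + 1L, cigar,
                   seqs, aln$mismatches)
    writeLines(c(header, rec), path)
    invisible(path)
}

#' Import a transcriptome SAM/BAM as aligned footprints
#'
#' Reconstructs \code{untemplated_A} from 3'-terminal soft-clipped bases
#' when (and only when) every clipped base is A; a 3' soft clip containing
#' any non-A base contributes to the mismatch interpretation and is
#' ignored as a tail. Records whose CIGAR contains indels or skips are
#' dropped with a message (the ungapped model cannot represent them);
#' their count is available as \code{attr(x, "skipped_indel")}.
#'
#' @param path SAM or BAM file.
#' @return aligned-footprint data.frame as from
#'   \code{\link{alignFootprints}}.
#' @export
readSam <- function(path) {
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        bam <- Rsamtools::asBam(path,
                                destination = tempfile(fileext = ""),
                                overwrite = TRUE, indexDestination = FALSE)
    }
    ga <- GenomicAlignments::readGAlignments(
        bam, use.names = TRUE,
        param = Rsamtools::ScanBamParam(what = c("seq", "flag"),
                                        tag = "NM"))
    cig <- GenomicAlignments::cigar(ga)
    bad <- grepl("[IDNHP]", cig)
    n_bad <- sum(bad)
    if (n_bad > 0L)
        message(n_bad, " record(s) with indels/skips dropped")
    ga <- ga[!bad]
    cig <- cig[!bad]
    if (length(ga) == 0L) {
        out <- data.frame(read_id = character(), transcript_id = character(),
                          start = integer(), end = integer(),
                          length = integer(), untemplated_A = integer(),
                          mismatches = integer(), umi5 = character(),
                          umi3 = character(), status = character(),
                          stringsAsFactors = FALSE)
        attr(out, "skipped_indel") <- n_bad
        return(out)
    }
    seqs <- as.character(S4Vectors::mcols(ga)$seq)
    nm <- S4Vectors::mcols(ga)$NM
    nm[is.na(nm)] <- 0L
    mlen <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
    clip3 <- clip5 <- integer(length(cig))
    has3 <- grepl("\\d+S$", cig)
    clip3[has3] <- as.integer(sub(".*?(\\d+)S$", "\\1", cig[has3]))
    has5 <- grepl("^\\d+S", cig)
    clip5[has5] <- as.integer(sub("^(\\d+)S.*", "\\1", cig[has5]))
    tail_seq <- substring(seqs, nchar(seqs) - clip3 + 1L, nchar(seqs))
    tail_is_A <- clip3 > 0L & !grepl("[^A]", tail_seq)
    untA <- ifelse(tail_is_A, clip3, 0L)
    out <- data.frame(
        read_id = names(ga),
        transcript_id = as.character(GenomicRanges::seqnames(ga)),
        start = GenomicRanges::start(ga) - 1L,
        end = GenomicRanges::start(ga) - 1L + mlen,
        length = mlen,
        untemplated_A = untA,
        mismatches = pmax(0L, nm),
        umi5 = "", umi3 = "",
        status = "aligned",
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "skipped_indel") <- n_bad
    ignore5 <- sum(clip5 > 0L)
    if (ignore5 > 0L)
        message(ignore5, " record(s) carry 5' soft clips; ",
                "clipped bases ignored")
    out
}

#' Run the trim/filter/align front end on one library
#'
#' @param reads named character vector of raw reads (or FASTQ path).
#' @param reference named \code{DNAStringSet}/character transcriptome.
#' @param contaminants optional contaminant sequences.
#' @param ... passed to \code{\link{trimReads}} and
#'   \code{\link{alignFootprints}}.
#' @param maxMismatchFrac mismatch ceiling for alignment.
#' @return list with \code{alignments}, \code{trimmed},
#'   \code{accounting}.
#' @export
processLibrary <- function(reads, reference, contaminants = NULL,
                           maxMismatchFrac = 0.1, ...) {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
        !grepl("^[ACGTN]+$", reads))
        reads <- readFastq(reads)
    trimmed <- trimReads(reads, ...)
    part <- filterContaminants(trimmed,
                               if (is.null(contaminants)) character()
                               else contaminants)
    aln <- alignFootprints(part$kept, reference,
                           maxMismatchFrac = maxMismatchFrac)
    list(alignments = aln, trimmed = trimmed,
         accounting = readAccounting(trimmed, part$contaminant, aln))
}
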