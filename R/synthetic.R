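#' @title Synthetic footprint libraries and screen plates
#' @name synthetic
#' @description Generators that emulate the statistical structure of the
#'   deposited NGD footprint libraries and reporter-SGA plate scans, so the
#'   whole pipeline is testable at desk scale: monosome footprints in three
#'   size classes (16/21/28 nt) with stacked-ribosome stall geometry on the
#'   stall reporter, disome footprints (44-62 nt), in vitro cleavage
#'   fragments, reads carrying untemplated 3' A's, and 1536-format colony
#'   plates with spatial artifacts.
#'
#' Geometry conventions: an A-site position is the first nucleotide of the
#' A-site codon; a collided ribosome's A site sits exactly 30 nt upstream
#' of its lead's; the endonucleolytic cut point is placed at the 5'
#' boundary of the collided ribosome's A-site codon. Cut points are encoded
#' half-open (first nucleotide beyond the protected fragment).
NULL

.ADAPTER <- "CACTCGGGCACCAAGGA"
.UMI5_LEN <- 4L
.UMI3_LEN <- 6L
.COLLISION_SPACING <- 30L

#' Scenario configuration for footprint library simulation
#'
#' Captures one genotype's expected footprint population: the mix of size
#' classes, where lead-ribosome A sites sit within the stall insert, the
#' uniform background over coding regions, and sequencing noise.
#'
#' @param genotypeLabel free-text genotype, e.g. \code{"dom34 ski2"}.
#' @param classWeights named numeric, expected read fraction per size class
#'   (must sum to 1); names are size-class labels (\code{"16"},
#'   \code{"21"}, \code{"28"} for monosomes).
#' @param stallCodonWeights named numeric over stall-codon indices
#'   (1-based within the repeat) for lead-ribosome A-site placement;
#'   default codons 2-5, uniform.
#' @param backgroundRate expected background reads per CDS nucleotide.
#' @param nReads total reads to emit.
#' @param seed RNG seed (the library is byte-reproducible from it).
#' @param mismatchRate per-templated-base substitution probability.
#' @param readLength sequencing read length the raw reads are truncated to.
#' @param cutOffset sub-codon shift of the cut point relative to the 5'
#'   boundary of the collided ribosome's A-site codon (default 0).
#' @return a validated list of class \code{"ScenarioConfig"}.
#' @export
scenarioConfig <- function(genotypeLabel = "dom34 ski2",
                           classWeights = c("16" = 0.25, "21" = 0.45,
                                            "28" = 0.30),
                           stallCodonWeights = setNames(rep(0.25, 4), 2:5),
                           backgroundRate = 1,
                           nReads = 50000L,
                           seed = 1L,
                           mismatchRate = 0.001,
                           readLength = 51L,
                           cutOffset = 0L) {
    if (any(classWeights < 0) || any(stallCodonWeights < 0))
        stop("weights must be nonnegative")
    if (abs(sum(classWeights) - 1) > 1e-9)
        stop("classWeights must sum to 1")
    if (nReads < 0) stop("nReads must be >= 0")
    if (mismatchRate < 0 || mismatchRate > 1)
        stop("mismatchRate must be in [0, 1]")
    structure(list(genotypeLabel = genotypeLabel,
                   classWeights = classWeights,
                   stallCodonWeights = stallCodonWeights /
                       sum(stallCodonWeights),
                   backgroundRate = backgroundRate,
                   nReads = as.integer(nReads), seed = as.integer(seed),
                   mismatchRate = mismatchRate,
                   readLength = as.integer(readLength),
                   cutOffset = as.integer(cutOffset)),
              class = "ScenarioConfig")
}

#' Preset scenarios for the canonical deletion genotypes
#'
#' Encodes the qualitative footprint populations of the profiling
#' genotypes: \code{ski2} (cleavage intermediates degraded by Dom34 rescue,
#' few 16 nt reads), \code{dom34 ski2} (16 nt fragments stabilized),
#' \code{cue2 dom34 ski2} (endonuclease deleted: no 16 nt fragments while
#' 21/28 nt populations are unaffected) and \code{slh1 dom34 ski2}
#' (RQT helicase deleted: cleavage strongly increased).
#'
#' @param genotype one of \code{"ski2"}, \code{"dom34 ski2"},
#'   \code{"cue2 dom34 ski2"}, \code{"slh1 dom34 ski2"}.
#' @param ... overrides passed on to \code{\link{scenarioConfig}}.
#' @return a \code{ScenarioConfig}.
#' @export
scenarioPreset <- function(genotype = c("dom34 ski2", "ski2",
                                        "cue2 dom34 ski2",
                                        "slh1 dom34 ski2"), ...) {
    genotype <- match.arg(genotype)
    w <- switch(genotype,
        "ski2"            = c("16" = 0.03, "21" = 0.57, "28" = 0.40),
        "dom34 ski2"      = c("16" = 0.25, "21" = 0.45, "28" = 0.30),
        "cue2 dom34 ski2" = c("16" = 0.00, "21" = 0.60, "28" = 0.40),
        "slh1 dom34 ski2" = c("16" = 0.45, "21" = 0.30, "28" = 0.25))
    scenarioConfig(genotypeLabel = genotype, classWeights = w, ...)
}

#' Place one monosome footprint from its inferred site
#'
#' Inverts the size-class inference rules: draws a read length from the
#' class and positions the footprint so that the default offset table maps
#' it back to \code{site} exactly. For the 5'-offset classes \code{site} is
#' the A-site codon start; for the 16-class it is the cut point (the
#' half-open 3' end).
#'
#' @param site target transcript coordinate (0-based).
#' @param sizeClass \code{"16"}, \code{"21"} or \code{"28"} (monosome mode)
#'   or a disome/invitro class label with \code{table} set accordingly.
#' @param table an \linkS4class{OffsetTable} (default monosome table).
#' @return list with \code{start}, \code{end} (0-based half-open) and
#'   \code{length}, or \code{NULL} when the footprint would run off the
#'   transcript 5' end (the caller counts such skips).
#' @export
placeMonosomeRead <- function(site, sizeClass,
                              table = defaultOffsetTable("monosome")) {
    rules <- offsetRules(table)
    sub <- rules[rules$size_class == as.character(sizeClass), , drop = FALSE]
    if (nrow(sub) == 0L) stop("unknown size class: ", sizeClass)
    len <- sub$length[sample.int(nrow(sub), 1L)]
    if (sub$rule[1L] == "fiveprime_offset") {
        off <- sub$offset[sub$length == len]
        start <- site - off
        if (start < 0L) return(NULL)
        list(start = as.integer(start), end = as.integer(start + len),
             length = as.integer(len))
    } else {
        start <- site - len
        if (start < 0L) return(NULL)
        list(start = as.integer(start), end = as.integer(site),
             length = as.integer(len))
    }
}

# vectorized placement of many footprints of one class (see
# placeMonosomeRead for the single-read contract); drops (and counts)
# footprints that would run off the 5' end
.place_many <- function(sites, sizeClass, table) {
    rules <- offsetRules(table)
    sub <- rules[rules$size_class == as.character(sizeClass), , drop = FALSE]
    if (nrow(sub) == 0L) stop("unknown size class: ", sizeClass)
    k <- length(sites)
    li <- sample.int(nrow(sub), k, replace = TRUE)
    len <- sub$length[li]
    start <- if (sub$rule[1L] == "fiveprime_offset")
        sites - sub$offset[li] else sites - len
    ok <- start >= 0L
    list(df = data.frame(start = as.integer(start[ok]),
                         end = as.integer(start[ok] + len[ok]),
                         length = as.integer(len[ok]),
                         site = as.integer(sites[ok]),
                         stringsAsFactors = FALSE),
         skipped = sum(!ok))
}

#' Wrap footprints in the library's adapter/UMI structure
#'
#' Produces raw read sequences with the layout
#' \code{[4 random nt][footprint][6 random nt][constant 3' adapter]},
#' truncated to the sequencing read length. The 4-nt prefix models the
#' random nucleotides of the RT primer; the 6 random nt are the adapter's
#' N6 block.
#'
#' @param footprints character vector of footprint sequences.
#' @param readLength sequencing read length (default 51).
#' @return character vector of raw read sequences.
#' @export
attachAdapterUmis <- function(footprints, readLength = 51L) {
    n <- length(footprints)
    if (n == 0L) return(character())
    if (any(!nzchar(footprints))) stop("footprints must be nonempty")
    bases <- c("A", "C", "G", "T")
    rand_block <- function(w) {
        m <- matrix(bases[sample.int(4L, n * w, replace = TRUE)], ncol = w)
        do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }
    raw <- paste0(rand_block(.UMI5_LEN), footprints, rand_block(.UMI3_LEN),
                  .ADAPTER)
    substr(raw, 1L, readLength)
}

# substitute bases with probability `rate`, never producing the original base
.inject_mismatches <- function(seqs, rate) {
    if (rate <= 0) return(seqs)
    bases <- c("A", "C", "G", "T")
    n_hit <- rbinom(length(seqs), nchar(seqs), rate)
    for (i in which(n_hit > 0L)) {
        ch <- strsplit(seqs[i], "")[[1L]]
        for (j in sample.int(length(ch), n_hit[i]))
            ch[j] <- sample(setdiff(bases, ch[j]), 1L)
        seqs[i] <- paste(ch, collapse = "")
    }
    unname(seqs)
}

#' Write reads as FASTQ
#'
#' Plain 4-line FASTQ with constant quality (the pipeline ignores base
#' qualities).
#'
#' @param reads named character vector (names become read identifiers).
#' @param path output file.
#' @param quality quality character replicated over each read.
#' @export
writeFastq <- function(reads, path, quality = "I") {
    if (length(reads) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
    out <- rbind(paste0("@", ids), as.character(reads), "+",
                 vapply(nchar(reads), function(n)
                     strrep(quality, n), character(1L)))
    writeLines(as.vector(out), path)
    invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
readFastq <- function(path) {
    lines <- readLines(path)
    if (length(lines) == 0L) return(character())
    ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1L, length(lines), 4L)]))
    setNames(lines[seq(2L, length(lines), 4L)], ids)
}

# assemble the reference used by the simulators: reporter + controls
.sim_reference <- function(construct, controls) {
    constructs <- c(list(construct), controls)
    nms <- vapply(constructs, function(x) x@name, character(1L))
    seqs <- Biostrings::DNAStringSet(lapply(constructs, transcriptSeq))
    names(seqs) <- nms
    cds <- do.call(rbind, lapply(constructs, function(x)
        data.frame(transcript = x@name, start = x@cds[1L], end = x@cds[2L],
                   stringsAsFactors = FALSE)))
    list(seqs = seqs, cds = cds)
}

# draw uniform background footprints over all CDSs; lengths drawn from the
# 5'-offset classes of `table` (never from cut-point classes, which are the
# cleavage diagnostic)
.background_reads <- function(n, ref, table) {
    if (n <= 0L) return(NULL)
    rules <- offsetRules(table)
    rules <- rules[rules$rule == "fiveprime_offset", , drop = FALSE]
    lens <- ref$cds$end - ref$cds$start
    tx_i <- sample.int(nrow(ref$cds), n, replace = TRUE, prob = lens)
    ri <- sample.int(nrow(rules), n, replace = TRUE)
    len <- rules$length[ri]
    off <- rules$offset[ri]
    cls <- rules$size_class[ri]
    # A site uniform over internal codon starts, keeping the footprint
    # inside the transcript
    cds_start <- ref$cds$start[tx_i]
    cds_end <- ref$cds$end[tx_i]
    n_cod <- (cds_end - cds_start) %/% 3L
    min_cod <- ceiling(max(rules$offset) / 3) + 2L
    cod <- floor(runif(n, min = min_cod, max = n_cod - 8))
    a <- cds_start + 3L * as.integer(cod)
    start <- a - off
    data.frame(transcript = ref$cds$transcript[tx_i], class = cls,
               type = "background", start = start, end = start + len,
               length = len, site = a, kind = "a_site_codon_start",
               stringsAsFactors = FALSE)
}

#' Simulate a monosome NGD footprint library
#'
#' Emits raw FASTQ-style reads with the stall geometry of the NGD
#' reporter: 21-nt-class lead-ribosome footprints with A sites at stall
#' codons drawn from \code{stallCodonWeights}; 28-nt-class collided
#' footprints with A sites 30 nt upstream of a sampled lead A site;
#' 16-nt-class fragments whose 3' ends mark cut points at the 5' boundary
#' of the collided ribosome's A-site codon; and uniform background over
#' all CDSs including the control transcript. Every footprint is wrapped
#' by \code{\link{attachAdapterUmis}}; generation is reproducible from the
#' scenario seed.
#'
#' @param construct a \linkS4class{ReporterConstruct}; must carry a stall
#'   insert unless all stall-derived class weights are zero.
#' @param scenario a \code{\link{scenarioConfig}}.
#' @param controls list of control constructs included in the reference
#'   (default: the RFP control).
#' @param fastq optional path; when given, the raw reads are also written
#'   as FASTQ.
#' @return list with \code{reads} (named character, raw sequences),
#'   \code{truth} (per-read data.frame: class, type, transcript, start,
#'   end, length, site, kind), \code{reference} (list of \code{seqs} and
#'   \code{cds}) and \code{skipped} (reads dropped at the 5' boundary).
#' @export
simulateNgdLibrary <- function(construct, scenario,
                               controls = list(buildControlTranscript()),
                               fastq = NULL) {
    stopifnot(inherits(scenario, "ScenarioConfig"))
    ref <- .sim_reference(construct, controls)
    table <- defaultOffsetTable("monosome")
    .with_seed(scenario$seed, {
        total_nt <- sum(ref$cds$end - ref$cds$start)
        n_bg <- min(scenario$nReads,
                    as.integer(round(scenario$backgroundRate * total_nt)))
        n_sig <- scenario$nReads - n_bg
        cw <- scenario$classWeights
        n_by_class <- if (n_sig > 0L)
            as.vector(rmultinom(1L, n_sig, cw)) else rep(0L, length(cw))
        names(n_by_class) <- names(cw)
        need_stall <- any(n_by_class > 0L)
        if (need_stall && !hasStallInsert(construct))
            stop("stall-derived reads requested but construct has no stall insert")
        stall_start <- if (hasStallInsert(construct))
            stallInterval(construct)[1L] else NA_integer_
        scw <- scenario$stallCodonWeights
        codon_idx <- as.integer(names(scw))
        lead_sites <- function(k) {
            idx <- codon_idx[sample.int(length(codon_idx), k,
                                        replace = TRUE, prob = scw)]
            stall_start + 3L * (idx - 1L)
        }
        nb <- function(cl) if (cl %in% names(n_by_class))
            n_by_class[[cl]] else 0L
        rows <- list()
        skipped <- 0L
        emit <- function(sites, class, type, kind) {
            p <- .place_many(sites, class, table)
            skipped <<- skipped + p$skipped
            if (nrow(p$df) == 0L) return(NULL)
            cbind(data.frame(transcript = construct@name, class = class,
                             type = type, stringsAsFactors = FALSE),
                  p$df[, c("start", "end", "length", "site")],
                  data.frame(kind = kind, stringsAsFactors = FALSE))
        }
        if (nb("21") > 0L)
            rows$lead <- emit(lead_sites(nb("21")), "21", "lead",
                              "a_site_codon_start")
        if (nb("28") > 0L)
            rows$coll <- emit(lead_sites(nb("28")) - .COLLISION_SPACING,
                              "28", "collided", "a_site_codon_start")
        if (nb("16") > 0L)
            rows$cut <- emit(lead_sites(nb("16")) -
                                 .COLLISION_SPACING + scenario$cutOffset,
                             "16", "cleaved", "cut_point")
        rows$bg <- .background_reads(n_bg, ref, table)
        truth <- do.call(rbind, rows)
        if (is.null(truth)) {
            truth <- data.frame(transcript = character(), class = character(),
                                type = character(), start = integer(),
                                end = integer(), length = integer(),
                                site = integer(), kind = character())
        }
        if (nrow(truth)) {
            truth <- truth[sample.int(nrow(truth)), , drop = FALSE]
            truth$read_id <- sprintf("sim%07d", seq_len(nrow(truth)))
            rownames(truth) <- NULL
            fp <- substring(as.character(ref$seqs[truth$transcript]),
                            truth$start + 1L, truth$end)
            fp <- .inject_mismatches(fp, scenario$mismatchRate)
            reads <- setNames(attachAdapterUmis(fp, scenario$readLength),
                              truth$read_id)
        } else {
            reads <- character()
        }
        if (!is.null(fastq)) writeFastq(reads, fastq)
        list(reads = reads, truth = truth, reference = ref, skipped = skipped)
    })
}

#' Simulate a disome footprint library
#'
#' Long footprints from stacked ribosome pairs: 60-class (57-62 nt) and
#' 54-class (51-54 nt) footprints whose 5' ends map the lead ribosome's A
#' site at offset 47, and 46-class (44-48 nt) fragments whose 3' ends mark
#' cut points. Geometry follows \code{\link{simulateNgdLibrary}}.
#'
#' @inheritParams simulateNgdLibrary
#' @return as \code{\link{simulateNgdLibrary}}.
#' @export
simulateDisomeLibrary <- function(construct,
                                  scenario = scenarioConfig(
                                      classWeights = c("60" = 0.4,
                                                       "54" = 0.3,
                                                       "46" = 0.3),
                                      readLength = 100L),
                                  controls = list(buildControlTranscript()),
                                  fastq = NULL) {
    stopifnot(inherits(scenario, "ScenarioConfig"))
    if (!all(c("60", "54", "46") %in% names(scenario$classWeights)))
        stop("disome scenario needs class weights for classes 60, 54, 46")
    if (scenario$readLength < 62L + .UMI5_LEN + .UMI3_LEN + 5L)
        warning("readLength too short to retain the adapter on 62 nt ",
                "footprints; such reads will be untrimmable")
    ref <- .sim_reference(construct, controls)
    table <- defaultOffsetTable("disome")
    .with_seed(scenario$seed, {
        total_nt <- sum(ref$cds$end - ref$cds$start)
        n_bg <- min(scenario$nReads,
                    as.integer(round(scenario$backgroundRate * total_nt)))
        n_sig <- scenario$nReads - n_bg
        cw <- scenario$classWeights
        n_by_class <- if (n_sig > 0L)
            as.vector(rmultinom(1L, n_sig, cw)) else rep(0L, length(cw))
        names(n_by_class) <- names(cw)
        if (any(n_by_class > 0L) && !hasStallInsert(construct))
            stop("stall-derived reads requested but construct has no stall insert")
        stall_start <- if (hasStallInsert(construct))
            stallInterval(construct)[1L] else NA_integer_
        scw <- scenario$stallCodonWeights
        codon_idx <- as.integer(names(scw))
        lead_sites <- function(k) {
            idx <- codon_idx[sample.int(length(codon_idx), k,
                                        replace = TRUE, prob = scw)]
            stall_start + 3L * (idx - 1L)
        }
        nb <- function(cl) if (cl %in% names(n_by_class))
            n_by_class[[cl]] else 0L
        skipped <- 0L
        emit <- function(sites, class, type, kind) {
            p <- .place_many(sites, class, table)
            skipped <<- skipped + p$skipped
            if (nrow(p$df) == 0L) return(NULL)
            cbind(data.frame(transcript = construct@name, class = class,
                             type = type, stringsAsFactors = FALSE),
                  p$df[, c("start", "end", "length", "site")],
                  data.frame(kind = kind, stringsAsFactors = FALSE))
        }
        rows <- list()
        if (nb("60") > 0L)
            rows$lead60 <- emit(lead_sites(nb("60")), "60",
                                "disome_lead", "a_site_codon_start")
        if (nb("54") > 0L)
            rows$lead54 <- emit(lead_sites(nb("54")), "54",
                                "disome_lead", "a_site_codon_start")
        if (nb("46") > 0L)
            rows$cut <- emit(lead_sites(nb("46")) -
                                 .COLLISION_SPACING + scenario$cutOffset,
                             "46", "cleaved", "cut_point")
        rows$bg <- .background_reads(n_bg, ref, table)
        truth <- do.call(rbind, rows)
        if (!is.null(truth) && nrow(truth)) {
            truth <- truth[sample.int(nrow(truth)), , drop = FALSE]
            truth$read_id <- sprintf("dis%07d", seq_len(nrow(truth)))
            rownames(truth) <- NULL
            fp <- substring(as.character(ref$seqs[truth$transcript]),
                            truth$start + 1L, truth$end)
            fp <- .inject_mismatches(fp, scenario$mismatchRate)
            reads <- setNames(attachAdapterUmis(fp, scenario$readLength),
                              truth$read_id)
        } else {
            truth <- data.frame()
            reads <- character()
        }
        if (!is.null(fastq)) writeFastq(reads, fastq)
        list(reads = reads, truth = truth, reference = ref, skipped = skipped)
    })
}

#' Simulate footprints from prematurely polyadenylated mRNAs
#'
#' Ribosomes that translate into a premature poly(A) tail protect
#' fragments whose templated portion ends at the polyadenylation junction
#' and whose 3' end carries untemplated A's. Emits monosome-size reads
#' (15-34 nt including the tail); sequencing errors are never applied to
#' the untemplated tail, keeping the ground truth exact.
#'
#' @param reference list with \code{seqs} (named \code{DNAStringSet}) and
#'   \code{cds} (data.frame \code{transcript,start,end}).
#' @param specs data.frame with columns \code{gene_id},
#'   \code{junction_position} (0-based transcript coordinate of the first
#'   poly(A) nucleotide), \code{tail_read_count},
#'   \code{untemplated_A_per_read}.
#' @param seed RNG seed.
#' @param readLength sequencing read length.
#' @return list with \code{reads} and \code{truth} as in
#'   \code{\link{simulateNgdLibrary}} (truth column \code{untemplated_A}
#'   added).
#' @export
simulatePolyAReads <- function(reference, specs, seed = 1L,
                               readLength = 51L) {
    stopifnot(all(c("gene_id", "junction_position", "tail_read_count",
                    "untemplated_A_per_read") %in% names(specs)))
    for (i in seq_len(nrow(specs))) {
        g <- specs$gene_id[i]
        cds <- reference$cds[reference$cds$transcript == g, , drop = FALSE]
        if (nrow(cds) == 0L) stop("unknown gene: ", g)
        j <- specs$junction_position[i]
        if (j <= cds$start[1L] || j >= cds$end[1L])
            stop("junction for ", g, " not inside its CDS")
        if (j < 34L)
            stop("junction for ", g, " within 34 nt of the transcript start")
    }
    .with_seed(seed, {
        rows <- list()
        for (i in seq_len(nrow(specs))) {
            k <- specs$tail_read_count[i]
            if (k <= 0L) next
            nA <- specs$untemplated_A_per_read[i]
            if (nA < 0L) stop("untemplated_A_per_read must be >= 0")
            j <- specs$junction_position[i]
            tmax <- min(34L - nA, j)
            tmin <- 15L
            if (tmax < tmin)
                stop("tail too long for a monosome-size read (gene ",
                     specs$gene_id[i], ")")
            templ <- sample(seq.int(tmin, tmax), k, replace = TRUE)
            rows[[i]] <- data.frame(
                transcript = specs$gene_id[i], class = NA_character_,
                type = "polyA", start = j - templ, end = j, length = templ,
                site = j, kind = "cut_point", untemplated_A = nA,
                stringsAsFactors = FALSE)
        }
        truth <- do.call(rbind, rows)
        if (is.null(truth) || !nrow(truth))
            return(list(reads = character(), truth = data.frame()))
        truth$read_id <- sprintf("pa%07d", seq_len(nrow(truth)))
        rownames(truth) <- NULL
        fp <- substring(as.character(reference$seqs[truth$transcript]),
                        truth$start + 1L, truth$end)
        fp <- paste0(fp, strrep("A", truth$untemplated_A))
        reads <- setNames(attachAdapterUmis(fp, readLength), truth$read_id)
        list(reads = reads, truth = truth)
    })
}

#' Simulate a start-codon metagene fixture for offset calibration
#'
#' Generates synthetic CDS-bearing transcripts and already-aligned
#' footprints whose 5' ends are placed by the default monosome offset
#' table, with an enriched initiation-proximal population (AUG in the P
#' site, A site at \code{start + 3}) over a uniform elongation background.
#' This is the fixture on which \code{\link{calibrateOffsets}} must return
#' the table it inverted.
#'
#' @param nCds number of synthetic transcripts.
#' @param readsPerLength reads emitted per transcript per read length.
#' @param lengths read lengths to simulate (default: all 5'-offset lengths
#'   of the monosome table).
#' @param initFraction fraction of reads placed at the initiation codon.
#' @param cdsLength CDS length (nt) of each synthetic transcript.
#' @param utr UTR length on both sides.
#' @param seed RNG seed.
#' @return list with \code{alignments} (an AlignedFootprint data.frame),
#'   \code{cds} (annotation data.frame) and \code{seqs}.
#' @export
simulateCalibrationLibrary <- function(nCds = 20L, readsPerLength = 250L,
                                       lengths = NULL, initFraction = 0.3,
                                       cdsLength = 600L, utr = 60L,
                                       seed = 1L) {
    table <- defaultOffsetTable("monosome")
    rules <- offsetRules(table)
    rules <- rules[rules$rule == "fiveprime_offset", , drop = FALSE]
    if (is.null(lengths)) lengths <- rules$length
    if (!all(lengths %in% rules$length))
        stop("lengths must be 5'-offset lengths of the monosome table")
    .with_seed(seed, {
        bases <- c("C", "G", "T", "A")
        seqs <- character(nCds)
        for (i in seq_len(nCds)) {
            u5 <- paste(sample(bases, utr, replace = TRUE, prob =
                                   c(0.3, 0.3, 0.3, 0.1)), collapse = "")
            u3 <- paste(sample(bases, utr, replace = TRUE, prob =
                                   c(0.3, 0.3, 0.3, 0.1)), collapse = "")
            seqs[i] <- paste0(u5, .make_cds(cdsLength, start_atg = TRUE,
                                            stop_end = TRUE), u3)
        }
        names(seqs) <- sprintf("cds%03d", seq_len(nCds))
        cds <- data.frame(transcript = names(seqs), start = utr,
                          end = utr + cdsLength, stringsAsFactors = FALSE)
        rows <- list()
        for (i in seq_len(nCds)) {
            for (L in lengths) {
                off <- rules$offset[rules$length == L]
                n_init <- as.integer(round(initFraction * readsPerLength))
                n_elong <- readsPerLength - n_init
                cod <- sample.int(cdsLength %/% 3L - 20L, n_elong,
                                  replace = TRUE) + 2L
                a <- c(rep.int(utr + 3L, n_init), utr + 3L * cod)
                start <- a - off
                rows[[length(rows) + 1L]] <- data.frame(
                    transcript = names(seqs)[i], start = start,
                    end = start + L, length = L, untemplated_A = 0L,
                    mismatches = 0L, status = "aligned",
                    stringsAsFactors = FALSE)
            }
        }
        aln <- do.call(rbind, rows)
        aln$read_id <- sprintf("cal%07d", seq_len(nrow(aln)))
        aln$transcript_id <- aln$transcript
        aln$transcript <- NULL
        list(alignments = aln[, c("read_id", "transcript_id", "start", "end",
                                  "length", "untemplated_A", "mismatches",
                                  "status")],
             cds = cds, seqs = Biostrings::DNAStringSet(seqs))
    })
}

#' Simulate a matched pair of reporter screen plates
#'
#' Generates one NGD-reporter and one OPT-reporter 1536-format plate with
#' the structure the screen pipeline assumes: each non-border strain
#' occupies a 2x2 colony block; the outermost block ring carries border
#' strains; log-normal GFP/RFP intensities around strain-specific means
#' (strain effects shared between the two plates, as for a real strain);
#' a smooth spatial gradient per channel; spiked hits shift GFP on the NGD
#' plate only; a configurable fraction of colony sizes falls outside the
#' [1500, 6000] pixel window.
#'
#' @param nRows,nCols grid dimensions (default 32 x 48).
#' @param nSpike number of spiked hit strains.
#' @param effectSd spike effect size in units of the strain-level standard
#'   deviation of log2(GFP/RFP) (default 6).
#' @param spikeDirection \code{"down"} (reduced GFP, the endonuclease-like
#'   signature) or \code{"up"}.
#' @param gradient list with numeric \code{gfp} and \code{rfp}, each
#'   \code{c(col_amp, row_amp)} amplitudes (log2 units) of smooth spatial
#'   trends; set to zeros for a flat plate.
#' @param sizeOutlierFrac fraction of colonies given sizes outside
#'   [1500, 6000] px.
#' @param sigmaStrain,sigmaStrainRfp strain-to-strain sd of log2 GFP / RFP.
#' @param sigmaColony colony-to-colony sd (log2) within a strain.
#' @param seed RNG seed.
#' @return list with \code{ngd} and \code{opt} (\linkS4class{PlateGrid}),
#'   \code{spiked} (strain ids) and \code{strainEffectSd} (the strain-level
#'   sd used to scale the spikes).
#' @export
simulatePlatePair <- function(nRows = 32L, nCols = 48L, nSpike = 10L,
                              effectSd = 6, spikeDirection = c("down", "up"),
                              gradient = list(gfp = c(col_amp = 0.15,
                                                      row_amp = 0.10),
                                              rfp = c(col_amp = 0.05,
                                                      row_amp = 0.05)),
                              sizeOutlierFrac = 0.02,
                              sigmaStrain = 0.15, sigmaStrainRfp = 0.05,
                              sigmaColony = 0.10, seed = 1L) {
    spikeDirection <- match.arg(spikeDirection)
    if (nRows %% 2L || nCols %% 2L)
        stop("grid dimensions must be even (2x2 colony blocks)")
    .with_seed(seed, {
        brow <- ceiling(seq_len(nRows) / 2)
        bcol <- ceiling(seq_len(nCols) / 2)
        nbr <- nRows %/% 2L; nbc <- nCols %/% 2L
        pos <- expand.grid(row = seq_len(nRows), col = seq_len(nCols))
        pos$brow <- brow[pos$row]; pos$bcol <- bcol[pos$col]
        pos$is_border <- pos$brow %in% c(1L, nbr) | pos$bcol %in% c(1L, nbc)
        block_id <- (pos$brow - 1L) * nbc + pos$bcol
        interior_blocks <- sort(unique(block_id[!pos$is_border]))
        strain_of_block <- setNames(rep(NA_character_,
                                        max(block_id)), seq_len(max(block_id)))
        strain_of_block[as.character(interior_blocks)] <-
            sprintf("strain%03d", seq_along(interior_blocks))
        pos$strain <- ifelse(pos$is_border, "border",
                             strain_of_block[as.character(block_id)])
        strains <- sprintf("strain%03d", seq_along(interior_blocks))
        n_strain <- length(strains)
        eff_g <- setNames(rnorm(n_strain, 0, sigmaStrain), strains)
        eff_r <- setNames(rnorm(n_strain, 0, sigmaStrainRfp), strains)
        # strain-level sd of the (median-of-4) log2 ratio; 0.30 is the
        # variance-reduction factor of the median of 4 normal draws
        sd_total <- sqrt(sigmaStrain^2 + sigmaStrainRfp^2 +
                             0.30 * 2 * sigmaColony^2)
        spiked <- if (nSpike > 0L) sample(strains, nSpike) else character()
        delta <- (if (spikeDirection == "down") -1 else 1) *
            effectSd * sd_total
        grad <- function(amp, r, c)
            amp[["col_amp"]] * cos(pi * (c - 1) / (nCols - 1)) +
            amp[["row_amp"]] * sin(pi * (r - 1) / (nRows - 1))
        make_plate <- function(plate_id, reporter, spike_here) {
            d <- pos[, c("row", "col", "strain", "is_border")]
            sg <- ifelse(d$strain == "border", 0, eff_g[d$strain])
            sr <- ifelse(d$strain == "border", 0, eff_r[d$strain])
            sp <- if (spike_here)
                ifelse(d$strain %in% spiked, delta, 0) else 0
            lg <- log2(20000) + sg + sp + grad(gradient$gfp, d$row, d$col) +
                rnorm(nrow(d), 0, sigmaColony)
            lr <- log2(15000) + sr + grad(gradient$rfp, d$row, d$col) +
                rnorm(nrow(d), 0, sigmaColony)
            d$gfp <- 2^lg
            d$rfp <- 2^lr
            d$size_px <- pmin(pmax(round(rnorm(nrow(d), 3500, 600)), 1600),
                              5800)
            n_out <- round(sizeOutlierFrac * nrow(d))
            if (n_out > 0L) {
                out_i <- sample.int(nrow(d), n_out)
                lows <- runif(n_out) < 0.5
                d$size_px[out_i] <- ifelse(lows,
                                           round(runif(n_out, 900, 1400)),
                                           round(runif(n_out, 6200, 7500)))
            }
            d <- d[, c("row", "col", "strain", "gfp", "rfp", "size_px",
                       "is_border")]
            new("PlateGrid", plateId = plate_id, reporter = reporter,
                nrow = as.integer(nRows), ncol = as.integer(nCols), data = d)
        }
        list(ngd = make_plate("plate1_NGD", "NGD-CGA", TRUE),
             opt = make_plate("plate1_OPT", "OPT", FALSE),
             spiked = sort(spiked), strainEffectSd = sd_total)
    })
}
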