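#' @title Pipeline orchestration
#' @name pipeline
#' @description One-call orchestration of the desk-scale analysis:
#'   simulate (or load) a footprint library, trim, filter, align, classify
#'   and infer sites, build tracks, call peaks and spacing, and optionally
#'   score a simulated screen plate pair. Every run writes a manifest
#'   recording package version, seed, parameters, and per-stage read
#'   accounting; deterministic stages are byte-reproducible from the
#'   manifest.
NULL

#' Validate and normalize a pipeline configuration
#'
#' @param config list with elements \code{outdir} (required),
#'   \code{seed}, \code{scenario} (a \code{\link{scenarioConfig}} or
#'   preset name), \code{fastq} (optional existing FASTQ instead of
#'   simulation), \code{reporterKind}, \code{stages} (subset of
#'   \code{c("simulate", "align", "tracks", "ngd", "screen")}),
#'   \code{peakMinFraction}, \code{peakMinCount}, \code{upstreamNt},
#'   \code{screenSeed}.
#' @return the normalized config (defaults filled).
#' @export
validateRunConfig <- function(config) {
    if (is.null(config$outdir)) stop("config$outdir is required")
    defaults <- list(seed = 1L, reporterKind = "NGD-CGA",
                     stages = c("simulate", "align", "tracks", "ngd"),
                     peakMinFraction = 0.05, peakMinCount = 5L,
                     upstreamNt = 300L, screenSeed = NULL, fastq = NULL)
    for (nm in names(defaults))
        if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    if (is.null(config$scenario))
        config$scenario <- scenarioConfig(seed = config$seed)
    if (is.character(config$scenario))
        config$scenario <- scenarioPreset(config$scenario,
                                          seed = config$seed)
    if (!is.null(config$fastq) && !file.exists(config$fastq))
        stop("config$fastq does not exist: ", config$fastq)
    bad <- setdiff(config$stages,
                   c("simulate", "align", "tracks", "ngd", "screen"))
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    config
}

#' Run the footprint pipeline
#'
#' @param config configuration list; see
#'   \code{\link{validateRunConfig}}.
#' @return invisibly, a list with the stage outputs (\code{tracks},
#'   \code{peaks}, \code{spacing}, \code{screen}, \code{accounting},
#'   \code{manifest}).
#' @export
runPipeline <- function(config) {
    config <- validateRunConfig(config)
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(package = "NGDprofiler",
                     version = as.character(utils::packageVersion("NGDprofiler")),
                     seed = config$seed,
                     scenario = unclass(config$scenario),
                     stages = config$stages,
                     peakMinFraction = config$peakMinFraction,
                     peakMinCount = config$peakMinCount,
                     upstreamNt = config$upstreamNt)
    out <- list()
    construct <- buildReporter(config$reporterKind)
    rfp <- buildControlTranscript()

    if ("simulate" %in% config$stages || is.null(config$fastq)) {
        sim <- simulateNgdLibrary(construct, config$scenario,
                                  controls = list(rfp))
        reads <- sim$reads
        reference <- sim$reference
        writeFastq(reads, file.path(config$outdir, "library.fastq"))
        manifest$n_reads_simulated <- length(reads)
    } else {
        reads <- readFastq(config$fastq)
        reference <- .sim_reference(construct, list(rfp))
        manifest$fastq <- config$fastq
    }

    if (any(c("align", "tracks", "ngd") %in% config$stages)) {
        proc <- processLibrary(reads, reference$seqs)
        out$accounting <- proc$accounting
        manifest$read_accounting <- as.list(proc$accounting)
        calls <- inferSites(proc$alignments,
                            transcriptLengths = setNames(
                                nchar(as.character(reference$seqs)),
                                names(reference$seqs)))
        manifest$dropped_boundary <- attr(calls, "dropped_boundary")
        out$calls <- calls
    }

    if (any(c("tracks", "ngd") %in% config$stages)) {
        txlen <- Biostrings::width(reference$seqs)[
            match(construct@name, names(reference$seqs))]
        tracks <- lapply(setNames(c("16", "21", "28"),
                                  c("16", "21", "28")), function(cl)
            buildTrack(out$calls, construct@name, txlen, sizeClass = cl))
        out$tracks <- tracks
        for (cl in names(tracks))
            writeTrackBedGraph(tracks[[cl]],
                               file.path(config$outdir,
                                         sprintf("track_%s.bedGraph", cl)))
    }

    if ("ngd" %in% config$stages) {
        peaks <- lapply(out$tracks, callPeaks,
                        minFraction = config$peakMinFraction,
                        minCount = config$peakMinCount)
        out$peaks <- peaks
        spacing <- list()
        if (nrow(peaks[["16"]]) && nrow(peaks[["21"]]))
            spacing$cut_vs_lead <- peakSpacing(peaks[["16"]], peaks[["21"]])
        if (nrow(peaks[["28"]]) && nrow(peaks[["21"]]))
            spacing$collided_vs_lead <- peakSpacing(peaks[["28"]],
                                                    peaks[["21"]])
        out$spacing <- spacing
        manifest$modal_spacing <- lapply(spacing, `[[`, "modal_spacing")
        spc <- data.frame(
            comparison = names(spacing),
            modal_spacing = vapply(spacing, `[[`, numeric(1L),
                                   "modal_spacing"),
            n_pairs = vapply(spacing, `[[`, numeric(1L), "n_pairs"))
        write.table(spc, file.path(config$outdir, "spacing.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }

    if ("screen" %in% config$stages) {
        sseed <- if (is.null(config$screenSeed)) config$seed
                 else config$screenSeed
        plates <- simulatePlatePair(seed = sseed)
        res <- screenPipeline(plates$ngd, plates$opt)
        out$screen <- res
        write.table(res$hits, file.path(config$outdir, "screen_hits.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$screen_hits <- nrow(res$hits)
    }

    manifest_path <- file.path(config$outdir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    out$manifest <- manifest
    invisible(out)
}
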