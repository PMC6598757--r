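# Shared fixtures, memoised so expensive simulations run once per suite.

.fixture_env <- new.env(parent = emptyenv())

# the canonical NGD-CGA monosome library (50k reads) run through the full
# trim/align/classify/track pipeline
ngd_fixture <- function() {
    if (is.null(.fixture_env$ngd)) {
        rep <- buildReporter("NGD-CGA")
        sc <- scenarioConfig(nReads = 50000L, seed = 7L)
        sim <- simulateNgdLibrary(rep, sc)
        proc <- processLibrary(sim$reads, sim$reference$seqs)
        txlen <- setNames(Biostrings::width(sim$reference$seqs),
                          names(sim$reference$seqs))
        calls <- inferSites(proc$alignments, transcriptLengths = txlen)
        tracks <- lapply(setNames(nm = c("16", "21", "28")), function(cl)
            buildTrack(calls, "NGD-CGA", txlen[["NGD-CGA"]], sizeClass = cl))
        .fixture_env$ngd <- list(construct = rep, scenario = sc, sim = sim,
                                 proc = proc, calls = calls, tracks = tracks,
                                 peaks = lapply(tracks, callPeaks))
    }
    .fixture_env$ngd
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
    paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Independent all-positions ungapped alignment oracle (full containment
# only; test reads are generated away from transcript ends). Vectorized
# over placements; algorithmically unrelated to the package's search.
oracle_align <- function(read, refs, max_mm = 0.1, min_prefix = 15L) {
    rch <- strsplit(read, "")[[1L]]
    L <- length(rch)
    isA <- rch == "A"
    best_score <- -1L
    ties <- 0L
    best <- NULL
    for (t in seq_along(refs)) {
        xch <- strsplit(refs[[t]], "")[[1L]]
        Tn <- length(xch)
        if (Tn < L) next
        P <- Tn - L + 1L
        M <- vapply(seq_len(L), function(k)
            xch[k + 0:(P - 1L)] != rch[k], logical(P))
        if (P == 1L) M <- matrix(M, nrow = 1L)
        mm_full <- rowSums(M)
        run <- rep(TRUE, P)
        tail_len <- integer(P)
        for (k in rev(seq_len(L))) {
            run <- run & M[, k] & isA[k]
            tail_len <- tail_len + run
        }
        templ <- L - tail_len
        fallback <- templ < min_prefix
        tail_len[fallback] <- 0L
        templ[fallback] <- L
        mm <- as.integer(mm_full) - ifelse(fallback, 0L, tail_len)
        valid <- mm <= floor(max_mm * templ)
        score <- ifelse(valid, templ - mm, -1L)
        mx <- max(score)
        if (mx > best_score) {
            best_score <- mx
            ties <- sum(score == mx)
            p <- which(score == mx)[1L]
            best <- list(tx = t, start = p - 1L, length = templ[p],
                         untemplated_A = tail_len[p], mismatches = mm[p])
        } else if (mx == best_score && mx >= 0L) {
            ties <- ties + sum(score == mx)
        }
    }
    if (best_score < 0L) return(list(status = "unaligned"))
    if (ties > 1L) return(list(status = "multimapped"))
    c(list(status = "aligned"), best)
}

# site-call data.frame straight from simulator ground truth
truth_calls <- function(truth) {
    data.frame(read_id = truth$read_id, transcript_id = truth$transcript,
               position = truth$site, kind = truth$kind,
               size_class = truth$class, stringsAsFactors = FALSE)
}
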