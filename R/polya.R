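#' @title Premature polyadenylation and endonuclease-target calling
#' @name polya_cue2
#' @description Genome-wide detection of prematurely polyadenylated genes
#'   from footprints carrying untemplated 3' A's (ribosomes translating
#'   into a premature poly(A) tail), and calling of endonuclease target
#'   genes from the reproducible reduction of short (15-17 nt) footprints
#'   upon deletion of the endonuclease.
NULL

#' Per-gene footprint count summaries
#'
#' @param alignments aligned-footprint data.frame for one sample.
#' @param sampleId sample label attached to the rows.
#' @param minA untemplated-A threshold for the poly(A) read count
#'   (default 2, i.e. more than one A).
#' @return data.frame (GeneFootprintStats): \code{gene_id},
#'   \code{sample_id}, \code{count_15_17}, \code{count_20_32},
#'   \code{count_15_34}, \code{polyA_read_count}.
#' @export
geneFootprintStats <- function(alignments, sampleId = "sample1",
                               minA = 2L) {
    aln <- alignments[alignments$status == "aligned", , drop = FALSE]
    total_len <- aln$length + aln$untemplated_A
    genes <- sort(unique(aln$transcript_id))
    cnt <- function(sel) {
        tab <- table(factor(aln$transcript_id[sel], levels = genes))
        as.integer(tab)
    }
    data.frame(gene_id = genes, sample_id = sampleId,
               count_15_17 = cnt(aln$length >= 15L & aln$length <= 17L),
               count_20_32 = cnt(aln$length >= 20L & aln$length <= 32L),
               count_15_34 = cnt(total_len >= 15L & total_len <= 34L),
               polyA_read_count = cnt(total_len >= 15L & total_len <= 34L &
                                          aln$untemplated_A >= minA),
               stringsAsFactors = FALSE)
}

#' Flag prematurely polyadenylated genes
#'
#' A gene is flagged when every required sample contains at least
#' \code{minReads} monosome-size footprints (total length within
#' \code{sizeRange}, untemplated tail included) carrying more than
#' \code{minA - 1} untemplated 3' A's. The canonical thresholds are 3
#' reads with >= 2 untemplated A's in both replicates of the
#' helicase/endonuclease/rescue/exosome quadruple deletion, where
#' cleavage intermediates accumulate.
#'
#' @param samples named list of aligned-footprint data.frames, one per
#'   sample.
#' @param requiredSamples names of the samples that must each pass the
#'   threshold (default: all).
#' @param minReads minimum qualifying reads per sample (default 3).
#' @param minA minimum untemplated A count per read (default 2).
#' @param sizeRange total-read-length window (default c(15, 34)).
#' @return character vector of flagged gene ids.
#' @export
flagPrematurePolyA <- function(samples, requiredSamples = names(samples),
                               minReads = 3L, minA = 2L,
                               sizeRange = c(15L, 34L)) {
    if (is.null(names(samples)) || any(!nzchar(names(samples))))
        stop("samples must be a named list")
    missing <- setdiff(requiredSamples, names(samples))
    if (length(missing))
        stop("missing required replicate sample(s): ",
             paste(missing, collapse = ", "))
    per_sample <- lapply(requiredSamples, function(s) {
        aln <- samples[[s]]
        aln <- aln[aln$status == "aligned", , drop = FALSE]
        total_len <- aln$length + aln$untemplated_A
        qual <- total_len >= sizeRange[1L] & total_len <= sizeRange[2L] &
            aln$untemplated_A >= minA
        tab <- table(aln$transcript_id[qual])
        names(tab)[tab >= minReads]
    })
    Reduce(intersect, per_sample)
}

#' Short-to-long footprint ratio
#'
#' \code{(count_15_17 + pseudocount) / (count_20_32 + pseudocount)}: the
#' per-gene abundance of cleavage-derived 16-class fragments relative to
#' ordinary elongating footprints. Endonuclease deletion collapses this
#' ratio on its substrates.
#'
#' @param stats GeneFootprintStats data.frame (or any data.frame with
#'   \code{count_15_17} and \code{count_20_32}).
#' @param pseudocount additive pseudocount (default 1).
#' @return numeric vector of ratios, one per row.
#' @export
shortLongRatio <- function(stats, pseudocount = 1) {
    (stats$count_15_17 + pseudocount) / (stats$count_20_32 + pseudocount)
}

#' Call endonuclease target genes from short-footprint counts
#'
#' Two-condition negative-binomial test on per-gene 16-class (15-17 nt)
#' counts: median-of-ratios size factors; per-gene dispersion as the
#' maximum of the method-of-moments estimate and a fitted mean-dispersion
#' trend (conservative sharing); per-group means by the moment estimator
#' \code{sum(counts) / sum(size factors)}; Wald test on
#' the log fold change with Benjamini-Hochberg adjustment. A gene is a
#' target when \code{padj < alpha} and the deletion condition is reduced.
#' This is a documented stand-in for the named differential-count package
#' the original analysis delegated to; a cross-check against that package
#' lives in the test suite.
#'
#' @param counts integer matrix, genes x samples (rownames = gene ids).
#' @param condition factor/character per sample, two levels; the first
#'   level (or \code{"control"} if present) is the reference.
#' @param alpha adjusted-p threshold (default 0.005).
#' @param strict also require every deletion replicate's normalized count
#'   to lie below every control replicate's (off by default; the
#'   operational reading of "reproducible reduction" is the pooled test).
#' @return data.frame (TargetCallResult): \code{gene_id}, \code{baseMean},
#'   \code{log2FoldChange}, \code{pvalue}, \code{padj}, \code{is_target}.
#'   Genes with zero counts in all samples are excluded from testing.
#' @export
callCue2Targets <- function(counts, condition, alpha = 0.005,
                            strict = FALSE) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
    condition <- as.character(condition)
    lev <- unique(condition)
    if (length(lev) != 2L)
        stop("condition must have exactly two levels")
    ref <- if ("control" %in% lev) "control" else lev[1L]
    del <- setdiff(lev, ref)
    ctrl_i <- which(condition == ref)
    del_i <- which(condition == del)
    if (length(ctrl_i) < 2L || length(del_i) < 2L)
        stop("need >= 2 replicates per condition")
    if (any(colSums(counts) == 0))
        stop("a sample has zero total counts")
    # median-of-ratios size factors
    logg <- rowMeans(log(counts))
    usable <- is.finite(logg)
    if (!any(usable)) stop("no gene has positive counts in all samples")
    sf <- apply(counts, 2L, function(x)
        median(exp(log(x[usable]) - logg[usable])))
    if (any(!is.finite(sf) | sf <= 0))
        stop("undefined size factor; condition with zero counts?")
    expressed <- rowSums(counts) > 0
    k <- counts[expressed, , drop = FALSE]
    norm <- sweep(k, 2L, sf, "/")
    m <- rowMeans(norm)
    # per-condition method-of-moments dispersion (estimating within each
    # condition avoids inflating the dispersion of truly changing genes),
    # df-weighted across conditions
    mom_cond <- function(idx) {
        mi <- rowMeans(norm[, idx, drop = FALSE])
        vi <- apply(norm[, idx, drop = FALSE], 1L, var)
        (vi - mi) / pmax(mi, 1e-8)^2
    }
    df_c <- length(ctrl_i) - 1L
    df_d <- length(del_i) - 1L
    disp_mom <- pmax((mom_cond(ctrl_i) * df_c + mom_cond(del_i) * df_d) /
                         (df_c + df_d), 1e-8)
    # mean-dispersion trend disp ~ a0 + a1/mean, then log-space shrinkage
    # of the noisy gene-wise estimate toward the trend (weight by the
    # residual df against a prior worth `prior_df` observations)
    fit_ok <- m > 0 & is.finite(disp_mom)
    trend <- tryCatch({
        cf <- coef(lm(disp_mom[fit_ok] ~ I(1 / m[fit_ok])))
        pmax(cf[1L] + cf[2L] / m, 1e-8)
    }, error = function(e) rep(median(disp_mom[fit_ok]), length(m)))
    prior_df <- 4
    w <- (df_c + df_d) / (df_c + df_d + prior_df)
    disp <- exp(w * log(pmax(disp_mom, trend / 10)) +
                    (1 - w) * log(trend))
    # per-group moment estimates of the normalized mean
    s_c <- sum(sf[ctrl_i]); s_d <- sum(sf[del_i])
    q_c <- rowSums(k[, ctrl_i, drop = FALSE]) / s_c
    q_d <- rowSums(k[, del_i, drop = FALSE]) / s_d
    q_c0 <- pmax(q_c, 0.5 / s_c)
    q_d0 <- pmax(q_d, 0.5 / s_d)
    lfc <- log2(q_d0 / q_c0)
    # Wald statistic on ln q_d - ln q_c with NB Fisher information
    info <- function(q, idx) {
        mu <- outer(q, sf[idx])
        rowSums(mu / (1 + disp * mu))
    }
    se <- sqrt(1 / info(q_c0, ctrl_i) + 1 / info(q_d0, del_i))
    z <- (log(q_d0) - log(q_c0)) / se
    p <- 2 * pnorm(-abs(z))
    padj <- p.adjust(p, method = "BH")
    is_target <- padj < alpha & lfc < 0
    if (strict) {
        all_below <- apply(norm, 1L, function(x)
            max(x[del_i]) < min(x[ctrl_i]))
        is_target <- is_target & all_below
    }
    data.frame(gene_id = rownames(k), baseMean = m,
               log2FoldChange = lfc, pvalue = p, padj = padj,
               is_target = is_target, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Overlap between polyadenylation and endonuclease-target gene sets
#'
#' @param polyAGenes,cue2Genes character vectors of gene ids.
#' @return named integer vector \code{c(n_polyA, n_cue2, n_overlap)}.
#' @export
overlapSets <- function(polyAGenes, cue2Genes) {
    c(n_polyA = length(unique(polyAGenes)),
      n_cue2 = length(unique(cue2Genes)),
      n_overlap = length(intersect(polyAGenes, cue2Genes)))
}
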