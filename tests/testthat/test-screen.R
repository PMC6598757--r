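# small hand-built plate: 4 x 4, outer ring flagged as border
tiny_plate <- function(sizes = rep(3000, 4L)) {
    d <- expand.grid(row = 1:4, col = 1:4)
    d$is_border <- d$row %in% c(1L, 4L) | d$col %in% c(1L, 4L)
    d$strain <- ifelse(d$is_border, "border", "s1")
    d$gfp <- 1000
    d$rfp <- 800
    d$size_px <- 3000
    d$size_px[!d$is_border] <- sizes
    new("PlateGrid", plateId = "tiny", reporter = "NGD-CGA", nrow = 4L,
        ncol = 4L, data = d[, c("row", "col", "strain", "gfp", "rfp",
                                "size_px", "is_border")])
}

test_that("colony filtering removes borders and size outliers inclusively", {
    g <- tiny_plate(sizes = c(1499, 1500, 6000, 6001))
    res <- filterColonies(g)
    expect_identical(res$report[["border"]], 12L)
    expect_identical(res$report[["size_outlier"]], 2L)   # 1499 and 6001
    kept <- plateData(res$grid)
    expect_setequal(kept$size_px, c(1500, 6000))
    expect_warning(filterColonies(tiny_plate(sizes = rep(100, 4L))),
                   "no colonies")
})

test_that("strain scores aggregate colonies by median", {
    g <- tiny_plate()
    d <- plateData(g)
    d$gfp[!d$is_border] <- c(100, 200, 300, 400)
    d$rfp[!d$is_border] <- c(100, 200, 300, 400)
    g@data <- d
    sc <- scoreStrains(filterColonies(g)$grid)
    expect_equal(sc$med_gfp, 250)
    expect_equal(sc$log2_ratio, 0)        # equal medians
    expect_identical(sc$n_colonies_used, 4L)
    # a single surviving colony uses that colony's values
    g2 <- tiny_plate(sizes = c(3000, 100, 100, 100))
    sc2 <- scoreStrains(filterColonies(g2)$grid)
    expect_identical(sc2$n_colonies_used, 1L)
})

# gaussian score table on a synthetic plate layout
gauss_scores <- function(n = 300L, f = function(row, col) 0, sd = 0.1,
                         seed = 71L) {
    set.seed(seed)
    pos <- expand.grid(row = seq_len(15L), col = seq_len(20L))[seq_len(n), ]
    data.frame(strain = sprintf("s%03d", seq_len(n)), plate_id = "p1",
               n_colonies_used = 4L, med_gfp = 1000, med_rfp = 800,
               log2_ratio = f(pos$row, pos$col) + rnorm(n, 0, sd),
               row = pos$row, col = pos$col, stringsAsFactors = FALSE)
}

test_that("LOESS normalization recovers flat and gradient surfaces", {
    # low-noise fixtures isolate the fit itself; realistic noise is
    # exercised by the end-to-end spike-recovery test below
    flat <- loessNormalize(gauss_scores(sd = 0.01))
    expect_lt(max(abs(flat$loess_adjusted -
                          (flat$log2_ratio - mean(flat$log2_ratio)))), 0.01)
    # pure linear column gradient is removed
    grad <- loessNormalize(gauss_scores(f = function(r, c) 0.05 * c,
                                        sd = 0.02))
    colmeans <- tapply(grad$loess_adjusted, grad$col, mean)
    expect_lt(max(abs(colmeans)), 0.02)
    # location invariance: adding a constant changes nothing but the level
    s1 <- gauss_scores()
    s2 <- transform(s1, log2_ratio = log2_ratio + 3)
    a1 <- loessNormalize(s1)$loess_adjusted
    a2 <- loessNormalize(s2)$loess_adjusted
    expect_lt(max(abs((a1 - mean(a1)) - (a2 - mean(a2)))), 1e-10)
    expect_warning(loessNormalize(gauss_scores(n = 5L)), "fewer than 10")
})

test_that("plate Z-scores standardize exactly", {
    sc <- gauss_scores(n = 2L)
    sc$loess_adjusted <- c(-1, 1)
    # symmetric pair standardizes symmetrically (sample sd convention)
    expect_equal(zscorePlate(sc)$z, c(-1, 1) / sd(c(-1, 1)))
    sc300 <- loessNormalize(gauss_scores())
    z <- zscorePlate(sc300)$z
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sd(z) - 1), 1e-9)
    # a strain placed 3 plate-sd above the mean scores close to z = 3
    sc300$loess_adjusted[5L] <- mean(sc300$loess_adjusted) +
        3 * sd(sc300$loess_adjusted)
    expect_lt(abs(zscorePlate(sc300)$z[5L] - 3), 0.2)
    sc0 <- sc300; sc0$loess_adjusted <- 0
    expect_error(zscorePlate(sc0), "zero")
})

test_that("dual-reporter hit calling enforces strict cutoffs", {
    zn <- data.frame(strain = c("a", "b", "c", "d", "e"),
                     z = c(-4.0, -4.0, 2.5, 3.1, 3.1))
    zo <- data.frame(strain = c("a", "b", "c", "d", "e"),
                     z = c(0.3, -3.0, 0.0, 0.2, -2.5))
    hits <- callHits(zn, zo)
    expect_identical(hits$strain, c("a", "d"))
    expect_identical(hits$direction, c("decreased", "increased"))
    expect_false("b" %in% hits$strain)   # OPT-affected
    expect_false("c" %in% hits$strain)   # |z| = 2.5 is not > 2.5 (strict)
    expect_false("e" %in% hits$strain)   # OPT boundary -2.5 not inside
    expect_error(callHits(zn, data.frame(strain = "x", z = 0)),
                 "shared")
})

test_that("hit-set overlaps count shared candidates", {
    a <- sprintf("h%02d", 1:10)
    ov <- candidateOverlaps(list(CGA = a, AAA = a))
    expect_identical(ov[["CGA&AAA"]], 10L)
    ov2 <- candidateOverlaps(list(CGA = a[1:5], AAA = a[6:10]))
    expect_identical(ov2[["CGA&AAA"]], 0L)
    # 8 shared + 2 reporter-specific hits each
    cga <- c(sprintf("sh%02d", 1:8), "c1", "c2")
    aaa <- c(sprintf("sh%02d", 1:8), "a1", "a2")
    ov3 <- candidateOverlaps(list(CGA = cga, AAA = aaa))
    expect_identical(ov3[["CGA&AAA"]], 8L)
    expect_identical(ov3[["CGA"]], 10L)
})

test_that("screen pipeline recovers spiked hits across seeds", {
    tp <- fp <- fn <- 0L
    for (seed in 1:10) {
        pp <- simulatePlatePair(seed = seed)
        res <- screenPipeline(pp$ngd, pp$opt)
        called <- res$hits$strain
        tp <- tp + length(intersect(called, pp$spiked))
        fp <- fp + length(setdiff(called, pp$spiked))
        fn <- fn + length(setdiff(pp$spiked, called))
        # per-plate standardization holds after the full pipeline
        expect_lt(abs(mean(res$ngdScores$z)), 1e-9)
        expect_lt(abs(sd(res$ngdScores$z) - 1), 1e-9)
        expect_lt(abs(mean(res$optScores$z)), 1e-9)
        # spiked effects reduce GFP: all true positives score negative
        expect_true(all(res$hits$direction[res$hits$strain %in%
                                               pp$spiked] == "decreased"))
    }
    precision <- tp / (tp + fp)
    recall <- tp / (tp + fn)
    expect_gte(precision, 0.95)
    expect_gte(recall, 0.95)
})

test_that("scores are invariant to plate-wide intensity scaling", {
    pp <- simulatePlatePair(seed = 77L)
    scaled <- pp$ngd
    d <- plateData(scaled)
    d$gfp <- d$gfp * 7.3
    d$rfp <- d$rfp * 7.3
    scaled@data <- d
    z1 <- screenPipeline(pp$ngd, pp$opt)$ngdScores
    z2 <- screenPipeline(scaled, pp$opt)$ngdScores
    expect_equal(z1$z, z2$z, tolerance = 1e-9)
})

test_that("border removal never changes another strain's raw score", {
    pp <- simulatePlatePair(seed = 78L)
    full <- scoreStrains(filterColonies(pp$ngd)$grid)
    # drop one border colony by hand before the pipeline
    g2 <- pp$ngd
    d <- plateData(g2)
    drop <- which(d$is_border)[1L]
    g2@data <- d[-drop, ]
    redo <- scoreStrains(filterColonies(g2)$grid)
    expect_identical(full, redo)
})

test_that("plate grids round trip through the delimited format", {
    pp <- simulatePlatePair(seed = 79L)
    path <- tempfile(fileext = ".tsv")
    writePlateGrid(pp$ngd, path)
    back <- readPlateGrid(path)
    expect_identical(plateId(back), plateId(pp$ngd))
    expect_equal(plateData(back), plateData(pp$ngd), ignore_attr = TRUE)
})
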