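test_that("placeMonosomeRead inverts the default offset rules", {
    set.seed(11)
    tab <- defaultOffsetTable("monosome")
    rules <- offsetRules(tab)
    for (i in 1:200) {
        cls <- sample(c("16", "21", "28"), 1L)
        p <- placeMonosomeRead(500L, cls, tab)
        expect_false(is.null(p))
        expect_identical(p$end - p$start, p$length)
        sub <- rules[rules$size_class == cls, ]
        expect_true(p$length %in% sub$length)
        if (cls == "16") {
            expect_identical(p$end, 500L)           # 3' end = cut point
        } else {
            off <- sub$offset[sub$length == p$length]
            expect_identical(p$start, 500L - off)   # 5' end = site - offset
        }
    }
    # documented examples: 21 nt at offset 17, 28 nt at offset 16
    repeat { p <- placeMonosomeRead(500L, "21"); if (p$length == 21L) break }
    expect_identical(p$start, 483L)
    repeat { p <- placeMonosomeRead(500L, "28"); if (p$length == 28L) break }
    expect_identical(p$start, 484L)
    # boundary: site 16 admits only the length-20 (offset 16) placement
    got <- integer()
    for (i in 1:100) {
        p <- placeMonosomeRead(16L, "21")
        if (!is.null(p)) { expect_identical(p$start, 0L)
                           got <- c(got, p$length) }
    }
    expect_true(all(got == 20L))
})

test_that("disome placement uses offset 47 and 3'-end cut rule", {
    set.seed(12)
    tab <- defaultOffsetTable("disome")
    for (i in 1:100) {
        p <- placeMonosomeRead(500L, "60", tab)
        expect_identical(p$start, 500L - 47L)
        expect_true(p$length %in% 57:62)
        p <- placeMonosomeRead(500L, "54", tab)
        expect_identical(p$start, 500L - 47L)
        p <- placeMonosomeRead(500L, "46", tab)
        expect_identical(p$end, 500L)
        expect_true(p$length %in% 44:48)
    }
})

test_that("attachAdapterUmis wraps footprints at the documented layout", {
    set.seed(13)
    fp21 <- random_seq(21)
    r <- attachAdapterUmis(fp21, readLength = 50L)
    expect_identical(nchar(r), 48L)                  # 4 + 21 + 6 + 17
    expect_identical(substr(r, 32L, 48L), "CACTCGGGCACCAAGGA")
    expect_identical(substr(r, 5L, 25L), fp21)
    fp16 <- random_seq(16)
    r16 <- attachAdapterUmis(fp16, readLength = 51L)
    expect_identical(substr(r16, 27L, 43L), "CACTCGGGCACCAAGGA")
    # determinism under a fixed seed
    set.seed(99); a <- attachAdapterUmis(c(fp16, fp21))
    set.seed(99); b <- attachAdapterUmis(c(fp16, fp21))
    expect_identical(a, b)
    expect_error(attachAdapterUmis(""), "nonempty")
})

test_that("simulated library matches configured class weights and geometry", {
    fx <- ngd_fixture()
    truth <- fx$sim$truth
    sig <- truth[truth$type != "background", ]
    frac <- table(sig$class) / nrow(sig)
    cw <- fx$scenario$classWeights
    for (cl in names(cw))
        expect_lt(abs(frac[[cl]] - cw[[cl]]), 0.02)  # binomial at n = 50k
    # stall geometry: lead A sites at stall codons 2-5
    st <- stallInterval(fx$construct)[1L]
    lead <- sig[sig$type == "lead", ]
    expect_setequal(unique(lead$site), st + 3L * (2:5 - 1L))
    # collided A sites and cut points exactly 30 nt upstream of a lead site
    expect_setequal(unique(sig$site[sig$type == "collided"]),
                    st + 3L * (2:5 - 1L) - 30L)
    expect_setequal(unique(sig$site[sig$type == "cleaved"]),
                    st + 3L * (2:5 - 1L) - 30L)
    # trimmed lengths always within the declared class ranges
    expect_true(all(sig$length[sig$class == "16"] %in% 15:17))
    expect_true(all(sig$length[sig$class == "21"] %in% 20:22))
    expect_true(all(sig$length[sig$class == "28"] %in% 27:32))
})

test_that("zero-weight classes and empty libraries are honoured", {
    rep <- buildReporter("NGD-CGA")
    cue2 <- scenarioPreset("cue2 dom34 ski2", nReads = 5000L, seed = 3L)
    sim <- simulateNgdLibrary(rep, cue2)
    expect_identical(sum(sim$truth$class == "16"), 0L)
    empty <- simulateNgdLibrary(rep, scenarioConfig(nReads = 0L,
                                                    backgroundRate = 0))
    expect_length(empty$reads, 0L)
    fq <- tempfile(fileext = ".fastq")
    writeFastq(empty$reads, fq)
    expect_identical(length(readLines(fq)), 0L)
})

test_that("identical seeds give byte-identical libraries", {
    rep <- buildReporter("NGD-CGA")
    sc <- scenarioConfig(nReads = 2000L, seed = 42L)
    f1 <- tempfile(); f2 <- tempfile()
    simulateNgdLibrary(rep, sc, fastq = f1)
    simulateNgdLibrary(rep, sc, fastq = f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("disome library inverts the disome offset table", {
    rep <- buildReporter("NGD-CGA")
    sc <- scenarioConfig(classWeights = c("60" = 0.4, "54" = 0.3,
                                          "46" = 0.3),
                         nReads = 4000L, readLength = 100L, seed = 5L)
    sim <- simulateDisomeLibrary(rep, sc)
    sig <- sim$truth[sim$truth$type != "background", ]
    s60 <- sig[sig$class == "60", ]
    expect_true(all(s60$start == s60$site - 47L))
    expect_true(all(s60$length %in% 57:62))
    s54 <- sig[sig$class == "54", ]
    expect_true(all(s54$start == s54$site - 47L))
    s46 <- sig[sig$class == "46", ]
    expect_true(all(s46$end == s46$site))            # 3' end = cut point
    expect_true(all(s46$length %in% 44:48))
})

test_that("polyA reads end at the junction with untemplated A tails", {
    rep <- buildReporter("NGD-CGA")
    ref <- simulateNgdLibrary(rep, scenarioConfig(nReads = 0L,
                                                  backgroundRate = 0))$reference
    txt <- as.character(ref$seqs[["NGD-CGA"]])
    j <- 600L   # junction where the reference resumes with a non-A base
    while (substr(txt, j + 1L, j + 1L) == "A") j <- j + 1L
    specs <- data.frame(gene_id = "NGD-CGA", junction_position = j,
                        tail_read_count = 5L, untemplated_A_per_read = 3L)
    sim <- simulatePolyAReads(ref, specs, seed = 2L)
    expect_identical(nrow(sim$truth), 5L)
    for (i in seq_len(nrow(sim$truth))) {
        tr <- sim$truth[i, ]
        raw <- sim$reads[[tr$read_id]]
        fp <- substr(raw, 5L, 4L + tr$length + tr$untemplated_A)
        # templated part is the reference up to the junction...
        expect_identical(substr(fp, 1L, tr$length),
                         substr(txt, tr$start + 1L, tr$end))
        # ...followed by A's the reference does not continue with
        expect_identical(substr(fp, tr$length + 1L, nchar(fp)), "AAA")
        expect_false(substr(txt, tr$end + 1L, tr$end + 1L) == "A")
        expect_true(tr$length + tr$untemplated_A <= 34L)
    }
    # A = 0 reads are plain footprints; counts are additive across specs
    specs2 <- rbind(specs,
                    data.frame(gene_id = "NGD-CGA", junction_position = 900L,
                               tail_read_count = 4L,
                               untemplated_A_per_read = 0L))
    sim2 <- simulatePolyAReads(ref, specs2, seed = 2L)
    expect_identical(nrow(sim2$truth), 9L)
    expect_error(simulatePolyAReads(ref, transform(specs,
                                                   junction_position = 20L)),
                 "within 34 nt")
})

test_that("plate pairs have 1536 layout, 2x2 strain blocks, border ring", {
    pp <- simulatePlatePair(seed = 21L, sizeOutlierFrac = 0)
    d <- plateData(pp$ngd)
    expect_identical(nrow(d), 32L * 48L)
    tab <- table(d$strain[!d$is_border])
    expect_true(all(tab == 4L))
    expect_true(all(d$is_border[d$row <= 2L | d$row >= 31L |
                                    d$col <= 2L | d$col >= 47L]))
    expect_true(all(d$size_px >= 1500 & d$size_px <= 6000))
    # outlier fraction materializes outside the window
    pp2 <- simulatePlatePair(seed = 21L, sizeOutlierFrac = 0.05)
    d2 <- plateData(pp2$ngd)
    expect_gt(sum(d2$size_px < 1500 | d2$size_px > 6000), 0L)
})
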