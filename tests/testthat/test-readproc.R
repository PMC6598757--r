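test_that("trimming recovers footprints wrapped by the adapter/UMI layout", {
    set.seed(31)
    fps <- vapply(sample(15:34, 1000L, replace = TRUE), random_seq,
                  character(1L))
    raw <- attachAdapterUmis(fps, readLength = 51L)
    tr <- trimReads(setNames(raw, sprintf("r%04d", seq_along(raw))))
    expect_true(all(tr$status == "kept"))
    expect_identical(tr$insert, fps)
    expect_true(all(nchar(tr$umi5) == 4L & nchar(tr$umi3) == 6L))
    # one internal adapter mismatch is tolerated
    mut <- raw[1L]
    apos <- 4L + nchar(fps[1L]) + 6L + 8L   # 8th adapter base
    substr(mut, apos, apos) <- if (substr(mut, apos, apos) == "A") "C" else "A"
    tr1 <- trimReads(mut)
    expect_identical(tr1$status, "kept")
    expect_identical(tr1$insert, fps[1L])
})

test_that("adapter-less and adapter-only reads get terminal statuses", {
    set.seed(32)
    expect_identical(trimReads(random_seq(51))$status, "no_adapter")
    only <- paste0("ACGT", "CACTCGGGCACCAAGGA")   # UMI5 then adapter
    expect_identical(trimReads(only)$status, "too_short")
    # a long insert over the configured maximum
    big <- attachAdapterUmis(random_seq(95), readLength = 130L)
    expect_identical(trimReads(big, maxInsert = 90L)$status, "too_long")
})

test_that("contaminant filtering removes near-matches only", {
    set.seed(33)
    cont <- random_seq(120)
    reads <- c(sub = substr(cont, 31L, 51L),    # exact 21-nt substring
               far = random_seq(21))
    mk <- function(x) data.frame(read_id = names(x), insert = unname(x),
                                 umi5 = "", umi3 = "", status = "kept",
                                 stringsAsFactors = FALSE)
    part <- filterContaminants(mk(reads), cont)
    expect_identical(part$contaminant$read_id, "sub")
    expect_identical(part$kept$read_id, "far")
    # empty contaminant set is the identity
    id <- filterContaminants(mk(reads), character())
    expect_identical(id$kept, mk(reads))
    # 3 mismatches in 21 nt exceed the 10% tolerance; 2 do not
    x <- substr(cont, 31L, 51L)
    mut <- function(s, k) {
        for (i in seq_len(k)) {
            b <- substr(s, i * 3L, i * 3L)
            substr(s, i * 3L, i * 3L) <- setdiff(c("A", "C", "G", "T"), b)[1L]
        }
        s
    }
    expect_identical(nrow(filterContaminants(mk(c(m3 = mut(x, 3L))),
                                             cont)$contaminant), 0L)
    expect_identical(nrow(filterContaminants(mk(c(m2 = mut(x, 2L))),
                                             cont)$contaminant), 1L)
})

test_that("alignment handles exact, tailed and multimapping reads", {
    set.seed(34)
    ref <- c(tx1 = random_seq(600))
    # exact substring
    aln <- alignFootprints(c(r1 = substr(ref, 101L, 121L)), ref)
    expect_identical(aln$status, "aligned")
    expect_identical(aln$start, 100L)
    expect_identical(aln$untemplated_A, 0L)
    expect_identical(aln$mismatches, 0L)
    # 18-nt match + AAA where the reference continues with non-A
    p <- 200L
    while (grepl("A", substr(ref, p + 19L, p + 21L), fixed = TRUE))
        p <- p + 1L
    read <- paste0(substr(ref, p + 1L, p + 18L), "AAA")
    aln <- alignFootprints(setNames(read, "tail"), ref)
    expect_identical(aln$length, 18L)
    expect_identical(aln$untemplated_A, 3L)
    expect_identical(aln$end, p + 18L)
    # duplicated substring: equally good placements are multimapped
    dup <- paste0(random_seq(100), substr(ref, 301L, 330L))
    aln <- alignFootprints(c(mm = substr(ref, 306L, 325L)),
                           c(ref, tx2 = dup))
    expect_identical(aln$status, "multimapped")
    # unalignable read
    aln <- alignFootprints(c(none = random_seq(25)), ref)
    expect_identical(aln$status, "unaligned")
})

test_that("alignment agrees with the all-positions brute-force oracle", {
    set.seed(35)
    refs <- c(tx1 = random_seq(800), tx2 = random_seq(400))
    n <- 1000L
    reads <- character(n)
    for (i in seq_len(n)) {
        kind <- sample(c("exact", "mismatch", "tail", "random"), 1L,
                       prob = c(0.35, 0.25, 0.25, 0.15))
        t <- sample(1:2, 1L)
        L <- sample(15:32, 1L)
        p <- sample(nchar(refs[t]) - L - 5L, 1L)
        s <- substr(refs[t], p, p + L - 1L)
        if (kind == "mismatch") {
            i1 <- sample(L, 1L)
            substr(s, i1, i1) <- sample(c("A", "C", "G", "T"), 1L)
        } else if (kind == "tail") {
            nA <- sample(1:4, 1L)
            s <- paste0(substr(s, 1L, L - nA), strrep("A", nA))
        } else if (kind == "random") {
            s <- random_seq(L)
        }
        reads[i] <- s
    }
    got <- alignFootprints(setNames(reads, sprintf("r%04d", 1:n)), refs)
    for (i in seq_len(n)) {
        want <- oracle_align(reads[i], refs)
        expect_identical(got$status[i], want$status, label = reads[i])
        if (want$status == "aligned") {
            expect_identical(got$transcript_id[i], names(refs)[want$tx])
            expect_identical(got$start[i], want$start)
            expect_identical(got$length[i], want$length)
            expect_identical(got$untemplated_A[i], want$untemplated_A)
            expect_identical(got$mismatches[i], want$mismatches)
        }
    }
})

test_that("SAM round trip preserves intervals, clips and read ids", {
    set.seed(36)
    ref <- c(txA = random_seq(700), txB = random_seq(500))
    n <- 500L
    tx <- sample(names(ref), n, replace = TRUE)
    len <- sample(15:32, n, replace = TRUE)
    start <- vapply(seq_len(n), function(i)
        sample.int(nchar(ref[tx[i]]) - len[i] - 6L, 1L), integer(1L)) - 1L
    aln <- data.frame(read_id = sprintf("s%04d", seq_len(n)),
                      transcript_id = tx, start = start,
                      end = start + len, length = len,
                      untemplated_A = sample(0:3, n, replace = TRUE),
                      mismatches = 0L, umi5 = "", umi3 = "",
                      status = "aligned", stringsAsFactors = FALSE)
    sam <- tempfile(fileext = ".sam")
    writeSam(aln, ref, sam)
    back <- readSam(sam)
    cols <- c("read_id", "transcript_id", "start", "end", "length",
              "untemplated_A")
    expect_identical(back[order(back$read_id), cols],
                     aln[order(aln$read_id), cols], ignore_attr = TRUE)
    # a 3' soft clip that is not all-A is not an untemplated tail
    rec <- sprintf("clip\t0\ttxA\t11\t255\t18M3S\t*\t0\t0\t%s\t*\tNM:i:0",
                   paste0(substr(ref["txA"], 11L, 28L), "AAG"))
    sam2 <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6", sprintf("@SQ\tSN:txA\tLN:%d",
                                        nchar(ref["txA"])), rec), sam2)
    back2 <- readSam(sam2)
    expect_identical(back2$untemplated_A, 0L)
    expect_identical(back2$length, 18L)
    # indel records are skipped with a count
    rec3 <- sprintf("indel\t0\ttxA\t11\t255\t10M2D8M\t*\t0\t0\t%s\t*",
                    substr(ref["txA"], 11L, 28L))
    sam3 <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6", sprintf("@SQ\tSN:txA\tLN:%d",
                                        nchar(ref["txA"])), rec3), sam3)
    expect_message(back3 <- readSam(sam3), "indel")
    expect_identical(nrow(back3), 0L)
    expect_identical(attr(back3, "skipped_indel"), 1L)
    # empty alignment set -> header-only SAM
    sam4 <- tempfile(fileext = ".sam")
    writeSam(aln[0L, ], ref, sam4)
    expect_true(all(grepl("^@", readLines(sam4))))
})

test_that("every read lands in exactly one accounting category", {
    set.seed(37)
    ref <- c(tx1 = random_seq(900))
    cont <- random_seq(150)
    fps <- c(vapply(sample(15:32, 300L, replace = TRUE), random_seq,
                    character(1L)),                       # unalignable
             vapply(1:300, function(i) {
                 L <- sample(15:32, 1L)
                 p <- sample(nchar(ref) - L, 1L)
                 substr(ref, p, p + L - 1L)
             }, character(1L)),                           # alignable
             vapply(1:100, function(i) substr(cont, 21L, 41L),
                    character(1L)))                       # contaminant
    raw <- attachAdapterUmis(fps)
    raw <- c(raw, vapply(1:50, function(i) random_seq(51L), character(1L)))
    names(raw) <- sprintf("r%04d", seq_along(raw))
    trimmed <- trimReads(raw)
    part <- filterContaminants(trimmed, cont)
    aln <- alignFootprints(part$kept, ref)
    acc <- readAccounting(trimmed, part$contaminant, aln)
    expect_identical(sum(acc), length(raw))
    expect_gte(acc[["contaminant"]], 100L)
    expect_gte(acc[["no_adapter"]], 45L)
})

test_that("UMI deduplication collapses identical placements only", {
    aln <- data.frame(read_id = c("a", "b", "c"),
                      transcript_id = "tx", start = c(10L, 10L, 10L),
                      end = c(31L, 31L, 31L), length = 21L,
                      untemplated_A = 0L, mismatches = 0L,
                      umi5 = c("ACGT", "ACGT", "TTTT"),
                      umi3 = c("AAACCC", "AAACCC", "AAACCC"),
                      status = "aligned", stringsAsFactors = FALSE)
    dd <- dedupUmis(aln)
    expect_setequal(dd$read_id, c("a", "c"))
})
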