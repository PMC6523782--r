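test_that("FASTA parsing normalizes case and maps U to T", {
    f <- writeTempFasta(c(">a", "ACGT", ">b", "TTTT"))
    x <- readTranscripts(f)
    expect_equal(as.character(x), c(a = "ACGT", b = "TTTT"))

    f2 <- writeTempFasta(c(">a desc", "acgu"))
    x2 <- readTranscripts(f2)
    expect_equal(unname(as.character(x2)), "ACGT")
    expect_equal(names(x2), "a")

    # multi-line sequence bodies
    f3 <- writeTempFasta(c(">m", "ACGT", "ACGT"))
    expect_equal(unname(as.character(readTranscripts(f3))), "ACGTACGT")
})

test_that("FASTA parsing rejects degenerate input", {
    empty <- tempfile(); file.create(empty)
    expect_error(readTranscripts(empty), "empty")
    expect_error(readTranscripts(tempfile()), "not found")
    bad <- writeTempFasta(c("ACGT", ">a"))
    expect_error(readTranscripts(bad), "malformed")
})

test_that("two-FASTA and TSV label routes agree", {
    pos <- writeTempFasta(c(">m1", "ACGT"))
    neg <- writeTempFasta(c(">l1", "TTTT", ">l2", "GGGG"))
    x <- readLabeledTranscripts(pos, neg)
    expect_equal(transcriptLabels(x), c(1L, 0L, 0L))

    tsv <- tempfile()
    writeLines(c("m1\t1", "l1\t0", "l2\t0"), tsv)
    all <- writeTempFasta(c(">l1", "TTTT", ">m1", "ACGT", ">l2", "GGGG"))
    y <- attachLabels(readTranscripts(all), tsv)
    expect_equal(transcriptLabels(y), c(0L, 1L, 0L))
})

test_that("cleaning drops short and ambiguous records, preserving order", {
    seqs <- c(short = strrep("ACGT", 37),              # 148 nt
              ok1 = strrep("ACGT", 63),                # 252 nt
              amb = paste0(strrep("ACGT", 74), "N"),   # 297 nt with N
              ok2 = strrep("GATC", 50))                # 200 nt exactly
    cl <- cleanSequences(Biostrings::BStringSet(seqs))
    expect_equal(names(cl), c("ok1", "ok2"))
    expect_true(all(nchar(as.character(cl)) >= 200))
    expect_false(any(grepl("[^ACTG]", as.character(cl))))

    # idempotence
    cl2 <- cleanSequences(cl)
    expect_identical(as.character(cl2), as.character(cl))

    # stripping mode keeps the record when enough bases remain
    st <- cleanSequences(Biostrings::BStringSet(seqs), stripAmbiguous = TRUE)
    expect_true("amb" %in% names(st))
    expect_equal(nchar(as.character(st[["amb"]])), 296L)

    expect_length(cleanSequences(Biostrings::BStringSet(character(0))), 0L)
})

make_labelled <- function(n0, n1, len = 210L) {
    set.seed(99)
    seqs <- vapply(seq_len(n0 + n1), function(i)
        paste(sample(c("A", "C", "T", "G"), len, replace = TRUE),
              collapse = ""), character(1L))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- sprintf("r%03d", seq_along(x))
    S4Vectors::mcols(x) <- S4Vectors::DataFrame(
        label = rep(c(0L, 1L), c(n0, n1)))
    x
}

test_that("balanced split obeys the 7:3 stratified arithmetic", {
    x <- make_labelled(70, 70)
    sp <- balancedSplit(x, trainFrac = 0.7, seed = 5)
    expect_length(sp$train, 98L)
    expect_length(sp$test, 42L)
    expect_equal(unname(table(transcriptLabels(sp$train))), c(49L, 49L),
                 ignore_attr = TRUE)
    expect_equal(unname(table(transcriptLabels(sp$test))), c(21L, 21L),
                 ignore_attr = TRUE)
    expect_length(intersect(names(sp$train), names(sp$test)), 0L)
})

test_that("majority class is downsampled to 1:1 before splitting", {
    x <- make_labelled(100, 60)
    sp <- balancedSplit(x, seed = 3)
    labs <- c(transcriptLabels(sp$train), transcriptLabels(sp$test))
    expect_equal(sum(labs == 0L), 60L)
    expect_equal(sum(labs == 1L), 60L)
})

test_that("splits are reproducible and single-class input fails", {
    x <- make_labelled(30, 30)
    a <- balancedSplit(x, seed = 11)
    b <- balancedSplit(x, seed = 11)
    expect_identical(names(a$train), names(b$train))
    expect_identical(names(a$test), names(b$test))
    c_ <- balancedSplit(x, seed = 12)
    expect_false(identical(names(a$train), names(c_$train)))

    y <- make_labelled(10, 0)
    S4Vectors::mcols(y)$label <- rep(0L, 10L)
    expect_error(balancedSplit(y), "both classes")
})

test_that("k-fold indices form a stratified partition", {
    x <- make_labelled(10, 10)
    folds <- kfoldIndices(x, kFolds = 10, seed = 2)
    expect_length(folds, 10L)
    tests <- lapply(folds, `[[`, "test")
    expect_equal(lengths(tests), rep(2L, 10L))
    expect_equal(sort(unlist(tests)), 1:20)
    for (f in folds) {
        expect_length(intersect(f$train, f$test), 0L)
        expect_equal(sort(c(f$train, f$test)), 1:20)
    }
    expect_error(kfoldIndices(x, kFolds = 20), "smallest class")
})
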