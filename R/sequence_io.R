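#' Read transcript sequences from FASTA
#'
#' Parses a (possibly multi-line) FASTA file of nucleotide sequences.
#' Sequences are uppercased and RNA-style U residues are mapped to T, so
#' both DNA- and RNA-formatted transcript FASTA are accepted. No filtering
#' happens here; see [cleanSequences()].
#'
#' @param path path to a FASTA file.
#' @param label optional single label (0 = lncRNA, 1 = mRNA) attached to
#'   every record, or `NA` for unlabelled input.
#' @return A [Biostrings::BStringSet] with record ids as names and an
#'   integer `label` metadata column.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1", "acgu", ">t2", "TTTT"), fa)
#' readTranscripts(fa)
#' @export
readTranscripts <- function(path, label = NA_integer_) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    first <- readLines(path, n = 1L)
    if (length(first) == 0L)
        stop("FASTA file is empty: ", path)
    if (!startsWith(first, ">"))
        stop("malformed FASTA (first line must start with '>'): ", path)
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0L)
        stop("FASTA file contains no records: ", path)
    x <- Biostrings::BStringSet(chartr("U", "T", toupper(as.character(x))))
    # keep only the first whitespace-delimited word of each header
    names(x) <- sub("\\s.*$", "", names(x))
    S4Vectors::mcols(x) <- S4Vectors::DataFrame(
        label = rep(as.integer(label), length(x)))
    x
}

#' Read a labelled two-class dataset from paired FASTA files
#'
#' @param posPath FASTA of the positive class (mRNA, label 1).
#' @param negPath FASTA of the negative class (lncRNA, label 0).
#' @return A labelled `BStringSet` concatenating both files.
#' @export
readLabeledTranscripts <- function(posPath, negPath) {
    pos <- readTranscripts(posPath, label = 1L)
    neg <- readTranscripts(negPath, label = 0L)
    if (any(names(pos) %in% names(neg)))
        stop("record ids are shared between the two classes")
    out <- c(pos, neg)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        label = c(rep(1L, length(pos)), rep(0L, length(neg))))
    out
}

#' Attach labels from a two-column TSV
#'
#' @param records an `XStringSet` of transcripts.
#' @param path TSV file with columns `id` and `label` (0/1), no header or
#'   with header.
#' @return `records` with the `label` metadata column filled in.
#' @export
attachLabels <- function(records, path) {
    tab <- utils::read.delim(path, header = FALSE,
                             col.names = c("id", "label"),
                             colClasses = c("character", "character"))
    if (identical(tolower(tab$id[1L]), "id")) tab <- tab[-1L, , drop = FALSE]
    lab <- suppressWarnings(as.integer(tab$label))
    if (any(is.na(lab)) || !all(lab %in% c(0L, 1L)))
        stop("labels must be 0 (lncRNA) or 1 (mRNA)")
    idx <- match(names(records), tab$id)
    if (anyNA(idx))
        stop("no label found for record(s): ",
             paste(head(names(records)[is.na(idx)], 5L), collapse = ", "))
    S4Vectors::mcols(records)$label <- lab[idx]
    records
}

#' Extract labels from a transcript set
#'
#' @param records an `XStringSet` with a `label` metadata column.
#' @return integer vector of labels.
#' @export
transcriptLabels <- function(records) {
    lab <- S4Vectors::mcols(records)$label
    if (is.null(lab)) rep(NA_integer_, length(records)) else as.integer(lab)
}

#' Clean transcript records
#'
#' Applies the dataset hygiene rules used throughout the package: records
#' shorter than `minLen` nucleotides are removed, and records containing
#' any character other than A, C, T, G are removed entirely (dropping, not
#' stripping, avoids creating artificial k-mer junctions). With
#' `stripAmbiguous = TRUE` the offending characters are instead deleted
#' before the length filter, for input that is known to contain sparse Ns.
#' Record order is preserved and the operation is idempotent.
#'
#' @param records an `XStringSet` (labels in `mcols` are carried through).
#' @param minLen minimum surviving length in nucleotides (default 200).
#' @param stripAmbiguous strip non-ACTG characters instead of dropping the
#'   whole record.
#' @param verbose report how many records each rule removed.
#' @return A [Biostrings::DNAStringSet] of surviving records.
#' @export
cleanSequences <- function(records, minLen = 200L, stripAmbiguous = FALSE,
                           verbose = FALSE) {
    seqs <- as.character(records)
    labs <- transcriptLabels(records)
    ids <- names(records)
    if (is.null(ids)) ids <- as.character(seq_along(seqs))
    nAmbig <- 0L
    if (stripAmbiguous) {
        seqs <- gsub("[^ACTG]", "", seqs)
    } else {
        ok <- !grepl("[^ACTG]", seqs)
        nAmbig <- sum(!ok)
        seqs <- seqs[ok]; labs <- labs[ok]; ids <- ids[ok]
    }
    long <- nchar(seqs) >= minLen
    nShort <- sum(!long)
    seqs <- seqs[long]; labs <- labs[long]; ids <- ids[long]
    if (verbose)
        message(sprintf("dropped %d record(s) with non-ACTG characters, %d shorter than %d nt",
                        nAmbig, nShort, minLen))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(label = labs)
    out
}

#' Balanced, stratified train/test split
#'
#' Optionally downsamples the majority class at random so both classes are
#' used in a 1:1 ratio, then splits each class independently (stratified)
#' into strictly non-overlapping training and test sets. Deterministic for
#' a given `seed`.
#'
#' @param records labelled `XStringSet` (every label 0 or 1).
#' @param trainFrac fraction of each class assigned to training
#'   (default 0.7 for a 7:3 split).
#' @param balance downsample the majority class to the minority size first.
#' @param seed integer RNG seed.
#' @return A list with elements `train` and `test` (subsets of `records`),
#'   plus `seed`.
#' @export
balancedSplit <- function(records, trainFrac = 0.7, balance = TRUE,
                          seed = 1L) {
    labs <- transcriptLabels(records)
    if (anyNA(labs)) stop("all records must be labelled")
    if (length(unique(labs)) < 2L)
        stop("both classes must be present to split")
    if (trainFrac <= 0 || trainFrac >= 1)
        stop("'trainFrac' must lie in (0, 1)")
    set.seed(seed)
    idx0 <- which(labs == 0L)
    idx1 <- which(labs == 1L)
    if (balance) {
        m <- min(length(idx0), length(idx1))
        if (length(idx0) > m) idx0 <- sort(sample(idx0, m))
        if (length(idx1) > m) idx1 <- sort(sample(idx1, m))
    }
    takeTrain <- function(idx) {
        nTrain <- round(trainFrac * length(idx))
        sort(sample(idx, nTrain))
    }
    tr0 <- takeTrain(idx0); tr1 <- takeTrain(idx1)
    trainIdx <- sort(c(tr0, tr1))
    testIdx <- sort(c(setdiff(idx0, tr0), setdiff(idx1, tr1)))
    list(train = records[trainIdx], test = records[testIdx],
         seed = as.integer(seed))
}

#' Stratified k-fold cross-validation indices
#'
#' Partitions the records into `kFolds` folds, stratified by label: each
#' class is shuffled and dealt round-robin so test folds are pairwise
#' disjoint and jointly cover every record.
#'
#' @param records labelled `XStringSet`.
#' @param kFolds number of folds (default 10).
#' @param seed integer RNG seed.
#' @return A list of `kFolds` lists, each with integer vectors `train` and
#'   `test` of record indices.
#' @export
kfoldIndices <- function(records, kFolds = 10L, seed = 1L) {
    labs <- transcriptLabels(records)
    if (anyNA(labs)) stop("all records must be labelled")
    if (kFolds < 2L) stop("'kFolds' must be >= 2")
    counts <- table(labs)
    if (kFolds > min(counts))
        stop(sprintf("'kFolds' (%d) exceeds the smallest class size (%d)",
                     kFolds, min(counts)))
    set.seed(seed)
    fold <- integer(length(labs))
    for (cl in names(counts)) {
        idx <- sample(which(labs == as.integer(cl)))
        fold[idx] <- rep_len(seq_len(kFolds), length(idx))
    }
    lapply(seq_len(kFolds), function(f)
        list(train = which(fold != f), test = which(fold == f)))
}

#' Write transcripts as FASTA with a label sidecar
#'
#' @param records labelled `XStringSet`.
#' @param fastaPath output FASTA path.
#' @param labelPath optional output TSV path (`id<TAB>label`).
#' @return `fastaPath`, invisibly.
#' @export
writeTranscripts <- function(records, fastaPath, labelPath = NULL) {
    Biostrings::writeXStringSet(records, fastaPath)
    if (!is.null(labelPath)) {
        utils::write.table(
            data.frame(id = names(records), label = transcriptLabels(records)),
            labelPath, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
    }
    invisible(fastaPath)
}
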