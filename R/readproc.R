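#' Read a barcode sheet
#'
#' TSV with columns `sample` and `barcode` (4-nt by default). Duplicate
#' barcodes or samples are an error at load time.
#'
#' @param path TSV path.
#' @param barcode_length expected barcode length.
#' @return data.frame with columns `sample`, `barcode`.
#' @export
readBarcodeSheet <- function(path, barcode_length = 4) {
    df <- read.delim(path, colClasses = "character")
    if (!all(c("sample", "barcode") %in% names(df)))
        stop("barcode sheet needs 'sample' and 'barcode' columns")
    validateBarcodes(df, barcode_length)
    df
}

validateBarcodes <- function(sheet, barcode_length = 4) {
    if (anyDuplicated(sheet$barcode))
        stop("duplicate barcodes in sheet: ",
             paste(unique(sheet$barcode[duplicated(sheet$barcode)]),
                   collapse = ", "))
    if (anyDuplicated(sheet$sample))
        stop("duplicate sample names in sheet")
    if (!all(nchar(sheet$barcode) == barcode_length))
        stop("all barcodes must be ", barcode_length, " nt")
    invisible(sheet)
}

#' Demultiplex reads by their leading inline barcode
#'
#' Routes each read by exact match of its first `barcode_length` bases
#' against the sheet; non-matching reads go to `undetermined`. The barcode
#' prefix is retained on the read — stripping happens at collapse time, so
#' collapsing can use the full `[barcode][UMI][insert]` sequence.
#'
#' @param reads character vector of read sequences.
#' @param sheet data.frame with columns `sample`, `barcode`
#'   (see [readBarcodeSheet()]).
#' @param barcode_length barcode length (default 4).
#' @return Named list of read vectors, one per sample, plus
#'   `undetermined`.
#' @examples
#' demultiplex(c("ACGTAAAA", "TTTTCCCC"),
#'             data.frame(sample = "s1", barcode = "ACGT"))
#' @export
demultiplex <- function(reads, sheet, barcode_length = 4) {
    validateBarcodes(sheet, barcode_length)
    prefix <- substr(reads, 1, barcode_length)
    idx <- match(prefix, sheet$barcode)
    out <- lapply(seq_len(nrow(sheet)), function(i) reads[!is.na(idx) & idx == i])
    names(out) <- sheet$sample
    out$undetermined <- reads[is.na(idx)]
    out
}

# all start positions where adapter (or a terminal prefix >= min_partial)
# matches seq exactly
.adapterStarts <- function(seq, adapter, allow_partial, min_partial) {
    L <- nchar(seq)
    alen <- nchar(adapter)
    starts <- integer(0)
    m <- gregexpr(adapter, seq, fixed = TRUE)[[1]]
    if (m[1] != -1L) starts <- as.integer(m)
    if (allow_partial && min(alen - 1, L) >= min_partial) {
        for (k in seq(min_partial, min(alen - 1, L)))
            if (substr(seq, L - k + 1, L) == substr(adapter, 1, k))
                starts <- c(starts, L - k + 1L)
    }
    sort(unique(starts))
}

#' Trim the 3' adapter by scanning from the read's 3' end
#'
#' Finds exact occurrences of the 3' adapter by scanning candidate start
#' positions in 1-nt increments and trims everything from the match start
#' onward, keeping the 5' portion (`[barcode][UMI][insert]`). When several
#' full matches exist, `match = "rightmost"` (default) takes the one
#' closest to the 3' end, per the scan direction; `"leftmost"` is exposed
#' because an insert containing the adapter motif is pathological either
#' way. When no full match exists and `allow_partial` is on, an adapter
#' prefix running off the read end (>= `min_partial` matched bases, longest
#' overlap preferred) counts as a match — with 50-nt reads and <= 30-nt
#' inserts behind a 12-nt prefix the full adapter is usually present, so
#' this rarely fires.
#'
#' @param reads character vector of read sequences.
#' @param adapter3 adapter sequence (non-empty).
#' @param match `"rightmost"` or `"leftmost"` full-match tie-break.
#' @param allow_partial allow terminal adapter-prefix matches.
#' @param min_partial minimum matched bases for a terminal partial match.
#' @return data.frame with columns `retained` (5' portion; the read itself
#'   when no adapter was found) and `found` (logical).
#' @examples
#' trimAdapter3("ACGTACGTAGATCG", "AGATCG")
#' @export
trimAdapter3 <- function(reads, adapter3, match = c("rightmost", "leftmost"),
                         allow_partial = TRUE, min_partial = 5) {
    match <- match.arg(match)
    stopifnot(nchar(adapter3) >= 1, min_partial >= 1)
    alen <- nchar(adapter3)
    retained <- reads
    found <- logical(length(reads))
    for (i in seq_along(reads)) {
        starts <- .adapterStarts(reads[i], adapter3, allow_partial, min_partial)
        if (!length(starts)) next
        L <- nchar(reads[i])
        full <- starts[starts <= L - alen + 1]
        pos <- if (length(full)) {
            if (match == "rightmost") max(full) else min(full)
        } else min(starts)   # longest terminal overlap
        retained[i] <- substr(reads[i], 1, pos - 1)
        found[i] <- TRUE
    }
    data.frame(retained = retained, found = found, stringsAsFactors = FALSE)
}

#' Process reads: trim, decompose and classify
#'
#' Applies [trimAdapter3()], then splits each trimmed read into barcode,
#' UMI and insert and assigns a status: `ok` (insert of at least
#' `min_insert` nt), `dimer` (adapter found immediately after barcode+UMI,
#' insert empty), `too_short` (trimmed read shorter than barcode+UMI, or
#' insert of 1 to `min_insert - 1` nt), `no_adapter` (read untouched).
#'
#' @param reads character vector of read sequences (one sample).
#' @param adapter3 3' adapter sequence.
#' @param barcode_length,umi_length layout prefix lengths (defaults 4, 8).
#' @param min_insert minimum insert length for status `ok` (default 15).
#' @param sample sample name recorded on each row.
#' @param ... passed to [trimAdapter3()].
#' @return data.frame with columns `sample`, `read`, `retained`, `barcode`,
#'   `umi`, `insert`, `status`.
#' @export
processReads <- function(reads, adapter3, barcode_length = 4, umi_length = 8,
                         min_insert = 15, sample = NA_character_, ...) {
    tr <- trimAdapter3(reads, adapter3, ...)
    prefix <- barcode_length + umi_length
    n <- length(reads)
    status <- rep("ok", n)
    status[!tr$found] <- "no_adapter"
    short <- tr$found & nchar(tr$retained) < prefix
    status[short] <- "too_short"
    insert_len <- nchar(tr$retained) - prefix
    status[tr$found & !short & insert_len == 0] <- "dimer"
    status[tr$found & !short & insert_len > 0 & insert_len < min_insert] <- "too_short"
    data.frame(
        sample = sample,
        read = reads,
        retained = tr$retained,
        barcode = ifelse(status %in% c("ok", "dimer"),
                         substr(tr$retained, 1, barcode_length), NA),
        umi = ifelse(status %in% c("ok", "dimer"),
                     substr(tr$retained, barcode_length + 1, prefix), NA),
        insert = ifelse(status == "ok",
                        substr(tr$retained, prefix + 1, nchar(tr$retained)),
                        ifelse(status == "dimer", "", NA)),
        status = status,
        stringsAsFactors = FALSE)
}

#' Collapse reads of one sample to raw and UMI-deduplicated counts
#'
#' Raw (non-collapsed) counts tally every `ok` read per insert after
#' stripping the barcode+UMI prefix; collapsed counts tally distinct full
#' trimmed sequences — equivalently distinct (UMI, insert) pairs within the
#' barcode — treating identical reads as amplification products of one
#' molecule. Collapsing is exact: no error-tolerant UMI network merging.
#'
#' @param processed data.frame from [processReads()] for one sample.
#' @param umi_length UMI length (for the label-space bound check).
#' @return A list of class `CollapseResult`: `raw_counts` and
#'   `collapsed_counts` (named integer vectors per insert) and `umis`
#'   (data.frame `insert`, `umi`, `reads`).
#' @examples
#' pr <- processReads(c("ACGTAAAACCCCTTTTGGGTTTTGGGTTAGATCG",
#'                      "ACGTAAAACCCCTTTTGGGTTTTGGGTTAGATCG"), "AGATCG")
#' collapseReads(pr)$raw_counts
#' @export
collapseReads <- function(processed, umi_length = 8) {
    ok <- processed[processed$status == "ok", , drop = FALSE]
    if (!nrow(ok)) {
        empty <- setNames(integer(0), character(0))
        return(structure(list(raw_counts = empty, collapsed_counts = empty,
                              umis = data.frame(insert = character(0),
                                                umi = character(0),
                                                reads = integer(0))),
                         class = "CollapseResult"))
    }
    raw <- table(ok$insert)
    fam <- stats::aggregate(list(reads = rep(1L, nrow(ok))),
                            by = list(insert = ok$insert, umi = ok$umi),
                            FUN = sum)
    fam <- fam[order(fam$insert, fam$umi), , drop = FALSE]
    rownames(fam) <- NULL
    collapsed <- table(fam$insert)
    res <- structure(list(
        raw_counts = setNames(as.integer(raw), names(raw)),
        collapsed_counts = setNames(as.integer(collapsed), names(collapsed)),
        umis = fam), class = "CollapseResult")
    stopifnot(all(res$collapsed_counts <= res$raw_counts),
              all(res$collapsed_counts <= 4^umi_length))
    res
}

#' @export
print.CollapseResult <- function(x, ...) {
    cat("CollapseResult:", length(x$raw_counts), "distinct inserts;",
        sum(x$raw_counts), "reads ->", sum(x$collapsed_counts),
        "distinct molecules (UMI-collapsed)\n")
    invisible(x)
}

#' Adapter-dimer fraction of a processed read set
#'
#' @param processed data.frame from [processReads()] (non-empty).
#' @return Fraction of reads with status `dimer`.
#' @export
dimerFraction <- function(processed) {
    if (!nrow(processed)) stop("no processed reads")
    mean(processed$status == "dimer")
}
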