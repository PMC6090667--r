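#' Exact-match reference index
#'
#' A set of DNA-normalized reference sequences (U -> T, uppercase) queried
#' by exact full-length substring matching, replacing a no-mismatch
#' short-read aligner. Stranded annotation sets (mature miRNA, 21U) are
#' matched against the forward strand only; genome indices match both
#' strands.
#'
#' @slot name index name.
#' @slot sequences a [Biostrings::DNAStringSet] of normalized entries.
#' @slot bothStrands logical: also search reverse complements.
#' @seealso [referenceIndex()], [alignExact()]
#' @export
setClass("ReferenceIndex", representation(
    name = "character", sequences = "DNAStringSet", bothStrands = "logical"))

setValidity("ReferenceIndex", function(object) {
    msg <- character()
    if (length(object@sequences) == 0) msg <- c(msg, "empty reference")
    if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
        msg <- c(msg, "entries must have unique ids")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceIndex", function(object) {
    cat("ReferenceIndex '", object@name, "': ", length(object@sequences),
        " entries (", sum(width(object@sequences)), " nt), ",
        if (object@bothStrands) "both strands" else "forward strand",
        "\n", sep = "")
})

#' Build a reference index from FASTA or sequences
#'
#' Accepts a FASTA path (miRBase dialect allowed: U bases, headers whose
#' first whitespace-delimited token is the feature id), a named character
#' vector, or an `XStringSet`. Sequences are normalized to uppercase DNA.
#'
#' @param x FASTA path, named character vector, or `XStringSet`.
#' @param name index name (defaults to the file name).
#' @param bothStrands search reverse complements too (use for genomes).
#' @return A [ReferenceIndex-class].
#' @examples
#' idx <- referenceIndex(c(`cel-miR-1-5p` = "UGGAAUGUAAAGAAGUAUGUA"),
#'                       name = "mirna")
#' alignExact("TGGAATGTAAAGAAGTATGTA", idx, max_hits = 1)
#' @export
referenceIndex <- function(x, name = NULL, bothStrands = FALSE) {
    if (is.character(x) && length(x) == 1 && is.null(names(x)) && file.exists(x)) {
        if (is.null(name)) name <- tools::file_path_sans_ext(basename(x))
        x <- readBStringSet(x)
    }
    seqs <- if (is(x, "XStringSet")) setNames(as.character(x), names(x)) else x
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    names(seqs) <- vapply(strsplit(names(seqs), "\\s+"),
                          function(t) t[1], "")
    seqs <- toupper(chartr("Uu", "Tt", seqs))
    if (is.null(name)) name <- "reference"
    new("ReferenceIndex", name = name,
        sequences = DNAStringSet(seqs), bothStrands = bothStrands)
}

#' Exact full-length alignment with a hit-count gate
#'
#' Counts all exact substring occurrences of each insert in the index
#' (both strands for genome indices) and classifies it: `aligned` when
#' 1 to `max_hits` occurrences are found, `ambiguous` when more than
#' `max_hits` (excluded from counting, mirroring an aligner's `-m` gate),
#' `unaligned` when none. For `max_hits = 1` the hosting entry is reported
#' as the feature.
#'
#' @param inserts character vector of non-empty DNA insert sequences.
#' @param index a [ReferenceIndex-class].
#' @param max_hits maximum allowed occurrences (1 for annotation sets,
#'   10 for genomes).
#' @return data.frame with columns `insert`, `n_hits`, `feature`
#'   (`NA` unless uniquely assigned), `status`.
#' @export
alignExact <- function(inserts, index, max_hits = 1) {
    stopifnot(is(index, "ReferenceIndex"), max_hits >= 1)
    if (!length(inserts))
        return(data.frame(insert = character(0), n_hits = integer(0),
                          feature = character(0), status = character(0)))
    if (any(!nzchar(inserts))) stop("empty insert sequence")
    if (any(!grepl("^[ACGT]+$", inserts)))
        stop("inserts must be DNA (A/C/G/T) sequences")
    subject <- index@sequences
    n_hits <- integer(length(inserts))
    feature <- rep(NA_character_, length(inserts))
    for (i in seq_along(inserts)) {
        cnt <- vcountPattern(inserts[i], subject)
        if (index@bothStrands)
            cnt <- cnt + vcountPattern(
                as.character(reverseComplement(DNAString(inserts[i]))), subject)
        n_hits[i] <- sum(cnt)
        if (n_hits[i] >= 1 && n_hits[i] <= max_hits && max_hits == 1)
            feature[i] <- names(subject)[which(cnt > 0)][1]
    }
    status <- ifelse(n_hits == 0, "unaligned",
                     ifelse(n_hits > max_hits, "ambiguous", "aligned"))
    data.frame(insert = inserts, n_hits = n_hits, feature = feature,
               status = status, stringsAsFactors = FALSE)
}

#' Count reads/molecules per reference feature
#'
#' Aligns the distinct inserts of a [collapseReads()] result to an
#' annotation index (unique-hit policy, `max_hits = 1`) in a single pass
#' and sums the raw (read) and collapsed (distinct-UMI) weights of inserts
#' uniquely assigned to each feature. Ambiguous and unaligned weights are
#' tallied separately so that total mass is conserved.
#'
#' @param collapse a `CollapseResult`.
#' @param index a [ReferenceIndex-class] (annotation set).
#' @return A list with `raw` and `collapsed` (named numeric vectors over
#'   all index features) and `unassigned` / `ambiguous` two-element vectors
#'   carrying the residual raw/collapsed mass.
#' @export
countFeatures <- function(collapse, index) {
    stopifnot(inherits(collapse, "CollapseResult"))
    feats <- names(index@sequences)
    raw <- setNames(numeric(length(feats)), feats)
    collapsed <- raw
    inserts <- names(collapse$raw_counts)
    res <- list(raw = raw, collapsed = collapsed,
                unassigned = c(raw = 0, collapsed = 0),
                ambiguous = c(raw = 0, collapsed = 0))
    if (!length(inserts)) return(res)
    aln <- alignExact(inserts, index, max_hits = 1)
    for (i in seq_along(inserts)) {
        w_raw <- collapse$raw_counts[[inserts[i]]]
        w_col <- collapse$collapsed_counts[[inserts[i]]]
        if (aln$status[i] == "aligned") {
            f <- aln$feature[i]
            res$raw[f] <- res$raw[f] + w_raw
            res$collapsed[f] <- res$collapsed[f] + w_col
        } else if (aln$status[i] == "ambiguous") {
            res$ambiguous <- res$ambiguous + c(w_raw, w_col)
        } else {
            res$unassigned <- res$unassigned + c(w_raw, w_col)
        }
    }
    res
}

#' Small RNA count experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying the two count
#' flavors of a UMI workflow in parallel: assay `raw` (read counts) and
#' assay `collapsed` (distinct-UMI molecule counts), features x samples.
#'
#' @seealso [buildCountExperiment()], [rawCounts()], [collapsedCounts()]
#' @export
setClass("SmallRNAExperiment", contains = "SummarizedExperiment")

setValidity("SmallRNAExperiment", function(object) {
    msg <- character()
    if (!all(c("raw", "collapsed") %in% assayNames(object)))
        msg <- c(msg, "assays 'raw' and 'collapsed' are required")
    else {
        if (any(assay(object, "raw") < 0) || any(assay(object, "collapsed") < 0))
            msg <- c(msg, "counts must be non-negative")
        if (any(assay(object, "collapsed") > assay(object, "raw")))
            msg <- c(msg, "collapsed counts cannot exceed raw counts")
    }
    if (length(msg)) msg else TRUE
})

#' Build a count experiment from per-sample collapse results
#'
#' @param collapses named list of `CollapseResult` objects (one per sample).
#' @param index annotation [ReferenceIndex-class] (unique-hit counting).
#' @return A [SmallRNAExperiment-class] with assays `raw` and `collapsed`;
#'   per-sample unassigned/ambiguous residual mass is kept in
#'   `metadata()$residual`.
#' @export
buildCountExperiment <- function(collapses, index) {
    stopifnot(length(collapses) > 0, !is.null(names(collapses)))
    per <- lapply(collapses, countFeatures, index = index)
    feats <- names(index@sequences)
    raw <- vapply(per, function(p) p$raw, numeric(length(feats)))
    col <- vapply(per, function(p) p$collapsed, numeric(length(feats)))
    if (length(feats) == 1) {           # vapply drops to vector
        raw <- matrix(raw, nrow = 1)
        col <- matrix(col, nrow = 1)
    }
    dimnames(raw) <- dimnames(col) <- list(feats, names(collapses))
    se <- SummarizedExperiment(
        assays = list(raw = raw, collapsed = col),
        metadata = list(residual = lapply(per, function(p)
            list(unassigned = p$unassigned, ambiguous = p$ambiguous))))
    new("SmallRNAExperiment", se)
}

#' @describeIn SmallRNAExperiment-class read-count (non-collapsed) matrix
#' @param x a `SmallRNAExperiment`
#' @export
rawCounts <- function(x) assay(x, "raw")

#' @describeIn SmallRNAExperiment-class distinct-UMI (collapsed) matrix
#' @export
collapsedCounts <- function(x) assay(x, "collapsed")

#' Weighted insert length distribution
#'
#' @param inserts character vector of insert sequences.
#' @param weights per-insert weights (default 1; e.g. raw or collapsed
#'   counts).
#' @param range inclusive length range reported per-length (default 15-30
#'   nt); lengths outside go to an `outside` bucket.
#' @return Named numeric vector over the lengths in `range` plus
#'   `outside`.
#' @export
lengthDistribution <- function(inserts, weights = NULL, range = c(15, 30)) {
    if (is.null(weights)) weights <- rep(1, length(inserts))
    stopifnot(length(weights) == length(inserts))
    lens <- nchar(inserts)
    bins <- seq(range[1], range[2])
    out <- setNames(numeric(length(bins) + 1), c(bins, "outside"))
    for (i in seq_along(inserts)) {
        key <- if (lens[i] >= range[1] && lens[i] <= range[2])
            as.character(lens[i]) else "outside"
        out[key] <- out[key] + weights[i]
    }
    out
}

#' Hierarchical per-length classification of inserts
#'
#' Reproduces the nested classification of small RNA length profiles:
#' tier 1 counts inserts aligning to the genome (exact match, at most
#' `genome_max_hits` occurrences); tier 2 the subset of tier 1 not
#' aligning to any mature miRNA; tier 3 the subset of tier 2 also not
#' aligning to any 21U-RNA. Tiers are strictly nested by construction.
#'
#' @param inserts character vector of distinct insert sequences.
#' @param genome_index,mirna_index,p21u_index [ReferenceIndex-class]
#'   objects; the genome index should have `bothStrands = TRUE`.
#' @param weights per-insert weights (default 1).
#' @param range per-length reporting range (default 15-30 nt).
#' @param genome_max_hits occurrence gate for the genome tier (default 10;
#'   a sequence within the gate is counted once regardless of hit
#'   multiplicity).
#' @return data.frame with columns `length`, `genome_aligned`,
#'   `not_mirna`, `not_mirna_not_21u`.
#' @export
classifyHierarchy <- function(inserts, genome_index, mirna_index, p21u_index,
                              weights = NULL, range = c(15, 30),
                              genome_max_hits = 10) {
    if (is.null(weights)) weights <- rep(1, length(inserts))
    g <- alignExact(inserts, genome_index, max_hits = genome_max_hits)
    m <- alignExact(inserts, mirna_index, max_hits = 1)
    u <- alignExact(inserts, p21u_index, max_hits = 1)
    tier1 <- g$status == "aligned"
    tier2 <- tier1 & m$n_hits == 0
    tier3 <- tier2 & u$n_hits == 0
    lens <- c(seq(range[1], range[2]))
    sumTier <- function(sel) vapply(lens, function(L)
        sum(weights[sel & nchar(inserts) == L]), numeric(1))
    data.frame(length = lens,
               genome_aligned = sumTier(tier1),
               not_mirna = sumTier(tier2),
               not_mirna_not_21u = sumTier(tier3))
}

#' First-nucleotide composition of inserts
#'
#' Weighted frequency of the 5'-most base among inserts, optionally
#' restricted to one insert length (e.g. the 5' G preference of 26-nt
#' primary siRNAs).
#'
#' @param inserts character vector of insert sequences (DNA alphabet).
#' @param weights per-insert weights (default 1).
#' @param length optional length filter in nt.
#' @return Named numeric vector over A/C/G/T summing to 1; when no insert
#'   passes the filter, a zero vector is returned with a warning.
#' @export
firstNtProfile <- function(inserts, weights = NULL, length = NULL) {
    if (is.null(weights)) weights <- rep(1, base::length(inserts))
    if (!is.null(length)) {
        keep <- nchar(inserts) == length
        inserts <- inserts[keep]
        weights <- weights[keep]
    }
    out <- setNames(numeric(4), c("A", "C", "G", "T"))
    if (!base::length(inserts) || sum(weights) == 0) {
        warning("no inserts selected for first-nucleotide profile")
        return(out)
    }
    first <- substr(inserts, 1, 1)
    for (b in names(out)) out[b] <- sum(weights[first == b])
    out / sum(out)
}
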