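# Shared fixtures built in code.

# tiny calibration for planner unit tests: concentrations A=35 < B=40
toyCalibration <- function() {
    SpriCalibration(matrix(c(50, 90, 2, 60), 2, byrow = TRUE,
                           dimnames = list(c("40", "20"), c("35", "40"))))
}

# independent brute-force oracle for the 3'-scan trimmer: try every start
# position; rightmost full match wins, otherwise longest terminal partial
oracleTrim <- function(seq, adapter, match = "rightmost",
                       allow_partial = TRUE, min_partial = 5) {
    L <- nchar(seq); alen <- nchar(adapter)
    full <- integer(0)
    for (p in seq_len(max(L - alen + 1, 0)))
        if (substring(seq, p, p + alen - 1) == adapter) full <- c(full, p)
    if (length(full)) {
        pos <- if (match == "rightmost") max(full) else min(full)
        return(list(retained = substring(seq, 1, pos - 1), found = TRUE))
    }
    if (allow_partial) {
        for (k in rev(seq_len(min(alen - 1, L)))) {   # longest overlap first
            if (k < min_partial) break
            if (substring(seq, L - k + 1, L) == substring(adapter, 1, k))
                return(list(retained = substring(seq, 1, L - k),
                            found = TRUE))
        }
    }
    list(retained = seq, found = FALSE)
}

randomDNA <- function(n, len) {
    len <- rep(len, length.out = n)
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
              collapse = ""), "")
}

# brute-force substring-occurrence counter (independent of Biostrings)
oracleHits <- function(insert, refs, bothStrands = FALSE) {
    rc <- function(s) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    countIn <- function(pat, s) {
        n <- 0L
        for (p in seq_len(max(nchar(s) - nchar(pat) + 1, 0)))
            if (substring(s, p, p + nchar(pat) - 1) == pat) n <- n + 1L
        n
    }
    tot <- sum(vapply(refs, countIn, integer(1), pat = insert))
    if (bothStrands)
        tot <- tot + sum(vapply(refs, countIn, integer(1), pat = rc(insert)))
    tot
}

# toy miRNA-style references (DNA, distinct 22-mers)
toyMirnaRefs <- function() {
    c(`mir-1`  = "TGGAATGTAAAGAAGTATGTAT",
      `mir-35` = "TCACCGGGTGGAAACTAGCAGT",
      `mir-58` = "TGAGATCGTTCAGTACGGCAAT")
}
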