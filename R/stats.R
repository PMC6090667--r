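#' Replicate dispersion of a feature
#'
#' Squared relative difference of a feature's normalized counts between
#' replicate libraries, with the smaller value as base: for two replicates
#' `a <= b` the statistic is `((b - a)/a)^2`, so replicates differing by
#' 10% give 0.01. With more than two replicates the mean over all pairs is
#' returned. The statistic is scale-invariant. A pair with one zero count
#' yields `Inf`; an all-zero feature is undefined (`NA` with a warning).
#'
#' @param a numeric vector of replicate values, or the first of two values.
#' @param b optional second value when `a` is scalar.
#' @return A single dispersion value.
#' @examples
#' replicateDispersion(100, 110)   # 0.01
#' replicateDispersion(c(50, 60))  # 0.04
#' @export
replicateDispersion <- function(a, b = NULL) {
    x <- if (is.null(b)) a else c(a, b)
    stopifnot(is.numeric(x), length(x) >= 2, all(x >= 0))
    if (all(x == 0)) {
        warning("all replicate values are zero; dispersion undefined")
        return(NA_real_)
    }
    pairs <- utils::combn(x, 2)
    vals <- apply(pairs, 2, function(p) {
        lo <- min(p); hi <- max(p)
        if (hi == 0) return(0)
        if (lo == 0) return(Inf)
        (hi - lo)^2 / lo^2
    })
    mean(vals)
}

#' Per-feature replicate dispersion of a count matrix
#'
#' @param mat numeric matrix, features x replicate samples (normalized
#'   counts).
#' @return Named numeric vector of dispersions; all-zero features are `NA`
#'   (skipped with a notice).
#' @export
dispersionByFeature <- function(mat) {
    stopifnot(is.matrix(mat), ncol(mat) >= 2)
    out <- apply(mat, 1, function(x) {
        if (all(x == 0)) NA_real_
        else suppressWarnings(replicateDispersion(x))
    })
    n_skip <- sum(is.na(out))
    if (n_skip > 0)
        message(n_skip, " all-zero feature(s) skipped in dispersion")
    out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: each sample's factor is the median,
#' over features with all-positive counts, of the ratio of its count to
#' the feature's geometric mean across samples. Normalized counts are
#' `count / factor`.
#'
#' @param counts numeric matrix, features x samples.
#' @return Named numeric vector of size factors (one per sample).
#' @examples
#' sizeFactorsMedianRatio(rbind(c(100, 200), c(10, 20), c(40, 80)))
#' @export
sizeFactorsMedianRatio <- function(counts) {
    stopifnot(is.matrix(counts), all(counts >= 0))
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos))
        stop("no feature with all-positive counts; ",
             "consider adding a pseudocount before normalizing")
    logg <- rowMeans(log(counts[pos, , drop = FALSE]))
    apply(counts[pos, , drop = FALSE], 2,
          function(cnt) exp(median(log(cnt) - logg)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (delegates to
#' [stats::p.adjust()] after input validation).
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param tab 2x2 matrix of non-negative counts with all margins positive.
#' @return List with `statistic` and `p.value`.
#' @export
chiSquare2x2 <- function(tab) {
    tab <- as.matrix(tab)
    stopifnot(all(dim(tab) == 2), all(tab >= 0))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("all margins of the 2x2 table must be positive")
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p.value = unname(ct$p.value))
}

#' Expected number of distinct UMI labels
#'
#' With `n` molecules labelled independently and uniformly from `K`
#' labels, the expected number of distinct labels is
#' `K * (1 - (1 - 1/K)^n)`; collisions make the observed distinct count an
#' undercount of `n` as the copy/label ratio `n/K` grows.
#'
#' @param n molecule count(s), >= 0.
#' @param K label-space size (e.g. `4^8` for 8-nt UMIs).
#' @return Expected distinct label count(s).
#' @export
umiExpectedDistinct <- function(n, K) {
    stopifnot(all(n >= 0), K >= 1)
    K * (1 - (1 - 1 / K)^n)
}

#' Expected UMI undercounting rate
#'
#' `1 - E[distinct]/n`: the expected fraction of molecules lost to label
#' collisions at a given copy/label ratio.
#'
#' @inheritParams umiExpectedDistinct
#' @return Expected undercount fraction(s) in \[0, 1).
#' @export
umiUndercount <- function(n, K) {
    stopifnot(all(n >= 1))
    1 - umiExpectedDistinct(n, K) / n
}

#' Correct an observed distinct-UMI count for label collisions
#'
#' Inverts [umiExpectedDistinct()]: for `d` observed distinct labels out
#' of `K`, the moment estimate of the molecule count is
#' `-K * log(1 - d/K)`. A saturated count (`d >= K`) is uncorrectable.
#'
#' @param d observed distinct label count(s), `0 <= d < K`.
#' @param K label-space size.
#' @return Estimated molecule count(s).
#' @examples
#' umiCorrect(umiExpectedDistinct(64, 256), 256)  # ~64
#' @export
umiCorrect <- function(d, K) {
    stopifnot(all(d >= 0), K >= 1)
    if (any(d >= K))
        stop("distinct count saturates the label space (d >= K); ",
             "uncorrectable — use longer UMIs")
    -K * log(1 - d / K)
}

#' Per-feature adapter (barcode) bias between two libraries
#'
#' Absolute log2 ratio of a feature's normalized counts in two libraries
#' of the same sample prepared with different barcodes; a pseudocount
#' keeps zero-count features finite. Under unbiased preparation the
#' expectation is 0.
#'
#' @param counts_bc1,counts_bc2 normalized count vectors over the same
#'   features.
#' @param pseudocount added to both counts (default 0.5).
#' @return Numeric vector of per-feature bias values.
#' @export
barcodeBias <- function(counts_bc1, counts_bc2, pseudocount = 0.5) {
    stopifnot(length(counts_bc1) == length(counts_bc2))
    abs(log2((counts_bc1 + pseudocount) / (counts_bc2 + pseudocount)))
}

#' Summarize bias improvement between count flavors
#'
#' Compares per-feature barcode bias computed from raw (non-collapsed)
#' counts against the bias from UMI-collapsed counts.
#'
#' @param bias_raw,bias_collapsed vectors from [barcodeBias()] on the two
#'   flavors.
#' @return List with `fraction_improved` (share of features whose bias
#'   decreased), `mean_reduction` (mean of raw - collapsed) and
#'   `per_feature` improvements.
#' @export
biasImprovement <- function(bias_raw, bias_collapsed) {
    stopifnot(length(bias_raw) == length(bias_collapsed))
    impr <- bias_raw - bias_collapsed
    list(fraction_improved = mean(impr > 0),
         mean_reduction = mean(impr),
         per_feature = impr)
}

#' Two-group negative-binomial differential expression test
#'
#' Normalizes counts by median-of-ratios size factors, fits a per-feature
#' negative-binomial dispersion by method of moments pooled across the two
#' conditions, and tests equality of group means with a Wald statistic on
#' log means (delta-method variance `(1/m + phi)/n` per group). P-values
#' are BH-adjusted and a feature is called `up`/`down` only when the
#' pseudocounted fold change is at least `min_fold` and the adjusted
#' p-value is below `alpha` (defaults 5 and 0.01). `up` means higher in
#' the non-reference condition. The pseudocount (0.5) enters the reported
#' fold change only, never the test statistic; features with a zero group
#' mean cannot be Wald-tested and are reported with `NA` p-values.
#'
#' @param counts numeric matrix, features x samples.
#' @param condition factor/character of length `ncol(counts)` with exactly
#'   two levels, each with >= 2 replicates.
#' @param reference the baseline condition (denominator of the fold
#'   change); defaults to the first factor level.
#' @param size_factors optional per-sample factors (e.g. `rep(1, n)` to
#'   skip normalization); estimated from the matrix when `NULL`.
#' @param min_fold,alpha call thresholds.
#' @param dispersion_floor lower bound for the MoM dispersion.
#' @return data.frame with columns `feature`, `baseMeanRef`,
#'   `baseMeanAlt`, `log2fc`, `pvalue`, `padj`, `call`.
#' @export
deTest <- function(counts, condition, reference = NULL, size_factors = NULL,
                   min_fold = 5, alpha = 0.01, dispersion_floor = 1e-8) {
    stopifnot(is.matrix(counts), ncol(counts) == length(condition))
    condition <- as.factor(condition)
    if (nlevels(condition) != 2)
        stop("exactly two conditions are required")
    if (any(table(condition) < 2))
        stop("each condition needs at least two replicates")
    if (is.null(reference)) reference <- levels(condition)[1]
    stopifnot(reference %in% levels(condition))
    other <- setdiff(levels(condition), reference)

    if (is.null(size_factors)) size_factors <- sizeFactorsMedianRatio(counts)
    stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0))
    norm <- sweep(counts, 2, size_factors, "/")

    A <- norm[, condition == reference, drop = FALSE]
    B <- norm[, condition == other, drop = FALSE]
    nA <- ncol(A); nB <- ncol(B)
    mA <- rowMeans(A); mB <- rowMeans(B)
    vA <- apply(A, 1, var); vB <- apply(B, 1, var)

    momPhi <- function(m, v) ifelse(m > 0, (v - m) / m^2, NA_real_)
    phiA <- momPhi(mA, vA); phiB <- momPhi(mB, vB)
    phi <- rowMeans(cbind(phiA, phiB), na.rm = TRUE)
    phi[is.nan(phi)] <- dispersion_floor
    phi <- pmax(phi, dispersion_floor)

    testable <- mA > 0 & mB > 0
    z <- rep(NA_real_, nrow(counts))
    se2 <- (1 / mA + phi) / nA + (1 / mB + phi) / nB
    z[testable] <- (log(mB) - log(mA))[testable] / sqrt(se2[testable])
    pvalue <- 2 * pnorm(-abs(z))
    padj <- bhAdjust(pvalue)

    ratio <- (mB + 0.5) / (mA + 0.5)
    call <- rep("ns", nrow(counts))
    sig <- !is.na(padj) & padj < alpha
    call[sig & ratio >= min_fold] <- "up"
    call[sig & ratio <= 1 / min_fold] <- "down"

    data.frame(
        feature = if (is.null(rownames(counts)))
            sprintf("f%d", seq_len(nrow(counts))) else rownames(counts),
        baseMeanRef = mA, baseMeanAlt = mB,
        log2fc = log2(ratio), pvalue = pvalue, padj = padj,
        call = call, row.names = NULL, stringsAsFactors = FALSE)
}
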