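test_that("replicateDispersion matches the squared-relative-difference rule", {
    expect_identical(replicateDispersion(100, 110), 0.01)
    expect_identical(replicateDispersion(110, 100), 0.01)
    expect_equal(replicateDispersion(50, 60), 0.04)
    expect_equal(replicateDispersion(7, 7), 0)
    expect_equal(replicateDispersion(c(100, 110, 121)),
                 mean(c(0.01, (21 / 100)^2, 0.01)))
    expect_identical(replicateDispersion(0, 5), Inf)
    expect_warning(d <- replicateDispersion(0, 0), "zero")
    expect_true(is.na(d))
})

test_that("replicateDispersion is scale-invariant", {
    set.seed(111)
    for (i in 1:50) {
        ab <- runif(2, 1, 1000)
        cc <- runif(1, 0.01, 100)
        expect_equal(replicateDispersion(cc * ab[1], cc * ab[2]),
                     replicateDispersion(ab[1], ab[2]))
    }
})

test_that("dispersionByFeature skips all-zero features with a notice", {
    mat <- rbind(a = c(100, 110), b = c(0, 0), c = c(5, 5))
    expect_message(d <- dispersionByFeature(mat), "skipped")
    expect_equal(unname(d["a"]), 0.01)
    expect_true(is.na(d["b"]))
    expect_equal(unname(d["c"]), 0)
})

test_that("median-of-ratios size factors match the hand example", {
    m <- rbind(c(100, 200), c(10, 20), c(40, 80))
    sf <- sizeFactorsMedianRatio(m)
    expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

    same <- cbind(c(5, 9, 2), c(5, 9, 2))
    expect_equal(unname(sizeFactorsMedianRatio(same)), c(1, 1))

    # equivariance: scaling one sample scales its factor relative to others
    sf2 <- sizeFactorsMedianRatio(cbind(m[, 1], m[, 2] * 3))
    expect_equal((sf2[2] / sf2[1]) / (sf[2] / sf[1]), 3, ignore_attr = TRUE)

    expect_error(sizeFactorsMedianRatio(rbind(c(0, 1), c(2, 0))),
                 "pseudocount")
})

test_that("size factors agree with DESeq2 on random matrices", {
    skip_if_not_installed("DESeq2")
    set.seed(121)
    m <- matrix(rnbinom(600, mu = 50, size = 5) + 1L, ncol = 4)
    expect_equal(unname(sizeFactorsMedianRatio(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-10)
})

test_that("bhAdjust performs the step-up adjustment", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    p <- c(0.001, 0.4, 0.02, 0.9)
    expect_equal(order(bhAdjust(p)), order(p))   # order-preserving
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("chiSquare2x2 is Pearson without continuity correction", {
    flat <- chiSquare2x2(matrix(10, 2, 2))
    expect_equal(flat$statistic, 0)
    expect_equal(flat$p.value, 1)

    tab <- matrix(c(10, 20, 20, 10), 2)
    res <- chiSquare2x2(tab)
    expect_equal(res$statistic, 60 * (10 * 10 - 20 * 20)^2 / (30^4),
                 tolerance = 1e-12)
    expect_equal(res$statistic, chiSquare2x2(t(tab))$statistic)
    expect_error(chiSquare2x2(matrix(c(0, 0, 5, 5), 2)), "margins")
})

test_that("umiExpectedDistinct matches Monte-Carlo label sampling", {
    expect_equal(umiExpectedDistinct(1, 17), 1)
    expect_equal(umiExpectedDistinct(1, 4^8), 1)
    expect_equal(umiExpectedDistinct(0, 64), 0)
    # saturation limit
    expect_equal(umiExpectedDistinct(1e6, 256), 256, tolerance = 1e-6)

    set.seed(131)
    n <- 64; K <- 256
    mc <- mean(vapply(seq_len(1e5), function(i)
        length(unique(sample.int(K, n, replace = TRUE))), numeric(1)))
    expect_equal(umiExpectedDistinct(n, K), mc, tolerance = 0.005)
})

test_that("umiCorrect inverts the collision model", {
    expect_equal(umiCorrect(1, 4^8), 1, tolerance = 1 / (2 * 4^8) + 1e-5)
    # the estimator inverts the Poisson form of the model; the residual
    # relative bias against the exact binomial expectation is ~1/(2K)
    expect_equal(umiCorrect(umiExpectedDistinct(64, 256), 256), 64,
                 tolerance = 0.005)
    expect_equal(umiCorrect(56.725, 256), 64.1, tolerance = 0.001)
    for (n in c(2, 10, 50, 100, 128)) {   # n <= 0.5 K
        K <- 256
        expect_equal(umiCorrect(umiExpectedDistinct(n, K), K) / n, 1,
                     tolerance = 0.005)
    }
    expect_error(umiCorrect(256, 256), "saturat")
})

test_that("analytic undercount over copy/label ratios 0.2-0.6 sits in the 9-25% band", {
    K <- 4^8
    ratios <- seq(0.2, 0.6, by = 0.05)
    uc <- umiUndercount(ratios * K, K)
    expect_true(all(uc >= 0.09))
    expect_true(all(uc <= 0.25))
    expect_false(is.unsorted(uc))   # undercount grows with saturation
})

test_that("barcodeBias and biasImprovement behave as documented", {
    expect_equal(barcodeBias(10, 10), 0)
    expect_equal(barcodeBias(100, 50), log2(100.5 / 50.5))
    expect_equal(barcodeBias(100, 50), 0.99284, tolerance = 1e-5)
    expect_equal(barcodeBias(50, 100), barcodeBias(100, 50))  # symmetric

    imp <- biasImprovement(c(1, 0.5, 0.2), c(0.3, 0.6, 0.1))
    expect_equal(imp$fraction_improved, 2 / 3)
    expect_equal(imp$mean_reduction, mean(c(0.7, -0.1, 0.1)))
})

test_that("collapsing lowers barcode bias under library-specific PCR bias", {
    cfg <- simConfig(seed = 141, pcr_cycles = 8, seq_error_rate = 0,
                     dimer_fraction = 0, n_reads = 15000,
                     per_template_efficiency = distSpec("uniform",
                                                        min = 0.2, max = 1),
                     abundance = list(meanlog = 3, sdlog = 0.8))
    pop <- makePopulation(cfg, c(miRNA = 1), 30)
    lig <- rep(0.9, nrow(pop))     # shared ligation, independent PCR draws
    libA <- simulateLibrary(pop, libraryLayout("ACGT"), cfg, seed = 142,
                            ligation_probs = lig)
    libB <- simulateLibrary(pop, libraryLayout("TGCA"), cfg, seed = 143,
                            ligation_probs = lig)
    idx <- referenceIndex(setNames(chartr("U", "T", pop$sequence),
                                   pop$seq_id), "truth")
    se <- buildCountExperiment(list(
        A = collapseReads(processReads(libA$reads, "AGATCGGAAGAGCACACGTCT")),
        B = collapseReads(processReads(libB$reads, "AGATCGGAAGAGCACACGTCT"))),
        idx)
    norm <- function(m) sweep(m, 2, colSums(m) / mean(colSums(m)), "/")
    raw <- norm(rawCounts(se)); col <- norm(collapsedCounts(se))
    b_raw <- barcodeBias(raw[, "A"], raw[, "B"])
    b_col <- barcodeBias(col[, "A"], col[, "B"])
    expect_lt(median(b_col), median(b_raw))
    expect_gt(biasImprovement(b_raw, b_col)$fraction_improved, 0.5)
})

test_that("deTest calls no features on identical groups", {
    m <- matrix(rep(c(50, 80, 120), each = 6), nrow = 3, byrow = TRUE)
    res <- deTest(m, rep(c("e", "l"), each = 3))
    expect_true(all(res$log2fc == 0))
    expect_true(all(res$call == "ns"))
})

test_that("deTest flags an unambiguous 20-fold change", {
    m <- matrix(c(10, 10, 10, 200, 200, 200), nrow = 1)
    res <- deTest(m, rep(c("e", "l"), each = 3), size_factors = rep(1, 6))
    expect_equal(res$call, "up")
    expect_gt(res$log2fc, log2(5))
    expect_lt(res$padj, 0.01)
    res_rev <- deTest(m, rep(c("e", "l"), each = 3), reference = "l",
                      size_factors = rep(1, 6))
    expect_equal(res_rev$call, "down")
    expect_equal(res_rev$log2fc, -res$log2fc)
})

test_that("deTest recovers planted effects with controlled false calls", {
    set.seed(151)
    n_feat <- 200; n_true <- 20; reps <- 3
    mu <- exp(runif(n_feat, log(30), log(500)))
    fold <- rep(1, n_feat); fold[seq_len(n_true)] <- 8
    size <- 1 / 0.05                     # NB dispersion 0.05
    mk <- function(m) matrix(rnbinom(n_feat * reps, mu = rep(m, reps),
                                     size = size), ncol = reps)
    counts <- cbind(mk(mu), mk(mu * fold))
    rownames(counts) <- sprintf("f%03d", seq_len(n_feat))
    res <- deTest(counts, rep(c("e", "l"), each = reps))
    called_true <- sum(res$call[seq_len(n_true)] == "up")
    false_calls <- sum(res$call[-seq_len(n_true)] != "ns")
    expect_gte(called_true, 0.8 * n_true)
    expect_lte(false_calls, 2)
})

test_that("deTest type-I error at padj threshold is controlled on null data", {
    set.seed(161)
    n_feat <- 300
    counts <- matrix(rnbinom(n_feat * 6, mu = 100, size = 10), ncol = 6)
    res <- deTest(counts, rep(c("a", "b"), each = 3))
    expect_lte(sum(res$call != "ns"), 3)  # ~0 expected; binomial slack
})

test_that("collapsed counts disperse less than raw counts across technical replicates", {
    cfg <- simConfig(seed = 171, pcr_cycles = 8, seq_error_rate = 0,
                     dimer_fraction = 0, n_reads = 15000,
                     per_template_efficiency = distSpec("uniform",
                                                        min = 0.2, max = 1),
                     ligation_prob = distSpec("fixed", value = 0.9),
                     abundance = list(meanlog = 3, sdlog = 0.8))
    pop <- makePopulation(cfg, c(miRNA = 1), 30)
    idx <- referenceIndex(setNames(chartr("U", "T", pop$sequence),
                                   pop$seq_id), "truth")
    libs <- lapply(c(172, 173, 174), function(s)
        simulateLibrary(pop, libraryLayout("ACGT"), cfg, seed = s))
    cls <- lapply(libs, function(l)
        collapseReads(processReads(l$reads, "AGATCGGAAGAGCACACGTCT")))
    names(cls) <- paste0("t", 1:3)
    se <- buildCountExperiment(cls, idx)
    normDisp <- function(m) {
        sf <- sizeFactorsMedianRatio(m)
        d <- suppressMessages(dispersionByFeature(sweep(m, 2, sf, "/")))
        mean(d[is.finite(d)], na.rm = TRUE)
    }
    expect_lt(normDisp(collapsedCounts(se)), normDisp(rawCounts(se)))
})

test_that("raw/collapsed ratio grows with abundance as UMI labels saturate", {
    # 4-nt UMIs (K = 256) against copy numbers up to the thousands: the
    # most abundant species saturate the label space, so their collapsed
    # counts cap while raw counts keep growing
    cfg <- simConfig(seed = 181, pcr_cycles = 5, seq_error_rate = 0,
                     dimer_fraction = 0, n_reads = 30000,
                     per_template_efficiency = distSpec("fixed", value = 0.8),
                     ligation_prob = distSpec("fixed", value = 1),
                     abundance = list(meanlog = 4, sdlog = 1.5))
    pop <- makePopulation(cfg, c(miRNA = 1), 30)
    lay <- libraryLayout("ACGT", umi_length = 4)
    lib <- simulateLibrary(pop, lay, cfg)
    cl <- collapseReads(processReads(lib$reads, lay$adapter3,
                                     umi_length = 4), umi_length = 4)
    dna <- chartr("U", "T", pop$sequence)
    keep <- dna %in% names(cl$raw_counts)
    ratio <- cl$raw_counts[dna[keep]] / cl$collapsed_counts[dna[keep]]
    expect_gt(cor(lib$truth$ligated_count[keep], ratio,
                  method = "spearman"), 0.5)
    expect_true(all(cl$collapsed_counts <= 4^4))
})
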