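#' Pipeline run configuration
#'
#' Bundles the read layout, reference paths, calling thresholds and seed of
#' a pipeline run. Validation (threshold signs, file existence) happens
#' here, before any compute.
#'
#' @param adapter3 3' adapter sequence as sequenced.
#' @param barcode_length,umi_length,min_insert read layout parameters
#'   (defaults 4, 8, 15).
#' @param mirna_fasta,p21u_fasta,genome_fasta optional reference FASTA
#'   paths; must exist when given.
#' @param min_fold,alpha differential-expression call thresholds
#'   (defaults 5, 0.01).
#' @param min_keep,max_remove SPRI planning thresholds in percent
#'   (defaults 40, 5).
#' @param seed integer seed owned by the run; recorded in the report.
#' @param output_dir optional directory for per-stage artifacts.
#' @return A list of class `runConfig`.
#' @export
runConfig <- function(adapter3 = "AGATCGGAAGAGCACACGTCT",
                      barcode_length = 4, umi_length = 8, min_insert = 15,
                      mirna_fasta = NULL, p21u_fasta = NULL,
                      genome_fasta = NULL, min_fold = 5, alpha = 0.01,
                      min_keep = 40, max_remove = 5, seed = 1,
                      output_dir = NULL) {
    stopifnot(nchar(adapter3) >= 1, barcode_length >= 1, umi_length >= 1,
              min_insert >= 1, min_fold > 0, alpha > 0, min_keep > 0,
              max_remove > 0, is.numeric(seed))
    for (p in c(mirna_fasta, p21u_fasta, genome_fasta))
        if (!file.exists(p))
            stop("reference path does not exist: ", p)
    structure(list(adapter3 = adapter3, barcode_length = barcode_length,
                   umi_length = umi_length, min_insert = min_insert,
                   mirna_fasta = mirna_fasta, p21u_fasta = p21u_fasta,
                   genome_fasta = genome_fasta, min_fold = min_fold,
                   alpha = alpha, min_keep = min_keep,
                   max_remove = max_remove, seed = as.integer(seed),
                   output_dir = output_dir),
              class = "runConfig")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full small RNA pipeline
#'
#' Executes simulate-or-ingest, demultiplex, trim, collapse, quantify and
#' statistics in order and returns a structured report. The run is a pure
#' function of its inputs and the configured seed: identical seeds yield
#' identical reports.
#'
#' @param config a [runConfig()].
#' @param fastq FASTQ path(s) to ingest (alternative to `simulation`).
#' @param sheet barcode sheet data.frame (`sample`, `barcode`) or TSV path.
#' @param simulation optional list to simulate instead of ingest:
#'   `class_mix`, `n_species`, `sim_config` (a [simConfig()]; its seed is
#'   ignored — the run's seed governs) and optionally `rpph_treated`.
#'   Samples/barcodes come from `sheet`; per-species ligation bias is
#'   shared across samples, PCR draws are independent per library.
#' @param condition optional named vector mapping sample -> condition for
#'   dispersion summaries and (with two conditions, >= 2 replicates each)
#'   differential expression on collapsed miRNA counts.
#' @return A report list (also written as JSON to `config$output_dir` when
#'   set): seed, read/status tallies, per-sample dimer fraction, length
#'   histograms, optional count matrices, dispersion summaries and DE
#'   table.
#' @export
runPipeline <- function(config, fastq = NULL, sheet = NULL,
                        simulation = NULL, condition = NULL) {
    stopifnot(inherits(config, "runConfig"))
    set.seed(config$seed)
    if (is.character(sheet)) sheet <- readBarcodeSheet(sheet, config$barcode_length)
    if (is.null(sheet)) stop("a barcode sheet is required")
    validateBarcodes(sheet, config$barcode_length)

    input <- .stage("input", {
        if (!is.null(simulation)) {
            stopifnot(!is.null(simulation$class_mix),
                      !is.null(simulation$n_species))
            sc <- simulation$sim_config
            if (is.null(sc)) sc <- simConfig()
            sc$seed <- NULL                       # the run's RNG governs
            pop <- makePopulation(sc, simulation$class_mix,
                                  simulation$n_species, seed = NULL)
            lig <- drawSpec(sc$ligation_prob, nrow(pop))
            libs <- lapply(seq_len(nrow(sheet)), function(i) {
                lay <- libraryLayout(
                    sheet$barcode[i], config$umi_length, config$adapter3,
                    rpph_treated = isTRUE(simulation$rpph_treated),
                    barcode_length = config$barcode_length)
                simulateLibrary(pop, lay, sc, seed = NULL,
                                ligation_probs = lig)
            })
            list(reads = unlist(lapply(libs, `[[`, "reads"),
                                use.names = FALSE),
                 truth = lapply(setNames(libs, sheet$sample),
                                function(l) l$truth))
        } else if (!is.null(fastq)) {
            list(reads = unlist(lapply(fastq, readFastq),
                                use.names = FALSE),
                 truth = NULL)
        } else stop("either fastq or simulation must be given")
    })
    reads <- input$reads
    truth <- input$truth

    demuxed <- .stage("demultiplex", demultiplex(reads, sheet,
                                                 config$barcode_length))
    samples <- sheet$sample

    processed <- .stage("trim", lapply(setNames(samples, samples), function(s)
        processReads(demuxed[[s]], config$adapter3, config$barcode_length,
                     config$umi_length, config$min_insert, sample = s)))
    collapses <- .stage("collapse",
                        lapply(processed, collapseReads, umi_length = config$umi_length))

    report <- list(
        seed = config$seed,
        n_reads = length(reads),
        n_undetermined = length(demuxed$undetermined),
        samples = lapply(processed, function(pr) list(
            n = nrow(pr),
            status = as.list(table(pr$status)),
            dimer_fraction = dimerFraction(pr))),
        length_distribution = lapply(collapses, function(cl)
            as.list(lengthDistribution(names(cl$collapsed_counts),
                                       cl$collapsed_counts))))

    se <- NULL
    if (!is.null(config$mirna_fasta)) {
        se <- .stage("quantify", {
            idx <- referenceIndex(config$mirna_fasta, "mirna")
            buildCountExperiment(collapses, idx)
        })
        report$mirna_counts <- list(raw = as.data.frame(rawCounts(se)),
                                    collapsed = as.data.frame(collapsedCounts(se)))
    }
    if (!is.null(config$genome_fasta) && !is.null(config$mirna_fasta) &&
        !is.null(config$p21u_fasta)) {
        report$hierarchy <- .stage("profile", {
            gi <- referenceIndex(config$genome_fasta, "genome", bothStrands = TRUE)
            mi <- referenceIndex(config$mirna_fasta, "mirna")
            ui <- referenceIndex(config$p21u_fasta, "p21u")
            lapply(collapses, function(cl)
                classifyHierarchy(names(cl$collapsed_counts), gi, mi, ui,
                                  weights = cl$collapsed_counts))
        })
    }

    if (!is.null(condition) && !is.null(se)) {
        report$stats <- .stage("stats", {
            cond <- condition[colnames(se)]
            out <- list()
            for (flavor in c("raw", "collapsed")) {
                mat <- assay(se, flavor)
                disp <- lapply(unique(cond), function(g) {
                    sub <- mat[, cond == g, drop = FALSE]
                    if (ncol(sub) < 2) return(NULL)
                    sf <- tryCatch(sizeFactorsMedianRatio(sub),
                                   error = function(e) rep(1, ncol(sub)))
                    d <- suppressMessages(
                        dispersionByFeature(sweep(sub, 2, sf, "/")))
                    mean(d[is.finite(d)], na.rm = TRUE)
                })
                out[[paste0("mean_dispersion_", flavor)]] <-
                    setNames(disp, unique(cond))
            }
            if (length(unique(cond)) == 2 && all(table(cond) >= 2))
                out$de <- deTest(assay(se, "collapsed"), cond,
                                 min_fold = config$min_fold,
                                 alpha = config$alpha)
            out
        })
    }
    if (!is.null(truth)) report$truth <- truth

    if (!is.null(config$output_dir)) {
        dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(
            report[setdiff(names(report), "truth")],
            file.path(config$output_dir, "report.json"),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
        if (!is.null(se)) {
            writeCountMatrix(rawCounts(se),
                             file.path(config$output_dir, "counts_raw.tsv"))
            writeCountMatrix(collapsedCounts(se),
                             file.path(config$output_dir, "counts_collapsed.tsv"))
        }
    }
    report
}

#' Write / read a count matrix as TSV
#'
#' Features x samples with a `feature` column and a header row of sample
#' ids.
#'
#' @param mat numeric matrix with feature row names.
#' @param path TSV path.
#' @return `path` (write) or the matrix (read).
#' @export
writeCountMatrix <- function(mat, path) {
    df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountMatrix
#' @export
readCountMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df[[1]]
    mat
}
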