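#' Distribution specification for simulator parameters
#'
#' Small helper describing how a per-template probability (ligation or PCR
#' efficiency) is drawn. `beta` draws from `Beta(shape1, shape2)`, `uniform`
#' from `U(min, max)`, `fixed` always returns `value`.
#'
#' @param dist one of `"beta"`, `"uniform"`, `"fixed"`.
#' @param shape1,shape2 beta parameters.
#' @param min,max uniform bounds (within \[0, 1\]).
#' @param value fixed probability.
#' @return A list of class `distSpec`.
#' @export
distSpec <- function(dist = c("beta", "uniform", "fixed"),
                     shape1 = 2, shape2 = 2, min = 0, max = 1, value = 1) {
    dist <- match.arg(dist)
    stopifnot(min >= 0, max <= 1, min <= max, value >= 0, value <= 1)
    structure(list(dist = dist, shape1 = shape1, shape2 = shape2,
                   min = min, max = max, value = value),
              class = "distSpec")
}

drawSpec <- function(spec, n) {
    switch(spec$dist,
           beta = rbeta(n, spec$shape1, spec$shape2),
           uniform = runif(n, spec$min, spec$max),
           fixed = rep(spec$value, n))
}

#' Library layout of a barcoded, UMI-labelled small RNA read
#'
#' Reads are laid out as `[barcode][UMI][insert][3' adapter][filler]`,
#' truncated to `read_length`: the 5' adapter (upstream of the sequencing
#' start) carries a 4-nt sample barcode followed by the random UMI, the
#' insert is the small RNA itself, and sequencing runs through the 3'
#' adapter when the insert is short.
#'
#' @param barcode 4-nt sample barcode (DNA alphabet).
#' @param umi_length UMI length in nt (default 8).
#' @param adapter3 3' adapter sequence as it appears in the read.
#' @param read_length sequenced read length (default 50, single-end).
#' @param rpph_treated logical; when `TRUE` the library emulates 5'
#'   polyphosphatase treatment, so 5'-triphosphate species become ligatable.
#'   When `FALSE` (default) only 5'-monophosphate species enter the library.
#' @param barcode_length expected barcode length.
#' @return A list of class `libraryLayout`.
#' @export
libraryLayout <- function(barcode, umi_length = 8,
                          adapter3 = "AGATCGGAAGAGCACACGTCT",
                          read_length = 50, rpph_treated = FALSE,
                          barcode_length = 4) {
    stopifnot(nchar(barcode) == barcode_length,
              grepl("^[ACGT]+$", barcode), umi_length >= 1,
              nchar(adapter3) >= 1)
    if (read_length < barcode_length + umi_length)
        stop("read_length shorter than barcode + UMI")
    structure(list(barcode = barcode, umi_length = umi_length,
                   adapter3 = adapter3, read_length = read_length,
                   rpph_treated = rpph_treated,
                   barcode_length = barcode_length),
              class = "libraryLayout")
}

#' Simulation configuration
#'
#' Encodes the bias mechanisms the pipeline must undo: per-template ligation
#' preference (adapter/ligation bias), per-template PCR amplification
#' efficiency (preferential amplification), adapter-dimer contamination and
#' uniform sequencing substitution errors.
#'
#' @param seed integer seed owned by the simulation run (`NULL` to inherit
#'   the caller's RNG state).
#' @param pcr_cycles number of PCR cycles (each copy duplicates per cycle
#'   with its template's efficiency probability).
#' @param per_template_efficiency a [distSpec()] over (0, 1\].
#' @param ligation_prob a [distSpec()] over (0, 1\].
#' @param n_reads number of sequenced reads.
#' @param dimer_fraction expected fraction of adapter-dimer reads.
#' @param seq_error_rate per-base substitution probability.
#' @param abundance log-normal molecule-count parameters
#'   (`meanlog`, `sdlog`).
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(seed = NULL, pcr_cycles = 6,
                      per_template_efficiency = distSpec("beta", 8, 4),
                      ligation_prob = distSpec("beta", 8, 2),
                      n_reads = 10000, dimer_fraction = 0.01,
                      seq_error_rate = 0.001,
                      abundance = list(meanlog = 3.5, sdlog = 1.2)) {
    stopifnot(pcr_cycles >= 0, n_reads >= 1,
              dimer_fraction >= 0, dimer_fraction <= 1,
              seq_error_rate >= 0, seq_error_rate <= 1)
    structure(list(seed = seed, pcr_cycles = pcr_cycles,
                   per_template_efficiency = per_template_efficiency,
                   ligation_prob = ligation_prob, n_reads = n_reads,
                   dimer_fraction = dimer_fraction,
                   seq_error_rate = seq_error_rate, abundance = abundance),
              class = "simConfig")
}

# length / first-nucleotide / 5'-phosphate constraints per small RNA class
.CLASS_SPECS <- list(
    miRNA           = list(lengths = c(22, 23), lweights = c(0.75, 0.25),
                           first = c("A", "C", "G", "U"), phos = "monophosphate"),
    p21U            = list(lengths = 21, lweights = 1,
                           first = "U", phos = "monophosphate"),
    primary_siRNA   = list(lengths = 26, lweights = 1,
                           first = "G", phos = "monophosphate"),
    secondary_siRNA = list(lengths = c(21, 22), lweights = c(0.5, 0.5),
                           first = c("A", "C", "G", "U"), phos = "triphosphate"),
    rRNA_fragment   = list(lengths = 20:40, lweights = rep(1, 21),
                           first = c("A", "C", "G", "U"), phos = "monophosphate"),
    other           = list(lengths = 15:30, lweights = rep(1, 16),
                           first = c("A", "C", "G", "U"), phos = "monophosphate"))

.randomRNA <- function(len, first) {
    body <- sample(c("A", "C", "G", "U"), len - 1, replace = TRUE)
    paste0(sample(first, 1), paste(body, collapse = ""))
}

#' Generate a ground-truth small RNA population
#'
#' Draws `n_species` distinct species with class-appropriate lengths, first
#' nucleotides and 5'-phosphate states (miRNA 22-23 nt; 21U-RNA 21 nt with
#' 5' U; primary siRNA 26 nt with 5' G; secondary siRNA 21-22 nt,
#' 5'-triphosphate; rRNA degradation fragments 20-40 nt) and log-normal
#' true molecule counts.
#'
#' @param config a [simConfig()]; its seed (if any) makes the draw
#'   reproducible.
#' @param class_mix named non-negative weights over the classes above.
#' @param n_species number of distinct species (> 0).
#' @param seed overrides `config$seed`.
#' @return A data.frame with columns `seq_id`, `sequence` (RNA alphabet),
#'   `class`, `five_prime_state`, `true_count`.
#' @examples
#' pop <- makePopulation(simConfig(seed = 1), c(miRNA = 1, p21U = 1), 10)
#' table(pop$class)
#' @export
makePopulation <- function(config, class_mix, n_species, seed = config$seed) {
    stopifnot(inherits(config, "simConfig"), n_species > 0,
              all(class_mix >= 0), any(class_mix > 0),
              all(names(class_mix) %in% names(.CLASS_SPECS)))
    if (!is.null(seed)) set.seed(seed)
    classes <- sample(names(class_mix), n_species, replace = TRUE,
                      prob = class_mix)
    seqs <- character(n_species)
    for (i in seq_len(n_species)) {
        spec <- .CLASS_SPECS[[classes[i]]]
        repeat {
            len <- if (length(spec$lengths) == 1) spec$lengths else
                sample(spec$lengths, 1, prob = spec$lweights)
            s <- .randomRNA(len, spec$first)
            if (!s %in% seqs[seq_len(i - 1)]) break
        }
        seqs[i] <- s
    }
    counts <- pmax(1L, as.integer(round(rlnorm(
        n_species, config$abundance$meanlog, config$abundance$sdlog))))
    data.frame(
        seq_id = sprintf("sp%04d", seq_len(n_species)),
        sequence = seqs,
        class = classes,
        five_prime_state = vapply(classes,
                                  function(cl) .CLASS_SPECS[[cl]]$phos, ""),
        true_count = counts,
        row.names = NULL, stringsAsFactors = FALSE)
}

.randomUMIs <- function(n, len) {
    if (n == 0) return(character(0))
    m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

.addSeqErrors <- function(reads, rate) {
    if (rate <= 0 || !length(reads)) return(reads)
    nerr <- rbinom(length(reads), nchar(reads), rate)
    for (i in which(nerr > 0)) {
        chars <- strsplit(reads[i], "")[[1]]
        pos <- sample.int(length(chars), nerr[i])
        for (p in pos)
            chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
        reads[i] <- paste(chars, collapse = "")
    }
    reads
}

#' Simulate a sequenced small RNA library with ground truth
#'
#' Emulates library preparation and sequencing for one barcoded sample:
#' each molecule of a species is 3'/5'-adapter-ligated with a per-species
#' ligation probability (5'-triphosphate species only when the layout is
#' RppH-treated), receives an independent uniform random UMI, is amplified
#' by a Galton-Watson PCR (each copy duplicates per cycle with the
#' template's efficiency probability), and reads are sampled from the
#' amplified pool (without replacement when depth allows, with replacement
#' otherwise). Adapter-dimer reads (no insert) are injected at the
#' configured fraction; uniform substitution errors are applied last.
#'
#' @param population data.frame from [makePopulation()].
#' @param layout a [libraryLayout()].
#' @param config a [simConfig()].
#' @param seed overrides `config$seed`.
#' @param ligation_probs,pcr_efficiencies optional numeric vectors (one per
#'   species) overriding the random per-template draws — useful to share
#'   ligation bias between replicate libraries.
#' @return A list with `reads` (character vector of read sequences),
#'   `truth` (per-species data.frame adding `ligation_prob`,
#'   `pcr_efficiency`, `ligated_count`), `molecules` (data.frame
#'   `seq_id`, `umi` of ligated molecules) and `n_dimer` (dimer reads
#'   injected).
#' @examples
#' pop <- makePopulation(simConfig(seed = 2), c(miRNA = 1), 5)
#' lib <- simulateLibrary(pop, libraryLayout("ACGT"),
#'                        simConfig(seed = 2, n_reads = 200))
#' substr(lib$reads[1:3], 1, 12)
#' @export
simulateLibrary <- function(population, layout, config, seed = config$seed,
                            ligation_probs = NULL, pcr_efficiencies = NULL) {
    stopifnot(inherits(layout, "libraryLayout"),
              inherits(config, "simConfig"), nrow(population) > 0)
    if (!is.null(seed)) set.seed(seed)
    ns <- nrow(population)
    if (is.null(ligation_probs))
        ligation_probs <- drawSpec(config$ligation_prob, ns)
    if (is.null(pcr_efficiencies))
        pcr_efficiencies <- drawSpec(config$per_template_efficiency, ns)
    stopifnot(length(ligation_probs) == ns, length(pcr_efficiencies) == ns)

    # phosphate gate: direct 5' ligation requires a monophosphate end
    gate <- population$five_prime_state == "monophosphate" | layout$rpph_treated
    p_lig <- ifelse(gate, ligation_probs, 0)
    ligated <- rbinom(ns, population$true_count, p_lig)

    species_of <- rep.int(seq_len(ns), ligated)
    n_mol <- length(species_of)
    umis <- .randomUMIs(n_mol, layout$umi_length)

    # Galton-Watson PCR: per cycle every copy duplicates with its template's
    # efficiency; duplicates keep the molecule's UMI
    copies <- rep(1L, n_mol)
    eff <- pcr_efficiencies[species_of]
    for (cyc in seq_len(config$pcr_cycles))
        copies <- copies + rbinom(n_mol, copies, eff)

    n_dimer <- rbinom(1, config$n_reads, config$dimer_fraction)
    n_main <- config$n_reads - n_dimer
    pool <- rep.int(seq_len(n_mol), copies)
    sampled <- if (n_main == 0 || n_mol == 0) integer(0)
               else pool[sample.int(length(pool), n_main,
                                    replace = n_main > length(pool))]

    inserts <- chartr("U", "T", population$sequence)[species_of[sampled]]
    reads <- if (length(sampled))
        paste0(layout$barcode, umis[sampled], inserts, layout$adapter3)
    else character(0)
    dimers <- if (n_dimer > 0)
        paste0(layout$barcode, .randomUMIs(n_dimer, layout$umi_length),
               layout$adapter3) else character(0)
    reads <- c(reads, dimers)
    if (length(reads)) {
        # pad with post-adapter filler and truncate to the sequenced length
        reads <- substr(paste0(reads, strrep("A", layout$read_length)),
                        1, layout$read_length)
        reads <- .addSeqErrors(reads, config$seq_error_rate)
    }

    truth <- population
    truth$ligation_prob <- p_lig
    truth$pcr_efficiency <- pcr_efficiencies
    truth$ligated_count <- ligated
    list(reads = reads, truth = truth,
         molecules = data.frame(seq_id = population$seq_id[species_of],
                                umi = umis, stringsAsFactors = FALSE),
         n_dimer = n_dimer)
}

#' Write reads to a FASTQ file
#'
#' Standard 4-line FASTQ with constant quality `I`; `.gz` paths are
#' compressed.
#'
#' @param reads character vector of read sequences.
#' @param path output path.
#' @param ids read identifiers (default `read1`, `read2`, ...).
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path, ids = sprintf("read%d", seq_along(reads))) {
    x <- DNAStringSet(reads)
    names(x) <- ids
    q <- PhredQuality(BStringSet(strrep("I", nchar(reads))))
    writeXStringSet(QualityScaledDNAStringSet(x, q), path, format = "fastq",
                    compress = grepl("\\.gz$", path))
    invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path (optionally gzipped).
#' @return Named character vector of read sequences.
#' @export
readFastq <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    setNames(as.character(x), names(x))
}

#' Write a simulation truth table as TSV
#'
#' @param truth the `truth` component of [simulateLibrary()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
    write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
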