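#' SPRI binding-efficiency calibration table
#'
#' Binding efficiency (percent of input eluted from the beads) of
#' single-stranded oligonucleotides, indexed by oligo length (nt, rows) and
#' final isopropanol concentration (percent v/v, columns) at a fixed 7.5%
#' PEG. Cells may be missing (`NA`): a missing cell means the condition was
#' not tested, never that binding was zero.
#'
#' @slot efficiency numeric matrix, rows named by oligo length, columns by
#'   isopropanol percent; values in \[0, 100\] or `NA`.
#'
#' @seealso [spriCalibration()] for the packaged calibration,
#'   [readCalibration()] to load one from TSV, [bindingEfficiency()].
#' @export
setClass("SpriCalibration", representation(efficiency = "matrix"))

setValidity("SpriCalibration", function(object) {
    eff <- object@efficiency
    msg <- character()
    if (!is.numeric(eff))
        msg <- c(msg, "efficiency must be a numeric matrix")
    if (is.null(rownames(eff)) || is.null(colnames(eff)))
        msg <- c(msg, "efficiency matrix must have length row names and concentration column names")
    vals <- eff[!is.na(eff)]
    if (length(vals) && (any(vals < 0) || any(vals > 100)))
        msg <- c(msg, "efficiencies must lie in [0, 100]")
    if (anyDuplicated(rownames(eff)) || anyDuplicated(colnames(eff)))
        msg <- c(msg, "duplicated lengths or concentrations")
    concs <- suppressWarnings(as.numeric(colnames(eff)))
    if (anyNA(concs) || is.unsorted(concs, strictly = TRUE))
        msg <- c(msg, "concentration columns must be strictly increasing numerics")
    if (length(msg)) msg else TRUE
})

#' Construct a calibration table
#'
#' @param efficiency numeric matrix of binding efficiencies (percent), rows
#'   named by oligo length in nt, columns by isopropanol percent, `NA` for
#'   untested cells.
#' @return A [SpriCalibration-class] object. Rows whose stored efficiencies
#'   decrease with isopropanol trigger a warning (binding is expected to be
#'   monotone in the crowding agent) but are kept as given.
#' @examples
#' cal <- SpriCalibration(matrix(c(50, 90, 2, 60), 2, byrow = TRUE,
#'                        dimnames = list(c(40, 20), c(35, 40))))
#' bindingEfficiency(cal, 40, 35)
#' @export
SpriCalibration <- function(efficiency) {
    storage.mode(efficiency) <- "double"
    obj <- new("SpriCalibration", efficiency = efficiency)
    for (L in rownames(efficiency)) {
        row <- efficiency[L, ]
        row <- row[!is.na(row)]
        if (length(row) > 1 && is.unsorted(row))
            warning("binding efficiencies for length ", L,
                    " nt are not non-decreasing in isopropanol", call. = FALSE)
    }
    obj
}

#' @describeIn SpriCalibration-class oligo lengths (nt) in the table
#' @param object,x a `SpriCalibration`
#' @export
calibrationLengths <- function(x) as.numeric(rownames(x@efficiency))

#' @describeIn SpriCalibration-class isopropanol concentrations (percent)
#' @export
calibrationConcentrations <- function(x) as.numeric(colnames(x@efficiency))

#' @describeIn SpriCalibration-class the efficiency matrix
#' @export
calibrationMatrix <- function(x) x@efficiency

setMethod("show", "SpriCalibration", function(object) {
    eff <- object@efficiency
    cat("SpriCalibration: ", nrow(eff), " oligo lengths x ", ncol(eff),
        " isopropanol concentrations (", sum(is.na(eff)), " untested cells)\n",
        sep = "")
    print(eff)
})

#' Read a calibration table from TSV
#'
#' Expected layout: header `length<TAB><conc1><TAB><conc2>...`, one row per
#' oligo length, numeric cells or `ND` for untested conditions.
#'
#' @param path path to the TSV file.
#' @return A [SpriCalibration-class] object.
#' @export
readCalibration <- function(path) {
    df <- read.delim(path, check.names = FALSE, colClasses = "character")
    if (names(df)[1] != "length")
        stop("calibration TSV must start with a 'length' column")
    lens <- df[[1]]
    cells <- as.matrix(df[, -1, drop = FALSE])
    cells[toupper(trimws(cells)) == "ND"] <- NA
    eff <- matrix(as.numeric(cells), nrow = nrow(cells),
                  dimnames = list(lens, names(df)[-1]))
    SpriCalibration(eff)
}

#' Packaged ssDNA binding calibration (7.5% PEG, 30-54.5% isopropanol)
#'
#' The calibration shipped with the package: binding efficiencies of ssDNA
#' oligos of 19-66 nt to SPRI beads across nine isopropanol concentrations,
#' measured fluorometrically as percent of input recovered in the eluate.
#'
#' @return A [SpriCalibration-class] object.
#' @examples
#' cal <- spriCalibration()
#' bindingEfficiency(cal, 66, 44)
#' @export
spriCalibration <- function() {
    readCalibration(system.file("extdata", "spri_calibration.tsv",
                                package = "umisrna", mustWork = TRUE))
}

#' Look up (or interpolate) a binding efficiency
#'
#' Exact lookup at tabulated (length, isopropanol) knots; with
#' `interpolate = TRUE`, linear interpolation along the isopropanol axis
#' between the nearest non-missing knots that bracket the requested
#' concentration. No interpolation is ever performed across lengths.
#'
#' @param table a [SpriCalibration-class].
#' @param length oligo length in nt; must be tabulated.
#' @param iso_pct isopropanol concentration (percent).
#' @param interpolate allow linear interpolation between concentrations.
#' @return Efficiency in percent, or `NA` when the condition is untested and
#'   cannot be bracketed by non-missing knots.
#' @examples
#' cal <- spriCalibration()
#' bindingEfficiency(cal, 66, 30)                      # tabulated knot
#' bindingEfficiency(cal, 66, 31, interpolate = TRUE)  # between knots
#' @export
bindingEfficiency <- function(table, length, iso_pct, interpolate = FALSE) {
    stopifnot(is(table, "SpriCalibration"))
    lens <- calibrationLengths(table)
    if (!length %in% lens)
        stop("unknown length ", length, " nt; tabulated lengths: ",
             paste(sort(lens), collapse = ", "))
    concs <- calibrationConcentrations(table)
    row <- table@efficiency[as.character(length), ]
    if (iso_pct %in% concs && (!interpolate || !is.na(row[match(iso_pct, concs)])))
        return(unname(row[match(iso_pct, concs)]))
    if (!interpolate)
        stop("isopropanol ", iso_pct,
             "% is not a tabulated concentration; set interpolate = TRUE")
    if (iso_pct < min(concs) || iso_pct > max(concs))
        stop("isopropanol ", iso_pct, "% outside the tabulated range [",
             min(concs), ", ", max(concs), "]")
    known <- which(!is.na(row))
    lo <- known[concs[known] <= iso_pct]
    hi <- known[concs[known] >= iso_pct]
    if (!length(lo) || !length(hi))
        return(NA_real_)
    i <- lo[which.max(concs[lo])]
    j <- hi[which.min(concs[hi])]
    if (i == j)
        return(unname(row[i]))
    unname(row[i] + (row[j] - row[i]) * (iso_pct - concs[i]) / (concs[j] - concs[i]))
}
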