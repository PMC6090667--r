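#' SPRI binding mix
#'
#' Volumes making up a SPRI binding reaction: sample, 20% PEG bead solution
#' and 100% isopropanol, such that the final concentrations of PEG and
#' isopropanol are the requested percentages of the total volume.
#'
#' @slot sampleVolume,totalVolume,pegVolume,isoVolume volumes in microlitres.
#' @slot pegPct,isoPct final concentrations in percent.
#' @seealso [computeMix()]
#' @export
setClass("SpriMix", representation(
    sampleVolume = "numeric", pegPct = "numeric", isoPct = "numeric",
    totalVolume = "numeric", pegVolume = "numeric", isoVolume = "numeric"))

setValidity("SpriMix", function(object) {
    v <- c(object@sampleVolume, object@totalVolume, object@pegVolume,
           object@isoVolume)
    msg <- character()
    if (any(v < 0)) msg <- c(msg, "volumes must be non-negative")
    resid <- object@sampleVolume + object@pegVolume + object@isoVolume -
        object@totalVolume
    if (abs(resid) > 1e-9 * max(object@totalVolume, 1))
        msg <- c(msg, "component volumes do not sum to the total volume")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SpriMix", function(object) {
    cat(sprintf(
        "SPRI mix for %.6g ul sample at %.4g%% PEG / %.4g%% isopropanol:\n",
        object@sampleVolume, object@pegPct, object@isoPct))
    cat(sprintf("  20%% PEG bead solution: %.6g ul\n", object@pegVolume))
    cat(sprintf("  100%% isopropanol:      %.6g ul\n", object@isoVolume))
    cat(sprintf("  total volume:          %.6g ul\n", object@totalVolume))
})

#' Compute SPRI bead / isopropanol mixing volumes
#'
#' Solves the binding-mix equation `X + 5PV/100 + QV/100 = V` for the total
#' volume `V`, where `X` is the sample volume, `P` the desired final PEG
#' percentage (stock 20%, hence the factor 5) and `Q` the desired final
#' isopropanol percentage (stock 100%). The component volumes are
#' `5PV/100` of PEG solution and `QV/100` of isopropanol.
#'
#' @param sample_volume sample volume X in microlitres (> 0).
#' @param peg_pct desired final PEG concentration P in percent.
#' @param iso_pct desired final isopropanol concentration Q in percent.
#' @return A [SpriMix-class] object.
#' @examples
#' computeMix(50, 7.5, 54.5)   # total volume 625 ul
#' @export
computeMix <- function(sample_volume, peg_pct, iso_pct) {
    stopifnot(is.numeric(sample_volume), length(sample_volume) == 1,
              sample_volume > 0, peg_pct >= 0, iso_pct >= 0)
    denom <- 1 - 5 * peg_pct / 100 - iso_pct / 100
    if (denom <= 0)
        stop(errorCondition(
            sprintf(paste0("infeasible mix: requires 5*P/100 + Q/100 < 1 ",
                           "but P = %g, Q = %g give %g"),
                    peg_pct, iso_pct, 1 - denom),
            class = "umisrna_infeasible_mix"))
    V <- sample_volume / denom
    new("SpriMix", sampleVolume = sample_volume, pegPct = peg_pct,
        isoPct = iso_pct, totalVolume = V,
        pegVolume = 5 * peg_pct * V / 100, isoVolume = iso_pct * V / 100)
}

#' Size-selection plan
#'
#' A single-step SPRI condition separating a kept length from a removed
#' length, with the predicted binding efficiency of each.
#'
#' @slot keepLength,removeLength oligo lengths in nt.
#' @slot concentration chosen isopropanol percent (a tabulated column).
#' @slot keepEfficiency,removeEfficiency predicted efficiencies in percent.
#' @seealso [planSeparation()]
#' @export
setClass("SelectionPlan", representation(
    keepLength = "numeric", removeLength = "numeric",
    concentration = "numeric", keepEfficiency = "numeric",
    removeEfficiency = "numeric"))

setMethod("show", "SelectionPlan", function(object) {
    cat(sprintf(
        paste0("SPRI selection: bind %g-nt at %.4g%% isopropanol ",
               "(keep %.4g%%, carry-over of %g-nt: %.4g%%)\n"),
        object@keepLength, object@concentration, object@keepEfficiency,
        object@removeLength, object@removeEfficiency))
})

#' Plan a one-step SPRI size separation
#'
#' Scans the tabulated isopropanol concentrations in increasing order and
#' returns the first (lowest) one at which the kept length binds with at
#' least `min_keep` percent efficiency while the removed length binds with
#' at most `max_remove` percent. The lowest qualifying concentration is
#' preferred because short-fragment carry-over grows with isopropanol. A
#' concentration qualifies only when both efficiencies are available —
#' directly tabulated, or (with `interpolate = TRUE`) bracketed by
#' non-missing knots; separation is never asserted from untested cells.
#'
#' @param table a [SpriCalibration-class].
#' @param keep_length length (nt) to retain on the beads.
#' @param remove_length shorter length (nt) to leave in the supernatant.
#' @param min_keep minimum acceptable binding of `keep_length` (percent).
#' @param max_remove maximum acceptable binding of `remove_length` (percent).
#' @param interpolate allow interpolated efficiencies at interior untested
#'   cells (the chosen concentration is always a tabulated column).
#' @return A [SelectionPlan-class]; if no tabulated concentration qualifies,
#'   an error of class `umisrna_no_separation` whose `best` field holds the
#'   best trade-off examined (the concentration maximizing
#'   keep - remove efficiency).
#' @examples
#' planSeparation(spriCalibration(), keep_length = 66, remove_length = 44)
#' @export
planSeparation <- function(table, keep_length, remove_length,
                           min_keep = 40, max_remove = 5,
                           interpolate = FALSE) {
    stopifnot(is(table, "SpriCalibration"), keep_length > remove_length,
              min_keep > 0, max_remove > 0)
    lens <- calibrationLengths(table)
    for (L in c(keep_length, remove_length))
        if (!L %in% lens)
            stop("unknown length ", L, " nt; tabulated lengths: ",
                 paste(sort(lens), collapse = ", "))
    concs <- sort(calibrationConcentrations(table))
    best <- NULL
    for (q in concs) {
        ek <- bindingEfficiency(table, keep_length, q, interpolate = interpolate)
        er <- bindingEfficiency(table, remove_length, q, interpolate = interpolate)
        if (is.na(ek) || is.na(er)) next
        if (is.null(best) || (ek - er) > (best$keep - best$remove))
            best <- list(conc = q, keep = ek, remove = er)
        if (ek >= min_keep && er <= max_remove)
            return(new("SelectionPlan", keepLength = keep_length,
                       removeLength = remove_length, concentration = q,
                       keepEfficiency = ek, removeEfficiency = er))
    }
    stop(errorCondition(
        sprintf(paste0("no separating condition for keep %g nt / remove ",
                       "%g nt at min_keep = %g%%, max_remove = %g%%"),
                keep_length, remove_length, min_keep, max_remove),
        class = "umisrna_no_separation", best = best))
}

#' Simulate a two-step SPRI size selection (expectation mode)
#'
#' Deterministic expectations for a double-sided selection: a first bead
#' binding at `step1_iso` captures fraction `e1(L)` of every length `L`
#' (eluted as `elution1`); the supernatant is re-bound at `step2_iso`
#' capturing `e2(L)` of what remains (`elution2`); the rest is discarded.
#' Mass is conserved per length.
#'
#' @param pool named numeric vector: fragment length (nt) -> abundance
#'   (non-negative, arbitrary units).
#' @param table a [SpriCalibration-class].
#' @param step1_iso,step2_iso isopropanol percent for the two bindings.
#' @param interpolate passed to [bindingEfficiency()].
#' @return A list with components `elution1`, `elution2`, `discarded`, each
#'   a pool like `pool`.
#' @examples
#' cal <- spriCalibration()
#' simulateTwoStep(c(`66` = 100, `44` = 100), cal, 32, 54.5,
#'                 interpolate = TRUE)
#' @export
simulateTwoStep <- function(pool, table, step1_iso, step2_iso,
                            interpolate = TRUE) {
    stopifnot(is.numeric(pool), !is.null(names(pool)), all(pool >= 0))
    lens <- as.numeric(names(pool))
    eff <- function(iso) vapply(lens, function(L) {
        e <- bindingEfficiency(table, L, iso, interpolate = interpolate)
        if (is.na(e))
            stop("binding efficiency unavailable for length ", L,
                 " nt at ", iso, "% isopropanol")
        e / 100
    }, numeric(1))
    e1 <- eff(step1_iso)
    e2 <- eff(step2_iso)
    elution1 <- pool * e1
    supernatant <- pool - elution1
    elution2 <- supernatant * e2
    list(elution1 = elution1, elution2 = elution2,
         discarded = supernatant - elution2)
}
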