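#' @import methods
NULL

## ---------------------------------------------------------------------------
## AP-MS side
## ---------------------------------------------------------------------------

#' Spectral-count table
#'
#' Long-format container for AP-MS spectral counts: one record per
#' (protein, purification run) pair. A protein absent from a run is an
#' implicit count of zero (Mascot-style missingness); zeros are not
#' materialized on disk or in the table. The `kind` flag records where the
#' table sits in the pipeline: `"raw"` (integer Mascot counts), `"imputed"`
#' (zeros replaced by positive noise draws, still on the spectral-count
#' scale) or `"normalized"` (divided by the bait count of each run).
#'
#' @slot counts data.frame with columns `protein_id`, `run_id`, `count`.
#' @slot kind one of `"raw"`, `"imputed"`, `"normalized"`.
#'
#' @seealso [readSpectralCounts()], [normalizeByBait()], [imputeZeroCounts()]
#' @export
setClass("SpectralCounts",
    representation(counts = "data.frame", kind = "character"))

.validSpectralCounts <- function(object) {
    msg <- character()
    df <- object@counts
    need <- c("protein_id", "run_id", "count")
    if (!all(need %in% names(df)))
        return(sprintf("counts must have columns %s",
                       paste(need, collapse = ", ")))
    if (length(object@kind) != 1L ||
        !object@kind %in% c("raw", "imputed", "normalized"))
        msg <- c(msg, "kind must be one of 'raw', 'imputed', 'normalized'")
    if (nrow(df)) {
        if (!is.character(df$protein_id) || !is.character(df$run_id))
            msg <- c(msg, "protein_id and run_id must be character")
        if (anyNA(df$protein_id) || anyNA(df$run_id) || anyNA(df$count))
            msg <- c(msg, "missing values are not allowed")
        if (!is.numeric(df$count))
            msg <- c(msg, "count must be numeric")
        else {
            if (any(!is.finite(df$count)))
                msg <- c(msg, "counts must be finite")
            else if (any(df$count < 0))
                msg <- c(msg, "counts must be non-negative")
            if (identical(object@kind, "raw") &&
                any(df$count != round(df$count)))
                msg <- c(msg, "raw tables must contain integer counts only")
        }
        key <- paste(df$protein_id, df$run_id, sep = "\r")
        if (anyDuplicated(key)) {
            dup <- df[duplicated(key), , drop = FALSE][1L, ]
            msg <- c(msg, sprintf(
                "duplicated (protein_id, run_id) pair: (%s, %s)",
                dup$protein_id, dup$run_id))
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("SpectralCounts", .validSpectralCounts)

#' Construct a SpectralCounts object
#'
#' @param counts data.frame with columns `protein_id`, `run_id`, `count`.
#' @param kind `"raw"`, `"imputed"` or `"normalized"`.
#' @return A validated [SpectralCounts-class] object.
#' @examples
#' SpectralCounts(data.frame(protein_id = "POLR3A", run_id = "WT_r1",
#'                           count = 42), kind = "raw")
#' @export
SpectralCounts <- function(counts, kind = c("raw", "imputed", "normalized")) {
    kind <- match.arg(kind)
    counts <- as.data.frame(counts)
    counts$protein_id <- as.character(counts$protein_id)
    counts$run_id <- as.character(counts$run_id)
    counts$count <- as.numeric(counts$count)
    rownames(counts) <- NULL
    new("SpectralCounts", counts = counts[c("protein_id", "run_id", "count")],
        kind = kind)
}

#' Purification run design
#'
#' Metadata for the AP-MS purification runs: condition (`WT`, `MUT:<name>`
#' or `EV` for the empty-vector control), replicate index, and the pairing
#' between each mutant run and the wild-type run acquired alongside it.
#' A WT run and the MUT runs paired with it share the same `pair_id`; the
#' pairing must be a bijection between each mutant variant's runs and the
#' WT runs. EV runs carry no pair.
#'
#' @slot design data.frame with columns `run_id`, `condition`,
#'   `replicate_index`, `pair_id`.
#' @seealso [readRunDesign()]
#' @export
setClass("RunDesign", representation(design = "data.frame"))

.validRunDesign <- function(object) {
    msg <- character()
    df <- object@design
    need <- c("run_id", "condition", "replicate_index", "pair_id")
    if (!all(need %in% names(df)))
        return(sprintf("design must have columns %s",
                       paste(need, collapse = ", ")))
    if (anyDuplicated(df$run_id))
        msg <- c(msg, "run_id values must be unique")
    ok <- grepl("^(WT|EV|MUT:.+)$", df$condition)
    if (!all(ok))
        msg <- c(msg, sprintf("unknown condition token(s): %s",
                              paste(unique(df$condition[!ok]), collapse = ", ")))
    ri <- df$replicate_index
    if (anyNA(ri) || !is.numeric(ri) || any(ri < 1) || any(ri != round(ri)))
        msg <- c(msg, "replicate_index must be an integer >= 1")
    wt <- df[df$condition == "WT", , drop = FALSE]
    if (nrow(wt)) {
        if (anyNA(wt$pair_id) || any(!nzchar(wt$pair_id)))
            msg <- c(msg, "every WT run needs a pair_id")
        else if (anyDuplicated(wt$pair_id))
            msg <- c(msg, "WT pair_id values must be unique")
    }
    isMut <- grepl("^MUT:", df$condition)
    for (v in unique(df$condition[isMut])) {
        mu <- df[df$condition == v, , drop = FALSE]
        if (anyNA(mu$pair_id) || any(!nzchar(mu$pair_id))) {
            msg <- c(msg, sprintf("every %s run needs a pair_id", v))
            next
        }
        if (anyDuplicated(mu$pair_id))
            msg <- c(msg, sprintf(
                "two %s runs are paired to the same WT run", v))
        dangling <- setdiff(mu$pair_id, wt$pair_id)
        if (length(dangling))
            msg <- c(msg, sprintf("%s run paired to nonexistent WT run (%s)",
                                  v, paste(dangling, collapse = ", ")))
        else if (!setequal(mu$pair_id, wt$pair_id))
            msg <- c(msg, sprintf(
                "pairing between %s and WT runs is not a bijection", v))
    }
    if (length(msg)) msg else TRUE
}
setValidity("RunDesign", .validRunDesign)

#' Construct a RunDesign object
#'
#' @param design data.frame with columns `run_id`, `condition`,
#'   `replicate_index`, `pair_id` (`NA` for EV runs).
#' @return A validated [RunDesign-class] object.
#' @export
RunDesign <- function(design) {
    design <- as.data.frame(design)
    design$run_id <- as.character(design$run_id)
    design$condition <- as.character(design$condition)
    design$replicate_index <- as.integer(design$replicate_index)
    design$pair_id <- as.character(design$pair_id)
    rownames(design) <- NULL
    new("RunDesign",
        design = design[c("run_id", "condition", "replicate_index", "pair_id")])
}

#' Scoring configuration for the AP-MS differential analysis
#'
#' Holds every tunable constant of the spectral-count scoring scheme: the
#' bait identity, the >5 empty-vector enrichment threshold of the
#' high-confidence interactor filter, the lowest-20% noise window used to
#' impute zero counts, the replicate-presence requirement, the significance
#' level, the symmetric fold-change gates, the heatmap display cap, the
#' scale of the ratio t-test and the imputation RNG seed.
#'
#' @slot baitId bait protein identifier (default `"POLR1C"`).
#' @slot hciRatioThreshold strict lower bound on the arm/EV mean-count
#'   ratio (default 5).
#' @slot noiseQuantile fraction of the lowest nonzero counts defining the
#'   per-run noise distribution (default 0.20).
#' @slot nRequiredReplicates replicates in which a protein must be
#'   identified (default 3).
#' @slot alpha adjusted-p significance level (default 0.05).
#' @slot fcUpper upper fold-change gate (default 1.5).
#' @slot fcLower lower fold-change gate (default 1/1.5).
#' @slot displayCap floor applied to log2 mean ratios for display
#'   (default -4.5).
#' @slot ratioScale `"raw"` tests mean(MUT/WT) against 1; `"log2"` tests
#'   mean(log2 MUT/WT) against 0.
#' @slot rngSeed seed for the imputation draws.
#' @export
setClass("ScoringConfig",
    representation(baitId = "character", hciRatioThreshold = "numeric",
                   noiseQuantile = "numeric", nRequiredReplicates = "integer",
                   alpha = "numeric", fcUpper = "numeric", fcLower = "numeric",
                   displayCap = "numeric", ratioScale = "character",
                   rngSeed = "integer"))

.validScoringConfig <- function(object) {
    msg <- character()
    if (!length(object@baitId) || !nzchar(object@baitId))
        msg <- c(msg, "baitId must be a nonempty protein id")
    if (object@hciRatioThreshold <= 0)
        msg <- c(msg, "hciRatioThreshold must be > 0")
    if (object@noiseQuantile <= 0 || object@noiseQuantile >= 1)
        msg <- c(msg, "noiseQuantile must lie in (0, 1)")
    if (object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must lie in (0, 1)")
    if (!(object@fcLower > 0 && object@fcLower < 1 && object@fcUpper > 1))
        msg <- c(msg, "need 0 < fcLower < 1 < fcUpper")
    if (object@nRequiredReplicates < 2L)
        msg <- c(msg, "nRequiredReplicates must be >= 2")
    if (!object@ratioScale %in% c("raw", "log2"))
        msg <- c(msg, "ratioScale must be 'raw' or 'log2'")
    if (length(msg)) msg else TRUE
}
setValidity("ScoringConfig", .validScoringConfig)

#' @rdname ScoringConfig-class
#' @param baitId,hciRatioThreshold,noiseQuantile,nRequiredReplicates,alpha
#'   see the class slots.
#' @param fcUpper,fcLower,displayCap,ratioScale,rngSeed see the class slots.
#' @return A validated [ScoringConfig-class] object.
#' @examples
#' scoringConfig(baitId = "POLR1C", ratioScale = "log2")
#' @export
scoringConfig <- function(baitId = "POLR1C", hciRatioThreshold = 5,
                          noiseQuantile = 0.20, nRequiredReplicates = 3L,
                          alpha = 0.05, fcUpper = 1.5, fcLower = 1 / 1.5,
                          displayCap = -4.5, ratioScale = c("raw", "log2"),
                          rngSeed = 1L) {
    ratioScale <- match.arg(ratioScale)
    new("ScoringConfig", baitId = baitId,
        hciRatioThreshold = hciRatioThreshold, noiseQuantile = noiseQuantile,
        nRequiredReplicates = as.integer(nRequiredReplicates), alpha = alpha,
        fcUpper = fcUpper, fcLower = fcLower, displayCap = displayCap,
        ratioScale = ratioScale, rngSeed = as.integer(rngSeed))
}

## ---------------------------------------------------------------------------
## ChIP side
## ---------------------------------------------------------------------------

#' Binned genome coverage signal
#'
#' Per-chromosome coverage aggregated into fixed-width bins; each bin holds
#' the mean per-base read depth within the bin. Values are stored as
#' run-length encodings ([S4Vectors::Rle]) so per-base resolution is cheap.
#'
#' @slot signal named list of `Rle` vectors, one per chromosome.
#' @slot binWidth bin width in base pairs.
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @slot librarySize total number of reads in the library.
#' @slot state `"raw"`, `"rpm"` or `"input-subtracted"`.
#' @seealso [loadSignal()], [normalizeSubtractInput()]
#' @export
setClass("BinnedSignal",
    representation(signal = "list", binWidth = "integer",
                   chromLengths = "numeric", librarySize = "numeric",
                   state = "character"))

.validBinnedSignal <- function(object) {
    msg <- character()
    if (object@binWidth < 1L)
        msg <- c(msg, "binWidth must be >= 1")
    if (!object@state %in% c("raw", "rpm", "input-subtracted"))
        msg <- c(msg, "state must be 'raw', 'rpm' or 'input-subtracted'")
    if (is.null(names(object@signal)) ||
        !setequal(names(object@signal), names(object@chromLengths)))
        msg <- c(msg, "signal and chromLengths must share chromosome names")
    else {
        for (ch in names(object@signal)) {
            x <- object@signal[[ch]]
            if (!is(x, "Rle")) {
                msg <- c(msg, "signal entries must be Rle vectors")
                break
            }
            nbin <- ceiling(object@chromLengths[[ch]] / object@binWidth)
            if (length(x) != nbin)
                msg <- c(msg, sprintf(
                    "%s: expected %d bins, got %d", ch, nbin, length(x)))
            if (length(x) && min(S4Vectors::runValue(x)) < 0)
                msg <- c(msg, sprintf("%s: negative bin values", ch))
        }
    }
    if (object@librarySize < 0)
        msg <- c(msg, "librarySize must be >= 0")
    if (length(msg)) msg else TRUE
}
setValidity("BinnedSignal", .validBinnedSignal)

#' Aggregate profile configuration
#'
#' Window layout for TSS-anchored aggregate profiles: `nWindowsPerSide`
#' windows of `windowWidth` bp on each side of the transcription start
#' site, the only supported reference point.
#'
#' @slot nWindowsPerSide windows on each side of the TSS (default 100).
#' @slot windowWidth window width in bp (default 10).
#' @slot reference reference point, `"TSS"`.
#' @export
setClass("ProfileConfig",
    representation(nWindowsPerSide = "integer", windowWidth = "integer",
                   reference = "character"))

setValidity("ProfileConfig", function(object) {
    msg <- character()
    if (object@nWindowsPerSide < 1L)
        msg <- c(msg, "nWindowsPerSide must be >= 1")
    if (object@windowWidth < 1L)
        msg <- c(msg, "windowWidth must be >= 1")
    if (!identical(object@reference, "TSS"))
        msg <- c(msg, "reference must be 'TSS'")
    if (length(msg)) msg else TRUE
})

#' @rdname ProfileConfig-class
#' @param nWindowsPerSide,windowWidth,reference see the class slots.
#' @return A validated [ProfileConfig-class] object.
#' @export
profileConfig <- function(nWindowsPerSide = 100L, windowWidth = 10L,
                          reference = "TSS") {
    new("ProfileConfig", nWindowsPerSide = as.integer(nWindowsPerSide),
        windowWidth = as.integer(windowWidth), reference = reference)
}

#' TSS-anchored aggregate occupancy profile
#'
#' Mean input-subtracted occupancy over `2 * nWindowsPerSide` windows
#' flanking the TSS, averaged with equal weight across the genes of one
#' promoter class. Window 1 is the most upstream window in gene
#' orientation (minus-strand genes are flipped before averaging).
#'
#' @slot geneClass `"type1"`, `"type2"`, `"type3"` or `"rDNA"`.
#' @slot values numeric vector of per-window mean signal.
#' @slot nGenes number of genes averaged.
#' @slot nWindowsPerSide,windowWidth window layout used.
#' @seealso [aggregateProfile()], [compareOccupancy()]
#' @export
setClass("AggregateProfile",
    representation(geneClass = "character", values = "numeric",
                   nGenes = "integer", nWindowsPerSide = "integer",
                   windowWidth = "integer"))

setValidity("AggregateProfile", function(object) {
    msg <- character()
    if (length(object@values) != 2L * object@nWindowsPerSide)
        msg <- c(msg, "values must have length 2 * nWindowsPerSide")
    if (object@nGenes < 1L)
        msg <- c(msg, "nGenes must be >= 1")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic-data side
## ---------------------------------------------------------------------------

#' Two-polymerase complex model for the AP-MS simulator
#'
#' Describes the protein universe of a FLAG pull-down of a subunit shared
#' between RNA polymerase I and III: Pol I-specific subunits, subunits
#' shared by both enzymes (including the bait), Pol III-specific subunits,
#' and a pool of nonspecific background proteins. Per-protein expected raw
#' spectral counts in a wild-type purification are stored in `abundances`.
#'
#' @slot pol1Specific,shared,pol3Specific character vectors of subunit ids.
#' @slot baitId the tagged bait; must belong to `shared`.
#' @slot nBackground number of nonspecific background proteins.
#' @slot abundances named numeric vector of expected WT spectral counts for
#'   every complex subunit.
#' @slot backgroundMeanlog,backgroundSdlog lognormal parameters for
#'   background protein abundances.
#' @export
setClass("ComplexModel",
    representation(pol1Specific = "character", shared = "character",
                   pol3Specific = "character", baitId = "character",
                   nBackground = "integer", abundances = "numeric",
                   backgroundMeanlog = "numeric", backgroundSdlog = "numeric"))

setValidity("ComplexModel", function(object) {
    msg <- character()
    cats <- list(object@pol1Specific, object@shared, object@pol3Specific)
    all_ids <- unlist(cats)
    if (anyDuplicated(all_ids))
        msg <- c(msg, "subunit category lists must be disjoint")
    if (!object@baitId %in% object@shared)
        msg <- c(msg, "bait must belong to the shared subunits")
    if (!all(all_ids %in% names(object@abundances)))
        msg <- c(msg, "every subunit needs an abundance")
    if (any(object@abundances <= 0))
        msg <- c(msg, "abundances must be > 0")
    if (object@nBackground < 0L)
        msg <- c(msg, "nBackground must be >= 0")
    if (length(msg)) msg else TRUE
})

#' AP-MS simulation scenario
#'
#' Per-category MUT/WT fold effects plus replicate noise and dropout. The
#' leukodystrophy scenario depletes Pol III-specific subunits (fold 0.25)
#' while leaving Pol I-specific and shared subunits untouched; the TCS
#' scenario leaves every category at fold 1.
#'
#' @slot name scenario label.
#' @slot variant mutant name used in the run design (`MUT:<variant>`).
#' @slot foldPol1,foldShared,foldPol3 multiplicative MUT effects per
#'   category.
#' @slot cv lognormal replicate coefficient of variation.
#' @slot dropout probability that a low-abundance protein (expected count
#'   < 5) yields a zero in a run.
#' @seealso [leukodystrophyScenario()], [tcsScenario()]
#' @export
setClass("ApmsScenario",
    representation(name = "character", variant = "character",
                   foldPol1 = "numeric", foldShared = "numeric",
                   foldPol3 = "numeric", cv = "numeric", dropout = "numeric"))

setValidity("ApmsScenario", function(object) {
    msg <- character()
    if (any(c(object@foldPol1, object@foldShared, object@foldPol3) <= 0))
        msg <- c(msg, "fold effects must be > 0")
    if (object@cv < 0)
        msg <- c(msg, "cv must be >= 0")
    if (object@dropout < 0 || object@dropout >= 1)
        msg <- c(msg, "dropout must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})
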