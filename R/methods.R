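#' @rdname accessors
#' @export
setMethod("spectralCounts", "SpectralCounts", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("countKind", "SpectralCounts", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("designTable", "RunDesign", function(x) x@design)

#' @rdname accessors
#' @export
setMethod("binWidth", "BinnedSignal", function(x) x@binWidth)

#' @rdname accessors
#' @export
setMethod("librarySize", "BinnedSignal", function(x) x@librarySize)

#' @rdname accessors
#' @export
setMethod("signalState", "BinnedSignal", function(x) x@state)

#' @rdname accessors
#' @export
setMethod("chromLengths", "BinnedSignal", function(x) x@chromLengths)

#' @rdname accessors
#' @export
setMethod("profileValues", "AggregateProfile", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("geneClass", "AggregateProfile", function(x) x@geneClass)

#' @rdname accessors
#' @export
setMethod("nGenes", "AggregateProfile", function(x) x@nGenes)

setMethod("show", "SpectralCounts", function(object) {
    df <- object@counts
    cat(sprintf("SpectralCounts (%s): %d records, %d proteins, %d runs\n",
                object@kind, nrow(df), length(unique(df$protein_id)),
                length(unique(df$run_id))))
})

setMethod("show", "RunDesign", function(object) {
    df <- object@design
    tab <- table(df$condition)
    cat(sprintf("RunDesign: %d runs (%s)\n", nrow(df),
                paste(sprintf("%s x%d", names(tab), as.integer(tab)),
                      collapse = ", ")))
})

setMethod("show", "ScoringConfig", function(object) {
    cat(sprintf(paste0(
        "ScoringConfig: bait=%s, EV ratio > %g, noise quantile %g,\n",
        "  %d replicates required, alpha=%g, fold gates (%.4g, %.4g),\n",
        "  display cap %g, ratio scale '%s', seed %d\n"),
        object@baitId, object@hciRatioThreshold, object@noiseQuantile,
        object@nRequiredReplicates, object@alpha, object@fcLower,
        object@fcUpper, object@displayCap, object@ratioScale,
        object@rngSeed))
})

setMethod("show", "BinnedSignal", function(object) {
    cat(sprintf(
        "BinnedSignal (%s): %d chromosome(s), bin width %d bp, %g reads\n",
        object@state, length(object@signal), object@binWidth,
        object@librarySize))
})

setMethod("show", "ProfileConfig", function(object) {
    cat(sprintf("ProfileConfig: %d x %d bp windows on each side of the %s\n",
                object@nWindowsPerSide, object@windowWidth,
                object@reference))
})

setMethod("show", "AggregateProfile", function(object) {
    cat(sprintf(
        "AggregateProfile (%s): %d genes, %d windows, mean signal %.4g\n",
        object@geneClass, object@nGenes, length(object@values),
        mean(object@values, na.rm = TRUE)))
})

setMethod("show", "ComplexModel", function(object) {
    cat(sprintf(paste0(
        "ComplexModel: bait %s; %d Pol I-specific, %d shared, ",
        "%d Pol III-specific subunits, %d background proteins\n"),
        object@baitId, length(object@pol1Specific), length(object@shared),
        length(object@pol3Specific), object@nBackground))
})

setMethod("show", "ApmsScenario", function(object) {
    cat(sprintf(paste0(
        "ApmsScenario '%s' (variant %s): folds pol1=%g shared=%g pol3=%g, ",
        "cv=%g, dropout=%g\n"),
        object@name, object@variant, object@foldPol1, object@foldShared,
        object@foldPol3, object@cv, object@dropout))
})
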