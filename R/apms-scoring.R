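## AP-MS statistical core: bait normalization, zero-count noise imputation,
## high-confidence interactor filtering, paired differential ratio tests,
## multiple-testing adjustment and significance classification.

#' Normalize spectral counts by the bait
#'
#' Divides every count by its run's bait spectral count so that
#' purifications of different efficiency become comparable; the bait's
#' normalized count is exactly 1 in every run. The bait must have a
#' strictly positive count in every run of the table (after imputation
#' this always holds).
#'
#' @param x a [SpectralCounts-class] object (raw or imputed).
#' @param baitId bait protein id.
#' @return A [SpectralCounts-class] object with `kind = "normalized"`.
#' @examples
#' x <- SpectralCounts(data.frame(protein_id = c("POLR1C", "POLR3A"),
#'                                run_id = "WT_r1", count = c(50, 25)))
#' spectralCounts(normalizeByBait(x, "POLR1C"))
#' @export
normalizeByBait <- function(x, baitId = "POLR1C") {
    stopifnot(is(x, "SpectralCounts"))
    df <- x@counts
    runs <- sort(unique(df$run_id))
    isBait <- df$protein_id == baitId
    bait <- df$count[isBait][match(runs, df$run_id[isBait])]
    bad <- is.na(bait) | bait <= 0
    if (any(bad))
        stop("normalization error: bait '", baitId,
             "' absent or zero in run(s): ",
             paste(runs[bad], collapse = ", "), call. = FALSE)
    df$count <- df$count / bait[match(df$run_id, runs)]
    SpectralCounts(df, kind = "normalized")
}

#' Impute zero spectral counts from the per-run noise floor
#'
#' Emulates the background noise of an LC-MS/MS analysis: within each run,
#' the lowest `noiseQuantile` fraction of the nonzero spectral counts
#' defines a noise distribution, and every zero count (explicit or
#' implicit, for each protein of the analysis universe) is replaced by an
#' independent draw from Normal(mean, sd) of that window, truncated below
#' at `max(0.01, mean - 3 sd)` so all imputed counts are positive. Nonzero
#' counts are untouched and the result is reproducible given the seed.
#'
#' The noise window uses the lowest `max(2, ceiling(q * m))` of the `m`
#' nonzero counts so its standard deviation is always defined; runs with
#' fewer than 2 nonzero counts are rejected.
#'
#' @param x a [SpectralCounts-class] object with `kind = "raw"`.
#' @param config a [ScoringConfig-class]; supplies `noiseQuantile` and the
#'   default seed.
#' @param proteins analysis universe: proteins whose zeros are imputed.
#'   Defaults to every protein observed (count > 0) anywhere in `x`.
#' @param seed RNG seed (defaults to `config@rngSeed`).
#' @return A [SpectralCounts-class] object with `kind = "imputed"` covering
#'   every (universe protein, run) pair.
#' @export
imputeZeroCounts <- function(x, config = scoringConfig(), proteins = NULL,
                             seed = NULL) {
    stopifnot(is(x, "SpectralCounts"), is(config, "ScoringConfig"))
    seed <- seed %||% config@rngSeed
    df <- x@counts
    runs <- sort(unique(df$run_id))
    universe <- sort(unique(
        proteins %||% unique(df$protein_id[df$count > 0])))
    q <- config@noiseQuantile
    withSeed(seed, {
        pieces <- vector("list", length(runs))
        for (i in seq_along(runs)) {
            r <- runs[i]
            sub <- df[df$run_id == r, , drop = FALSE]
            nz <- sub$count[sub$count > 0]
            if (length(nz) < 2L)
                stop("imputation error: run '", r,
                     "' has fewer than 2 nonzero counts", call. = FALSE)
            k <- max(2L, ceiling(q * length(nz)))
            s <- sort(nz)[seq_len(k)]
            mu <- mean(s)
            sdev <- stats::sd(s)
            cur <- countMatrix(x, universe, r)[, 1L]
            zero <- cur == 0
            if (any(zero)) {
                draws <- stats::rnorm(sum(zero), mean = mu, sd = sdev)
                floorVal <- max(0.01, mu - 3 * sdev)
                cur[zero] <- pmax(draws, floorVal)
            }
            extra <- sub[!sub$protein_id %in% universe, , drop = FALSE]
            pieces[[i]] <- rbind(
                data.frame(protein_id = universe, run_id = r, count = cur,
                           stringsAsFactors = FALSE),
                extra)
        }
        out <- do.call(rbind, pieces)
        rownames(out) <- NULL
        SpectralCounts(out, kind = "imputed")
    })
}

#' Flag high-confidence interactors against the empty-vector control
#'
#' A protein is a high-confidence interactor of the bait if it was
#' identified (raw count > 0) in all replicates of the WT arm or in all
#' replicates of the mutant arm, AND that arm's mean imputed spectral
#' count exceeds `hciRatioThreshold` times the mean imputed count in the
#' empty-vector (EV) purifications -- strictly (a ratio of exactly 5 is
#' excluded). Presence is judged on pre-imputation raw counts: an imputed
#' zero is not an identification. The enrichment ratio is computed on the
#' spectral-count scale (EV runs contain no bait, so bait-normalized EV
#' counts would not be commensurable with the bait arms).
#'
#' @param raw raw [SpectralCounts-class] table (pre-imputation).
#' @param imputed imputed [SpectralCounts-class] table on the
#'   spectral-count scale (see [imputeZeroCounts()]).
#' @param design a [RunDesign-class] object.
#' @param variant mutant name (the design's `MUT:<variant>` token).
#' @param config a [ScoringConfig-class] object.
#' @return data.frame with one row per universe protein: per-condition
#'   mean imputed counts, EV ratios, `high_confidence` flag and `basis`
#'   (`"WT"`, `"MUT"` or `"both"`; `NA` when not flagged).
#' @export
flagHighConfidence <- function(raw, imputed, design, variant,
                               config = scoringConfig()) {
    stopifnot(is(raw, "SpectralCounts"), is(imputed, "SpectralCounts"),
              is(design, "RunDesign"))
    dd <- design@design
    wtRuns <- dd$run_id[dd$condition == "WT"]
    mutRuns <- dd$run_id[dd$condition == paste0("MUT:", variant)]
    evRuns <- dd$run_id[dd$condition == "EV"]
    nreq <- config@nRequiredReplicates
    if (length(evRuns) < nreq)
        stop("design error: need at least ", nreq, " EV runs, found ",
             length(evRuns), call. = FALSE)
    if (length(wtRuns) < nreq || length(mutRuns) < nreq)
        stop("design error: need at least ", nreq,
             " WT and MUT:", variant, " runs", call. = FALSE)
    universe <- sort(unique(imputed@counts$protein_id))
    rawWT <- countMatrix(raw, universe, wtRuns)
    rawMUT <- countMatrix(raw, universe, mutRuns)
    impWT <- countMatrix(imputed, universe, wtRuns)
    impMUT <- countMatrix(imputed, universe, mutRuns)
    impEV <- countMatrix(imputed, universe, evRuns)
    presWT <- rowSums(rawWT > 0) == length(wtRuns)
    presMUT <- rowSums(rawMUT > 0) == length(mutRuns)
    meanWT <- rowMeans(impWT)
    meanMUT <- rowMeans(impMUT)
    meanEV <- rowMeans(impEV)
    ratioWT <- ifelse(meanEV > 0, meanWT / meanEV, Inf)
    ratioMUT <- ifelse(meanEV > 0, meanMUT / meanEV, Inf)
    thr <- config@hciRatioThreshold
    okWT <- presWT & ratioWT > thr
    okMUT <- presMUT & ratioMUT > thr
    basis <- rep(NA_character_, length(universe))
    basis[okWT] <- "WT"
    basis[okMUT] <- "MUT"
    basis[okWT & okMUT] <- "both"
    data.frame(protein_id = universe, mean_wt = meanWT, mean_mut = meanMUT,
               mean_ev = meanEV, ratio_wt_ev = ratioWT,
               ratio_mut_ev = ratioMUT, high_confidence = okWT | okMUT,
               basis = basis, row.names = NULL, stringsAsFactors = FALSE)
}

# Two-tailed one-sample t-test of `y` against `null`; zero-variance series
# at the null give p = 1 (no evidence), off the null p = 0.
.oneSampleT <- function(y, null) {
    n <- length(y)
    s <- stats::sd(y)
    m <- mean(y)
    if (s == 0) {
        if (m == null) return(c(t = 0, p = 1))
        return(c(t = sign(m - null) * Inf, p = 0))
    }
    tt <- (m - null) / (s / sqrt(n))
    c(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1))
}

#' Paired differential interaction test
#'
#' For each protein, forms the per-pair spectral-count ratios
#' MUT/WT on the bait-normalized, imputed scale and performs a two-tailed
#' one-sample t-test: on the raw ratio scale the mean ratio is tested
#' against 1; on the log2 scale the mean log2 ratio is tested against 0.
#' The reported fold change `mean_ratio` is always the arithmetic mean of
#' the per-pair ratios. Degrees of freedom are `n_pairs - 1`.
#'
#' @param normalized bait-normalized imputed [SpectralCounts-class] table.
#' @param design a [RunDesign-class] object.
#' @param variant mutant name.
#' @param proteins proteins to test (normally the high-confidence set).
#' @param config a [ScoringConfig-class]; `ratioScale` selects the test
#'   scale.
#' @return data.frame with per-pair ratio columns (`ratio_<pair_id>`),
#'   `mean_ratio`, `log2_mean_ratio`, `t_statistic`, `df`, `p_raw` and an
#'   unset `p_adjusted`.
#' @export
differentialInteractionTest <- function(normalized, design, variant, proteins,
                                        config = scoringConfig()) {
    stopifnot(is(normalized, "SpectralCounts"), is(design, "RunDesign"))
    dd <- design@design
    wt <- dd[dd$condition == "WT", , drop = FALSE]
    mu <- dd[dd$condition == paste0("MUT:", variant), , drop = FALSE]
    pairs <- sort(intersect(wt$pair_id, mu$pair_id))
    if (length(pairs) < 2L)
        stop("test error: fewer than 2 MUT/WT pairs for variant ", variant,
             call. = FALSE)
    wtRun <- wt$run_id[match(pairs, wt$pair_id)]
    muRun <- mu$run_id[match(pairs, mu$pair_id)]
    proteins <- sort(unique(proteins))
    W <- countMatrix(normalized, proteins, wtRun)
    M <- countMatrix(normalized, proteins, muRun)
    if (any(W <= 0))
        stop("test error: nonpositive WT denominator; impute before testing",
             call. = FALSE)
    R <- M / W
    scale2 <- identical(config@ratioScale, "log2")
    stats_ <- t(vapply(seq_len(nrow(R)), function(i) {
        if (scale2) .oneSampleT(log2(R[i, ]), 0) else .oneSampleT(R[i, ], 1)
    }, c(t = 0, p = 0)))
    meanRatio <- rowMeans(R)
    out <- data.frame(protein_id = proteins, stringsAsFactors = FALSE)
    for (j in seq_along(pairs))
        out[[paste0("ratio_", pairs[j])]] <- R[, j]
    out$mean_ratio <- meanRatio
    out$log2_mean_ratio <- log2(meanRatio)
    out$t_statistic <- stats_[, "t"]
    out$df <- length(pairs) - 1L
    out$p_raw <- stats_[, "p"]
    out$p_adjusted <- NA_real_
    out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment: p-values are ranked, scaled by
#' n/rank, made monotone from the largest down and capped at 1; the output
#' keeps the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, elementwise >= the input.
#' @examples
#' adjustBH(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjustBH <- function(p) {
    if (!is.numeric(p))
        stop("validation error: p-values must be numeric", call. = FALSE)
    if (length(p) == 0L) return(numeric())
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("validation error: p-values must lie in [0, 1]", call. = FALSE)
    stats::p.adjust(p, method = "BH")
}

#' Classify differential interactions
#'
#' Applies the dual significance criterion: a protein interacts
#' differentially when its adjusted p-value is below `alpha` AND its mean
#' MUT/WT fold change falls outside the (`fcLower`, `fcUpper`) band --
#' `decreased` below, `increased` above; everything else tested is
#' `not_significant`.
#'
#' @param results data.frame from [differentialInteractionTest()] with
#'   `p_adjusted` filled in.
#' @param config a [ScoringConfig-class] object.
#' @return The data.frame with a `label` column added.
#' @export
classifyInteractions <- function(results, config = scoringConfig()) {
    if (anyNA(results$p_adjusted))
        stop("p_adjusted must be set for every result", call. = FALSE)
    sig <- results$p_adjusted < config@alpha
    lab <- rep("not_significant", nrow(results))
    lab[sig & results$mean_ratio < config@fcLower] <- "decreased"
    lab[sig & results$mean_ratio > config@fcUpper] <- "increased"
    results$label <- lab
    results
}

#' Build display tables (heatmap matrix and volcano tables)
#'
#' Assembles a protein x variant matrix of log2 mean MUT/WT ratios, with
#' values below `displayCap` replaced by the cap, plus one volcano table
#' per variant (capped log2 mean ratio, -log10 adjusted p, label, and a
#' `significant` colour flag).
#'
#' @param resultsList named list (variant -> classified results data.frame).
#' @param config a [ScoringConfig-class] object.
#' @return list with elements `heatmap` (data.frame, proteins x variants)
#'   and `volcano` (named list of data.frames).
#' @export
buildDisplayMatrix <- function(resultsList, config = scoringConfig()) {
    stopifnot(is.list(resultsList), !is.null(names(resultsList)))
    cap <- config@displayCap
    tested <- lapply(resultsList, function(r)
        r[r$label != "not_tested", , drop = FALSE])
    proteins <- sort(unique(unlist(lapply(tested, `[[`, "protein_id"))))
    hm <- matrix(NA_real_, nrow = length(proteins),
                 ncol = length(resultsList),
                 dimnames = list(proteins, names(resultsList)))
    volcano <- list()
    for (v in names(resultsList)) {
        r <- tested[[v]]
        if (any(r$mean_ratio <= 0))
            stop("internal error: nonpositive mean ratio; counts must be ",
                 "imputed before testing", call. = FALSE)
        l2 <- pmax(log2(r$mean_ratio), cap)
        hm[match(r$protein_id, proteins), v] <- l2
        volcano[[v]] <- data.frame(
            protein_id = r$protein_id, log2_mean_ratio = l2,
            neg_log10_p_adjusted = -log10(r$p_adjusted), label = r$label,
            significant = r$label %in% c("decreased", "increased"),
            stringsAsFactors = FALSE)
    }
    list(heatmap = data.frame(protein_id = proteins, hm,
                              row.names = NULL, check.names = FALSE,
                              stringsAsFactors = FALSE),
         volcano = volcano)
}

#' Run the full AP-MS differential pipeline for one mutant
#'
#' Sequences the scoring stages for one `MUT:<variant>` vs WT comparison:
#' restrict to the WT/MUT/EV trio, define the analysis universe (proteins
#' observed in at least one of those runs), impute zeros per run, normalize
#' by the bait, filter high-confidence interactors, run the paired ratio
#' t-tests, adjust with Benjamini-Hochberg within this comparison's
#' high-confidence family, and classify. Proteins outside the
#' high-confidence set carry the label `not_tested`.
#'
#' @param raw raw [SpectralCounts-class] table (already cleaned of
#'   contaminants/isoforms).
#' @param design a [RunDesign-class] object.
#' @param variant mutant name.
#' @param config a [ScoringConfig-class] object.
#' @return list with `interactors` (the [flagHighConfidence()] table) and
#'   `results` (classified differential results for the whole universe).
#' @export
apmsDifferential <- function(raw, design, variant, config = scoringConfig()) {
    dd <- design@design
    keepRuns <- dd$run_id[dd$condition %in%
                          c("WT", "EV", paste0("MUT:", variant))]
    df <- raw@counts[raw@counts$run_id %in% keepRuns, , drop = FALSE]
    sub <- SpectralCounts(df, kind = raw@kind)
    universe <- sort(unique(df$protein_id[df$count > 0]))
    imputed <- imputeZeroCounts(sub, config, proteins = universe)
    normalized <- normalizeByBait(imputed, config@baitId)
    hci <- flagHighConfidence(sub, imputed, design, variant, config)
    testSet <- hci$protein_id[hci$high_confidence]
    if (length(testSet)) {
        res <- differentialInteractionTest(normalized, design, variant,
                                           testSet, config)
        res$p_adjusted <- adjustBH(res$p_raw)
        res <- classifyInteractions(res, config)
        res$basis <- hci$basis[match(res$protein_id, hci$protein_id)]
    } else {
        res <- NULL
    }
    rest <- setdiff(universe, testSet)
    if (length(rest)) {
        pad <- data.frame(protein_id = rest, stringsAsFactors = FALSE)
        if (!is.null(res)) {
            for (cn in setdiff(names(res), c("protein_id", "label")))
                pad[[cn]] <- if (is.character(res[[cn]]))
                    NA_character_ else NA_real_
        } else {
            pad$mean_ratio <- NA_real_
            pad$p_adjusted <- NA_real_
            pad$basis <- NA_character_
        }
        pad$label <- "not_tested"
        res <- if (is.null(res)) pad else rbind(res, pad[names(res)])
    }
    res <- res[order(res$protein_id), , drop = FALSE]
    rownames(res) <- NULL
    list(interactors = hci, results = res)
}
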