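## Synthetic-data generators: AP-MS spectral-count tables for a bait shared
## between two polymerase complexes, and ChIP/input read sets over Pol III
## gene classes plus an rDNA control contig. Both are deterministic given
## their seed and emit exactly the dialects the readers consume.

#' Construct a two-polymerase complex model
#'
#' Defaults mirror the human Pol I / Pol III subunit organization around
#' the shared POLR1C bait: six Pol I-specific subunits, seven shared
#' subunits, and the Pol III-specific set (named POLR3A-POLR3K style; the
#' category, not the identity, carries the statistics). Expected wild-type
#' spectral counts default to 60 per complex subunit and 120 for the bait,
#' values chosen for statistical power at three replicates; background
#' protein abundances are drawn per dataset from a lognormal.
#'
#' @param pol1Specific,shared,pol3Specific subunit id vectors.
#' @param baitId the tagged subunit (must be in `shared`).
#' @param nBackground number of nonspecific background proteins.
#' @param baseAbundance expected WT spectral count per complex subunit;
#'   scalar, or a named vector of per-subunit overrides on top of the
#'   scalar default.
#' @param baitAbundance expected bait spectral count.
#' @param backgroundMeanlog,backgroundSdlog lognormal parameters for
#'   background abundances.
#' @return A validated [ComplexModel-class] object.
#' @export
complexModel <- function(
        pol1Specific = c("POLR1A", "POLR1B", "POLR1E", "CD3EAP", "TWISTNB",
                         "ZNRD1"),
        shared = c("POLR2E", "POLR2F", "POLR2H", "POLR2K", "POLR2L",
                   "POLR1C", "POLR1D"),
        pol3Specific = c("POLR3A", "POLR3B", "POLR3C", "POLR3D", "POLR3E",
                         "POLR3F", "POLR3G", "POLR3GL", "POLR3H", "POLR3K"),
        baitId = "POLR1C", nBackground = 50L, baseAbundance = 60,
        baitAbundance = 120, backgroundMeanlog = log(4),
        backgroundSdlog = 1) {
    subs <- c(pol1Specific, shared, pol3Specific)
    ab <- stats::setNames(rep(baseAbundance[[1L]], length(subs)), subs)
    if (!is.null(names(baseAbundance)))
        ab[names(baseAbundance)] <- baseAbundance
    ab[baitId] <- baitAbundance
    new("ComplexModel", pol1Specific = pol1Specific, shared = shared,
        pol3Specific = pol3Specific, baitId = baitId,
        nBackground = as.integer(nBackground), abundances = ab,
        backgroundMeanlog = backgroundMeanlog,
        backgroundSdlog = backgroundSdlog)
}

#' @rdname ApmsScenario-class
#' @param name,variant,foldPol1,foldShared,foldPol3,cv,dropout see the
#'   class slots.
#' @return A validated [ApmsScenario-class] object.
#' @export
apmsScenario <- function(name, variant, foldPol1 = 1, foldShared = 1,
                         foldPol3 = 1, cv = 0.10, dropout = 0.2) {
    new("ApmsScenario", name = name, variant = variant,
        foldPol1 = foldPol1, foldShared = foldShared, foldPol3 = foldPol3,
        cv = cv, dropout = dropout)
}

#' @rdname ApmsScenario-class
#' @details `leukodystrophyScenario()` models an assembly-defective mutant:
#' Pol III-specific subunits are pulled down at a quarter of the wild-type
#' level while Pol I-specific and shared subunits are unaffected.
#' `tcsScenario()` models an assembly-neutral mutant: every fold is 1.
#' @export
leukodystrophyScenario <- function(variant = "N32I", cv = 0.10,
                                   dropout = 0.2) {
    apmsScenario("leukodystrophy", variant, foldPol1 = 1, foldShared = 1,
                 foldPol3 = 0.25, cv = cv, dropout = dropout)
}

#' @rdname ApmsScenario-class
#' @export
tcsScenario <- function(variant = "R279Q", cv = 0.10, dropout = 0.2) {
    apmsScenario("tcs", variant, foldPol1 = 1, foldShared = 1,
                 foldPol3 = 1, cv = cv, dropout = dropout)
}

.categoryFold <- function(model, scenario) {
    f <- stats::setNames(rep(1, length(model@abundances)),
                         names(model@abundances))
    f[model@pol1Specific] <- scenario@foldPol1
    f[model@shared] <- scenario@foldShared
    f[model@pol3Specific] <- scenario@foldPol3
    f[model@baitId] <- 1          # bait expression is fold-unaffected
    f
}

#' Simulate an AP-MS spectral-count dataset
#'
#' Draws raw spectral counts for `nReplicates` runs each of WT, one mutant
#' and the empty-vector control, with correct MUT/WT pairing. Counts are
#' Poisson with mean = base abundance x category fold (mutant runs only)
#' x a lognormal replicate factor with the scenario CV (a Poisson-lognormal
#' over-dispersed count model). EV runs contain only background proteins;
#' background proteins bind nonspecifically in every condition at the same
#' abundance. Proteins with expected count below 5 drop out (count 0) with
#' probability `dropout`, mimicking identification missingness at the MS
#' noise floor. Zero counts are implicit (absent rows). Deterministic
#' given `seed`.
#'
#' @param model a [ComplexModel-class] object.
#' @param scenario an [ApmsScenario-class] object.
#' @param nReplicates replicates per condition (>= 2; default 3).
#' @param seed RNG seed.
#' @return list with `counts` (raw [SpectralCounts-class]) and `design`
#'   (a [RunDesign-class]).
#' @examples
#' sim <- simulateApmsDataset(complexModel(), leukodystrophyScenario(),
#'                            seed = 7)
#' sim$design
#' @export
simulateApmsDataset <- function(model, scenario, nReplicates = 3L,
                                seed = 1L) {
    stopifnot(is(model, "ComplexModel"), is(scenario, "ApmsScenario"),
              nReplicates >= 2L)
    nR <- as.integer(nReplicates)
    v <- scenario@variant
    runs <- data.frame(
        run_id = c(sprintf("WT_r%d", seq_len(nR)),
                   sprintf("MUT_%s_r%d", v, seq_len(nR)),
                   sprintf("EV_r%d", seq_len(nR))),
        condition = rep(c("WT", paste0("MUT:", v), "EV"), each = nR),
        replicate_index = rep(seq_len(nR), 3L),
        pair_id = c(sprintf("p%d", seq_len(nR)), sprintf("p%d", seq_len(nR)),
                    rep(NA_character_, nR)),
        stringsAsFactors = FALSE)
    fold <- .categoryFold(model, scenario)
    cv <- scenario@cv
    sdlog <- sqrt(log1p(cv^2))
    meanlog <- -sdlog^2 / 2                 # unit-mean replicate factor
    withSeed(seed, {
        bg <- if (model@nBackground > 0L)
            stats::setNames(
                stats::rlnorm(model@nBackground, model@backgroundMeanlog,
                              model@backgroundSdlog),
                sprintf("BKG%03d", seq_len(model@nBackground)))
        else numeric()
        pieces <- vector("list", nrow(runs))
        for (i in seq_len(nrow(runs))) {
            cond <- runs$condition[i]
            if (cond == "EV") {
                ab <- bg
            } else {
                subAb <- model@abundances
                if (startsWith(cond, "MUT:"))
                    subAb <- subAb * fold[names(subAb)]
                ab <- c(subAb, bg)
            }
            if (!length(ab)) next
            lam <- ab * if (cv > 0)
                stats::rlnorm(length(ab), meanlog, sdlog) else 1
            counts <- stats::rpois(length(ab), lam)
            low <- ab < 5
            if (any(low) && scenario@dropout > 0) {
                drop <- low &
                    stats::runif(length(ab)) < scenario@dropout
                counts[drop] <- 0L
            }
            keep <- counts > 0
            if (any(keep))
                pieces[[i]] <- data.frame(
                    protein_id = names(ab)[keep], run_id = runs$run_id[i],
                    count = as.numeric(counts[keep]),
                    stringsAsFactors = FALSE)
        }
        tab <- do.call(rbind, pieces)
        rownames(tab) <- NULL
        list(counts = SpectralCounts(tab, kind = "raw"),
             design = RunDesign(runs))
    })
}

#' Simulate a ChIP/input read dataset over Pol III gene classes
#'
#' Places genes of the three Pol III promoter classes non-overlapping (with
#' at least 1 kb flanks) on a main contig and one rDNA gene on a dedicated
#' rDNA contig, then generates three read libraries as BED files: ChIP of
#' the wild-type bait, ChIP of the mutant, and input chromatin. Each ChIP
#' library is uniform Poisson background plus per-gene enrichment: read
#' count ~ Poisson(class depth x mutant fold), read centres ~
#' Normal(TSS, `peakSd`). The mutant fold is forced to 1 at rDNA (the
#' Pol I control locus). The input library is background only, at the same
#' background rate as the ChIP libraries. Deterministic given `seed`.
#'
#' @param dir output directory (created if needed).
#' @param occupancy named vector: expected WT ChIP reads per gene for
#'   `type1`, `type2`, `type3`, `rDNA`.
#' @param foldMut named vector of MUT/WT occupancy folds per class
#'   (`rDNA` is forced to 1).
#' @param nGenes named vector: genes per Pol III class on the main contig.
#' @param chromLength,rdnaLength contig lengths (bp).
#' @param readLength read length (bp).
#' @param backgroundRate background reads per bp (ChIP and input).
#' @param peakSd s.d. (bp) of read centres around the TSS.
#' @param seed RNG seed.
#' @return list with file paths (`chip_wt`, `chip_mut`, `input`,
#'   `annotations`, `chrom_sizes`), the annotation data.frame and the
#'   chromosome sizes vector.
#' @export
simulateChipDataset <- function(dir,
        occupancy = c(type1 = 600, type2 = 400, type3 = 500, rDNA = 8000),
        foldMut = c(type1 = 0.4, type2 = 0.4, type3 = 0.4, rDNA = 1),
        nGenes = c(type1 = 20L, type2 = 40L, type3 = 15L),
        chromLength = 400000L, rdnaLength = 43000L, readLength = 50L,
        backgroundRate = 0.03, peakSd = 200, seed = 1L) {
    stopifnot(all(c("type1", "type2", "type3", "rDNA") %in% names(occupancy)),
              all(nGenes >= 1L), all(occupancy > 0), all(foldMut > 0))
    foldMut["rDNA"] <- 1
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    nTot <- sum(nGenes)
    margin <- 2000L                       # 1 kb flank + peak tails
    spacing <- (chromLength - 2L * margin) %/% nTot
    if (spacing < 2000L)
        stop("placement error: cannot place ", nTot, " genes with 1 kb ",
             "flanks on a ", chromLength, " bp contig", call. = FALSE)
    withSeed(seed, {
        classes <- sample(rep(names(nGenes), times = nGenes))
        jitter <- floor(stats::runif(nTot, 0, max(1, spacing - 2000L)))
        anno <- data.frame(
            gene_id = sprintf("G%03d", seq_len(nTot)),
            chrom = "chrS",
            tss = margin + (seq_len(nTot) - 1L) * spacing + jitter,
            strand = sample(c("+", "-"), nTot, replace = TRUE),
            gene_class = classes, stringsAsFactors = FALSE)
        anno <- rbind(anno, data.frame(
            gene_id = "RDNA1", chrom = "rDNA",
            tss = as.integer(rdnaLength %/% 2), strand = "+",
            gene_class = "rDNA", stringsAsFactors = FALSE))
        chromSizes <- c(chrS = as.numeric(chromLength),
                        rDNA = as.numeric(rdnaLength))
        rl <- as.integer(readLength)

        bgReads <- function() {
            do.call(rbind, lapply(names(chromSizes), function(ch) {
                len <- chromSizes[[ch]]
                nb <- stats::rpois(1L, backgroundRate * len)
                if (!nb) return(NULL)
                start <- floor(stats::runif(nb, 0, len - rl))
                data.frame(chrom = ch, start = start, stringsAsFactors = FALSE)
            }))
        }
        peakReads <- function(fold) {
            do.call(rbind, lapply(seq_len(nrow(anno)), function(i) {
                cls <- anno$gene_class[i]
                lam <- occupancy[[cls]] * fold[[cls]]
                ne <- stats::rpois(1L, lam)
                if (!ne) return(NULL)
                len <- chromSizes[[anno$chrom[i]]]
                centre <- round(stats::rnorm(ne, anno$tss[i], peakSd))
                start <- pmin(pmax(centre - rl %/% 2L, 0), len - rl)
                data.frame(chrom = anno$chrom[i], start = start,
                           stringsAsFactors = FALSE)
            }))
        }
        writeBed <- function(reads, path) {
            reads <- reads[order(reads$chrom, reads$start), , drop = FALSE]
            n <- nrow(reads)
            bed <- data.frame(
                chrom = reads$chrom, start = as.integer(reads$start),
                end = as.integer(reads$start) + rl,
                name = sprintf("read%07d", seq_len(n)), score = 0L,
                strand = sample(c("+", "-"), n, replace = TRUE),
                stringsAsFactors = FALSE)
            tmp <- tempfile(tmpdir = dirname(path))
            utils::write.table(bed, tmp, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE)
            file.rename(tmp, path)
            path
        }

        unitFold <- stats::setNames(rep(1, length(foldMut)), names(foldMut))
        paths <- list(
            chip_wt = writeBed(rbind(bgReads(), peakReads(unitFold)),
                               file.path(dir, "chip_WT.bed")),
            chip_mut = writeBed(rbind(bgReads(), peakReads(foldMut)),
                                file.path(dir, "chip_MUT.bed")),
            input = writeBed(bgReads(), file.path(dir, "input.bed")))
        annoPath <- file.path(dir, "annotations.tsv")
        writeTsv(anno, annoPath, full = TRUE)
        csPath <- file.path(dir, "chrom_sizes.tsv")
        tmp <- tempfile(tmpdir = dir)
        utils::write.table(
            data.frame(names(chromSizes),
                       format(chromSizes, scientific = FALSE, trim = TRUE)),
            tmp, sep = "\t", quote = FALSE, row.names = FALSE,
            col.names = FALSE)
        file.rename(tmp, csPath)
        c(paths, list(annotations = annoPath, chrom_sizes = csPath,
                      annotation_table = anno, chrom_sizes_vector = chromSizes))
    })
}
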