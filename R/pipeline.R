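## End-to-end orchestration: simulate, AP-MS scoring, ChIP occupancy, with
## seed control, atomic TSV outputs and a JSON run manifest.

.defaultPipelineConfig <- function() {
    list(
        seed = 1L,
        paths = list(
            counts = NULL, design = NULL, annotations = NULL,
            chrom_sizes = NULL, chip_wt = NULL, chip_mut = NULL,
            input = NULL),
        scoring = list(
            bait_id = "POLR1C", hci_ratio_threshold = 5,
            noise_quantile = 0.20, n_required_replicates = 3L,
            alpha = 0.05, fc_upper = 1.5, fc_lower = 1 / 1.5,
            display_cap = -4.5, ratio_scale = "raw"),
        profile = list(n_windows_per_side = 100L, window_width = 10L),
        chip = list(bin_width = 10L, scale = "none"),
        simulate = list(
            scenario = "leukodystrophy", variant = NULL,
            n_replicates = 3L, cv = 0.10, dropout = 0.2,
            chip_fold = 0.4),
        log_level = "info")
}

.mergeConfig <- function(base, user) {
    for (nm in names(user)) {
        if (is.list(base[[nm]]) && is.list(user[[nm]]))
            base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
        else
            base[[nm]] <- user[[nm]]
    }
    base
}

.logMsg <- function(level, cfgLevel, ...) {
    ranks <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
    if (ranks[[level]] >= ranks[[cfgLevel %||% "info"]])
        message(sprintf("[%s] %s", toupper(level), paste0(...)))
}

.scoringFromConfig <- function(sc, seed) {
    scoringConfig(baitId = sc$bait_id,
                  hciRatioThreshold = sc$hci_ratio_threshold,
                  noiseQuantile = sc$noise_quantile,
                  nRequiredReplicates = sc$n_required_replicates,
                  alpha = sc$alpha, fcUpper = sc$fc_upper,
                  fcLower = sc$fc_lower, displayCap = sc$display_cap,
                  ratioScale = sc$ratio_scale, rngSeed = seed)
}

#' Run the pipeline end-to-end
#'
#' Orchestrates the two analyses from a plain-text configuration:
#' `"simulate"` writes synthetic AP-MS and ChIP inputs, `"apms"` runs the
#' differential-interaction scoring for every mutant variant in the design,
#' `"chip"` runs the input-subtracted TSS-anchored occupancy comparison,
#' and `"all"` chains them. All outputs are fixed-dialect TSVs written
#' atomically to `outDir`, plus a `manifest.json` recording the config,
#' seed, package version and row counts; identical config + seed reproduce
#' every output byte for byte.
#'
#' @param config path to a YAML config file, or a named list; omitted
#'   fields fall back to package defaults. When simulating, input paths
#'   default to the simulation outputs under `outDir/sim`.
#' @param mode one of `"all"`, `"simulate"`, `"apms"`, `"chip"`.
#' @param outDir output directory (created if needed).
#' @param seed global RNG seed; overrides the config seed.
#' @return Invisibly, a list of written file paths.
#' @examples
#' \donttest{
#' out <- tempfile()
#' runPipeline(mode = "all", outDir = out, seed = 11)
#' list.files(out)
#' }
#' @export
runPipeline <- function(config = list(),
                        mode = c("all", "simulate", "apms", "chip"),
                        outDir = "polrscreen_out", seed = NULL) {
    mode <- match.arg(mode)
    if (is.character(config)) {
        if (!file.exists(config))
            stop("config file not found: ", config, call. = FALSE)
        config <- yaml::read_yaml(config)
    }
    cfg <- .mergeConfig(.defaultPipelineConfig(), config)
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    lvl <- cfg$log_level
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    written <- character()

    if (mode %in% c("simulate", "all")) {
        .logMsg("info", lvl, "simulating synthetic datasets (seed ",
                cfg$seed, ")")
        simDir <- file.path(outDir, "sim")
        dir.create(simDir, showWarnings = FALSE, recursive = TRUE)
        scen <- switch(cfg$simulate$scenario,
            leukodystrophy = leukodystrophyScenario(
                variant = cfg$simulate$variant %||% "N32I",
                cv = cfg$simulate$cv, dropout = cfg$simulate$dropout),
            tcs = tcsScenario(
                variant = cfg$simulate$variant %||% "R279Q",
                cv = cfg$simulate$cv, dropout = cfg$simulate$dropout),
            stop("unknown scenario: ", cfg$simulate$scenario, call. = FALSE))
        sim <- simulateApmsDataset(complexModel(), scen,
                                   nReplicates = cfg$simulate$n_replicates,
                                   seed = cfg$seed)
        countsPath <- file.path(simDir, "spectral_counts.tsv")
        designPath <- file.path(simDir, "run_design.tsv")
        writeSpectralCounts(sim$counts, countsPath)
        writeRunDesign(sim$design, designPath)
        f <- cfg$simulate$chip_fold
        chip <- simulateChipDataset(
            simDir, foldMut = c(type1 = f, type2 = f, type3 = f, rDNA = 1),
            seed = cfg$seed + 1L)
        cfg$paths$counts <- cfg$paths$counts %||% countsPath
        cfg$paths$design <- cfg$paths$design %||% designPath
        cfg$paths$annotations <- cfg$paths$annotations %||% chip$annotations
        cfg$paths$chrom_sizes <- cfg$paths$chrom_sizes %||% chip$chrom_sizes
        cfg$paths$chip_wt <- cfg$paths$chip_wt %||% chip$chip_wt
        cfg$paths$chip_mut <- cfg$paths$chip_mut %||% chip$chip_mut
        cfg$paths$input <- cfg$paths$input %||% chip$input
        written <- c(written, countsPath, designPath, chip$chip_wt,
                     chip$chip_mut, chip$input, chip$annotations,
                     chip$chrom_sizes)
    }

    rowCounts <- list()

    if (mode %in% c("apms", "all")) {
        for (nm in c("counts", "design"))
            if (is.null(cfg$paths[[nm]]) || !file.exists(cfg$paths[[nm]]))
                stop("apms stage: missing input file for '", nm, "': ",
                     cfg$paths[[nm]] %||% "(unset)", call. = FALSE)
        .logMsg("info", lvl, "scoring AP-MS differential interactions")
        sc <- .scoringFromConfig(cfg$scoring, cfg$seed)
        raw <- cleanProteinTable(readSpectralCounts(cfg$paths$counts))
        design <- readRunDesign(cfg$paths$design)
        dd <- designTable(design)
        variants <- sub("^MUT:", "",
                        unique(dd$condition[grepl("^MUT:", dd$condition)]))
        if (!length(variants))
            stop("apms stage: design contains no MUT runs", call. = FALSE)
        allRes <- list()
        for (v in variants)
            allRes[[v]] <- apmsDifferential(raw, design, v, sc)
        combined <- do.call(rbind, lapply(variants, function(v) {
            r <- allRes[[v]]$results
            cbind(variant = v, r, stringsAsFactors = FALSE)
        }))
        resPath <- file.path(outDir, "differential_results.tsv")
        writeTsv(combined, resPath)
        disp <- buildDisplayMatrix(
            stats::setNames(lapply(allRes, `[[`, "results"), variants), sc)
        hmPath <- file.path(outDir, "heatmap_matrix.tsv")
        writeTsv(disp$heatmap, hmPath)
        written <- c(written, resPath, hmPath)
        rowCounts$differential_results <- nrow(combined)
        for (v in variants) {
            vp <- file.path(outDir, sprintf("volcano_%s.tsv", v))
            writeTsv(disp$volcano[[v]], vp)
            written <- c(written, vp)
        }
    }

    if (mode %in% c("chip", "all")) {
        for (nm in c("annotations", "chrom_sizes", "chip_wt", "chip_mut",
                     "input"))
            if (is.null(cfg$paths[[nm]]) || !file.exists(cfg$paths[[nm]]))
                stop("chip stage: missing input file for '", nm, "': ",
                     cfg$paths[[nm]] %||% "(unset)", call. = FALSE)
        .logMsg("info", lvl, "computing TSS-anchored occupancy profiles")
        anno <- readGeneAnnotation(cfg$paths$annotations)
        cs <- readChromSizes(cfg$paths$chrom_sizes)
        pc <- profileConfig(cfg$profile$n_windows_per_side,
                            cfg$profile$window_width)
        bw <- cfg$chip$bin_width
        inputSig <- loadSignal(cfg$paths$input, bw, cs)
        sigs <- list(
            WT = normalizeSubtractInput(
                loadSignal(cfg$paths$chip_wt, bw, cs), inputSig,
                scale = cfg$chip$scale),
            MUT = normalizeSubtractInput(
                loadSignal(cfg$paths$chip_mut, bw, cs), inputSig,
                scale = cfg$chip$scale))
        comps <- list()
        for (cls in intersect(.geneClasses, unique(anno$gene_class))) {
            profs <- lapply(sigs, aggregateProfile, annotations = anno,
                            geneClass = cls, config = pc)
            for (cond in names(profs)) {
                p <- profs[[cond]]
                off <- (seq_len(2L * pc@nWindowsPerSide) -
                        pc@nWindowsPerSide - 1L) * pc@windowWidth
                pp <- file.path(outDir,
                                sprintf("profile_%s_%s.tsv", cls, cond))
                writeTsv(data.frame(
                    window_index = seq_along(profileValues(p)),
                    offset_bp = off, mean_signal = profileValues(p)), pp)
                written <- c(written, pp)
            }
            comps[[cls]] <- compareOccupancy(profs$WT, profs$MUT)
        }
        cmp <- do.call(rbind, comps)
        rownames(cmp) <- NULL
        cmpPath <- file.path(outDir, "occupancy_comparison.tsv")
        writeTsv(cmp, cmpPath)
        written <- c(written, cmpPath)
        rowCounts$occupancy_comparison <- nrow(cmp)
    }

    # keep manifests portable: paths under outDir are recorded relative to it
    root <- paste0(normalizePath(outDir, winslash = "/"), "/")
    cfg$paths <- lapply(cfg$paths, function(p) {
        if (is.null(p) || !file.exists(p)) return(p)
        sub(root, "", normalizePath(p, winslash = "/"), fixed = TRUE)
    })
    manifest <- list(
        package = "PolrScreen",
        version = as.character(utils::packageVersion("PolrScreen")),
        mode = mode, seed = cfg$seed, config = cfg,
        row_counts = rowCounts,
        outputs = basename(written))
    manPath <- file.path(outDir, "manifest.json")
    tmp <- tempfile(tmpdir = outDir)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", digits = NA)
    file.rename(tmp, manPath)
    .logMsg("info", lvl, "wrote ", length(written) + 1L, " files to ",
            outDir)
    invisible(c(written, manPath))
}
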