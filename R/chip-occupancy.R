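## Input-subtracted, TSS-anchored aggregate occupancy over Pol III gene
## classes and an rDNA control. Coordinates are BED-style 0-based
## half-open throughout; annotation TSS values are already the start site
## (for minus-strand genes the annotation carries the gene's 3'-most,
## i.e. transcription-start, coordinate).

.geneClasses <- c("type1", "type2", "type3", "rDNA")

#' Read a chromosome sizes table
#'
#' Standard headerless two-column `chrom.sizes` TSV.
#'
#' @param path path to the file.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            col.names = c("chrom", "size"),
                            colClasses = c("character", "numeric"))
    if (any(df$size <= 0) || anyDuplicated(df$chrom))
        stop("invalid chromosome sizes in ", path, call. = FALSE)
    stats::setNames(df$size, df$chrom)
}

#' Read a gene annotation table
#'
#' Header TSV with columns `gene_id`, `chrom`, `tss` (0-based), `strand`
#' (+/-) and `gene_class` (one of type1, type2, type3, rDNA -- the three
#' Pol III promoter classes plus the Pol I rDNA control).
#'
#' @param path path to the TSV.
#' @return Validated data.frame.
#' @export
readGeneAnnotation <- function(path) {
    df <- .readTsv(path)
    need <- c("gene_id", "chrom", "tss", "strand", "gene_class")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("format error in ", path, ": missing column(s) ",
             paste(miss, collapse = ", "), call. = FALSE)
    df$tss <- suppressWarnings(as.numeric(df$tss))
    validateGeneAnnotation(df[need])
}

#' Validate a gene annotation data.frame
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `gene_class`.
#' @return The data.frame, invisibly validated.
#' @export
validateGeneAnnotation <- function(df) {
    if (anyDuplicated(df$gene_id))
        stop("gene_id values must be unique", call. = FALSE)
    if (anyNA(df$tss) || any(df$tss < 0) || any(df$tss != round(df$tss)))
        stop("tss must be a non-negative integer coordinate", call. = FALSE)
    if (!all(df$strand %in% c("+", "-")))
        stop("strand must be '+' or '-'", call. = FALSE)
    bad <- setdiff(unique(df$gene_class), .geneClasses)
    if (length(bad))
        stop("unknown gene_class value(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    df
}

#' Load aligned reads into a binned coverage signal
#'
#' Reads a BED file of aligned read intervals and computes per-base
#' coverage aggregated into bins of `binWidth` bp: each bin's value is the
#' mean per-base depth within the bin, so reads spanning bin boundaries
#' contribute proportionally to their overlap. The trailing bin of a
#' chromosome may be shorter; its mean is taken over its actual bases.
#'
#' @param path BED file (>= 3 columns; 0-based half-open intervals).
#' @param binWidth bin width in bp.
#' @param chromSizes named vector of chromosome lengths (see
#'   [readChromSizes()]).
#' @return A [BinnedSignal-class] object with `state = "raw"`.
#' @export
loadSignal <- function(path, binWidth = 10L, chromSizes) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    binWidth <- as.integer(binWidth)
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || all(!nzchar(lines))) {
        gr <- GenomicRanges::GRanges()
    } else {
        gr <- tryCatch(
            rtracklayer::import(path, format = "bed"),
            error = function(e)
                stop("parse error in ", path, ": ", conditionMessage(e),
                     call. = FALSE))
    }
    if (length(gr)) {
        chs <- as.character(GenomicRanges::seqnames(gr))
        unknown <- setdiff(unique(chs), names(chromSizes))
        if (length(unknown))
            stop("validation error: unknown chromosome(s) in ", path, ": ",
                 paste(unknown, collapse = ", "), call. = FALSE)
        past <- BiocGenerics::end(gr) > chromSizes[chs] |
            BiocGenerics::start(gr) < 1L
        if (any(past))
            stop("validation error: record beyond chromosome end in ", path,
                 " (first offender: line for ", chs[which(past)[1L]], ":",
                 BiocGenerics::start(gr)[which(past)[1L]] - 1L, "-",
                 BiocGenerics::end(gr)[which(past)[1L]], ")", call. = FALSE)
        GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
        GenomeInfoDb::seqlengths(gr) <- unname(chromSizes)
        cov <- GenomicRanges::coverage(gr)
    } else {
        cov <- S4Vectors::SimpleList(lapply(chromSizes, function(len)
            S4Vectors::Rle(0L, len)))
    }
    sig <- lapply(names(chromSizes), function(ch) {
        len <- chromSizes[[ch]]
        x <- cov[[ch]]
        if (binWidth == 1L)
            return(S4Vectors::Rle(as.numeric(S4Vectors::runValue(x)),
                                  S4Vectors::runLength(x)))
        starts <- seq.int(1L, len, by = binWidth)
        v <- IRanges::Views(x, start = starts,
                            end = pmin(starts + binWidth - 1L, len))
        S4Vectors::Rle(IRanges::viewMeans(v))
    })
    names(sig) <- names(chromSizes)
    new("BinnedSignal", signal = sig, binWidth = binWidth,
        chromLengths = stats::setNames(as.numeric(chromSizes),
                                       names(chromSizes)),
        librarySize = as.numeric(length(gr)), state = "raw")
}

#' Subtract input signal from ChIP signal
#'
#' Per-bin subtraction of the input (whole-chromatin) track from the ChIP
#' track, clamped at zero (occupancy cannot be negative). By default the
#' subtraction is performed on the native depth scale, which is calibrated
#' when ChIP and input libraries were sequenced to comparable background
#' depth; `scale = "rpm"` rescales both tracks to reads-per-million first,
#' for libraries of unequal depth. Both tracks must share the chromosome
#' set and bin width.
#'
#' @param chip,input [BinnedSignal-class] objects with `state = "raw"`.
#' @param scale `"none"` (native scale, default) or `"rpm"`.
#' @return A [BinnedSignal-class] object with `state = "input-subtracted"`.
#' @export
normalizeSubtractInput <- function(chip, input, scale = c("none", "rpm")) {
    scale <- match.arg(scale)
    stopifnot(is(chip, "BinnedSignal"), is(input, "BinnedSignal"))
    if (chip@binWidth != input@binWidth ||
        !setequal(names(chip@signal), names(input@signal)) ||
        !isTRUE(all.equal(chip@chromLengths[names(chip@signal)],
                          input@chromLengths[names(chip@signal)])))
        stop("grid error: chip and input bin grids differ", call. = FALSE)
    fc <- fi <- 1
    if (scale == "rpm") {
        if (chip@librarySize <= 0 || input@librarySize <= 0)
            stop("grid error: rpm scaling needs nonzero library sizes",
                 call. = FALSE)
        fc <- 1e6 / chip@librarySize
        fi <- 1e6 / input@librarySize
    }
    sig <- lapply(names(chip@signal), function(ch) {
        d <- chip@signal[[ch]] * fc - input@signal[[ch]] * fi
        pmax(d, 0)
    })
    names(sig) <- names(chip@signal)
    new("BinnedSignal", signal = sig, binWidth = chip@binWidth,
        chromLengths = chip@chromLengths, librarySize = chip@librarySize,
        state = "input-subtracted")
}

# Per-base values over the 0-based half-open interval [start0, end0) of one
# chromosome; out-of-bounds bases are NA.
.decodeRegion <- function(bs, chrom, start0, end0) {
    len <- bs@chromLengths[[chrom]]
    if (is.null(len))
        stop("unknown chromosome: ", chrom, call. = FALSE)
    n <- end0 - start0
    out <- rep(NA_real_, n)
    pos <- start0:(end0 - 1L)           # 0-based bases
    inb <- pos >= 0 & pos < len
    if (!any(inb)) return(out)
    bw <- bs@binWidth
    bins <- pos[inb] %/% bw + 1L        # 1-based bin indices
    lo <- min(bins); hi <- max(bins)
    vals <- as.numeric(S4Vectors::window(bs@signal[[chrom]], lo, hi))
    out[inb] <- vals[bins - lo + 1L]
    out
}

#' TSS-anchored aggregate profile for one gene class
#'
#' For every gene of the class, lays out `nWindowsPerSide` windows of
#' `windowWidth` bp on both sides of the TSS, computes the mean per-base
#' signal in each window, orients the windows 5' to 3' along the gene
#' (minus-strand genes are mirrored so window 1 is always the most
#' upstream), and averages across genes with equal weight. Windows
#' extending past a chromosome end contribute only their in-bounds bases.
#'
#' @param signal an input-subtracted [BinnedSignal-class] object.
#' @param annotations gene annotation data.frame
#'   (see [readGeneAnnotation()]).
#' @param geneClass one of `"type1"`, `"type2"`, `"type3"`, `"rDNA"`.
#' @param config a [ProfileConfig-class] object.
#' @return An [AggregateProfile-class] object.
#' @export
aggregateProfile <- function(signal, annotations, geneClass,
                             config = profileConfig()) {
    stopifnot(is(signal, "BinnedSignal"))
    genes <- annotations[annotations$gene_class == geneClass, , drop = FALSE]
    if (!nrow(genes))
        stop("empty-class error: no genes of class ", geneClass,
             call. = FALSE)
    n <- config@nWindowsPerSide
    w <- config@windowWidth
    span <- n * w
    prof <- matrix(NA_real_, nrow = nrow(genes), ncol = 2L * n)
    for (i in seq_len(nrow(genes))) {
        tss <- genes$tss[i]
        minus <- genes$strand[i] == "-"
        # plus strand: [tss - span, tss + span); minus strand shifted by one
        # so the TSS base is the first base of the first downstream window
        # in gene orientation.
        s0 <- if (minus) tss - span + 1L else tss - span
        pb <- .decodeRegion(signal, genes$chrom[i], s0, s0 + 2L * span)
        m <- matrix(pb, nrow = w)
        win <- colMeans(m, na.rm = TRUE)    # NaN when fully out of bounds
        if (minus) win <- rev(win)
        prof[i, ] <- win
    }
    vals <- colMeans(prof, na.rm = TRUE)
    new("AggregateProfile", geneClass = geneClass, values = vals,
        nGenes = nrow(genes), nWindowsPerSide = n, windowWidth = w)
}

#' Compare occupancy between two aggregate profiles
#'
#' Summarizes two same-class profiles (e.g. wild type vs mutant) by their
#' mean window signal and reports the ratio b/a with its log2 transform.
#' A zero reference mean is flagged degenerate rather than divided by.
#'
#' @param a,b [AggregateProfile-class] objects of the same gene class and
#'   window layout (`a` is the reference, typically WT).
#' @return One-row data.frame: `gene_class`, `mean_a`, `mean_b`, `ratio`,
#'   `log2_ratio`, `n_genes_a`, `n_genes_b`, `degenerate`.
#' @export
compareOccupancy <- function(a, b) {
    stopifnot(is(a, "AggregateProfile"), is(b, "AggregateProfile"))
    if (!identical(a@geneClass, b@geneClass))
        stop("comparison error: gene classes differ (", a@geneClass,
             " vs ", b@geneClass, ")", call. = FALSE)
    if (a@nWindowsPerSide != b@nWindowsPerSide ||
        a@windowWidth != b@windowWidth)
        stop("comparison error: window layouts differ", call. = FALSE)
    ma <- mean(a@values, na.rm = TRUE)
    mb <- mean(b@values, na.rm = TRUE)
    degenerate <- ma == 0
    ratio <- if (degenerate) NA_real_ else mb / ma
    data.frame(gene_class = a@geneClass, mean_a = ma, mean_b = mb,
               ratio = ratio, log2_ratio = if (degenerate) NA_real_ else
                   log2(ratio),
               n_genes_a = a@nGenes, n_genes_b = b@nGenes,
               degenerate = degenerate, stringsAsFactors = FALSE)
}
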