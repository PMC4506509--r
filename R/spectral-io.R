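## Reading and sanitizing spectral-count tables and run designs.
##
## On-disk dialects (tab-separated, UTF-8, header required):
##   counts: protein_id  run_id  count
##   design: run_id  condition  replicate_index  pair_id
## Condition tokens are exactly `WT`, `MUT:<name>` or `EV`. A protein absent
## from a run is an implicit raw count of zero; readers never materialize
## zeros.

.readTsv <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "", stringsAsFactors = FALSE,
                      colClasses = "character", check.names = FALSE)
}

#' Read a spectral-count table
#'
#' Parses a long-format TSV of spectral counts (columns `protein_id`,
#' `run_id`, `count`) into a [SpectralCounts-class] object. Duplicate
#' (protein, run) rows, negative counts and (for `kind = "raw"`)
#' non-integer counts are rejected.
#'
#' @param path path to the TSV file.
#' @param kind `"raw"` for integer Mascot-style counts, `"normalized"` for
#'   fractional bait-normalized counts.
#' @return A [SpectralCounts-class] object.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("protein_id\trun_id\tcount", "POLR3A\tWT_r1\t12"), f)
#' readSpectralCounts(f)
#' @export
readSpectralCounts <- function(path, kind = c("raw", "normalized")) {
    kind <- match.arg(kind)
    df <- .readTsv(path)
    need <- c("protein_id", "run_id", "count")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("format error in ", path, ": missing column(s) ",
             paste(miss, collapse = ", "), call. = FALSE)
    cnt <- suppressWarnings(as.numeric(df$count))
    if (anyNA(cnt))
        stop("format error in ", path, ": non-numeric count values",
             call. = FALSE)
    df$count <- cnt
    SpectralCounts(df[need], kind = kind)
}

#' Write a spectral-count table
#'
#' Inverse of [readSpectralCounts()]: writes the long-format TSV dialect.
#' Counts are written at full precision so that a write/read round trip
#' reproduces the table exactly.
#'
#' @param x a [SpectralCounts-class] object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeSpectralCounts <- function(x, path) {
    stopifnot(is(x, "SpectralCounts"))
    df <- x@counts
    if (identical(x@kind, "raw")) {
        df$count <- format(df$count, scientific = FALSE, trim = TRUE)
    } else {
        df$count <- format(df$count, digits = 17, scientific = FALSE,
                           trim = TRUE)
    }
    writeTsv(df, path, full = TRUE)
}

#' Read a purification run design
#'
#' Parses the design TSV (columns `run_id`, `condition`,
#' `replicate_index`, `pair_id`) and validates the MUT/WT pairing: within
#' each mutant variant the pairing must be a bijection onto the WT runs.
#' Empty or `"."` pair fields (EV runs) are read as missing.
#'
#' @param path path to the design TSV.
#' @return A [RunDesign-class] object.
#' @export
readRunDesign <- function(path) {
    df <- .readTsv(path)
    need <- c("run_id", "condition", "replicate_index", "pair_id")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("format error in ", path, ": missing column(s) ",
             paste(miss, collapse = ", "), call. = FALSE)
    ri <- suppressWarnings(as.integer(df$replicate_index))
    if (anyNA(ri))
        stop("format error in ", path, ": non-integer replicate_index",
             call. = FALSE)
    df$replicate_index <- ri
    df$pair_id[df$pair_id %in% c("", ".", "NA")] <- NA_character_
    RunDesign(df[need])
}

#' Write a run design
#'
#' @param x a [RunDesign-class] object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeRunDesign <- function(x, path) {
    stopifnot(is(x, "RunDesign"))
    df <- x@design
    df$pair_id[is.na(df$pair_id)] <- "."
    writeTsv(df, path, full = TRUE)
}

#' Default contaminant list
#'
#' Common keratin contaminants of affinity-purification mass spectrometry;
#' keratins are shed from skin and are not expressed in HeLa cells, so any
#' keratin identification in a pull-down is nonspecific. Override or extend
#' as needed for other cell systems.
#'
#' @return Character vector of protein ids.
#' @export
defaultContaminants <- function() {
    c("KRT1", "KRT2", "KRT4", "KRT5", "KRT6A", "KRT6B", "KRT8", "KRT9",
      "KRT10", "KRT13", "KRT14", "KRT16", "KRT17", "KRT18", "KRT19")
}

#' Remove contaminants and collapse indistinguishable isoforms
#'
#' Drops known contaminant proteins, then merges proteins mapped to the
#' same isoform group into a single record per run with counts summed.
#' Contaminant removal happens first, so a contaminant mapped into an
#' isoform group is still removed. The raw/normalized flag is preserved.
#'
#' @param x a [SpectralCounts-class] object.
#' @param contaminants character vector of protein ids to drop
#'   (default [defaultContaminants()]).
#' @param isoformMap named character vector mapping `protein_id` to a group
#'   id; proteins not named map to themselves. `NULL` for identity.
#' @return A [SpectralCounts-class] object.
#' @examples
#' x <- SpectralCounts(data.frame(
#'     protein_id = c("KRT1", "POLR3A_iso1", "POLR3A_iso2"),
#'     run_id = "WT_r1", count = c(9, 3, 2)))
#' cleanProteinTable(x, contaminants = "KRT1",
#'     isoformMap = c(POLR3A_iso1 = "POLR3A", POLR3A_iso2 = "POLR3A"))
#' @export
cleanProteinTable <- function(x, contaminants = defaultContaminants(),
                              isoformMap = NULL) {
    stopifnot(is(x, "SpectralCounts"))
    df <- x@counts
    df <- df[!df$protein_id %in% contaminants, , drop = FALSE]
    if (!is.null(isoformMap) && nrow(df)) {
        hit <- match(df$protein_id, names(isoformMap))
        df$protein_id <- ifelse(is.na(hit), df$protein_id,
                                unname(isoformMap[hit]))
        agg <- stats::aggregate(count ~ protein_id + run_id, data = df,
                                FUN = sum)
        df <- agg[order(agg$protein_id, agg$run_id), , drop = FALSE]
    }
    rownames(df) <- NULL
    SpectralCounts(df, kind = x@kind)
}
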