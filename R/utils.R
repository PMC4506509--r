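# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# RNG state.
withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()),
                    add = TRUE)
        } else {
            on.exit(suppressWarnings(
                rm(".Random.seed", envir = globalenv())), add = TRUE)
        }
        set.seed(as.integer(seed))
    }
    force(code)
}

# Write a data.frame as a TSV atomically (write to a temp file in the same
# directory, then rename). Numeric columns are emitted with 6 significant
# digits unless full = TRUE.
writeTsv <- function(df, path, full = FALSE) {
    out <- df
    if (!full) {
        for (j in seq_along(out)) {
            if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
                out[[j]] <- formatC(out[[j]], digits = 6, format = "g")
        }
    }
    tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
    utils::write.table(out, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    if (!file.rename(tmp, path)) {
        file.copy(tmp, path, overwrite = TRUE)
        unlink(tmp)
    }
    invisible(path)
}

# Wide protein x run matrix from a long table; absent pairs are zero.
countMatrix <- function(x, proteins, runs) {
    df <- x@counts
    m <- matrix(0, nrow = length(proteins), ncol = length(runs),
                dimnames = list(proteins, runs))
    keep <- df$protein_id %in% proteins & df$run_id %in% runs
    df <- df[keep, , drop = FALSE]
    if (nrow(df))
        m[cbind(match(df$protein_id, proteins), match(df$run_id, runs))] <-
            df$count
    m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
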