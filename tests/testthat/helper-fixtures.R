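# Fixtures built in code and independent brute-force oracles used across
# the suite. Oracles deliberately use naive loops / closed forms so they
# share no code path with the package implementation.

# --- AP-MS fixtures ---------------------------------------------------------

makeDesign <- function(n = 3L, variant = "N32I", ev = TRUE) {
    df <- data.frame(
        run_id = c(sprintf("WT_r%d", 1:n), sprintf("MUT_%s_r%d", variant, 1:n),
                   if (ev) sprintf("EV_r%d", 1:n)),
        condition = c(rep("WT", n), rep(paste0("MUT:", variant), n),
                      if (ev) rep("EV", n)),
        replicate_index = c(1:n, 1:n, if (ev) 1:n),
        pair_id = c(sprintf("p%d", 1:n), sprintf("p%d", 1:n),
                    if (ev) rep(NA_character_, n)),
        stringsAsFactors = FALSE)
    RunDesign(df)
}

# long table from a named list run_id -> named count vector
countsFromList <- function(lst, kind = "raw") {
    df <- do.call(rbind, lapply(names(lst), function(r) {
        v <- lst[[r]]
        data.frame(protein_id = names(v), run_id = r, count = unname(v),
                   stringsAsFactors = FALSE)
    }))
    SpectralCounts(df, kind = kind)
}

# --- statistical oracles ----------------------------------------------------

# Brute-force Benjamini-Hochberg step-up: literal definition, O(n^2).
bhOracle <- function(p) {
    n <- length(p)
    out <- numeric(n)
    ord <- order(p)
    for (k in seq_len(n)) {
        i <- ord[k]
        # adjusted p(i) = min over j >= rank(i) of p(j) * n / j, capped at 1
        vals <- vapply(k:n, function(j) p[ord[j]] * n / j, 0)
        out[i] <- min(1, min(vals))
    }
    out
}

# closed-form two-tailed p for the t distribution with 2 df
tP2df <- function(t) {
    Ft <- 0.5 * (1 + t / sqrt(2 + t^2))
    2 * (1 - Ft)
}

# --- ChIP oracles -----------------------------------------------------------

# per-base coverage of 0-based half-open reads on one chromosome
perBaseCoverage <- function(starts, ends, len) {
    cov <- numeric(len)
    for (i in seq_along(starts)) {
        idx <- (starts[i] + 1L):ends[i]   # 1-based bases
        cov[idx] <- cov[idx] + 1
    }
    cov
}

# bin means of per-base coverage; trailing bin over its actual bases
binMeansOracle <- function(cov, binWidth) {
    len <- length(cov)
    starts <- seq(1L, len, by = binWidth)
    vapply(starts, function(s) mean(cov[s:min(s + binWidth - 1L, len)]), 0)
}

# explicit-loop TSS-anchored aggregate profile over per-base signal
profileOracle <- function(perBase, genes, n, w) {
    out <- matrix(NA_real_, nrow = nrow(genes), ncol = 2L * n)
    for (g in seq_len(nrow(genes))) {
        tss <- genes$tss[g]
        minus <- genes$strand[g] == "-"
        sig <- perBase[[genes$chrom[g]]]
        len <- length(sig)
        for (k in seq_len(2L * n)) {
            if (!minus) {
                a0 <- tss - n * w + (k - 1L) * w   # 0-based window start
            } else {
                # window k is the k-th most upstream in gene orientation
                a0 <- tss + n * w + 1L - k * w
            }
            vals <- c()
            for (b0 in a0:(a0 + w - 1L)) {
                if (b0 >= 0 && b0 < len) vals <- c(vals, sig[b0 + 1L])
            }
            out[g, k] <- if (length(vals)) mean(vals) else NaN
        }
    }
    colMeans(out, na.rm = TRUE)
}

writeBedFile <- function(df, path = tempfile(fileext = ".bed")) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    path
}

randomBed <- function(nReads, chromSizes, readLen = 20L) {
    ch <- sample(names(chromSizes), nReads, replace = TRUE)
    start <- vapply(ch, function(c1)
        floor(runif(1, 0, chromSizes[[c1]] - readLen)), 0)
    data.frame(chrom = ch, start = as.integer(start),
               end = as.integer(start) + readLen,
               name = sprintf("r%d", seq_len(nReads)), score = 0L,
               strand = sample(c("+", "-"), nReads, TRUE),
               stringsAsFactors = FALSE)
}
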