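test_that("bait normalization rescales each run by its bait count", {
    x <- countsFromList(list(
        r1 = c(POLR1C = 40, X = 20, Y = 8),
        r2 = c(POLR1C = 50, X = 25),
        r3 = c(POLR1C = 60, X = 30)))
    y <- normalizeByBait(x, "POLR1C")
    df <- spectralCounts(y)
    expect_identical(countKind(y), "normalized")
    expect_equal(df$count[df$protein_id == "POLR1C"], rep(1, 3))
    expect_equal(df$count[df$protein_id == "X"], rep(0.5, 3))
    expect_equal(df$count[df$protein_id == "Y" & df$run_id == "r1"], 0.2)

    # ratios of non-bait proteins are invariant to rescaling a run
    x2 <- countsFromList(list(r1 = c(POLR1C = 80, X = 40, Y = 16),
                              r2 = c(POLR1C = 50, X = 25),
                              r3 = c(POLR1C = 60, X = 30)))
    y2 <- normalizeByBait(x2, "POLR1C")
    expect_equal(spectralCounts(y2)$count, spectralCounts(y)$count)

    xe <- countsFromList(list(r1 = c(POLR1C = 40, X = 2),
                              r3 = c(X = 5, Z = 2)))
    expect_error(normalizeByBait(xe, "POLR1C"), "r3")
})

test_that("zero imputation draws from the per-run low-count noise window", {
    base <- c(2, 3, 5, 8, 13, 21, 40, 100)
    zeros <- sprintf("z%04d", 1:10000)
    df <- data.frame(protein_id = c(sprintf("p%d", seq_along(base)), zeros),
                     run_id = "r1",
                     count = c(base, rep(0, length(zeros))),
                     stringsAsFactors = FALSE)
    x <- SpectralCounts(df)
    cfg <- scoringConfig(rngSeed = 99L)
    # the zero-count proteins belong to the analysis universe (observed in
    # other runs of the real design), so name them explicitly here
    y <- imputeZeroCounts(x, cfg, proteins = df$protein_id)
    dfy <- spectralCounts(y)
    expect_identical(countKind(y), "imputed")
    # nonzero counts untouched
    expect_equal(sort(dfy$count[dfy$protein_id %in%
                                sprintf("p%d", seq_along(base))]),
                 sort(base))
    draws <- dfy$count[dfy$protein_id %in% zeros]
    expect_true(all(draws > 0))
    # lowest ceil(0.2 * 8) = 2 counts define the window: mean 2.5, sd ~0.7071
    mu <- mean(c(2, 3)); sdev <- sd(c(2, 3))
    expect_lt(abs(mean(draws) - mu), 4 * sdev / sqrt(length(draws)) + 0.01)
    expect_lt(abs(sd(draws) - sdev), 0.05)
    # distribution check against the target normal (truncation mass ~0.1%)
    ks <- suppressWarnings(ks.test(draws, "pnorm", mean = mu, sd = sdev))
    expect_gt(ks$p.value, 1e-3)
})

test_that("imputation is deterministic, touches only zeros, and needs >= 2 nonzero counts", {
    x <- countsFromList(list(r1 = c(a = 4, b = 9, c = 2),
                             r2 = c(a = 7, b = 1, d = 3)))
    cfg <- scoringConfig(rngSeed = 7L)
    y1 <- imputeZeroCounts(x, cfg, proteins = c("a", "b", "c", "d"))
    y2 <- imputeZeroCounts(x, cfg, proteins = c("a", "b", "c", "d"))
    expect_identical(spectralCounts(y1), spectralCounts(y2))
    d1 <- spectralCounts(y1)
    expect_true(all(d1$count > 0))
    # observed entries unchanged
    expect_equal(d1$count[d1$protein_id == "a" & d1$run_id == "r1"], 4)
    expect_equal(d1$count[d1$protein_id == "d" & d1$run_id == "r2"], 3)
    # implicit zeros materialized for the universe
    expect_equal(nrow(d1), 8L)

    # a run without zeros (universe = observed proteins) is unchanged
    xz <- countsFromList(list(r1 = c(a = 4, b = 9), r2 = c(a = 1, b = 2)))
    yz <- imputeZeroCounts(xz, cfg)
    expect_equal(sort(spectralCounts(yz)$count), sort(c(4, 9, 1, 2)))

    xbad <- countsFromList(list(r1 = c(a = 4), r2 = c(a = 1, b = 2)))
    expect_error(imputeZeroCounts(xbad, cfg, proteins = c("a", "b")), "r1")
})

test_that("high-confidence filter applies presence and strict >5 EV enrichment", {
    design <- makeDesign(3L)
    runs <- designTable(design)$run_id
    # prot A: present everywhere, WT mean 0.6 vs EV 0.1 (ratio 6) -> flagged
    # prot B: ratio exactly 5 -> not flagged
    # prot C: missing in one WT and one MUT replicate -> not flagged
    mk <- function(a, b, c1, bait) c(A = a, B = b, C = c1, POLR1C = bait)
    raw <- countsFromList(list(
        WT_r1 = c(A = 6, B = 5, C = 0, POLR1C = 10),
        WT_r2 = c(A = 6, B = 5, C = 4, POLR1C = 10),
        WT_r3 = c(A = 6, B = 5, C = 4, POLR1C = 10),
        MUT_N32I_r1 = c(A = 6, B = 5, C = 4, POLR1C = 10),
        MUT_N32I_r2 = c(A = 6, B = 5, C = 0, POLR1C = 10),
        MUT_N32I_r3 = c(A = 6, B = 5, C = 4, POLR1C = 10),
        EV_r1 = c(A = 1, B = 1, C = 0.1, POLR1C = 0.1),
        EV_r2 = c(A = 1, B = 1, C = 0.1, POLR1C = 0.1),
        EV_r3 = c(A = 1, B = 1, C = 0.1, POLR1C = 0.1)), kind = "normalized")
    imp <- SpectralCounts(spectralCounts(raw), kind = "imputed")
    # presence judged on raw integer counts
    rawInt <- countsFromList(list(
        WT_r1 = c(A = 6, B = 5, POLR1C = 10),
        WT_r2 = c(A = 6, B = 5, C = 4, POLR1C = 10),
        WT_r3 = c(A = 6, B = 5, C = 4, POLR1C = 10),
        MUT_N32I_r1 = c(A = 6, B = 5, C = 4, POLR1C = 10),
        MUT_N32I_r2 = c(A = 6, B = 5, POLR1C = 10),
        MUT_N32I_r3 = c(A = 6, B = 5, C = 4, POLR1C = 10),
        EV_r1 = c(A = 1, B = 1, POLR1C = 1),
        EV_r2 = c(A = 1, B = 1, POLR1C = 1),
        EV_r3 = c(A = 1, B = 1, POLR1C = 1)))
    hci <- flagHighConfidence(rawInt, imp, design, "N32I", scoringConfig())
    expect_true(hci$high_confidence[hci$protein_id == "A"])
    expect_identical(hci$basis[hci$protein_id == "A"], "both")
    expect_equal(hci$ratio_wt_ev[hci$protein_id == "A"], 6)
    expect_false(hci$high_confidence[hci$protein_id == "B"])  # ratio == 5
    expect_false(hci$high_confidence[hci$protein_id == "C"])  # presence
    # high ratio for POLR1C (10 / 0.1 = 100) -> flagged, as the bait must be
    expect_true(hci$high_confidence[hci$protein_id == "POLR1C"])

    noEV <- makeDesign(3L, ev = FALSE)
    expect_error(flagHighConfidence(rawInt, imp, noEV, "N32I"),
                 "design error")
})

test_that("paired ratio t-test matches the closed form and handles degeneracies", {
    design <- makeDesign(3L, ev = FALSE)
    mkTab <- function(wt, mut) countsFromList(list(
        WT_r1 = c(X = wt[1]), WT_r2 = c(X = wt[2]), WT_r3 = c(X = wt[3]),
        MUT_N32I_r1 = c(X = mut[1]), MUT_N32I_r2 = c(X = mut[2]),
        MUT_N32I_r3 = c(X = mut[3])), kind = "normalized")

    res <- differentialInteractionTest(mkTab(c(1, 1, 1), c(2.0, 2.2, 1.8)),
                                       design, "N32I", "X")
    expect_equal(res$t_statistic, 8.6603, tolerance = 1e-4)
    expect_equal(res$df, 2L)
    expect_equal(res$p_raw, tP2df(res$t_statistic), tolerance = 1e-9)
    expect_equal(res$p_raw, 0.0131, tolerance = 1e-2)
    expect_equal(res$mean_ratio, 2)

    # null with zero variance -> p = 1
    res0 <- differentialInteractionTest(mkTab(c(2, 3, 4), c(2, 3, 4)),
                                        design, "N32I", "X")
    expect_equal(res0$mean_ratio, 1)
    expect_equal(res0$p_raw, 1)

    # log2-scale symmetry: (r, r, r)-ish series and its reciprocal give equal p
    cfgL <- scoringConfig(ratioScale = "log2")
    up <- differentialInteractionTest(mkTab(c(1, 1, 1), c(2.0, 2.4, 1.9)),
                                      design, "N32I", "X", cfgL)
    dn <- differentialInteractionTest(mkTab(c(2.0, 2.4, 1.9), c(1, 1, 1)),
                                      design, "N32I", "X", cfgL)
    expect_equal(up$p_raw, dn$p_raw, tolerance = 1e-12)

    # agrees with stats::t.test on random ratio series
    set.seed(3)
    for (i in 1:25) {
        r <- exp(rnorm(3, 0, 0.3))
        res <- differentialInteractionTest(mkTab(c(1, 1, 1), r),
                                           design, "N32I", "X")
        ref <- t.test(r, mu = 1)
        expect_equal(res$t_statistic, unname(ref$statistic),
                     tolerance = 1e-12)
        expect_equal(res$p_raw, ref$p.value, tolerance = 1e-12)
    }

    d2 <- makeDesign(2L, ev = FALSE)
    onePair <- RunDesign(designTable(d2)[c(1, 3), ])
    expect_error(differentialInteractionTest(
        mkTab(c(1, 1, 1), c(2, 2, 2)), onePair, "N32I", "X"),
        "fewer than 2")
})

test_that("BH adjustment matches the step-up definition and dominates raw p", {
    expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(adjustBH(0.03), 0.03)
    expect_error(adjustBH(c(0.1, 1.2)), "validation error")
    set.seed(5)
    for (i in 1:50) {
        p <- runif(sample(1:40, 1))
        adj <- adjustBH(p)
        expect_equal(adj, bhOracle(p), tolerance = 1e-15)
        expect_true(all(adj >= p & adj <= 1))
    }
})

test_that("classification applies the dual alpha + fold-change criterion", {
    res <- data.frame(protein_id = c("a", "b", "c", "d"),
                      mean_ratio = c(0.30, 1.20, 3.0, 2.0),
                      p_adjusted = c(0.01, 0.001, 0.06, 0.02))
    out <- classifyInteractions(res, scoringConfig())
    expect_identical(out$label,
                     c("decreased", "not_significant", "not_significant",
                       "increased"))
    res$p_adjusted[1] <- NA
    expect_error(classifyInteractions(res), "p_adjusted")
})

test_that("display matrix caps log2 ratios and flags volcano significance", {
    res <- data.frame(
        protein_id = c("a", "b", "c"),
        mean_ratio = c(0.02, 1, 0.5),
        p_adjusted = c(0.001, 0.9, 0.2),
        label = c("decreased", "not_significant", "not_significant"),
        stringsAsFactors = FALSE)
    disp <- buildDisplayMatrix(list(N32I = res), scoringConfig())
    hm <- disp$heatmap
    expect_equal(hm$N32I[hm$protein_id == "a"], -4.5)   # log2(0.02) = -5.64
    expect_equal(hm$N32I[hm$protein_id == "b"], 0)
    expect_equal(hm$N32I[hm$protein_id == "c"], -1)
    v <- disp$volcano$N32I
    expect_identical(v$significant, c(TRUE, FALSE, FALSE))
    expect_equal(v$neg_log10_p_adjusted[1], 3)
})
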