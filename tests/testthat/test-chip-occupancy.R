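test_that("loadSignal bins coverage as mean per-base depth", {
    cs <- c(chr1 = 2000)
    # empty BED
    empty <- tempfile(fileext = ".bed")
    file.create(empty)
    bs <- loadSignal(empty, 10, cs)
    expect_equal(librarySize(bs), 0)
    expect_true(all(as.numeric(chromLengths(bs)) == 2000))
    expect_true(all(as.numeric(bs@signal$chr1) == 0))

    # one read [995, 1005) with 10 bp bins -> two bins of 0.5
    one <- writeBedFile(data.frame("chr1", 995L, 1005L, "r1", 0L, "+"))
    b1 <- loadSignal(one, 10, cs)
    v <- as.numeric(b1@signal$chr1)
    expect_equal(v[100], 0.5)   # bin [990, 1000)
    expect_equal(v[101], 0.5)   # bin [1000, 1010)
    expect_equal(sum(v), 1)     # 10 read-bases / 10 bp bins
    expect_equal(librarySize(b1), 1)

    # malformed line -> parse error; out-of-bounds record -> validation error
    bad <- tempfile(fileext = ".bed")
    writeLines("chr1\tnotanumber\t50", bad)
    expect_error(loadSignal(bad, 10, cs), "parse error")
    oob <- writeBedFile(data.frame("chr1", 1990L, 2010L, "r1", 0L, "+"))
    expect_error(loadSignal(oob, 10, cs), "validation error")
})

test_that("binned coverage matches a per-base brute-force oracle and conserves mass", {
    set.seed(21)
    cs <- c(chrA = 900, chrB = 450)
    for (i in 1:5) {
        bed <- randomBed(50, cs, readLen = 17L)
        path <- writeBedFile(bed)
        for (bw in c(1L, 7L, 10L)) {
            bs <- loadSignal(path, bw, cs)
            for (ch in names(cs)) {
                sel <- bed$chrom == ch
                cov <- perBaseCoverage(bed$start[sel], bed$end[sel],
                                       cs[[ch]])
                expect_equal(as.numeric(bs@signal[[ch]]),
                             binMeansOracle(cov, bw), tolerance = 1e-12)
            }
            # mass conservation: sum(bin mean x bin width) = total read-bases
            mass <- sum(vapply(names(cs), function(ch) {
                v <- as.numeric(bs@signal[[ch]])
                starts <- seq(1, cs[[ch]], by = bw)
                widths <- pmin(starts + bw - 1, cs[[ch]]) - starts + 1
                sum(v * widths)
            }, 0))
            expect_equal(mass, 50 * 17, tolerance = 1e-9)
        }
    }
})

test_that("input subtraction scales, subtracts and clamps at zero", {
    mkSig <- function(vals, lib) new("BinnedSignal",
        signal = list(chr1 = S4Vectors::Rle(vals)), binWidth = 10L,
        chromLengths = c(chr1 = 10 * length(vals)), librarySize = lib,
        state = "raw")
    chip <- mkSig(c(5, 1, 4), 2e6)
    input <- mkSig(c(2, 2, 1), 1e6)

    nat <- normalizeSubtractInput(chip, input, scale = "none")
    expect_equal(as.numeric(nat@signal$chr1), c(3, 0, 3))
    expect_identical(signalState(nat), "input-subtracted")

    # rpm: chip/2 - input/1 per million, clamped
    rpm <- normalizeSubtractInput(chip, input, scale = "rpm")
    expect_equal(as.numeric(rpm@signal$chr1),
                 pmax(c(5 / 2, 1 / 2, 4 / 2) - c(2, 2, 1), 0))

    bad <- mkSig(c(5, 1), 1e6)
    expect_error(normalizeSubtractInput(chip, bad), "grid error")
})

test_that("aggregate profiles are constant on constant signal and strand-symmetric", {
    cs <- c(chr1 = 6000)
    mkConst <- function(val) new("BinnedSignal",
        signal = list(chr1 = S4Vectors::Rle(val, 6000)), binWidth = 1L,
        chromLengths = cs, librarySize = 100, state = "input-subtracted")
    anno <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       tss = c(2000, 4000), strand = c("+", "-"),
                       gene_class = "type2", stringsAsFactors = FALSE)
    pc <- profileConfig(100L, 10L)
    p <- aggregateProfile(mkConst(1), anno, "type2", pc)
    expect_equal(profileValues(p), rep(1, 200))
    expect_equal(nGenes(p), 2L)
    expect_error(aggregateProfile(mkConst(1), anno, "type1"),
                 "empty-class")

    # mirror symmetry: a minus-strand gene in a base-mirrored landscape
    # produces the profile of the plus-strand gene exactly
    set.seed(8)
    len <- 5000
    sig <- rpois(len, 2) * 1.0
    tssP <- 2500L
    tssM <- 2100L
    mirror <- numeric(len)
    # base x (0-based) in the mirrored track = base tssP + tssM - x of sig
    for (x0 in 0:(len - 1)) {
        src <- tssP + tssM - x0
        mirror[x0 + 1] <- if (src >= 0 && src < len) sig[src + 1] else 0
    }
    mk <- function(v) new("BinnedSignal",
        signal = list(chr1 = S4Vectors::Rle(v)), binWidth = 1L,
        chromLengths = c(chr1 = len), librarySize = 1,
        state = "input-subtracted")
    aP <- data.frame(gene_id = "gp", chrom = "chr1", tss = tssP,
                     strand = "+", gene_class = "type1",
                     stringsAsFactors = FALSE)
    aM <- data.frame(gene_id = "gm", chrom = "chr1", tss = tssM,
                     strand = "-", gene_class = "type1",
                     stringsAsFactors = FALSE)
    pc2 <- profileConfig(50L, 10L)
    pP <- aggregateProfile(mk(sig), aP, "type1", pc2)
    pM <- aggregateProfile(mk(mirror), aM, "type1", pc2)
    expect_equal(profileValues(pM), profileValues(pP), tolerance = 1e-12)
})

test_that("aggregate profile matches an explicit per-base oracle", {
    set.seed(31)
    cs <- c(chrA = 5000, chrB = 4000)
    pc <- profileConfig(40L, 10L)
    for (rep in 1:3) {
        bed <- randomBed(300, cs, readLen = 25L)
        path <- writeBedFile(bed)
        bs <- loadSignal(path, 1L, cs)
        genes <- data.frame(
            gene_id = sprintf("g%d", 1:10),
            chrom = sample(names(cs), 10, TRUE),
            tss = sample(300:3500, 10),
            strand = sample(c("+", "-"), 10, TRUE),
            gene_class = "type2", stringsAsFactors = FALSE)
        p <- aggregateProfile(bs, genes, "type2", pc)
        perBase <- lapply(names(cs), function(ch) {
            sel <- bed$chrom == ch
            perBaseCoverage(bed$start[sel], bed$end[sel], cs[[ch]])
        })
        names(perBase) <- names(cs)
        expect_equal(profileValues(p), profileOracle(perBase, genes, 40L, 10L),
                     tolerance = 1e-12)
    }
})

test_that("profiles are invariant to gene order and flat on shuffled reads", {
    set.seed(12)
    cs <- c(chr1 = 60000)
    bed <- randomBed(4000, cs, readLen = 30L)
    bs <- loadSignal(writeBedFile(bed), 1L, cs)
    genes <- data.frame(gene_id = sprintf("g%d", 1:12), chrom = "chr1",
                        tss = seq(3000, 56000, length.out = 12),
                        strand = rep(c("+", "-"), 6), gene_class = "type3",
                        stringsAsFactors = FALSE)
    genes$tss <- round(genes$tss)
    pc <- profileConfig(100L, 10L)
    p1 <- aggregateProfile(bs, genes, "type3", pc)
    p2 <- aggregateProfile(bs, genes[sample(nrow(genes)), ], "type3", pc)
    expect_equal(profileValues(p1), profileValues(p2))
    # uniform reads -> profile flat: no window strays far from the mean and
    # the two halves agree (reads span ~3 windows, so adjacent windows are
    # correlated; the half-mean s.e. uses the effective sample size)
    v <- profileValues(p1)
    expect_true(all(abs(v - mean(v)) < 6 * sd(v)))
    expect_lt(abs(mean(v[1:100]) - mean(v[101:200])),
              4 * sd(v) / sqrt(100 / 3))
})

test_that("occupancy comparison reports ratio of profile means", {
    mkProf <- function(vals, cls = "type1") new("AggregateProfile",
        geneClass = cls, values = vals, nGenes = 3L,
        nWindowsPerSide = as.integer(length(vals) / 2), windowWidth = 10L)
    a <- mkProf(rep(2, 200)); b <- mkProf(rep(1, 200))
    cmp <- compareOccupancy(a, b)
    expect_equal(cmp$ratio, 0.5)
    expect_equal(cmp$log2_ratio, -1)
    same <- compareOccupancy(a, a)
    expect_equal(same$ratio, 1)
    expect_equal(same$log2_ratio, 0)

    set.seed(4)
    va <- runif(200, 1, 3); vb <- runif(200, 0.5, 2)
    cmp2 <- compareOccupancy(mkProf(va), mkProf(vb))
    expect_equal(cmp2$ratio, mean(vb) / mean(va), tolerance = 1e-12)

    expect_error(compareOccupancy(a, mkProf(rep(1, 200), "rDNA")),
                 "comparison error")
    z <- compareOccupancy(mkProf(rep(0, 200)), b)
    expect_true(z$degenerate)
    expect_true(is.na(z$ratio))
})
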