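test_that("exon collapsing takes unions and removes shared regions", {
    one <- data.frame(chrom = "chr1", start = c(1, 51), end = c(100, 150),
                      gene_id = "A")
    expect_equal(collapseGeneModel(one)$collapsed_length, 150L)

    two <- data.frame(chrom = "chr1", start = c(1, 91), end = c(100, 200),
                      gene_id = c("A", "B"))
    got <- collapseGeneModel(two)
    # brute-force base-level set arithmetic as the oracle
    aBases <- 1:100; bBases <- 91:200
    shared <- intersect(aBases, bBases)
    expect_equal(got$collapsed_length[got$gene_id == "A"],
                 length(setdiff(aBases, shared)))
    expect_equal(got$collapsed_length[got$gene_id == "B"],
                 length(setdiff(bBases, shared)))

    dup <- data.frame(chrom = "chr1", start = c(10, 10), end = c(60, 60),
                      gene_id = c("A", "B"))
    gotDup <- collapseGeneModel(dup)
    expect_true(all(gotDup$collapsed_length == 0L))
    expect_true(all(gotDup$flagged))

    bad <- data.frame(chrom = "chr1", start = 100, end = 50,
                      gene_id = "A")
    expect_error(collapseGeneModel(bad), "line 1")
})

test_that("collapsing agrees with base-level arithmetic on random loci", {
    set.seed(42)
    for (rep in 1:5) {
        n <- 12
        st <- sample(1:500, n, TRUE)
        en <- st + sample(10:120, n, TRUE)
        gid <- sample(c("A", "B", "C"), n, TRUE)
        df <- data.frame(chrom = "chr1", start = st, end = en,
                         gene_id = gid)
        got <- collapseGeneModel(df)
        bases <- lapply(split(seq_len(n), gid), function(i)
            unique(unlist(mapply(seq, st[i], en[i], SIMPLIFY = FALSE))))
        for (g in names(bases)) {
            others <- unique(unlist(bases[setdiff(names(bases), g)]))
            expect_equal(got$collapsed_length[got$gene_id == g],
                         length(setdiff(bases[[g]], others)))
        }
    }
})

test_that("subsampling is an exact without-replacement draw", {
    m <- matrix(c(8L, 2L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
    expect_identical(subsampleCounts(m, 10, seed = 1), m)  # full draw
    draws <- vapply(1:4000, function(s)
        subsampleCounts(m, 5, seed = s)[, 1], integer(2))
    expect_true(all(colSums(draws) == 5))
    expect_true(all(draws <= c(8L, 2L)))
    # hypergeometric expectation: E = depth * c / total = (4, 1)
    sdh <- sqrt(5 * 0.8 * 0.2 * (10 - 5) / (10 - 1))
    expect_lt(abs(mean(draws[1, ]) - 4), 3 * sdh / sqrt(4000))

    big <- matrix(rpois(600, 50) + 1L, 100, 6,
                  dimnames = list(sprintf("g%03d", 1:100),
                                  paste0("s", 1:6)))
    storage.mode(big) <- "integer"
    sub <- subsampleCounts(big, 1000, seed = 7)
    expect_true(all(colSums(sub) == 1000))
    expect_true(all(sub <= big))
    expect_error(subsampleCounts(big, 10^7, seed = 1), "s1")
})

test_that("RPKM follows its defining formula and scaling invariance", {
    ann <- data.frame(gene_id = c("g1", "g2"),
                      collapsed_length = c(1000L, 2500L))
    m <- matrix(c(1L, 300L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
    r <- computeRPKM(m, ann, totalReads = c(s1 = 1e6))
    expect_equal(unname(r@.Data["g1", 1]), 1.0)
    r2 <- computeRPKM(m, ann, totalReads = c(s1 = 1e7))
    expect_equal(unname(r2@.Data["g2", 1]), 300 * 1e9 / (1e7 * 2500))
    m0 <- m; m0["g1", 1] <- 0L
    expect_equal(unname(computeRPKM(m0, ann)@.Data["g1", 1]), 0)
    # uniform depth scaling cancels
    mc <- m * 5L
    storage.mode(mc) <- "integer"
    expect_equal(computeRPKM(mc, ann, totalReads = 5e6)@.Data,
                 computeRPKM(m, ann, totalReads = 1e6)@.Data)
    annBad <- data.frame(gene_id = c("g1", "g2"),
                         collapsed_length = c(0L, 2500L))
    expect_error(computeRPKM(m, annBad), "g1")
    expect_equal(exprUnit(r), "RPKM")
})

test_that("quantile normalization equalizes distributions, rank-safely", {
    m <- matrix(c(1, 3, 2, 6), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    qn <- quantileNormalize(ExprMatrix(m, "RPKM"))
    expect_equal(qn@.Data,
                 matrix(c(1.5, 4.5, 1.5, 4.5), 2, 2,
                        dimnames = dimnames(m)))
    expect_equal(exprUnit(qn), "qnorm-RPKM")

    same <- matrix(rep(c(2, 5, 9), 3), 3, 3,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
    expect_equal(quantileNormalize(ExprMatrix(same, "RPKM"))@.Data,
                 same)  # fixed point

    # ties receive the mean of the reference values at their tied ranks
    tied <- matrix(c(1, 2, 2, 4, 1, 2, 3, 4), 4, 2,
                   dimnames = list(paste0("g", 1:4), c("s1", "s2")))
    qt <- quantileNormalize(ExprMatrix(tied, "RPKM"))
    ref <- rowMeans(apply(tied, 2, sort))
    expect_equal(unname(qt@.Data[2, 1]), mean(ref[2:3]))
    expect_equal(unname(qt@.Data[3, 1]), mean(ref[2:3]))

    # column-sorted vectors identical on continuous data
    set.seed(1)
    r <- matrix(rlnorm(400), 80, 5,
                dimnames = list(sprintf("g%02d", 1:80), paste0("s", 1:5)))
    qr <- quantileNormalize(ExprMatrix(r, "RPKM"))@.Data
    srt <- apply(qr, 2, sort)
    expect_lt(max(abs(srt - srt[, 1])), 1e-12)
    # rank order preserved within columns
    expect_identical(apply(qr, 2, rank), apply(r, 2, rank))

    expect_error(quantileNormalize(ExprMatrix(r[, 1, drop = FALSE],
                                              "RPKM")), "2 samples")
})

test_that("log2-first quantile normalization round-trips the scale", {
    set.seed(2)
    counts <- matrix(rpois(300, 30), 60, 5,
                     dimnames = list(sprintf("g%02d", 1:60),
                                     paste0("s", 1:5)))
    qn <- quantileNormalize(counts, log2First = TRUE, pseudocount = 1)
    expect_true(all(qn@.Data >= 0))
    expect_equal(exprUnit(qn), "qnorm-log2count")
    ql <- quantileNormalize(counts, log2First = TRUE, keepLog = TRUE)
    expect_equal(qn@.Data, pmax(2^ql@.Data - 1, 0))
})

test_that("TMM factors match the brute-force trimming oracle", {
    set.seed(9)
    cases <- list(
        matrix(rpois(600, 60) + 1L, 100, 6),
        matrix(rpois(900, 20) + 1L, 150, 6),
        {
            m <- matrix(rpois(300, 80) + 1L, 50, 6)
            m[7, 3] <- m[7, 3] * 8L  # one inflated gene
            m
        })
    for (m in cases) {
        dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                            paste0("s", seq_len(ncol(m))))
        storage.mode(m) <- "integer"
        f <- tmmFactors(m)
        expect_equal(as.numeric(f), oracleTMMFactors(m), tolerance = 1e-10)
        expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
    }
})

test_that("TMM degenerate cases and errors", {
    m <- matrix(rep(c(10L, 20L, 40L, 80L), 3), 4, 3,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
    expect_equal(as.numeric(tmmFactors(m)), rep(1, 3), tolerance = 1e-12)
    # exact scalar multiple of the reference: depth absorbs the scalar
    m2 <- m; m2[, 3] <- m[, 1] * 4L
    expect_equal(as.numeric(tmmFactors(m2, refSample = "s1"))[3], 1,
                 tolerance = 1e-12)
    dis <- matrix(c(5L, 0L, 0L, 7L), 2, 2,
                  dimnames = list(c("g1", "g2"), c("s1", "s2")))
    expect_error(tmmFactors(dis, refSample = "s1"), "no expressed gene")
})

test_that("expressed-gene set obeys its rule semantics", {
    m <- matrix(c(0.2, 1, 0.4, 1), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    e <- ExprMatrix(m, "RPKM")
    expect_setequal(expressedGeneSet(e, 0.3, "any"), c("g1", "g2"))
    expect_setequal(expressedGeneSet(e, 0.3, "all"), "g2")
    z <- ExprMatrix(matrix(c(0, 2, 0, 0), 2, 2,
                           dimnames = dimnames(m)), "RPKM")
    expect_setequal(expressedGeneSet(z, 0, "any"), "g2")
    set.seed(4)
    r <- ExprMatrix(matrix(rexp(200), 40, 5,
                           dimnames = list(sprintf("g%02d", 1:40),
                                           paste0("s", 1:5))), "RPKM")
    expect_true(all(expressedGeneSet(r, 0.5, "all") %in%
                        expressedGeneSet(r, 0.5, "any")))
    expect_error(expressedGeneSet(ExprMatrix(m, "residual"), 0.3),
                 "RPKM")
})
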