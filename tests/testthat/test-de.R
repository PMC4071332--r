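test_that("design matrices are validated and contrasts resolved", {
    meta <- makeGridMeta()
    set.seed(19)
    meta$rin <- pmin(pmax(meta$rin + rnorm(nrow(meta), 0, 0.3), 1), 10)
    ds <- DesignSpec("time", c("0", "84"), useIndividual = TRUE,
                     rin = "linear")
    X <- designMatrix(ds, meta)
    expect_equal(nrow(X), nrow(meta))
    expect_equal(qr(X)$rank, ncol(X))
    expect_error(designMatrix(DesignSpec("time", c("0", "99")), meta),
                 "absent")
    expect_error(DesignSpec("time", c("0", "84"), useTime = FALSE),
                 "requires useTime")
})

test_that("common dispersion recovers simulation truth", {
    set.seed(20)
    mu <- rep(100, 6)
    pois <- matrix(rpois(1200 * 6, 100), 1200, 6,
                   dimnames = list(sprintf("g%04d", 1:1200),
                                   paste0("s", 1:6)))
    dPois <- estimateCommonDispersion(pois)
    expect_lte(dPois$common, 0.01)

    nb <- matrix(rnbinom(1500 * 6, mu = 100, size = 1 / 0.2), 1500, 6,
                 dimnames = list(sprintf("g%04d", 1:1500),
                                 paste0("s", 1:6)))
    dNb <- estimateCommonDispersion(nb)
    expect_gte(dNb$common, 0.15)
    expect_lte(dNb$common, 0.25)

    one <- matrix(c(5L, 5L), 1, 2,
                  dimnames = list("g1", c("s1", "s2")))
    expect_true(is.finite(estimateCommonDispersion(one)$common))
    zero <- matrix(0L, 2, 2, dimnames = list(c("a", "b"),
                                             c("s1", "s2")))
    expect_error(estimateCommonDispersion(zero), "all-zero")
})

test_that("NB GLM p-values are uniform under the null", {
    set.seed(21)
    n <- 1500
    counts <- matrix(rnbinom(n * 6, mu = 80, size = 1 / 0.05), n, 6,
                     dimnames = list(sprintf("g%04d", 1:n),
                                     paste0("s", 1:6)))
    meta <- data.frame(sample_id = paste0("s", 1:6),
                       individual_id = rep(c("ind1", "ind2"), each = 3),
                       time_h = 0, rin = 9)
    ds <- DesignSpec("individual", c("ind1", "ind2"), useTime = FALSE)
    res <- nbGlmTest(counts, meta, ds, dispersion = 0.05,
                     normFactors = stats::setNames(rep(1, 6),
                                                   colnames(counts)))
    ks <- suppressWarnings(ks.test(res$p_value, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("NB GLM recovers a planted two-fold change", {
    set.seed(22)
    n <- 400
    hit <- 1:40  # a 2-fold change planted in 10% of genes
    mu <- matrix(100, n, 6)
    mu[hit, 4:6] <- 200
    counts <- matrix(rnbinom(n * 6, mu = mu, size = 1 / 0.02), n, 6,
                     dimnames = list(sprintf("g%04d", 1:n),
                                     paste0("s", 1:6)))
    meta <- data.frame(sample_id = paste0("s", 1:6),
                       individual_id = rep(c("ind1", "ind2"), each = 3),
                       time_h = 0, rin = 9)
    ds <- DesignSpec("individual", c("ind1", "ind2"), useTime = FALSE)
    res <- nbGlmTest(counts, meta, ds, dispersion = 0.02)
    expect_equal(mean(res$log2_fold_change[res$gene_id %in%
                                           rownames(counts)[hit]]),
                 1, tolerance = 0.08)
})

test_that("NB GLM matches an exact Poisson-regression oracle as phi -> 0", {
    set.seed(23)
    n <- 60
    counts <- matrix(rpois(n * 6, 40), n, 6,
                     dimnames = list(sprintf("g%03d", 1:n),
                                     paste0("s", 1:6)))
    meta <- data.frame(sample_id = paste0("s", 1:6),
                       individual_id = rep(c("ind1", "ind2"), each = 3),
                       time_h = 0, rin = 9)
    ds <- DesignSpec("individual", c("ind1", "ind2"), useTime = FALSE)
    nf <- stats::setNames(rep(1, 6), colnames(counts))
    res <- nbGlmTest(counts, meta, ds, dispersion = 0, normFactors = nf)
    pOracle <- oraclePoissonLRT(counts[res$gene_id, ],
                                rep(c("a", "b"), each = 3),
                                log(colSums(counts)))
    expect_lt(max(abs(res$p_value - pOracle)), 1e-6)
})

test_that("RIN residualization removes exactly the linear RIN signal", {
    meta <- makeGridMeta()
    rin <- meta$rin
    n <- 50
    set.seed(24)
    base <- rnorm(n, 8, 2)
    slope <- rnorm(n, -0.5, 0.2)
    vLin <- outer(slope, rin) + base
    dimnames(vLin) <- list(sprintf("g%02d", 1:n), meta$sample_id)
    e <- ExprMatrix(vLin, "qnorm-log2count")
    r <- regressOutRin(e, meta)
    expect_equal(exprUnit(r), "residual")
    # perfectly linear input collapses to the gene mean
    expect_equal(r@.Data, matrix(rowMeans(vLin), n, ncol(vLin),
                 dimnames = dimnames(vLin)), tolerance = 1e-10)
    # residuals orthogonal to RIN
    noise <- matrix(rnorm(n * nrow(meta)), n)
    v2 <- vLin + noise
    dimnames(v2) <- dimnames(vLin)
    r2 <- regressOutRin(ExprMatrix(v2, "qnorm-log2count"), meta)
    resid <- r2@.Data - rowMeans(r2@.Data)
    expect_lt(max(abs(resid %*% (rin - mean(rin)))), 1e-9)
    # idempotence
    r3 <- regressOutRin(r2, meta)
    expect_equal(r3@.Data, r2@.Data, tolerance = 1e-10)
    # input orthogonal to RIN passes through unchanged
    rc <- rin - mean(rin)
    orth <- noise - (noise %*% rc) %*% t(rc) / sum(rc^2)
    dimnames(orth) <- dimnames(vLin)
    rOrth <- regressOutRin(ExprMatrix(orth, "qnorm-log2count"), meta)
    expect_equal(rOrth@.Data, orth, tolerance = 1e-10)
    metaConst <- transform(meta, rin = 5)
    expect_error(regressOutRin(e, metaConst), "constant")
})

test_that("residual-based DE finds planted effects and nothing else", {
    meta <- makeGridMeta(inds = c("ind1", "ind2"))
    n <- 300
    set.seed(25)
    v <- matrix(rnorm(n * nrow(meta), 6, 0.3), n, nrow(meta),
                dimnames = list(sprintf("g%03d", 1:n), meta$sample_id))
    # identical profiles between individuals: no calls at any FDR
    vSame <- v
    vSame[, meta$individual_id == "ind2"] <-
        vSame[, meta$individual_id == "ind1"]
    null <- deOnResiduals(ExprMatrix(vSame, "residual"), meta,
                          c("ind1", "ind2"))
    expect_true(all(null$p_value == 1))
    expect_equal(sum(null$q_value < 0.999), 0)
    # planted effect in 10% of genes
    hit <- 1:30
    v2 <- v
    v2[hit, meta$individual_id == "ind2"] <-
        v2[hit, meta$individual_id == "ind2"] + 1.2
    res <- deOnResiduals(ExprMatrix(v2, "residual"), meta,
                         c("ind1", "ind2"))
    called <- which(res$q_value < 0.05)
    expect_gt(mean(hit %in% called), 0.9)        # recall
    fdp <- mean(!(called %in% hit))
    expect_lte(fdp, 0.05 + 3 * sqrt(0.05 * 0.95 / length(called)))
    expect_error(deOnResiduals(ExprMatrix(v, "residual"),
                               meta[-1, ], c("ind1", "ind2")),
                 "mismatch")
})

test_that("shrunken fold changes follow the prior-count formula", {
    counts <- rbind(g1 = c(100L, 50L), g2 = c(0L, 0L),
                    filler = c(900L, 950L))  # equal library sizes
    colnames(counts) <- c("s1", "s2")
    meta <- data.frame(sample_id = c("s1", "s2"),
                       individual_id = c("ind1", "ind2"),
                       time_h = 0, rin = 9)
    ds <- DesignSpec("individual", c("ind2", "ind1"), useTime = FALSE)
    fc <- shrunkenLogFC(counts, meta, ds, priorCount = 0.5)
    expect_equal(unname(fc["g1"]), log2(100.5 / 50.5), tolerance = 1e-6)
    expect_equal(unname(fc["g2"]), 0, tolerance = 1e-9)
    raw <- log2((counts[, 1] / sum(counts[, 1])) /
                (counts[, 2] / sum(counts[, 2])))
    expect_lte(abs(fc["g1"]), abs(raw["g1"]) + 1e-8)
})

test_that("variable-gene ranking and overlap arithmetic", {
    set.seed(26)
    m <- matrix(rnorm(14094 * 4, 5, 1), 14094, 4,
                dimnames = list(sprintf("g%05d", 1:14094),
                                paste0("s", 1:4)))
    e <- ExprMatrix(m, "qnorm-log2count")
    top <- topVariableGenes(e, fraction = 0.10)
    expect_length(top, 1410)
    expect_length(topVariableGenes(e, fraction = 1), 14094)
    m2 <- m[1:50, ]
    m2["g00007", ] <- c(-50, 50, -50, 50)
    top2 <- topVariableGenes(ExprMatrix(m2, "qnorm-log2count"),
                             fraction = 0.02)
    expect_identical(top2[1], "g00007")
    expect_error(topVariableGenes(e, fraction = 0), "fraction")

    expect_equal(deOverlap(c("a", "b"), c("a", "b", "c")), 100)
    expect_equal(deOverlap(c("a", "b"), c("x")), 0)
    expect_equal(deOverlap(sprintf("d%03d", 1:100),
                           sprintf("d%03d", 1:87)), 87)
    expect_error(deOverlap(character(), "a"), "empty")
})
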