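test_that("noise-free exponential data are recovered to machine precision", {
    meta <- makeGridMeta()
    t <- meta$time_h
    v <- matrix(exp(2 - 0.05 * t), 1, nrow(meta),
                dimnames = list("g1", meta$sample_id))
    fit <- fitDecayRates(ExprMatrix(v, "qnorm-RPKM"), meta, minValue = 0)
    expect_equal(fit$slope, -0.05, tolerance = 1e-12)
    expect_equal(fit$b0, 2, tolerance = 1e-12)
    expect_equal(fit$k, 0.05, tolerance = 1e-12)
    expect_true(fit$exact_fit)
    expect_equal(fit$p_value, 0)

    const <- matrix(3, 1, nrow(meta),
                    dimnames = list("g1", meta$sample_id))
    fc <- fitDecayRates(ExprMatrix(const, "qnorm-RPKM"), meta,
                        minValue = 0)
    expect_equal(fc$slope, 0)
    expect_equal(fc$p_value, 1)
})

test_that("decay fits agree with lm() on noisy data", {
    meta <- makeGridMeta()
    set.seed(10)
    v <- matrix(exp(1.5 - 0.02 * meta$time_h +
                    rnorm(nrow(meta), 0, 0.3)), 1, nrow(meta),
                dimnames = list("g1", meta$sample_id))
    fit <- fitDecayRates(ExprMatrix(v, "qnorm-RPKM"), meta, minValue = 0)
    ref <- summary(lm(log(v[1, ]) ~ meta$time_h))$coefficients
    expect_equal(fit$slope, ref[2, 1], tolerance = 1e-12)
    expect_equal(fit$se_slope, ref[2, 2], tolerance = 1e-12)
    expect_equal(fit$p_value, ref[2, 4], tolerance = 1e-12)
})

test_that("the low-expression rule excludes under-observed genes", {
    meta <- makeGridMeta(inds = "ind1")
    v <- matrix(c(0.1, 0.1, 0.1, 0.5, 0.6,   # only 2 usable values
                  1, 1, 1, 1, 1), 2, 5, byrow = TRUE,
                dimnames = list(c("gBad", "gOk"), meta$sample_id))
    fit <- fitDecayRates(ExprMatrix(v, "qnorm-RPKM"), meta,
                         minValue = 0.3)
    expect_identical(fit$gene_id, "gOk")
    expect_identical(S4Vectors::metadata(fit)$excluded, "gBad")
})

test_that("mean fitted slope over a complete quantile-normalized matrix is zero", {
    meta <- makeGridMeta()
    set.seed(77)
    m <- matrix(rlnorm(400 * nrow(meta), 3, 1.4), 400, nrow(meta),
                dimnames = list(sprintf("g%03d", 1:400), meta$sample_id))
    qn <- quantileNormalize(ExprMatrix(m, "RPKM"))
    fit <- fitDecayRates(qn, meta, minValue = 0)
    expect_lt(abs(mean(fit$slope)), 1e-8)
})

test_that("q-values match an independent step-up oracle", {
    expect_equal(computeQvalues(rep(1, 5)), rep(1, 5))
    expect_equal(computeQvalues(0.2), 0.2)  # singleton: pi0 forced to 1
    set.seed(13)
    p <- runif(1000)
    expect_lt(max(abs(computeQvalues(p) - oracleQvalues(p))), 1e-12)
    pMix <- c(rbeta(300, 0.2, 4), runif(700))  # skewed alternative mix
    expect_lt(max(abs(computeQvalues(pMix) - oracleQvalues(pMix))),
              1e-12)
    q <- computeQvalues(p)
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
    expect_true(all(q >= 0 & q <= 1))
    expect_error(computeQvalues(numeric()), "empty")
    expect_error(computeQvalues(c(0.5, 2)), "0, 1")
})

test_that("classification respects the FDR partition and gene order", {
    meta <- makeGridMeta()
    set.seed(5)
    m <- matrix(rlnorm(200 * nrow(meta), 2, 1), 200, nrow(meta),
                dimnames = list(sprintf("g%03d", 1:200), meta$sample_id))
    fit <- fitDecayRates(quantileNormalize(ExprMatrix(m, "RPKM")),
                         meta, minValue = 0)
    cls <- classifyDecay(fit, alpha = 0.05)
    tab <- table(factor(cls$decay_class,
                        c("fast", "average", "slow")))
    expect_equal(sum(tab), nrow(cls))
    expect_true(all(cls$decay_class[cls$q_value >= 0.05] == "average"))
    expect_true(all(cls$slope[cls$decay_class == "fast"] < 0))
    expect_true(all(cls$slope[cls$decay_class == "slow"] > 0))
    expect_error(classifyDecay(fit, alpha = 1.2), "alpha")
    # invariance to gene order
    perm <- sample(nrow(m))
    clsP <- classifyDecay(fitDecayRates(
        quantileNormalize(ExprMatrix(m[perm, ], "RPKM")), meta,
        minValue = 0), alpha = 0.05)
    expect_identical(cls$decay_class[match(clsP$gene_id, cls$gene_id)],
                     clsP$decay_class)
})

test_that("direct classification conventions", {
    df <- S4Vectors::DataFrame(
        gene_id = c("a", "b"), b0 = 0, slope = c(-0.02, -0.02),
        k = c(0.02, 0.02), se_slope = 0.01, n_obs = 15L,
        p_value = c(0.9, 1e-5), q_value = c(0.5, 0.001),
        exact_fit = FALSE, row.names = c("a", "b"))
    cls <- classifyDecay(methods::new("DecayFit", df), alpha = 0.01)
    expect_identical(cls$decay_class, c("average", "fast"))
})

test_that("feature associations detect planted monotone relations", {
    meta <- makeGridMeta()
    set.seed(31)
    n <- 150
    gc <- runif(n, 0.3, 0.7)
    # faster decay (more negative slope) at higher GC, by construction
    k <- 0.001 + 0.1 * (gc - 0.3)
    v <- t(sapply(seq_len(n), function(i)
        exp(3 - k[i] * meta$time_h + rnorm(nrow(meta), 0, 0.01))))
    dimnames(v) <- list(sprintf("g%03d", 1:n), meta$sample_id)
    ann <- data.frame(gene_id = rownames(v), gc_fraction = gc,
                      cds_length = sample(500:3000, n))
    fit <- fitDecayRates(ExprMatrix(v, "qnorm-RPKM"), meta, minValue = 0)
    fa <- featureDecayAssociation(fit, ann, "gc_fraction")
    expect_lt(fa$rho, -0.95)
    expect_lt(fa$p_value, 1e-10)
    # controlling for the feature itself annihilates the association
    fself <- featureDecayAssociation(fit, ann, "gc_fraction",
                                     controlFor = "gc_fraction")
    expect_lt(abs(fself$rho), 1e-8)
    annConst <- transform(ann, gc_fraction = 0.5)
    expect_error(featureDecayAssociation(fit, annConst, "gc_fraction"),
                 "constant")
})

test_that("biotype enrichment matches exact hypergeometric enumeration", {
    mk <- function(tab) {
        n <- sum(tab)
        cls <- rep(c("slow", "slow", "average", "average"),
                   c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
        bio <- rep(c("pseudogene", "protein_coding", "pseudogene",
                     "protein_coding"),
                   c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
        df <- S4Vectors::DataFrame(
            gene_id = sprintf("g%02d", seq_len(n)), b0 = 0, slope = 0.1,
            k = -0.1, se_slope = 0.1, n_obs = 15L, p_value = 0.5,
            q_value = 0.5, exact_fit = FALSE, decay_class = cls,
            row.names = sprintf("g%02d", seq_len(n)))
        list(fits = methods::new("DecayFit", df),
             ann = data.frame(gene_id = df$gene_id, biotype = bio))
    }
    bal <- mk(matrix(c(10, 10, 10, 10), 2, byrow = TRUE))
    resBal <- biotypeEnrichment(bal$fits, bal$ann, "slow", "pseudogene")
    expect_equal(resBal$odds_ratio, 1, tolerance = 1e-6)
    expect_equal(resBal$p_value, 1)

    skew <- mk(matrix(c(8, 2, 1, 5), 2, byrow = TRUE))
    res <- biotypeEnrichment(skew$fits, skew$ann, "slow", "pseudogene")
    expect_equal(res$p_value,
                 oracleFisherP(matrix(c(8, 2, 1, 5), 2, byrow = TRUE)),
                 tolerance = 1e-10)
    expect_gt(res$odds_ratio, 1)
})

test_that("slow-degrader pseudogene enrichment is planted in the generator", {
    cfg <- SimConfig(nGenes = 3000L, seed = 17L)
    tr <- drawGeneParams(cfg)
    tab <- table(tr$decay_class_true == "slow",
                 tr$biotype == "pseudogene")
    or <- (tab["TRUE", "TRUE"] / tab["TRUE", "FALSE"]) /
        (tab["FALSE", "TRUE"] / tab["FALSE", "FALSE"])
    expect_gt(or, 1)
})
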