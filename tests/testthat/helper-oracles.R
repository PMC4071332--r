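# Independent reference implementations used as oracles, plus small
# fixture builders. These deliberately use plain loops and base R so they
# share no code path with the package.

# Sample metadata for a complete individuals x times grid.
makeGridMeta <- function(times = c(0, 12, 24, 48, 84),
                         inds = c("ind1", "ind2", "ind3"),
                         rin = NULL) {
    meta <- expand.grid(individual_id = inds, time_h = times,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta <- meta[order(meta$individual_id, meta$time_h), ]
    meta$sample_id <- sprintf("%s_t%03d", meta$individual_id,
                              meta$time_h)
    meta$rin <- if (is.null(rin))
        stats::approx(c(0, 12, 24, 48, 84), c(9.3, 7.9, 6.4, 5.1, 3.8),
                      xout = meta$time_h, rule = 2)$y
    else rin
    rownames(meta) <- meta$sample_id
    meta
}

# Brute-force TMM: step-by-step re-implementation of the doubly trimmed,
# precision-weighted mean of M-values with upper-quartile reference choice
# and geometric-mean-1 rescaling.
oracleTMMFactors <- function(counts, trimM = 0.3, trimA = 0.05) {
    lib <- colSums(counts)
    uq <- numeric(ncol(counts))
    for (j in seq_len(ncol(counts)))
        uq[j] <- stats::quantile(counts[, j], 0.75) / lib[j]
    ref <- which.min(abs(uq - mean(uq)))
    f <- numeric(ncol(counts))
    for (j in seq_len(ncol(counts))) {
        obs <- counts[, j]; nO <- lib[j]
        rf <- counts[, ref]; nR <- lib[ref]
        M <- log2((obs / nO) / (rf / nR))
        A <- (log2(obs / nO) + log2(rf / nR)) / 2
        w <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
        fin <- is.finite(M) & is.finite(A)
        M <- M[fin]; A <- A[fin]; w <- w[fin]
        if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
        n <- length(M)
        loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
        loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
        keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
        f[j] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
    }
    f / exp(mean(log(f)))
}

# Loop-based Storey q-values: BH step-up bound scaled by the smoother pi0.
oracleQvalues <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
    m <- length(p)
    pi0l <- numeric(length(lambda))
    for (i in seq_along(lambda))
        pi0l[i] <- sum(p > lambda[i]) / (m * (1 - lambda[i]))
    pi0 <- stats::predict(stats::smooth.spline(lambda, pi0l, df = 3),
                          x = max(lambda))$y
    pi0 <- min(max(pi0, 1 / m), 1)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
        val <- min(pi0 * m * p[o[i]] / i, prev, 1)
        q[o[i]] <- val
        prev <- val
    }
    q
}

# Exact Poisson-regression LRT p-values via stats::glm, one gene at a time.
oraclePoissonLRT <- function(counts, group, offset) {
    vapply(seq_len(nrow(counts)), function(i) {
        d <- data.frame(y = counts[i, ], g = group, off = offset)
        f1 <- stats::glm(y ~ g + offset(off), family = stats::poisson,
                         data = d)
        f0 <- stats::glm(y ~ 1 + offset(off), family = stats::poisson,
                         data = d)
        stats::pchisq(f0$deviance - f1$deviance, df = 1,
                      lower.tail = FALSE)
    }, numeric(1))
}

# Exhaustive bucket assignment for presence/absence over a detection
# pattern matrix detAllByTime / detAnyByTime (genes x times, logical).
oraclePresenceBuckets <- function(detAll, detAny) {
    nt <- ncol(detAll)
    bucket <- rep("intermittent", nrow(detAll))
    for (g in seq_len(nrow(detAll))) {
        if (!any(detAny[g, ])) { bucket[g] <- "never"; next }
        for (ti in seq_len(nt)) {
            if (all(detAll[g, 1:ti]) &&
                (ti == nt || !any(detAny[g, (ti + 1):nt]))) {
                bucket[g] <- paste0("seenUntil_", ti)
                break
            }
            if (ti > 1 && all(detAll[g, ti:nt]) &&
                !any(detAny[g, 1:(ti - 1)])) {
                bucket[g] <- paste0("unseenBefore_", ti)
                break
            }
        }
    }
    bucket
}

# Two-sided Fisher exact p by explicit enumeration of hypergeometric
# tables with the observed margins.
oracleFisherP <- function(tab) {
    a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    support <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- stats::dhyper(support, c1, n - c1, r1)
    pObs <- stats::dhyper(a, c1, n - c1, r1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}
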