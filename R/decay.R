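#' @include AllClasses.R utils.R
NULL

#' Per-gene decay rates from a degradation time course
#'
#' Fits the log-linear form of first-order decay,
#' `ln y(t) = b0 + slope * t + eps`, to each gene by ordinary least squares,
#' pooling every library of every individual as an observation. Because the
#' input is quantile-normalized, the genome-wide mean rate is absorbed into
#' the shared value distribution and the fitted slope measures decay
#' *relative to the mean rate*: the decay constant is `k = -slope`, negative
#' slopes mark faster-than-average degraders and positive slopes slower
#' ones, and the mean slope over a complete matrix is 0. Observations below
#' `minValue` (unreliable low-expression measurements) are discarded
#' per gene; genes retaining fewer than 3 observations (or no spread in the
#' covariate) are excluded from the tested set and listed in
#' `metadata()$excluded`. The two-sided p-value tests `slope = 0` against a
#' t distribution with `n_obs - 2` df; Storey q-values are attached with
#' [computeQvalues()]. A noise-free collinear fit is reported with
#' `se_slope = 0`, `p_value` 0 (or 1 when the slope is also 0) and
#' `exact_fit = TRUE`.
#'
#' As a robustness option the regression covariate can be the sample RIN
#' instead of time; because the appropriate orientation of RIN is a matter
#' of convention, both are available (`"raw"` regresses on RIN as measured,
#' `"negated"` on minus RIN so that the slope sign convention matches the
#' time fit).
#'
#' @param expr an [ExprMatrix-class], by default quantile-normalized RPKM
#'   (linear scale; the natural log is taken internally).
#' @param meta per-sample data.frame with `sample_id`, `time_h`, `rin`.
#' @param minValue discard observations below this value (default 0.3).
#' @param covariate `"time"` (hours) or `"rin"`.
#' @param rinOrientation `"raw"` or `"negated"`, used when
#'   `covariate = "rin"`.
#' @param allowedUnits acceptable unit tags of `expr`.
#' @return A [DecayFit-class] with columns `gene_id`, `b0`, `slope`, `k`,
#'   `se_slope`, `n_obs`, `p_value`, `q_value`, `exact_fit`.
#' @examples
#' t <- rep(c(0, 12, 24, 48, 84), 3)
#' v <- matrix(exp(2 - 0.05 * t), 1, 15,
#'             dimnames = list("g1", paste0("s", 1:15)))
#' meta <- data.frame(sample_id = paste0("s", 1:15), individual_id = "i",
#'                    time_h = t, rin = 9)
#' fit <- fitDecayRates(ExprMatrix(v, "qnorm-RPKM"), meta, minValue = 0)
#' fit$slope  # -0.05
#' @export
fitDecayRates <- function(expr, meta, minValue = 0.3,
                          covariate = c("time", "rin"),
                          rinOrientation = c("raw", "negated"),
                          allowedUnits = c("qnorm-RPKM", "RPKM")) {
    covariate <- match.arg(covariate)
    rinOrientation <- match.arg(rinOrientation)
    if (!methods::is(expr, "ExprMatrix") ||
        !exprUnit(expr) %in% allowedUnits)
        stop("fitDecayRates expects an ExprMatrix with unit in: ",
             paste(allowedUnits, collapse = ", "))
    .assertSampleMeta(meta, colnames(expr))
    meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
    x <- switch(covariate,
        time = meta$time_h,
        rin = if (rinOrientation == "negated") -meta$rin else meta$rin)
    v <- .baseMatrix(expr)
    genes <- rownames(v)
    res <- vector("list", length(genes))
    excluded <- character()
    for (g in seq_along(genes)) {
        vg <- v[g, ]
        keep <- is.finite(vg) & vg > 0 & vg >= minValue
        n <- sum(keep)
        if (n < 3L || stats::var(x[keep]) == 0) {
            excluded <- c(excluded, genes[g])
            next
        }
        xi <- x[keep]; yi <- log(vg[keep])
        xm <- mean(xi); ym <- mean(yi)
        sxx <- sum((xi - xm)^2)
        slope <- sum((xi - xm) * (yi - ym)) / sxx
        b0 <- ym - slope * xm
        ssr <- sum((yi - b0 - slope * xi)^2)
        exact <- ssr <= 1e-12 * max(1, sum(yi^2))
        if (exact) {
            se <- 0
            p <- if (abs(slope) <= 1e-12) 1 else 0
        } else {
            se <- sqrt(ssr / (n - 2) / sxx)
            p <- 2 * stats::pt(-abs(slope / se), df = n - 2)
        }
        res[[g]] <- list(genes[g], b0, slope, se, n, p, exact)
    }
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res))
        stop("no gene retained at least 3 usable observations")
    out <- DataFrame(
        gene_id = vapply(res, `[[`, character(1), 1L),
        b0 = vapply(res, `[[`, numeric(1), 2L),
        slope = vapply(res, `[[`, numeric(1), 3L),
        se_slope = vapply(res, `[[`, numeric(1), 4L),
        n_obs = vapply(res, function(r) as.integer(r[[5L]]), integer(1)),
        p_value = vapply(res, `[[`, numeric(1), 6L),
        exact_fit = vapply(res, `[[`, logical(1), 7L))
    out$k <- -out$slope
    out$q_value <- computeQvalues(out$p_value)
    rownames(out) <- out$gene_id
    out <- out[, c("gene_id", "b0", "slope", "k", "se_slope", "n_obs",
                   "p_value", "q_value", "exact_fit")]
    fit <- methods::new("DecayFit", out)
    metadata(fit) <- list(excluded = excluded, covariate = covariate,
                          minValue = minValue, nTested = nrow(out))
    fit
}

#' Storey q-values
#'
#' Converts p-values into q-values (the minimum FDR at which each test is
#' called significant). The null proportion pi0 is estimated on the lambda
#' grid `mean(p > lambda) / (1 - lambda)` and smoothed with a cubic
#' smoothing spline (df = 3), taking the smoothed value at the largest
#' lambda; it is clamped to `[1/m, 1]` for stability (a single p-value
#' therefore gets `q = p`). q-values are monotone non-decreasing in p and
#' never exceed 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param lambda tuning grid for the pi0 estimate.
#' @return Numeric vector of q-values, same order as `p`.
#' @examples
#' computeQvalues(c(1, 1, 1))  # all 1
#' @export
computeQvalues <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
    if (length(p) == 0L) stop("empty p-value vector")
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1] with no NA")
    m <- length(p)
    if (m == 1L || length(lambda) < 4L) {
        pi0 <- 1
    } else {
        pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l),
                       numeric(1))
        sp <- stats::smooth.spline(lambda, pi0l, df = 3)
        pi0 <- stats::predict(sp, x = max(lambda))$y
        pi0 <- min(max(pi0, 1 / m), 1)
    }
    o <- order(p, decreasing = TRUE)
    qs <- pmin(pi0 * m * p[o] / (m:1), 1)
    q <- numeric(m)
    q[o] <- cummin(qs)
    q
}

#' Classify genes as fast, average or slow degraders
#'
#' Partitions fitted genes at FDR level `alpha`: `fast` (q < alpha, slope
#' < 0: degraded significantly faster than the mean rate), `slow` (q <
#' alpha, slope > 0) and `average` (q >= alpha).
#'
#' @param fits a [DecayFit-class] with q-values.
#' @param alpha FDR level in (0, 1); default 0.01.
#' @return The fits with a `decay_class` column and `alpha` recorded in
#'   `metadata()`.
#' @examples
#' # see fitDecayRates(); classifyDecay(fit) adds decay_class
#' @export
classifyDecay <- function(fits, alpha = 0.01) {
    if (!methods::is(fits, "DecayFit")) stop("fits must be a DecayFit")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    if (is.null(fits$q_value)) stop("q-values missing; run computeQvalues")
    cls <- rep("average", nrow(fits))
    cls[fits$q_value < alpha & fits$slope < 0] <- "fast"
    cls[fits$q_value < alpha & fits$slope > 0] <- "slow"
    # column appends must happen on the parent class: a validity-checked
    # subclass cannot represent the intermediate single-column object
    df <- methods::as(fits, "DFrame")
    df$decay_class <- cls
    out <- methods::new("DecayFit", df)
    metadata(out) <- c(metadata(fits), list(alpha = alpha))
    out
}

#' Association between decay rate and a transcript feature
#'
#' Spearman correlation between the fitted slope and a per-gene feature
#' (e.g. `gc_fraction`, `cds_length`, `utr3_length`). With `controlFor`,
#' reports the partial Spearman correlation: the Pearson correlation of the
#' residuals after regressing the ranks of both variables on the ranks of
#' the controlled covariate.
#'
#' @param fits a [DecayFit-class].
#' @param annotation data.frame/`DataFrame` with `gene_id` and the feature
#'   column(s).
#' @param feature feature column name.
#' @param controlFor optional second feature to control for.
#' @return One-row `DataFrame`: `feature`, `rho`, `p_value`, `partial`,
#'   `control`.
#' @export
featureDecayAssociation <- function(fits, annotation, feature,
                                    controlFor = NULL) {
    ann <- as.data.frame(annotation)
    if (!feature %in% colnames(ann))
        stop("annotation lacks feature column: ", feature)
    idx <- match(fits$gene_id, ann$gene_id)
    f <- ann[[feature]][idx]
    s <- fits$slope
    ok <- is.finite(f) & is.finite(s)
    if (!is.null(controlFor)) {
        if (!controlFor %in% colnames(ann))
            stop("annotation lacks control column: ", controlFor)
        cvar <- ann[[controlFor]][idx]
        ok <- ok & is.finite(cvar)
    }
    if (sum(ok) < 10L)
        stop("feature present for fewer than 10 fitted genes")
    f <- f[ok]; s <- s[ok]
    if (stats::var(f) == 0)
        stop("feature '", feature, "' is constant: correlation undefined")
    if (is.null(controlFor)) {
        ct <- stats::cor.test(s, f, method = "spearman", exact = FALSE)
        rho <- unname(ct$estimate); p <- ct$p.value
        partial <- FALSE; control <- NA_character_
    } else {
        cvar <- ann[[controlFor]][idx][ok]
        rs <- rank(s); rf <- rank(f); rc <- rank(cvar)
        e1 <- stats::resid(stats::lm(rs ~ rc))
        e2 <- stats::resid(stats::lm(rf ~ rc))
        if (stats::var(e2) <= 1e-12 * max(stats::var(rf), 1)) {
            rho <- 0; p <- 1  # control absorbs the feature entirely
        } else {
            ct <- stats::cor.test(e1, e2)
            rho <- unname(ct$estimate); p <- ct$p.value
        }
        partial <- TRUE; control <- controlFor
    }
    DataFrame(feature = feature, rho = rho, p_value = p,
              partial = partial, control = control)
}

#' Biotype enrichment within a decay class
#'
#' Fisher's exact test (two-sided) on the 2x2 table of (gene in
#' `classLabel` vs not) against (gene of `biotypeLabel` vs not).
#'
#' @param fits a classified [DecayFit-class] (see [classifyDecay()]).
#' @param annotation data.frame/`DataFrame` with `gene_id` and `biotype`.
#' @param classLabel decay class tested, e.g. `"slow"`.
#' @param biotypeLabel biotype tested, e.g. `"pseudogene"`.
#' @return One-row `DataFrame`: `decay_class`, `biotype`, `odds_ratio`
#'   (conditional MLE), `p_value`; the 2x2 table is attached as
#'   `metadata()$table`.
#' @export
biotypeEnrichment <- function(fits, annotation, classLabel = "slow",
                              biotypeLabel = "pseudogene") {
    if (is.null(fits$decay_class))
        stop("fits lack decay_class; run classifyDecay first")
    ann <- as.data.frame(annotation)
    if (!"biotype" %in% colnames(ann))
        stop("annotation lacks a biotype column")
    bt <- ann$biotype[match(fits$gene_id, ann$gene_id)]
    ok <- !is.na(bt)
    inClass <- factor(fits$decay_class[ok] == classLabel,
                      levels = c(TRUE, FALSE))
    inBio <- factor(bt[ok] == biotypeLabel, levels = c(TRUE, FALSE))
    tab <- table(inClass, inBio)
    if (any(rowSums(tab) == 0))
        stop("empty margin: decay class '", classLabel,
             "' is all-or-none in the data")
    if (any(colSums(tab) == 0))
        stop("empty margin: biotype '", biotypeLabel,
             "' is all-or-none in the data")
    ft <- stats::fisher.test(tab)
    out <- DataFrame(decay_class = classLabel, biotype = biotypeLabel,
                     odds_ratio = unname(ft$estimate),
                     p_value = ft$p.value)
    metadata(out)$table <- tab
    out
}
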