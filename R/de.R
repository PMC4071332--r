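#' @include AllClasses.R utils.R decay.R normalize.R
NULL

#' Model matrix for a design specification
#'
#' @param design a [DesignSpec-class].
#' @param meta per-sample data.frame with `sample_id`, `individual_id`,
#'   `time_h`, `rin`, ordered as the count/expression columns.
#' @return Numeric model matrix (samples x coefficients), full rank.
#' @export
designMatrix <- function(design, meta) {
    validObject(design)
    .assertSampleMeta(meta)
    df <- data.frame(row.names = meta$sample_id)
    if (design@useIndividual)
        df$individual <- factor(meta$individual_id)
    if (design@useTime)
        df$time <- factor(meta$time_h,
                          levels = sort(unique(meta$time_h)))
    if (design@rin == "linear") df$rin <- meta$rin
    if (design@rin == "bins")
        df$rin <- cut(meta$rin, breaks = design@rinBins)
    X <- if (ncol(df)) stats::model.matrix(~ ., data = df)
        else matrix(1, nrow(meta), 1,
                    dimnames = list(meta$sample_id, "(Intercept)"))
    if (qr(X)$rank < ncol(X))
        stop("design matrix is not full rank (collinear covariates)")
    lv <- design@contrastLevels
    have <- if (design@contrastType == "time")
        as.character(sort(unique(meta$time_h))) else
        unique(meta$individual_id)
    if (!all(lv %in% have))
        stop("contrast level(s) absent from the design: ",
             paste(setdiff(lv, have), collapse = ", "))
    X
}

# Numeric contrast vector (level 2 minus level 1) on designMatrix columns.
.contrastVector <- function(design, X) {
    var <- if (design@contrastType == "time") "time" else "individual"
    cv <- stats::setNames(numeric(ncol(X)), colnames(X))
    for (sgn in c(-1, 1)) {
        lvl <- design@contrastLevels[(sgn + 3) / 2]
        col <- paste0(var, lvl)
        if (col %in% names(cv)) cv[col] <- cv[col] + sgn
        # baseline level contributes nothing (absorbed by the intercept)
    }
    if (all(cv == 0))
        stop("degenerate contrast: the two levels are identical")
    cv
}

#' Common negative-binomial dispersion for a count matrix
#'
#' Estimates a single dispersion phi shared by all genes by maximizing the
#' Cox-Reid adjusted profile likelihood under the given design
#' (`edgeR::estimateGLMCommonDisp`); optionally adds per-gene dispersions
#' shrunk towards the common value by empirical Bayes
#' (`edgeR::estimateGLMTagwiseDisp`). `phi = 0` (the Poisson limit) is
#' admissible.
#'
#' @param counts genes x samples integer matrix.
#' @param meta per-sample metadata (needed when `design` is a
#'   [DesignSpec-class]).
#' @param design a [DesignSpec-class] or a prebuilt model matrix; `NULL`
#'   uses an intercept-only design.
#' @param tagwise also return per-gene shrunken dispersions.
#' @return List with `common` (scalar phi >= 0) and `tagwise` (per-gene
#'   vector or `NULL`).
#' @export
estimateCommonDispersion <- function(counts, meta = NULL, design = NULL,
                                     tagwise = FALSE) {
    .assertCountMatrix(counts)
    if (sum(counts) == 0) stop("all-zero count matrix")
    X <- if (is.null(design))
        matrix(1, ncol(counts), 1)
    else if (methods::is(design, "DesignSpec"))
        designMatrix(design, meta)
    else as.matrix(design)
    off <- log(colSums(counts))
    common <- edgeR::estimateGLMCommonDisp(counts, design = X,
                                           offset = off)
    if (is.na(common)) common <- 0
    tw <- if (tagwise)
        edgeR::estimateGLMTagwiseDisp(counts, design = X, offset = off,
                                      dispersion = common)
    else NULL
    list(common = common, tagwise = tw)
}

#' Negative-binomial GLM differential-expression test
#'
#' Fits a per-gene NB log-link GLM (`edgeR::glmFit`) with offsets
#' `log(library size x TMM factor)` under the covariates declared in
#' `design`, and tests the declared contrast by likelihood ratio
#' (`edgeR::glmLRT`). Including RIN in the design (the `glm+rin` strategy)
#' is controlled solely by the [DesignSpec-class]. Genes are prefiltered to
#' those with at least `minCount` reads in every library (the complete-
#' observation rule); FDR is controlled with Storey q-values by default, or
#' Benjamini-Hochberg on request.
#'
#' @param counts genes x samples integer matrix.
#' @param meta per-sample metadata.
#' @param design a [DesignSpec-class].
#' @param normFactors optional TMM factors (computed via [tmmFactors()]
#'   when `NULL`).
#' @param dispersion optional dispersion (scalar or per-gene); estimated
#'   via [estimateCommonDispersion()] when `NULL`.
#' @param minCount prefilter: minimum reads required in every library
#'   (default 1; 0 disables).
#' @param fdrMethod `"qvalue"` or `"BH"`.
#' @return A [DEResult-class]; `metadata()` records strategy, contrast,
#'   dispersion and any non-converged genes (their p-values are `NA`).
#' @export
nbGlmTest <- function(counts, meta, design, normFactors = NULL,
                      dispersion = NULL, minCount = 1L,
                      fdrMethod = c("qvalue", "BH")) {
    fdrMethod <- match.arg(fdrMethod)
    .assertCountMatrix(counts)
    .assertSampleMeta(meta, colnames(counts))
    meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
    if (minCount > 0)
        counts <- counts[rowSums(counts >= minCount) == ncol(counts), ,
                         drop = FALSE]
    if (nrow(counts) == 0L)
        stop("no gene passes the minimum-count prefilter")
    X <- designMatrix(design, meta)
    cv <- .contrastVector(design, X)
    if (is.null(normFactors)) normFactors <- tmmFactors(counts)
    offset <- log(colSums(counts) * normFactors[colnames(counts)])
    if (is.null(dispersion))
        dispersion <- estimateCommonDispersion(counts, meta, X)$common
    fit <- edgeR::glmFit(counts, design = X, dispersion = dispersion,
                         offset = offset)
    lrt <- edgeR::glmLRT(fit, contrast = cv)
    tab <- lrt$table
    p <- tab$PValue
    failed <- if (!is.null(fit$failed)) which(fit$failed) else integer()
    if (length(failed)) p[failed] <- NA_real_
    okp <- !is.na(p)
    q <- rep(NA_real_, length(p))
    q[okp] <- if (fdrMethod == "qvalue") computeQvalues(p[okp])
        else stats::p.adjust(p[okp], "BH")
    strategy <- if (design@rin == "none") "glm" else "glm+rin"
    out <- DataFrame(gene_id = rownames(counts),
                     log2_fold_change = tab$logFC,
                     statistic = tab$LR,
                     p_value = p, q_value = q,
                     row.names = rownames(counts))
    metadata(out) <- list(
        strategy = strategy,
        contrast = paste(design@contrastType,
                         design@contrastLevels[2L], "vs",
                         design@contrastLevels[1L]),
        dispersion = dispersion,
        nonconverged = rownames(counts)[failed],
        fdrMethod = fdrMethod)
    methods::new("DEResult", out)
}

#' Remove the linear RIN contribution from each gene's expression
#'
#' Per gene, fits ordinary least squares of (log-scale) expression on RIN
#' with an intercept and returns the residuals plus the gene mean, so
#' expression levels are preserved while everything linearly attributable
#' to RNA quality is removed. Residuals are exactly uncorrelated with RIN.
#' The operation is idempotent.
#'
#' @param expr an [ExprMatrix-class] on a log scale (e.g. quantile-
#'   normalized log2 counts).
#' @param meta per-sample metadata with a non-constant `rin` column.
#' @return An [ExprMatrix-class] with unit `"residual"`.
#' @export
regressOutRin <- function(expr, meta) {
    if (!methods::is(expr, "ExprMatrix"))
        stop("expr must be an ExprMatrix")
    .assertSampleMeta(meta, colnames(expr))
    meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
    if (stats::var(meta$rin) == 0)
        stop("RIN is constant across samples: nothing to regress out")
    v <- .baseMatrix(expr)
    X <- cbind(1, meta$rin)
    B <- solve(crossprod(X), crossprod(X, t(v)))
    resid <- t(t(v) - X %*% B)
    ExprMatrix(resid + rowMeans(v), "residual")
}

#' Linear-model differential expression on RIN-residualized values
#'
#' Per gene, a Gaussian linear model of residual expression on the grouping
#' factor, tested with a two-sided equal-variance t test of the declared
#' pair of groups (individuals by default, time points on request).
#'
#' @param expr an [ExprMatrix-class] with unit `"residual"` (see
#'   [regressOutRin()]).
#' @param meta per-sample metadata.
#' @param contrast length-2 vector of group labels (second minus first).
#' @param type group by `"individual"` or `"time"`.
#' @param fdrMethod `"qvalue"` or `"BH"`.
#' @return A [DEResult-class] with strategy `"residual"`.
#' @export
deOnResiduals <- function(expr, meta, contrast,
                          type = c("individual", "time"),
                          fdrMethod = c("qvalue", "BH")) {
    type <- match.arg(type)
    fdrMethod <- match.arg(fdrMethod)
    if (!methods::is(expr, "ExprMatrix") || exprUnit(expr) != "residual")
        stop("deOnResiduals expects an ExprMatrix with unit 'residual'")
    .assertSampleMeta(meta, colnames(expr))
    meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
    grp <- if (type == "individual") meta$individual_id
        else as.character(meta$time_h)
    sa <- which(grp == as.character(contrast[1L]))
    sb <- which(grp == as.character(contrast[2L]))
    if (length(sa) < 2L || length(sb) < 2L)
        stop("each contrasted group needs at least 2 samples")
    v <- .baseMatrix(expr)
    va <- v[, sa, drop = FALSE]; vb <- v[, sb, drop = FALSE]
    na <- length(sa); nb <- length(sb)
    ma <- rowMeans(va); mb <- rowMeans(vb)
    ss <- rowSums((va - ma)^2) + rowSums((vb - mb)^2)
    df <- na + nb - 2
    se <- sqrt(ss / df * (1 / na + 1 / nb))
    d <- mb - ma
    tstat <- ifelse(se > 0, d / se, ifelse(d == 0, 0, Inf * sign(d)))
    p <- 2 * stats::pt(-abs(tstat), df = df)
    q <- if (fdrMethod == "qvalue") computeQvalues(p)
        else stats::p.adjust(p, "BH")
    out <- DataFrame(gene_id = rownames(v),
                     log2_fold_change = d, statistic = tstat,
                     p_value = p, q_value = q, row.names = rownames(v))
    metadata(out) <- list(
        strategy = "residual",
        contrast = paste(type, contrast[2L], "vs", contrast[1L]),
        fdrMethod = fdrMethod)
    methods::new("DEResult", out)
}

#' Shrunken (variance-stabilized) log2 fold changes
#'
#' Predictive log2 fold changes via `edgeR::predFC`: a prior count scaled
#' by relative library size is added to every cell before fitting, which
#' shrinks fold changes of weakly covered genes towards 0 while leaving
#' well-covered genes essentially untouched.
#'
#' @param counts genes x samples integer matrix.
#' @param meta per-sample metadata.
#' @param design a [DesignSpec-class] naming the contrast.
#' @param priorCount prior count (> 0), default 0.5.
#' @param dispersion NB dispersion used in the stabilizing fit (default 0).
#' @return Named numeric vector of per-gene shrunken log2 fold changes for
#'   the design's contrast.
#' @export
shrunkenLogFC <- function(counts, meta, design, priorCount = 0.5,
                          dispersion = 0) {
    .assertCountMatrix(counts)
    if (priorCount <= 0) stop("priorCount must be > 0")
    .assertSampleMeta(meta, colnames(counts))
    meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
    X <- designMatrix(design, meta)
    cv <- .contrastVector(design, X)
    cf <- edgeR::predFC(counts, design = X, prior.count = priorCount,
                        offset = log(colSums(counts)),
                        dispersion = dispersion)
    stats::setNames(as.numeric(cf %*% cv), rownames(counts))
}

#' Most variable genes across a sample subset
#'
#' Ranks genes by expression variance across the given samples and returns
#' the top fraction (ties broken deterministically by gene id).
#'
#' @param expr an [ExprMatrix-class].
#' @param samples sample ids to use (default: all).
#' @param fraction proportion of genes to return, in (0, 1\].
#' @return Character vector of `ceiling(fraction * nGenes)` gene ids,
#'   most variable first.
#' @export
topVariableGenes <- function(expr, samples = colnames(expr),
                             fraction = 0.10) {
    if (fraction <= 0 || fraction > 1)
        stop("fraction must lie in (0, 1]")
    if (length(samples) < 2L)
        stop("need at least 2 samples to rank variance")
    v <- .baseMatrix(expr)[, samples, drop = FALSE]
    vars <- apply(v, 1, stats::var)
    ord <- order(-vars, rownames(v))
    rownames(v)[ord][seq_len(ceiling(fraction * nrow(v)))]
}

#' Percent overlap of a DE gene set with a reference set
#'
#' @param deGenes non-empty character vector of DE gene ids.
#' @param referenceGenes character vector (e.g. top variable genes).
#' @return `100 * |de intersect reference| / |de|`.
#' @examples
#' deOverlap(c("a", "b"), c("b", "c"))  # 50
#' @export
deOverlap <- function(deGenes, referenceGenes) {
    if (length(deGenes) == 0L)
        stop("overlap undefined for an empty DE set")
    100 * length(intersect(deGenes, referenceGenes)) / length(deGenes)
}

#' Compare DE strategies across contrasts
#'
#' Runs the three degradation-handling strategies over the requested
#' contrasts and tabulates, for each, the number of genes called at the
#' given FDR and the percent overlap with the most variable genes across
#' individuals at the earliest time point. Time contrasts use a model with
#' individual + time (naive) or individual + time + linear RIN; individual
#' contrasts treat every library of an individual as a replicate (naive:
#' individual only; RIN-aware: individual + linear RIN). The residual
#' strategy tests group differences on RIN-residualized expression.
#'
#' @param counts genes x samples integer matrix.
#' @param meta per-sample metadata.
#' @param exprLog log-scale [ExprMatrix-class] used for the residual
#'   strategy and the variable-gene reference (e.g. quantile-normalized
#'   log2 counts).
#' @param timeContrasts list of length-2 time-point vectors.
#' @param indivContrasts list of length-2 individual-id vectors.
#' @param fdr FDR threshold for calling genes (default 0.05).
#' @param varFraction fraction for the variable-gene reference set.
#' @param fdrMethod `"qvalue"` or `"BH"`.
#' @return List: `summary` (data.frame strategy x contrast x n_de x
#'   overlap_pct), `results` (named list of [DEResult-class]),
#'   `referenceGenes` (the variable-gene set).
#' @export
deStrategySummary <- function(counts, meta, exprLog,
                              timeContrasts = list(),
                              indivContrasts = list(),
                              fdr = 0.05, varFraction = 0.10,
                              fdrMethod = c("qvalue", "BH")) {
    fdrMethod <- match.arg(fdrMethod)
    .assertCountMatrix(counts)
    .assertSampleMeta(meta, colnames(counts))
    meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
    t0 <- min(meta$time_h)
    refGenes <- topVariableGenes(exprLog,
        samples = meta$sample_id[meta$time_h == t0],
        fraction = varFraction)
    resid <- regressOutRin(exprLog, meta)
    results <- list()
    rows <- list()
    addRow <- function(res, label) {
        called <- res$gene_id[!is.na(res$q_value) & res$q_value < fdr]
        ov <- if (length(called)) deOverlap(called, refGenes) else NA_real_
        results[[label]] <<- res
        rows[[label]] <<- data.frame(
            strategy = metadata(res)$strategy,
            contrast = metadata(res)$contrast,
            n_de = length(called), overlap_pct = ov,
            stringsAsFactors = FALSE)
    }
    for (tc in timeContrasts) {
        lv <- as.character(tc)
        for (rin in c("none", "linear")) {
            ds <- DesignSpec("time", lv, useIndividual = TRUE, rin = rin)
            res <- nbGlmTest(counts, meta, ds, fdrMethod = fdrMethod)
            addRow(res, paste0("time_", lv[1L], "v", lv[2L], "_",
                               if (rin == "none") "glm" else "glm+rin"))
        }
        addRow(deOnResiduals(resid, meta, lv, type = "time",
                             fdrMethod = fdrMethod),
               paste0("time_", lv[1L], "v", lv[2L], "_residual"))
    }
    for (ic in indivContrasts) {
        lv <- as.character(ic)
        for (rin in c("none", "linear")) {
            ds <- DesignSpec("individual", lv, useTime = FALSE,
                             useIndividual = TRUE, rin = rin)
            res <- nbGlmTest(counts, meta, ds, fdrMethod = fdrMethod)
            addRow(res, paste0("indiv_", lv[1L], "v", lv[2L], "_",
                               if (rin == "none") "glm" else "glm+rin"))
        }
        addRow(deOnResiduals(resid, meta, lv, type = "individual",
                             fdrMethod = fdrMethod),
               paste0("indiv_", lv[1L], "v", lv[2L], "_residual"))
    }
    list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
         results = results, referenceGenes = refGenes)
}
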