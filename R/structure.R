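#' @include AllClasses.R utils.R
NULL

#' Principal components of an expression matrix
#'
#' PCA with samples as observations and genes as variables, on the centered
#' (optionally unit-scaled) matrix. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is positive.
#' Zero-variance genes are dropped when scaling.
#'
#' @param expr an [ExprMatrix-class] (log-scale values recommended).
#' @param center,scale passed to the decomposition (default center only).
#' @param nComponents number of components to keep (`NULL` = all; more
#'   than the matrix rank is an error).
#' @return A [PCAResult-class].
#' @export
pcaExpression <- function(expr, center = TRUE, scale = FALSE,
                          nComponents = NULL) {
    v <- .baseMatrix(expr)
    if (ncol(v) < 2L) stop("PCA needs at least 2 samples")
    if (scale) {
        keep <- apply(v, 1, stats::var) > 0
        v <- v[keep, , drop = FALSE]
    }
    pr <- stats::prcomp(t(v), center = center, scale. = scale)
    tot <- sum(pr$sdev^2)
    ve <- if (tot > 0) pr$sdev^2 / tot else rep(0, length(pr$sdev))
    rank <- sum(pr$sdev > max(pr$sdev) * 1e-12)
    if (!is.null(nComponents)) {
        if (nComponents > rank)
            stop("requested ", nComponents, " components but the matrix ",
                 "rank is ", rank)
        idx <- seq_len(nComponents)
    } else idx <- seq_along(pr$sdev)
    scores <- pr$x[, idx, drop = FALSE]
    load <- pr$rotation[, idx, drop = FALSE]
    for (j in seq_len(ncol(load))) {
        i <- which.max(abs(load[, j]))
        if (load[i, j] < 0) {
            load[, j] <- -load[, j]
            scores[, j] <- -scores[, j]
        }
    }
    methods::new("PCAResult", scores = scores, loadings = load,
                 varExplained = ve[idx])
}

#' Association between principal components and a sample covariate
#'
#' Each component's scores are regressed on the covariate: a linear model
#' F test for continuous covariates, one-way ANOVA for categorical ones.
#'
#' @param pca a [PCAResult-class].
#' @param meta per-sample metadata (rows matched to score rownames via
#'   `sample_id`).
#' @param covariate metadata column name (e.g. `"rin"`, `"time_h"`,
#'   `"individual_id"`).
#' @return Named numeric vector: one p-value per component.
#' @export
pcCovariateAssociation <- function(pca, meta, covariate) {
    if (!covariate %in% colnames(meta))
        stop("metadata lacks covariate column: ", covariate)
    idx <- match(rownames(pca@scores), meta$sample_id)
    if (any(is.na(idx)))
        stop("metadata is missing sample(s): ",
             paste(rownames(pca@scores)[is.na(idx)], collapse = ", "))
    cov <- meta[[covariate]][idx]
    if (length(unique(cov)) < 2L)
        stop("covariate '", covariate, "' is constant across samples")
    vapply(seq_len(ncol(pca@scores)), function(j) {
        sc <- pca@scores[, j]
        if (is.numeric(cov)) {
            fit <- stats::lm(sc ~ cov)
            fs <- summary(fit)$fstatistic
            if (is.null(fs)) return(NA_real_)
            stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)
        } else {
            stats::anova(stats::aov(sc ~ factor(cov)))[["Pr(>F)"]][1L]
        }
    }, numeric(1)) -> p
    stats::setNames(p, colnames(pca@scores))
}

#' Spearman correlation matrix of samples with clustering order
#'
#' Pairwise Spearman correlations over the (optionally subset) genes,
#' with an average-linkage hierarchical clustering on the distance
#' `1 - rho` to order the samples for heatmap display.
#'
#' @param expr an [ExprMatrix-class].
#' @param geneSubset optional gene ids to restrict to.
#' @return List: `rho` (symmetric sample x sample matrix, unit diagonal),
#'   `order` (sample ids in dendrogram order), `hclust` (the tree).
#' @export
spearmanSampleMatrix <- function(expr, geneSubset = NULL) {
    v <- .baseMatrix(expr)
    if (ncol(v) < 2L) stop("need at least 2 samples")
    if (!is.null(geneSubset)) {
        miss <- setdiff(geneSubset, rownames(v))
        if (length(miss))
            stop("gene subset not in matrix: ",
                 paste(utils::head(miss, 5), collapse = ", "))
        v <- v[geneSubset, , drop = FALSE]
    }
    novar <- apply(v, 2, stats::var) == 0
    if (any(novar))
        stop("sample(s) with zero expression variance: ",
             paste(colnames(v)[novar], collapse = ", "))
    rho <- stats::cor(v, method = "spearman")
    hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
    list(rho = rho, order = colnames(v)[hc$order], hclust = hc)
}

#' Library-complexity metrics along a degradation time course
#'
#' Per-sample mean and median RPKM and the number of detected genes
#' (RPKM >= threshold), aggregated per time point, with a linear-model
#' association of each metric against RIN. Degraded libraries concentrate
#' their reads on slowly decaying genes, producing an excess of low-RPKM
#' genes (median down) alongside a few very high values (mean up) and a
#' falling detected-gene count.
#'
#' @param expr an [ExprMatrix-class] with unit `"RPKM"` or `"qnorm-RPKM"`.
#' @param meta per-sample metadata.
#' @param threshold detection threshold (default 0.3).
#' @return List: `perSample`, `perTime` (aggregated means) and
#'   `association` (slope and p of each metric on RIN).
#' @export
complexityMetrics <- function(expr, meta, threshold = 0.3) {
    if (!methods::is(expr, "ExprMatrix") ||
        !exprUnit(expr) %in% c("RPKM", "qnorm-RPKM"))
        stop("complexityMetrics expects an RPKM-unit ExprMatrix")
    v <- .baseMatrix(expr)
    if (nrow(v) == 0L || ncol(v) == 0L) stop("empty expression matrix")
    .assertSampleMeta(meta, colnames(v))
    meta <- meta[match(colnames(v), meta$sample_id), , drop = FALSE]
    perSample <- data.frame(
        sample_id = meta$sample_id,
        individual_id = meta$individual_id,
        time_h = meta$time_h,
        rin = meta$rin,
        mean_rpkm = colMeans(v),
        median_rpkm = apply(v, 2, stats::median),
        n_detected = colSums(v >= threshold & v > 0),
        row.names = NULL)
    perTime <- do.call(rbind, lapply(split(perSample, perSample$time_h),
        function(d) data.frame(time_h = d$time_h[1L],
                               mean_rin = mean(d$rin),
                               mean_rpkm = mean(d$mean_rpkm),
                               median_rpkm = mean(d$median_rpkm),
                               n_detected = mean(d$n_detected))))
    rownames(perTime) <- NULL
    association <- do.call(rbind, lapply(
        c("mean_rpkm", "median_rpkm", "n_detected"), function(m) {
            fit <- stats::lm(perSample[[m]] ~ perSample$rin)
            co <- summary(fit)$coefficients
            data.frame(metric = m, slope_vs_rin = co[2L, 1L],
                       p_value = co[2L, 4L])
        }))
    list(perSample = perSample, perTime = perTime,
         association = association)
}

#' Gene presence/absence buckets over a time course
#'
#' Classifies genes by their detection pattern (RPKM >= threshold in a
#' sample) across a complete individual x time grid. A gene is *seen until*
#' time T when it is detected in **every** individual at every time point
#' up to and including T and in **no** individual afterwards; it is
#' *unseen before* T when detected in every individual from T onward and in
#' none earlier. Genes with intermittent patterns (detected, absent,
#' detected again, or partial detection across individuals) fall in neither
#' bucket and are reported separately. Mean RPKM is computed over the
#' samples at the time points where the bucket deems the gene present.
#'
#' @param expr an [ExprMatrix-class] with unit `"RPKM"` or `"qnorm-RPKM"`.
#' @param meta per-sample metadata covering every individual at every time
#'   point.
#' @param threshold detection threshold (default 0.3).
#' @return List: `table` (per time point: bucket sizes and mean RPKM when
#'   seen), `seenUntil` / `unseenBefore` (named lists of gene ids),
#'   `intermittent` and `neverDetected` (gene id vectors).
#' @export
presenceAbsenceTable <- function(expr, meta, threshold = 0.3) {
    if (!methods::is(expr, "ExprMatrix") ||
        !exprUnit(expr) %in% c("RPKM", "qnorm-RPKM"))
        stop("presenceAbsenceTable expects an RPKM-unit ExprMatrix")
    v <- .baseMatrix(expr)
    .assertSampleMeta(meta, colnames(v))
    meta <- meta[match(colnames(v), meta$sample_id), , drop = FALSE]
    times <- sort(unique(meta$time_h))
    inds <- unique(meta$individual_id)
    grid <- table(meta$individual_id, meta$time_h)
    if (any(grid == 0))
        stop("incomplete design: every individual needs a sample at ",
             "every time point")
    det <- v >= threshold & v > 0
    # per gene x time: detected in all / any individuals at that time
    detAll <- detAny <- matrix(NA, nrow(v), length(times),
                               dimnames = list(rownames(v), times))
    for (ti in seq_along(times)) {
        cols <- meta$sample_id[meta$time_h == times[ti]]
        detAll[, ti] <- rowSums(det[, cols, drop = FALSE]) ==
            length(cols)
        detAny[, ti] <- rowSums(det[, cols, drop = FALSE]) > 0
    }
    nt <- length(times)
    seenUntil <- unseenBefore <- stats::setNames(
        vector("list", nt), as.character(times))
    meanSeen <- function(genes, tIdx) {
        if (!length(genes)) return(NA_real_)
        cols <- meta$sample_id[meta$time_h %in% times[tIdx]]
        mean(v[genes, cols, drop = FALSE])
    }
    tab <- data.frame(time_h = times, n_seen_until = 0L,
                      mean_rpkm_seen_until = NA_real_,
                      n_unseen_before = NA_integer_,
                      mean_rpkm_unseen_before = NA_real_)
    for (ti in seq_len(nt)) {
        pre <- seq_len(ti); post <- setdiff(seq_len(nt), pre)
        su <- rownames(v)[rowSums(detAll[, pre, drop = FALSE]) == ti &
            (length(post) == 0L |
             rowSums(detAny[, post, drop = FALSE]) == 0)]
        seenUntil[[ti]] <- su
        tab$n_seen_until[ti] <- length(su)
        tab$mean_rpkm_seen_until[ti] <- meanSeen(su, pre)
        if (ti > 1L) {
            from <- ti:nt; before <- seq_len(ti - 1L)
            ub <- rownames(v)[
                rowSums(detAll[, from, drop = FALSE]) == length(from) &
                rowSums(detAny[, before, drop = FALSE]) == 0]
            unseenBefore[[ti]] <- ub
            tab$n_unseen_before[ti] <- length(ub)
            tab$mean_rpkm_unseen_before[ti] <- meanSeen(ub, from)
        }
    }
    bucketed <- c(unlist(seenUntil), unlist(unseenBefore))
    everAny <- rownames(v)[rowSums(detAny) > 0]
    list(table = tab, seenUntil = seenUntil,
         unseenBefore = unseenBefore,
         intermittent = setdiff(everAny, bucketed),
         neverDetected = rownames(v)[rowSums(detAny) == 0])
}
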