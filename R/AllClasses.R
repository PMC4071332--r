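#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Simulation configuration for a degradation time course
#'
#' Holds every parameter of the ground-truth generator: experiment layout
#' (genes, individuals, time points), the decay-rate mixture (fractions and
#' per-hour rate magnitudes of fast and slow degraders around a reference
#' rate), baseline abundance distribution, per-individual expression effects,
#' sequencing depth and negative-binomial dispersion, the exogenous spike-in
#' mass fraction, and the RIN calibration (piecewise-linear anchors plus
#' sample-level jitter).
#'
#' @slot nGenes number of genes.
#' @slot nIndividuals number of individuals; each contributes one library per
#'   time point.
#' @slot timePointsH strictly increasing sampling times in hours.
#' @slot fracFast,fracSlow expected proportions of fast and slow degraders.
#' @slot kReference reference (average-class) decay rate, per hour.
#' @slot kFastMean,kSlowMean mean magnitude of the rate excess of fast genes /
#'   rate deficit of slow genes, per hour.
#' @slot kClassShape gamma shape controlling within-class spread of the fast
#'   and slow rate offsets (larger = tighter around the class mean).
#' @slot baselineLogMean,baselineLogSd natural-log mean and sd of baseline
#'   transcript abundance (arbitrary mass units).
#' @slot indivEffectSd natural-log sd of per-individual expression effects.
#' @slot indivEffectFrac fraction of genes carrying individual effects.
#' @slot nbDispersion negative-binomial dispersion phi (>= 0; 0 = Poisson).
#' @slot readsPerLibrary expected sequencing depth per library.
#' @slot spikeMassFraction proportion of the initial (0 h) transcript mass
#'   that is exogenous spike-in; the spike mass itself never decays.
#' @slot rinAnchorTimes,rinAnchorValues piecewise-linear RIN calibration
#'   (time in hours -> expected RIN).
#' @slot rinNoiseSd sd of sample-level RIN jitter around the calibration.
#' @slot seed integer seed; all randomness derives from it.
#'
#' @seealso [SimConfig()] for the constructor with documented defaults.
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        nGenes = "integer",
        nIndividuals = "integer",
        timePointsH = "numeric",
        fracFast = "numeric",
        fracSlow = "numeric",
        kReference = "numeric",
        kFastMean = "numeric",
        kSlowMean = "numeric",
        kClassShape = "numeric",
        baselineLogMean = "numeric",
        baselineLogSd = "numeric",
        indivEffectSd = "numeric",
        indivEffectFrac = "numeric",
        nbDispersion = "numeric",
        readsPerLibrary = "numeric",
        spikeMassFraction = "numeric",
        rinAnchorTimes = "numeric",
        rinAnchorValues = "numeric",
        rinNoiseSd = "numeric",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
    if (length(object@timePointsH) < 1L ||
        any(diff(object@timePointsH) <= 0))
        msg <- c(msg, "timePointsH must be strictly increasing")
    if (object@fracFast < 0 || object@fracSlow < 0 ||
        object@fracFast + object@fracSlow > 1)
        msg <- c(msg, "fracFast and fracSlow must be >= 0 with sum <= 1")
    if (object@kReference < 0) msg <- c(msg, "kReference must be >= 0")
    if (object@kFastMean < 0 || object@kSlowMean < 0)
        msg <- c(msg, "kFastMean and kSlowMean must be >= 0")
    if (object@kClassShape <= 0) msg <- c(msg, "kClassShape must be > 0")
    if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
    if (object@readsPerLibrary <= 0)
        msg <- c(msg, "readsPerLibrary must be > 0")
    if (object@spikeMassFraction <= 0 || object@spikeMassFraction >= 1)
        msg <- c(msg, "spikeMassFraction must lie in (0, 1)")
    if (length(object@rinAnchorTimes) == 0L)
        msg <- c(msg, "rinAnchorTimes must be non-empty")
    if (length(object@rinAnchorTimes) != length(object@rinAnchorValues))
        msg <- c(msg, "rinAnchorTimes and rinAnchorValues lengths differ")
    if (any(object@rinAnchorValues < 1) || any(object@rinAnchorValues > 10))
        msg <- c(msg, "rinAnchorValues must lie in [1, 10]")
    if (length(object@rinAnchorTimes) > 1L &&
        any(diff(object@rinAnchorTimes) <= 0))
        msg <- c(msg, "rinAnchorTimes must be strictly increasing")
    if (object@rinNoiseSd < 0) msg <- c(msg, "rinNoiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe a degradation time course patterned on an ex vivo PBMC
#' experiment: three individuals sampled at 0, 12, 24, 48 and 84 hours, mean
#' RIN declining from 9.3 to 3.8 along published per-time-point anchors
#' (the 48 h anchor of 5.1 is an interpolation, not an observed mean), a 1%
#' constant-mass spike-in, and a 15%/15%/70% fast/slow/average decay-rate
#' mixture around a reference rate of 0.03/h. Average-class genes sit exactly
#' at the reference rate; fast and slow offsets are gamma-distributed around
#' their class means. See the methods vignette for the reasoning behind each
#' default.
#'
#' @param nGenes,nIndividuals,timePointsH experiment layout.
#' @param fracFast,fracSlow class proportions.
#' @param kReference,kFastMean,kSlowMean,kClassShape decay-rate mixture
#'   (per hour).
#' @param baselineLogMean,baselineLogSd baseline log-abundance distribution.
#' @param indivEffectSd,indivEffectFrac individual-effect scale and the
#'   fraction of genes carrying one.
#' @param nbDispersion negative-binomial dispersion (0 = Poisson).
#' @param readsPerLibrary expected library depth.
#' @param spikeMassFraction initial spike-in mass fraction.
#' @param rinAnchorTimes,rinAnchorValues RIN calibration anchors.
#' @param rinNoiseSd sample-level RIN jitter sd.
#' @param seed integer seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(nGenes = 500, seed = 7L)
#' cfg
#' @export
SimConfig <- function(nGenes = 2000L,
                      nIndividuals = 3L,
                      timePointsH = c(0, 12, 24, 48, 84),
                      fracFast = 0.15,
                      fracSlow = 0.15,
                      kReference = 0.03,
                      kFastMean = 0.05,
                      kSlowMean = 0.02,
                      kClassShape = 8,
                      baselineLogMean = log(50),
                      baselineLogSd = 1.5,
                      indivEffectSd = 0.6,
                      indivEffectFrac = 0.10,
                      nbDispersion = 0.01,
                      readsPerLibrary = 2e6,
                      spikeMassFraction = 0.01,
                      rinAnchorTimes = c(0, 12, 24, 48, 84),
                      rinAnchorValues = c(9.3, 7.9, 6.4, 5.1, 3.8),
                      rinNoiseSd = 0.25,
                      seed = 1L) {
    new("SimConfig",
        nGenes = as.integer(nGenes),
        nIndividuals = as.integer(nIndividuals),
        timePointsH = as.numeric(timePointsH),
        fracFast = fracFast, fracSlow = fracSlow,
        kReference = kReference, kFastMean = kFastMean,
        kSlowMean = kSlowMean, kClassShape = kClassShape,
        baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
        indivEffectSd = indivEffectSd, indivEffectFrac = indivEffectFrac,
        nbDispersion = nbDispersion,
        readsPerLibrary = as.numeric(readsPerLibrary),
        spikeMassFraction = spikeMassFraction,
        rinAnchorTimes = as.numeric(rinAnchorTimes),
        rinAnchorValues = as.numeric(rinAnchorValues),
        rinNoiseSd = rinNoiseSd,
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes x", object@nIndividuals,
        "individuals x", length(object@timePointsH), "time points\n")
    cat("  time (h):", paste(object@timePointsH, collapse = ", "), "\n")
    cat("  decay: reference", object@kReference, "/h; fast",
        sprintf("%.0f%%", 100 * object@fracFast), "(+", object@kFastMean,
        "/h), slow", sprintf("%.0f%%", 100 * object@fracSlow), "(-",
        object@kSlowMean, "/h)\n")
    cat("  depth:", format(object@readsPerLibrary, big.mark = ","),
        "reads; NB dispersion", object@nbDispersion, "; spike",
        sprintf("%.1f%%", 100 * object@spikeMassFraction), "\n")
    cat("  RIN anchors:", paste(sprintf("%g h=%g", object@rinAnchorTimes,
        object@rinAnchorValues), collapse = ", "),
        "; jitter sd", object@rinNoiseSd, "\n")
    cat("  seed:", object@seed, "\n")
})

#' Simulated degradation experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one `counts`
#' assay (genes x libraries), the full per-gene ground truth in `rowData`
#' (true decay rate, class, baseline, synthetic annotation), per-sample
#' metadata and spike-in bookkeeping in `colData`, and the generating
#' [SimConfig-class] plus the individual-effect matrix in `metadata`.
#'
#' @seealso [simulateDegradation()], [groundTruth()], [sampleMeta()],
#'   [spikeCounts()], [simConfig()]
#' @exportClass DegradationExperiment
setClass("DegradationExperiment", contains = "SummarizedExperiment")

#' Expression matrix with an explicit unit tag
#'
#' A numeric genes x samples matrix whose measurement unit is carried as a
#' class attribute and propagated (or rewritten) by every transform.
#' Recognized units: `"RPKM"`, `"log2count"`, `"qnorm-RPKM"`,
#' `"qnorm-log2count"`, `"residual"`.
#'
#' @slot unit single character unit tag.
#' @seealso [ExprMatrix()], [exprUnit()]
#' @exportClass ExprMatrix
setClass("ExprMatrix", contains = "matrix",
    representation(unit = "character"))

.exprUnits <- c("RPKM", "log2count", "qnorm-RPKM", "qnorm-log2count",
                "residual")

setValidity("ExprMatrix", function(object) {
    msg <- character()
    if (length(object@unit) != 1L || is.na(object@unit))
        msg <- c(msg, "unit must be a single non-NA string")
    else if (!object@unit %in% .exprUnits)
        msg <- c(msg, paste0("unit must be one of: ",
                             paste(.exprUnits, collapse = ", ")))
    if (object@unit %in% c("RPKM", "qnorm-RPKM") &&
        any(object@.Data < 0, na.rm = TRUE))
        msg <- c(msg, "RPKM-unit values must be >= 0")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene (row) and sample (column) names are required")
    if (length(msg)) msg else TRUE
})

#' Construct a unit-tagged expression matrix
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param unit unit tag, one of `"RPKM"`, `"log2count"`, `"qnorm-RPKM"`,
#'   `"qnorm-log2count"`, `"residual"`.
#' @return An [ExprMatrix-class].
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExprMatrix(m, "RPKM")
#' @export
ExprMatrix <- function(values, unit) {
    new("ExprMatrix", as.matrix(values), unit = unit)
}

#' @describeIn ExprMatrix-class subsetting preserves the unit tag.
#' @param x,i,j,...,drop matrix subsetting arguments.
#' @export
setMethod("[", "ExprMatrix", function(x, i, j, ..., drop = FALSE) {
    ExprMatrix(callNextMethod(x@.Data, i, j, ..., drop = FALSE), x@unit)
})

setMethod("show", "ExprMatrix", function(object) {
    cat("ExprMatrix:", nrow(object), "genes x", ncol(object),
        "samples [unit:", object@unit, "]\n")
    n <- min(5L, nrow(object)); m <- min(5L, ncol(object))
    print(object@.Data[seq_len(n), seq_len(m), drop = FALSE])
    if (nrow(object) > n || ncol(object) > m) cat("...\n")
})

#' Per-gene decay-rate fits
#'
#' A `DataFrame` subclass with one row per tested gene: intercept `b0` and
#' `slope` of the log-linear decay fit (natural-log scale, per hour; the
#' decay constant `k = -slope`), slope standard error, observation count,
#' p- and q-values, and after [classifyDecay()] a `decay_class` column
#' (`fast`/`average`/`slow`). `metadata()` records the fitting options and,
#' once classified, the FDR level `alpha`. Genes excluded by the minimum-
#' observation rule are listed in `metadata()$excluded`.
#'
#' @seealso [fitDecayRates()], [classifyDecay()]
#' @exportClass DecayFit
setClass("DecayFit", contains = "DFrame")

setValidity("DecayFit", function(object) {
    need <- c("gene_id", "b0", "slope", "k", "se_slope", "n_obs", "p_value")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(paste("missing columns:", paste(miss, collapse = ", ")))
    p <- object$p_value
    if (any(p < 0 | p > 1, na.rm = TRUE))
        return("p_value outside [0, 1]")
    if (any(object$n_obs < 3L))
        return("fits require n_obs >= 3")
    TRUE
})

#' Differential-expression results for one contrast under one strategy
#'
#' A `DataFrame` subclass with one row per tested gene: `gene_id`,
#' `log2_fold_change`, test `statistic`, `p_value` and `q_value`.
#' `metadata()` carries the `strategy` (`"glm"`, `"glm+rin"` or
#' `"residual"`) and the human-readable `contrast` label.
#'
#' @seealso [nbGlmTest()], [deOnResiduals()]
#' @exportClass DEResult
setClass("DEResult", contains = "DFrame")

setValidity("DEResult", function(object) {
    need <- c("gene_id", "log2_fold_change", "statistic", "p_value",
              "q_value")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(paste("missing columns:", paste(miss, collapse = ", ")))
    ok <- function(v) all(v >= 0 & v <= 1, na.rm = TRUE)
    if (!ok(object$p_value) || !ok(object$q_value))
        return("p_value/q_value outside [0, 1]")
    st <- metadata(object)$strategy
    if (is.null(st) || !st %in% c("glm", "glm+rin", "residual"))
        return("metadata()$strategy must be glm, glm+rin or residual")
    TRUE
})

#' Design specification for differential-expression models
#'
#' Declares which covariates enter the per-gene model and which contrast is
#' tested. Time enters as a categorical factor (each time point its own
#' level); the individual enters as a categorical factor; RIN optionally
#' enters as a single linear continuous covariate or as categorical bins.
#'
#' @slot useTime,useIndividual logical; include the factor.
#' @slot rin `"none"`, `"linear"` or `"bins"`.
#' @slot rinBins number of equal-width RIN bins when `rin = "bins"`.
#' @slot contrastType `"time"` or `"individual"`.
#' @slot contrastLevels length-2 character vector: the contrast is
#'   level 2 minus level 1.
#' @seealso [DesignSpec()], [designMatrix()]
#' @exportClass DesignSpec
setClass("DesignSpec",
    representation(useTime = "logical", useIndividual = "logical",
                   rin = "character", rinBins = "integer",
                   contrastType = "character",
                   contrastLevels = "character"))

setValidity("DesignSpec", function(object) {
    msg <- character()
    if (!object@rin %in% c("none", "linear", "bins"))
        msg <- c(msg, "rin must be none, linear or bins")
    if (!object@contrastType %in% c("time", "individual"))
        msg <- c(msg, "contrastType must be time or individual")
    if (length(object@contrastLevels) != 2L)
        msg <- c(msg, "contrastLevels must have length 2")
    if (object@contrastType == "time" && !object@useTime)
        msg <- c(msg, "a time contrast requires useTime = TRUE")
    if (object@contrastType == "individual" && !object@useIndividual)
        msg <- c(msg, "an individual contrast requires useIndividual = TRUE")
    if (object@rin == "bins" && object@rinBins < 2L)
        msg <- c(msg, "rinBins must be >= 2")
    if (length(msg)) msg else TRUE
})

#' Construct a design specification
#'
#' @param contrastType `"time"` or `"individual"`.
#' @param contrastLevels the two levels compared (second minus first), e.g.
#'   `c("0", "84")` or `c("ind1", "ind3")`.
#' @param useTime,useIndividual include the categorical factor.
#' @param rin `"none"`, `"linear"` (single continuous covariate) or
#'   `"bins"` (categorical).
#' @param rinBins number of bins when `rin = "bins"`.
#' @return A [DesignSpec-class].
#' @examples
#' DesignSpec("time", c("0", "84"), useIndividual = TRUE, rin = "linear")
#' @export
DesignSpec <- function(contrastType, contrastLevels,
                       useTime = contrastType == "time",
                       useIndividual = TRUE,
                       rin = "none", rinBins = 4L) {
    new("DesignSpec", useTime = useTime, useIndividual = useIndividual,
        rin = rin, rinBins = as.integer(rinBins),
        contrastType = contrastType,
        contrastLevels = as.character(contrastLevels))
}

setMethod("show", "DesignSpec", function(object) {
    covs <- c(if (object@useTime) "time", if (object@useIndividual)
        "individual", if (object@rin != "none") paste0("rin(", object@rin,
        ")"))
    cat("DesignSpec: ~", paste(covs, collapse = " + "), "\n")
    cat("  contrast:", object@contrastType, "=",
        object@contrastLevels[2L], "vs", object@contrastLevels[1L], "\n")
})

#' Principal-component analysis of an expression matrix
#'
#' @slot scores samples x components score matrix.
#' @slot loadings genes x components loading matrix.
#' @slot varExplained fraction of variance per component (non-increasing).
#' @seealso [pcaExpression()], [pcCovariateAssociation()]
#' @exportClass PCAResult
setClass("PCAResult",
    representation(scores = "matrix", loadings = "matrix",
                   varExplained = "numeric"))

setValidity("PCAResult", function(object) {
    v <- object@varExplained
    if (any(diff(v) > 1e-8)) return("varExplained must be non-increasing")
    if (sum(v) > 1 + 1e-8) return("varExplained sums to more than 1")
    if (ncol(object@scores) != length(v))
        return("scores/varExplained dimension mismatch")
    TRUE
})

setMethod("show", "PCAResult", function(object) {
    k <- min(5L, length(object@varExplained))
    cat("PCAResult:", nrow(object@scores), "samples,",
        length(object@varExplained), "components\n")
    cat("  variance explained:",
        paste(sprintf("PC%d=%.1f%%", seq_len(k),
                      100 * object@varExplained[seq_len(k)]),
              collapse = ", "), if (length(object@varExplained) > k) "...",
        "\n")
})
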