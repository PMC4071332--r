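#' @include AllClasses.R
NULL

#' Accessors for simulated degradation experiments
#'
#' `simConfig()` returns the generating [SimConfig-class]; `groundTruth()`
#' the per-gene truth table (decay rate, class, baseline, synthetic
#' annotation) as a `DataFrame`; `sampleMeta()` the per-sample metadata
#' (individual, time, RIN, library size) as a `data.frame`; `spikeCounts()`
#' the per-library spike-in read counts; `individualEffects()` the genes x
#' individuals matrix of true natural-log expression effects.
#'
#' @param x a [DegradationExperiment-class].
#' @return See individual descriptions.
#' @examples
#' sim <- simulateDegradation(SimConfig(nGenes = 100, seed = 1L))
#' head(sampleMeta(sim))
#' spikeCounts(sim)
#' @name degradation-accessors
NULL

#' @rdname degradation-accessors
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))

#' @rdname degradation-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname degradation-accessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname degradation-accessors
#' @export
setGeneric("spikeCounts", function(x) standardGeneric("spikeCounts"))

#' @rdname degradation-accessors
#' @export
setGeneric("individualEffects",
    function(x) standardGeneric("individualEffects"))

#' @rdname degradation-accessors
#' @export
setMethod("simConfig", "DegradationExperiment",
    function(x) metadata(x)$config)

#' @rdname degradation-accessors
#' @export
setMethod("groundTruth", "DegradationExperiment",
    function(x) rowData(x))

#' @rdname degradation-accessors
#' @export
setMethod("sampleMeta", "DegradationExperiment",
    function(x) as.data.frame(colData(x)))

#' @rdname degradation-accessors
#' @export
setMethod("spikeCounts", "DegradationExperiment",
    function(x) stats::setNames(colData(x)$spike_count, colnames(x)))

#' @rdname degradation-accessors
#' @export
setMethod("individualEffects", "DegradationExperiment",
    function(x) metadata(x)$individualEffects)

#' Unit tag of an expression matrix
#'
#' @param x an [ExprMatrix-class].
#' @return Single character unit tag.
#' @examples
#' m <- matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' exprUnit(ExprMatrix(m, "RPKM"))
#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))

#' @rdname exprUnit
#' @export
setMethod("exprUnit", "ExprMatrix", function(x) x@unit)
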