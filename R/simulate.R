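#' @include AllClasses.R utils.R
NULL

#' RIN trajectory along a degradation time course
#'
#' Expected RIN at each time is the piecewise-linear interpolation of the
#' configured anchors (extrapolation beyond the anchor range is clamped to
#' the terminal anchor values); sample-level jitter of sd `rinNoiseSd` is
#' added and the result is clamped to the instrument range \[1, 10\].
#'
#' @param timesH numeric vector of times in hours, one per sample.
#' @param config a [SimConfig-class] supplying anchors and jitter sd.
#' @param seed integer seed for the jitter (default: the config seed).
#' @return Numeric vector of RIN values in \[1, 10\].
#' @examples
#' cfg <- SimConfig(rinNoiseSd = 0)
#' rinTrajectory(c(0, 84), cfg)  # 9.3 and 3.8
#' @export
rinTrajectory <- function(timesH, config, seed = config@seed) {
    validObject(config)
    if (length(config@rinAnchorTimes) == 0L)
        stop("RIN anchor list is empty")
    expected <- if (length(config@rinAnchorTimes) == 1L)
        rep(config@rinAnchorValues, length(timesH))
    else
        stats::approx(config@rinAnchorTimes, config@rinAnchorValues,
                      xout = timesH, rule = 2)$y
    noise <- if (config@rinNoiseSd > 0)
        withSeed(seed, stats::rnorm(length(timesH), 0, config@rinNoiseSd))
    else rep(0, length(timesH))
    pmin(pmax(expected + noise, 1), 10)
}

#' Effective degradation age implied by a RIN value
#'
#' The simulator treats RIN as a direct readout of how degraded a sample is:
#' the effective degradation age is linear in RIN, scaled so that the full
#' anchor RIN range maps onto the full anchor time range (with the default
#' anchors, RIN 9.3 maps to 0 h and RIN 3.8 to 84 h). A sample whose RIN sits
#' slightly above the 0 h anchor gets a slightly negative age, i.e. it is
#' marginally fresher than the nominal 0 h state.
#'
#' @param rin numeric RIN values.
#' @param config a [SimConfig-class].
#' @return Effective degradation age in hours (same length as `rin`).
#' @examples
#' cfg <- SimConfig()
#' degradationAge(c(9.3, 3.8), cfg)  # 0 and 84
#' @export
degradationAge <- function(rin, config) {
    dv <- config@rinAnchorValues[1L] -
        config@rinAnchorValues[length(config@rinAnchorValues)]
    dt <- config@rinAnchorTimes[length(config@rinAnchorTimes)] -
        config@rinAnchorTimes[1L]
    if (dv <= 0 || dt <= 0)
        return(rep(0, length(rin)))  # flat calibration: no degradation axis
    (config@rinAnchorValues[1L] - rin) * dt / dv
}

#' Draw per-gene ground-truth parameters
#'
#' Assigns each gene a decay class (fast/average/slow) by the configured
#' proportions, a decay rate `k` (per hour) equal to the reference rate plus
#' a gamma-distributed class offset (average-class genes sit exactly at the
#' reference rate; slow offsets are truncated so `k >= 0`), a log-normal
#' baseline abundance, and synthetic transcript annotation whose features
#' covary with the decay class: fast degraders have longer CDS and 3'UTRs
#' and higher GC content, while pseudogenes are enriched among slow
#' degraders.
#'
#' @param config a [SimConfig-class].
#' @param seed integer seed (default: the config seed).
#' @return A `DataFrame` with one row per gene: `gene_id`,
#'   `decay_class_true`, `k` (1/h), `k_rel` (offset from the reference
#'   rate), `expected_slope` (`-k_rel`, the noise-free relative log-slope),
#'   `baseline`, annotation columns (`collapsed_length`, `gc_fraction`,
#'   `cds_length`, `utr5_length`, `utr3_length`,
#'   `total_transcript_length`, `biotype`) and `indiv_de` (whether the gene
#'   carries individual effects).
#' @examples
#' truth <- drawGeneParams(SimConfig(nGenes = 10, seed = 3L))
#' table(truth$decay_class_true)
#' @export
drawGeneParams <- function(config, seed = config@seed) {
    validObject(config)
    n <- config@nGenes
    withSeed(seed, {
        cls <- sample(c("fast", "slow", "average"), n, replace = TRUE,
                      prob = c(config@fracFast, config@fracSlow,
                               1 - config@fracFast - config@fracSlow))
        delta <- numeric(n)
        nf <- sum(cls == "fast"); ns <- sum(cls == "slow")
        sh <- config@kClassShape
        if (nf && config@kFastMean > 0)
            delta[cls == "fast"] <- stats::rgamma(nf, shape = sh,
                rate = sh / config@kFastMean)
        if (ns && config@kSlowMean > 0)
            delta[cls == "slow"] <- -pmin(stats::rgamma(ns, shape = sh,
                rate = sh / config@kSlowMean), config@kReference)
        k <- config@kReference + delta
        baseline <- stats::rlnorm(n, config@baselineLogMean,
                                  config@baselineLogSd)

        # synthetic annotation; class-linked means emulate the empirical
        # association of long CDS/3'UTR and high GC with fast decay, and of
        # pseudogenes with slow decay
        cdsMean <- c(fast = log(1800), average = log(1100), slow = log(800))
        u3Mean <- c(fast = log(900), average = log(550), slow = log(400))
        gcMean <- c(fast = 0.49, average = 0.45, slow = 0.43)
        pPseudo <- c(fast = 0.01, average = 0.04, slow = 0.12)
        utr5 <- pmax(round(stats::rlnorm(n, log(150), 0.4)), 30)
        cds <- pmax(round(stats::rlnorm(n, cdsMean[cls], 0.5)), 90)
        utr3 <- pmax(round(stats::rlnorm(n, u3Mean[cls], 0.6)), 30)
        gc <- stats::rbeta(n, gcMean[cls] * 60, (1 - gcMean[cls]) * 60)
        u <- stats::runif(n)
        biotype <- ifelse(u < pPseudo[cls], "pseudogene",
                          ifelse(u < pPseudo[cls] + 0.05, "lincRNA",
                                 "protein_coding"))
        total <- utr5 + cds + utr3
        DataFrame(
            gene_id = sprintf("gene%05d", seq_len(n)),
            decay_class_true = cls,
            k = k, k_rel = delta, expected_slope = -delta,
            baseline = baseline,
            collapsed_length = as.integer(total),
            gc_fraction = gc,
            cds_length = as.integer(cds),
            utr5_length = as.integer(utr5),
            utr3_length = as.integer(utr3),
            total_transcript_length = as.integer(total),
            biotype = biotype,
            indiv_de = stats::runif(n) < config@indivEffectFrac,
            row.names = sprintf("gene%05d", seq_len(n)))
    })
}

#' Proportion of library mass that is exogenous spike-in
#'
#' @param endogenousMass,spikeMass non-negative masses (vectorized; each
#'   pair must not be both zero).
#' @return `spikeMass / (spikeMass + endogenousMass)`.
#' @examples
#' spikeFraction(99, 1)  # 0.01
#' @export
spikeFraction <- function(endogenousMass, spikeMass) {
    if (any(endogenousMass < 0) || any(spikeMass < 0))
        stop("masses must be >= 0")
    tot <- endogenousMass + spikeMass
    if (any(tot == 0))
        stop("spike fraction undefined when both masses are zero")
    spikeMass / tot
}

#' Simulate read counts for a degradation time course
#'
#' For each library, the expected endogenous mass of gene g is
#' `baseline_g * exp(individual effect) * exp(-k_g * tau)`, where `tau` is
#' the effective degradation age implied by the library's RIN (see
#' [degradationAge()]). The exogenous spike-in mass is the configured
#' fraction of that individual's initial (0 h) endogenous mass and is
#' constant over the time course. Reads are allocated to genes and the
#' spike-in proportionally to mass, with negative-binomial noise of
#' dispersion `nbDispersion` (Poisson when 0), so each library totals
#' `readsPerLibrary` up to sampling noise. Per-library random streams are
#' derived independently from `seed`, making the counts of one library
#' independent of how many others are generated.
#'
#' @param truth per-gene ground truth from [drawGeneParams()].
#' @param meta per-sample data.frame with `sample_id`, `individual_id`,
#'   `time_h` and `rin`.
#' @param config a [SimConfig-class].
#' @param seed integer seed (default: the config seed).
#' @param individualEffects optional genes x individuals matrix of
#'   natural-log expression effects (default: none).
#' @return A list with `counts` (integer genes x samples matrix) and
#'   `spike` (integer spike-in count per sample).
#' @examples
#' cfg <- SimConfig(nGenes = 50, seed = 2L)
#' truth <- drawGeneParams(cfg)
#' meta <- data.frame(sample_id = c("a", "b"), individual_id = "ind1",
#'                    time_h = c(0, 84), rin = c(9.3, 3.8))
#' cs <- simulateCounts(truth, meta, cfg)
#' colSums(cs$counts) + cs$spike
#' @export
simulateCounts <- function(truth, meta, config, seed = config@seed,
                           individualEffects = NULL) {
    validObject(config)
    .assertSampleMeta(meta)
    n <- nrow(truth)
    inds <- unique(meta$individual_id)
    if (is.null(individualEffects)) {
        individualEffects <- matrix(0, n, length(inds),
                                    dimnames = list(truth$gene_id, inds))
    }
    counts <- matrix(0L, n, nrow(meta),
                     dimnames = list(truth$gene_id, meta$sample_id))
    spike <- integer(nrow(meta))
    phi <- config@nbDispersion
    for (i in seq_len(nrow(meta))) {
        ind <- meta$individual_id[i]
        eff <- exp(individualEffects[, ind])
        tau <- degradationAge(meta$rin[i], config)
        m <- truth$baseline * eff * exp(-truth$k * tau)
        m0 <- sum(truth$baseline * eff)
        s <- config@spikeMassFraction / (1 - config@spikeMassFraction) * m0
        mu <- config@readsPerLibrary * c(m, s) / (sum(m) + s)
        draw <- withSeed(.streamSeed(seed, i), {
            if (phi > 0) stats::rnbinom(n + 1L, mu = mu, size = 1 / phi)
            else stats::rpois(n + 1L, lambda = mu)
        })
        counts[, i] <- as.integer(draw[seq_len(n)])
        spike[i] <- as.integer(draw[n + 1L])
    }
    storage.mode(counts) <- "integer"
    list(counts = counts, spike = stats::setNames(spike, meta$sample_id))
}

#' Simulate a complete degradation experiment
#'
#' Draws per-gene ground truth ([drawGeneParams()]), per-individual
#' expression effects for the configured fraction of genes, a RIN value for
#' every individual x time-point library ([rinTrajectory()]), and read
#' counts ([simulateCounts()]), and assembles everything into a
#' [DegradationExperiment-class].
#'
#' @param config a [SimConfig-class].
#' @return A [DegradationExperiment-class]: `counts` assay, ground truth in
#'   `rowData()`, sample metadata (including spike-in counts and true
#'   masses) in `colData()`, and the config plus individual-effect matrix in
#'   `metadata()`.
#' @examples
#' sim <- simulateDegradation(SimConfig(nGenes = 200, seed = 11L))
#' sim
#' @export
simulateDegradation <- function(config) {
    validObject(config)
    truth <- drawGeneParams(config)
    inds <- sprintf("ind%d", seq_len(config@nIndividuals))
    eff <- matrix(0, config@nGenes, config@nIndividuals,
                  dimnames = list(truth$gene_id, inds))
    hit <- truth$indiv_de
    if (any(hit))
        eff[hit, ] <- withSeed(.streamSeed(config@seed, 0), matrix(
            stats::rnorm(sum(hit) * config@nIndividuals, 0,
                         config@indivEffectSd),
            sum(hit), config@nIndividuals))
    meta <- expand.grid(individual_id = inds,
                        time_h = config@timePointsH,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta <- meta[order(meta$individual_id, meta$time_h), , drop = FALSE]
    meta$sample_id <- sprintf("%s_t%03d", meta$individual_id,
                              as.integer(round(meta$time_h)))
    rownames(meta) <- meta$sample_id
    meta$rin <- vapply(seq_len(nrow(meta)), function(i)
        rinTrajectory(meta$time_h[i], config,
                      seed = .streamSeed(config@seed, 1000000 + i)),
        numeric(1))
    cs <- simulateCounts(truth, meta, config, seed = config@seed,
                         individualEffects = eff)
    tau <- degradationAge(meta$rin, config)
    endo <- vapply(seq_len(nrow(meta)), function(i) {
        e <- exp(eff[, meta$individual_id[i]])
        sum(truth$baseline * e * exp(-truth$k * tau[i]))
    }, numeric(1))
    m0 <- vapply(seq_len(nrow(meta)), function(i)
        sum(truth$baseline * exp(eff[, meta$individual_id[i]])),
        numeric(1))
    cd <- DataFrame(meta,
        tau_h = tau,
        endo_mass = endo,
        spike_mass = config@spikeMassFraction /
            (1 - config@spikeMassFraction) * m0,
        spike_count = as.integer(cs$spike),
        library_size = colSums(cs$counts) + cs$spike)
    se <- SummarizedExperiment(assays = list(counts = cs$counts),
                               rowData = truth, colData = cd)
    metadata(se) <- list(config = config, individualEffects = eff)
    new("DegradationExperiment", se)
}

setMethod("show", "DegradationExperiment", function(object) {
    cat("DegradationExperiment:", nrow(object), "genes x", ncol(object),
        "libraries\n")
    cls <- table(rowData(object)$decay_class_true)
    cat("  decay classes:", paste(names(cls), cls, sep = "=",
        collapse = ", "), "\n")
    cat("  time points (h):",
        paste(sort(unique(colData(object)$time_h)), collapse = ", "), "\n")
    cat("  RIN range:",
        sprintf("%.2f-%.2f", min(colData(object)$rin),
                max(colData(object)$rin)), "\n")
    invisible(NULL)
})
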