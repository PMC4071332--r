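#' @include AllClasses.R utils.R normalize.R decay.R de.R structure.R
NULL

#' Read a gene-level count matrix
#'
#' TSV layout: header row of sample ids, first column of gene ids. MTX
#' layout: MatrixMarket triplet file accompanied by one-id-per-line row
#' (gene) and column (sample) name files. Malformed input (duplicate ids,
#' non-integer or negative cells) is rejected with coordinates, never
#' coerced.
#'
#' @param path count file.
#' @param format `"tsv"` or `"mtx"`.
#' @param rowNamesPath,colNamesPath name files for `"mtx"`.
#' @return Integer genes x samples matrix.
#' @export
readCounts <- function(path, format = c("tsv", "mtx"),
                       rowNamesPath = NULL, colNamesPath = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (format == "tsv") {
        df <- utils::read.delim(path, header = TRUE, sep = "\t",
                                check.names = FALSE, comment.char = "#",
                                stringsAsFactors = FALSE)
        if (ncol(df) < 2L) stop("count TSV needs gene ids + >=1 sample")
        genes <- as.character(df[[1L]])
        if (anyDuplicated(genes))
            stop("duplicate gene id(s): ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", "))
        m <- as.matrix(df[, -1L, drop = FALSE])
        if (anyDuplicated(colnames(m)))
            stop("duplicate sample id(s) in header")
        suppressWarnings(storage.mode(m) <- "numeric")
        bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
        if (nrow(bad))
            stop("non-integer, negative or non-numeric count at gene '",
                 genes[bad[1L, 1L]], "', sample '",
                 colnames(m)[bad[1L, 2L]], "'")
        rownames(m) <- genes
        storage.mode(m) <- "integer"
        m
    } else {
        if (is.null(rowNamesPath) || is.null(colNamesPath))
            stop("MTX input needs rowNamesPath and colNamesPath")
        mm <- as.matrix(Matrix::readMM(path))
        genes <- readLines(rowNamesPath)
        samples <- readLines(colNamesPath)
        if (nrow(mm) != length(genes) || ncol(mm) != length(samples))
            stop("MTX dimensions (", nrow(mm), " x ", ncol(mm),
                 ") do not match the name files (", length(genes), " x ",
                 length(samples), ")")
        dimnames(mm) <- list(genes, samples)
        if (any(mm < 0 | mm != round(mm)))
            stop("MTX contains negative or non-integer entries")
        storage.mode(mm) <- "integer"
        .assertCountMatrix(mm)
    }
}

#' Write a count matrix
#'
#' @param counts integer genes x samples matrix.
#' @param path output file.
#' @param format `"tsv"` or `"mtx"`.
#' @param rowNamesPath,colNamesPath name files for `"mtx"`.
#' @param comment optional `#`-prefixed header line(s) (TSV only).
#' @return Invisibly, `path`.
#' @export
writeCounts <- function(counts, path, format = c("tsv", "mtx"),
                        rowNamesPath = NULL, colNamesPath = NULL,
                        comment = NULL) {
    format <- match.arg(format)
    .assertCountMatrix(counts)
    if (format == "tsv") {
        con <- file(path, "w")
        on.exit(close(con))
        if (!is.null(comment)) writeLines(paste0("# ", comment), con)
        df <- data.frame(gene_id = rownames(counts), counts,
                         check.names = FALSE)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        if (is.null(rowNamesPath) || is.null(colNamesPath))
            stop("MTX output needs rowNamesPath and colNamesPath")
        Matrix::writeMM(methods::as(Matrix::Matrix(counts,
            sparse = TRUE), "generalMatrix"), path)
        writeLines(rownames(counts), rowNamesPath)
        writeLines(colnames(counts), colNamesPath)
    }
    invisible(path)
}

#' Read sample metadata
#'
#' Requires columns `sample_id`, `individual_id`, `time_h`, `rin`
#' (optional `library_size`). RIN must lie in \[1, 10\] and times must be
#' non-negative; sample ids must be unique and, when a count matrix is
#' supplied, match its columns exactly.
#'
#' @param path TSV file.
#' @param counts optional count matrix to cross-check sample ids against.
#' @return Validated data.frame.
#' @export
readMetadata <- function(path, counts = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                              comment.char = "#",
                              stringsAsFactors = FALSE)
    .assertSampleMeta(meta,
        samples = if (!is.null(counts)) colnames(counts) else NULL)
    if (!is.numeric(meta$time_h) || !is.numeric(meta$rin))
        stop("time_h and rin must be numeric")
    meta
}

# Median length of per-transcript feature sums, per gene.
.medianFeatureLength <- function(gr, genes) {
    if (length(gr) == 0L)
        return(stats::setNames(rep(NA_real_, length(genes)), genes))
    tx <- paste(gr$gene_id, gr$transcript_id)
    perTx <- tapply(GenomicRanges::width(gr), tx, sum)
    gid <- vapply(strsplit(names(perTx), " "), `[`, character(1), 1L)
    med <- tapply(as.numeric(perTx), gid, stats::median)
    out <- stats::setNames(rep(NA_real_, length(genes)), genes)
    out[names(med)] <- med
    out
}

#' Read gene annotation
#'
#' Either a GTF (exon records are collapsed into per-gene exon-union
#' lengths via [collapseGeneModel()]; CDS and UTR lengths are summarized
#' as the median across transcripts where those records exist, and GC
#' content — which needs sequence — is `NA`) or a precomputed feature
#' table with columns `gene_id`, `collapsed_length`, `gc_fraction`,
#' `cds_length`, `utr5_length`, `utr3_length`, `biotype` (optional
#' `total_transcript_length`, computed from the UTR/CDS columns when
#' absent).
#'
#' @param path annotation file.
#' @param format `"feature_tsv"` or `"gtf"`.
#' @return A `DataFrame`, one row per gene.
#' @export
readAnnotation <- function(path, format = c("feature_tsv", "gtf")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (format == "feature_tsv") {
        df <- utils::read.delim(path, header = TRUE, sep = "\t",
                                comment.char = "#",
                                stringsAsFactors = FALSE)
        need <- c("gene_id", "collapsed_length", "gc_fraction",
                  "cds_length", "utr5_length", "utr3_length", "biotype")
        miss <- setdiff(need, colnames(df))
        if (length(miss))
            stop("feature table is missing column(s): ",
                 paste(miss, collapse = ", "))
        if (anyDuplicated(df$gene_id)) stop("duplicate gene ids")
        if (any(df$gc_fraction < 0 | df$gc_fraction > 1, na.rm = TRUE))
            stop("gc_fraction outside [0, 1]")
        if (!"total_transcript_length" %in% colnames(df))
            df$total_transcript_length <-
                df$utr5_length + df$cds_length + df$utr3_length
        DataFrame(df, row.names = df$gene_id)
    } else {
        gr <- rtracklayer::import(path, format = "gtf")
        ex <- gr[gr$type == "exon"]
        if (length(ex) == 0L) stop("GTF contains no exon records")
        if (is.null(ex$gene_id) || any(is.na(ex$gene_id)))
            stop("GTF exon records lack gene_id attributes")
        cl <- collapseGeneModel(GRanges(
            GenomicRanges::seqnames(ex),
            IRanges(GenomicRanges::start(ex), GenomicRanges::end(ex)),
            gene_id = ex$gene_id))
        genes <- cl$gene_id
        cds <- .medianFeatureLength(gr[gr$type == "CDS"], genes)
        u5 <- .medianFeatureLength(
            gr[gr$type %in% c("five_prime_utr", "5UTR")], genes)
        u3 <- .medianFeatureLength(
            gr[gr$type %in% c("three_prime_utr", "3UTR")], genes)
        bio <- if (!is.null(gr$gene_biotype)) {
            b <- tapply(as.character(gr$gene_biotype), gr$gene_id,
                        function(x) x[1L])
            unname(b[genes])
        } else rep(NA_character_, length(genes))
        DataFrame(gene_id = genes,
                  collapsed_length = cl$collapsed_length,
                  flagged = cl$flagged,
                  gc_fraction = NA_real_,
                  cds_length = cds, utr5_length = u5, utr3_length = u3,
                  total_transcript_length = u5 + cds + u3,
                  biotype = bio, row.names = genes)
    }
}

#' Write / read a unit-tagged expression matrix as TSV
#'
#' The unit tag travels in a `# unit=` comment line so a round trip
#' preserves it.
#'
#' @param expr an [ExprMatrix-class].
#' @param path file path.
#' @param comment optional extra `#` header line.
#' @return `writeExprMatrix` returns `path` invisibly; `readExprMatrix`
#'   returns the [ExprMatrix-class].
#' @export
writeExprMatrix <- function(expr, path, comment = NULL) {
    stopifnot(methods::is(expr, "ExprMatrix"))
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comment)) writeLines(paste0("# ", comment), con)
    writeLines(paste0("# unit=", exprUnit(expr)), con)
    df <- data.frame(gene_id = rownames(expr), .baseMatrix(expr),
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeExprMatrix
#' @export
readExprMatrix <- function(path) {
    lines <- readLines(path, n = 10L)
    unitLine <- grep("^# unit=", lines, value = TRUE)
    if (!length(unitLine)) stop("missing '# unit=' header line")
    unit <- sub("^# unit=", "", unitLine[1L])
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    ExprMatrix(m, unit)
}

#' Configuration for the end-to-end pipeline
#'
#' @param outputDir directory for the TSV artifacts.
#' @param countsPath,metadataPath,annotationPath input files; leave all
#'   `NULL` to simulate the inputs from `sim`.
#' @param sim a [SimConfig-class] used when simulating.
#' @param subsampleDepth `NULL` (skip), `"min"` (lowest library size) or a
#'   number of reads.
#' @param pseudocount log2 pseudocount.
#' @param rpkmThreshold expression/detection threshold (default 0.3).
#' @param decayFdr FDR for decay classification (default 0.01).
#' @param deFdr FDR for DE calls (default 0.05).
#' @param varFraction variable-gene fraction (default 0.10).
#' @param seed integer seed for the stochastic stages.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outputDir,
                           countsPath = NULL, metadataPath = NULL,
                           annotationPath = NULL,
                           sim = SimConfig(),
                           subsampleDepth = NULL,
                           pseudocount = 1,
                           rpkmThreshold = 0.3,
                           decayFdr = 0.01,
                           deFdr = 0.05,
                           varFraction = 0.10,
                           seed = 1L) {
    stopifnot(rpkmThreshold >= 0,
              decayFdr > 0, decayFdr < 1,
              deFdr >= 0, deFdr < 1,
              varFraction > 0, varFraction <= 1)
    structure(list(outputDir = outputDir, countsPath = countsPath,
                   metadataPath = metadataPath,
                   annotationPath = annotationPath, sim = sim,
                   subsampleDepth = subsampleDepth,
                   pseudocount = pseudocount,
                   rpkmThreshold = rpkmThreshold, decayFdr = decayFdr,
                   deFdr = deFdr, varFraction = varFraction,
                   seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' Run the degradation analysis pipeline end to end
#'
#' Stages: simulate (or load) counts -> optional depth subsampling ->
#' RPKM + quantile normalization -> per-gene decay fits and classification
#' -> differential expression under the three RIN strategies -> sample-
#' structure diagnostics. Every artifact is written as TSV under
#' `config$outputDir` with a header comment recording the seed and a hash
#' of the configuration; a run log records per-stage gene counts. A stage
#' failure aborts with the stage name; artifacts of completed stages are
#' preserved.
#'
#' @param config a [pipelineConfig()] list.
#' @return Invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    hashed <- config[setdiff(names(config), "outputDir")]
    stamp <- paste0("seed=", config$seed, " config=",
                    .hashString(paste(deparse(hashed), collapse = "")))
    paths <- list()
    log <- c(paste0("rnadecay ",
                    as.character(utils::packageVersion("rnadecay"))),
             paste0("R ", R.version.string), stamp)
    stage <- function(name, code) {
        tryCatch(code, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    out <- function(name) file.path(config$outputDir, name)
    wtsv <- function(df, name) {
        con <- file(out(name), "w")
        on.exit(close(con))
        writeLines(paste0("# ", stamp), con)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths[[name]] <<- out(name)
    }

    # ingest or simulate
    simulated <- is.null(config$countsPath)
    if (simulated) {
        sim <- stage("simulate", {
            sc <- config$sim
            sc@seed <- config$seed
            simulateDegradation(sc)
        })
        counts <- assay(sim, "counts")
        meta <- sampleMeta(sim)
        annotation <- as.data.frame(groundTruth(sim))
        wtsv(data.frame(gene_id = rownames(counts), counts,
                        check.names = FALSE), "counts.tsv")
        wtsv(meta, "metadata.tsv")
        wtsv(annotation, "ground_truth.tsv")
    } else {
        counts <- stage("read_counts", readCounts(config$countsPath))
        meta <- stage("read_metadata",
                      readMetadata(config$metadataPath, counts))
        annotation <- stage("read_annotation",
            as.data.frame(readAnnotation(config$annotationPath)))
    }
    log <- c(log, paste0("genes in: ", nrow(counts)))

    if (!is.null(config$subsampleDepth)) {
        depth <- if (identical(config$subsampleDepth, "min"))
            min(colSums(counts)) else config$subsampleDepth
        counts <- stage("subsample",
                        subsampleCounts(counts, depth,
                                        seed = config$seed))
        log <- c(log, paste0("subsampled to depth: ", depth))
    }

    # normalization
    rpkm <- stage("rpkm", computeRPKM(counts, annotation))
    qn <- stage("quantile_normalize", quantileNormalize(rpkm))
    lexpr <- stage("log_quantile_normalize",
        quantileNormalize(counts, log2First = TRUE,
                          pseudocount = config$pseudocount,
                          keepLog = TRUE))
    paths[["rpkm.tsv"]] <- writeExprMatrix(rpkm, out("rpkm.tsv"), stamp)
    paths[["qnorm_rpkm.tsv"]] <-
        writeExprMatrix(qn, out("qnorm_rpkm.tsv"), stamp)

    # decay
    tested <- expressedGeneSet(qn, config$rpkmThreshold, rule = "all")
    log <- c(log, paste0("genes expressed (all samples >= ",
                         config$rpkmThreshold, "): ", length(tested)))
    fits <- stage("decay", {
        f <- fitDecayRates(qn[tested, ], meta,
                           minValue = config$rpkmThreshold)
        classifyDecay(f, alpha = config$decayFdr)
    })
    log <- c(log, paste0("genes with decay fits: ", nrow(fits)),
             paste0("decay classes: ",
                    paste(names(table(fits$decay_class)),
                          table(fits$decay_class), sep = "=",
                          collapse = ", ")))
    wtsv(as.data.frame(fits), "decay_fits.tsv")

    # differential expression, three strategies
    times <- sort(unique(meta$time_h))
    inds <- sort(unique(meta$individual_id))
    timeContrasts <- lapply(times[-1L], function(t) c(times[1L], t))
    indivContrasts <- if (length(inds) >= 2L)
        utils::combn(inds, 2L, simplify = FALSE) else list()
    de <- stage("differential_expression",
        deStrategySummary(counts, meta, lexpr,
                          timeContrasts = timeContrasts,
                          indivContrasts = indivContrasts,
                          fdr = config$deFdr,
                          varFraction = config$varFraction))
    wtsv(de$summary, "de_summary.tsv")
    for (nm in names(de$results))
        wtsv(as.data.frame(de$results[[nm]]), paste0("de_", nm, ".tsv"))

    # sample structure
    pca <- stage("pca", pcaExpression(lexpr))
    wtsv(data.frame(sample_id = rownames(pca@scores), pca@scores,
                    check.names = FALSE), "pca_scores.tsv")
    assoc <- data.frame(
        component = colnames(pca@scores),
        p_rin = pcCovariateAssociation(pca, meta, "rin"),
        p_time = pcCovariateAssociation(pca, meta, "time_h"),
        p_individual = pcCovariateAssociation(pca, meta,
                                              "individual_id"))
    wtsv(assoc, "pc_covariate_pvalues.tsv")
    sp <- stage("correlation", spearmanSampleMatrix(lexpr))
    wtsv(data.frame(sample_id = rownames(sp$rho), sp$rho,
                    check.names = FALSE), "spearman_rho.tsv")
    cx <- stage("complexity",
                complexityMetrics(rpkm, meta, config$rpkmThreshold))
    wtsv(cx$perSample, "complexity_per_sample.tsv")
    wtsv(cx$association, "complexity_vs_rin.tsv")
    pa <- stage("presence_absence",
                presenceAbsenceTable(rpkm, meta, config$rpkmThreshold))
    wtsv(pa$table, "presence_absence.tsv")

    writeLines(log, out("run_log.txt"))
    paths[["run_log.txt"]] <- out("run_log.txt")
    invisible(paths)
}
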