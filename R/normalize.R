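#' @include AllClasses.R utils.R
#' @importFrom GenomicRanges GRanges reduce disjoin width findOverlaps
#'   countOverlaps strand strand<- mcols
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits split
NULL

#' Collapse exon models into per-gene union lengths
#'
#' Each gene's exons (across all its transcripts) are merged into the union
#' of their intervals; any base covered by the exons of more than one gene
#' is then removed from every gene covering it. Genes whose entire exonic
#' territory is shared (collapsed length 0) are flagged.
#'
#' @param exons either a `GRanges` with a `gene_id` metadata column, or a
#'   data.frame with columns `chrom`, `start`, `end`, `gene_id` (1-based
#'   inclusive coordinates, GTF convention). Strand is ignored: the union is
#'   strand-agnostic.
#' @return A `DataFrame` with `gene_id`, `collapsed_length` (bp) and
#'   `flagged` (length zero after removing shared regions).
#' @examples
#' ex <- data.frame(chrom = "chr1", start = c(1, 51), end = c(100, 150),
#'                  gene_id = "A")
#' collapseGeneModel(ex)$collapsed_length  # 150
#' @export
collapseGeneModel <- function(exons) {
    if (is.data.frame(exons)) {
        need <- c("chrom", "start", "end", "gene_id")
        miss <- setdiff(need, colnames(exons))
        if (length(miss))
            stop("exon table is missing column(s): ",
                 paste(miss, collapse = ", "))
        bad <- which(exons$end < exons$start)
        if (length(bad))
            stop("malformed exon interval (end < start) at line ",
                 bad[1L])
        exons <- GRanges(exons$chrom,
                         IRanges(exons$start, exons$end),
                         gene_id = as.character(exons$gene_id))
    }
    if (!methods::is(exons, "GRanges") ||
        is.null(mcols(exons)$gene_id))
        stop("exons must be a GRanges with a gene_id column or a ",
             "chrom/start/end/gene_id data.frame")
    strand(exons) <- "*"
    grl <- reduce(S4Vectors::split(exons, mcols(exons)$gene_id))
    uni <- unlist(grl, use.names = FALSE)
    dj <- disjoin(uni)
    keep <- dj[countOverlaps(dj, grl) == 1L]
    len <- stats::setNames(rep(0L, length(grl)), names(grl))
    if (length(keep)) {
        ov <- findOverlaps(grl, keep)
        agg <- tapply(width(keep)[subjectHits(ov)],
                      names(grl)[queryHits(ov)], sum)
        len[names(agg)] <- as.integer(agg)
    }
    DataFrame(gene_id = names(len), collapsed_length = unname(len),
              flagged = unname(len) == 0L, row.names = names(len))
}

#' Subsample a count matrix to a fixed depth per library
#'
#' Draws `depth` reads from each library without replacement (multivariate
#' hypergeometric), the in-silico analogue of sequencing every library to
#' the same depth. Column sums of the result equal `depth` exactly and no
#' cell ever exceeds its input value. Each library uses its own random
#' stream derived from `seed`.
#'
#' @param counts genes x samples integer matrix.
#' @param depth target reads per library; every column sum must be >= depth.
#' @param seed integer seed.
#' @return Subsampled integer count matrix of the same shape.
#' @examples
#' m <- matrix(c(8L, 2L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' colSums(subsampleCounts(m, 5, seed = 1))
#' @export
subsampleCounts <- function(counts, depth, seed = 1L) {
    .assertCountMatrix(counts)
    cs <- colSums(counts)
    low <- which(cs < depth)
    if (length(low))
        stop("depth ", depth, " exceeds the library size of sample(s): ",
             paste(colnames(counts)[low], collapse = ", "))
    out <- counts
    for (j in seq_len(ncol(counts))) {
        out[, j] <- withSeed(.streamSeed(seed, j), {
            rest <- cs[j]
            d <- depth
            x <- integer(nrow(counts))
            for (i in seq_len(nrow(counts))) {
                ci <- counts[i, j]
                if (d == 0L) break
                xi <- stats::rhyper(1L, ci, rest - ci, d)
                x[i] <- xi
                d <- d - xi
                rest <- rest - ci
            }
            x
        })
    }
    storage.mode(out) <- "integer"
    out
}

#' Reads per kilobase of collapsed transcript per million mapped reads
#'
#' `RPKM_gs = 1e9 * c_gs / (N_s * L_g)` with `L_g` the collapsed exon-union
#' length and `N_s` by default the number of reads assigned to the
#' quantified genes (the matrix column sum); pass `totalReads` to use a
#' different denominator (e.g. all mapped reads).
#'
#' @param counts genes x samples integer matrix.
#' @param annotation a data.frame or `DataFrame` with `gene_id` and
#'   `collapsed_length` covering every gene in `counts`.
#' @param totalReads optional per-sample read totals to use as `N_s`.
#' @return An [ExprMatrix-class] with unit `"RPKM"`.
#' @examples
#' m <- matrix(1L, 1, 1, dimnames = list("g1", "s1"))
#' ann <- data.frame(gene_id = "g1", collapsed_length = 1000L)
#' computeRPKM(m, ann, totalReads = 1e6)  # 1.0
#' @export
computeRPKM <- function(counts, annotation, totalReads = NULL) {
    .assertCountMatrix(counts)
    ann <- as.data.frame(annotation)
    if (!all(c("gene_id", "collapsed_length") %in% colnames(ann)))
        stop("annotation must carry gene_id and collapsed_length")
    len <- ann$collapsed_length[match(rownames(counts), ann$gene_id)]
    bad <- which(is.na(len) | len <= 0)
    if (length(bad))
        stop("zero, missing or unannotated collapsed length for gene(s): ",
             paste(rownames(counts)[bad], collapse = ", "))
    N <- if (is.null(totalReads)) colSums(counts) else totalReads
    if (any(N <= 0)) stop("per-sample read totals must be > 0")
    rpkm <- 1e9 * sweep(counts, 2, N, "/") / len
    ExprMatrix(rpkm, "RPKM")
}

#' Quantile normalization across samples
#'
#' Forces every column to share one empirical distribution: the per-rank
#' mean of the column-sorted input values. Within-column rank order is
#' preserved; ties receive the mean of the reference values across their
#' tied ranks. With `log2First`, values are `log2(x + pseudocount)`
#' transformed before normalization and back-transformed (and floored at 0)
#' afterwards, the usual treatment for raw counts.
#'
#' @param expr an [ExprMatrix-class] (or plain matrix, treated as counts).
#' @param log2First log2-transform before normalizing, undo afterwards.
#' @param pseudocount added inside the log2 (default 1 preserves zeros).
#' @param keepLog with `log2First`, skip the back-transform and return the
#'   normalized values on the log2 scale (useful for PCA, correlation and
#'   residual analyses).
#' @return An [ExprMatrix-class] with unit `"qnorm-RPKM"` (RPKM input) or
#'   `"qnorm-log2count"` (count-scale input).
#' @examples
#' m <- matrix(c(1, 3, 2, 6), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' quantileNormalize(ExprMatrix(m, "RPKM"))  # both columns (1.5, 4.5)
#' @export
quantileNormalize <- function(expr, log2First = FALSE, pseudocount = 1,
                              keepLog = FALSE) {
    unitIn <- if (methods::is(expr, "ExprMatrix")) exprUnit(expr)
        else "log2count"
    v <- .baseMatrix(expr)
    if (ncol(v) < 2L)
        stop("quantile normalization needs at least 2 samples")
    if (any(!is.finite(v)))
        stop("expression values must be finite")
    if (log2First) v <- log2(v + pseudocount)
    vv <- v
    dimnames(vv) <- NULL  # names disable sort(index.return=) inside limma
    qn <- limma::normalizeQuantiles(vv, ties = TRUE)
    if (log2First && !keepLog) qn <- pmax(2^qn - pseudocount, 0)
    dimnames(qn) <- dimnames(expr)
    unitOut <- if (unitIn %in% c("RPKM", "qnorm-RPKM")) "qnorm-RPKM"
        else "qnorm-log2count"
    ExprMatrix(qn, unitOut)
}

#' TMM scaling factors (trimmed mean of M-values)
#'
#' Between-sample normalization factors robust to composition shifts: for
#' each sample versus a reference, per-gene log ratios (M) and average log
#' abundances (A) of depth-normalized counts are doubly trimmed (30% on M,
#' 5% on A by default) and the factor is two to the precision-weighted mean
#' of the retained M values. Factors are rescaled to geometric mean 1. The
#' reference defaults to the sample whose upper-quartile expression is
#' closest to the mean upper quartile. Computation is delegated to
#' `edgeR::calcNormFactors`.
#'
#' @param counts genes x samples integer matrix.
#' @param refSample optional reference sample id.
#' @param trimM,trimA trim proportions for log ratios and abundances.
#' @return Named numeric vector of positive factors (geometric mean 1) with
#'   the reference sample id in `attr(, "ref_sample")`.
#' @examples
#' m <- matrix(rpois(60, 50) + 1L, 10, 6)
#' dimnames(m) <- list(paste0("g", 1:10), paste0("s", 1:6))
#' prod(tmmFactors(m))  # 1 up to rounding
#' @export
tmmFactors <- function(counts, refSample = NULL, trimM = 0.3,
                       trimA = 0.05) {
    .assertCountMatrix(counts)
    if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
    lib <- colSums(counts)
    if (is.null(refSample)) {
        f75 <- apply(counts, 2, function(x)
            stats::quantile(x, 0.75) / sum(x))
        ref <- which.min(abs(f75 - mean(f75)))
    } else {
        ref <- match(refSample, colnames(counts))
        if (is.na(ref)) stop("unknown reference sample: ", refSample)
    }
    shared <- vapply(seq_len(ncol(counts)), function(j)
        any(counts[, j] > 0 & counts[, ref] > 0), logical(1))
    if (!all(shared))
        stop("sample(s) sharing no expressed gene with the reference: ",
             paste(colnames(counts)[!shared], collapse = ", "))
    f <- edgeR::calcNormFactors(counts, lib.size = lib, method = "TMM",
                                refColumn = ref, logratioTrim = trimM,
                                sumTrim = trimA, doWeighting = TRUE)
    structure(stats::setNames(as.numeric(f), colnames(counts)),
              ref_sample = colnames(counts)[ref])
}

#' Expressed-gene set at an RPKM threshold
#'
#' @param expr an [ExprMatrix-class] with unit `"RPKM"` or `"qnorm-RPKM"`.
#' @param threshold detection threshold (default 0.3 RPKM).
#' @param rule `"any"` keeps genes detected in at least one sample;
#'   `"all"` requires detection in every sample.
#' @return Character vector of gene ids.
#' @examples
#' m <- matrix(c(0.2, 0.4, 1, 1), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expressedGeneSet(ExprMatrix(m, "RPKM"), 0.3, "any")
#' expressedGeneSet(ExprMatrix(m, "RPKM"), 0.3, "all")
#' @export
expressedGeneSet <- function(expr, threshold = 0.3,
                             rule = c("any", "all")) {
    rule <- match.arg(rule)
    if (!methods::is(expr, "ExprMatrix") ||
        !exprUnit(expr) %in% c("RPKM", "qnorm-RPKM"))
        stop("expressedGeneSet expects an ExprMatrix with an RPKM unit")
    v <- .baseMatrix(expr)
    det <- v >= threshold & v > 0  # a zero never counts as detected
    keep <- if (rule == "any") rowSums(det) >= 1L
        else rowSums(det) == ncol(det)
    rownames(expr)[keep]
}
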