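# Internal helpers: local RNG scoping and derived per-sample streams.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(seed)
    force(code)
}

# Deterministic sub-stream seed for unit i of a stage keyed by `seed`.
# Keeps results order-independent across samples and within 32-bit range.
.streamSeed <- function(seed, i) {
    s <- (as.double(seed) %% 2147483647) * 69069 + as.double(i) * 104729
    as.integer(s %% 2147483629) + 1L
}

# Demote an ExprMatrix (or anything matrix-like) to a plain base matrix.
.baseMatrix <- function(x) {
    if (isVirtualClass(class(x)) || is.object(x)) {
        if (methods::is(x, "ExprMatrix")) return(x@.Data)
    }
    as.matrix(x)
}

# FNV-1a hash of a character scalar, hex string; used to stamp outputs.
.hashString <- function(x) {
    h <- 2166136261
    for (b in utf8ToInt(x)) {
        h <- bitwXor(as.integer(h %% 2^31), b)
        h <- (as.double(h) * 16777619) %% 2^32
    }
    sprintf("%08x", as.integer(h %% 2^31))
}

.assertCountMatrix <- function(counts) {
    if (!is.matrix(counts) || !is.numeric(counts))
        stop("counts must be a numeric matrix")
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have gene rownames and sample colnames")
    if (anyDuplicated(rownames(counts)))
        stop("duplicate gene ids in counts")
    if (anyDuplicated(colnames(counts)))
        stop("duplicate sample ids in counts")
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    invisible(counts)
}

.assertSampleMeta <- function(meta, samples = NULL) {
    need <- c("sample_id", "individual_id", "time_h", "rin")
    miss <- setdiff(need, colnames(meta))
    if (length(miss))
        stop("sample metadata is missing column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(meta$sample_id))
        stop("duplicated sample_id in metadata")
    if (any(meta$rin < 1 | meta$rin > 10))
        stop("RIN values must lie in [1, 10]")
    if (any(meta$time_h < 0))
        stop("time_h must be >= 0")
    if (!is.null(samples)) {
        extra <- setdiff(meta$sample_id, samples)
        missing <- setdiff(samples, meta$sample_id)
        if (length(extra) || length(missing))
            stop("metadata/count sample mismatch; only in metadata: {",
                 paste(extra, collapse = ", "), "}; only in counts: {",
                 paste(missing, collapse = ", "), "}")
    }
    invisible(meta)
}
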