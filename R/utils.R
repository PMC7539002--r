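## Internal helpers shared across modules.

# Derive a per-stage / per-chromosome seed from a master seed. Documented
# scheme: (seed + 7919 * counter) mod (2^31 - 1). Deterministic, keeps the
# result inside R's 32-bit integer range.
deriveSeed <- function(seed, counter) {
    as.integer((as.numeric(seed) + 7919 * as.numeric(counter)) %%
               (2^31 - 1))
}

# gsub-normalized biotype comparison: the annotation and the filter list may
# use spaces or hyphens where GENCODE uses underscores.
normalizeBiotype <- function(x) gsub("[ -]", "_", x)

.assertScalarNumber <- function(x, name, positive = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop("'", name, "' must be a single finite number", call. = FALSE)
    if (positive && x <= 0)
        stop("'", name, "' must be positive", call. = FALSE)
    invisible(x)
}

# Upper-triangle values of a square matrix (no diagonal).
upperTri <- function(m) m[upper.tri(m)]
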