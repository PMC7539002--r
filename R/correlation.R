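#' Spearman correlation matrix between bins
#'
#' rho(i, j) is the Pearson correlation of the average-ranked (midrank)
#' values of bins i and j across the group's samples. Constant bins carry no
#' rank information: their coefficients are set to NA and the offending rows
#' are reported in attribute \code{"constant_bins"} (inside [callDCEs()] such
#' bins are excluded beforehand, see [survivingBins()]).
#'
#' @param values numeric matrix, bins x samples (>= 3 samples).
#' @return symmetric matrix with unit diagonal (NA rows for constant bins).
#' @export
spearmanMatrix <- function(values) {
    values <- as.matrix(values)
    if (ncol(values) < 3L) stop("need at least 3 samples")
    rho <- suppressWarnings(stats::cor(t(values), method = "spearman"))
    const <- unname(which(apply(values, 1, function(x) min(x) == max(x))))
    if (length(const)) {
        rho[const, ] <- NA_real_
        rho[, const] <- NA_real_
        attr(rho, "constant_bins") <- const
    }
    diag(rho)[setdiff(seq_len(nrow(rho)), const)] <- 1
    rho
}

# Midranks of every row in one rank() call: adding a per-row offset larger
# than the value range makes rows non-overlapping in the global order, so
# global midranks minus the per-row base give within-row midranks exactly
# (ties only ever tie within a row).
.rowMidranks <- function(m) {
    n <- nrow(m); S <- ncol(m)
    off <- (seq_len(n) - 1) * (diff(range(m)) + 1)
    g <- rank(as.vector(m + off))
    matrix(g, n, S) - (seq_len(n) - 1) * S
}

# Spearman via explicit midranks + normalized cross product; numerically
# identical to stats::cor(t(m), method = "spearman") (unit tested) but
# cheaper inside the permutation loop. Constant rows give NaN, handled by
# the caller.
.fastSpearman <- function(m) {
    r <- .rowMidranks(m)
    r <- r - rowMeans(r)
    s <- sqrt(rowSums(r^2))
    tcrossprod(r / s)
}

# One within-sample shuffle: permute the bin values independently inside
# each sample (column), then rebuild the full Spearman matrix.
.shuffledSpearman <- function(values) {
    n <- nrow(values)
    shuf <- vapply(seq_len(ncol(values)),
                   function(j) values[sample.int(n), j],
                   numeric(n))
    .fastSpearman(shuf)
}

#' Monte-Carlo permutation mask for a correlation matrix
#'
#' For each of \code{nPerm} rounds the bin values of every sample are
#' shuffled independently, the full Spearman matrix is recomputed once, and
#' each coefficient's extremeness is tallied. The p-value is the plain
#' fraction of rounds in which the permuted coefficient was as or more
#' extreme than the observed one (two-sided on |rho| by default; the minimum
#' attainable p is 0). Coefficients with p > alpha are set to 0 in
#' \code{maskedRho}. Bit-for-bit reproducible given (values, nPerm, alpha,
#' seed); rounds consume one seeded RNG stream sequentially.
#'
#' @param values numeric matrix, bins x samples, for one group/chromosome.
#' @param rho optional precomputed matrix from [spearmanMatrix()].
#' @param nPerm number of permutation rounds (>= 1).
#' @param alpha significance threshold (coefficients with p > alpha zeroed).
#' @param seed RNG seed (recorded in the object).
#' @param sided "two" counts |rho_perm| >= |rho_obs|; "one" counts
#'   rho_perm >= rho_obs.
#' @param chrom,group labels stored in the result.
#' @param binIndexMap surviving-bin indices in the full grid (defaults to
#'   1..n).
#' @return a [MaskedCorrelation-class].
#' @export
permutationMask <- function(values, rho = NULL, nPerm = 1000, alpha = 0.05,
                            seed = 1L, sided = c("two", "one"),
                            chrom = "chr", group = "group",
                            binIndexMap = NULL) {
    sided <- match.arg(sided)
    values <- as.matrix(values)
    if (nPerm < 1L) stop("nPerm must be >= 1")
    if (is.null(rho)) rho <- spearmanMatrix(values)
    n <- nrow(values)
    if (is.null(binIndexMap)) binIndexMap <- seq_len(n)
    naEntry <- is.na(rho)
    obs <- if (sided == "two") abs(rho) else rho
    obs[naEntry] <- Inf                  # never counted as exceeded
    cnt <- matrix(0, n, n)
    set.seed(seed)
    for (r in seq_len(nPerm)) {
        rp <- .shuffledSpearman(values)
        rp[is.na(rp)] <- 0
        if (sided == "two") rp <- abs(rp)
        cnt <- cnt + (rp >= obs)
    }
    pval <- cnt / nPerm
    pval[naEntry] <- NA_real_
    diag(pval) <- 0
    masked <- rho
    masked[!naEntry & pval > alpha] <- 0
    new("MaskedCorrelation", chrom = chrom, group = group,
        binIndex = as.integer(binIndexMap), rho = rho, pval = pval,
        maskedRho = masked, nPerm = as.integer(nPerm),
        alpha = as.numeric(alpha), seed = as.integer(seed), sided = sided)
}

#' Fraction of retained off-diagonal coefficients
#'
#' @param mc a [MaskedCorrelation-class].
#' @return proportion of off-diagonal entries with p <= alpha.
#' @export
retainedFraction <- function(mc) {
    p <- upperTri(pvalMatrix(mc))
    mean(p <= mc@alpha, na.rm = TRUE)
}
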