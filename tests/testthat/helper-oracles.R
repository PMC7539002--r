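# Independent brute-force oracles. These deliberately avoid the package's
# code paths: plain loops, raw-value pairwise counts, per-basepair label
# tables.

# Spearman of two vectors: midranks + explicit Pearson formula.
oracleSpearman <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    dx <- rx - mean(rx); dy <- ry - mean(ry)
    sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Bin signal by explicit double loop over cross-window pairs.
oracleBinSignal <- function(m, w) {
    n <- nrow(m)
    out <- rep(NA_real_, n)
    for (i in w:(n - w)) {
        acc <- 0
        for (a in (i - w + 1):i)
            for (b in (i + 1):(i + w))
                acc <- acc + m[a, b]
        out[i] <- acc / (w * w)
    }
    out[seq_len(w - 1)] <- out[w]
    out[(n - w + 1):n] <- out[n - w]
    out
}

# Exact rank-sum p-value by enumerating the pairwise-count U statistic over
# every assignment of the pooled raw values (ties counted 1/2).
oracleRankSumP <- function(x, y, alternative = "greater") {
    pool <- c(x, y)
    n1 <- length(x); N <- length(pool)
    U <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    uobs <- U(x, y)
    mu <- n1 * (N - n1) / 2
    us <- apply(utils::combn(N, n1), 2,
                function(ii) U(pool[ii], pool[-ii]))
    switch(alternative,
           greater = mean(us >= uobs),
           less = mean(us <= uobs),
           two.sided = mean(abs(us - mu) >= abs(uobs - mu)))
}

# Jaccard by explicit basepair sets.
oracleJaccard <- function(s1, e1, s2, e2) {
    a <- s1:e1; b <- s2:e2
    length(intersect(a, b)) / length(union(a, b))
}

# BP segmentation distance via per-basepair segment labels: every bp of
# [1, L] gets the id of its segment in each partition (intervals plus
# background), then the pair-overlap table feeds the published formula.
oracleBpDist <- function(intA, intB, L) {
    labelize <- function(ints) {
        cuts <- rep(FALSE, L + 1)
        cuts[1] <- TRUE
        if (nrow(ints)) {
            cuts[ints$start] <- TRUE
            cuts[ints$end + 1] <- TRUE
        }
        cumsum(cuts[seq_len(L)])
    }
    la <- labelize(intA); lb <- labelize(intB)
    tab <- table(la, lb)
    lenA <- table(la); lenB <- table(lb)
    acc <- 0
    for (i in rownames(tab)) for (j in colnames(tab)) {
        o <- tab[i, j]
        if (o > 0)
            acc <- acc + o * (1 - o / max(lenA[[i]], lenB[[j]]))
    }
    acc / L
}

# Independent reading of the two fusion criteria: walk the domain list,
# recomputing each chain's state from scratch; a pair may fuse when the gap
# is at most 2 bins, every gap bin is low-signal, the chain's cumulative
# intervening bins stay at most 2 and the chain holds at most 3 domains.
oracleFusion <- function(dom, sigv, threshold = 0.25) {
    m <- nrow(dom)
    chain <- seq_len(m)
    if (m > 1) {
        for (k in 2:m) {
            members <- which(chain[seq_len(k - 1)] == chain[k - 1])
            gap <- (dom$end[k - 1] + 1):(dom$start[k] - 1)
            if (dom$start[k] == dom$end[k - 1] + 1) gap <- integer(0)
            low <- all(sigv[gap] < threshold)
            cum <- 0L
            if (length(members) > 1)
                for (idx in 2:length(members)) {
                    a <- members[idx - 1]; b <- members[idx]
                    cum <- cum + (dom$start[b] - dom$end[a] - 1L)
                }
            ok <- length(gap) <= 2 && low &&
                cum + length(gap) <= 2 && length(members) < 3
            chain[k] <- if (ok) chain[k - 1] else chain[k - 1] + 1L
        }
    }
    out <- do.call(rbind, lapply(split(seq_len(m), chain), function(ii)
        data.frame(start = dom$start[min(ii)], end = dom$end[max(ii)],
                   n = length(ii))))
    rownames(out) <- NULL
    out
}
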