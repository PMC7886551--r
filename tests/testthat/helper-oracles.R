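## Independent brute-force oracles, kept deliberately separate from the
## implementation paths they check.

## exact two-sided rank-sum p by enumerating every rank assignment
## (valid only without ties); mirrors the doubled-tail convention
enumWilcoxonP <- function(a, b) {
    m <- length(a); n <- length(b); N <- m + n
    ranks <- rank(c(a, b))
    obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
    subsets <- utils::combn(N, m)
    ws <- colSums(matrix(seq_len(N)[subsets], nrow = m)) - m * (m + 1) / 2
    p <- if (obs > m * n / 2) 2 * mean(ws >= obs) else 2 * mean(ws <= obs)
    min(1, p)
}

## sup-distance between ECDFs evaluated over the pooled support
enumKsD <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
}

## closed-form 2x2 chi-squared
chi2x2Closed <- function(tab) {
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

## d-squared formula (untied data only)
spearmanD2 <- function(x, y) {
    n <- length(x)
    d <- rank(x) - rank(y)
    1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

## concordant-pair AUROC with half credit for ties
bruteAuroc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    pr <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    mean(pr)
}

## long-format event-table builder for query tests
makeEvents <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
        data.frame(patient_id = r[[1]], event_type = r[[2]],
                   timestamp = r[[3]], attr_name = r[[4]],
                   attr_value = as.character(r[[5]]),
                   stringsAsFactors = FALSE)))
}

## small all-continuous matrix for engine tests
makeGaussianMatrix <- function(n, rho = 0, seed = 1) {
    set.seed(seed)
    sigma <- matrix(c(1, rho, rho, 1), 2)
    z <- matrix(stats::rnorm(2 * n), n) %*% chol(sigma)
    d <- data.frame(x = z[, 1], y = z[, 2])
    FeatureMatrix(d, FeatureSpec(c("x", "y"), "continuous"))
}
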