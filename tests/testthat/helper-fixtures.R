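# shared helpers: tiny fixture writers and brute-force oracles

writeStemFixture <- function(lines, sep = ",") {
    f <- tempfile(fileext = ".csv")
    writeLines(gsub(",", sep, lines, fixed = TRUE), f)
    f
}

# naive O(n^2) double-loop K estimator with explicit weights, kept deliberately
# independent of the package's sorted-cumsum implementation
bruteForceK <- function(pp, r, correction = "none") {
    x <- pp@x; y <- pp@y; n <- length(x)
    w <- pp@window
    area <- w@width * w@height
    vapply(r, function(rr) {
        acc <- 0
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (i == j) next
            dx <- abs(x[i] - x[j]); dy <- abs(y[i] - y[j])
            if (sqrt(dx^2 + dy^2) <= rr) {
                e <- if (correction == "translation")
                    area / ((w@width - dx) * (w@height - dy)) else 1
                acc <- acc + e
            }
        }
        area / (n * (n - 1)) * acc
    }, numeric(1))
}

# published 3 x 5 contingency counts expanded to one row per species, with
# synthetic sigma values attached to the cluster-model winners
countsToResults <- function(tab, sigmaSeed = 1) {
    set.seed(sigmaSeed)
    rows <- list()
    id <- 0L
    for (g in colnames(tab)) for (m in rownames(tab)) {
        k <- tab[m, g]
        if (k == 0) next
        ids <- sprintf("fix%03d", id + seq_len(k)); id <- id + k
        rows[[length(rows) + 1L]] <- data.frame(
            species = ids, group = g, best_model = m,
            sigma = if (m == "IPP") NA_real_ else rlnorm(k, log(12), 0.4))
    }
    do.call(rbind, rows)
}
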