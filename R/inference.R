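#' Published BCI 1995 syndrome-by-model species counts
#'
#' The packaged 3 x 5 contingency table of species counts by best-fitting
#' point-process class (IPP / HPCP / IPCP) and dispersal syndrome group for
#' the 229 woody species of the Barro Colorado Island 1995 census with at
#' least 20 mapped individuals, as published for that census. Rows are model
#' classes, columns the five syndrome groups; the grand total is 229.
#'
#' @return 3 x 5 integer matrix with dimnames (model class x group).
#' @examples
#' bciSyndromeModelCounts()
#' @export
bciSyndromeModelCounts <- function() {
    path <- system.file("extdata", "bci1995_syndrome_model_counts.csv",
                        package = "stemPPM", mustWork = TRUE)
    df <- read.csv(path, stringsAsFactors = FALSE)
    m <- t(as.matrix(df[c("IPP", "HPCP", "IPCP")]))
    colnames(m) <- df$group
    storage.mode(m) <- "integer"
    m
}

.modelClasses <- c("IPP", "HPCP", "IPCP")

#' Contingency table of best-fitting model class by syndrome group
#'
#' Counts species by (model class, syndrome group). Rows are always the three
#' classes IPP, HPCP, IPCP; columns the five syndrome groups (see
#' [syndromeGroups()]), in canonical order.
#'
#' @param results data.frame with columns `species`, `group`, `best_model`
#'   (one row per species).
#' @param groups column labels to use (default the five canonical groups).
#' @return 3 x length(groups) integer matrix.
#' @export
buildContingency <- function(results, groups = syndromeGroups()) {
    if (anyDuplicated(results$species))
        stop("each species must appear once")
    if (!all(results$best_model %in% .modelClasses))
        stop("unknown model class: ",
             setdiff(results$best_model, .modelClasses)[1L])
    unknown <- setdiff(results$group, groups)
    if (length(unknown)) stop("unknown group label: ", unknown[1L])
    tab <- table(factor(results$best_model, levels = .modelClasses),
                 factor(results$group, levels = groups))
    m <- matrix(as.integer(tab), nrow = length(.modelClasses),
                dimnames = list(.modelClasses, groups))
    m
}

#' Percentage shares of a syndrome-by-model table
#'
#' @param table 3 x c count matrix (classes x groups).
#' @return list with `total` (share of each class in the grand total, %),
#'   `withinClass` (distribution of each class's species across groups, %)
#'   and `withinGroup` (distribution of each group's species across classes,
#'   %).
#' @export
contingencyShares <- function(table) {
    N <- sum(table)
    list(total = rowSums(table) / N * 100,
         withinClass = sweep(table, 1L, rowSums(table), "/") * 100,
         withinGroup = sweep(table, 2L, colSums(table), "/") * 100)
}

# log multivariate hypergeometric probability of a table given its margins
.logHyperProb <- function(tab) {
    sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
        lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Monte-Carlo Fisher exact test for an r x c table
#'
#' Tests independence of rows and columns: `nSims` tables are drawn with the
#' observed margins fixed (Patefield's algorithm), the test statistic is the
#' multivariate-hypergeometric probability of each table, and
#' p = (1 + #\{simulated tables at most as probable as the observed one\}) /
#' (nSims + 1). Rows or columns with zero marginal are dropped with a
#' warning before testing.
#'
#' @param table matrix of non-negative counts with at least 2 rows and
#'   columns of positive marginal.
#' @param nSims number of Monte-Carlo tables (default 10000, minimum 1000).
#' @param seed optional integer seed.
#' @return list with elements statistic (log table probability), p_value,
#'   method, n_sims.
#' @examples
#' fisherExactMC(bciSyndromeModelCounts(), nSims = 10000, seed = 1)$p_value
#' @export
fisherExactMC <- function(table, nSims = 10000, seed = NULL) {
    stopifnot(nSims >= 1000)
    table <- as.matrix(table)
    if (any(table < 0) || any(table != round(table)))
        stop("table must contain non-negative integer counts")
    zr <- rowSums(table) == 0; zc <- colSums(table) == 0
    if (any(zr) || any(zc)) {
        warning("dropping ", sum(zr), " zero row(s) and ", sum(zc),
                " zero column(s)")
        table <- table[!zr, !zc, drop = FALSE]
    }
    if (nrow(table) < 2L || ncol(table) < 2L)
        stop("need at least 2 rows and 2 columns with positive marginals")
    obs <- .logHyperProb(table)
    p <- withSeed(seed, {
        sims <- r2dtable(nSims, rowSums(table), colSums(table))
        lp <- vapply(sims, .logHyperProb, numeric(1))
        # tolerance guards equal-probability tables against rounding
        (1 + sum(lp <= obs + 1e-7)) / (nSims + 1)
    })
    list(statistic = obs, p_value = p,
         method = "Fisher exact test, Monte-Carlo p (fixed margins)",
         n_sims = nSims)
}

#' Exhaustive r x c Fisher exact test (small tables)
#'
#' Exact enumeration of all tables with the observed margins; p is the total
#' probability of tables no more probable than the observed one. Intended as
#' an independent check of [fisherExactMC()] on small tables.
#'
#' @param table small matrix of non-negative counts.
#' @return exact p-value.
#' @export
fisherExactEnum <- function(table) {
    table <- as.matrix(table)
    rs <- rowSums(table); cs <- colSums(table)
    obs <- .logHyperProb(table)
    pTot <- 0
    recurse <- function(filled, rowIdx) {
        if (rowIdx == nrow(table)) {
            last <- cs - colSums(filled)
            if (any(last < 0)) return()
            tab <- rbind(filled, last)
            lp <- .logHyperProb(tab)
            if (lp <= obs + 1e-7) pTot <<- pTot + exp(lp)
            return()
        }
        remCol <- cs - colSums(filled)
        fillRow <- function(row, colIdx, left) {
            if (colIdx == ncol(table)) {
                if (left <= remCol[colIdx])
                    recurse(rbind(filled, c(row, left)), rowIdx + 1L)
                return()
            }
            for (v in 0:min(left, remCol[colIdx]))
                fillRow(c(row, v), colIdx + 1L, left - v)
        }
        fillRow(numeric(0), 1L, rs[rowIdx])
    }
    recurse(matrix(0, 0L, ncol(table)), 1L)
    min(pTot, 1)
}

#' Adjusted standardized residuals of a contingency table
#'
#' r_ij = (O_ij - E_ij) / sqrt(E_ij (1 - row_i/N) (1 - col_j/N)) with
#' E_ij = row_i col_j / N. These are unit-variance under independence, so
#' |r| > 2 flags a cell departing from independence at roughly the 5% level
#' and |r| > 4 far beyond it. Cells with zero expectation get residual 0
#' with a warning.
#'
#' @param table matrix of non-negative counts with positive grand total.
#' @return matrix of residuals, same shape and dimnames.
#' @export
contingencyResiduals <- function(table) {
    table <- as.matrix(table)
    N <- sum(table)
    if (N <= 0) stop("positive grand total required")
    rs <- rowSums(table); cs <- colSums(table)
    E <- outer(rs, cs) / N
    V <- E * outer(1 - rs / N, 1 - cs / N)
    res <- matrix(0, nrow(table), ncol(table), dimnames = dimnames(table))
    ok <- E > 0 & V > 0
    if (any(E == 0)) warning("zero expected cell(s); residual reported as 0")
    res[ok] <- (table[ok] - E[ok]) / sqrt(V[ok])
    res
}

#' Kruskal-Wallis rank test across groups of cluster scales
#'
#' H statistic with midrank ties and tie correction, df = number of groups
#' minus 1, chi-square p-value (delegates to [stats::kruskal.test()]). If
#' all observations are identical, H = 0 and p = 1 with a warning.
#'
#' @param groups named list of numeric vectors (>= 2 non-empty groups).
#' @return list with statistic, df, p_value, method.
#' @export
kruskalWallisTest <- function(groups) {
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    if (length(groups) < 2L) stop("need at least 2 non-empty groups")
    vals <- unlist(groups, use.names = FALSE)
    if (length(unique(vals)) == 1L) {
        warning("all observations identical; H = 0")
        return(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                    method = "Kruskal-Wallis rank sum test"))
    }
    kt <- kruskal.test(groups)
    list(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, method = "Kruskal-Wallis rank sum test")
}

#' Two-sample Wilcoxon rank-sum test
#'
#' W is the sum of midranks of sample `a` minus n_a (n_a + 1) / 2 (so W runs
#' from 0 to n_a n_b, with n_a n_b / 2 under exchangeability). The p-value is
#' exact (enumeration) for small tie-free samples and uses the normal
#' approximation with tie and continuity correction otherwise (delegates to
#' [stats::wilcox.test()]).
#'
#' @param a,b numeric samples.
#' @param alternative "two.sided" (default), "less" or "greater".
#' @param exact force exact/approximate p; NULL picks automatically.
#' @return list with statistic (W), p_value, method, alternative.
#' @export
wilcoxonRankSum <- function(a, b, alternative = c("two.sided", "less",
                            "greater"), exact = NULL) {
    alternative <- match.arg(alternative)
    if (!length(a) || !length(b)) stop("both samples must be non-empty")
    wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                       exact = exact, correct = TRUE))
    # wilcox.test reports the rank-sum-minus-offset W already; recompute via
    # midranks so ties give the documented n_a n_b / 2 symmetry point exactly
    rk <- rank(c(a, b))
    W <- sum(rk[seq_along(a)]) - length(a) * (length(a) + 1) / 2
    list(statistic = W, p_value = wt$p.value, method = wt$method,
         alternative = alternative)
}

#' Per-group summary of fitted cluster scales
#'
#' For each (syndrome group, model class in {HPCP, IPCP}) cell: species
#' count, mean fitted sigma and SE = sd / sqrt(n) across species. Species
#' whose best model is IPP define no sigma and are excluded. Also returns
#' the pooled cluster-species set (HPCP and IPCP winners), the input to the
#' rank tests.
#'
#' @param results data.frame with columns species, group, best_model, sigma.
#' @param groups group labels (default canonical five).
#' @return list with `cells` (data.frame group, model, n, mean_sigma,
#'   se_sigma), and `pooled` (data.frame species, group, best_model, sigma
#'   for cluster-model winners).
#' @export
summarizeSigma <- function(results, groups = syndromeGroups()) {
    cl <- results[results$best_model %in% c("HPCP", "IPCP"), , drop = FALSE]
    grid <- expand.grid(group = groups, model = c("HPCP", "IPCP"),
                        stringsAsFactors = FALSE)
    cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
        s <- cl$sigma[cl$group == grid$group[i] &
                      cl$best_model == grid$model[i]]
        s <- s[is.finite(s)]
        n <- length(s)
        if (n == 1L) warning("single sigma in cell ", grid$group[i], "/",
                             grid$model[i], "; SE = 0")
        data.frame(group = grid$group[i], model = grid$model[i], n = n,
                   mean_sigma = if (n) mean(s) else NA_real_,
                   se_sigma = if (n > 1L) sd(s) / sqrt(n) else
                       if (n == 1L) 0 else NA_real_)
    }))
    list(cells = cells,
         pooled = cl[c("species", "group", "best_model", "sigma")])
}
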