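.groupToTraits <- function(group) {
    syn <- ifelse(grepl("^zoo-", group), "zoochorous", group)
    fr <- ifelse(grepl("^zoo-", group), sub("^zoo-", "", group),
                 "not-applicable")
    data.frame(syndrome = syn, fruit_class = fr, stringsAsFactors = FALSE)
}

#' Configuration of a synthetic multi-species community
#'
#' Defines the generating conditions of a synthetic stem map emulating a
#' tropical forest-dynamics census: a 1000 x 500 m window, 229 species, the
#' five dispersal-syndrome groups in the published 8/24/112/58/27
#' proportions, per-group mixtures over the generating model classes
#' (IPP/HPCP/IPCP), log-normal abundances (heavy right tail, as in tropical
#' plots) truncated at the 20-individual census threshold, per-group
#' log-normal cluster scales sigma, and Gaussian-bump trend surfaces with
#' bump scales of at least 50 m for the inhomogeneous species — keeping
#' heterogeneity (>= 50 m) and dispersal limitation (sigma mostly <= 25 m)
#' identifiable by construction.
#'
#' @param window a [Window-class] (default 1000 x 500 m).
#' @param nSpecies number of species (default 229).
#' @param groupProbs named probabilities of the five syndrome groups.
#' @param classMix named list (one entry per group) of probability vectors
#'   over c(IPP, HPCP, IPCP). Default: the published per-group frequencies.
#' @param sigmaMeanlog,sigmaSdlog named per-group log-normal parameters of
#'   the cluster scale sigma (m).
#' @param abundanceMeanlog,abundanceSdlog log-normal abundance parameters.
#' @param minN minimum individuals per retained species (default 20).
#' @param trendScale range of trend-surface bump scales (m), min >= 50.
#' @param muMeanlog,muSdlog log-normal parameters of the mean offspring
#'   count per parent for cluster species.
#' @return a list of class "communityConfig".
#' @export
communityConfig <- function(window = Window(1000, 500), nSpecies = 229,
        groupProbs = c(autochorous = 8, anemochorous = 24, `zoo-small` = 112,
                       `zoo-medium` = 58, `zoo-large` = 27) / 229,
        classMix = NULL,
        sigmaMeanlog = setNames(rep(log(12), 5), syndromeGroups()),
        sigmaSdlog = setNames(rep(0.4, 5), syndromeGroups()),
        abundanceMeanlog = log(60), abundanceSdlog = 0.8, minN = 20,
        trendScale = c(50, 150), muMeanlog = log(10), muSdlog = 0.4) {
    if (is.null(classMix)) {
        counts <- bciSyndromeModelCounts()
        classMix <- lapply(colnames(counts), function(g)
            counts[, g] / sum(counts[, g]))
        names(classMix) <- colnames(counts)
    }
    stopifnot(abs(sum(groupProbs) - 1) < 1e-8,
              all(vapply(classMix, function(p) abs(sum(p) - 1) < 1e-8,
                         logical(1))),
              all(unlist(sigmaMeanlog) > -Inf), all(unlist(sigmaSdlog) >= 0),
              minN >= 1, trendScale[1L] >= 50)
    structure(list(window = window, nSpecies = nSpecies,
                   groupProbs = groupProbs, classMix = classMix,
                   sigmaMeanlog = sigmaMeanlog, sigmaSdlog = sigmaSdlog,
                   abundanceMeanlog = abundanceMeanlog,
                   abundanceSdlog = abundanceSdlog, minN = minN,
                   trendScale = trendScale, muMeanlog = muMeanlog,
                   muSdlog = muSdlog),
              class = "communityConfig")
}

#' Named community scenario presets
#'
#' * `paper_like`: the default configuration — group sizes and per-group
#'   model-class mixtures matching the published contingency table (overall
#'   IPCP weight 144/229).
#' * `null_uniform`: identical sigma distribution and identical class mixture
#'   across all groups — the null for type-I calibration of the rank tests.
#' * `anemochorous_clustered`: HPCP-heavy anemochorous group (weights
#'   0.05/0.80/0.15) against an IPCP-leaning remainder, for power checks of
#'   the contingency test.
#'
#' @param name one of "null_uniform", "paper_like", "anemochorous_clustered".
#' @param ... overrides passed on to [communityConfig()].
#' @return a "communityConfig".
#' @export
scenarioPreset <- function(name, ...) {
    presets <- c("null_uniform", "paper_like", "anemochorous_clustered")
    if (!name %in% presets)
        stop("unknown preset '", name, "'; available: ",
             paste(presets, collapse = ", "))
    gps <- syndromeGroups()
    cfg <- switch(name,
        paper_like = communityConfig(...),
        null_uniform = {
            mix <- setNames(rep(list(c(IPP = 0.2, HPCP = 0.4, IPCP = 0.4)),
                                5), gps)
            communityConfig(classMix = mix, ...)
        },
        anemochorous_clustered = {
            mix <- setNames(rep(list(c(IPP = 0.15, HPCP = 0.15,
                                       IPCP = 0.70)), 5), gps)
            mix[["anemochorous"]] <- c(IPP = 0.05, HPCP = 0.80, IPCP = 0.15)
            communityConfig(classMix = mix, ...)
        })
    cfg
}

# Simulate one species of target abundance nTarget from its generating class;
# re-simulates (bounded) until the census threshold is met.
.simulateSpecies <- function(class, nTarget, sigma, hTrue, mu, cfg, id) {
    area <- windowArea(cfg$window)
    for (attempt in seq_len(20L)) {
        pp <- switch(class,
            CSR = simulateCSR(nTarget / area, cfg$window, speciesId = id),
            IPP = {
                surf <- trendSurface(cfg$window, minScale = hTrue,
                                     maxScale = hTrue, targetMass = nTarget)
                simulateIPP(surf, speciesId = id)
            },
            HPCP = simulateHPCP(nTarget / (mu * area), mu, sigma,
                                cfg$window, speciesId = id),
            IPCP = {
                surf <- trendSurface(cfg$window, minScale = hTrue,
                                     maxScale = hTrue, targetMass = nTarget)
                thin <- surfaceMass(surf) / (max(surf@values) * area)
                simulateHPCP(nTarget / (mu * area * thin), mu, sigma,
                             cfg$window, speciesId = id) |>
                    (\(pp0) {
                        keep <- runif(npoints(pp0)) <
                            evalSurface(surf, pp0@x, pp0@y) /
                                max(surf@values)
                        PointPattern(pp0@x[keep], pp0@y[keep], cfg$window, id)
                    })()
            },
            stop("unknown generating class: ", class))
        if (npoints(pp) >= cfg$minN) return(pp)
    }
    stop("infeasible config: species '", id, "' (class ", class,
         ", target n = ", round(nTarget),
         ") failed to reach minN after bounded redraws")
}

#' Generate a synthetic community with known ground truth
#'
#' Draws, for every species, a syndrome group, a generating model class from
#' the group's mixture, an abundance (log-normal, re-drawn until at least
#' `minN`), a cluster scale sigma and — for inhomogeneous classes — a fresh
#' Gaussian-bump trend surface, then simulates the stem map from the matching
#' process. Per-species randomness is driven by stable sub-seeds of `seed`,
#' so the output is bit-reproducible and adding a species never perturbs the
#' others.
#'
#' @param config a [communityConfig()].
#' @param seed integer seed (required for reproducibility).
#' @return list with `stems` (data.frame species, x, y), `traits`
#'   (data.frame species, syndrome, fruit_class), and `truth` (data.frame
#'   species, group, true_class, sigma, h_true, mu, n) — the ground-truth
#'   ledger with one record per emitted species.
#' @export
generateCommunity <- function(config, seed) {
    stopifnot(inherits(config, "communityConfig"))
    if (config$nSpecies == 0L)
        return(list(
            stems = data.frame(species = character(0), x = numeric(0),
                               y = numeric(0)),
            traits = data.frame(species = character(0),
                                syndrome = character(0),
                                fruit_class = character(0)),
            truth = data.frame(species = character(0), group = character(0),
                               true_class = character(0), sigma = numeric(0),
                               h_true = numeric(0), mu = numeric(0),
                               n = integer(0))))
    ids <- sprintf("sp%03d", seq_len(config$nSpecies))
    rows <- lapply(ids, function(id) {
        withSeed(subSeed(seed, id), {
            g <- sample(names(config$groupProbs), 1L,
                        prob = config$groupProbs)
            mix <- config$classMix[[g]]
            cls <- sample(c("IPP", "HPCP", "IPCP"), 1L, prob = mix)
            nT <- 0
            for (tr in seq_len(1000L)) {
                nT <- rlnorm(1L, config$abundanceMeanlog,
                             config$abundanceSdlog)
                if (nT >= config$minN) break
            }
            if (nT < config$minN)
                stop("infeasible config: abundance distribution cannot ",
                     "reach minN")
            sg <- rlnorm(1L, config$sigmaMeanlog[[g]], config$sigmaSdlog[[g]])
            mu <- rlnorm(1L, config$muMeanlog, config$muSdlog)
            hT <- runif(1L, config$trendScale[1L], config$trendScale[2L])
            pp <- .simulateSpecies(cls, nT, sg, hT, mu, config, id)
            list(pattern = pp,
                 truth = data.frame(species = id, group = g,
                     true_class = cls,
                     sigma = if (cls %in% c("HPCP", "IPCP")) sg else NA_real_,
                     h_true = if (cls %in% c("IPP", "IPCP")) hT else NA_real_,
                     mu = if (cls %in% c("HPCP", "IPCP")) mu else NA_real_,
                     n = npoints(pp)))
        })
    })
    stems <- do.call(rbind, lapply(rows, function(r)
        data.frame(species = speciesId(r$pattern), x = r$pattern@x,
                   y = r$pattern@y)))
    truth <- do.call(rbind, lapply(rows, `[[`, "truth"))
    traits <- cbind(data.frame(species = truth$species),
                    .groupToTraits(truth$group))
    list(stems = stems, traits = traits, truth = truth)
}

#' Write the three community outputs to a directory
#'
#' Standard stem-map CSV (species, x, y), trait CSV and ground-truth CSV.
#'
#' @param community result of [generateCommunity()].
#' @param dir output directory (created if missing).
#' @return named character vector of the three paths, invisibly.
#' @export
writeCommunity <- function(community, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(stems = file.path(dir, "stems.csv"),
               traits = file.path(dir, "traits.csv"),
               truth = file.path(dir, "truth.csv"))
    write.csv(community$stems, paths["stems"], row.names = FALSE,
              quote = FALSE)
    write.csv(community$traits, paths["traits"], row.names = FALSE,
              quote = FALSE)
    write.csv(community$truth, paths["truth"], row.names = FALSE,
              quote = FALSE)
    invisible(paths)
}
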