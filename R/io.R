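#' Read a stem map into per-species point patterns
#'
#' Reads a delimited stem map (one row per individual) and splits it into one
#' [PointPattern-class] per distinct species. The delimiter is auto-detected
#' between comma and tab. A header-only file yields an empty list.
#'
#' @param path path to a delimited text file with a header.
#' @param window the [Window-class] the coordinates live in.
#' @param columns named character vector mapping the roles `species`, `x`, `y`
#'   to column names in the file.
#' @return named list of [PointPattern-class], one per species.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("species,x,y", "sp1,1,1", "sp1,2,2", "sp2,5,5"), f)
#' pats <- readStemMap(f, Window(10, 10))
#' vapply(pats, npoints, integer(1))
#' @export
readStemMap <- function(path, window,
                        columns = c(species = "species", x = "x", y = "y")) {
    stopifnot(is(window, "Window"))
    df <- .readDelimAuto(path)
    miss <- setdiff(unname(columns), names(df))
    if (length(miss))
        stop("missing column(s) in stem map: ", paste(miss, collapse = ", "))
    if (nrow(df) == 0L)
        return(setNames(list(), character(0)))
    sp <- as.character(df[[columns[["species"]]]])
    xs <- .asNumericStrict(df[[columns[["x"]]]], columns[["x"]])
    ys <- .asNumericStrict(df[[columns[["y"]]]], columns[["y"]])
    bad <- which(xs < 0 | xs > window@width | ys < 0 | ys > window@height)
    if (length(bad))
        stop(sprintf("point outside window at row %d: (%g, %g)",
                     bad[1L], xs[bad[1L]], ys[bad[1L]]))
    idx <- split(seq_along(sp), sp)
    out <- lapply(names(idx), function(s)
        PointPattern(xs[idx[[s]]], ys[idx[[s]]], window, s))
    setNames(out, names(idx))
}

#' Split a stem-map data.frame into per-species point patterns
#'
#' In-memory counterpart of [readStemMap()]: takes a data.frame with columns
#' species, x, y and returns one [PointPattern-class] per distinct species.
#'
#' @param stems data.frame with columns species, x, y.
#' @param window the [Window-class] the coordinates live in.
#' @return named list of [PointPattern-class].
#' @export
patternsFromData <- function(stems, window) {
    stopifnot(is(window, "Window"),
              all(c("species", "x", "y") %in% names(stems)))
    idx <- split(seq_len(nrow(stems)), as.character(stems$species))
    setNames(lapply(names(idx), function(s)
        PointPattern(stems$x[idx[[s]]], stems$y[idx[[s]]], window, s)),
        names(idx))
}

.readDelimAuto <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

.asNumericStrict <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out)) {
        bad <- which(is.na(out))[1L]
        stop(sprintf("malformed numeric in column '%s' at row %d: '%s'",
                     what, bad, v[bad]))
    }
    out
}

#' Read a species trait table
#'
#' Reads a CSV of species traits with columns `species`, `syndrome` and
#' `fruit_class`. Syndromes are autochorous, anemochorous or zoochorous;
#' fruit size classes (small < 2 cm, medium 2-5 cm, large > 5 cm) apply to
#' zoochorous species only, all other species carry `not-applicable`.
#'
#' @param path path to the trait CSV/TSV.
#' @return data.frame with columns species, syndrome, fruit_class, group,
#'   where `group` is one of the five analysis groups (autochorous,
#'   anemochorous, zoo-small, zoo-medium, zoo-large).
#' @export
readTraitTable <- function(path) {
    df <- .readDelimAuto(path)
    need <- c("species", "syndrome", "fruit_class")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("missing column(s) in trait table: ", paste(miss, collapse = ", "))
    df$species <- as.character(df$species)
    if (anyDuplicated(df$species))
        stop("duplicate species in trait table: ",
             df$species[duplicated(df$species)][1L])
    okSyn <- c("autochorous", "anemochorous", "zoochorous")
    if (!all(df$syndrome %in% okSyn))
        stop("unknown syndrome: ", setdiff(df$syndrome, okSyn)[1L])
    okFr <- c("small", "medium", "large", "not-applicable")
    if (!all(df$fruit_class %in% okFr))
        stop("unknown fruit_class: ", setdiff(df$fruit_class, okFr)[1L])
    inconsistent <- xor(df$syndrome == "zoochorous",
                        df$fruit_class != "not-applicable")
    if (any(inconsistent))
        stop("fruit_class must be a size class iff syndrome is zoochorous ",
             "(offending species: ", df$species[inconsistent][1L], ")")
    df$group <- syndromeGroup(df$syndrome, df$fruit_class)
    df[c("species", "syndrome", "fruit_class", "group")]
}

#' Map syndrome and fruit class to the five analysis groups
#'
#' @param syndrome character vector of dispersal syndromes.
#' @param fruit_class character vector of fruit-size classes.
#' @return character vector over the five groups: autochorous, anemochorous,
#'   zoo-small, zoo-medium, zoo-large.
#' @export
syndromeGroup <- function(syndrome, fruit_class) {
    ifelse(syndrome == "zoochorous", paste0("zoo-", fruit_class), syndrome)
}

#' The five analysis-group labels, in canonical order
#' @export
syndromeGroups <- function() {
    c("autochorous", "anemochorous", "zoo-small", "zoo-medium", "zoo-large")
}

#' Drop species below a minimum abundance
#'
#' Spatial model fitting needs a reasonable minimum population size; the
#' conventional census threshold is 20 mapped individuals. Retains exactly
#' the species with n >= minN and reports the discarded ones via message().
#'
#' @param patterns named list of [PointPattern-class].
#' @param minN minimum number of individuals (default 20).
#' @return the retained sub-list, same ordering.
#' @export
filterMinAbundance <- function(patterns, minN = 20) {
    stopifnot(minN >= 1)
    n <- vapply(patterns, npoints, integer(1))
    dropped <- names(patterns)[n < minN]
    if (length(dropped))
        message("discarding ", length(dropped), " species below n = ", minN,
                ": ", paste(dropped, collapse = ", "))
    patterns[n >= minN]
}

#' Write the per-species results table
#'
#' One row per species: best-fitting model class, syndrome group, fitted
#' cluster scale sigma (NA for IPP winners), reported mean cluster size
#' 2 sigma, bandwidth and AIC. Always comma-delimited; round-trips through
#' [readResultsTable()].
#'
#' @param results data.frame with at least columns species, best_model,
#'   group, sigma, bandwidth, AIC.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeResultsTable <- function(results, path) {
    need <- c("species", "best_model", "group", "sigma", "bandwidth", "AIC")
    miss <- setdiff(need, names(results))
    if (length(miss))
        stop("results table missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(results$species))
        stop("duplicate species_id in results: ",
             results$species[duplicated(results$species)][1L])
    out <- results[need]
    out$cluster_size <- 2 * out$sigma
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read back a per-species results table written by [writeResultsTable()]
#' @param path path to the CSV.
#' @return data.frame.
#' @export
readResultsTable <- function(path) {
    read.csv(path, stringsAsFactors = FALSE)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# global stream is untouched. seed = NULL runs on the current stream.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Stable 31-bit sub-seed from a top-level seed and a species label, so adding
# a species to a community never perturbs the streams of the others.
subSeed <- function(seed, label) {
    h <- 0
    for (code in utf8ToInt(as.character(label)))
        h <- (h * 31 + code) %% 2147483647
    as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}
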