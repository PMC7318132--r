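# Intrinsic-reactivity data and the selectivity synthesis.
#
# Activation barriers for hydrogen abstraction at each candidate site are
# consumed as data (the package ships the transcribed testosterone barrier
# set for CYP-mediated hydroxylation, with and without dispersion
# correction). Reactivity enters the selectivity ranking through Boltzmann
# weights; accessibility through the profile percentages.

.R_KCAL <- 1.987204e-3  # gas constant, kcal mol^-1 K^-1 (fixed for reproducibility)

#' Load an activation-barrier table
#'
#' Reads a TSV with columns `site`, `dft_kcalmol` and `d3_kcalmol`
#' (`site`/`dft`/`d3` also accepted). With no argument, loads the packaged
#' testosterone hydrogen-abstraction barrier set (11 sites; `dft` = plain
#' hybrid-functional barrier, `d3` = dispersion-corrected), which also
#' serves for dihydrotestosterone since the corresponding sites share the
#' steroid scaffold and their intrinsic reactivities track each other.
#'
#' @param path TSV path, or NULL for the packaged table.
#' @return data.frame with columns `site`, `dft`, `d3` (kcal/mol).
#' @examples
#' tb <- loadBarrierTable()
#' tb[tb$site == "19", ]
#' @export
loadBarrierTable <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "tes_activation_barriers.tsv",
                            package = "nacprofiler", mustWork = TRUE)
    if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
    tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                            encoding = "UTF-8", check.names = FALSE)
    names(tb) <- sub("_kcalmol$", "", names(tb))
    if (!all(c("site", "dft", "d3") %in% names(tb)))
        stop("barrier table must have columns site, dft(_kcalmol), d3(_kcalmol)")
    tb <- tb[, c("site", "dft", "d3")]
    if (anyDuplicated(tb$site))
        stop(sprintf("duplicate site in barrier table: '%s'",
                     tb$site[duplicated(tb$site)][1L]))
    if (any(!is.finite(tb$dft)) || any(!is.finite(tb$d3)) ||
        any(tb$dft <= 0) || any(tb$d3 <= 0))
        stop("barriers must be finite and > 0")
    tb
}

#' Load experimental per-site turnover rates
#'
#' Reads a TSV with columns `site` and `rate_per_min`. With no argument,
#' loads the packaged recombinant-CYP3A4 testosterone hydroxylation rates
#' (sites 6β, 2β, 15β, 1β).
#'
#' @param path TSV path, or NULL for the packaged table.
#' @return named numeric vector of rates (min^-1).
#' @export
loadExperimentalRates <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "tes_cyp3a4_rates.tsv",
                            package = "nacprofiler", mustWork = TRUE)
    if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
    tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                            encoding = "UTF-8")
    if (!all(c("site", "rate_per_min") %in% names(tb)))
        stop("rate table must have columns site, rate_per_min")
    if (anyDuplicated(tb$site)) stop("duplicate site in rate table")
    if (any(tb$rate_per_min <= 0)) stop("rates must be > 0")
    setNames(tb$rate_per_min, tb$site)
}

.barrierColumn <- function(table, column = c("d3", "dft")) {
    column <- match.arg(column)
    setNames(table[[column]], table$site)
}

#' Site with the lowest activation barrier
#'
#' @param table barrier table from [loadBarrierTable()].
#' @param column `"d3"` (dispersion-corrected, default) or `"dft"`.
#' @return list with `site` and `barrier` (kcal/mol); ties broken by the
#'   lexicographically smallest site label.
#' @export
minBarrierSite <- function(table, column = c("d3", "dft")) {
    b <- .barrierColumn(table, column)
    if (length(b) == 0L) stop("empty barrier table")
    cand <- names(b)[b == min(b)]
    site <- sort(cand)[1L]
    list(site = site, barrier = unname(b[site]))
}

#' Signed barrier difference between two sites
#'
#' @param table barrier table from [loadBarrierTable()].
#' @param siteA,siteB site labels.
#' @param column `"d3"` (default) or `"dft"`.
#' @return `barrier(siteA) - barrier(siteB)` in kcal/mol.
#' @export
barrierDifference <- function(table, siteA, siteB, column = c("d3", "dft")) {
    b <- .barrierColumn(table, column)
    for (s in c(siteA, siteB))
        if (!s %in% names(b)) stop(sprintf("unknown site: '%s'", s))
    unname(b[siteA] - b[siteB])
}

#' Boltzmann weights from activation barriers
#'
#' `w_s = exp(-E_s / RT) / sum_t exp(-E_t / RT)` with
#' `R = 1.987204e-3 kcal mol^-1 K^-1`. Computed after subtracting the
#' minimum barrier, so spreads of hundreds of kcal/mol cannot overflow.
#' Weights are invariant under adding a constant to all barriers, and their
#' ordering is the reverse of the barrier ordering.
#'
#' @param table barrier table from [loadBarrierTable()].
#' @param column `"d3"` (default) or `"dft"`.
#' @param temperature in Kelvin (default 298.15).
#' @return named numeric vector of weights summing to 1;
#'   `attr(, "temperature")` records the temperature used.
#' @export
boltzmannWeights <- function(table, column = c("d3", "dft"),
                             temperature = 298.15) {
    if (!is.finite(temperature) || temperature <= 0)
        stop("temperature must be > 0 K")
    b <- .barrierColumn(table, column)
    if (length(b) == 0L) stop("empty barrier table")
    e <- exp(-(b - min(b)) / (.R_KCAL * temperature))
    w <- e / sum(e)
    attr(w, "temperature") <- temperature
    w
}

#' Combine accessibility and reactivity into a selectivity ranking
#'
#' Scores each site as `accessibility percentage x Boltzmann weight`,
#' renormalized to sum 1 over the sites present in both inputs. A site with
#' zero accessibility scores zero no matter how reactive it is (the enzyme
#' environment gates the intrinsic chemistry); a site absent from the
#' barrier table is reported with weight `NA` and excluded from the
#' normalized ranking, with a warning. Sites in the barrier table but not
#' the profile enter with accessibility 0. The score is scale-invariant in
#' both factors.
#'
#' @param profile an [AccessibilityProfile-class] object (or a data.frame
#'   with columns `site` and `percentage`).
#' @param weights named weight vector from [boltzmannWeights()].
#' @return data.frame with columns `site`, `accessibility`, `weight`,
#'   `score`, `rank`, ordered by descending score (ties by label; `NA`
#'   weights last).
#' @export
combineSelectivity <- function(profile, weights) {
    tb <- if (is(profile, "AccessibilityProfile")) profileTable(profile)
          else as.data.frame(profile)
    if (nrow(tb) == 0L && length(weights) == 0L)
        stop("both the profile and the weights are empty")
    acc <- setNames(tb$percentage, tb$site)
    sites <- union(names(acc), names(weights))
    a <- ifelse(sites %in% names(acc), acc[sites], 0)
    w <- ifelse(sites %in% names(weights), weights[sites], NA_real_)
    if (any(is.na(w)))
        warning(sprintf("site(s) without a barrier entry excluded from the ranking: %s",
                        paste(sites[is.na(w)], collapse = ", ")))
    raw <- a * w
    tot <- sum(raw, na.rm = TRUE)
    score <- if (tot > 0) raw / tot else raw * 0
    out <- data.frame(site = sites, accessibility = as.numeric(a),
                      weight = as.numeric(w), score = as.numeric(score),
                      stringsAsFactors = FALSE)
    out <- out[order(is.na(out$score), -out$score, out$site), , drop = FALSE]
    out$rank <- ifelse(is.na(out$score), NA_integer_, seq_len(nrow(out)))
    rownames(out) <- NULL
    attr(out, "temperature") <- attr(weights, "temperature")
    out
}

#' Spearman rank correlation between two per-site quantities
#'
#' Computed on the sites common to both inputs, with average ranks for
#' ties. Used to compare intrinsic-reactivity barriers with experimental
#' turnover rates (a perfect inverse ordering gives -1).
#'
#' @param x,y named numeric vectors (site -> value), >= 3 common sites.
#' @return Spearman rho in `[-1, 1]`.
#' @export
spearmanRank <- function(x, y) {
    common <- intersect(names(x), names(y))
    if (length(common) < 3L)
        stop("need at least 3 common sites")
    unname(stats::cor(x[common], y[common], method = "spearman"))
}
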