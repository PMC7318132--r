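# Configuration loading and end-to-end pipeline orchestration for the four
# workflows: simulate, profile, rmsf and selectivity.

.CONFIG_DEFAULTS <- list(
    dMin = 2.0, dMax = 3.5, thetaMin = 120,
    temperature = 298.15, denominator = "events", skipFrames = 0L,
    column = "d3", atomName = "CA", fe = "FE", oxo = "O1",
    logLevel = "info")

.CONFIG_KEYS <- list(
    profile = c("trajectory", "sitemap", "out", "fe", "oxo", "dMin", "dMax",
                "thetaMin", "denominator", "skipFrames", "logLevel"),
    rmsf = c("structures", "out", "atomName", "logLevel"),
    selectivity = c("profile", "out", "barriers", "column", "temperature",
                    "logLevel"),
    simulate = c("spec", "out", "sites", "nFrames", "seed", "dHit",
                 "thetaHit", "coaccessProb", "logLevel"))

.REQUIRED_KEYS <- list(
    profile = c("trajectory", "sitemap", "out"),
    rmsf = c("structures", "out"),
    selectivity = c("profile", "out"),
    simulate = c("out"))

#' Load and validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration (or takes a bare named list),
#' rejects unknown keys, fills defaults (NAC criterion 2.0/3.5/120,
#' temperature 298.15 K, events denominator, no frame skipping) and
#' validates every constraint before any computation runs.
#'
#' @param source file path (`.yaml`/`.yml`/`.json`) or named list.
#' @param command one of `"profile"`, `"rmsf"`, `"selectivity"`,
#'   `"simulate"`.
#' @return validated config list with `command` attached.
#' @export
loadConfig <- function(source, command = c("profile", "rmsf", "selectivity",
                                           "simulate")) {
    command <- match.arg(command)
    cfg <- if (is.character(source) && length(source) == 1L) {
        if (!file.exists(source))
            stop(sprintf("config file not found: '%s'", source))
        if (grepl("\\.json$", source, ignore.case = TRUE))
            jsonlite::read_json(source, simplifyVector = TRUE)
        else yaml::read_yaml(source)
    } else if (is.list(source)) source
    else stop("config source must be a file path or a named list")
    if (is.null(cfg)) cfg <- list()

    allowed <- .CONFIG_KEYS[[command]]
    unknown <- setdiff(names(cfg), allowed)
    if (length(unknown) > 0L)
        stop(sprintf("unknown config key(s) for '%s': %s", command,
                     paste(unknown, collapse = ", ")))
    for (k in intersect(allowed, names(.CONFIG_DEFAULTS)))
        if (is.null(cfg[[k]])) cfg[[k]] <- .CONFIG_DEFAULTS[[k]]
    missing <- setdiff(.REQUIRED_KEYS[[command]], names(cfg))
    if (length(missing) > 0L)
        stop(sprintf("missing required config key(s) for '%s': %s", command,
                     paste(missing, collapse = ", ")))

    chk <- function(ok, key, what)
        if (!ok) stop(sprintf("config key '%s': %s", key, what))
    if (!is.null(cfg$dMin)) {
        chk(is.numeric(cfg$dMin) && cfg$dMin > 0, "dMin", "must be > 0")
        chk(is.numeric(cfg$dMax) && cfg$dMax > cfg$dMin, "dMax",
            "must exceed dMin")
        chk(is.numeric(cfg$thetaMin) && cfg$thetaMin > 0 &&
                cfg$thetaMin < 180, "thetaMin", "must be in (0, 180)")
    }
    if (!is.null(cfg$temperature))
        chk(is.numeric(cfg$temperature) && cfg$temperature > 0,
            "temperature", "must be > 0 K")
    if (!is.null(cfg$denominator))
        chk(cfg$denominator %in% c("events", "frames"), "denominator",
            "must be 'events' or 'frames'")
    if (!is.null(cfg$skipFrames))
        chk(is.numeric(cfg$skipFrames) && cfg$skipFrames >= 0,
            "skipFrames", "must be >= 0")
    if (!is.null(cfg$column))
        chk(cfg$column %in% c("d3", "dft"), "column",
            "must be 'd3' or 'dft'")
    if (!is.null(cfg$logLevel))
        chk(cfg$logLevel %in% c("quiet", "info", "debug"), "logLevel",
            "must be quiet|info|debug")
    cfg$command <- command
    cfg
}

.logMsg <- function(cfg, ...) {
    if (!identical(cfg$logLevel, "quiet"))
        message(sprintf(...))
    invisible(NULL)
}

#' Run a pipeline command
#'
#' Orchestrates the four workflows end to end, writing TSV outputs (each
#' with a JSON mirror) into the configured output directory. All writes are
#' atomic (temp file + rename), so a failed run leaves no partial data
#' files; diagnostics go to the message stream, never into output files.
#'
#' \describe{
#'   \item{simulate}{synthetic spec -> `trajectory.pdb`, `sitemap.yaml`,
#'     `truth.json`.}
#'   \item{profile}{trajectory + sitemap -> `profile.tsv/.json`,
#'     `timeseries.tsv/.json`.}
#'   \item{rmsf}{structure list -> `rmsf.tsv/.json`.}
#'   \item{selectivity}{profile JSON + barrier table ->
#'     `ranking.tsv/.json`.}
#' }
#'
#' @param command one of `"profile"`, `"rmsf"`, `"selectivity"`,
#'   `"simulate"`.
#' @param config config list from [loadConfig()] (a bare list is accepted
#'   and validated first).
#' @return invisibly, a named vector of the files written.
#' @export
runPipeline <- function(command, config) {
    if (is.null(config$command) || !identical(config$command, command))
        config <- loadConfig(config, command)
    out <- config$out
    if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
    switch(command,
           simulate = .runSimulate(config),
           profile = .runProfile(config),
           rmsf = .runRmsf(config),
           selectivity = .runSelectivity(config))
}

.runSimulate <- function(cfg) {
    spec <- if (!is.null(cfg$spec)) {
        raw <- if (is.character(cfg$spec)) {
            if (!file.exists(cfg$spec))
                stop(sprintf("spec file not found: '%s'", cfg$spec))
            if (grepl("\\.json$", cfg$spec, ignore.case = TRUE))
                jsonlite::read_json(cfg$spec, simplifyVector = TRUE)
            else yaml::read_yaml(cfg$spec)
        } else cfg$spec
        syntheticSpec(unlist(raw$sites),
                      nFrames = raw$nFrames %||% 1000L,
                      seed = raw$seed %||% 1L,
                      dHit = raw$dHit %||% c(2.1, 3.4),
                      thetaHit = raw$thetaHit %||% c(125, 175),
                      coaccessProb = raw$coaccessProb %||% 0)
    } else {
        if (is.null(cfg$sites)) stop("simulate needs a 'spec' file or 'sites'")
        syntheticSpec(unlist(cfg$sites),
                      nFrames = cfg$nFrames %||% 1000L,
                      seed = cfg$seed %||% 1L,
                      dHit = cfg$dHit %||% c(2.1, 3.4),
                      thetaHit = cfg$thetaHit %||% c(125, 175),
                      coaccessProb = cfg$coaccessProb %||% 0)
    }
    .logMsg(cfg, "simulating %d frames over %d site(s), seed %d",
            spec@nFrames, nrow(spec@sites), spec@seed)
    paths <- writeSyntheticBundle(spec, cfg$out)
    invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.runProfile <- function(cfg) {
    traj <- readMultiModelPDB(cfg$trajectory)
    map <- readSiteMap(cfg$sitemap, traj)
    center <- catalyticCenter(traj, cfg$fe, cfg$oxo)
    crit <- nacCriterion(cfg$dMin, cfg$dMax, cfg$thetaMin)
    .logMsg(cfg, "profiling %d frames, %d site(s)", nFrames(traj),
            length(siteLabels(map)))
    prof <- accessibilityProfile(traj, map, center, crit,
                                 denominator = cfg$denominator,
                                 skipFrames = cfg$skipFrames)
    series <- accessTimeSeries(traj, map, center, crit,
                               skipFrames = cfg$skipFrames)
    paths <- c(profile = file.path(cfg$out, "profile.tsv"),
               timeseries = file.path(cfg$out, "timeseries.tsv"))
    writeProfileTable(prof, paths[["profile"]])
    writeTimeSeriesTable(series, paths[["timeseries"]])
    invisible(paths)
}

.runRmsf <- function(cfg) {
    paths <- cfg$structures
    if (length(paths) < 2L) stop("rmsf needs at least 2 structure files")
    structures <- lapply(paths, readMultiModelPDB)
    res <- ensembleRmsf(structures, atomName = cfg$atomName)
    .logMsg(cfg, "RMSF over %d structures, %d residue(s)", length(paths),
            nrow(res))
    out <- file.path(cfg$out, "rmsf.tsv")
    writeRmsfTable(res, out)
    invisible(c(rmsf = out))
}

.runSelectivity <- function(cfg) {
    pj <- jsonlite::read_json(cfg$profile, simplifyVector = TRUE)
    if (is.null(pj$sites))
        stop(sprintf("'%s' is not a profile JSON (no 'sites')", cfg$profile))
    tb <- loadBarrierTable(cfg$barriers)
    w <- boltzmannWeights(tb, cfg$column, cfg$temperature)
    ranking <- combineSelectivity(pj$sites, w)
    .logMsg(cfg, "ranked %d site(s) at %.2f K", nrow(ranking),
            cfg$temperature)
    out <- file.path(cfg$out, "ranking.tsv")
    writeRankingTable(ranking, out)
    invisible(c(ranking = out))
}
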