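# Multi-model PDB input, atom selection and tabular output.
#
# PDB field parsing and writing are delegated to bio3d; this layer adds the
# contracts the profiler relies on: models validated for identical atom
# counts/order before parsing, altloc resolution by highest occupancy, and
# deterministic tabular writers with JSON mirrors.

#' Construct a Trajectory
#'
#' @param topology data.frame with columns `serial`, `name`, `resname`,
#'   `resid`, `chain`, `element`.
#' @param coords either an `nAtoms x 3 x nFrames` array, an `nAtoms x 3`
#'   matrix (one frame), or a list of `nAtoms x 3` matrices.
#' @return a [Trajectory-class] object.
#' @export
newTrajectory <- function(topology, coords) {
    if (is.list(coords) && !is.array(coords))
        coords <- simplify2array(coords)
    coords <- as.array(coords)
    if (length(dim(coords)) == 2L)
        dim(coords) <- c(dim(coords), 1L)
    storage.mode(coords) <- "double"
    topology$serial <- as.integer(topology$serial)
    topology$resid <- as.integer(topology$resid)
    rownames(topology) <- NULL
    new("Trajectory", topology = topology, coords = coords)
}

# Validate MODEL blocks line-by-line before handing the file to bio3d:
# bio3d silently recycles coordinates when models differ in size, so the
# format errors required here are detected up front.
.validateModels <- function(lines, path) {
    rec <- substr(lines, 1L, 6L)
    isAtom <- rec == "ATOM  " | rec == "HETATM"
    if (!any(isAtom))
        stop(sprintf("format error in '%s': no ATOM/HETATM records", path))
    xyzText <- cbind(substr(lines[isAtom], 31L, 38L),
                     substr(lines[isAtom], 39L, 46L),
                     substr(lines[isAtom], 47L, 54L))
    bad <- which(is.na(suppressWarnings(array(as.numeric(xyzText),
                                              dim(xyzText)))),
                 arr.ind = TRUE)
    if (nrow(bad) > 0L) {
        lineno <- which(isAtom)[bad[1L, 1L]]
        stop(sprintf("format error in '%s': unparseable coordinate field at line %d",
                     path, lineno))
    }
    modelId <- cumsum(grepl("^MODEL", lines))[isAtom]
    if (max(modelId) == 0L) return(invisible(1L))   # single unnumbered model
    if (any(modelId == 0L))
        stop(sprintf("format error in '%s': ATOM records outside MODEL blocks",
                     path))
    # atom identity = name + altloc + residue name + chain + residue id
    ident <- substr(lines[isAtom], 13L, 27L)
    byModel <- split(ident, modelId)
    refN <- length(byModel[[1L]])
    for (m in seq_along(byModel)) {
        if (length(byModel[[m]]) != refN)
            stop(sprintf(
                "format error in '%s': model %d has %d atoms, expected %d",
                path, m, length(byModel[[m]]), refN))
        if (!identical(byModel[[m]], byModel[[1L]]))
            stop(sprintf(
                "format error in '%s': model %d atom order differs from model 1",
                path, m))
    }
    invisible(length(byModel))
}

# Altloc resolution: one atom per (name, resname, chain, resid, insert)
# group; keep the highest occupancy, ties -> first encountered.
.resolveAltloc <- function(atom) {
    alt <- atom$alt
    if (all(is.na(alt))) return(seq_len(nrow(atom)))
    grp <- paste(atom$elety, atom$resid, atom$chain, atom$resno, atom$insert,
                 sep = "\r")
    occ <- ifelse(is.na(atom$o), 1, atom$o)
    keep <- logical(nrow(atom))
    for (g in split(seq_len(nrow(atom)), grp)) {
        if (length(g) == 1L || all(is.na(alt[g]))) keep[g] <- TRUE
        else keep[g[which.max(occ[g])]] <- TRUE   # which.max: ties -> first
    }
    which(keep)
}

#' Read a multi-model PDB file as a Trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records is read as a single-frame trajectory. The topology is taken from
#' the first model. Alternate locations are resolved to the highest
#' occupancy (ties to the first encountered). Only ATOM/HETATM/MODEL/ENDMDL
#' records are interpreted. Models must have identical atom counts and
#' order, or a format error naming the offending model is raised.
#'
#' @param path PDB file path.
#' @return a [Trajectory-class] object, coordinates in Angstrom as read.
#' @export
readMultiModelPDB <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: '%s'", path))
    lines <- readLines(path, warn = FALSE)
    .validateModels(lines, path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    keep <- .resolveAltloc(pdb$atom)
    atom <- pdb$atom[keep, , drop = FALSE]
    xyzcols <- as.vector(rbind(3L * (keep - 1L) + 1L,
                               3L * (keep - 1L) + 2L,
                               3L * (keep - 1L) + 3L))
    xyz <- pdb$xyz[, xyzcols, drop = FALSE]         # nFrames x 3N
    nfr <- nrow(xyz); nat <- nrow(atom)
    coords <- array(NA_real_, c(nat, 3L, nfr))
    for (f in seq_len(nfr))
        coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    top <- data.frame(serial = atom$eleno,
                      name = atom$elety,
                      resname = atom$resid,
                      resid = atom$resno,
                      chain = ifelse(is.na(atom$chain), "", atom$chain),
                      element = ifelse(is.na(atom$elesy), "", atom$elesy),
                      stringsAsFactors = FALSE)
    newTrajectory(top, coords)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' Coordinates are written at the PDB fixed-column precision (3 decimals,
#' Angstrom); one MODEL block per frame.
#'
#' @param trajectory a [Trajectory-class] object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeMultiModelPDB <- function(trajectory, path) {
    stopifnot(is(trajectory, "Trajectory"))
    top <- topology(trajectory)
    nfr <- nFrames(trajectory)
    xyz <- t(apply(trajectory@coords, 3L, function(m) as.vector(t(m))))
    if (nfr == 1L) xyz <- matrix(xyz, nrow = 1L)
    .atomicWrite(path, function(tmp) {
        bio3d::write.pdb(file = tmp, xyz = xyz,
                         eleno = top$serial, elety = top$name,
                         resid = top$resname, resno = top$resid,
                         chain = ifelse(nzchar(top$chain), top$chain, " "),
                         elesy = top$element,
                         o = rep(1, nrow(top)), b = rep(0, nrow(top)))
    })
    invisible(path)
}

#' Build an atom selector
#'
#' A selector names an atom by `atomName` (required) plus optional
#' `residueName`, `residueId` and `chain` restrictions.
#'
#' @param atomName atom name, required (e.g. "FE").
#' @param residueName,residueId,chain optional restrictions.
#' @return a list of class `"AtomSelector"`.
#' @export
atomSelector <- function(atomName, residueName = NULL, residueId = NULL,
                         chain = NULL) {
    if (missing(atomName) || is.null(atomName) || !nzchar(atomName))
        stop("atomName is required")
    structure(list(atomName = atomName, residueName = residueName,
                   residueId = if (is.null(residueId)) NULL
                               else as.integer(residueId),
                   chain = chain),
              class = "AtomSelector")
}

#' Resolve an atom selector to a unique topology index
#'
#' @param trajectory a [Trajectory-class] object.
#' @param selector an [atomSelector()] (or a bare list with the same
#'   fields, or a single atom name string).
#' @return the unique 1-based topology index.
#' @export
resolveSelector <- function(trajectory, selector) {
    stopifnot(is(trajectory, "Trajectory"))
    if (is.character(selector) && length(selector) == 1L)
        selector <- atomSelector(selector)
    if (is.null(selector$atomName) || !nzchar(selector$atomName))
        stop("selector must set atomName")
    top <- topology(trajectory)
    hit <- top$name == selector$atomName
    if (!is.null(selector$residueName))
        hit <- hit & top$resname == selector$residueName
    if (!is.null(selector$residueId))
        hit <- hit & top$resid == as.integer(selector$residueId)
    if (!is.null(selector$chain))
        hit <- hit & top$chain == selector$chain
    idx <- which(hit)
    set <- Filter(Negate(is.null),
                  selector[c("atomName", "residueName", "residueId", "chain")])
    desc <- paste(names(set), unlist(set), sep = "=", collapse = ", ")
    if (length(idx) == 0L)
        stop(sprintf("no atom matches selector (%s)", desc))
    if (length(idx) > 1L)
        stop(sprintf("ambiguous selector (%s): matches serials %s", desc,
                     paste(top$serial[idx], collapse = ", ")))
    idx
}

# Atomic write: `writer` receives a temp path in the destination directory;
# the temp file is renamed over `path` only on success, so failed runs
# leave no partial output behind.
.atomicWrite <- function(path, writer) {
    dir <- dirname(path)
    if (!dir.exists(dir))
        stop(sprintf("output directory does not exist: '%s'", dir))
    tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    writer(tmp)
    if (!file.rename(tmp, path))
        stop(sprintf("cannot write output file: '%s'", path))
    invisible(path)
}

.writeTsv <- function(df, path) {
    .atomicWrite(path, function(tmp) {
        con <- file(tmp, open = "wb")
        on.exit(close(con))
        writeLines(paste(names(df), collapse = "\t"), con, sep = "\n",
                   useBytes = TRUE)
        if (nrow(df) > 0L) {
            rows <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
            writeLines(enc2utf8(rows), con, sep = "\n", useBytes = TRUE)
        }
    })
}

.jsonMirrorPath <- function(path) sub("\\.tsv$", ".json", path)

#' Write an accessibility profile as TSV (with a JSON mirror)
#'
#' Rows are ordered by descending percentage, ties broken by site label;
#' percentages are printed with 2 decimals. A JSON mirror (same stem,
#' `.json`) additionally carries the ensemble counters.
#'
#' @param profile an [AccessibilityProfile-class] object.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeProfileTable <- function(profile, path) {
    stopifnot(is(profile, "AccessibilityProfile"))
    tb <- profileTable(profile)
    out <- data.frame(site = tb$site, events = tb$events,
                      percentage = sprintf("%.2f", tb$percentage),
                      stereo_class = tb$stereoClass,
                      stringsAsFactors = FALSE)
    .writeTsv(out, path)
    .atomicWrite(.jsonMirrorPath(path), function(tmp) {
        jsonlite::write_json(
            list(sites = tb,
                 total_events = totalEvents(profile),
                 total_frames = totalFrames(profile),
                 frames_with_access = framesWithAccess(profile),
                 denominator = profile@denominator),
            tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    invisible(path)
}

#' Write an RMSF table as TSV (with a JSON mirror)
#'
#' Columns: chain, residue_id, rmsf_A and a `flexible` flag marking
#' residues with RMSF >= 1.0 Angstrom.
#'
#' @param rmsf data.frame from [ensembleRmsf()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeRmsfTable <- function(rmsf, path) {
    out <- data.frame(chain = rmsf$chain, residue_id = rmsf$resid,
                      rmsf_A = sprintf("%.4f", rmsf$rmsf),
                      flexible = rmsf$flexible, stringsAsFactors = FALSE)
    .writeTsv(out, path)
    .atomicWrite(.jsonMirrorPath(path), function(tmp) {
        jsonlite::write_json(
            list(selection = attr(rmsf, "selection"),
                 residues = rmsf),
            tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    invisible(path)
}

#' Write a selectivity ranking as TSV (with a JSON mirror)
#'
#' @param ranking data.frame from [combineSelectivity()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeRankingTable <- function(ranking, path) {
    out <- data.frame(site = ranking$site,
                      accessibility_pct = sprintf("%.2f", ranking$accessibility),
                      weight = ifelse(is.na(ranking$weight), "n/a",
                                      sprintf("%.6g", ranking$weight)),
                      score = ifelse(is.na(ranking$score), "n/a",
                                     sprintf("%.6g", ranking$score)),
                      rank = ifelse(is.na(ranking$rank), "n/a",
                                    as.character(ranking$rank)),
                      stringsAsFactors = FALSE)
    .writeTsv(out, path)
    .atomicWrite(.jsonMirrorPath(path), function(tmp) {
        jsonlite::write_json(list(ranking = ranking, temperature_K =
                                      attr(ranking, "temperature")),
                             tmp, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    })
    invisible(path)
}

#' Write a per-event access time series as TSV (with a JSON mirror)
#'
#' One row per (frame, site) access event, in frame order.
#'
#' @param series data.frame from [accessTimeSeries()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeTimeSeriesTable <- function(series, path) {
    out <- data.frame(frame = series$frame, site = series$site,
                      best_hydrogen = series$bestHydrogen,
                      h_oxo_A = sprintf("%.4f", series$hOxo),
                      h_oxo_fe_deg = sprintf("%.3f", series$hOxoFe),
                      stringsAsFactors = FALSE)
    .writeTsv(out, path)
    .atomicWrite(.jsonMirrorPath(path), function(tmp) {
        jsonlite::write_json(list(events = series,
                                  total_frames = attr(series, "totalFrames")),
                             tmp, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    })
    invisible(path)
}
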