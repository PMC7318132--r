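# Near-attack-conformation classification and per-site accessibility
# profiling. A site is "accessed" in a frame when at least one of its
# candidate hydrogens lies 2.0-3.5 Angstrom from the Compound I oxo atom
# with an H-oxo-Fe angle above 120 degrees (defaults; both configurable).

#' Construct a NAC criterion
#'
#' @param dMin,dMax H-oxo distance window in Angstrom, bounds inclusive
#'   (defaults 2.0 and 3.5).
#' @param thetaMin H-oxo-Fe angle threshold in degrees, strict (default 120).
#' @return a [NacCriterion-class] object.
#' @export
nacCriterion <- function(dMin = 2.0, dMax = 3.5, thetaMin = 120) {
    new("NacCriterion", dMin = as.numeric(dMin), dMax = as.numeric(dMax),
        thetaMin = as.numeric(thetaMin))
}

#' Locate the catalytic center in a trajectory
#'
#' Resolves the iron and oxo atoms and checks that their separation stays
#' in the physically sensible Fe(IV)=O range (1.4-2.2 Angstrom) in every
#' frame; frames outside the range trigger a warning, not an error, since a
#' drifting heme is a data-quality signal rather than a structural
#' impossibility.
#'
#' @param trajectory a [Trajectory-class] object.
#' @param fe,oxo atom selectors (see [atomSelector()]), bare atom-name
#'   strings, or 1-based topology indices.
#' @return a [CatalyticCenter-class] object.
#' @export
catalyticCenter <- function(trajectory, fe = "FE", oxo = "O1") {
    toIndex <- function(x) {
        if (is.numeric(x)) as.integer(x) else resolveSelector(trajectory, x)
    }
    feI <- toIndex(fe); oxoI <- toIndex(oxo)
    center <- new("CatalyticCenter", feIndex = feI, oxoIndex = oxoI)
    diff <- trajectory@coords[feI, , , drop = FALSE] -
        trajectory@coords[oxoI, , , drop = FALSE]
    dim(diff) <- dim(trajectory@coords)[2:3]
    d <- sqrt(colSums(diff^2))
    bad <- which(d <= 1.4 | d >= 2.2)
    if (length(bad) > 0L)
        warning(sprintf(
            "Fe-oxo distance outside (1.4, 2.2) Angstrom in %d frame(s), e.g. %.3f in frame %d",
            length(bad), d[bad[1L]], bad[1L]))
    center
}

#' Construct a SiteMap from hydrogen indices
#'
#' @param sites named list mapping a site label to
#'   `list(hydrogens = <indices>, stereoClass = <class>)`.
#' @param trajectory optional [Trajectory-class]; when given, indices are
#'   checked against the topology and must point at hydrogen-named atoms.
#' @return a [SiteMap-class] object.
#' @export
siteMap <- function(sites, trajectory = NULL) {
    sm <- new("SiteMap", sites = lapply(sites, function(e)
        list(hydrogens = as.integer(e$hydrogens),
             stereoClass = as.character(e$stereoClass))))
    if (!is.null(trajectory)) {
        nmax <- nAtoms(trajectory)
        for (lab in siteLabels(sm)) {
            h <- sm@sites[[lab]]$hydrogens
            if (any(h > nmax))
                stop(sprintf("site '%s': hydrogen index out of range", lab))
        }
    }
    sm
}

#' Read a SiteMap from a YAML/JSON file
#'
#' The file maps each site label to a list of atom selectors and a stereo
#' class, e.g. `sites: {"19": {hydrogens: [{atom_name: H1}], class: methyl}}`.
#' Selectors are resolved against the trajectory topology.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param trajectory the [Trajectory-class] the selectors refer to.
#' @return a [SiteMap-class] object.
#' @export
readSiteMap <- function(path, trajectory) {
    if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path) else yaml::read_yaml(path)
    if (is.null(raw$sites)) stop("sitemap file must have a top-level 'sites' map")
    sites <- lapply(raw$sites, function(e) {
        hyd <- vapply(e$hydrogens, function(sel) {
            resolveSelector(trajectory, atomSelector(
                atomName = sel$atom_name,
                residueName = sel$residue_name,
                residueId = sel$residue_id,
                chain = sel$chain_id))
        }, integer(1))
        list(hydrogens = hyd, stereoClass = e$class)
    })
    siteMap(sites, trajectory)
}

#' Write a SiteMap as a YAML file
#'
#' Hydrogen indices are exported as atom-name selectors, so the file can be
#' resolved against a round-tripped PDB of the same topology. Requires the
#' referenced atom names to be unique in the topology.
#'
#' @param map a [SiteMap-class] object.
#' @param trajectory the [Trajectory-class] providing atom names.
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
writeSiteMap <- function(map, trajectory, path) {
    top <- topology(trajectory)
    cls <- stereoClasses(map)
    entries <- lapply(siteLabels(map), function(lab) {
        h <- map@sites[[lab]]$hydrogens
        nm <- top$name[h]
        if (any(vapply(nm, function(x) sum(top$name == x), integer(1)) > 1L))
            stop(sprintf("site '%s': atom names are not unique in the topology",
                         lab))
        list(hydrogens = lapply(nm, function(x) list(atom_name = x)),
             class = unname(cls[[lab]]))
    })
    names(entries) <- siteLabels(map)
    .atomicWrite(path, function(tmp)
        yaml::write_yaml(list(sites = entries), tmp))
    invisible(path)
}

#' Evaluate one hydrogen against the NAC criterion
#'
#' @param frame nAtoms x 3 coordinate matrix (one frame), Angstrom.
#' @param hIndex hydrogen atom index.
#' @param center a [CatalyticCenter-class] object.
#' @param criterion a [NacCriterion-class] object.
#' @return list with `accessible` (logical), `hOxo` (Angstrom) and
#'   `hOxoFe` (degrees).
#' @export
evaluateHydrogen <- function(frame, hIndex, center,
                             criterion = nacCriterion()) {
    frame <- as.matrix(frame)
    h <- frame[hIndex, ]; oxo <- frame[center@oxoIndex, ]
    fe <- frame[center@feIndex, ]
    d <- pairwiseDistance(h, oxo)
    theta <- threePointAngle(h, oxo, fe)
    list(accessible = d >= criterion@dMin && d <= criterion@dMax &&
             theta > criterion@thetaMin,
         hOxo = d, hOxoFe = theta)
}

# Vectorized geometry over all frames for one hydrogen index.
# coords: nAtoms x 3 x nFrames. Returns list(d, theta), each length nFrames.
.hydrogenGeometry <- function(coords, hIndex, center) {
    H <- coords[hIndex, , , drop = FALSE]; dim(H) <- dim(coords)[2:3]
    O <- coords[center@oxoIndex, , , drop = FALSE]; dim(O) <- dim(coords)[2:3]
    FE <- coords[center@feIndex, , , drop = FALSE]; dim(FE) <- dim(coords)[2:3]
    u <- H - O                      # 3 x nFrames
    v <- FE - O
    d <- sqrt(colSums(u^2))
    nv <- sqrt(colSums(v^2))
    if (any(d <= 1e-6) || any(nv <= 1e-6))
        stop("degenerate geometry: hydrogen or iron coincides with the oxo atom")
    cosang <- colSums(u * v) / (d * nv)
    theta <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    list(d = d, theta = theta)
}

# Core classifier: per-site, per-frame accessibility with best-hydrogen
# geometry. Returns a list with per-site logical matrices and event details.
.classifyAll <- function(coords, map, center, criterion) {
    nfr <- dim(coords)[3L]
    labs <- names(map@sites)
    events <- vector("list", length(labs)); names(events) <- labs
    for (lab in labs) {
        hs <- map@sites[[lab]]$hydrogens
        dmat <- matrix(NA_real_, nfr, length(hs))
        tmat <- matrix(NA_real_, nfr, length(hs))
        for (j in seq_along(hs)) {
            g <- .hydrogenGeometry(coords, hs[j], center)
            dmat[, j] <- g$d; tmat[, j] <- g$theta
        }
        acc <- dmat >= criterion@dMin & dmat <= criterion@dMax &
            tmat > criterion@thetaMin
        hit <- rowSums(acc) > 0L
        # best hydrogen: accessible with minimal H-oxo; ties -> lowest index.
        # max.col on negated distances picks the first maximum, i.e. the
        # lowest-index minimum after masking inaccessible hydrogens.
        dmask <- dmat; dmask[!acc] <- Inf
        best <- max.col(-dmask, ties.method = "first")
        rows <- which(hit)
        events[[lab]] <- data.frame(
            frame = rows,
            site = rep(lab, length(rows)),
            bestHydrogen = hs[best[rows]],
            hOxo = dmat[cbind(rows, best[rows])],
            hOxoFe = tmat[cbind(rows, best[rows])],
            stringsAsFactors = FALSE)
    }
    events
}

#' Classify one frame against the NAC criterion
#'
#' For each site, the site yields at most one event per frame: it is
#' accessed when at least one of its hydrogens is accessible, and the
#' reported hydrogen is the accessible one with the smallest H-oxo distance
#' (ties broken by lowest atom index). Distinct sites may each yield an
#' event in the same frame.
#'
#' @param frame nAtoms x 3 coordinate matrix, Angstrom.
#' @param map a [SiteMap-class] object.
#' @param center a [CatalyticCenter-class] object.
#' @param criterion a [NacCriterion-class] object.
#' @return data.frame with one row per accessed site: `site`,
#'   `bestHydrogen`, `hOxo`, `hOxoFe` (empty when no site is accessed).
#' @export
classifyFrame <- function(frame, map, center, criterion = nacCriterion()) {
    coords <- as.matrix(frame)
    dim(coords) <- c(dim(coords), 1L)
    ev <- .classifyAll(coords, map, center, criterion)
    out <- do.call(rbind, ev)
    out <- out[, c("site", "bestHydrogen", "hOxo", "hOxoFe"), drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Per-frame access time series
#'
#' Runs the frame classifier over a whole trajectory and returns the long
#' event table: one row per (frame, site) access event, ordered by frame
#' then site label. Aggregating this table reproduces
#' [accessibilityProfile()] counts exactly; frames with no event contribute
#' no rows.
#'
#' @inheritParams accessibilityProfile
#' @return data.frame with columns `frame`, `site`, `bestHydrogen`, `hOxo`,
#'   `hOxoFe`; `attr(, "totalFrames")` records the ensemble size.
#' @export
accessTimeSeries <- function(trajectory, map, center,
                             criterion = nacCriterion(), skipFrames = 0L) {
    stopifnot(is(trajectory, "Trajectory"), is(map, "SiteMap"))
    coords <- .skipFrames(trajectory, skipFrames)
    ev <- .classifyAll(coords, map, center, criterion)
    out <- do.call(rbind, ev)
    out <- out[order(out$frame, out$site), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "totalFrames") <- dim(coords)[3L]
    out
}

.skipFrames <- function(trajectory, skipFrames) {
    skipFrames <- as.integer(skipFrames)
    if (skipFrames < 0L || skipFrames >= nFrames(trajectory))
        stop("skipFrames must be in [0, nFrames - 1]")
    trajectory@coords[, , (skipFrames + 1L):nFrames(trajectory),
                      drop = FALSE]
}

#' Per-site accessibility profile over an ensemble
#'
#' For each site, counts the frames in which the site was accessed (at
#' least one of its hydrogens in a near-attack conformation) and expresses
#' the count as a percentage. Under `denominator = "events"` (default) the
#' divisor is the total number of (frame, site) access events, so a frame
#' exposing two sites contributes two to the denominator and percentages
#' always sum to 100; under `"frames"` the divisor is the number of frames
#' with at least one access.
#'
#' @param trajectory a [Trajectory-class] object.
#' @param map a [SiteMap-class] object.
#' @param center a [CatalyticCenter-class] object.
#' @param criterion a [NacCriterion-class] object.
#' @param denominator `"events"` (default) or `"frames"`.
#' @param skipFrames number of leading frames to drop before profiling
#'   (equilibration trimming; default 0).
#' @return an [AccessibilityProfile-class] object.
#' @export
accessibilityProfile <- function(trajectory, map, center,
                                 criterion = nacCriterion(),
                                 denominator = c("events", "frames"),
                                 skipFrames = 0L) {
    stopifnot(is(trajectory, "Trajectory"), is(map, "SiteMap"))
    denominator <- match.arg(denominator)
    coords <- .skipFrames(trajectory, skipFrames)
    ev <- .classifyAll(coords, map, center, criterion)
    counts <- vapply(ev, nrow, integer(1))
    totalFrames <- dim(coords)[3L]
    totalEvents <- sum(counts)
    framesAcc <- length(unique(unlist(lapply(ev, `[[`, "frame"))))
    denomN <- if (denominator == "events") totalEvents else framesAcc
    pct <- if (denomN > 0L) 100 * counts / denomN else rep(0, length(counts))
    if (totalEvents == 0L)
        warning("no access events observed; all percentages are zero")
    tb <- data.frame(site = names(counts), events = as.integer(counts),
                     percentage = as.numeric(pct),
                     stereoClass = unname(stereoClasses(map)[names(counts)]),
                     stringsAsFactors = FALSE)
    tb <- tb[order(-tb$percentage, tb$site), , drop = FALSE]
    rownames(tb) <- NULL
    new("AccessibilityProfile", table = tb,
        totalEvents = as.integer(totalEvents),
        totalFrames = as.integer(totalFrames),
        framesWithAccess = as.integer(framesAcc),
        denominator = denominator)
}

#' Share of access events per stereochemical class
#'
#' Sums the per-site percentages by stereo class; the alpha share quantifies
#' how often a scaffold flip exposes alpha-face hydrogens to the oxo moiety.
#'
#' @param profile an [AccessibilityProfile-class] object.
#' @param map the [SiteMap-class] the profile was computed from.
#' @return named numeric vector over `alpha`, `beta`, `methyl`, `other`.
#' @export
stereoSummary <- function(profile, map) {
    stopifnot(is(profile, "AccessibilityProfile"), is(map, "SiteMap"))
    tb <- profileTable(profile)
    if (!all(tb$site %in% siteLabels(map)))
        stop("profile contains sites absent from the site map")
    cls <- stereoClasses(map)[tb$site]
    out <- setNames(numeric(length(.STEREO_CLASSES)), .STEREO_CLASSES)
    agg <- tapply(tb$percentage, cls, sum)
    out[names(agg)] <- agg
    out
}
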