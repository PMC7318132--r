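#' @import methods
NULL

#' Trajectory: a structural ensemble with a fixed topology
#'
#' A `Trajectory` holds an ordered atom table (the topology) and one
#' coordinate set per frame, all in Angstrom. Every frame must supply one
#' 3-vector per topology atom, in the same atom order; this mirrors the
#' snapshot series written out by molecular-dynamics engines as multi-model
#' PDB.
#'
#' The topology is a `data.frame` with columns `serial` (PDB serial,
#' preserved for reporting), `name` (atom name), `resname`, `resid`
#' (residue number), `chain` and `element`. Atom indices used throughout
#' the package are 1-based positions in this table.
#'
#' @slot topology data.frame of atom records (see Details).
#' @slot coords numeric array of dimension `c(nAtoms, 3, nFrames)`, Angstrom.
#'
#' @seealso [readMultiModelPDB()], [frameCoords()], [nFrames()]
#' @export
setClass("Trajectory", slots = c(topology = "data.frame", coords = "array"))

setValidity("Trajectory", function(object) {
    top <- object@topology
    need <- c("serial", "name", "resname", "resid", "chain", "element")
    if (!all(need %in% names(top)))
        return(paste("topology must have columns:", paste(need, collapse = ", ")))
    d <- dim(object@coords)
    if (length(d) != 3L || d[2L] != 3L)
        return("coords must be an nAtoms x 3 x nFrames array")
    if (d[3L] < 1L)
        return("a Trajectory needs at least one frame")
    if (d[1L] != nrow(top))
        return("coords first dimension must equal the number of topology atoms")
    if (nrow(top) > 0L && any(!nzchar(top$name)))
        return("atom names must be non-empty")
    if (any(!is.finite(object@coords)))
        return("all coordinates must be finite")
    TRUE
})

#' Near-attack-conformation criterion
#'
#' The geometric definition of an accessible (near-attack) conformation for
#' hydrogen abstraction by Compound I: the hydrogen-to-oxo distance must lie
#' inside `[dMin, dMax]` (bounds inclusive) and the hydrogen-oxo-iron angle
#' must exceed `thetaMin` (strict). Defaults are the standard HAT window of
#' 2.0-3.5 Angstrom and 120 degrees.
#'
#' @slot dMin,dMax numeric, Angstrom; `0 < dMin < dMax`.
#' @slot thetaMin numeric, degrees in (0, 180).
#' @export
setClass("NacCriterion",
         slots = c(dMin = "numeric", dMax = "numeric", thetaMin = "numeric"))

setValidity("NacCriterion", function(object) {
    if (length(object@dMin) != 1L || length(object@dMax) != 1L ||
        length(object@thetaMin) != 1L)
        return("dMin, dMax and thetaMin must be scalars")
    if (!is.finite(object@dMin) || !is.finite(object@dMax) ||
        !is.finite(object@thetaMin))
        return("criterion values must be finite")
    if (!(object@dMin > 0 && object@dMin < object@dMax))
        return("need 0 < dMin < dMax")
    if (!(object@thetaMin > 0 && object@thetaMin < 180))
        return("need 0 < thetaMin < 180")
    TRUE
})

#' Catalytic center of the heme
#'
#' Indices (1-based, into a trajectory topology) of the iron and oxo atoms
#' of Compound I. Construct with [catalyticCenter()], which resolves atom
#' selectors and sanity-checks the Fe-oxo distance across frames.
#'
#' @slot feIndex,oxoIndex integer atom indices.
#' @export
setClass("CatalyticCenter",
         slots = c(feIndex = "integer", oxoIndex = "integer"))

setValidity("CatalyticCenter", function(object) {
    if (length(object@feIndex) != 1L || length(object@oxoIndex) != 1L)
        return("feIndex and oxoIndex must be single indices")
    if (is.na(object@feIndex) || is.na(object@oxoIndex))
        return("indices must not be NA")
    if (object@feIndex < 1L || object@oxoIndex < 1L)
        return("indices must be >= 1")
    if (object@feIndex == object@oxoIndex)
        return("feIndex and oxoIndex must differ")
    TRUE
})

#' Site map: candidate hydrogens per site of metabolism
#'
#' Maps each site-of-metabolism label (e.g. `"6β"`, `"19"`) to the
#' topology indices of its candidate abstractable hydrogens and a
#' stereochemical class. Stereo-distinct hydrogens on one carbon (6α vs
#' 6β) are separate sites; a methyl site owns its three equivalent
#' hydrogens. Hydrogen index lists must be pairwise disjoint across sites.
#'
#' @slot sites named list; each element is `list(hydrogens = <integer>,
#'   stereoClass = <"alpha"|"beta"|"methyl"|"other">)`.
#' @seealso [siteMap()], [readSiteMap()]
#' @export
setClass("SiteMap", slots = c(sites = "list"))

.STEREO_CLASSES <- c("alpha", "beta", "methyl", "other")

setValidity("SiteMap", function(object) {
    s <- object@sites
    if (length(s) == 0L) return("a SiteMap needs at least one site")
    if (is.null(names(s)) || any(!nzchar(names(s))))
        return("all sites must be named")
    if (anyDuplicated(names(s)))
        return("duplicate site labels")
    allh <- integer(0)
    for (lab in names(s)) {
        e <- s[[lab]]
        if (!is.list(e) || !all(c("hydrogens", "stereoClass") %in% names(e)))
            return(sprintf("site '%s' must have $hydrogens and $stereoClass", lab))
        h <- e$hydrogens
        if (length(h) == 0L || !is.numeric(h) || any(h != as.integer(h)) ||
            any(h < 1L))
            return(sprintf("site '%s': hydrogens must be positive integer indices", lab))
        if (!e$stereoClass %in% .STEREO_CLASSES)
            return(sprintf("site '%s': stereoClass must be one of %s", lab,
                           paste(.STEREO_CLASSES, collapse = "|")))
        allh <- c(allh, as.integer(h))
    }
    if (anyDuplicated(allh))
        return("hydrogen indices must be disjoint across sites")
    TRUE
})

#' Per-site accessibility profile over an ensemble
#'
#' The per-site access-event statistic: for each site, the number of frames
#' in which at least one of its hydrogens satisfied the NAC criterion, and
#' the corresponding percentage. Under the default `"events"` denominator a
#' site's percentage is its event count divided by the total number of
#' (frame, site) access events, so percentages sum to 100 whenever any
#' event was observed; under the `"frames"` denominator the divisor is the
#' number of frames with at least one access (percentages may then exceed
#' 100 in total when sites co-occur).
#'
#' @slot table data.frame with columns `site`, `events`, `percentage`,
#'   `stereoClass`, ordered by descending percentage (ties by label).
#' @slot totalEvents,totalFrames,framesWithAccess integer counters.
#' @slot denominator `"events"` or `"frames"`.
#' @seealso [accessibilityProfile()], [stereoSummary()]
#' @export
setClass("AccessibilityProfile",
         slots = c(table = "data.frame", totalEvents = "integer",
                   totalFrames = "integer", framesWithAccess = "integer",
                   denominator = "character"))

setValidity("AccessibilityProfile", function(object) {
    tb <- object@table
    need <- c("site", "events", "percentage", "stereoClass")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    if (!object@denominator %in% c("events", "frames"))
        return("denominator must be 'events' or 'frames'")
    if (any(tb$events < 0L)) return("event counts must be >= 0")
    if (any(tb$events > object@totalFrames))
        return("a site cannot have more events than frames")
    if (object@totalEvents != sum(tb$events))
        return("totalEvents must equal the sum of per-site events")
    if (object@framesWithAccess > object@totalFrames)
        return("framesWithAccess cannot exceed totalFrames")
    if (object@totalEvents > 0L && object@denominator == "events") {
        if (abs(sum(tb$percentage) - 100) > 1e-6)
            return("percentages must sum to 100 under the events denominator")
    }
    if (object@totalEvents == 0L && any(tb$percentage != 0))
        return("percentages must all be zero when no events were observed")
    TRUE
})

#' Specification of a synthetic active-site trajectory
#'
#' Defines the stochastic ground truth for [simulateTrajectory()]: per frame
#' one site (or none) is drawn from a categorical distribution and one of
#' its hydrogens is placed at a "hit" geometry satisfying the default NAC
#' criterion, while every other hydrogen is placed at a "miss" geometry
#' violating it by construction. The expected per-site percentage is
#' `100 * p_s / sum(p)` and the expected fraction of frames with access is
#' `sum(p)` (see [expectedProfile()]).
#'
#' @slot sites data.frame with columns `label`, `prob`, `stereoClass`,
#'   `nHydrogens` (1-3 hydrogens per site).
#' @slot nFrames,seed integers.
#' @slot dHit numeric length 2, hit-distance window (inside 2.0-3.5).
#' @slot thetaHit numeric length 2, hit-angle window (above 120, below 180).
#' @slot coaccessProb probability that a frame with a primary hit also hits
#'   a second, distinct site (exercises the event-vs-frame denominator).
#' @seealso [syntheticSpec()], [simulateTrajectory()], [expectedProfile()]
#' @export
setClass("SyntheticSpec",
         slots = c(sites = "data.frame", nFrames = "integer",
                   seed = "integer", dHit = "numeric", thetaHit = "numeric",
                   coaccessProb = "numeric"))

setValidity("SyntheticSpec", function(object) {
    s <- object@sites
    need <- c("label", "prob", "stereoClass", "nHydrogens")
    if (!all(need %in% names(s)))
        return(paste("sites must have columns:", paste(need, collapse = ", ")))
    if (nrow(s) < 1L) return("need at least one site")
    if (anyDuplicated(s$label)) return("duplicate site labels")
    if (any(s$prob < 0) || sum(s$prob) > 1 + 1e-12)
        return("site probabilities must be >= 0 and sum to <= 1")
    if (!all(s$stereoClass %in% .STEREO_CLASSES))
        return("invalid stereoClass")
    if (any(!s$nHydrogens %in% 1:3))
        return("nHydrogens must be 1, 2 or 3")
    if (object@nFrames < 1L) return("nFrames must be >= 1")
    if (length(object@dHit) != 2L || object@dHit[1L] >= object@dHit[2L])
        return("dHit must be an increasing length-2 window")
    if (object@dHit[1L] < 2.0 || object@dHit[2L] > 3.5)
        return("dHit window must lie inside the 2.0-3.5 Angstrom criterion")
    if (length(object@thetaHit) != 2L || object@thetaHit[1L] >= object@thetaHit[2L])
        return("thetaHit must be an increasing length-2 window")
    if (object@thetaHit[1L] <= 120 || object@thetaHit[2L] >= 180)
        return("thetaHit window must lie strictly inside (120, 180) degrees")
    if (object@coaccessProb < 0 || object@coaccessProb > 1)
        return("coaccessProb must be in [0, 1]")
    if (object@coaccessProb > 0 && nrow(s) < 2L)
        return("coaccessProb > 0 needs at least two sites")
    TRUE
})
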