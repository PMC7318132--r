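# Synthetic active-site trajectories with known per-site accessibility
# ground truth.
#
# The generator emulates only what the profiler measures: per frame, sites
# compete stochastically for exposure to the oxo moiety, the winning site
# places one hydrogen at a geometry satisfying the NAC criterion, and every
# other hydrogen is placed at a geometry violating it by construction.
# Hydrogens move independently between frames -- there is no rigid-body
# substrate, force field or thermostat -- so the output is a statistical
# stand-in for an MD ensemble, not a simulation of one.

.FE_OXO_D <- 1.62  # Angstrom, ferryl Fe=O bond length used for the toy center

#' Construct a synthetic-trajectory specification
#'
#' @param sites named numeric vector of per-site hit probabilities
#'   (`sum <= 1`; the remainder is the no-access background), or a
#'   data.frame with columns `label`, `prob`, `stereoClass`, `nHydrogens`.
#' @param stereoClass,nHydrogens per-site vectors used when `sites` is a
#'   probability vector (recycled; defaults "other" and 1, with 3 hydrogens
#'   for `stereoClass = "methyl"`).
#' @param nFrames number of frames to simulate.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param dHit hit-distance window, inside the 2.0-3.5 criterion
#'   (default 2.1-3.4 Angstrom).
#' @param thetaHit hit-angle window, above the 120-degree threshold
#'   (default 125-175 degrees).
#' @param coaccessProb probability that a frame with a primary hit also
#'   exposes a second, distinct site (default 0).
#' @return a [SyntheticSpec-class] object.
#' @examples
#' syntheticSpec(c("19" = 0.45, "6β" = 0.05), nFrames = 1000, seed = 1)
#' @export
syntheticSpec <- function(sites, stereoClass = NULL, nHydrogens = NULL,
                          nFrames = 1000L, seed = 1L,
                          dHit = c(2.1, 3.4), thetaHit = c(125, 175),
                          coaccessProb = 0) {
    if (is.numeric(sites)) {
        labs <- names(sites)
        if (is.null(labs)) stop("site probabilities must be named")
        if (is.null(stereoClass))
            stereoClass <- vapply(labs, .guessStereoClass, character(1))
        stereoClass <- rep_len(stereoClass, length(sites))
        if (is.null(nHydrogens))
            nHydrogens <- ifelse(stereoClass == "methyl", 3L, 1L)
        nHydrogens <- rep_len(as.integer(nHydrogens), length(sites))
        sites <- data.frame(label = labs, prob = as.numeric(sites),
                            stereoClass = stereoClass,
                            nHydrogens = nHydrogens,
                            stringsAsFactors = FALSE)
    }
    new("SyntheticSpec", sites = as.data.frame(sites),
        nFrames = as.integer(nFrames), seed = as.integer(seed),
        dHit = as.numeric(dHit), thetaHit = as.numeric(thetaHit),
        coaccessProb = as.numeric(coaccessProb))
}

# Steroid site-label conventions: trailing alpha/beta mark the face,
# the angular methyls are 18 and 19.
.guessStereoClass <- function(label) {
    if (label %in% c("18", "19")) return("methyl")
    if (grepl("\u03b1$", label)) return("alpha")
    if (grepl("\u03b2$", label)) return("beta")
    "other"
}

#' Build the toy active-site topology for a synthetic spec
#'
#' A minimal Compound I plus substrate skeleton: Fe at the origin, the oxo
#' atom at (0, 0, 1.62) Angstrom, one dummy carbon per site and one
#' hydrogen atom per site hydrogen, all with unique atom names so that
#' selectors resolve unambiguously. Hydrogens start at a non-accessible
#' geometry.
#'
#' @param spec a [SyntheticSpec-class] object.
#' @return list with `trajectory` (single frame), `map` ([SiteMap-class])
#'   and `center` ([CatalyticCenter-class]).
#' @export
buildToyTopology <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    s <- spec@sites
    nH <- sum(s$nHydrogens)
    nAt <- 2L + nrow(s) + nH
    name <- character(nAt); resname <- character(nAt)
    resid <- integer(nAt); element <- character(nAt)
    name[1:2] <- c("FE", "O1"); resname[1:2] <- "HEM"; resid[1:2] <- 501L
    element[1:2] <- c("FE", "O")
    xyz <- matrix(0, nAt, 3L)
    xyz[2L, ] <- c(0, 0, .FE_OXO_D)
    # dummy substrate carbons on a ring above the heme plane
    k <- nrow(s)
    ang <- 2 * pi * (seq_len(k) - 1L) / k
    for (i in seq_len(k)) {
        row <- 2L + i
        name[row] <- paste0("C", i); resname[row] <- "LIG"
        resid[row] <- 502L; element[row] <- "C"
        xyz[row, ] <- c(4.5 * cos(ang[i]), 4.5 * sin(ang[i]), 3.0)
    }
    sites <- list(); hrow <- 2L + k
    for (i in seq_len(k)) {
        idx <- integer(s$nHydrogens[i])
        for (j in seq_len(s$nHydrogens[i])) {
            hrow <- hrow + 1L
            name[hrow] <- paste0("H", hrow); resname[hrow] <- "LIG"
            resid[hrow] <- 502L; element[hrow] <- "H"
            xyz[hrow, ] <- xyz[2L + i, ] + c(0, 0, 1.1)   # miss by distance
            idx[j] <- hrow
        }
        sites[[s$label[i]]] <- list(hydrogens = idx,
                                    stereoClass = s$stereoClass[i])
    }
    top <- data.frame(serial = seq_len(nAt), name = name, resname = resname,
                      resid = resid, chain = "A", element = element,
                      stringsAsFactors = FALSE)
    traj <- newTrajectory(top, xyz)
    list(trajectory = traj, map = siteMap(sites, traj),
         center = catalyticCenter(traj, "FE", "O1"))
}

# Hit geometry: H placed at distance d from the oxo with the H-oxo-Fe angle
# theta; the azimuth is uniform, so directions are isotropic subject to
# theta. The oxo sits at (0,0,1.62) with Fe along -z, hence the polar angle
# from +z is 180 - theta.
.hitPosition <- function(d, theta, phi) {
    alpha <- (180 - theta) * pi / 180
    c(d * sin(alpha) * cos(phi), d * sin(alpha) * sin(phi),
      .FE_OXO_D + d * cos(alpha))
}

# Miss geometry: distance-miss (d >= 4.0 regardless of direction) or
# angle-miss (theta <= 110 at criterion-range distance); both violate the
# default criterion by construction.
.missPosition <- function(kind, d, theta, phi) {
    if (kind == "distance") {
        u <- c(sin(theta * pi / 180) * cos(phi),
               sin(theta * pi / 180) * sin(phi), cos(theta * pi / 180))
        c(0, 0, .FE_OXO_D) + d * u
    } else .hitPosition(d, theta, phi)
}

#' Simulate a synthetic trajectory
#'
#' Per frame, one site (or the no-access background) is drawn from the
#' categorical distribution given by the spec probabilities; one uniformly
#' chosen hydrogen of the hit site is placed at a hit geometry and every
#' other site hydrogen at a miss geometry. With `coaccessProb > 0`, a frame
#' with a primary hit additionally hits a second distinct site (chosen with
#' probability proportional to the site probabilities) with that
#' probability. All randomness comes from one seeded generator consumed in
#' a fixed order (site draws, co-access draws, then per-frame geometry), so
#' the same spec always yields bit-identical coordinates.
#'
#' @param spec a [SyntheticSpec-class] object.
#' @return a [Trajectory-class] with `spec@nFrames` frames over the
#'   [buildToyTopology()] topology.
#' @export
simulateTrajectory <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    toy <- buildToyTopology(spec)
    base <- frameCoords(toy$trajectory, 1L)
    s <- spec@sites
    k <- nrow(s)
    nfr <- spec@nFrames
    hlist <- siteHydrogens(toy$map)[s$label]
    allH <- unlist(hlist)

    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec@seed)

    # draw order is fixed and documented: primary site per frame, then
    # co-access companions, then geometry frame by frame
    primary <- sample.int(k + 1L, nfr, replace = TRUE,
                          prob = c(1 - sum(s$prob), s$prob)) - 1L
    secondary <- rep(0L, nfr)
    if (spec@coaccessProb > 0) {
        co <- stats::runif(nfr) < spec@coaccessProb & primary > 0L
        for (f in which(co)) {
            p2 <- s$prob; p2[primary[f]] <- 0
            if (sum(p2) > 0)
                secondary[f] <- sample.int(k, 1L, prob = p2)
        }
    }
    coords <- array(NA_real_, c(nrow(base), 3L, nfr))
    for (f in seq_len(nfr)) {
        m <- base
        hit <- c(primary[f], secondary[f])
        hit <- hit[hit > 0L]
        hitH <- integer(0)
        for (si in hit) {
            hs <- hlist[[si]]
            h <- hs[sample.int(length(hs), 1L)]
            d <- stats::runif(1L, spec@dHit[1L], spec@dHit[2L])
            th <- stats::runif(1L, spec@thetaHit[1L], spec@thetaHit[2L])
            ph <- stats::runif(1L, 0, 2 * pi)
            m[h, ] <- .hitPosition(d, th, ph)
            hitH <- c(hitH, h)
        }
        for (h in setdiff(allH, hitH)) {
            if (stats::runif(1L) < 0.5)
                m[h, ] <- .missPosition("distance",
                                        stats::runif(1L, 4.5, 7.0),
                                        stats::runif(1L, 0, 180),
                                        stats::runif(1L, 0, 2 * pi))
            else
                m[h, ] <- .missPosition("angle",
                                        stats::runif(1L, spec@dHit[1L], spec@dHit[2L]),
                                        stats::runif(1L, 30, 110),
                                        stats::runif(1L, 0, 2 * pi))
        }
        coords[, , f] <- m
    }
    newTrajectory(topology(toy$trajectory), coords)
}

#' Closed-form ground truth for a synthetic spec
#'
#' Expected per-site percentage is `100 * p_s / sum(p)` and the expected
#' fraction of frames with access is `sum(p)`. Stated for
#' `coaccessProb = 0`; with co-access enabled the closed form covers
#' primary hits only and a warning is issued.
#'
#' @param spec a [SyntheticSpec-class] object.
#' @return list with `percentages` (named vector) and `accessFraction`.
#' @export
expectedProfile <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    p <- setNames(spec@sites$prob, spec@sites$label)
    tot <- sum(p)
    if (spec@coaccessProb > 0)
        warning("expectedProfile assumes coaccessProb = 0; expectations cover primary hits only")
    if (tot == 0) {
        warning("all site probabilities are zero")
        return(list(percentages = p * 0, accessFraction = 0))
    }
    list(percentages = 100 * p / tot, accessFraction = tot)
}

#' Write a synthetic bundle: trajectory, sitemap and ground truth
#'
#' Emits `trajectory.pdb` (multi-model), `sitemap.yaml` and `truth.json`
#' into `dir`, all consumable by the pipeline unchanged.
#'
#' @param spec a [SyntheticSpec-class] object.
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
writeSyntheticBundle <- function(spec, dir) {
    stopifnot(is(spec, "SyntheticSpec"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    traj <- simulateTrajectory(spec)
    toy <- buildToyTopology(spec)
    paths <- c(trajectory = file.path(dir, "trajectory.pdb"),
               sitemap = file.path(dir, "sitemap.yaml"),
               truth = file.path(dir, "truth.json"))
    writeMultiModelPDB(traj, paths[["trajectory"]])
    writeSiteMap(toy$map, traj, paths[["sitemap"]])
    gt <- suppressWarnings(expectedProfile(spec))
    .atomicWrite(paths[["truth"]], function(tmp)
        jsonlite::write_json(
            list(expected_percentages = as.list(gt$percentages),
                 expected_access_fraction = gt$accessFraction,
                 n_frames = spec@nFrames, seed = spec@seed),
            tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE))
    invisible(paths)
}
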