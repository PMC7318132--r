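# Accessors and show methods for the core classes.

#' Number of frames in a trajectory
#' @param x a [Trajectory-class] object.
#' @return integer.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3L])

#' Number of atoms in a trajectory topology
#' @param x a [Trajectory-class] object.
#' @return integer.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1L])

#' Topology atom table
#' @param x a [Trajectory-class] object.
#' @return data.frame of atom records.
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname topology
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' Coordinates of one frame
#' @param x a [Trajectory-class] object.
#' @param i frame index (1-based).
#' @return nAtoms x 3 numeric matrix, Angstrom.
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "Trajectory", function(x, i) {
    i <- as.integer(i)
    if (length(i) != 1L || is.na(i) || i < 1L || i > nFrames(x))
        stop("frame index out of range")
    m <- x@coords[, , i, drop = FALSE]
    dim(m) <- dim(x@coords)[1:2]
    colnames(m) <- c("x", "y", "z")
    m
})

#' Site labels of a SiteMap or profile
#' @param x a [SiteMap-class] or [AccessibilityProfile-class] object.
#' @return character vector of site labels.
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname siteLabels
#' @export
setMethod("siteLabels", "SiteMap", function(x) names(x@sites))

#' @rdname siteLabels
#' @export
setMethod("siteLabels", "AccessibilityProfile", function(x) x@table$site)

#' Stereochemical class per site
#' @param x a [SiteMap-class] object.
#' @return named character vector.
#' @export
setGeneric("stereoClasses", function(x) standardGeneric("stereoClasses"))

#' @rdname stereoClasses
#' @export
setMethod("stereoClasses", "SiteMap", function(x)
    vapply(x@sites, function(e) e$stereoClass, character(1)))

#' Hydrogen indices per site
#' @param x a [SiteMap-class] object.
#' @return named list of integer vectors.
#' @export
setGeneric("siteHydrogens", function(x) standardGeneric("siteHydrogens"))

#' @rdname siteHydrogens
#' @export
setMethod("siteHydrogens", "SiteMap", function(x)
    lapply(x@sites, function(e) as.integer(e$hydrogens)))

#' Profile table and counters
#'
#' `profileTable` returns the per-site table (site, events, percentage,
#' stereoClass); the counter accessors return the ensemble-level totals.
#'
#' @param x an [AccessibilityProfile-class] object.
#' @return `profileTable`: data.frame; the others: integer scalars.
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname profileTable
#' @export
setMethod("profileTable", "AccessibilityProfile", function(x) x@table)

#' @rdname profileTable
#' @export
setGeneric("totalEvents", function(x) standardGeneric("totalEvents"))

#' @rdname profileTable
#' @export
setMethod("totalEvents", "AccessibilityProfile", function(x) x@totalEvents)

#' @rdname profileTable
#' @export
setGeneric("totalFrames", function(x) standardGeneric("totalFrames"))

#' @rdname profileTable
#' @export
setMethod("totalFrames", "AccessibilityProfile", function(x) x@totalFrames)

#' @rdname profileTable
#' @export
setGeneric("framesWithAccess", function(x) standardGeneric("framesWithAccess"))

#' @rdname profileTable
#' @export
setMethod("framesWithAccess", "AccessibilityProfile",
          function(x) x@framesWithAccess)

setMethod("show", "Trajectory", function(object) {
    cat(sprintf("Trajectory: %d atoms, %d frame(s)\n",
                nAtoms(object), nFrames(object)))
    res <- unique(object@topology[, c("resname", "resid", "chain")])
    cat(sprintf("  residues: %d (%s)\n", nrow(res),
                paste(utils::head(paste0(res$resname, res$resid), 5L),
                      collapse = ", ")))
    invisible(NULL)
})

setMethod("show", "NacCriterion", function(object) {
    cat(sprintf(
        "NAC criterion: %.2f <= H-oxo <= %.2f Angstrom, H-oxo-Fe > %.1f deg\n",
        object@dMin, object@dMax, object@thetaMin))
    invisible(NULL)
})

setMethod("show", "SiteMap", function(object) {
    cls <- stereoClasses(object)
    nh <- vapply(object@sites, function(e) length(e$hydrogens), integer(1))
    cat(sprintf("SiteMap: %d site(s)\n", length(object@sites)))
    for (lab in names(object@sites))
        cat(sprintf("  %-6s %-7s %d hydrogen(s)\n", lab, cls[[lab]], nh[[lab]]))
    invisible(NULL)
})

setMethod("show", "AccessibilityProfile", function(object) {
    cat(sprintf(
        "AccessibilityProfile: %d frames, %d with access, %d events (denominator: %s)\n",
        object@totalFrames, object@framesWithAccess, object@totalEvents,
        object@denominator))
    print(object@table, row.names = FALSE)
    invisible(NULL)
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: %d site(s), %d frames, seed %d, P(background) = %.3f\n",
        nrow(object@sites), object@nFrames, object@seed,
        1 - sum(object@sites$prob)))
    print(object@sites, row.names = FALSE)
    invisible(NULL)
})
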