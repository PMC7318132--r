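# Vector geometry primitives: distances, angles, Kabsch superposition and
# per-residue ensemble RMSF.

.DEGEN_TOL <- 1e-6  # Angstrom; below this two points are treated as coincident

#' Euclidean distance between two points
#'
#' @param p,q numeric 3-vectors, Angstrom.
#' @return distance in Angstrom.
#' @examples
#' pairwiseDistance(c(0, 0, 0), c(0, 0, 2.5))
#' @export
pairwiseDistance <- function(p, q) {
    p <- as.numeric(p); q <- as.numeric(q)
    if (length(p) != 3L || length(q) != 3L)
        stop("points must be 3-vectors")
    if (any(!is.finite(p)) || any(!is.finite(q)))
        stop("points must be finite")
    sqrt(sum((p - q)^2))
}

#' Angle at a vertex between two points, in degrees
#'
#' Returns the angle between the vectors `a - vertex` and `c - vertex`,
#' in `[0, 180]` degrees. In NAC usage the vertex is the oxo atom, `a` the
#' abstractable hydrogen and `c` the heme iron.
#'
#' @param a,vertex,c numeric 3-vectors, Angstrom.
#' @return angle in degrees.
#' @examples
#' threePointAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
threePointAngle <- function(a, vertex, c) {
    a <- as.numeric(a); vertex <- as.numeric(vertex); c <- as.numeric(c)
    if (any(!is.finite(c(a, vertex, c)))) stop("points must be finite")
    u <- a - vertex
    v <- c - vertex
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu <= .DEGEN_TOL || nv <= .DEGEN_TOL)
        stop("degenerate geometry: a point coincides with the vertex")
    cosang <- sum(u * v) / (nu * nv)
    acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Computes the proper rotation and translation that superpose `mobile`
#' onto `reference` with least-squares RMSD. Reflections are corrected, so
#' the returned rotation always has determinant +1; a mirror-image point
#' set therefore retains a positive RMSD.
#'
#' @param mobile,reference N x 3 numeric matrices (N >= 3, not collinear).
#' @return list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom). The fitted coordinates are
#'   `mobile %*% t(rotation) + translation` (rows as points).
#' @export
kabschSuperpose <- function(mobile, reference) {
    mobile <- as.matrix(mobile); reference <- as.matrix(reference)
    if (ncol(mobile) != 3L || ncol(reference) != 3L)
        stop("coordinate matrices must have 3 columns")
    if (nrow(mobile) != nrow(reference))
        stop("mobile and reference must have the same number of points")
    n <- nrow(mobile)
    if (n < 3L) stop("need at least 3 points")
    if (any(!is.finite(mobile)) || any(!is.finite(reference)))
        stop("coordinates must be finite")
    cm <- colMeans(mobile); cr <- colMeans(reference)
    P <- sweep(mobile, 2L, cm)
    Q <- sweep(reference, 2L, cr)
    # rank check: collinear (or coincident) point sets have no unique fit
    if (sum(svd(P)$d > .DEGEN_TOL) < 2L || sum(svd(Q)$d > .DEGEN_TOL) < 2L)
        stop("degenerate point set: points are collinear or coincident")
    s <- svd(crossprod(P, Q))                 # t(P) %*% Q = U D V'
    d <- sign(det(s$v %*% t(s$u)))
    if (d == 0) d <- 1
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)  # proper rotation, det +1
    fitted <- P %*% t(R)
    rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
    list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

#' Apply a rigid transform to row-wise coordinates
#' @param coords N x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed N x 3 matrix.
#' @export
applyTransform <- function(coords, rotation, translation) {
    sweep(as.matrix(coords) %*% t(rotation), 2L, -as.numeric(translation))
}

#' Per-residue RMSF over a structural ensemble
#'
#' Computes the root-mean-square fluctuation of one designated atom per
#' residue (default the alpha-carbon, `"CA"`) across an ensemble of
#' structures sharing a residue numbering. Residues whose selected atom is
#' missing from any structure are dropped from both fitting and reporting,
#' with a warning. With `fit = TRUE` every structure is first superposed
#' onto the first via [kabschSuperpose()] on the common selected atoms;
#' `fit = FALSE` uses the coordinates as given (useful when the ensemble is
#' already aligned, and for closed-form checks, since fitting on the same
#' atoms being measured slightly redistributes their deviations).
#'
#' RMSF of a residue is `sqrt(mean over structures of the squared deviation
#' of its atom from the ensemble-mean position)`.
#'
#' @param structures list of [Trajectory-class] objects (frame 1 of each is
#'   used), or a single multi-frame Trajectory whose frames form the
#'   ensemble.
#' @param atomName atom name selecting one atom per residue (default "CA").
#' @param fit superpose onto the first structure first? Default TRUE.
#' @return data.frame with columns `chain`, `resid`, `rmsf` (Angstrom) and
#'   `flexible` (TRUE when rmsf >= 1.0 Angstrom); the selection is recorded
#'   in `attr(, "selection")`.
#' @export
ensembleRmsf <- function(structures, atomName = "CA", fit = TRUE) {
    if (is(structures, "Trajectory")) {
        traj <- structures
        structures <- lapply(seq_len(nFrames(traj)), function(i)
            newTrajectory(topology(traj), frameCoords(traj, i)))
    }
    if (!is.list(structures) || length(structures) < 2L)
        stop("need at least 2 structures")
    if (!all(vapply(structures, is, logical(1), class2 = "Trajectory")))
        stop("structures must be Trajectory objects")

    key <- function(s) {
        top <- topology(s)
        sel <- which(top$name == atomName)
        data.frame(idx = sel, key = paste(top$chain[sel], top$resid[sel],
                                          sep = "|"))
    }
    keys <- lapply(structures, key)
    if (any(vapply(keys, nrow, integer(1)) == 0L))
        stop(sprintf("no atoms named '%s' found in every structure", atomName))
    if (any(vapply(keys, function(k) anyDuplicated(k$key) > 0L, logical(1))))
        stop(sprintf("atom name '%s' is not unique within a residue", atomName))
    common <- Reduce(intersect, lapply(keys, `[[`, "key"))
    if (length(common) == 0L) stop("no residues common to all structures")
    dropped <- setdiff(unique(unlist(lapply(keys, `[[`, "key"))), common)
    if (length(dropped) > 0L)
        warning(sprintf("%d residue(s) missing from some structures were dropped",
                        length(dropped)))

    getXyz <- function(s, k) {
        m <- frameCoords(s, 1L)[k$idx[match(common, k$key)], , drop = FALSE]
        m
    }
    xyz <- mapply(getXyz, structures, keys, SIMPLIFY = FALSE)
    if (fit) {
        ref <- xyz[[1L]]
        # a rotational fit needs >= 3 non-collinear atoms; below that, fall
        # back to centroid alignment (translation only)
        rotatable <- nrow(ref) >= 3L &&
            sum(svd(sweep(ref, 2L, colMeans(ref)))$d > .DEGEN_TOL) >= 2L
        xyz <- lapply(xyz, function(m) {
            if (rotatable) {
                tr <- kabschSuperpose(m, ref)
                applyTransform(m, tr$rotation, tr$translation)
            } else sweep(m, 2L, colMeans(m) - colMeans(ref))
        })
    }
    arr <- simplify2array(xyz)                       # n x 3 x nStruct
    mean_pos <- apply(arr, c(1L, 2L), mean)
    sqdev <- apply(sweep(arr, c(1L, 2L), mean_pos)^2, c(1L, 3L), sum)
    rmsf <- sqrt(rowMeans(sqdev))

    parts <- strsplit(common, "|", fixed = TRUE)
    out <- data.frame(chain = vapply(parts, `[`, character(1), 1L),
                      resid = as.integer(vapply(parts, `[`, character(1), 2L)),
                      rmsf = rmsf, flexible = rmsf >= 1.0,
                      stringsAsFactors = FALSE)
    out <- out[order(out$chain, out$resid), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "selection") <- sprintf("one '%s' atom per residue, %d structures%s",
                                      atomName, length(structures),
                                      if (fit) ", superposed onto the first"
                                      else ", no superposition")
    out
}
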