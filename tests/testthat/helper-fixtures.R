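# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# Minimal PDB ATOM line at v3.3 fixed columns.
pdbLine <- function(serial, name, resname, chain, resid, x, y, z,
                    occ = 1.0, alt = " ", element = "") {
    sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, alt, resname, chain, resid, x, y, z, occ, 0, element)
}

# Write a multi-model PDB with `frames` = list of data.frames having
# columns name, resname, chain, resid, x, y, z (optional alt, occ).
writeFixturePdb <- function(frames, path = tempfile(fileext = ".pdb")) {
    lines <- character(0)
    for (f in seq_along(frames)) {
        df <- frames[[f]]
        lines <- c(lines, sprintf("MODEL     %4d", f))
        for (i in seq_len(nrow(df))) {
            alt <- if ("alt" %in% names(df)) df$alt[i] else " "
            occ <- if ("occ" %in% names(df)) df$occ[i] else 1.0
            lines <- c(lines, pdbLine(i, df$name[i], df$resname[i],
                                      df$chain[i], df$resid[i],
                                      df$x[i], df$y[i], df$z[i],
                                      occ = occ, alt = alt))
        }
        lines <- c(lines, "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
    path
}

# A five-atom frame: Fe, oxo, one carbon, two hydrogens.
fiveAtomFrame <- function(shift = 0) {
    data.frame(name = c("FE", "O1", "C1", "H1", "H2"),
               resname = c("HEM", "HEM", "LIG", "LIG", "LIG"),
               chain = "A", resid = c(501L, 501L, 502L, 502L, 502L),
               x = c(0, 0, 2, 1, 3) + shift,
               y = c(0, 0, 1, 0.5, 1),
               z = c(0, 1.62, 3, 2.5, 3.5),
               stringsAsFactors = FALSE)
}

# Direct trajectory with Fe at origin, oxo on +z at 1.62 A, and explicitly
# placed hydrogens (list of per-frame H coordinate matrices, one row per
# hydrogen). Returns trajectory + center.
geometryTrajectory <- function(hFrames, hNames = NULL) {
    nH <- nrow(hFrames[[1L]])
    if (is.null(hNames)) hNames <- paste0("H", seq_len(nH))
    top <- data.frame(serial = seq_len(2L + nH),
                      name = c("FE", "O1", hNames),
                      resname = c("HEM", "HEM", rep("LIG", nH)),
                      resid = c(501L, 501L, rep(502L, nH)),
                      chain = "A",
                      element = c("FE", "O", rep("H", nH)),
                      stringsAsFactors = FALSE)
    frames <- lapply(hFrames, function(h)
        rbind(c(0, 0, 0), c(0, 0, 1.62), as.matrix(h)))
    traj <- newTrajectory(top, frames)
    list(trajectory = traj,
         center = catalyticCenter(traj, "FE", "O1"),
         hIndex = 2L + seq_len(nH))
}

# Position of a hydrogen with prescribed H-oxo distance (A) and H-oxo-Fe
# angle (deg) around the fixture center (oxo at (0,0,1.62), Fe at origin).
hAt <- function(d, theta, phi = 0) {
    alpha <- (180 - theta) * pi / 180
    c(d * sin(alpha) * cos(phi), d * sin(alpha) * sin(phi),
      1.62 + d * cos(alpha))
}

# Random rigid transform (uniform-ish rotation via QR, bounded translation).
randomRigid <- function() {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    list(rotation = q, translation = rnorm(3, sd = 5))
}

# Brute-force NAC evaluation of one frame: per-hydrogen distance/angle from
# first principles, independent of the package classifier internals.
bruteForceEvents <- function(frame, map, center, criterion) {
    oxo <- frame[center@oxoIndex, ]; fe <- frame[center@feIndex, ]
    out <- list()
    for (lab in siteLabels(map)) {
        hs <- siteHydrogens(map)[[lab]]
        best <- NULL
        for (h in hs) {
            v <- frame[h, ] - oxo
            d <- sqrt(sum(v^2))
            w <- fe - oxo
            ct <- sum(v * w) / (d * sqrt(sum(w^2)))
            th <- acos(min(1, max(-1, ct))) * 180 / pi
            ok <- d >= criterion@dMin && d <= criterion@dMax &&
                th > criterion@thetaMin
            if (ok && (is.null(best) || d < best$hOxo))
                best <- list(site = lab, bestHydrogen = h, hOxo = d,
                             hOxoFe = th)
        }
        if (!is.null(best)) out[[lab]] <- best
    }
    if (length(out) == 0L)
        return(data.frame(site = character(0), bestHydrogen = integer(0),
                          hOxo = numeric(0), hOxoFe = numeric(0)))
    do.call(rbind, lapply(out, as.data.frame))
}
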