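# Distances, angles, Kabsch superposition, RMSF.

test_that("distances and angles match closed-form cases", {
    expect_equal(pairwiseDistance(c(0, 0, 0), c(0, 0, 2.5)), 2.5)
    expect_equal(pairwiseDistance(c(1, 2, 2), c(0, 0, 0)), 3.0)
    expect_equal(pairwiseDistance(c(1, 1, 1), c(1, 1, 1)), 0)
    expect_error(pairwiseDistance(c(0, 0, NA), c(0, 0, 0)), "finite")

    expect_equal(threePointAngle(c(0, 0, 2.5), c(0, 0, 0), c(0, 0, -1.62)),
                 180)
    expect_equal(threePointAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
    # equilateral triangle
    expect_equal(threePointAngle(c(1, 0, 0), c(0, 0, 0),
                                 c(0.5, sqrt(3) / 2, 0)), 60)
    expect_error(threePointAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                 "degenerate")
})

test_that("distance and angle are invariant under rigid transforms", {
    set.seed(101)
    for (i in 1:25) {
        pts <- matrix(rnorm(9, sd = 3), 3)
        tr <- randomRigid()
        moved <- applyTransform(pts, tr$rotation, tr$translation)
        expect_equal(pairwiseDistance(moved[1, ], moved[2, ]),
                     pairwiseDistance(pts[1, ], pts[2, ]), tolerance = 1e-9)
        a0 <- tryCatch(threePointAngle(pts[1, ], pts[2, ], pts[3, ]),
                       error = function(e) NA)
        if (!is.na(a0))
            expect_equal(threePointAngle(moved[1, ], moved[2, ], moved[3, ]),
                         a0, tolerance = 1e-7)
    }
})

test_that("kabschSuperpose recovers known transforms and rejects mirrors", {
    pts <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.2, 1.5),
                  ncol = 3, byrow = TRUE)           # non-coplanar
    # identity
    fit <- kabschSuperpose(pts, pts)
    expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
    expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-9)
    expect_equal(fit$rmsd, 0, tolerance = 1e-9)

    # known rotation (90 deg about z) + translation
    Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
    ref <- applyTransform(pts, Rz, c(1, 1, 1))
    fit <- kabschSuperpose(pts, ref)
    expect_equal(fit$rotation, Rz, tolerance = 1e-9)
    expect_equal(fit$translation, c(1, 1, 1), tolerance = 1e-9)
    expect_lt(fit$rmsd, 1e-6)
    expect_equal(applyTransform(pts, fit$rotation, fit$translation), ref,
                 tolerance = 1e-9)

    # chiral set vs its mirror: det stays +1, rmsd stays positive
    mirror <- pts %*% diag(c(-1, 1, 1))
    fit <- kabschSuperpose(mirror, pts)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_gt(fit$rmsd, 0.05)

    expect_error(kabschSuperpose(pts[1:2, ], pts[1:2, ]), "3 points")
    expect_error(kabschSuperpose(pts, pts[1:3, ]), "same number")
    line <- cbind(0:3, 0, 0)
    expect_error(kabschSuperpose(line, line), "degenerate")
})

test_that("kabsch rmsd matches a brute-force rotation-grid minimum", {
    # brute force: search proper rotations (Euler angles) on a grid, then
    # refine the best grid point with Nelder-Mead; for a fixed rotation the
    # optimal translation aligns the centroids, so only rotations are
    # searched.
    eulerR <- function(a, b, g) {
        ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
        cg <- cos(g); sg <- sin(g)
        matrix(c(ca * cb * cg - sa * sg, -ca * cb * sg - sa * cg, ca * sb,
                 sa * cb * cg + ca * sg, -sa * cb * sg + ca * cg, sa * sb,
                 -sb * cg, sb * sg, cb), 3, byrow = TRUE)
    }
    bruteMinRmsd <- function(mobile, reference, n = 18) {
        P <- sweep(mobile, 2, colMeans(mobile))
        Q <- sweep(reference, 2, colMeans(reference))
        f <- function(ang) {
            R <- eulerR(ang[1], ang[2], ang[3])
            sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
        }
        ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
        angb <- seq(0, pi, length.out = n %/% 2 + 1)
        best <- Inf; bestAng <- c(0, 0, 0)
        for (a in ang) for (b in angb) for (g in ang) {
            r <- f(c(a, b, g))
            if (r < best) { best <- r; bestAng <- c(a, b, g) }
        }
        stats::optim(bestAng, f, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 2000))$value
    }
    set.seed(77)
    for (i in 1:3) {
        mobile <- matrix(rnorm(12), 4)
        reference <- matrix(rnorm(12), 4)
        fit <- kabschSuperpose(mobile, reference)
        brute <- bruteMinRmsd(mobile, reference)
        expect_lte(fit$rmsd, brute + 1e-9)  # never worse than the search
        expect_lt(abs(fit$rmsd - brute), 1e-3)
    }
})

test_that("kabsch agrees with an independent superposition routine", {
    set.seed(5)
    mobile <- matrix(rnorm(30), 10)
    tr <- randomRigid()
    reference <- applyTransform(mobile, tr$rotation, tr$translation) +
        matrix(rnorm(30, sd = 0.05), 10)
    fit <- kabschSuperpose(mobile, reference)
    bfit <- bio3d::fit.xyz(as.vector(t(reference)),
                           as.vector(t(mobile)),
                           fixed.inds = 1:30, mobile.inds = 1:30)
    brmsd <- bio3d::rmsd(as.vector(t(reference)), bfit)
    expect_lt(abs(fit$rmsd - brmsd), 5.1e-4)  # bio3d rounds to 3 decimals
})

test_that("ensemble RMSF matches closed forms", {
    spec <- syntheticSpec(c(A = 0.5), nFrames = 1, seed = 1)
    toy <- buildToyTopology(spec)
    top <- topology(toy$trajectory)
    base <- frameCoords(toy$trajectory, 1L)

    # identical copies -> all RMSF zero
    copies <- lapply(1:4, function(i) newTrajectory(top, base))
    r0 <- ensembleRmsf(copies, atomName = "C1")
    expect_equal(r0$rmsf, 0, tolerance = 1e-9)

    # one atom at mean +/- d/2 -> that residue's RMSF = d/2 (no fitting,
    # so the displacement is not redistributed by the superposition)
    d <- 0.8
    m2 <- base; m2[3L, 1L] <- m2[3L, 1L] + d
    r1 <- ensembleRmsf(list(newTrajectory(top, base),
                            newTrajectory(top, m2)),
                       atomName = "C1", fit = FALSE)
    expect_equal(r1$rmsf[r1$resid == 502L], d / 2, tolerance = 1e-12)
    expect_false(r1$flexible[r1$resid == 502L])

    # copies differing only by a global translation -> RMSF ~ 0 after fit
    shifted <- newTrajectory(top, base + matrix(rep(c(3, -2, 5),
                                                    each = nrow(base)),
                                                ncol = 3))
    r2 <- ensembleRmsf(list(newTrajectory(top, base), shifted),
                       atomName = "C1", fit = TRUE)
    expect_lt(max(r2$rmsf), 1e-6)

    expect_error(ensembleRmsf(copies[1L], atomName = "C1"), "at least 2")
    expect_error(ensembleRmsf(copies, atomName = "XX"), "no atoms named")
})

test_that("residues missing from some structures are dropped with a warning", {
    top <- data.frame(serial = 1:3, name = "CA",
                      resname = "ALA", resid = 1:3, chain = "A",
                      element = "C", stringsAsFactors = FALSE)
    xyz <- matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 1), 3, byrow = TRUE)
    full <- newTrajectory(top, xyz)
    partial <- newTrajectory(top[1:2, ], xyz[1:2, ])
    expect_warning(r <- ensembleRmsf(list(full, partial), fit = FALSE),
                   "dropped")
    expect_equal(nrow(r), 2L)
    expect_equal(r$resid, 1:2)
})
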