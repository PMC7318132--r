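# NAC criterion evaluation, frame classification and accessibility profiles.

test_that("evaluateHydrogen applies inclusive distance and strict angle bounds", {
    g <- geometryTrajectory(list(rbind(hAt(2.5, 180))))
    frame <- frameCoords(g$trajectory, 1L)
    r <- evaluateHydrogen(frame, g$hIndex[1L], g$center)
    expect_true(r$accessible)
    expect_equal(r$hOxo, 2.5, tolerance = 1e-9)
    expect_equal(r$hOxoFe, 180, tolerance = 1e-6)

    # beyond the distance window
    g2 <- geometryTrajectory(list(rbind(hAt(3.6, 180))))
    expect_false(evaluateHydrogen(frameCoords(g2$trajectory, 1L),
                                  g2$hIndex[1L], g2$center)$accessible)

    # boundary semantics: distance bounds inclusive, angle bound strict.
    # The criterion is pinned to the exact measured geometry of a probe
    # hydrogen, so the comparisons are evaluated exactly at the boundary
    # without floating-point reconstruction error.
    gp <- geometryTrajectory(list(rbind(hAt(2.7, 140))))
    probe <- evaluateHydrogen(frameCoords(gp$trajectory, 1L),
                              gp$hIndex[1L], gp$center)
    atBound <- function(crit)
        evaluateHydrogen(frameCoords(gp$trajectory, 1L), gp$hIndex[1L],
                         gp$center, crit)$accessible
    # d == dMax and d == dMin are accessible (inclusive)
    expect_true(atBound(nacCriterion(dMax = probe$hOxo)))
    expect_true(atBound(nacCriterion(dMin = probe$hOxo)))
    # theta == thetaMin is NOT accessible (strict)
    expect_false(atBound(nacCriterion(thetaMin = probe$hOxoFe)))
    expect_true(atBound(nacCriterion(thetaMin = probe$hOxoFe - 1e-9)))

    # hydrogen on top of the oxo atom is degenerate
    gd <- geometryTrajectory(list(rbind(c(0, 0, 1.62))))
    expect_error(evaluateHydrogen(frameCoords(gd$trajectory, 1L),
                                  gd$hIndex[1L], gd$center), "degenerate")
})

test_that("classifyFrame emits one event per accessed site with the best hydrogen", {
    # site M (methyl, 3 H): two accessible at different distances; site B:
    # one accessible; site X: none
    h <- rbind(hAt(3.0, 160), hAt(2.4, 150), hAt(6.0, 160),   # M
               hAt(2.9, 170),                                 # B
               hAt(2.5, 100))                                 # X (angle fails)
    g <- geometryTrajectory(list(h))
    map <- siteMap(list(M = list(hydrogens = g$hIndex[1:3],
                                 stereoClass = "methyl"),
                        B = list(hydrogens = g$hIndex[4L],
                                 stereoClass = "beta"),
                        X = list(hydrogens = g$hIndex[5L],
                                 stereoClass = "alpha")),
                   g$trajectory)
    ev <- classifyFrame(frameCoords(g$trajectory, 1L), map, g$center)
    expect_equal(sort(ev$site), c("B", "M"))
    expect_equal(ev$bestHydrogen[ev$site == "M"], g$hIndex[2L])
    expect_equal(ev$hOxo[ev$site == "M"], 2.4, tolerance = 1e-9)

    # tie on distance -> lowest atom index
    h2 <- rbind(hAt(2.4, 150, phi = 0), hAt(2.4, 150, phi = 2), hAt(6, 90))
    g2 <- geometryTrajectory(list(h2))
    map2 <- siteMap(list(M = list(hydrogens = g2$hIndex[1:3],
                                  stereoClass = "methyl")), g2$trajectory)
    ev2 <- classifyFrame(frameCoords(g2$trajectory, 1L), map2, g2$center)
    expect_equal(nrow(ev2), 1L)
    expect_equal(ev2$bestHydrogen, g2$hIndex[1L])

    # no accessible hydrogen -> empty
    g3 <- geometryTrajectory(list(rbind(hAt(6, 90))))
    map3 <- siteMap(list(A = list(hydrogens = g3$hIndex[1L],
                                  stereoClass = "other")), g3$trajectory)
    expect_equal(nrow(classifyFrame(frameCoords(g3$trajectory, 1L),
                                    map3, g3$center)), 0L)
})

test_that("classifyFrame matches brute-force evaluation on random frames", {
    set.seed(2024)
    crit <- nacCriterion()
    nAgree <- 0L
    for (i in 1:300) {
        # 5 hydrogens thrown anywhere near the center, 2 sites
        h <- matrix(rnorm(15, sd = 2.5), 5) +
            matrix(rep(c(0, 0, 1.62), each = 5), 5)
        g <- geometryTrajectory(list(h))
        map <- siteMap(list(A = list(hydrogens = g$hIndex[1:3],
                                     stereoClass = "methyl"),
                            B = list(hydrogens = g$hIndex[4:5],
                                     stereoClass = "beta")), g$trajectory)
        frame <- frameCoords(g$trajectory, 1L)
        got <- classifyFrame(frame, map, g$center, crit)
        want <- bruteForceEvents(frame, map, g$center, crit)
        got <- got[order(got$site), ]; want <- want[order(want$site), ]
        expect_equal(got$site, want$site)
        expect_equal(got$bestHydrogen, want$bestHydrogen)
        expect_equal(got$hOxo, want$hOxo, tolerance = 1e-12)
        expect_equal(got$hOxoFe, want$hOxoFe, tolerance = 1e-9)
        nAgree <- nAgree + 1L
    }
    expect_equal(nAgree, 300L)
})

test_that("events are invariant under a rigid transform of the whole frame", {
    set.seed(31)
    h <- rbind(hAt(2.7, 155), hAt(3.2, 130), hAt(5, 100), hAt(2.2, 115))
    g <- geometryTrajectory(list(h))
    map <- siteMap(list(A = list(hydrogens = g$hIndex[1:2],
                                 stereoClass = "beta"),
                        B = list(hydrogens = g$hIndex[3:4],
                                 stereoClass = "alpha")), g$trajectory)
    frame <- frameCoords(g$trajectory, 1L)
    base <- classifyFrame(frame, map, g$center)
    for (i in 1:10) {
        tr <- randomRigid()
        moved <- applyTransform(frame, tr$rotation, tr$translation)
        ev <- classifyFrame(moved, map, g$center)
        expect_equal(ev$site, base$site)
        expect_equal(ev$bestHydrogen, base$bestHydrogen)
        expect_equal(ev$hOxo, base$hOxo, tolerance = 1e-9)
        expect_equal(ev$hOxoFe, base$hOxoFe, tolerance = 1e-6)
    }
})

test_that("accessibilityProfile reproduces the hand-enumerated example", {
    # 4 frames: f1,f2 access {A}; f3 accesses {A,B}; f4 none
    hitA <- hAt(2.5, 160); hitB <- hAt(3.0, 150, phi = 1); miss <- hAt(6, 90)
    frames <- list(rbind(hitA, miss), rbind(hitA, miss),
                   rbind(hitA, hitB), rbind(miss, miss))
    g <- geometryTrajectory(frames)
    map <- siteMap(list(A = list(hydrogens = g$hIndex[1L], stereoClass = "beta"),
                        B = list(hydrogens = g$hIndex[2L], stereoClass = "methyl")),
                   g$trajectory)
    prof <- accessibilityProfile(g$trajectory, map, g$center)
    tb <- profileTable(prof)
    expect_equal(tb$site, c("A", "B"))
    expect_equal(tb$events, c(3L, 1L))
    expect_equal(tb$percentage, c(75, 25))
    expect_equal(totalEvents(prof), 4L)
    expect_equal(totalFrames(prof), 4L)
    expect_equal(framesWithAccess(prof), 3L)

    # frames denominator: divide by frames-with-access instead
    proff <- accessibilityProfile(g$trajectory, map, g$center,
                                  denominator = "frames")
    tbf <- profileTable(proff)
    expect_equal(tbf$percentage[tbf$site == "A"], 100)
    expect_equal(tbf$percentage[tbf$site == "B"], 100 / 3)

    # time series agrees frame by frame and in aggregate
    ts <- accessTimeSeries(g$trajectory, map, g$center)
    expect_equal(nrow(ts), 4L)
    expect_equal(split(ts$site, ts$frame),
                 list(`1` = "A", `2` = "A", `3` = c("A", "B")))
    expect_equal(as.vector(table(ts$site)[tb$site]), tb$events)
    expect_equal(attr(ts, "totalFrames"), 4L)

    # skipFrames drops leading frames from both outputs
    prof2 <- accessibilityProfile(g$trajectory, map, g$center,
                                  skipFrames = 2L)
    expect_equal(totalFrames(prof2), 2L)
    expect_equal(profileTable(prof2)$events,
                 c(1L, 1L))

    # no access at all: zero percentages plus a warning
    g0 <- geometryTrajectory(list(rbind(miss, miss)))
    map0 <- siteMap(list(A = list(hydrogens = g0$hIndex[1L], stereoClass = "beta"),
                         B = list(hydrogens = g0$hIndex[2L], stereoClass = "methyl")),
                    g0$trajectory)
    expect_warning(p0 <- accessibilityProfile(g0$trajectory, map0, g0$center),
                   "no access")
    expect_equal(profileTable(p0)$percentage, c(0, 0))
    expect_equal(totalEvents(p0), 0L)
})

test_that("percentages sum to 100 and widening the criterion never loses events", {
    set.seed(99)
    for (rep in 1:10) {
        spec <- syntheticSpec(setNames(runif(3, 0.05, 0.25), c("a", "b", "c")),
                              stereoClass = c("alpha", "beta", "methyl"),
                              nFrames = 300, seed = 1000 + rep)
        traj <- simulateTrajectory(spec)
        toy <- buildToyTopology(spec)
        prof <- accessibilityProfile(traj, toy$map, toy$center)
        if (totalEvents(prof) > 0)
            expect_equal(sum(profileTable(prof)$percentage), 100,
                         tolerance = 1e-6)
        # widen: lower dMin, raise dMax, lower thetaMin
        wide <- nacCriterion(dMin = 1.0, dMax = 5.0, thetaMin = 100)
        profW <- accessibilityProfile(traj, toy$map, toy$center, wide)
        tight <- profileTable(prof); loose <- profileTable(profW)
        expect_true(all(loose$events[match(tight$site, loose$site)] >=
                            tight$events))
    }
})

test_that("stereoSummary aggregates percentages by class", {
    mk <- function(sites, events, classes) {
        tot <- sum(events)
        tb <- data.frame(site = sites, events = as.integer(events),
                         percentage = if (tot > 0) 100 * events / tot
                                      else events * 0,
                         stereoClass = classes, stringsAsFactors = FALSE)
        tb <- tb[order(-tb$percentage, tb$site), ]
        new("AccessibilityProfile", table = tb, totalEvents = as.integer(tot),
            totalFrames = 100L, framesWithAccess = as.integer(min(tot, 100L)),
            denominator = "events")
    }
    map <- siteMap(list("6β" = list(hydrogens = 1L, stereoClass = "beta"),
                        "19" = list(hydrogens = 2L, stereoClass = "methyl"),
                        "2α" = list(hydrogens = 3L, stereoClass = "alpha")))
    s1 <- stereoSummary(mk(c("6β", "19"), c(60, 40), c("beta", "methyl")), map)
    expect_equal(unname(s1[c("beta", "methyl", "alpha")]), c(60, 40, 0))

    s2 <- stereoSummary(mk(c("6β", "2α", "19"), c(50, 25, 25),
                           c("beta", "alpha", "methyl")), map)
    expect_equal(unname(s2[c("beta", "alpha", "methyl")]), c(50, 25, 25))

    s0 <- stereoSummary(mk(c("6β", "19"), c(0, 0), c("beta", "methyl")), map)
    expect_equal(unname(s0), rep(0, 4))

    bad <- mk("7γ", 10, "other")
    expect_error(stereoSummary(bad, map), "absent")
})

test_that("catalyticCenter warns on implausible Fe-oxo distances", {
    g <- geometryTrajectory(list(rbind(hAt(2.5, 160))))
    expect_silent(catalyticCenter(g$trajectory, "FE", "O1"))
    # stretch the oxo away
    top <- topology(g$trajectory)
    m <- frameCoords(g$trajectory, 1L)
    m[2L, 3L] <- 3.0
    bad <- newTrajectory(top, m)
    expect_warning(catalyticCenter(bad, "FE", "O1"), "Fe-oxo")
    expect_error(new("CatalyticCenter", feIndex = 1L, oxoIndex = 1L))
})
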