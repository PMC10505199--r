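## Coarse-graining grid, Gamma_p fields, magnitude profiles and the
## hexanematic crossover.

test_that("grid spacing is exactly R_cc/2 with the documented node count", {
  ml <- latticeMonolayer(a = 16, box = c(140, 140))
  expect_equal(rcc(ml), 16, tolerance = 1e-9)
  g <- makeGrid(ml, fov = 124)
  expect_equal(g$spacing, 8)
  expect_equal(g$dim, c(16L, 16L))  # floor(124/8) + 1
  gg <- g$grid
  expect_equal(sort(unique(round(diff(sort(unique(gg[, 1]))), 9))), 8)
  ## clipped to the box when the box is smaller than the fov
  ml2 <- latticeMonolayer(a = 16, box = c(100, 100))
  g2 <- makeGrid(ml2, fov = 124)
  expect_true(all(g2$grid >= 0 & g2$grid <= 100))
  expect_error(makeGrid(ml, fov = 2), "smaller than one grid cell")
})

test_that("radius ladder steps by R_cc/2 up to half the fov diagonal", {
  rl <- radiusLadder(16, fov = 124)
  expect_equal(rl[1], 8)
  expect_equal(unique(diff(rl)), 8)
  expect_lte(max(rl), sqrt(2) * 124 / 2)
})

test_that("constant-gamma monolayers give constant Gamma and empty disks give NA", {
  ml <- latticeMonolayer(a = 10, box = c(80, 80))
  f6 <- coarseGamma(ml, p = 6L, fov = 80)
  ## all interior cells share gamma_6 up to phase; perfect lattice: identical
  pr <- meanAbsProfile(f6)
  expect_true(all(abs(pr$mean_abs - 1) < 1e-9))
  ## tiny radius around a node far from any centroid -> NA
  g <- makeGrid(ml, fov = 80)
  fTiny <- coarseGamma(ml, p = 6L, radii = 0.05, grid = g, fov = 80)
  expect_true(any(is.na(fieldValues(fTiny))))
})

test_that("coarseGamma equals the brute-force disk sum on toy monolayers", {
  ml <- toyMonolayer(n = 20, box = c(50, 50), seed = 7)
  st <- shapeTable(ml)
  grid <- makeGrid(ml, fov = 50)
  radii <- c(0.7, 1.5, 2) * rcc(ml)
  for (p in c(2L, 6L)) {
    fld <- coarseGamma(ml, st, p = p, radii = radii, grid = grid)
    ## independent oracle: direct double loop over nodes and cells with the
    ## strict Heaviside factor
    ids <- cellIds(ml)
    keep <- !isBorder(ml)
    ctr <- centroids(ml)[keep, , drop = FALSE]
    gam <- vapply(cellPolygons(ml)[keep], function(cp) gammaP(cp, p), complex(1))
    for (k in seq_along(radii)) {
      for (n in seq_len(nrow(grid$grid))) {
        d <- sqrt((ctr[, 1] - grid$grid[n, 1])^2 + (ctr[, 2] - grid$grid[n, 2])^2)
        inside <- d < radii[k]
        want <- if (any(inside)) sum(gam[inside]) / sum(inside) else NA_complex_
        expect_identical(is.na(fieldValues(fld)[n, k]), is.na(want))
        if (!is.na(want)) {
          expect_equal(fieldValues(fld)[n, k], want, tolerance = 1e-13)
          expect_equal(diskCounts(fld)[n, k], sum(inside))
        }
      }
    }
  }
})

test_that("cells exactly at distance R are excluded (strict Heaviside)", {
  ## hand-built monolayer of unit squares with exactly representable
  ## centroid distances to the probe node
  sq <- function(x0, y0) rbind(c(x0, y0), c(x0 + 1, y0),
                               c(x0 + 1, y0 + 1), c(x0, y0 + 1))
  ml <- Monolayer(list(CellPolygon(1L, sq(0, 0), neighborIds = 2L),
                       CellPolygon(2L, sq(1, 0), neighborIds = 1L)),
                  box = c(10, 10))
  node <- c(4.5, 0.5)  # distances: 4 to cell 1, 3 to cell 2 (exact)
  grid <- list(grid = rbind(node), dim = c(1L, 1L), spacing = 1, origin = node)
  counts <- vapply(c(3, 4, 4.5), function(R) {
    diskCounts(coarseGamma(ml, p = 6L, radii = R, grid = grid))[1, 1]
  }, integer(1))
  ## Theta(0) = 0: a cell at distance exactly R is excluded
  expect_equal(counts, c(0L, 1L, 2L))
})

test_that("the R -> infinity limit reproduces the global complex mean", {
  ml <- toyMonolayer(n = 30, box = c(60, 60), seed = 5)
  keep <- !isBorder(ml)
  gam <- vapply(cellPolygons(ml)[keep], function(cp) gammaP(cp, 2), complex(1))
  fld <- coarseGamma(ml, p = 2L, radii = 1e6, fov = 60)
  v <- fieldValues(fld)[, 1]
  expect_true(all(abs(v - mean(gam)) < 1e-12))
})

test_that("profiles are bounded by 1 and random phases decay toward 0", {
  decayOk <- 0L
  for (s in 1:5) {
    ml <- generateMonolayer(monolayerConfig(boxWidth = 150, boxHeight = 150,
                                            targetRcc = 12, jitter = 0.5,
                                            seed = s))
    f6 <- coarseGamma(ml, p = 6L, fov = 150)
    pr <- meanAbsProfile(f6)
    expect_true(all(pr$mean_abs >= 0 & pr$mean_abs <= 1 + 1e-12))
    ## trend: late-ladder mean below early-ladder mean
    nr <- nrow(pr)
    if (mean(pr$mean_abs[(nr - 2):nr]) < mean(pr$mean_abs[1:3])) {
      decayOk <- decayOk + 1L
    }
  }
  expect_gte(decayOk, 4L)
})

test_that("crossover interpolation and degenerate statuses behave as specified", {
  mk <- function(delta6) {
    data.frame(radius = c(16, 24), radius_norm = c(1, 1.5),
               mean_abs = delta6, n_nodes = 10L)
  }
  ## Delta = +0.2 then -0.2 across [R_cc, 1.5 R_cc] -> root at 1.25 R_cc
  pr <- hexanematicCrossover(mk(c(0.5, 0.3)), mk(c(0.3, 0.5)), rcc = 16)
  expect_equal(crossoverScale(pr), 1.25)
  expect_equal(pr@status, "crossover")
  ## hexatic-dominated: Delta > 0 everywhere
  pr2 <- hexanematicCrossover(mk(c(0.5, 0.4)), mk(c(0.2, 0.2)), rcc = 16)
  expect_true(is.na(crossoverScale(pr2)))
  expect_equal(pr2@status, "hexatic-dominated")
  ## nematic-dominated: Delta <= 0 at the smallest radius
  pr3 <- hexanematicCrossover(mk(c(0.1, 0.4)), mk(c(0.2, 0.2)), rcc = 16)
  expect_equal(pr3@status, "nematic-dominated")
  expect_error(hexanematicCrossover(mk(c(1, 1)),
                                    data.frame(radius = c(1, 2),
                                               radius_norm = c(1, 2),
                                               mean_abs = c(1, 1),
                                               n_nodes = 1L), rcc = 16),
               "ladders")
})

test_that("a perfect hexagonal lattice is hexatic-dominated at all scales", {
  ml <- latticeMonolayer(a = 12, box = c(110, 110))
  an <- crossoverAnalysis(ml, fov = 110)
  expect_equal(an$profile@status, "hexatic-dominated")
  expect_true(is.na(crossoverScale(an$profile)))
  expect_true(all(an$profile@delta > 0))
})
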