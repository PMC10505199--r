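## Shape index and p-fold shape function.

test_that("shape index matches closed forms and is scale-invariant", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(shapeIndex(sq), 4)
  hx <- regularPolygon(6, circumradius = 7.3, center = c(1, 2))
  expect_equal(shapeIndex(hx), 6 / sqrt(3 * sqrt(3) / 2), tolerance = 1e-12)
  expect_equal(shapeIndex(sq * 10), shapeIndex(sq), tolerance = 1e-12)
  expect_error(shapeIndex(rbind(c(0, 0), c(1, 0), c(2, 0))), "zero-area")
})

test_that("gamma_p on the regular hexagon gives |gamma_6| = 1 and |gamma_2| = 0", {
  hx <- regularPolygon(6, circumradius = 2, center = c(-1, 4), rotation = 0.7)
  expect_equal(Mod(gammaP(hx, 6)), 1, tolerance = 1e-12)
  expect_equal(Mod(gammaP(hx, 2)), 0, tolerance = 1e-12)
})

test_that("an elongated hexagon has finite |gamma_2| and |gamma_6|", {
  hx <- regularPolygon(6)
  el <- cbind(hx[, 1] * 1.4, hx[, 2] / 1.4)
  expect_gt(Mod(gammaP(el, 2)), 0.1)
  expect_gt(Mod(gammaP(el, 6)), 0.1)
})

test_that("gamma_p matches a brute-force evaluation on random polygons", {
  for (s in 1:10) {
    xy <- randomPolygon(nv = 5 + s %% 4, seed = s)
    for (p in c(1L, 2L, 3L, 6L)) {
      expect_equal(gammaP(xy, p), gammaBrute(xy, p, polygonCentroid(xy)),
                   tolerance = 1e-12)
    }
  }
})

test_that("gamma_2 of a 2x1 rectangle aligns with the long axis", {
  rect <- rbind(c(-1, -0.5), c(1, -0.5), c(1, 0.5), c(-1, 0.5))
  ## direct evaluation on the 4 vertices: r identical, angles +-atan(1/2)
  g2 <- gammaP(rect, 2)
  expect_gt(Re(g2), 0)
  expect_equal(Im(g2), 0, tolerance = 1e-12)
  expect_equal(pFoldOrientation(rect, 2), 0, tolerance = 1e-12)
})

test_that("gamma_p is translation/scale invariant and rotation covariant", {
  for (s in 1:20) {
    xy <- randomPolygon(nv = 6 + s %% 5, seed = 100 + s)
    p <- 2L + 4L * (s %% 2L)  # alternate p = 2 and p = 6
    g <- gammaP(xy, p)
    expect_equal(gammaP(sweep(xy, 2L, c(-3.2, 7.7)), p), g, tolerance = 1e-9)
    expect_equal(gammaP(xy * 4.5, p), g, tolerance = 1e-9)
    alpha <- 0.3 + 0.1 * s
    gr <- gammaP(rotatePolygon(xy, alpha), p)
    expect_equal(Mod(gr), Mod(g), tolerance = 1e-9)
    expect_equal(Arg(gr * exp(-1i * p * alpha)), Arg(g), tolerance = 1e-9)
  }
})

test_that("|gamma_p| never exceeds 1 (1000 random polygons)", {
  mx <- 0
  for (s in 1:1000) {
    xy <- randomPolygon(nv = 3 + s %% 9, seed = 2000 + s)
    mx <- max(mx, Mod(gammaP(xy, 2)), Mod(gammaP(xy, 6)))
  }
  expect_lte(mx, 1 + 1e-12)
})

test_that("degenerate gamma_p inputs error", {
  expect_error(gammaP(rbind(c(0, 0), c(1, 1)), 2), "3 vertices")
  expect_error(gammaP(regularPolygon(5), 0), "positive")
})

test_that("ensemble average is magnitude-first and excludes border cells", {
  expect_equal(ensembleAverage(c(0, 1)), 0.5)
  ml <- latticeMonolayer()
  expect_equal(ensembleAverage(ml, 6), 1, tolerance = 1e-9)
  expect_equal(ensembleAverage(ml, 2), 0, tolerance = 1e-9)
  st <- shapeTable(ml)
  ## magnitude first: complex phases must not cancel
  stRot <- st
  expect_equal(ensembleAverage(stRot, 6), 1, tolerance = 1e-9)
  expect_error(ensembleAverage(numeric()), "empty")
})

test_that("shape table carries p0 and gamma columns for interior analysis", {
  ml <- toyMonolayer(n = 40, seed = 9)
  st <- shapeTable(ml, p = c(2L, 6L))
  expect_setequal(st$cell_id, cellIds(ml))
  expect_true(all(c("p0", "abs_gamma2", "theta2", "abs_gamma6", "theta6") %in% names(st)))
  expect_true(all(st$abs_gamma2 <= 1 + 1e-12))
  expect_true(all(st$p0 >= 2 * sqrt(pi)))
  expect_true(all(st$theta6 >= 0 & st$theta6 < 2 * pi / 6 + 1e-12))
})

test_that("mean cell-cell distance matches lattice closed forms", {
  ml <- latticeMonolayer(a = 10)
  expect_equal(meanCellCellDistance(ml), 10, tolerance = 1e-9)
  expect_equal(meanCellCellDistance(ml, per = "cell"), 10, tolerance = 1e-9)
  expect_error(meanCellCellDistance(Monolayer(
    list(CellPolygon(1L, regularPolygon(6))), box = c(4, 4))), "neighbor")
})

test_that("stretched lattice R_cc equals the mean of stretched neighbor vectors", {
  e <- 1.3
  cfg <- monolayerConfig(boxWidth = 120, boxHeight = 120, targetRcc = 12,
                         jitter = 0, grainSize = Inf, elongation = e)
  ml <- generateMonolayer(cfg)
  a <- cfg@targetRcc / hexanematic:::meanStretchFactor(e)
  ## the 3 distinct neighbor directions of the triangular lattice under
  ## (e, 1/e): (1,0) and (1/2, +-sqrt(3)/2)
  d <- c(a * e,
         a * sqrt((e / 2)^2 + (sqrt(3) / (2 * e))^2),
         a * sqrt((e / 2)^2 + (sqrt(3) / (2 * e))^2))
  ## interior pair mix is 1:2 between the two lengths
  expect_equal(rcc(ml), mean(d), tolerance = 0.02)
})

test_that("neighbor distribution is normalized with mode 6 on fixtures", {
  ml <- latticeMonolayer()
  nd <- neighborDistribution(ml)
  expect_equal(unname(nd["6"]), 1)
  for (s in 1:3) {
    ml <- generateMonolayer(monolayerConfig(seed = s))
    nd <- neighborDistribution(ml)
    expect_equal(sum(nd), 1, tolerance = 1e-12)
    expect_equal(names(nd)[which.max(nd)], "6")
  }
})

test_that("p0 and |gamma_2| rise together with elongation (rank correlation)", {
  es <- c(1, 1.05, 1.1, 1.15, 1.2, 1.25)
  stats <- t(vapply(es, function(e) {
    ml <- generateMonolayer(monolayerConfig(boxWidth = 140, boxHeight = 140,
                                            elongation = e, seed = 3))
    st <- shapeTable(ml)
    int <- !st$is_border
    c(mean(st$p0[int]), mean(st$abs_gamma2[int]))
  }, numeric(2)))
  expect_gt(stats::cor(stats[, 1], stats[, 2], method = "spearman"), 0.9)
})
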