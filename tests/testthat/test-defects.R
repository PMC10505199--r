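## Orientation fields, plaquette winding numbers and defect detection.

squareGrid <- function(n, spacing = 1, origin = c(0, 0)) {
  gx <- origin[1] + spacing * (seq_len(n) - 1L)
  gy <- origin[2] + spacing * (seq_len(n) - 1L)
  list(grid = cbind(x = rep(gx, times = n), y = rep(gy, each = n)),
       dim = as.integer(c(n, n)), spacing = spacing, origin = origin)
}

test_that("orientation field folds the phase into [0, 2 pi / p)", {
  g <- squareGrid(4)
  fld <- fieldFromOrientation(rep(pi / 4, 16), g, p = 2)
  of <- orientationField(fld, 1L)
  expect_true(all(abs(of$theta - pi / 4) < 1e-12))
  ## global rotation by alpha shifts theta by alpha mod pi
  alpha <- 0.4
  fld2 <- fieldFromOrientation(rep(pi / 4 + alpha, 16), g, p = 2)
  of2 <- orientationField(fld2, 1L)
  expect_true(all(abs((of2$theta - of$theta - alpha) %% pi) < 1e-9 |
                  abs(((of2$theta - of$theta - alpha) %% pi) - pi) < 1e-9))
})

test_that("winding numbers of uniform and seeded plaquettes are exact", {
  expect_equal(windingNumber(rep(0.3, 4), 2), 0)
  ## +1/2 nematic defect at the origin: theta = atan2(y, x) / 2 at the four
  ## corners of a unit plaquette centered on the origin, counterclockwise
  corners <- rbind(c(-0.5, -0.5), c(0.5, -0.5), c(0.5, 0.5), c(-0.5, 0.5))
  th <- atan2(corners[, 2], corners[, 1]) / 2
  expect_equal(windingNumber(th %% pi, 2), 0.5)
  ## -1/6 hexatic anti-defect
  th6 <- -atan2(corners[, 2], corners[, 1]) / 6
  expect_equal(windingNumber(th6 %% (pi / 3), 6), -1 / 6)
  expect_error(windingNumber(c(0, 1, NA, 2), 2), "finite")
})

test_that("plaquette winding equals dense 64-point contour integration", {
  ## analytic p-atic defect fields sampled on a dense circular contour
  denseWinding <- function(centers, charges, p, center, radius = 0.45) {
    ang <- seq(0, 2 * pi, length.out = 65L)[-65L]
    pts <- cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang))
    th <- defectPhaseField(pts, centers, charges, p)
    d <- hexanematic:::wrapPatic(diff(c(th, th[1L])), p)
    sum(d) / (2 * pi)
  }
  cases <- list(list(p = 2, s = 0.5), list(p = 2, s = -0.5),
                list(p = 6, s = 1 / 6), list(p = 6, s = -1 / 6))
  for (cs in cases) {
    centers <- rbind(c(0.1, -0.07))
    corners <- rbind(c(-0.5, -0.5), c(0.5, -0.5), c(0.5, 0.5), c(-0.5, 0.5))
    th <- defectPhaseField(corners, centers, cs$s, cs$p)
    expect_equal(windingNumber(th, cs$p), cs$s)
    expect_equal(denseWinding(centers, cs$s, cs$p, c(0, 0)), cs$s,
                 tolerance = 1e-9)
  }
})

test_that("findDefects locates a seeded +-1/2 pair with correct charges", {
  g <- squareGrid(21, spacing = 1)
  centers <- rbind(c(5.3, 10.2), c(15.6, 10.4))
  charges <- c(0.5, -0.5)
  th <- defectPhaseField(g$grid, centers, charges, p = 2)
  fld <- fieldFromOrientation(th, g, p = 2)
  ds <- findDefects(fld, nCells = 100L)
  expect_equal(length(defectCharges(ds)), 2L)
  expect_setequal(defectCharges(ds), c(0.5, -0.5))
  ## positions within one plaquette of the seeds
  pos <- defectPositions(ds)
  for (k in 1:2) {
    i <- which(defectCharges(ds) == charges[k])
    expect_lt(max(abs(pos[i, ] - centers[k, ])), 1.001)
  }
  expect_equal(defectDensity(ds), 2)
  expect_equal(sum(defectCharges(ds)), 0)
})

test_that("a smooth defect-free field yields an empty DefectSet", {
  g <- squareGrid(12)
  th <- (0.3 + 0.01 * g$grid[, 1] + 0.02 * g$grid[, 2]) %% (pi / 3)
  ds <- findDefects(fieldFromOrientation(th, g, p = 6), nCells = 50L)
  expect_equal(length(defectCharges(ds)), 0L)
  expect_equal(defectDensity(ds), 0)
})

test_that("coarse-graining neutralizes a close defect pair in real monolayers", {
  ## nematic defects of a generated monolayer disappear as R grows
  ml <- generateMonolayer(monolayerConfig(boxWidth = 150, boxHeight = 150,
                                          targetRcc = 14, elongation = 1.1,
                                          seed = 8))
  an <- crossoverAnalysis(ml, fov = 150)
  dd <- defectDensityVsRadius(ml, p = 2, fov = 150, analysis = an)
  n <- dd$profile$n_defects
  expect_gt(n[1], n[length(n)])
  expect_equal(n[length(n)], 0)
})

test_that("defect density decreases under coarse-graining on fixtures", {
  rhos <- vapply(1:5, function(s) {
    ml <- generateMonolayer(monolayerConfig(boxWidth = 140, boxHeight = 140,
                                            targetRcc = 13, elongation = 1.12,
                                            seed = s))
    dd <- defectDensityVsRadius(ml, p = 2, fov = 140)
    suppressWarnings(stats::cor(dd$profile$radius, dd$profile$density_per_100,
                                method = "spearman"))
  }, numeric(1))
  expect_true(all(rhos < 0))
})

test_that("density per 100 cells is invariant under doubling the cell count", {
  ## the same number of cells features the same number of defects: the
  ## per-100-cell rate at the first ladder rung is intensive. Single
  ## fixtures carry few defects, so the rate is aggregated over seeds.
  dens <- vapply(c(140, 200), function(bx) {
    tot <- 0; cells <- 0
    for (s in 1:6) {
      ml <- generateMonolayer(monolayerConfig(boxWidth = bx, boxHeight = bx,
                                              targetRcc = 13,
                                              elongation = 1.12, seed = s))
      dd <- defectDensityVsRadius(ml, p = 2, fov = bx)
      tot <- tot + dd$profile$n_defects[1]
      cells <- cells + nCells(ml, interior = TRUE)
    }
    100 * tot / cells
  }, numeric(1))
  expect_lt(abs(dens[2] - dens[1]) / dens[1], 0.2)
})

test_that("plaquettes touching undefined nodes are skipped with a warning", {
  g <- squareGrid(4)
  vals <- matrix(exp(1i * 2 * hexanematic:::withSeed(1L, runif(16))), ncol = 1L)
  vals[6] <- NA_complex_
  fld <- methods::new("CoarseField", p = 2L, radii = 1, rcc = 1,
                      grid = g$grid, gridDim = g$dim, values = vals,
                      counts = matrix(1L, 16, 1))
  expect_warning(findDefects(fld, nCells = 10L), "skipped")
})
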