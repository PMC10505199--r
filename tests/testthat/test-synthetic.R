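## The generator: lattice symmetry, determinism, confluency, density and
## elongation control.

test_that("jitter 0 single crystal gives a perfect triangular tiling of hexagons", {
  cfg <- monolayerConfig(boxWidth = 80, boxHeight = 80, targetRcc = 10,
                         jitter = 0, grainSize = Inf)
  ml <- generateMonolayer(cfg)
  int <- !isBorder(ml)
  expect_gt(sum(int), 10)
  nv <- vapply(cellPolygons(ml)[int], function(cp) nrow(cp@vertices), integer(1))
  expect_true(all(nv == 6L))
  nb <- lengths(adjacencyList(ml))[int]
  expect_true(all(nb == 6L))
  ## every interior cell is a regular hexagon: |gamma_6| = 1
  g6 <- vapply(cellPolygons(ml)[int], function(cp) Mod(gammaP(cp, 6)), numeric(1))
  expect_true(all(abs(g6 - 1) < 1e-9))
  expect_equal(rcc(ml), 10, tolerance = 1e-9)
})

test_that("tessellation partitions the box (confluency)", {
  cfg <- monolayerConfig(boxWidth = 100, boxHeight = 80, targetRcc = 13,
                         jitter = 0.4, seed = 5)
  ml <- generateMonolayer(cfg)
  expect_equal(sum(cellAreas(ml)), 100 * 80, tolerance = 1e-6)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- monolayerConfig(jitter = 0.3, seed = 17)
  p1 <- generateSeedPoints(cfg)
  p2 <- generateSeedPoints(cfg)
  expect_identical(p1, p2)
  r1 <- simulateJunctionImage(cfg)
  r2 <- simulateJunctionImage(cfg)
  expect_identical(r1$image, r2$image)
})

test_that("elongation 2 at jitter 0 stretches the lattice 2x along x", {
  base <- monolayerConfig(boxWidth = 100, boxHeight = 100, targetRcc = 10,
                          jitter = 0, grainSize = Inf)
  str2 <- monolayerConfig(boxWidth = 100, boxHeight = 100, targetRcc = 10,
                          jitter = 0, grainSize = Inf, elongation = 2,
                          elongationAxis = 0)
  pts <- generateSeedPoints(str2)
  ## the point set must be an affine (2, 1/2) image of a triangular
  ## lattice: inverse-stretched pairwise displacements lie on the lattice
  a <- str2@targetRcc / hexanematic:::meanStretchFactor(2)
  rel <- sweep(pts, 2L, pts[1, ])
  un <- cbind(rel[, 1] / 2, rel[, 2] * 2)
  ## lattice coordinates in the basis (a, 0), (a/2, a sqrt(3)/2)
  j <- un[, 2] / (a * sqrt(3) / 2)
  i <- un[, 1] / a - j / 2
  expect_lt(max(abs(i - round(i))), 1e-6)
  expect_lt(max(abs(j - round(j))), 1e-6)
})

test_that("cell gamma_2 orientation equals the elongation axis on stretched lattices", {
  for (axis in c(0, pi / 5)) {
    cfg <- monolayerConfig(boxWidth = 120, boxHeight = 120, targetRcc = 12,
                           jitter = 0, grainSize = Inf, elongation = 1.4,
                           elongationAxis = axis)
    ml <- generateMonolayer(cfg)
    int <- which(!isBorder(ml))
    th2 <- vapply(cellPolygons(ml)[int],
                  function(cp) pFoldOrientation(cp, 2), numeric(1))
    ## orientation is defined modulo pi
    dev <- abs(((th2 - axis + pi / 2) %% pi) - pi / 2)
    expect_lt(max(dev), 1e-6)
  }
})

test_that("|gamma_2| increases strictly with elongation on the perfect lattice", {
  g2 <- vapply(c(1, 1.2, 1.5, 2), function(e) {
    cfg <- monolayerConfig(boxWidth = 100, boxHeight = 100, targetRcc = 10,
                           jitter = 0, grainSize = Inf, elongation = e)
    ml <- generateMonolayer(cfg)
    mean(vapply(cellPolygons(ml)[!isBorder(ml)],
                function(cp) Mod(gammaP(cp, 2)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(g2) > 0))
  expect_lt(g2[1], 1e-9)
})

test_that("realized mean cell-cell distance tracks the target within 5%", {
  for (jit in c(0.2, 0.5)) {
    rccs <- vapply(1:5, function(s) {
      rcc(generateMonolayer(monolayerConfig(boxWidth = 140, boxHeight = 140,
                                            targetRcc = 16, jitter = jit,
                                            seed = s)))
    }, numeric(1))
    expect_lt(abs(mean(rccs) / 16 - 1), 0.05)
  }
})

test_that("mean interior neighbor count is close to 6 (planar tiling)", {
  counts <- unlist(lapply(1:5, function(s) {
    ml <- toyMonolayer(n = 120, box = c(100, 100), seed = s)
    lengths(adjacencyList(ml))[!isBorder(ml)]
  }))
  expect_gt(length(counts), 100)
  expect_lt(abs(mean(counts) - 6), 0.1)
})

test_that("generator rejects invalid configurations and degenerate input", {
  expect_error(monolayerConfig(jitter = 1.5), "jitter")
  expect_error(monolayerConfig(elongation = 0.8), "elongation")
  expect_error(generateMonolayer(monolayerConfig(boxWidth = 20, boxHeight = 20,
                                                 targetRcc = 16)), "too small")
  pts <- triangularLattice(10, c(60, 60))
  pts2 <- rbind(pts, pts[3, , drop = FALSE])
  expect_error(tessellate(pts2, c(60, 60)), "duplicate")
  expect_error(tessellate(cbind(1:20, 2 * (1:20)), c(60, 60)), "collinear")
})

test_that("rendering refuses a pixel size too coarse to resolve cells", {
  ml <- generateMonolayer(monolayerConfig(seed = 2))
  cfg <- monolayerConfig(seed = 2, pixelSize = 3)
  expect_error(renderJunctionImage(ml, cfg), "too coarse")
})

test_that("noiseless thin-line rendering thresholds back to the drawn edges", {
  cfg <- monolayerConfig(boxWidth = 60, boxHeight = 60, targetRcc = 12,
                         jitter = 0.2, seed = 4, lineWidthPx = 1,
                         blurSigmaPx = 0, noiseSd = 0)
  ren <- simulateJunctionImage(cfg)
  sk <- skeletonizeJunctions(ren$image, threshold = "fixed:0.5",
                             smoothSigmaPx = 0, pruneLen = 0L)
  ## every skeleton pixel lies within 1 px of a ground-truth edge
  segs <- hexanematic:::uniqueEdges(ren$monolayer)
  px <- cfg@pixelSize
  skp <- which(sk, arr.ind = TRUE)
  xy <- cbind((skp[, 2] - 0.5) * px, (skp[, 1] - 0.5) * px)
  dseg <- function(p) {
    d <- Inf
    for (s in seq_len(nrow(segs))) {
      a <- segs[s, 1:2]; b <- segs[s, 3:4]
      ab <- b - a; t <- sum((p - a) * ab) / sum(ab^2)
      t <- min(1, max(0, t))
      d <- min(d, sqrt(sum((a + t * ab - p)^2)))
    }
    d
  }
  idx <- hexanematic:::withSeed(1L, sample(seq_len(nrow(xy)), 200))
  dmax <- max(vapply(idx, function(i) dseg(xy[i, ]), numeric(1)))
  expect_lt(dmax, 1 * px + 1e-9)
})
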