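## Junction-image segmentation: threshold the junction-marker signal,
## skeletonize it to a 1-px network, take branch points (pixels where at
## least three cells meet) as cell vertices, and rebuild each cell as the
## straight-line polygon through the ordered vertices on its face. The
## skeleton curvature between vertices is deliberately discarded: the
## polygon representation is the analysis substrate.
##
## Image conventions: numeric matrix, rows = y (down), columns = x (right),
## origin at the top-left corner; pixel (r, c) is centered at
## x = (c - 0.5) * pixelSize, y = (r - 0.5) * pixelSize.

## matrix shift with zero fill; dr, dc in matrix index direction
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs + dr, cs + dc] <- m[rs, cs]
  out
}

## Otsu threshold on a 256-bin histogram
otsuThreshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) stop("no junction signal: image is constant")
  h <- as.numeric(tabulate(pmin(256L, 1L + floor((img - rng[1]) / diff(rng) * 256)),
                           nbins = 256L))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(256L))
  muT <- mu[256L]
  n <- w[256L]
  between <- (muT * w - mu * n)^2 / (w * (n - w))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  rng[1] + (k / 256) * diff(rng)
}

#' Skeletonize a junction-marker image
#'
#' Thresholds the image (Otsu by default), removes connected components
#' smaller than `minComponentPx`, and thins the mask to a 1-px-wide
#' skeleton (Zhang-Suen).
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param threshold `"otsu"`, a numeric threshold, or `"fixed:<value>"`.
#' @param minComponentPx suprathreshold components smaller than this many
#'   pixels are discarded (default 10).
#' @param smoothSigmaPx Gaussian pre-smoothing of the image before
#'   thresholding (px); suppresses ragged mask edges and the skeleton
#'   spurs they cause. 0 disables (default 1).
#' @param pruneLen skeleton spur branches up to this length (px) are
#'   removed after thinning (default 6; 0 disables).
#' @return Logical matrix: the skeleton.
#' @export
skeletonizeJunctions <- function(image, threshold = "otsu", minComponentPx = 10L,
                                 smoothSigmaPx = 1, pruneLen = 6L) {
  if (smoothSigmaPx > 0) {
    sm <- EBImage::gblur(image, sigma = smoothSigmaPx)
    image <- matrix(as.numeric(sm), nrow(image), ncol(image))
  }
  if (is.character(threshold)) {
    if (identical(threshold, "otsu")) {
      th <- otsuThreshold(image)
    } else if (startsWith(threshold, "fixed:")) {
      th <- as.numeric(sub("^fixed:", "", threshold))
    } else stop("threshold must be 'otsu', 'fixed:<value>' or a number")
  } else th <- as.numeric(threshold)
  mask <- image > th
  if (!any(mask)) stop("no junction signal: empty suprathreshold set")
  if (minComponentPx > 0L) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < minComponentPx)
    if (length(small)) mask[lab %in% small] <- FALSE
    if (!any(mask)) stop("no junction signal: all components below minComponentPx")
  }
  pruneSpurs(zhangSuen(mask), pruneLen)
}

## remove spur branches by peeling endpoint pixels n times
pruneSpurs <- function(sk, n) {
  img <- sk != 0
  storage.mode(img) <- "integer"
  for (k in seq_len(n)) {
    nb <- shiftMat(img, 1L, 0L) + shiftMat(img, -1L, 0L) +
          shiftMat(img, 0L, 1L) + shiftMat(img, 0L, -1L) +
          shiftMat(img, 1L, 1L) + shiftMat(img, 1L, -1L) +
          shiftMat(img, -1L, 1L) + shiftMat(img, -1L, -1L)
    ends <- img == 1L & nb <= 1L
    if (!any(ends)) break
    img[ends] <- 0L
  }
  img == 1L
}

## Zhang-Suen thinning, vectorized over the image
zhangSuen <- function(mask) {
  img <- mask != 0
  storage.mode(img) <- "integer"
  repeat {
    changedAny <- FALSE
    for (pass in 0:1) {
      ## neighbors in the conventional order P2..P9 (N, NE, E, SE, S, SW, W, NW)
      ## with y down: N is row - 1 -> shift the image down to read it
      P2 <- shiftMat(img, +1L, 0L);  P3 <- shiftMat(img, +1L, -1L)
      P4 <- shiftMat(img, 0L, -1L);  P5 <- shiftMat(img, -1L, -1L)
      P6 <- shiftMat(img, -1L, 0L);  P7 <- shiftMat(img, -1L, +1L)
      P8 <- shiftMat(img, 0L, +1L);  P9 <- shiftMat(img, +1L, +1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
           (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
           (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
           (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
      if (pass == 0L) {
        cond <- img == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        cond <- img == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      if (any(cond)) {
        img[cond] <- 0L
        changedAny <- TRUE
      }
    }
    if (!changedAny) break
  }
  img == 1L
}

#' Detect cell vertices on a skeleton
#'
#' Branch points -- skeleton pixels where at least three skeleton arms
#' meet -- are clustered by single linkage with radius `clusterRadius`
#' (the thinning splits one biological junction into adjacent branch
#' pixels), and each cluster is reported at its centroid. An arm count of
#' three or more is established by the crossing number (cyclic background
#' to foreground transitions around the pixel), which, unlike a plain
#' neighbor count, is not fooled by staircase pixels on diagonal lines.
#'
#' @param skeleton logical matrix from [skeletonizeJunctions()].
#' @param clusterRadius single-linkage merge radius in px (default 2).
#' @return n x 2 matrix of vertex positions in pixel coordinates
#'   (x = column - 0.5, y = row - 0.5); zero rows when the skeleton has no
#'   branch points.
#' @export
detectVertices <- function(skeleton, clusterRadius = 2) {
  sk <- skeleton != 0
  storage.mode(sk) <- "integer"
  ## crossing number: 0->1 transitions in the cyclic 8-neighborhood
  P2 <- shiftMat(sk, +1L, 0L);  P3 <- shiftMat(sk, +1L, -1L)
  P4 <- shiftMat(sk, 0L, -1L);  P5 <- shiftMat(sk, -1L, -1L)
  P6 <- shiftMat(sk, -1L, 0L);  P7 <- shiftMat(sk, -1L, +1L)
  P8 <- shiftMat(sk, 0L, +1L);  P9 <- shiftMat(sk, +1L, +1L)
  A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
       (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
       (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
       (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
  branch <- which(sk == 1L & A >= 3L, arr.ind = TRUE)
  if (nrow(branch) == 0L) {
    return(matrix(numeric(), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  }
  pts <- cbind(x = branch[, "col"] - 0.5, y = branch[, "row"] - 0.5)
  if (nrow(pts) > 1L) {
    cl <- stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                        h = clusterRadius)
  } else cl <- 1L
  ctr <- t(vapply(split(seq_len(nrow(pts)), cl),
                  function(ix) colMeans(pts[ix, , drop = FALSE]), numeric(2)))
  colnames(ctr) <- c("x", "y")
  ctr
}

#' Refine vertex positions by local intensity weighting
#'
#' Sub-pixel localization of junction vertices: each vertex is moved to
#' the centroid of the suprathreshold (smoothed) junction signal within a
#' small window, which is approximately symmetric about the true junction
#' center. This removes the inward bias that skeleton branch-pixel chains
#' impose on the cluster centroids.
#'
#' @param vertices vertex matrix from [detectVertices()] (pixel coords).
#' @param image the junction image (same orientation), ideally smoothed.
#' @param threshold intensity threshold defining the junction signal.
#' @param radius window radius in px (default 3).
#' @return The refined vertex matrix.
#' @export
refineVertices <- function(vertices, image, threshold, radius = 3L) {
  H <- nrow(image); W <- ncol(image)
  for (i in seq_len(nrow(vertices))) {
    c0 <- as.integer(round(vertices[i, 1] + 0.5))
    r0 <- as.integer(round(vertices[i, 2] + 0.5))
    rs <- max(1L, r0 - radius):min(H, r0 + radius)
    cs <- max(1L, c0 - radius):min(W, c0 + radius)
    w <- image[rs, cs, drop = FALSE] - threshold
    w[w < 0] <- 0
    if (sum(w) > 0) {
      vertices[i, 1] <- sum(rep(cs - 0.5, each = length(rs)) * w) / sum(w)
      vertices[i, 2] <- sum(rep(rs - 0.5, times = length(cs)) * w) / sum(w)
    }
  }
  vertices
}

#' Reconstruct cell polygons from a skeleton and its vertices
#'
#' The enclosed faces of the junction network (4-connected components of
#' the skeleton complement) become cells. Each face's polygon is the set
#' of detected vertices on its boundary, ordered by angle around the face
#' centroid and connected by straight lines. Two faces are neighbors when
#' a piece of skeleton away from any vertex separates them (a shared
#' junction edge); for an interior cell the neighbor count then equals the
#' vertex count. Faces touching the image border are flagged `is_border`.
#' Faces with fewer than 3 vertices are dropped with a warning.
#'
#' @param skeleton logical matrix.
#' @param vertices vertex matrix from [detectVertices()] (pixel coords).
#' @param pixelSize um per pixel.
#' @param vertexRadius px radius of the window used to assign vertices to
#'   faces (default 5).
#' @param minFacePx faces smaller than this many pixels are ignored as
#'   skeletonization debris (default 9).
#' @param borderBandPx faces reaching within this many pixels of the
#'   image edge are flagged as border cells (default 4).
#' @return A [Monolayer-class] in um coordinates.
#' @export
buildPolygons <- function(skeleton, vertices, pixelSize,
                          vertexRadius = 5L, minFacePx = 9L,
                          borderBandPx = 4L) {
  sk <- skeleton != 0
  H <- nrow(sk); W <- ncol(sk)
  lab <- EBImage::bwlabel(!sk)  # 4-connected faces
  nf <- max(lab)
  if (nf == 0L) stop("skeleton leaves no enclosed faces")
  sizes <- tabulate(lab[lab > 0L], nbins = nf)
  ## faces reaching within borderBandPx of the image edge are border cells
  ## (the field of view cuts them; a rasterized boundary ridge may sit
  ## between such a face and the edge itself)
  band <- unique(c(seq_len(min(borderBandPx, H)), seq(max(1L, H - borderBandPx + 1L), H)))
  bandC <- unique(c(seq_len(min(borderBandPx, W)), seq(max(1L, W - borderBandPx + 1L), W)))
  borderLabs <- unique(c(lab[band, ], lab[, bandC]))
  borderLabs <- borderLabs[borderLabs > 0L]

  ## face centroids in pixel coordinates
  idx <- which(lab > 0L)
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  ll <- lab[idx]
  cx <- tapply(cc - 0.5, ll, mean)
  cy <- tapply(rr - 0.5, ll, mean)

  ## vertex -> incident faces: among labels in the window, keep those whose
  ## nearest pixel is within 1.5 px of the overall nearest face pixel (the
  ## junction blob is locally symmetric about the vertex, so the incident
  ## faces sit at nearly equal distances; farther labels lie across a ridge)
  nV <- nrow(vertices)
  vFaces <- vector("list", nV)
  for (v in seq_len(nV)) {
    c0 <- as.integer(round(vertices[v, 1] + 0.5))
    r0 <- as.integer(round(vertices[v, 2] + 0.5))
    rs <- max(1L, r0 - vertexRadius):min(H, r0 + vertexRadius)
    cs <- max(1L, c0 - vertexRadius):min(W, c0 + vertexRadius)
    win <- as.matrix(lab[rs, cs, drop = FALSE])
    labs <- setdiff(unique(as.vector(win)), 0L)
    if (!length(labs)) { vFaces[[v]] <- integer(); next }
    dmin <- vapply(labs, function(L) {
      ij <- which(win == L, arr.ind = TRUE)
      min((rs[ij[, 1]] - vertices[v, 2] - 0.5)^2 +
          (cs[ij[, 2]] - vertices[v, 1] - 0.5)^2)
    }, numeric(1))
    dmin <- sqrt(dmin)
    vFaces[[v]] <- labs[dmin <= min(dmin) + 1.5]
  }

  ## adjacency votes from skeleton pixels away from vertices
  vzone <- matrix(FALSE, H, W)
  if (nV > 0L) {
    rad <- 2L
    off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
    off <- off[off$dr^2 + off$dc^2 <= rad^2, , drop = FALSE]
    vr <- as.integer(round(vertices[, 2] + 0.5))
    vc <- as.integer(round(vertices[, 1] + 0.5))
    for (k in seq_len(nrow(off))) {
      r2 <- vr + off$dr[k]; c2 <- vc + off$dc[k]
      ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
      vzone[cbind(r2[ok], c2[ok])] <- TRUE
    }
  }
  skIdx <- which(sk & !vzone)
  pairVotes <- new.env(hash = TRUE, parent = emptyenv())
  if (length(skIdx)) {
    sr <- ((skIdx - 1L) %% H) + 1L
    sc <- ((skIdx - 1L) %/% H) + 1L
    nbr <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                 c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
    labAt <- matrix(0L, length(skIdx), nrow(nbr))
    for (k in seq_len(nrow(nbr))) {
      r2 <- sr + nbr[k, 1]; c2 <- sc + nbr[k, 2]
      ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
      vals <- integer(length(skIdx))
      vals[ok] <- lab[cbind(r2[ok], c2[ok])]
      labAt[, k] <- vals
    }
    for (i in seq_len(nrow(labAt))) {
      u <- unique(labAt[i, ])
      u <- u[u > 0L]
      if (length(u) == 2L) {
        key <- paste(min(u), max(u))
        cur <- if (exists(key, pairVotes, inherits = FALSE)) get(key, pairVotes) else 0L
        assign(key, cur + 1L, pairVotes)
      }
    }
  }
  votedPairs <- do.call(rbind, lapply(ls(pairVotes), function(k) {
    as.integer(strsplit(k, " ")[[1]])
  }))

  ## assemble faces -> polygons
  keepFace <- which(sizes >= minFacePx)
  faceVerts <- vector("list", nf)
  for (v in seq_len(nV)) for (f in vFaces[[v]]) {
    faceVerts[[f]] <- c(faceVerts[[f]], v)
  }
  ## inverse incidence for the shared-vertex adjacency
  faceVerts2 <- vector("list", nV)
  for (f in keepFace) {
    for (v in unique(faceVerts[[f]])) {
      faceVerts2[[v]] <- c(faceVerts2[[v]], f)
    }
  }
  dropped <- 0L
  cells <- list()
  faceToId <- integer(nf)
  nextId <- 0L
  for (f in keepFace) {
    vs <- unique(faceVerts[[f]])
    if (length(vs) < 3L) { dropped <- dropped + 1L; next }
    vxy <- vertices[vs, , drop = FALSE]
    ang <- atan2(vxy[, 2] - cy[[as.character(f)]], vxy[, 1] - cx[[as.character(f)]])
    vxy <- vxy[order(ang), , drop = FALSE]
    cp <- tryCatch(
      CellPolygon(cellId = nextId + 1L, vertices = vxy * pixelSize,
                  isBorder = f %in% borderLabs),
      error = function(e) NULL)
    if (is.null(cp)) { dropped <- dropped + 1L; next }
    nextId <- nextId + 1L
    faceToId[f] <- nextId
    cells[[nextId]] <- cp
  }
  if (dropped > 0L) {
    warning(sprintf("%d faces dropped (fewer than 3 vertices or degenerate polygon)", dropped))
  }
  if (!length(cells)) stop("no valid cell polygons reconstructed")
  ## adjacency: faces separated by a skeleton edge (vote pairs), united
  ## with faces sharing two vertices (an edge of the straight-line
  ## tiling); the union is robust to vertex-assignment misses on one side
  ## and to short edges hidden inside vertex clusters on the other
  pairCount <- new.env(hash = TRUE, parent = emptyenv())
  for (v in seq_len(nV)) {
    fs <- faceVerts2[[v]]
    if (length(fs) < 2L) next
    for (a in seq_len(length(fs) - 1L)) for (b in seq(a + 1L, length(fs))) {
      key <- paste(min(fs[a], fs[b]), max(fs[a], fs[b]))
      cur <- if (exists(key, pairCount, inherits = FALSE)) get(key, pairCount) else 0L
      assign(key, cur + 1L, pairCount)
    }
  }
  sharedPairs <- do.call(rbind, lapply(ls(pairCount), function(k) {
    if (get(k, pairCount) >= 2L) as.integer(strsplit(k, " ")[[1]]) else NULL
  }))
  allPairs <- rbind(votedPairs, sharedPairs)
  if (!is.null(allPairs)) {
    for (r in seq_len(nrow(allPairs))) {
      ia <- faceToId[allPairs[r, 1]]
      ib <- faceToId[allPairs[r, 2]]
      if (ia > 0L && ib > 0L && ia != ib) {
        cells[[ia]]@neighborIds <- union(cells[[ia]]@neighborIds, ib)
        cells[[ib]]@neighborIds <- union(cells[[ib]]@neighborIds, ia)
      }
    }
  }
  Monolayer(cells = cells, box = c(W, H) * pixelSize, pixelSize = pixelSize)
}

#' Segment a junction-marker image into a Monolayer
#'
#' [skeletonizeJunctions()], [detectVertices()] and [buildPolygons()] in
#' sequence.
#'
#' @param image numeric matrix (rows = y), or a list with an `image`
#'   element as returned by [renderJunctionImage()].
#' @param pixelSize um per pixel (taken from the render list if present).
#' @param threshold see [skeletonizeJunctions()].
#' @param minComponentPx,smoothSigmaPx see [skeletonizeJunctions()].
#' @param refine sub-pixel vertex refinement via [refineVertices()]
#'   (default TRUE).
#' @param ... passed to [buildPolygons()].
#' @return A [Monolayer-class].
#' @export
segmentMonolayer <- function(image, pixelSize = NULL, threshold = "otsu",
                             minComponentPx = 10L, smoothSigmaPx = 1,
                             refine = TRUE, ...) {
  if (is.list(image)) {
    if (is.null(pixelSize)) pixelSize <- image$pixelSize
    image <- image$image
  }
  if (is.null(pixelSize)) stop("pixelSize is required")
  sk <- skeletonizeJunctions(image, threshold = threshold,
                             minComponentPx = minComponentPx,
                             smoothSigmaPx = smoothSigmaPx)
  vx <- detectVertices(sk)
  if (refine && nrow(vx)) {
    sm <- if (smoothSigmaPx > 0) {
      matrix(as.numeric(EBImage::gblur(image, sigma = smoothSigmaPx)),
             nrow(image), ncol(image))
    } else image
    th <- if (identical(threshold, "otsu")) otsuThreshold(sm) else
      if (is.character(threshold)) as.numeric(sub("^fixed:", "", threshold)) else
      as.numeric(threshold)
    vx <- refineVertices(vx, sm, th)
  }
  buildPolygons(sk, vx, pixelSize = pixelSize, ...)
}

#' Segmentation accuracy against ground truth
#'
#' Matches segmented cells to ground-truth cells by mutual nearest
#' centroids within `maxDist` and reports recovery and error metrics for
#' the interior ground-truth cells: the recovered fraction, centroid
#' errors, relative area errors, and the F1 score of the neighbor relation
#' restricted to matched interior cells.
#'
#' @param truth ground-truth [Monolayer-class].
#' @param seg segmented [Monolayer-class].
#' @param maxDist maximum centroid distance for a match (um), default 3.
#' @return A list: `recovered` (fraction of interior truth cells matched),
#'   `centroidError` (um, per matched cell), `areaError` (relative, per
#'   matched cell), `medianAreaError`, `neighborF1`, `matches` (data.frame
#'   truth_id, seg_id).
#' @export
segmentationAccuracy <- function(truth, seg, maxDist = 3) {
  tIds <- cellIds(truth); sIds <- cellIds(seg)
  tInt <- !isBorder(truth)
  tc <- centroids(truth); sc <- centroids(seg)
  d <- sqrt(outer(tc[, 1], sc[, 1], "-")^2 + outer(tc[, 2], sc[, 2], "-")^2)
  ## mutual nearest neighbor matching
  bestS <- apply(d, 1L, which.min)
  bestT <- apply(d, 2L, which.min)
  ti <- seq_along(tIds)
  mutual <- bestT[bestS] == ti & d[cbind(ti, bestS)] <= maxDist
  matches <- data.frame(truth_idx = ti[mutual & tInt],
                        seg_idx = bestS[mutual & tInt])
  recovered <- nrow(matches) / sum(tInt)
  ce <- d[cbind(matches$truth_idx, matches$seg_idx)]
  ta <- cellAreas(truth)[matches$truth_idx]
  sa <- cellAreas(seg)[matches$seg_idx]
  ae <- abs(sa - ta) / ta
  ## neighbor-relation F1 over matched interior truth cells
  tMap <- integer(length(tIds)); tMap[matches$truth_idx] <- matches$seg_idx
  tAdj <- adjacencyList(truth); sAdj <- adjacencyList(seg)
  tp <- 0L; fp <- 0L; fn <- 0L
  mt <- matches$truth_idx
  for (i in mt) {
    tnb <- tAdj[[i]]
    tnb <- match(tnb, tIds)
    tnb <- tnb[tnb %in% mt & tnb > i]
    snb <- match(sAdj[[tMap[i]]], sIds)
    for (j in tnb) {
      if (tMap[j] %in% snb) tp <- tp + 1L else fn <- fn + 1L
    }
    ## false positives: segmented neighbors among matched cells that are
    ## not truth neighbors
    backT <- match(snb, tMap)  # seg idx -> truth idx
    backT <- backT[!is.na(backT) & backT > i & backT %in% mt]
    fp <- fp + sum(!(backT %in% tnb))
  }
  f1 <- if (tp + fp + fn == 0L) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  list(recovered = recovered, centroidError = ce, areaError = ae,
       medianAreaError = stats::median(ae), neighborF1 = f1,
       matches = data.frame(truth_id = tIds[matches$truth_idx],
                            seg_id = sIds[matches$seg_idx]))
}
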