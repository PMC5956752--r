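#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a bone mesh
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param regions named list of integer vertex-index vectors labelling
#'   anatomical point selections (e.g. `condyle`, `shaft`, `plateau`).
#' @return A [BoneMesh-class].
#' @export
boneMesh <- function(vertices, faces, regions = list()) {
  storage.mode(faces) <- "integer"
  new("BoneMesh", vertices = as.matrix(vertices), faces = faces,
      regions = regions)
}

#' @rdname accessors
#' @export
setMethod("vertices", "BoneMesh", function(object) object@vertices)

#' @rdname accessors
#' @export
setMethod("faces", "BoneMesh", function(object) object@faces)

#' @rdname accessors
#' @export
setMethod("regions", "BoneMesh", function(object) object@regions)

setMethod("show", "BoneMesh", function(object) {
  cat(sprintf("BoneMesh: %d vertices, %d faces", nrow(object@vertices),
              nrow(object@faces)))
  if (length(object@regions))
    cat(sprintf(", regions: %s", paste(names(object@regions),
                                       collapse = ", ")))
  cat("\n")
})

#' Region vertices of a mesh
#'
#' @param mesh a [BoneMesh-class].
#' @param region region name, or an integer vector of vertex indices.
#' @return Matrix of the selected vertices (mm).
#' @export
regionPoints <- function(mesh, region) {
  idx <- if (is.character(region)) {
    if (is.null(mesh@regions[[region]]))
      stop("mesh has no region labelled '", region, "'")
    mesh@regions[[region]]
  } else as.integer(region)
  mesh@vertices[idx, , drop = FALSE]
}

#' Rigidly transform a mesh
#'
#' @param mesh a [BoneMesh-class].
#' @param transform a [RigidTransform-class].
#' @return The transformed [BoneMesh-class] (regions preserved).
#' @export
transformMesh <- function(mesh, transform) {
  boneMesh(transformPoints(transform, mesh@vertices), mesh@faces,
           mesh@regions)
}

## ---------------------------------------------------------------------------
## mesh-plane and mesh-line intersections
## ---------------------------------------------------------------------------

#' Cross-section of a mesh with a plane
#'
#' Intersects every triangle with the plane through
#' `origin + level * axis` with normal `axis`, chains the resulting
#' segments into a closed boundary loop, and returns its points in order.
#'
#' @param mesh a [BoneMesh-class].
#' @param level signed distance of the slice plane along `axis` from
#'   `origin`, mm.
#' @param axis unit 3-vector: the long axis the level is measured along.
#' @param origin reference point the level is measured from (default the
#'   vertex centroid projected to the axis through 0; pass the bone's
#'   plateau apex for anatomical levels).
#' @return A list: `points3d` (n x 3 ordered boundary points),
#'   `points2d` (n x 2 in-plane coordinates), `basis` (3 x 2 in-plane unit
#'   vectors), `planePoint` (3-vector), `area` (polygon area, mm^2).
#' @export
sliceCrossSection <- function(mesh, level, axis = c(0, 1, 0),
                              origin = c(0, 0, 0)) {
  axis <- unitize(axis)
  p0 <- origin + level * axis
  v <- mesh@vertices
  d <- as.numeric((v - matrix(p0, nrow(v), 3, byrow = TRUE)) %*% axis)
  f <- mesh@faces
  d1 <- d[f[, 1]]; d2 <- d[f[, 2]]; d3 <- d[f[, 3]]
  crosses <- (pmax(d1, d2, d3) > 0) & (pmin(d1, d2, d3) < 0)
  if (!any(crosses))
    stop("slice level does not intersect the mesh")
  segs <- list()
  for (fi in which(crosses)) {
    ids <- f[fi, ]
    dv <- d[ids]
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      da <- dv[e[1]]; db <- dv[e[2]]
      if ((da > 0 && db < 0) || (da < 0 && db > 0)) {
        t <- da / (da - db)
        pts[[length(pts) + 1L]] <-
          v[ids[e[1]], ] + t * (v[ids[e[2]], ] - v[ids[e[1]], ])
      }
    }
    if (length(pts) == 2L)
      segs[[length(segs) + 1L]] <- rbind(pts[[1]], pts[[2]])
  }
  if (length(segs) < 3L)
    stop("slice produced a degenerate cross-section")
  ## in-plane basis
  u <- unitize(cross3(axis, if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  w <- cross3(axis, u)
  toPlane <- function(p) c(sum((p - p0) * u), sum((p - p0) * w))
  s2 <- lapply(segs, function(s) rbind(toPlane(s[1, ]), toPlane(s[2, ])))
  ## chain segments into a loop by endpoint matching
  n <- length(s2)
  ends <- do.call(rbind, lapply(s2, function(s) c(s[1, ], s[2, ])))
  used <- logical(n)
  ord <- integer(0)
  flip <- logical(0)
  cur <- 1L; used[1L] <- TRUE; ord <- 1L; flip <- FALSE
  curPt <- ends[1L, 3:4]
  tol <- 1e-6 * max(abs(ends), 1)
  for (step in seq_len(n - 1L)) {
    d2a <- (ends[, 1] - curPt[1])^2 + (ends[, 2] - curPt[2])^2
    d2b <- (ends[, 3] - curPt[1])^2 + (ends[, 4] - curPt[2])^2
    d2a[used] <- Inf; d2b[used] <- Inf
    ka <- which.min(d2a); kb <- which.min(d2b)
    if (d2a[ka] <= d2b[kb]) {
      if (!is.finite(d2a[ka])) break
      ord <- c(ord, ka); flip <- c(flip, FALSE); used[ka] <- TRUE
      curPt <- ends[ka, 3:4]
    } else {
      if (!is.finite(d2b[kb])) break
      ord <- c(ord, kb); flip <- c(flip, TRUE); used[kb] <- TRUE
      curPt <- ends[kb, 1:2]
    }
  }
  pts2 <- do.call(rbind, lapply(seq_along(ord), function(k) {
    s <- s2[[ord[k]]]
    if (flip[k]) s[2, , drop = FALSE] else s[1, , drop = FALSE]
  }))
  ## drop consecutive duplicates
  keep <- c(TRUE, rowSums((pts2[-1, , drop = FALSE] -
                           pts2[-nrow(pts2), , drop = FALSE])^2) > tol^2)
  pts2 <- pts2[keep, , drop = FALSE]
  basis <- cbind(u, w)
  pts3 <- matrix(p0, nrow(pts2), 3, byrow = TRUE) + pts2 %*% t(basis)
  nP <- nrow(pts2)
  area <- abs(sum(pts2[, 1] * pts2[c(2:nP, 1), 2] -
                  pts2[c(2:nP, 1), 1] * pts2[, 2])) / 2
  list(points3d = pts3, points2d = pts2, basis = basis, planePoint = p0,
       area = area)
}

#' Intersections of a line with a mesh surface
#'
#' Used to clip the condylar cylinder axis by the medial and lateral bony
#' surfaces. Returns the sorted signed parameters t of all triangle
#' intersections of the line `point + t * direction`.
#'
#' @param mesh a [BoneMesh-class].
#' @param point a point on the line, mm.
#' @param direction line direction (need not be unit length).
#' @return Sorted numeric vector of parameters t (mm when `direction` is a
#'   unit vector); empty if the line misses the mesh.
#' @export
lineMeshIntersections <- function(mesh, point, direction) {
  dirU <- unitize(direction)
  v <- mesh@vertices
  f <- mesh@faces
  v1 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v1
  e2 <- v[f[, 3], , drop = FALSE] - v1
  ## Moller-Trumbore, vectorized over triangles
  h <- cbind(dirU[2] * e2[, 3] - dirU[3] * e2[, 2],
             dirU[3] * e2[, 1] - dirU[1] * e2[, 3],
             dirU[1] * e2[, 2] - dirU[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  s <- matrix(point, nrow(v1), 3, byrow = TRUE) - v1
  u <- rowSums(s * h) / a
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  vv <- (q[, 1] * dirU[1] + q[, 2] * dirU[2] + q[, 3] * dirU[3]) / a
  tt <- rowSums(e2 * q) / a
  hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9
  sort(tt[hit])
}

## ---------------------------------------------------------------------------
## primitive meshes
## ---------------------------------------------------------------------------

#' Primitive meshes
#'
#' Building blocks for the synthetic bones and for tests: closed cylinders
#' (optionally elliptical), axis-aligned boxes and UV spheres.
#'
#' @param radius cylinder/sphere radius, mm (for `meshCylinder`, a length-2
#'   vector gives an elliptical section with the two semi-axes).
#' @param from,to axis end points of the cylinder, mm.
#' @param nTheta angular tessellation.
#' @param nLen lengthwise tessellation.
#' @param uDir optional unit vector fixing the direction of the first
#'   section semi-axis (needed for elliptical sections).
#' @return A [BoneMesh-class]; side-surface vertex indices are stored in
#'   region `side`, end caps in `cap1`/`cap2`.
#' @name primitives
NULL

#' @rdname primitives
#' @export
meshCylinder <- function(radius, from, to, nTheta = 72L, nLen = 8L,
                         uDir = NULL) {
  r <- if (length(radius) == 1L) c(radius, radius) else radius
  stopifnot(all(r > 0))
  axis <- to - from
  len <- vnorm(axis)
  d <- unitize(axis)
  if (is.null(uDir))
    uDir <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(uDir - sum(uDir * d) * d)
  w <- cross3(d, u)
  th <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  ring <- cbind(r[1] * cos(th), r[2] * sin(th))
  vlist <- list()
  for (iz in seq_len(nLen + 1L)) {
    z <- len * (iz - 1L) / nLen
    ctr <- from + z * d
    vlist[[iz]] <- matrix(ctr, nTheta, 3, byrow = TRUE) +
      ring[, 1] %o% u + ring[, 2] %o% w
  }
  verts <- do.call(rbind, vlist)
  nSide <- nrow(verts)
  fcs <- list()
  for (iz in seq_len(nLen)) {
    b0 <- (iz - 1L) * nTheta
    b1 <- iz * nTheta
    i <- seq_len(nTheta)
    j <- c(seq_len(nTheta)[-1], 1L)
    fcs[[length(fcs) + 1L]] <- cbind(b0 + i, b0 + j, b1 + i)
    fcs[[length(fcs) + 1L]] <- cbind(b0 + j, b1 + j, b1 + i)
  }
  ## caps: centre fans
  c1 <- nSide + 1L
  c2 <- nSide + 2L
  verts <- rbind(verts, from, to)
  i <- seq_len(nTheta)
  j <- c(seq_len(nTheta)[-1], 1L)
  fcs[[length(fcs) + 1L]] <- cbind(i, j, c1)
  topBase <- nLen * nTheta
  fcs[[length(fcs) + 1L]] <- cbind(topBase + j, topBase + i, c2)
  boneMesh(verts, do.call(rbind, fcs),
           regions = list(side = seq_len(nSide),
                          cap1 = c(seq_len(nTheta), c1),
                          cap2 = c(topBase + seq_len(nTheta), c2)))
}

#' @rdname primitives
#' @param center box/sphere centre, mm.
#' @param size box edge lengths, mm (3-vector).
#' @export
meshBox <- function(center, size) {
  h <- size / 2
  sgn <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  verts <- sweep(sweep(sgn, 2, h, "*"), 2, center, "+")
  quads <- rbind(c(1, 2, 4, 3), c(5, 7, 8, 6), c(1, 5, 6, 2),
                 c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 6, 8, 4))
  fcs <- do.call(rbind, lapply(seq_len(6), function(k) {
    q <- quads[k, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  boneMesh(verts, fcs)
}

#' @rdname primitives
#' @param nU,nV sphere tessellation (longitude, latitude).
#' @export
meshSphere <- function(radius, center = c(0, 0, 0), nU = 48L, nV = 24L) {
  phi <- seq(0, pi, length.out = nV + 1L)
  th <- seq(0, 2 * pi, length.out = nU + 1L)[-(nU + 1L)]
  verts <- list()
  for (iv in seq_len(nV + 1L)) {
    verts[[iv]] <- cbind(radius * sin(phi[iv]) * cos(th),
                         radius * sin(phi[iv]) * sin(th),
                         radius * cos(phi[iv]))
  }
  verts <- sweep(do.call(rbind, verts), 2, center, "+")
  fcs <- list()
  for (iv in seq_len(nV)) {
    b0 <- (iv - 1L) * nU
    b1 <- iv * nU
    i <- seq_len(nU)
    j <- c(seq_len(nU)[-1], 1L)
    fcs[[length(fcs) + 1L]] <- cbind(b0 + i, b0 + j, b1 + i)
    fcs[[length(fcs) + 1L]] <- cbind(b0 + j, b1 + j, b1 + i)
  }
  boneMesh(verts, do.call(rbind, fcs))
}

#' Merge meshes into one multi-part mesh
#'
#' @param ... [BoneMesh-class] objects.
#' @param regions optional named list of region labels to attach, each a
#'   list(part = part index, region = region name in that part) or raw
#'   indices.
#' @return A single [BoneMesh-class]; per-part regions are prefixed with
#'   the part number unless overridden.
#' @keywords internal
mergeMeshes <- function(...) {
  parts <- list(...)
  offs <- 0L
  verts <- list(); fcs <- list(); regs <- list()
  for (k in seq_along(parts)) {
    m <- parts[[k]]
    verts[[k]] <- m@vertices
    fcs[[k]] <- m@faces + offs
    for (rn in names(m@regions))
      regs[[paste0("part", k, ".", rn)]] <- m@regions[[rn]] + offs
    offs <- offs + nrow(m@vertices)
  }
  boneMesh(do.call(rbind, verts), do.call(rbind, fcs), regs)
}

## ---------------------------------------------------------------------------
## STL / PLY I/O (ASCII)
## ---------------------------------------------------------------------------

#' Read and write surface meshes
#'
#' Minimal ASCII STL and ASCII PLY support for exchanging bone models.
#' STL stores independent triangles, so `readSTL` welds coincident
#' vertices. Region labels are carried in a JSON sidecar
#' (`<path>.regions.json`) of vertex-index lists when present.
#'
#' @param mesh a [BoneMesh-class].
#' @param path file path.
#' @param writeRegions write the region sidecar if the mesh has regions.
#' @return `readSTL`/`readPLY` return a [BoneMesh-class].
#' @name mesh-io
NULL

#' @rdname mesh-io
#' @export
writeSTL <- function(mesh, path, writeRegions = TRUE) {
  v <- mesh@vertices
  f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (k in seq_len(nrow(f))) {
    p1 <- v[f[k, 1], ]; p2 <- v[f[k, 2], ]; p3 <- v[f[k, 3], ]
    n <- cross3(p2 - p1, p3 - p1)
    nl <- vnorm(n)
    n <- if (nl > 1e-12) n / nl else c(0, 0, 1)
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", p1[1], p1[2], p1[3]),
      sprintf("      vertex %.9g %.9g %.9g", p2[1], p2[2], p2[3]),
      sprintf("      vertex %.9g %.9g %.9g", p3[1], p3[2], p3[3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid mesh", con)
  if (writeRegions && length(mesh@regions))
    jsonlite::write_json(mesh@regions, paste0(path, ".regions.json"))
  invisible(path)
}

#' @rdname mesh-io
#' @export
readSTL <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  if (nrow(nums) %% 3L != 0L) stop("malformed ASCII STL: ", path)
  key <- apply(round(nums, 9), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- nums[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  fcs <- matrix(idx, ncol = 3, byrow = TRUE)
  regPath <- paste0(path, ".regions.json")
  regions <- if (file.exists(regPath)) {
    lapply(jsonlite::fromJSON(regPath), as.integer)
  } else list()
  boneMesh(verts, fcs, regions)
}

#' @rdname mesh-io
#' @export
writePLY <- function(mesh, path, writeRegions = TRUE) {
  v <- mesh@vertices
  f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
  if (writeRegions && length(mesh@regions))
    jsonlite::write_json(mesh@regions, paste0(path, ".regions.json"))
  invisible(path)
}

#' @rdname mesh-io
#' @export
readPLY <- function(path) {
  lines <- readLines(path)
  endH <- match("end_header", lines)
  if (is.na(endH)) stop("malformed PLY: ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vLines <- lines[(endH + 1L):(endH + nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vLines), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  fLines <- lines[(endH + nv + 1L):(endH + nv + nf)]
  fcs <- do.call(rbind, lapply(strsplit(trimws(fLines), "\\s+"), function(x)
    as.integer(x[2:4]) + 1L))
  regPath <- paste0(path, ".regions.json")
  regions <- if (file.exists(regPath)) {
    lapply(jsonlite::fromJSON(regPath), as.integer)
  } else list()
  boneMesh(verts, fcs, regions)
}
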