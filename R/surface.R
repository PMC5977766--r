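#' Triangulated surface
#'
#' A faceted (triangle-mesh) representation of a lumen wall patch, as
#' produced by segmentation pipelines exporting STL. Stored as an `n x 3`
#' vertex matrix (metres) and an `m x 3` integer triangle index matrix.
#'
#' @param vertices numeric matrix, one 3D point per row (m).
#' @param triangles integer matrix, one triple of 1-based vertex indices
#'   per row.
#' @param provenance optional list recording generating parameters.
#' @return An object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, triangles, provenance = list()) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)),
                      ncol = ncol(as.matrix(triangles)))
  if (ncol(vertices) != 3L || ncol(triangles) != 3L) {
    stopf("vertices and triangles must have 3 columns")
  }
  if (any(!is.finite(vertices))) stopf("vertex coordinates must be finite")
  if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
    stopf("triangle indices out of range")
  }
  areas <- triangle_areas(vertices, triangles)
  if (any(areas <= 0)) {
    stopf("surface contains %d degenerate (zero-area) triangles",
          sum(areas <= 0))
  }
  structure(list(vertices = vertices, triangles = triangles,
                 provenance = provenance),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("Triangulated surface: %d vertices, %d triangles, area %.6g m^2\n",
              nrow(x$vertices), nrow(x$triangles), surface_area(x)))
  invisible(x)
}

triangle_areas <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  u <- p2 - p1
  v <- p3 - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Axial extent of the tessellated patch: the carved span plus one lumen
# diameter of margin on each side, clipped to the vessel.
stenotic_patch_span <- function(geom, margin = 1) {
  c(max(0, geom$Ls - geom$Ds / 2 - margin * geom$D),
    min(geom$L, geom$Ls + geom$Ds / 2 + margin * geom$D))
}

# Smooth wall point of the parametric lumen surface at (theta, z): the
# cylinder point, replaced by its central projection onto the carving
# sphere wherever the cylinder point falls inside the sphere.
wall_points <- function(geom, theta, z) {
  R <- geom$D / 2
  px <- R * cos(theta)
  py <- R * sin(theta)
  pz <- z
  dx <- px - geom$d
  dz <- pz - geom$Ls
  dist <- sqrt(dx^2 + py^2 + dz^2)
  inside <- dist < geom$Ds / 2
  if (any(inside)) {
    f <- (geom$Ds / 2) / dist[inside]
    px[inside] <- geom$d + dx[inside] * f
    py[inside] <- py[inside] * f
    pz[inside] <- geom$Ls + dz[inside] * f
  }
  cbind(px, py, pz)
}

#' Tessellate the stenotic lumen wall
#'
#' Samples the lumen wall of the stenotic region (the carved span plus one
#' diameter of margin each side) on a structured axial-by-circumferential
#' grid. Grid points on the cylinder that fall inside the carving sphere
#' are projected onto the sphere (centrally, towards the sphere centre),
#' giving a continuous faceted surface with exactly
#' `N = 2 * n_axial * n_circ` triangles, watertight over the sampled
#' patch (closed circumferentially, open at the two axial ends).
#'
#' @param geom a [stenosis_geometry()].
#' @param n_axial number of axial intervals, >= 2.
#' @param n_circ number of circumferential intervals, >= 3.
#' @param margin axial margin either side of the carved span, in lumen
#'   diameters.
#' @return A [tri_surface()].
#' @export
tessellate <- function(geom, n_axial, n_circ, margin = 1) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  n_axial <- as.integer(n_axial)
  n_circ <- as.integer(n_circ)
  if (n_axial < 2L) stopf("n_axial must be >= 2")
  if (n_circ < 3L) stopf("n_circ must be >= 3")
  span <- stenotic_patch_span(geom, margin)
  zs <- seq(span[1], span[2], length.out = n_axial + 1L)
  thetas <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  grid <- expand.grid(theta = thetas, z = zs)
  verts <- wall_points(geom, grid$theta, grid$z)
  idx <- function(i, j) (j - 1L) * n_circ + ((i - 1L) %% n_circ) + 1L
  tris <- matrix(0L, nrow = 2L * n_axial * n_circ, ncol = 3L)
  k <- 1L
  for (j in seq_len(n_axial)) {
    for (i in seq_len(n_circ)) {
      v00 <- idx(i, j);      v10 <- idx(i + 1L, j)
      v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
      tris[k, ] <- c(v00, v10, v11); k <- k + 1L
      tris[k, ] <- c(v00, v11, v01); k <- k + 1L
    }
  }
  tri_surface(verts, tris,
              provenance = list(n_axial = n_axial, n_circ = n_circ,
                                margin = margin, D = geom$D))
}

#' Total area of a triangulated surface
#'
#' @param surf a [tri_surface()].
#' @return Sum of triangle areas (m^2).
#' @export
surface_area <- function(surf) {
  stopifnot(inherits(surf, "tri_surface"))
  sum(triangle_areas(surf$vertices, surf$triangles))
}

#' Surface Resolution Index
#'
#' \eqn{\mathrm{SRI} = N / (S_{\mathrm{area}} / D^2)}: triangles per unit
#' of dimensionless surface complexity, quantifying the quality of a
#' faceted lumen representation. The perfectly smooth analytic surface is
#' assigned `SRI = Inf`; finite surfaces always return a finite positive
#' value. Invariant under rigid motions and under uniform rescaling
#' applied to the surface and `D` together.
#'
#' @param surf a [tri_surface()], or `NULL` for the analytic smooth model.
#' @param D reference lumen diameter (m).
#' @return Dimensionless SRI (`Inf` for the smooth model).
#' @export
sri <- function(surf, D) {
  assert_scalar_num(D, "D", lower = .Machine$double.eps)
  if (is.null(surf)) return(Inf)
  stopifnot(inherits(surf, "tri_surface"))
  area <- surface_area(surf)
  if (area <= 0) stopf("surface area must be positive")
  nrow(surf$triangles) / (area / D^2)
}

# Unit normals for STL export, recomputed from vertex winding.
triangle_normals <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  u <- p2 - p1
  v <- p3 - p1
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, .Machine$double.xmin)
}

#' Write / read STL surface files
#'
#' Both the binary dialect (80-byte header, little-endian 32-bit floats)
#' and the ASCII dialect are supported. A binary round trip preserves the
#' triangle count exactly and vertex coordinates at 32-bit float
#' precision; normals are recomputed from vertex winding on write.
#'
#' @param surf a [tri_surface()].
#' @param path file path.
#' @param mode `"binary"` or `"ascii"`.
#' @return `write_stl()` returns `path` invisibly; `read_stl()` returns a
#'   [tri_surface()] (as a triangle soup: three vertices per triangle).
#' @export
write_stl <- function(surf, path, mode = c("binary", "ascii")) {
  stopifnot(inherits(surf, "tri_surface"))
  mode <- match.arg(mode)
  nt <- nrow(surf$triangles)
  normals <- triangle_normals(surf$vertices, surf$triangles)
  v1 <- surf$vertices[surf$triangles[, 1], , drop = FALSE]
  v2 <- surf$vertices[surf$triangles[, 2], , drop = FALSE]
  v3 <- surf$vertices[surf$triangles[, 3], , drop = FALSE]
  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- utf8ToInt("ffrsens binary STL")
    writeBin(as.raw(c(header, rep(0L, 80L - length(header)))), con)
    writeBin(as.integer(nt), con, size = 4L, endian = "little")
    # 12 floats per facet: normal, v1, v2, v3; then a 2-byte attribute
    dat <- cbind(normals, v1, v2, v3)
    for (i in seq_len(nt)) {
      writeBin(as.numeric(dat[i, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    lines <- character(0)
    fmt <- function(p) sprintf("%.9e %.9e %.9e", p[1], p[2], p[3])
    lines <- c("solid ffrsens")
    for (i in seq_len(nt)) {
      lines <- c(lines,
                 paste0("  facet normal ", fmt(normals[i, ])),
                 "    outer loop",
                 paste0("      vertex ", fmt(v1[i, ])),
                 paste0("      vertex ", fmt(v2[i, ])),
                 paste0("      vertex ", fmt(v3[i, ])),
                 "    endloop",
                 "  endfacet")
    }
    lines <- c(lines, "endsolid ffrsens")
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = 80L)
  close(con)
  if (length(head_raw) < 80L ||
      grepl("^solid", rawToChar(head_raw[1:5]))) {
    return(read_stl_ascii(path))
  }
  read_stl_binary(path)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + nt * 50
  if (sz < expected) {
    stopf(paste0("truncated binary STL `%s`: header promises %d triangles",
                 " (%d bytes) but file has %d bytes"),
          path, nt, expected, sz)
  }
  verts <- matrix(NA_real_, nrow = 3L * nt, ncol = 3L)
  for (i in seq_len(nt)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    verts[3L * i - 2L, ] <- vals[4:6]
    verts[3L * i - 1L, ] <- vals[7:9]
    verts[3L * i, ] <- vals[10:12]
  }
  tri_surface(verts, matrix(seq_len(3L * nt), ncol = 3L, byrow = TRUE),
              provenance = list(source = path, dialect = "binary"))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    stopf("malformed ASCII STL `%s`: %d vertex lines (line %s)",
          path, length(vl), if (length(vl)) vl[length(vl)] else "NA")
  }
  parts <- strsplit(trimws(lines[vl]), "\\s+")
  verts <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(verts))) {
    stopf("malformed ASCII STL `%s`: non-numeric vertex coordinates", path)
  }
  nt <- nrow(verts) / 3L
  tri_surface(verts, matrix(seq_len(3L * nt), ncol = 3L, byrow = TRUE),
              provenance = list(source = path, dialect = "ascii"))
}
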