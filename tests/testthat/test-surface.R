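test_that("tessellation has the constructed count and near-cylinder area off the carve", {
  # almost-unstenosed lumen: the patch is essentially a cylinder of the
  # span length, whose faceted area has the O(n_circ^-2) chord deficit
  g <- stenosis_geometry(D = 5e-3, Ds = 9.7e-3, severity = 1e-6)
  s <- tessellate(g, 12, 96)
  expect_identical(nrow(s$triangles), 2L * 12L * 96L)
  span <- diff(ffrsens:::stenotic_patch_span(g, 1))
  expect_equal(surface_area(s), pi * g$D * span, tolerance = 5e-4)
  # count formula holds for arbitrary valid resolutions
  s2 <- tessellate(nominal_geometry(), 7, 13)
  expect_identical(nrow(s2$triangles), 2L * 7L * 13L)
  expect_error(tessellate(nominal_geometry(), 1, 10), "n_axial")
  expect_error(tessellate(nominal_geometry(), 10, 2), "n_circ")
})

test_that("triangulated area equals an independent cross-product summation", {
  # single right triangle with unit legs
  tri <- tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3)))
  expect_equal(surface_area(tri), 0.5)
  # unit cube as 12 triangles
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  expect_equal(surface_area(tri_surface(v, f)), 6)
  # random surface versus a direct per-triangle cross-product loop
  set.seed(77)
  surf <- tessellate(nominal_geometry(), 9, 11)
  direct <- sum(vapply(seq_len(nrow(surf$triangles)), function(i) {
    p <- surf$vertices[surf$triangles[i, ], ]
    0.5 * sqrt(sum(pracma::cross(p[2, ] - p[1, ], p[3, ] - p[1, ])^2))
  }, numeric(1)))
  expect_equal(surface_area(surf), direct, tolerance = 1e-12)
})

test_that("refinement drives the faceted area towards the smooth-patch quadrature", {
  g <- nominal_geometry()
  smooth <- smooth_patch_area_oracle(g)
  errs <- vapply(c(10L, 20L, 40L), function(n) {
    abs(surface_area(tessellate(g, n, n)) - smooth)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / smooth, 5e-3)
})

test_that("SRI follows its definition, scaling and invariances", {
  g <- nominal_geometry()
  surf <- tessellate(g, 15, 20)
  N <- nrow(surf$triangles)
  expect_equal(sri(surf, g$D), N / (surface_area(surf) / g$D^2))
  expect_identical(sri(NULL, g$D), Inf)  # smooth-model sentinel
  # subdividing every triangle into 4 leaves the surface identical and
  # multiplies SRI by exactly 4
  sub4 <- function(s) {
    v <- s$vertices; f <- s$triangles
    nv <- nrow(v)
    mids <- rbind((v[f[, 1], ] + v[f[, 2], ]) / 2,
                  (v[f[, 2], ] + v[f[, 3], ]) / 2,
                  (v[f[, 3], ] + v[f[, 1], ]) / 2)
    m <- nrow(f)
    i12 <- nv + seq_len(m); i23 <- nv + m + seq_len(m)
    i31 <- nv + 2L * m + seq_len(m)
    tri_surface(rbind(v, mids),
                rbind(cbind(f[, 1], i12, i31), cbind(i12, f[, 2], i23),
                      cbind(i31, i23, f[, 3]), cbind(i12, i23, i31)))
  }
  expect_equal(sri(sub4(surf), g$D), 4 * sri(surf, g$D), tolerance = 1e-12)
  # rigid motion: rotate + translate
  th <- 0.7
  Rm <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- tri_surface(sweep(surf$vertices %*% t(Rm), 2, c(1, -2, 3), "+"),
                       surf$triangles)
  expect_equal(sri(moved, g$D), sri(surf, g$D), tolerance = 1e-12)
  # simultaneous uniform rescaling of surface and D
  scaled <- tri_surface(surf$vertices * 2.5, surf$triangles)
  expect_equal(sri(scaled, g$D * 2.5), sri(surf, g$D), tolerance = 1e-12)
  # SRI grows proportionally to N along a refinement ladder (area converges)
  s1 <- tessellate(g, 20, 20); s2 <- tessellate(g, 40, 40)
  ratio <- sri(s2, g$D) / sri(s1, g$D)
  expect_equal(ratio, 4, tolerance = 0.01)
})

test_that("STL round trips preserve topology and coordinates", {
  surf <- tessellate(nominal_geometry(), 6, 8)
  # binary: exact at 32-bit float precision
  fb <- tempfile(fileext = ".stl")
  write_stl(surf, fb, "binary")
  rb <- read_stl(fb)
  expect_identical(nrow(rb$triangles), nrow(surf$triangles))
  soup <- surf$vertices[t(surf$triangles), ]
  expect_equal(rb$vertices, soup, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(sri(rb, 5.15e-3), sri(surf, 5.15e-3), tolerance = 1e-6)
  # ascii dialect
  fa <- tempfile(fileext = ".stl")
  write_stl(surf, fa, "ascii")
  ra <- read_stl(fa)
  expect_identical(nrow(ra$triangles), nrow(surf$triangles))
  expect_equal(ra$vertices, soup, tolerance = 1e-8, ignore_attr = TRUE)
  # a 2-triangle surface survives exactly in binary (float32 values)
  two <- tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0.5)),
                     rbind(c(1, 2, 3), c(2, 4, 3)))
  ft <- tempfile(fileext = ".stl")
  write_stl(two, ft, "binary")
  rt <- read_stl(ft)
  expect_equal(rt$vertices, two$vertices[t(two$triangles), ],
               ignore_attr = TRUE)
  # truncated binary file: parse error naming expected vs found size
  bytes <- readBin(fb, "raw", file.info(fb)$size)
  trunc <- tempfile(fileext = ".stl")
  writeBin(bytes[1:200], trunc)
  expect_error(read_stl(trunc), "truncated.*promises", ignore.case = TRUE)
})
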