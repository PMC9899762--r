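test_that("areas and volume fractions follow the area identity", {
  p <- two_circle_profile(r_out = 2, r_in = 1)
  af <- areas_and_fractions(p)
  expect_equal(af$lumen_volume_fraction, 0.25, tolerance = 1e-4)
  expect_equal(af$endothelium_volume_fraction, 0.75, tolerance = 1e-4)
  expect_identical(af$lumen_volume_fraction + af$endothelium_volume_fraction, 1)
  expect_equal(af$endothelium_area, af$capillary_area - af$lumen_area)
})

test_that("size ratios equal area over circumference", {
  p <- two_circle_profile(r_out = 4, r_in = 2)
  sr <- size_ratios(p)
  expect_equal(sr$capillary_size, 2, tolerance = 1e-4)
  expect_equal(sr$lumen_size, 1, tolerance = 1e-4)
  sq <- capillary_profile("g", "a", "p",
                          abluminal = square_contour(2, c(0, 0)),
                          lumen = square_contour(1, c(0.5, 0.5)))
  expect_equal(size_ratios(sq)$capillary_size, 0.5)
})

test_that("grid-overlay BL thickness recovers concentric and eccentric annuli", {
  p <- two_circle_profile(r_out = 3.5, r_in = 3.2, center = c(4, 4),
                          bl_inner = circle_contour(3.0, c(4, 4)),
                          bl_outer = circle_contour(3.1, c(4, 4)))
  expect_equal(bl_thickness_goia(p), 0.1, tolerance = 0.005)

  # coincident contours: zero thickness by continuity
  ring <- circle_contour(3.0, c(4, 4))
  p0 <- two_circle_profile(r_out = 3.5, r_in = 3.2, center = c(4, 4),
                           bl_inner = ring, bl_outer = ring)
  expect_identical(bl_thickness_goia(p0), 0)

  # eccentric annulus vs a dense normal-distance oracle
  off <- 0.05
  pe <- two_circle_profile(r_out = 3.5, r_in = 3.2, center = c(4, 4),
                           bl_inner = circle_contour(3.0, c(4, 4), n = 1440),
                           bl_outer = circle_contour(3.1, c(4 + off, 4), n = 1440))
  goia <- bl_thickness_goia(pe)
  # oracle: cast radial normals from 1e4 points of the inner circle and
  # intersect with the outer circle analytically
  th <- seq(0, 2 * pi, length.out = 10001)[-10001]
  u <- cbind(cos(th), sin(th))
  pt <- sweep(3.0 * u, 2, c(4, 4), `+`)
  cc <- c(4 + off, 4)
  dists <- vapply(seq_along(th), function(i) {
    d <- pt[i, ] - cc
    bq <- sum(d * u[i, ]); cq <- sum(d^2) - 3.1^2
    -bq + sqrt(bq^2 - cq)
  }, numeric(1))
  expect_equal(goia, mean(dists), tolerance = 0.05)
  expect_gt(max(dists), 0.14)   # individual crossings spread around the mean
  expect_lt(min(dists), 0.06)

  # too few admissible crossings
  tiny <- two_circle_profile(r_out = 0.2, r_in = 0.1, center = c(0.25, 0.25),
                             n = 90,
                             bl_inner = circle_contour(0.15, c(0.25, 0.25), n = 90),
                             bl_outer = circle_contour(0.18, c(0.25, 0.25), n = 90))
  expect_error(bl_thickness_goia(tiny, grid_pitch = 5), "admissible grid crossings")
})

test_that("crossings next to pericyte adhesion arcs are excluded", {
  ctr <- c(4, 4)
  inner <- circle_contour(3.0, ctr, n = 1440)
  # outer contour locally thickened except where a pericyte sits
  outer <- circle_contour(3.1, ctr, n = 1440)
  arc <- capmorph:::boundary_arc(unclass(outer), 0, 6)
  p <- two_circle_profile(r_out = 3.5, r_in = 3.2, center = ctr,
                          bl_inner = inner, bl_outer = outer,
                          pericyte_adhesion = list(arc))
  with_excl <- bl_thickness_goia(p, exclusion_radius = 0.25)
  no_excl <- bl_thickness_goia(p, exclusion_radius = 0)
  expect_equal(with_excl, 0.1, tolerance = 0.005)
  expect_equal(no_excl, 0.1, tolerance = 0.005)
})

test_that("tight junction tortuosity is arc length over bounding diagonal", {
  straight <- polyline(rbind(c(0, 0), c(3, 4)))
  expect_identical(tj_tortuosity(straight), 1)
  # semicircular arc of radius 1: length pi, box 2 x 1
  th <- seq(0, pi, length.out = 2001)
  semi <- polyline(cbind(cos(th), sin(th)))
  expect_equal(tj_tortuosity(semi), pi / sqrt(5), tolerance = 1e-4)
  # zig-zag with arc length 6.25 inside a 3 x 4 box
  z <- capmorph:::zigzag_polyline(1.25, w = 3, h = 4)
  expect_equal(capmorph::path_length(z), 6.25, tolerance = 1e-9)
  expect_equal(tj_tortuosity(z), 1.25, tolerance = 1e-9)
  expect_error(polyline(rbind(c(0, 0), c(0, 0))), "zero arc length")
  # the bounding rectangle is axis-aligned: rotation changes the value
  zz <- capmorph:::zigzag_polyline(2, w = 3, h = 4)
  phi <- pi / 4
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  expect_gt(abs(tj_tortuosity(polyline(unclass(zz) %*% rot)) -
                  tj_tortuosity(zz)), 0.01)
})

test_that("vesicle density pools counts over pooled field areas", {
  f1 <- tibble::tibble(area = c(1, 1, 1), count = c(2, 3, 3))
  expect_equal(vesicle_density(f1), 8 / 3)
  f2 <- tibble::tibble(area = c(0.5, 0.5, 1), count = c(2, 2, 4))
  expect_equal(vesicle_density(f2), 4)
  expect_error(vesicle_density(f1[1:2, ]), "3-5 fields")
  expect_error(vesicle_density(dplyr::bind_rows(f1, f1)), "3-5 fields")
  expect_error(vesicle_density(tibble::tibble(area = c(1, 0, 1), count = 0:2)),
               "positive")
})

test_that("pericyte and astrocyte metrics sum processes and arcs", {
  ctr <- c(5, 5)
  bl_out <- circle_contour(2.1, ctr)
  base <- list(r_out = 2, r_in = 1, center = ctr,
               bl_inner = circle_contour(2.05, ctr), bl_outer = bl_out)
  p0 <- do.call(two_circle_profile, base)
  expect_equal(unlist(pericyte_metrics(p0)), c(pericyte_area = 0,
               pericyte_volume_fraction = 0, pericyte_adhesion = 0,
               pericyte_coverage = 0))
  expect_equal(unlist(astrocyte_metrics(p0)),
               c(astrocyte_adhesion = 0, astrocyte_coverage = 0))

  r_unit <- sqrt(1 / pi)  # 1 um^2 discs
  p2 <- do.call(two_circle_profile, c(base, list(
    pericytes = list(circle_contour(r_unit, c(9, 5), n = 2000),
                     circle_contour(r_unit, c(1, 5), n = 2000)))))
  pm <- pericyte_metrics(p2)
  expect_equal(pm$pericyte_area, 2, tolerance = 1e-4)
  expect_equal(pm$pericyte_volume_fraction, 2 / polygon_area(p2$abluminal),
               tolerance = 1e-4)

  circ <- polygon_perimeter(bl_out)
  full <- capmorph:::boundary_arc(unclass(bl_out), 0, circ)
  p3 <- do.call(two_circle_profile, c(base, list(astrocyte_adhesion = list(full))))
  am <- astrocyte_metrics(p3)
  expect_equal(am$astrocyte_adhesion, circ, tolerance = 1e-9)
  expect_equal(am$astrocyte_coverage, 1, tolerance = 1e-9)
})

test_that("hole area measures painted truth inside the perivascular band", {
  px <- 0.05
  n <- 200                      # 10 x 10 um image
  ctr <- c(5, 5)
  img <- matrix(0.3, n, n)
  p_no <- two_circle_profile(r_out = 2, r_in = 1, center = ctr,
                             intensity_image = img, pixel_size = px)
  expect_identical(hole_area(p_no), 0)

  # paint a 2 x 1 um bright rectangle fully inside the band (band spans
  # radii 2..4 around the abluminal circle)
  xs <- (seq_len(n) - 0.5) * px
  cols <- which(xs >= 7.6 & xs < 9.6)   # x extent 2 um, right of the vessel
  rows <- which(xs >= 4.5 & xs < 5.5)   # y extent 1 um
  img2 <- img
  img2[rows, cols] <- 0.9
  p_yes <- two_circle_profile(r_out = 2, r_in = 1, center = ctr,
                              intensity_image = img2, pixel_size = px)
  expect_equal(hole_area(p_yes), 2, tolerance = 0.02 * 2)

  # same rectangle entirely outside a narrow band
  expect_identical(hole_area(p_yes, band_width = 0.5), 0)
  expect_error(hole_area(two_circle_profile()), "no intensity image")
})

test_that("profile inclusion follows the sampling criteria", {
  mk <- function(ncell, cross, blood, nucleus) {
    two_circle_profile(n_endothelial_cells = ncell, is_cross_section = cross,
                       contains_blood_or_plasma = blood,
                       has_visible_nucleus = nucleus)
  }
  expect_true(profile_passes_inclusion(mk(2, TRUE, FALSE, FALSE)))
  expect_false(profile_passes_inclusion(mk(3, TRUE, FALSE, FALSE)))
  expect_false(profile_passes_inclusion(mk(1, TRUE, FALSE, TRUE)))
  expect_false(profile_passes_inclusion(mk(1, FALSE, FALSE, FALSE)))
  expect_false(profile_passes_inclusion(mk(1, TRUE, TRUE, FALSE)))
  expect_error(profile_passes_inclusion(two_circle_profile()), "flags")
})

test_that("measure_profile yields missing values for absent annotations", {
  p <- two_circle_profile(r_out = 2, r_in = 1)
  rec <- measure_profile(p)
  expect_true(is.na(rec$hole_area))
  expect_true(is.na(rec$bl_thickness))
  expect_true(is.na(rec$tj_tortuosity))
  expect_true(is.na(rec$vesicle_density))
  expect_false(anyNA(rec[c("capillary_area", "lumen_area",
                           "circularity_capillary", "roundness_lumen",
                           "lumen_size", "capillary_size")]))
  expect_identical(rec$lumen_volume_fraction + rec$endothelium_volume_fraction, 1)
})
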