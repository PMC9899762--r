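#' Morphometry of annotated capillary profiles
#'
#' Every parameter is computed from the manual annotations in micrometre
#' coordinates; only the electron-lucent "hole" area touches pixel
#' intensities. Per-profile records are returned as tibbles so a dataset of
#' profiles maps straight into the animal-level aggregation and group
#' comparison steps.
#'
#' @name morphometry
NULL

#' Areas and volume fractions of a capillary profile
#'
#' The endothelium area is the capillary (abluminal) area minus the lumen
#' area, so the endothelium and lumen volume fractions sum to exactly 1 on
#' every profile by construction.
#'
#' @param p a [capillary_profile()].
#' @return tibble with `capillary_area`, `lumen_area`, `endothelium_area`
#'   (square micrometres), `lumen_volume_fraction` and
#'   `endothelium_volume_fraction`.
#' @export
areas_and_fractions <- function(p) {
  ca <- polygon_area(p$abluminal)
  la <- polygon_area(p$lumen)
  if (la >= ca) stop("lumen area must be smaller than capillary area", call. = FALSE)
  lvf <- la / ca
  tibble::tibble(capillary_area = ca, lumen_area = la,
                 endothelium_area = ca - la,
                 lumen_volume_fraction = lvf,
                 endothelium_volume_fraction = 1 - lvf)
}

#' Lumen and capillary size ratios
#'
#' Area divided by circumference for each contour; for a circle of radius r
#' this equals r/2, so the ratio tracks calibre while damping outline
#' irregularity.
#'
#' @inheritParams areas_and_fractions
#' @return tibble with `lumen_size` and `capillary_size` in micrometres.
#' @export
size_ratios <- function(p) {
  tibble::tibble(
    lumen_size = polygon_area(p$lumen) / polygon_perimeter(p$lumen),
    capillary_size = polygon_area(p$abluminal) / polygon_perimeter(p$abluminal))
}

#' Basal lamina thickness by grid overlay (GOIA)
#'
#' A square grid of pitch `grid_pitch` is laid over the profile; wherever a
#' gridline crosses the inner basal lamina contour, the local thickness is
#' the distance from that crossing to the outer contour along the outward
#' normal of the inner contour. Crossings closer than `exclusion_radius` to
#' any pericyte adhesion arc are excluded, because the lamina splits and
#' thins where it envelops a pericyte. The estimate is the mean over at
#' least `min_crossings` admissible crossings.
#'
#' @inheritParams areas_and_fractions
#' @param grid_pitch grid spacing in micrometres (default 0.5).
#' @param exclusion_radius distance to a pericyte adhesion arc below which a
#'   crossing is discarded, micrometres (default 0.25).
#' @param min_crossings minimum admissible crossings (default 3).
#' @return mean thickness in micrometres; 0 when the two contours coincide
#'   exactly.
#' @export
bl_thickness_goia <- function(p, grid_pitch = 0.5, exclusion_radius = 0.25,
                              min_crossings = 3L) {
  if (is.null(p$bl_inner) || is.null(p$bl_outer)) {
    stop("basal lamina contours are not annotated", call. = FALSE)
  }
  inner <- unclass(p$bl_inner); outer <- unclass(p$bl_outer)
  if (nrow(inner) == nrow(outer) && max(abs(inner - outer)) < 1e-12) {
    return(0)  # coincident contours: zero thickness, by continuity
  }
  cross <- goia_crossings(inner, grid_pitch)
  if (length(p$pericyte_adhesion) > 0 && nrow(cross$pts) > 0) {
    keep <- rep(TRUE, nrow(cross$pts))
    for (arc in p$pericyte_adhesion) {
      d <- points_to_path_distance(cross$pts[, 1], cross$pts[, 2], unclass(arc))
      keep <- keep & (d > exclusion_radius)
    }
    cross$pts <- cross$pts[keep, , drop = FALSE]
    cross$normals <- cross$normals[keep, , drop = FALSE]
  }
  th <- numeric(0)
  for (i in seq_len(nrow(cross$pts))) {
    pt <- cross$pts[i, ]; nrm <- cross$normals[i, ]
    # orient the normal away from the inner region
    probe <- pt + 1e-6 * nrm
    if (points_in_polygon(probe[1], probe[2], p$bl_inner)) nrm <- -nrm
    t <- ray_polygon_first_hit(pt, nrm, outer)
    if (!is.na(t)) th <- c(th, t)
  }
  if (length(th) < min_crossings) {
    stop(sprintf("profile %s/%s/%s: only %d admissible grid crossings (need >= %d); use a finer grid",
                 p$group, p$animal, p$profile, length(th), min_crossings),
         call. = FALSE)
  }
  mean(th)
}

# Gridline intersections with a closed contour: points plus unit edge normals.
goia_crossings <- function(xy, pitch) {
  ring <- rbind(xy, xy[1, ])
  pts <- NULL; normals <- NULL
  rng_x <- range(xy[, 1]); rng_y <- range(xy[, 2])
  grid_lines <- function(rng) {
    from <- ceiling(rng[1] / pitch) * pitch
    if (from > rng[2]) numeric(0) else seq(from, rng[2], by = pitch)
  }
  vlines <- grid_lines(rng_x)
  hlines <- grid_lines(rng_y)
  for (i in seq_len(nrow(ring) - 1)) {
    a <- ring[i, ]; b <- ring[i + 1, ]
    e <- b - a
    len <- sqrt(sum(e^2)); if (len == 0) next
    nrm <- c(e[2], -e[1]) / len
    for (cx in vlines) {
      if ((a[1] - cx) * (b[1] - cx) < 0) {
        f <- (cx - a[1]) / e[1]
        pts <- rbind(pts, a + f * e); normals <- rbind(normals, nrm)
      }
    }
    for (cy in hlines) {
      if ((a[2] - cy) * (b[2] - cy) < 0) {
        f <- (cy - a[2]) / e[2]
        pts <- rbind(pts, a + f * e); normals <- rbind(normals, nrm)
      }
    }
  }
  if (is.null(pts)) pts <- matrix(numeric(0), 0, 2)
  if (is.null(normals)) normals <- matrix(numeric(0), 0, 2)
  list(pts = pts, normals = normals)
}

#' Tight-junction tortuosity
#'
#' Junction path length divided by the diagonal of the axis-aligned
#' rectangle that contains the complete trace (from the luminal side to the
#' basal lamina). A straight junction gives 1; interdigitated junctions give
#' larger values. The bounding rectangle is axis-aligned, so the value is
#' not rotation-invariant -- traces are measured in the image frame.
#'
#' @param tj an open [polyline()].
#' @return tortuosity ratio (dimensionless).
#' @export
tj_tortuosity <- function(tj) {
  xy <- unclass(tj)
  w <- diff(range(xy[, 1])); h <- diff(range(xy[, 2]))
  diag <- sqrt(w^2 + h^2)
  if (diag <= 0) stop("tight junction trace has a zero-extent bounding box", call. = FALSE)
  path_length(xy) / diag
}

#' Pinocytic vesicle density
#'
#' Vesicles are counted in several fields of endothelial cytoplasm; the
#' field areas are pooled into one reference area and the density is total
#' count over total area.
#'
#' @param fields data frame with columns `area` (square micrometres) and
#'   `count`.
#' @param min_fields,max_fields admissible number of counting fields
#'   (defaults 3 and 5).
#' @return density in vesicles per square micrometre.
#' @export
vesicle_density <- function(fields, min_fields = 3L, max_fields = 5L) {
  stopifnot(is.data.frame(fields), all(c("area", "count") %in% names(fields)))
  n <- nrow(fields)
  if (n < min_fields || n > max_fields) {
    stop(sprintf("vesicle counting needs %d-%d fields, got %d",
                 min_fields, max_fields, n), call. = FALSE)
  }
  if (any(fields$area <= 0)) stop("field areas must be positive", call. = FALSE)
  if (any(fields$count < 0)) stop("counts must be non-negative", call. = FALSE)
  sum(fields$count) / sum(fields$area)
}

#' Pericyte process metrics
#'
#' Areas of all pericyte processes on the profile are summed; the pericyte
#' volume fraction is that sum over the capillary area. Adhesion is the
#' summed length of the traced contact arcs, and coverage divides it by the
#' basal lamina circumference (the outer contour's perimeter, where the
#' arcs are traced).
#'
#' @inheritParams areas_and_fractions
#' @return tibble with `pericyte_area`, `pericyte_volume_fraction`,
#'   `pericyte_adhesion`, `pericyte_coverage`.
#' @export
pericyte_metrics <- function(p) {
  area <- sum(vapply(p$pericytes, polygon_area, numeric(1)))
  adhesion <- sum(vapply(p$pericyte_adhesion, path_length, numeric(1)))
  circ <- if (!is.null(p$bl_outer)) polygon_perimeter(p$bl_outer) else NA_real_
  tibble::tibble(
    pericyte_area = area,
    pericyte_volume_fraction = area / polygon_area(p$abluminal),
    pericyte_adhesion = adhesion,
    pericyte_coverage = if (adhesion == 0) 0 else adhesion / circ)
}

#' Astrocyte endfoot adhesion metrics
#'
#' @inheritParams areas_and_fractions
#' @return tibble with `astrocyte_adhesion` (micrometres) and
#'   `astrocyte_coverage` (fraction of the basal lamina circumference).
#' @export
astrocyte_metrics <- function(p) {
  adhesion <- sum(vapply(p$astrocyte_adhesion, path_length, numeric(1)))
  circ <- if (!is.null(p$bl_outer)) polygon_perimeter(p$bl_outer) else NA_real_
  tibble::tibble(
    astrocyte_adhesion = adhesion,
    astrocyte_coverage = if (adhesion == 0) 0 else adhesion / circ)
}

#' Electron-lucent ("hole") area around a capillary
#'
#' Unequivocally bright perivascular regions mark degraded neuropil where
#' the astrocyte endfoot area can no longer be delineated. Pixels are
#' thresholded, connected components are labelled, and every component that
#' intersects the perivascular band (from the abluminal contour out to
#' `band_width`) contributes its full area.
#'
#' The default threshold is Otsu's method computed on the band pixels, with
#' a bimodality guard: if the mean separation between the two Otsu classes
#' is below `guard_k` times the below-class standard deviation, the band is
#' considered hole-free and 0 is returned. This keeps pure-noise backgrounds
#' from yielding spurious holes. Pass a fixed `threshold` to bypass both.
#'
#' @inheritParams areas_and_fractions
#' @param band_width width of the perivascular band in micrometres
#'   (default 2).
#' @param threshold fixed grey-level threshold in `[0, 1]`, or `NULL` for
#'   Otsu with the bimodality guard.
#' @param guard_k bimodality guard factor (default 4).
#' @return total hole area in square micrometres.
#' @export
hole_area <- function(p, band_width = 2, threshold = NULL, guard_k = 4) {
  img <- p$intensity_image
  if (is.null(img)) {
    stop("profile has no intensity image; hole area needs pixels", call. = FALSE)
  }
  px <- p$pixel_size
  nr <- nrow(img); nc <- ncol(img)
  cx <- (rep(seq_len(nc), each = nr) - 0.5) * px
  cy <- (rep(seq_len(nr), times = nc) - 0.5) * px
  inside <- points_in_polygon(cx, cy, p$abluminal)
  d <- points_to_path_distance(cx, cy, unclass(p$abluminal), closed = TRUE)
  band <- matrix(!inside & d <= band_width, nr, nc)
  vals <- img[band]
  if (length(vals) == 0) return(0)
  if (is.null(threshold)) {
    # Otsu seeds the split; intermeans iteration then centres the threshold
    # between the class means, off the flat ridge of the between-class
    # variance where upper-tail background noise would leak through
    thr <- otsu_threshold(vals)
    for (i in 1:20) {
      lo_m <- mean(vals[vals <= thr]); hi_m <- mean(vals[vals > thr])
      if (!is.finite(lo_m) || !is.finite(hi_m)) break
      new_thr <- (lo_m + hi_m) / 2
      if (abs(new_thr - thr) < 1e-6) break
      thr <- new_thr
    }
    lo <- vals[vals <= thr]; hi <- vals[vals > thr]
    if (length(hi) == 0 || length(lo) < 2) return(0)
    sep <- mean(hi) - mean(lo)
    if (!is.finite(sep) || sep <= guard_k * stats::sd(lo)) return(0)
  } else {
    thr <- threshold
  }
  bright <- img > thr
  if (!any(bright & band)) return(0)
  lab <- EBImage::bwlabel(EBImage::Image(bright * 1))
  lab <- EBImage::imageData(lab)
  hit <- setdiff(unique(lab[band & bright]), 0)
  if (length(hit) == 0) return(0)
  sum(lab %in% hit) * px^2
}

# Otsu's threshold on a numeric vector in [0, 1].
otsu_threshold <- function(v, levels = 256L) {
  h <- tabulate(pmin(levels, pmax(1L, as.integer(v * (levels - 1)) + 1L)), levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b) - 0.5) / (levels - 1)
}

#' Measure one capillary profile
#'
#' Runs every morphometric operation on a profile and returns the complete
#' record as a one-row tibble. Parameters whose annotations are absent
#' (basal lamina contours, TJ traces, vesicle fields, intensity image) come
#' back as `NA`, never as zeros.
#'
#' @inheritParams areas_and_fractions
#' @param grid_pitch,exclusion_radius passed to [bl_thickness_goia()].
#' @param band_width,threshold passed to [hole_area()].
#' @param check_inclusion error if the profile fails
#'   [profile_passes_inclusion()]; set `FALSE` to measure anyway.
#' @return one-row tibble (a morphometry record).
#' @export
measure_profile <- function(p, grid_pitch = 0.5, exclusion_radius = 0.25,
                            band_width = 2, threshold = NULL,
                            check_inclusion = FALSE) {
  if (check_inclusion && !profile_passes_inclusion(p)) {
    stop(sprintf("profile %s/%s/%s fails the sampling inclusion criteria",
                 p$group, p$animal, p$profile), call. = FALSE)
  }
  af <- areas_and_fractions(p)
  sr <- size_ratios(p)
  pm <- pericyte_metrics(p)
  am <- astrocyte_metrics(p)
  bl <- if (!is.null(p$bl_inner) && !is.null(p$bl_outer)) {
    bl_thickness_goia(p, grid_pitch, exclusion_radius)
  } else NA_real_
  tort <- if (length(p$tj) > 0) {
    mean(vapply(p$tj, tj_tortuosity, numeric(1)))
  } else NA_real_
  vd <- if (!is.null(p$vesicle_fields) && nrow(p$vesicle_fields) > 0) {
    vesicle_density(p$vesicle_fields)
  } else NA_real_
  ha <- if (!is.null(p$intensity_image)) {
    hole_area(p, band_width = band_width, threshold = threshold)
  } else NA_real_
  tibble::tibble(
    group = p$group, animal = p$animal, profile = p$profile,
    capillary_area = af$capillary_area, lumen_area = af$lumen_area,
    endothelium_area = af$endothelium_area,
    circularity_capillary = circularity(p$abluminal),
    circularity_lumen = circularity(p$lumen),
    roundness_capillary = roundness(p$abluminal),
    roundness_lumen = roundness(p$lumen),
    lumen_volume_fraction = af$lumen_volume_fraction,
    endothelium_volume_fraction = af$endothelium_volume_fraction,
    lumen_size = sr$lumen_size, capillary_size = sr$capillary_size,
    bl_thickness = bl, tj_tortuosity = tort, vesicle_density = vd,
    pericyte_area = pm$pericyte_area,
    pericyte_volume_fraction = pm$pericyte_volume_fraction,
    pericyte_adhesion = pm$pericyte_adhesion,
    pericyte_coverage = pm$pericyte_coverage,
    astrocyte_adhesion = am$astrocyte_adhesion,
    astrocyte_coverage = am$astrocyte_coverage,
    hole_area = ha)
}

#' Measure a list of capillary profiles
#'
#' @param profiles list of [capillary_profile()] objects.
#' @param include_only drop profiles failing [profile_passes_inclusion()]
#'   before measuring (profiles with unset flags are kept).
#' @param ... passed to [measure_profile()].
#' @return tibble with one row per measured profile.
#' @export
measure_profiles <- function(profiles, include_only = FALSE, ...) {
  if (include_only) {
    keep <- vapply(profiles, function(p) {
      if (anyNA(c(p$flags$n_endothelial_cells, p$flags$is_cross_section,
                  p$flags$contains_blood_or_plasma, p$flags$has_visible_nucleus))) {
        TRUE
      } else profile_passes_inclusion(p)
    }, logical(1))
    profiles <- profiles[keep]
  }
  purrr::map_dfr(profiles, measure_profile, ...)
}
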