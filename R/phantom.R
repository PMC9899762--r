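#' Reference group parameters for phantom generation
#'
#' Group means and standard deviations of the nine generator-controlled
#' ultrastructural parameters, one column set per experimental group (SHAM,
#' SAH, SAH+Mino). These are the default sampling distributions of
#' [phantom_config()]; the SHAM hole-area mean is 0 (intact neuropil shows
#' no electron-lucent perivascular space).
#'
#' @return tibble with columns `parameter`, `group`, `mean`, `sd`.
#' @export
reference_group_parameters <- function() {
  tab <- tibble::tribble(
    ~parameter,              ~SHAM_m, ~SHAM_s, ~SAH_m, ~SAH_s, ~Mino_m, ~Mino_s,
    "capillary_area",          34.45,    8.67,  20.58,   5.25,   29.86,  5.036,
    "lumen_volume_fraction",    0.60,    0.07,   0.30,   0.10,    0.65,   0.06,
    "bl_thickness",             0.10,   0.002,   0.10,   0.02,    0.10,   0.07,
    "tj_tortuosity",            1.25,    0.16,   1.25,   0.08,    1.05,   0.04,
    "pericyte_area",            5.56,    0.98,   1.80,   0.40,    5.17,   1.67,
    "pericyte_adhesion",        7.43,    1.07,   5.68,   0.20,    7.93,   1.80,
    "astrocyte_adhesion",      16.80,    2.04,   7.70,   3.49,   13.20,   2.58,
    "hole_area",                0.00,    0.00,  22.29,   4.18,    0.00,   0.00,
    "vesicle_density",          7.48,    0.25,   4.67,   0.77,    8.10,   0.84)
  long <- tidyr::pivot_longer(tab, -"parameter",
                              names_to = c("group", ".value"),
                              names_sep = "_")
  long$group <- c(SHAM = "SHAM", SAH = "SAH", Mino = "SAH+Mino")[long$group]
  names(long)[names(long) == "m"] <- "mean"
  names(long)[names(long) == "s"] <- "sd"
  long
}

#' Configuration for the capillary phantom generator
#'
#' Each ultrastructural parameter is sampled from a truncated normal
#' distribution (truncated at its physical bounds: areas, lengths and
#' densities at 0, fractions inside (0, 1)); the defaults are the matching
#' group column of [reference_group_parameters()].
#'
#' @param group group label, one of `"SHAM"`, `"SAH"`, `"SAH+Mino"`.
#' @param params named list of `c(mean, sd)` pairs overriding individual
#'   parameter distributions; names as in [reference_group_parameters()].
#' @param n_animals,profiles_per_animal dataset layout for
#'   [make_group_dataset()].
#' @param pixel_size micrometres per pixel of generated intensity images.
#' @param field_range admissible number of vesicle counting fields (length-2
#'   integer, default 3..5, the number actually used per profile is drawn
#'   uniformly from this range).
#' @param field_area nominal counting-field area in square micrometres.
#' @param hole_intensity,background_intensity grey levels in `[0, 1]` used
#'   when painting intensity images.
#' @param noise_sd grey-level noise standard deviation.
#' @param with_image generate an aligned intensity image (needed for hole
#'   detection; skip to speed up purely geometric studies).
#' @param n_vertices vertices per generated contour.
#' @param seed integer seed; all randomness in the generator derives from it.
#' @return object of class `"phantom_config"`.
#' @export
phantom_config <- function(group = c("SHAM", "SAH", "SAH+Mino"),
                           params = list(),
                           n_animals = 4L, profiles_per_animal = 10L,
                           pixel_size = 0.08,
                           field_range = c(3L, 5L), field_area = 1,
                           hole_intensity = 0.85, background_intensity = 0.30,
                           noise_sd = 0.02, with_image = TRUE,
                           n_vertices = 192L, seed = 1L) {
  group <- match.arg(group)
  ref <- reference_group_parameters()
  ref <- ref[ref$group == group, ]
  defaults <- stats::setNames(
    lapply(seq_len(nrow(ref)), function(i) c(ref$mean[i], ref$sd[i])),
    ref$parameter)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown phantom parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(params)] <- params
  for (nm in names(defaults)) {
    v <- defaults[[nm]]
    if (length(v) != 2 || v[2] < 0) {
      stop(sprintf("parameter %s needs c(mean, sd) with sd >= 0", nm), call. = FALSE)
    }
  }
  lvf <- defaults$lumen_volume_fraction[1]
  if (lvf <= 0 || lvf >= 1) stop("lumen_volume_fraction mean must be in (0, 1)", call. = FALSE)
  stopifnot(n_animals >= 1, profiles_per_animal >= 1, pixel_size > 0,
            length(field_range) == 2, field_range[1] >= 1,
            field_range[2] >= field_range[1], field_area > 0,
            hole_intensity > background_intensity,
            noise_sd >= 0, n_vertices >= 32)
  structure(list(group = group, params = defaults,
                 n_animals = as.integer(n_animals),
                 profiles_per_animal = as.integer(profiles_per_animal),
                 pixel_size = pixel_size,
                 field_range = as.integer(field_range),
                 field_area = field_area,
                 hole_intensity = hole_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, with_image = isTRUE(with_image),
                 n_vertices = as.integer(n_vertices),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Run code under a derived seed, restoring the caller's RNG state after.
with_subseed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic per-profile substream seed (kept below 2^31).
derive_seed <- function(seed, animal_index, profile_index) {
  (as.double(seed) * 2654435 + animal_index * 97561 + profile_index * 7919) %%
    2147483647
}

# Mean of a normal(mu, sd) truncated to [lower, upper].
truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Truncated-normal draw by rejection, moment-matched: the pre-truncation
# location is solved so the post-truncation mean equals `mean`, so group
# means of the drawn parameters are the specified means, not biased by the
# physical bounds.
rtruncn <- function(mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  if (mean <= lower || mean >= upper) {
    stop("parameter mean must lie strictly inside its physical bounds",
         call. = FALSE)
  }
  mu <- tryCatch(
    stats::uniroot(function(m) truncnorm_mean(m, sd, lower, upper) - mean,
                   lower = mean - 6 * sd, upper = mean + 6 * sd,
                   tol = 1e-10)$root,
    error = function(e) mean)
  for (i in 1:10000) {
    x <- stats::rnorm(1, mu, sd)
    if (x >= lower && x <= upper) return(x)
  }
  stop("truncated-normal rejection sampling failed; bounds exclude nearly all mass",
       call. = FALSE)
}

# Fourier-perturbed ellipse with exact area, centered at `center`.
fourier_contour <- function(area, center, n_vertices, aspect = NULL,
                            irregularity = 0.04, harmonics = 2:5) {
  if (is.null(aspect)) aspect <- stats::runif(1, 0.75, 1)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- rep(1, n_vertices)
  for (k in harmonics) {
    r <- r + stats::rnorm(1, 0, irregularity / sqrt(k)) * cos(k * th + stats::runif(1, 0, 2 * pi))
  }
  r <- pmax(r, 0.2)
  xy <- cbind(r * cos(th), aspect * r * sin(th))
  s <- sqrt(area / abs(signed_area(xy)))
  xy <- xy * s
  xy[, 1] <- xy[, 1] + center[1]
  xy[, 2] <- xy[, 2] + center[2]
  contour(xy, check_simple = FALSE)
}

# Outward vertex-normal offset of a closed contour by distance t, with the
# bisector correction so the perpendicular face distance equals t.
offset_contour <- function(c, t) {
  xy <- unclass(c)
  n <- nrow(xy)
  prev <- xy[c(n, seq_len(n - 1)), ]
  nxt <- xy[c(seq_len(n)[-1], 1), ]
  e1 <- xy - prev; e2 <- nxt - xy
  norm1 <- cbind(e1[, 2], -e1[, 1]) / sqrt(rowSums(e1^2))
  norm2 <- cbind(e2[, 2], -e2[, 1]) / sqrt(rowSums(e2^2))
  bis <- norm1 + norm2
  bl <- sqrt(rowSums(bis^2))
  bis <- bis / bl
  # cos of half-angle between adjacent edge normals
  cos_half <- pmax(bl / 2, 0.1)
  # ensure outward orientation (positive signed area convention flips sign)
  probe <- xy[1, ] + 1e-6 * bis[1, ]
  sgn <- if (points_in_polygon(probe[1], probe[2], c)) -1 else 1
  out <- xy + sgn * bis * (t / cos_half)
  contour(out, check_simple = FALSE)
}

# Zig-zag polyline inside an axis-aligned w x h box whose arc length is
# exactly tortuosity * box diagonal (solved by uniroot on the zig
# amplitude). The path runs corner to corner along the diagonal with
# sine-tapered perpendicular offsets of alternating sign, so the bounding
# box stays exactly w x h while tortuosity up to ~3 is representable.
zigzag_polyline <- function(tortuosity, w = 1, h = 1.33, origin = c(0, 0),
                            n_seg = 12L) {
  if (tortuosity < 1) stop("tortuosity must be >= 1", call. = FALSE)
  d <- sqrt(w^2 + h^2)
  u <- c(-h, w) / d                      # unit perpendicular to the diagonal
  f <- seq(0, 1, length.out = n_seg + 1)
  base <- cbind(f * w, f * h)
  taper <- sin(pi * f) * (-1)^(seq_len(n_seg + 1))
  pts_at <- function(A) base + A * taper %o% u
  len_at <- function(A) sum(sqrt(rowSums(diff(pts_at(A))^2)))
  # largest amplitude keeping every vertex inside the box
  interior <- which(abs(taper) > 1e-12)
  per_vertex <- pmin(pmin(base[interior, 1], w - base[interior, 1]) / abs(u[1]),
                     pmin(base[interior, 2], h - base[interior, 2]) / abs(u[2])) /
    abs(taper[interior])
  A_max <- 0.95 * min(per_vertex)
  target <- tortuosity * d
  if (len_at(A_max) < target) {
    stop(sprintf("tortuosity %.3f not representable by the zig-zag template",
                 tortuosity), call. = FALSE)
  }
  A <- if (tortuosity == 1) 0 else
    stats::uniroot(function(a) len_at(a) - target, c(0, A_max), tol = 1e-12)$root
  pts <- pts_at(A)
  polyline(cbind(pts[, 1] + origin[1], pts[, 2] + origin[2]))
}

# Split `total` into n parts, each at least frac_min of total.
random_partition <- function(total, n, frac_min = 0.2) {
  if (n == 1) return(total)
  w <- stats::runif(n, frac_min, 1)
  total * w / sum(w)
}

# Place n disjoint arcs of given lengths on a closed contour of perimeter C:
# random global offset, gaps share the slack randomly.
place_arcs <- function(c, lengths) {
  C <- polygon_perimeter(c)
  n <- length(lengths)
  slack <- C - sum(lengths)
  stopifnot(slack >= 0)
  gaps <- random_partition(slack, n, frac_min = 0.05)
  start <- stats::runif(1, 0, C)
  arcs <- vector("list", n)
  pos <- start
  for (i in seq_len(n)) {
    arcs[[i]] <- boundary_arc(unclass(c), pos, lengths[i])
    pos <- pos + lengths[i] + gaps[i]
  }
  arcs
}

# Elongated elliptical blob of exact area, centered at `center`, long axis
# along unit vector `u`.
blob_contour <- function(area, center, u, elongation = 2.5, n_vertices = 48L) {
  b <- sqrt(area / (pi * elongation))
  a <- elongation * b
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  ex <- a * cos(th); ey <- b * sin(th)
  v <- c(-u[2], u[1])
  xy <- cbind(center[1] + ex * u[1] + ey * v[1],
              center[2] + ex * u[2] + ey * v[2])
  s <- sqrt(area / abs(signed_area(xy)))
  ctr <- colMeans(xy)
  xy <- sweep(sweep(xy, 2, ctr), 2, c(s, s), `*`)
  xy <- sweep(xy, 2, ctr, `+`)
  contour(xy, check_simple = FALSE)
}

#' Generate one capillary phantom with known ground truth
#'
#' Draws the nine ultrastructural parameters from the configured truncated
#' normals and builds a geometrically consistent annotated profile:
#' Fourier-perturbed elliptical abluminal contour scaled to the drawn area;
#' a concentric lumen scaled to the drawn lumen volume fraction; basal
#' lamina contours separated by the drawn thickness; pericyte blobs whose
#' summed area and adhesion arcs match the drawn values; astrocyte adhesion
#' arcs of the drawn total length; a zig-zag tight junction with exactly
#' the drawn tortuosity; Poisson vesicle counts at the drawn density; and,
#' when an image is requested, bright perivascular "holes" painted pixel by
#' pixel to the drawn total area. Adhesion draws that cannot fit on the
#' basal lamina circumference are re-drawn a bounded number of times.
#'
#' @param config a [phantom_config()].
#' @param animal_id,profile_id identifiers recorded on the profile; the
#'   per-profile random substream is derived from `config$seed` and these
#'   ids' indices.
#' @param animal_index,profile_index integer indices used to derive the
#'   substream (default 1).
#' @return list with `profile` (a [capillary_profile()]) and `truth`
#'   (one-row tibble of drawn and realized ground-truth values).
#' @export
make_capillary_phantom <- function(config, animal_id = "a1", profile_id = "p1",
                                   animal_index = 1L, profile_index = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  base <- derive_seed(config$seed, animal_index, profile_index)
  # rare joint draws (small capillary + long adhesion) are geometrically
  # infeasible; redraw the whole profile from a perturbed substream
  for (redraw in 0:4) {
    res <- tryCatch(
      with_subseed((base + redraw * 131071) %% 2147483647,
                   build_phantom(config, animal_id, profile_id)),
      error = function(e) {
        if (redraw < 4 && grepl("infeasible geometry", conditionMessage(e))) NULL
        else stop(e)
      })
    if (!is.null(res)) return(res)
  }
}

build_phantom <- function(config, animal_id, profile_id) {
  pr <- config$params
  draw <- function(nm, lower = 0, upper = Inf) {
    rtruncn(pr[[nm]][1], pr[[nm]][2], lower, upper)
  }
  cap_area <- draw("capillary_area", lower = 2)
  lvf <- draw("lumen_volume_fraction", lower = 0.05, upper = 0.95)
  bl_t <- draw("bl_thickness", lower = 0.01)
  tort <- draw("tj_tortuosity", lower = 1, upper = 1.7)
  peri_area <- draw("pericyte_area")
  hole <- draw("hole_area")
  vdens <- draw("vesicle_density")

  center_pad <- sqrt(cap_area) * 0.9 + 2.8
  ablum <- fourier_contour(cap_area, c(center_pad, center_pad), config$n_vertices)
  lum_xy <- sweep(unclass(ablum), 2, c(center_pad, center_pad))
  lum_xy <- lum_xy * sqrt(lvf)
  lumen <- contour(sweep(lum_xy, 2, c(center_pad, center_pad), `+`),
                   check_simple = FALSE)
  bl_inner <- ablum
  bl_outer <- offset_contour(bl_inner, bl_t)
  circ <- polygon_perimeter(bl_outer)

  # adhesion lengths must fit on the BL circumference; redraw if not
  peri_adh <- NA_real_; astro_adh <- NA_real_
  for (attempt in 1:50) {
    peri_adh <- draw("pericyte_adhesion")
    if (peri_adh <= 0.9 * circ) break
    if (attempt == 50) stop("pericyte adhesion draw exceeds BL circumference; infeasible geometry",
                            call. = FALSE)
  }
  for (attempt in 1:50) {
    astro_adh <- draw("astrocyte_adhesion")
    if (astro_adh <= 0.95 * circ) break
    if (attempt == 50) stop("astrocyte adhesion draw exceeds BL circumference; infeasible geometry",
                            call. = FALSE)
  }

  pericytes <- list(); peri_arcs <- list()
  if (peri_adh > 0 && peri_area > 0) {
    n_peri <- if (peri_area > 3 && stats::runif(1) < 0.5) 2L else 1L
    adh_parts <- random_partition(peri_adh, n_peri)
    area_parts <- adh_parts / sum(adh_parts) * peri_area
    peri_arcs <- place_arcs(bl_outer, adh_parts)
    for (i in seq_len(n_peri)) {
      arc <- unclass(peri_arcs[[i]])
      mid <- arc[ceiling(nrow(arc) / 2), ]
      tang <- arc[nrow(arc), ] - arc[1, ]
      tang <- tang / sqrt(sum(tang^2))
      nrm <- c(tang[2], -tang[1])
      if (points_in_polygon(mid[1] + 1e-6 * nrm[1], mid[2] + 1e-6 * nrm[2], bl_outer)) {
        nrm <- -nrm
      }
      b_semi <- sqrt(area_parts[i] / (pi * 2.5)) # minor semi-axis of the blob
      ctr <- mid + nrm * (b_semi + 0.05)
      pericytes[[i]] <- blob_contour(area_parts[i], ctr, tang)
    }
  }

  astro_arcs <- list()
  if (astro_adh > 0) {
    n_astro <- sample(1:3, 1)
    astro_parts <- random_partition(astro_adh, n_astro)
    astro_arcs <- place_arcs(bl_outer, astro_parts)
  }

  tj <- zigzag_polyline(tort, w = 0.9, h = 1.2,
                        origin = c(center_pad + stats::runif(1, -1, 1),
                                   center_pad + stats::runif(1, -1, 1)))

  n_fields <- if (config$field_range[1] == config$field_range[2]) {
    config$field_range[1]
  } else sample(seq(config$field_range[1], config$field_range[2]), 1)
  f_areas <- config$field_area * stats::runif(n_fields, 0.8, 1.2)
  f_counts <- stats::rpois(n_fields, vdens * f_areas)
  fields <- tibble::tibble(area = f_areas, count = f_counts)
  vdens_real <- sum(f_counts) / sum(f_areas)

  img <- NULL; hole_real <- 0; px <- config$pixel_size
  if (config$with_image) {
    painted <- paint_image(ablum, hole, config)
    img <- painted$img
    hole_real <- painted$realized
  }

  profile <- capillary_profile(
    group = config$group, animal = animal_id, profile = profile_id,
    abluminal = ablum, lumen = lumen,
    bl_inner = bl_inner, bl_outer = bl_outer,
    pericytes = pericytes, pericyte_adhesion = peri_arcs,
    astrocyte_adhesion = astro_arcs, tj = list(tj),
    vesicle_fields = fields, intensity_image = img, pixel_size = px,
    n_endothelial_cells = sample(1:2, 1), is_cross_section = TRUE,
    contains_blood_or_plasma = FALSE, has_visible_nucleus = FALSE)

  truth <- tibble::tibble(
    group = config$group, animal = animal_id, profile = profile_id,
    capillary_area = cap_area, lumen_volume_fraction = lvf,
    lumen_area = lvf * cap_area, endothelium_area = (1 - lvf) * cap_area,
    bl_thickness = bl_t, tj_tortuosity = tort,
    pericyte_area = peri_area * (length(pericytes) > 0),
    pericyte_adhesion = if (length(peri_arcs) > 0) peri_adh else 0,
    astrocyte_adhesion = astro_adh,
    hole_area = hole, realized_hole_area = hole_real,
    vesicle_density = vdens, realized_vesicle_density = vdens_real,
    bl_circumference = circ)

  list(profile = profile, truth = truth)
}

# Paint the intensity image: background noise everywhere, bright "hole"
# pixels chosen inside the perivascular band so the painted pixel count
# matches the drawn area as closely as the grid allows.
paint_image <- function(ablum, hole_target, config) {
  px <- config$pixel_size
  xy <- unclass(ablum)
  extent <- max(xy[, 1] + 2.6, xy[, 2] + 2.6)
  npix <- ceiling(extent / px)
  img <- matrix(stats::rnorm(npix * npix, config$background_intensity,
                             config$noise_sd), npix, npix)
  realized <- 0
  if (hole_target > 0) {
    cxs <- (rep(seq_len(npix), each = npix) - 0.5) * px
    cys <- (rep(seq_len(npix), times = npix) - 0.5) * px
    inside <- points_in_polygon(cxs, cys, ablum)
    d <- points_to_path_distance(cxs, cys, xy, closed = TRUE)
    band_idx <- which(!inside & d <= 1.9)
    k <- round(hole_target / px^2)
    k <- min(k, length(band_idx))
    if (k > 0) {
      seed_i <- band_idx[sample.int(length(band_idx), 1)]
      dd <- (cxs[band_idx] - cxs[seed_i])^2 + (cys[band_idx] - cys[seed_i])^2
      chosen <- band_idx[order(dd)[seq_len(k)]]
      img[chosen] <- stats::rnorm(k, config$hole_intensity, config$noise_sd)
      realized <- k * px^2
    }
  }
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- c(npix, npix)
  list(img = img, realized = realized)
}

#' Generate a multi-group phantom dataset
#'
#' Builds `n_animals * profiles_per_animal` phantoms per group config, with
#' deterministic per-profile random substreams so the same seed always
#' yields an identical dataset.
#'
#' @param configs list of [phantom_config()] objects, one per group.
#' @param seed optional master seed overriding each config's own seed.
#' @return list with `profiles` (named list of [capillary_profile()]s) and
#'   `truth` (tibble, one row per profile).
#' @export
make_group_dataset <- function(configs, seed = NULL) {
  if (inherits(configs, "phantom_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1)
  profiles <- list(); truths <- list()
  for (cf in configs) {
    stopifnot(inherits(cf, "phantom_config"))
    if (!is.null(seed)) cf$seed <- as.integer(seed)
    for (a in seq_len(cf$n_animals)) {
      for (p in seq_len(cf$profiles_per_animal)) {
        aid <- sprintf("%s_a%02d", cf$group, a)
        pid <- sprintf("p%03d", p)
        ph <- make_capillary_phantom(cf, aid, pid,
                                     animal_index = a, profile_index = p)
        key <- paste(cf$group, aid, pid, sep = "/")
        profiles[[key]] <- ph$profile
        truths[[key]] <- ph$truth
      }
    }
  }
  list(profiles = profiles, truth = dplyr::bind_rows(truths))
}
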