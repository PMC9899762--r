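#' An annotated capillary cross-section
#'
#' Bundles every manual annotation drawn on one electron micrograph of a
#' capillary profile: the abluminal (outer endothelial) and luminal contours,
#' the inner and outer basal lamina contours, pericyte process contours and
#' their adhesion arcs, astrocyte adhesion arcs, tight-junction polylines,
#' vesicle count fields, and an optional aligned grayscale intensity image
#' for electron-lucent "hole" detection. All coordinates are micrometres
#' with y increasing downward.
#'
#' @param group,animal,profile identifiers (experimental group label, animal
#'   id, profile id within animal).
#' @param pixel_size micrometres per pixel of `intensity_image`.
#' @param abluminal,lumen closed [contour()]s of the outer endothelial
#'   membrane (capillary) and the lumen.
#' @param bl_inner,bl_outer closed [contour()]s of the basal lamina faces;
#'   may be `NULL` when the BL was not annotated.
#' @param pericytes list of closed [contour()]s of pericyte processes.
#' @param pericyte_adhesion,astrocyte_adhesion lists of open [polyline()]s
#'   traced where the process contacts the basal lamina.
#' @param tj list of open [polyline()]s tracing tight junctions from the
#'   luminal side to the basal lamina.
#' @param vesicle_fields data frame with columns `area` (square micrometres)
#'   and `count` for each endothelial cytoplasm counting field.
#' @param intensity_image optional numeric matrix in `[0, 1]` (rows = y),
#'   aligned to the annotations through `pixel_size`.
#' @param n_endothelial_cells,is_cross_section,contains_blood_or_plasma,has_visible_nucleus
#'   sampling flags used by [profile_passes_inclusion()].
#' @return object of class `"capillary_profile"`.
#' @export
capillary_profile <- function(group, animal, profile,
                              abluminal, lumen,
                              bl_inner = NULL, bl_outer = NULL,
                              pericytes = list(),
                              pericyte_adhesion = list(),
                              astrocyte_adhesion = list(),
                              tj = list(),
                              vesicle_fields = NULL,
                              intensity_image = NULL,
                              pixel_size = NA_real_,
                              n_endothelial_cells = NA_integer_,
                              is_cross_section = NA,
                              contains_blood_or_plasma = NA,
                              has_visible_nucleus = NA) {
  p <- structure(
    list(group = as.character(group), animal = as.character(animal),
         profile = as.character(profile),
         abluminal = abluminal, lumen = lumen,
         bl_inner = bl_inner, bl_outer = bl_outer,
         pericytes = pericytes,
         pericyte_adhesion = pericyte_adhesion,
         astrocyte_adhesion = astrocyte_adhesion,
         tj = tj,
         vesicle_fields = vesicle_fields,
         intensity_image = intensity_image,
         pixel_size = pixel_size,
         flags = list(n_endothelial_cells = as.integer(n_endothelial_cells),
                      is_cross_section = is_cross_section,
                      contains_blood_or_plasma = contains_blood_or_plasma,
                      has_visible_nucleus = has_visible_nucleus)),
    class = "capillary_profile")
  validate_profile(p)
  p
}

#' Validate a capillary profile's geometric invariants
#'
#' Checks that the lumen lies strictly inside the abluminal contour and has
#' the smaller area, that the basal lamina contours nest correctly, that
#' adhesion arcs do not exceed the basal lamina circumference, and that
#' vesicle fields have positive areas and non-negative counts.
#'
#' @param p a [capillary_profile()].
#' @return `p`, invisibly; errors name the violated invariant.
#' @export
validate_profile <- function(p) {
  stopifnot(inherits(p, "capillary_profile"))
  stopifnot(inherits(p$abluminal, "contour"), inherits(p$lumen, "contour"))
  if (polygon_area(p$lumen) >= polygon_area(p$abluminal)) {
    stop("lumen area must be smaller than capillary area", call. = FALSE)
  }
  lum <- unclass(p$lumen)
  if (!all(points_in_polygon(lum[, 1], lum[, 2], p$abluminal))) {
    stop("luminal contour must lie inside the abluminal contour", call. = FALSE)
  }
  if (!is.null(p$bl_inner) && !is.null(p$bl_outer)) {
    inner <- unclass(p$bl_inner)
    coincide <- nrow(inner) == nrow(unclass(p$bl_outer)) &&
      max(abs(inner - unclass(p$bl_outer))) < 1e-12
    if (!coincide && !all(points_in_polygon(inner[, 1], inner[, 2], p$bl_outer))) {
      stop("bl_inner must lie inside (or coincide with) bl_outer", call. = FALSE)
    }
    circ <- polygon_perimeter(p$bl_outer)
    for (arc in c(p$pericyte_adhesion, p$astrocyte_adhesion)) {
      if (path_length(arc) > circ * (1 + 1e-9)) {
        stop("adhesion arc longer than basal lamina circumference", call. = FALSE)
      }
    }
  }
  for (pc in p$pericytes) stopifnot(inherits(pc, "contour"))
  if (!is.null(p$vesicle_fields)) {
    vf <- p$vesicle_fields
    if (!all(c("area", "count") %in% names(vf))) {
      stop("vesicle_fields needs columns `area` and `count`", call. = FALSE)
    }
    if (any(vf$area <= 0) || any(vf$count < 0)) {
      stop("vesicle field areas must be positive and counts non-negative",
           call. = FALSE)
    }
  }
  if (!is.null(p$intensity_image)) {
    if (!is.matrix(p$intensity_image) || !is.numeric(p$intensity_image)) {
      stop("intensity_image must be a numeric matrix", call. = FALSE)
    }
    if (is.na(p$pixel_size) || p$pixel_size <= 0) {
      stop("pixel_size must be positive when an intensity image is attached",
           call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.capillary_profile <- function(x, ...) {
  cat(sprintf("<capillary_profile %s/%s/%s>\n", x$group, x$animal, x$profile))
  cat(sprintf("  capillary area %.2f um^2, lumen area %.2f um^2\n",
              polygon_area(x$abluminal), polygon_area(x$lumen)))
  cat(sprintf("  %d pericyte(s), %d TJ trace(s), %d vesicle field(s), image: %s\n",
              length(x$pericytes), length(x$tj),
              if (is.null(x$vesicle_fields)) 0L else nrow(x$vesicle_fields),
              if (is.null(x$intensity_image)) "none" else
                paste(dim(x$intensity_image), collapse = "x")))
  invisible(x)
}

#' Sampling inclusion rule for capillary profiles
#'
#' A profile enters quantitative analysis only if the lumen is lined by no
#' more than two endothelial cells, the vessel is cut in cross-section, the
#' lumen contains no blood cells or plasma, and no endothelial or pericyte
#' nucleus is visible (nuclei generate extreme area measurements and are too
#' infrequent to sample adequately).
#'
#' @param p a [capillary_profile()].
#' @param max_endothelial_cells inclusion bound on lining cells (default 2).
#' @return `TRUE` or `FALSE`.
#' @export
profile_passes_inclusion <- function(p, max_endothelial_cells = 2L) {
  f <- p$flags
  vals <- c(f$n_endothelial_cells, f$is_cross_section,
            f$contains_blood_or_plasma, f$has_visible_nucleus)
  if (anyNA(vals)) {
    stop("inclusion flags are not all set for profile ",
         paste(p$group, p$animal, p$profile, sep = "/"), call. = FALSE)
  }
  f$n_endothelial_cells <= max_endothelial_cells &&
    isTRUE(f$is_cross_section) &&
    !isTRUE(f$contains_blood_or_plasma) &&
    !isTRUE(f$has_visible_nucleus)
}
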