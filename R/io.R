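#' Annotation and table input/output
#'
#' Profiles travel as layered JSON annotation files (micrometre
#' coordinates, named layers) with an optional companion grayscale TIFF;
#' volumes travel as multi-page TIFF stacks with a YAML sidecar carrying
#' the voxel size; tables are plain CSV. Everything the package writes it
#' can read back.
#'
#' @name io
NULL

layer_to_json <- function(x, kind) {
  list(kind = kind, coordinates = unclass(x))
}

json_to_contour <- function(lay, name) {
  if (!identical(lay$kind, "contour")) {
    stop(sprintf("layer '%s' must have kind 'contour'", name), call. = FALSE)
  }
  tryCatch(contour(do.call(rbind, lapply(lay$coordinates, as.numeric))),
           error = function(e) {
             stop(sprintf("layer '%s': %s", name, conditionMessage(e)),
                  call. = FALSE)
           })
}

json_to_polyline <- function(lay, name) {
  if (!identical(lay$kind, "polyline")) {
    stop(sprintf("layer '%s' must have kind 'polyline'", name), call. = FALSE)
  }
  tryCatch(polyline(do.call(rbind, lapply(lay$coordinates, as.numeric))),
           error = function(e) {
             stop(sprintf("layer '%s': %s", name, conditionMessage(e)),
                  call. = FALSE)
           })
}

#' Write a capillary profile annotation file
#'
#' @param p a [capillary_profile()].
#' @param path output JSON path.
#' @param image_path optional path for the intensity image (16-bit
#'   grayscale TIFF), recorded in the annotation file relative to its
#'   directory.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(p, path, image_path = NULL) {
  stopifnot(inherits(p, "capillary_profile"))
  layers <- list(abluminal = layer_to_json(p$abluminal, "contour"),
                 lumen = layer_to_json(p$lumen, "contour"))
  if (!is.null(p$bl_inner)) layers$bl_inner <- layer_to_json(p$bl_inner, "contour")
  if (!is.null(p$bl_outer)) layers$bl_outer <- layer_to_json(p$bl_outer, "contour")
  layers$pericyte <- lapply(p$pericytes, layer_to_json, kind = "contour")
  layers$pericyte_adhesion <- lapply(p$pericyte_adhesion, layer_to_json,
                                     kind = "polyline")
  layers$astrocyte_adhesion <- lapply(p$astrocyte_adhesion, layer_to_json,
                                      kind = "polyline")
  layers$tj <- lapply(p$tj, layer_to_json, kind = "polyline")
  obj <- list(format = "capmorph-annotation", version = 1L,
              coordinate_unit = "micrometre",
              group = p$group, animal = p$animal, profile = p$profile,
              pixel_size = p$pixel_size,
              flags = p$flags,
              layers = layers,
              vesicle_fields = if (is.null(p$vesicle_fields)) list() else
                as.data.frame(p$vesicle_fields),
              image = NULL)
  if (!is.null(p$intensity_image) && !is.null(image_path)) {
    tiff::writeTIFF(pmin(pmax(p$intensity_image, 0), 1), image_path,
                    bits.per.sample = 16L)
    obj$image <- basename(image_path)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a capillary profile annotation file
#'
#' Reconstructs the profile and re-validates every geometric invariant;
#' malformed files error with the offending layer named.
#'
#' @param path annotation JSON path.
#' @param read_image load the companion intensity TIFF if the annotation
#'   references one.
#' @return a [capillary_profile()].
#' @export
read_annotation <- function(path, read_image = TRUE) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "capmorph-annotation")) {
    stop(sprintf("%s: not a capmorph annotation file", path), call. = FALSE)
  }
  lay <- obj$layers
  known <- c("abluminal", "lumen", "bl_inner", "bl_outer",
             "pericyte", "pericyte_adhesion", "astrocyte_adhesion", "tj")
  unknown <- setdiff(names(lay), known)
  if (length(unknown) > 0) {
    stop(sprintf("%s: unknown layer(s): %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  img <- NULL
  if (read_image && !is.null(obj$image)) {
    img_path <- file.path(dirname(path), obj$image)
    img <- tiff::readTIFF(img_path)
    if (length(dim(img)) == 3) img <- img[, , 1]
  }
  vf <- if (length(obj$vesicle_fields) > 0) {
    dplyr::bind_rows(lapply(obj$vesicle_fields, function(r) {
      tibble::tibble(area = as.numeric(r$area), count = as.numeric(r$count))
    }))
  } else NULL
  fl <- obj$flags
  capillary_profile(
    group = obj$group, animal = obj$animal, profile = obj$profile,
    abluminal = json_to_contour(lay$abluminal, "abluminal"),
    lumen = json_to_contour(lay$lumen, "lumen"),
    bl_inner = if (!is.null(lay$bl_inner)) json_to_contour(lay$bl_inner, "bl_inner"),
    bl_outer = if (!is.null(lay$bl_outer)) json_to_contour(lay$bl_outer, "bl_outer"),
    pericytes = lapply(seq_along(lay$pericyte), function(i) {
      json_to_contour(lay$pericyte[[i]], sprintf("pericyte[%d]", i))
    }),
    pericyte_adhesion = lapply(seq_along(lay$pericyte_adhesion), function(i) {
      json_to_polyline(lay$pericyte_adhesion[[i]], sprintf("pericyte_adhesion[%d]", i))
    }),
    astrocyte_adhesion = lapply(seq_along(lay$astrocyte_adhesion), function(i) {
      json_to_polyline(lay$astrocyte_adhesion[[i]], sprintf("astrocyte_adhesion[%d]", i))
    }),
    tj = lapply(seq_along(lay$tj), function(i) {
      json_to_polyline(lay$tj[[i]], sprintf("tj[%d]", i))
    }),
    vesicle_fields = vf,
    intensity_image = img,
    pixel_size = if (is.null(obj$pixel_size)) NA_real_ else as.numeric(obj$pixel_size),
    n_endothelial_cells = fl$n_endothelial_cells %||% NA_integer_,
    is_cross_section = fl$is_cross_section %||% NA,
    contains_blood_or_plasma = fl$contains_blood_or_plasma %||% NA,
    has_visible_nucleus = fl$has_visible_nucleus %||% NA)
}

#' Write a two-channel volume as multi-page TIFF stacks
#'
#' @param v a [volume_pair()].
#' @param path_a,path_b output TIFF paths (one z-page per slice).
#' @param sidecar optional YAML path recording the voxel size.
#' @return invisibly, the paths.
#' @export
write_volume_pair <- function(v, path_a, path_b, sidecar = NULL) {
  stopifnot(inherits(v, "volume_pair"))
  to_pages <- function(x) {
    mx <- max(x, 1e-12)
    lapply(seq_len(dim(x)[3]), function(k) x[, , k] / mx)
  }
  tiff::writeTIFF(to_pages(v$channel_a), path_a, bits.per.sample = 16L)
  tiff::writeTIFF(to_pages(v$channel_b), path_b, bits.per.sample = 16L)
  if (!is.null(sidecar)) {
    yaml::write_yaml(list(voxel_size = as.numeric(v$voxel_size)), sidecar)
  }
  invisible(c(path_a, path_b))
}

#' Read a two-channel volume from multi-page TIFF stacks
#'
#' @param path_a,path_b TIFF stack paths (identical shapes required).
#' @param voxel_size length-3 micrometre voxel size; read from `sidecar`
#'   when `NULL`.
#' @param sidecar YAML sidecar path with a `voxel_size` entry.
#' @return a [volume_pair()].
#' @export
read_volume_pair <- function(path_a, path_b, voxel_size = NULL, sidecar = NULL) {
  if (is.null(voxel_size)) {
    if (is.null(sidecar)) stop("give voxel_size or a sidecar file", call. = FALSE)
    voxel_size <- as.numeric(yaml::read_yaml(sidecar)$voxel_size)
  }
  to_array <- function(pages) {
    if (is.matrix(pages)) pages <- list(pages)
    pages <- lapply(pages, function(pg) if (length(dim(pg)) == 3) pg[, , 1] else pg)
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  }
  a <- to_array(tiff::readTIFF(path_a, all = TRUE))
  b <- to_array(tiff::readTIFF(path_b, all = TRUE))
  if (!identical(dim(a), dim(b))) {
    stop("channel stacks have mismatched shapes", call. = FALSE)
  }
  volume_pair(a, b, voxel_size)
}

#' Write and read tabular results
#'
#' Thin CSV wrappers that preserve the attributes the analysis functions
#' rely on (reference gene, control group).
#'
#' @param x tibble to write.
#' @param path CSV path.
#' @return `path` (write) or a tibble (read), invisibly for writers.
#' @export
write_records <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname write_records
#' @param reference_gene,control_group attached as attributes for
#'   [ddct_fold_changes()].
#' @export
read_ct_table <- function(path, reference_gene = "GAPDH",
                          control_group = "SHAM") {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(out)))
  structure(out, reference_gene = reference_gene,
            control_group = control_group)
}

#' @rdname write_records
#' @export
read_grade_sheet <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("animal", paste0("seg", 1:6)) %in% names(out)))
  out
}

#' @rdname write_records
#' @export
read_lane_table <- function(path, control_group = "SHAM") {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("membrane", "sample", "group", "band",
            "background_above", "background_below", "loading")
  stopifnot(all(need %in% names(out)))
  structure(out, control_group = control_group)
}
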