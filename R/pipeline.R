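#' Run the simulate -> measure -> aggregate -> compare pipeline
#'
#' Mirrors the study's analysis order: generate (or load) capillary
#' profiles, measure every ultrastructural parameter, aggregate regions of
#' interest to animal-level means, and compare the groups with
#' FDR-corrected pairwise tests. All outputs are written as CSV under
#' `output_dir` together with a YAML run log recording the effective
#' parameters, so a rerun with the same seed is byte-identical (the log's
#' timestamp aside).
#'
#' @param groups character vector of group labels to simulate (defaults to
#'   all three study groups with their reference parameter distributions).
#' @param n_animals,profiles_per_animal dataset layout per group.
#' @param seed master seed; every stage's randomness derives from it.
#' @param output_dir directory for the result CSVs (created if missing);
#'   `NULL` skips writing.
#' @param with_image generate intensity images (enables hole-area
#'   measurement; slower).
#' @param grid_pitch,band_width,exclusion_radius measurement parameters,
#'   see [measure_profile()].
#' @param alpha,fdr_method,fdr_scope comparison parameters, see
#'   [compare_groups()].
#' @return list with `truth`, `records`, `summaries` (tibbles), `stats`
#'   (a [compare_groups()] result), `report` (a [report_table()]) and
#'   `paths` of written files; invisibly.
#' @export
run_pipeline <- function(groups = c("SHAM", "SAH", "SAH+Mino"),
                         n_animals = 4L, profiles_per_animal = 10L,
                         seed = 1L, output_dir = NULL, with_image = TRUE,
                         grid_pitch = 0.5, band_width = 2,
                         exclusion_radius = 0.25,
                         alpha = 0.05, fdr_method = "BH",
                         fdr_scope = "per_parameter") {
  configs <- lapply(groups, function(g) {
    phantom_config(group = g, n_animals = n_animals,
                   profiles_per_animal = profiles_per_animal,
                   with_image = with_image, seed = seed)
  })
  ds <- make_group_dataset(configs)
  records <- measure_profiles(ds$profiles, include_only = TRUE,
                              grid_pitch = grid_pitch,
                              exclusion_radius = exclusion_radius,
                              band_width = band_width)
  summaries <- per_animal_means(records)
  if (length(unique(summaries$group)) >= 2) {
    stats <- compare_groups(summaries, alpha = alpha, fdr_method = fdr_method,
                            fdr_scope = fdr_scope)
    report <- report_table(stats)
  } else {
    stats <- NULL
    report <- NULL
  }
  paths <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      truth = write_records(ds$truth, file.path(output_dir, "ground_truth.csv")),
      records = write_records(records, file.path(output_dir, "records.csv")),
      summaries = write_records(summaries, file.path(output_dir, "animal_means.csv")))
    if (!is.null(stats)) {
      paths <- c(paths,
        anova = write_records(stats$anova, file.path(output_dir, "anova.csv")),
        pairwise = write_records(stats$pairwise, file.path(output_dir, "pairwise.csv")),
        report = write_records(report, file.path(output_dir, "report.csv")))
    }
    yaml::write_yaml(
      list(package = "capmorph",
           version = as.character(utils::packageVersion("capmorph")),
           seed = seed, groups = groups, n_animals = n_animals,
           profiles_per_animal = profiles_per_animal,
           with_image = with_image, grid_pitch = grid_pitch,
           band_width = band_width, exclusion_radius = exclusion_radius,
           alpha = alpha, fdr_method = fdr_method, fdr_scope = fdr_scope),
      file.path(output_dir, "run_log.yaml"))
    paths <- c(paths, log = file.path(output_dir, "run_log.yaml"))
  }
  invisible(list(truth = ds$truth, records = records, summaries = summaries,
                 stats = stats, report = report, paths = paths))
}

#' Draw an annotated capillary profile
#'
#' @param object a [capillary_profile()].
#' @param ... ignored.
#' @return a ggplot object showing every annotation layer (and the
#'   intensity image underneath when present).
#' @export
autoplot.capillary_profile <- function(object, ...) {
  as_df <- function(x, name, id = 1L, close = FALSE) {
    xy <- unclass(x)
    if (close) xy <- rbind(xy, xy[1, ])
    tibble::tibble(x = xy[, 1], y = xy[, 2], layer = name,
                   piece = paste(name, id))
  }
  dfs <- list(as_df(object$abluminal, "abluminal", close = TRUE),
              as_df(object$lumen, "lumen", close = TRUE))
  if (!is.null(object$bl_outer)) {
    dfs <- c(dfs, list(as_df(object$bl_outer, "basal lamina", close = TRUE)))
  }
  for (i in seq_along(object$pericytes)) {
    dfs <- c(dfs, list(as_df(object$pericytes[[i]], "pericyte", i, close = TRUE)))
  }
  for (i in seq_along(object$astrocyte_adhesion)) {
    dfs <- c(dfs, list(as_df(object$astrocyte_adhesion[[i]], "astrocyte adhesion", i)))
  }
  for (i in seq_along(object$tj)) {
    dfs <- c(dfs, list(as_df(object$tj[[i]], "tight junction", i)))
  }
  df <- dplyr::bind_rows(dfs)
  pl <- ggplot2::ggplot()
  if (!is.null(object$intensity_image)) {
    img <- object$intensity_image
    px <- object$pixel_size
    imdf <- tibble::tibble(
      x = (rep(seq_len(ncol(img)), each = nrow(img)) - 0.5) * px,
      y = (rep(seq_len(nrow(img)), times = ncol(img)) - 0.5) * px,
      v = as.vector(img))
    pl <- pl + ggplot2::geom_raster(data = imdf,
                                    ggplot2::aes(x = .data$x, y = .data$y,
                                                 fill = .data$v)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  pl + ggplot2::geom_path(data = df,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$layer,
                                       group = .data$piece),
                          linewidth = 0.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = NULL,
                  title = sprintf("%s / %s / %s", object$group, object$animal,
                                  object$profile)) +
    ggplot2::theme_minimal()
}
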