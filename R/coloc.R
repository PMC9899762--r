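#' Threshold-based 3-D colocalization
#'
#' Automatic dual-channel thresholding in the Costes style: an orthogonal
#' regression relates the two channels, candidate thresholds walk down the
#' intensity range along that regression line, and the chosen thresholds
#' are the highest for which the voxels below both thresholds are no longer
#' positively correlated. Above-threshold voxels are the colocalized
#' compartment over which percent material and the Pearson coefficient are
#' reported.
#'
#' @name colocalization
NULL

#' Pearson correlation between two channels
#'
#' @param a,b numeric arrays of identical shape.
#' @param mask optional logical array restricting the voxel set.
#' @return product-moment correlation.
#' @export
pearson_cc <- function(a, b, mask = NULL) {
  stopifnot(identical(dim(a), dim(b)))
  av <- as.vector(a); bv <- as.vector(b)
  if (!is.null(mask)) {
    m <- as.vector(mask)
    av <- av[m]; bv <- bv[m]
  }
  if (length(av) < 2) stop("need at least 2 voxels", call. = FALSE)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    stop("zero variance in a channel; correlation undefined", call. = FALSE)
  }
  stats::cor(av, bv)
}

# Orthogonal regression of b on a computed on standardized intensities
# (the standardized major axis): both channels carry noise, so neither is
# privileged, and standardizing first makes the fit -- and therefore the
# automatic thresholds -- equivariant under per-channel intensity scaling.
tls_regression <- function(av, bv) {
  sa <- stats::sd(av); sb <- stats::sd(bv)
  if (sa == 0 || sb == 0) stop("degenerate channel relation (zero variance)", call. = FALSE)
  slope <- sign(stats::cov(av, bv) + 0) * sb / sa
  if (slope == 0) slope <- sb / sa
  list(slope = slope, intercept = mean(bv) - slope * mean(av))
}

#' Costes automatic thresholds for a channel pair
#'
#' Scans candidate thresholds for channel A from the top of its intensity
#' range downwards (integer grey levels for integer data, otherwise
#' `n_steps` quantile steps), pairing each with `T_b = slope * T_a +
#' intercept` from the orthogonal regression. The first candidate at which
#' the Pearson correlation of the voxels below both thresholds drops to
#' zero or below wins. Voxels that are zero in both channels are excluded
#' from the regression. If the below-threshold correlation never reaches
#' zero the scan bottoms out and the minimum intensity is returned with
#' `exhausted = TRUE` (this is the expected outcome for perfectly
#' correlated channels, where every voxel is colocalized).
#'
#' @param v a [volume_pair()].
#' @param n_steps quantile scan resolution for non-integer data.
#' @param min_voxels smallest below-threshold population for which the
#'   correlation is evaluated.
#' @return list with `t_a`, `t_b`, `slope`, `intercept`, `exhausted`.
#' @export
costes_thresholds <- function(v, n_steps = 256L, min_voxels = 20L) {
  a <- as.vector(v$channel_a); b <- as.vector(v$channel_b)
  nz <- !(a == 0 & b == 0)
  if (sum(nz) < min_voxels) stop("too few non-empty voxels", call. = FALSE)
  fit <- tls_regression(a[nz], b[nz])
  # the below-threshold population at the top of the scan is the whole
  # stack: if it is already non-positively correlated, the highest
  # admissible threshold is the maximum intensity and nothing colocalizes
  if (stats::cor(a[nz], b[nz]) <= 0) {
    return(list(t_a = max(a), t_b = fit$slope * max(a) + fit$intercept,
                slope = fit$slope, intercept = fit$intercept,
                exhausted = FALSE))
  }
  is_int <- all(a == round(a)) && all(b == round(b))
  cand <- if (is_int) {
    sort(unique(a), decreasing = TRUE)
  } else {
    sort(unique(stats::quantile(a, probs = seq(1, 0, length.out = n_steps),
                                names = FALSE)), decreasing = TRUE)
  }
  t_a <- min(a); exhausted <- TRUE
  for (ta in cand) {
    tb <- fit$slope * ta + fit$intercept
    below <- which(a < ta & b < tb)
    if (length(below) < min_voxels) next
    sa <- a[below]; sb <- b[below]
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) next
    r <- stats::cor(sa, sb)
    if (r <= 0) {
      t_a <- ta; exhausted <- FALSE
      break
    }
  }
  if (exhausted) {
    warning("below-threshold correlation never reached zero; thresholds set to the minimum intensity")
  }
  list(t_a = t_a, t_b = fit$slope * t_a + fit$intercept,
       slope = fit$slope, intercept = fit$intercept, exhausted = exhausted)
}

#' Colocalization statistics for a channel pair
#'
#' Colocalized voxels are those above both Costes thresholds. Percent
#' material is the share of each channel's total intensity residing in
#' those voxels; the Pearson coefficient is computed over the colocalized
#' voxels (a whole-stack coefficient is also reported). Channels are
#' classified as correlated when the colocalized-voxel coefficient is at
#' least `cutoff`.
#'
#' @param v a [volume_pair()].
#' @param cutoff correlation classification boundary (default 0.5;
#'   `pcc >= cutoff` is correlated).
#' @param thresholds optional precomputed [costes_thresholds()] result.
#' @param ... passed to [costes_thresholds()].
#' @return one-row tibble of class `"coloc_result"` with the thresholds,
#'   regression, `pcc` (colocalized voxels), `pcc_all` (whole stack),
#'   `percent_material_a`, `percent_material_b`, `n_coloc`, `correlated`.
#'   An empty colocalized set yields zero percentages, `NA` correlation and
#'   `correlated = FALSE`.
#' @export
coloc_stats <- function(v, cutoff = 0.5, thresholds = NULL, ...) {
  stopifnot(inherits(v, "volume_pair"))
  th <- if (is.null(thresholds)) costes_thresholds(v, ...) else thresholds
  a <- as.vector(v$channel_a); b <- as.vector(v$channel_b)
  sel <- a > th$t_a & b > th$t_b
  n_coloc <- sum(sel)
  pm_a <- if (sum(a) > 0) 100 * sum(a[sel]) / sum(a) else 0
  pm_b <- if (sum(b) > 0) 100 * sum(b[sel]) / sum(b) else 0
  pcc <- if (n_coloc >= 2 && stats::sd(a[sel]) > 0 && stats::sd(b[sel]) > 0) {
    stats::cor(a[sel], b[sel])
  } else NA_real_
  out <- tibble::tibble(
    t_a = th$t_a, t_b = th$t_b, slope = th$slope, intercept = th$intercept,
    threshold_exhausted = th$exhausted,
    pcc = pcc, pcc_all = pearson_cc(v$channel_a, v$channel_b),
    percent_material_a = pm_a, percent_material_b = pm_b,
    n_coloc = n_coloc,
    correlated = !is.na(pcc) && pcc >= cutoff)
  class(out) <- c("coloc_result", class(out))
  out
}

#' Channel scattergram with Costes thresholds
#'
#' @param object a [volume_pair()].
#' @param result optional [coloc_stats()] row; computed if missing.
#' @param max_points subsample cap for plotting.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.volume_pair <- function(object, result = NULL, max_points = 20000, ...) {
  if (is.null(result)) result <- coloc_stats(object)
  df <- tibble::tibble(a = as.vector(object$channel_a),
                       b = as.vector(object$channel_b))
  if (nrow(df) > max_points) df <- dplyr::slice_sample(df, n = max_points)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_vline(xintercept = result$t_a, colour = "red", linetype = 2) +
    ggplot2::geom_hline(yintercept = result$t_b, colour = "red", linetype = 2) +
    ggplot2::geom_abline(slope = result$slope, intercept = result$intercept,
                         colour = "blue") +
    ggplot2::labs(x = "channel A intensity", y = "channel B intensity",
                  title = sprintf("PCC (colocalized) = %.3f, %%MC A = %.1f, B = %.1f",
                                  result$pcc, result$percent_material_a,
                                  result$percent_material_b)) +
    ggplot2::theme_minimal()
}
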