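#' Relative expression by the comparative CT (2^-ddCT) method
#'
#' For each sample, delta-CT is the target gene's CT minus the reference
#' gene's CT (amplification efficiency fixed at 2, the Livak assumption).
#' Delta-delta-CT subtracts the arithmetic mean delta-CT of the control
#' group for the same gene, and the fold change is `2^-ddCT`. Centering on
#' the arithmetic mean of delta-CT makes the geometric mean of the control
#' group's folds exactly 1.
#'
#' @param ct tibble with columns `sample`, `group`, `gene`, `ct`
#'   (e.g. from [make_ct_table()] or [read_ct_table()]).
#' @param reference_gene reference gene name; defaults to the table's
#'   `reference_gene` attribute, then `"GAPDH"`.
#' @param control_group control group label; defaults to the table's
#'   `control_group` attribute, then `"SHAM"`.
#' @return tibble with columns `sample`, `group`, `gene`, `dct`, `ddct`,
#'   `fold`.
#' @export
ddct_fold_changes <- function(ct, reference_gene = NULL, control_group = NULL) {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(ct)))
  if (is.null(reference_gene)) {
    reference_gene <- attr(ct, "reference_gene") %||% "GAPDH"
  }
  if (is.null(control_group)) {
    control_group <- attr(ct, "control_group") %||% "SHAM"
  }
  if (any(!is.finite(ct$ct))) stop("CT values must be finite", call. = FALSE)
  refs <- ct[ct$gene == reference_gene, c("sample", "ct")]
  names(refs)[2] <- "ct_ref"
  targets <- ct[ct$gene != reference_gene, ]
  missing_ref <- setdiff(unique(targets$sample), refs$sample)
  if (length(missing_ref) > 0) {
    stop("sample(s) lack a reference-gene row: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  if (!any(targets$group == control_group)) {
    stop(sprintf("control group '%s' has no samples", control_group), call. = FALSE)
  }
  out <- dplyr::left_join(targets, refs, by = "sample")
  out$dct <- out$ct - out$ct_ref
  out <- dplyr::group_by(out, .data$gene)
  out <- dplyr::mutate(out,
                       ddct = .data$dct - mean(.data$dct[.data$group == control_group]))
  out <- dplyr::ungroup(out)
  out$fold <- 2^(-out$ddct)
  out[, c("sample", "group", "gene", "dct", "ddct", "fold")]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Immunoblot fold changes with background and loading normalization
#'
#' Each band intensity is adjusted by the mean of the membrane background
#' measured above and beneath the lane (floored at zero), normalized
#' against the loading-control band, and expressed as a fold change versus
#' the mean normalized level of the control samples **on the same
#' membrane**, which cancels per-membrane gain.
#'
#' @param lanes tibble with columns `membrane`, `sample`, `group`, `band`,
#'   `background_above`, `background_below`, `loading` (e.g. from
#'   [make_lane_table()]).
#' @param control_group control group label; defaults to the table's
#'   `control_group` attribute, then `"SHAM"`.
#' @return tibble with columns `membrane`, `sample`, `group`, `adjusted`,
#'   `normalized`, `fold`.
#' @export
blot_fold_changes <- function(lanes, control_group = NULL) {
  need <- c("membrane", "sample", "group", "band",
            "background_above", "background_below", "loading")
  stopifnot(all(need %in% names(lanes)))
  if (is.null(control_group)) {
    control_group <- attr(lanes, "control_group") %||% "SHAM"
  }
  if (any(lanes$loading <= 0)) {
    stop("loading-control intensities must be positive", call. = FALSE)
  }
  out <- dplyr::mutate(lanes,
    adjusted = pmax(.data$band -
                      (.data$background_above + .data$background_below) / 2, 0),
    normalized = .data$adjusted / .data$loading)
  by_membrane <- dplyr::group_by(out, .data$membrane)
  ctl_counts <- dplyr::summarise(by_membrane,
                                 n_ctl = sum(.data$group == control_group))
  if (any(ctl_counts$n_ctl == 0)) {
    stop("membrane(s) without control-group samples: ",
         paste(ctl_counts$membrane[ctl_counts$n_ctl == 0], collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::mutate(by_membrane,
    fold = .data$normalized /
      mean(.data$normalized[.data$group == control_group]))
  dplyr::ungroup(out)[, c("membrane", "sample", "group",
                          "adjusted", "normalized", "fold")]
}

#' Gelatinolytic activity from a zymogram lane profile
#'
#' On a gelatin zymogram, active gelatinase shows as a clear band (an
#' intensity minimum) on the stained background, so activity is the summed
#' depth of the trace below the local background level across the band
#' window, floored at zero. When a loading value from a parallel protein
#' gel is supplied, the activity is divided by it.
#'
#' @param trace numeric vector: the 1-D densitometric profile along the
#'   lane.
#' @param band_window integer indices of the band region within `trace`.
#' @param background_window integer indices used to estimate the local
#'   background level (its mean intensity).
#' @param loading optional positive loading value for normalization.
#' @return activity in intensity units (per loading unit if normalized).
#' @export
zymogram_activity <- function(trace, band_window, background_window,
                              loading = NULL) {
  stopifnot(is.numeric(trace), length(trace) >= 2)
  if (length(band_window) == 0 || length(background_window) == 0) {
    stop("band and background windows must be non-empty", call. = FALSE)
  }
  if (any(band_window < 1) || any(band_window > length(trace)) ||
      any(background_window < 1) || any(background_window > length(trace))) {
    stop("window indices fall outside the trace", call. = FALSE)
  }
  bg <- mean(trace[background_window])
  activity <- sum(pmax(bg - trace[band_window], 0))
  if (!is.null(loading)) {
    if (loading <= 0) stop("loading value must be positive", call. = FALSE)
    activity <- activity / loading
  }
  activity
}
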