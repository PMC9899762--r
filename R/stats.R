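#' SAH grade of one animal
#'
#' The basal brain (including brainstem) is divided into six segments, each
#' graded 0-3 by the amount of subarachnoid blood; the animal's grade is
#' the sum, ranging 0-18.
#'
#' @param segments integer vector of exactly six segment grades in 0..3.
#' @return integer grade in 0..18.
#' @export
sah_grade <- function(segments) {
  if (length(segments) != 6) {
    stop("a grade sheet has exactly six segments", call. = FALSE)
  }
  if (anyNA(segments) || any(segments != round(segments)) ||
      any(segments < 0) || any(segments > 3)) {
    stop("segment grades must be integers in 0..3", call. = FALSE)
  }
  as.integer(sum(segments))
}

#' SAH grades for a sheet of animals
#'
#' @param sheets tibble with columns `animal` and `seg1`..`seg6` (e.g. from
#'   [make_grade_sheet()]).
#' @return the input tibble with a `grade` column appended.
#' @export
sah_grades <- function(sheets) {
  segs <- paste0("seg", 1:6)
  stopifnot(all(c("animal", segs) %in% names(sheets)))
  m <- as.matrix(sheets[, segs])
  sheets$grade <- vapply(seq_len(nrow(m)), function(i) sah_grade(m[i, ]),
                         integer(1))
  sheets
}

#' Inclusion filter on SAH grade
#'
#' Animals enter the study only if their SAH grade reaches `min_grade`
#' (default 8), ensuring a consistent hemorrhage burden across the
#' experimental groups.
#'
#' @inheritParams sah_grades
#' @param min_grade minimum grade for inclusion (default 8; the boundary is
#'   inclusive).
#' @return character vector of kept animal ids.
#' @export
inclusion_filter <- function(sheets, min_grade = 8L) {
  if (nrow(sheets) == 0) return(character(0))
  g <- sah_grades(sheets)
  g$animal[g$grade >= min_grade]
}

#' Aggregate profile records to animal-level means
#'
#' Means from multiple regions of interest are averaged into one value per
#' parameter per animal; all later statistics run on these animal-level
#' means, so the animal is the experimental unit. Missing values are
#' excluded parameter-wise.
#'
#' @param records tibble of morphometry records (from [measure_profiles()]),
#'   with `group` and `animal` identifier columns and numeric parameter
#'   columns.
#' @return tibble with one row per animal: `group`, `animal`, `n_profiles`,
#'   and the per-parameter means.
#' @export
per_animal_means <- function(records) {
  stopifnot(all(c("group", "animal") %in% names(records)))
  if (nrow(records) == 0) stop("no records to aggregate", call. = FALSE)
  num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$group, .data$animal),
    n_profiles = dplyr::n(),
    dplyr::across(dplyr::all_of(num_cols),
                  ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
    .groups = "drop")
  out
}

#' Three-group comparison with FDR-corrected pairwise tests
#'
#' For every parameter, a classical one-way ANOVA is fit on the
#' animal-level means, followed by pairwise Welch t-tests between all group
#' pairs with Benjamini-Hochberg adjustment. By default the adjustment is
#' applied within each parameter's family of pairwise comparisons
#' (`fdr_scope = "per_parameter"`); `"pooled"` adjusts across all
#' parameters at once. Star flags encode the identity of the significant
#' comparison -- `*` for group 2 vs group 1, `**` for group 3 vs group 1,
#' `***` for group 3 vs group 2 (in `group_order`) -- not significance
#' tiers.
#'
#' @param summaries animal-level tibble from [per_animal_means()].
#' @param parameters character vector of parameter columns to test
#'   (default: all numeric columns except `n_profiles`).
#' @param group_order group factor order; the first level is the control.
#' @param alpha significance threshold on adjusted p values (default 0.05).
#' @param fdr_method adjustment method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @param fdr_scope `"per_parameter"` or `"pooled"`.
#' @return object of class `"group_comparison"`; see [tidy.group_comparison()]
#'   and [glance.group_comparison()].
#' @export
compare_groups <- function(summaries, parameters = NULL,
                           group_order = c("SHAM", "SAH", "SAH+Mino"),
                           alpha = 0.05, fdr_method = "BH",
                           fdr_scope = c("per_parameter", "pooled")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(all(c("group", "animal") %in% names(summaries)))
  groups <- intersect(group_order, unique(summaries$group))
  groups <- c(groups, setdiff(unique(summaries$group), groups))
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  counts <- table(summaries$group)
  if (any(counts < 2)) {
    stop("every group needs at least two animals: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  if (is.null(parameters)) {
    parameters <- setdiff(
      names(summaries)[vapply(summaries, is.numeric, logical(1))],
      "n_profiles")
  }
  summaries$group <- factor(summaries$group, levels = groups)

  pairs <- utils::combn(length(groups), 2)
  star_symbols <- vapply(seq_len(ncol(pairs)), function(i) {
    strrep("*", i)
  }, character(1))

  anova_rows <- list(); pair_rows <- list(); group_rows <- list()
  for (par in parameters) {
    x <- summaries[[par]]
    ok <- is.finite(x)
    dat <- data.frame(y = x[ok], g = summaries$group[ok])
    gr <- dplyr::summarise(dplyr::group_by(summaries, .data$group),
                           mean = mean(.data[[par]], na.rm = TRUE),
                           sd = stats::sd(.data[[par]], na.rm = TRUE),
                           n = sum(is.finite(.data[[par]])),
                           .groups = "drop")
    gr$parameter <- par
    group_rows[[par]] <- gr
    if (length(unique(dat$g[!is.na(dat$y)])) < 2 || nrow(dat) < 3) {
      anova_rows[[par]] <- tibble::tibble(parameter = par, f = NA_real_,
                                          df1 = NA_real_, df2 = NA_real_,
                                          p = NA_real_)
      next
    }
    fit <- stats::anova(stats::lm(y ~ g, data = dat))
    anova_rows[[par]] <- tibble::tibble(
      parameter = par, f = fit$`F value`[1],
      df1 = fit$Df[1], df2 = fit$Df[2], p = fit$`Pr(>F)`[1])
    for (i in seq_len(ncol(pairs))) {
      g1 <- groups[pairs[1, i]]; g2 <- groups[pairs[2, i]]
      y1 <- dat$y[dat$g == g1]; y2 <- dat$y[dat$g == g2]
      p <- if (length(y1) >= 2 && length(y2) >= 2 &&
               (stats::sd(y1) > 0 || stats::sd(y2) > 0)) {
        stats::t.test(y2, y1)$p.value
      } else NA_real_
      pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
        parameter = par,
        comparison = paste(g2, "vs", g1),
        group1 = g1, group2 = g2,
        mean1 = mean(y1), mean2 = mean(y2),
        p = p, star = star_symbols[i])
    }
  }
  pairwise <- dplyr::bind_rows(pair_rows)
  if (nrow(pairwise) > 0) {
    if (fdr_scope == "per_parameter") {
      pairwise <- dplyr::mutate(dplyr::group_by(pairwise, .data$parameter),
                                q = stats::p.adjust(.data$p, method = fdr_method))
      pairwise <- dplyr::ungroup(pairwise)
    } else {
      pairwise$q <- stats::p.adjust(pairwise$p, method = fdr_method)
    }
    pairwise$significant <- !is.na(pairwise$q) & pairwise$q < alpha
  }
  structure(list(anova = dplyr::bind_rows(anova_rows),
                 pairwise = pairwise,
                 group_stats = dplyr::bind_rows(group_rows)[,
                   c("parameter", "group", "mean", "sd", "n")],
                 groups = groups, alpha = alpha,
                 fdr_method = fdr_method, fdr_scope = fdr_scope),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %d parameter(s), groups %s; %s FDR (%s), alpha = %g>\n",
              nrow(x$anova), paste(x$groups, collapse = ", "),
              x$fdr_method, x$fdr_scope, x$alpha))
  sig <- x$pairwise[x$pairwise$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    cat("significant pairwise comparisons:\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %-28s %-22s q = %.4g %s\n", sig$parameter[i],
                  sig$comparison[i], sig$q[i], sig$star[i]))
    }
  } else {
    cat("no significant pairwise comparisons\n")
  }
  invisible(x)
}

#' Tidy the pairwise comparisons of a group comparison
#'
#' @param x a [compare_groups()] result.
#' @param ... ignored.
#' @return tibble with one row per parameter and pairwise comparison:
#'   groups, means, raw `p`, FDR-adjusted `q`, star flag and significance.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$pairwise
}

#' One-row-per-parameter summary of a group comparison
#'
#' @inheritParams tidy.group_comparison
#' @return tibble with the per-parameter ANOVA (`f`, `df1`, `df2`, `p`) and
#'   the concatenated star flags of significant pairwise comparisons.
#' @export
glance.group_comparison <- function(x, ...) {
  stars <- dplyr::summarise(
    dplyr::group_by(x$pairwise, .data$parameter),
    stars = paste(.data$star[.data$significant], collapse = " "))
  dplyr::left_join(x$anova, stars, by = "parameter")
}

#' Report table of group means with star annotations
#'
#' One row per parameter, one mean and SD column pair per group, and a
#' star column marking which pairwise comparisons were significant (star
#' symbols encode comparison identity, not significance tiers).
#'
#' @inheritParams tidy.group_comparison
#' @param digits significant digits for formatting.
#' @return tibble in wide (report) layout.
#' @export
report_table <- function(x, digits = 4) {
  stopifnot(inherits(x, "group_comparison"))
  wide <- tidyr::pivot_wider(x$group_stats, id_cols = "parameter",
                             names_from = "group",
                             values_from = c("mean", "sd"))
  stars <- dplyr::summarise(
    dplyr::group_by(x$pairwise, .data$parameter),
    stars = paste(.data$star[.data$significant], collapse = " "))
  out <- dplyr::left_join(wide, stars, by = "parameter")
  out$stars[is.na(out$stars)] <- ""
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = digits)
  out
}

#' Group means and spreads with significance flags
#'
#' Bar chart of group means with SD error bars, one facet per parameter,
#' annotated with the star flags of significant pairwise comparisons.
#'
#' @param object a [compare_groups()] result.
#' @param parameters subset of parameters to plot (default: all).
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.group_comparison <- function(object, parameters = NULL, ...) {
  gs <- object$group_stats
  if (!is.null(parameters)) gs <- gs[gs$parameter %in% parameters, ]
  stars <- dplyr::summarise(
    dplyr::group_by(object$pairwise, .data$parameter),
    stars = paste(.data$star[.data$significant], collapse = " "))
  gs <- dplyr::left_join(gs, stars, by = "parameter")
  gs$group <- factor(gs$group, levels = object$groups)
  lab <- dplyr::summarise(dplyr::group_by(gs, .data$parameter),
                          y = max(.data$mean + .data$sd, na.rm = TRUE),
                          stars = .data$stars[1])
  ggplot2::ggplot(gs, ggplot2::aes(x = .data$group, y = .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(width = 0.7, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::geom_text(data = lab, inherit.aes = FALSE,
                       ggplot2::aes(x = 1, y = .data$y * 1.08,
                                    label = .data$stars),
                       hjust = 0, size = 5) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "animal-level mean ± SD") +
    ggplot2::theme_minimal()
}
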