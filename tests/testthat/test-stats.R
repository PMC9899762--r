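test_that("SAH grades sum six segments and respect their bounds", {
  expect_identical(sah_grade(rep(3L, 6)), 18L)
  expect_identical(sah_grade(rep(0L, 6)), 0L)
  expect_identical(sah_grade(c(2, 1, 3, 0, 1, 2)), 9L)
  expect_error(sah_grade(rep(1, 5)), "six segments")
  expect_error(sah_grade(c(4, 0, 0, 0, 0, 0)), "0..3")
  expect_error(sah_grade(c(1.5, 0, 0, 0, 0, 0)), "0..3")
  set.seed(3)
  for (k in 1:20) {
    g <- sample(0:3, 6, replace = TRUE)
    expect_identical(sah_grade(sample(g)), sah_grade(g))  # permutation invariant
    expect_gte(sah_grade(g), 0L); expect_lte(sah_grade(g), 18L)
  }
})

test_that("the grade-8 inclusion boundary is inclusive", {
  sheets <- tibble::tibble(animal = c("r1", "r2", "r3"),
                           seg1 = c(3, 2, 0), seg2 = c(2, 2, 0),
                           seg3 = c(1, 1, 0), seg4 = c(1, 1, 0),
                           seg5 = c(1, 1, 0), seg6 = c(0, 0, 0))
  # grades: 8, 7, 0
  expect_identical(inclusion_filter(sheets), "r1")
  expect_identical(inclusion_filter(sheets, min_grade = 7), c("r1", "r2"))
  expect_identical(inclusion_filter(sheets[0, ]), character(0))
})

test_that("animal-level means average profiles and skip missing values", {
  rec <- tibble::tibble(group = "SHAM", animal = c("a", "a", "a", "b"),
                        profile = c("1", "2", "3", "1"),
                        x = c(1, 2, 3, 10), y = c(4, NA, 6, 8))
  s <- per_animal_means(rec)
  expect_equal(s$x[s$animal == "a"], 2)
  expect_equal(s$y[s$animal == "a"], 5)      # NA excluded pairwise
  expect_equal(s$n_profiles, c(3, 1))
  all_na <- tibble::tibble(group = "g", animal = "a", z = NA_real_)
  expect_true(is.na(per_animal_means(all_na)$z))
})

test_that("ANOVA F matches a brute-force sum-of-squares oracle", {
  set.seed(17)
  s <- tibble::tibble(
    group = rep(c("SHAM", "SAH", "SAH+Mino"), each = 4),
    animal = paste0("a", 1:12),
    par1 = rnorm(12, rep(c(10, 7, 9), each = 4)),
    par2 = rnorm(12, 5))
  cmp <- compare_groups(s, parameters = c("par1", "par2"))
  for (par in c("par1", "par2")) {
    y <- s[[par]]; g <- s$group
    grand <- mean(y)
    ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
    ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
    f_oracle <- (ssb / 2) / (ssw / 9)
    expect_equal(cmp$anova$f[cmp$anova$parameter == par], f_oracle,
                 tolerance = 1e-9)
  }
  expect_equal(cmp$anova$df1, c(2, 2))
  expect_equal(cmp$anova$df2, c(9, 9))
})

test_that("identical groups give F = 0 and no stars", {
  s <- tibble::tibble(group = rep(c("SHAM", "SAH", "SAH+Mino"), each = 3),
                      animal = paste0("a", 1:9),
                      par = rep(c(1, 2, 3), times = 3))
  cmp <- compare_groups(s, parameters = "par")
  expect_equal(cmp$anova$f, 0, tolerance = 1e-12)
  expect_false(any(cmp$pairwise$significant))
  expect_equal(glance(cmp)$stars, "")
})

test_that("FDR adjustment is monotone, bounded and order-equivariant", {
  set.seed(23)
  s <- tibble::tibble(
    group = rep(c("SHAM", "SAH", "SAH+Mino"), each = 4),
    animal = paste0("a", 1:12),
    par1 = rnorm(12, rep(c(1, 2, 1.4), each = 4)),
    par2 = rnorm(12, rep(c(5, 5.2, 5.1), each = 4)))
  cmp <- compare_groups(s, parameters = c("par1", "par2"))
  pw <- tidy(cmp)
  expect_true(all(pw$q >= pw$p - 1e-12))
  expect_true(all(pw$q <= 1))
  # within a parameter, BH preserves the p-value ordering
  for (par in unique(pw$parameter)) {
    sub <- pw[pw$parameter == par, ]
    expect_true(all(diff(sub$q[order(sub$p)]) >= -1e-12))
  }
  # star flags encode the comparison identity
  expect_equal(unique(pw$star[pw$comparison == "SAH vs SHAM"]), "*")
  expect_equal(unique(pw$star[pw$comparison == "SAH+Mino vs SHAM"]), "**")
  expect_equal(unique(pw$star[pw$comparison == "SAH+Mino vs SAH"]), "***")
  # pooled scope adjusts across parameters at once
  cmp_pooled <- compare_groups(s, parameters = c("par1", "par2"),
                               fdr_scope = "pooled")
  expect_equal(cmp_pooled$pairwise$q,
               stats::p.adjust(cmp_pooled$pairwise$p, "BH"))
})

test_that("group comparison validates its inputs", {
  s <- tibble::tibble(group = c("A", "A", "B"), animal = c("a", "b", "c"),
                      x = 1:3)
  expect_error(compare_groups(s), "at least two animals")
  one <- tibble::tibble(group = "A", animal = c("a", "b"), x = 1:2)
  expect_error(compare_groups(one), "at least two groups")
})

test_that("the report table carries group means, SDs and star flags", {
  set.seed(9)
  s <- tibble::tibble(
    group = rep(c("SHAM", "SAH", "SAH+Mino"), each = 4),
    animal = paste0("a", 1:12),
    lumen_volume_fraction = c(rnorm(4, 0.6, 0.03), rnorm(4, 0.3, 0.03),
                              rnorm(4, 0.65, 0.03)))
  cmp <- compare_groups(s)
  rep_tab <- report_table(cmp)
  expect_setequal(names(rep_tab),
                  c("parameter", "mean_SHAM", "mean_SAH", "mean_SAH+Mino",
                    "sd_SHAM", "sd_SAH", "sd_SAH+Mino", "stars"))
  expect_match(rep_tab$stars, "\\*")
  expect_s3_class(autoplot(cmp), "ggplot")
})
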