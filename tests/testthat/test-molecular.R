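test_that("ddCT folds follow the one-cycle-per-doubling rule", {
  ct <- tibble::tibble(
    sample = rep(c("s1", "s2", "t1"), each = 2),
    group = rep(c("SHAM", "SHAM", "SAH"), each = 2),
    gene = rep(c("GAPDH", "mmp9"), 3),
    ct = c(18, 21, 18, 21, 18, 20))   # treated sample one cycle lower
  fc <- ddct_fold_changes(ct, reference_gene = "GAPDH", control_group = "SHAM")
  expect_equal(fc$fold[fc$group == "SHAM"], c(1, 1))   # at the control mean
  expect_equal(fc$ddct[fc$sample == "t1"], -1)
  expect_equal(fc$fold[fc$sample == "t1"], 2)          # ddCT -1 doubles
  # geometric mean of control folds is exactly 1
  expect_equal(exp(mean(log(fc$fold[fc$group == "SHAM"]))), 1)
})

test_that("ddCT is invariant to per-sample CT shifts and recovers generator folds", {
  eff <- tibble::tibble(gene = c("occludin", "occludin", "mmp2"),
                        group = c("SAH", "SAH+Mino", "SAH"),
                        fold = c(0.5, 2, 4))
  ct <- make_ct_table(c("occludin", "mmp2"), eff, n_per_group = 3,
                      noise_sd = 0, load_sd = 0.7, seed = 8)
  fc <- ddct_fold_changes(ct)
  got <- dplyr::summarise(dplyr::group_by(fc, .data$group, .data$gene),
                          fold = mean(fold), .groups = "drop")
  expect_equal(got$fold[got$group == "SAH" & got$gene == "occludin"], 0.5)
  expect_equal(got$fold[got$group == "SAH+Mino" & got$gene == "occludin"], 2)
  expect_equal(got$fold[got$group == "SAH" & got$gene == "mmp2"], 4)
  expect_true(all(got$fold[got$group == "SHAM"] == 1))
  # adding a constant to every CT of one sample cancels in the delta
  ct2 <- ct
  ct2$ct[ct2$sample == ct2$sample[1]] <- ct2$ct[ct2$sample == ct2$sample[1]] + 3.3
  expect_equal(ddct_fold_changes(ct2)$fold, fc$fold)
  # a sample without its reference row is named in the error
  bad <- ct[!(ct$sample == "SAH_02" & ct$gene == "GAPDH"), ]
  expect_error(ddct_fold_changes(bad), "SAH_02")
})

test_that("empty CT tables are handled without error", {
  ct <- make_ct_table("x", n_per_group = 0)
  expect_equal(nrow(ct), 0)
})

test_that("blot folds normalize background, loading and membrane gain", {
  lanes <- tibble::tibble(
    membrane = "m1", sample = c("c1", "c2", "t1"),
    group = c("SHAM", "SHAM", "SAH"),
    band = c(500, 700, 1000),
    background_above = c(50, 100, 100),
    background_below = c(70, 120, 120),
    loading = c(220, 295, 445))
  fc <- blot_fold_changes(lanes, control_group = "SHAM")
  expect_equal(fc$adjusted[3], 890)
  expect_equal(fc$normalized[3], 2)
  expect_equal(fc$normalized[1:2], c(2, 2))
  expect_equal(fc$fold, c(1, 1, 1))   # controls at their own mean
  expect_error(blot_fold_changes(dplyr::mutate(lanes, loading = 0)),
               "positive")
})

test_that("blot folds are invariant to per-membrane gain", {
  lanes <- make_lane_table(group_folds = c(SHAM = 1, SAH = 1.8, `SAH+Mino` = 1.2),
                           n_membranes = 2, gains = c(1, 3.5), noise_sd = 0,
                           seed = 2)
  fc <- blot_fold_changes(lanes)
  by_m <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(fc, .data$membrane, .data$group),
                     fold = mean(fold), .groups = "drop"),
    names_from = "membrane", values_from = "fold")
  expect_equal(by_m$m1, by_m$m2)
  expect_equal(sort(by_m$m1), c(1, 1.2, 1.8))
  # a membrane without control samples is rejected
  no_ctl <- lanes[!(lanes$membrane == "m2" & lanes$group == "SHAM"), ]
  expect_error(blot_fold_changes(no_ctl), "m2")
})

test_that("zymogram activity integrates band depth below background", {
  flat <- rep(100, 60)
  expect_equal(zymogram_activity(flat, 20:40, 1:10), 0)
  dip <- flat; dip[21:40] <- 90
  expect_equal(zymogram_activity(dip, 21:40, 1:10), 200)
  dip3 <- flat; dip3[21:40] <- 100 - 30
  expect_equal(zymogram_activity(dip3, 21:40, 1:10) /
                 zymogram_activity(dip, 21:40, 1:10), 3)
  expect_equal(zymogram_activity(dip, 21:40, 1:10, loading = 4), 50)
  expect_error(zymogram_activity(dip, integer(0), 1:10), "non-empty")
  expect_error(zymogram_activity(dip, 55:70, 1:10), "outside")
})
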