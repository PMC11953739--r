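test_that("classify_levels labels metrics against the thresholds", {
  thr <- chemo_thresholds()
  expect_identical(classify_levels(1.95, 0.5, 0.8, thr),
                   list(dispersal_level = "high", rr_level = "high",
                        ci_level = "high", ci_sign = "positive"))
  expect_identical(classify_levels(1.95, 0.5, -0.99, thr),
                   list(dispersal_level = "high", rr_level = "high",
                        ci_level = "high", ci_sign = "negative"))
  expect_identical(classify_levels(0.4, 0.1, NA_real_, thr),
                   list(dispersal_level = "low", rr_level = "low",
                        ci_level = "low", ci_sign = "none"))
  # thresholds are inclusive at the boundary
  expect_identical(classify_levels(1.8, 0.4, 0.5, thr)$ci_level, "high")
})

test_that("dispersal regimes use nearest-anchor boundaries", {
  expect_identical(dispersal_regime(1.97), "uniform~2")
  expect_identical(dispersal_regime(0.95), "central~1")
  expect_identical(dispersal_regime(0.1), "single_quadrant~0")
  expect_identical(dispersal_regime(1.5), "uniform~2")
  expect_identical(dispersal_regime(0.5), "central~1")
})

test_that("preconditions demand worm numbers and dispersing controls", {
  good <- good_experiment()
  pre <- check_preconditions(good)
  expect_true(pre$interpretable)
  expect_length(pre$reasons, 0)

  central <- good
  central[1:2, c("c_left", "c_midleft", "c_midright", "c_right")] <-
    rep(c(2L, 73L, 73L, 2L), each = 2)  # control dispersal ~1
  pre <- check_preconditions(central)
  expect_false(pre$interpretable)
  expect_match(pre$reasons,
               "attraction to center and/or defective locomotion",
               all = FALSE, fixed = TRUE)

  onequad <- good
  onequad[1:2, c("c_left", "c_midleft", "c_midright", "c_right")] <-
    rep(c(148L, 2L, 0L, 0L), each = 2)  # control dispersal ~0
  pre <- check_preconditions(onequad)
  expect_false(pre$interpretable)
  expect_match(pre$reasons, "unknown gradient", all = FALSE)

  low_n <- good
  low_n[3, c("c_left", "c_midleft", "c_midright", "c_right")] <-
    c(5L, 15L, 25L, 35L)
  pre <- check_preconditions(low_n)
  expect_false(pre$interpretable)
  expect_match(pre$reasons, "only 80 worms, need > 100", all = FALSE)

  no_ctrl <- good[good$assay_type == "chemotaxis", ]
  class(no_ctrl) <- c("arena_tbl", "data.frame")
  expect_error(check_preconditions(no_ctrl), "no paired dispersal arena")
})

test_that("the verdict lookup is total, deterministic, and sign-resolved", {
  levels <- c("high", "low")
  combos <- expand.grid(d = levels, r = levels, c = levels,
                        stringsAsFactors = FALSE)
  verdicts <- character(0)
  for (i in seq_len(nrow(combos))) {
    v_pos <- infer_verdict(combos$d[i], combos$r[i], combos$c[i], "positive")
    v_neg <- infer_verdict(combos$d[i], combos$r[i], combos$c[i], "negative")
    v_none <- infer_verdict(combos$d[i], combos$r[i], combos$c[i], "none")
    for (v in c(v_pos, v_neg, v_none)) {
      expect_type(v, "character")
      expect_gt(nchar(v), 0)
    }
    # determinism
    expect_identical(
      v_pos, infer_verdict(combos$d[i], combos$r[i], combos$c[i], "positive"))
    if (combos$c[i] == "high") {
      # sign resolution flips attraction <-> aversion, nothing else
      expect_match(v_pos, "attraction to the odorant")
      expect_match(v_neg, "aversion to the odorant")
      expect_identical(sub("attraction to the odorant",
                           "aversion to the odorant", v_pos, fixed = TRUE),
                       v_neg)
      expect_match(v_none, "attraction \\(positive chemotaxis index\\)")
    }
    verdicts <- c(verdicts, v_none)
  }
  # the 8 combinations map to 8 distinct statements
  expect_identical(length(unique(verdicts)), 8L)

  expect_match(infer_verdict("high", "high", "low"),
               "aversion to the origin on chemotaxis plates only and/or attraction to the vehicle",
               fixed = TRUE)
  expect_identical(
    infer_verdict("low", "low", "low"),
    "locomotion defect and/or attraction to the origin across all plates")
  expect_error(infer_verdict("medium", "high", "low"), "high.*or.*low")
  expect_error(infer_verdict("high", "high", "high", "up"), "ci_sign")
})

test_that("the decision chart recovers attraction and flips under mirror", {
  res <- run_decision_chart(good_experiment())
  expect_true(res$interpretable)
  expect_identical(res$verdict, "attraction to the odorant")
  expect_identical(res$ci_sign, "positive")
  expect_identical(res$control_regime, "uniform~2")
  expect_identical(nrow(res$per_arena), 4L)

  # mirroring every chemotaxis arena's counts negates all indices and
  # flips the verdict between attraction and aversion, nothing else
  mirrored <- good_experiment()
  chem <- mirrored$assay_type == "chemotaxis"
  cols <- c("c_left", "c_midleft", "c_midright", "c_right")
  mirrored[chem, cols] <- mirrored[chem, rev(cols)]
  res_m <- run_decision_chart(mirrored)
  expect_true(res_m$interpretable)
  expect_identical(res_m$verdict, "aversion to the odorant")
  expect_equal(res_m$medians$chemotaxis_index,
               -res$medians$chemotaxis_index)
  expect_identical(res_m$medians$response_ratio,
                   res$medians$response_ratio)
  expect_identical(res_m$medians$dispersal, res$medians$dispersal)
})

test_that("the chart refuses low worm counts regardless of metrics", {
  low_n <- good_experiment()
  cols <- c("c_left", "c_midleft", "c_midright", "c_right")
  low_n[low_n$assay_type == "chemotaxis", cols] <-
    matrix(rep(c(3L, 7L, 20L, 60L), each = 4), nrow = 4)  # 90 worms, CI 0.9
  res <- run_decision_chart(low_n)
  expect_false(res$interpretable)
  expect_null(res$verdict)
  expect_match(res$precondition_failures, "need > 100", all = FALSE)
})

test_that("lowering the dispersal threshold is monotone", {
  borderline <- good_experiment()
  borderline[1:2, c("c_left", "c_midleft", "c_midright", "c_right")] <-
    rep(c(20L, 55L, 55L, 20L), each = 2)  # control dispersal ~1.86
  thr_strict <- chemo_thresholds(dispersal_high_min = 1.9)
  thr_loose <- chemo_thresholds(dispersal_high_min = 1.8)
  expect_false(run_decision_chart(borderline, thr_strict)$interpretable)
  expect_true(run_decision_chart(borderline, thr_loose)$interpretable)
  # property: interpretable never becomes non-interpretable as the
  # threshold decreases
  ok <- vapply(seq(2, 0, by = -0.25), function(thr) {
    check_preconditions(
      borderline,
      thresholds = chemo_thresholds(dispersal_high_min = thr))$interpretable
  }, logical(1))
  expect_true(all(diff(ok) >= 0))  # once TRUE, stays TRUE
})

test_that("thresholds read from key:value files and reject junk", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "dispersal_high_min: 1.7",
               "min_worms = 51"), path)
  thr <- read_thresholds(path)
  expect_identical(thr$dispersal_high_min, 1.7)
  expect_identical(thr$min_worms, 51L)
  expect_identical(thr$ci_high_min_abs, 0.5)  # default retained
  writeLines("frobnicate: 3", path)
  expect_error(read_thresholds(path), "unknown threshold key")
  expect_error(chemo_thresholds(dispersal_high_min = 3), "dispersal")
})
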