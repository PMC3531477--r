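test_that("corrected intensity implements the local-background formula", {
  # pure-background region must vanish exactly
  expect_identical(corrected_intensity(list(A_s = 10, I_s = 50,
                                            A_l = 20, I_l = 100)), 0)
  # hand arithmetic of the printed formula
  expect_identical(corrected_intensity(list(A_s = 10, I_s = 150,
                                            A_l = 20, I_l = 200)), 100)
  expect_error(corrected_intensity(list(A_s = 10, I_s = 1,
                                        A_l = 10, I_l = 1)),
               "A_l must exceed A_s")
  expect_warning(
    out <- corrected_intensity(list(A_s = 10, I_s = 10, A_l = 20, I_l = 40)),
    "negative")
  expect_equal(out, -20)  # returned unclamped
})

test_that("adding a constant to every pixel leaves corrections unchanged", {
  set.seed(1)
  for (i in 1:25) {
    A_s <- sample(5:50, 1)
    A_l <- A_s + sample(5:40, 1)
    I_s <- stats::runif(1, 0, 1e4)
    I_l <- I_s + stats::runif(1, 0, 1e4)
    # negative corrections are legitimate inputs to this invariance
    base <- suppressWarnings(
      corrected_intensity(list(A_s = A_s, I_s = I_s, A_l = A_l, I_l = I_l)))
    cc <- stats::runif(1, -50, 50)
    shifted <- suppressWarnings(
      corrected_intensity(list(A_s = A_s, I_s = I_s + cc * A_s,
                               A_l = A_l, I_l = I_l + cc * A_l)))
    expect_equal(shifted, base, tolerance = 1e-9)
  }
})

test_that("corrected intensity recovers rendered ground-truth signals", {
  sc <- noise_free_spot_scene(seed = 12L)
  meas <- match_regions_to_truth(quantify_scene(sc), sc$spots)
  expect_equal(nrow(meas), nrow(sc$spots))
  expect_true(all(abs(meas$corrected / meas$true_signal - 1) < 0.01))
})

test_that("cell totals obey the ploidy identity", {
  meas <- data.frame(nucleus_id = c(1, 1, 2), corrected = c(40, 60, 7))
  ct <- cell_total(meas, 1, ploidy = 4)
  expect_equal(ct$total_corrected_intensity, 100)
  expect_equal(ct$per_genome_intensity, 25)
  expect_identical(ct$per_genome_intensity * ct$ploidy,
                   ct$total_corrected_intensity)
  expect_equal(cell_total(meas, 2, ploidy = 1)$total_corrected_intensity, 7)
  # equal per-genome values in a 4C spermatocyte vs a 1C daughter: 4:1 totals
  s4 <- cell_total(data.frame(nucleus_id = 1, corrected = 100), 1, ploidy = 4)
  t2 <- cell_total(data.frame(nucleus_id = 1, corrected = 25), 1, ploidy = 1)
  expect_equal(s4$per_genome_intensity, t2$per_genome_intensity)
  expect_equal(s4$total_corrected_intensity / t2$total_corrected_intensity, 4)
  expect_error(cell_total(meas, 99), "lookup error")
})

test_that("within-cell normalization sums to exactly 100 per nucleus", {
  expect_equal(normalize_within_cell(c(25, 25, 25, 25)), rep(25, 4))
  expect_equal(normalize_within_cell(c(2, 1, 1)), c(50, 25, 25))
  df <- data.frame(nucleus_id = rep(1:3, each = 4),
                   corrected = stats::runif(12, 1, 50))
  out <- normalize_within_cell(df)
  sums <- tapply(out$relative_pct, out$nucleus_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_error(normalize_within_cell(c(-1, 0.5)), "empty-cell normalization")
})

test_that("control normalization maps the control mean to exactly 100", {
  expect_equal(normalize_to_control(10, c(10, 30)), 50)
  ctrl <- stats::rlnorm(20, 3)
  expect_equal(mean(normalize_to_control(ctrl, ctrl)), 100)
  expect_error(normalize_to_control(1, numeric(0)), "empty control")
})

test_that("chromosome assignment matches generator labels on S5 scenes", {
  bench <- s5_benchmark()
  spots <- bench$spots
  expect_gte(nrow(spots), 100L)
  agreement <- mean(spots$chromosome_class == spots$true_class)
  expect_gte(agreement, 0.95)
})

test_that("assignment handles missing landmarks and merged X/4 clusters", {
  regions <- data.frame(nucleus_id = 1, row = c(10, 30, 50), col = 10,
                        corrected = c(5, 5, 5))
  no_lm <- data.frame(nucleus_id = integer(0), landmark_class = character(0),
                      row = numeric(0), col = numeric(0))
  expect_equal(assign_chromosomes(regions, no_lm),
               rep("unassigned", 3))
  # one cluster is nearest to both the chr4 dot and the X region: excluded
  merged <- data.frame(nucleus_id = 1,
                       landmark_class = c("bright_dot_chr4",
                                          "irregular_X_region"),
                       row = c(8, 12), col = c(10, 10))
  cls <- assign_chromosomes(regions, merged)
  expect_equal(cls[1], "unassigned")
  expect_false("pair4" %in% cls)
  expect_false("X" %in% cls)
})

test_that("the outlier rule matches exhaustive brute force on all positions", {
  expect_equal(identify_intensity_outlier(c(1, 1, 1, 2.2), 1.5), 4L)
  expect_true(is.na(identify_intensity_outlier(c(1, 1, 1, 1), 1.5)))
  # the 2-fold Y signal among eight values is always flagged, at any position
  brute <- function(v, thr) {
    best <- which.max(v)
    if (v[best] > thr * stats::median(v[-best])) best else NA_integer_
  }
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    v <- stats::runif(n, 0.8, 1.2)
    if (rep %% 2 == 0) v[sample(n, 1)] <- 2 * stats::median(v)
    expect_identical(identify_intensity_outlier(v, 1.5), brute(v, 1.5))
  }
  for (pos in 1:8) {
    v <- rep(1, 8); v[pos] <- 2
    expect_identical(identify_intensity_outlier(v, 1.5), pos)
  }
  expect_error(identify_intensity_outlier(c(1, 2), 1.5), "at least 3")
})

test_that("group comparison matches the closed-form Welch t statistic", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$fold_change, 1)
  expect_equal(same$p_value, 1)

  a <- c(10, 10, 10, 10); b <- c(20, 20, 20, 21)
  res <- compare_groups(a, b)
  expect_equal(res$fold_change, 2.025)
  # closed-form oracle: t = dm / sqrt(va/na + vb/nb), Welch-Satterthwaite df
  va <- stats::var(a) / 4; vb <- stats::var(b) / 4
  tstat <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / 3 + vb^2 / 3)
  expect_equal(res$p_value, 2 * stats::pt(-abs(tstat), df), tolerance = 1e-9)
  expect_lt(res$p_value, 0.001)

  # zero variance in both groups
  expect_equal(compare_groups(c(5, 5), c(5, 5))$p_value, 1)
  expect_equal(compare_groups(c(5, 5), c(6, 6))$p_value, 0)
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})

test_that("well-separated groups are essentially always detected", {
  set.seed(7)
  reject <- vapply(1:200, function(i) {
    a <- stats::rnorm(10); b <- stats::rnorm(10, mean = 5)
    compare_groups(a, b)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(reject), 0.99)
})
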