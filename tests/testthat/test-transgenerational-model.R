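test_that("germline passes apply the sex-specific loading step", {
  p <- germline_params(a_m = 10, a_f = 10)
  expect_equal(germline_pass(100, "male", p), 110)
  expect_equal(germline_pass(100, "female", p), 90)
  expect_warning(out <- germline_pass(5, "female", p), "floored")
  expect_equal(out, 0)
  p0 <- germline_params(a_m = 0, a_f = 0)
  expect_equal(germline_pass(123, "male", p0), 123)
  expect_equal(germline_pass(123, "female", p0), 123)
  pm <- germline_params(mode = "multiplicative", male_factor = 1.2,
                        female_factor = 0.8)
  expect_equal(germline_pass(100, "male", pm), 120)
  expect_equal(germline_pass(100, "female", pm), 80)
})

test_that("symmetric additive loading stabilizes the parental difference", {
  p <- germline_params(L0 = 100, a_m = 10, a_f = 10)
  g1 <- advance_autosomes(100, 100, p)
  expect_equal(c(g1$P, g1$M), c(110, 90))
  g2 <- advance_autosomes(g1$P, g1$M, p)
  expect_equal(c(g2$P, g2$M), c(110, 90))  # stable from generation 1 on
  traj <- autosome_trajectory(p, 10)
  expect_true(all(traj$difference[-1] == 20))
  expect_true(all(traj$mean == 100))  # conservation of the autosomal mean
  expect_lte(stabilization_generation(p), 2L)
  # zero increments: already stable at founding
  expect_equal(stabilization_generation(germline_params(a_m = 0, a_f = 0)),
               0L)
})

test_that("multiplicative symmetric loading keeps the mean and fixes the CV", {
  delta <- 0.1
  p <- germline_params(mode = "multiplicative", male_factor = 1 + delta,
                       female_factor = 1 - delta)
  traj <- autosome_trajectory(p, 8)
  expect_equal(traj$mean, rep(100, 9), tolerance = 1e-12)
  # difference/mean settles at 2*delta from generation 1
  expect_equal(traj$difference[-1] / traj$mean[-1], rep(2 * delta, 8),
               tolerance = 1e-12)
  expect_lte(stabilization_generation(p), 2L)
})

test_that("asymmetric multiplicative growth is reported as non-convergent", {
  p <- germline_params(mode = "multiplicative", male_factor = 1.3,
                       female_factor = 0.9)
  expect_error(stabilization_generation(p, horizon = 15), "non-convergent")
})

test_that("Y increases monotonically iff the male germline overloads", {
  p <- germline_params(L0 = 100, a_m = 10, a_f = 10)
  expect_equal(y_trajectory(p, 3), c(110, 120, 130))
  expect_equal(y_trajectory(germline_params(a_m = 0), 5), rep(100, 5))
  expect_true(all(diff(y_trajectory(p, 10)) > 0))
  pm <- germline_params(mode = "multiplicative", male_factor = 1.05)
  expect_true(all(diff(y_trajectory(pm, 10)) > 0))
  expect_true(all(diff(y_trajectory(
    germline_params(mode = "multiplicative", male_factor = 1), 5)) == 0))
})

test_that("X drifts down by a/3 per generation and the class order holds", {
  expect_equal(x_expected_trajectory(germline_params(a_m = 9, a_f = 9), 3),
               c(97, 94, 91))
  expect_equal(x_expected_trajectory(germline_params(a_m = 0, a_f = 0), 4),
               rep(100, 4))
  # symmetric a > 0, t >= 1: X expected < autosome mean < Y
  for (a in c(2, 10, 25)) {
    p <- germline_params(a_m = a, a_f = a)
    n <- 8
    xs <- x_expected_trajectory(p, n)
    ys <- y_trajectory(p, n)
    ms <- autosome_trajectory(p, n)$mean[-1]
    expect_true(all(xs < ms & ms < ys))
  }
})

test_that("perturbations scale lineage levels and mixing is arithmetic", {
  st <- lineage_state(100, "Y", "paternal", 1)
  expect_equal(apply_perturbation(st, 0.33)$level, 33)
  expect_equal(apply_perturbation(st, 1)$level, 100)
  expect_equal(apply_perturbation(st, 7)$level, 700)
  expect_equal(apply_perturbation(st, 7)$chromosome_class, "Y")
  expect_error(apply_perturbation(st, 0), "factor")
  expect_equal(embryo_mix(1, 1), 1)
  expect_equal(embryo_mix(0.5, 1), 0.75)
  expect_equal(embryo_mix(0, 1), 0.5)  # gynogenetic-haploid limit
})

test_that("template maintenance never restores or creates centromeric protein", {
  expect_equal(template_maintenance(0.71, 20), 0.71)
  expect_equal(template_maintenance(0, 50), 0)
  expect_equal(template_maintenance(1.7, 0), 1.7)
  # with germline passes, restoration is exactly a_m per male-line generation
  p <- germline_params(a_m = 10, a_f = 10)
  depleted <- 33
  restored <- germline_pass(template_maintenance(depleted, 20), "male", p)
  expect_equal(restored - depleted, p$a_m)
})

test_that("stochastic lineage means match deterministic expectations", {
  p <- germline_params(L0 = 100, a_m = 10, a_f = 10)
  n_gen <- 6L; n_lin <- 10000L
  traj <- autosome_trajectory(p, n_gen)
  expected <- list(autosome = traj$mean[n_gen + 1],
                   X = x_expected_trajectory(p, n_gen)[n_gen],
                   Y = y_trajectory(p, n_gen)[n_gen])
  for (cl in names(expected)) {
    draws <- sample_lineages(p, n_gen, n_lin, cl, seed = 99L)
    final <- draws[, n_gen]
    se <- stats::sd(final) / sqrt(n_lin)
    if (se == 0) {
      expect_equal(mean(final), expected[[cl]])
    } else {
      expect_lt(abs(mean(final) - expected[[cl]]), 3 * se)
    }
  }
  # determinism of the sampler
  expect_identical(sample_lineages(p, 3, 100, "X", seed = 5L),
                   sample_lineages(p, 3, 100, "X", seed = 5L))
})
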