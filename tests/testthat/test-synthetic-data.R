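test_that("identical config and seed give bit-identical scenes", {
  cfg <- scene_config("spermatocyte_S5", image_size = c(256L, 256L),
                      n_nuclei = 1L, seed = 42L)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$gfp_image, b$gfp_image)
  expect_identical(a$dna_image, b$dna_image)
  expect_identical(a$spots, b$spots)
  expect_identical(a$dna_landmarks, b$dna_landmarks)
  c2 <- generate_scene(scene_config("spermatocyte_S5",
                                    image_size = c(256L, 256L),
                                    n_nuclei = 1L, seed = 43L))
  expect_false(identical(a$gfp_image, c2$gfp_image))
})

test_that("rendered mass is conserved without noise or background", {
  cfg <- scene_config("sperm", image_size = c(64L, 64L), n_nuclei = 1L,
                      base_intensity = 250, background_level = 0,
                      diffuse_nuclear_level = 0, noise_sd = 0, seed = 2L)
  sc <- generate_scene(cfg)
  expect_equal(sum(sc$spots$true_signal), 1000)  # 4 centromere units
  expect_lt(abs(sum(sc$gfp_image) - 1000) / 1000, 0.001)

  # multi-nucleus scene with background and diffuse signal subtracted out
  cfg2 <- scene_config("spermatocyte_S5", image_size = c(400L, 400L),
                       n_nuclei = 4L, noise_sd = 0, seed = 5L)
  sc2 <- generate_scene(cfg2)
  bg <- cfg2$background_level * length(sc2$gfp_image) +
    cfg2$diffuse_nuclear_level * sum(sc2$nucleus_masks > 0)
  rendered <- sum(sc2$gfp_image) - bg
  expect_lt(abs(rendered - sum(sc2$spots$true_signal)) /
              sum(sc2$spots$true_signal), 0.005)
})

test_that("sperm spot-count frequencies follow the clustering distribution", {
  probs <- c(`4` = 0.46, `3` = 0.42, `2` = 0.12)
  n_total <- 0L
  counts <- c(`4` = 0L, `3` = 0L, `2` = 0L)
  for (s in 1:12) {
    sc <- generate_scene(scene_config("sperm", n_nuclei = 100L,
                                      noise_sd = 0, seed = 100L + s))
    k <- table(sc$spots$nucleus_id)
    n_total <- n_total + length(k)
    tk <- table(factor(k, levels = c("4", "3", "2")))
    counts <- counts + as.integer(tk)
  }
  expect_gte(n_total, 1000L)
  for (lvl in names(probs)) {
    se <- sqrt(probs[[lvl]] * (1 - probs[[lvl]]) / n_total)
    expect_lt(abs(counts[[lvl]] / n_total - probs[[lvl]]), 3 * se)
  }
})

test_that("scene invariants hold: spots inside masks, S5 territory layout", {
  for (stage in c("sperm", "spermatocyte_S5", "embryo_metaphase")) {
    sc <- generate_scene(scene_config(stage, n_nuclei = 2L,
                                      image_size = c(384L, 384L), seed = 9L))
    expect_true(all(sc$spots$true_signal > 0))
    idx <- cbind(round(sc$spots$row), round(sc$spots$col))
    expect_true(all(sc$nucleus_masks[idx] == sc$spots$nucleus_id))
  }
  sc <- generate_scene(scene_config("spermatocyte_S5", n_nuclei = 3L,
                                    image_size = c(512L, 512L), seed = 21L))
  for (nuc in 1:3) {
    cls <- sc$spots$chromosome_class[sc$spots$nucleus_id == nuc]
    expect_equal(sum(cls == "A2or3"), 4L)
    expect_equal(sum(cls == "pair4"), 1L)
    expect_equal(sum(cls == "X"), 1L)
    expect_equal(sum(cls == "Y"), 1L)
    lmc <- sc$dna_landmarks$landmark_class[sc$dna_landmarks$nucleus_id == nuc]
    expect_equal(sum(lmc == "homogeneous_territory"), 2L)
    expect_equal(sum(lmc == "bright_dot_chr4"), 1L)
    expect_equal(sum(lmc == "irregular_X_region"), 1L)
  }
})

test_that("layouts that cannot fit raise a scene overflow error", {
  expect_error(generate_scene(scene_config("spermatocyte_S5",
                                           image_size = c(64L, 64L),
                                           n_nuclei = 1L)),
               "scene overflow")
  expect_error(generate_scene(scene_config("sperm", image_size = c(64L, 64L),
                                           n_nuclei = 30L)),
               "scene overflow")
})

test_that("scene files round trip through TIFF + CSV", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(scene_config("spermatocyte_S5", n_nuclei = 1L,
                                    image_size = c(256L, 256L), seed = 7L))
  write_scene(sc, dir)
  back <- read_scene(dir)
  expect_identical(back$gfp_image, round(sc$gfp_image))
  expect_identical(back$dna_image, round(sc$dna_image))
  expect_identical(back$nucleus_masks, sc$nucleus_masks + 0)
  expect_equal(back$spots$true_signal, sc$spots$true_signal)
  expect_equal(back$spots$row, sc$spots$row, tolerance = 1e-12)
  expect_equal(back$config$seed, 7)
  expect_equal(back$config$stage, "spermatocyte_S5")
  # writing the re-read scene again is byte-identical (integer fixed point)
  dir2 <- withr::local_tempdir()
  sc2 <- sc
  sc2$gfp_image <- back$gfp_image
  sc2$dna_image <- back$dna_image
  write_scene(sc2, dir2)
  expect_identical(readBin(file.path(dir, "scene_gfp.tif"), "raw", 1e7),
                   readBin(file.path(dir2, "scene_gfp.tif"), "raw", 1e7))
})

test_that("degenerate and overflowing scenes still write valid artifacts", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(scene_config("sperm", n_nuclei = 1L,
                                    image_size = c(64L, 64L), seed = 3L))
  sc$spots <- sc$spots[0, , drop = FALSE]  # empty spot table is not an error
  write_scene(sc, dir)
  back <- read_scene(dir)
  expect_equal(nrow(back$spots), 0L)
  # 16-bit overflow propagates the dynamic-range error
  sc$gfp_image[1, 1] <- 1e6
  expect_error(write_scene(sc, withr::local_tempdir()), "dynamic-range")
})

test_that("cross panels scale only the paternal half-set", {
  base <- scene_config("embryo_metaphase", image_size = c(256L, 256L),
                       n_nuclei = 4L, noise_sd = 0, seed = 30L)
  panel1 <- generate_cross_panel(1, 2, base)
  panel05 <- generate_cross_panel(0.5, 2, base)
  panel7 <- generate_cross_panel(7, 2, base)
  t1 <- do.call(rbind, lapply(panel1, `[[`, "spots"))
  t05 <- do.call(rbind, lapply(panel05, `[[`, "spots"))
  t7 <- do.call(rbind, lapply(panel7, `[[`, "spots"))
  mean_by <- function(tab, origin) {
    mean(tab$true_signal[tab$parental_origin == origin])
  }
  expect_equal(mean_by(t1, "paternal"), mean_by(t1, "maternal"))
  expect_equal(mean_by(t05, "paternal") / mean_by(t05, "maternal"), 0.5)
  # per-nucleus total at factor f is (f + 1) / 2 of the unperturbed total
  expect_equal(sum(t7$true_signal) / sum(t1$true_signal), (7 + 1) / 2)
  expect_error(generate_cross_panel(0, 1, base), "father_perturbation")
})
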