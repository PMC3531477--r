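# Synthetic two-channel microscopy scenes with ground truth.
#
# Scenes emulate maximum-projected squash preparations: a GFP channel with
# centromeric CenH3 spots rendered as pixel-integrated isotropic Gaussians,
# and a DNA channel carrying the stage-specific chromatin landmarks used for
# chromosome assignment. All randomness is governed by `config$seed`.

STAGE_LEVELS <- c("sperm", "spermatocyte_S5", "embryo_metaphase", "wing_disc")

# Nucleus radii (px) per stage; spermatocytes are large cells with three
# chromosome territories, sperm nuclei are small with unclustered centromeres.
STAGE_RADIUS <- c(sperm = 10, spermatocyte_S5 = 80,
                  embryo_metaphase = 40, wing_disc = 14)
STAGE_DEFAULT_N <- c(sperm = 24, spermatocyte_S5 = 4,
                     embryo_metaphase = 9, wing_disc = 16)
DNA_NUCLEAR_LEVEL <- 300  # a.u. per pixel of generic nuclear DNA staining

#' Configuration for a synthetic scene
#'
#' Bundles and validates all generator parameters. Intensity scale and SNR
#' are calibration choices (real preparations publish neither): the defaults
#' put one centromere unit at 20000 a.u. integrated signal over a
#' `spot_sigma = 2` px point-spread function, on a 100 a.u. background with
#' 8 a.u. Gaussian noise and a dim diffuse nuclear GFP pool.
#'
#' @param stage One of `"sperm"`, `"spermatocyte_S5"`, `"embryo_metaphase"`,
#'   `"wing_disc"`.
#' @param image_size Integer `(height, width)`, each at least 64.
#' @param spot_sigma Gaussian PSF standard deviation in pixels (> 0).
#' @param base_intensity Integrated signal of one centromere unit (a.u.).
#' @param relative_intensity_map Named multipliers per chromosome class. The
#'   default encodes the elevated Y centromere (2x) and the paired
#'   chromosome-4 centromeres (2 units in one spot) seen in S5 spermatocytes.
#' @param background_level Constant background (a.u. per pixel).
#' @param diffuse_nuclear_level Diffuse GFP level inside nuclei (a.u./px).
#' @param noise_sd Standard deviation of additive Gaussian noise (a.u.),
#'   clipped at zero.
#' @param n_nuclei Number of nuclei; stage-specific default.
#' @param clustering_probabilities Distribution of the number of resolvable
#'   sperm spots, named by spot count. Default is the observed 46%/42%/12%
#'   frequency of 4/3/2 signals in mature sperm.
#' @param paternal_factor Multiplier applied to paternal half-set signals in
#'   embryo scenes (used by [generate_cross_panel()]).
#' @param seed Integer seed driving all scene randomness.
#' @return An object of class `scene_config`.
#' @export
#' @examples
#' cfg <- scene_config("sperm", n_nuclei = 4, seed = 7)
#' sc <- generate_scene(cfg)
#' head(sc$spots)
scene_config <- function(stage,
                         image_size = c(512L, 512L),
                         spot_sigma = 2,
                         base_intensity = 20000,
                         relative_intensity_map = c(A2or3 = 1, pair4 = 2,
                                                    X = 1, Y = 2,
                                                    unassigned = 1),
                         background_level = 100,
                         diffuse_nuclear_level = 8,
                         noise_sd = 8,
                         n_nuclei = NULL,
                         clustering_probabilities = c(`4` = 0.46, `3` = 0.42,
                                                      `2` = 0.12),
                         paternal_factor = 1,
                         seed = 1L) {
  stage <- match.arg(stage, STAGE_LEVELS)
  if (length(image_size) != 2L || any(image_size < 64)) {
    stop_param("parameter error: image_size must be (height, width) >= 64x64")
  }
  check_scalar_number(spot_sigma, "spot_sigma", lower = 0, strict_lower = TRUE)
  check_scalar_number(base_intensity, "base_intensity", lower = 0)
  check_scalar_number(background_level, "background_level", lower = 0)
  check_scalar_number(diffuse_nuclear_level, "diffuse_nuclear_level", lower = 0)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(paternal_factor, "paternal_factor",
                      lower = 0, strict_lower = TRUE)
  if (any(relative_intensity_map < 0)) {
    stop_param("parameter error: relative_intensity_map must be nonnegative")
  }
  n_nuclei <- n_nuclei %||% STAGE_DEFAULT_N[[stage]]
  check_scalar_number(n_nuclei, "n_nuclei", lower = 1)
  if (is.null(names(clustering_probabilities)) ||
      any(clustering_probabilities < 0) ||
      abs(sum(clustering_probabilities) - 1) > 1e-8) {
    stop_param("parameter error: clustering_probabilities must be named ",
               "spot-count probabilities summing to 1")
  }
  structure(list(
    stage = stage,
    image_size = as.integer(image_size),
    spot_sigma = spot_sigma,
    base_intensity = base_intensity,
    relative_intensity_map = relative_intensity_map,
    background_level = background_level,
    diffuse_nuclear_level = diffuse_nuclear_level,
    noise_sd = noise_sd,
    n_nuclei = as.integer(n_nuclei),
    clustering_probabilities = clustering_probabilities,
    paternal_factor = paternal_factor,
    seed = as.integer(seed)
  ), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>", x$stage, "\n",
      " image:", paste(x$image_size, collapse = "x"),
      " nuclei:", x$n_nuclei, " seed:", x$seed, "\n",
      " psf sigma:", x$spot_sigma, "px  unit signal:", x$base_intensity,
      " bg:", x$background_level, " noise sd:", x$noise_sd, "\n")
  invisible(x)
}

# Add a pixel-integrated isotropic Gaussian of total mass `mass` centered at
# (row, col) (1-based, may be fractional). The per-pixel weight is the exact
# integral of the Gaussian over the pixel square, so the rendered mass equals
# `mass` up to window truncation (< 1e-5 at 5 sigma).
render_blob <- function(img, row, col, sigma, mass) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(5 * sigma)
  rows <- max(1L, floor(row - r)):min(h, ceiling(row + r))
  cols <- max(1L, floor(col - r)):min(w, ceiling(col + r))
  if (!length(rows) || !length(cols)) return(img)
  wr <- stats::pnorm((rows + 0.5 - row) / sigma) -
    stats::pnorm((rows - 0.5 - row) / sigma)
  wc <- stats::pnorm((cols + 0.5 - col) / sigma) -
    stats::pnorm((cols - 0.5 - col) / sigma)
  img[rows, cols] <- img[rows, cols] + mass * (wr %o% wc)
  img
}

disk_mask_indices <- function(h, w, row, col, radius) {
  rows <- max(1L, floor(row - radius)):min(h, ceiling(row + radius))
  cols <- max(1L, floor(col - radius)):min(w, ceiling(col + radius))
  grid <- expand.grid(r = rows, c = cols)
  keep <- (grid$r - row)^2 + (grid$c - col)^2 <= radius^2
  (grid$c[keep] - 1L) * h + grid$r[keep]
}

# Partition 4 sperm centromeres into k non-empty resolvable clusters.
partition_members <- function(n_members, k) {
  repeat {
    assign <- sample.int(k, n_members, replace = TRUE)
    if (length(unique(assign)) == k) return(assign)
  }
}

ring_points <- function(center, radius, n, rot = stats::runif(1, 0, 2 * pi)) {
  ang <- rot + 2 * pi * (seq_len(n) - 1) / n
  cbind(row = center[1] + radius * sin(ang),
        col = center[2] + radius * cos(ang))
}

empty_spots <- function() {
  data.frame(nucleus_id = integer(0), spot_id = integer(0),
             chromosome_class = character(0), row = numeric(0),
             col = numeric(0), true_signal = numeric(0),
             parental_origin = character(0), n_members = integer(0),
             stringsAsFactors = FALSE)
}

empty_landmarks <- function() {
  data.frame(nucleus_id = integer(0), landmark_class = character(0),
             row = numeric(0), col = numeric(0), stringsAsFactors = FALSE)
}

spot_row <- function(nucleus_id, class, pos, signal,
                     origin = NA_character_, n_members = 1L) {
  data.frame(nucleus_id = nucleus_id, spot_id = NA_integer_,
             chromosome_class = class, row = pos[1], col = pos[2],
             true_signal = signal, parental_origin = origin,
             n_members = as.integer(n_members), stringsAsFactors = FALSE)
}

# Stage-specific layout of one nucleus: spots, DNA landmarks and DNA blobs.
layout_nucleus <- function(stage, nucleus_id, center, radius, config) {
  unit <- config$base_intensity
  rel <- config$relative_intensity_map
  spots <- empty_spots(); landmarks <- empty_landmarks()
  dna_blobs <- data.frame(row = numeric(0), col = numeric(0),
                          sigma = numeric(0), mass = numeric(0))
  if (stage == "sperm") {
    counts <- as.integer(names(config$clustering_probabilities))
    k <- sample(counts, 1L, prob = config$clustering_probabilities)
    assign <- partition_members(4L, k)
    pos <- ring_points(center, 0.55 * radius, k)
    for (j in seq_len(k)) {
      size <- sum(assign == j)
      spots <- rbind(spots, spot_row(nucleus_id, "unassigned", pos[j, ],
                                     size * unit * rel[["unassigned"]],
                                     n_members = size))
    }
  } else if (stage == "spermatocyte_S5") {
    terr <- ring_points(center, 0.55 * radius, 3)
    # two major-autosome territories: two spots each, homogeneous DNA
    for (t in 1:2) {
      dir <- stats::runif(1, 0, 2 * pi)
      off <- 12 * c(sin(dir), cos(dir))
      for (s in c(-1, 1)) {
        spots <- rbind(spots, spot_row(nucleus_id, "A2or3",
                                       terr[t, ] + s * off,
                                       unit * rel[["A2or3"]]))
      }
      landmarks <- rbind(landmarks, data.frame(
        nucleus_id = nucleus_id, landmark_class = "homogeneous_territory",
        row = terr[t, 1], col = terr[t, 2], stringsAsFactors = FALSE))
      dna_blobs <- rbind(dna_blobs, data.frame(
        row = terr[t, 1], col = terr[t, 2], sigma = 18, mass = 60000))
    }
    # X-Y-4 territory: paired-4 spot next to a bright DNA dot, X spot near an
    # irregular weaker DNA region, Y spot (elevated) with no DNA landmark
    xy4 <- ring_points(terr[3, ], 16, 3)
    p4 <- xy4[1, ]; px <- xy4[2, ]; py <- xy4[3, ]
    spots <- rbind(spots,
                   spot_row(nucleus_id, "pair4", p4, unit * rel[["pair4"]]),
                   spot_row(nucleus_id, "X", px, unit * rel[["X"]]),
                   spot_row(nucleus_id, "Y", py, unit * rel[["Y"]]))
    a4 <- stats::runif(1, 0, 2 * pi)
    d4 <- p4 + 5 * c(sin(a4), cos(a4))
    dx <- px + stats::runif(2, -3, 3)
    landmarks <- rbind(landmarks,
      data.frame(nucleus_id = nucleus_id, landmark_class = "bright_dot_chr4",
                 row = d4[1], col = d4[2], stringsAsFactors = FALSE),
      data.frame(nucleus_id = nucleus_id, landmark_class = "irregular_X_region",
                 row = dx[1], col = dx[2], stringsAsFactors = FALSE))
    dna_blobs <- rbind(dna_blobs,
      data.frame(row = d4[1], col = d4[2], sigma = 2, mass = 25000),
      data.frame(row = dx[1] + stats::runif(3, -4, 4),
                 col = dx[2] + stats::runif(3, -4, 4),
                 sigma = 4, mass = 5000))
  } else if (stage == "embryo_metaphase") {
    # gonomeric-style plate: paternal half-set on one semicircle,
    # maternal on the other
    pos <- ring_points(center, 24, 8)
    origin <- rep(c("paternal", "maternal"), each = 4)
    fac <- ifelse(origin == "paternal", config$paternal_factor, 1)
    for (j in 1:8) {
      spots <- rbind(spots, spot_row(nucleus_id, "unassigned", pos[j, ],
                                     unit * rel[["unassigned"]] * fac[j],
                                     origin = origin[j]))
    }
  } else {  # wing_disc: chromocenter-clustered centromeres, one merged spot
    jitter <- stats::runif(2, -2, 2)
    spots <- rbind(spots, spot_row(nucleus_id, "unassigned", center + jitter,
                                   8 * unit * rel[["unassigned"]],
                                   n_members = 8L))
  }
  list(spots = spots, landmarks = landmarks, dna_blobs = dna_blobs)
}

#' Generate a synthetic ground-truth scene
#'
#' Renders a two-channel scene (GFP + DNA) for the configured stage, drawing
#' every random quantity from `config$seed`: identical configurations give
#' bit-identical scenes. Spots are isotropic Gaussians whose rendered mass
#' equals their `true_signal`; the DNA channel carries the landmarks used by
#' [assign_chromosomes()] (bright chromosome-4 dot, weaker irregular X
#' region, homogeneous major-autosome territories).
#'
#' @param config A [scene_config()].
#' @return An object of class `ground_truth_scene` with elements
#'   `gfp_image`, `dna_image`, `spots` (ground-truth table), `nucleus_masks`
#'   (integer label matrix), `dna_landmarks`, and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$image_size[1]; w <- config$image_size[2]
  radius <- STAGE_RADIUS[[config$stage]]
  g <- ceiling(sqrt(config$n_nuclei))
  cell_h <- floor(h / g); cell_w <- floor(w / g)
  if (min(cell_h, cell_w) < 2 * (radius + 6)) {
    stop_param("scene overflow: ", config$n_nuclei, " ", config$stage,
               " nuclei (radius ", radius, " px) do not fit in ",
               h, "x", w)
  }
  with_seed(config$seed, {
    gfp <- matrix(config$background_level, h, w)
    dna <- matrix(config$background_level, h, w)
    masks <- matrix(0L, h, w)
    spots <- empty_spots(); landmarks <- empty_landmarks()
    slack_h <- cell_h / 2 - radius - 6; slack_w <- cell_w / 2 - radius - 6
    for (i in seq_len(config$n_nuclei)) {
      gr <- (i - 1) %/% g; gc <- (i - 1) %% g
      center <- c(gr * cell_h + cell_h / 2 + stats::runif(1, -slack_h, slack_h),
                  gc * cell_w + cell_w / 2 + stats::runif(1, -slack_w, slack_w))
      idx <- disk_mask_indices(h, w, center[1], center[2], radius)
      masks[idx] <- i
      gfp[idx] <- gfp[idx] + config$diffuse_nuclear_level
      dna[idx] <- dna[idx] + DNA_NUCLEAR_LEVEL
      lay <- layout_nucleus(config$stage, i, center, radius, config)
      for (j in seq_len(nrow(lay$spots))) {
        gfp <- render_blob(gfp, lay$spots$row[j], lay$spots$col[j],
                           config$spot_sigma, lay$spots$true_signal[j])
      }
      for (j in seq_len(nrow(lay$dna_blobs))) {
        dna <- render_blob(dna, lay$dna_blobs$row[j], lay$dna_blobs$col[j],
                           lay$dna_blobs$sigma[j], lay$dna_blobs$mass[j])
      }
      spots <- rbind(spots, lay$spots)
      landmarks <- rbind(landmarks, lay$landmarks)
    }
    if (nrow(spots)) spots$spot_id <- seq_len(nrow(spots))
    if (config$noise_sd > 0) {
      gfp <- gfp + stats::rnorm(h * w, sd = config$noise_sd)
      dna <- dna + stats::rnorm(h * w, sd = config$noise_sd)
    }
    gfp[gfp < 0] <- 0
    dna[dna < 0] <- 0
    structure(list(gfp_image = gfp, dna_image = dna, spots = spots,
                   nucleus_masks = masks, dna_landmarks = landmarks,
                   config = config),
              class = "ground_truth_scene")
  })
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat("<ground_truth_scene>", x$config$stage, "\n",
      " image:", paste(dim(x$gfp_image), collapse = "x"),
      " nuclei:", x$config$n_nuclei,
      " spots:", nrow(x$spots), " seed:", x$config$seed, "\n")
  invisible(x)
}

#' Generate an embryo panel with a perturbed paternal contribution
#'
#' Produces embryo-metaphase scenes in which the paternal half-set of
#' centromeric signals is scaled by `father_perturbation` (e.g. 0.33 or 0.5
#' for sperm depletion, 7 for overexpression) while the maternal half-set is
#' untouched. Ground truth records each spot's parental origin. Scene `i`
#' uses seed `config$seed + i - 1`.
#'
#' @param father_perturbation Multiplicative factor (> 0) on paternal signals.
#' @param n_embryos Number of scenes to generate.
#' @param config Base [scene_config()]; the stage is forced to
#'   `"embryo_metaphase"`.
#' @return List of `ground_truth_scene` objects.
#' @export
generate_cross_panel <- function(father_perturbation, n_embryos, config) {
  check_scalar_number(father_perturbation, "father_perturbation",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(n_embryos, "n_embryos", lower = 1)
  lapply(seq_len(n_embryos), function(i) {
    cfg <- config
    cfg$stage <- "embryo_metaphase"
    cfg$paternal_factor <- father_perturbation
    cfg$seed <- config$seed + i - 1L
    generate_scene(cfg)
  })
}

#' Write a scene to disk
#'
#' Writes the GFP and DNA channels and the nucleus label image as 16-bit
#' TIFFs (values rounded to integers; out-of-range values raise a
#' dynamic-range error), the ground-truth and landmark tables as CSV, and
#' the configuration as a `key: value` text file. Coordinates in the CSV
#' files are 0-based `(row, col)` with origin top-left, as documented in
#' their header comments.
#'
#' @param scene A `ground_truth_scene`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix, default `"scene"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  stopifnot(inherits(scene, "ground_truth_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(suffix) file.path(dir, paste0(prefix, "_", suffix))
  paths <- c(gfp = p("gfp.tif"), dna = p("dna.tif"), nuclei = p("nuclei.tif"),
             truth = p("truth.csv"), landmarks = p("landmarks.csv"),
             config = p("config.cfg"))
  write_tiff16(scene$gfp_image, paths[["gfp"]])
  write_tiff16(scene$dna_image, paths[["dna"]])
  write_tiff16(scene$nucleus_masks, paths[["nuclei"]])

  truth <- scene$spots
  if (nrow(truth)) {
    truth$row <- truth$row - 1
    truth$col <- truth$col - 1
  }
  hdr <- c("# ground truth spots; row/col are 0-based pixel coordinates,",
           "# (row, col) order, origin at the top-left image corner")
  con <- file(paths[["truth"]], "w")
  writeLines(hdr, con)
  utils::write.csv(truth, con, row.names = FALSE)
  close(con)

  lm <- scene$dna_landmarks
  if (nrow(lm)) {
    lm$row <- lm$row - 1
    lm$col <- lm$col - 1
  }
  con <- file(paths[["landmarks"]], "w")
  writeLines(hdr[2], con)
  utils::write.csv(lm, con, row.names = FALSE)
  close(con)

  cfg <- scene$config
  write_config(list(
    stage = cfg$stage,
    image_size = cfg$image_size,
    spot_sigma = cfg$spot_sigma,
    base_intensity = cfg$base_intensity,
    relative_intensity_map = cfg$relative_intensity_map,
    background_level = cfg$background_level,
    diffuse_nuclear_level = cfg$diffuse_nuclear_level,
    noise_sd = cfg$noise_sd,
    n_nuclei = cfg$n_nuclei,
    clustering_probabilities = cfg$clustering_probabilities,
    paternal_factor = cfg$paternal_factor,
    seed = cfg$seed
  ), paths[["config"]])
  invisible(paths)
}

#' Read back a scene written by [write_scene()]
#'
#' @param dir Directory containing the files.
#' @param prefix File-name prefix used when writing.
#' @return A list with `gfp_image`, `dna_image`, `nucleus_masks`, `spots`,
#'   `dna_landmarks` and `config` (a plain list). Images carry the 16-bit
#'   quantization applied on write; coordinates are converted back to
#'   1-based.
#' @export
read_scene <- function(dir, prefix = "scene") {
  p <- function(suffix) file.path(dir, paste0(prefix, "_", suffix))
  spots <- utils::read.csv(p("truth.csv"), comment.char = "#",
                           stringsAsFactors = FALSE)
  lm <- utils::read.csv(p("landmarks.csv"), comment.char = "#",
                        stringsAsFactors = FALSE)
  if (nrow(spots)) {
    spots$row <- spots$row + 1
    spots$col <- spots$col + 1
  }
  if (nrow(lm)) {
    lm$row <- lm$row + 1
    lm$col <- lm$col + 1
  }
  list(gfp_image = read_tiff16(p("gfp.tif")),
       dna_image = read_tiff16(p("dna.tif")),
       nucleus_masks = read_tiff16(p("nuclei.tif")),
       spots = spots, dna_landmarks = lm,
       config = read_config(p("config.cfg")))
}
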