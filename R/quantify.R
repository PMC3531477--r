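# Background-corrected centromeric intensities and the normalization
# schemes used downstream: within-cell percentages (sum set to 100),
# control-mean-100 arbitrary units, and per-genome (ploidy-corrected)
# totals.

#' Local-background-corrected integrated spot intensity
#'
#' Computes `I_s - A_s * (I_l - I_s) / (A_l - A_s)`: the mean pixel value of
#' the ring between the enlarged and the selected region estimates the local
#' diffuse signal (background plus any noncentromeric pool), which is
#' subtracted over the selected area. Adding a constant to every pixel
#' leaves the result unchanged, and a pure-background region yields exactly
#' zero. Negative values are returned as-is (preserving linearity for group
#' statistics) with a warning.
#'
#' @param region A data frame or list with fields `A_s`, `I_s`, `A_l`,
#'   `I_l` (vectors allowed), e.g. the output of [segment_spots()].
#' @return Numeric vector of corrected intensities (a.u.).
#' @export
#' @examples
#' corrected_intensity(list(A_s = 10, I_s = 150, A_l = 20, I_l = 200))  # 100
corrected_intensity <- function(region) {
  A_s <- region$A_s; I_s <- region$I_s; A_l <- region$A_l; I_l <- region$I_l
  if (is.null(A_s) || is.null(I_s) || is.null(A_l) || is.null(I_l)) {
    stop_param("parameter error: region must carry A_s, I_s, A_l, I_l")
  }
  if (any(A_l <= A_s)) {
    stop_param("precondition violation: A_l must exceed A_s ",
               "(division by zero in background estimate)")
  }
  out <- I_s - A_s * (I_l - I_s) / (A_l - A_s)
  if (any(out < 0)) {
    warning("negative corrected intensity for ", sum(out < 0),
            " region(s); returned unclamped", call. = FALSE)
  }
  out
}

#' Quantify all spots of a scene
#'
#' Convenience wrapper: segments the GFP channel, computes corrected
#' intensities, and (when DNA landmarks are available) assigns chromosome
#' classes.
#'
#' @param scene A `ground_truth_scene` or the list returned by
#'   [read_scene()].
#' @param params A [segment_params()].
#' @return Measurement data frame: `nucleus_id`, `region_id`,
#'   `chromosome_class`, `A_s`, `I_s`, `A_l`, `I_l`, `corrected`, centroid
#'   `row`/`col`.
#' @export
quantify_scene <- function(scene, params = segment_params()) {
  regions <- segment_spots(scene$gfp_image, params,
                           nucleus_labels = scene$nucleus_masks)
  regions$corrected <- if (nrow(regions)) {
    suppressWarnings(corrected_intensity(regions))
  } else {
    numeric(0)
  }
  lm <- scene$dna_landmarks
  regions$chromosome_class <- if (!is.null(lm) && nrow(regions)) {
    assign_chromosomes(regions, lm)
  } else {
    rep("unassigned", nrow(regions))
  }
  regions[c("nucleus_id", "region_id", "chromosome_class",
            "A_s", "I_s", "A_l", "I_l", "corrected", "row", "col")]
}

#' Per-cell total and per-genome intensity
#'
#' Sums corrected intensities over one nucleus and divides by the genome
#' ploidy (e.g. 4 for an S4-6 spermatocyte, 1 for a spermatid), so that
#' `per_genome_intensity * ploidy == total_corrected_intensity` exactly.
#'
#' @param measurements Data frame with `nucleus_id` and `corrected` columns.
#' @param nucleus_id Nucleus to total.
#' @param ploidy Genome equivalents (default 1).
#' @return One-row data frame: `nucleus_id`, `total_corrected_intensity`,
#'   `ploidy`, `per_genome_intensity`.
#' @export
cell_total <- function(measurements, nucleus_id, ploidy = 1) {
  check_scalar_number(ploidy, "ploidy", lower = 0, strict_lower = TRUE)
  sel <- measurements$nucleus_id == nucleus_id
  if (!any(sel, na.rm = TRUE)) {
    stop_param("lookup error: no measurements for nucleus ", nucleus_id)
  }
  total <- sum(measurements$corrected[which(sel)])
  data.frame(nucleus_id = nucleus_id, total_corrected_intensity = total,
             ploidy = ploidy, per_genome_intensity = total / ploidy)
}

#' Within-cell relative intensities (percent)
#'
#' Rescales each nucleus so its corrected intensities sum to 100, the
#' within-spermatocyte normalization used for chromosome-specific
#' comparisons.
#'
#' @param measurements Either a numeric vector of corrected intensities for
#'   one cell, or a data frame with `nucleus_id` and `corrected` columns.
#' @return For a vector input, the percentages; for a data frame, the input
#'   with a `relative_pct` column added.
#' @export
#' @examples
#' normalize_within_cell(c(2, 1, 1))  # 50, 25, 25
normalize_within_cell <- function(measurements) {
  pct <- function(x) {
    total <- sum(x)
    if (!is.finite(total) || total <= 0) {
      stop_param("empty-cell normalization error: nonpositive cell total")
    }
    100 * x / total
  }
  if (is.numeric(measurements)) return(pct(measurements))
  stopifnot(is.data.frame(measurements))
  measurements$relative_pct <- stats::ave(measurements$corrected,
                                          measurements$nucleus_id, FUN = pct)
  measurements
}

#' Normalize to a control group mean of 100 a.u.
#'
#' @param values Numeric vector to rescale.
#' @param control_values Control-group values; their mean maps to exactly
#'   100.
#' @return `values * 100 / mean(control_values)`.
#' @export
normalize_to_control <- function(values, control_values) {
  if (!length(control_values)) {
    stop_param("parameter error: empty control group")
  }
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) {
    stop_param("parameter error: control mean must be positive")
  }
  values * 100 / m
}

#' Assign chromosome classes from DNA-staining landmarks
#'
#' Implements the S5-spermatocyte assignment heuristics: the spot nearest
#' the bright chromosome-4 DNA dot is the paired-4 centromere pair; the spot
#' nearest the weaker irregular X region is the X centromere; spots within
#' reach of a homogeneous major-autosome territory are class `A2or3`; a
#' single remaining spot (the one not associated with intense DNA staining)
#' is the Y. Ties are broken by proximity, then by higher corrected
#' intensity. If the chromosome-4 dot and the X region select the same
#' region (X and 4 signals merged into one cluster), that region is excluded
#' as `unassigned`. Nuclei without landmarks get all spots `unassigned`.
#'
#' @param regions Data frame with `nucleus_id`, `row`, `col` and optionally
#'   `corrected` columns (one row per spot region).
#' @param dna_landmarks Data frame with `nucleus_id`, `landmark_class`
#'   (`bright_dot_chr4`, `irregular_X_region`, `homogeneous_territory`),
#'   `row`, `col`.
#' @param max_dist Distance cap in pixels for any landmark association.
#' @return Character vector of classes aligned with `regions` rows: one of
#'   `"pair4"`, `"X"`, `"Y"`, `"A2or3"`, `"unassigned"`.
#' @export
assign_chromosomes <- function(regions, dna_landmarks, max_dist = 15) {
  n <- nrow(regions)
  cls <- rep("unassigned", n)
  if (!n) return(cls)
  corrected <- regions$corrected %||% rep(0, n)
  for (nuc in unique(regions$nucleus_id)) {
    ridx <- which(regions$nucleus_id == nuc)
    lm <- dna_landmarks[dna_landmarks$nucleus_id == nuc, , drop = FALSE]
    if (!nrow(lm)) next
    d <- outer(seq_along(ridx), seq_len(nrow(lm)), function(i, j) {
      sqrt((regions$row[ridx[i]] - lm$row[j])^2 +
             (regions$col[ridx[i]] - lm$col[j])^2)
    })
    nearest_to <- function(lm_j, excluded) {
      cand <- setdiff(seq_along(ridx), excluded)
      cand <- cand[d[cand, lm_j] <= max_dist]
      if (!length(cand)) return(NA_integer_)
      cand[order(d[cand, lm_j], -corrected[ridx[cand]])][1]
    }
    taken <- integer(0)
    j4 <- which(lm$landmark_class == "bright_dot_chr4")[1]
    jx <- which(lm$landmark_class == "irregular_X_region")[1]
    i4 <- if (!is.na(j4)) nearest_to(j4, taken) else NA_integer_
    ix <- if (!is.na(jx)) nearest_to(jx, taken) else NA_integer_
    if (!is.na(i4) && !is.na(ix) && i4 == ix) {
      # X and chromosome-4 signals merged into one cluster: exclude it
      taken <- c(taken, i4)
    } else {
      if (!is.na(i4)) {
        cls[ridx[i4]] <- "pair4"
        taken <- c(taken, i4)
      }
      if (!is.na(ix)) {
        ix <- nearest_to(jx, taken)  # re-resolve in case pair4 took it
        if (!is.na(ix)) {
          cls[ridx[ix]] <- "X"
          taken <- c(taken, ix)
        }
      }
    }
    jh <- which(lm$landmark_class == "homogeneous_territory")
    for (i in setdiff(seq_along(ridx), taken)) {
      if (length(jh) && min(d[i, jh]) <= max_dist) {
        cls[ridx[i]] <- "A2or3"
        taken <- c(taken, i)
      }
    }
    left <- setdiff(seq_along(ridx), taken)
    left <- left[cls[ridx[left]] == "unassigned"]
    # a lone leftover spot, not tied to intense DNA staining, is the Y
    if (length(left) == 1L && !is.na(j4) && !is.na(jx)) {
      cls[ridx[left]] <- "Y"
    }
  }
  cls
}

#' Flag a single strong intensity outlier within a cell
#'
#' Returns the index of the maximum value if it exceeds `ratio_threshold`
#' times the median of the remaining values (the rule that picks out the
#' elevated Y kinetochore among the signals of one cell), otherwise `NA`.
#'
#' @param values Numeric vector, length at least 3.
#' @param ratio_threshold Ratio over the median of the other values
#'   (default 1.5: a 2-fold signal is always flagged, equal signals never).
#' @return Integer index of the outlier, or `NA_integer_`.
#' @export
#' @examples
#' identify_intensity_outlier(c(1, 1, 1, 2.2))  # 4
identify_intensity_outlier <- function(values, ratio_threshold = 1.5) {
  if (length(values) < 3) {
    stop_param("parameter error: need at least 3 values")
  }
  check_scalar_number(ratio_threshold, "ratio_threshold",
                      lower = 0, strict_lower = TRUE)
  i <- which.max(values)
  if (values[i] > ratio_threshold * stats::median(values[-i])) i
  else NA_integer_
}

#' Compare two measurement groups
#'
#' Fold change of group means (`mean_b / mean_a`) and a two-sample
#' unequal-variance (Welch) t test. If both groups have zero variance the
#' p value is 1 for equal means (0 otherwise) by convention.
#'
#' @param group_a,group_b Numeric vectors, each of length at least 2
#'   (`group_a` is the reference, typically the control).
#' @return List with `fold_change`, `p_value`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`.
#' @export
compare_groups <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_param("parameter error: each group needs n >= 2")
  }
  p <- tryCatch(stats::t.test(group_a, group_b, var.equal = FALSE)$p.value,
                error = function(e) {
                  if (isTRUE(all.equal(mean(group_a), mean(group_b)))) 1 else 0
                })
  list(fold_change = mean(group_b) / mean(group_a), p_value = p,
       mean_a = mean(group_a), mean_b = mean(group_b),
       n_a = length(group_a), n_b = length(group_b))
}
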