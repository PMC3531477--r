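# Closed-form dilution and ploidy arithmetic for meiosis and the early
# embryonic cleavage cycles.

#' Embryo model parameters
#'
#' @param diploid_cellularization_cycle Syncytial cycle at which a diploid
#'   embryo cellularizes (default 13).
#' @param detection_threshold Labeled fraction below which a paternal label
#'   counts as undetectable. Default 0.3: strictly between the mitosis-2
#'   fraction (0.5, detected) and the mitosis-3 fraction (0.25, not
#'   detected), the only constraint the observations provide.
#' @return Object of class `embryo_model_params`.
#' @export
embryo_model_params <- function(diploid_cellularization_cycle = 13L,
                                detection_threshold = 0.3) {
  check_scalar_number(diploid_cellularization_cycle,
                      "diploid_cellularization_cycle", lower = 1)
  check_scalar_number(detection_threshold, "detection_threshold")
  if (detection_threshold <= 0 || detection_threshold >= 1) {
    stop_param("parameter error: detection_threshold must be in (0, 1)")
  }
  structure(list(
    diploid_cellularization_cycle = as.integer(diploid_cellularization_cycle),
    detection_threshold = detection_threshold
  ), class = "embryo_model_params")
}

#' Per-genome meiotic dilution factor
#'
#' Meiosis partitions the centromeric CenH3 of one 4C spermatocyte among
#' four 1C spermatids with no net loading during the two divisions, so the
#' per-genome (and per-cell) amount drops by the ploidy ratio: a factor of
#' 4. (A per-spot reading differs because sister centromeres are paired into
#' single spots; the per-genome factor is the unambiguous one.)
#'
#' @param spermatocyte_ploidy Genome equivalents before meiosis (default 4).
#' @param spermatid_ploidy Genome equivalents after meiosis (default 1).
#' @return The dilution factor (default arithmetic: 4).
#' @export
meiotic_dilution_factor <- function(spermatocyte_ploidy = 4,
                                    spermatid_ploidy = 1) {
  check_scalar_number(spermatocyte_ploidy, "spermatocyte_ploidy",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(spermatid_ploidy, "spermatid_ploidy",
                      lower = 0, strict_lower = TRUE)
  spermatocyte_ploidy / spermatid_ploidy
}

#' Labeled fraction of paternal centromeric CenH3 at mitosis k
#'
#' Each S phase partitions the inherited label onto the two sister
#' centromeres while unlabeled maternally provided protein restores the
#' total, so the labeled fraction halves every cycle:
#' `(1/2)^(k - 1)` at mitosis `k` (fraction 1 at mitosis 1, before any
#' replication dilution).
#'
#' @param k Mitosis index (>= 1, vectorized).
#' @return Labeled fraction(s).
#' @export
#' @examples
#' label_fraction_at_mitosis(1:3)  # 1, 0.5, 0.25
label_fraction_at_mitosis <- function(k) {
  if (any(k < 1) || any(k != round(k))) {
    stop_param("parameter error: mitosis index k must be an integer >= 1")
  }
  0.5^(k - 1)
}

#' Is the paternal label still detectable at mitosis k?
#'
#' @param k Mitosis index (vectorized).
#' @param params An [embryo_model_params()].
#' @return Logical: labeled fraction at or above the detection threshold.
#' @export
label_detectable <- function(k, params = embryo_model_params()) {
  label_fraction_at_mitosis(k) >= params$detection_threshold
}

#' Cellularization cycle under the nucleocytoplasmic-ratio trigger
#'
#' Cellularization triggers once total genome content reaches the diploid
#' threshold: the minimal cycle `c` with
#' `2^c * ploidy >= 2^diploid_cycle * 2`. Diploid embryos cellularize at
#' cycle 13; gynogenetic haploids need one extra doubling and cellularize
#' at cycle 14.
#'
#' @param ploidy 1 (haploid) or 2 (diploid).
#' @param params An [embryo_model_params()].
#' @return Integer cycle count.
#' @export
cellularization_cycle <- function(ploidy, params = embryo_model_params()) {
  if (!ploidy %in% c(1, 2)) {
    stop_param("parameter error: ploidy must be 1 or 2")
  }
  threshold <- 2^params$diploid_cellularization_cycle * 2
  for (cyc in seq_len(64L)) {
    if (2^cyc * ploidy >= threshold) return(cyc)
  }
  stop_param("parameter error: no cellularization cycle within 64 cycles")
}

#' Nuclear density ratio between two ploidies at cellularization
#'
#' Nuclei double each syncytial cycle, so the density at cellularization
#' scales as `2^cycle`; haploids, cellularizing one cycle later, show a
#' 2-fold higher density than diploids.
#'
#' @param ploidy_a,ploidy_b Ploidies to compare (numerator / denominator).
#' @param params An [embryo_model_params()].
#' @return Density ratio.
#' @export
#' @examples
#' nuclear_density_ratio(1, 2)  # 2
nuclear_density_ratio <- function(ploidy_a = 1, ploidy_b = 2,
                                  params = embryo_model_params()) {
  2^cellularization_cycle(ploidy_a, params) /
    2^cellularization_cycle(ploidy_b, params)
}

#' Expected transgene transmission fraction
#'
#' Mendelian expectation for the fraction of progeny inheriting a paternal
#' transgene: 1/2 from a hemizygous father, 1 from a homozygous father. The
#' observed near-universal paternal signal (11 of 12 pronuclei from
#' hemizygous fathers) exceeds this bound, rejecting zygotic expression as
#' the source of the signal.
#'
#' @param father `"hemizygous"` or `"homozygous"`.
#' @return Expected transmission fraction.
#' @export
mendelian_transmission_fraction <- function(father = c("hemizygous",
                                                       "homozygous")) {
  father <- match.arg(father)
  if (father == "hemizygous") 0.5 else 1.0
}
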