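# Deterministic recursion for sex-specific germline loading of centromeric
# CenH3 across generations.
#
# The model: every passage of a centromere through the male germline adds
# (or multiplies in) a loading increment; passage through the female
# germline removes one. A chromosome in either parent descends from the
# grandfather or the grandmother with the transmission weights of its
# class: autosomes 1/2-1/2, X 1/3 male / 2/3 female, Y always male.
# Generation 0 is the founder population at uniform level L0; a generation
# is read out at the gamete stage, after germline passage. Expected-value
# propagation is deterministic; a seeded stochastic lineage sampler is
# provided as a cross-check.

#' Germline loading-model parameters
#'
#' @param L0 Founder centromeric level (a.u., > 0).
#' @param a_m Additive male-germline overloading increment (a.u.).
#' @param a_f Additive female-germline underloading decrement (a.u.).
#' @param male_factor Multiplicative male factor (> 0), used in
#'   multiplicative mode.
#' @param female_factor Multiplicative female factor (> 0).
#' @param mode `"additive"` (default) or `"multiplicative"`. The symmetric
#'   additive case `a_m == a_f` is the equal-over/underloading scenario.
#' @param n_generations Default horizon for trajectory helpers.
#' @return Object of class `germline_params`.
#' @export
#' @examples
#' p <- germline_params()                 # symmetric additive defaults
#' advance_autosomes(100, 100, p)         # generation 1: 110 / 90
germline_params <- function(L0 = 100, a_m = 10, a_f = 10,
                            male_factor = 1.1, female_factor = 0.9,
                            mode = c("additive", "multiplicative"),
                            n_generations = 10L) {
  mode <- match.arg(mode)
  check_scalar_number(L0, "L0", lower = 0, strict_lower = TRUE)
  check_scalar_number(a_m, "a_m", lower = 0)
  check_scalar_number(a_f, "a_f", lower = 0)
  check_scalar_number(male_factor, "male_factor", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(female_factor, "female_factor", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(n_generations, "n_generations", lower = 1)
  structure(list(L0 = L0, a_m = a_m, a_f = a_f,
                 male_factor = male_factor, female_factor = female_factor,
                 mode = mode, n_generations = as.integer(n_generations)),
            class = "germline_params")
}

#' @export
print.germline_params <- function(x, ...) {
  cat("<germline_params>", x$mode, "mode; L0 =", x$L0, "\n")
  if (x$mode == "additive") {
    cat("  male +", x$a_m, " female -", x$a_f, "per passage\n")
  } else {
    cat("  male x", x$male_factor, " female x", x$female_factor,
        "per passage\n")
  }
  invisible(x)
}

#' One germline passage
#'
#' Applies the sex-specific loading step to a level: additive mode adds
#' `a_m` (male) or subtracts `a_f` (female), flooring at zero (protein
#' amounts are nonnegative; a floored value triggers a warning);
#' multiplicative mode multiplies by the sex factor.
#'
#' @param level Nonnegative level(s) (vectorized).
#' @param sex `"male"` or `"female"`.
#' @param params A [germline_params()].
#' @return Updated level(s).
#' @export
germline_pass <- function(level, sex = c("male", "female"), params) {
  sex <- match.arg(sex)
  if (any(level < 0)) stop_param("parameter error: level must be >= 0")
  out <- if (params$mode == "additive") {
    if (sex == "male") level + params$a_m else level - params$a_f
  } else {
    level * if (sex == "male") params$male_factor else params$female_factor
  }
  if (any(out < 0)) {
    warning("level floored at 0 after female-germline underloading",
            call. = FALSE)
    out[out < 0] <- 0
  }
  out
}

#' Advance paternal/maternal autosomal levels by one generation
#'
#' An autosome in either parent descends from the grandfather or the
#' grandmother with equal weight, so the parental expected level is
#' `(P_t + M_t) / 2`; the next paternal (maternal) level is that mean after
#' a male (female) germline passage.
#'
#' @param P_t,M_t Current paternal and maternal expected levels.
#' @param params A [germline_params()].
#' @return List with elements `P` and `M` for generation `t + 1`.
#' @export
advance_autosomes <- function(P_t, M_t, params) {
  if (P_t < 0 || M_t < 0) stop_param("parameter error: levels must be >= 0")
  mid <- (P_t + M_t) / 2
  list(P = germline_pass(mid, "male", params),
       M = germline_pass(mid, "female", params))
}

#' Paternal/maternal autosome trajectory
#'
#' Iterates [advance_autosomes()] from founders at `L0`.
#'
#' @param params A [germline_params()].
#' @param n Number of generations (default `params$n_generations`).
#' @return Data frame with columns `generation` (0..n), `P`, `M`, `mean`,
#'   `difference`.
#' @export
autosome_trajectory <- function(params, n = params$n_generations) {
  check_scalar_number(n, "n", lower = 1)
  P <- M <- numeric(n + 1)
  P[1] <- M[1] <- params$L0
  for (t in seq_len(n)) {
    step <- advance_autosomes(P[t], M[t], params)
    P[t + 1] <- step$P
    M[t + 1] <- step$M
  }
  data.frame(generation = 0:n, P = P, M = M,
             mean = (P + M) / 2, difference = P - M)
}

#' Y-centromere trajectory
#'
#' The Y is transmitted exclusively through the male germline, so its level
#' experiences male overloading every generation; with any positive male
#' increment it increases without bound in the absence of counterbalancing
#' mechanisms.
#'
#' @param params A [germline_params()].
#' @param n Number of generations.
#' @return Numeric vector of levels at generations `1..n`.
#' @export
y_trajectory <- function(params, n = params$n_generations) {
  check_scalar_number(n, "n", lower = 1)
  out <- numeric(n)
  lvl <- params$L0
  for (t in seq_len(n)) {
    lvl <- germline_pass(lvl, "male", params)
    out[t] <- lvl
  }
  out
}

#' Expected X-centromere trajectory
#'
#' The X spends 1/3 of its passages in the male and 2/3 in the female
#' germline, so its expected update is the weighted mixture of the two
#' passages; in the symmetric additive case it loses `a/3` per generation
#' (floored at zero). With symmetric loading the X sits below the autosomal
#' mean, which sits below the Y.
#'
#' @param params A [germline_params()].
#' @param n Number of generations.
#' @return Numeric vector of expected levels at generations `1..n`.
#' @export
x_expected_trajectory <- function(params, n = params$n_generations) {
  check_scalar_number(n, "n", lower = 1)
  out <- numeric(n)
  lvl <- params$L0
  for (t in seq_len(n)) {
    lvl <- (germline_pass(lvl, "male", params) +
              2 * suppressWarnings(germline_pass(lvl, "female", params))) / 3
    if (lvl < 0) lvl <- 0
    out[t] <- lvl
  }
  out
}

#' First generation at which the paternal-maternal difference stabilizes
#'
#' Returns the first generation `t` with
#' `|(P_t - M_t) - (P_horizon - M_horizon)| <= tol`. With equal over- and
#' underloading this is at most 2, matching the two-generation
#' stabilization of the parental difference.
#'
#' @param params A [germline_params()].
#' @param horizon Generations to iterate (>= 3).
#' @param tol Absolute tolerance on the difference.
#' @return Integer generation index (0 means already stable at founding).
#' @export
stabilization_generation <- function(params, horizon = 20L, tol = 1e-9) {
  check_scalar_number(horizon, "horizon", lower = 3)
  traj <- autosome_trajectory(params, horizon)
  target <- traj$difference[horizon + 1]
  # the difference must actually have settled by the horizon
  if (abs(traj$difference[horizon] - target) > tol) {
    stop_param("non-convergent parameters: difference still changing at ",
               "horizon ", horizon)
  }
  hit <- which(abs(traj$difference - target) <= tol)
  # require stability from that point on, not a transient crossing
  hit <- hit[vapply(hit, function(i) {
    all(abs(traj$difference[i:(horizon + 1)] - target) <= tol)
  }, logical(1))]
  if (!length(hit)) {
    stop_param("non-convergent parameters: no stabilization within horizon ",
               horizon)
  }
  as.integer(traj$generation[hit[1]])
}

#' Centromere lineage state
#'
#' @param level Centromeric level (a.u., >= 0).
#' @param chromosome_class `"autosome"`, `"X"` or `"Y"`.
#' @param parental_origin `"paternal"` or `"maternal"`.
#' @param generation Generation index (0 = founders).
#' @return Object of class `lineage_state`.
#' @export
lineage_state <- function(level, chromosome_class = "autosome",
                          parental_origin = "paternal", generation = 0L) {
  check_scalar_number(level, "level", lower = 0)
  structure(list(level = level,
                 chromosome_class = match.arg(chromosome_class,
                                              c("autosome", "X", "Y")),
                 parental_origin = match.arg(parental_origin,
                                             c("paternal", "maternal")),
                 generation = as.integer(generation)),
            class = "lineage_state")
}

#' Apply an experimental perturbation to a lineage
#'
#' Multiplies the level by `factor` (e.g. 0.33 for RNAi depletion in sperm,
#' 7 for overexpression), leaving all other fields unchanged.
#'
#' @param state A [lineage_state()].
#' @param factor Multiplicative factor (> 0).
#' @return The perturbed `lineage_state`.
#' @export
apply_perturbation <- function(state, factor) {
  stopifnot(inherits(state, "lineage_state"))
  check_scalar_number(factor, "factor", lower = 0, strict_lower = TRUE)
  state$level <- state$level * factor
  state
}

#' Expected per-nucleus total after fertilization
#'
#' Half of the centromeres of an embryo are paternal, half maternal, so on
#' a scale where the unperturbed total is 1 the expected relative total is
#' `(paternal + maternal) / 2`.
#'
#' @param paternal_level,maternal_level Relative levels (>= 0).
#' @return Relative per-nucleus total.
#' @export
#' @examples
#' embryo_mix(0.5, 1)  # 0.75
embryo_mix <- function(paternal_level, maternal_level) {
  if (any(paternal_level < 0) || any(maternal_level < 0)) {
    stop_param("parameter error: levels must be >= 0")
  }
  (paternal_level + maternal_level) / 2
}

#' Template-governed maintenance across mitotic cycles
#'
#' Under template-governed loading, the amount partitioned onto sister
#' centromeres each S phase instructs loading of an exactly equivalent new
#' amount, so the centromeric level is invariant across mitotic cycles; in
#' particular a depleted level is never restored and a zero level never
#' acquires protein de novo.
#'
#' @param level Centromeric level (>= 0).
#' @param n_cycles Number of mitotic cycles (>= 0).
#' @return `level`, unchanged.
#' @export
template_maintenance <- function(level, n_cycles) {
  if (any(level < 0)) stop_param("parameter error: level must be >= 0")
  check_scalar_number(n_cycles, "n_cycles", lower = 0)
  level
}

#' Stochastic lineage sampler (cross-check of the deterministic model)
#'
#' Samples individual centromere lineages: each generation the carrier
#' parent's sex is drawn with the transmission weights of the chromosome
#' class (autosome 1/2, X 1/3 male, Y always male) and the corresponding
#' germline passage is applied. Lineage means converge to the deterministic
#' expectations.
#'
#' @param params A [germline_params()].
#' @param n_generations Generations to simulate.
#' @param n_lineages Number of independent lineages.
#' @param chromosome_class `"autosome"`, `"X"` or `"Y"`.
#' @param seed Integer seed.
#' @return Matrix (`n_lineages` x `n_generations`) of levels; column means
#'   estimate the expected trajectory.
#' @export
sample_lineages <- function(params, n_generations, n_lineages = 1000L,
                            chromosome_class = c("autosome", "X", "Y"),
                            seed = 1L) {
  chromosome_class <- match.arg(chromosome_class)
  check_scalar_number(n_generations, "n_generations", lower = 1)
  check_scalar_number(n_lineages, "n_lineages", lower = 1)
  p_male <- switch(chromosome_class, autosome = 0.5, X = 1 / 3, Y = 1)
  with_seed(seed, {
    levels <- matrix(0, n_lineages, n_generations)
    lvl <- rep(params$L0, n_lineages)
    for (t in seq_len(n_generations)) {
      male <- stats::runif(n_lineages) < p_male
      lvl[male] <- germline_pass(lvl[male], "male", params)
      lvl[!male] <- suppressWarnings(
        germline_pass(lvl[!male], "female", params))
      levels[, t] <- lvl
    }
    levels
  })
}
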