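# Synthetic one-compartment oral PK data with known ground truth, emulating
# the control-versus-coadministration design of the literature interaction
# studies: a metal-interaction "treatment" arm scales bioavailability by
# f_mult and the absorption rate constant by ka_mult.

#' Define a simulation scenario
#'
#' @param true_ka,true_ke absorption and elimination rate constants (1/h).
#' @param dose dose (mg).
#' @param f bioavailability fraction in (0, 1].
#' @param vd volume of distribution (L).
#' @param schedule strictly increasing sampling times (h). Must extend at
#'   least 3 half-lives past Tmax so a terminal phase exists.
#' @param noise_model `"none"`, `"proportional_lognormal"` or
#'   `"additive_gaussian"`.
#' @param sigma noise scale: standard deviation of log-concentration for the
#'   lognormal model, absolute concentration sd (ug/mL) for the Gaussian one.
#' @param lognormal_mean_preserving if `TRUE`, divide lognormal noise by
#'   `exp(sigma^2/2)` so the mean (rather than the median) of the noisy
#'   concentration equals the model value.
#' @param f_mult,ka_mult treatment-arm effect multipliers on `f` (in (0, 1])
#'   and `ka` (> 0); applied only to the treatment arm.
#' @param seed master seed; per-subject substreams are derived from it so
#'   enlarging a cohort never reshuffles earlier subjects.
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(true_ka = 1.0, true_ke = 0.1, dose = 200,
                                f = 0.9, vd = 100,
                                schedule = c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6,
                                             8, 12, 24, 36, 48),
                                noise_model = c("none", "proportional_lognormal",
                                                "additive_gaussian"),
                                sigma = 0.05,
                                lognormal_mean_preserving = FALSE,
                                f_mult = 1, ka_mult = 1, seed = 1L) {
  noise_model <- match.arg(noise_model)
  check_positive(true_ka, "true_ka"); check_positive(true_ke, "true_ke")
  check_positive(dose, "dose"); check_positive(vd, "vd")
  if (f <= 0 || f > 1) stop("f must lie in (0, 1]", call. = FALSE)
  if (f_mult <= 0 || f_mult > 1) stop("f_mult must lie in (0, 1]", call. = FALSE)
  check_positive(ka_mult, "ka_mult")
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing", call. = FALSE)
  tmax <- tmax_forward(true_ka, true_ke)
  t_half <- log(2) / true_ke
  if (max(schedule) < tmax + 3 * t_half)
    stop(sprintf("schedule must extend to at least Tmax + 3 half-lives = %.3g h", tmax + 3 * t_half),
         call. = FALSE)
  structure(list(true_ka = true_ka, true_ke = true_ke, dose = dose, f = f,
                 vd = vd, schedule = schedule, noise_model = noise_model,
                 sigma = sigma,
                 lognormal_mean_preserving = lognormal_mean_preserving,
                 f_mult = f_mult, ka_mult = ka_mult, seed = as.integer(seed)),
            class = "simulation_scenario")
}

# Deterministic per-subject substream seed: subjects keep their stream when
# the cohort grows or arms are simulated in a different order.
subject_seed <- function(scenario, arm, subject) {
  arm_code <- if (arm == "control") 0L else 1L
  # all intermediates stay below 2^53 so the modulus is exact
  ((scenario$seed %% 1000003) * 1000033 + arm_code * 97003 + subject * 7919) %% 2147483647
}

#' Simulate one concentration curve
#'
#' Bateman concentrations at the scenario's schedule with arm-specific
#' parameters (`f*f_mult`, `ka*ka_mult` for the treatment arm), noise applied
#' per the scenario's model, concentrations clipped at zero.
#'
#' @param scenario a [simulation_scenario()].
#' @param arm `"control"` or `"treatment"`.
#' @param subject subject index (selects the noise substream).
#' @return a [concentration_curve()].
#' @export
simulate_curve <- function(scenario, arm = c("control", "treatment"), subject = 1L) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  arm <- match.arg(arm)
  f <- scenario$f * if (arm == "treatment") scenario$f_mult else 1
  ka <- scenario$true_ka * if (arm == "treatment") scenario$ka_mult else 1
  conc <- bateman_concentration(scenario$schedule, scenario$dose, f,
                                scenario$vd, ka, scenario$true_ke)
  if (scenario$noise_model != "none") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(subject_seed(scenario, arm, subject))
    n <- length(conc)
    conc <- switch(scenario$noise_model,
      proportional_lognormal = {
        mult <- exp(scenario$sigma * stats::rnorm(n))
        if (scenario$lognormal_mean_preserving) mult <- mult / exp(scenario$sigma^2 / 2)
        conc * mult
      },
      additive_gaussian = conc + stats::rnorm(n, sd = scenario$sigma)
    )
    conc <- pmax(conc, 0)
  }
  concentration_curve(scenario$schedule, conc, fq = "synthetic", coadmin = arm,
                      dose = scenario$dose)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a control-versus-coadministration interaction study
#'
#' Simulates `n_subjects` control and treatment curves, extracts PK
#' parameters from each with [extract_pk()], averages Cmax/AUC/ka per arm
#' and reports the relative changes, alongside the analytic ground truth:
#' in this model `AUC = f*dose/(vd*ke)` does not depend on `ka`, so
#' `%dAUC = 100*(f_mult - 1)` and `%dka = 100*(ka_mult - 1)` exactly.
#'
#' @param scenario a [simulation_scenario()].
#' @param n_subjects subjects per arm.
#' @param branch passed to [extract_pk()].
#' @return list with `record` (data frame in the study-record schema),
#'   `truth` (analytic percent changes), `n_failed` (extraction failures).
#' @export
simulate_interaction_study <- function(scenario, n_subjects = 12L,
                                       branch = "absorption_limited") {
  stopifnot(inherits(scenario, "simulation_scenario"), n_subjects >= 1L)
  run_arm <- function(arm) {
    res <- lapply(seq_len(n_subjects), function(s) {
      curve <- simulate_curve(scenario, arm, subject = s)
      tryCatch(extract_pk(curve, branch = branch), error = function(e) NULL)
    })
    ok <- !vapply(res, is.null, logical(1))
    list(cmax = vapply(res[ok], function(p) p$cmax, numeric(1)),
         auc = vapply(res[ok], function(p) p$auc, numeric(1)),
         ka = vapply(res[ok], function(p) p$ka, numeric(1)),
         n_failed = sum(!ok))
  }
  ctrl <- run_arm("control"); trt <- run_arm("treatment")
  n_failed <- ctrl$n_failed + trt$n_failed
  if (n_failed > 0.2 * 2 * n_subjects)
    stop(sprintf("interaction study failed: %d of %d extractions unusable",
                 n_failed, 2 * n_subjects), call. = FALSE)
  record <- data.frame(
    fq = "synthetic", metal = NA_character_, metal_source = "simulated",
    pct_cmax = relative_change(mean(ctrl$cmax), mean(trt$cmax)),
    pct_auc = relative_change(mean(ctrl$auc), mean(trt$auc)),
    pct_ka = relative_change(mean(ctrl$ka), mean(trt$ka)),
    reference_tag = "synthetic", stringsAsFactors = FALSE)
  truth <- c(pct_auc = 100 * (scenario$f_mult - 1),
             pct_ka = 100 * (scenario$ka_mult - 1))
  list(record = record, truth = truth, n_failed = n_failed)
}

#' Write / read simulation scenarios as JSON
#' @param scenario a [simulation_scenario()].
#' @param path JSON file path.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(simulation_scenario, x)
}
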