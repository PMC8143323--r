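# Extraction of PK parameters from concentration-time point tables: terminal
# log-linear slope for ke, observed peak (or tabulated) Tmax, inversion of
# the Tmax relation for ka, and trapezoid + extrapolated-tail AUC.

#' Concentration-time curve for one administration arm
#'
#' @param times sampling times (h), strictly increasing, at least 4 points.
#' @param concentrations plasma concentrations (ug/mL), non-negative,
#'   same length as `times`.
#' @param fq drug label.
#' @param coadmin coadministration label.
#' @param dose dose (mg), optional.
#' @return object of class `concentration_curve`.
#' @export
concentration_curve <- function(times, concentrations, fq = NA_character_,
                                coadmin = "control", dose = NA_real_) {
  if (length(times) != length(concentrations))
    stop("times and concentrations must have equal length", call. = FALSE)
  if (length(times) < 4L)
    stop("a concentration curve needs at least 4 points", call. = FALSE)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("times must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 fq = fq, coadmin = coadmin, dose = dose),
            class = "concentration_curve")
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf("<concentration_curve %s/%s: %d points, t = %g..%g h, Cmax = %g>\n",
              x$fq, x$coadmin, length(x$times), min(x$times), max(x$times),
              max(x$concentrations)))
  invisible(x)
}

#' Select the post-absorption (terminal) phase of a curve
#'
#' Returns the indices of all samples strictly after the observed peak with
#' positive concentration. The observed-peak sample itself is excluded; the
#' first occurrence of the maximum is taken as the peak when tied.
#'
#' @param curve a [concentration_curve()].
#' @param min_points minimum acceptable number of terminal points (>= 3).
#' @return integer vector of indices into the curve.
#' @export
select_terminal_phase <- function(curve, min_points = 3L) {
  stopifnot(inherits(curve, "concentration_curve"))
  if (min_points < 3L) stop("min_points must be at least 3", call. = FALSE)
  peak <- which.max(curve$concentrations)
  idx <- which(seq_along(curve$times) > peak & curve$concentrations > 0)
  if (length(idx) < min_points)
    stop(sprintf("terminal phase selection failed: only %d post-peak positive point(s), need %d",
                 length(idx), min_points), call. = FALSE)
  idx
}

#' Fit the terminal elimination slope
#'
#' Ordinary least squares of log10(concentration) on time over the selected
#' points; on a log10 axis the elimination phase has slope `-ke/ln(10)`, so
#' `ke = -slope * ln(10)`.
#'
#' @param curve a [concentration_curve()].
#' @param indices point indices to use (e.g. from [select_terminal_phase()]).
#' @return object of class `terminal_fit`: list with `ke`, `log_intercept`
#'   (log10 scale), `r_squared`, `indices_used`.
#' @export
fit_terminal_slope <- function(curve, indices) {
  stopifnot(inherits(curve, "concentration_curve"))
  if (length(indices) < 3L) stop("terminal fit needs at least 3 points", call. = FALSE)
  tt <- curve$times[indices]
  cc <- curve$concentrations[indices]
  if (any(cc <= 0)) stop("terminal fit requires positive concentrations", call. = FALSE)
  if (length(unique(tt)) < 2L) stop("terminal fit is singular: all times equal", call. = FALSE)
  fit <- stats::lm(log10(cc) ~ tt)
  slope <- unname(stats::coef(fit)[2])
  ke <- -slope * log(10)
  if (!is.finite(ke) || ke <= 0)
    stop(sprintf("terminal slope is non-negative (slope = %.4g); no elimination phase", slope),
         call. = FALSE)
  # computed directly so noise-free (perfect) fits stay silent
  y <- log10(cc)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(ke = ke, log_intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, indices_used = indices),
            class = "terminal_fit")
}

#' @export
print.terminal_fit <- function(x, ...) {
  cat(sprintf("<terminal_fit ke = %.4g /h (t1/2 = %.3g h), r^2 = %.4f, %d points>\n",
              x$ke, log(2) / x$ke, x$r_squared, length(x$indices_used)))
  invisible(x)
}

# Linear trapezoid over the sampled range plus log-linear tail C_last/ke.
auc_trapezoid_tail <- function(times, conc, ke = NULL) {
  auc <- sum(diff(times) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
  tail_part <- 0
  c_last <- conc[length(conc)]
  if (!is.null(ke) && c_last > 0) tail_part <- c_last / ke
  auc + tail_part
}

#' Extract PK parameters from a concentration-time curve
#'
#' Reproduces the tabulated-data extraction procedure: `ke` from the terminal
#' log-linear slope, `t_half = ln(2)/ke`, `Tmax` from the observed peak (or a
#' provided tabulated value, which takes precedence when available), `ka` by
#' inverting the Tmax relation on the requested branch, `Cmax` as the largest
#' observed concentration, and AUC by linear trapezoid over the sampled range
#' plus the log-linear extrapolated tail `C_last/ke`.
#'
#' @param curve a [concentration_curve()].
#' @param tmax_source `"observed_peak"` (default) or `"provided"`.
#' @param provided_tmax tabulated Tmax (h), required when
#'   `tmax_source = "provided"`.
#' @param branch passed to [solve_ka()].
#' @param min_points minimum terminal points, passed to
#'   [select_terminal_phase()].
#' @return a [pk_parameters()] object.
#' @export
extract_pk <- function(curve, tmax_source = c("observed_peak", "provided"),
                       provided_tmax = NULL,
                       branch = c("absorption_limited", "flip_flop"),
                       min_points = 3L) {
  stopifnot(inherits(curve, "concentration_curve"))
  tmax_source <- match.arg(tmax_source)
  branch <- match.arg(branch)
  idx <- select_terminal_phase(curve, min_points = min_points)
  fit <- fit_terminal_slope(curve, idx)
  ke <- fit$ke
  tmax <- if (tmax_source == "provided") {
    if (is.null(provided_tmax)) stop("provided_tmax is required", call. = FALSE)
    provided_tmax
  } else {
    curve$times[which.max(curve$concentrations)]
  }
  ka <- solve_ka(tmax, ke, branch = branch)
  auc <- auc_trapezoid_tail(curve$times, curve$concentrations, ke = ke)
  pk_parameters(
    fq = if (is.na(curve$fq)) "unknown" else curve$fq,
    coadmin = curve$coadmin,
    dose = curve$dose,
    cmax = max(curve$concentrations),
    tmax = tmax,
    t_half = log(2) / ke,
    auc = auc,
    ke = ke,
    ka = as.numeric(ka),
    branch = attr(ka, "branch")
  )
}

#' Read concentration curves from CSV
#'
#' Accepts a per-arm file with columns `time_h, conc_ug_ml`, or a long
#' format with an additional `arm` column; returns one curve per arm.
#'
#' @param path CSV file.
#' @param fq,coadmin,dose labels applied to single-arm files.
#' @return a [concentration_curve()] (single arm) or named list of curves.
#' @export
read_curves <- function(path, fq = NA_character_, coadmin = "control", dose = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "conc_ug_ml") %in% names(df)))
    stop("curve CSV needs columns time_h, conc_ug_ml", call. = FALSE)
  if ("arm" %in% names(df)) {
    arms <- split(df, df$arm)
    lapply(arms, function(a)
      concentration_curve(a$time_h, a$conc_ug_ml, fq = fq, coadmin = unique(a$arm)[1], dose = dose))
  } else {
    concentration_curve(df$time_h, df$conc_ug_ml, fq = fq, coadmin = coadmin, dose = dose)
  }
}

#' Write a concentration curve to CSV
#'
#' @param curve a [concentration_curve()].
#' @param path output file.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "concentration_curve"))
  utils::write.csv(data.frame(time_h = curve$times, conc_ug_ml = curve$concentrations),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
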