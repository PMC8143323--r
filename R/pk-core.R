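# One-compartment oral-absorption kinetics: interconversion of half-life and
# elimination rate, the Tmax relation between absorption and elimination rate
# constants (forward and inverted), the Bateman concentration function, and
# relative-change arithmetic for coadministration studies.

check_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("%s must be a positive finite number", what), call. = FALSE)
  invisible(x)
}

#' Elimination rate constant from half-life
#'
#' `ke = ln(2) / t_half`. The exact natural-log constant is used internally;
#' the familiar 0.693 approximation appears only in documentation.
#'
#' @param t_half elimination half-life (h).
#' @return first-order elimination rate constant (1/h).
#' @seealso [half_life_from_ke()] for the inverse.
#' @examples
#' ke_from_half_life(log(2))  # 1
#' @export
ke_from_half_life <- function(t_half) {
  check_positive(t_half, "t_half")
  log(2) / t_half
}

#' Half-life from elimination rate constant
#'
#' @param ke first-order elimination rate constant (1/h).
#' @return elimination half-life (h).
#' @export
half_life_from_ke <- function(ke) {
  check_positive(ke, "ke")
  log(2) / ke
}

#' Time of maximum concentration from the rate constants
#'
#' For first-order absorption (rate `ka`) into a one-compartment model with
#' first-order elimination (rate `ke`), the peak time is
#' `Tmax = ln(ka/ke) / (ka - ke)`, with the continuous limit `1/ke` as
#' `ka -> ke`. The function is symmetric under swapping `ka` and `ke`.
#'
#' @param ka absorption rate constant (1/h).
#' @param ke elimination rate constant (1/h).
#' @return Tmax (h).
#' @examples
#' tmax_forward(1, 0.1)  # log(10)/0.9
#' @export
tmax_forward <- function(ka, ke) {
  check_positive(ka, "ka"); check_positive(ke, "ke")
  n <- max(length(ka), length(ke))
  ka <- rep_len(ka, n); ke <- rep_len(ke, n)
  out <- numeric(n)
  degen <- abs(ka - ke) / ke < 1e-10
  out[degen] <- 1 / ke[degen]
  out[!degen] <- log(ka[!degen] / ke[!degen]) / (ka[!degen] - ke[!degen])
  out
}

#' Solve the Tmax relation for the absorption rate constant
#'
#' Inverts `Tmax = ln(ka/ke)/(ka - ke)` for `ka` given `Tmax` and `ke`. The
#' observed peak time is compatible with two assignments of the fast and
#' slow rate: `ka > ke` (absorption-limited, the conventional regime and the
#' default) or `ka < ke` (flip-flop kinetics, where absorption limits the
#' terminal phase). For a fixed `ke` the relation is monotone in `ka`, so
#' the absorption-limited root exists iff `Tmax < 1/ke` and the flip-flop
#' root iff `Tmax > 1/ke`; at `Tmax = 1/ke` both collapse to `ka = ke`.
#' Which regime applies cannot be decided from `Tmax` and the terminal
#' slope alone, so the solved value is annotated with its branch.
#'
#' Root finding is bracketed bisection/Brent in `log(ka)` over
#' `[ke(1+1e-9), ke*1e6]` (upper branch) or `[ke*1e-6, ke(1-1e-9)]` (lower
#' branch); the relation is monotone on each branch so the bracket is
#' globally convergent.
#'
#' @param tmax observed time of maximum concentration (h).
#' @param ke elimination rate constant (1/h).
#' @param branch which root: `"absorption_limited"` (ka > ke, default) or
#'   `"flip_flop"` (ka < ke).
#' @return absorption rate constant ka (1/h) with attribute `branch`.
#' @examples
#' solve_ka(tmax_forward(1, 0.1), ke = 0.1)  # 1
#' @export
solve_ka <- function(tmax, ke, branch = c("absorption_limited", "flip_flop")) {
  branch <- match.arg(branch)
  check_positive(tmax, "tmax"); check_positive(ke, "ke")
  bound <- 1 / ke
  if (abs(tmax - bound) / bound < 1e-9) {
    ka <- ke
    attr(ka, "branch") <- "degenerate"
    return(ka)
  }
  # tmax_forward(., ke) is monotone decreasing in ka, equal to 1/ke at
  # ka = ke: the absorption-limited root (ka > ke) exists iff tmax < 1/ke
  # and the flip-flop root (ka < ke) iff tmax > 1/ke.
  if (branch == "absorption_limited" && tmax > bound)
    stop(sprintf("no absorption-limited solution: tmax = %.6g h exceeds the bound 1/ke = %.6g h",
                 tmax, bound), call. = FALSE)
  if (branch == "flip_flop" && tmax < bound)
    stop(sprintf("no flip-flop solution: tmax = %.6g h is below the bound 1/ke = %.6g h",
                 tmax, bound), call. = FALSE)
  f <- function(log_ka) tmax_forward(exp(log_ka), ke) - tmax
  interval <- if (branch == "absorption_limited") {
    c(log(ke * (1 + 1e-9)), log(ke * 1e6))
  } else {
    c(log(ke * 1e-6), log(ke * (1 - 1e-9)))
  }
  flo <- f(interval[1]); fhi <- f(interval[2])
  if (sign(flo) == sign(fhi))
    stop(sprintf("no %s root for tmax = %.6g, ke = %.6g (bound 1/ke = %.6g)",
                 branch, tmax, ke, bound), call. = FALSE)
  root <- stats::uniroot(f, interval, tol = 1e-14)$root
  ka <- exp(root)
  # polish in ka space
  for (k in 1:3) {
    tf <- tmax_forward(ka, ke)
    if (abs(ka - ke) / ke < 1e-9) break
    dt <- (log(ka / ke) * -1 / (ka - ke)^2 + 1 / (ka * (ka - ke)))
    step <- (tf - tmax) / dt
    cand <- ka - step
    if (is.finite(cand) && cand > 0 &&
        ((branch == "absorption_limited" && cand > ke) ||
         (branch == "flip_flop" && cand < ke)))
      ka <- cand
  }
  attr(ka, "branch") <- branch
  ka
}

#' Bateman plasma concentration curve
#'
#' Concentration after a single oral dose under first-order absorption and
#' elimination:
#' `C(t) = F*Dose*ka / (Vd*(ka-ke)) * (exp(-ke*t) - exp(-ka*t))`, with the
#' removable singularity at `ka = ke` replaced by its series limit
#' `F*Dose*ke*t/Vd * exp(-ke*t)`. Dose in mg and Vd in L give mg/L, which is
#' numerically identical to ug/mL.
#'
#' @param t time since dose (h); vectorised.
#' @param dose administered dose (mg).
#' @param f bioavailability fraction in (0, 1].
#' @param vd volume of distribution (L).
#' @param ka,ke absorption and elimination rate constants (1/h).
#' @return concentration (ug/mL).
#' @export
bateman_concentration <- function(t, dose, f, vd, ka, ke) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("t must be non-negative and finite", call. = FALSE)
  check_positive(dose, "dose"); check_positive(vd, "vd")
  check_positive(ka, "ka"); check_positive(ke, "ke")
  if (!is.numeric(f) || f <= 0 || f > 1)
    stop("f must lie in (0, 1]", call. = FALSE)
  if (abs(ka - ke) / ke < 1e-10) {
    f * dose * ke * t / vd * exp(-ke * t)
  } else {
    f * dose * ka / (vd * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
  }
}

#' Relative change in percent
#'
#' `100 * (treatment - control) / control`, the convention used for
#' coadministration study records (a positive value is an increase).
#'
#' @param control,treatment values on the same scale; control must be nonzero.
#' @return percent change.
#' @examples
#' relative_change(10, 5)  # -50
#' @export
relative_change <- function(control, treatment) {
  if (!is.numeric(control) || any(control == 0))
    stop("control value must be nonzero", call. = FALSE)
  100 * (treatment - control) / control
}

# ---------------------------------------------------------------------------
# PK parameter records -------------------------------------------------------

#' Pharmacokinetic parameter set for one administration arm
#'
#' Container for the parameters of a single administration arm (one drug,
#' one coadministration condition). All numeric fields are optional; present
#' fields are validated for positivity, `f` for (0, 1], and for mutual
#' consistency: `ke * t_half = ln 2` and the Tmax relation between `ka`,
#' `ke` and `tmax` must hold within 1e-6 relative when all members are
#' present.
#'
#' @param fq drug name.
#' @param coadmin coadministration label (e.g. "control", "Maalox").
#' @param dose dose (mg); `cmax` (ug/mL); `tmax` (h); `t_half` (h);
#'   `auc` (ug h/mL); `ke`, `ka` (1/h); `vd` (L); `cl` (L/h);
#'   `f` bioavailability fraction.
#' @param cmax,tmax,t_half,auc,ke,ka,vd,cl,f see above.
#' @param branch which Tmax root `ka` came from, if solved.
#' @return object of class `pk_parameters`.
#' @export
pk_parameters <- function(fq, coadmin = "control", dose = NA, cmax = NA,
                          tmax = NA, t_half = NA, auc = NA, ke = NA, ka = NA,
                          vd = NA, cl = NA, f = NA, branch = NA_character_) {
  stopifnot(is.character(fq), length(fq) == 1L)
  x <- list(fq = fq, coadmin = coadmin, dose = dose, cmax = cmax, tmax = tmax,
            t_half = t_half, auc = auc, ke = ke, ka = ka, vd = vd, cl = cl,
            f = f, branch = branch)
  for (fld in c("dose", "cmax", "tmax", "t_half", "auc", "ke", "ka", "vd", "cl")) {
    v <- x[[fld]]
    if (!is.na(v) && v <= 0)
      stop(sprintf("pk_parameters: %s must be positive (got %g)", fld, v), call. = FALSE)
  }
  if (!is.na(f) && (f <= 0 || f > 1))
    stop("pk_parameters: f must lie in (0, 1]", call. = FALSE)
  if (!is.na(x$ke) && !is.na(x$t_half)) {
    if (abs(x$ke * x$t_half - log(2)) / log(2) > 1e-6)
      stop("pk_parameters: ke and t_half are inconsistent with ke*t_half = ln 2", call. = FALSE)
  }
  if (!is.na(x$ka) && !is.na(x$ke) && !is.na(x$tmax)) {
    if (abs(tmax_forward(x$ka, x$ke) - x$tmax) / x$tmax > 1e-6)
      stop("pk_parameters: ka, ke and tmax do not satisfy the Tmax relation", call. = FALSE)
  }
  structure(x, class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf("<pk_parameters %s / %s>\n", x$fq, x$coadmin))
  flds <- c("dose", "cmax", "tmax", "t_half", "auc", "ke", "ka", "vd", "cl", "f")
  for (fld in flds) if (!is.na(x[[fld]])) cat(sprintf("  %-7s %g\n", fld, x[[fld]]))
  if (!is.na(x$branch)) cat(sprintf("  branch  %s\n", x$branch))
  invisible(x)
}

.pk_csv_cols <- c(fq = "fq", coadmin_label = "coadmin", dose_mg = "dose",
                  cmax_ug_ml = "cmax", tmax_h = "tmax", thalf_h = "t_half",
                  auc_ug_h_ml = "auc", ke_per_h = "ke", ka_per_h = "ka",
                  branch = "branch")

#' Write PK arm records to CSV
#'
#' Column schema: `fq, coadmin_label, dose_mg, cmax_ug_ml, tmax_h, thalf_h,
#' auc_ug_h_ml, ke_per_h, ka_per_h, branch`.
#'
#' @param arms a list of [pk_parameters()] objects.
#' @param path output file.
#' @export
write_pk_arms <- function(arms, path) {
  if (inherits(arms, "pk_parameters")) arms <- list(arms)
  df <- do.call(rbind, lapply(arms, function(a) {
    data.frame(lapply(.pk_csv_cols, function(fld) {
      v <- a[[fld]]
      if (is.null(v)) NA else v
    }), stringsAsFactors = FALSE)
  }))
  names(df) <- names(.pk_csv_cols)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read PK arm records from CSV
#'
#' @param path CSV file in the [write_pk_arms()] schema.
#' @return list of [pk_parameters()] objects.
#' @export
read_pk_arms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(.pk_csv_cols), names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("PK arm CSV is missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    pk_parameters(fq = r$fq, coadmin = r$coadmin_label, dose = r$dose_mg,
                  cmax = r$cmax_ug_ml, tmax = r$tmax_h, t_half = r$thalf_h,
                  auc = r$auc_ug_h_ml, ke = r$ke_per_h, ka = r$ka_per_h,
                  branch = if (is.na(r$branch)) NA_character_ else r$branch)
  })
}
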