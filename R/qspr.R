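# Assembly of the coadministration study table and the univariate linear
# structure-property regressions of percent AUC change against molecular
# descriptors and computed binding energies.

#' Load the packaged coadministration study records
#'
#' One row per published control-versus-coadministration comparison: FQ,
#' multivalent metal, metal source, relative percent changes in Cmax, AUC
#' and the calculated absorption rate constant, and the source reference
#' tag. Missing values (unreported AUC or ka) are explicit `NA`s.
#'
#' @param path CSV file; defaults to the packaged table.
#' @return data frame of study records.
#' @export
study_records <- function(path = system.file("extdata", "metal_coadmin_studies.csv",
                                             package = "fqchelate")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(reference_tag = "character"))
  needed <- c("fq", "metal", "metal_source", "pct_cmax", "pct_auc", "pct_ka", "reference_tag")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("study record CSV is missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  bad <- !is.na(df$pct_auc) & df$pct_auc <= -100
  if (any(bad)) stop("percent changes must be greater than -100", call. = FALSE)
  df
}

#' Write study records to CSV
#'
#' Serializes in the exact packaged format (one decimal place for percent
#' changes, literal `NA` for missing cells), so reading the packaged table
#' and re-writing it is byte-identical -- a guard against silent
#' transcription edits.
#'
#' @param records data frame from [study_records()].
#' @param path output CSV.
#' @export
write_study_records <- function(records, path) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f", v))
  lines <- c("fq,metal,metal_source,pct_cmax,pct_auc,pct_ka,reference_tag",
             sprintf("%s,%s,%s,%s,%s,%s,%s",
                     records$fq, records$metal, records$metal_source,
                     fmt(records$pct_cmax), fmt(records$pct_auc),
                     fmt(records$pct_ka), records$reference_tag))
  writeLines(lines, path)
  invisible(path)
}

#' Load the packaged reference descriptor table
#'
#' The transcription of the published descriptor table (monoisotopic MW,
#' TPSA, Wildman-Crippen logP at two decimals) used as the regression-test
#' reference for [descriptor_table()].
#'
#' @return data frame: `name`, `generation`, `mw`, `tpsa`, `logp`.
#' @export
reference_descriptors <- function() {
  utils::read.csv(system.file("extdata", "fq_descriptors_reference.csv",
                              package = "fqchelate"), stringsAsFactors = FALSE)
}

#' Load the packaged FQ SMILES fixture
#'
#' @return data frame: `name`, `generation`, `smiles`.
#' @export
fq_smiles <- function() {
  utils::read.delim(system.file("extdata", "fq_smiles.tsv", package = "fqchelate"),
                    stringsAsFactors = FALSE)
}

#' Compute the descriptor table for a set of molecules
#'
#' @param molecules data frame with columns `name`, `smiles` (and optionally
#'   `generation`), e.g. from [fq_smiles()].
#' @return data frame: `name`, `generation`, `formula`, `mw` (monoisotopic),
#'   `tpsa`, `logp`.
#' @export
descriptor_table <- function(molecules = fq_smiles()) {
  rows <- lapply(seq_len(nrow(molecules)), function(i) {
    g <- parse_smiles(molecules$smiles[i], name = molecules$name[i])
    if (mg_n_components(g) != 1L)
      stop(sprintf("molecule '%s' is not a single connected structure", molecules$name[i]),
           call. = FALSE)
    data.frame(
      name = molecules$name[i],
      generation = if ("generation" %in% names(molecules)) molecules$generation[i] else NA_character_,
      formula = mg_formula(g),
      mw = monoisotopic_mass(g),
      tpsa = tpsa(g),
      logp = crippen_logp(g),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble the per-FQ percent-AUC-change dataset
#'
#' For each FQ, selects the AUC change from the highest-priority available
#' metal source. The default priority is aluminum hydroxide first (with the
#' crossover-study reference tag "71" preferred when one FQ has several
#' aluminum hydroxide rows), then Maalox; FQs with no row from any listed
#' source are excluded and reported in the `excluded` attribute.
#'
#' @param records data frame from [study_records()].
#' @param preference character vector of metal sources in priority order.
#' @param prefer_tag reference tag preferred on within-source ties.
#' @param collapse_duplicates if `TRUE`, drop ofloxacin when levofloxacin is
#'   also present: the two rows are the same structure (racemate and its
#'   active enantiomer) with identical descriptor values, so keeping both
#'   double-weights one molecule in the regressions.
#' @return data frame `fq`, `pct_auc`, `metal_source`, `reference_tag`, with
#'   attribute `excluded` naming FQs dropped for lack of data.
#' @export
assemble_auc_dataset <- function(records = study_records(),
                                 preference = c("aluminum hydroxide", "Maalox"),
                                 prefer_tag = "71",
                                 collapse_duplicates = FALSE) {
  records <- records[order(records$fq, records$metal_source, records$reference_tag), ]
  out <- list(); excluded <- character(0)
  for (fq in unique(records$fq)) {
    chosen <- NULL
    for (src in preference) {
      rows <- records[records$fq == fq & records$metal_source == src & !is.na(records$pct_auc), ]
      if (nrow(rows) == 0L) next
      if (nrow(rows) > 1L) {
        tagged <- rows[rows$reference_tag == prefer_tag, ]
        if (nrow(tagged) == 1L) rows <- tagged
        else if (nrow(tagged) > 1L || nrow(unique(rows[c("pct_auc")])) > 1L)
          stop(sprintf("ambiguous selection for %s from %s: %s", fq, src,
                       paste(rows$pct_auc, collapse = " / ")), call. = FALSE)
        else rows <- rows[1, ]
      }
      chosen <- rows
      break
    }
    if (is.null(chosen)) excluded <- c(excluded, fq)
    else out[[length(out) + 1L]] <- chosen[, c("fq", "pct_auc", "metal_source", "reference_tag")]
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  if (collapse_duplicates && all(c("ofloxacin", "levofloxacin") %in% df$fq))
    df <- df[df$fq != "ofloxacin", ]
  attr(df, "excluded") <- excluded
  df
}

#' Ordinary least squares line with R-squared
#'
#' Simple univariate OLS; `r_squared = 1 - SS_res/SS_tot`, which equals the
#' squared Pearson correlation for a simple linear fit. A constant response
#' yields `r_squared = 0` with a warning; a constant predictor is an error.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param x_name,y_name labels carried into the result.
#' @return object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `n`, `x_name`, `y_name`.
#' @export
linear_fit <- function(x, y, x_name = deparse(substitute(x)),
                       y_name = deparse(substitute(y))) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate predictor: x is constant", call. = FALSE)
  if (stats::sd(y) == 0) {
    warning("constant response: r_squared defined as 0")
    fit <- list(slope = 0, intercept = y[1], r_squared = 0)
  } else {
    lmfit <- stats::lm(y ~ x)
    cf <- stats::coef(lmfit)
    # 1 - SS_res/SS_tot computed directly (perfect fits stay warning-free)
    r2 <- 1 - sum(stats::residuals(lmfit)^2) / sum((y - mean(y))^2)
    fit <- list(slope = unname(cf[2]), intercept = unname(cf[1]),
                r_squared = r2)
  }
  structure(c(fit, list(n = length(x), x_name = x_name, y_name = y_name)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<fit %s ~ %s: slope %.4g, intercept %.4g, r^2 = %.4f (%.2f), n = %d>\n",
              x$y_name, x$x_name, x$slope, x$intercept, x$r_squared,
              round(x$r_squared, 2), x$n))
  invisible(x)
}

#' Structure-property regressions of AUC change
#'
#' Regresses percent AUC change on each univariate predictor: monoisotopic
#' MW, TPSA and Wildman-Crippen logP from the descriptor table, plus the
#' electronic chelation binding energy when an energy table is supplied.
#'
#' @param auc_pairs data frame `fq`, `pct_auc` from [assemble_auc_dataset()].
#' @param descriptors data frame `name`, `mw`, `tpsa`, `logp` from
#'   [descriptor_table()] (or [reference_descriptors()]).
#' @param energies optional data frame `fq` (or `name`), `delta_e_bind`.
#' @return data frame: one row per predictor with `predictor`, `slope`,
#'   `intercept`, `r_squared`, `r_squared_2dp`, `n`.
#' @export
qspr_regressions <- function(auc_pairs, descriptors = descriptor_table(),
                             energies = NULL) {
  key <- if ("name" %in% names(descriptors)) "name" else "fq"
  idx <- match(auc_pairs$fq, descriptors[[key]])
  if (anyNA(idx))
    stop(sprintf("assembly error: no descriptors for %s",
                 paste(auc_pairs$fq[is.na(idx)], collapse = ", ")), call. = FALSE)
  preds <- list(mw = descriptors$mw[idx], tpsa = descriptors$tpsa[idx],
                logp = descriptors$logp[idx])
  if (!is.null(energies)) {
    ekey <- if ("fq" %in% names(energies)) "fq" else "name"
    eidx <- match(auc_pairs$fq, energies[[ekey]])
    if (anyNA(eidx))
      stop(sprintf("assembly error: no binding energy for %s",
                   paste(auc_pairs$fq[is.na(eidx)], collapse = ", ")), call. = FALSE)
    preds$delta_e_bind <- energies$delta_e_bind[eidx]
  }
  rows <- lapply(names(preds), function(p) {
    fit <- linear_fit(preds[[p]], auc_pairs$pct_auc, x_name = p, y_name = "pct_auc")
    data.frame(predictor = p, slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, r_squared_2dp = round(fit$r_squared, 2),
               n = fit$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
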