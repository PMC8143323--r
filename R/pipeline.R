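# Pipeline configuration and subcommand dispatch. The Rscript front end at
# inst/cli/fqchelate.R is a thin wrapper over run_subcommand(); everything
# here is callable directly from R.

#' Pipeline configuration
#'
#' Flat key-value configuration shared by all subcommands. Defaults
#' reproduce the packaged reference analysis: aluminum hydroxide (tag "71")
#' preferred with Maalox fallback, the oxo-aromatic descriptor convention,
#' and the absorption-limited branch of the Tmax inversion.
#'
#' @param input input file path (subcommand-specific).
#' @param output output file path; `NULL` writes to stdout-adjacent default.
#' @param source_preference metal-source priority for the AUC assembly.
#' @param prefer_tag reference tag preferred on ties.
#' @param collapse_duplicates collapse the ofloxacin/levofloxacin duplicate
#'   structure in the regression dataset.
#' @param oxo_ring_aromatic descriptor aromaticity convention switch.
#' @param branch default Tmax-inversion branch.
#' @param digits rounding precision for reports.
#' @param seed integer seed for stochastic subcommands.
#' @param energies optional energy-ledger path for the binding-energy
#'   regression.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, output = NULL,
                            source_preference = c("aluminum hydroxide", "Maalox"),
                            prefer_tag = "71",
                            collapse_duplicates = FALSE,
                            oxo_ring_aromatic = TRUE,
                            branch = "absorption_limited",
                            digits = 2L, seed = 1L, energies = NULL) {
  structure(list(input = input, output = output,
                 source_preference = source_preference, prefer_tag = prefer_tag,
                 collapse_duplicates = collapse_duplicates,
                 oxo_ring_aromatic = oxo_ring_aromatic, branch = branch,
                 digits = as.integer(digits), seed = as.integer(seed),
                 energies = energies),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with a flat key space; missing keys take defaults.
#' @param overrides named list of values overriding the file (CLI flags).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) jsonlite::read_json(path, simplifyVector = TRUE) else list()
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(pipeline_config, vals)
}

.subcommands <- c("simulate", "extract-ka", "descriptors", "chelate-prep",
                  "energies", "qspr", "reproduce")

#' Run a pipeline subcommand
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{read a scenario JSON (`input`), write control and
#'     treatment curves plus the study record CSV.}
#'   \item{extract-ka}{read a curve CSV (`input`), write extracted PK
#'     parameters in the PK-arm CSV schema.}
#'   \item{descriptors}{compute the descriptor table for a SMILES TSV
#'     (`input`, defaults to the packaged FQ set).}
#'   \item{chelate-prep}{read an FQ cation XYZ (`input`), build Al/Mg/Ca
#'     chelate starting geometries and staged job specifications.}
#'   \item{energies}{read an energy ledger JSON (`input`), write binding
#'     energies per metal.}
#'   \item{qspr}{assemble the AUC dataset and run the descriptor
#'     regressions (plus binding-energy regression when `energies` set).}
#'   \item{reproduce}{descriptors on the packaged SMILES fixture compared
#'     against the packaged reference table, then the qspr regressions; the
#'     returned report carries both computed and reference values.}
#' }
#'
#' @param name subcommand name.
#' @param config a [pipeline_config()].
#' @return subcommand-specific result, invisibly where files are written.
#' @export
run_subcommand <- function(name, config = pipeline_config()) {
  if (!(name %in% .subcommands))
    stop(sprintf("usage error: unknown subcommand '%s' (expected one of %s)",
                 name, paste(.subcommands, collapse = ", ")), call. = FALSE)
  stopifnot(inherits(config, "pipeline_config"))
  old <- options(fqchelate.oxo_ring_aromatic = config$oxo_ring_aromatic)
  on.exit(options(old), add = TRUE)
  switch(name,
    "simulate" = {
      sc <- read_scenario(config$input)
      sc$seed <- config$seed
      study <- simulate_interaction_study(sc)
      out <- if (is.null(config$output)) "interaction_study.csv" else config$output
      utils::write.csv(study$record, out, row.names = FALSE, quote = FALSE)
      base <- sub("\\.csv$", "", out)
      write_curve(simulate_curve(sc, "control"), paste0(base, "_control_curve.csv"))
      write_curve(simulate_curve(sc, "treatment"), paste0(base, "_treatment_curve.csv"))
      invisible(study)
    },
    "extract-ka" = {
      curves <- read_curves(config$input)
      if (inherits(curves, "concentration_curve")) curves <- list(curves)
      arms <- lapply(curves, extract_pk, branch = config$branch)
      out <- if (is.null(config$output)) "pk_arms.csv" else config$output
      write_pk_arms(arms, out)
      invisible(arms)
    },
    "descriptors" = {
      mols <- if (is.null(config$input)) fq_smiles()
              else utils::read.delim(config$input, stringsAsFactors = FALSE)
      tab <- descriptor_table(mols)
      tab$mw <- round(tab$mw, config$digits)
      tab$tpsa <- round(tab$tpsa, config$digits)
      tab$logp <- round(tab$logp, config$digits)
      if (!is.null(config$output))
        utils::write.csv(tab, config$output, row.names = FALSE, quote = FALSE)
      tab
    },
    "chelate-prep" = {
      geo <- read_xyz(config$input)
      specs <- list()
      for (m in c("Al", "Mg", "Ca")) {
        cx <- build_chelate_geometry(geo, m)
        for (stage in c("optimize", "frequencies", "single_point"))
          specs[[sprintf("%s_%s", cx$label, stage)]] <- qm_jobspec(cx, stage)
      }
      if (!is.null(config$output)) {
        dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
        for (nm in names(specs))
          write_jobspec(specs[[nm]], file.path(config$output, paste0(nm, ".json")))
      }
      invisible(specs)
    },
    "energies" = {
      ledger <- read_energy_ledger(config$input)
      tab <- ledger_binding_energies(ledger)
      if (!is.null(config$output))
        utils::write.csv(tab, config$output, row.names = FALSE, quote = FALSE)
      tab
    },
    "qspr" = {
      auc <- assemble_auc_dataset(study_records(),
                                  preference = config$source_preference,
                                  prefer_tag = config$prefer_tag,
                                  collapse_duplicates = config$collapse_duplicates)
      energies <- NULL
      if (!is.null(config$energies)) {
        ledger <- read_energy_ledger(config$energies)
        energies <- ledger_binding_energies(ledger)
      }
      tab <- qspr_regressions(auc, descriptor_table(), energies = energies)
      if (!is.null(config$output))
        utils::write.csv(tab, config$output, row.names = FALSE, quote = FALSE)
      tab
    },
    "reproduce" = {
      computed <- descriptor_table()
      ref <- reference_descriptors()
      idx <- match(computed$name, ref$name)
      desc_report <- data.frame(
        name = computed$name,
        mw = round(computed$mw, 2), mw_ref = ref$mw[idx],
        tpsa = round(computed$tpsa, 2), tpsa_ref = ref$tpsa[idx],
        logp = round(computed$logp, 2), logp_ref = ref$logp[idx],
        stringsAsFactors = FALSE)
      desc_report$match <- desc_report$mw == desc_report$mw_ref &
        desc_report$tpsa == desc_report$tpsa_ref &
        desc_report$logp == desc_report$logp_ref
      auc <- assemble_auc_dataset(collapse_duplicates = config$collapse_duplicates)
      reg <- qspr_regressions(auc, computed)
      res <- list(descriptors = desc_report, regressions = reg)
      if (!is.null(config$output)) {
        jsonlite::write_json(res, config$output, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows", pretty = TRUE)
        invisible(res)
      } else res
    }
  )
}
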