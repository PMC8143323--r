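# Stoichiometric bookkeeping of fluoroquinolone-metal chelation energetics.
#
# The modeled reaction displaces two waters from the octahedral hexahydrate:
#   FQH+  +  M(H2O)6^n+   ->   [FQ.M(H2O)4]^(n+1)+  +  2 H2O
# Electronic binding energies use solvated (PCM) single points; Gibbs
# binding energies add the 310 K gas-phase thermal correction to the same
# single points. All energies are bookkept in hartree and reported in
# kcal/mol via 1 hartree = 627.5095 kcal/mol.

#' Convert hartree to kcal/mol (and back)
#'
#' @param x energy value(s).
#' @return converted energy.
#' @export
hartree_to_kcal <- function(x) x * HARTREE_TO_KCAL

#' @rdname hartree_to_kcal
#' @export
kcal_to_hartree <- function(x) x / HARTREE_TO_KCAL

.species_roles <- c("fq_cation", "metal_hexahydrate", "chelate_complex", "water")

parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop(sprintf("cannot parse formula '%s'", formula), call. = FALSE)
  counts <- integer(0)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

#' Chemical species with quantum-chemistry energy components
#'
#' A species record for the binding-energy bookkeeping: identity, role,
#' charge/multiplicity, optional composition (formula or 3D geometry) and
#' the staged energy components in hartree.
#'
#' Charge bookkeeping is validated against the role: the FQ cation carries
#' +1 (carboxyl un-ionized, terminal piperazine N protonated under the
#' acidic gastric conditions modeled), the free metals are octahedral
#' hexahydrates at their ionic charge (+2 for Mg/Ca, +3 for Al), water is
#' neutral, and a chelate complex carries the sum.
#'
#' @param label species label.
#' @param role one of `"fq_cation"`, `"metal_hexahydrate"`,
#'   `"chelate_complex"`, `"water"`.
#' @param charge formal charge (e).
#' @param multiplicity spin multiplicity (all species here are singlets).
#' @param formula molecular formula, e.g. `"C17H19FN3O3"` (charge given
#'   separately). Used for atom-conservation checks when no geometry is
#'   attached.
#' @param geometry optional data frame `element, x, y, z` (Angstrom).
#' @param e_opt electronic energy at the optimization level (hartree).
#' @param g_thermal_corr Gibbs thermal correction at 310 K (hartree).
#' @param e_pcm_sp solvated (PCM water) single-point energy (hartree).
#' @param metal metal element for hexahydrate/complex roles.
#' @return object of class `qm_species`.
#' @export
species <- function(label, role, charge, multiplicity = 1L,
                    formula = NA_character_, geometry = NULL,
                    e_opt = NA_real_, g_thermal_corr = NA_real_,
                    e_pcm_sp = NA_real_, metal = NA_character_) {
  role <- match.arg(role, .species_roles)
  charge <- as.integer(charge)
  if (role == "water" && charge != 0L)
    stop("water must be neutral", call. = FALSE)
  if (role == "fq_cation" && charge != 1L)
    stop("fq_cation must carry charge +1 (N-protonated, un-ionized carboxyl)", call. = FALSE)
  if (role == "metal_hexahydrate") {
    if (is.na(metal) || !(metal %in% names(.metal_charge)))
      stop("metal_hexahydrate requires metal one of Mg, Ca, Al", call. = FALSE)
    if (charge != .metal_charge[[metal]])
      stop(sprintf("%s hexahydrate must carry charge +%d", metal, .metal_charge[[metal]]),
           call. = FALSE)
  }
  if (role == "chelate_complex") {
    if (is.na(metal) || !(metal %in% names(.metal_charge)))
      stop("chelate_complex requires metal one of Mg, Ca, Al", call. = FALSE)
    if (charge != .metal_charge[[metal]] + 1L)
      stop(sprintf("chelate complex with %s must carry charge +%d (fq +1 plus metal charge)",
                   metal, .metal_charge[[metal]] + 1L), call. = FALSE)
  }
  if (multiplicity != 1L)
    stop("all species in this model are closed-shell singlets", call. = FALSE)
  structure(list(label = label, role = role, charge = charge,
                 multiplicity = as.integer(multiplicity), formula = formula,
                 geometry = geometry, e_opt = e_opt,
                 g_thermal_corr = g_thermal_corr, e_pcm_sp = e_pcm_sp,
                 metal = metal),
            class = "qm_species")
}

#' @export
print.qm_species <- function(x, ...) {
  cat(sprintf("<qm_species %s (%s) charge %+d mult %d>\n", x$label, x$role,
              x$charge, x$multiplicity))
  invisible(x)
}

species_composition <- function(sp) {
  if (!is.null(sp$geometry)) {
    tab <- table(sp$geometry$element)
    counts <- as.integer(tab); names(counts) <- names(tab)
    return(counts)
  }
  parse_formula(sp$formula)
}

sum_composition <- function(species_counts) {
  total <- integer(0)
  for (sc in species_counts) {
    comp <- sc$comp * sc$n
    for (el in names(comp)) total[el] <- (if (el %in% names(total)) total[[el]] else 0L) + comp[[el]]
  }
  total[order(names(total))]
}

#' Binding energy of the chelation reaction
#'
#' Computes `dE = [E(complex) + n_water*E(water) - E(fq) - E(hexahydrate)]`
#' converted to kcal/mol. With `energy_field = "e_pcm_sp"` this is the
#' electronic (PCM single-point) binding energy; with `"gibbs"` the same
#' combination is applied to `e_pcm_sp + g_thermal_corr` per species (the
#' 310 K gas-phase thermal correction added to the solvated single point at
#' the optimization geometry).
#'
#' Element counts and total charge must balance across the reaction; a
#' violation raises a stoichiometry error naming the residual.
#'
#' @param complex,fq,metal_hexahydrate,water [species()] records.
#' @param energy_field `"e_pcm_sp"` or `"gibbs"`.
#' @param n_water_displaced waters released on chelation (default 2: two of
#'   the six hydration waters are replaced by the bidentate donor oxygens).
#' @return binding energy in kcal/mol.
#' @export
binding_energy <- function(complex, fq, metal_hexahydrate, water,
                           energy_field = c("e_pcm_sp", "gibbs"),
                           n_water_displaced = 2L) {
  energy_field <- match.arg(energy_field)
  for (sp in list(complex, fq, metal_hexahydrate, water))
    stopifnot(inherits(sp, "qm_species"))
  if (complex$role != "chelate_complex" || fq$role != "fq_cation" ||
      metal_hexahydrate$role != "metal_hexahydrate" || water$role != "water")
    stop("species roles do not match the binding reaction", call. = FALSE)
  # charge conservation
  q_react <- fq$charge + metal_hexahydrate$charge
  q_prod <- complex$charge + n_water_displaced * water$charge
  if (q_react != q_prod)
    stop(sprintf("stoichiometry error: charge residual %+d (reactants %+d, products %+d)",
                 q_prod - q_react, q_react, q_prod), call. = FALSE)
  # atom conservation
  comps <- lapply(list(complex, fq, metal_hexahydrate, water), species_composition)
  if (any(vapply(comps, is.null, logical(1))))
    stop("ledger error: every species needs a formula or geometry for the conservation check",
         call. = FALSE)
  react <- sum_composition(list(list(comp = comps[[2]], n = 1L),
                                list(comp = comps[[3]], n = 1L)))
  prod <- sum_composition(list(list(comp = comps[[1]], n = 1L),
                               list(comp = comps[[4]], n = n_water_displaced)))
  all_el <- union(names(react), names(prod))
  resid <- vapply(all_el, function(el) {
    p <- if (el %in% names(prod)) prod[[el]] else 0L
    r <- if (el %in% names(react)) react[[el]] else 0L
    p - r
  }, integer(1))
  if (any(resid != 0L))
    stop(sprintf("stoichiometry error: element residual(s) %s",
                 paste(sprintf("%s%+d", all_el[resid != 0L], resid[resid != 0L]), collapse = ", ")),
         call. = FALSE)
  get_e <- function(sp) {
    if (energy_field == "e_pcm_sp") {
      if (is.na(sp$e_pcm_sp))
        stop(sprintf("ledger error: species '%s' lacks e_pcm_sp", sp$label), call. = FALSE)
      sp$e_pcm_sp
    } else {
      if (is.na(sp$e_pcm_sp) || is.na(sp$g_thermal_corr))
        stop(sprintf("ledger error: species '%s' lacks e_pcm_sp or g_thermal_corr", sp$label),
             call. = FALSE)
      sp$e_pcm_sp + sp$g_thermal_corr
    }
  }
  delta_hartree <- get_e(complex) + n_water_displaced * get_e(water) -
    get_e(fq) - get_e(metal_hexahydrate)
  hartree_to_kcal(delta_hartree)
}

# ---------------------------------------------------------------------------
# Staged quantum-chemistry job specifications --------------------------------

.qm_stages <- c("optimize", "frequencies", "single_point")

#' Emit a staged quantum-chemistry job specification
#'
#' Builds an engine-agnostic description of one stage of the energy
#' workflow: geometry optimization and frequencies at PBE-D3BJ/6-31G(d)
#' (frequencies thermally evaluated at 310 K, approximate GI-tract
#' temperature), then a PBE-D3BJ/6-31+G(d,p) single point in PCM water.
#'
#' @param sp a [species()] with geometry attached.
#' @param stage `"optimize"`, `"frequencies"` or `"single_point"`.
#' @return object of class `qm_jobspec`.
#' @export
qm_jobspec <- function(sp, stage = c("optimize", "frequencies", "single_point")) {
  stopifnot(inherits(sp, "qm_species"))
  stage <- match.arg(stage)
  if (is.null(sp$geometry))
    stop(sprintf("jobspec error: species '%s' has no geometry", sp$label), call. = FALSE)
  structure(list(
    label = sp$label,
    stage = stage,
    method = "PBE",
    dispersion = "D3BJ",
    basis = if (stage == "single_point") "6-31+G(d,p)" else "6-31G(d)",
    solvent_model = if (stage == "single_point") "pcm_water" else "none",
    temperature_k = if (stage == "frequencies") 310 else NA_real_,
    charge = sp$charge,
    multiplicity = sp$multiplicity,
    geometry = sp$geometry
  ), class = "qm_jobspec")
}

#' Serialize / parse a job specification (JSON)
#'
#' `emit -> parse -> emit` is byte-identical.
#'
#' @param spec a [qm_jobspec()].
#' @param path optional file; when `NULL` the JSON text is returned.
#' @export
write_jobspec <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "qm_jobspec"))
  x <- unclass(spec)
  x$geometry <- lapply(seq_len(nrow(spec$geometry)), function(i)
    list(element = spec$geometry$element[i],
         x = spec$geometry$x[i], y = spec$geometry$y[i], z = spec$geometry$z[i]))
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' @rdname write_jobspec
#' @param text JSON text (alternative to `path`).
#' @export
read_jobspec <- function(path = NULL, text = NULL) {
  x <- if (is.null(text)) jsonlite::read_json(path) else jsonlite::fromJSON(text, simplifyVector = FALSE)
  geo <- do.call(rbind, lapply(x$geometry, function(a)
    data.frame(element = a$element, x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)))
  structure(list(
    label = x$label, stage = x$stage, method = x$method,
    dispersion = x$dispersion, basis = x$basis, solvent_model = x$solvent_model,
    temperature_k = if (is.null(x$temperature_k)) NA_real_ else x$temperature_k,
    charge = as.integer(x$charge), multiplicity = as.integer(x$multiplicity),
    geometry = geo
  ), class = "qm_jobspec")
}

# ---------------------------------------------------------------------------
# Energy ledgers -------------------------------------------------------------

#' Read an energy ledger (JSON) into species records
#'
#' The ledger is a JSON array of species entries with fields `label`,
#' `role`, `charge`, `formula`, and the hartree energy components
#' `e_opt`, `g_thermal_corr`, `e_pcm_sp` (plus `metal` where applicable).
#'
#' @param path JSON file.
#' @return named list of [species()] records (names = labels).
#' @export
read_energy_ledger <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(entries, function(e) {
    species(label = e$label, role = e$role, charge = e$charge,
            multiplicity = if (is.null(e$multiplicity)) 1L else e$multiplicity,
            formula = if (is.null(e$formula)) NA_character_ else e$formula,
            e_opt = if (is.null(e$e_opt)) NA_real_ else e$e_opt,
            g_thermal_corr = if (is.null(e$g_thermal_corr)) NA_real_ else e$g_thermal_corr,
            e_pcm_sp = if (is.null(e$e_pcm_sp)) NA_real_ else e$e_pcm_sp,
            metal = if (is.null(e$metal)) NA_character_ else e$metal)
  })
  names(out) <- vapply(out, function(s) s$label, character(1))
  out
}

#' Binding energies for every metal in a ledger
#'
#' Convenience wrapper: pairs each chelate complex in a ledger with the
#' matching hexahydrate, the FQ cation and water, and computes electronic
#' and Gibbs binding energies.
#'
#' @param ledger named list from [read_energy_ledger()].
#' @param n_water_displaced see [binding_energy()].
#' @return data frame: `metal`, `delta_e_bind`, `delta_g_bind` (kcal/mol).
#' @export
ledger_binding_energies <- function(ledger, n_water_displaced = 2L) {
  roles <- vapply(ledger, function(s) s$role, character(1))
  fq <- ledger[[which(roles == "fq_cation")[1]]]
  water <- ledger[[which(roles == "water")[1]]]
  complexes <- ledger[roles == "chelate_complex"]
  hexa <- ledger[roles == "metal_hexahydrate"]
  hexa_metal <- vapply(hexa, function(s) s$metal, character(1))
  out <- do.call(rbind, lapply(complexes, function(cx) {
    mh <- hexa[[which(hexa_metal == cx$metal)[1]]]
    data.frame(
      metal = cx$metal,
      delta_e_bind = binding_energy(cx, fq, mh, water, "e_pcm_sp", n_water_displaced),
      delta_g_bind = binding_energy(cx, fq, mh, water, "gibbs", n_water_displaced),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
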