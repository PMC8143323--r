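# Physicochemical descriptors from SMILES: monoisotopic / average molecular
# mass, Ertl fragment-contribution TPSA (N/O/S/P polar), and Wildman-Crippen
# atom-contribution logP. All three operate on the mol_graph produced by
# parse_smiles() and are therefore invariant to the atom order of the input
# SMILES spelling.

as_mol_graph <- function(x, ...) {
  if (inherits(x, "mol_graph")) x else parse_smiles(x, ...)
}

#' Monoisotopic molecular mass
#'
#' Sum of most-abundant-isotope atomic masses over all atoms, hydrogens
#' included.
#'
#' @param x a SMILES string or a `mol_graph`.
#' @return mass in g/mol.
#' @examples
#' \donttest{monoisotopic_mass("O")  # 18.0106}
#' @export
monoisotopic_mass <- function(x) {
  g <- as_mol_graph(x)
  sum(.monoisotopic_mass[g$atoms$element])
}

#' Average (abundance-weighted) molecular mass
#'
#' Standard atomic weights summed over all atoms. Exposed under a distinct
#' name because the packaged reference descriptor table uses monoisotopic
#' masses; see [monoisotopic_mass()].
#' @inheritParams monoisotopic_mass
#' @return mass in g/mol.
#' @export
average_mass <- function(x) {
  g <- as_mol_graph(x)
  sum(.average_mass[g$atoms$element])
}

# ---------------------------------------------------------------------------
# Ertl TPSA ----------------------------------------------------------------

# Fragment contributions (Angstrom^2) of the Ertl topological polar surface
# area model, keyed by atom environment. Key fields: element, aromatic flag,
# charge sign, H count, and counts of single/double/triple/aromatic bonds to
# heavy atoms ("s","d","t","ar"), plus a 3-ring flag for N/O.
tpsa_contribution <- function(elt, arom, chg, nH, s, d, t, ar, in3) {
  if (elt == "N") {
    if (!arom) {
      if (chg == 0) {
        if (nH == 0 && s == 3 && d == 0 && t == 0) return(if (in3) 3.01 else 3.24)
        if (nH == 0 && s == 1 && d == 1 && t == 0) return(12.36)
        if (nH == 0 && s == 0 && d == 0 && t == 1) return(23.79)
        if (nH == 0 && s == 1 && d == 2) return(11.68)
        if (nH == 0 && d == 1 && t == 1) return(4.12)
        if (nH == 1 && s == 2 && d == 0) return(if (in3) 21.94 else 12.03)
        if (nH == 1 && s == 0 && d == 1) return(23.85)
        if (nH == 2 && s == 1 && d == 0) return(26.02)
      } else if (chg > 0) {
        if (nH == 0 && s == 4) return(0.00)
        if (nH == 0 && s == 2 && d == 1) return(3.01)
        if (nH == 0 && s == 1 && t == 1) return(4.36)
        if (nH == 1 && s == 3) return(4.44)
        if (nH == 1 && s == 1 && d == 1) return(13.97)
        if (nH == 2 && s == 2) return(16.61)
        if (nH == 2 && s == 0 && d == 1) return(25.59)
        if (nH == 3 && s == 1) return(27.64)
      }
    } else {
      if (chg == 0) {
        if (nH == 0 && ar == 2 && s == 0 && d == 0) return(12.89)
        if (nH == 0 && ar == 3 && s == 0) return(4.41)
        if (nH == 0 && ar == 2 && s == 1) return(4.93)
        if (nH == 0 && ar == 2 && d == 1) return(8.39)
        if (nH == 1 && ar == 2) return(15.79)
      } else if (chg > 0) {
        if (nH == 0 && ar == 3) return(4.10)
        if (nH == 0 && ar == 2 && s == 1) return(3.88)
        if (nH == 1 && ar == 2) return(14.14)
      }
    }
    # Ertl single-atom estimation rule for environments outside the table
    # (heavy-atom connections only count toward the attachment penalty)
    est <- 30.5 - (s + d + t + ar) * 8.2 + nH * 1.5
    message(sprintf("tpsa: no published N contribution for environment (H%d s%d d%d t%d ar%d chg%+d); using estimation rule",
                    nH, s, d, t, ar, chg))
    return(max(est, 0))
  }
  if (elt == "O") {
    if (!arom) {
      if (chg == 0) {
        if (nH == 0 && s == 2 && d == 0) return(if (in3) 12.53 else 9.23)
        if (nH == 0 && s == 0 && d == 1) return(17.07)
        if (nH == 1 && s == 1) return(20.23)
      } else if (chg < 0) {
        if (nH == 0 && s == 1 && d == 0) return(23.06)
      }
    } else {
      if (nH == 0 && ar == 2) return(13.14)
    }
    est <- 28.5 - (s + d + t + ar) * 8.6 + nH * 1.5
    message(sprintf("tpsa: no published O contribution for environment (H%d s%d d%d ar%d chg%+d); using estimation rule",
                    nH, s, d, ar, chg))
    return(max(est, 0))
  }
  if (elt == "S") {
    if (!arom && chg == 0) {
      if (nH == 0 && s == 2 && d == 0) return(25.30)
      if (nH == 0 && s == 0 && d == 1) return(32.09)
      if (nH == 0 && s == 2 && d == 1) return(19.21)
      if (nH == 0 && s == 2 && d == 2) return(8.38)
      if (nH == 1 && s == 1) return(38.80)
    } else if (arom) {
      if (nH == 0 && ar == 2 && d == 0) return(28.24)
      if (nH == 0 && ar == 2 && d == 1) return(21.70)
    }
    return(0)
  }
  if (elt == "P") {
    if (!arom && chg == 0) {
      if (nH == 0 && s == 3 && d == 0) return(13.59)
      if (nH == 0 && s == 1 && d == 1) return(34.14)
      if (nH == 0 && s == 3 && d == 1) return(9.81)
      if (nH == 1 && s == 2 && d == 1) return(23.47)
    }
    return(0)
  }
  0
}

#' Topological polar surface area (Ertl fragment contributions)
#'
#' Sum of published polar-fragment surface contributions over polar-atom
#' environments, treating nitrogen, oxygen, sulfur and phosphorus as polar by
#' default. Environments with no published contribution fall back to the
#' Ertl single-atom estimation rule and emit a message.
#'
#' @inheritParams monoisotopic_mass
#' @param polar_elements elements considered polar.
#' @return TPSA in Angstrom^2.
#' @examples
#' \donttest{tpsa("C")  # 0: no polar atoms}
#' @export
tpsa <- function(x, polar_elements = c("N", "O", "S", "P")) {
  g <- as_mol_graph(x)
  total <- 0
  for (i in seq_len(nrow(g$atoms))) {
    elt <- g$atoms$element[i]
    if (!(elt %in% polar_elements)) next
    nb <- mg_neighbors(g, i)
    heavy <- nb[g$atoms$element[nb] != "H"]
    s <- d <- t <- ar <- 0L
    for (j in heavy) {
      b <- mg_bond_to(g, i, j)
      if (b$aromatic[1]) ar <- ar + 1L
      else if (b$order[1] == 1L) s <- s + 1L
      else if (b$order[1] == 2L) d <- d + 1L
      else if (b$order[1] == 3L) t <- t + 1L
    }
    total <- total + tpsa_contribution(
      elt, g$atoms$aromatic[i], g$atoms$charge[i], g$atoms$n_h[i],
      s, d, t, ar, g$atoms$in_ring3[i])
  }
  total
}

# ---------------------------------------------------------------------------
# Wildman-Crippen logP ------------------------------------------------------

# Atom-class contributions of the Wildman-Crippen logP model. Classification
# follows the published atom-type hierarchy (first match in table order);
# each helper below tests one type against the local environment.
.crippen_logp_value <- c(
  C1 = 0.1441, C2 = 0, C3 = -0.2035, C4 = -0.2051, C5 = -0.2783, C6 = 0.1551,
  C7 = 0.0017, C8 = 0.08452, C9 = -0.1444, C10 = -0.0516, C11 = 0.1193,
  C12 = -0.0967, C13 = -0.5443, C14 = 0, C15 = 0.245, C16 = 0.198, C17 = 0,
  C18 = 0.1581, C19 = 0.2955, C20 = 0.2713, C21 = 0.136, C22 = 0.4619,
  C23 = 0.5437, C24 = 0.1893, C25 = -0.8186, C26 = 0.264, C27 = 0.2148,
  CS = 0.08129,
  H1 = 0.123, H2 = -0.2677, H3 = 0.2142, H4 = 0.298, HS = 0.1125,
  N1 = -1.019, N2 = -0.7096, N3 = -1.027, N4 = -0.5188, N5 = 0.08387,
  N6 = 0.1836, N7 = -0.3187, N8 = -0.4458, N9 = 0.01508, N10 = -1.95,
  N11 = -0.3239, N12 = -1.119, N13 = -0.3396, N14 = 0.2887, NS = -0.4806,
  O1 = 0.1552, O2 = -0.2893, O3 = -0.0684, O4 = -0.4195, O5 = 0.0335,
  O6 = -0.3339, O7 = -1.189, O8 = 0.1788, O9 = -0.1526, O10 = 0.1129,
  O11 = 0.4833, O12 = -1.326, OS = -0.1188,
  F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857, Hal = -2.996,
  P = 0.8612, S1 = 0.6482, S2 = -0.0024, S3 = 0.6237,
  Me1 = -0.3808, Me2 = -0.0025
)

.me1_elements <- c("Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba",
                   "B", "Al", "Ga", "In", "Tl", "Si", "Ge", "Sn", "Pb",
                   "As", "Sb", "Bi", "Se", "Te", "Po")
.me2_elements <- c("Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
                   "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
                   "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg")
.common_organic <- c("C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# Classify one atom. env: precomputed neighbourhood summary (see below).
crippen_atom_type <- function(env) {
  e <- env
  with(e, {
    if (elt == "C" && !arom) {
      # aliphatic carbon
      if (nH == 4L || (nH == 3L && nC_al >= 1L) || (nH == 2L && nC_al >= 2L && !has_dbl)) return("C1")
      if ((nH == 1L && nC_al >= 3L) || (nH == 0L && nC_al >= 4L)) return("C2")
      if ((nH == 3L && nHet_al >= 1L) ||
          (nH == 2L && degree == 4L && nHet_al >= 1L && nHeavy_al >= 2L)) return("C3")
      if ((nH == 1L && degree == 4L && nHet_al >= 1L && nHeavy_al >= 3L) ||
          (nH == 0L && degree == 4L && nHet_al >= 1L && nHeavy_al >= 4L)) return("C4")
      if (has_dbl_het_al) return("C5")
      if (has_dbl_C_al &&
          ((nH == 2L) || (nH == 1L && nHeavy_al >= 2L) ||
           (nH == 0L && nHeavy_al >= 3L) || n_dbl_C_al >= 2L)) return("C6")
      if (has_triple) return("C7")
      if (nH == 3L && nC_ar >= 1L) return("C8")
      if (nH == 3L && nAr >= 1L) return("C9")
      if (nH == 2L && degree == 4L && nAr >= 1L) return("C10")
      if (nH == 1L && degree == 4L && nAr >= 1L) return("C11")
      if (nH == 0L && degree == 4L && nAr >= 1L) return("C12")
      if (has_dbl_C_al && nAr >= 1L) return("C26")
      if (has_dbl_C_ar) return("C26")
      if (degree == 4L && nUncommon_al >= 1L) return("C27")
      return("CS")
    }
    if (elt == "C" && arom) {
      if (nH == 0L && nUncommonC13_single >= 1L) return("C13")
      if (nF >= 1L) return("C14")
      if (nCl >= 1L) return("C15")
      if (nBr >= 1L) return("C16")
      if (nI >= 1L) return("C17")
      if (nH >= 1L) return("C18")
      if (n_ar_bonds == 3L) return("C19")
      if (n_single_ar_nbr >= 1L) return("C20")
      if (n_single_C_al >= 1L) return("C21")
      if (n_single_N_al >= 1L) return("C22")
      if (n_single_O_al >= 1L) return("C23")
      if (n_single_S_al >= 1L) return("C24")
      if (has_dbl_CNO_al) return("C25")
      return("CS")
    }
    if (elt == "H") {
      if (h_attached %in% c("C", "H")) return("H1")
      if (h_attached == "O") {
        if (h_o_nbr_cx4_or_c) return("H2")
        if (h_o_nbr_not_cnos) return("H2")
        if (h_o_nbr_n) return("H3")
        if (h_o_nbr_acid || h_o_nbr_os) return("H4")
        return("HS")
      }
      if (h_attached == "N") return("H3")
      if (!(h_attached %in% c("C", "N", "O"))) return("H2")
      return("HS")
    }
    if (elt == "N") {
      if (!arom && charge == 0L) {
        if (nH == 2L && nHeavy_al >= 1L && !has_dbl) return("N1")
        if (nH == 1L && nHeavy_al >= 2L && !has_dbl) return("N2")
        if (nH == 2L && nAr >= 1L) return("N3")
        if (nH == 1L && nAr >= 1L && !has_dbl) return("N4")
        if (nH == 1L && has_dbl) return("N5")
        if (nH == 0L && has_dbl && nHeavy_total >= 2L) return("N6")
        if (nH == 0L && nHeavy_al >= 3L) return("N7")
        if (nH == 0L && nAr >= 1L && nHeavy_total >= 3L) return("N8")
        if (has_triple) return("N9")
      }
      if (!arom && charge > 0L && nH >= 1L) return("N10")
      if (arom && charge <= 0L) return("N11")
      if (arom && charge > 0L) return("N12")
      if (!arom && charge > 0L && nH == 0L && nHeavy_total >= 3L) return("N13")
      if (charge != 0L || has_triple) return("N14")
      return("NS")
    }
    if (elt == "O") {
      if (arom) return("O1")
      if (nH >= 1L) return("O2")
      if (charge == 0L && nHeavy_al == 2L && !has_dbl) return("O3")
      if (charge == 0L && nAr >= 1L && nHeavy_total == 2L && !has_dbl) return("O4")
      if (has_dbl_NO || (charge < 0L && nN >= 1L)) return("O5")
      if ((charge < 0L && nS >= 1L) || has_dbl_S) return("O6")
      if (charge < 0L && carboxylate) return("O12")
      if (charge < 0L) return("O7")
      if (has_dbl_C_ar) return("O8")
      if (has_dbl_C_al) {
        if (o9_env) return("O9")
        if (o10_env) return("O10")
        if (o11_env) return("O11")
      }
      return("OS")
    }
    if (elt == "S") {
      if (charge != 0L || has_dbl_NOPS) return("S2")
      if (arom) return("S3")
      return("S1")
    }
    if (elt %in% c("F", "Cl", "Br", "I")) {
      if (charge != 0L) return("Hal")
      return(elt)
    }
    if (elt %in% c("Li", "Na", "K", "Rb", "Cs") && charge > 0L) return("Hal")
    if (elt == "P") return("P")
    if (elt %in% .me1_elements) return("Me1")
    if (elt %in% .me2_elements) return("Me2")
    stop(sprintf("crippen_logp: no atom type for element %s", elt), call. = FALSE)
  })
}

# Neighbourhood summary used by crippen_atom_type().
crippen_env <- function(g, i) {
  a <- g$atoms
  nb <- mg_neighbors(g, i)
  nb_h <- nb[a$element[nb] == "H"]
  heavy <- nb[a$element[nb] != "H"]
  binfo <- lapply(nb, function(j) mg_bond_to(g, i, j)[1, ])
  names(binfo) <- as.character(nb)
  is_ar <- a$aromatic
  elt_of <- a$element
  # bond classes to heavy neighbours
  h_single_al <- function(el) sum(vapply(heavy, function(j) {
    b <- binfo[[as.character(j)]]
    b$order == 1L && !b$aromatic && !is_ar[j] && elt_of[j] == el
  }, logical(1)))
  dbl_to <- function(pred) any(vapply(heavy, function(j) {
    b <- binfo[[as.character(j)]]
    b$order == 2L && !b$aromatic && pred(j)
  }, logical(1)))
  env <- list(
    elt = elt_of[i], arom = is_ar[i], charge = a$charge[i],
    nH = length(nb_h), degree = length(nb),
    nHeavy_total = length(heavy),
    nHeavy_al = sum(!is_ar[heavy]),
    nC_al = sum(elt_of[heavy] == "C" & !is_ar[heavy]),
    nC_ar = sum(elt_of[heavy] == "C" & is_ar[heavy]),
    nAr = sum(is_ar[heavy]),
    nHet_al = sum(elt_of[heavy] %in% c("N", "O", "P", "S", "F", "Cl", "Br", "I") & !is_ar[heavy]),
    nUncommon_al = sum(!(elt_of[heavy] %in% c(.common_organic, "H")) & !is_ar[heavy]),
    nF = sum(elt_of[heavy] == "F"), nCl = sum(elt_of[heavy] == "Cl"),
    nBr = sum(elt_of[heavy] == "Br"), nI = sum(elt_of[heavy] == "I"),
    nN = sum(elt_of[heavy] == "N"), nS = sum(elt_of[heavy] == "S"),
    has_dbl = dbl_to(function(j) TRUE),
    has_dbl_C_al = dbl_to(function(j) elt_of[j] == "C" && !is_ar[j]),
    has_dbl_C_ar = dbl_to(function(j) elt_of[j] == "C" && is_ar[j]),
    has_dbl_het_al = dbl_to(function(j) elt_of[j] != "C" && !is_ar[j]),
    has_dbl_CNO_al = dbl_to(function(j) elt_of[j] %in% c("C", "N", "O") && !is_ar[j]),
    has_dbl_NO = dbl_to(function(j) elt_of[j] %in% c("N", "O")),
    has_dbl_S = dbl_to(function(j) elt_of[j] == "S"),
    has_dbl_NOPS = dbl_to(function(j) elt_of[j] %in% c("N", "O", "P", "S")),
    has_triple = any(vapply(heavy, function(j) binfo[[as.character(j)]]$order == 3L, logical(1))),
    n_dbl_C_al = sum(vapply(heavy, function(j) {
      b <- binfo[[as.character(j)]]
      b$order == 2L && !b$aromatic && elt_of[j] == "C" && !is_ar[j]
    }, logical(1))),
    n_ar_bonds = sum(vapply(heavy, function(j) binfo[[as.character(j)]]$aromatic, logical(1))),
    n_single_ar_nbr = sum(vapply(heavy, function(j) {
      b <- binfo[[as.character(j)]]
      b$order == 1L && !b$aromatic && is_ar[j]
    }, logical(1))),
    n_single_C_al = h_single_al("C"),
    n_single_N_al = h_single_al("N"),
    n_single_O_al = h_single_al("O"),
    n_single_S_al = h_single_al("S"),
    nUncommonC13_single = sum(vapply(heavy, function(j) {
      b <- binfo[[as.character(j)]]
      b$order == 1L && !b$aromatic && !is_ar[j] &&
        !(elt_of[j] %in% c("C", "N", "O", "S", "F", "Cl", "Br", "I", "H"))
    }, logical(1)))
  )
  # hydrogen-specific context
  if (env$elt == "H") {
    att <- nb[1]
    env$h_attached <- elt_of[att]
    env$h_o_nbr_cx4_or_c <- FALSE; env$h_o_nbr_not_cnos <- FALSE
    env$h_o_nbr_n <- FALSE; env$h_o_nbr_acid <- FALSE; env$h_o_nbr_os <- FALSE
    if (elt_of[att] == "O") {
      others <- setdiff(mg_neighbors(g, att), i)
      for (j in others) {
        ej <- elt_of[j]
        if (ej == "C" && !is_ar[j] && length(mg_neighbors(g, j)) == 4L) env$h_o_nbr_cx4_or_c <- TRUE
        if (ej == "C" && is_ar[j]) env$h_o_nbr_cx4_or_c <- TRUE
        if (!(ej %in% c("C", "N", "O", "S"))) env$h_o_nbr_not_cnos <- TRUE
        if (ej == "N") env$h_o_nbr_n <- TRUE
        if (ej %in% c("O", "S")) env$h_o_nbr_os <- TRUE
        if (ej == "C") {
          cnb <- setdiff(mg_neighbors(g, j), att)
          for (k in cnb) {
            b <- mg_bond_to(g, j, k)
            if (b$order[1] == 2L && !b$aromatic[1] &&
                elt_of[k] %in% c("C", "N", "O", "S")) env$h_o_nbr_acid <- TRUE
          }
        }
      }
    }
  }
  # carbonyl-carbon context for O9/O10/O11
  env$carboxylate <- FALSE; env$o9_env <- FALSE; env$o10_env <- FALSE; env$o11_env <- FALSE
  if (env$elt == "O") {
    dbl_c <- heavy[vapply(heavy, function(j) {
      b <- binfo[[as.character(j)]]
      b$order == 2L && !b$aromatic && elt_of[j] == "C" && !is_ar[j]
    }, logical(1))]
    single_c <- heavy[vapply(heavy, function(j) {
      b <- binfo[[as.character(j)]]
      b$order == 1L && elt_of[j] == "C"
    }, logical(1))]
    if (env$charge < 0L && length(single_c) == 1L) {
      cnb <- setdiff(mg_neighbors(g, single_c), i)
      env$carboxylate <- any(vapply(cnb, function(k) {
        b <- mg_bond_to(g, single_c, k)
        b$order[1] == 2L && elt_of[k] == "O"
      }, logical(1)))
    }
    if (length(dbl_c) == 1L) {
      cc <- dbl_c
      cc_nb <- setdiff(mg_neighbors(g, cc), i)
      cc_h <- sum(elt_of[cc_nb] == "H")
      cc_heavy <- cc_nb[elt_of[cc_nb] != "H"]
      cc_al_C <- sum(elt_of[cc_heavy] == "C" & !is_ar[cc_heavy])
      cc_ar_C <- sum(elt_of[cc_heavy] == "C" & is_ar[cc_heavy])
      cc_al_heavy <- sum(!is_ar[cc_heavy])
      cc_ar_heavy <- sum(is_ar[cc_heavy])
      cc_NO <- sum(elt_of[cc_heavy] %in% c("N", "O") & !is_ar[cc_heavy])
      cc_dbl_O2 <- any(vapply(cc_heavy, function(k) {
        b <- mg_bond_to(g, cc, k)
        b$order[1] == 2L && elt_of[k] == "O"
      }, logical(1)))
      env$o9_env <- (cc_h == 1L && cc_al_C >= 1L) ||
        (cc_al_C >= 1L && cc_al_heavy >= 2L) ||
        (cc_h == 1L && cc_NO >= 1L) || (cc_h == 2L) || cc_dbl_O2
      # O10 patterns need two distinct carbonyl-carbon substituents:
      # ([C,c])(a) or (c)([A;!#1]); plus the aromatic-aldehyde case
      two_distinct <- FALSE
      if (length(cc_heavy) >= 2L) {
        for (p in cc_heavy) for (q in cc_heavy) {
          if (p == q) next
          if (elt_of[p] == "C" && is_ar[q]) two_distinct <- TRUE
          if (elt_of[p] == "C" && is_ar[p] && !is_ar[q]) two_distinct <- TRUE
        }
      }
      env$o10_env <- (cc_h == 1L && cc_ar_C >= 1L) || two_distinct
      env$o11_env <- length(cc_heavy) == 2L && all(elt_of[cc_heavy] != "C")
    }
  }
  env
}

#' Wildman-Crippen logP
#'
#' Octanol/water partition coefficient estimated by summing published typed
#' atomic contributions over all atoms, hydrogens included. Atom typing
#' follows the published hierarchy (first matching class in table order)
#' under the same aromaticity convention as [tpsa()]. Atoms that fit no
#' specific class receive the published wildcard contribution for their
#' element and a message is emitted.
#'
#' @inheritParams monoisotopic_mass
#' @return unitless logP estimate.
#' @export
crippen_logp <- function(x) {
  sum(crippen_contributions(as_mol_graph(x))$logp)
}

#' Per-atom Wildman-Crippen contributions
#'
#' @inheritParams monoisotopic_mass
#' @return data frame with one row per atom: `element`, `type`, `logp`.
#' @export
crippen_contributions <- function(x) {
  g <- as_mol_graph(x)
  types <- vapply(seq_len(nrow(g$atoms)), function(i)
    crippen_atom_type(crippen_env(g, i)), character(1))
  wildcard <- types %in% c("CS", "NS", "OS", "HS")
  if (any(wildcard))
    message(sprintf("crippen_logp: %d atom(s) assigned wildcard contributions (%s)",
                    sum(wildcard), paste(unique(g$atoms$element[wildcard]), collapse = ", ")))
  data.frame(
    element = g$atoms$element,
    type = types,
    logp = unname(.crippen_logp_value[types]),
    stringsAsFactors = FALSE
  )
}
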