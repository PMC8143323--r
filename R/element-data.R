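# Atomic mass tables and the hartree -> kcal/mol conversion constant.

#' Conversion constant between hartree and kcal/mol
#'
#' One hartree expressed in kcal/mol, the convention used throughout the
#' binding-energy bookkeeping.
#' @export
HARTREE_TO_KCAL <- 627.5095

# Most-abundant-isotope masses (u), CODATA/AME2020 values.
.monoisotopic_mass <- c(
  H  = 1.00782503207,
  B  = 11.0093054,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.99840322,
  Na = 22.98976928,
  Mg = 23.98504170,
  Al = 26.98153863,
  Si = 27.97692653,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  K  = 38.96370668,
  Ca = 39.96259098,
  Fe = 55.93493750,
  Cu = 62.92959750,
  Zn = 63.92914220,
  Br = 78.91833710,
  I  = 126.90447300
)

# Standard (abundance-weighted) atomic weights, IUPAC 2021 conventional values.
.average_mass <- c(
  H  = 1.008,
  B  = 10.81,
  C  = 12.011,
  N  = 14.007,
  O  = 15.999,
  F  = 18.998403,
  Na = 22.98977,
  Mg = 24.305,
  Al = 26.981538,
  Si = 28.085,
  P  = 30.973762,
  S  = 32.06,
  Cl = 35.45,
  K  = 39.0983,
  Ca = 40.078,
  Fe = 55.845,
  Cu = 63.546,
  Zn = 65.38,
  Br = 79.904,
  I  = 126.90447
)

# Formal charge of the free aquo ions handled by the chelate builder.
.metal_charge <- c(Mg = 2L, Ca = 2L, Al = 3L)

# Starting metal-oxygen coordination distances (Angstrom) for octahedral
# complex construction, by metal.
.metal_o_distance <- c(Al = 1.9, Mg = 2.1, Ca = 2.4)
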