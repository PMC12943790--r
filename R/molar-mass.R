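# Atomic weights: IUPAC 2021 conventional values. Embedded as a constant so a
# ~0.05 g/mol-insensitive computation needs no external data file.
.atomic_weights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904)

#' Molar mass from a Hill-notation chemical formula
#'
#' Parses element symbols with optional integer counts (e.g. `"C16H24ClNO5"`)
#' and sums conventional atomic weights. Needed to convert specific (J/g) DSC
#' enthalpies of fusion to the molar (J/mol) values the liquidus equations use.
#'
#' @param formula Chemical formula string; element symbols are one capital
#'   letter optionally followed by one lowercase letter, each with an optional
#'   integer count.
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass_from_formula("C16H24ClNO5")  # 345.82
#' molar_mass_from_formula("H2O")          # 18.02
#' @export
molar_mass_from_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  formula <- trimws(formula)
  if (!nzchar(formula)) stop("empty chemical formula", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse chemical formula '", formula, "'", call. = FALSE)
  total <- 0
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    cnt <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!sym %in% names(.atomic_weights))
      stop("unknown element symbol '", sym, "' in formula '", formula, "'",
           call. = FALSE)
    total <- total + .atomic_weights[[sym]] * n
  }
  total
}

#' Convert a specific enthalpy of fusion to a molar one
#'
#' @param dh_specific Enthalpy of fusion in J/g (> 0).
#' @param molar_mass Molar mass in g/mol (> 0).
#' @return Molar enthalpy of fusion in J/mol.
#' @examples
#' specific_to_molar_enthalpy(171, molar_mass_from_formula("C16H24ClNO5"))
#' @export
specific_to_molar_enthalpy <- function(dh_specific, molar_mass) {
  stopifnot(is.numeric(dh_specific), is.numeric(molar_mass))
  if (any(dh_specific <= 0) || any(molar_mass <= 0))
    stop("dh_specific and molar_mass must be > 0", call. = FALSE)
  dh_specific * molar_mass
}
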