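#' @title Crystalline phase records
#' @description Constructors and validators for the solid phases that make up a
#'   resolution system: the two enantiomers, an optional racemic compound, the
#'   resolving agent, the diastereomeric salt pair, and optional double or
#'   other salts.
#' @name phase
NULL

.phase_roles <- c("enantiomer", "racemic_compound", "resolving_agent",
                  "diastereomeric_salt", "double_salt", "other_salt")

#' Create a crystalline phase record
#'
#' A crystalline phase is one solid species of the ternary resolution system.
#' It carries the two DSC observables that drive every liquidus calculation --
#' the melting (fusion) temperature and the molar enthalpy of fusion -- plus a
#' barycentric position in the composition triangle spanned by the two
#' enantiomers and the resolving agent.
#'
#' Temperatures are stored in kelvin; Celsius inputs are converted on ingest
#' (+273.15). Specific enthalpies (J/g) are converted to molar (J/mol) using
#' the molar mass, which may itself be derived from a Hill-notation formula.
#'
#' @param name Short unique label, e.g. `"4''"`.
#' @param role One of `"enantiomer"`, `"racemic_compound"`, `"resolving_agent"`,
#'   `"diastereomeric_salt"`, `"double_salt"`, `"other_salt"`.
#' @param coords Barycentric triple (fractions of enantiomer-1, enantiomer-2,
#'   resolving agent), non-negative, summing to 1 within `1e-9`. This is the
#'   phase's stoichiometric position counted in mole fractions of molecules, so
#'   a 1:1 salt of enantiomer-1 sits at `c(0.5, 0, 0.5)` and a 2 agent : 1
#'   racemate double salt at `c(0.25, 0.25, 0.5)`.
#' @param t_fus Melting temperature (DSC peak), in the unit given by
#'   `t_fus_unit`. `NA` marks a phase without usable DSC data (e.g. amorphous).
#' @param dh_fus Enthalpy of fusion, in the unit given by `dh_fus_unit`.
#' @param formula Chemical formula in Hill notation, optional if `molar_mass`
#'   is given.
#' @param molar_mass Molar mass in g/mol; computed from `formula` when absent.
#'   If both are supplied they must agree within 0.1 g/mol.
#' @param t_fus_unit `"K"` (default) or `"C"`.
#' @param dh_fus_unit `"J/mol"` (default) or `"J/g"`; the latter requires a
#'   molar mass (possibly via `formula`).
#' @return An object of class `crystalline_phase`: a list with fields `name`,
#'   `role`, `coords`, `t_fus` (K), `dh_fus` (J/mol), `molar_mass`, `formula`.
#' @examples
#' salt <- crystalline_phase("4''", "diastereomeric_salt", c(0.5, 0, 0.5),
#'                           t_fus = 150, t_fus_unit = "C",
#'                           dh_fus = 171, dh_fus_unit = "J/g",
#'                           formula = "C16H24ClNO5")
#' salt$t_fus   # 423.15 K
#' salt$dh_fus  # 59135.2 J/mol
#' @export
crystalline_phase <- function(name, role, coords,
                              t_fus = NA_real_, dh_fus = NA_real_,
                              formula = NULL, molar_mass = NULL,
                              t_fus_unit = "K", dh_fus_unit = "J/mol") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, .phase_roles)
  t_fus_unit <- match.arg(t_fus_unit, c("K", "C"))
  dh_fus_unit <- match.arg(dh_fus_unit, c("J/mol", "J/g"))

  coords <- as.numeric(coords)
  if (length(coords) != 3L || anyNA(coords))
    stop("'coords' must be a numeric barycentric triple", call. = FALSE)
  if (any(coords < -1e-12) || any(coords > 1 + 1e-12))
    stop("coords of phase '", name, "' must lie in [0, 1]", call. = FALSE)
  if (abs(sum(coords) - 1) > 1e-9)
    stop("coords of phase '", name, "' must sum to 1 (got ",
         format(sum(coords), digits = 12), ")", call. = FALSE)
  coords <- pmin(pmax(coords, 0), 1)

  if (!is.null(formula) && (is.na(formula) || !nzchar(formula))) formula <- NULL
  if (!is.null(molar_mass) && is.na(molar_mass)) molar_mass <- NULL
  if (!is.null(formula)) {
    mm_formula <- molar_mass_from_formula(formula)
    if (!is.null(molar_mass)) {
      if (abs(molar_mass - mm_formula) > 0.1)
        stop("molar_mass (", molar_mass, ") and formula-derived mass (",
             round(mm_formula, 2), ") of phase '", name,
             "' disagree by more than 0.1 g/mol", call. = FALSE)
    } else {
      molar_mass <- mm_formula
    }
  }
  if (!is.null(molar_mass) && molar_mass <= 0)
    stop("molar_mass must be > 0", call. = FALSE)

  t_fus <- as.numeric(t_fus)
  if (!is.na(t_fus)) {
    if (t_fus_unit == "C") t_fus <- t_fus + 273.15
    if (t_fus <= 0)
      stop("t_fus of phase '", name, "' must be > 0 K", call. = FALSE)
  }

  dh_fus <- as.numeric(dh_fus)
  if (!is.na(dh_fus)) {
    if (dh_fus <= 0)
      stop("dh_fus of phase '", name, "' must be > 0", call. = FALSE)
    if (dh_fus_unit == "J/g") {
      if (is.null(molar_mass))
        stop("phase '", name, "': a specific enthalpy (J/g) needs a molar ",
             "mass or formula for conversion to J/mol", call. = FALSE)
      dh_fus <- specific_to_molar_enthalpy(dh_fus, molar_mass)
    }
  }

  structure(list(name = name, role = role, coords = coords,
                 t_fus = t_fus, dh_fus = dh_fus,
                 molar_mass = molar_mass, formula = formula),
            class = "crystalline_phase")
}

#' Does a phase carry usable melting data?
#'
#' @param phase A `crystalline_phase`.
#' @return `TRUE` when both `t_fus` and `dh_fus` are present; amorphous or
#'   unmeasured phases return `FALSE`.
#' @export
has_thermo_data <- function(phase) {
  stopifnot(inherits(phase, "crystalline_phase"))
  !is.na(phase$t_fus) && !is.na(phase$dh_fus)
}

#' @export
print.crystalline_phase <- function(x, ...) {
  tf <- if (is.na(x$t_fus)) "no melting data"
        else sprintf("T_fus = %.2f K (%.2f °C), dH_fus = %.0f J/mol",
                     x$t_fus, x$t_fus - 273.15, x$dh_fus)
  cat(sprintf("<crystalline_phase> %s [%s]\n  %s\n  coords = (%.4g, %.4g, %.4g)\n",
              x$name, x$role, tf, x$coords[1], x$coords[2], x$coords[3]))
  invisible(x)
}

#' Bundle crystalline phases into a resolution system
#'
#' @param phases List of [crystalline_phase()] records with unique names.
#' @param components Names of the three base components spanning the
#'   composition triangle, ordered (enantiomer-1, enantiomer-2, resolving
#'   agent).
#' @return An object of class `phase_set`.
#' @export
phase_set <- function(phases,
                      components = c("enantiomer-1", "enantiomer-2",
                                     "resolving-agent")) {
  if (inherits(phases, "crystalline_phase")) phases <- list(phases)
  stopifnot(is.list(phases), length(phases) >= 1L)
  ok <- vapply(phases, inherits, logical(1), "crystalline_phase")
  if (!all(ok))
    stop("all elements of 'phases' must be crystalline_phase objects",
         call. = FALSE)
  nms <- vapply(phases, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate phase names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  stopifnot(is.character(components), length(components) == 3L)
  names(phases) <- nms
  structure(list(phases = phases, components = components),
            class = "phase_set")
}

#' Look up a phase by name
#'
#' @param ps A [phase_set()].
#' @param name Phase label.
#' @return The matching `crystalline_phase`; errors with the list of available
#'   names when absent.
#' @export
get_phase <- function(ps, name) {
  stopifnot(inherits(ps, "phase_set"))
  if (!name %in% names(ps$phases))
    stop("unknown phase '", name, "'; available: ",
         paste(names(ps$phases), collapse = ", "), call. = FALSE)
  ps$phases[[name]]
}

#' @export
print.phase_set <- function(x, ...) {
  cat(sprintf("<phase_set> %d phases over (%s)\n", length(x$phases),
              paste(x$components, collapse = ", ")))
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
as.data.frame.phase_set <- function(x, ...) {
  data.frame(
    name = vapply(x$phases, `[[`, character(1), "name"),
    role = vapply(x$phases, `[[`, character(1), "role"),
    t_fus_K = vapply(x$phases, `[[`, numeric(1), "t_fus"),
    dh_fus_J_mol = vapply(x$phases, `[[`, numeric(1), "dh_fus"),
    coord1 = vapply(x$phases, function(p) p$coords[1], numeric(1)),
    coord2 = vapply(x$phases, function(p) p$coords[2], numeric(1)),
    coord3 = vapply(x$phases, function(p) p$coords[3], numeric(1)),
    stringsAsFactors = FALSE)
}

#' Swap the two enantiomer base components of a system
#'
#' Relabels the composition triangle by exchanging the first two barycentric
#' components of every phase (a mirror about the vertical median). Phase
#' identities and melting data are untouched. Used for the mirror-symmetry
#' invariance of domain maps and verdicts.
#'
#' @param ps A [phase_set()].
#' @return The mirrored `phase_set`.
#' @export
mirror_phase_set <- function(ps) {
  stopifnot(inherits(ps, "phase_set"))
  ps$phases <- lapply(ps$phases, function(p) {
    p$coords <- p$coords[c(2L, 1L, 3L)]
    p
  })
  ps$components <- ps$components[c(2L, 1L, 3L)]
  ps
}

#' Validate a barycentric composition
#' @noRd
.check_composition <- function(comp) {
  comp <- as.numeric(comp)
  if (length(comp) != 3L || anyNA(comp))
    stop("composition must be a numeric barycentric triple", call. = FALSE)
  if (any(comp < -1e-9))
    stop("composition components must be non-negative", call. = FALSE)
  if (abs(sum(comp) - 1) > 1e-9)
    stop("composition must sum to 1", call. = FALSE)
  pmin(pmax(comp, 0), 1)
}
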