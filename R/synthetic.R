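#' Generate a random ideal-eutectic resolution system
#'
#' Draws a synthetic phase set shaped like the worked case studies: an
#' enantiomer pair with identical melting data at the triangle's base
#' corners, an optional 1:1 racemic compound at the base midpoint, a
#' diastereomeric salt pair at the edge midpoints, an optional crystalline
#' resolving agent at the apex, an optional 2 agent : 1 racemate double salt
#' at the (0.25, 0.25, 0.5) test point, and optionally further 2:1 salts.
#' All draws are uniform over the given ranges; the racemic compound's
#' melting point is drawn near the enantiomers' (as real racemic compounds
#' are) and its enthalpy above theirs, so the three-branch binary sections
#' are generically solvable.
#'
#' Every generated system satisfies the phase invariants and is valid input
#' to the solvers, the diagram assembly, and the verdict rules. The same seed
#' always reproduces the same system; the caller's random number generator
#' state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_salts Number of salt phases beyond any double salt: 2 gives the
#'   diastereomeric pair; 3 or 4 add 2:1 agent-rich salts on the
#'   enantiomer-agent edges (role `other_salt`).
#' @param t_fus_range Melting temperature range, kelvin, within [250, 600].
#' @param dh_range Molar enthalpy-of-fusion range, J/mol, positive.
#' @param with_double_salt Add a double salt at (0.25, 0.25, 0.5)?
#' @param with_racemic_compound Add the 1:1 racemic compound?
#' @param with_agent_phase Add a crystalline resolving-agent phase at the
#'   apex?
#' @param double_salt_dominant Force the double salt's melting point above
#'   both salts'?
#' @return A [phase_set()].
#' @examples
#' ps <- generate_synthetic_system(1)
#' names(ps$phases)
#' @export
generate_synthetic_system <- function(seed, n_salts = 2,
                                      t_fus_range = c(330, 480),
                                      dh_range = c(15000, 65000),
                                      with_double_salt = FALSE,
                                      with_racemic_compound = TRUE,
                                      with_agent_phase = TRUE,
                                      double_salt_dominant = FALSE) {
  stopifnot(length(t_fus_range) == 2L, length(dh_range) == 2L)
  if (t_fus_range[1] < 250 || t_fus_range[2] > 600 ||
      t_fus_range[1] >= t_fus_range[2])
    stop("t_fus_range must be an increasing interval within [250, 600] K",
         call. = FALSE)
  if (dh_range[1] <= 0 || dh_range[1] >= dh_range[2])
    stop("dh_range must be an increasing positive interval", call. = FALSE)
  if (!n_salts %in% 2:4)
    stop("n_salts must be 2, 3 or 4", call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  rT <- function(lo = t_fus_range[1], hi = t_fus_range[2]) stats::runif(1, lo, hi)
  rH <- function(lo = dh_range[1], hi = dh_range[2]) stats::runif(1, lo, hi)

  t_en <- rT(); h_en <- rH()
  phases <- list(
    crystalline_phase("E1", "enantiomer", c(1, 0, 0),
                      t_fus = t_en, dh_fus = h_en),
    crystalline_phase("E2", "enantiomer", c(0, 1, 0),
                      t_fus = t_en, dh_fus = h_en))

  if (with_racemic_compound) {
    t_rac <- min(max(rT(t_en - 30, t_en + 5), t_fus_range[1]), t_fus_range[2])
    h_rac <- min(h_en * stats::runif(1, 1.2, 2.2), dh_range[2] * 2)
    phases <- c(phases, list(
      crystalline_phase("RAC", "racemic_compound", c(0.5, 0.5, 0),
                        t_fus = t_rac, dh_fus = h_rac)))
  }

  t_s1 <- rT(); t_s2 <- rT()
  phases <- c(phases, list(
    crystalline_phase("S1", "diastereomeric_salt", c(0.5, 0, 0.5),
                      t_fus = t_s1, dh_fus = rH()),
    crystalline_phase("S2", "diastereomeric_salt", c(0, 0.5, 0.5),
                      t_fus = t_s2, dh_fus = rH())))

  if (with_agent_phase)
    phases <- c(phases, list(
      crystalline_phase("AG", "resolving_agent", c(0, 0, 1),
                        t_fus = rT(), dh_fus = rH())))

  if (n_salts >= 3)
    phases <- c(phases, list(
      crystalline_phase("S3", "other_salt", c(0, 1 / 3, 2 / 3),
                        t_fus = rT(), dh_fus = rH())))
  if (n_salts >= 4)
    phases <- c(phases, list(
      crystalline_phase("S4", "other_salt", c(1 / 3, 0, 2 / 3),
                        t_fus = rT(), dh_fus = rH())))

  if (with_double_salt) {
    t_db <- if (double_salt_dominant)
      min(max(t_s1, t_s2) + stats::runif(1, 5, 40), 600) else rT()
    phases <- c(phases, list(
      crystalline_phase("DB", "double_salt", c(0.25, 0.25, 0.5),
                        t_fus = t_db, dh_fus = rH() * 1.5)))
  }

  phase_set(phases, components = c("synthetic-enantiomer-1",
                                   "synthetic-enantiomer-2",
                                   "synthetic-agent"))
}
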