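#' @title Pseudo-binary melting diagrams
#' @description Eutectic point solving and assembly of two- and three-phase
#'   binary sections: simple salt pairs, enantiomer / racemic-compound /
#'   enantiomer systems, and salt / double-salt / salt sections.
#' @name binary
NULL

.eutectic_point <- function(x_A, T_eu, phases, degenerate = FALSE) {
  structure(list(x_A = x_A, T_eu = T_eu, phases = phases,
                 degenerate = degenerate),
            class = "eutectic_point")
}

#' @export
print.eutectic_point <- function(x, ...) {
  cat(sprintf("<eutectic_point> %s / %s: x(%s) = %.5f, T_eu = %.3f K (%.2f °C)%s\n",
              x$phases[1], x$phases[2], x$phases[1], x$x_A, x$T_eu,
              x$T_eu - 273.15,
              if (isTRUE(x$degenerate)) " [degenerate: identical data]" else ""))
  invisible(x)
}

#' Solve the eutectic point of a simple binary pair
#'
#' Under the ideal-eutectic assumption each phase's liquidus follows the
#' Schroeder-van Laar equation, so the eutectic is the unique temperature at
#' which the two saturation fractions sum to one:
#' \eqn{x_A(T) + x_B(T) = 1}. Both fractions increase strictly with T and the
#' sum exceeds 1 at the lower of the two melting points, so a bracketed root
#' solve on T in (1 K, min t_fus) converges to the single crossing.
#'
#' For the diastereomeric salt pair of a resolution system, the eutectic
#' composition estimates the eutonic (solubility) ratio that governs
#' fractional crystallization.
#'
#' Two distinct phases with identical (t_fus, dh_fus) have coinciding
#' liquidus branches; the midpoint `x_A = 0.5` is returned exactly, flagged
#' `degenerate`.
#'
#' @param phaseA,phaseB [crystalline_phase()] records with melting data.
#' @return An `eutectic_point`: `x_A` (mole fraction of `phaseA` at the
#'   eutectic), `T_eu` (kelvin), `phases`, `degenerate`.
#' @examples
#' a <- crystalline_phase("A", "diastereomeric_salt", c(0.5, 0, 0.5),
#'                        t_fus = 423.15, dh_fus = 59135)
#' b <- crystalline_phase("B", "diastereomeric_salt", c(0, 0.5, 0.5),
#'                        t_fus = 373.15, dh_fus = 25937)
#' solve_simple_eutectic(a, b)  # x_A ~ 0.086
#' @export
solve_simple_eutectic <- function(phaseA, phaseB) {
  .need_thermo(phaseA, "solve_simple_eutectic")
  .need_thermo(phaseB, "solve_simple_eutectic")
  if (identical(phaseA$name, phaseB$name))
    stop("cannot solve a eutectic between a phase ('", phaseA$name,
         "') and itself", call. = FALSE)
  if (phaseA$t_fus == phaseB$t_fus && phaseA$dh_fus == phaseB$dh_fus) {
    T_eu <- svl_T_at_fraction(phaseA, 0.5)
    return(.eutectic_point(0.5, T_eu, c(phaseA$name, phaseB$name),
                           degenerate = TRUE))
  }
  h <- function(temp) {
    as.numeric(svl_fraction_at_T(phaseA, temp)) +
      as.numeric(svl_fraction_at_T(phaseB, temp)) - 1
  }
  hi <- min(phaseA$t_fus, phaseB$t_fus) - 1e-6
  if (h(hi) < 0)
    stop("no eutectic: liquidus fractions of '", phaseA$name, "' and '",
         phaseB$name, "' never sum to 1 below their melting points",
         call. = FALSE)
  if (h(1) > 0) stop("no eutectic above 1 K", call. = FALSE)
  root <- stats::uniroot(h, c(1, hi), tol = 1e-10)
  T_eu <- root$root
  x_A <- as.numeric(svl_fraction_at_T(phaseA, T_eu))
  if (abs(h(T_eu)) > 1e-8)
    stop("eutectic solve did not converge to |dx| < 1e-8", call. = FALSE)
  .eutectic_point(x_A, T_eu, c(phaseA$name, phaseB$name))
}

# Eutectic between the Schroeder-van Laar branch of an end member and the
# Prigogine-Defay branch of a central 1:1 compound, on the end member's side
# of the section. Solved as a scalar root in T of
#   x_svl(T) = (1 + sqrt(1 - q(T))) / 2,  q(T) = exp[dH_RS/R (1/T_RS - 1/T)],
# the right-hand side being the compound branch's composition on this side.
.svl_pd_eutectic <- function(end, compound) {
  g <- function(temp) {
    q <- exp(compound$dh_fus / .R_GAS * (1 / compound$t_fus - 1 / temp))
    as.numeric(svl_fraction_at_T(end, temp)) -
      (1 + sqrt(pmax(0, 1 - q))) / 2
  }
  hi <- min(end$t_fus, compound$t_fus) - 1e-6
  if (g(hi) <= 0)
    stop("compound '", compound$name, "' is everywhere metastable against '",
         end$name, "': its liquidus never rises above the end member's",
         call. = FALSE)
  root <- stats::uniroot(g, c(1, hi), tol = 1e-10)
  T_eu <- root$root
  x_end <- as.numeric(svl_fraction_at_T(end, T_eu))
  if (abs(g(T_eu)) > 1e-8)
    stop("eutectic solve did not converge to |dx| < 1e-8", call. = FALSE)
  list(T_eu = T_eu, x_end = x_end)
}

# Shared construction for enantiomer/racemic-compound/enantiomer and
# salt/double-salt/salt sections. Section coordinate x = mole fraction of
# endA, the compound counting as 0.5 A + 0.5 B.
.solve_three_phase_binary <- function(endA, compound, endB) {
  .need_thermo(endA, "binary section")
  .need_thermo(compound, "binary section")
  .need_thermo(endB, "binary section")
  mid <- (endA$coords + endB$coords) / 2
  if (max(abs(compound$coords - mid)) > 1e-6)
    stop("compound '", compound$name, "' must sit midway between '",
         endA$name, "' and '", endB$name, "' on the section", call. = FALSE)

  sideA <- .svl_pd_eutectic(endA, compound)
  sideB <- .svl_pd_eutectic(endB, compound)
  x_euA <- sideA$x_end            # section coordinate, A-rich side
  x_euB <- 1 - sideB$x_end        # section coordinate, B-rich side

  eutectics <- list(
    .eutectic_point(x_euB, sideB$T_eu, c(endB$name, compound$name)),
    .eutectic_point(x_euA, sideA$T_eu, c(compound$name, endA$name)))

  branches <- list(
    list(phase = endB$name, type = "svl", range = c(0, x_euB),
         f = function(x) svl_T_at_fraction(endB, 1 - x)),
    list(phase = compound$name, type = "pd", range = c(x_euB, x_euA),
         f = function(x) pd_T_at_fraction(compound, x)),
    list(phase = endA$name, type = "svl", range = c(x_euA, 1),
         f = function(x) svl_T_at_fraction(endA, x)))

  structure(list(phases = list(endB, compound, endA),
                 section = c(endB$name, compound$name, endA$name),
                 x_axis = paste0("mole fraction of ", endA$name),
                 branches = branches, eutectics = eutectics),
            class = "binary_diagram")
}

#' Binary diagram of an enantiomer pair with a racemic compound
#'
#' Three liquidus branches: Schroeder-van Laar for each enantiomer near the
#' pure ends, Prigogine-Defay for the racemic compound in the middle, with
#' the two flanking eutectics located by scalar root solves in temperature.
#' For enantiomers (identical melting data) the diagram is mirror-symmetric
#' about x = 0.5.
#'
#' @param enantiomerS,enantiomerR The two enantiomer phases.
#' @param racemicCompound The 1:1 racemic compound phase, positioned midway
#'   between the enantiomers.
#' @return A `binary_diagram`: ordered `section`, `branches` (each with a
#'   sampler `f(x)` and validity `range`), and two `eutectics`. The section
#'   coordinate is the mole fraction of `enantiomerS`.
#' @export
solve_racemic_binary <- function(enantiomerS, racemicCompound, enantiomerR) {
  .solve_three_phase_binary(enantiomerS, racemicCompound, enantiomerR)
}

#' Binary section of a salt pair with their double salt
#'
#' Same construction as [solve_racemic_binary()], the double salt formally
#' playing the racemic-compound role on the salt-salt pseudo-binary axis
#' (the compound counted as 0.5 of each end salt).
#'
#' @param saltA,saltB The diastereomeric salt pair.
#' @param doubleSalt Their 1:1 crystalline addition compound, at the midpoint
#'   of the two salts' coordinates.
#' @return A `binary_diagram`; section coordinate is the mole fraction of
#'   `saltA`.
#' @export
solve_compound_binary <- function(saltA, doubleSalt, saltB) {
  .solve_three_phase_binary(saltA, doubleSalt, saltB)
}

#' Assemble a binary diagram for a simple two-phase section
#'
#' @param phaseA,phaseB The two phases; the section coordinate is the mole
#'   fraction of `phaseA`.
#' @return A `binary_diagram` with two Schroeder-van Laar branches meeting at
#'   the [solve_simple_eutectic()] point.
#' @export
solve_binary_section <- function(phaseA, phaseB) {
  eu <- solve_simple_eutectic(phaseA, phaseB)
  branches <- list(
    list(phase = phaseB$name, type = "svl", range = c(0, eu$x_A),
         f = function(x) svl_T_at_fraction(phaseB, 1 - x)),
    list(phase = phaseA$name, type = "svl", range = c(eu$x_A, 1),
         f = function(x) svl_T_at_fraction(phaseA, x)))
  structure(list(phases = list(phaseB, phaseA),
                 section = c(phaseB$name, phaseA$name),
                 x_axis = paste0("mole fraction of ", phaseA$name),
                 branches = branches, eutectics = list(eu)),
            class = "binary_diagram")
}

#' Evaluate the liquidus envelope of a binary diagram
#'
#' The equilibrium liquidus at a section composition is the branch valid
#' there (the upper envelope of all branches; branch validity intervals abut
#' at the eutectic compositions).
#'
#' @param diagram A `binary_diagram`.
#' @param x Section coordinate(s) in `[0, 1]`.
#' @return A data frame with columns `x`, `T_K`, `T_C`, `phase`.
#' @export
binary_envelope <- function(diagram, x) {
  stopifnot(inherits(diagram, "binary_diagram"), is.numeric(x))
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]", call. = FALSE)
  temp <- numeric(length(x))
  phase <- character(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    for (br in diagram$branches) {
      if (xi >= br$range[1] - 1e-12 && xi <= br$range[2] + 1e-12) {
        xi_cl <- min(max(xi, br$range[1]), br$range[2])
        # PD branch endpoints at exactly 0/1 cannot occur: eutectics are interior
        temp[i] <- if (br$type == "pd") br$f(min(max(xi_cl, 1e-12), 1 - 1e-12))
                   else br$f(xi_cl)
        phase[i] <- br$phase
        break
      }
    }
  }
  data.frame(x = x, T_K = temp, T_C = temp - 273.15, phase = phase,
             stringsAsFactors = FALSE)
}

#' Sample a binary diagram on a regular composition grid
#'
#' @param diagram A `binary_diagram`.
#' @param n Number of grid points over `[0, 1]` (default 201).
#' @return A data frame as in [binary_envelope()].
#' @export
sample_binary_diagram <- function(diagram, n = 201) {
  stopifnot(n >= 2)
  binary_envelope(diagram, seq(0, 1, length.out = n))
}

#' Export a binary diagram to JSON (and optionally CSV)
#'
#' Writes the branch samples (temperatures in both K and degrees C) and the
#' eutectic list.
#'
#' @param diagram A `binary_diagram`.
#' @param path Output JSON file path.
#' @param n Grid points for sampling (default 201).
#' @param csv Optional CSV path for the sample table.
#' @return Invisibly, the exported list.
#' @export
export_binary_diagram <- function(diagram, path, n = 201, csv = NULL) {
  samples <- sample_binary_diagram(diagram, n)
  out <- list(
    section = diagram$section,
    x_axis = diagram$x_axis,
    eutectics = lapply(diagram$eutectics, function(e)
      list(x = e$x_A, T_K = e$T_eu, T_C = e$T_eu - 273.15,
           phases = e$phases, degenerate = isTRUE(e$degenerate))),
    samples = samples)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  if (!is.null(csv)) utils::write.csv(samples, csv, row.names = FALSE)
  invisible(out)
}

#' @export
print.binary_diagram <- function(x, ...) {
  cat(sprintf("<binary_diagram> section %s (x = %s)\n",
              paste(x$section, collapse = " / "), x$x_axis))
  for (e in x$eutectics) print(e)
  invisible(x)
}
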