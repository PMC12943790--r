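#' @title Resolvability metrics and verdict rules
#' @description The quantitative screening outputs: eutectic composition of
#'   the diastereomeric salt pair, the Fogassy resolubility parameter, the
#'   melting-point-gap rule, and the double-salt test-point verdict.
#' @name metrics
NULL

#' Fogassy resolubility parameter
#'
#' The theoretical maximum efficiency of a resolution implied by the salt
#' pair's eutectic composition:
#' \deqn{F_{max} = 2 - \frac{1}{1 - x_{eu}},}
#' where `x_eu` is the mole fraction of the favored (higher-melting,
#' less-soluble) salt at the binary eutectic. It equals 1 at `x_eu = 0`
#' (the favored salt crystallizes alone), falls to 0 at `x_eu = 0.5`
#' (no discrimination), and is strictly decreasing in between.
#'
#' @param x_eu Mole fraction(s) of the favored salt at the eutectic, in
#'   `[0, 1)`.
#' @return `F_max`, dimensionless.
#' @examples
#' fogassy_parameter(0.086)  # ~0.906
#' fogassy_parameter(0.30)   # ~0.57
#' @export
fogassy_parameter <- function(x_eu) {
  stopifnot(is.numeric(x_eu))
  if (any(x_eu < 0) || any(x_eu >= 1))
    stop("x_eu must lie in [0, 1)", call. = FALSE)
  2 - 1 / (1 - x_eu)
}

#' Eutectic metrics of a diastereomeric salt pair
#'
#' Solves the salt pair's binary eutectic and reports `x_eu` as the mole
#' fraction of the HIGHER-melting (favored, less-soluble) salt, the melting
#' point gap, and the Fogassy parameter.
#'
#' @param saltA,saltB The two diastereomeric salt phases (order immaterial).
#' @return A list: `x_eu`, `delta_Tm` (kelvin), `F_max`, `T_eu` (kelvin),
#'   `favored` (name of the higher-melting salt), `eutectic` (the full
#'   [solve_simple_eutectic()] record).
#' @export
salt_pair_metrics <- function(saltA, saltB) {
  .need_thermo(saltA, "salt_pair_metrics")
  .need_thermo(saltB, "salt_pair_metrics")
  if (saltB$t_fus > saltA$t_fus) { tmp <- saltA; saltA <- saltB; saltB <- tmp }
  eu <- solve_simple_eutectic(saltA, saltB)
  list(x_eu = eu$x_A,
       delta_Tm = abs(saltA$t_fus - saltB$t_fus),
       F_max = fogassy_parameter(eu$x_A),
       T_eu = eu$T_eu,
       favored = saltA$name,
       eutectic = eu)
}

.verdicts <- c("promising", "inefficient", "blocked_by_double_salt",
               "indeterminate")

#' Resolution verdict for an assembled ternary diagram
#'
#' Applies the screening rules to a resolution system:
#' \itemize{
#'   \item if a double salt dominates at the 1:1 racemate : resolving-agent
#'     test composition `(0.25, 0.25, 0.5)`, the resolution is
#'     `blocked_by_double_salt` -- the starting mixture only yields the
#'     addition compound of both salts;
#'   \item otherwise `promising` when the salt pair's melting points differ
#'     by at least 20 K, `inefficient` below that;
#'   \item `indeterminate` when a required salt lacks melting data (e.g. an
#'     amorphous salt, which by the empirical rule stays in the mother
#'     liquor).
#' }
#' For promising systems the notes record the recommended initial
#' racemate : agent mixing-ratio segment: the span of the racemate-agent
#' mixing line lying inside the favored salt's domain.
#'
#' @param diagram A [ternary_diagram()].
#' @param test_point The test composition (default `c(0.25, 0.25, 0.5)`, the
#'   1:1 molar ratio of racemate to resolving agent).
#' @return An object of class `resolution_report`: `salt_pair`, `x_eu`,
#'   `F_max`, `delta_Tm`, `T_eu`, `test_point_phase`, `double_salt_present`,
#'   `verdict`, `mixing_segment` (agent mole-fraction range, or `NULL`),
#'   `notes`.
#' @export
resolution_verdict <- function(diagram, test_point = c(0.25, 0.25, 0.5)) {
  stopifnot(inherits(diagram, "ternary_diagram"))
  ps <- diagram$phase_set
  roles <- vapply(ps$phases, `[[`, character(1), "role")
  salts <- ps$phases[roles == "diastereomeric_salt"]
  double_present <- any(roles == "double_salt")
  notes <- character(0)

  tp <- tryCatch(liquidus_at(diagram, test_point), error = function(e) NULL)
  tp_phase <- if (is.null(tp)) NA_character_ else tp$phase
  if (!is.null(tp))
    notes <- c(notes, sprintf(
      "dominating solid at the 1:1 test point (%.2f, %.2f, %.2f): %s (liquidus %.1f °C)",
      test_point[1], test_point[2], test_point[3], tp$phase, tp$T_C))

  metrics <- NULL
  if (length(salts) == 2L &&
      all(vapply(salts, has_thermo_data, logical(1)))) {
    metrics <- salt_pair_metrics(salts[[1]], salts[[2]])
  } else if (length(salts) == 2L) {
    amorph <- names(salts)[!vapply(salts, has_thermo_data, logical(1))]
    notes <- c(notes, paste0(
      "salt(s) without melting data (amorphous or unmeasured): ",
      paste(amorph, collapse = ", "),
      "; an amorphous salt is expected to remain in the mother liquor, but ",
      "the quantitative eutectic metrics cannot be computed"))
  } else {
    notes <- c(notes, sprintf(
      "expected a diastereomeric salt pair, found %d salt phase(s)",
      length(salts)))
  }

  blocked <- !is.na(tp_phase) &&
    tp_phase %in% names(ps$phases) &&
    ps$phases[[tp_phase]]$role == "double_salt"

  verdict <-
    if (blocked) "blocked_by_double_salt"
    else if (is.null(metrics)) "indeterminate"
    else if (metrics$delta_Tm >= 20) "promising"
    else "inefficient"

  mixing_segment <- NULL
  if (verdict == "promising" && !is.null(metrics)) {
    # racemate-agent mixing line: s = agent mole fraction, comp = ((1-s)/2,
    # (1-s)/2, s); keep the span dominated by the favored salt
    s_grid <- seq(0, 1, length.out = 401)
    dom <- vapply(s_grid, function(s) {
      r <- .liquidus_impl(diagram, c((1 - s) / 2, (1 - s) / 2, s))
      if (is.null(r)) NA_character_ else r$phase
    }, character(1))
    hit <- which(!is.na(dom) & dom == metrics$favored)
    if (length(hit)) {
      mixing_segment <- range(s_grid[hit])
      notes <- c(notes, sprintf(
        "recommended initial mixing ratios: agent mole fraction %.3f-%.3f on the racemate-agent line (favored salt %s dominates)",
        mixing_segment[1], mixing_segment[2], metrics$favored))
    }
  }
  if (blocked)
    notes <- c(notes, paste0(
      "the 1:1 starting mixture can only yield the double salt '", tp_phase,
      "'; no initial composition on the racemate-agent line favors either ",
      "diastereomeric salt"))

  structure(list(
    salt_pair = names(salts),
    x_eu = if (is.null(metrics)) NA_real_ else metrics$x_eu,
    F_max = if (is.null(metrics)) NA_real_ else metrics$F_max,
    delta_Tm = if (is.null(metrics)) NA_real_ else metrics$delta_Tm,
    T_eu = if (is.null(metrics)) NA_real_ else metrics$T_eu,
    favored = if (is.null(metrics)) NA_character_ else metrics$favored,
    test_point = test_point,
    test_point_phase = tp_phase,
    double_salt_present = double_present,
    verdict = verdict,
    mixing_segment = mixing_segment,
    notes = notes), class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat("<resolution_report>\n")
  cat("  salt pair:          ", paste(x$salt_pair, collapse = " / "), "\n")
  if (!is.na(x$delta_Tm))
    cat(sprintf("  melting point gap:   %.1f K\n", x$delta_Tm))
  if (!is.na(x$x_eu)) {
    cat(sprintf("  x_eu (favored %s):  %.4f\n", x$favored, x$x_eu))
    cat(sprintf("  F_max:               %.3f\n", x$F_max))
    cat(sprintf("  T_eu:                %.2f K (%.2f °C)\n",
                x$T_eu, x$T_eu - 273.15))
  }
  cat("  test-point phase:   ", x$test_point_phase, "\n")
  cat("  double salt present:", x$double_salt_present, "\n")
  cat("  verdict:            ", x$verdict, "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Export a resolution report to JSON
#'
#' @param report A [resolution_verdict()] result.
#' @param path Output JSON path.
#' @return Invisibly, the exported list.
#' @export
export_resolution_report <- function(report, path) {
  stopifnot(inherits(report, "resolution_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(unclass(report))
}
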