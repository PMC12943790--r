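.case_labels <- c("case1_4ClMA_CHEA", "case2_2ClMA_CHEA",
                  "case3_2ClMA_pregabalin", "mpaa_chea_reference",
                  "tetramisole_dbta_reference")

#' Load a packaged case study
#'
#' Three fully worked resolution systems ship with the package, plus two
#' literature reference fixtures:
#' \describe{
#'   \item{`case1_4ClMA_CHEA`}{rac-4-chloromandelic acid with
#'     (S)-1-cyclohexylethylamine: salt pair plus a double salt sitting at
#'     the 1:1 test point; resolution blocked.}
#'   \item{`case2_2ClMA_CHEA`}{rac-2-chloromandelic acid with the same amine:
#'     likewise blocked by a double salt.}
#'   \item{`case3_2ClMA_pregabalin`}{rac-2-chloromandelic acid with
#'     (S)-pregabalin: no double salt, a 50 K salt melting gap, a promising
#'     resolution. Salt/agent enthalpies are stored as the reported
#'     decomposition-corrected specific values (J/g) and converted to J/mol
#'     at load time via the molar masses of their formulas.}
#'   \item{`mpaa_chea_reference`}{published summary metrics only
#'     (x_eu = 0.30, ~25 K gap, F_max = 0.57); no phase table.}
#'   \item{`tetramisole_dbta_reference`}{8-phase topology (coordinates and
#'     roles, including a 2:1 base:acid salt) without melting data; exercises
#'     triangulation and verdict degradation.}
#' }
#'
#' @param label One of the labels above.
#' @return An object of class `case_study`: `label`, `description`,
#'   `phase_set` (`NULL` for the metrics-only fixture), `reference` (named
#'   list of literature metrics, or `NULL`), `provenance` (per-phase field
#'   notes).
#' @examples
#' cs <- load_case("case3_2ClMA_pregabalin")
#' get_phase(cs$phase_set, "4''")$t_fus  # 423.15 K
#' @export
load_case <- function(label) {
  if (!is.character(label) || length(label) != 1L || !label %in% .case_labels)
    stop("unknown case label '", label, "'; available: ",
         paste(.case_labels, collapse = ", "), call. = FALSE)
  path <- system.file("extdata", paste0(label, ".json"),
                      package = "chiralmelt", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  ps <- NULL
  provenance <- NULL
  if (!is.null(raw$phases)) {
    ps <- read_phase_table(path)
    provenance <- lapply(raw$phases, function(r) r$provenance)
    names(provenance) <- vapply(raw$phases, function(r)
      as.character(r$name), character(1))
  }
  reference <- if (!is.null(raw$reference))
    lapply(raw$reference, function(v) if (is.list(v)) v else unlist(v))
  structure(list(label = raw$label, description = raw$description,
                 phase_set = ps, reference = reference,
                 provenance = provenance),
            class = "case_study")
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("<case_study> %s\n%s\n", x$label, x$description))
  if (!is.null(x$phase_set)) print(x$phase_set)
  if (!is.null(x$reference)) {
    cat("reference metrics:\n")
    for (k in setdiff(names(x$reference), "provenance"))
      cat(sprintf("  %s = %s\n", k, format(x$reference[[k]])))
  }
  invisible(x)
}
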