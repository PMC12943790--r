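#' @title Phase-table ingest and export
#' @description CSV/JSON reading and writing of crystalline-phase tables.
#'   CSV columns: `name, role, formula, molar_mass, t_fus, t_fus_unit (C|K),
#'   dh_fus, dh_fus_unit (J/mol|J/g), coord1, coord2, coord3`. The JSON form
#'   uses the same keys, with `coords` as a triple, plus optional top-level
#'   `components` and per-phase `provenance` notes.
#' @name phase-io
NULL

.phase_from_record <- function(rec) {
  getf <- function(key, default = NULL) {
    v <- rec[[key]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) default else v
  }
  coords <- getf("coords")
  if (is.null(coords))
    coords <- c(getf("coord1", NA_real_), getf("coord2", NA_real_),
                getf("coord3", NA_real_))
  crystalline_phase(
    name = as.character(rec$name),
    role = as.character(rec$role),
    coords = as.numeric(coords),
    t_fus = as.numeric(getf("t_fus", NA_real_)),
    dh_fus = as.numeric(getf("dh_fus", NA_real_)),
    formula = getf("formula"),
    molar_mass = getf("molar_mass"),
    t_fus_unit = getf("t_fus_unit", "K"),
    dh_fus_unit = getf("dh_fus_unit", "J/mol"))
}

#' Read a phase table from CSV or JSON
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @param components Base component names, used when the file does not carry
#'   them (CSV never does).
#' @return A [phase_set()].
#' @export
read_phase_table <- function(path,
                             components = c("enantiomer-1", "enantiomer-2",
                                            "resolving-agent")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop("no phases in ", path, call. = FALSE)
    recs <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  } else if (ext == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    recs <- if (!is.null(raw$phases)) raw$phases else raw
    if (!length(recs)) stop("no phases in ", path, call. = FALSE)
    recs <- lapply(recs, function(r) {
      if (!is.null(r$coords)) r$coords <- unlist(r$coords)
      r
    })
    if (!is.null(raw$components)) components <- unlist(raw$components)
  } else {
    stop("unsupported phase-table format '.", ext, "' (use .csv or .json)",
         call. = FALSE)
  }
  phase_set(lapply(recs, .phase_from_record), components = components)
}

#' Write a phase table to CSV
#'
#' Writes the internal kelvin / J-per-mol representation (units columns are
#' `K` and `J/mol`), round-trippable through [read_phase_table()].
#'
#' @param ps A [phase_set()].
#' @param path Output CSV path.
#' @return Invisibly, the written data frame.
#' @export
write_phase_table <- function(ps, path) {
  stopifnot(inherits(ps, "phase_set"))
  df <- data.frame(
    name = vapply(ps$phases, `[[`, character(1), "name"),
    role = vapply(ps$phases, `[[`, character(1), "role"),
    formula = vapply(ps$phases, function(p)
      if (is.null(p$formula)) NA_character_ else p$formula, character(1)),
    molar_mass = vapply(ps$phases, function(p)
      if (is.null(p$molar_mass)) NA_real_ else p$molar_mass, numeric(1)),
    t_fus = vapply(ps$phases, `[[`, numeric(1), "t_fus"),
    t_fus_unit = "K",
    dh_fus = vapply(ps$phases, `[[`, numeric(1), "dh_fus"),
    dh_fus_unit = "J/mol",
    coord1 = vapply(ps$phases, function(p) p$coords[1], numeric(1)),
    coord2 = vapply(ps$phases, function(p) p$coords[2], numeric(1)),
    coord3 = vapply(ps$phases, function(p) p$coords[3], numeric(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
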