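#' @title Ternary melting phase diagrams
#' @description Assembly of the full triangular diagram from sub-ternary
#'   eutectic systems, evaluation of the liquidus surface and dominating-phase
#'   domains, and location of ternary eutectic points.
#' @name ternary
NULL

# Embed barycentric (c1, c2, c3) into the plane: component 1 at (0,0),
# component 2 at (1,0), component 3 at the apex (0.5, sqrt(3)/2).
.simplex_xy <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  cbind(x = coords[, 2] + 0.5 * coords[, 3],
        y = sqrt(3) / 2 * coords[, 3])
}

.circumcircle <- function(p1, p2, p3) {
  d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
            p3[1] * (p1[2] - p2[2]))
  if (abs(d) < 1e-12) return(NULL)
  s1 <- sum(p1^2); s2 <- sum(p2^2); s3 <- sum(p3^2)
  ux <- (s1 * (p2[2] - p3[2]) + s2 * (p3[2] - p1[2]) + s3 * (p1[2] - p2[2])) / d
  uy <- (s1 * (p3[1] - p2[1]) + s2 * (p1[1] - p3[1]) + s3 * (p2[1] - p1[1])) / d
  c(ux, uy, sqrt((p1[1] - ux)^2 + (p1[2] - uy)^2))
}

.tri_area <- function(p1, p2, p3) {
  abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
      (p3[1] - p1[1]) * (p2[2] - p1[2])) / 2
}

# do open triangle interiors overlap? (shared edges / vertices do not count)
.tri_overlap <- function(a, b) {
  inside <- function(p, tri) {
    s <- function(p1, p2, q)
      (p2[1] - p1[1]) * (q[2] - p1[2]) - (p2[2] - p1[2]) * (q[1] - p1[1])
    d1 <- s(tri[1, ], tri[2, ], p); d2 <- s(tri[2, ], tri[3, ], p)
    d3 <- s(tri[3, ], tri[1, ], p)
    (d1 > 1e-12 & d2 > 1e-12 & d3 > 1e-12) |
      (d1 < -1e-12 & d2 < -1e-12 & d3 < -1e-12)
  }
  ctr <- function(tri, w) colSums(tri * w) # weighted interior points
  ws <- list(c(1, 1, 1) / 3, c(.5, .25, .25), c(.25, .5, .25), c(.25, .25, .5))
  for (w in ws) {
    if (inside(ctr(a, w), b)) return(TRUE)
    if (inside(ctr(b, w), a)) return(TRUE)
  }
  FALSE
}

#' Partition a phase set into sub-ternary eutectic triplets
#'
#' The full triangular diagram is assembled from sub-ternary systems, each an
#' assumed-eutectic triplet of crystalline phases. When `explicit_triplets`
#' is supplied (the construction the practitioner picked by hand), the
#' triplets are validated and used. Otherwise phase coordinate points are
#' triangulated by the empty-circumcircle (Delaunay) rule, which also
#' guarantees no triangle holds another phase point in its interior or on an
#' interior edge. Cocircular ties are resolved by a greedy
#' smallest-circumradius tiling.
#'
#' @param ps A [phase_set()] with at least 3 phases at pairwise distinct
#'   coordinates.
#' @param explicit_triplets Optional list of character triples of phase names
#'   overriding the automatic triangulation.
#' @return A list of sub-ternary records, each with `phases` (names) and
#'   `coords` (3 x 3 matrix, rows = phases).
#' @export
triangulate <- function(ps, explicit_triplets = NULL) {
  stopifnot(inherits(ps, "phase_set"))
  phases <- ps$phases
  n <- length(phases)
  if (n < 3) stop("need at least 3 phases to triangulate", call. = FALSE)
  coords <- t(vapply(phases, `[[`, numeric(3), "coords"))
  nms <- names(phases)
  if (anyDuplicated(round(coords, 9)))
    stop("phases must have pairwise distinct coordinates", call. = FALSE)
  pts <- .simplex_xy(coords)

  mk_sub <- function(idx) {
    list(phases = nms[idx],
         coords = coords[idx, , drop = FALSE])
  }

  if (!is.null(explicit_triplets)) {
    subs <- lapply(explicit_triplets, function(tri) {
      tri <- as.character(tri)
      if (length(tri) != 3L)
        stop("each explicit triplet must name exactly 3 phases", call. = FALSE)
      unknown <- setdiff(tri, nms)
      if (length(unknown))
        stop("explicit triplet references unknown phase(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      idx <- match(tri, nms)
      if (.tri_area(pts[idx[1], ], pts[idx[2], ], pts[idx[3], ]) < 1e-12)
        stop("explicit triplet (", paste(tri, collapse = ", "),
             ") is degenerate (collinear)", call. = FALSE)
      for (m in setdiff(seq_len(n), idx)) {
        y <- tryCatch(.barycentric(coords[idx, , drop = FALSE], coords[m, ]),
                      error = function(e) NULL)
        if (!is.null(y) && all(y > 1e-9))
          stop("phase '", nms[m], "' lies inside explicit triplet (",
               paste(tri, collapse = ", "), ")", call. = FALSE)
      }
      mk_sub(idx)
    })
    return(subs)
  }

  combs <- utils::combn(n, 3)
  cand <- list()
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    cc <- .circumcircle(pts[idx[1], ], pts[idx[2], ], pts[idx[3], ])
    if (is.null(cc)) next  # degenerate (collinear) triple
    others <- setdiff(seq_len(n), idx)
    d <- sqrt((pts[others, 1] - cc[1])^2 + (pts[others, 2] - cc[2])^2)
    if (any(d < cc[3] - 1e-7)) next  # another point strictly inside
    cand[[length(cand) + 1L]] <- list(idx = idx, r = cc[3])
  }
  if (!length(cand))
    stop("degenerate phase coordinates: no valid sub-ternary triangle ",
         "(all phases collinear?)", call. = FALSE)

  hull <- grDevices::chull(pts)
  hull_area <- .poly_area(pts[hull, , drop = FALSE])
  tot <- sum(vapply(cand, function(cd)
    .tri_area(pts[cd$idx[1], ], pts[cd$idx[2], ], pts[cd$idx[3], ]),
    numeric(1)))
  if (abs(tot - hull_area) > 1e-9) {
    # cocircular ambiguity: greedily tile by increasing circumradius
    ord <- order(vapply(cand, `[[`, numeric(1), "r"))
    chosen <- list()
    for (k in ord) {
      tri_k <- pts[cand[[k]]$idx, , drop = FALSE]
      if (!any(vapply(chosen, function(ch)
        .tri_overlap(tri_k, pts[ch$idx, , drop = FALSE]), logical(1))))
        chosen[[length(chosen) + 1L]] <- cand[[k]]
    }
    cand <- chosen
    tot <- sum(vapply(cand, function(cd)
      .tri_area(pts[cd$idx[1], ], pts[cd$idx[2], ], pts[cd$idx[3], ]),
      numeric(1)))
    if (abs(tot - hull_area) > 1e-9)
      stop("triangulation failed to tile the phase convex hull", call. = FALSE)
  }
  lapply(cand, function(cd) mk_sub(cd$idx))
}

.poly_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# Barycentric coordinates of composition `comp` with respect to the
# stoichiometries of three phases (rows of `tri_coords`). Both live on the
# 2-simplex, so a 3x3 linear solve does it; columns sum to 1 and so do the
# weights.
.barycentric <- function(tri_coords, comp) {
  M <- t(tri_coords)
  y <- solve(M, comp)
  as.numeric(y)
}

#' Assemble a ternary melting phase diagram
#'
#' Triangulates the phase set into sub-ternary eutectic systems and solves
#' each triplet's ternary eutectic. The result supports liquidus evaluation
#' ([liquidus_at()]), domain mapping ([domain_map()]), plotting and export.
#'
#' @param ps A [phase_set()].
#' @param explicit_triplets Optional hand-picked sub-ternary triplets, see
#'   [triangulate()].
#' @return An object of class `ternary_diagram` with fields `phase_set`,
#'   `subternaries`, and `eutectics` (one per subternary; `NULL` where a
#'   triplet lacks melting data).
#' @export
ternary_diagram <- function(ps, explicit_triplets = NULL) {
  subs <- triangulate(ps, explicit_triplets)
  eutectics <- lapply(subs, function(s) {
    trip <- ps$phases[s$phases]
    if (!all(vapply(trip, has_thermo_data, logical(1)))) return(NULL)
    tryCatch(ternary_eutectic(trip), error = function(e) NULL)
  })
  structure(list(phase_set = ps, subternaries = subs, eutectics = eutectics),
            class = "ternary_diagram")
}

#' Ternary eutectic of a sub-ternary triplet
#'
#' The three-phase extension of the ideal liquidus: the eutectic temperature
#' T* solves \eqn{\sum_i \exp[\Delta H_i / R (1/T^f_i - 1/T^*)] = 1} over the
#' triplet. Each term increases strictly with T and the sum exceeds 1 at the
#' lowest melting point of the triplet, so a bracketed root solve finds the
#' unique crossing. The eutectic composition is the triple of saturation
#' fractions at T*, mapped into the composition triangle through the phases'
#' stoichiometric coordinates.
#'
#' @param triplet List of three [crystalline_phase()] records with melting
#'   data.
#' @return A list: `composition` (barycentric triple over the base
#'   components), `T_eu` (kelvin), `fractions` (per-phase melt fractions at
#'   the eutectic), `phases` (names).
#' @export
ternary_eutectic <- function(triplet) {
  stopifnot(is.list(triplet), length(triplet) == 3L)
  for (p in triplet) .need_thermo(p, "ternary_eutectic")
  h <- function(temp) {
    sum(vapply(triplet, function(p)
      as.numeric(svl_fraction_at_T(p, temp)), numeric(1))) - 1
  }
  hi <- min(vapply(triplet, `[[`, numeric(1), "t_fus")) - 1e-6
  if (h(hi) < 0)
    stop("no ternary eutectic below the lowest melting point of the triplet",
         call. = FALSE)
  if (h(1) > 0) stop("no ternary eutectic above 1 K", call. = FALSE)
  T_eu <- stats::uniroot(h, c(1, hi), tol = 1e-10)$root
  fr <- vapply(triplet, function(p)
    as.numeric(svl_fraction_at_T(p, T_eu)), numeric(1))
  coords <- t(vapply(triplet, `[[`, numeric(3), "coords"))
  comp <- as.numeric(fr %*% coords)
  list(composition = comp, T_eu = T_eu, fractions = fr,
       phases = vapply(triplet, `[[`, character(1), "name"))
}

# Internal liquidus evaluation; returns NULL when `comp` is outside every
# subternary (outside the phase convex hull).
.liquidus_impl <- function(diagram, comp) {
  for (k in seq_along(diagram$subternaries)) {
    s <- diagram$subternaries[[k]]
    y <- tryCatch(.barycentric(s$coords, comp), error = function(e) NULL)
    if (is.null(y) || min(y) < -1e-9) next
    y <- pmin(pmax(y, 0), 1)
    best_T <- -Inf
    best_phase <- NA_character_
    for (i in 1:3) {
      if (y[i] <= 0) next
      p <- diagram$phase_set$phases[[s$phases[i]]]
      if (!has_thermo_data(p)) next
      Ti <- svl_T_at_fraction(p, y[i])
      if (Ti > best_T) { best_T <- Ti; best_phase <- p$name }
    }
    if (!is.finite(best_T)) next  # triplet without melting data
    return(list(T_K = best_T, phase = best_phase, subternary = k, y = y))
  }
  NULL
}

#' Liquidus temperature and dominating solid at a composition
#'
#' Locates the sub-ternary triangle holding the composition, expresses it in
#' barycentric coordinates of that triplet's phase stoichiometries, evaluates
#' each phase's Schroeder-van Laar branch at its coordinate, and returns the
#' highest branch: the equilibrium (dominating) solid is the one of highest
#' liquidus temperature, i.e. highest melting point and lowest solubility.
#'
#' @param diagram A [ternary_diagram()].
#' @param comp Barycentric composition over the base components.
#' @return A list: `T_K`, `T_C`, `phase` (dominating solid's name),
#'   `subternary` (index), `y` (barycentric weights in the subternary).
#' @examples
#' \dontrun{
#' td <- ternary_diagram(load_case("case3_2ClMA_pregabalin")$phase_set)
#' liquidus_at(td, c(0.25, 0.25, 0.5))  # 1:1 racemate : agent test point
#' }
#' @export
liquidus_at <- function(diagram, comp) {
  stopifnot(inherits(diagram, "ternary_diagram"))
  comp <- .check_composition(comp)
  res <- .liquidus_impl(diagram, comp)
  if (is.null(res))
    stop("composition (", paste(format(comp, digits = 4), collapse = ", "),
         ") lies outside every sub-ternary (outside the phase convex hull), ",
         "or no phase there has melting data", call. = FALSE)
  res$T_C <- res$T_K - 273.15
  res
}

#' Raster map of dominating-solid domains
#'
#' Samples [liquidus_at()] on a regular barycentric lattice and tallies each
#' phase's domain area as a fraction of the sampled (valid) region. This is
#' the quantitative counterpart of the domain picture drawn in triangular
#' diagrams: one compositional region per dominating crystalline phase.
#'
#' @param diagram A [ternary_diagram()].
#' @param grid_density Lattice points per triangle edge (default 201, i.e. a
#'   201 x 201 barycentric lattice).
#' @return An object of class `domain_map`: data frame `grid` (columns `c1`,
#'   `c2`, `c3`, `T_K`, `phase`; `NA` phase marks points outside the phase
#'   hull) and named numeric `areas` (simplex-area fractions over valid
#'   cells, summing to 1).
#' @export
domain_map <- function(diagram, grid_density = 201) {
  stopifnot(inherits(diagram, "ternary_diagram"), grid_density >= 2)
  g <- grid_density - 1L
  ij <- expand.grid(i = 0:g, j = 0:g)
  ij <- ij[ij$i + ij$j <= g, ]
  comp <- cbind(c1 = ij$i / g, c2 = ij$j / g, c3 = (g - ij$i - ij$j) / g)

  n_pts <- nrow(comp)
  best_T <- rep(-Inf, n_pts)
  phase <- rep(NA_character_, n_pts)
  located <- rep(FALSE, n_pts)

  for (s in diagram$subternaries) {
    Minv <- solve(t(s$coords))
    Y <- comp %*% t(Minv)                       # n_pts x 3 barycentric weights
    inside <- !located & Y[, 1] >= -1e-9 & Y[, 2] >= -1e-9 & Y[, 3] >= -1e-9
    if (!any(inside)) next
    Yi <- pmin(pmax(Y[inside, , drop = FALSE], 0), 1)
    bT <- rep(-Inf, nrow(Yi))
    bP <- rep(NA_character_, nrow(Yi))
    for (i in 1:3) {
      p <- diagram$phase_set$phases[[s$phases[i]]]
      if (!has_thermo_data(p)) next
      yi <- Yi[, i]
      pos <- yi > 0
      Ti <- rep(-Inf, nrow(Yi))
      Ti[pos] <- 1 / (1 / p$t_fus - .R_GAS * log(yi[pos]) / p$dh_fus)
      upd <- Ti > bT
      bT[upd] <- Ti[upd]
      bP[upd] <- p$name
    }
    ok <- is.finite(bT)
    idx <- which(inside)[ok]
    best_T[idx] <- bT[ok]
    phase[idx] <- bP[ok]
    located[idx] <- TRUE
  }

  grid <- data.frame(c1 = comp[, 1], c2 = comp[, 2], c3 = comp[, 3],
                     T_K = ifelse(located, best_T, NA_real_),
                     phase = phase, stringsAsFactors = FALSE)
  valid <- !is.na(grid$phase)
  areas <- if (any(valid)) {
    tab <- table(grid$phase[valid])
    as.numeric(tab) / sum(tab)
  } else numeric(0)
  names(areas) <- if (any(valid)) names(table(grid$phase[valid])) else NULL
  structure(list(grid = grid, areas = areas, grid_density = grid_density),
            class = "domain_map")
}

#' @export
print.domain_map <- function(x, ...) {
  cat(sprintf("<domain_map> %d x %d barycentric lattice, %d valid cells\n",
              x$grid_density, x$grid_density, sum(!is.na(x$grid$phase))))
  cat("domain area fractions:\n")
  print(round(x$areas, 4))
  invisible(x)
}

#' @export
print.ternary_diagram <- function(x, ...) {
  cat(sprintf("<ternary_diagram> %d phases, %d sub-ternaries over (%s)\n",
              length(x$phase_set$phases), length(x$subternaries),
              paste(x$phase_set$components, collapse = ", ")))
  for (k in seq_along(x$subternaries)) {
    s <- x$subternaries[[k]]
    e <- x$eutectics[[k]]
    cat(sprintf("  [%d] (%s)%s\n", k, paste(s$phases, collapse = ", "),
                if (is.null(e)) " - no melting data"
                else sprintf(": T_eu = %.2f K (%.2f °C)",
                             e$T_eu, e$T_eu - 273.15)))
  }
  invisible(x)
}

# run-length encode the phase raster for compact JSON export
.rle_phases <- function(phase) {
  r <- rle(ifelse(is.na(phase), "", phase))
  list(lengths = r$lengths, values = r$values)
}

#' Export a ternary diagram to JSON
#'
#' Writes phases, sub-ternary triplets, ternary eutectics, and a run-length
#' encoded dominating-phase raster.
#'
#' @param diagram A [ternary_diagram()].
#' @param path Output JSON path.
#' @param grid_density Raster density (default 201).
#' @return Invisibly, the exported list.
#' @export
export_ternary_diagram <- function(diagram, path, grid_density = 201) {
  dm <- domain_map(diagram, grid_density)
  out <- list(
    components = diagram$phase_set$components,
    phases = lapply(diagram$phase_set$phases, function(p)
      list(name = p$name, role = p$role, t_fus_K = p$t_fus,
           dh_fus_J_mol = p$dh_fus, coords = p$coords)),
    subternaries = lapply(diagram$subternaries, `[[`, "phases"),
    ternary_eutectics = lapply(diagram$eutectics, function(e)
      if (is.null(e)) NULL
      else list(phases = e$phases, composition = e$composition,
                T_K = e$T_eu, T_C = e$T_eu - 273.15)),
    domain_areas = as.list(dm$areas),
    raster = c(list(grid_density = grid_density),
               .rle_phases(dm$grid$phase)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
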