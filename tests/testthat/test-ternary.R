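sorted_triplets <- function(subs)
  sort(vapply(subs, function(s) paste(sort(s$phases), collapse = "|"),
              character(1)))

test_that("the pregabalin phase set splits into the four expected sub-ternaries", {
  ps <- load_case("case3_2ClMA_pregabalin")$phase_set
  subs <- triangulate(ps)
  expect_length(subs, 4)
  expect_identical(
    sorted_triplets(subs),
    sort(c("1''|2''|4''", "2''|3''|5''", "2''|4''|5''", "4''|5''|6''")))
})

test_that("three corner phases give exactly one sub-ternary", {
  ps <- phase_set(list(
    mk_enantiomer("A", 400, 3e4),
    mk_enantiomer("B", 400, 3e4, side = 2),
    crystalline_phase("C", "resolving_agent", c(0, 0, 1),
                      t_fus = 420, dh_fus = 4e4)))
  subs <- triangulate(ps)
  expect_length(subs, 1)
  expect_setequal(subs[[1]]$phases, c("A", "B", "C"))
})

test_that("the double salt's sub-ternaries separate the two salt domains", {
  ps <- load_case("case1_4ClMA_CHEA")$phase_set
  subs <- triangulate(ps)
  trips <- lapply(subs, `[[`, "phases")
  for (salt in c("4", "5", "6"))
    expect_true(any(vapply(trips, function(tr) salt %in% tr, logical(1))))
  # no sub-ternary holds both pair salts: the double salt sits between them
  expect_false(any(vapply(trips, function(tr)
    all(c("4", "6") %in% tr), logical(1))))
})

test_that("explicit triplets are validated before use", {
  ps <- load_case("case3_2ClMA_pregabalin")$phase_set
  picked <- list(c("1''", "2''", "4''"), c("2''", "3''", "5''"),
                 c("2''", "4''", "5''"), c("4''", "5''", "6''"))
  subs <- triangulate(ps, explicit_triplets = picked)
  expect_length(subs, 4)
  expect_error(triangulate(ps, explicit_triplets = list(c("1''", "2''", "zz"))),
               "unknown phase")
  expect_error(triangulate(ps, explicit_triplets = list(c("1''", "2''"))),
               "exactly 3")
  expect_error(triangulate(ps, explicit_triplets = list(c("1''", "2''", "1''"))),
               "degenerate|collinear")
  # a triplet enclosing another phase is rejected
  inner <- phase_set(list(
    mk_enantiomer("A", 400, 3e4), mk_enantiomer("B", 400, 3e4, side = 2),
    crystalline_phase("C", "resolving_agent", c(0, 0, 1), t_fus = 420, dh_fus = 4e4),
    crystalline_phase("D", "other_salt", c(1, 1, 1) / 3, t_fus = 380, dh_fus = 2e4)))
  expect_error(triangulate(inner, explicit_triplets = list(c("A", "B", "C"))),
               "inside")
  # automatic triangulation splits around the interior phase instead
  expect_length(triangulate(inner), 3)
})

test_that("collinear phase sets cannot be triangulated", {
  ps <- phase_set(list(
    mk_enantiomer("A", 400, 3e4),
    mk_enantiomer("B", 400, 3e4, side = 2),
    mk_compound("C", 390, 4e4)))
  expect_error(triangulate(ps), "collinear|degenerate")
})

test_that("ternary eutectics solve the three-branch closure", {
  # three identical phases: equal fractions by symmetry
  ps3 <- phase_set(list(
    mk_enantiomer("A", 410, 3e4), mk_enantiomer("B", 410, 3e4, side = 2),
    crystalline_phase("C", "resolving_agent", c(0, 0, 1),
                      t_fus = 410, dh_fus = 3e4)))
  eu <- ternary_eutectic(ps3$phases)
  expect_equal(unname(eu$fractions), rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(eu$fractions), 1, tolerance = 1e-9)
  expect_equal(eu$composition, rep(1 / 3, 3), tolerance = 1e-9)

  # pregabalin sub-ternaries: root matches the scan, sits below edge eutectics
  ps <- load_case("case3_2ClMA_pregabalin")$phase_set
  td <- ternary_diagram(ps)
  for (k in seq_along(td$subternaries)) {
    trip <- ps$phases[td$subternaries[[k]]$phases]
    eu <- td$eutectics[[k]]
    t3 <- vapply(trip, `[[`, numeric(1), "t_fus")
    h3 <- vapply(trip, `[[`, numeric(1), "dh_fus")
    expect_lt(abs(eu$T_eu - oracle_ternary_eutectic(t3, h3)), 0.01)
    for (pair in list(1:2, 2:3, c(1, 3))) {
      edge <- solve_simple_eutectic(trip[[pair[1]]], trip[[pair[2]]])
      expect_lte(eu$T_eu, edge$T_eu)
    }
  }
})

test_that("the liquidus surface recovers melting points and the test-point solid", {
  ps <- load_case("case3_2ClMA_pregabalin")$phase_set
  td <- ternary_diagram(ps)
  for (p in ps$phases) {
    at <- liquidus_at(td, p$coords)
    expect_identical(at$phase, p$name)
    expect_equal(at$T_K, p$t_fus, tolerance = 1e-9)
  }
  tp <- liquidus_at(td, c(0.25, 0.25, 0.5))
  expect_identical(tp$phase, "4''")

  for (lab in c("case1_4ClMA_CHEA", "case2_2ClMA_CHEA")) {
    tdc <- ternary_diagram(load_case(lab)$phase_set)
    tpc <- liquidus_at(tdc, c(0.25, 0.25, 0.5))
    expect_identical(tdc$phase_set$phases[[tpc$phase]]$role, "double_salt")
  }
  # compositions outside the phase hull are refused (cases 1-2 have no
  # crystalline agent phase at the apex)
  td1 <- ternary_diagram(load_case("case1_4ClMA_CHEA")$phase_set)
  expect_error(liquidus_at(td1, c(0.05, 0.05, 0.9)), "outside")
  expect_error(liquidus_at(td1, c(0.5, 0.6, -0.1)), "non-negative")
})

test_that("the surface restricted to a salt-salt edge equals the binary envelope", {
  ps <- load_case("case3_2ClMA_pregabalin")$phase_set
  td <- ternary_diagram(ps)
  a <- get_phase(ps, "4''"); b <- get_phase(ps, "5''")
  d <- solve_binary_section(a, b)
  for (x in seq(0.05, 0.95, by = 0.05)) {
    comp <- x * a$coords + (1 - x) * b$coords
    expect_equal(liquidus_at(td, comp)$T_K, binary_envelope(d, x)$T_K,
                 tolerance = 1e-6 / 400)
  }
})

test_that("domain maps partition the triangle into sensible areas", {
  # three identical corner phases: equal thirds
  ps3 <- phase_set(list(
    mk_enantiomer("A", 410, 3e4), mk_enantiomer("B", 410, 3e4, side = 2),
    crystalline_phase("C", "resolving_agent", c(0, 0, 1),
                      t_fus = 410, dh_fus = 3e4)))
  dm3 <- domain_map(ternary_diagram(ps3), 101)
  expect_equal(sum(dm3$areas), 1, tolerance = 1e-12)
  expect_true(all(abs(dm3$areas - 1 / 3) < 2 / 101))

  # pregabalin: strongly asymmetric, favored salt's domain much larger
  dm <- domain_map(ternary_diagram(load_case("case3_2ClMA_pregabalin")$phase_set), 101)
  expect_gt(dm$areas[["4''"]], dm$areas[["5''"]])
  expect_equal(sum(dm$areas), 1, tolerance = 1e-12)

  # the CHEA systems are nearly mirror-symmetric about the vertical median
  dm1 <- domain_map(ternary_diagram(load_case("case1_4ClMA_CHEA")$phase_set), 101)
  expect_lt(abs(dm1$areas[["4"]] - dm1$areas[["6"]]), 0.1)
  expect_lt(abs(dm1$areas[["1"]] - dm1$areas[["3"]]), 0.05)
})

test_that("relabeling the enantiomers mirrors the domain map exactly", {
  for (seed in c(3, 17)) {
    ps <- generate_synthetic_system(seed, with_double_salt = seed %% 2 == 0)
    dm <- domain_map(ternary_diagram(ps), 41)
    dmm <- domain_map(ternary_diagram(mirror_phase_set(ps)), 41)
    g <- dm$grid; gm <- dmm$grid
    ord <- order(g$c1, g$c2); ordm <- order(gm$c2, gm$c1)
    expect_identical(g$phase[ord], gm$phase[ordm])
  }
})

test_that("ternary diagrams export with a run-length encoded raster", {
  td <- ternary_diagram(load_case("case3_2ClMA_pregabalin")$phase_set)
  path <- file.path(tempdir(), "ternary.json")
  export_ternary_diagram(td, path, grid_density = 41)
  back <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_length(back$subternaries, 4)
  expect_equal(sum(unlist(back$domain_areas)), 1, tolerance = 1e-9)
  expect_equal(sum(unlist(back$raster$lengths)), sum(1:41))
})
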