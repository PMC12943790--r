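test_that("the pregabalin salt pair's eutectic sits at x = 0.086", {
  a <- mk_salt("4''", 423.15, 171 * molar_mass_from_formula("C16H24ClNO5"))
  b <- mk_salt("5''", 373.15, 75 * molar_mass_from_formula("C16H24ClNO5"), side = 2)
  eu <- solve_simple_eutectic(a, b)
  expect_equal(eu$x_A, 0.086, tolerance = 0.005 / 0.086)
  expect_lt(eu$T_eu, 373.15)
  # both branch equations hold at the reported point
  expect_equal(as.numeric(svl_fraction_at_T(a, eu$T_eu)), eu$x_A,
               tolerance = 1e-6)
  expect_equal(as.numeric(svl_fraction_at_T(b, eu$T_eu)), 1 - eu$x_A,
               tolerance = 1e-6)
})

test_that("identical data give the symmetric midpoint, identical names an error", {
  a <- mk_salt("A", 410, 3e4)
  b <- mk_salt("B", 410, 3e4, side = 2)
  eu <- solve_simple_eutectic(a, b)
  expect_identical(eu$x_A, 0.5)
  expect_true(eu$degenerate)
  expect_equal(eu$T_eu, svl_T_at_fraction(a, 0.5))
  expect_error(solve_simple_eutectic(a, a), "itself")
})

test_that("swapping the argument order mirrors x and preserves T exactly", {
  a <- mk_salt("A", 434.1, 31585)
  b <- mk_salt("B", 430.1, 26736, side = 2)
  e1 <- solve_simple_eutectic(a, b)
  e2 <- solve_simple_eutectic(b, a)
  expect_identical(e1$T_eu, e2$T_eu)
  expect_equal(e1$x_A, 1 - e2$x_A, tolerance = 1e-8)
})

test_that("pairwise eutectics agree with the brute-force temperature scan", {
  set.seed(101)
  for (k in 1:50) {
    tA <- runif(1, 330, 480); hA <- runif(1, 1.5e4, 6.5e4)
    tB <- runif(1, 330, 480); hB <- runif(1, 1.5e4, 6.5e4)
    a <- mk_salt("A", tA, hA); b <- mk_salt("B", tB, hB, side = 2)
    eu <- solve_simple_eutectic(a, b)
    ora <- oracle_pair_eutectic(tA, hA, tB, hB)
    expect_lt(abs(eu$T_eu - ora$T_eu), 0.01)
    expect_lt(eu$T_eu, min(tA, tB))
    expect_gt(eu$x_A, 0); expect_lt(eu$x_A, 1)
  }
})

test_that("the 2-chloromandelic acid racemic system is mirror-symmetric", {
  en1 <- mk_enantiomer("1'", 393.1, 24033)
  en2 <- mk_enantiomer("3'", 393.1, 24033, side = 2)
  rac <- mk_compound("2'", 362.1, 43076)
  d <- solve_racemic_binary(en1, rac, en2)
  xe <- vapply(d$eutectics, `[[`, numeric(1), "x_A")
  expect_equal(sort(xe), sort(1 - xe), tolerance = 1e-9)
  Te <- vapply(d$eutectics, `[[`, numeric(1), "T_eu")
  expect_equal(Te[1], Te[2], tolerance = 1e-9)
  # liquidus curves in the racemic region are nearly flat: eutectics hug 0.5
  expect_true(all(abs(xe - 0.5) < 0.05))
  # eutectic below every involved melting point
  expect_true(all(Te < 362.1))
})

test_that("the racemic binary envelope is continuous and covers the section", {
  en1 <- mk_enantiomer("1", 396.3, 21850)
  en2 <- mk_enantiomer("3", 396.3, 21850, side = 2)
  rac <- mk_compound("2", 395.4, 50418)
  d <- solve_racemic_binary(en1, rac, en2)
  # both eutectics exist below the compound's melting point
  expect_length(d$eutectics, 2)
  for (e in d$eutectics) expect_lt(e$T_eu, 395.4)
  # branches tile [0, 1] without gaps
  rng <- t(vapply(d$branches, `[[`, numeric(2), "range"))
  expect_equal(rng[1, 1], 0)
  expect_equal(rng[nrow(rng), 2], 1)
  expect_equal(rng[-1, 1], rng[-nrow(rng), 2])
  # adjacent branches agree at the eutectic compositions
  for (e in d$eutectics) {
    temps <- vapply(d$branches, function(br) {
      if (e$x_A >= br$range[1] - 1e-12 && e$x_A <= br$range[2] + 1e-12)
        br$f(e$x_A) else NA_real_
    }, numeric(1))
    temps <- temps[!is.na(temps)]
    expect_gte(length(temps), 2)
    expect_lt(max(temps) - min(temps), 0.01)
  }
  # sides agree with the independent scan
  ora <- oracle_svl_pd_eutectic(396.3, 21850, 395.4, 50418)
  eA <- d$eutectics[[2]]
  expect_lt(abs(eA$T_eu - ora$T_eu), 0.01)
  expect_equal(eA$x_A, ora$x_end, tolerance = 1e-3)
})

test_that("a double salt section behaves as a formal racemic compound", {
  sA <- mk_salt("4'", 413.1, 13200)
  sB <- mk_salt("6'", 400.6, 13714, side = 2)
  db <- mk_compound("5'", 424.6, 54832, role = "double_salt",
                    coords = c(0.25, 0.25, 0.5))
  d <- solve_compound_binary(sA, db, sB)
  # the compound branch peaks at x = 0.5 with the double salt's own melting point
  pd_br <- d$branches[[2]]
  expect_identical(pd_br$phase, "5'")
  expect_equal(pd_br$f(0.5), 424.6, tolerance = 1e-12)
  # both eutectics, checked against the scan oracle
  oA <- oracle_svl_pd_eutectic(413.1, 13200, 424.6, 54832)
  oB <- oracle_svl_pd_eutectic(400.6, 13714, 424.6, 54832)
  expect_lt(abs(d$eutectics[[2]]$T_eu - oA$T_eu), 0.01)
  expect_lt(abs(d$eutectics[[1]]$T_eu - oB$T_eu), 0.01)
  expect_equal(d$eutectics[[2]]$x_A, oA$x_end, tolerance = 1e-3)
  expect_equal(d$eutectics[[1]]$x_A, 1 - oB$x_end, tolerance = 1e-3)
  # with the double salt removed, the plain pair eutectic lies between them
  e_pair <- solve_simple_eutectic(sA, sB)
  expect_gt(e_pair$x_A, d$eutectics[[1]]$x_A)
  expect_lt(e_pair$x_A, d$eutectics[[2]]$x_A)
  # symmetric flanking salts give mirror-image eutectics
  sB2 <- mk_salt("6sym", 413.1, 13200, side = 2)
  dsym <- solve_compound_binary(sA, db, sB2)
  xs <- vapply(dsym$eutectics, `[[`, numeric(1), "x_A")
  expect_equal(sort(xs), sort(1 - xs), tolerance = 1e-9)
})

test_that("a compound melting far below the end members is flagged metastable", {
  en1 <- mk_enantiomer("E1", 420, 21850)
  en2 <- mk_enantiomer("E2", 420, 21850, side = 2)
  low <- mk_compound("C", 300, 40000)
  expect_error(solve_racemic_binary(en1, low, en2), "metastable")
  off <- mk_compound("C", 390, 40000, coords = c(0.6, 0.4, 0))
  expect_error(solve_racemic_binary(en1, off, en2), "midway")
})

test_that("growing compound enthalpy pushes the eutectics outward monotonically", {
  en1 <- mk_enantiomer("E1", 393.1, 24033)
  en2 <- mk_enantiomer("E2", 393.1, 24033, side = 2)
  xs <- vapply(c(3e4, 6e4, 1.2e5, 3e5), function(dh) {
    d <- solve_racemic_binary(en1, mk_compound("C", 393.1, dh), en2)
    ora <- oracle_svl_pd_eutectic(393.1, 24033, 393.1, dh)
    e <- d$eutectics[[2]]
    expect_lt(abs(e$T_eu - ora$T_eu), 0.01)
    e$x_A
  }, numeric(1))
  expect_true(all(diff(xs) > 0))   # compound-rich-side eutectic drifts toward 1
})

test_that("binary diagrams sample and export cleanly", {
  a <- mk_salt("A", 423.15, 59135)
  b <- mk_salt("B", 373.15, 25937, side = 2)
  d <- solve_binary_section(a, b)
  s <- sample_binary_diagram(d, 101)
  expect_equal(nrow(s), 101)
  expect_equal(s$T_K[s$x == 1], a$t_fus)
  expect_equal(s$T_K[s$x == 0], b$t_fus)
  expect_setequal(unique(s$phase), c("A", "B"))
  expect_equal(s$T_C, s$T_K - 273.15)
  path <- file.path(tempdir(), "bin.json")
  csv <- file.path(tempdir(), "bin.csv")
  export_binary_diagram(d, path, n = 51, csv = csv)
  back <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(back$eutectics[[1]]$x, d$eutectics[[1]]$x_A, tolerance = 1e-12)
  expect_equal(nrow(utils::read.csv(csv)), 51)
})
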