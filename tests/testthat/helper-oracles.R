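# Independent brute-force oracles: plain closed-form evaluation on dense
# temperature grids, sharing no code with the package's root solvers.

.RG <- 8.314

# saturation fraction of a phase (t, h) at temperature T (plain formula)
.ora_x <- function(t, h, temp) exp(h / .RG * (1 / t - 1 / temp))

# brute-force scan for the simple pairwise eutectic: coarse 0.1 K pass over
# (150 K, min t_fus), refined on a 0.001 K grid around the coarse minimum
oracle_pair_eutectic <- function(tA, hA, tB, hB) {
  hi <- min(tA, tB) - 1e-3
  coarse <- seq(150, hi, by = 0.1)
  mis <- abs(.ora_x(tA, hA, coarse) + .ora_x(tB, hB, coarse) - 1)
  t0 <- coarse[which.min(mis)]
  fine <- seq(max(150, t0 - 0.2), min(hi, t0 + 0.2), by = 0.001)
  mis <- abs(.ora_x(tA, hA, fine) + .ora_x(tB, hB, fine) - 1)
  T_eu <- fine[which.min(mis)]
  list(T_eu = T_eu, x_A = .ora_x(tA, hA, T_eu))
}

# brute-force scan for the eutectic between an end member's ideal branch and
# a central 1:1 compound's branch, on the end member's side of the section
oracle_svl_pd_eutectic <- function(tE, hE, tC, hC) {
  hi <- min(tE, tC) - 1e-3
  upper <- function(temp) {
    q <- exp(hC / .RG * (1 / tC - 1 / temp))
    (1 + sqrt(pmax(0, 1 - q))) / 2
  }
  coarse <- seq(150, hi, by = 0.1)
  mis <- abs(.ora_x(tE, hE, coarse) - upper(coarse))
  t0 <- coarse[which.min(mis)]
  fine <- seq(max(150, t0 - 0.2), min(hi, t0 + 0.2), by = 0.001)
  mis <- abs(.ora_x(tE, hE, fine) - upper(fine))
  T_eu <- fine[which.min(mis)]
  list(T_eu = T_eu, x_end = .ora_x(tE, hE, T_eu))
}

# brute-force scan for a three-phase (ternary) eutectic temperature
oracle_ternary_eutectic <- function(t3, h3) {
  hi <- min(t3) - 1e-3
  coarse <- seq(150, hi, by = 0.1)
  mis <- abs(.ora_x(t3[1], h3[1], coarse) + .ora_x(t3[2], h3[2], coarse) +
               .ora_x(t3[3], h3[3], coarse) - 1)
  t0 <- coarse[which.min(mis)]
  fine <- seq(max(150, t0 - 0.2), min(hi, t0 + 0.2), by = 0.001)
  mis <- abs(.ora_x(t3[1], h3[1], fine) + .ora_x(t3[2], h3[2], fine) +
               .ora_x(t3[3], h3[3], fine) - 1)
  fine[which.min(mis)]
}

# quick builders for bare phases at standard positions
mk_salt <- function(name, t, h, side = 1) {
  coords <- if (side == 1) c(0.5, 0, 0.5) else c(0, 0.5, 0.5)
  crystalline_phase(name, "diastereomeric_salt", coords, t_fus = t, dh_fus = h)
}
mk_enantiomer <- function(name, t, h, side = 1) {
  coords <- if (side == 1) c(1, 0, 0) else c(0, 1, 0)
  crystalline_phase(name, "enantiomer", coords, t_fus = t, dh_fus = h)
}
mk_compound <- function(name, t, h, role = "racemic_compound",
                        coords = c(0.5, 0.5, 0)) {
  crystalline_phase(name, role, coords, t_fus = t, dh_fus = h)
}
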