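test_that("angle stability cutoff follows sqrt(2 m RT / k)", {
  # closed form with RT = 0.592488 kcal/mol at 298.15 K
  expect_equal(angle_cutoff(40), sqrt(20 * RT_298 / 40), tolerance = 1e-12)
  expect_equal(angle_cutoff(40), 0.544, tolerance = 1e-3)
  expect_equal(angle_cutoff(20), 0.770, tolerance = 1e-3)
  # stiff limit
  expect_lt(angle_cutoff(1e9), 1e-3)
  expect_error(angle_cutoff(0), "> 0")
  expect_error(angle_cutoff(-5), "> 0")
  # pass predicate excludes near-collinear equilibria
  expect_true(angle_passes_cutoff(90, 20))
  expect_false(angle_passes_cutoff(179, 20))
  expect_false(angle_passes_cutoff(2, 20))
})

test_that("equilibrium values use arithmetic means for r and circular means for angles", {
  fx <- make_helix_complex(12, "ring-tail", 12, seed = 5)
  atoms <- c(P1 = 5L, P2 = 9L, P3 = 13L, L1 = fx$ligand_map[1],
             L2 = fx$ligand_map[2], L3 = fx$ligand_map[3])
  single <- measure_equilibrium_values(fx$system, atoms)
  g <- function(i) as.numeric(fx$system$atoms[i, c("x", "y", "z")])
  expect_equal(unname(single[["r0"]]), coord_distance(g(5), g(atoms[["L1"]])))
  expect_equal(
    unname(single[["thetaB0"]]),
    coord_angle(g(5), g(atoms[["L1"]]), g(atoms[["L2"]]))
  )
  # identical frames: trajectory mean equals the single-frame geometry
  traj <- trajectory(fx$system, rep(list(coords(fx$system)), 3))
  multi <- measure_equilibrium_values(traj, atoms)
  expect_equal(multi, single, tolerance = 1e-10)
})

test_that("dihedral averaging wraps correctly and distances average arithmetically", {
  expect_equal(circular_mean(c(179, -179)), 180)
  expect_equal(mean(c(4, 6)), 5)
})

test_that("force constants follow the quadratic distance rule", {
  k5 <- assign_force_constants(5)
  expect_equal(k5$k_thetaB, 40)
  expect_equal(k5$k_r, 20)
  expect_equal(k5$k_thetaA, 20)
  expect_equal(k5$k_phiA, 20)
  expect_equal(assign_force_constants(10)$k_thetaB, 160)
  expect_equal(assign_force_constants(2.5)$k_thetaB, 10)
  expect_error(assign_force_constants(0), "positive")
})

test_that("restraint invariants are enforced", {
  mk <- function(...) boresch_restraint(c(P1 = 1, P2 = 2, P3 = 3, L1 = 4, L2 = 5, L3 = 6), ...)
  expect_error(
    boresch_restraint(c(P1 = 1, P2 = 1, P3 = 3, L1 = 4, L2 = 5, L3 = 6),
      5, 90, 90, 0, 0, 0, 20, 20, 40, 20, 20, 20
    ),
    "distinct"
  )
  expect_error(mk(-1, 90, 90, 0, 0, 0, 20, 20, 40, 20, 20, 20), "positive")
  expect_error(mk(5, 190, 90, 0, 0, 0, 20, 20, 40, 20, 20, 20), "between 0 and 180")
  expect_error(mk(5, 90, 90, 0, 0, 0, -20, 20, 40, 20, 20, 20), "non-negative")
})

reference_restraint <- function(r0 = 5, thA = 90, thB = 90,
                                k = assign_force_constants(r0)) {
  boresch_restraint(
    c(P1 = 1, P2 = 2, P3 = 3, L1 = 4, L2 = 5, L3 = 6),
    r0, thA, thB, 10, -30, 150,
    k$k_r, k$k_thetaA, k$k_thetaB, k$k_phiA, k$k_phiB, k$k_phiC
  )
}

test_that("release correction obeys its logarithmic identities", {
  br <- reference_restraint()
  dg <- analytic_release_correction(br)
  # doubling the standard volume shifts dG by exactly -RT ln 2; realized here
  # through the equivalent r0^2 rescaling of the closed form
  v_term <- -RT_298 * log(2)
  direct <- local({
    ks <- c(br$k_r, br$k_thetaA, br$k_thetaB, br$k_phiA, br$k_phiB, br$k_phiC)
    num <- 8 * pi^2 * (2 * 1660) * sqrt(prod(ks))
    den <- br$r0^2 * sin(pi / 2) * sin(pi / 2) * (2 * pi * RT_298)^3
    -RT_298 * log(num / den)
  })
  expect_equal(direct - dg, v_term, tolerance = 1e-10)
  # multiplying every force constant by 4 changes dG by -3 RT ln 4
  k4 <- lapply(assign_force_constants(5), function(x) 4 * x)
  br4 <- reference_restraint(k = k4)
  expect_equal(
    analytic_release_correction(br4) - dg,
    -3 * RT_298 * log(4),
    tolerance = 1e-10
  )
  bad <- reference_restraint()
  bad$k_phiC <- 0
  expect_error(analytic_release_correction(bad), "zero force constants")
})

test_that("closed form matches the exact configurational integral up to the
           stiff-spring correction at the canonical 5 A geometry", {
  br <- reference_restraint(5, 90, 90)
  dg_a <- analytic_release_correction(br)
  dg_q <- quadrature_release(br)
  corr <- stiff_spring_correction(br)
  # the residual after removing the predicted Laplace correction is tiny -
  # a sharper check of both routes than a loose absolute band
  expect_lt(abs(dg_a - dg_q - corr), 0.002)
  expect_lt(abs(dg_a - dg_q), 0.015)
})

test_that("release correction agrees with quadrature within 0.01 kcal/mol over
           the anchor-selection operating range", {
  r0s <- seq(10, 30, length.out = 10)
  angA <- c(90, 75, 110, 60, 120, 95, 85, 70, 105, 90)
  angB <- c(90, 110, 70, 100, 80, 65, 115, 95, 85, 120)
  diffs <- vapply(seq_along(r0s), function(i) {
    br <- reference_restraint(r0s[i], angA[i], angB[i])
    abs(analytic_release_correction(br) - quadrature_release(br))
  }, 1.0)
  expect_true(all(diffs < 0.01))
})

test_that("restraint JSON and intermolecular block round-trip", {
  br <- reference_restraint(12, 85, 95)
  f <- withr::local_tempfile(fileext = ".json")
  write_boresch_json(br, f)
  back <- read_boresch_json(f)
  expect_equal(back, br, tolerance = 1e-12)
  blk <- boresch_intermolecular(br, scaleA = 0, scaleB = 1)
  expect_length(blk$bonds, 1)
  expect_length(blk$angles, 2)
  expect_length(blk$dihedrals, 3)
  # A-state force constant off, B-state on, GROMACS units
  expect_equal(blk$bonds[[1]]$params[2], 0)
  expect_equal(blk$bonds[[1]]$params[4], 20 * 4.184 * 100)
  expect_equal(blk$bonds[[1]]$params[1], 1.2) # nm
})
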