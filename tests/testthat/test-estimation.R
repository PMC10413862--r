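test_that("XVG writer and parser round-trip reduced potentials", {
  h <- make_harmonic_reduced_potentials(c(1, 2, 4), n_per_state = 50, seed = 2)
  d <- withr::local_tempdir()
  files <- write_dhdl_xvg(h$rp, d)
  expect_length(files, 3)
  back <- parse_dhdl(files)
  expect_equal(back$n_k, h$rp$n_k)
  # per-sample constants differ (energies are stored relative to the sampled
  # state) but all physical content - energy differences - survives
  for (k in 1:3) {
    du_orig <- h$rp$u - matrix(h$rp$u[k, ], 3, ncol(h$rp$u), byrow = TRUE)
    du_back <- back$u - matrix(back$u[k, ], 3, ncol(back$u), byrow = TRUE)
    expect_equal(du_back, du_orig, tolerance = 1e-6)
  }
  # and the free energies agree
  expect_equal(mbar_solve(back)$f, mbar_solve(h$rp)$f, tolerance = 1e-6)
})

test_that("constant-energy files give a constant matrix and bad files fail loudly", {
  d <- withr::local_tempdir()
  for (k in 0:1) {
    writeLines(c(
      "@ s0 legend \"H to 0\"", "@ s1 legend \"H to 1\"",
      sprintf("%d 1.0 1.0", 0:4 * 10)
    ), file.path(d, sprintf("s%d.xvg", k)))
  }
  rp <- parse_dhdl(file.path(d, c("s0.xvg", "s1.xvg")))
  expect_equal(rp$n_k, c(5L, 5L))
  expect_true(all(abs(diff(as.vector(rp$u))) < 1e-12))
  # truncated line
  writeLines(c("1 2.0 2.0", "2 2.0"), file.path(d, "bad.xvg"))
  expect_error(parse_dhdl(file.path(d, c("s0.xvg", "bad.xvg"))), "line")
  # missing state column
  writeLines(c("1 2.0", "2 2.0"), file.path(d, "short.xvg"))
  expect_error(parse_dhdl(file.path(d, c("s0.xvg", "short.xvg"))), "state column")
})

test_that("equilibration discard removes the leading fraction per state", {
  h <- make_harmonic_reduced_potentials(c(1, 2), n_per_state = 100, seed = 1)
  trimmed <- discard_equilibration(h$rp) # default 1 ns of 10 ns
  expect_equal(trimmed$n_k, c(90L, 90L))
  # retained samples are the later ones, order preserved
  expect_equal(trimmed$u[, 1], h$rp$u[, 11])
  expect_equal(discard_equilibration(h$rp, burn = 0), h$rp)
  expect_error(discard_equilibration(h$rp, burn = 10, total = 10), "smaller")
})

test_that("identical states give zero free energy difference and uniform overlap", {
  h <- make_harmonic_reduced_potentials(c(2, 2, 2), n_per_state = 400, seed = 3)
  m <- mbar_solve(h$rp)
  expect_true(all(abs(m$f) < 3 * pmax(m$df, 1e-6) + 1e-8))
  O <- overlap_matrix(m)
  expect_equal(rowSums(O), rep(1, 3), tolerance = 1e-6)
  expect_true(all(abs(O - 1 / 3) < 0.05))
})

test_that("the two-state stiffness-ratio free energy is recovered within 3 SE", {
  h <- make_harmonic_reduced_potentials(c(1, 4), n_per_state = 5000, seed = 17)
  m <- mbar_solve(h$rp)
  expect_equal(h$f_analytic[2], 0.5 * log(4))
  expect_lt(abs(m$f[2] - 0.5 * log(4)), 3 * m$df[2])
})

test_that("multistate and two-state (BAR) estimators agree to 1e-6", {
  for (seed in c(1, 5, 9)) {
    h <- make_harmonic_reduced_potentials(c(1, 3), n_per_state = 800, seed = seed)
    expect_equal(mbar_solve(h$rp, tol = 1e-12)$f[2], bar_solve(h$rp), tolerance = 1e-6)
  }
  # asymmetric sample counts too
  h <- make_harmonic_reduced_potentials(c(1, 2), n_per_state = c(500, 1500), seed = 4)
  expect_equal(mbar_solve(h$rp, tol = 1e-12)$f[2], bar_solve(h$rp), tolerance = 1e-6)
})

test_that("disjoint states are flagged and give a near-identity overlap", {
  # two stiff wells far apart: no phase-space overlap
  n <- 200
  set.seed(8)
  x <- c(rnorm(n, 0, 0.05), rnorm(n, 10, 0.05))
  u <- rbind(200 * x^2 / 2, 200 * (x - 10)^2 / 2)
  u <- pmin(u, 1e4) # keep finite
  rp <- reduced_potentials(u, c(n, n))
  expect_warning(m <- mbar_solve(rp), "overlap")
  expect_true(m$flagged)
  O <- m$overlap
  expect_equal(rowSums(O), rep(1, 2), tolerance = 1e-6)
  expect_true(all(diag(O) > 0.999))
})

test_that("edge assembly follows the cycle bookkeeping", {
  # synthetic legs: dG_BC = 2, dG_D = 1, releases 3 and 3, solvent 0.5
  est <- assemble_edge(
    legs = list(BC = 2, D = 1, hydration_A = 1, hydration_B = 1.5),
    restraint_a = 3, restraint_b = 3
  )
  expect_equal(est$ddg, 2.5)
  expect_equal(sum(est$breakdown), est$ddg, tolerance = 1e-10)
  # identity edge: symmetric legs cancel exactly
  id <- assemble_edge(
    legs = list(BC = 1.2, D = -1.2, hydration_A = 0.7, hydration_B = 0.7),
    restraint_a = 2.5, restraint_b = 2.5
  )
  expect_equal(id$ddg, 0)
  # direction reversal with negated legs negates the estimate
  fwd <- assemble_edge(
    legs = list(BC = 2, D = 1, charged_solvent = 0.5),
    restraint_a = 3, restraint_b = 4
  )
  rev <- assemble_edge(
    legs = list(BC = -2, D = -1, charged_solvent = -0.5),
    restraint_a = 4, restraint_b = 3
  )
  expect_equal(rev$ddg, -fwd$ddg, tolerance = 1e-12)
  # missing legs are reported by name
  expect_error(assemble_edge(list(BC = 1), 1, 1), "missing legs")
  # uncertainties add in quadrature
  lr <- function(dg, u) structure(list(leg = "x", dg = dg, uncertainty = u), class = "leg_result")
  est2 <- assemble_edge(
    legs = list(BC = lr(2, 0.3), D = lr(1, 0.4), charged_solvent = lr(0.5, 0.12)),
    restraint_a = 3, restraint_b = 3
  )
  expect_equal(est2$uncertainty, sqrt(0.3^2 + 0.4^2 + 0.12^2))
})

test_that("harmonic ladder free energies are recovered across seeds", {
  stiff <- c(1, 2, 4, 8, 16)
  fails <- 0
  for (seed in 1:20) {
    h <- make_harmonic_reduced_potentials(stiff, n_per_state = 5000, seed = seed)
    m <- mbar_solve(h$rp)
    ok <- all(abs(m$f - h$f_analytic) <= 3 * pmax(m$df, 1e-12))
    if (!ok) fails <- fails + 1
  }
  expect_lte(fails, 1) # 95%+ pass rate over 20 seeds
})
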