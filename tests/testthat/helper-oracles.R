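# Independent oracles used by the tests. These deliberately re-derive
# quantities through routes the package does not use.

RT_298 <- rt_kcal(298.15)

# Exact 6-D configurational-integral release correction by 1-D quadrature
# of the separable integrand (Jacobian r^2 sin(thetaA) sin(thetaB)).
# Integration windows of +/- 12 sigma keep the adaptive quadrature on the
# peak; the integrand is below 1e-30 of its maximum outside.
quadrature_release <- function(br, temperature = 298.15) {
  rt <- rt_kcal(temperature)
  b <- 1 / rt
  gi <- function(f, k, x0, lo, hi) {
    s <- 1 / sqrt(b * k)
    stats::integrate(f, max(lo, x0 - 12 * s), min(hi, x0 + 12 * s),
      rel.tol = 1e-12
    )$value
  }
  d2r <- pi / 180
  Ir <- gi(function(r) r^2 * exp(-b * br$k_r * (r - br$r0)^2 / 2), br$k_r, br$r0, 0, Inf)
  Ia <- gi(
    function(t) sin(t) * exp(-b * br$k_thetaA * (t - br$thetaA0 * d2r)^2 / 2),
    br$k_thetaA, br$thetaA0 * d2r, 0, pi
  )
  Ib <- gi(
    function(t) sin(t) * exp(-b * br$k_thetaB * (t - br$thetaB0 * d2r)^2 / 2),
    br$k_thetaB, br$thetaB0 * d2r, 0, pi
  )
  Ip <- function(k) gi(function(p) exp(-b * k * p^2 / 2), k, 0, -pi, pi)
  Z <- Ir * Ia * Ib * Ip(br$k_phiA) * Ip(br$k_phiB) * Ip(br$k_phiC)
  -rt * log(8 * pi^2 * 1660 / Z)
}

# Leading stiff-spring (Laplace) correction separating the closed form from
# the exact integral.
stiff_spring_correction <- function(br, temperature = 298.15) {
  rt <- rt_kcal(temperature)
  rt^2 * (1 / (2 * br$k_thetaA) + 1 / (2 * br$k_thetaB) - 1 / (br$k_r * br$r0^2))
}

# Two-state Bennett acceptance ratio estimate by direct root finding on the
# implicit BAR equation (independent of the multistate solver).
bar_solve <- function(rp) {
  stopifnot(nrow(rp$u) == 2)
  n1 <- rp$n_k[1]
  n2 <- rp$n_k[2]
  i1 <- seq_len(n1)
  i2 <- n1 + seq_len(n2)
  w_f <- rp$u[2, i1] - rp$u[1, i1] # forward work, samples from state 1
  w_r <- rp$u[1, i2] - rp$u[2, i2] # reverse work, samples from state 2
  M <- log(n1 / n2)
  g <- function(df) {
    sum(1 / (1 + exp(M + w_f - df))) - sum(1 / (1 + exp(-M + w_r + df)))
  }
  stats::uniroot(g, c(-200, 200), tol = 1e-12)$root
}

# convenience: toluene-like molecule graph (6-ring + methyl)
toluene_graph <- function() {
  molecule_graph(
    atoms = data.frame(
      index = 1:7, element = "C", formal_charge = 0,
      stringsAsFactors = FALSE
    ),
    bonds = data.frame(
      from = c(1:5, 6, 1),
      to = c(2:6, 1, 7),
      order = c(2, 1, 2, 1, 2, 1, 1)
    )
  )
}

# standalone system + single-moleculetype topology for the fixture ligand
fixture_ligand_parts <- function(fx) {
  list(
    system = molecular_system(fx$system$atoms[fx$ligand_map, , drop = FALSE],
      box = fx$system$box
    ),
    topology = gmx_topology(
      atomtypes = fx$topology$atomtypes,
      moleculetypes = fx$topology$moleculetypes["LIG"],
      molecules = data.frame(name = "LIG", count = 1L, stringsAsFactors = FALSE),
      defaults = fx$topology$defaults
    )
  )
}

# merged dual-ligand fixture complex with selected restraints
fixture_edge <- function(seed_a = 3, seed_b = 4, n_frames = 60) {
  fxA <- make_helix_complex(20, "ring-tail", 12, seed = seed_a)
  fxB <- make_helix_complex(20, "linear", 12, seed = seed_b)
  merged <- merge_ligand_into_complex(
    list(system = fxA$system, topology = fxA$topology),
    fixture_ligand_parts(fxB),
    "LIG"
  )
  traj <- make_fluctuating_trajectory(merged$system, 0.02, n_frames = n_frames, seed = 7)
  brA <- suppressWarnings(
    select_boresch_restraint(merged$system, traj, fxA$ligand_graph, merged$ligand_a_atoms)
  )
  brB <- suppressWarnings(
    select_boresch_restraint(merged$system, traj, fxB$ligand_graph, merged$ligand_b_atoms)
  )
  list(merged = merged, traj = traj, brA = brA, brB = brB, fxA = fxA, fxB = fxB)
}

# minimal two-type topology for nonbonded bookkeeping tests
tiny_two_ligand_top <- function() {
  at <- data.frame(
    name = c("X1", "X2", "X3", "Y1", "Y2"),
    at_num = 6, mass = 12.01, charge = 0, ptype = "A",
    sigma = c(0.30, 0.32, 0.34, 0.36, 0.38),
    epsilon = c(0.5, 0.4, 0.3, 0.2, 0.1),
    stringsAsFactors = FALSE
  )
  mk <- function(name, types) {
    list(
      name = name, nrexcl = 3L,
      atoms = data.frame(
        nr = seq_along(types), type = types, resnr = 1, residue = name,
        atom = paste0("A", seq_along(types)), cgnr = 1, charge = 0.1,
        mass = 12.01, typeB = NA_character_, chargeB = NA_real_,
        massB = NA_real_, stringsAsFactors = FALSE
      ),
      bonded = list()
    )
  }
  gmx_topology(
    atomtypes = at,
    moleculetypes = list(
      MOLA = mk("MOLA", c("X1", "X2", "X3")),
      MOLB = mk("MOLB", c("Y1", "Y2"))
    ),
    molecules = data.frame(
      name = c("MOLA", "MOLB"), count = c(1L, 1L),
      stringsAsFactors = FALSE
    )
  )
}

benzene_sdf_text <- c(
  "benzene", "  septop", "",
  "  6  6  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    1.4000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.2124    0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.2124   -0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000   -1.4000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -1.2124   -0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -1.2124    0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  2  0  0  0  0", "  2  3  1  0  0  0  0", "  3  4  2  0  0  0  0",
  "  4  5  1  0  0  0  0", "  5  6  2  0  0  0  0", "  6  1  1  0  0  0  0",
  "M  END", "$$$$"
)

ethane_sdf_text <- c(
  "ethane", "  septop", "",
  "  2  1  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.5400    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0  0  0  0",
  "M  END", "$$$$"
)
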