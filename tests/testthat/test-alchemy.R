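test_that("merging inserts ligand B after ligand A with updated bookkeeping", {
  fxA <- make_helix_complex(12, "ring-tail", 12, seed = 3)
  fxB <- make_helix_complex(12, "linear", 12, seed = 4)
  ligB <- fixture_ligand_parts(fxB)
  merged <- merge_ligand_into_complex(
    list(system = fxA$system, topology = fxA$topology), ligB, "LIG"
  )
  nprot <- length(fxA$protein_atoms)
  expect_equal(nrow(merged$system$atoms), nprot + 8 + 6)
  expect_equal(merged$ligand_a_atoms, nprot + 1:8)
  expect_equal(merged$ligand_b_atoms, nprot + 8 + 1:6)
  # name clash resolved by suffixing
  expect_equal(merged$ligand_b_name, "LIG_B")
  expect_equal(merged$topology$molecules$name, c("PROT", "LIG", "LIG_B"))
  expect_equal(septop:::.top_atom_count(merged$topology), nrow(merged$system$atoms))
  # coordinate/topology mismatch rejected
  short <- ligB
  short$system <- molecular_system(ligB$system$atoms[1:3, ], ligB$system$box)
  expect_error(
    merge_ligand_into_complex(
      list(system = fxA$system, topology = fxA$topology), short, "LIG"
    ),
    "mismatch"
  )
})

test_that("uniquified ligand types keep their parameters and are idempotent", {
  top <- tiny_two_ligand_top()
  t1 <- uniquify_ligand_atomtypes(top, "MOLA", "_A")
  expect_equal(t1$moleculetypes$MOLA$atoms$type, c("X1_A", "X2_A", "X3_A"))
  for (tp in c("X1", "X2", "X3")) {
    orig <- top$atomtypes[top$atomtypes$name == tp, ]
    clone <- t1$atomtypes[t1$atomtypes$name == paste0(tp, "_A"), ]
    expect_equal(clone$sigma, orig$sigma)
    expect_equal(clone$epsilon, orig$epsilon)
  }
  # idempotence
  t2 <- uniquify_ligand_atomtypes(t1, "MOLA", "_A")
  expect_equal(t2, t1)
  # two ligands end with disjoint type sets
  t3 <- uniquify_ligand_atomtypes(t1, "MOLB", "_B")
  expect_length(
    intersect(t3$moleculetypes$MOLA$atoms$type, t3$moleculetypes$MOLB$atoms$type),
    0
  )
})

test_that("scaled and dummy type variants implement the epsilon scaling", {
  top <- uniquify_ligand_atomtypes(tiny_two_ligand_top(), "MOLA", "_A")
  s <- add_scaled_atomtypes(top, "MOLA", 0.5)
  at <- s$atomtypes
  expect_equal(at$epsilon[at$name == "X1_A_s"], 0.5 * 0.5)
  expect_equal(at$epsilon[at$name == "X1_A_d"], 0)
  expect_equal(at$sigma[at$name == "X1_A_s"], at$sigma[at$name == "X1_A"])
  # gamma = 1 leaves the scaled clone identical to the original
  s1 <- add_scaled_atomtypes(top, "MOLA", 1)
  expect_equal(
    s1$atomtypes$epsilon[s1$atomtypes$name == "X2_A_s"],
    s1$atomtypes$epsilon[s1$atomtypes$name == "X2_A"]
  )
  # per-atom override splits a private type and applies its own gamma
  so <- add_scaled_atomtypes(top, "MOLA", 0.5, overrides = c(`2` = 0.01))
  a2type <- so$moleculetypes$MOLA$atoms$type[2]
  eps_base <- top$atomtypes$epsilon[top$atomtypes$name == "X2_A"]
  expect_equal(
    so$atomtypes$epsilon[so$atomtypes$name == paste0(a2type, "_s")],
    0.01 * eps_base
  )
  expect_equal(
    so$atomtypes$epsilon[so$atomtypes$name == "X1_A_s"],
    0.5 * top$atomtypes$epsilon[top$atomtypes$name == "X1_A"]
  )
  expect_error(add_scaled_atomtypes(top, "MOLA", 1.5), "gamma")
})

test_that("inter-ligand vdW is excluded for every type-variant pair", {
  top <- tiny_two_ligand_top()
  top <- uniquify_ligand_atomtypes(top, "MOLA", "_A")
  top <- uniquify_ligand_atomtypes(top, "MOLB", "_B")
  ta <- ligand_type_variants(top, "MOLA") # 3 base types
  tb <- ligand_type_variants(top, "MOLB") # 2 base types
  z <- zero_interligand_vdw(top, ta, tb)
  expect_equal(nrow(z$nonbond_params), 3 * 2)
  expect_true(all(z$nonbond_params$epsilon == 0))
  # LJ energy across the ligands is exactly zero at any distance
  for (r in c(0.2, 0.35, 1.0)) {
    expect_equal(lj_pair_energy(z, ta[1], tb[1], r), 0)
  }
  # but not within a ligand
  expect_false(lj_pair_energy(z, ta[1], ta[2], 0.35) == 0)
  expect_error(zero_interligand_vdw(top, ta, ta), "overlap")
})

test_that("complex leg topologies realize the eps-HREX state table", {
  ed <- fixture_edge()
  legs <- build_complex_leg_topologies(ed$merged, ed$brA, ed$brB, alchemical_protocol())
  bc <- legs$topology_BC
  d <- legs$topology_D
  ligA <- legs$ligand_a_name
  ligB <- legs$ligand_b_name
  aA <- bc$moleculetypes[[ligA]]$atoms
  aB <- bc$moleculetypes[[ligB]]$atoms
  orig <- ed$merged$topology$moleculetypes[[ligA]]$atoms

  # end-state physics: BC state A of ligand A equals the unmodified input
  type_par <- function(top, types, what) {
    top$atomtypes[[what]][match(types, top$atomtypes$name)]
  }
  expect_identical(type_par(bc, aA$type, "sigma"), type_par(ed$merged$topology, orig$type, "sigma"))
  expect_identical(type_par(bc, aA$type, "epsilon"), type_par(ed$merged$topology, orig$type, "epsilon"))
  expect_identical(aA$charge, orig$charge)
  # BC state B: ligand A uncharged at scaled vdW; ligand B charged
  expect_true(all(aA$chargeB == 0))
  expect_true(all(endsWith(aA$typeB, "_s")))
  expect_equal(aB$chargeB, orig2 <- ed$merged$topology$moleculetypes[[ligB]]$atoms$charge)
  # BC state A: ligand B is an uncharged dummy
  expect_true(all(aB$charge == 0))
  expect_true(all(type_par(bc, aB$type, "epsilon") == 0))
  # scaled epsilon is gamma times the original
  eps_scaled <- type_par(bc, aA$typeB, "epsilon")
  eps_orig <- type_par(ed$merged$topology, orig$type, "epsilon")
  expect_equal(eps_scaled, 0.5 * eps_orig)

  # path continuity: BC state B == D state A, field by field
  for (lig in c(ligA, ligB)) {
    expect_identical(bc$moleculetypes[[lig]]$atoms$typeB, d$moleculetypes[[lig]]$atoms$type)
    expect_identical(bc$moleculetypes[[lig]]$atoms$chargeB, d$moleculetypes[[lig]]$atoms$charge)
  }
  # D state B: ligand A dummy/uncharged, ligand B fully restored
  dA <- d$moleculetypes[[ligA]]$atoms
  dB <- d$moleculetypes[[ligB]]$atoms
  origB <- ed$merged$topology$moleculetypes[[ligB]]$atoms
  expect_true(all(type_par(d, dA$typeB, "epsilon") == 0))
  expect_true(all(dA$chargeB == 0))
  expect_identical(
    type_par(d, dB$typeB, "epsilon"),
    type_par(ed$merged$topology, origB$type, "epsilon")
  )
  expect_identical(dB$chargeB, origB$charge)
})

test_that("restraint force constants follow the leg roles", {
  ed <- fixture_edge()
  legs <- build_complex_leg_topologies(ed$merged, ed$brA, ed$brB, alchemical_protocol())
  bc_bonds <- legs$topology_BC$intermolecular$bonds
  d_bonds <- legs$topology_D$intermolecular$bonds
  # two distance restraints: ligand A first, ligand B second
  kA_bc <- bc_bonds[[1]]$params[c(2, 4)]
  kB_bc <- bc_bonds[[2]]$params[c(2, 4)]
  kA_d <- d_bonds[[1]]$params[c(2, 4)]
  kB_d <- d_bonds[[2]]$params[c(2, 4)]
  full_A <- 20 * 4.184 * 100
  expect_equal(kA_bc, c(0, full_A)) # A restrained during leg B
  expect_equal(kB_bc, c(full_A, full_A)) # B restrained throughout BC
  expect_equal(kA_d, c(full_A, full_A)) # A stays restrained in D (released analytically)
  expect_equal(kB_d, c(full_A, 0)) # B released across leg D
})

test_that("net system charge is conserved across states for equal-charge ligands", {
  ed <- fixture_edge()
  legs <- build_complex_leg_topologies(ed$merged, ed$brA, ed$brB, alchemical_protocol())
  for (top in list(legs$topology_BC, legs$topology_D)) {
    qa <- 0
    qb <- 0
    for (m in top$molecules$name) {
      a <- top$moleculetypes[[m]]$atoms
      qa <- qa + sum(a$charge)
      qb <- qb + sum(ifelse(is.na(a$chargeB), a$charge, a$chargeB))
    }
    expect_equal(qa, qb, tolerance = 1e-10)
  }
})

test_that("neutral solvent topologies decouple the ligand in the B state", {
  fxA <- make_helix_complex(12, "ring-tail", 12, seed = 3)
  fxB <- make_helix_complex(12, "linear", 12, seed = 4)
  st <- build_solvent_topologies(fixture_ligand_parts(fxA), fixture_ligand_parts(fxB))
  expect_false(st$charged)
  for (top in list(st$hydration_A, st$hydration_B)) {
    a <- top$moleculetypes[[1]]$atoms
    expect_true(all(a$chargeB == 0))
    eps_b <- top$atomtypes$epsilon[match(a$typeB, top$atomtypes$name)]
    expect_true(all(eps_b == 0))
    # A state untouched
    expect_false(all(a$charge == 0))
  }
})

test_that("charged solvent protocol restrains the ligands half a box edge apart", {
  fxA <- make_helix_complex(12, "ring-tail", 12, seed = 3, net_charge = 1)
  fxB <- make_helix_complex(12, "linear", 12, seed = 4, net_charge = 1)
  la <- fixture_ligand_parts(fxA)
  lb <- fixture_ligand_parts(fxB)
  st <- build_solvent_topologies(la, lb, charged = TRUE, box = c(60, 60, 60))
  expect_true(st$charged)
  expect_equal(st$restraint$equilibrium, 30)
  expect_equal(st$restraint$k, 2.4)
  # restraint present at full strength in both states of both topologies
  for (top in list(st$topology_BC, st$topology_D)) {
    p <- top$intermolecular$bonds[[1]]$params
    expect_equal(p[1], 3.0) # nm
    expect_equal(p[2], p[4])
    expect_equal(p[2], 2.4 * 4.184 * 100)
  }
  # two-stage gentle equilibration
  expect_equal(vapply(st$equilibration, `[[`, 1.0, "k"), c(0.0024, 2.4))
  expect_equal(vapply(st$equilibration, `[[`, 1.0, "duration_ps"), c(10, 10))
  # gamma = 0.3 scaling in the solvent
  tv <- st$topology_BC$moleculetypes[[st$ligand_a_name]]$type_variants
  eps_s <- st$topology_BC$atomtypes$epsilon[match(tv$scaled[1], st$topology_BC$atomtypes$name)]
  eps_b <- st$topology_BC$atomtypes$epsilon[match(tv$base[1], st$topology_BC$atomtypes$name)]
  expect_equal(eps_s, 0.3 * eps_b)
  # mismatched net charges are a method violation
  lb0 <- fixture_ligand_parts(make_helix_complex(12, "linear", 12, seed = 4))
  expect_error(build_solvent_topologies(la, lb0, charged = TRUE, box = c(60, 60, 60)), "net charge")
})

test_that("dihedral restraints are appended with state-scaled force constants", {
  top <- tiny_two_ligand_top()
  t1 <- add_dihedral_restraints(top, "MOLA", list(c(1, 2, 3, 1)), values = 60, k = 20,
                                scaleA = 0, scaleB = 1)
  rows <- t1$moleculetypes$MOLA$bonded$dihedral_restraints
  expect_length(rows, 1)
  expect_equal(rows[[1]]$params[1], 60)
  expect_equal(rows[[1]]$params[3], 0)
  expect_equal(rows[[1]]$params[6], 20 * 4.184)
  # harmonic restraint energy vanishes at its equilibrium angle
  k <- rows[[1]]$params[6]
  energy <- function(phi) 0.5 * k * ((phi - 60) * pi / 180)^2
  expect_equal(energy(60), 0)
  # empty torsion list is the identity
  expect_equal(add_dihedral_restraints(top, "MOLA", list()), top)
  # unknown atoms rejected
  expect_error(add_dihedral_restraints(top, "MOLA", list(c(1, 2, 3, 99))), "existing")
})

test_that("backbone superposition aligns rigid copies exactly", {
  fx <- make_helix_complex(12, "ring-tail", 12, seed = 3)
  sys <- fx$system
  R <- diag(3)[c(2, 3, 1), ] # proper rotation
  moved <- septop:::.set_coords(sys, coords(sys) %*% R + 5)
  back <- superpose_backbone(moved, sys)
  expect_equal(coords(back), coords(sys), tolerance = 1e-8)
})
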