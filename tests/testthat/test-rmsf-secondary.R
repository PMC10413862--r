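test_that("RMSF is zero for identical frames and errors on a single frame", {
  fx <- make_helix_complex(10, "ring-tail", 12, seed = 1)
  frames <- lapply(1:5, function(i) coords(fx$system))
  traj <- trajectory(fx$system, frames)
  expect_true(all(compute_rmsf(traj) < 1e-10))
  expect_error(compute_rmsf(trajectory(fx$system, frames[1])), "single frame")
})

test_that("isotropic jitter reproduces the sqrt(3)-sigma closed form", {
  fx <- make_helix_complex(12, "ring-tail", 12, seed = 2)
  traj <- make_fluctuating_trajectory(fx$system, 0.02, n_frames = 500, seed = 11)
  r <- compute_rmsf(traj)
  expected <- 0.02 * sqrt(3)
  # atoms near the superposition frame see the closed form directly; atoms
  # far from the backbone additionally pick up rigid-fit noise, so the bound
  # is looser there
  bb <- as.character(fx$system$atoms$index[fx$system$atoms$name %in% c("N", "CA", "C", "CB")])
  expect_true(all(abs(r[bb] - expected) / expected < 0.10))
  expect_true(all(abs(r - expected) / expected < 0.30))
  expect_lt(abs(median(r) - expected) / expected, 0.05)
})

test_that("two-point alternating displacement gives RMSF equal to d", {
  fx <- make_helix_complex(10, "ring-tail", 12, seed = 1)
  ref <- coords(fx$system)
  d <- 0.37
  lig <- fx$ligand_map[1] # perturb a non-backbone atom; backbone drives the fit
  f1 <- ref
  f1[lig, 1] <- f1[lig, 1] + d
  f2 <- ref
  f2[lig, 1] <- f2[lig, 1] - d
  traj <- trajectory(fx$system, rep(list(f1, f2), 10))
  r <- compute_rmsf(traj)
  expect_equal(unname(r[as.character(lig)]), d, tolerance = 1e-6)
})

test_that("sigma = 0.2 A on one atom pushes only that atom over the cutoff", {
  fx <- make_helix_complex(12, "ring-tail", 12, seed = 2)
  n <- nrow(fx$system$atoms)
  sigma <- rep(0.002, n)
  victim <- fx$ligand_map[2]
  sigma[victim] <- 0.2
  traj <- make_fluctuating_trajectory(fx$system, sigma, n_frames = 300, seed = 3)
  r <- compute_rmsf(traj)
  over <- as.integer(names(r)[r > 0.1])
  expect_equal(over, victim)
})

test_that("an ideal helix is labeled helix in its interior", {
  fx <- make_helix_complex(20, "ring-tail", 12, seed = 1)
  prot <- molecular_system(fx$system$atoms[fx$protein_atoms, ], fx$system$box)
  ss <- assign_secondary_structure(prot)
  expect_true(all(ss$label[3:18] == "helix"))
  expect_true(sum(ss$label == "helix") >= 16)
})

test_that("an extended chain carries no helix labels", {
  # build a strand with phi = psi = 180 by internal coordinates
  N <- list(c(0, 0, 0))
  CA <- list(c(1.458, 0, 0))
  C <- list(place_atom(c(0, 0, 1), N[[1]], CA[[1]], 1.525, 111.2, 60))
  for (i in 1:7) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]], 1.329, 116.2, 180)
    CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]], 1.458, 121.7, 180)
    C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]], 1.525, 111.2, 180)
  }
  atoms <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(
      name = c("N", "CA", "C"), element = c("N", "C", "C"),
      resid = i, resname = "ALA", chain = "A",
      x = c(N[[i]][1], CA[[i]][1], C[[i]][1]),
      y = c(N[[i]][2], CA[[i]][2], C[[i]][2]),
      z = c(N[[i]][3], CA[[i]][3], C[[i]][3]),
      stringsAsFactors = FALSE
    )
  }))
  atoms <- cbind(index = seq_len(nrow(atoms)), atoms)
  ss <- assign_secondary_structure(molecular_system(atoms))
  expect_true(all(ss$label != "helix"))
  # phi in [-180, -90] with psi 180 is the sheet window; runs of >= 3 only
  expect_true(all(ss$label %in% c("sheet", "coil")))
})

test_that("short helical stretches are removed by the run-length filter", {
  ss <- data.frame(
    chain = "A", resid = 1:10,
    label = c("coil", "coil", "helix", "helix", "coil", "coil", "coil", "coil", "coil", "coil"),
    stringsAsFactors = FALSE
  )
  filtered <- septop:::.run_length_filter(ss$label, helix_min = 4, sheet_min = 3)
  expect_true(all(filtered == "coil"))
  kept <- septop:::.run_length_filter(
    c("helix", "helix", "helix", "helix", "coil"),
    helix_min = 4, sheet_min = 3
  )
  expect_equal(sum(kept == "helix"), 4)
})

test_that("missing backbone atoms yield coil with a warning", {
  fx <- make_helix_complex(10, "ring-tail", 12, seed = 1)
  at <- fx$system$atoms[fx$protein_atoms, ]
  at <- at[!(at$resid == 5 & at$name == "CA"), ]
  expect_warning(ss <- assign_secondary_structure(molecular_system(at)), "missing backbone")
  expect_equal(ss$label[ss$resid == 5], "coil")
})
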