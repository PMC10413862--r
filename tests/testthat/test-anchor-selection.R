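# brute-force oracle for the diameter-path / ring-middle ligand heuristic:
# enumerates every longest shortest path, every valid middle, and the
# resulting candidate anchor triples
ligand_anchor_oracle <- function(graph) {
  hg <- septop:::.heavy_graph(graph)
  d <- hg$dist
  dm <- max(d)
  solutions <- list()
  ends <- which(d == dm, arr.ind = TRUE)
  ends <- ends[ends[, 1] < ends[, 2], , drop = FALSE]
  for (r in seq_len(nrow(ends))) {
    paths <- igraph::all_shortest_paths(
      hg$graph,
      from = igraph::V(hg$graph)[ends[r, 1]],
      to = igraph::V(hg$graph)[ends[r, 2]]
    )$res
    for (p in paths) {
      pid <- as.integer(names(p))
      L <- length(pid)
      mids <- if (L %% 2 == 1) pid[(L + 1) / 2] else pid[c(L / 2, L / 2 + 1)]
      mc <- match(as.character(mids), rownames(d))
      dmid <- if (length(mc) == 1) d[, mc] else rowMeans(d[, mc])
      names(dmid) <- hg$indices
      ring <- hg$indices[graph$atoms$in_ring[match(hg$indices, graph$atoms$index)]]
      if (!length(ring)) next
      ord <- ring[order(dmid[as.character(ring)], ring)]
      solutions[[length(solutions) + 1]] <- ord[1:3]
    }
  }
  solutions
}

test_that("toluene anchors are the ring carbons nearest the diameter-path middle", {
  tol <- toluene_graph()
  sel <- select_ligand_anchors(tol)
  oracle <- ligand_anchor_oracle(tol)
  expect_true(any(vapply(oracle, function(s) setequal(s, sel), TRUE)))
  # all selected atoms are ring atoms mutually connected in the ring
  expect_true(all(sel %in% 1:6))
  # L1 is the atom closest to the path middle: never the para position (4)
  expect_false(sel[1] == 4)
})

test_that("SMARTS override selects the matched atoms directly", {
  tol <- toluene_graph()
  cfg <- restraint_search_config(ligand_smarts = "c1ccccc1")
  sel <- select_ligand_anchors(tol, config = cfg)
  expect_length(sel, 3)
  expect_true(all(sel %in% 1:6))
  cfg2 <- restraint_search_config(ligand_smarts = "N")
  expect_error(select_ligand_anchors(tol, config = cfg2), "match")
})

test_that("ring-free molecules fall back to central chain atoms with a warning", {
  hexane <- molecule_graph(
    atoms = data.frame(index = 1:6, element = "C", formal_charge = 0),
    bonds = data.frame(from = 1:5, to = 2:6, order = 1)
  )
  expect_warning(sel <- select_ligand_anchors(hexane), "no ring atoms")
  # middle of the 1..6 chain: atoms 3 and 4 plus one neighbor
  expect_true(all(sel %in% 2:5))
  expect_true(all(c(3, 4) %in% sel))
})

test_that("atoms fluctuating above the cutoff are excluded from anchor duty", {
  tol <- toluene_graph()
  rmsf <- setNames(rep(0.02, 7), 1:7)
  rmsf[c("1", "2")] <- 0.5
  sel <- select_ligand_anchors(tol, rmsf = rmsf)
  expect_false(any(c(1, 2) %in% sel))
  rmsf_all <- setNames(rep(0.5, 7), 1:7)
  expect_error(select_ligand_anchors(tol, rmsf = rmsf_all), "RMSF")
})

test_that("protein anchor cascade is deterministic and self-consistent", {
  fx <- make_helix_complex(20, "ring-tail", 12, seed = 3)
  traj <- make_fluctuating_trajectory(fx$system, 0.02, n_frames = 80, seed = 7)
  br1 <- suppressWarnings(
    select_boresch_restraint(fx$system, traj, fx$ligand_graph, fx$ligand_map)
  )
  br2 <- suppressWarnings(
    select_boresch_restraint(fx$system, traj, fx$ligand_graph, fx$ligand_map)
  )
  expect_equal(br1, br2)
  # selected restraints pass their own stability checks
  expect_true(angle_passes_cutoff(br1$thetaA0, br1$k_thetaA))
  expect_true(angle_passes_cutoff(br1$thetaB0, br1$k_thetaB))
  expect_true(all(c(br1$phiA0, br1$phiB0, br1$phiC0) > -150))
  expect_true(all(c(br1$phiA0, br1$phiB0, br1$phiC0) < 150))
  # six distinct atoms, protein anchors on backbone/CB of interior residues
  idx <- unlist(br1$atoms)
  expect_length(unique(idx), 6)
  at <- fx$system$atoms
  expect_true(all(at$name[match(idx[1:3], at$index)] %in% c("N", "CA", "C", "CB")))
})

test_that("each filter reports its own failure", {
  fx <- make_helix_complex(20, "ring-tail", 12, seed = 3)
  L <- fx$ligand_map[select_ligand_anchors(fx$ligand_graph)]
  # uniformly large fluctuations: RMSF filter empties the pool
  noisy <- make_fluctuating_trajectory(fx$system, 0.2, n_frames = 60, seed = 1)
  expect_error(
    select_protein_anchors(fx$system, noisy, L, ligand_atoms = fx$ligand_map),
    "RMSF filter"
  )
  # ligand too far away: distance filter empties the pool
  far <- make_helix_complex(20, "ring-tail", 40, seed = 3, box = c(120, 120, 120))
  trajf <- make_fluctuating_trajectory(far$system, 0.02, n_frames = 60, seed = 1)
  Lf <- far$ligand_map[select_ligand_anchors(far$ligand_graph)]
  expect_error(
    select_protein_anchors(far$system, trajf, Lf, ligand_atoms = far$ligand_map),
    "distance filter"
  )
})

test_that("protein anchors are reused across an edge only when they pass both checks", {
  ed <- fixture_edge()
  P <- c(ed$brA$atoms$P1, ed$brA$atoms$P2, ed$brA$atoms$P3)
  LB <- c(ed$brB$atoms$L1, ed$brB$atoms$L2, ed$brB$atoms$L3)
  ok <- check_protein_anchors(ed$merged$system, ed$traj, P, LB)
  reused <- identical(P, c(ed$brB$atoms$P1, ed$brB$atoms$P2, ed$brB$atoms$P3))
  # an anchor set failing the second system's checks must not be reused
  if (!ok) expect_false(reused)
  # and a passing set is a valid (not necessarily identical) choice
  expect_true(check_protein_anchors(
    ed$merged$system, ed$traj,
    c(ed$brB$atoms$P1, ed$brB$atoms$P2, ed$brB$atoms$P3), LB
  ))
})
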