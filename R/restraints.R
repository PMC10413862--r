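#' Configuration for Boresch restraint reference-atom search
#'
#' Tunable cutoffs of the anchor-selection cascade. Defaults follow the
#' SepTop selection heuristics: fluctuation cutoff 0.1 A (for ~2 ns equilibration
#' sampled every 4 ps), protein atoms 10-30 A from the ligand, first/second
#' protein anchors at least 0.5 nm apart, dihedral equilibria kept inside
#' (-150, 150) degrees, angle/dihedral circular spreads below 100 and
#' 300 deg^2, and angle equilibria at least `sqrt(2 * 10 RT / k)` away from 0
#' and 180 degrees (the 10 RT stability rule under the harmonic 1/2 k x^2
#' convention).
#'
#' @param rmsf_cutoff RMSF exclusion cutoff (Angstrom).
#' @param min_distance,max_distance Protein-ligand distance window (Angstrom).
#' @param min_p1_p2_sep Minimum P1-P2 separation (Angstrom; 5 A = 0.5 nm).
#' @param dihedral_window Allowed dihedral equilibrium range (degrees).
#' @param angle_spread_cutoff Max circular spread of candidate angles (deg^2).
#' @param dihedral_spread_cutoff Max circular spread of candidate dihedrals
#'   (deg^2).
#' @param stability_multiple Energy multiple m in the `sqrt(2 m RT / k)`
#'   angle cutoff (units of RT).
#' @param temperature Temperature (K).
#' @param ligand_smarts Optional SMARTS override for ligand anchor atoms.
#' @return List of class `restraint_search_config`.
#' @export
restraint_search_config <- function(rmsf_cutoff = 0.1,
                                    min_distance = 10,
                                    max_distance = 30,
                                    min_p1_p2_sep = 5,
                                    dihedral_window = c(-150, 150),
                                    angle_spread_cutoff = 100,
                                    dihedral_spread_cutoff = 300,
                                    stability_multiple = 10,
                                    temperature = 298.15,
                                    ligand_smarts = NULL) {
  stopifnot(
    rmsf_cutoff > 0, min_distance > 0, max_distance > min_distance,
    min_p1_p2_sep > 0, angle_spread_cutoff > 0, dihedral_spread_cutoff > 0,
    stability_multiple > 0, temperature > 0,
    length(dihedral_window) == 2,
    dihedral_window[1] > -180, dihedral_window[2] < 180,
    dihedral_window[1] < dihedral_window[2]
  )
  structure(
    list(
      rmsf_cutoff = rmsf_cutoff,
      min_distance = min_distance,
      max_distance = max_distance,
      min_p1_p2_sep = min_p1_p2_sep,
      dihedral_window = dihedral_window,
      angle_spread_cutoff = angle_spread_cutoff,
      dihedral_spread_cutoff = dihedral_spread_cutoff,
      stability_multiple = stability_multiple,
      temperature = temperature,
      ligand_smarts = ligand_smarts
    ),
    class = "restraint_search_config"
  )
}

#' Stability cutoff for harmonic angle restraints
#'
#' Half-width `Delta = sqrt(2 m RT / k)` (radians) of the region around the
#' minimum that a harmonic restraint `1/2 k (theta - theta0)^2` can reach at
#' an energy of m RT. An equilibrium angle is numerically safe when
#' `Delta < theta0 < pi - Delta`, keeping the restrained angle m RT away
#' from the singular 0/180-degree geometries.
#'
#' @param k Force constant (kcal mol-1 rad-2), > 0.
#' @param temperature Temperature (K).
#' @param multiple Energy multiple m (default 10).
#' @return Cutoff Delta in radians.
#' @export
angle_cutoff <- function(k, temperature = 298.15, multiple = 10) {
  if (!is.numeric(k) || any(k <= 0)) stop("force constant must be > 0")
  sqrt(2 * multiple * rt_kcal(temperature) / k)
}

#' @rdname angle_cutoff
#' @param theta0 Equilibrium angle (degrees).
#' @return `angle_passes_cutoff`: logical.
#' @export
angle_passes_cutoff <- function(theta0, k, temperature = 298.15, multiple = 10) {
  d <- angle_cutoff(k, temperature, multiple)
  th <- .rad(theta0)
  th > d & th < pi - d
}

#' Boresch-style orientational restraint
#'
#' Six reference atoms (three protein: P1, P2, P3; three ligand: L1, L2, L3)
#' restrained through one distance (P1-L1), two angles (P2-P1-L1 and
#' P1-L1-L2) and three dihedrals (P3-P2-P1-L1, P2-P1-L1-L2, P1-L1-L2-L3).
#' Distances in Angstrom, angles in degrees, force constants in
#' kcal mol-1 A-2 / kcal mol-1 rad-2 under the `1/2 k x^2` convention.
#'
#' @param atoms Named list or vector with integer elements `P1`, `P2`, `P3`,
#'   `L1`, `L2`, `L3` (atom indices in the complex).
#' @param r0 Equilibrium P1-L1 distance (Angstrom).
#' @param thetaA0,thetaB0 Equilibrium angles (degrees).
#' @param phiA0,phiB0,phiC0 Equilibrium dihedrals (degrees).
#' @param k_r,k_thetaA,k_thetaB,k_phiA,k_phiB,k_phiC Force constants.
#' @return Object of class `boresch_restraint`.
#' @export
boresch_restraint <- function(atoms, r0, thetaA0, thetaB0, phiA0, phiB0, phiC0,
                              k_r, k_thetaA, k_thetaB, k_phiA, k_phiB, k_phiC) {
  atoms <- as.list(atoms)
  need <- c("P1", "P2", "P3", "L1", "L2", "L3")
  if (!all(need %in% names(atoms))) {
    stop("restraint atoms must be named P1, P2, P3, L1, L2, L3")
  }
  idx <- unlist(atoms[need])
  if (anyDuplicated(idx)) stop("the six restraint atoms must be distinct")
  if (r0 <= 0) stop("r0 must be positive")
  if (thetaA0 <= 0 || thetaA0 >= 180 || thetaB0 <= 0 || thetaB0 >= 180) {
    stop("angle equilibria must lie strictly between 0 and 180 degrees")
  }
  ks <- c(k_r, k_thetaA, k_thetaB, k_phiA, k_phiB, k_phiC)
  if (any(ks < 0)) stop("force constants must be non-negative")
  structure(
    list(
      atoms = atoms[need],
      r0 = r0, thetaA0 = thetaA0, thetaB0 = thetaB0,
      phiA0 = phiA0, phiB0 = phiB0, phiC0 = phiC0,
      k_r = k_r, k_thetaA = k_thetaA, k_thetaB = k_thetaB,
      k_phiA = k_phiA, k_phiB = k_phiB, k_phiC = k_phiC
    ),
    class = "boresch_restraint"
  )
}

#' @export
print.boresch_restraint <- function(x, ...) {
  cat(sprintf(
    "boresch_restraint: P(%d,%d,%d) L(%d,%d,%d)\n",
    x$atoms$P1, x$atoms$P2, x$atoms$P3, x$atoms$L1, x$atoms$L2, x$atoms$L3
  ))
  cat(sprintf(
    "  r0 %.2f A (k %.1f), thetaA %.1f (k %.1f), thetaB %.1f (k %.1f)\n",
    x$r0, x$k_r, x$thetaA0, x$k_thetaA, x$thetaB0, x$k_thetaB
  ))
  cat(sprintf(
    "  phiA %.1f phiB %.1f phiC %.1f deg (k %.1f, %.1f, %.1f)\n",
    x$phiA0, x$phiB0, x$phiC0, x$k_phiA, x$k_phiB, x$k_phiC
  ))
  invisible(x)
}

#' Select ligand anchor atoms for Boresch restraints
#'
#' With a SMARTS override, the first three matched heavy atoms are used.
#' Otherwise the heavy-atom bond graph is analysed: all-pairs shortest paths
#' are computed, the longest shortest path (a graph diameter path) located,
#' and the three ring atoms nearest the middle of that path (by graph
#' distance, within one connected ring system) are selected; the atom closest
#' to the path middle becomes L1. A molecule with no rings falls back to the
#' three heavy atoms centered on the path middle, with a warning. When an
#' RMSF profile is supplied, atoms fluctuating above the cutoff are excluded
#' first.
#'
#' @param graph A [molecule_graph()].
#' @param rmsf Optional per-atom RMSF vector (Angstrom) aligned with
#'   `graph$atoms$index` (names = atom indices).
#' @param config A [restraint_search_config()].
#' @return Integer vector `c(L1, L2, L3)` of ligand atom indices.
#' @export
select_ligand_anchors <- function(graph, rmsf = NULL,
                                  config = restraint_search_config()) {
  stopifnot(inherits(graph, "molecule_graph"))
  if (!is.null(config$ligand_smarts)) {
    matches <- match_smarts(graph, config$ligand_smarts)
    if (!length(matches)) stop("ligand SMARTS override matched no atoms")
    m <- matches[[1]]
    heavy <- m[graph$atoms$element[match(m, graph$atoms$index)] != "H"]
    heavy <- heavy[!duplicated(heavy)]
    if (length(heavy) < 3) stop("ligand SMARTS override must match at least 3 heavy atoms")
    return(heavy[1:3])
  }
  hg <- .heavy_graph(graph)
  eligible <- hg$indices
  if (!is.null(rmsf)) {
    r <- rmsf[as.character(eligible)]
    eligible <- eligible[is.na(r) | r <= config$rmsf_cutoff]
  }
  if (length(hg$indices) < 3) stop("ligand must have at least 3 heavy atoms")
  if (length(eligible) < 3) stop("fewer than 3 ligand atoms pass the RMSF filter")
  d <- hg$dist
  if (any(is.infinite(d))) stop("ligand heavy-atom graph is disconnected")
  # longest shortest path; ties broken by ascending (i, j) atom-index pair
  ends <- which(d == max(d), arr.ind = TRUE)
  ends <- ends[ends[, 1] < ends[, 2], , drop = FALSE]
  ord <- order(hg$indices[ends[, 1]], hg$indices[ends[, 2]])
  ends <- ends[ord[1], ]
  vpath <- igraph::shortest_paths(
    hg$graph,
    from = igraph::V(hg$graph)[ends[1]],
    to = igraph::V(hg$graph)[ends[2]]
  )$vpath[[1]]
  path_idx <- as.integer(names(vpath))
  L <- length(path_idx)
  mids <- if (L %% 2 == 1) path_idx[(L + 1) / 2] else path_idx[c(L / 2, L / 2 + 1)]
  mid_cols <- match(as.character(mids), rownames(d))
  dmid_all <- if (length(mid_cols) == 1) d[, mid_cols] else rowMeans(d[, mid_cols])
  names(dmid_all) <- hg$indices
  dmid <- dmid_all[as.character(eligible)]
  inring <- graph$atoms$in_ring[match(eligible, graph$atoms$index)]
  if (!any(inring)) {
    warning("ligand has no ring atoms; falling back to chain atoms at the path middle")
    ord <- order(dmid, eligible)
    sel <- eligible[ord[1:3]]
    return(sel[order(dmid[as.character(sel)], sel)])
  }
  ring_atoms <- eligible[inring]
  # ring systems = connected components of the ring-atom subgraph
  sub <- igraph::induced_subgraph(hg$graph, as.character(ring_atoms))
  comp <- igraph::components(sub)
  membership <- comp$membership[as.character(ring_atoms)]
  best_sys <- membership[order(dmid[as.character(ring_atoms)], ring_atoms)][1]
  sys_atoms <- ring_atoms[membership == best_sys]
  if (length(sys_atoms) < 3) stop("central ring system has fewer than 3 eligible atoms")
  ord <- order(dmid[as.character(sys_atoms)], sys_atoms)
  sel <- sys_atoms[ord[1:3]]
  sel
}

.atom_pos <- function(system, index) {
  row <- match(index, system$atoms$index)
  as.numeric(system$atoms[row, c("x", "y", "z")])
}

.frame_pos <- function(frame, system, index) {
  frame[match(index, system$atoms$index), ]
}

#' Select protein anchor atoms for Boresch restraints
#'
#' Progressive filtering of the protein for stable reference atoms:
#' backbone + C-beta atoms of central residues of helices (or helices and
#' sheets when helix is not the dominant secondary structure), fluctuating
#' less than the RMSF cutoff, and sitting 10-30 A from the nearest ligand
#' heavy atom. P1 is the first surviving atom (ascending index) whose angle
#' P1-L1-L2 passes the 10 RT stability cutoff, whose dihedral P1-L1-L2-L3
#' lies in (-150, 150) degrees, and whose angle/dihedral circular spreads
#' over the trajectory stay below 100 / 300 deg^2. P2 additionally must lie
#' at least 0.5 nm from P1 and within half the shortest box edge, passing
#' the analogous checks on P2-P1-L1 and P2-P1-L1-L2. P3 maximizes
#' min(distance to P1, distance to P2) subject to the box limit and the
#' P3-P2-P1-L1 dihedral checks.
#'
#' @param system The complex [molecular_system()].
#' @param traj Optional [trajectory()]; trajectory-dependent filters are
#'   skipped with a warning when absent.
#' @param ligand_anchors Integer vector `c(L1, L2, L3)` of complex atom
#'   indices.
#' @param ligand_atoms Integer vector of all ligand heavy-atom indices in the
#'   complex (defaults to `ligand_anchors`).
#' @param config A [restraint_search_config()].
#' @param secondary Optional externally computed `secondary_structure`
#'   assignment.
#' @return Integer vector `c(P1, P2, P3)`.
#' @export
select_protein_anchors <- function(system, traj = NULL, ligand_anchors,
                                   ligand_atoms = ligand_anchors,
                                   config = restraint_search_config(),
                                   secondary = NULL) {
  stopifnot(inherits(system, "molecular_system"), length(ligand_anchors) == 3)
  at <- system$atoms
  protein_rows <- which(!(at$index %in% ligand_atoms) &
    at$name %in% c("N", "CA", "C", "CB"))
  if (!length(protein_rows)) stop("protein anchor search: no backbone/CB atoms found")
  if (is.null(secondary)) {
    # residues carrying a CA atom count as protein; ligands/solvent are skipped
    reskey <- paste(at$chain, at$resid, sep = "//")
    has_ca <- unique(reskey[at$name == "CA"])
    keep <- reskey %in% has_ca & !(at$index %in% ligand_atoms)
    prot_sys <- molecular_system(at[keep, , drop = FALSE], box = system$box)
    secondary <- assign_secondary_structure(prot_sys)
  }
  n_helix <- sum(secondary$label == "helix")
  n_sheet <- sum(secondary$label == "sheet")
  use_labels <- if (n_helix > n_sheet) "helix" else c("helix", "sheet")
  elements <- secondary_structure_elements(secondary)
  elements <- elements[elements$label %in% use_labels, , drop = FALSE]
  central <- character()
  for (k in seq_len(nrow(elements))) {
    rr <- seq(elements$start[k], elements$end[k])
    if (length(rr) > 2) rr <- rr[-c(1, length(rr))] # drop the two terminal residues
    else next
    central <- c(central, paste(elements$chain[k], rr, sep = "//"))
  }
  pool <- at$index[protein_rows]
  pool <- pool[paste(at$chain[protein_rows], at$resid[protein_rows], sep = "//") %in% central]
  if (!length(pool)) stop("protein anchor search failed at the secondary-structure filter")
  if (!is.null(traj)) {
    rmsf <- compute_rmsf(traj)
    r <- rmsf[as.character(pool)]
    pool <- pool[!is.na(r) & r < config$rmsf_cutoff]
    if (!length(pool)) stop("protein anchor search failed at the RMSF filter")
  } else {
    warning("no trajectory supplied; skipping RMSF and spread filters")
  }
  lig_xyz <- do.call(rbind, lapply(ligand_atoms, .atom_pos, system = system))
  dmin <- vapply(pool, function(i) {
    p <- .atom_pos(system, i)
    min(sqrt(colSums((t(lig_xyz) - p)^2)))
  }, 1.0)
  pool <- pool[dmin >= config$min_distance & dmin <= config$max_distance]
  if (!length(pool)) stop("protein anchor search failed at the ligand-distance filter")
  pool <- sort(pool)

  L1 <- ligand_anchors[1]
  L2 <- ligand_anchors[2]
  L3 <- ligand_anchors[3]
  half_box <- if (!is.null(system$box)) min(system$box) / 2 else Inf

  spread_ok <- function(idx4_angle, idx4_dih) {
    if (is.null(traj)) {
      return(TRUE)
    }
    angs <- vapply(traj$frames, function(f) {
      coord_angle(
        .frame_pos(f, system, idx4_angle[1]),
        .frame_pos(f, system, idx4_angle[2]),
        .frame_pos(f, system, idx4_angle[3])
      )
    }, 1.0)
    dihs <- vapply(traj$frames, function(f) {
      coord_dihedral(
        .frame_pos(f, system, idx4_dih[1]),
        .frame_pos(f, system, idx4_dih[2]),
        .frame_pos(f, system, idx4_dih[3]),
        .frame_pos(f, system, idx4_dih[4])
      )
    }, 1.0)
    circular_spread(angs) < config$angle_spread_cutoff &&
      circular_spread(dihs) < config$dihedral_spread_cutoff
  }

  check_candidate <- function(p, angle_atoms, dih_atoms, angle_k) {
    th <- coord_angle(
      .atom_pos(system, angle_atoms[1]),
      .atom_pos(system, angle_atoms[2]),
      .atom_pos(system, angle_atoms[3])
    )
    if (!angle_passes_cutoff(th, angle_k, config$temperature, config$stability_multiple)) {
      return(FALSE)
    }
    dh <- coord_dihedral(
      .atom_pos(system, dih_atoms[1]),
      .atom_pos(system, dih_atoms[2]),
      .atom_pos(system, dih_atoms[3]),
      .atom_pos(system, dih_atoms[4])
    )
    if (dh <= config$dihedral_window[1] || dh >= config$dihedral_window[2]) {
      return(FALSE)
    }
    spread_ok(angle_atoms, dih_atoms)
  }

  P1 <- NA_integer_
  for (p in pool) {
    r <- coord_distance(.atom_pos(system, p), .atom_pos(system, L1))
    k_thetaB <- 40 * (r / 5)^2
    if (check_candidate(p, c(p, L1, L2), c(p, L1, L2, L3), k_thetaB)) {
      P1 <- p
      break
    }
  }
  if (is.na(P1)) stop("protein anchor search failed at the P1 angle/dihedral filter")

  P2 <- NA_integer_
  p1_xyz <- .atom_pos(system, P1)
  for (p in setdiff(pool, P1)) {
    dp <- coord_distance(.atom_pos(system, p), p1_xyz)
    if (dp < config$min_p1_p2_sep || dp > half_box) next
    if (check_candidate(p, c(p, P1, L1), c(p, P1, L1, L2), 20)) {
      P2 <- p
      break
    }
  }
  if (is.na(P2)) stop("protein anchor search failed at the P2 separation/angle filter")

  p2_xyz <- .atom_pos(system, P2)
  cand3 <- setdiff(pool, c(P1, P2))
  best <- NA_integer_
  best_score <- -Inf
  for (p in cand3) {
    d1 <- coord_distance(.atom_pos(system, p), p1_xyz)
    d2 <- coord_distance(.atom_pos(system, p), p2_xyz)
    if (d1 > half_box || d2 > half_box) next
    dh_atoms <- c(p, P2, P1, L1)
    dh <- coord_dihedral(
      .atom_pos(system, dh_atoms[1]), .atom_pos(system, dh_atoms[2]),
      .atom_pos(system, dh_atoms[3]), .atom_pos(system, dh_atoms[4])
    )
    if (dh <= config$dihedral_window[1] || dh >= config$dihedral_window[2]) next
    if (!is.null(traj)) {
      dihs <- vapply(traj$frames, function(f) {
        coord_dihedral(
          .frame_pos(f, system, p), .frame_pos(f, system, P2),
          .frame_pos(f, system, P1), .frame_pos(f, system, L1)
        )
      }, 1.0)
      if (circular_spread(dihs) >= config$dihedral_spread_cutoff) next
    }
    score <- min(d1, d2)
    if (score > best_score + 1e-12 ||
      (abs(score - best_score) <= 1e-12 && (is.na(best) || p < best))) {
      best <- p
      best_score <- score
    }
  }
  if (is.na(best)) stop("protein anchor search failed at the P3 dihedral/box filter")
  c(P1 = P1, P2 = P2, P3 = best)
}

#' Verify previously selected protein anchors against another complex
#'
#' Used for edge setup: the protein anchors chosen for one ligand are reused
#' for the other ligand of the edge when they pass the angle, dihedral and
#' spread checks in that second system; otherwise anchors are re-selected.
#'
#' @inheritParams select_protein_anchors
#' @param protein_anchors Integer vector `c(P1, P2, P3)`.
#' @return Logical.
#' @export
check_protein_anchors <- function(system, traj = NULL, protein_anchors,
                                  ligand_anchors,
                                  config = restraint_search_config()) {
  ok <- tryCatch(
    {
      r <- coord_distance(
        .atom_pos(system, protein_anchors[1]),
        .atom_pos(system, ligand_anchors[1])
      )
      vals <- measure_equilibrium_values(
        if (is.null(traj)) system else traj,
        c(
          P1 = protein_anchors[1], P2 = protein_anchors[2], P3 = protein_anchors[3],
          L1 = ligand_anchors[1], L2 = ligand_anchors[2], L3 = ligand_anchors[3]
        ),
        system = system
      )
      k <- assign_force_constants(vals[["r0"]])
      all(
        angle_passes_cutoff(vals[["thetaA0"]], k$k_thetaA, config$temperature,
                            config$stability_multiple),
        angle_passes_cutoff(vals[["thetaB0"]], k$k_thetaB, config$temperature,
                            config$stability_multiple),
        vals[c("phiA0", "phiB0", "phiC0")] > config$dihedral_window[1],
        vals[c("phiA0", "phiB0", "phiC0")] < config$dihedral_window[2]
      )
    },
    error = function(e) FALSE
  )
  isTRUE(ok)
}

#' Measure restraint equilibrium values
#'
#' Distance by the arithmetic mean over frames, angles and dihedrals by the
#' circular mean, reported in (-180, 180]. A single structure gives that
#' frame's geometry.
#'
#' @param x A [trajectory()] or [molecular_system()].
#' @param atoms Named vector/list with `P1`, `P2`, `P3`, `L1`, `L2`, `L3`.
#' @param system Reference system for index lookup when `x` is a trajectory
#'   (defaults to `x$system`).
#' @return Named numeric vector `r0`, `thetaA0`, `thetaB0`, `phiA0`,
#'   `phiB0`, `phiC0` (Angstrom / degrees).
#' @export
measure_equilibrium_values <- function(x, atoms, system = NULL) {
  atoms <- as.list(atoms)
  if (inherits(x, "molecular_system")) {
    system <- x
    frames <- list(coords(x))
  } else if (inherits(x, "trajectory")) {
    if (is.null(system)) system <- x$system
    frames <- x$frames
  } else {
    stop("x must be a molecular_system or trajectory")
  }
  g <- function(f, nm) .frame_pos(f, system, atoms[[nm]])
  per_frame <- function(fun) vapply(frames, fun, 1.0)
  r <- per_frame(function(f) coord_distance(g(f, "P1"), g(f, "L1")))
  thA <- per_frame(function(f) coord_angle(g(f, "P2"), g(f, "P1"), g(f, "L1")))
  thB <- per_frame(function(f) coord_angle(g(f, "P1"), g(f, "L1"), g(f, "L2")))
  phA <- per_frame(function(f) coord_dihedral(g(f, "P3"), g(f, "P2"), g(f, "P1"), g(f, "L1")))
  phB <- per_frame(function(f) coord_dihedral(g(f, "P2"), g(f, "P1"), g(f, "L1"), g(f, "L2")))
  phC <- per_frame(function(f) coord_dihedral(g(f, "P1"), g(f, "L1"), g(f, "L2"), g(f, "L3")))
  c(
    r0 = mean(r),
    thetaA0 = circular_mean(thA),
    thetaB0 = circular_mean(thB),
    phiA0 = circular_mean(phA),
    phiB0 = circular_mean(phB),
    phiC0 = circular_mean(phC)
  )
}

#' Assign restraint force constants
#'
#' The distance and five of the six force constants are fixed at
#' 20 kcal mol-1 A-2 / rad-2. The angle adjacent to the distance restraint
#' (P1-L1-L2) is scaled quadratically with the equilibrium distance so that
#' the arc length the ligand can sweep stays roughly constant: 40 kcal
#' mol-1 rad-2 at r0 = 5 A, growing as `40 (r0 / 5)^2`.
#'
#' @param r0 Equilibrium P1-L1 distance (Angstrom), > 0.
#' @return Named list of force constants `k_r`, `k_thetaA`, `k_thetaB`,
#'   `k_phiA`, `k_phiB`, `k_phiC`.
#' @export
assign_force_constants <- function(r0) {
  if (!is.numeric(r0) || r0 <= 0) stop("r0 must be positive")
  list(
    k_r = 20,
    k_thetaA = 20,
    k_thetaB = 40 * (r0 / 5)^2,
    k_phiA = 20,
    k_phiB = 20,
    k_phiC = 20
  )
}

#' Full restraint selection for one complex
#'
#' Convenience wrapper running ligand anchor selection, protein anchor
#' selection, equilibrium measurement and force-constant assignment.
#'
#' @inheritParams select_protein_anchors
#' @param ligand_graph [molecule_graph()] of the ligand.
#' @param ligand_map Integer vector mapping ligand graph atom indices to
#'   complex atom indices (`ligand_map[i]` = complex index of graph atom i).
#' @return A [boresch_restraint()].
#' @export
select_boresch_restraint <- function(system, traj = NULL, ligand_graph,
                                     ligand_map,
                                     config = restraint_search_config(),
                                     secondary = NULL) {
  lig_rmsf <- NULL
  if (!is.null(traj)) {
    rmsf_all <- compute_rmsf(traj)
    lig_rmsf <- rmsf_all[as.character(ligand_map)]
    names(lig_rmsf) <- ligand_graph$atoms$index
  }
  L <- select_ligand_anchors(ligand_graph, rmsf = lig_rmsf, config = config)
  Lg <- ligand_map[L]
  heavy <- ligand_map[ligand_graph$atoms$index[ligand_graph$atoms$element != "H"]]
  P <- select_protein_anchors(
    system, traj, Lg,
    ligand_atoms = heavy, config = config, secondary = secondary
  )
  atoms <- c(P1 = unname(P[1]), P2 = unname(P[2]), P3 = unname(P[3]),
             L1 = Lg[1], L2 = Lg[2], L3 = Lg[3])
  vals <- measure_equilibrium_values(if (is.null(traj)) system else traj,
    atoms,
    system = system
  )
  k <- assign_force_constants(vals[["r0"]])
  boresch_restraint(
    atoms = atoms,
    r0 = vals[["r0"]], thetaA0 = vals[["thetaA0"]], thetaB0 = vals[["thetaB0"]],
    phiA0 = vals[["phiA0"]], phiB0 = vals[["phiB0"]], phiC0 = vals[["phiC0"]],
    k_r = k$k_r, k_thetaA = k$k_thetaA, k_thetaB = k$k_thetaB,
    k_phiA = k$k_phiA, k_phiB = k$k_phiB, k_phiC = k$k_phiC
  )
}

#' Analytic standard-state restraint-release correction
#'
#' Free energy of releasing a fully restrained, non-interacting ligand from
#' its Boresch restraint into the standard-state volume V = 1660 A^3
#' (1 M), from the closed-form expression for the ratio of a freely
#' translating/rotating ligand's configurational integral (8 pi^2 V) to
#' that of the six harmonically restrained external degrees of freedom:
#'
#' `dG = -RT ln( 8 pi^2 V sqrt(k_r k_thA k_thB k_phA k_phB k_phC) /
#'   (r0^2 sin(thA0) sin(thB0) (2 pi RT)^3) )`
#'
#' under the `1/2 k x^2` convention. The sign convention is
#' released-into-solution minus restrained; a stiff restraint (large k)
#' gives a large negative release free energy.
#'
#' @param restraint A [boresch_restraint()] with all force constants > 0.
#' @param temperature Temperature (K).
#' @return Release free energy in kcal/mol.
#' @export
analytic_release_correction <- function(restraint, temperature = 298.15) {
  stopifnot(inherits(restraint, "boresch_restraint"))
  ks <- c(
    restraint$k_r, restraint$k_thetaA, restraint$k_thetaB,
    restraint$k_phiA, restraint$k_phiB, restraint$k_phiC
  )
  if (any(ks == 0)) stop("release correction undefined for zero force constants")
  rt <- rt_kcal(temperature)
  num <- 8 * pi^2 * .V_STANDARD * sqrt(prod(ks))
  den <- restraint$r0^2 * sin(.rad(restraint$thetaA0)) * sin(.rad(restraint$thetaB0)) *
    (2 * pi * rt)^3
  -rt * log(num / den)
}

#' Emit a Boresch restraint as a GROMACS intermolecular block
#'
#' Builds the `[ intermolecular_interactions ]` sections (harmonic bond
#' funct 6, angles funct 1, dihedrals funct 2) with A-state and B-state force
#' constants scaled by `scaleA` / `scaleB`, converting to GROMACS units
#' (nm, kJ mol-1).
#'
#' @param restraint A [boresch_restraint()] with atom indices global to the
#'   combined system.
#' @param scaleA,scaleB Multipliers on all force constants in the A and B
#'   alchemical states (0 = off, 1 = full).
#' @return Named list of sections suitable for the `intermolecular` field of
#'   [gmx_topology()].
#' @export
boresch_intermolecular <- function(restraint, scaleA = 1, scaleB = 1) {
  a <- restraint$atoms
  kb <- function(k) kcal_to_kj(k) * 100 # kcal/mol/A^2 -> kJ/mol/nm^2
  ka <- function(k) kcal_to_kj(k) # kcal/mol/rad^2 -> kJ/mol/rad^2
  row <- function(atoms, funct, p0, kfull, conv) {
    list(
      atoms = as.integer(atoms), funct = as.integer(funct),
      params = c(p0, conv(kfull) * scaleA, p0, conv(kfull) * scaleB)
    )
  }
  list(
    bonds = list(
      row(c(a$P1, a$L1), 6, restraint$r0 / 10, restraint$k_r, kb)
    ),
    angles = list(
      row(c(a$P2, a$P1, a$L1), 1, restraint$thetaA0, restraint$k_thetaA, ka),
      row(c(a$P1, a$L1, a$L2), 1, restraint$thetaB0, restraint$k_thetaB, ka)
    ),
    dihedrals = list(
      row(c(a$P3, a$P2, a$P1, a$L1), 2, restraint$phiA0, restraint$k_phiA, ka),
      row(c(a$P2, a$P1, a$L1, a$L2), 2, restraint$phiB0, restraint$k_phiB, ka),
      row(c(a$P1, a$L1, a$L2, a$L3), 2, restraint$phiC0, restraint$k_phiC, ka)
    )
  )
}

#' Write restraint metadata as JSON
#'
#' Sidecar consumed by the analysis layer (atoms, equilibrium values, force
#' constants, all in the package's kcal/A/degree conventions).
#'
#' @param restraint A [boresch_restraint()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boresch_json <- function(restraint, path) {
  jsonlite::write_json(
    unclass(restraint),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read restraint metadata from JSON
#'
#' @param path Path written by [write_boresch_json()].
#' @return A [boresch_restraint()].
#' @export
read_boresch_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  boresch_restraint(
    atoms = x$atoms,
    r0 = x$r0, thetaA0 = x$thetaA0, thetaB0 = x$thetaB0,
    phiA0 = x$phiA0, phiB0 = x$phiB0, phiC0 = x$phiC0,
    k_r = x$k_r, k_thetaA = x$k_thetaA, k_thetaB = x$k_thetaB,
    k_phiA = x$k_phiA, k_phiB = x$k_phiB, k_phiC = x$k_phiC
  )
}
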