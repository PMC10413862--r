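# Synthetic fixture generators: every downstream stage can be exercised on
# fully controlled inputs with known ground truth. These are geometric and
# statistical stand-ins (ideal helix, toy ligand, 1-D harmonic states), not
# force-field-realistic systems.

#' Ideal helix-plus-ligand complex
#'
#' Builds a poly-alanine alpha-helix (N, CA, C, CB per residue; phi = -57,
#' psi = -47, omega = 180 degrees, standard backbone bond geometry) with a
#' toy ligand placed at a prescribed distance from the helix-axis midpoint,
#' plus a minimal valid topology. The `ring-tail` ligand is a six-membered
#' carbon ring with a two-atom tail; `linear` is a hexane-like chain.
#'
#' @param n_res Number of residues (>= 8, so interior residues exist).
#' @param ligand `"ring-tail"` or `"linear"`.
#' @param site_distance Distance (Angstrom) from the helix-axis midpoint to
#'   the ligand center.
#' @param seed RNG seed (controls the ligand orientation).
#' @param net_charge Net formal charge assigned to the ligand.
#' @param box Box edge lengths (Angstrom).
#' @return List: `system` (complex), `topology`, `ligand_graph`,
#'   `ligand_map` (complex atom index of each ligand graph atom),
#'   `protein_atoms`.
#' @export
make_helix_complex <- function(n_res = 20, ligand = c("ring-tail", "linear"),
                               site_distance = 12, seed = 1,
                               net_charge = 0, box = c(60, 60, 60)) {
  ligand <- match.arg(ligand)
  if (n_res < 8) stop("n_res must be at least 8 (no interior residues otherwise)")
  set.seed(seed)
  phi <- -57
  psi <- -47
  # backbone by sequential internal-coordinate construction
  N <- list(c(0, 0, 0))
  CA <- list(c(1.458, 0, 0))
  C <- list(place_atom(c(0, 0, 1), N[[1]], CA[[1]], 1.525, 111.2, 57.8))
  for (i in seq_len(n_res - 1)) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]], 1.329, 116.2, psi)
    CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]], 1.458, 121.7, 180)
    C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]], 1.525, 111.2, phi)
  }
  CB <- lapply(seq_len(n_res), function(i) {
    place_atom(C[[i]], N[[i]], CA[[i]], 1.53, 110.5, 122.5)
  })
  prot <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    data.frame(
      name = c("N", "CA", "C", "CB"),
      element = c("N", "C", "C", "C"),
      resid = i, resname = "ALA", chain = "A",
      x = c(N[[i]][1], CA[[i]][1], C[[i]][1], CB[[i]][1]),
      y = c(N[[i]][2], CA[[i]][2], C[[i]][2], CB[[i]][2]),
      z = c(N[[i]][3], CA[[i]][3], C[[i]][3], CB[[i]][3]),
      stringsAsFactors = FALSE
    )
  }))

  # helix axis from the principal component of the CA trace
  ca_xyz <- do.call(rbind, CA)
  centroid <- colMeans(ca_xyz)
  axis <- svd(sweep(ca_xyz, 2, centroid))$v[, 1]
  perp <- c(-axis[2], axis[1], 0)
  if (.vnorm(perp) < 1e-6) perp <- c(1, 0, 0)
  perp <- perp / .vnorm(perp)
  lig_center <- centroid + site_distance * perp

  if (ligand == "ring-tail") {
    ang <- seq(0, 2 * pi, length.out = 7)[1:6]
    ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
    tail <- rbind(
      c(2.9, 0, 0),
      c(4.4, 0, 0)
    )
    lxyz <- rbind(ring, tail)
    bonds <- data.frame(
      from = c(1:6, 1, 7),
      to = c(2:6, 1, 7, 8),
      order = c(rep(1, 6), 1, 1)
    )
  } else {
    # sp3 zig-zag chain (collinear atoms would make dihedrals degenerate)
    lxyz <- matrix(0, 6, 3)
    lxyz[2, ] <- c(1.53, 0, 0)
    lxyz[3, ] <- place_atom(c(0, 0, 1), lxyz[1, ], lxyz[2, ], 1.53, 111, 60)
    for (i in 4:6) {
      lxyz[i, ] <- place_atom(lxyz[i - 3, ], lxyz[i - 2, ], lxyz[i - 1, ], 1.53, 111, 180)
    }
    bonds <- data.frame(from = 1:5, to = 2:6, order = 1)
  }
  # random (seeded) rigid rotation of the ligand
  qq <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(qq) < 0) qq[, 1] <- -qq[, 1]
  lxyz <- sweep(lxyz, 2, colMeans(lxyz)) %*% qq
  lxyz <- sweep(lxyz, 2, lig_center, "+")
  nlig <- nrow(lxyz)
  lig <- data.frame(
    name = paste0("C", seq_len(nlig)),
    element = "C",
    resid = n_res + 1, resname = "LIG", chain = "L",
    x = lxyz[, 1], y = lxyz[, 2], z = lxyz[, 3],
    stringsAsFactors = FALSE
  )
  atoms <- rbind(prot, lig)
  # shift everything into the box interior
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, box / 2 - colMeans(xyz), "+")
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms <- cbind(index = seq_len(nrow(atoms)), atoms)
  system <- molecular_system(atoms, box = box)

  lig_charges <- rep(0, nlig)
  if (nlig >= 2) {
    lig_charges[1:2] <- c(0.05, -0.05)
  }
  lig_charges[1] <- lig_charges[1] + net_charge
  atypes <- .atomtypes_frame(
    name = c("NBB", "CT1", "CBB", "CB3", "LC"),
    sigma = c(0.325, 0.400, 0.375, 0.390, 0.355),
    epsilon = c(0.71, 0.20, 0.44, 0.29, 0.29),
    mass = c(14.01, 12.01, 12.01, 12.01, 12.01)
  )
  prot_atoms <- data.frame(
    nr = seq_len(nrow(prot)),
    type = rep(c("NBB", "CT1", "CBB", "CB3"), n_res),
    resnr = rep(seq_len(n_res), each = 4),
    residue = "ALA",
    atom = rep(c("N", "CA", "C", "CB"), n_res),
    cgnr = rep(seq_len(n_res), each = 4),
    charge = rep(c(-0.3, 0.1, 0.2, 0.0), n_res),
    mass = rep(c(14.01, 12.01, 12.01, 12.01), n_res),
    typeB = NA_character_, chargeB = NA_real_, massB = NA_real_,
    stringsAsFactors = FALSE
  )
  lig_atoms <- data.frame(
    nr = seq_len(nlig), type = "LC", resnr = 1, residue = "LIG",
    atom = paste0("C", seq_len(nlig)), cgnr = 1,
    charge = lig_charges, mass = 12.01,
    typeB = NA_character_, chargeB = NA_real_, massB = NA_real_,
    stringsAsFactors = FALSE
  )
  lig_bonded <- list(bonds = lapply(seq_len(nrow(bonds)), function(i) {
    list(atoms = c(bonds$from[i], bonds$to[i]), funct = 1L, params = c(0.15, 250000))
  }))
  topology <- gmx_topology(
    atomtypes = atypes,
    moleculetypes = list(
      PROT = list(name = "PROT", nrexcl = 3L, atoms = prot_atoms, bonded = list()),
      LIG = list(name = "LIG", nrexcl = 3L, atoms = lig_atoms, bonded = lig_bonded)
    ),
    molecules = data.frame(
      name = c("PROT", "LIG"), count = c(1L, 1L),
      stringsAsFactors = FALSE
    ),
    defaults = data.frame(
      nbfunc = 1L, comb_rule = 2L, gen_pairs = "yes",
      fudgeLJ = 0.5, fudgeQQ = 0.8333, stringsAsFactors = FALSE
    ),
    system_name = "helix fixture"
  )
  graph <- molecule_graph(
    atoms = data.frame(
      index = seq_len(nlig), element = "C",
      formal_charge = c(net_charge, rep(0, nlig - 1)),
      stringsAsFactors = FALSE
    ),
    bonds = bonds,
    coords = lxyz
  )
  list(
    system = system,
    topology = topology,
    ligand_graph = graph,
    ligand_map = nrow(prot) + seq_len(nlig),
    protein_atoms = seq_len(nrow(prot))
  )
}

#' Trajectory with prescribed per-atom fluctuations
#'
#' Frames are the reference coordinates plus isotropic Gaussian noise with
#' per-atom standard deviation sigma per axis, so the expected RMSF of an
#' atom is `sigma * sqrt(3)`. Default cadence mirrors a 2 ns equilibration
#' saved every 4 ps (500 frames).
#'
#' @param system Reference [molecular_system()].
#' @param sigma_profile Per-atom sigma (Angstrom); scalar or vector.
#' @param n_frames Number of frames.
#' @param interval Frame interval (ps).
#' @param seed RNG seed.
#' @return A [trajectory()].
#' @export
make_fluctuating_trajectory <- function(system, sigma_profile, n_frames = 500,
                                        interval = 4, seed = 1) {
  n <- nrow(system$atoms)
  sigma <- rep_len(sigma_profile, n)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  set.seed(seed)
  ref <- coords(system)
  frames <- lapply(seq_len(n_frames), function(i) {
    ref + matrix(stats::rnorm(n * 3, sd = sigma), n, 3)
  })
  trajectory(system, frames, frame_interval = interval)
}

#' Harmonic-state reduced potentials with known free energies
#'
#' K one-dimensional harmonic states `u_k(x) = a_k x^2 / 2 + c_k` in reduced
#' units; samples are drawn exactly from each state's Gaussian, and the
#' analytic reduced free energies `f_k = ln(a_k / a_1) / 2 + (c_k - c_1)`
#' are returned alongside. The standard fixture for estimator validation.
#'
#' @param stiffnesses Reduced stiffness a_k per state (length K >= 2).
#' @param offsets Reduced energy offsets c_k (recycled).
#' @param n_per_state Samples drawn from each state (recycled).
#' @param seed RNG seed.
#' @return List: `rp` ([reduced_potentials()]), `f_analytic`, `samples`.
#' @export
make_harmonic_reduced_potentials <- function(stiffnesses, offsets = 0,
                                             n_per_state = 1000, seed = 1) {
  K <- length(stiffnesses)
  if (K < 2) stop("need at least 2 states")
  if (any(stiffnesses <= 0)) stop("stiffnesses must be positive")
  offsets <- rep_len(offsets, K)
  n_per_state <- rep_len(as.integer(n_per_state), K)
  set.seed(seed)
  x <- unlist(lapply(seq_len(K), function(k) {
    stats::rnorm(n_per_state[k], sd = 1 / sqrt(stiffnesses[k]))
  }))
  u <- vapply(x, function(xi) stiffnesses * xi^2 / 2 + offsets, numeric(K))
  f <- log(stiffnesses / stiffnesses[1]) / 2 + (offsets - offsets[1])
  list(
    rp = reduced_potentials(u, n_per_state),
    f_analytic = f,
    samples = x
  )
}

#' Noisy relative free-energy network with known truth
#'
#' True node values are drawn uniformly over +/- `dg_spread / 2`; edges (a
#' random spanning tree plus random extra pairs, so the graph is connected)
#' carry the true node difference plus Gaussian noise. Optionally a number
#' of non-tree edges (each guaranteed to sit on a cycle) are corrupted by
#' `+delta` and recorded in the ground truth.
#'
#' @param n_nodes Number of ligands.
#' @param n_edges Number of edges (>= n_nodes - 1).
#' @param dg_spread Range of true values (kcal/mol).
#' @param edge_sigma Gaussian noise on each edge (kcal/mol).
#' @param bad_edges Number of corrupted edges.
#' @param delta Corruption added to each bad edge (kcal/mol).
#' @param seed RNG seed.
#' @return List: `network` ([fe_network()]), `truth` (named dG vector),
#'   `bad_edges` (edge ids "from->to").
#' @export
make_noisy_network <- function(n_nodes, n_edges, dg_spread = 3,
                               edge_sigma = 0.2, bad_edges = 0, delta = 2,
                               seed = 1) {
  if (n_edges < n_nodes - 1) stop("need at least n_nodes - 1 edges for connectivity")
  max_edges <- choose(n_nodes, 2)
  if (n_edges > max_edges) stop("too many edges for ", n_nodes, " nodes")
  if (bad_edges > n_edges - (n_nodes - 1)) {
    stop("bad_edges cannot exceed the number of non-tree edges")
  }
  set.seed(seed)
  ids <- sprintf("lig%02d", seq_len(n_nodes))
  dg <- stats::setNames(stats::runif(n_nodes, -dg_spread / 2, dg_spread / 2), ids)
  # random spanning tree
  perm <- sample(ids)
  tree <- data.frame(
    from = vapply(2:n_nodes, function(i) perm[sample.int(i - 1, 1)], ""),
    to = perm[2:n_nodes],
    stringsAsFactors = FALSE
  )
  used <- .pair_key(tree$from, tree$to)
  extra <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  while (nrow(tree) + nrow(extra) < n_edges) {
    pair <- sample(ids, 2)
    k <- .pair_key(pair[1], pair[2])
    if (k %in% used) next
    used <- c(used, k)
    extra <- rbind(extra, data.frame(
      from = pair[1], to = pair[2],
      stringsAsFactors = FALSE
    ))
  }
  edges <- rbind(tree, extra)
  edges$ddg <- dg[edges$to] - dg[edges$from] +
    stats::rnorm(nrow(edges), sd = edge_sigma)
  edges$sigma <- if (edge_sigma > 0) edge_sigma else NA_real_
  bad_ids <- character()
  if (bad_edges > 0) {
    # corrupt only identifiable edges: an edge with a degree-2 endpoint lies
    # in exactly the same cycles as its partner edge, so no cycle-based
    # diagnostic can single it out; prefer non-tree edges whose endpoints
    # both touch at least three edges
    deg <- table(c(edges$from, edges$to))
    extra_rows <- nrow(tree) + seq_len(nrow(extra))
    discr <- extra_rows[deg[edges$from[extra_rows]] >= 3 &
      deg[edges$to[extra_rows]] >= 3]
    pool <- if (length(discr) >= bad_edges) discr else extra_rows
    pick <- sample(seq_along(pool), bad_edges)
    rows <- pool[pick]
    edges$ddg[rows] <- edges$ddg[rows] + delta
    bad_ids <- .edge_id(edges[rows, , drop = FALSE])
  }
  net <- fe_network(
    data.frame(id = ids, exp_dg = unname(dg), stringsAsFactors = FALSE),
    edges
  )
  list(network = net, truth = dg, bad_edges = bad_ids, delta = delta)
}
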