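#' Alchemical protocol settings
#'
#' Parameters of the epsilon-scaled replica-exchange (eps-HREX) variant of
#' the dual-ligand binding-site transformation: the Lennard-Jones epsilon of
#' every ligand atom type is multiplied by `gamma` in the intermediate
#' states (0.5 in the complex, 0.3 in the solvent by default), with optional
#' per-atom gamma overrides (e.g. 0.01 on a slowly rotating R-group) and
#' optional dihedral restraints on rotatable bonds.
#'
#' @param gamma_complex LJ-epsilon scaling factor for binding-site legs.
#' @param gamma_solvent LJ-epsilon scaling factor for the charged-ligand
#'   solvent leg.
#' @param gamma_overrides List with optional elements `A` and `B`, each a
#'   named numeric vector mapping ligand atom numbers (within the ligand
#'   moleculetype) to an override gamma.
#' @param dihedral_softening Optional named numeric vector of force-constant
#'   scale factors for ligand torsions (reserved for rotamer-sampling
#'   problems).
#' @param enable_dihedral_restraints Restrain rotatable bonds of both ligands
#'   through the adapted cycle.
#' @param torsions List with optional elements `A` and `B`: each a list of
#'   integer 4-vectors (atom numbers within the ligand moleculetype) to
#'   restrain when `enable_dihedral_restraints` is TRUE.
#' @param dihedral_k Dihedral restraint force constant
#'   (kcal mol-1 rad-2).
#' @return List of class `alchemical_protocol`.
#' @export
alchemical_protocol <- function(gamma_complex = 0.5, gamma_solvent = 0.3,
                                gamma_overrides = list(),
                                dihedral_softening = NULL,
                                enable_dihedral_restraints = FALSE,
                                torsions = list(),
                                dihedral_k = 20) {
  for (g in c(gamma_complex, gamma_solvent)) {
    if (g <= 0 || g > 1) stop("gamma must lie in (0, 1]")
  }
  for (side in names(gamma_overrides)) {
    ov <- gamma_overrides[[side]]
    if (any(ov <= 0 | ov > 1)) stop("override gamma must lie in (0, 1]")
  }
  structure(
    list(
      gamma_complex = gamma_complex,
      gamma_solvent = gamma_solvent,
      gamma_overrides = gamma_overrides,
      dihedral_softening = dihedral_softening,
      enable_dihedral_restraints = enable_dihedral_restraints,
      torsions = torsions,
      dihedral_k = dihedral_k
    ),
    class = "alchemical_protocol"
  )
}

#' Rigid backbone superposition of two systems
#'
#' Least-squares (Kabsch) fit of `mobile` onto `fixed` using backbone atoms
#' (N, CA, C) matched by residue id and atom name. A light-weight stand-in
#' for a dedicated structure-alignment tool; both protein frames of an edge
#' should be aligned before merging.
#'
#' @param mobile,fixed [molecular_system()] objects sharing backbone
#'   residues.
#' @return `mobile` with transformed coordinates.
#' @export
superpose_backbone <- function(mobile, fixed) {
  key <- function(s) paste(s$atoms$chain, s$atoms$resid, s$atoms$name, sep = "//")
  bb <- function(s) s$atoms$name %in% c("N", "CA", "C")
  km <- key(mobile)[bb(mobile)]
  kf <- key(fixed)[bb(fixed)]
  common <- intersect(km, kf)
  if (length(common) < 3) stop("fewer than 3 common backbone atoms to superpose on")
  mi <- match(common, key(mobile))
  fi <- match(common, key(fixed))
  fit <- .kabsch(coords(fixed)[fi, , drop = FALSE], coords(mobile)[mi, , drop = FALSE])
  .set_coords(mobile, .apply_fit(coords(mobile), fit))
}

# total atom count implied by a topology's [molecules] composition
.top_atom_count <- function(top) {
  sum(vapply(seq_len(nrow(top$molecules)), function(i) {
    top$molecules$count[i] * nrow(top$moleculetypes[[top$molecules$name[i]]]$atoms)
  }, 1L))
}

# global atom index range of the first copy of a moleculetype
.mol_atom_range <- function(top, name) {
  offset <- 0L
  for (i in seq_len(nrow(top$molecules))) {
    m <- top$molecules$name[i]
    n <- nrow(top$moleculetypes[[m]]$atoms)
    if (m == name) {
      return(seq.int(offset + 1L, offset + n))
    }
    offset <- offset + top$molecules$count[i] * n
  }
  stop("moleculetype not in composition: ", name)
}

.merge_atomtypes <- function(a, b) {
  common <- intersect(a$name, b$name)
  for (nm in common) {
    ra <- a[a$name == nm, c("sigma", "epsilon")]
    rb <- b[b$name == nm, c("sigma", "epsilon")]
    if (any(abs(as.numeric(ra[1, ]) - as.numeric(rb[1, ])) > 1e-12)) {
      stop("conflicting parameters for shared atom type ", nm)
    }
  }
  rbind(a, b[!(b$name %in% a$name), , drop = FALSE])
}

#' Merge a second ligand into a protein-ligand complex
#'
#' Inserts ligand B's coordinates directly after ligand A's block and its
#' moleculetype into the complex topology, renaming on moleculetype clashes
#' (suffix `_B`). The combined coordinate file holds protein, ligand A,
#' ligand B, then solvent; the composition list is updated accordingly.
#'
#' @param complex List with `system` ([molecular_system()]) and `topology`
#'   ([gmx_topology()]) of the solvated protein-ligand-A complex.
#' @param ligand List with `system` and `topology` of ligand B (already
#'   aligned into the binding site frame).
#' @param ligand_a_name Moleculetype name of ligand A in the complex
#'   topology.
#' @return List `system`, `topology`, `ligand_a_name`, `ligand_b_name`,
#'   `ligand_a_atoms`, `ligand_b_atoms` (global coordinate indices).
#' @export
merge_ligand_into_complex <- function(complex, ligand, ligand_a_name) {
  ctop <- complex$topology
  csys <- complex$system
  ltop <- ligand$topology
  lsys <- ligand$system
  if (!(ligand_a_name %in% names(ctop$moleculetypes))) {
    stop("ligand A moleculetype not found: ", ligand_a_name)
  }
  if (nrow(csys$atoms) != .top_atom_count(ctop)) {
    stop("complex coordinate/topology atom-count mismatch")
  }
  lig_names <- setdiff(ltop$molecules$name, c())
  if (length(lig_names) != 1) stop("ligand topology must contain exactly one molecule")
  bname <- lig_names[1]
  bmol <- ltop$moleculetypes[[bname]]
  if (nrow(lsys$atoms) != nrow(bmol$atoms)) {
    stop("ligand coordinate/topology atom-count mismatch")
  }
  if (bname %in% names(ctop$moleculetypes)) {
    bname_new <- paste0(bname, "_B")
    if (bname_new %in% names(ctop$moleculetypes)) {
      stop("cannot rename clashing moleculetype: ", bname_new, " also exists")
    }
    bmol$name <- bname_new
    bname <- bname_new
  }
  a_range <- .mol_atom_range(ctop, ligand_a_name)
  insert_at <- max(a_range)

  atoms <- csys$atoms
  latoms <- lsys$atoms
  nb <- nrow(latoms)
  latoms$index <- seq_len(nb) + insert_at
  before <- atoms[seq_len(insert_at), , drop = FALSE]
  after <- atoms[-seq_len(insert_at), , drop = FALSE]
  if (nrow(after)) after$index <- after$index + nb
  merged_atoms <- rbind(before, latoms, after)
  merged_atoms$index <- seq_len(nrow(merged_atoms))
  msys <- molecular_system(merged_atoms, box = csys$box)

  mtypes <- .merge_atomtypes(ctop$atomtypes, ltop$atomtypes)
  mols <- ctop$moleculetypes
  mols[[bname]] <- bmol
  comp <- ctop$molecules
  apos <- which(comp$name == ligand_a_name)[1]
  comp <- rbind(
    comp[seq_len(apos), , drop = FALSE],
    data.frame(name = bname, count = 1L, stringsAsFactors = FALSE),
    if (apos < nrow(comp)) comp[(apos + 1):nrow(comp), , drop = FALSE]
  )
  nb_params <- ctop$nonbond_params
  if (!is.null(ltop$nonbond_params)) {
    nb_params <- unique(rbind(nb_params, ltop$nonbond_params))
  }
  mtop <- gmx_topology(
    atomtypes = mtypes, moleculetypes = mols, molecules = comp,
    nonbond_params = nb_params, intermolecular = ctop$intermolecular,
    defaults = ctop$defaults, system_name = ctop$system_name
  )
  list(
    system = msys, topology = mtop,
    ligand_a_name = ligand_a_name, ligand_b_name = bname,
    ligand_a_atoms = a_range,
    ligand_b_atoms = seq_len(nb) + insert_at
  )
}

#' Give a ligand its own private atom types
#'
#' Clones every atom type used by the ligand moleculetype under a new
#' suffixed name (identical sigma/epsilon) and repoints the ligand atoms, so
#' that pairwise nonbonded overrides can later target this ligand alone.
#' Idempotent for a given suffix.
#'
#' @param top A [gmx_topology()].
#' @param ligand_id Moleculetype name of the ligand.
#' @param suffix Type-name suffix (e.g. `"_A"`).
#' @return Modified topology.
#' @export
uniquify_ligand_atomtypes <- function(top, ligand_id, suffix) {
  mol <- top$moleculetypes[[ligand_id]]
  if (is.null(mol)) stop("no such moleculetype: ", ligand_id)
  remap <- function(tp) {
    if (is.na(tp) || endsWith(tp, suffix)) tp else paste0(tp, suffix)
  }
  used <- unique(c(mol$atoms$type, mol$atoms$typeB[!is.na(mol$atoms$typeB)]))
  for (tp in used) {
    new <- remap(tp)
    if (new == tp) next
    if (new %in% top$atomtypes$name) {
      # suffix collision with an unrelated pre-existing type
      src <- top$atomtypes[top$atomtypes$name == tp, ]
      dst <- top$atomtypes[top$atomtypes$name == new, ]
      if (abs(src$sigma - dst$sigma) > 1e-12 || abs(src$epsilon - dst$epsilon) > 1e-12) {
        stop("suffix collision: type ", new, " already exists with different parameters")
      }
      next
    }
    clone <- top$atomtypes[top$atomtypes$name == tp, ]
    clone$name <- new
    top$atomtypes <- rbind(top$atomtypes, clone)
  }
  mol$atoms$type <- vapply(mol$atoms$type, remap, "")
  mol$atoms$typeB <- vapply(mol$atoms$typeB, remap, "")
  top$moleculetypes[[ligand_id]] <- mol
  validate_gmx_topology(top)
  top
}

#' Add scaled and dummy variants of a ligand's atom types
#'
#' For every atom type used by the (already uniquified) ligand, adds a
#' "scaled" clone with `epsilon' = gamma * epsilon` (per-atom overrides
#' taking precedence) and a "dummy" clone with `epsilon' = 0`; sigma is
#' never changed. Overridden atoms are first split onto private per-atom
#' types so the override applies to those atoms alone. The variant map is
#' stored on the moleculetype as `type_variants`.
#'
#' @param top A [gmx_topology()].
#' @param ligand_id Moleculetype name.
#' @param gamma Default LJ-epsilon scaling factor in (0, 1].
#' @param overrides Optional named numeric vector: names are ligand atom
#'   numbers, values the override gamma.
#' @return Modified topology.
#' @export
add_scaled_atomtypes <- function(top, ligand_id, gamma, overrides = NULL) {
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  mol <- top$moleculetypes[[ligand_id]]
  if (is.null(mol)) stop("no such moleculetype: ", ligand_id)
  if (!is.null(overrides) && length(overrides)) {
    if (any(overrides <= 0 | overrides > 1)) stop("override gamma must lie in (0, 1]")
    for (nr in as.integer(names(overrides))) {
      row <- which(mol$atoms$nr == nr)
      if (!length(row)) stop("override references missing ligand atom ", nr)
      tp <- mol$atoms$type[row]
      private <- paste0(tp, "_o", nr)
      if (!(private %in% top$atomtypes$name)) {
        clone <- top$atomtypes[top$atomtypes$name == tp, ]
        clone$name <- private
        top$atomtypes <- rbind(top$atomtypes, clone)
      }
      mol$atoms$type[row] <- private
      if (!is.na(mol$atoms$typeB[row])) mol$atoms$typeB[row] <- private
    }
  }
  atom_gamma <- rep(gamma, nrow(mol$atoms))
  if (!is.null(overrides) && length(overrides)) {
    hit <- match(mol$atoms$nr, as.integer(names(overrides)))
    atom_gamma[!is.na(hit)] <- overrides[hit[!is.na(hit)]]
  }
  used <- unique(mol$atoms$type)
  variants <- data.frame(
    base = used,
    scaled = paste0(used, "_s"),
    dummy = paste0(used, "_d"),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(used)) {
    tp <- used[i]
    g <- unique(atom_gamma[mol$atoms$type == tp])
    if (length(g) > 1) stop("inconsistent gamma for type ", tp)
    src <- top$atomtypes[top$atomtypes$name == tp, ]
    for (variant in c("scaled", "dummy")) {
      new <- variants[[variant]][i]
      if (new %in% top$atomtypes$name) next
      clone <- src
      clone$name <- new
      clone$epsilon <- if (variant == "scaled") src$epsilon * g else 0
      top$atomtypes <- rbind(top$atomtypes, clone)
    }
  }
  mol$type_variants <- variants
  top$moleculetypes[[ligand_id]] <- mol
  validate_gmx_topology(top)
  top
}

#' All atom-type variants (base, scaled, dummy) used by a ligand
#'
#' @param top A [gmx_topology()].
#' @param ligand_id Moleculetype name.
#' @return Character vector of type names.
#' @export
ligand_type_variants <- function(top, ligand_id) {
  mol <- top$moleculetypes[[ligand_id]]
  if (is.null(mol)) stop("no such moleculetype: ", ligand_id)
  base <- unique(c(mol$atoms$type, mol$atoms$typeB[!is.na(mol$atoms$typeB)]))
  if (!is.null(mol$type_variants)) {
    base <- unique(c(base, unlist(mol$type_variants, use.names = FALSE)))
  }
  base
}

# pair sigma under the topology's combination rule (default: arithmetic mean)
.comb_sigma <- function(top, t1, t2) {
  at <- top$atomtypes
  s1 <- at$sigma[at$name == t1]
  s2 <- at$sigma[at$name == t2]
  rule <- if (!is.null(top$defaults)) top$defaults$comb_rule else 2L
  if (isTRUE(rule == 3)) sqrt(s1 * s2) else (s1 + s2) / 2
}

#' Zero the van der Waals interaction between two ligands' atom types
#'
#' Adds one `[ nonbond_params ]` override per (ligand-A variant x ligand-B
#' variant) type pair with epsilon = 0, removing all LJ interaction between
#' the two ligands in every alchemical state. Coulomb interactions are
#' deliberately left alone: the engine interpolates Hamiltonians linearly,
#' and no end state has both ligands' charges on simultaneously.
#'
#' @param top A [gmx_topology()].
#' @param types_a,types_b Character vectors of the two ligands' atom-type
#'   variants (disjoint).
#' @return Modified topology.
#' @export
zero_interligand_vdw <- function(top, types_a, types_b) {
  if (length(intersect(types_a, types_b))) {
    stop("ligand type sets overlap; uniquify atom types first")
  }
  rows <- expand.grid(type1 = types_a, type2 = types_b, stringsAsFactors = FALSE)
  rows$sigma <- vapply(seq_len(nrow(rows)), function(i) {
    .comb_sigma(top, rows$type1[i], rows$type2[i])
  }, 1.0)
  rows$epsilon <- 0
  top$nonbond_params <- rbind(top$nonbond_params, rows)
  validate_gmx_topology(top)
  top
}

#' Lennard-Jones pair energy under a topology
#'
#' `V(r) = 4 eps [(sigma/r)^12 - (sigma/r)^6]` with sigma/epsilon taken from
#' a `[ nonbond_params ]` override when one exists for the type pair, else
#' from the combination rule.
#'
#' @param top A [gmx_topology()].
#' @param t1,t2 Atom type names.
#' @param r Distance in nm.
#' @return Energy in kJ/mol.
#' @export
lj_pair_energy <- function(top, t1, t2, r) {
  at <- top$atomtypes
  nb <- top$nonbond_params
  sigma <- NULL
  if (!is.null(nb) && nrow(nb)) {
    hit <- which((nb$type1 == t1 & nb$type2 == t2) | (nb$type1 == t2 & nb$type2 == t1))
    if (length(hit)) {
      sigma <- nb$sigma[hit[1]]
      eps <- nb$epsilon[hit[1]]
    }
  }
  if (is.null(sigma)) {
    sigma <- .comb_sigma(top, t1, t2)
    eps <- sqrt(at$epsilon[at$name == t1] * at$epsilon[at$name == t2])
  }
  4 * eps * ((sigma / r)^12 - (sigma / r)^6)
}

.set_ligand_states <- function(top, ligand_id, stateA, stateB) {
  # stateA/stateB: list(type = "base"|"scaled"|"dummy", charge = "full"|"zero")
  mol <- top$moleculetypes[[ligand_id]]
  tv <- mol$type_variants
  if (is.null(tv)) stop("ligand ", ligand_id, " has no scaled/dummy variants yet")
  pick <- function(which_type, base_types) {
    idx <- match(base_types, tv$base)
    switch(which_type,
      base = base_types,
      scaled = tv$scaled[idx],
      dummy = tv$dummy[idx]
    )
  }
  base <- mol$atoms$type
  # atoms may currently point at any variant; resolve back to base first
  for (col in c("scaled", "dummy")) {
    hit <- match(base, tv[[col]])
    base[!is.na(hit)] <- tv$base[hit[!is.na(hit)]]
  }
  q <- mol$atoms$charge
  mol$atoms$type <- pick(stateA$type, base)
  mol$atoms$charge <- if (stateA$charge == "full") q else 0
  mol$atoms$typeB <- pick(stateB$type, base)
  mol$atoms$chargeB <- if (stateB$charge == "full") q else 0
  if (all(is.na(mol$atoms$massB))) mol$atoms$massB <- mol$atoms$mass
  mol$atoms$.full_charge <- q
  top$moleculetypes[[ligand_id]] <- mol
  top
}

.assert_state_continuity <- function(top_bc, top_d, ligand_ids) {
  for (lig in ligand_ids) {
    bc <- top_bc$moleculetypes[[lig]]$atoms
    d <- top_d$moleculetypes[[lig]]$atoms
    if (!identical(bc$typeB, d$type) ||
      max(abs(bc$chargeB - d$charge)) > 0) {
      stop("internal error: alchemical path discontinuity for ", lig)
    }
  }
  invisible(TRUE)
}

#' Build the two binding-site leg topologies of the cycle
#'
#' Realizes the eps-HREX state table on the merged dual-ligand complex. The
#' combined B+C leg topology goes from (ligand A fully interacting, ligand B
#' a restrained dummy) to (both ligands at scaled vdW, A uncharged and
#' restrained, B charged and restrained); the leg D topology continues to
#' (A a restrained dummy - released analytically afterwards - and B fully
#' interacting, unrestrained). State B of the first topology is asserted to
#' equal state A of the second, field by field.
#'
#' @param merged Result of [merge_ligand_into_complex()].
#' @param restraint_a,restraint_b [boresch_restraint()] objects for the two
#'   ligands (atom indices global to the merged system).
#' @param protocol An [alchemical_protocol()].
#' @return List of class `leg_topology_set`: `topology_BC`, `topology_D`,
#'   `system`, `restraints`, ligand names and atom index vectors.
#' @export
build_complex_leg_topologies <- function(merged, restraint_a, restraint_b,
                                         protocol = alchemical_protocol()) {
  top <- merged$topology
  ligA <- merged$ligand_a_name
  ligB <- merged$ligand_b_name
  top <- uniquify_ligand_atomtypes(top, ligA, "_LA")
  top <- uniquify_ligand_atomtypes(top, ligB, "_LB")
  top <- add_scaled_atomtypes(
    top, ligA, protocol$gamma_complex,
    overrides = protocol$gamma_overrides$A
  )
  top <- add_scaled_atomtypes(
    top, ligB, protocol$gamma_complex,
    overrides = protocol$gamma_overrides$B
  )
  top <- zero_interligand_vdw(
    top,
    ligand_type_variants(top, ligA),
    ligand_type_variants(top, ligB)
  )

  bc <- top
  bc <- .set_ligand_states(bc, ligA,
    stateA = list(type = "base", charge = "full"),
    stateB = list(type = "scaled", charge = "zero")
  )
  bc <- .set_ligand_states(bc, ligB,
    stateA = list(type = "dummy", charge = "zero"),
    stateB = list(type = "scaled", charge = "full")
  )
  bc$intermolecular <- .merge_intermolecular(
    boresch_intermolecular(restraint_a, scaleA = 0, scaleB = 1),
    boresch_intermolecular(restraint_b, scaleA = 1, scaleB = 1)
  )

  d <- top
  d <- .set_ligand_states(d, ligA,
    stateA = list(type = "scaled", charge = "zero"),
    stateB = list(type = "dummy", charge = "zero")
  )
  d <- .set_ligand_states(d, ligB,
    stateA = list(type = "scaled", charge = "full"),
    stateB = list(type = "base", charge = "full")
  )
  d$intermolecular <- .merge_intermolecular(
    boresch_intermolecular(restraint_a, scaleA = 1, scaleB = 1),
    boresch_intermolecular(restraint_b, scaleA = 1, scaleB = 0)
  )

  if (isTRUE(protocol$enable_dihedral_restraints)) {
    tA <- protocol$torsions$A
    tB <- protocol$torsions$B
    k <- protocol$dihedral_k
    # decoupled->coupled ligand (B): restrained throughout the complex legs,
    # released in leg D; interacting->decoupled ligand (A): turned on in leg B
    # together with the orientational restraints, kept on afterwards.
    if (length(tA)) {
      bc <- add_dihedral_restraints(bc, ligA, tA, k = k, scaleA = 0, scaleB = 1)
      d <- add_dihedral_restraints(d, ligA, tA, k = k, scaleA = 1, scaleB = 1)
    }
    if (length(tB)) {
      bc <- add_dihedral_restraints(bc, ligB, tB, k = k, scaleA = 1, scaleB = 1)
      d <- add_dihedral_restraints(d, ligB, tB, k = k, scaleA = 1, scaleB = 0)
    }
  }

  .assert_state_continuity(bc, d, c(ligA, ligB))
  structure(
    list(
      topology_BC = bc, topology_D = d, system = merged$system,
      restraints = list(A = restraint_a, B = restraint_b),
      ligand_a_name = ligA, ligand_b_name = ligB,
      ligand_a_atoms = merged$ligand_a_atoms,
      ligand_b_atoms = merged$ligand_b_atoms
    ),
    class = "leg_topology_set"
  )
}

.merge_intermolecular <- function(...) {
  blocks <- list(...)
  out <- list()
  for (b in blocks) {
    for (sec in names(b)) out[[sec]] <- c(out[[sec]], b[[sec]])
  }
  out
}

#' Add dihedral restraints on ligand torsions
#'
#' Appends `[ dihedral_restraints ]` rows (funct 1) to the ligand
#' moleculetype with A-state and B-state force constants `scaleA * k` and
#' `scaleB * k`. Equilibrium values default to the torsion angles measured
#' from supplied values. The restraint energy is zero at the equilibrium
#' angle.
#'
#' @param top A [gmx_topology()].
#' @param ligand_id Moleculetype name.
#' @param torsions List of integer 4-vectors (atom numbers within the
#'   moleculetype).
#' @param values Equilibrium angles in degrees (recycled; default 0).
#' @param k Force constant (kcal mol-1 rad-2).
#' @param scaleA,scaleB State multipliers on k.
#' @return Modified topology.
#' @export
add_dihedral_restraints <- function(top, ligand_id, torsions, values = 0,
                                    k = 20, scaleA = 1, scaleB = 1) {
  if (!length(torsions)) {
    return(top)
  }
  mol <- top$moleculetypes[[ligand_id]]
  if (is.null(mol)) stop("no such moleculetype: ", ligand_id)
  values <- rep_len(values, length(torsions))
  bonds <- mol$bonded$bonds
  bonded_pair <- function(i, j) {
    if (is.null(bonds)) {
      return(TRUE)
    }
    any(vapply(bonds, function(b) {
      all(sort(b$atoms[1:2]) == sort(c(i, j)))
    }, TRUE))
  }
  kj <- kcal_to_kj(k)
  for (t in seq_along(torsions)) {
    q <- as.integer(torsions[[t]])
    if (length(q) != 4 || !all(q %in% mol$atoms$nr)) {
      stop("torsion ", t, " does not reference 4 existing ligand atoms")
    }
    if (!all(vapply(1:3, function(i) bonded_pair(q[i], q[i + 1]), TRUE))) {
      warning("torsion ", paste(q, collapse = "-"), " is not bonded-connected")
    }
    mol$bonded$dihedral_restraints <- c(
      mol$bonded$dihedral_restraints,
      list(list(
        atoms = q, funct = 1L,
        params = c(values[t], 0, kj * scaleA, values[t], 0, kj * scaleB)
      ))
    )
  }
  top$moleculetypes[[ligand_id]] <- mol
  top
}

.net_charge <- function(top, ligand_id, state = "A") {
  a <- top$moleculetypes[[ligand_id]]$atoms
  q <- if (state == "A") a$charge else ifelse(is.na(a$chargeB), a$charge, a$chargeB)
  round(sum(q))
}

#' Build solvent-leg topologies
#'
#' Neutral ligands get two independent absolute-hydration topologies, each
#' decoupling its ligand (B state: dummy vdW types, zero charges). Ligands
#' sharing a non-zero net charge get a charge-preserving dual-ligand box:
#' both ligands present, held half the shortest box edge apart by a single
#' harmonic distance restraint (2.4 kcal mol-1 A-2) between the heavy atoms
#' nearest each ligand's center of mass, with one ligand decoupled while the
#' other couples through LJ-epsilon scaling at `gamma_solvent`. Two short
#' NVT pre-equilibrations are prescribed: 10 ps at k = 0.0024 then 10 ps at
#' the full force constant.
#'
#' @param lig_a,lig_b Lists with `system` and `topology` of the two solvated
#'   ligands (single ligand moleculetype each).
#' @param charged Use the charge-preserving dual-ligand protocol.
#' @param protocol An [alchemical_protocol()].
#' @param box Box edge lengths (Angstrom) for the charged dual-ligand box
#'   (defaults to ligand A's box).
#' @return For neutral ligands: list of class `solvent_topology_set` with
#'   `hydration_A` and `hydration_B` topologies. For charged ligands: the
#'   same class with `topology_BC`, `topology_D`, `system`, `restraint` and
#'   `equilibration` stages.
#' @export
build_solvent_topologies <- function(lig_a, lig_b, charged = FALSE,
                                     protocol = alchemical_protocol(),
                                     box = NULL) {
  name_a <- lig_a$topology$molecules$name[1]
  name_b <- lig_b$topology$molecules$name[1]
  if (!charged) {
    decouple <- function(lig, name) {
      top <- uniquify_ligand_atomtypes(lig$topology, name, "_L")
      top <- add_scaled_atomtypes(top, name, 1) # variants: only dummy is used
      .set_ligand_states(top, name,
        stateA = list(type = "base", charge = "full"),
        stateB = list(type = "dummy", charge = "zero")
      )
    }
    return(structure(
      list(
        charged = FALSE,
        hydration_A = decouple(lig_a, name_a),
        hydration_B = decouple(lig_b, name_b)
      ),
      class = "solvent_topology_set"
    ))
  }
  qa <- .net_charge(lig_a$topology, name_a)
  qb <- .net_charge(lig_b$topology, name_b)
  if (qa != qb) {
    stop(
      "charge-preserving solvent protocol requires equal net charges (",
      qa, " vs ", qb, ")"
    )
  }
  if (is.null(box)) box <- lig_a$system$box
  if (is.null(box)) stop("charged solvent protocol needs a periodic box")
  half <- min(box) / 2

  # combined coordinates: ligand A at the box center, ligand B half a box
  # edge away along x (wrapped inside the box)
  sys_a <- lig_a$system
  sys_b <- lig_b$system
  shift <- function(sys, target) {
    xyz <- coords(sys)
    com <- colMeans(xyz)
    .set_coords(sys, sweep(xyz, 2, target - com, "+"))
  }
  center <- box / 2
  sys_a <- shift(sys_a, center)
  sys_b <- shift(sys_b, c((center[1] + half) %% box[1], center[2], center[3]))
  atoms_b <- sys_b$atoms
  atoms_b$index <- atoms_b$index + nrow(sys_a$atoms)
  combined <- molecular_system(rbind(sys_a$atoms, atoms_b), box = box)

  if (name_b == name_a) name_b_new <- paste0(name_b, "_B") else name_b_new <- name_b
  molb <- lig_b$topology$moleculetypes[[lig_b$topology$molecules$name[1]]]
  molb$name <- name_b_new
  top <- gmx_topology(
    atomtypes = .merge_atomtypes(lig_a$topology$atomtypes, lig_b$topology$atomtypes),
    moleculetypes = c(
      lig_a$topology$moleculetypes[name_a],
      stats::setNames(list(molb), name_b_new)
    ),
    molecules = data.frame(
      name = c(name_a, name_b_new), count = c(1L, 1L),
      stringsAsFactors = FALSE
    ),
    defaults = lig_a$topology$defaults,
    system_name = "charged solvent leg"
  )
  top <- uniquify_ligand_atomtypes(top, name_a, "_LA")
  top <- uniquify_ligand_atomtypes(top, name_b_new, "_LB")
  top <- add_scaled_atomtypes(top, name_a, protocol$gamma_solvent)
  top <- add_scaled_atomtypes(top, name_b_new, protocol$gamma_solvent)
  top <- zero_interligand_vdw(
    top,
    ligand_type_variants(top, name_a),
    ligand_type_variants(top, name_b_new)
  )

  # restraint anchors: heavy atom nearest each ligand's center of mass
  anchor <- function(sys, offset = 0L) {
    heavy <- sys$atoms$element != "H"
    xyz <- coords(sys)
    com <- colMeans(xyz[heavy, , drop = FALSE])
    d <- sqrt(colSums((t(xyz) - com)^2))
    d[!heavy] <- Inf
    which.min(d) + offset
  }
  ai <- anchor(sys_a)
  aj <- anchor(sys_b, nrow(sys_a$atoms))
  k_full <- kcal_to_kj(2.4) * 100 # kJ/mol/nm^2
  dist_restraint <- function(k) {
    list(bonds = list(list(
      atoms = c(ai, aj), funct = 6L,
      params = c(half / 10, k, half / 10, k)
    )))
  }

  bc <- .set_ligand_states(top, name_a,
    stateA = list(type = "base", charge = "full"),
    stateB = list(type = "scaled", charge = "zero")
  )
  bc <- .set_ligand_states(bc, name_b_new,
    stateA = list(type = "dummy", charge = "zero"),
    stateB = list(type = "scaled", charge = "full")
  )
  bc$intermolecular <- dist_restraint(k_full)
  d <- .set_ligand_states(top, name_a,
    stateA = list(type = "scaled", charge = "zero"),
    stateB = list(type = "dummy", charge = "zero")
  )
  d <- .set_ligand_states(d, name_b_new,
    stateA = list(type = "scaled", charge = "full"),
    stateB = list(type = "base", charge = "full")
  )
  d$intermolecular <- dist_restraint(k_full)
  .assert_state_continuity(bc, d, c(name_a, name_b_new))

  structure(
    list(
      charged = TRUE,
      topology_BC = bc, topology_D = d, system = combined,
      restraint = list(
        atoms = c(ai, aj), k = 2.4, equilibrium = half,
        units = "kcal/mol/A^2, Angstrom"
      ),
      equilibration = list(
        list(k = 0.0024, duration_ps = 10, ensemble = "nvt"),
        list(k = 2.4, duration_ps = 10, ensemble = "nvt")
      ),
      ligand_a_name = name_a, ligand_b_name = name_b_new
    ),
    class = "solvent_topology_set"
  )
}
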