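#' Ligand molecule graph
#'
#' Chemical graph of a small molecule: heavy and hydrogen atoms with elements
#' and formal charges, bonds with orders, optional 3-D coordinates, and
#' per-atom ring membership (an atom is in-ring when it lies on any cycle of
#' the bond graph).
#'
#' @param atoms data.frame with columns `index`, `element`, `formal_charge`.
#' @param bonds data.frame with columns `from`, `to`, `order` (1-based atom
#'   indices).
#' @param coords Optional N x 3 matrix of coordinates (Angstrom).
#' @return An object of class `molecule_graph` with an `in_ring` column added
#'   to the atom table.
#' @export
molecule_graph <- function(atoms, bonds, coords = NULL) {
  stopifnot(all(c("index", "element", "formal_charge") %in% names(atoms)))
  if (nrow(bonds) > 0) {
    stopifnot(all(c("from", "to") %in% names(bonds)))
    if (!all(c(bonds$from, bonds$to) %in% atoms$index)) {
      stop("bond endpoints must reference existing atoms")
    }
    if (is.null(bonds$order)) bonds$order <- 1
  } else {
    bonds <- data.frame(from = integer(), to = integer(), order = numeric())
  }
  atoms$in_ring <- .ring_atoms(atoms$index, bonds)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == nrow(atoms), ncol(coords) == 3)
  }
  structure(
    list(atoms = atoms, bonds = bonds, coords = coords),
    class = "molecule_graph"
  )
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(
    "molecule_graph:", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds,",
    sum(x$atoms$in_ring), "ring atoms\n"
  )
  invisible(x)
}

# Ring membership: vertices inside a biconnected component that carries a
# cycle (more edges than a tree would have).
.ring_atoms <- function(indices, bonds) {
  if (nrow(bonds) == 0) {
    return(rep(FALSE, length(indices)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(bonds$from), to = as.character(bonds$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(indices))
  )
  bc <- igraph::biconnected_components(g)
  inring <- rep(FALSE, length(indices))
  names(inring) <- as.character(indices)
  for (comp in bc$components) {
    vs <- names(comp)
    sub <- igraph::induced_subgraph(g, vs)
    if (igraph::ecount(sub) >= length(vs) && length(vs) >= 3) {
      inring[vs] <- TRUE
    }
  }
  unname(inring)
}

#' Heavy-atom graph distance matrix of a molecule
#'
#' @param graph A `molecule_graph`.
#' @return List with `indices` (heavy-atom indices) and `dist` (graph distance
#'   matrix over heavy atoms, hydrogens excluded).
#' @keywords internal
.heavy_graph <- function(graph) {
  heavy <- graph$atoms$index[graph$atoms$element != "H"]
  b <- graph$bonds
  b <- b[b$from %in% heavy & b$to %in% heavy, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(b$from), to = as.character(b$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(heavy))
  )
  list(indices = heavy, graph = g, dist = igraph::distances(g))
}

#' Read a small molecule from SDF or MOL2
#'
#' SDF records are parsed with ChemmineR; MOL2 (TRIPOS) files are parsed
#' directly. Only the first record of a multi-record file is used (with a
#' warning). Ring membership is derived from the bond graph.
#'
#' @param path Path to the file.
#' @param format `"sdf"` or `"mol2"`; inferred from the extension when
#'   omitted.
#' @return A [molecule_graph()].
#' @export
read_small_molecule <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(tolower(format),
    sdf = .read_sdf(path),
    mol2 = .read_mol2(path),
    stop("unknown molecule format: ", format)
  )
}

.read_sdf <- function(path) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  if (length(sdfset) > 1) {
    warning("file contains ", length(sdfset), " records; using the first")
  }
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  charges <- rep(0L, n)
  # formal charges live in M  CHG property lines of the raw record
  all_lines <- readLines(path)
  rec_end <- grep("^\\$\\$\\$\\$", all_lines)
  raw <- all_lines[seq_len(if (length(rec_end)) rec_end[1] else length(all_lines))]
  for (ln in grep("^M  CHG", raw, value = TRUE)) {
    fields <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- fields[1]
    for (j in seq_len(k)) {
      charges[fields[2 * j]] <- fields[2 * j + 1]
    }
  }
  atoms <- data.frame(
    index = seq_len(n),
    element = elements,
    formal_charge = charges,
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    from = as.integer(bb[, 1]),
    to = as.integer(bb[, 2]),
    order = as.numeric(bb[, 3])
  )
  molecule_graph(atoms, bonds, coords = unname(ab[, 1:3, drop = FALSE]))
}

.read_mol2 <- function(path) {
  lines <- readLines(path)
  sec <- grep("^@<TRIPOS>", lines)
  if (!length(sec)) stop("MOL2 parse error: no TRIPOS sections in ", path)
  get_section <- function(name) {
    starts <- grep(paste0("^@<TRIPOS>", name, "\\s*$"), lines)
    if (!length(starts)) {
      return(character())
    }
    if (length(starts) > 1) warning("multiple MOL2 records; using the first")
    s <- starts[1] + 1
    e <- s
    while (e <= length(lines) && !grepl("^@<TRIPOS>", lines[e])) e <- e + 1
    out <- lines[s:(e - 1)]
    out[nzchar(trimws(out))]
  }
  at_lines <- get_section("ATOM")
  bd_lines <- get_section("BOND")
  if (!length(at_lines)) stop("MOL2 parse error: no ATOM section in ", path)
  parse_row <- function(ln) strsplit(trimws(ln), "\\s+")[[1]]
  at <- lapply(at_lines, parse_row)
  n <- length(at)
  coords <- matrix(0, n, 3)
  element <- character(n)
  charge <- numeric(n)
  for (k in seq_len(n)) {
    f <- at[[k]]
    if (length(f) < 6) stop("MOL2 parse error: short ATOM record: ", at_lines[k])
    coords[k, ] <- as.numeric(f[3:5])
    element[k] <- sub("\\..*$", "", f[6])
    charge[k] <- if (length(f) >= 9) round(as.numeric(f[9])) else 0
  }
  bonds <- data.frame(from = integer(), to = integer(), order = numeric())
  if (length(bd_lines)) {
    bd <- lapply(bd_lines, parse_row)
    bonds <- data.frame(
      from = vapply(bd, function(f) as.integer(f[2]), 1L),
      to = vapply(bd, function(f) as.integer(f[3]), 1L),
      order = vapply(bd, function(f) {
        suppressWarnings(o <- as.numeric(f[4]))
        if (is.na(o)) 1.5 else o # ar / am bond types
      }, 1)
    )
  }
  atoms <- data.frame(
    index = seq_len(n),
    element = element,
    formal_charge = charge,
    stringsAsFactors = FALSE
  )
  molecule_graph(atoms, bonds, coords = coords)
}
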