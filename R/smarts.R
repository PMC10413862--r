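# Minimal SMARTS-subset substructure matching.
#
# Supported syntax: organic-subset atom symbols (B, C, N, O, P, S, F, Cl, Br,
# I), lowercase aromatic forms, wildcards * / a / A, bracket atoms limited to
# an element or atomic number (charge/H-count fields are ignored), branches
# with parentheses, ring-closure digits (and %nn), and the bond symbols
# - = # : ~ (bond order is not constrained during matching; connectivity is).
# Aromaticity is approximated by ring membership of the target atom, which is
# what the anchor-selection use case needs. Matching itself is delegated to
# igraph's LAD subgraph-isomorphism solver with per-vertex candidate domains.

.ELEMENTS2 <- c("Cl", "Br")

.parse_smarts <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  atoms <- list() # each: list(element = <chr or NA>, aromatic = <lgl or NA>)
  edges <- list()
  stack <- integer()
  prev <- NA_integer_
  ring_open <- list()
  i <- 1
  n <- length(chars)
  add_atom <- function(element, aromatic) {
    atoms[[length(atoms) + 1]] <<- list(element = element, aromatic = aromatic)
    length(atoms)
  }
  add_edge <- function(a, b) {
    edges[[length(edges) + 1]] <<- c(a, b)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, prev)
      i <- i + 1
    } else if (ch == ")") {
      if (!length(stack)) stop("SMARTS parse error: unbalanced ')' in ", pattern)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1
    } else if (ch %in% c("-", "=", "#", ":", "~", "/", "\\")) {
      i <- i + 1 # bond orders not constrained
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        lab <- paste0(chars[i + 1], chars[i + 2])
        i <- i + 3
      } else {
        lab <- ch
        i <- i + 1
      }
      if (is.null(ring_open[[lab]])) {
        ring_open[[lab]] <- prev
      } else {
        add_edge(ring_open[[lab]], prev)
        ring_open[[lab]] <- NULL
      }
    } else if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) stop("SMARTS parse error: unterminated bracket atom in ", pattern)
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      spec <- .parse_bracket_atom(body, pattern)
      id <- add_atom(spec$element, spec$aromatic)
      if (!is.na(prev)) add_edge(prev, id)
      prev <- id
      i <- j + 1
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1]) else ""
      if (two %in% .ELEMENTS2) {
        id <- add_atom(two, FALSE)
        i <- i + 2
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        id <- add_atom(ch, FALSE)
        i <- i + 1
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        id <- add_atom(toupper(ch), TRUE)
        i <- i + 1
      } else if (ch == "*") {
        id <- add_atom(NA_character_, NA)
        i <- i + 1
      } else if (ch == "a") {
        id <- add_atom(NA_character_, TRUE)
        i <- i + 1
      } else if (ch == "A") {
        id <- add_atom(NA_character_, FALSE)
        i <- i + 1
      } else {
        stop("SMARTS parse error: unsupported token '", ch, "' in ", pattern)
      }
      if (!is.na(prev)) add_edge(prev, id)
      prev <- id
    }
  }
  if (length(ring_open)) {
    open_left <- !vapply(ring_open, is.null, TRUE)
    if (any(open_left)) stop("SMARTS parse error: unclosed ring bond in ", pattern)
  }
  list(atoms = atoms, edges = edges)
}

.parse_bracket_atom <- function(body, pattern) {
  if (grepl("^#[0-9]+", body)) {
    z <- as.integer(sub("^#([0-9]+).*$", "\\1", body))
    sym <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca")
    if (z > length(sym)) stop("SMARTS parse error: unsupported atomic number in ", pattern)
    return(list(element = sym[z], aromatic = NA))
  }
  m <- regmatches(body, regexpr("^[A-Za-z][a-z]?", body))
  if (!length(m)) stop("SMARTS parse error: cannot read bracket atom [", body, "]")
  if (m %in% c(.ELEMENTS2, "Si", "Se")) {
    return(list(element = m, aromatic = FALSE))
  }
  first <- substr(m, 1, 1)
  if (first %in% c("b", "c", "n", "o", "p", "s")) {
    list(element = toupper(first), aromatic = TRUE)
  } else {
    list(element = toupper(first), aromatic = FALSE)
  }
}

#' Match a SMARTS-subset pattern against a molecule graph
#'
#' Substructure search supporting a practical subset of SMARTS (see source
#' for the exact grammar). Aromatic (lowercase) atoms are required to sit in
#' a ring of the target; bond orders are not constrained.
#'
#' @param graph A [molecule_graph()].
#' @param pattern SMARTS pattern string.
#' @return List of integer vectors, one per match, giving the matched target
#'   atom indices in pattern-atom order; empty list when there is no match.
#' @export
match_smarts <- function(graph, pattern) {
  q <- .parse_smarts(pattern)
  nq <- length(q$atoms)
  if (nq == 0) stop("empty SMARTS pattern")
  tg_atoms <- graph$atoms
  tg <- igraph::graph_from_data_frame(
    data.frame(
      from = as.character(graph$bonds$from),
      to = as.character(graph$bonds$to)
    ),
    directed = FALSE,
    vertices = data.frame(name = as.character(tg_atoms$index))
  )
  if (nq == 1) {
    ok <- .atom_domain(q$atoms[[1]], tg_atoms)
    return(lapply(tg_atoms$index[ok], function(i) i))
  }
  em <- do.call(rbind, q$edges)
  pg <- igraph::graph_from_edgelist(em, directed = FALSE)
  domains <- lapply(q$atoms, function(at) {
    which(.atom_domain(at, tg_atoms))
  })
  if (any(vapply(domains, length, 1L) == 0)) {
    return(list())
  }
  iso <- igraph::subgraph_isomorphisms(
    pattern = pg, target = tg, method = "lad",
    induced = FALSE, domains = domains
  )
  lapply(iso, function(m) tg_atoms$index[as.integer(m)])
}

.atom_domain <- function(at, tg_atoms) {
  ok <- rep(TRUE, nrow(tg_atoms))
  if (!is.na(at$element)) ok <- ok & tg_atoms$element == at$element
  if (!is.na(at$aromatic) && isTRUE(at$aromatic)) ok <- ok & tg_atoms$in_ring
  ok
}
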