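#' GROMACS topology container
#'
#' In-memory representation of a GROMACS `.top`/`.itp` force-field file:
#' atom types (Lennard-Jones sigma in nm, epsilon in kJ/mol), pairwise
#' nonbonded overrides, molecule types with per-atom A/B alchemical state
#' columns, an optional intermolecular (restraint) block addressed by global
#' atom indices, and the molecule composition of the system. All fields keep
#' GROMACS native units (nm, kJ/mol).
#'
#' Bonded sections are stored per moleculetype as lists of rows; each row is
#' `list(atoms = <integer vector>, funct = <int>, params = <numeric vector>)`.
#'
#' @param atomtypes data.frame with columns `name`, `at_num`, `mass`,
#'   `charge`, `ptype`, `sigma`, `epsilon`.
#' @param moleculetypes Named list of moleculetype definitions, each
#'   `list(name, nrexcl, atoms = <data.frame>, bonded = <named list>)`. The
#'   atom table has columns `nr`, `type`, `resnr`, `residue`, `atom`, `cgnr`,
#'   `charge`, `mass`, `typeB`, `chargeB`, `massB` (B-state columns `NA` when
#'   absent).
#' @param molecules data.frame with columns `name`, `count` (system
#'   composition, in order).
#' @param nonbond_params data.frame with columns `type1`, `type2`, `sigma`,
#'   `epsilon` (pair overrides), or `NULL`.
#' @param intermolecular Named list of restraint sections (`bonds`, `angles`,
#'   `dihedrals`) of rows in the same shape as bonded rows, with global atom
#'   indices, or `NULL`.
#' @param defaults data.frame with columns `nbfunc`, `comb_rule`, `gen_pairs`,
#'   `fudgeLJ`, `fudgeQQ`, or `NULL`.
#' @param system_name Name emitted under `[ system ]`.
#' @return An object of class `gmx_topology`.
#' @export
gmx_topology <- function(atomtypes, moleculetypes, molecules,
                         nonbond_params = NULL, intermolecular = NULL,
                         defaults = NULL, system_name = "system") {
  top <- structure(
    list(
      defaults = defaults,
      atomtypes = atomtypes,
      nonbond_params = nonbond_params,
      moleculetypes = moleculetypes,
      intermolecular = intermolecular,
      molecules = molecules,
      system_name = system_name
    ),
    class = "gmx_topology"
  )
  validate_gmx_topology(top)
  top
}

#' @rdname gmx_topology
#' @param top A `gmx_topology`.
#' @export
validate_gmx_topology <- function(top) {
  stopifnot(inherits(top, "gmx_topology"))
  at <- top$atomtypes
  if (is.null(at) || nrow(at) < 1) stop("topology has no atom types")
  if (anyDuplicated(at$name)) stop("duplicate atom type names")
  known <- at$name
  if (!is.null(top$nonbond_params) && nrow(top$nonbond_params) > 0) {
    bad <- setdiff(unique(c(top$nonbond_params$type1, top$nonbond_params$type2)), known)
    if (length(bad)) stop("nonbond override references unknown types: ", paste(bad, collapse = ", "))
  }
  if (length(top$moleculetypes) == 0) stop("topology has no moleculetypes")
  for (mt in top$moleculetypes) {
    a <- mt$atoms
    if (nrow(a) < 1) stop("moleculetype ", mt$name, " has no atoms")
    if (!all(a$type %in% known)) {
      stop("moleculetype ", mt$name, " uses unknown A-state types: ",
           paste(setdiff(unique(a$type), known), collapse = ", "))
    }
    tb <- a$typeB[!is.na(a$typeB)]
    if (!all(tb %in% known)) {
      stop("moleculetype ", mt$name, " uses unknown B-state types: ",
           paste(setdiff(unique(tb), known), collapse = ", "))
    }
    if (!all(is.finite(a$charge))) stop("non-finite charges in ", mt$name)
    cb <- a$chargeB[!is.na(a$chargeB)]
    if (length(cb) && !all(is.finite(cb))) stop("non-finite B-state charges in ", mt$name)
  }
  if (is.null(top$molecules) || nrow(top$molecules) < 1) {
    stop("topology has an empty [ molecules ] composition")
  }
  bad <- setdiff(top$molecules$name, names(top$moleculetypes))
  if (length(bad)) stop("[ molecules ] lists undefined moleculetypes: ", paste(bad, collapse = ", "))
  invisible(top)
}

#' @export
print.gmx_topology <- function(x, ...) {
  cat(
    "gmx_topology:", nrow(x$atomtypes), "atom types,",
    length(x$moleculetypes), "moleculetypes,",
    if (is.null(x$nonbond_params)) 0 else nrow(x$nonbond_params), "nonbond overrides\n"
  )
  for (m in x$molecules$name) {
    cat(sprintf(
      "  %s x %d (%d atoms)\n", m,
      x$molecules$count[x$molecules$name == m][1],
      nrow(x$moleculetypes[[m]]$atoms)
    ))
  }
  invisible(x)
}

.atomtypes_frame <- function(name, sigma, epsilon, mass = 0, charge = 0,
                             at_num = 0, ptype = "A") {
  data.frame(
    name = name, at_num = at_num, mass = mass, charge = charge,
    ptype = ptype, sigma = sigma, epsilon = epsilon,
    stringsAsFactors = FALSE
  )
}

# number of leading atom-index fields per bonded directive
.BONDED_NATOMS <- c(
  bonds = 2, pairs = 2, angles = 3, dihedrals = 4,
  dihedral_restraints = 4, distance_restraints = 2,
  position_restraints = 1, exclusions = -1, settles = 1,
  constraints = 2, virtual_sites2 = 3
)

.SECTION_NAMES <- c(
  "defaults", "atomtypes", "nonbond_params", "pairtypes", "bondtypes",
  "angletypes", "dihedraltypes", "moleculetype", "atoms",
  names(.BONDED_NATOMS), "system", "molecules", "intermolecular_interactions"
)

#' Parse a GROMACS topology file
#'
#' Reads the `.top`/`.itp` dialect: `[ atomtypes ]`, `[ nonbond_params ]`,
#' `[ moleculetype ]`/`[ atoms ]` with optional B-state columns, bonded
#' sections, `[ intermolecular_interactions ]` restraint blocks and
#' `[ molecules ]`. `#include` lines are resolved against `include_paths`.
#'
#' @param path Path to the topology file.
#' @param include_paths Directories searched for `#include` files (the file's
#'   own directory is always searched first).
#' @return A [gmx_topology()].
#' @export
parse_gmx_topology <- function(path, include_paths = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- .read_top_lines(path, c(dirname(path), include_paths))
  state <- list(
    defaults = NULL, atomtypes = NULL, nonbond_params = NULL,
    moleculetypes = list(), intermolecular = NULL,
    molecules = NULL, system_name = "system"
  )
  section <- NULL
  current_mol <- NULL
  in_intermol <- FALSE
  finish_mol <- function(state, current_mol) {
    if (!is.null(current_mol)) {
      state$moleculetypes[[current_mol$name]] <- current_mol
    }
    state
  }
  for (i in seq_along(lines$text)) {
    ln <- lines$text[i]
    where <- lines$where[i]
    raw <- sub(";.*$", "", ln)
    raw <- trimws(raw)
    if (!nzchar(raw)) next
    if (grepl("^\\[", raw)) {
      if (!grepl("^\\[\\s*[A-Za-z_0-9-]+\\s*\\]$", raw)) {
        stop("topology parse error at ", where, ": malformed section header '", raw, "'")
      }
      sec <- tolower(gsub("[][ ]", "", raw))
      if (!sec %in% .SECTION_NAMES) {
        stop("topology parse error at ", where, ": unknown directive [ ", sec, " ]")
      }
      if (sec == "moleculetype") {
        state <- finish_mol(state, current_mol)
        current_mol <- list(name = NULL, nrexcl = NA_integer_,
                            atoms = NULL, bonded = list())
        in_intermol <- FALSE
      } else if (sec == "intermolecular_interactions") {
        state <- finish_mol(state, current_mol)
        current_mol <- NULL
        in_intermol <- TRUE
        if (is.null(state$intermolecular)) state$intermolecular <- list()
      } else if (sec %in% c("system", "molecules", "atomtypes", "nonbond_params", "defaults")) {
        if (!(sec %in% names(.BONDED_NATOMS))) {
          state <- finish_mol(state, current_mol)
          current_mol <- NULL
          in_intermol <- FALSE
        }
      }
      section <- sec
      next
    }
    if (is.null(section)) {
      stop("topology parse error at ", where, ": data before any section header")
    }
    f <- strsplit(raw, "\\s+")[[1]]
    if (section == "defaults") {
      state$defaults <- data.frame(
        nbfunc = as.integer(f[1]),
        comb_rule = as.integer(f[2]),
        gen_pairs = if (length(f) >= 3) f[3] else "no",
        fudgeLJ = if (length(f) >= 4) as.numeric(f[4]) else 1,
        fudgeQQ = if (length(f) >= 5) as.numeric(f[5]) else 1,
        stringsAsFactors = FALSE
      )
    } else if (section == "atomtypes") {
      row <- .parse_atomtype_row(f, where)
      state$atomtypes <- rbind(state$atomtypes, row)
    } else if (section == "nonbond_params") {
      if (length(f) < 5) stop("topology parse error at ", where, ": short nonbond_params row")
      state$nonbond_params <- rbind(
        state$nonbond_params,
        data.frame(
          type1 = f[1], type2 = f[2],
          sigma = as.numeric(f[4]), epsilon = as.numeric(f[5]),
          stringsAsFactors = FALSE
        )
      )
    } else if (section == "moleculetype") {
      if (is.null(current_mol)) stop("topology parse error at ", where, ": stray moleculetype row")
      current_mol$name <- f[1]
      current_mol$nrexcl <- as.integer(f[2])
    } else if (section == "atoms") {
      if (is.null(current_mol)) stop("topology parse error at ", where, ": [ atoms ] outside moleculetype")
      current_mol$atoms <- rbind(current_mol$atoms, .parse_atom_row(f, where))
    } else if (section %in% names(.BONDED_NATOMS)) {
      row <- .parse_bonded_row(section, f, where)
      if (in_intermol) {
        state$intermolecular[[section]] <- c(state$intermolecular[[section]], list(row))
      } else {
        if (is.null(current_mol)) {
          stop("topology parse error at ", where, ": [ ", section, " ] outside moleculetype")
        }
        current_mol$bonded[[section]] <- c(current_mol$bonded[[section]], list(row))
      }
    } else if (section == "system") {
      state$system_name <- raw
    } else if (section == "molecules") {
      if (length(f) < 2) stop("topology parse error at ", where, ": short molecules row")
      state$molecules <- rbind(
        state$molecules,
        data.frame(name = f[1], count = as.integer(f[2]), stringsAsFactors = FALSE)
      )
    }
  }
  state <- finish_mol(state, current_mol)
  if (is.null(state$molecules) && length(state$moleculetypes)) {
    # bare .itp: assume one copy of each declared moleculetype
    state$molecules <- data.frame(
      name = names(state$moleculetypes),
      count = 1L, stringsAsFactors = FALSE
    )
  }
  gmx_topology(
    atomtypes = state$atomtypes,
    moleculetypes = state$moleculetypes,
    molecules = state$molecules,
    nonbond_params = state$nonbond_params,
    intermolecular = state$intermolecular,
    defaults = state$defaults,
    system_name = state$system_name
  )
}

.read_top_lines <- function(path, search) {
  out_text <- character()
  out_where <- character()
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*#include", ln)) {
      inc <- sub("^\\s*#include\\s+[\"<]([^\">]+)[\">].*$", "\\1", ln)
      hit <- NULL
      for (d in search) {
        cand <- file.path(d, inc)
        if (file.exists(cand)) {
          hit <- cand
          break
        }
      }
      if (is.null(hit)) stop("cannot resolve #include \"", inc, "\" from ", path, ":", i)
      sub <- .read_top_lines(hit, unique(c(dirname(hit), search)))
      out_text <- c(out_text, sub$text)
      out_where <- c(out_where, sub$where)
    } else if (grepl("^\\s*#", ln)) {
      next # other preprocessor lines (#ifdef blocks not supported) are skipped
    } else {
      out_text <- c(out_text, ln)
      out_where <- c(out_where, paste0(basename(path), ":", i))
    }
  }
  list(text = out_text, where = out_where)
}

.parse_atomtype_row <- function(f, where) {
  p <- which(toupper(f) %in% c("A", "S", "V", "D") & nchar(f) == 1)
  p <- p[p >= 2 & p <= length(f) - 2]
  if (!length(p)) stop("topology parse error at ", where, ": cannot locate ptype in atomtypes row")
  p <- p[length(p)]
  sigma <- suppressWarnings(as.numeric(f[p + 1]))
  epsilon <- suppressWarnings(as.numeric(f[p + 2]))
  if (is.na(sigma) || is.na(epsilon)) {
    stop("topology parse error at ", where, ": bad sigma/epsilon in atomtypes row")
  }
  mass <- if (p >= 3) suppressWarnings(as.numeric(f[p - 2])) else 0
  charge <- if (p >= 2) suppressWarnings(as.numeric(f[p - 1])) else 0
  at_num <- if (p >= 4) suppressWarnings(as.numeric(f[p - 3])) else 0
  .atomtypes_frame(
    name = f[1], sigma = sigma, epsilon = epsilon,
    mass = ifelse(is.na(mass), 0, mass),
    charge = ifelse(is.na(charge), 0, charge),
    at_num = ifelse(is.na(at_num), 0, at_num),
    ptype = toupper(f[p])
  )
}

.parse_atom_row <- function(f, where) {
  if (length(f) < 7) stop("topology parse error at ", where, ": short atoms row")
  num <- function(x) if (is.na(x)) NA_real_ else suppressWarnings(as.numeric(x))
  data.frame(
    nr = as.integer(f[1]), type = f[2], resnr = as.integer(f[3]),
    residue = f[4], atom = f[5], cgnr = as.integer(f[6]),
    charge = as.numeric(f[7]),
    mass = if (length(f) >= 8) num(f[8]) else NA_real_,
    typeB = if (length(f) >= 9) f[9] else NA_character_,
    chargeB = if (length(f) >= 10) num(f[10]) else NA_real_,
    massB = if (length(f) >= 11) num(f[11]) else NA_real_,
    stringsAsFactors = FALSE
  )
}

.parse_bonded_row <- function(section, f, where) {
  na <- .BONDED_NATOMS[[section]]
  if (na < 0) { # exclusions: all fields are atom indices
    return(list(atoms = as.integer(f), funct = NA_integer_, params = numeric()))
  }
  if (length(f) < na + 1) {
    stop("topology parse error at ", where, ": short [ ", section, " ] row")
  }
  atoms <- suppressWarnings(as.integer(f[seq_len(na)]))
  if (any(is.na(atoms))) stop("topology parse error at ", where, ": bad atom index in [ ", section, " ]")
  params <- suppressWarnings(as.numeric(f[-seq_len(na + 1)]))
  if (length(params) && any(is.na(params))) {
    stop("topology parse error at ", where, ": non-numeric parameter in [ ", section, " ]")
  }
  list(atoms = atoms, funct = as.integer(f[na + 1]), params = params)
}

#' Write a GROMACS topology file
#'
#' Emits a complete `.top` in canonical section order. The output re-parses
#' (with [parse_gmx_topology()]) to a topology structurally equal to the
#' input, and is byte-stable given identical input.
#'
#' @param top A [gmx_topology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmx_topology <- function(top, path) {
  validate_gmx_topology(top)
  num <- function(x) formatC(x, format = "g", digits = 10)
  out <- character()
  add <- function(...) out <<- c(out, ...)
  if (!is.null(top$defaults)) {
    d <- top$defaults
    add("[ defaults ]", sprintf(
      "%d %d %s %s %s", d$nbfunc, d$comb_rule, d$gen_pairs,
      num(d$fudgeLJ), num(d$fudgeQQ)
    ), "")
  }
  at <- top$atomtypes
  add("[ atomtypes ]")
  add(sprintf(
    "%-12s %4d %10s %10s %2s %14s %14s",
    at$name, as.integer(at$at_num), num(at$mass), num(at$charge),
    at$ptype, num(at$sigma), num(at$epsilon)
  ), "")
  if (!is.null(top$nonbond_params) && nrow(top$nonbond_params) > 0) {
    nb <- top$nonbond_params
    add("[ nonbond_params ]")
    add(sprintf(
      "%-12s %-12s 1 %14s %14s",
      nb$type1, nb$type2, num(nb$sigma), num(nb$epsilon)
    ), "")
  }
  for (mt in top$moleculetypes) {
    add("[ moleculetype ]", sprintf("%s %d", mt$name, mt$nrexcl), "", "[ atoms ]")
    a <- mt$atoms
    for (k in seq_len(nrow(a))) {
      base <- sprintf(
        "%6d %-12s %6d %-6s %-6s %6d %12s %10s",
        a$nr[k], a$type[k], a$resnr[k], a$residue[k], a$atom[k],
        a$cgnr[k], num(a$charge[k]),
        num(ifelse(is.na(a$mass[k]), 0, a$mass[k]))
      )
      if (!is.na(a$typeB[k])) {
        base <- paste(
          base,
          sprintf(
            "%-12s %12s %10s", a$typeB[k],
            num(ifelse(is.na(a$chargeB[k]), 0, a$chargeB[k])),
            num(ifelse(is.na(a$massB[k]), ifelse(is.na(a$mass[k]), 0, a$mass[k]), a$massB[k]))
          )
        )
      }
      add(base)
    }
    add("")
    for (sec in names(mt$bonded)) {
      add(sprintf("[ %s ]", sec))
      for (row in mt$bonded[[sec]]) add(.format_bonded_row(row, num))
      add("")
    }
  }
  add("[ system ]", top$system_name, "", "[ molecules ]")
  add(sprintf("%-12s %6d", top$molecules$name, top$molecules$count), "")
  if (!is.null(top$intermolecular) && length(top$intermolecular)) {
    add("[ intermolecular_interactions ]")
    for (sec in names(top$intermolecular)) {
      add(sprintf("[ %s ]", sec))
      for (row in top$intermolecular[[sec]]) add(.format_bonded_row(row, num))
      add("")
    }
  }
  writeLines(out, path)
  invisible(path)
}

.format_bonded_row <- function(row, num) {
  if (is.na(row$funct)) {
    return(paste(sprintf("%6d", row$atoms), collapse = " "))
  }
  paste(
    paste(sprintf("%6d", row$atoms), collapse = " "),
    sprintf("%4d", row$funct),
    if (length(row$params)) paste(num(row$params), collapse = " ") else "",
    sep = " "
  )
}
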