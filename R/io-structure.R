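#' Molecular system and trajectory containers
#'
#' A `molecular_system` holds an ordered atom table (1-based indices,
#' Cartesian coordinates in Angstrom) plus an optional rectangular periodic
#' box (edge lengths in Angstrom). A `trajectory` holds a reference system
#' plus a list of per-frame coordinate matrices and the time between frames.
#'
#' @param atoms data.frame with columns `index`, `name`, `element`,
#'   `resid`, `resname`, `chain`, `x`, `y`, `z` (coordinates in Angstrom).
#' @param box Numeric vector of 3 box edge lengths in Angstrom, or `NULL`.
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, box = NULL) {
  req <- c("index", "name", "element", "resid", "resname", "chain", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1) stop("a molecular system needs at least one atom")
  if (anyDuplicated(atoms$index)) stop("atom indices must be unique")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be 3 positive edge lengths (Angstrom)")
    }
  }
  structure(list(atoms = atoms, box = box), class = "molecular_system")
}

#' @rdname molecular_system
#' @param system Reference `molecular_system`.
#' @param frames List of N x 3 coordinate matrices (Angstrom), one per frame.
#' @param frame_interval Time between stored frames in ps.
#' @export
trajectory <- function(system, frames, frame_interval = 4) {
  stopifnot(inherits(system, "molecular_system"), is.list(frames), length(frames) >= 1)
  n <- nrow(system$atoms)
  for (f in frames) {
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3) {
      stop("every frame must be an N x 3 matrix matching the reference atom count")
    }
  }
  structure(
    list(system = system, frames = frames, frame_interval = frame_interval),
    class = "trajectory"
  )
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("molecular_system:", nrow(x$atoms), "atoms")
  if (!is.null(x$box)) cat(sprintf(", box %.2f x %.2f x %.2f A", x$box[1], x$box[2], x$box[3]))
  cat("\n")
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(
    "trajectory:", length(x$frames), "frames x", nrow(x$system$atoms),
    "atoms,", x$frame_interval, "ps/frame\n"
  )
  invisible(x)
}

#' Coordinates of a system as an N x 3 matrix (Angstrom)
#'
#' @param system A `molecular_system`.
#' @return N x 3 numeric matrix.
#' @export
coords <- function(system) {
  as.matrix(system$atoms[, c("x", "y", "z")])
}

.set_coords <- function(system, xyz) {
  system$atoms$x <- xyz[, 1]
  system$atoms$y <- xyz[, 2]
  system$atoms$z <- xyz[, 3]
  system
}

.guess_element <- function(name) {
  el <- sub("^[0-9]*", "", trimws(name))
  two <- c(
    "CL", "BR", "NA", "MG", "ZN", "FE", "CA", "MN", "CU", "SE"
  )
  first2 <- toupper(substr(el, 1, 2))
  ifelse(
    nchar(el) >= 2 & first2 %in% two & !grepl("^C[ABGDEZ]", toupper(el)),
    paste0(substr(first2, 1, 1), tolower(substr(first2, 2, 2))),
    toupper(substr(el, 1, 1))
  )
}

#' Read a structure or trajectory file
#'
#' Reads PDB (via bio3d) or GROMACS GRO files. Multi-model PDB and
#' multi-frame GRO files return a [trajectory()]; single-frame files return a
#' [molecular_system()]. GRO coordinates (nm) are converted to the internal
#' Angstrom convention on input.
#'
#' @param path Path to the file.
#' @param format `"pdb"` or `"gro"`; inferred from the file extension when
#'   omitted.
#' @param frame_interval Frame spacing in ps recorded on multi-frame input.
#' @return A `molecular_system` or `trajectory`.
#' @export
read_structure <- function(path, format = NULL, frame_interval = 4) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  switch(format,
    pdb = .read_pdb(path, frame_interval),
    gro = .read_gro(path, frame_interval),
    stop("unknown structure format: ", format, " (use 'pdb' or 'gro')")
  )
}

.read_pdb <- function(path, frame_interval) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    index = seq_len(nrow(at)),
    name = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "", .guess_element(at$elety), at$elesy),
    resid = at$resno,
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  sys <- molecular_system(atoms)
  nframes <- nrow(pdb$xyz)
  if (is.null(nframes) || nframes <= 1) {
    return(sys)
  }
  frames <- lapply(seq_len(nframes), function(i) {
    matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
  })
  sys <- .set_coords(sys, frames[[1]])
  trajectory(sys, frames, frame_interval)
}

.read_gro <- function(path, frame_interval) {
  lines <- readLines(path)
  frames <- list()
  atoms_df <- NULL
  box <- NULL
  i <- 1
  nline <- length(lines)
  while (i <= nline && nzchar(trimws(paste(lines[i:min(i + 1, nline)], collapse = "")))) {
    if (i + 1 > nline) break
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(natoms)) stop("GRO parse error at line ", i + 1, ": bad atom count")
    if (i + 1 + natoms + 1 > nline) stop("GRO file truncated after line ", i + 1)
    block <- lines[(i + 2):(i + 1 + natoms)]
    xyz <- matrix(0, natoms, 3)
    if (is.null(atoms_df)) {
      resid <- integer(natoms)
      resname <- character(natoms)
      aname <- character(natoms)
    }
    for (k in seq_len(natoms)) {
      ln <- block[k]
      if (nchar(ln) < 44) stop("GRO parse error at line ", i + 1 + k, ": short atom record")
      v <- suppressWarnings(as.numeric(c(
        substr(ln, 21, 28), substr(ln, 29, 36), substr(ln, 37, 44)
      )))
      if (any(is.na(v))) stop("GRO parse error at line ", i + 1 + k, ": bad coordinates")
      xyz[k, ] <- v * 10 # nm -> Angstrom
      if (is.null(atoms_df)) {
        resid[k] <- as.integer(trimws(substr(ln, 1, 5)))
        resname[k] <- trimws(substr(ln, 6, 10))
        aname[k] <- trimws(substr(ln, 11, 15))
      }
    }
    boxline <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2 + natoms]), "\\s+")[[1]]))
    if (length(boxline) < 3 || any(is.na(boxline[1:3]))) {
      stop("GRO parse error at line ", i + 2 + natoms, ": bad box line")
    }
    box <- boxline[1:3] * 10
    if (is.null(atoms_df)) {
      atoms_df <- data.frame(
        index = seq_len(natoms),
        name = aname,
        element = .guess_element(aname),
        resid = resid,
        resname = resname,
        chain = "A",
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE
      )
    }
    frames[[length(frames) + 1]] <- xyz
    i <- i + natoms + 3
    while (i <= nline && !nzchar(trimws(lines[i])) ) i <- i + 1
  }
  if (is.null(atoms_df)) stop("GRO parse error: no frames found")
  sys <- molecular_system(atoms_df, box = box)
  if (length(frames) == 1) {
    return(sys)
  }
  trajectory(sys, frames, frame_interval)
}

#' Write a structure or trajectory file
#'
#' Writes PDB (via bio3d, MODEL records for trajectories) or GRO (nm, one
#' block per frame). Output re-reads to the same coordinates within format
#' precision (1e-3 A for PDB, 1e-2 A for GRO).
#'
#' @param x A `molecular_system` or `trajectory`.
#' @param path Output path.
#' @param format `"pdb"` or `"gro"`; inferred from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  if (inherits(x, "molecular_system")) {
    sys <- x
    frames <- list(coords(x))
  } else if (inherits(x, "trajectory")) {
    sys <- x$system
    frames <- x$frames
  } else {
    stop("x must be a molecular_system or trajectory")
  }
  switch(format,
    pdb = .write_pdb(sys, frames, path),
    gro = .write_gro(sys, frames, path),
    stop("unknown structure format: ", format)
  )
  invisible(path)
}

.write_pdb <- function(sys, frames, path) {
  at <- sys$atoms
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = at$resid,
    resid = at$resname,
    eleno = at$index,
    elety = at$name,
    chain = at$chain,
    elesy = at$element
  )
}

.write_gro <- function(sys, frames, path) {
  at <- sys$atoms
  box <- if (is.null(sys$box)) c(0, 0, 0) else sys$box
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines("generated by septop", con)
    writeLines(sprintf("%5d", nrow(at)), con)
    writeLines(sprintf(
      "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
      at$resid %% 100000, substr(at$resname, 1, 5), substr(at$name, 1, 5),
      at$index %% 100000,
      f[, 1] / 10, f[, 2] / 10, f[, 3] / 10
    ), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10), con)
  }
}
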