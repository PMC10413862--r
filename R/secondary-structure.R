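#' Assign secondary structure from backbone dihedrals
#'
#' Classifies each protein residue as helix, sheet or coil from its
#' phi/psi backbone dihedrals: helix for phi in [-100, -30] and psi in
#' [-80, -5]; sheet for phi in [-180, -90] with psi in [90, 180] or
#' psi <= -170; coil otherwise. Isolated assignments are removed by a
#' run-length filter requiring at least 4 consecutive helix residues and at
#' least 3 consecutive sheet residues. Residues lacking any backbone atom
#' (N, CA, C) are labeled coil with a warning; chain-terminal residues
#' (undefined phi or psi) are coil.
#'
#' This window-based assignment stands in for a hydrogen-bond-pattern
#' algorithm; an externally computed assignment can be supplied wherever a
#' `secondary_structure` result is accepted.
#'
#' @param system A [molecular_system()] containing protein backbone atoms.
#' @return data.frame of class `secondary_structure` with columns `chain`,
#'   `resid`, `label` (one row per residue, file order).
#' @export
assign_secondary_structure <- function(system) {
  stopifnot(inherits(system, "molecular_system"))
  at <- system$atoms
  key <- paste(at$chain, at$resid, sep = "//")
  resk <- unique(key)
  n <- length(resk)
  getpos <- function(k, name) {
    hit <- which(key == k & at$name == name)
    if (!length(hit)) {
      return(NULL)
    }
    as.numeric(at[hit[1], c("x", "y", "z")])
  }
  Npos <- lapply(resk, getpos, "N")
  CApos <- lapply(resk, getpos, "CA")
  Cpos <- lapply(resk, getpos, "C")
  chain <- vapply(strsplit(resk, "//", fixed = TRUE), `[`, "", 1)
  resid <- as.integer(vapply(strsplit(resk, "//", fixed = TRUE), `[`, "", 2))
  incomplete <- vapply(seq_len(n), function(i) {
    is.null(Npos[[i]]) || is.null(CApos[[i]]) || is.null(Cpos[[i]])
  }, TRUE)
  if (any(incomplete)) {
    warning(
      "residues with missing backbone atoms labeled coil: ",
      paste(resid[incomplete], collapse = ", ")
    )
  }
  label <- rep("coil", n)
  consecutive <- function(i, j) {
    i >= 1 && j <= n && chain[i] == chain[j] && resid[j] - resid[i] == 1 &&
      !incomplete[i] && !incomplete[j]
  }
  for (i in seq_len(n)) {
    if (incomplete[i]) next
    if (!consecutive(i - 1, i) || !consecutive(i, i + 1)) next
    phi <- coord_dihedral(Cpos[[i - 1]], Npos[[i]], CApos[[i]], Cpos[[i]])
    psi <- coord_dihedral(Npos[[i]], CApos[[i]], Cpos[[i]], Npos[[i + 1]])
    if (phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5) {
      label[i] <- "helix"
    } else if (phi >= -180 && phi <= -90 && (psi >= 90 || psi <= -170)) {
      label[i] <- "sheet"
    }
  }
  label <- .run_length_filter(label, helix_min = 4, sheet_min = 3)
  out <- data.frame(
    chain = chain, resid = resid, label = label,
    stringsAsFactors = FALSE
  )
  class(out) <- c("secondary_structure", class(out))
  out
}

.run_length_filter <- function(label, helix_min, sheet_min) {
  r <- rle(label)
  drop <- (r$values == "helix" & r$lengths < helix_min) |
    (r$values == "sheet" & r$lengths < sheet_min)
  r$values[drop] <- "coil"
  inverse.rle(r)
}

#' Secondary-structure elements (runs) of an assignment
#'
#' @param ss A `secondary_structure` data.frame.
#' @return data.frame with one row per helix/sheet element: `chain`, `label`,
#'   `start`, `end` (residue ids).
#' @export
secondary_structure_elements <- function(ss) {
  r <- rle(paste(ss$chain, ss$label, sep = "//"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- grepl("//(helix|sheet)$", r$values)
  data.frame(
    chain = ss$chain[starts[keep]],
    label = ss$label[starts[keep]],
    start = ss$resid[starts[keep]],
    end = ss$resid[ends[keep]],
    stringsAsFactors = FALSE
  )
}
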