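#' Reduced-potential container for multistate estimation
#'
#' `u` is a K x N matrix: `u[k, n]` is the reduced (dimensionless) potential
#' of sample n evaluated at state k. `n_k` gives how many samples came from
#' each state; samples are stored grouped by source state, in state order.
#' Because every multistate weight is invariant under adding a per-sample
#' constant, energies measured relative to the sampled state are valid
#' input.
#'
#' @param u K x N numeric matrix of reduced potentials.
#' @param n_k Integer vector of per-state sample counts (sums to N).
#' @param labels Optional state labels.
#' @return Object of class `reduced_potentials`.
#' @export
reduced_potentials <- function(u, n_k, labels = NULL) {
  u <- as.matrix(u)
  n_k <- as.integer(n_k)
  if (length(n_k) != nrow(u)) stop("n_k must have one entry per state (row of u)")
  if (sum(n_k) != ncol(u)) stop("sum(n_k) must equal the number of samples (columns of u)")
  if (!all(is.finite(u))) stop("reduced potentials must be finite")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(u)))
  structure(
    list(u = u, n_k = n_k, labels = labels),
    class = "reduced_potentials"
  )
}

#' @export
print.reduced_potentials <- function(x, ...) {
  cat(
    "reduced_potentials:", nrow(x$u), "states,", ncol(x$u), "samples (n_k:",
    paste(x$n_k, collapse = ", "), ")\n"
  )
  invisible(x)
}

# index columns of samples drawn from state k
.state_cols <- function(rp, k) {
  ends <- cumsum(rp$n_k)
  starts <- ends - rp$n_k + 1
  seq.int(starts[k], ends[k])
}

.R_KJ <- 8.31446261815324e-3 # kJ mol-1 K-1

#' Write per-window energy differences as XVG
#'
#' Emits one GROMACS-style `.xvg` per sampled state: a time column followed
#' by K columns holding the potential-energy difference (kJ/mol) between
#' each evaluated state and the sampled state, with legend headers naming
#' the states. Used to exercise the parser and to serialize synthetic data.
#'
#' @param rp A [reduced_potentials()].
#' @param dir Output directory.
#' @param temperature Temperature (K) used to de-reduce energies.
#' @param dt Time between samples (ps).
#' @return Character vector of file paths, one per state.
#' @export
write_dhdl_xvg <- function(rp, dir, temperature = 298.15, dt = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- nrow(rp$u)
  beta <- 1 / (.R_KJ * temperature)
  paths <- character(K)
  for (k in seq_len(K)) {
    cols <- .state_cols(rp, k)
    de <- (rp$u[, cols, drop = FALSE] -
      matrix(rp$u[k, cols], K, length(cols), byrow = TRUE)) / beta
    path <- file.path(dir, sprintf("dhdl_state_%02d.xvg", k - 1))
    con <- file(path, "w")
    writeLines(c(
      sprintf("# septop cross-evaluated energies, sampled state %d of %d", k - 1, K),
      sprintf("@    title \"dH/dl and energy differences, state %d\"", k - 1),
      "@    xaxis  label \"Time (ps)\"",
      "@    yaxis  label \"Energy (kJ/mol)\"",
      sprintf("@ s%d legend \"\\xD\\f{}H to state %d\"", seq_len(K) - 1, seq_len(K) - 1)
    ), con)
    t <- (seq_along(cols) - 1) * dt
    for (i in seq_along(cols)) {
      writeLines(paste(
        formatC(c(t[i], de[, i]), format = "g", digits = 10),
        collapse = " "
      ), con)
    }
    close(con)
    paths[k] <- path
  }
  paths
}

#' Parse cross-evaluated energy files into reduced potentials
#'
#' Reads one XVG file per sampled state (in state order). Each file must
#' carry a time column plus one energy-difference column per state of the
#' leg (kJ/mol); energies are reduced with beta = 1/(R T).
#'
#' @param files Character vector of XVG paths, one per state, state order.
#' @param temperature Temperature (K).
#' @return A [reduced_potentials()].
#' @export
parse_dhdl <- function(files, temperature = 298.15) {
  K <- length(files)
  beta <- 1 / (.R_KJ * temperature)
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    lines <- readLines(files[k])
    data_lines <- lines[!grepl("^[#@]", lines) & nzchar(trimws(lines))]
    if (!length(data_lines)) stop("no data rows in ", files[k])
    rows <- lapply(seq_along(data_lines), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(data_lines[i]), "\\s+")[[1]]))
      if (any(is.na(v))) {
        stop("parse error in ", files[k], " at data line ", i, ": non-numeric field")
      }
      v
    })
    ncols <- unique(vapply(rows, length, 1L))
    if (length(ncols) != 1) {
      bad <- which(vapply(rows, length, 1L) != ncols[1])[1]
      stop("parse error in ", files[k], " at data line ", bad, ": ragged row")
    }
    if (ncols != K + 1) {
      stop(
        "file ", files[k], " has ", ncols - 1, " state columns; expected ", K,
        " (missing state column?)"
      )
    }
    m <- do.call(rbind, rows)
    # order by the time column, then drop it
    m <- m[order(m[, 1]), -1, drop = FALSE]
    blocks[[k]] <- t(m) * beta
  }
  u <- do.call(cbind, blocks)
  reduced_potentials(u, n_k = vapply(blocks, ncol, 1L))
}

#' Discard initial equilibration samples
#'
#' Removes the first `burn / total` fraction of each state's samples
#' (default: the first 1 ns of a 10 ns production window).
#'
#' @param rp A [reduced_potentials()].
#' @param burn Discarded initial time per window (same units as `total`).
#' @param total Total production time per window.
#' @return A [reduced_potentials()] with the remaining samples.
#' @export
discard_equilibration <- function(rp, burn = 1, total = 10) {
  if (burn < 0) stop("burn must be non-negative")
  if (burn >= total) stop("burn must be smaller than the total production time")
  frac <- burn / total
  keep_cols <- integer()
  new_nk <- integer(length(rp$n_k))
  for (k in seq_along(rp$n_k)) {
    cols <- .state_cols(rp, k)
    ndrop <- floor(frac * length(cols) + 1e-9)
    keep <- cols[seq_along(cols) > ndrop]
    keep_cols <- c(keep_cols, keep)
    new_nk[k] <- length(keep)
  }
  reduced_potentials(rp$u[, keep_cols, drop = FALSE], new_nk, rp$labels)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# column-wise logsumexp of a matrix plus per-row offsets:
# returns log( colSums( exp(a + offset) ) )
.col_logsumexp <- function(a, offset) {
  x <- a + offset
  m <- apply(x, 2, max)
  m + log(colSums(exp(sweep(x, 2, m))))
}

#' Solve the multistate (MBAR) self-consistency equations
#'
#' Estimates per-state reduced free energies f_k (f_1 = 0) satisfying
#' `f_k = -ln sum_n exp(-u_kn) / sum_l N_l exp(f_l - u_ln)`, by quasi-Newton
#' minimization of the convex multistate likelihood followed by
#' self-consistent polishing to the requested relative tolerance.
#' Uncertainties come from the asymptotic covariance of the estimator.
#'
#' @param rp A [reduced_potentials()]; every state must either carry samples
#'   or be listed in `evaluation_only`.
#' @param tol Relative self-consistency tolerance.
#' @param evaluation_only Optional integer vector of states known to carry
#'   no samples (cross-evaluation only).
#' @param max_iter Iteration cap for the polishing stage.
#' @return List of class `mbar_result`: `f` (reduced free energies, f_1 = 0),
#'   `df` (uncertainty of f_k - f_1), `theta` (covariance of f), `w` (N x K
#'   weight matrix), `n_k`, and `flagged` (TRUE when some state shares no
#'   weight with the rest).
#' @export
mbar_solve <- function(rp, tol = 1e-8, evaluation_only = integer(), max_iter = 10000) {
  u <- rp$u
  n_k <- rp$n_k
  K <- nrow(u)
  if (any(n_k == 0 & !(seq_len(K) %in% evaluation_only))) {
    stop("state(s) without samples: ", paste(which(n_k == 0), collapse = ", "),
      "; pass evaluation_only to allow them"
    )
  }
  sampled <- which(n_k > 0)
  logN <- log(n_k[sampled])
  us <- u[sampled, , drop = FALSE]
  # objective over sampled-state free energies (f[1] pinned to 0)
  obj <- function(fs) {
    logD <- .col_logsumexp(-us, fs + logN)
    sum(logD) - sum(n_k[sampled] * fs)
  }
  grad <- function(fs) {
    logD <- .col_logsumexp(-us, fs + logN)
    w <- exp(sweep(-us, 2, logD)) # K_s x N, rows: exp(-u - logD)
    n_k[sampled] * exp(fs) * rowSums(w) - n_k[sampled]
  }
  fs <- numeric(length(sampled))
  if (length(sampled) > 1) {
    fit <- stats::optim(
      fs[-1],
      fn = function(x) obj(c(0, x)),
      gr = function(x) grad(c(0, x))[-1],
      method = "BFGS",
      control = list(maxit = 1000, reltol = 1e-14)
    )
    fs <- c(0, fit$par)
  }
  # self-consistent polish
  for (it in seq_len(max_iter)) {
    logD <- .col_logsumexp(-us, fs + logN)
    fnew <- -vapply(seq_along(sampled), function(i) {
      .logsumexp(-us[i, ] - logD)
    }, 1.0)
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - fs) / pmax(abs(fnew), 1))
    fs <- fnew
    if (delta < tol * 1e-2) break
  }
  logD <- .col_logsumexp(-us, fs + logN)
  # free energies of all states (incl. evaluation-only) from the mixture
  f <- -vapply(seq_len(K), function(k) .logsumexp(-u[k, ] - logD), 1.0)
  f <- f - f[1]
  # weight matrix over all states
  w <- exp(sweep(t(u) * -1, 1, logD) + matrix(f, ncol(u), K, byrow = TRUE))
  # covariance via thin SVD of W
  sv <- svd(w)
  S <- sv$d
  V <- sv$v
  M <- diag(S, length(S)) %*% t(V) %*% (V * n_k) %*% diag(S, length(S))
  inner <- MASS::ginv(diag(length(S)) - M)
  theta <- V %*% diag(S, length(S)) %*% inner %*% diag(S, length(S)) %*% t(V)
  df <- sqrt(pmax(0, diag(theta) + theta[1, 1] - 2 * theta[1, ]))
  colw <- colSums(w[, , drop = FALSE])
  ov <- overlap_matrix_w(w, n_k)
  flagged <- any(vapply(seq_len(K), function(k) {
    n_k[k] > 0 && (sum(ov[k, -k]) < 1e-10)
  }, TRUE))
  if (flagged) warning("poorly overlapping states detected; estimates are unreliable")
  structure(
    list(
      f = f, df = df, theta = theta, w = w, n_k = n_k,
      overlap = ov, flagged = flagged
    ),
    class = "mbar_result"
  )
}

# overlap matrix from an N x K weight matrix: O_ij = sum_n W_ni W_nj N_j
overlap_matrix_w <- function(w, n_k) {
  unname(crossprod(w) %*% diag(n_k, length(n_k)))
}

#' Phase-space overlap matrix
#'
#' Entry (i, j) is the averaged multistate weight of state j over the
#' samples' mixture distribution restricted to state i's contribution; rows
#' sum to 1. Near-identity rows signal disjoint neighboring states.
#'
#' @param rp A [reduced_potentials()] or an `mbar_result`.
#' @return K x K matrix with unit row sums.
#' @export
overlap_matrix <- function(rp) {
  if (inherits(rp, "mbar_result")) {
    return(rp$overlap)
  }
  mbar_solve(rp)$overlap
}

#' Estimate one leg's free energy
#'
#' Runs [mbar_solve()] and reports the end-to-end free energy difference of
#' the leg in kcal/mol with its statistical uncertainty and overlap matrix.
#'
#' @param rp A [reduced_potentials()].
#' @param leg Leg identifier string.
#' @param temperature Temperature (K).
#' @return List of class `leg_result`: `leg`, `dg` (kcal/mol), `uncertainty`
#'   (kcal/mol), `overlap`, `mbar`.
#' @export
estimate_leg <- function(rp, leg = "leg", temperature = 298.15) {
  m <- mbar_solve(rp)
  K <- length(m$f)
  rt <- rt_kcal(temperature)
  structure(
    list(
      leg = leg,
      dg = (m$f[K] - m$f[1]) * rt,
      uncertainty = m$df[K] * rt,
      overlap = m$overlap,
      mbar = m
    ),
    class = "leg_result"
  )
}

#' @export
print.leg_result <- function(x, ...) {
  cat(sprintf(
    "leg_result '%s': dG = %.3f +/- %.3f kcal/mol\n",
    x$leg, x$dg, x$uncertainty
  ))
  invisible(x)
}

.leg_value <- function(x) if (inherits(x, "leg_result")) x$dg else as.numeric(x)
.leg_err <- function(x) if (inherits(x, "leg_result")) x$uncertainty else 0

#' Assemble an edge estimate from its legs
#'
#' Combines the binding-site legs, the analytic restraint-release
#' corrections and the solvent contribution into the relative binding free
#' energy of the edge:
#'
#' `ddG_bind(A->B) = [dG_BC + dG_D + dG_release(A) - dG_release(B)]
#'   - dG_solvent(A->B)`
#'
#' where `dG_solvent(A->B)` is `hydration_B - hydration_A` for neutral
#' ligands or the dual-ligand charged solvent leg value. The inter-ligand
#' distance restraint of the charged protocol contributes zero by
#' construction (identical in both end states). Uncertainties combine in
#' quadrature.
#'
#' @param legs Named list with `BC` and `D` ([estimate_leg()] results or
#'   numbers, kcal/mol) and either `hydration_A` and `hydration_B` or
#'   `charged_solvent`.
#' @param restraint_a,restraint_b [boresch_restraint()] objects, or numbers
#'   giving precomputed release corrections (kcal/mol).
#' @param temperature Temperature (K).
#' @param from,to Ligand identifiers.
#' @return List of class `edge_estimate` with `ddg`, `uncertainty`,
#'   `breakdown` (named numeric summing to `ddg`).
#' @export
assemble_edge <- function(legs, restraint_a, restraint_b,
                          temperature = 298.15, from = "A", to = "B") {
  need <- c("BC", "D")
  missing_legs <- setdiff(need, names(legs))
  has_hyd <- all(c("hydration_A", "hydration_B") %in% names(legs))
  has_charged <- "charged_solvent" %in% names(legs)
  if (!has_hyd && !has_charged) missing_legs <- c(missing_legs, "solvent leg(s)")
  if (length(missing_legs)) {
    stop("missing legs: ", paste(missing_legs, collapse = ", "))
  }
  rel <- function(r) {
    if (inherits(r, "boresch_restraint")) analytic_release_correction(r, temperature) else as.numeric(r)
  }
  dg_solvent <- if (has_charged) {
    .leg_value(legs$charged_solvent)
  } else {
    .leg_value(legs$hydration_B) - .leg_value(legs$hydration_A)
  }
  err_solvent2 <- if (has_charged) {
    .leg_err(legs$charged_solvent)^2
  } else {
    .leg_err(legs$hydration_A)^2 + .leg_err(legs$hydration_B)^2
  }
  breakdown <- c(
    dG_BC = .leg_value(legs$BC),
    dG_D = .leg_value(legs$D),
    dG_release_A = rel(restraint_a),
    dG_release_B = -rel(restraint_b),
    dG_solvent = -dg_solvent
  )
  ddg <- sum(breakdown)
  unc <- sqrt(.leg_err(legs$BC)^2 + .leg_err(legs$D)^2 + err_solvent2)
  structure(
    list(
      from = from, to = to,
      ddg = ddg, uncertainty = unc, breakdown = breakdown,
      temperature = temperature
    ),
    class = "edge_estimate"
  )
}

#' @export
print.edge_estimate <- function(x, ...) {
  cat(sprintf(
    "edge_estimate %s -> %s: ddG = %.3f +/- %.3f kcal/mol\n",
    x$from, x$to, x$ddg, x$uncertainty
  ))
  for (nm in names(x$breakdown)) {
    cat(sprintf("  %-14s %8.3f\n", nm, x$breakdown[[nm]]))
  }
  invisible(x)
}
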