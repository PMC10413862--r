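#' Lambda-window schedule for one leg
#'
#' Ordered alchemical windows with per-window component values. The
#' `windows` table carries the physical coupling components (`restraint_A`,
#' `restraint_B`, `vdw`, `coul`, each in [0, 1] and monotone along the
#' schedule); `gromacs` carries the three per-window vectors emitted into
#' run-parameter files (`restraint`, `vdw`, `coul`: the normalized A-to-B
#' progress of each interpolated component of that leg's topology).
#'
#' @param leg Leg identifier (e.g. `"BC"`, `"D"`, `"hydration"`).
#' @param windows data.frame as described above.
#' @param gromacs data.frame with columns `restraint`, `vdw`, `coul`.
#' @return Object of class `lambda_schedule`.
#' @export
lambda_schedule <- function(leg, windows, gromacs) {
  stopifnot(nrow(windows) >= 2, nrow(gromacs) == nrow(windows))
  for (col in c("restraint_A", "restraint_B", "vdw", "coul")) {
    v <- windows[[col]]
    if (is.null(v) || any(v < -1e-12 | v > 1 + 1e-12)) {
      stop("schedule component ", col, " must lie in [0, 1]")
    }
    if (any(diff(v) < -1e-12) && any(diff(v) > 1e-12)) {
      stop("schedule component ", col, " must be monotone")
    }
  }
  structure(
    list(leg = leg, windows = windows, gromacs = gromacs),
    class = "lambda_schedule"
  )
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat("lambda_schedule '", x$leg, "': ", nrow(x$windows), " windows\n", sep = "")
  print(round(x$windows, 3))
  invisible(x)
}

n_windows <- function(schedule) nrow(schedule$windows)

.even <- function(n) seq(0, 1, length.out = n)

#' Binding-site lambda schedule
#'
#' Default protocol: the combined B+C leg uses 12 windows in which the vdW
#' and restraint components complete their change over the first 8 windows
#' and the Coulomb component changes over the last 5 (window 8 shared:
#' vdW/restraint finished, Coulomb still at its start value); leg D uses 8
#' windows. 20 windows in total. Spacing is even per component unless custom
#' vectors are supplied through `config`.
#'
#' @param config List with optional elements `n_bc_vdw` (default 8),
#'   `n_bc_coul` (default 5), `n_d` (default 8), and optional custom vectors
#'   `bc_vdw`, `bc_coul`, `d_vdw` overriding the even spacing.
#' @return List of class `complex_schedule` with elements `BC` and `D`
#'   ([lambda_schedule()] each) and `total_windows`.
#' @export
build_complex_schedule <- function(config = list()) {
  n_vdw <- config$n_bc_vdw %||% 8
  n_coul <- config$n_bc_coul %||% 5
  n_d <- config$n_d %||% 8
  if (n_vdw < 2 || n_coul < 2 || n_d < 2) {
    stop("each leg needs at least 2 windows")
  }
  n_bc <- n_vdw + n_coul - 1 # shared window
  vdw_bc <- config$bc_vdw %||% c(.even(n_vdw), rep(1, n_coul - 1))
  coul_bc <- config$bc_coul %||% c(rep(0, n_vdw - 1), .even(n_coul))
  bc <- lambda_schedule(
    "BC",
    data.frame(
      window = seq_len(n_bc),
      restraint_A = vdw_bc, # ligand A orientational restraint turns on with vdW
      restraint_B = 1, # ligand B restrained throughout
      vdw = vdw_bc,
      coul = coul_bc
    ),
    data.frame(restraint = vdw_bc, vdw = vdw_bc, coul = coul_bc)
  )
  vdw_d <- config$d_vdw %||% .even(n_d)
  d <- lambda_schedule(
    "D",
    data.frame(
      window = seq_len(n_d),
      restraint_A = 1,
      restraint_B = 1 - vdw_d, # ligand B restraint released across leg D
      vdw = vdw_d,
      coul = 1
    ),
    data.frame(restraint = vdw_d, vdw = vdw_d, coul = vdw_d)
  )
  structure(
    list(BC = bc, D = d, total_windows = n_bc + n_d),
    class = "complex_schedule"
  )
}

#' Absolute-hydration lambda schedule
#'
#' 14 windows decoupling a neutral ligand in water: the Coulomb component
#' completes its change (charges off) over the first windows before any vdW
#' change begins.
#'
#' @param config List with optional `n_coul` (default 5) and `n_vdw`
#'   (default 10; one window shared).
#' @return A [lambda_schedule()] with leg id `"hydration"`.
#' @export
build_hydration_schedule <- function(config = list()) {
  n_coul <- config$n_coul %||% 5
  n_vdw <- config$n_vdw %||% 10
  if (n_coul < 2 || n_vdw < 2) stop("each phase needs at least 2 windows")
  n <- n_coul + n_vdw - 1
  coul <- c(.even(n_coul), rep(1, n_vdw - 1))
  vdw <- c(rep(0, n_coul - 1), .even(n_vdw))
  lambda_schedule(
    "hydration",
    data.frame(
      window = seq_len(n),
      restraint_A = 0, restraint_B = 0,
      vdw = vdw, coul = coul
    ),
    data.frame(restraint = rep(0, n), vdw = vdw, coul = coul)
  )
}

#' Charge-preserving dual-ligand solvent schedule
#'
#' 28 windows (14 per ligand) interleaving the decoupling of ligand A with
#' the coupling of ligand B through the gamma-scaled intermediate, mirroring
#' the binding-site ordering; the inter-ligand distance restraint stays at
#' full strength in every window. Window 1 has ligand A fully coupled and
#' ligand B fully decoupled; window 28 the reverse.
#'
#' @param config List with optional `n_stage1_vdw` (default 9),
#'   `n_stage1_coul` (default 6), `n_stage2` (default 14).
#' @return A [lambda_schedule()] with leg id `"charged-solvent"` and a
#'   `stage` column marking the two 14-window stages.
#' @export
build_charged_solvent_schedule <- function(config = list()) {
  n1v <- config$n_stage1_vdw %||% 9
  n1c <- config$n_stage1_coul %||% 6
  n2 <- config$n_stage2 %||% 14
  if (n1v < 2 || n1c < 2 || n2 < 2) stop("each stage needs at least 2 windows")
  n1 <- n1v + n1c - 1
  v1 <- c(.even(n1v), rep(1, n1c - 1))
  c1 <- c(rep(0, n1v - 1), .even(n1c))
  v2 <- .even(n2)
  n <- n1 + n2
  sched <- lambda_schedule(
    "charged-solvent",
    data.frame(
      window = seq_len(n),
      restraint_A = 1, restraint_B = 1,
      vdw = c(v1 / 2, 0.5 + v2 / 2),
      coul = c(c1, rep(1, n2))
    ),
    data.frame(
      restraint = rep(0, n), # restraint not interpolated: full k in A and B states
      vdw = c(v1, v2),
      coul = c(c1, v2)
    )
  )
  sched$windows$stage <- rep(c(1L, 2L), c(n1, n2))
  sched
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit GROMACS run parameters (MDP) for one window and phase
#'
#' Phases follow the SepTop run plan: steepest-descent minimization for
#' 5000 steps; 10 ps NVT equilibration at 298.15 K; 10 ns NPT production at
#' 1 bar with the stochastic-dynamics integrator at a 2 fs timestep and
#' Beutler soft-core on the vdW component. The free-energy block carries the
#' full per-component lambda vectors of the leg (so every window
#' cross-evaluates all states for MBAR) with `init-lambda-state` equal to
#' the supplied 0-based window index; replica-exchange metadata records a
#' 200-step attempt interval.
#'
#' @param schedule A [lambda_schedule()].
#' @param window 0-based lambda-state index within the schedule.
#' @param phase One of `"minimize"`, `"nvt-equil"`, `"production"`.
#' @param temperature Temperature (K).
#' @param production_ns Production length per window (ns).
#' @param sc_alpha,sc_power Beutler soft-core parameters.
#' @param nstdhdl dH/dlambda output cadence (steps).
#' @return Character scalar: the MDP file text.
#' @export
emit_run_parameters <- function(schedule, window, phase,
                                temperature = 298.15, production_ns = 10,
                                sc_alpha = 0.5, sc_power = 1,
                                nstdhdl = 100) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  n <- n_windows(schedule)
  if (window < 0 || window >= n) stop("window index out of range [0, ", n - 1, "]")
  vec <- function(x) paste(formatC(x, format = "g", digits = 6), collapse = " ")
  fep <- c(
    "free-energy              = yes",
    sprintf("init-lambda-state        = %d", window),
    sprintf("restraint-lambdas        = %s", vec(schedule$gromacs$restraint)),
    sprintf("vdw-lambdas              = %s", vec(schedule$gromacs$vdw)),
    sprintf("coul-lambdas             = %s", vec(schedule$gromacs$coul)),
    "calc-lambda-neighbors    = -1",
    sprintf("sc-alpha                 = %s", format(sc_alpha)),
    sprintf("sc-power                 = %d", sc_power),
    "sc-coul                  = no",
    sprintf("nstdhdl                  = %d", nstdhdl),
    "dhdl-print-energy        = total",
    "separate-dhdl-file       = yes"
  )
  common_tail <- c(
    "constraints              = h-bonds",
    "cutoff-scheme            = Verlet",
    sprintf("; replica-exchange attempt interval: %d steps (set on the mdrun command line)", 200L)
  )
  header <- sprintf("; septop leg %s, window %d, phase %s", schedule$leg, window, phase)
  body <- switch(phase,
    minimize = c(
      "integrator               = steep",
      "nsteps                   = 5000",
      "emtol                    = 100"
    ),
    `nvt-equil` = c(
      "integrator               = sd",
      "dt                       = 0.002",
      sprintf("nsteps                   = %d", as.integer(10 / 0.002)), # 10 ps
      sprintf("ref-t                    = %s", format(temperature)),
      "tau-t                    = 1.0",
      "tc-grps                  = System",
      "pcoupl                   = no",
      "gen-vel                  = yes",
      sprintf("gen-temp                 = %s", format(temperature))
    ),
    production = c(
      "integrator               = sd",
      "dt                       = 0.002",
      sprintf("nsteps                   = %d", as.integer(production_ns * 1000 / 0.002)),
      sprintf("ref-t                    = %s", format(temperature)),
      "tau-t                    = 1.0",
      "tc-grps                  = System",
      "pcoupl                   = Parrinello-Rahman",
      "ref-p                    = 1.0",
      "tau-p                    = 5.0",
      "compressibility          = 4.5e-5"
    ),
    stop("unknown phase: ", phase)
  )
  paste(c(header, body, fep, common_tail), collapse = "\n")
}

#' Write the full run plan of a leg
#'
#' One directory per window with minimize / nvt-equil / production MDP files
#' (production preceded by the other two phases) plus a YAML manifest
#' mapping windows to files, state indices and the replica-exchange attempt
#' interval.
#'
#' @param schedule A [lambda_schedule()].
#' @param out_dir Output directory (created).
#' @param topology_file Topology filename recorded in the manifest.
#' @param ... Passed to [emit_run_parameters()].
#' @return Path of the manifest, invisibly.
#' @export
write_run_plan <- function(schedule, out_dir, topology_file = "topol.top", ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_windows(schedule)
  manifest <- list(
    leg = schedule$leg,
    replica_exchange_interval_steps = 200L,
    topology = topology_file,
    windows = list()
  )
  for (w in seq_len(n) - 1L) {
    wdir <- file.path(out_dir, sprintf("window_%02d", w))
    dir.create(wdir, showWarnings = FALSE)
    files <- c()
    for (phase in c("minimize", "nvt-equil", "production")) {
      f <- file.path(wdir, paste0(sub("-.*", "", phase), ".mdp"))
      writeLines(emit_run_parameters(schedule, w, phase, ...), f)
      files[phase] <- basename(f)
    }
    manifest$windows[[w + 1]] <- list(
      state = w,
      directory = basename(wdir),
      mdp = as.list(files)
    )
  }
  mpath <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}
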