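#' Debye-Hueckel pair energy
#'
#' Screened Coulomb interaction in reduced units:
#' `U = B * qi * qj * exp(-r / lambda_D) / r`, with the Debye length set
#' by the force field's ionic strength and the prefactor `B` by its
#' dielectric constant and reduced-temperature mapping.
#'
#' @param qi,qj Bead charges in units of e.
#' @param r Separation, Angstrom (> 0).
#' @param ff A [force_field()].
#' @return Energy in reduced units.
#' @export
debye_huckel_energy <- function(qi, qj, r, ff = force_field()) {
  if (any(r <= 0)) stop("r must be positive")
  ff$B_dh * qi * qj * exp(-r / ff$lambda_d) / r
}

#' Forces and energy breakdown for a system configuration
#'
#' Evaluates the total coarse-grained potential and its exact negative
#' gradient at the given (or current) coordinates.
#'
#' @param system A [cg_system()].
#' @param positions Optional N x 3 coordinate matrix; defaults to the
#'   system's stored positions.
#' @return List: `forces` (N x 3), `energies` (named per-term vector),
#'   `potential` (their sum).
#' @export
compute_forces <- function(system, positions = NULL) {
  stopifnot(inherits(system, "cg_system"))
  x <- if (is.null(positions)) system$positions else as.matrix(positions)
  if (any(!is.finite(x))) stop("non-finite coordinates")
  .cg_forces(x, system$topo)
}

#' Single Langevin (BAOAB) integration step
#'
#' One step of the thermostatted integrator; with `friction = 0` this is
#' plain velocity Verlet. Reproducible under [set.seed()].
#'
#' @param system A [cg_system()].
#' @param state List with `positions` and `velocities` (N x 3 each).
#' @param params A [sim_params()].
#' @return Updated state list.
#' @export
langevin_step <- function(system, state, params = sim_params()) {
  res <- .cg_run(as.matrix(state$positions), as.matrix(state$velocities),
                 system$topo, params$dt, params$friction, params$t_reduced,
                 1L, 1L, 10)
  list(positions = res$x, velocities = res$v)
}

#' Maxwell-Boltzmann velocities
#'
#' @param n Number of beads.
#' @param t_reduced Reduced temperature (kB = 1, mass = 1).
#' @return N x 3 velocity matrix.
#' @export
maxwell_velocities <- function(n, t_reduced) {
  matrix(stats::rnorm(3 * n, sd = sqrt(t_reduced)), n, 3)
}

new_trajectory <- function(frames, energies, system, replica_id, seed,
                           save_interval, dt) {
  structure(list(frames = frames, energies = as.data.frame(energies),
                 system = system, replica_id = replica_id, seed = seed,
                 save_interval = save_interval, dt = dt),
            class = "cg_trajectory")
}

#' Hand-build a trajectory from explicit frames
#'
#' Mainly for testing contact analysis against enumerable cases.
#'
#' @param frames Array `(n_frames, n_beads, 3)` of coordinates.
#' @param system The [cg_system()] the frames belong to.
#' @param replica_id Replica label.
#' @return A `cg_trajectory`.
#' @export
trajectory_from_frames <- function(frames, system, replica_id = 1L) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[2] == system$n)
  new_trajectory(frames, NULL, system, replica_id, NA_integer_, NA_integer_,
                 NA_real_)
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> replica %s: %d frames x %d beads\n",
              x$replica_id, dim(x$frames)[1], dim(x$frames)[2]))
  invisible(x)
}

#' Run Langevin dynamics replicas
#'
#' Each replica gets a seed derived from the master seed
#' (`seed + replica - 1`), Maxwell-Boltzmann initial velocities, and an
#' independent trajectory; frames are saved every `save_interval` steps
#' (`n_steps = 0` records the initial configuration only). The box
#' constraint is periodic minimum-image by default (reflecting walls when
#' `pbc = FALSE` in the system).
#'
#' @param system A [cg_system()].
#' @param params A [sim_params()].
#' @return List of `cg_trajectory` objects, one per replica.
#' @export
run_simulation <- function(system, params = sim_params()) {
  stopifnot(inherits(system, "cg_system"), inherits(params, "sim_params"))
  lapply(seq_len(params$n_replicas), function(rep_i) {
    rep_seed <- params$seed + rep_i - 1L
    set.seed(rep_seed)
    v0 <- maxwell_velocities(system$n, params$t_reduced)
    res <- .cg_run(system$positions, v0, system$topo, params$dt,
                   params$friction, params$t_reduced, params$n_steps,
                   params$save_interval, 10)
    new_trajectory(res$frames, res$energies, system, rep_i, rep_seed,
                   params$save_interval, params$dt)
  })
}

#' Fraction of native contacts formed (Q)
#'
#' A native pair counts as formed in a frame when its distance is below
#' `tol * r0`. Returns the per-frame Q over a folded chain's contact set.
#'
#' @param traj A `cg_trajectory`.
#' @param chain_index Which chain's native contacts to score (default:
#'   first folded chain).
#' @param tol Formation tolerance relative to the native distance (1.2).
#' @return Numeric vector, one Q value per frame.
#' @export
native_fraction <- function(traj, chain_index = NULL, tol = 1.2) {
  sys <- traj$system
  if (is.null(chain_index))
    chain_index <- which(vapply(sys$chains, function(ch)
      ch$kind == "folded", logical(1)))[1]
  nc <- sys$contacts[[chain_index]]
  if (is.null(nc) || !nrow(nc$pairs)) stop("chain has no native contacts")
  off <- sys$offset[chain_index]
  i <- nc$pairs$i + off; j <- nc$pairs$j + off
  nf <- dim(traj$frames)[1]
  vapply(seq_len(nf), function(f) {
    xi <- traj$frames[f, i, , drop = TRUE]
    xj <- traj$frames[f, j, , drop = TRUE]
    d <- sqrt(rowSums((matrix(xi, ncol = 3) - matrix(xj, ncol = 3))^2))
    mean(d < tol * nc$pairs$r0)
  }, numeric(1))
}

#' Write a trajectory as XYZ plus an energy CSV
#'
#' @param traj A `cg_trajectory`.
#' @param xyz_file Output XYZ path.
#' @param energy_file Optional CSV path for the per-frame energy log.
#' @return Invisibly, the XYZ path.
#' @export
write_trajectory_xyz <- function(traj, xyz_file, energy_file = NULL) {
  nf <- dim(traj$frames)[1]
  n <- dim(traj$frames)[2]
  aa <- unlist(lapply(traj$system$chains, function(ch) ch$aa))
  con <- file(xyz_file, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(c(as.character(n), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", aa,
                       traj$frames[f, , 1], traj$frames[f, , 2],
                       traj$frames[f, , 3]), con)
  }
  if (!is.null(energy_file) && !is.null(traj$energies))
    utils::write.csv(traj$energies, energy_file, row.names = FALSE)
  invisible(xyz_file)
}

#' Read an XYZ trajectory back into frames
#'
#' @param xyz_file Path written by [write_trajectory_xyz()].
#' @return Array `(n_frames, n_beads, 3)`.
#' @export
read_trajectory_xyz <- function(xyz_file) {
  lines <- readLines(xyz_file)
  n <- as.integer(lines[1])
  block <- n + 2L
  nf <- length(lines) %/% block
  frames <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf)) {
    body <- lines[((f - 1L) * block + 3L):((f - 1L) * block + 2L + n)]
    parts <- do.call(rbind, strsplit(body, " ", fixed = TRUE))
    frames[f, , ] <- matrix(as.numeric(parts[, 2:4]), n, 3)
  }
  frames
}

#' Write system topology as structured JSON text
#'
#' Records per chain: kind, sequence, author numbering; enough for the
#' contact-analysis CLI to rebuild axis labels without the R objects.
#'
#' @param system A [cg_system()].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_topology_json <- function(system, file) {
  chains <- lapply(system$chains, function(ch)
    list(kind = ch$kind, sequence = ch$sequence,
         numbering = ch$residue_numbering))
  jsonlite::write_json(
    list(n_beads = system$n, box = system$topo$box, pbc = system$topo$pbc,
         chains = chains),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
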