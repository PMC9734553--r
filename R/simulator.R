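## simulator: NVT Langevin dynamics in a periodic cubic box.
##
## Protocol of record: 300 K, dt = 0.02 ps, friction 0.02 ps^-1, cubic
## periodic box, runs of >= 2.5 us with the last 2 us analyzed. Desk-scale
## runs use the same integrator and parameters with fewer steps.

#' Simulation configuration
#'
#' @param box Cubic box edge, nm (`0` = open boundaries).
#' @param n_steps Number of integration steps.
#' @param timestep Integration timestep, ps.
#' @param temperature Temperature, K.
#' @param friction Langevin friction coefficient, ps^-1.
#' @param save_interval Steps between saved frames.
#' @param log_interval Steps between energy-log rows (default
#'   `save_interval`).
#' @param seed Integer seed; together with the config and parameters it
#'   fully determines the trajectory.
#' @param equilibration_fraction Fraction of initial frames discarded by
#'   the analysis stage (default 0.2, mirroring the 2.5 us / last 2 us
#'   protocol).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(box = 20, n_steps = 200000L, timestep = 0.02,
                       temperature = 300, friction = 0.02,
                       save_interval = 500L, log_interval = NULL,
                       seed = 1L, equilibration_fraction = 0.2) {
  if (timestep <= 0) stop("timestep must be > 0")
  if (equilibration_fraction < 0 || equilibration_fraction >= 1)
    stop("equilibration_fraction must be in [0, 1)")
  if (n_steps < 0) stop("n_steps must be >= 0")
  structure(list(box = box, n_steps = as.integer(n_steps),
                 timestep = timestep, temperature = temperature,
                 friction = friction,
                 save_interval = as.integer(save_interval),
                 log_interval = as.integer(if (is.null(log_interval))
                   save_interval else log_interval),
                 seed = as.integer(seed),
                 equilibration_fraction = equilibration_fraction),
            class = "sim_config")
}

#' Place chains in the box and draw Maxwell-Boltzmann velocities
#'
#' The first chain is centered at the origin; further chains are placed
#' with a random rigid rotation and a random centre-of-mass offset, and
#' accepted only if every inter-chain bead distance exceeds the
#' excluded-volume diameter. Retries are bounded; persistent failure asks
#' for a larger box. Velocities are drawn from the Maxwell-Boltzmann
#' distribution at the configured temperature. The whole procedure is a
#' deterministic function of the config seed.
#'
#' @param models List of `cg_model` chains.
#' @param roles Chain roles (`"pr"` / `"kap"`).
#' @param config `sim_config`.
#' @param params `ff_params`.
#' @param max_offset Largest centre-of-mass offset tried, nm (default:
#'   half box edge, or 6 nm in open boundaries).
#' @return A `cg_system` with `positions` and `velocities` set.
#' @export
initialize_system <- function(models, roles, config = sim_config(),
                              params = ff_params(), max_offset = NULL) {
  sys <- build_system(models, roles, params, box = config$box)
  nper <- vapply(models, function(m) nchar(m$sequence), integer(1))
  off <- cumsum(c(0L, nper[-length(nper)]))
  if (is.null(max_offset))
    max_offset <- if (config$box > 0) config$box / 2 else 6
  .with_seed(config$seed, {
    placed <- NULL
    for (c in seq_along(models)) {
      p <- models[[c]]$positions
      p <- sweep(p, 2, colMeans(p))           # centre chain at origin
      if (c == 1L) {
        newp <- p
      } else {
        ok <- FALSE
        for (try in 1:200) {
          R <- .random_rotation()
          shift <- runif(3, -max_offset, max_offset)
          cand <- sweep(p %*% t(R), 2, shift, "+")
          d2 <- .min_interchain_dist2(cand, placed, config$box)
          if (d2 >= params$ev_sigma^2) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place chain ", c,
                      " without overlap; increase the box size")
        newp <- cand
      }
      idx <- off[c] + seq_len(nper[c])
      sys$positions[idx, ] <- newp
      placed <- rbind(placed, newp)
    }
    sigma <- sqrt(.kB * config$temperature / sys$mass)
    sys$velocities <- matrix(rnorm(3 * sys$n), sys$n, 3) * sigma
  })
  ## keep everything near the first octant centre for a clean PBC picture
  if (config$box > 0)
    sys$positions <- sys$positions + config$box / 2
  sys
}

.random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.min_interchain_dist2 <- function(a, b, box) {
  ## min over all pairs of squared min-image distance
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[i, ])
    if (box > 0) d <- d - box * round(d / box)
    best <- min(best, min(rowSums(d * d)))
  }
  best
}

#' Run Langevin dynamics
#'
#' Integrates the system with the BAOAB splitting of Langevin dynamics at
#' the configured temperature and friction, saving frames every
#' `save_interval` steps (the initial state is frame 1). The trajectory is
#' a deterministic function of (models, config, params, seed).
#'
#' @param x A `cg_system` from [initialize_system()], or a list of
#'   `cg_model` chains (then `roles` is required and the system is
#'   initialized here).
#' @param config `sim_config`.
#' @param params `ff_params`.
#' @param roles Chain roles when `x` is a model list.
#' @return Object of class `cg_trajectory`: `times` (ps), `frames`
#'   (n x 3 x n_frames array, nm), `box`, `chain_map`, `energy_log`,
#'   `final_state`, and config echoes.
#' @export
run_simulation <- function(x, config = sim_config(), params = ff_params(),
                           roles = NULL) {
  sys <- if (inherits(x, "cg_system")) x else {
    if (is.null(roles)) stop("roles required when passing model chains")
    initialize_system(x, roles, config, params)
  }
  pk <- .engine_pack(sys, params)
  pk$sys$vel <- sys$velocities
  out <- cpp_run_md(pk$sys, pk$par, config$n_steps, config$timestep,
                    config$friction, config$temperature,
                    config$seed + 1001, config$save_interval,
                    config$log_interval)
  traj <- structure(list(
    times = as.numeric(out$times),
    frames = out$frames,
    box = sys$box,
    chain_map = sys$chain_map,
    chain_ids = sys$chain_ids,
    roles = sys$roles,
    sequences = vapply(split(sys$sequence, sys$chain), paste,
                       character(1), collapse = ""),
    energy_log = out$energy_log,
    equilibration_fraction = config$equilibration_fraction,
    config = unclass(config),
    final_state = list(positions = out$positions,
                       velocities = out$velocities)
  ), class = "cg_trajectory")
  traj
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory: ", dim(x$frames)[3], " frames x ", dim(x$frames)[1],
      " beads, ", max(x$times), " ps, box ",
      if (x$box > 0) paste0(x$box, " nm") else "open", "\n", sep = "")
  invisible(x)
}

#' Write / read a trajectory as plain text
#'
#' Format: a header line, one JSON metadata line, then for each frame a
#' `F <time>` line followed by one `x y z` line per bead at 17
#' significant digits, so the round-trip is lossless.
#'
#' @param traj A `cg_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  nf <- dim(traj$frames)[3]
  n <- dim(traj$frames)[1]
  meta <- jsonlite::toJSON(list(
    format = "kapcg-traj", version = 1L, n_beads = n, n_frames = nf,
    box = traj$box, chain = traj$chain_map$chain,
    role = traj$chain_map$role, chain_ids = traj$chain_ids,
    roles = traj$roles, sequences = as.list(traj$sequences),
    equilibration_fraction = traj$equilibration_fraction),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#kapcg-traj 1", as.character(meta)), con)
  for (f in seq_len(nf)) {
    writeLines(paste("F", .num17(traj$times[f])), con)
    m <- traj$frames[, , f, drop = FALSE]
    writeLines(sprintf("%.17g %.17g %.17g", m[, 1, 1], m[, 2, 1],
                       m[, 3, 1]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || lines[1] != "#kapcg-traj 1")
    stop("not a kapcg trajectory file (or unsupported version): ", path)
  meta <- jsonlite::fromJSON(lines[2])
  n <- meta$n_beads; nf <- meta$n_frames
  if (nf < 1L) stop("trajectory has no frames")
  body <- lines[-(1:2)]
  if (length(body) != nf * (n + 1L)) stop("truncated trajectory file")
  times <- numeric(nf)
  frames <- array(NA_real_, c(n, 3, nf))
  for (f in seq_len(nf)) {
    blk <- body[((f - 1L) * (n + 1L) + 1L):(f * (n + 1L))]
    if (!startsWith(blk[1], "F ")) stop("corrupt frame header at frame ", f)
    times[f] <- as.numeric(sub("^F ", "", blk[1]))
    xyz <- scan(text = blk[-1], quiet = TRUE)
    frames[, , f] <- matrix(xyz, n, 3, byrow = TRUE)
  }
  structure(list(
    times = times, frames = frames, box = meta$box,
    chain_map = data.frame(bead = seq_len(n), chain = meta$chain,
                           role = meta$role),
    chain_ids = meta$chain_ids, roles = meta$roles,
    sequences = unlist(meta$sequences),
    energy_log = NULL,
    equilibration_fraction = meta$equilibration_fraction,
    config = NULL, final_state = NULL
  ), class = "cg_trajectory")
}

#' Export a PDB-format topology snapshot of frame 1
#'
#' Convenience export for external viewers; positions in Angstrom,
#' glycine placeholder names are not used — real residue identities are
#' written.
#'
#' @param traj A `cg_trajectory`.
#' @param path Output PDB path.
#' @param frame Frame index to export.
#' @export
export_pdb_snapshot <- function(traj, path, frame = 1L) {
  n <- dim(traj$frames)[1]
  seq_all <- unlist(strsplit(paste(traj$sequences, collapse = ""), ""))
  aa3 <- names(.AA3TO1)[match(seq_all, .AA3TO1)]
  ch <- LETTERS[traj$chain_map$chain]
  xyz <- traj$frames[, , frame] * 10
  resno <- sequence(tabulate(traj$chain_map$chain))
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), aa3, ch, resno, xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
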