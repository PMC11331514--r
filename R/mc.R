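#' Construct a Monte Carlo state from explicit coordinates
#'
#' Validates hard-core overlaps, wall bounds, box-size sanity (the bulk box
#' must exceed twice the ramp range so the short-ranged modification never
#' wraps) and, for the slit, electroneutrality including the wall charge.
#'
#' @param pos N x 3 matrix of ion center coordinates (Angstrom). Bulk
#'   coordinates are wrapped into the primary cell; slit z must lie within the
#'   accessible range.
#' @param valence integer-valued vector of ion valences (e0).
#' @param box a \code{\link{bulk_box}} or \code{\link{slit_box}}.
#' @param model a \code{\link{dielectric_ramp}}.
#' @param temperature temperature in K.
#' @return an object of class \code{mc_state}.
#' @export
mc_state <- function(pos, valence, box, model, temperature = 298) {
  stopifnot(inherits(box, "sim_box"), inherits(model, "dielectric_ramp"))
  pos <- as.matrix(pos)
  if (length(pos) == 0) pos <- matrix(numeric(0), ncol = 3)
  stopifnot(ncol(pos) == 3, nrow(pos) == length(valence))
  valence <- as.numeric(valence)
  if (inherits(box, "bulk_box")) {
    if (box$L <= 2 * (model$d + model$delta))
      stop("bulk box must satisfy L > 2*(d + delta) so the ramp never wraps")
    pos <- pos - box$L * floor(pos / box$L)
  } else {
    if (box$H <= model$d) stop("slit width H must exceed the ion diameter")
    zmax <- (box$H - model$d) / 2
    if (nrow(pos) > 0 && any(abs(pos[, 3]) > zmax + 1e-12))
      stop("ion center(s) outside the accessible slit range |z| <= (H-d)/2")
    pos[, 1:2] <- pos[, 1:2] - box$L * floor(pos[, 1:2] / box$L)
    net <- sum(valence) + 2 * box$sigma * box$L^2
    if (abs(net) > 1e-8)
      stop(sprintf("slit system not electroneutral: net charge %g e0", net))
  }
  box <- .ensure_corr_table(box, model)
  st <- structure(list(pos = pos, valence = valence, box = box, model = model,
                       temperature = temperature, beta_energy = 0,
                       sweep = 0L),
                  class = "mc_state")
  if (nrow(pos) > 1) {
    dmin <- cpp_min_pair_distance(pos, .geom_clist(box, model))
    if (dmin < model$d)
      stop(sprintf("hard-core overlap in configuration (min distance %.3f A)", dmin))
  }
  st$beta_energy <- total_energy(st)
  st
}

#' @export
print.mc_state <- function(x, ...) {
  n <- nrow(x$pos)
  cat(sprintf("MC state: %d ions (%d cations, %d anions), %s geometry\n",
              n, sum(x$valence > 0), sum(x$valence < 0), x$box$type))
  cat(sprintf("  beta*U = %.4f, sweep %d, T = %g K\n",
              x$beta_energy, x$sweep, x$temperature))
  invisible(x)
}

#' Total configurational energy
#'
#' Full O(N^2) pair sum (minimum image; charged-sheet terms in the slit), in
#' units of \eqn{k_B T}.
#'
#' @param state an \code{mc_state}.
#' @return energy in \eqn{k_B T}.
#' @export
total_energy <- function(state) {
  if (nrow(state$pos) < 2) return(0)
  cpp_total_energy(state$pos, state$valence,
                   .geom_clist(state$box, state$model),
                   .model_clist(state$model, state$temperature))
}

#' Interaction energy of one ion with the rest of the system
#'
#' @param state an \code{mc_state}.
#' @param i ion index (1-based).
#' @return energy in \eqn{k_B T}; the sum over all ions equals twice the
#'   total energy.
#' @export
particle_energy <- function(state, i) {
  n <- nrow(state$pos)
  stopifnot(i >= 1, i <= n)
  if (n < 2) return(0)
  cpp_particle_energy(state$pos, state$valence,
                      .geom_clist(state$box, state$model),
                      .model_clist(state$model, state$temperature),
                      as.integer(i - 1))
}

#' Seeded random initial configuration
#'
#' Non-overlapping configuration by seeded random insertion with rejection;
#' deterministic given (counts, geometry, seed). Insertion failure after the
#' per-ion attempt budget signals overpacking.
#'
#' @param n_plus,n_minus numbers of cations (+1) and anions (-1).
#' @param box simulation box.
#' @param model dielectric model (supplies the hard-sphere diameter).
#' @param temperature temperature in K.
#' @param seed optional integer seed (sets R's RNG).
#' @param max_attempts per-ion insertion attempt budget.
#' @param valences optional length-2 vector c(z_plus, z_minus) for non-unit
#'   valences; defaults to c(1, -1).
#' @return an \code{mc_state}.
#' @export
initialize_configuration <- function(n_plus, n_minus, box, model,
                                     temperature = 298, seed = NULL,
                                     max_attempts = 2000,
                                     valences = c(1, -1)) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_plus + n_minus
  valence <- c(rep(valences[1], n_plus), rep(valences[2], n_minus))
  L <- box$L
  slit <- inherits(box, "slit_box")
  zmax <- if (slit) (box$H - model$d) / 2 else NA
  if (slit && zmax <= 0) stop("slit too narrow for the ion diameter")
  pos <- matrix(NA_real_, nrow = n, ncol = 3)
  gl <- .geom_clist(box, model)
  d <- model$d
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- c(runif(1, 0, L), runif(1, 0, L),
                if (slit) runif(1, -zmax, zmax) else runif(1, 0, L))
      if (i == 1) { placed <- TRUE }
      else {
        dr <- sweep(pos[seq_len(i - 1), , drop = FALSE], 2, cand)
        dr <- min_image(dr, box)
        placed <- all(rowSums(dr^2) >= d^2)
      }
      if (placed) { pos[i, ] <- cand; break }
    }
    if (!placed)
      stop(sprintf("insertion failed for ion %d after %d attempts: box overpacked",
                   i, max_attempts))
  }
  mc_state(pos, valence, box, model, temperature)
}

#' Move schedule for a Monte Carlo run
#'
#' @param equil_sweeps,prod_sweeps equilibration and production sweeps (one
#'   sweep = N attempted moves).
#' @param sample_stride sweeps between production samples.
#' @param step maximum single-particle displacement (Angstrom).
#' @param cluster_frac fraction of attempts that are rigid cluster
#'   translations.
#' @param cluster_step maximum cluster translation (Angstrom).
#' @param delta_mv cluster-move connectivity distance (Angstrom); defaults to
#'   the analysis criterion d + 0.5 when a model is supplied at run time.
#' @param cluster_max largest cluster a cluster move will translate; larger
#'   connected components are rejected symmetrically (cheap guard against
#'   percolating clusters at high concentration).
#' @param tune adapt \code{step} toward 30--50\% acceptance during
#'   equilibration only (frozen for production, preserving detailed balance).
#' @param reconcile_every samples between reconciliations of the running
#'   energy against a full O(N^2) recomputation.
#' @param energy_tol abort threshold (in \eqn{k_B T}) for the reconciliation
#'   discrepancy; \code{NULL} selects 1e-6 per ion.
#' @return an object of class \code{mc_schedule}.
#' @export
mc_schedule <- function(equil_sweeps = 2000, prod_sweeps = 10000,
                        sample_stride = 10, step = 1.5, cluster_frac = 0.1,
                        cluster_step = 2, delta_mv = NULL, cluster_max = Inf,
                        tune = TRUE, reconcile_every = 100,
                        energy_tol = NULL) {
  stopifnot(equil_sweeps >= 0, prod_sweeps >= 0, sample_stride >= 1,
            step > 0, cluster_frac >= 0, cluster_frac <= 1, cluster_step > 0)
  structure(list(equil_sweeps = as.integer(equil_sweeps),
                 prod_sweeps = as.integer(prod_sweeps),
                 sample_stride = as.integer(sample_stride),
                 step = step, cluster_frac = cluster_frac,
                 cluster_step = cluster_step, delta_mv = delta_mv,
                 cluster_max = cluster_max, tune = tune,
                 reconcile_every = as.integer(reconcile_every),
                 energy_tol = energy_tol),
            class = "mc_schedule")
}

# one compiled chunk of sweeps; returns updated state + acceptance counters
.mc_chunk <- function(state, nsweeps, step, cluster_frac, cluster_step,
                      delta_mv, cluster_max = Inf) {
  if (nsweeps == 0 || nrow(state$pos) == 0)
    return(list(state = state, att_disp = 0, acc_disp = 0,
                att_cluster = 0, acc_cluster = 0))
  cmax <- if (is.finite(cluster_max)) as.integer(cluster_max)
          else .Machine$integer.max
  res <- cpp_run_sweeps(state$pos, state$valence,
                        .geom_clist(state$box, state$model),
                        .model_clist(state$model, state$temperature),
                        as.integer(nsweeps), step, cluster_frac, cluster_step,
                        delta_mv, state$beta_energy, cmax)
  state$pos <- res$pos
  state$beta_energy <- res$energy
  state$sweep <- state$sweep + as.integer(nsweeps)
  list(state = state, att_disp = res$att_disp, acc_disp = res$acc_disp,
       att_cluster = res$att_cluster, acc_cluster = res$acc_cluster)
}

#' Low-level: run raw MC sweeps on a state
#'
#' Thin wrapper over the compiled kernel, without sampling, tuning, or energy
#' reconciliation. Useful for tests and custom drivers.
#'
#' @param state an \code{mc_state}.
#' @param nsweeps number of sweeps.
#' @param step maximum displacement.
#' @param cluster_frac probability that an attempt is a cluster move.
#' @param cluster_step maximum cluster translation.
#' @param delta_mv cluster connectivity distance; default d + 0.5.
#' @return list with \code{state} and acceptance counters.
#' @export
mc_sweeps <- function(state, nsweeps, step = 1.5, cluster_frac = 0,
                      cluster_step = 2, delta_mv = NULL, cluster_max = Inf) {
  if (is.null(delta_mv)) delta_mv <- state$model$d + 0.5
  .mc_chunk(state, nsweeps, step, cluster_frac, cluster_step, delta_mv,
            cluster_max)
}

#' Run a Monte Carlo simulation
#'
#' Equilibration (with optional step tuning) followed by production sweeps.
#' Registered observers are evaluated on the state at every sampling stride;
#' the running energy is periodically reconciled against a full recomputation
#' and the run aborts if the discrepancy exceeds the tolerance. Fully
#' reproducible given the RNG seed (set \code{set.seed()} before calling).
#'
#' @param state an \code{mc_state}.
#' @param schedule an \code{\link{mc_schedule}}.
#' @param observers named list of functions of the state; each sample stores
#'   one return value per observer.
#' @param checkpoint_path optional file; a resumable checkpoint is written
#'   every \code{checkpoint_every} samples.
#' @param checkpoint_every samples between checkpoints.
#' @param quiet suppress progress messages.
#' @return list of class \code{mc_run}: final \code{state}, per-observer
#'   \code{samples}, sampled \code{energies}, acceptance statistics, the
#'   frozen schedule, and the maximum energy-reconciliation drift.
#' @export
run_mc <- function(state, schedule, observers = list(),
                   checkpoint_path = NULL, checkpoint_every = Inf,
                   quiet = TRUE) {
  stopifnot(inherits(state, "mc_state"), inherits(schedule, "mc_schedule"))
  sch <- schedule
  if (is.null(sch$delta_mv)) sch$delta_mv <- state$model$d + 0.5
  if (is.null(sch$cluster_max)) sch$cluster_max <- Inf
  if (is.null(sch$energy_tol)) sch$energy_tol <- 1e-6 * max(1, nrow(state$pos))

  acc <- c(att_disp = 0, acc_disp = 0, att_cluster = 0, acc_cluster = 0)
  # --- equilibration, with optional step tuning (equilibration only) ---
  if (sch$equil_sweeps > 0) {
    nchunk <- if (sch$tune) 10L else 1L
    per <- ceiling(sch$equil_sweeps / nchunk)
    done <- 0L
    for (ch in seq_len(nchunk)) {
      todo <- min(per, sch$equil_sweeps - done)
      if (todo <= 0) break
      r <- .mc_chunk(state, todo, sch$step, sch$cluster_frac,
                     sch$cluster_step, sch$delta_mv, sch$cluster_max)
      state <- r$state
      done <- done + todo
      if (sch$tune && r$att_disp > 0) {
        a <- r$acc_disp / r$att_disp
        if (a > 0.5) sch$step <- min(sch$step * 1.3, state$box$L / 2)
        if (a < 0.3) sch$step <- max(sch$step / 1.3, 0.02)
      }
    }
    state$beta_energy <- total_energy(state)  # re-anchor after equilibration
  }
  sch$tune <- FALSE  # step frozen from here on

  .mc_production(state, sch, observers, sample_start = 1L,
                 checkpoint_path = checkpoint_path,
                 checkpoint_every = checkpoint_every, quiet = quiet)
}

# production loop shared by run_mc and resume_mc
.mc_production <- function(state, sch, observers, sample_start,
                           checkpoint_path, checkpoint_every, quiet) {
  nsamples <- sch$prod_sweeps %/% sch$sample_stride
  samples <- lapply(observers, function(f) vector("list", nsamples))
  energies <- rep(NA_real_, nsamples)
  acc <- c(att_disp = 0, acc_disp = 0, att_cluster = 0, acc_cluster = 0)
  max_drift <- 0
  s <- sample_start
  while (s <= nsamples) {
    r <- .mc_chunk(state, sch$sample_stride, sch$step, sch$cluster_frac,
                   sch$cluster_step, sch$delta_mv, sch$cluster_max)
    state <- r$state
    acc <- acc + c(r$att_disp, r$acc_disp, r$att_cluster, r$acc_cluster)
    energies[s] <- state$beta_energy
    for (nm in names(observers))
      samples[[nm]][[s]] <- observers[[nm]](state)
    if (s %% sch$reconcile_every == 0 || s == nsamples) {
      exact <- total_energy(state)
      drift <- abs(exact - state$beta_energy)
      max_drift <- max(max_drift, drift)
      if (drift > sch$energy_tol)
        stop(sprintf(
          "energy bookkeeping drift %.3e kT exceeds tolerance %.3e at sample %d",
          drift, sch$energy_tol, s))
      state$beta_energy <- exact
      energies[s] <- exact
    }
    if (!is.null(checkpoint_path) && is.finite(checkpoint_every) &&
        s %% checkpoint_every == 0) {
      write_checkpoint(list(state = state, schedule = sch, sample_index = s,
                            rng = .Random.seed), checkpoint_path)
    }
    if (!quiet && s %% 100 == 0)
      message(sprintf("sample %d/%d, beta*U = %.2f", s, nsamples,
                      state$beta_energy))
    s <- s + 1L
  }
  names(acc) <- c("att_disp", "acc_disp", "att_cluster", "acc_cluster")
  structure(list(state = state, samples = samples, energies = energies,
                 acceptance = as.list(acc),
                 acc_rate_disp = if (acc[1] > 0) acc[2] / acc[1] else NA,
                 acc_rate_cluster = if (acc[3] > 0) acc[4] / acc[3] else NA,
                 schedule = sch, nsamples = nsamples, max_drift = max_drift,
                 sample_start = sample_start),
            class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("MC run: %d samples, final beta*U = %.3f\n",
              x$nsamples, x$state$beta_energy))
  cat(sprintf("  displacement acceptance %.1f%%, cluster acceptance %s\n",
              100 * x$acc_rate_disp,
              if (is.na(x$acc_rate_cluster)) "n/a"
              else sprintf("%.1f%%", 100 * x$acc_rate_cluster)))
  cat(sprintf("  max energy-bookkeeping drift %.2e kT\n", x$max_drift))
  invisible(x)
}

#' Write / read a resumable checkpoint
#'
#' The checkpoint stores positions, valences, counters, the frozen schedule
#' and the RNG state, so a resumed run reproduces the uninterrupted
#' observable stream bit for bit.
#'
#' @param checkpoint list as written by \code{\link{run_mc}} (state, schedule,
#'   sample_index, rng), or any serializable run object.
#' @param path file path.
#' @return \code{read_checkpoint} returns the checkpoint list.
#' @export
write_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)

#' Resume a production run from a checkpoint
#'
#' Restores the RNG state and continues the production loop from the sample
#' after the checkpoint; the returned samples cover the remaining indices and
#' are identical to the corresponding stretch of an uninterrupted run.
#'
#' @param checkpoint a checkpoint list or a path to one.
#' @param observers named list of observer functions (as in
#'   \code{\link{run_mc}}).
#' @param quiet suppress progress messages.
#' @return an \code{mc_run} covering samples
#'   \code{sample_index + 1 .. nsamples}.
#' @export
resume_mc <- function(checkpoint, observers = list(), quiet = TRUE) {
  if (is.character(checkpoint)) checkpoint <- read_checkpoint(checkpoint)
  assign(".Random.seed", checkpoint$rng, envir = globalenv())
  .mc_production(checkpoint$state, checkpoint$schedule, observers,
                 sample_start = checkpoint$sample_index + 1L,
                 checkpoint_path = NULL, checkpoint_every = Inf, quiet = quiet)
}
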