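# High-level drivers: configuration -> equilibrated run -> observables.

#' @keywords internal
.model_from_config <- function(cfg) {
  dielectric_ramp(eps_c = cfg$model$eps_c, eps_b = cfg$model$eps_b,
                  delta = cfg$model$delta, d = cfg$model$d)
}

#' @keywords internal
.schedule_from_config <- function(cfg) {
  s <- cfg$schedule
  mc_schedule(equil_sweeps = s$equil_sweeps, prod_sweeps = s$prod_sweeps,
              sample_stride = s$sample_stride, step = s$step,
              cluster_frac = s$cluster_frac, cluster_step = s$cluster_step,
              delta_mv = s$delta_mv,
              cluster_max = s$cluster_max %||% Inf)
}

#' Simulate a bulk electrolyte from a configuration
#'
#' Builds the model, box and initial configuration (species counts from the
#' molarity via 1 M = 6.02214e-4 ions/A^3, rounded per species, or explicit
#' counts), runs the schedule, and computes the standard bulk observables:
#' pooled RDFs with g_nn/g_cc, per-frame cluster partitions and the ion
#' cluster-size distribution.
#'
#' @param config an \code{rpmmc_config} (see \code{\link{default_config}}) or
#'   a path to a YAML configuration.
#' @param keep_frames store sampled frames in the result (needed for Widom
#'   estimation and re-analysis).
#' @return list with \code{run} (the \code{mc_run}), \code{rdf} (data
#'   frame), \code{clusters} (P_ion data frame), \code{partitions},
#'   \code{frames}, \code{state}, \code{box}, \code{model}, \code{config}.
#' @export
simulate_bulk <- function(config, keep_frames = TRUE) {
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(config, "rpmmc_config"), config$geometry$type == "bulk")
  set.seed(config$seed)
  model <- .model_from_config(config)
  box <- bulk_box(config$geometry$L)
  th <- config$thermo
  if (!is.null(th$molarity)) {
    n_each <- round(molar_to_density(th$molarity) * box$L^3)
    n_plus <- n_each; n_minus <- n_each
  } else {
    n_plus <- th$n_plus %||% 0; n_minus <- th$n_minus %||% 0
  }
  state <- initialize_configuration(n_plus, n_minus, box, model,
                                    temperature = th$temperature)
  sch <- .schedule_from_config(config)
  run <- run_mc(state, sch, observers = list(frames = function(s) s$pos))
  frames <- run$samples$frames
  delta <- config$observables$cluster_delta %||% (model$d + 0.5)
  rs <- rdf_init(box, bin_width = config$observables$rdf_bin)
  partitions <- vector("list", length(frames))
  fs <- run$state
  for (i in seq_along(frames)) {
    fs$pos <- frames[[i]]
    rs <- rdf_accumulate(rs, fs)
    partitions[[i]] <- cluster_decomposition(fs, delta)
  }
  out <- list(run = run, rdf = rdf_table(rs),
              clusters = cluster_size_distribution(partitions),
              partitions = partitions, state = run$state,
              box = box, model = model, config = config)
  out$frames <- if (keep_frames) frames else NULL
  out$run$samples$frames <- NULL
  out
}

#' Simulate an electrolyte in a charged slit from a configuration
#'
#' Species counts come from the molarity over the accessible slab volume
#' L^2 (H - d); wall neutralization adds \code{round(2 L^2 / sigma_inverse)}
#' counterions and the wall charge density is then set exactly to the value
#' those counterions neutralize, keeping the system electroneutral.
#'
#' @inheritParams simulate_bulk
#' @return as \code{\link{simulate_bulk}}, but with \code{profile} (the z
#'   density profile) and \code{midplane_molarity} instead of RDFs.
#' @export
simulate_slit <- function(config, keep_frames = TRUE) {
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(config, "rpmmc_config"), config$geometry$type == "slit")
  set.seed(config$seed)
  model <- .model_from_config(config)
  g <- config$geometry
  th <- config$thermo
  vol_acc <- g$L^2 * (g$H - model$d)
  if (!is.null(th$molarity)) {
    n_pairs <- round(molar_to_density(th$molarity) * vol_acc)
  } else {
    n_pairs <- th$n_minus %||% 0
  }
  n_counter <- if (is.null(g$sigma_inverse)) 0L
               else as.integer(round(2 * g$L^2 / g$sigma_inverse))
  sigma <- if (n_counter > 0) -n_counter / (2 * g$L^2) else 0
  box <- slit_box(g$L, g$H, sigma = sigma)
  state <- initialize_configuration(n_pairs + n_counter, n_pairs, box, model,
                                    temperature = th$temperature)
  sch <- .schedule_from_config(config)
  run <- run_mc(state, sch, observers = list(frames = function(s) s$pos))
  frames <- run$samples$frames
  profile <- density_profiles(frames, state$valence, box, d = model$d,
                              bin_width = config$observables$profile_bin)
  out <- list(run = run, profile = profile,
              midplane_molarity = midplane_concentration(profile),
              state = run$state, box = box, model = model, config = config)
  out$frames <- if (keep_frames) frames else NULL
  out$run$samples$frames <- NULL
  out
}
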