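# Shared equilibrium runs used by several test files. Each run is computed
# once per test session and cached; seeds and problem sizes are fixed
# constants (the methods vignette records the choices).

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, fn) {
  if (!exists(name, envir = .run_cache)) {
    assign(name, fn(), envir = .run_cache)
  }
  get(name, envir = .run_cache)
}

# standard bulk study configuration: N ions of a c-molar 1:1 salt
study_bulk_config <- function(molarity, eps_c = 23, eps_b = 78.3, seed = 1,
                              n_ions = 400, prod = 11000, equil = 3000) {
  cfg <- default_config()
  cfg$model$eps_c <- eps_c
  cfg$model$eps_b <- eps_b
  cfg$thermo$molarity <- molarity
  cfg$geometry$L <- (n_ions / molar_to_density(2 * molarity))^(1 / 3)
  cfg$schedule$equil_sweeps <- equil
  cfg$schedule$prod_sweeps <- prod
  cfg$schedule$sample_stride <- 10
  cfg$schedule$cluster_frac <- 0.15
  cfg$schedule$cluster_step <- 3
  cfg$schedule$cluster_max <- 64
  cfg$observables$rdf_bin <- 0.25
  cfg$seed <- seed
  cfg
}

# standard slit study configuration at the headline wall charge -1/70 e0/A^2
study_slit_config <- function(molarity, eps_c = 23, eps_b = 78.3, seed = 1,
                              L = 34, H = 50, prod = 7000, equil = 3000) {
  cfg <- default_config()
  cfg$model$eps_c <- eps_c
  cfg$model$eps_b <- eps_b
  cfg$thermo$molarity <- molarity
  cfg$geometry$type <- "slit"
  cfg$geometry$L <- L
  cfg$geometry$H <- H
  cfg$geometry$sigma_inverse <- 70
  cfg$schedule$equil_sweeps <- equil
  cfg$schedule$prod_sweeps <- prod
  cfg$schedule$sample_stride <- 10
  cfg$schedule$cluster_frac <- 0.1
  cfg$schedule$cluster_step <- 3
  cfg$schedule$cluster_max <- 64
  cfg$observables$profile_bin <- 1
  cfg$seed <- seed
  cfg
}

# Widom screening estimate on thinned frames of a bulk run. For the ramp
# model the window starts beyond the ramp + first coordination shell (8 A):
# closer separations measure local structure, not the asymptotic decay. A
# reduced test charge tames the heavy-tailed Boltzmann average at strongly
# coupled state points.
study_widom <- function(sim, molarity, insertions = 600, thin = 3,
                        charge = 1, lo = NULL, hi = NULL, n_boot = 100) {
  lamD <- debye_length(molarity)
  if (is.null(lo)) lo <- max(4, 0.8 * lamD)
  if (is.null(hi)) hi <- min(lo + 3 * lamD, sim$box$L / 2 - 1)
  fr <- sim$frames[seq(1, length(sim$frames), by = thin)]
  ws <- widom_settings(seq(lo, hi, length.out = 7), insertions = insertions,
                       charge = charge)
  wt <- pair_insertion_free_energy(fr, sim$state$valence, sim$box, sim$model,
                                   ws)
  suppressWarnings(effective_screening_length(wt, n_boot = n_boot))
}

study_widom_ramp <- function(sim, molarity) {
  study_widom(sim, molarity, insertions = 1500, thin = 2, charge = 0.4,
              lo = max(8, 1.2 * debye_length(molarity)))
}

run_uniform_005 <- function() cached_run("unif005", function() {
  simulate_bulk(study_bulk_config(0.05, eps_c = 78.3, seed = 11,
                                  prod = 16000, equil = 2000))
})

run_ramp_005 <- function() cached_run("ramp005", function() {
  simulate_bulk(study_bulk_config(0.05, seed = 115, n_ions = 300,
                                  prod = 10000))
})

run_uniform_025 <- function() cached_run("unif025", function() {
  simulate_bulk(study_bulk_config(0.25, eps_c = 78.3, seed = 12))
})

run_ramp_025 <- function() cached_run("ramp025", function() {
  simulate_bulk(study_bulk_config(0.25, seed = 125))
})

run_ramp_05 <- function() cached_run("ramp05", function() {
  simulate_bulk(study_bulk_config(0.5, seed = 150))
})

run_ramp_1M <- function() cached_run("ramp1M", function() {
  simulate_bulk(study_bulk_config(1, seed = 379, prod = 7000))
})

run_uniform23_1M <- function() cached_run("unif23_1M", function() {
  simulate_bulk(study_bulk_config(1, eps_c = 23, eps_b = 23, seed = 324,
                                  prod = 7000))
})

run_phase_scan <- function() cached_run("phase_scan", function() {
  lapply(c(20, 21, 23), function(ec) {
    # the homogeneous point needs the long equilibration: transient
    # aggregates from the random start must dissolve before sampling
    cfg <- study_bulk_config(3.45, eps_c = ec, seed = 600 + ec,
                             prod = 8000, equil = 10000)
    cfg$schedule$cluster_frac <- 0.1
    cfg$schedule$sample_stride <- 20
    simulate_bulk(cfg)
  })
})

run_widom_005 <- function() cached_run("widom005", function() {
  study_widom(run_uniform_005(), 0.05, n_boot = 100)
})

# long two-ion run shared by the engine and acceptance checks: sampled
# minimum-image pair distances and the quadrature reference on shared bins
run_two_ion <- function() cached_run("two_ion", function() {
  m <- dielectric_ramp(eps_c = 45)
  L <- 20
  st <- mc_state(rbind(c(5, 5, 5), c(8, 5, 5)), c(1, -1), bulk_box(L), m)
  set.seed(64)
  sch <- mc_schedule(equil_sweeps = 1000, prod_sweeps = 1.6e6,
                     sample_stride = 4, step = 5, cluster_frac = 0,
                     tune = FALSE, reconcile_every = 1e5)
  run <- run_mc(st, sch, observers = list(d = function(s)
    sqrt(sum(min_image(s$pos[1, ] - s$pos[2, ], s$box)^2))))
  dists <- unlist(run$samples$d)
  edges <- c(seq(3, 6, by = 0.25), 7, 8, 10)
  emp <- tabulate(findInterval(dists[dists < 10], edges),
                  nbins = length(edges) - 1)
  list(emp = emp / sum(emp),
       th = ora_pair_distance_density(m, 298, L, edges))
})

run_slit_pair <- function() cached_run("slit_pair", function() {
  list(ramp = simulate_slit(study_slit_config(1.4, seed = 71)),
       unif = simulate_slit(study_slit_config(1.4, eps_c = 23, eps_b = 23,
                                              seed = 72)))
})
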