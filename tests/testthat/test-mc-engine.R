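test_that("seeded initialization is deterministic, overlap-free, and bounded", {
  m <- dielectric_ramp()
  box <- bulk_box((200 / molar_to_density(1))^(1 / 3))
  s1 <- initialize_configuration(100, 100, box, m, seed = 17)
  s2 <- initialize_configuration(100, 100, box, m, seed = 17)
  expect_identical(s1$pos, s2$pos)
  expect_gte(rpmmc:::cpp_min_pair_distance(s1$pos,
                                           rpmmc:::.geom_clist(box, m)), 3)
  expect_true(all(s1$pos >= 0 & s1$pos < box$L))
  expect_equal(sum(s1$valence), 0)

  empty <- initialize_configuration(0, 0, box, m, seed = 1)
  expect_equal(nrow(empty$pos), 0)
  expect_equal(empty$beta_energy, 0)

  # overpacking: hard-sphere volume fraction far beyond random insertion
  expect_error(initialize_configuration(300, 300, bulk_box(13), m, seed = 2,
                                        max_attempts = 200), "overpacked")
})

test_that("particle energies sum to twice the total (bulk and slit)", {
  m <- dielectric_ramp()
  st <- initialize_configuration(12, 12, bulk_box(22), m, seed = 3)
  tot <- total_energy(st)
  expect_equal(sum(vapply(1:24, function(i) particle_energy(st, i),
                          numeric(1))), 2 * tot, tolerance = 1e-10)
  expect_equal(st$beta_energy, tot)

  L <- 16; nc <- 4
  box <- slit_box(L, 24, sigma = -nc / (2 * L^2))
  sts <- initialize_configuration(10 + nc, 10, box, m, seed = 4)
  tots <- total_energy(sts)
  expect_equal(sum(vapply(1:24, function(i) particle_energy(sts, i),
                          numeric(1))), 2 * tots, tolerance = 1e-8)

  # two unlike unit charges at contact in a large box
  fx <- make_fixture("unlike_pair", r = 3)
  expect_equal(particle_energy(fx$state, 1), -8.127, tolerance = 1e-3)
  expect_equal(particle_energy(fx$state, 2), particle_energy(fx$state, 1))

  # isolated ion in a bulk box has zero energy
  iso <- mc_state(matrix(c(5, 5, 5), 1), 1, bulk_box(30), m)
  expect_equal(particle_energy(iso, 1), 0)
})

test_that("bulk total energy matches the plain-R brute-force oracle", {
  m <- dielectric_ramp()
  set.seed(9)
  for (k in 1:5) {
    st <- initialize_configuration(8, 8, bulk_box(runif(1, 14, 25)), m)
    expect_equal(total_energy(st),
                 ora_bulk_energy(st$pos, st$valence, st$box$L),
                 tolerance = 1e-10)
  }
})

test_that("displacement moves obey Metropolis limits", {
  # negligible coupling: every non-overlapping move is accepted
  m0 <- dielectric_ramp(eps_c = 1e6, eps_b = 1e6)
  st <- initialize_configuration(20, 20, bulk_box(40), m0, seed = 10)
  set.seed(11)
  r <- mc_sweeps(st, 50, step = 0.4, cluster_frac = 0)
  expect_gt(r$acc_disp / r$att_disp, 0.97)
  # dense hard spheres at huge steps: overlaps are rejected, state stays legal
  stD <- initialize_configuration(60, 60, bulk_box(19), m0, seed = 12)
  rD <- mc_sweeps(stD, 100, step = 8, cluster_frac = 0)
  expect_lt(rD$acc_disp / rD$att_disp, 0.9)
  expect_gte(rpmmc:::cpp_min_pair_distance(
    rD$state$pos, rpmmc:::.geom_clist(stD$box, m0)), 3)
})

test_that("two-ion sampling reproduces the Boltzmann distance distribution", {
  # moderate contact well (~ -4 kT, eps_c = 45) so bound/free exchanges are
  # frequent enough to resolve the stationary distribution at the 1% level;
  # the ramp region is still fully exercised (shared long run, helper-runs)
  ti <- run_two_ion()
  expect_lt(0.5 * sum(abs(ti$emp - ti$th)), 0.01)
  expect_equal(sum(ti$emp), 1)
})

test_that("cluster moves preserve structure and respect the merge guard", {
  m <- dielectric_ramp()
  box <- bulk_box(30)
  # two tight pairs and a lone ion, all far apart
  pos <- rbind(c(5, 5, 5), c(8.1, 5, 5),
               c(20, 20, 20), c(20, 23.1, 20),
               c(5, 20, 12))
  st <- mc_state(pos, c(1, -1, 1, -1, 1), box, m)
  set.seed(14)
  # pure cluster moves with the analysis connectivity 3.5 A: the partition
  # {2,2,1} can never change (merges rejected, rigid moves cannot split)
  r <- mc_sweeps(st, 400, step = 1, cluster_frac = 1, cluster_step = 2,
                 delta_mv = 3.5)
  p <- cluster_decomposition(r$state, 3.5)
  expect_equal(sort(p$sizes), c(1L, 2L, 2L))
  expect_gt(r$acc_cluster / r$att_cluster, 0.5)  # free translations accepted
  # internal pair separations unchanged by rigid translations
  d12 <- sqrt(sum(min_image(r$state$pos[1, ] - r$state$pos[2, ], box)^2))
  expect_equal(d12, 3.1, tolerance = 1e-9)
  # positions did move
  expect_gt(max(abs(r$state$pos - pos)), 1)
})

test_that("sampling with and without cluster moves agrees (same equilibrium)", {
  m <- dielectric_ramp()
  box <- bulk_box(26)
  # mean configurational energy with a block-averaged standard error:
  # the two samplers must agree within joint statistical uncertainty
  mean_energy <- function(cluster_frac, seed) {
    st <- initialize_configuration(10, 10, box, m, seed = seed)
    set.seed(seed + 1)
    sch <- mc_schedule(equil_sweeps = 2000, prod_sweeps = 20000,
                       sample_stride = 10, step = 1.5,
                       cluster_frac = cluster_frac, cluster_step = 3,
                       tune = TRUE)
    run <- run_mc(st, sch)
    e <- run$energies
    blocks <- colMeans(matrix(e, ncol = 20))
    c(mean = mean(e), se = sd(blocks) / sqrt(20))
  }
  a <- mean_energy(0, 51)
  b <- mean_energy(0.3, 52)
  expect_lt(abs(a["mean"] - b["mean"]),
            4 * sqrt(a["se"]^2 + b["se"]^2) + 0.5)
})

test_that("running energy tracks full recomputation over 1e4 sweeps", {
  m <- dielectric_ramp()
  st <- initialize_configuration(50, 50, bulk_box(36), m, seed = 15)
  set.seed(16)
  r <- mc_sweeps(st, 1e4, step = 1.5, cluster_frac = 0.1, cluster_step = 3)
  drift <- abs(r$state$beta_energy - total_energy(r$state))
  expect_lt(drift, 1e-6 * 100)

  # slit bookkeeping too (interpolated sheet terms must match exactly)
  L <- 16; nc <- 4
  box <- slit_box(L, 24, sigma = -nc / (2 * L^2))
  sts <- initialize_configuration(10 + nc, 10, box, m, seed = 17)
  set.seed(18)
  rs <- mc_sweeps(sts, 3000, step = 1.2, cluster_frac = 0.1)
  expect_lt(abs(rs$state$beta_energy - total_energy(rs$state)), 1e-6 * 24)
  # hard constraints: no overlaps, no wall violations
  expect_gte(rpmmc:::cpp_min_pair_distance(
    rs$state$pos, rpmmc:::.geom_clist(box, m)), 3)
  expect_true(all(abs(rs$state$pos[, 3]) <= (24 - 3) / 2 + 1e-12))
})

test_that("run_mc: empty production, observers, reconciliation report", {
  m <- dielectric_ramp()
  st <- initialize_configuration(5, 5, bulk_box(20), m, seed = 19)
  set.seed(20)
  run0 <- run_mc(st, mc_schedule(equil_sweeps = 100, prod_sweeps = 0))
  expect_equal(run0$nsamples, 0)
  expect_length(run0$energies, 0)

  set.seed(21)
  run <- run_mc(st, mc_schedule(equil_sweeps = 200, prod_sweeps = 500,
                                sample_stride = 50),
                observers = list(e = function(s) s$beta_energy,
                                 n = function(s) nrow(s$pos)))
  expect_equal(run$nsamples, 10)
  expect_equal(unlist(run$samples$e), run$energies)
  expect_true(all(unlist(run$samples$n) == 10))
  expect_lt(run$max_drift, 1e-6 * 10)
})

test_that("checkpoint resume reproduces the uninterrupted sample stream", {
  m <- dielectric_ramp()
  box <- bulk_box(24)
  ck <- withr::local_tempfile(fileext = ".rds")
  obs <- list(e = function(s) s$beta_energy,
              x = function(s) s$pos[1, 1])
  mk <- function() initialize_configuration(8, 8, box, m, seed = 23)
  sch <- mc_schedule(equil_sweeps = 300, prod_sweeps = 2000,
                     sample_stride = 20, step = 1.5, cluster_frac = 0.1)

  st <- mk(); set.seed(24)
  # checkpoint mid-run (sample 60 of 100), then keep running to the end
  full <- run_mc(st, sch, observers = obs, checkpoint_path = ck,
                 checkpoint_every = 60)
  expect_true(file.exists(ck))
  expect_equal(full$nsamples, 100)

  res <- resume_mc(ck, observers = obs)
  expect_identical(unlist(res$samples$e), unlist(full$samples$e)[61:100])
  expect_identical(unlist(res$samples$x), unlist(full$samples$x)[61:100])
  expect_identical(res$state$pos, full$state$pos)
})
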