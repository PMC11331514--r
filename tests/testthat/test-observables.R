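test_that("RDF of a fixed 4-ion frame equals hand-computed shell counts", {
  fx <- make_fixture("square", side = 4)  # pair distances: 4 (x4) and 4*sqrt(2) (x2)
  rs <- rdf_init(fx$state$box, bin_width = 0.5)
  rs <- rdf_accumulate(rs, fx$state)
  tab <- rdf_table(rs)
  V <- fx$state$box$L^3
  shell <- function(lo) 4 / 3 * pi * ((lo + 0.5)^3 - lo^3)
  # unlike pairs: the four sides at distance 4 (bin [4, 4.5)); pairs_unlike = 4
  expect_equal(tab$g_pm[tab$r == 4.25], 4 / (4 * shell(4) / V))
  # like pairs: the two diagonals at 4 sqrt(2) = 5.657 (bin [5.5, 6)); pairs_like = 2
  expect_equal(tab$g_pp[tab$r == 5.75], 2 / (2 * shell(5.5) / V))
  expect_true(all(tab$g_pp[tab$r < 4] == 0))
  expect_true(all(tab$g_pm[tab$r < 4] == 0))
  # below the hard core every bin is empty by construction
  expect_true(all(tab$g_pm[tab$r < 3] == 0))
})

test_that("ideal near-uncharged hard-sphere gas gives flat g near 1", {
  # labelled hard spheres with negligible coupling (eps so large that
  # beta*u < 1e-5 everywhere): the low-density ideal limit
  m <- dielectric_ramp(eps_c = 1e6, eps_b = 1e6)
  box <- bulk_box(30)
  set.seed(21)
  st <- initialize_configuration(50, 50, box, m, seed = 21)
  sch <- mc_schedule(equil_sweeps = 200, prod_sweeps = 3000,
                     sample_stride = 5, step = 3, cluster_frac = 0,
                     tune = FALSE)
  run <- run_mc(st, sch, observers = list(frames = function(s) s$pos))
  rs <- rdf_init(box, bin_width = 1)
  fs <- run$state
  for (fr in run$samples$frames) { fs$pos <- fr; rs <- rdf_accumulate(rs, fs) }
  tab <- rdf_table(rs)
  sel <- tab$r > 4.5 & tab$r < 14
  expect_lt(max(abs(tab$g_nn[sel] - 1)), 0.08)
  expect_true(all(tab$g_pp[tab$r < 3] == 0))
})

test_that("g_nn/g_cc combinations equal the four-term species formulas", {
  set.seed(4)
  gpp_s <- runif(50); gmm_s <- runif(50)   # separate ++ and -- curves
  gpm_s <- runif(50); gmp_s <- gpm_s       # +- and -+ identical by symmetry
  g_pp <- (gpp_s + gmm_s) / 2
  g_pm <- (gpm_s + gmp_s) / 2
  d <- derive_gnn_gcc(g_pp, g_pm)
  expect_equal(d$g_nn, (gpp_s + gmm_s + gpm_s + gmp_s) / 4)
  expect_equal(d$g_cc, (gpm_s + gmp_s - gpp_s - gmm_s) / 4)
  expect_equal(derive_gnn_gcc(c(0, 1), c(2, 1))$g_nn, c(1, 1))
  expect_equal(derive_gnn_gcc(c(0, 1), c(2, 1))$g_cc, c(1, 0))
  expect_error(derive_gnn_gcc(1:3, 1:4), "mismatched")
})

test_that("cluster decomposition equals the graph-component oracle", {
  m <- dielectric_ramp()
  delta <- m$d + 0.5
  set.seed(31)
  for (k in 1:50) {
    L <- runif(1, 14, 30)
    n <- sample(6:24, 1)
    st <- initialize_configuration(ceiling(n / 2), floor(n / 2), bulk_box(L),
                                   m)
    # compact the gas a little so nontrivial clusters appear
    r <- mc_sweeps(st, 30, step = 1, cluster_frac = 0)
    part <- cluster_decomposition(r$state, delta)
    oracle <- ora_clusters(r$state$pos, L, delta)
    expect_true(same_partition(part$labels, oracle))
    expect_equal(sum(part$sizes), n)
  }
})

test_that("clusters may wrap the periodic box", {
  m <- dielectric_ramp()
  box <- bulk_box(20)
  # chain crossing the boundary: 19, 1 are 2 apart through the wall... use x
  pos <- rbind(c(19, 5, 5), c(2.2, 5, 5), c(5.4, 5, 5))
  st <- mc_state(pos, c(1, -1, 1), box, m)
  p <- cluster_decomposition(st, delta = 3.5)
  expect_equal(length(p$sizes), 1)
  expect_equal(p$sizes, 3L)
})

test_that("ion cluster-size distribution normalizes and matches hand counts", {
  tp <- make_fixture("two_pairs")
  p <- cluster_decomposition(tp$state)
  d <- cluster_size_distribution(p)
  expect_equal(d$p_ion[d$n_c == 2], 1)
  expect_equal(sum(d$p_ion), 1, tolerance = 1e-12)

  # all singletons
  m <- dielectric_ramp()
  st <- mc_state(rbind(c(5, 5, 5), c(15, 5, 5), c(25, 5, 5)), c(1, -1, 1),
                 bulk_box(32), m)
  d1 <- cluster_size_distribution(cluster_decomposition(st))
  expect_equal(d1$p_ion[1], 1)

  # mixed synthetic partitions across two frames:
  # frame A: sizes 2,2 (N=4); frame B: sizes 3,1 (N=4)
  pa <- structure(list(labels = c(1, 1, 2, 2), sizes = c(2L, 2L),
                       delta = 3.5, n = 4), class = "cluster_partition")
  pb <- structure(list(labels = c(1, 1, 1, 2), sizes = c(3L, 1L),
                       delta = 3.5, n = 4), class = "cluster_partition")
  d2 <- cluster_size_distribution(list(pa, pb))
  expect_equal(d2$p_ion, c((0 + 1 / 4) / 2, (1 + 0) / 2, (0 + 3 / 4) / 2))
  expect_equal(sum(d2$p_ion), 1, tolerance = 1e-12)
  expect_equal(mean_cluster_size(d2), 1 * 0.125 + 2 * 0.5 + 3 * 0.375)
})

test_that("Yukawa tail fitter: exact recovery, noise robustness, guards", {
  r <- seq(2, 30, by = 0.25)
  h <- 3 * exp(-r / 5) / r
  fit <- yukawa_tail_fit(r, h)
  expect_true(fit$applicable)
  expect_equal(fit$lambda, 5, tolerance = 1e-10)
  expect_equal(fit$amplitude, 3, tolerance = 1e-10)
  # negative-amplitude branch
  fitn <- yukawa_tail_fit(r, -h)
  expect_equal(fitn$lambda, 5, tolerance = 1e-10)
  expect_equal(fitn$amplitude, -3, tolerance = 1e-10)
  # 1% relative noise: lambda within 5% (median over replicates)
  set.seed(6)
  lams <- replicate(20, {
    yukawa_tail_fit(r, h * (1 + rnorm(length(r), sd = 0.01)))$lambda
  })
  expect_lt(max(abs(lams / 5 - 1)), 0.05)
  # oscillatory input signals fit-not-applicable
  osc <- yukawa_tail_fit(r, sin(r) * exp(-r / 5))
  expect_false(osc$applicable)
  expect_equal(osc$quality, "sign-change")
  # offset variant recovers the decay under a constant bias
  fb <- yukawa_tail_fit(r, h - 0.003, window = c(5, 15), offset = TRUE)
  expect_equal(fb$lambda, 5, tolerance = 1e-6)
  expect_equal(fb$offset, -0.003, tolerance = 1e-8)
})

test_that("phase-separation diagnostic classifies tails and flips at threshold", {
  r <- seq(10, 20, by = 0.25)
  flat <- phase_separation_diagnostic(r, rep(1, length(r)), window = c(10, 20))
  expect_equal(flat$class, "homogeneous")
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  declining <- 1.4 - 0.04 * (r - 10)  # 1.4 -> 1.0 across the window
  dd <- phase_separation_diagnostic(r, declining, window = c(10, 20))
  expect_equal(dd$class, "separated")
  expect_equal(dd$excess, 0.4, tolerance = 1e-10)

  # sweep the constructed slope through the threshold: classification flips
  # exactly where |slope| * window length crosses it
  for (excess in c(0.03, 0.049, 0.051, 0.2)) {
    g <- 1.3 - (excess / 10) * (r - 10)
    cl <- phase_separation_diagnostic(r, g, window = c(10, 20),
                                      slope_threshold = 0.05)$class
    expect_equal(cl, if (excess > 0.05) "separated" else "homogeneous")
  }
})

test_that("slit density profiles: normalization, counts, midplane estimate", {
  box <- slit_box(20, 30, sigma = 0)
  set.seed(41)
  # synthetic uniform frames: ideal gas between the walls
  frames <- replicate(200, cbind(runif(40, 0, 20), runif(40, 0, 20),
                                 runif(40, -13.5, 13.5)), simplify = FALSE)
  val <- rep(c(1, -1), 20)
  prof <- density_profiles(frames, val, box, d = 3, bin_width = 1)
  expect_equal(sum((prof$n_plus + prof$n_minus) * molar_to_density(1) *
                   attr(prof, "bin_width") * 400), 40, tolerance = 1e-10)
  target <- density_to_molar(20 / (400 * 27))
  expect_lt(max(abs((prof$n_plus - target) / target)), 0.25)  # noise only
  expect_equal(midplane_concentration(prof, width = 8),
               mean((prof$n_plus + prof$n_minus)[abs(prof$z) <= 4] / 2))
  # flat profile: midplane window choice is immaterial
  flat <- prof
  flat$n_plus <- rep(1, nrow(prof)); flat$n_minus <- rep(1, nrow(prof))
  expect_equal(midplane_concentration(flat, 5), 1)
  expect_equal(midplane_concentration(flat, 27), 1)
  # constructed double layer: midplane reports the plateau
  z <- prof$z
  dl <- prof
  dl$n_plus <- 0.5 + 2 * exp(-(13.5 - abs(z)) / 2)
  dl$n_minus <- 0.5 - 0.4 * exp(-(13.5 - abs(z)) / 2)
  expect_equal(midplane_concentration(dl, width = 4), 0.5, tolerance = 0.01)
})

test_that("local electroneutrality holds for a simulated homogeneous bulk", {
  sim <- run_uniform_025()
  tab <- sim$rdf
  lamD <- debye_length(0.25)
  # anchor the g_cc baseline on the far tail (canonical finite-size offset)
  base <- mean(tab$g_cc[tab$r > 6 * lamD])
  sel <- tab$r <= 5 * lamD
  q <- integrated_countercharge(tab$r[sel], tab$g_cc[sel] - base,
                                molar_to_density(0.25))
  expect_lt(abs(q - 1), 0.1)
})

test_that("co-ion exclusion shrinks and clusters grow with concentration", {
  deficit <- function(sim) {
    tab <- sim$rdf
    sel <- tab$r >= 3 & tab$r <= 12
    dr <- diff(tab$r)[1]
    sum(pmax(0, 1 - tab$g_pp[sel]) * dr)
  }
  d005 <- deficit(run_ramp_005())
  d05 <- deficit(run_ramp_05())
  d1 <- deficit(run_ramp_1M())
  expect_gt(d005, d05)
  # by 0.5 M the exclusion region has essentially vanished at this scale;
  # require monotonicity within bin noise
  expect_lt(d1, d05 + 0.05)
  # mean cluster size grows monotonically over the same scan
  m005 <- mean_cluster_size(run_ramp_005()$clusters)
  m05 <- mean_cluster_size(run_ramp_05()$clusters)
  m1 <- mean_cluster_size(run_ramp_1M()$clusters)
  expect_lt(m005, m05)
  expect_lt(m05, m1)
})

test_that("integrated countercharge has the right form on a Debye cloud", {
  # synthetic Debye-Hueckel g_cc integrates to ~1 e0 by construction
  n <- molar_to_density(0.25)
  lam <- debye_length(0.25)
  r <- seq(0.005, 60, by = 0.01)
  g_cc <- bjerrum_length(78.3) * exp(-r / lam) / r
  expect_equal(integrated_countercharge(r, g_cc, n), 1, tolerance = 1e-3)
})
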