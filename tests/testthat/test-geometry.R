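test_that("minimum image wraps periodic axes and leaves slit z unwrapped", {
  bb <- bulk_box(10)
  expect_equal(min_image(c(9, 0, 0), bb), c(-1, 0, 0))
  expect_equal(min_image(c(-9, 4.9, 0.2), bb), c(1, 4.9, 0.2))
  # tie at exactly L/2 resolves to the positive image
  expect_equal(min_image(c(5, -5, 0), bb), c(5, 5, 0))
  sb <- slit_box(10, 50)
  expect_equal(min_image(c(9, 0, 40), sb), c(-1, 0, 40))
  m <- matrix(c(9, 0, 40, 1, -6, 3), 2, 3, byrow = TRUE)
  expect_equal(min_image(m, sb), matrix(c(-1, 0, 40, 1, 4, 3), 2, 3,
                                        byrow = TRUE))
})

test_that("bulk pair energies are invariant under lattice translations", {
  m <- dielectric_ramp()
  box <- bulk_box(25)
  set.seed(5)
  st <- initialize_configuration(10, 10, box, m, seed = 5)
  e0 <- total_energy(st)
  for (shift in list(c(25, 0, 0), c(0, -25, 25), c(50, 25, -25))) {
    st2 <- mc_state(sweep(st$pos, 2, shift, "+"), st$valence, box, m)
    expect_equal(st2$beta_energy, e0, tolerance = 1e-10)
  }
})

test_that("minimum-image displacement norm is bounded by the cubic cell", {
  bb <- bulk_box(17)
  set.seed(8)
  dr <- matrix(runif(300, -100, 100), ncol = 3)
  w <- min_image(dr, bb)
  expect_true(all(sqrt(rowSums(w^2)) <= 17 * sqrt(3) / 2 + 1e-12))
  expect_true(all(abs(w) <= 17 / 2))
})

test_that("square-patch potential matches 2-D quadrature", {
  # (the in-plane singular point is checked against the exact closed form
  # below; adaptive quadrature cannot resolve it)
  cases <- list(c(1.5, -2, 3, 10), c(4, 4, 0.5, 10),
                c(0, 0, 7, 25), c(14, -3, 2, 10))
  for (p in cases) {
    f <- function(u, v) 1 / sqrt((p[1] - u)^2 + (p[2] - v)^2 + p[3]^2)
    q <- pracma::integral2(f, -p[4] / 2, p[4] / 2, -p[4] / 2, p[4] / 2,
                           reltol = 1e-10)$Q
    expect_equal(rpmmc:::cpp_patch_integral(p[1], p[2], p[3], p[4]), q,
                 tolerance = 1e-5)
  }
  # closed form at the center: 4 L ln(1 + sqrt(2))
  expect_equal(rpmmc:::cpp_patch_integral(0, 0, 0, 8), 4 * 8 * log(1 + sqrt(2)),
               tolerance = 1e-12)
})

test_that("charged-sheet correction: zero charge, large-L limit", {
  expect_identical(sheet_correction(2, 0, 1, 20), 0)
  expect_identical(sheet_correction(2, 1, 0, 20), 0)
  vals <- sapply(c(20, 50, 200, 2000), function(L)
    abs(sheet_correction(3, 1, -1, L, dxy = c(1, 2))))
  expect_true(all(diff(vals) < 0))   # decays toward zero as the patch grows
  expect_lt(vals[4], 0.02)
  expect_error(sheet_correction(2, 1, 1, -5), "positive")
})

test_that("slit total energy matches brute-force lateral image summation", {
  m <- dielectric_ramp()
  set.seed(7)
  for (L in c(12, 16, 20)) {
    repeat {
      pos <- cbind(runif(4, 0, L), runif(4, 0, L), runif(4, -4, 4))
      st <- tryCatch(mc_state(pos, c(1, -1, 1, -1), slit_box(L, 20, sigma = 0), m),
                     error = function(e) NULL)
      if (!is.null(st)) break
    }
    eb <- ora_slit_energy(pos, c(1, -1, 1, -1), L, M = 120)
    expect_equal(st$beta_energy, eb, tolerance = 1e-3)  # within 0.1%
  }
})

test_that("wall energy: hard exclusion outside, constant (zero) inside", {
  sl <- slit_box(20, 30, sigma_inverse = 70)
  expect_identical(wall_energy(13.51, 1, sl, d = 3), Inf)
  expect_identical(wall_energy(-13.6, -1, sl, d = 3), Inf)
  zz <- seq(-13.5, 13.5, by = 0.5)
  expect_true(all(wall_energy(zz, 1, sl, d = 3) == 0))
  s0 <- slit_box(20, 30, sigma = 0)
  expect_true(all(wall_energy(zz, 1, s0, d = 3) == 0))
})

test_that("slit construction enforces electroneutrality including wall charge", {
  m <- dielectric_ramp()
  L <- 16
  nc <- 4  # two extra cations per wall charge unit
  box <- slit_box(L, 30, sigma = -nc / (2 * L^2))
  pos <- cbind(rep(c(1, 5, 9, 13), 2), rep(c(2, 9), each = 4),
               rep(c(-5, 5), 4))
  st <- mc_state(pos, c(rep(1, 6), rep(-1, 2)), box, m)
  expect_s3_class(st, "mc_state")
  expect_error(mc_state(pos, c(rep(1, 4), rep(-1, 4)), box, m),
               "electroneutral")
})
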