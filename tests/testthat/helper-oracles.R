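# Independent oracles used by the tests: plain-R brute-force energies,
# graph-library cluster decomposition, quadrature reference distributions.
# These deliberately re-derive the physics by a different route than the
# package's compiled kernels.

# CODATA constants, restated independently of the package internals
ORA <- list(e0 = 1.602176634e-19, eps0 = 8.8541878128e-12,
            kB = 1.380649e-23, NAv = 6.02214076e23)

ora_bjerrum <- function(eps, Temp) {
  1e10 * ORA$e0^2 / (4 * pi * ORA$eps0 * eps * ORA$kB * Temp)
}

ora_eps_ramp <- function(r, d, delta, eps_c, eps_b) {
  ifelse(r <= d, eps_c,
         ifelse(r >= d + delta, eps_b,
                eps_c + (eps_b - eps_c) * (r - d) / delta))
}

# minimum-image displacement by explicit search over the 27 neighbour cells
ora_mi_dist <- function(ri, rj, L, slit = FALSE) {
  sh <- if (slit) expand.grid(sx = -1:1, sy = -1:1, sz = 0)
        else expand.grid(sx = -1:1, sy = -1:1, sz = -1:1)
  d0 <- ri - rj
  min(sqrt((d0[1] + sh$sx * L)^2 + (d0[2] + sh$sy * L)^2 +
           (d0[3] + sh$sz * L)^2))
}

# brute-force bulk energy (kT): explicit nearest-image search, explicit ramp
ora_bulk_energy <- function(pos, val, L, d = 3, delta = 3, eps_c = 23,
                            eps_b = 78.3, Temp = 298) {
  n <- nrow(pos)
  if (n < 2) return(0)
  lb1 <- ora_bjerrum(1, Temp)
  E <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- ora_mi_dist(pos[i, ], pos[j, ], L)
    if (r < d) return(Inf)
    E <- E + val[i] * val[j] * lb1 / ora_eps_ramp(r, d, delta, eps_c, eps_b) / r
  }
  E
}

# brute-force slit energy: minimum-image ramp term plus an explicit sum over
# lateral periodic images (Coulomb at eps_b), grouped by image cell and
# Richardson-extrapolated in the cutoff (the raw sum converges only ~1/M)
ora_slit_energy_at_M <- function(pos, val, L, M, d = 3, delta = 3,
                                 eps_c = 23, eps_b = 78.3, Temp = 298) {
  lb1 <- ora_bjerrum(1, Temp)
  lbb <- lb1 / eps_b
  n <- nrow(pos)
  mi <- function(x) x - L * round(x / L)
  E <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- mi(pos[i, 1] - pos[j, 1]); dy <- mi(pos[i, 2] - pos[j, 2])
    dz <- pos[i, 3] - pos[j, 3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    E <- E + val[i] * val[j] * lb1 /
      ora_eps_ramp(r, d, delta, eps_c, eps_b) / r
  }
  g <- expand.grid(nn = -M:M, mm = -M:M)
  g <- g[!(g$nn == 0 & g$mm == 0), ]
  sx <- g$nn * L; sy <- g$mm * L
  for (i in 1:n) for (j in 1:n) {
    dx <- if (i == j) 0 else mi(pos[i, 1] - pos[j, 1])
    dy <- if (i == j) 0 else mi(pos[i, 2] - pos[j, 2])
    dz <- pos[i, 3] - pos[j, 3]
    E <- E + 0.5 * lbb * val[i] * val[j] *
      sum(1 / sqrt((dx + sx)^2 + (dy + sy)^2 + dz^2))
  }
  E
}

ora_slit_energy <- function(pos, val, L, M = 120, ...) {
  e1 <- ora_slit_energy_at_M(pos, val, L, M %/% 2, ...)
  e2 <- ora_slit_energy_at_M(pos, val, L, M, ...)
  2 * e2 - e1
}

# vectorized variant for large frames: full MI distance matrix + igraph
ora_clusters_fast <- function(pos, L, delta) {
  mi <- function(d) d - L * round(d / L)
  dx <- mi(outer(pos[, 1], pos[, 1], "-"))
  dy <- mi(outer(pos[, 2], pos[, 2], "-"))
  dz <- mi(outer(pos[, 3], pos[, 3], "-"))
  adj <- sqrt(dx^2 + dy^2 + dz^2) <= delta
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(gr)$membership
}

# cluster decomposition via igraph connected components (BFS oracle)
ora_clusters <- function(pos, L, delta, slit = FALSE) {
  n <- nrow(pos)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- adj[j, i] <-
      ora_mi_dist(pos[i, ], pos[j, ], L, slit) <= delta
  }
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(gr)$membership
}

# two partitions describe the same clustering (labels up to renaming):
# canonicalize by replacing each label with the smallest member index
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(ave(seq_along(a), a, FUN = min), ave(seq_along(b), b, FUN = min))
}

# Boltzmann pair-distance density for two unlike ions in a periodic cube,
# restricted to r < L/2 (where the ideal measure is exactly 4 pi r^2 / V)
ora_pair_distance_density <- function(model, Temp, L, edges) {
  lb1 <- ora_bjerrum(1, Temp)
  f <- function(r) {
    u <- ifelse(r < model$d, Inf,
                -lb1 / ora_eps_ramp(r, model$d, model$delta, model$eps_c,
                                    model$eps_b) / r)
    ifelse(is.finite(u), 4 * pi * r^2 * exp(-u), 0)
  }
  probs <- vapply(seq_len(length(edges) - 1), function(k)
    integrate(f, edges[k], edges[k + 1], rel.tol = 1e-10)$value, numeric(1))
  probs / sum(probs)
}
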