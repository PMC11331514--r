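# Deterministic micro-configurations and synthetic curves for testing every
# operation without external data. Expected metadata values are computed by
# the plain-R brute-force routines at the bottom of this file (explicit
# double loops over all periodic considerations), independent of the
# compiled energy path.

#' Deterministic test fixtures
#'
#' Generates small hand-checkable configurations and synthetic observable
#' curves, each with independently brute-force-computed expected values
#' attached as metadata. Available fixtures:
#' \describe{
#'   \item{unlike_pair}{a +1/-1 pair at separation \code{r} in a bulk box;
#'     expected pair energy attached.}
#'   \item{square}{4 alternating charges on a square of side \code{side};
#'     expected total energy attached.}
#'   \item{chain3}{three ions in a chain with consecutive gaps \code{gap};
#'     expected single 3-cluster under delta >= gap.}
#'   \item{two_pairs}{two well-separated tight pairs; expected
#'     P_ion(2) = 1.}
#'   \item{gas}{seeded random 1:1 gas of \code{n_pairs} pairs at molarity
#'     \code{molarity}.}
#'   \item{yukawa_curve}{synthetic h(r) = A exp(-r/lambda)/r sampled on bins,
#'     optionally with relative Gaussian noise.}
#' }
#'
#' @param name fixture name (see Details).
#' @param ... fixture parameters: \code{r}, \code{side}, \code{gap},
#'   \code{L}, \code{n_pairs}, \code{molarity}, \code{A}, \code{lambda},
#'   \code{noise}, \code{seed}, \code{model}, \code{temperature}.
#' @return list with the configuration (\code{state}, or \code{r}/\code{h}
#'   for curves) and an \code{expected} metadata list.
#' @export
make_fixture <- function(name, ...) {
  args <- list(...)
  model <- args$model %||% dielectric_ramp()
  temperature <- args$temperature %||% 298
  switch(
    name,
    unlike_pair = {
      r <- args$r %||% 3
      L <- args$L %||% 40
      box <- bulk_box(L)
      pos <- rbind(c(L / 2 - r / 2, L / 2, L / 2),
                   c(L / 2 + r / 2, L / 2, L / 2))
      st <- mc_state(pos, c(1, -1), box, model, temperature)
      list(state = st,
           expected = list(
             pair_energy = .brute_bulk_energy(pos, c(1, -1), L, model,
                                              temperature),
             separation = r))
    },
    square = {
      side <- args$side %||% 4
      L <- args$L %||% 40
      box <- bulk_box(L)
      c0 <- L / 2
      pos <- rbind(c(c0, c0, c0), c(c0 + side, c0, c0),
                   c(c0 + side, c0 + side, c0), c(c0, c0 + side, c0))
      val <- c(1, -1, 1, -1)
      st <- mc_state(pos, val, box, model, temperature)
      list(state = st,
           expected = list(
             total_energy = .brute_bulk_energy(pos, val, L, model,
                                               temperature)))
    },
    chain3 = {
      gap <- args$gap %||% 3.2
      L <- args$L %||% 40
      box <- bulk_box(L)
      c0 <- L / 2
      pos <- rbind(c(c0 - gap, c0, c0), c(c0, c0, c0), c(c0 + gap, c0, c0))
      st <- mc_state(pos, c(1, -1, 1), box, model, temperature)
      list(state = st,
           expected = list(cluster_sizes_at = function(delta)
             if (delta >= gap) 3L else c(1L, 1L, 1L)))
    },
    two_pairs = {
      r <- args$r %||% 3.1
      L <- args$L %||% 40
      box <- bulk_box(L)
      pos <- rbind(c(5, 5, 5), c(5 + r, 5, 5),
                   c(25, 25, 25), c(25 + r, 25, 25))
      st <- mc_state(pos, c(1, -1, 1, -1), box, model, temperature)
      list(state = st, expected = list(p_ion_2 = 1))
    },
    gas = {
      n_pairs <- args$n_pairs %||% 100
      molarity <- args$molarity %||% 0.5
      seed <- args$seed %||% 1L
      L <- args$L %||% (2 * n_pairs / molar_to_density(2 * molarity))^(1 / 3)
      box <- bulk_box(L)
      st <- initialize_configuration(n_pairs, n_pairs, box, model,
                                     temperature, seed = seed)
      list(state = st, expected = list(L = L, molarity = molarity))
    },
    yukawa_curve = {
      A <- args$A %||% 3
      lambda <- args$lambda %||% 5
      noise <- args$noise %||% 0
      seed <- args$seed %||% 1L
      r <- args$r %||% seq(2, 30, by = 0.25)
      h <- A * exp(-r / lambda) / r
      if (noise > 0) {
        set.seed(seed)
        h <- h * (1 + rnorm(length(r), sd = noise))
      }
      list(r = r, h = h, expected = list(A = A, lambda = lambda))
    },
    stop(sprintf("unknown fixture '%s'", name))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force bulk energy: explicit nearest-image search over the 27
# neighbour cells (no arithmetic minimum-image shortcut), explicit piecewise
# permittivity. Independent of the compiled path; O(27 N^2), fixtures only.
.brute_bulk_energy <- function(pos, valence, L, model, temperature) {
  n <- nrow(pos)
  lb1 <- bjerrum_length(1, temperature)
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1)) * L
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d0 <- pos[i, ] - pos[j, ]
      rr <- min(sqrt(rowSums(sweep(shifts, 2, d0, "+")^2)))
      eps <- if (rr <= model$d) model$eps_c
             else if (rr >= model$d + model$delta) model$eps_b
             else model$eps_c + (model$eps_b - model$eps_c) *
                    (rr - model$d) / model$delta
      e <- e + if (rr < model$d) Inf
               else valence[i] * valence[j] * (lb1 / eps) / rr
    }
  }
  e
}
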