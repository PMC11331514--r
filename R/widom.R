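#' Settings for ghost-pair (Widom-type) screening estimation
#'
#' @param separations vector of ghost-pair separations r_k (Angstrom); must
#'   lie strictly between the ion diameter and L/2 of the frames they will be
#'   inserted into. The largest separation serves as the free-energy
#'   reference.
#' @param insertions ghost-pair insertions per frame per separation.
#' @param charge test-charge magnitude in e0 (the pair is +q/-q).
#' @return object of class \code{widom_settings}.
#' @export
widom_settings <- function(separations, insertions = 200, charge = 1) {
  stopifnot(length(separations) >= 2, all(diff(sort(separations)) > 0),
            insertions >= 1)
  structure(list(separations = sort(separations),
                 insertions = as.integer(insertions), charge = charge),
            class = "widom_settings")
}

#' Ghost-pair insertion free energy versus separation
#'
#' For each separation r_k, a +q/-q ghost pair is inserted at random positions
#' and orientations into each stored (never perturbed) equilibrium frame; the
#' Boltzmann factor of the total insertion energy (ghost-medium, with the same
#' ramp potential and hard core as real ions, plus the direct ghost-ghost
#' term) is averaged, and
#' \eqn{w(r_k) = -\ln\langle e^{-\beta \Delta U}\rangle} is reported relative
#' to the largest separation. In an empty box w reduces to the bare pair
#' interaction (shifted); in the Debye-Huckel regime w is the screened
#' Coulomb interaction, so its decay length estimates the screening length.
#'
#' @param frames list of N x 3 bulk position matrices.
#' @param valence ion valences matching the frames.
#' @param box a \code{\link{bulk_box}}.
#' @param model a \code{\link{dielectric_ramp}}.
#' @param settings a \code{\link{widom_settings}}.
#' @param temperature temperature in K.
#' @return object of class \code{widom_table}: data frame with \code{r} and
#'   \code{w} (k_B T); per-frame means kept as an attribute for
#'   bootstrapping.
#' @export
pair_insertion_free_energy <- function(frames, valence, box, model, settings,
                                       temperature = 298) {
  stopifnot(inherits(box, "bulk_box"), inherits(settings, "widom_settings"),
            length(frames) >= 1)
  rks <- settings$separations
  if (any(rks <= model$d) || any(rks >= box$L / 2))
    stop("separations must lie strictly between d and L/2")
  gl <- .geom_clist(box, model)
  ml <- .model_clist(model, temperature)
  nk <- length(rks)
  per_frame <- matrix(NA_real_, nrow = length(frames), ncol = nk)
  for (f in seq_along(frames)) {
    s <- cpp_widom_pair(frames[[f]], valence, gl, ml, rks,
                        settings$insertions, settings$charge)
    per_frame[f, ] <- s / settings$insertions
  }
  bmean <- colMeans(per_frame)
  if (any(bmean <= 0))
    stop("all insertions overlapped at some separation: system too dense ",
         "for this insertion budget")
  w <- -log(bmean)
  w <- w - w[nk]  # reference at the largest separation
  out <- data.frame(r = rks, w = w)
  attr(out, "per_frame") <- per_frame
  attr(out, "settings") <- settings
  attr(out, "reference") <- rks[nk]
  class(out) <- c("widom_table", "data.frame")
  out
}

#' Effective screening length from a ghost-pair free-energy table
#'
#' Fits \eqn{w(r) = -A e^{-r/\lambda}/r + C} (the screened interaction
#' between the ghost charges; the free offset \eqn{C} absorbs the reference
#' subtraction and its noise), seeded by a log-linear fit of
#' \eqn{\ln(r |w|)}; the reference point (w = 0 by construction) is
#' excluded. Bootstrap resampling over frames provides the uncertainty.
#' Non-monotone \eqn{|w| r} profiles (oscillatory regime) are flagged but
#' still yield an effective length; a decay slower than the no-screening
#' cutoff returns \code{lambda = Inf} with a flag.
#'
#' @param w_table a \code{\link{pair_insertion_free_energy}} result, or any
#'   data frame with columns \code{r} and \code{w}.
#' @param n_boot bootstrap replicates over frames (0 to skip).
#' @return object of class \code{screening_estimate} with \code{lambda},
#'   \code{amplitude}, bootstrap \code{lambda_se} and CI, and a quality flag.
#' @export
effective_screening_length <- function(w_table, n_boot = 200) {
  r <- w_table$r; w <- w_table$w
  refr <- attr(w_table, "reference")
  keep <- if (is.null(refr)) w != 0 else r != refr
  fit1 <- .fit_w_decay(r[keep], w[keep])
  est <- structure(list(lambda = fit1$lambda, amplitude = fit1$amplitude,
                        offset = fit1$offset,
                        lambda_se = NA_real_, lambda_ci = c(NA, NA),
                        window = range(r[keep]), r_squared = fit1$r_squared,
                        method = "widom-pair", applicable = fit1$applicable,
                        quality = fit1$quality, n_points = sum(keep)),
                   class = "screening_estimate")
  pf <- attr(w_table, "per_frame")
  if (!is.null(pf) && n_boot > 0 && nrow(pf) > 1 && est$applicable &&
      is.finite(est$lambda)) {
    nf <- nrow(pf); nk <- ncol(pf)
    lam <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nf, nf, replace = TRUE)
      m <- colMeans(pf[idx, , drop = FALSE])
      if (any(m <= 0)) next
      wb <- -log(m); wb <- wb - wb[nk]
      fb <- .fit_w_decay(r[keep], wb[keep])
      if (fb$applicable && is.finite(fb$lambda)) lam[b] <- fb$lambda
    }
    lam <- lam[is.finite(lam)]
    if (length(lam) >= 10) {
      est$lambda_se <- sd(lam)
      est$lambda_ci <- unname(quantile(lam, c(0.025, 0.975)))
    }
  }
  est
}

# core decay fit shared by the point estimate and the bootstrap:
# log-linear prefit (slope/no-screening gate) then nls with a free offset
.fit_w_decay <- function(r, w) {
  out <- list(lambda = NA_real_, amplitude = NA_real_, offset = NA_real_,
              r_squared = NA_real_, applicable = FALSE, quality = "ok")
  ok <- is.finite(w) & w != 0
  if (sum(ok) < 3) { out$quality <- "too-few-points"; return(out) }
  r <- r[ok]; w <- w[ok]
  sgn <- sign(w)
  if (length(unique(sgn)) > 1) out$quality <- "mixed-sign"
  y <- log(r * abs(w))
  # non-monotone |w|*r against r indicates an oscillatory regime
  if (out$quality == "ok" && any(diff(y[order(r)]) > 1e-12))
    out$quality <- "non-monotone"
  pre <- lm(y ~ r)
  slope <- coef(pre)[[2]]
  out$r_squared <- suppressWarnings(summary(pre)$r.squared)
  out$amplitude <- -sgn[1] * exp(coef(pre)[[1]])
  if (slope >= -1 / (10 * max(r))) {
    out$lambda <- Inf
    out$quality <- "no-screening"
    return(out)
  }
  out$lambda <- -1 / slope
  out$offset <- 0
  out$applicable <- TRUE
  if (length(r) >= 4) {
    # profiled least squares: for fixed lambda the amplitude and offset
    # solve a 2x2 linear system, so only lambda is optimized numerically
    # (same objective as a full nonlinear fit, but exact and fast)
    rss <- function(lambda) {
      b <- exp(-r / lambda) / r
      f <- stats::lm.fit(cbind(b, 1), w)
      sum(f$residuals^2)
    }
    lam0 <- out$lambda
    opt <- tryCatch(
      stats::optimize(rss, interval = c(0.2 * lam0, 30 * lam0),
                      tol = 1e-7 * lam0),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$minimum) && opt$minimum > 0) {
      lam <- opt$minimum
      b <- exp(-r / lam) / r
      cf <- stats::lm.fit(cbind(b, 1), w)$coefficients
      out$lambda <- lam
      out$amplitude <- -cf[[1]]  # A in w = -A exp(-r/lambda)/r + C
      out$offset <- cf[[2]]
    }
  }
  out
}
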