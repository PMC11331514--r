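#' Default run configuration
#'
#' The configuration dialect is YAML with five blocks (model, thermo,
#' geometry, schedule, observables) plus a seed. Defaults are the standard
#' state point of the modified model: d = 3 A, delta = 3 A, eps_c = 23,
#' eps_b = 78.3, T = 298 K, cluster criterion delta = d + 0.5 A. Molarity and
#' explicit counts are mutually exclusive inputs; the slit wall charge is
#' entered as the inverse area per unit charge (sigma_inverse = 70 means
#' sigma = -1/70 e0/A^2).
#'
#' @return nested configuration list of class \code{rpmmc_config}.
#' @export
default_config <- function() {
  structure(list(
    model = list(d = 3, delta = 3, eps_c = 23, eps_b = 78.3),
    thermo = list(temperature = 298, molarity = NULL,
                  n_plus = NULL, n_minus = NULL),
    geometry = list(type = "bulk", L = 60, H = NULL, sigma_inverse = NULL),
    schedule = list(equil_sweeps = 2000, prod_sweeps = 10000,
                    sample_stride = 10, step = 1.5, cluster_frac = 0.1,
                    cluster_step = 2, delta_mv = NULL, cluster_max = NULL),
    observables = list(rdf_bin = 0.1, cluster_delta = NULL,
                       profile_bin = 0.5, fit_window = NULL),
    seed = 1L
  ), class = "rpmmc_config")
}

#' Parse and validate a run configuration file
#'
#' Reads a YAML configuration, applies defaults for absent keys, rejects
#' unknown keys, and validates field values with field-level messages.
#'
#' @param path YAML file path.
#' @return validated configuration list of class \code{rpmmc_config}.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname parse_config
#' @param cfg a raw configuration list (e.g. already-parsed YAML).
#' @export
validate_config <- function(cfg) {
  def <- unclass(default_config())
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in setdiff(names(def), "seed")) {
    extra <- setdiff(names(cfg[[blk]]), names(def[[blk]]))
    if (length(extra))
      stop(sprintf("unknown key(s) in '%s': %s", blk,
                   paste(extra, collapse = ", ")))
    def[[blk]] <- modifyList(def[[blk]], cfg[[blk]] %||% list(),
                             keep.null = TRUE)
  }
  if (!is.null(cfg$seed)) def$seed <- as.integer(cfg$seed)
  m <- def$model
  if (m$d <= 0) stop("model$d must be positive")
  if (m$delta <= 0) stop("model$delta must be positive")
  if (m$eps_c < 1) stop("model$eps_c must be >= 1")
  if (m$eps_c > m$eps_b) stop("model$eps_c must not exceed model$eps_b")
  th <- def$thermo
  if (th$temperature <= 0) stop("thermo$temperature must be positive")
  has_mol <- !is.null(th$molarity)
  has_counts <- !is.null(th$n_plus) || !is.null(th$n_minus)
  if (has_mol && has_counts)
    stop("thermo: molarity and explicit counts are mutually exclusive")
  if (!has_mol && !has_counts)
    stop("thermo: give either molarity or n_plus/n_minus")
  g <- def$geometry
  if (!g$type %in% c("bulk", "slit")) stop("geometry$type must be bulk or slit")
  if (g$L <= 0) stop("geometry$L must be positive")
  if (g$type == "slit") {
    if (is.null(g$H) || g$H <= m$d)
      stop("geometry$H must be given and exceed the ion diameter")
  }
  s <- def$schedule
  if (s$cluster_frac < 0 || s$cluster_frac > 1)
    stop("schedule$cluster_frac must be in [0, 1]")
  if (s$step <= 0 || s$cluster_step <= 0)
    stop("schedule step sizes must be positive")
  structure(def, class = "rpmmc_config")
}

#' Serialize a configuration to YAML
#'
#' @param cfg an \code{rpmmc_config}.
#' @param path output file.
#' @return the path, invisibly. Round-trips through
#'   \code{\link{parse_config}}.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(.drop_null(unclass(cfg)), path)
  invisible(path)
}

.drop_null <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, .drop_null)
  x[!vapply(x, is.null, logical(1))]
}
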