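# Observable tables (TSV with '#' metadata headers), XYZ snapshots, and run
# manifests.

.write_tsv_with_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, paste(format(meta[[nm]]), collapse = " ")),
               con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write observable tables
#'
#' Tab-separated tables with \code{#}-prefixed metadata header lines
#' recording the parameter set and seed: \code{rdf.tsv} (r, g_pp, g_pm, g_nn,
#' g_cc), \code{clusters.tsv} (n_c, p_ion), \code{profile.tsv} (z, n_plus,
#' n_minus, dn), and \code{fits.tsv} (method, lambda, amplitude, window,
#' diagnostics).
#'
#' @param df the table to write (see the corresponding compute functions).
#' @param path output file.
#' @param meta named list written as \code{# key: value} header lines.
#' @return the path, invisibly.
#' @export
write_rdf_tsv <- function(df, path, meta = list()) {
  .write_tsv_with_meta(df, path, meta)
}

#' @rdname write_rdf_tsv
#' @export
write_clusters_tsv <- function(df, path, meta = list()) {
  .write_tsv_with_meta(df, path, meta)
}

#' @rdname write_rdf_tsv
#' @export
write_profile_tsv <- function(df, path, meta = list()) {
  .write_tsv_with_meta(df, path, meta)
}

#' @rdname write_rdf_tsv
#' @param fits list of \code{screening_estimate} objects (for
#'   \code{write_fits_tsv}).
#' @export
write_fits_tsv <- function(fits, path, meta = list()) {
  if (inherits(fits, "screening_estimate")) fits <- list(fits)
  df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(method = f$method, lambda = f$lambda,
               amplitude = f$amplitude, lambda_se = f$lambda_se,
               window_lo = f$window[1], window_hi = f$window[2],
               r_squared = f$r_squared, applicable = f$applicable,
               quality = f$quality)
  }))
  .write_tsv_with_meta(df, path, meta)
}

#' Read a TSV observable table (skipping metadata lines)
#'
#' @param path file written by one of the \code{write_*_tsv} functions.
#' @return data frame.
#' @export
read_tsv_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write / read an XYZ snapshot
#'
#' Cations are tagged CAT and anions ANI for visualization.
#'
#' @param state an \code{mc_state}.
#' @param path file path.
#' @param comment second-line comment.
#' @return \code{read_xyz} returns a list with \code{pos} and
#'   \code{valence}.
#' @export
write_xyz <- function(state, path, comment = "") {
  n <- nrow(state$pos)
  tags <- ifelse(state$valence > 0, "CAT", "ANI")
  lines <- c(as.character(n), comment,
             sprintf("%s %.8f %.8f %.8f", tags,
                     state$pos[, 1], state$pos[, 2], state$pos[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  parts <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  valence <- ifelse(vapply(parts, `[`, character(1), 1) == "CAT", 1, -1)
  list(pos = pos, valence = valence)
}

#' Write a run manifest
#'
#' YAML record of the resolved configuration, seed, package version and
#' runtime, sufficient to regenerate the run's outputs.
#'
#' @param cfg resolved \code{rpmmc_config}.
#' @param path output file.
#' @param extra named list of additional entries (runtimes, acceptance
#'   rates).
#' @return the path, invisibly.
#' @export
write_manifest <- function(cfg, path, extra = list()) {
  man <- c(list(package = "rpmmc",
                version = as.character(packageVersion("rpmmc")),
                date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                config = .drop_null(unclass(cfg))),
           extra)
  yaml::write_yaml(man, path)
  invisible(path)
}
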