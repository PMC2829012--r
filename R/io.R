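# Draw archives: kept sweeps as rectangular TSV plus a key-value metadata
# sidecar sufficient to re-execute the run.

#' Write posterior draws to a directory
#'
#' Writes `m.tsv` (one row per kept sweep, one column per gene), a
#' `latent.tsv` with the scalar latent chains the model produced (DPB: `N`;
#' DMB: `lambda`, `u_total`; MD: `r`, `m0`), and `meta.txt` with the seed,
#' prior, chain settings and the clamped-draw counter.
#'
#' @param draws A `posterior_draws` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_draws <- function(draws, dir) {
  stopifnot(inherits(draws, "posterior_draws"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(format(draws$m, digits = 10, trim = TRUE, scientific = TRUE),
              file.path(dir, "m.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  scalars <- Filter(function(x) is.null(dim(x)), draws$latent)
  if (length(scalars)) {
    write.table(as.data.frame(scalars), file.path(dir, "latent.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  alpha <- draws$prior$alpha
  meta <- c(
    model = draws$model,
    prior_alpha = if (is.character(alpha)) alpha else "custom",
    gamma_shape = draws$prior$gamma_shape,
    gamma_scale = draws$prior$gamma_scale,
    n_iterations = draws$config$n_iterations,
    burn_in = draws$config$burn_in,
    thin = draws$config$thin,
    seed = draws$config$seed,
    kept = nrow(draws$m),
    clamped_draws = draws$clamps
  )
  writeLines(paste(names(meta), meta, sep = ": "),
             file.path(dir, "meta.txt"))
  if (draws$clamps > 0) {
    warning(draws$clamps, " Dirichlet draws were clamped away from zero")
  }
  invisible(dir)
}
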