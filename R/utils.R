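# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed when `seed` is non-NULL, restoring
# the caller's RNG state afterwards so simulation helpers stay composable.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      abort("`seed` must be a single finite number or NULL.")
    }
    withr::with_seed(as.integer(seed), code)
  }
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s.", name, format(lower)))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s.", name, format(lower)))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s.", name, format(upper)))
  }
  invisible(x)
}

# Short md5 fingerprint of an R object (via its canonical JSON form), used to
# stamp output files so runs can be traced back to their configuration.
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}

pkg_version <- function() {
  as.character(utils::packageVersion("adiagait"))
}
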