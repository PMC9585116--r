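# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

expo_abort <- function(msg, class = "expo_error", ...) {
  rlang::abort(msg, class = c(class, "expo_error"), ...)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    expo_abort(sprintf("`%s` must be a single positive number, got %s.",
                       name, paste(format(x), collapse = ", ")),
               class = "expo_argument_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    expo_abort(sprintf("`%s` must be a single integer >= %d.", name, min),
               class = "expo_argument_error")
  }
  invisible(as.integer(x))
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    expo_abort(sprintf("`%s` is missing required column(s): %s.",
                       name, paste(missing, collapse = ", ")),
               class = "expo_schema_error")
  }
  invisible(df)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed_ <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Relative mass error in parts per million
#'
#' @param observed Observed neutral mass in Da.
#' @param reference Reference mass in Da (the denominator).
#' @return `(observed - reference) / reference * 1e6`, vectorised.
#' @export
ppm_error <- function(observed, reference) {
  (observed - reference) / reference * 1e6
}

# ppm distance between two experimental masses, using the smaller mass as
# denominator (the conservative convention for pairwise comparison).
ppm_between <- function(mass1, mass2) {
  abs(mass1 - mass2) / pmin(mass1, mass2) * 1e6
}

jaccard_similarity <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
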