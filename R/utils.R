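# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, then restores the caller's RNG state so
#' that seeded package internals never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derived from a master seed plus an arbitrary path of
# labels, e.g. derive_seed(seed, "profile", subject). Keeps the hierarchical
# RNG split independent of generation order; result always < 2^31.
derive_seed <- function(seed, ...) {
  parts <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                 collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# stop() with sprintf formatting and no call in the condition.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_square <- function(x) is.matrix(x) && nrow(x) == ncol(x)

check_finite_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) abort("%s must be a numeric matrix", what)
  if (any(!is.finite(x))) abort("%s contains NaN/Inf entries", what)
  invisible(x)
}

# Symmetrize against roundoff before handing a matrix to the symmetric
# eigensolver.
sym <- function(x) (x + t(x)) / 2

max_abs <- function(x) max(abs(x))
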