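# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Restores the caller's RNG state afterwards so that seeded helpers do not
#' perturb the global random stream.
#' @param seed integer seed, or NULL to use the current stream.
#' @param code expression to evaluate.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; keeps results independent across
# (subject, trial) while reproducible from one master seed. Stays < 2^31.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  x <- as.double(seed %% 2147483647L)
  for (k in seq_along(ids)) {
    x <- (x * 48271 + as.double(ids[k]) * 2654435761 %% 2147483647 + k * 7919) %%
      2147483647
  }
  as.integer(x %% 2147483646) + 1L
}

# argument validation with a consistent error class
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("mibmi_invalid_argument", "error")))
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_invalid(name, " must be a finite scalar in [", lower, ", ", upper, "]")
  invisible(x)
}

# half-open interval membership on a numeric grid, guarded against FP noise
fuzzy_leq <- function(a, b, tol = 1e-9) a <= b + tol
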