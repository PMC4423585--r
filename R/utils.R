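#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the previous RNG state
#' so that generators are pure functions of their seed arguments without
#' disturbing the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-stream seed below 2^31 from a master seed.
# Plain LCG-style mixing, exact in double precision.
derive_seed <- function(master, index, stream = 0L) {
  m <- 2147483629
  x <- (abs(as.double(master)) %% m)
  x <- (x * 48271 + as.double(index) * 69621 + as.double(stream) * 40014 + 1) %% m
  as.integer(x)
}

stop_icv <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "icvsampler_error")))
}

check_numeric_vector <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop_icv(sprintf("`%s` must be a finite numeric vector", name),
             "icv_input_error")
  if (positive && any(x <= 0))
    stop_icv(sprintf("`%s` must be strictly positive", name),
             "icv_input_error")
  invisible(x)
}
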