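`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG state so library calls never disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_domain(name, " must be a probability in [0, 1]")
  invisible(x)
}

zscore <- function(x, center = NULL, scale = NULL) {
  center <- center %||% mean(x, na.rm = TRUE)
  scale <- scale %||% sd(x, na.rm = TRUE)
  if (!is.finite(scale) || scale == 0) scale <- 1  # constant input: z = 0
  list(z = (x - center) / scale, center = center, scale = scale)
}
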