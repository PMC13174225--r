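#' Derive child seeds from a root seed
#'
#' Every stochastic stage of the pipeline takes an explicit integer seed. To
#' run many stages from a single run-level seed without correlated streams,
#' this fans a root seed out into `n` child seeds deterministically.
#'
#' @param seed Integer root seed.
#' @param n Number of child seeds required.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  # linear congruential fan-out; stays well inside 32-bit integer range
  s <- as.double(seed %% 2147483647)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647
    out[i] <- s
  }
  as.integer(ifelse(out == 0, 1, out))
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("interax_config_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("interax_numeric_error", "error")))
}
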