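#' Derive a child seed from a base seed and a stream label
#'
#' A single user-facing seed feeds every stochastic stage of the pipeline.
#' Stage- and cell-level streams are derived deterministically from it so a
#' stage can be rerun in isolation and still reproduce the full-pipeline
#' result, independent of execution order.
#'
#' @param seed integer base seed.
#' @param label character scalar naming the stream (e.g. `"detect/cell_3"`).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
spawn_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  # small deterministic string hash (polynomial rolling, 31-bit)
  h <- 0
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% 2147483629
  }
  as.integer((abs(seed) + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  ok_lo <- if (lower_open) x > lower else x >= lower
  ok_hi <- if (upper_open) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop(sprintf(
      "'%s' = %g out of range %s%g, %g%s", name, x,
      if (lower_open) "(" else "[", lower, upper,
      if (upper_open) ")" else "]"
    ), call. = FALSE)
  }
  invisible(x)
}
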