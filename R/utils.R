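#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a parent seed
#'
#' All stochastic entry points take an integer `seed`; internal stages derive
#' disjoint child seeds from it so that one experiment seed fans out to fold
#' assignment, weight initialisation and shuffling reproducibly. Kept below
#' 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed integer parent seed.
#' @param offset small non-negative integer identifying the consumer.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483629L)
}

stop_drusenseq <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "drusenseq_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_that <- function(cond, msg, class = "drusenseq_invalid") {
  if (!isTRUE(cond)) stop_drusenseq(msg, class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
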