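#' @useDynLib wmh2view, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd qnorm pnorm dnorm uniroot
#' @importFrom utils read.csv write.csv
NULL

# Derive a child seed from a master seed and one or more indices.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 9349 + 1) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_wmh <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "wmh2view_error")))
}
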