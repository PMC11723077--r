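#' @importFrom stats rnorm runif sd predict coef
#' @importFrom utils write.csv read.csv head
NULL

# Derive a reproducible child seed from a master seed and an index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)

sigmoid <- function(v) 1 / (1 + exp(-v))
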