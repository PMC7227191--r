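# internal helpers shared across modules

#' @importFrom stats rexp runif rpois setNames optim ks.test sd
#' @importFrom utils read.delim write.table head
NULL

# Set the RNG seed inside the *calling* function, restoring the caller's RNG
# state when that function exits.  A NULL seed leaves the RNG untouched.
set_local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) {
    return(invisible(NULL))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv(), inherits = FALSE)
    do.call("on.exit",
            list(bquote(assign(".Random.seed", .(old), envir = globalenv())),
                 add = TRUE),
            envir = envir)
  } else {
    do.call("on.exit",
            list(quote(suppressWarnings(rm(".Random.seed",
                                           envir = globalenv()))),
                 add = TRUE),
            envir = envir)
  }
  set.seed(as.integer(seed))
  invisible(NULL)
}

# log(exp(a) + exp(b)) without overflow; vectorised over a, b
log_add_exp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

# derive a stream of sub-seeds from one master seed, staying inside the
# 32-bit integer range
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(as.integer(seed))
  as.list(sample.int(.Machine$integer.max - 1L, n))
}
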