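# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  seed = NULL runs on the ambient stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Linear index (1-based) of parent configurations; first column varies fastest,
# matching the C++ scoring kernel.
configIndex <- function(states, arities) {
  if (length(arities) == 0L) {
    return(rep.int(1L, if (is.matrix(states)) nrow(states) else 1L))
  }
  states <- as.matrix(states)
  stride <- cumprod(c(1L, arities[-length(arities)]))
  as.integer(1L + (states - 1L) %*% stride)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# suffix helper that maps a zero-length input to a zero-length output
lagNames <- function(v) if (length(v)) paste0(v, ".lag") else character(0)
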