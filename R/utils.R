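# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so fixture generation never perturbs it.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Apply f to corresponding numeric leaves of identically shaped nested lists.
# Used for parameter arithmetic (gradients, Adam moments).
map_leaves <- function(f, ...) {
  xs <- list(...)
  x1 <- xs[[1]]
  if (is.list(x1)) {
    out <- vector("list", length(x1))
    names(out) <- names(x1)
    for (i in seq_along(x1)) {
      out[[i]] <- do.call(map_leaves, c(list(f), lapply(xs, `[[`, i)))
    }
    out
  } else {
    do.call(f, xs)
  }
}

# Reduce numeric leaves of a nested list with f (e.g. collect into a vector).
leaves <- function(x) {
  if (is.list(x)) unlist(lapply(x, leaves), use.names = FALSE) else as.vector(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}
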