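#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_grad <- function(pre) (pre > 0) * 1

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

leaky_relu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

# Flatten a nested list of numeric arrays into one vector, and back.
# Used by the Adam optimizer so parameter structure stays a plain list.
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(vec, template) {
  out <- utils::relist(vec, skeleton = template)
  restore <- function(o, t) {
    if (is.list(t)) {
      for (k in seq_along(t)) o[[k]] <- restore(o[[k]], t[[k]])
      o
    } else {
      if (!is.null(dim(t))) dim(o) <- dim(t)
      o
    }
  }
  restore(out, template)
}

# Glorot/Xavier uniform initialization
glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

# Sum matrix rows by group (group ids 1..K), returning a K x ncol matrix.
rowsum_by <- function(x, group, n_groups) {
  out <- matrix(0, n_groups, ncol(x))
  agg <- rowsum(x, group = group)
  out[as.integer(rownames(agg)), ] <- agg
  out
}
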