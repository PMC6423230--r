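`%||%` <- function(a, b) if (is.null(a)) b else a

# set.seed only when the caller supplied one, so nested calls can share a stream
.maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# round-half-up (base round() is banker's rounding; reports use half-up)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# one Dirichlet draw per row of the shape matrix
.rdirichlet_rows <- function(shape) {
  g <- matrix(stats::rgamma(length(shape), shape = shape), nrow(shape), ncol(shape))
  g / pmax(rowSums(g), .Machine$double.xmin)
}

.a1 <- function(n) sum(1 / seq_len(n - 1))
.a2 <- function(n) sum(1 / seq_len(n - 1)^2)
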