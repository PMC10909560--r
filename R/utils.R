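# numerically stable log(sum(exp(x))) per row of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# polynomial design matrix in coded time for a given order
poly_design <- function(time, order) {
  outer(time, 0:order, `^`)
}

stopifnot_prob_vector <- function(p, name, tol = 1e-12) {
  if (any(!is.finite(p)) || any(p < 0))
    stop(sprintf("'%s' must be a vector of nonnegative probabilities", name),
         call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("'%s' must sum to 1 (got %.15f)", name, sum(p)),
         call. = FALSE)
  invisible(p)
}

# derive a stream of distinct 31-bit seeds from one master seed
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}
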