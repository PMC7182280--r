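# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream. seed = NULL leaves the stream alone.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialise a stream so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Standardize a symmetric PSD covariance-like matrix to unit diagonal.
.cov2cor <- function(m) {
  d <- 1 / sqrt(diag(m))
  m <- m * tcrossprod(d)
  diag(m) <- 1
  (m + t(m)) / 2
}

.as_corr <- function(m, labels = NULL) {
  m <- (m + t(m)) / 2
  diag(m) <- 1
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  new("LDMatrix", m)
}

# Coerce z input (StatVector or numeric) to a plain numeric vector with the
# weight absorption Y_i = sqrt(w_i) Z_i applied.
.z_vector <- function(z) {
  if (is(z, "StatVector")) {
    y <- z@z
    if (length(z@weights)) y <- sqrt(z@weights) * y
    names(y) <- if (length(z@ids)) z@ids else NULL
    y
  } else {
    stopifnot(is.numeric(z), all(is.finite(z)))
    z
  }
}

.check_dims <- function(y, R) {
  if (length(y) != nrow(R))
    stop("length of the statistic vector (", length(y),
         ") does not match the correlation matrix dimension (", nrow(R), ")")
}
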