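#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rexp runif rbinom median sd cor cor.test t.test lm
#'   p.adjust pnorm plogis qf pf pt filter complete.cases coef setNames
#' @importFrom utils head tail write.csv read.csv
NULL

# clamp a numeric vector to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Seed handling: NULL means "use the current RNG stream"; an integer scopes a
# reproducible stream to the calling function without disturbing the caller's.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# nearest positive-definite projection by eigenvalue flooring (correlation
# matrices assembled from pairwise targets are not guaranteed PD)
nearest_pd <- function(m, floor = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values > floor)) return(m)
  v <- pmax(e$values, floor)
  m2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(m2))
  m2 <- m2 / tcrossprod(d)
  (m2 + t(m2)) / 2
}
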