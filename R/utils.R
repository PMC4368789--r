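# internal numerical helpers

# central finite differences; step scaled by coordinate magnitude
num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# symmetric pseudo-inverse fallback for near-singular information matrices
safe_solve <- function(H) {
  out <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(out) && all(is.finite(out))) return(out)
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  pos <- e$values > max(abs(e$values)) * 1e-10
  if (!any(pos)) return(matrix(NA_real_, nrow(H), ncol(H)))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

# large finite penalty returned by likelihoods on invalid parameter decodes
PENALTY <- 1e10

`%||%` <- function(a, b) if (is.null(a)) b else a
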