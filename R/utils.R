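# Internal helpers shared across modules.

# Derive `n` reproducible child seeds from one master seed.  Uses a single
# draw from the master stream so cohorts/runs stay reproducible even when the
# per-item work could be parallelised.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Moore-Penrose pseudoinverse solve for (possibly complex) A x = b.
# Returns A^+ %*% b via SVD; tolerance relative to the largest singular value.
pinv_solve <- function(A, b, tol = NULL) {
  sv <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  if (!any(keep)) return(rep(0 + 0i, ncol(A)))
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  v %*% ((Conj(t(u)) %*% b) / sv$d[keep])
}

# Principal-branch complex power lambda^p, with 0^0 = 1 and 0^p = 0 (p > 0).
principal_power <- function(lambda, p) {
  out <- exp(p * log(lambda))
  zero <- Mod(lambda) == 0
  if (any(zero)) out[zero] <- if (p == 0) 1 + 0i else 0 + 0i
  out
}

# Format complex values as "a+bi" strings for TSV round-trips.
format_complex <- function(z) {
  sprintf("%.17g%+.17gi", Re(z), Im(z))
}

parse_complex <- function(s) {
  as.complex(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
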