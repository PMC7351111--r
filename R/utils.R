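#' @keywords internal
"_PACKAGE"

# Deterministic substream seed derived from a master seed and integer indices.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
subseed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (i in seq_along(idx)) {
    h <- (h * 69069 + as.double(idx[i]) * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# 2D convolution ("same" size, zero padding) via FFT. Used by the
# Laplacian-of-Gaussian focus detector.
conv2_same <- function(img, kernel) {
  ni <- nrow(img); mi <- ncol(img)
  nk <- nrow(kernel); mk <- ncol(kernel)
  np <- ni + nk - 1L; mp <- mi + mk - 1L
  A <- matrix(0, np, mp); A[seq_len(ni), seq_len(mi)] <- img
  K <- matrix(0, np, mp); K[seq_len(nk), seq_len(mk)] <- kernel
  full <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (np * mp)
  r0 <- (nk - 1L) %/% 2L
  c0 <- (mk - 1L) %/% 2L
  full[r0 + seq_len(ni), c0 + seq_len(mi)]
}

# Pooled-variance two-sample two-tailed Student t test returning the p value.
# Degenerate zero-variance cases follow the documented conventions: equal
# means -> p = 1; unequal means with zero pooled variance -> p = 0.
student_t_p <- function(x, y, var_equal = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stopf("t test needs >= 2 observations per group")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return(if (mx == my) 1 else 0)
  }
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- (mx - my) / se
  2 * stats::pt(-abs(tstat), df)
}

#' Significance tier for a p value
#'
#' Maps a p value to the conventional figure-legend star tier:
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#' `"ns"` otherwise.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return character vector of tiers.
#' @examples
#' significance_tier(c(0.2, 0.04, 0.004, 4e-4))
#' @export
significance_tier <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  out <- ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
  out[is.na(p)] <- NA_character_
  out
}

# Sample SEM: sd / sqrt(n).
sem <- function(x) stats::sd(x) / sqrt(length(x))
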