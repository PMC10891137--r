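#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`, then
#' restores the caller's RNG state, so seeded routines leave no trace in the
#' session's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Presentation rounding used in reports (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Box (moving-window) sum of a matrix via an integral image.  The window is
# centred, truncated at the edges; w must be odd.
box_sum <- function(m, w) {
  stopifnot(w >= 1, w %% 2 == 1)
  h <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ii <- matrix(0, nr + 1L, nc + 1L)
  ii[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  ii[r2 + 1L, c2 + 1L, drop = FALSE] - ii[r1, c2 + 1L, drop = FALSE] -
    ii[r2 + 1L, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
}

# Repeated box blur; cheap stand-in for a Gaussian kernel on toy grids.
box_blur <- function(m, w, passes = 3L) {
  ones <- matrix(1, nrow(m), ncol(m))
  for (i in seq_len(passes)) {
    m <- box_sum(m, w) / box_sum(ones, w)
  }
  m
}

# Largest-remainder rounding of non-negative targets to integers preserving
# the (integer) total.  Deterministic: ties go to the lowest index.
round_preserve_sum <- function(x, total = round(sum(x))) {
  stopifnot(all(x >= -1e-9))
  x <- pmax(x, 0)
  fl <- floor(x)
  resid <- as.integer(round(total - sum(fl)))
  if (resid > 0) {
    ord <- order(-(x - fl), seq_along(x))
    fl[ord[seq_len(resid)]] <- fl[ord[seq_len(resid)]] + 1
  } else if (resid < 0) {
    ord <- order(x - fl, seq_along(x))
    k <- 0L; i <- 1L
    while (k < -resid) {
      j <- ord[i]
      if (fl[j] > 0) { fl[j] <- fl[j] - 1; k <- k + 1L }
      i <- i + 1L
    }
  }
  as.integer(fl)
}
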