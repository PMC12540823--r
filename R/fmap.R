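# Feature maps.
#
# Internally every activation is a (N*H*W) x C numeric matrix whose row index
# enumerates pixels sample-by-sample in row-major order:
#   row = (n-1)*H*W + (y-1)*W + x,   y = image row, x = image column (1-based).
# This layout makes 1x1 convolutions plain matrix products and keeps the C++
# kernels free of stride bookkeeping.

#' Create a feature map
#'
#' A feature map is the carrier of every intermediate activation in the
#' network: a spatial grid of `H x W` pixels with `C` channels, optionally
#' batched over `N` samples.
#'
#' @param x A numeric array with dim `c(H, W, C)` (single sample) or
#'   `c(H, W, C, N)` (batch).
#' @return An object of class `feature_map` with fields `x` (the
#'   `(N*H*W) x C` value matrix), `n`, `h`, `w`, `c`.
#' @examples
#' fm <- feature_map(array(rnorm(2 * 3 * 4), c(2, 3, 4)))
#' dim(as.array(fm))
#' @export
feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("feature_map expects an array with dim (H, W, C) or (H, W, C, N)")
  if (length(d) == 3L) d <- c(d, 1L)
  m <- matrix(aperm(array(x, d), c(2L, 1L, 4L, 3L)), ncol = d[3L])
  new_fmap(m, d[4L], d[1L], d[2L], d[3L])
}

new_fmap <- function(m, n, h, w, c) {
  structure(list(x = m, n = as.integer(n), h = as.integer(h),
                 w = as.integer(w), c = as.integer(c)),
            class = "feature_map")
}

#' @export
as.array.feature_map <- function(x, ...) {
  a <- array(x$x, c(x$w, x$h, x$n, x$c))
  out <- aperm(a, c(2L, 1L, 4L, 3L))
  if (x$n == 1L) dim(out) <- c(x$h, x$w, x$c)
  out
}

#' @export
dim.feature_map <- function(x) c(x$h, x$w, x$c, x$n)

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map %d x %d x %d (batch %d)>\n", x$h, x$w, x$c, x$n))
  invisible(x)
}

fmap_like <- function(fm, m, h = fm$h, w = fm$w) new_fmap(m, fm$n, h, w, ncol(m))

stopifnot_fmap <- function(x) {
  if (!inherits(x, "feature_map")) stop("expected a feature_map")
  invisible(x)
}
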