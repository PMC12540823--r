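# Leaf layers. Every layer is an environment with:
#   $kind     layer type tag
#   $p        named list of trainable arrays
#   $g        matching list of accumulated gradients
#   $children named list of sub-layers (composites)
#   $fwd(x, train), $bwd(dy)  closures caching what backward needs
# Gradients accumulate until zero_grads(); the AdamW step walks all layers.

new_layer <- function(kind, params = list()) {
  self <- new.env(parent = emptyenv())
  self$kind <- kind
  self$p <- params
  self$g <- lapply(params, function(a) array(0, dim = dim(a) %||% length(a)))
  self$children <- list()
  class(self) <- "seg_layer"
  self
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.seg_layer <- function(x, ...) {
  cat(sprintf("<seg_layer %s: %d parameters>\n", x$kind, count_parameters(x)))
  invisible(x)
}

walk_layers <- function(layer) {
  out <- list()
  if (length(layer$p)) out <- list(layer)
  for (ch in layer$children) out <- c(out, walk_layers(ch))
  out
}

#' Count trainable parameters
#'
#' Sums the sizes of every trainable weight array reachable from a layer or
#' assembled network (batch-norm running statistics are not trainable and are
#' excluded).
#'
#' @param x A layer created by one of the `nn_*()` constructors, or a network
#'   from [build_network()].
#' @return Integer scalar, the total number of trainable scalars.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "seg_network")) x <- x$root
  if (isTRUE(x$frozen)) return(0L)
  sum(vapply(walk_layers(x), function(l) {
    if (isTRUE(l$frozen)) 0 else sum(vapply(l$p, length, 1L))
  }, 1))
}

zero_grads <- function(layer) {
  for (l in walk_layers(layer))
    l$g <- lapply(l$p, function(a) array(0, dim = dim(a) %||% length(a)))
  invisible(layer)
}

# broadcast a per-channel vector across rows of an (m x C) matrix
col_bcast <- function(m, v) matrix(v, nrow = m, ncol = length(v), byrow = TRUE)

he_init <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)

## ---- dense (also serves as 1x1 convolution) --------------------------------

nn_dense <- function(ci, co, bias = TRUE, init_sd = NULL) {
  w <- if (is.null(init_sd)) he_init(ci, co, ci) else matrix(rnorm(ci * co, sd = init_sd), ci, co)
  params <- list(w = w)
  if (bias) params$b <- numeric(co)
  self <- new_layer("dense", params)
  self$fwd <- function(x, train = FALSE) {
    self$x <- x
    y <- x %*% self$p$w
    if (!is.null(self$p$b)) y <- y + col_bcast(nrow(y), self$p$b)
    y
  }
  self$bwd <- function(dy) {
    self$g$w <- self$g$w + crossprod(self$x, dy)
    if (!is.null(self$p$b)) self$g$b <- self$g$b + colSums(dy)
    dy %*% t(self$p$w)
  }
  self
}

## ---- spatial convolutions ---------------------------------------------------

nn_conv2d <- function(ci, co, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  self <- new_layer("conv2d", list(w = he_init(k * k * ci, co, k * k * ci)))
  self$k <- as.integer(k); self$stride <- as.integer(stride); self$pad <- as.integer(pad)
  self$ci <- ci; self$co <- co
  self$fwd <- function(fm, train = FALSE) {
    self$in_fm <- fm
    y <- .conv2d_fwd(fm$x, fm$n, fm$h, fm$w, fm$c, self$p$w, self$k, self$stride, self$pad)
    ho <- (fm$h + 2L * self$pad - self$k) %/% self$stride + 1L
    wo <- (fm$w + 2L * self$pad - self$k) %/% self$stride + 1L
    fmap_like(fm, y, ho, wo)
  }
  self$bwd <- function(dy) {
    fm <- self$in_fm
    r <- .conv2d_bwd(fm$x, dy$x, fm$n, fm$h, fm$w, fm$c, self$p$w,
                     self$k, self$stride, self$pad)
    self$g$w <- self$g$w + r$dk
    fmap_like(fm, r$dx)
  }
  self
}

nn_dwconv <- function(c, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L, bias = TRUE) {
  params <- list(w = he_init(k * k, c, k * k))
  if (bias) params$b <- numeric(c)
  self <- new_layer("dwconv", params)
  self$k <- as.integer(k); self$stride <- as.integer(stride); self$pad <- as.integer(pad)
  self$fwd <- function(fm, train = FALSE) {
    self$in_fm <- fm
    y <- .dwconv_fwd(fm$x, fm$n, fm$h, fm$w, fm$c, self$p$w, self$k, self$stride, self$pad)
    if (!is.null(self$p$b)) y <- y + col_bcast(nrow(y), self$p$b)
    ho <- (fm$h + 2L * self$pad - self$k) %/% self$stride + 1L
    wo <- (fm$w + 2L * self$pad - self$k) %/% self$stride + 1L
    fmap_like(fm, y, ho, wo)
  }
  self$bwd <- function(dy) {
    fm <- self$in_fm
    if (!is.null(self$p$b)) self$g$b <- self$g$b + colSums(dy$x)
    r <- .dwconv_bwd(fm$x, dy$x, fm$n, fm$h, fm$w, fm$c, self$p$w,
                     self$k, self$stride, self$pad)
    self$g$w <- self$g$w + r$dk
    fmap_like(fm, r$dx)
  }
  self
}

## ---- normalisation ----------------------------------------------------------

nn_batchnorm <- function(c, momentum = 0.1, eps = 1e-5) {
  self <- new_layer("batchnorm", list(gamma = rep(1, c), beta = numeric(c)))
  self$rm <- numeric(c); self$rv <- rep(1, c)
  self$momentum <- momentum; self$eps <- eps
  self$fwd <- function(fm, train = FALSE) {
    x <- fm$x; m <- nrow(x)
    if (train) {
      mu <- colMeans(x)
      v <- colMeans(x * x) - mu^2
      v[v < 0] <- 0
      self$rm <- (1 - self$momentum) * self$rm + self$momentum * mu
      self$rv <- (1 - self$momentum) * self$rv + self$momentum * v
    } else {
      mu <- self$rm; v <- self$rv
    }
    istd <- 1 / sqrt(v + self$eps)
    xhat <- (x - col_bcast(m, mu)) * col_bcast(m, istd)
    self$xhat <- xhat; self$istd <- istd; self$train_mode <- train
    fmap_like(fm, xhat * col_bcast(m, self$p$gamma) + col_bcast(m, self$p$beta))
  }
  self$bwd <- function(dy) {
    d <- dy$x; m <- nrow(d)
    self$g$gamma <- self$g$gamma + colSums(d * self$xhat)
    self$g$beta <- self$g$beta + colSums(d)
    dxhat <- d * col_bcast(m, self$p$gamma)
    if (self$train_mode) {
      s1 <- colSums(dxhat); s2 <- colSums(dxhat * self$xhat)
      dx <- (dxhat - col_bcast(m, s1 / m) - self$xhat * col_bcast(m, s2 / m)) *
        col_bcast(m, self$istd)
    } else {
      dx <- dxhat * col_bcast(m, self$istd)
    }
    fmap_like(dy, dx)
  }
  self
}

nn_layernorm <- function(c, eps = 1e-6) {
  self <- new_layer("layernorm", list(gamma = rep(1, c), beta = numeric(c)))
  self$eps <- eps
  self$fwd <- function(x, train = FALSE) {
    # x: plain matrix, normalised across channels within each row
    mu <- rowMeans(x)
    v <- rowMeans(x * x) - mu^2
    v[v < 0] <- 0
    istd <- 1 / sqrt(v + self$eps)
    xhat <- (x - mu) * istd
    self$xhat <- xhat; self$istd <- istd
    xhat * col_bcast(nrow(x), self$p$gamma) + col_bcast(nrow(x), self$p$beta)
  }
  self$bwd <- function(dy) {
    cc <- ncol(dy)
    self$g$gamma <- self$g$gamma + colSums(dy * self$xhat)
    self$g$beta <- self$g$beta + colSums(dy)
    dxhat <- dy * col_bcast(nrow(dy), self$p$gamma)
    (dxhat - rowSums(dxhat) / cc - self$xhat * (rowSums(dxhat * self$xhat) / cc)) * self$istd
  }
  self
}

## ---- activations (stateless apart from cached input) ------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_act <- function(type = c("silu", "relu", "sigmoid")) {
  type <- match.arg(type)
  self <- new_layer(paste0("act_", type))
  self$fwd <- function(x, train = FALSE) {
    self$is_fm <- inherits(x, "feature_map")
    m <- if (self$is_fm) x$x else x
    y <- switch(type,
      silu = { s <- sigmoid(m); self$s <- s; self$xin <- m; m * s },
      relu = { self$mask <- m > 0; m * self$mask },
      sigmoid = { s <- sigmoid(m); self$s <- s; s })
    if (self$is_fm) fmap_like(x, y) else y
  }
  self$bwd <- function(dy) {
    d <- if (inherits(dy, "feature_map")) dy$x else dy
    dx <- switch(type,
      silu = d * self$s * (1 + self$xin * (1 - self$s)),
      relu = d * self$mask,
      sigmoid = d * self$s * (1 - self$s))
    if (self$is_fm) fmap_like(dy, dx) else dx
  }
  self
}

## ---- generic user entry ------------------------------------------------------

#' Apply a layer to an input
#'
#' Runs the forward pass of any layer built by the `nn_*()` constructors.
#'
#' @param layer A layer object.
#' @param x Input: a [feature_map()] for spatial layers, a matrix for dense
#'   layers.
#' @param train Logical; `TRUE` uses training-mode statistics (batch norm) and
#'   caches intermediates for a subsequent backward pass.
#' @return The layer output, same container type as the input.
#' @export
layer_forward <- function(layer, x, train = FALSE) layer$fwd(x, train)
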