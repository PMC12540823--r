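# Visual state-space (VSS) blocks.
#
# The core operator is a per-channel diagonal linear state-space recurrence
#   H(t) = A H(t-1) + B X(t);  Y(t) = C H(t) + D X(t)
# applied along four traversals of the 2D grid (row-major forward/reverse,
# column-major forward/reverse) and averaged. A block wraps the scan with
# layer norm, channel expansion, a depthwise convolution, SiLU gating and a
# residual projection, as in the Mamba family of vision backbones.

#' Run the 1D state-space scan
#'
#' Exact linear recurrence `h_t = A h_{t-1} + B x_t`, `y_t = C h_t + D x_t`
#' with zero initial state, evaluated independently per channel. This is the
#' primitive behind the four-directional SS2D operator; parameters are the
#' *discrete* system matrices.
#'
#' @param x Numeric vector (single channel) or `T x C` matrix of input
#'   sequences.
#' @param A,B,C,D State-space parameters. Scalars apply to every channel;
#'   vectors of length `C` give one scalar state per channel; `C x S` matrices
#'   give an `S`-dimensional diagonal state per channel (`D` is always scalar
#'   per channel).
#' @return Output sequence(s), same shape as `x`.
#' @examples
#' ss2d_scan(c(1, 0, 0), A = 0.5, B = 1, C = 1, D = 0)  # 1, 0.5, 0.25
#' @export
ss2d_scan <- function(x, A, B, C, D = 0) {
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, ncol = 1L)
  nc <- ncol(x)
  coerce <- function(p, name) {
    if (is.null(dim(p))) {
      if (length(p) == 1L) p <- rep(p, nc)
      if (length(p) != nc) stop(name, " must be scalar, length-C or C x S")
      matrix(p, nrow = nc, ncol = 1L)
    } else {
      if (nrow(p) != nc) stop(name, " must have one row per channel")
      p
    }
  }
  Am <- coerce(A, "A"); Bm <- coerce(B, "B"); Cm <- coerce(C, "C")
  if (!all(dim(Am) == dim(Bm)) || !all(dim(Am) == dim(Cm)))
    stop("A, B, C must share dimensions")
  Dv <- if (length(D) == 1L) rep(D, nc) else D
  y <- .ssm_scan_fwd(x, 1L, nrow(x), nc, Am, Bm, Cm, Dv)
  if (vec_in) drop(y) else y
}

# scan-order permutations for an h x w grid (length h*w index vectors):
# 1 row-major forward, 2 row-major reverse, 3 column-major forward,
# 4 column-major reverse. For batches the per-sample pattern is offset.
scan_perms <- function(h, w, n) {
  hw <- h * w
  p1 <- seq_len(hw)
  p3 <- rep((0:(h - 1)) * w, times = w) + rep(seq_len(w), each = h)
  ps <- list(p1, rev(p1), p3, rev(p3))
  off <- (0:(n - 1)) * hw
  lapply(ps, function(p) as.vector(outer(p, off, "+")))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Visual state-space block constructor
#'
#' Layer-normalises the input, expands channels, applies a depthwise
#' convolution with SiLU, runs the state-space scan along four directional
#' traversals of the grid, averages the four outputs, gates them with a SiLU
#' branch, projects back to the input width and adds the residual. Output
#' shape equals input shape.
#'
#' The discrete transition is parameterised for stability: the continuous
#' diagonal is `-exp(A_log)` and the step is `softplus(dt)`, so every discrete
#' eigenvalue `exp(-softplus(dt) * exp(A_log))` lies strictly inside (0, 1).
#'
#' @param channels Input/output channel count.
#' @param expand Internal channel expansion ratio.
#' @param state State dimension per channel.
#' @param tie_directions Logical; share one parameter set across the four
#'   directions (used to test rotation equivariance).
#' @return A layer; apply with [layer_forward()].
#' @export
nn_vss_block <- function(channels, expand = 2L, state = 16L, tie_directions = FALSE) {
  ec <- as.integer(channels * expand)
  nd <- if (tie_directions) 1L else 4L
  dt0 <- exp(runif(ec * nd, log(1e-3), log(1e-1)))
  params <- list(
    A_log = array(log(matrix(seq_len(state), ec, state, byrow = TRUE)), c(ec, state, nd)),
    B = array(rnorm(ec * state * nd, sd = 1 / sqrt(state)), c(ec, state, nd)),
    C = array(rnorm(ec * state * nd, sd = 1 / sqrt(state)), c(ec, state, nd)),
    dt = matrix(log(expm1(dt0)), ec, nd),
    D = matrix(1, ec, nd))
  self <- new_layer("vss_block", params)
  self$channels <- channels; self$ec <- ec; self$state <- as.integer(state)
  self$tie <- tie_directions
  ch <- list(
    ln = nn_layernorm(channels),
    in_proj = nn_dense(channels, 2L * ec),
    dw = nn_dwconv(ec, 3L, 1L, bias = TRUE),
    act = nn_act("silu"),
    gate = nn_act("silu"),
    out_proj = nn_dense(ec, channels))
  self$children <- ch
  self$perm_cache <- list()

  get_perms <- function(h, w, n) {
    key <- paste(h, w, n, sep = "x")
    if (is.null(self$perm_cache[[key]])) self$perm_cache[[key]] <- scan_perms(h, w, n)
    self$perm_cache[[key]]
  }
  disc <- function(d) {
    di <- if (self$tie) 1L else d
    dt_s <- softplus(self$p$dt[, di])
    acont <- -exp(self$p$A_log[, , di])
    list(di = di, dt_s = dt_s, acont = acont,
         A = exp(acont * dt_s), B = self$p$B[, , di] * dt_s,
         C = self$p$C[, , di], D = self$p$D[, di])
  }

  self$fwd <- function(fm, train = FALSE) {
    stopifnot_fmap(fm)
    if (fm$c != self$channels)
      stop(sprintf("vss block expects %d channels, got %d", self$channels, fm$c))
    self$in_fm <- fm
    h <- ch$ln$fwd(fm$x, train)
    u <- ch$in_proj$fwd(h, train)
    ux <- u[, seq_len(ec), drop = FALSE]
    uz <- u[, ec + seq_len(ec), drop = FALSE]
    a <- ch$act$fwd(ch$dw$fwd(fmap_like(fm, ux), train), train)
    self$a_x <- a$x
    perms <- get_perms(fm$h, fm$w, fm$n)
    self$perms <- perms
    hw <- fm$h * fm$w
    ys <- 0
    for (d in 1:4) {
      pp <- disc(d)
      xp <- a$x[perms[[d]], , drop = FALSE]
      yp <- .ssm_scan_fwd(xp, fm$n, hw, ec, pp$A, pp$B, pp$C, pp$D)
      yd <- matrix(0, nrow(yp), ncol(yp))
      yd[perms[[d]], ] <- yp
      ys <- ys + yd
    }
    yscan <- ys / 4
    z <- ch$gate$fwd(uz, train)
    self$yscan <- yscan; self$z <- z
    out <- ch$out_proj$fwd(yscan * z, train) + fm$x
    fmap_like(fm, out)
  }

  self$bwd <- function(dy) {
    fm <- self$in_fm
    hw <- fm$h * fm$w
    dgated <- ch$out_proj$bwd(dy$x)
    dyscan <- dgated * self$z
    duz <- ch$gate$bwd(dgated * self$yscan)
    da_x <- matrix(0, nrow(dyscan), ncol(dyscan))
    for (d in 1:4) {
      pp <- disc(d)
      xp <- self$a_x[self$perms[[d]], , drop = FALSE]
      dyp <- dyscan[self$perms[[d]], , drop = FALSE] / 4
      r <- .ssm_scan_bwd(xp, dyp, fm$n, hw, ec, pp$A, pp$B, pp$C, pp$D)
      da_x[self$perms[[d]], ] <- da_x[self$perms[[d]], , drop = FALSE] + r$dx
      di <- pp$di
      # chain discrete -> raw parameterisation
      dA_raw <- r$da * pp$A                       # d/d(acont*dt) of exp
      self$g$A_log[, , di] <- self$g$A_log[, , di] + dA_raw * pp$dt_s * pp$acont
      ddt <- rowSums(dA_raw * pp$acont) + rowSums(r$db * self$p$B[, , di])
      self$g$dt[, di] <- self$g$dt[, di] + ddt * sigmoid(self$p$dt[, di])
      self$g$B[, , di] <- self$g$B[, , di] + r$db * pp$dt_s
      self$g$C[, , di] <- self$g$C[, , di] + r$dc
      self$g$D[, di] <- self$g$D[, di] + r$dd
    }
    dconv <- ch$dw$bwd(ch$act$bwd(fmap_like(fm, da_x)))
    du <- cbind(dconv$x, duz)
    dh <- ch$in_proj$bwd(du)
    dx <- ch$ln$bwd(dh) + dy$x
    fmap_like(fm, dx)
  }
  self
}

#' Apply a VSS block
#'
#' Functional convenience around [nn_vss_block()].
#'
#' @param x A [feature_map()].
#' @param layer Optionally a previously built block (otherwise one is created
#'   with fresh random weights).
#' @param ... Passed to [nn_vss_block()] when `layer` is `NULL`.
#' @param train Logical, training mode.
#' @return The output [feature_map()], same shape as `x`.
#' @export
vss_block <- function(x, layer = NULL, ..., train = FALSE) {
  if (is.null(layer)) layer <- nn_vss_block(x$c, ...)
  layer_forward(layer, x, train)
}

## ---- patch merging / expansion ----------------------------------------------

merge_indices <- function(h, w, n) {
  ho <- h %/% 2L; wo <- w %/% 2L
  oy <- rep(seq_len(ho), each = wo); ox <- rep(seq_len(wo), times = ho)
  tl <- (2L * oy - 2L) * w + (2L * ox - 1L)
  off <- rep((0:(n - 1)) * h * w, each = ho * wo)
  tl <- rep(tl, times = n) + off
  list(tl = tl, tr = tl + 1L, bl = tl + w, br = tl + w + 1L)
}

#' Patch merging layer
#'
#' Concatenates each non-overlapping 2x2 block of a feature map along the
#' channel axis in the order (top-left, top-right, bottom-left, bottom-right)
#' -- giving 4C channels at half resolution -- then linearly projects to 2C.
#'
#' @param channels Input channel count C.
#' @return A layer mapping `(H, W, C)` to `(H/2, W/2, 2C)`.
#' @export
nn_patch_merge <- function(channels) {
  self <- new_layer("patch_merge")
  self$channels <- channels
  ch <- list(proj = nn_dense(4L * channels, 2L * channels, bias = FALSE))
  self$children <- ch
  self$fwd <- function(fm, train = FALSE) {
    stopifnot_fmap(fm)
    if (fm$h %% 2L || fm$w %% 2L)
      stop(sprintf("patch merging needs even spatial size, got %d x %d", fm$h, fm$w))
    idx <- merge_indices(fm$h, fm$w, fm$n)
    self$idx <- idx; self$in_fm <- fm
    cat4 <- cbind(fm$x[idx$tl, , drop = FALSE], fm$x[idx$tr, , drop = FALSE],
                  fm$x[idx$bl, , drop = FALSE], fm$x[idx$br, , drop = FALSE])
    self$cat4 <- cat4
    new_fmap(ch$proj$fwd(cat4, train), fm$n, fm$h %/% 2L, fm$w %/% 2L, 2L * fm$c)
  }
  self$bwd <- function(dy) {
    fm <- self$in_fm; idx <- self$idx; cc <- fm$c
    dcat <- ch$proj$bwd(dy$x)
    dx <- matrix(0, nrow(fm$x), cc)
    dx[idx$tl, ] <- dcat[, seq_len(cc), drop = FALSE]
    dx[idx$tr, ] <- dcat[, cc + seq_len(cc), drop = FALSE]
    dx[idx$bl, ] <- dcat[, 2L * cc + seq_len(cc), drop = FALSE]
    dx[idx$br, ] <- dcat[, 3L * cc + seq_len(cc), drop = FALSE]
    fmap_like(fm, dx)
  }
  self
}

#' Merge 2x2 patches of a feature map
#'
#' @param x A [feature_map()] with even spatial size.
#' @param layer Optionally a prebuilt [nn_patch_merge()] layer.
#' @param project If `FALSE`, return the raw 4C concatenation (no learnable
#'   transformation) instead of the 2C projection.
#' @return A [feature_map()] at half resolution with `2C` (or `4C`) channels.
#' @examples
#' x <- feature_map(array(1:4, c(2, 2, 1)))
#' dim(patch_merge(x, project = FALSE))
#' @export
patch_merge <- function(x, layer = NULL, project = TRUE) {
  stopifnot_fmap(x)
  if (!project) {
    if (x$h %% 2L || x$w %% 2L) stop("patch merging needs even spatial size")
    idx <- merge_indices(x$h, x$w, x$n)
    cat4 <- cbind(x$x[idx$tl, , drop = FALSE], x$x[idx$tr, , drop = FALSE],
                  x$x[idx$bl, , drop = FALSE], x$x[idx$br, , drop = FALSE])
    return(new_fmap(cat4, x$n, x$h %/% 2L, x$w %/% 2L, 4L * x$c))
  }
  if (is.null(layer)) layer <- nn_patch_merge(x$c)
  layer_forward(layer, x)
}

#' Patch expansion layer
#'
#' The decoder inverse of patch merging: a linear map doubles the channels,
#' then each location's vector is rearranged into a 2x2 spatial block, mapping
#' `(H, W, C)` to `(2H, 2W, C/2)`.
#'
#' @param channels Input channel count C (must be even).
#' @return A layer.
#' @export
nn_patch_expand <- function(channels) {
  if (channels %% 2L) stop("patch expansion needs an even channel count")
  self <- new_layer("patch_expand")
  self$channels <- channels
  ch <- list(proj = nn_dense(channels, 2L * channels, bias = FALSE))
  self$children <- ch
  self$fwd <- function(fm, train = FALSE) {
    stopifnot_fmap(fm)
    z <- ch$proj$fwd(fm$x, train)
    co <- fm$c %/% 2L
    idx <- merge_indices(2L * fm$h, 2L * fm$w, fm$n)  # blocks of the output grid
    self$idx <- idx; self$in_fm <- fm; self$co <- co
    y <- matrix(0, fm$n * 4L * fm$h * fm$w, co)
    y[idx$tl, ] <- z[, seq_len(co), drop = FALSE]
    y[idx$tr, ] <- z[, co + seq_len(co), drop = FALSE]
    y[idx$bl, ] <- z[, 2L * co + seq_len(co), drop = FALSE]
    y[idx$br, ] <- z[, 3L * co + seq_len(co), drop = FALSE]
    new_fmap(y, fm$n, 2L * fm$h, 2L * fm$w, co)
  }
  self$bwd <- function(dy) {
    idx <- self$idx; co <- self$co
    dz <- cbind(dy$x[idx$tl, , drop = FALSE], dy$x[idx$tr, , drop = FALSE],
                dy$x[idx$bl, , drop = FALSE], dy$x[idx$br, , drop = FALSE])
    fmap_like(self$in_fm, ch$proj$bwd(dz))
  }
  self
}

#' Expand a feature map to double resolution
#'
#' @param x A [feature_map()] with an even channel count.
#' @param layer Optionally a prebuilt [nn_patch_expand()] layer.
#' @return A [feature_map()] of shape `(2H, 2W, C/2)`.
#' @export
patch_expand <- function(x, layer = NULL) {
  stopifnot_fmap(x)
  if (is.null(layer)) layer <- nn_patch_expand(x$c)
  layer_forward(layer, x)
}
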