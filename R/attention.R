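# Spatial (SAB) and channel (CAB) attention bridges.
#
# SAB pools the channels of each pixel into mean/max descriptors, convolves
# them with a 7x7 kernel and gates the map with the resulting sigmoid mask.
# CAB squeezes the map by global average pooling, passes it through a
# two-layer bottleneck and gates the channels. Both gates lie strictly in
# (0, 1), so the operators are contractive per element.

#' Spatial attention layer (SAB)
#'
#' @param channels Input channel count.
#' @param mode `"pooled"` (default) computes per-pixel channel-mean and
#'   channel-max descriptors and convolves the 2-channel descriptor map;
#'   `"literal"` applies the 7x7 convolution to the feature map itself.
#' @return A layer preserving input shape.
#' @export
nn_spatial_attention <- function(channels, mode = c("pooled", "literal")) {
  mode <- match.arg(mode)
  self <- new_layer("spatial_attention", list(b = 0))
  self$mode <- mode; self$channels <- channels
  ci <- if (mode == "pooled") 2L else channels
  ch <- list(conv = nn_conv2d(ci, 1L, k = 7L, stride = 1L, pad = 3L))
  self$children <- ch
  self$fwd <- function(fm, train = FALSE) {
    stopifnot_fmap(fm)
    x <- fm$x; m <- nrow(x)
    if (self$mode == "pooled") {
      mx_idx <- max.col(x, ties.method = "first")
      desc <- cbind(rowMeans(x), x[cbind(seq_len(m), mx_idx)])
      self$mx_idx <- mx_idx
      dfm <- fmap_like(fm, desc)
    } else {
      dfm <- fm
    }
    logit <- ch$conv$fwd(dfm, train)$x + as.vector(self$p$b)
    s <- sigmoid(logit)
    self$s <- s; self$in_fm <- fm
    fmap_like(fm, x * as.vector(s))
  }
  self$bwd <- function(dy) {
    fm <- self$in_fm; x <- fm$x; s <- as.vector(self$s)
    ds <- rowSums(dy$x * x)
    dx <- dy$x * s
    dlogit <- ds * s * (1 - s)
    self$g$b <- self$g$b + sum(dlogit)
    dd <- ch$conv$bwd(fmap_like(fm, matrix(dlogit, ncol = 1L)))$x
    if (self$mode == "pooled") {
      dx <- dx + dd[, 1L] / fm$c
      pick <- cbind(seq_len(nrow(x)), self$mx_idx)
      dx[pick] <- dx[pick] + dd[, 2L]
    } else {
      dx <- dx + dd
    }
    fmap_like(fm, dx)
  }
  self
}

#' Channel attention layer (CAB)
#'
#' @param channels Input channel count; must be divisible by `reduction`.
#' @param reduction Bottleneck reduction factor r.
#' @return A layer preserving input shape.
#' @export
nn_channel_attention <- function(channels, reduction = 8L) {
  if (channels %% reduction)
    stop(sprintf("channels (%d) must be divisible by reduction (%d)", channels, reduction))
  self <- new_layer("channel_attention")
  self$channels <- channels
  ch <- list(fc1 = nn_dense(channels, channels %/% reduction),
             relu = nn_act("relu"),
             fc2 = nn_dense(channels %/% reduction, channels),
             gate = nn_act("sigmoid"))
  self$children <- ch
  self$fwd <- function(fm, train = FALSE) {
    stopifnot_fmap(fm)
    hw <- fm$h * fm$w
    grp <- gap_groups(fm$n, hw)
    s <- rowsum(fm$x, grp) / hw
    a <- ch$gate$fwd(ch$fc2$fwd(ch$relu$fwd(ch$fc1$fwd(s, train), train), train), train)
    dimnames(a) <- NULL  # rowsum() attaches group names
    self$a <- a; self$grp <- grp; self$hw <- hw; self$in_fm <- fm
    fmap_like(fm, fm$x * a[grp, , drop = FALSE])
  }
  self$bwd <- function(dy) {
    fm <- self$in_fm; grp <- self$grp
    dx <- dy$x * self$a[grp, , drop = FALSE]
    da <- rowsum(dy$x * fm$x, grp)
    ds <- ch$fc1$bwd(ch$relu$bwd(ch$fc2$bwd(ch$gate$bwd(da))))
    fmap_like(fm, dx + ds[grp, , drop = FALSE] / self$hw)
  }
  self
}

#' Apply spatial attention to a feature map
#'
#' @param x A [feature_map()].
#' @param layer Optionally a prebuilt [nn_spatial_attention()] layer.
#' @param ... Passed to the constructor when `layer` is `NULL`.
#' @return Gated [feature_map()], same shape; the sigmoid mask is strictly in
#'   (0, 1).
#' @export
spatial_attention <- function(x, layer = NULL, ...) {
  if (is.null(layer)) layer <- nn_spatial_attention(x$c, ...)
  layer_forward(layer, x)
}

#' Apply channel attention to a feature map
#'
#' @inheritParams spatial_attention
#' @return Gated [feature_map()], same shape.
#' @export
channel_attention <- function(x, layer = NULL, ...) {
  if (is.null(layer)) layer <- nn_channel_attention(x$c, ...)
  layer_forward(layer, x)
}

#' Fuse VSS and attention branches
#'
#' Combines the state-space output with the spatial- and channel-attention
#' outputs, either by element-wise addition (default, parameter-free) or by
#' channel concatenation followed by a linear projection back to C.
#'
#' @param vss_out,sab_out,cab_out [feature_map()]s of identical shape.
#' @param mode `"add"` or `"concat"`.
#' @param layer For `"concat"`, optionally a prebuilt projection layer
#'   (a dense `3C -> C` map).
#' @return The fused [feature_map()], same shape as the inputs.
#' @export
fuse_attention <- function(vss_out, sab_out, cab_out, mode = c("add", "concat"),
                           layer = NULL) {
  mode <- match.arg(mode)
  if (!all(dim(vss_out) == dim(sab_out)) || !all(dim(vss_out) == dim(cab_out)))
    stop("fuse_attention inputs must share shape")
  if (mode == "add")
    return(fmap_like(vss_out, vss_out$x + sab_out$x + cab_out$x))
  if (is.null(layer)) layer <- nn_dense(3L * vss_out$c, vss_out$c)
  fmap_like(vss_out, layer$fwd(cbind(vss_out$x, sab_out$x, cab_out$x)))
}

# Attention site used in the bottleneck and decoder: v + SAB(v) + CAB(v)
# (add mode) or proj(concat(v, SAB(v), CAB(v))).
nn_attn_site <- function(channels, sab_mode = "pooled", fusion = "add", reduction = 8L) {
  self <- new_layer("attn_site")
  ch <- list(sab = nn_spatial_attention(channels, sab_mode),
             cab = nn_channel_attention(channels, reduction))
  if (fusion == "concat") ch$proj <- nn_dense(3L * channels, channels)
  self$children <- ch
  self$fusion <- fusion
  self$fwd <- function(fm, train = FALSE) {
    s <- ch$sab$fwd(fm, train)
    cb <- ch$cab$fwd(fm, train)
    if (self$fusion == "add") fmap_like(fm, fm$x + s$x + cb$x)
    else fmap_like(fm, ch$proj$fwd(cbind(fm$x, s$x, cb$x), train))
  }
  self$bwd <- function(dy) {
    if (self$fusion == "add") {
      d1 <- dy; d2 <- dy; d3 <- dy
    } else {
      dcat <- ch$proj$bwd(dy$x); cc <- dy$c
      d1 <- fmap_like(dy, dcat[, seq_len(cc), drop = FALSE])
      d2 <- fmap_like(dy, dcat[, cc + seq_len(cc), drop = FALSE])
      d3 <- fmap_like(dy, dcat[, 2L * cc + seq_len(cc), drop = FALSE])
    }
    ds <- ch$sab$bwd(d2)
    dc <- ch$cab$bwd(d3)
    fmap_like(dy, d1$x + ds$x + dc$x)
  }
  self
}
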