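# Mobile inverted bottleneck (MBConv) blocks and the hierarchical encoder.
#
# A block is: 1x1 expansion -> BN -> SiLU -> k x k depthwise -> BN -> SiLU
# -> squeeze-excitation -> 1x1 projection -> BN, with a residual connection
# when stride is 1 and the channel count is unchanged. Downsampling between
# stages is carried by the depthwise convolution of the first block.

nn_seq <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) && !inherits(layers[[1]], "seg_layer"))
    layers <- layers[[1]]
  self <- new_layer("seq")
  self$children <- layers
  self$fwd <- function(x, train = FALSE) {
    for (l in self$children) x <- l$fwd(x, train)
    x
  }
  self$bwd <- function(dy) {
    for (l in rev(self$children)) dy <- l$bwd(dy)
    dy
  }
  self
}

# global average pool over the spatial grid, per sample: (N*HW x C) -> (N x C)
gap_groups <- function(n, hw) rep(seq_len(n), each = hw)

#' MBConv block constructor
#'
#' Builds a mobile inverted bottleneck convolution block: pointwise expansion,
#' depthwise convolution, squeeze-excitation and pointwise projection, each
#' followed by batch normalisation, with SiLU activations and a residual
#' connection when the spatial size and channel count are preserved.
#'
#' @param in_channels,out_channels Input/output channel counts.
#' @param expansion Integer expansion factor of the inverted bottleneck.
#' @param kernel Odd depthwise kernel size.
#' @param stride 1 or 2; stride 2 halves the spatial size.
#' @param use_se Logical, include the squeeze-excitation gate.
#' @param se_ratio Squeeze width as a fraction of `in_channels`.
#' @return A layer; apply with [layer_forward()].
#' @examples
#' set.seed(1)
#' blk <- nn_mbconv(4, 4, expansion = 2)
#' x <- feature_map(array(runif(8 * 8 * 4), c(8, 8, 4)))
#' dim(layer_forward(blk, x))
#' @export
nn_mbconv <- function(in_channels, out_channels, expansion = 6L, kernel = 3L,
                      stride = 1L, use_se = TRUE, se_ratio = 0.25) {
  stopifnot(stride %in% c(1L, 2L), kernel %% 2L == 1L, expansion >= 1L)
  ce <- in_channels * expansion
  self <- new_layer("mbconv")
  self$ci <- in_channels; self$co <- out_channels; self$stride <- as.integer(stride)
  self$use_res <- stride == 1L && in_channels == out_channels
  self$use_se <- isTRUE(use_se)
  ch <- list()
  if (expansion > 1L) {
    ch$expand <- nn_dense(in_channels, ce, bias = FALSE)
    ch$bn1 <- nn_batchnorm(ce)
    ch$act1 <- nn_act("silu")
  }
  ch$dw <- nn_dwconv(ce, kernel, stride, bias = FALSE)
  ch$bn2 <- nn_batchnorm(ce)
  ch$act2 <- nn_act("silu")
  if (self$use_se) {
    cs <- max(1L, as.integer(round(in_channels * se_ratio)))
    ch$se_fc1 <- nn_dense(ce, cs)
    ch$se_act <- nn_act("silu")
    ch$se_fc2 <- nn_dense(cs, ce)
    ch$se_gate <- nn_act("sigmoid")
  }
  ch$proj <- nn_dense(ce, out_channels, bias = FALSE)
  ch$bn3 <- nn_batchnorm(out_channels)
  self$children <- ch
  self$expansion <- expansion

  self$fwd <- function(fm, train = FALSE) {
    stopifnot_fmap(fm)
    if (fm$c != self$ci) stop(sprintf("mbconv expects %d channels, got %d", self$ci, fm$c))
    self$x0 <- fm
    h <- fm
    if (self$expansion > 1L) {
      h <- fmap_like(h, ch$expand$fwd(h$x, train))
      h <- ch$act1$fwd(ch$bn1$fwd(h, train), train)
    }
    h <- ch$act2$fwd(ch$bn2$fwd(ch$dw$fwd(h, train), train), train)
    if (self$use_se) {
      hw <- h$h * h$w
      grp <- gap_groups(h$n, hw)
      self$se_grp <- grp; self$se_hw <- hw; self$se_hd <- h
      s <- rowsum(h$x, grp) / hw
      a <- ch$se_gate$fwd(ch$se_fc2$fwd(ch$se_act$fwd(ch$se_fc1$fwd(s, train), train), train), train)
      dimnames(a) <- NULL  # rowsum() attaches group names
      self$se_a <- a
      h <- fmap_like(h, h$x * a[grp, , drop = FALSE])
    }
    y <- ch$bn3$fwd(fmap_like(h, ch$proj$fwd(h$x, train)), train)
    if (self$use_res) y <- fmap_like(y, y$x + fm$x)
    y
  }
  self$bwd <- function(dy) {
    dres <- if (self$use_res) dy$x else NULL
    d <- ch$bn3$bwd(dy)
    d <- fmap_like(d, ch$proj$bwd(d$x))
    if (self$use_se) {
      hd <- self$se_hd; grp <- self$se_grp; a <- self$se_a
      dhd <- d$x * a[grp, , drop = FALSE]
      da <- rowsum(d$x * hd$x, grp)
      ds <- ch$se_fc1$bwd(ch$se_act$bwd(ch$se_fc2$bwd(ch$se_gate$bwd(da))))
      dhd <- dhd + ds[grp, , drop = FALSE] / self$se_hw
      d <- fmap_like(hd, dhd)
    }
    d <- ch$dw$bwd(ch$bn2$bwd(ch$act2$bwd(d)))
    if (self$expansion > 1L) {
      d <- ch$bn1$bwd(ch$act1$bwd(d))
      d <- fmap_like(self$x0, ch$expand$bwd(d$x))
    }
    if (!is.null(dres)) d <- fmap_like(d, d$x + dres)
    d
  }
  self
}

#' Apply an MBConv block to a feature map
#'
#' Functional convenience around [nn_mbconv()]: builds (or reuses) a block and
#' runs its forward pass.
#'
#' @param x A [feature_map()].
#' @param cfg List with `in_channels`, `out_channels`, `expansion`, `kernel`,
#'   `stride`, `use_se` (missing entries take the constructor defaults).
#' @param layer Optionally a previously built [nn_mbconv()] layer; `cfg` is
#'   then ignored.
#' @param train Logical, training mode.
#' @return The output [feature_map()].
#' @export
mbconv_block <- function(x, cfg = list(), layer = NULL, train = FALSE) {
  if (is.null(layer)) {
    cfg <- modifyList(list(in_channels = x$c, out_channels = x$c, expansion = 6L,
                           kernel = 3L, stride = 1L, use_se = TRUE), cfg)
    if (cfg$in_channels != x$c)
      stop(sprintf("configured in_channels %d does not match input %d", cfg$in_channels, x$c))
    layer <- nn_mbconv(cfg$in_channels, cfg$out_channels, cfg$expansion,
                       cfg$kernel, cfg$stride, cfg$use_se)
  }
  layer_forward(layer, x, train)
}
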