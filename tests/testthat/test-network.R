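test_that("patch expansion doubles resolution while halving channels", {
  set.seed(1)
  x <- rand_fm(8, 8, 4, seed = 2)
  out <- patch_expand(x)
  expect_equal(dim(out)[1:3], c(16L, 16L, 2L))

  x2 <- rand_fm(7, 7, 192, seed = 3)
  expect_equal(dim(patch_expand(x2))[1:3], c(14L, 14L, 96L))

  # patch_expand after patch_merge restores the original shape
  y <- patch_expand(patch_merge(x))
  expect_equal(dim(y), dim(x))

  expect_error(nn_patch_expand(5), "even")
})

test_that("decoder concatenation puts the skip first and the upsampled map second", {
  a <- feature_map(array(1:4, c(2, 2, 1)))     # skip
  b <- feature_map(array(11:14, c(2, 2, 1)))   # upsampled
  cat_fm <- mambaseg:::new_fmap(cbind(a$x, b$x), 1L, 2L, 2L, 2L)
  arr <- as.array(cat_fm)
  expect_equal(arr[, , 1], array(1:4, c(2, 2)))
  expect_equal(arr[, , 2], array(11:14, c(2, 2)))
})

test_that("config validation rejects bad settings before building", {
  expect_error(network_config(input_size = 100L), "divisible by 32")
  expect_error(network_config(n_classes = 1L), "n_classes")
  expect_error(network_config("tiny", stage_channels = c(8L, 12L, 20L)), "length 4")
})

test_that("tiny network forward obeys the output contracts", {
  set.seed(4)
  net <- build_network(network_config("tiny"))
  x <- rand_fm(64, 64, 3, n = 2, seed = 5, fun = runif)
  out <- net_forward(net, x)
  expect_equal(dim(out$probabilities), c(64, 64, 2, 2))
  expect_equal(dim(out$labels), c(64, 64, 2))
  sums <- apply(out$probabilities, c(1, 2, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-5))       # per-pixel softmax
  expect_true(all(out$labels %in% c(0, 1)))

  # evaluation mode is deterministic
  out2 <- net_forward(net, x)
  expect_identical(out$probabilities, out2$probabilities)

  # spatial size errors and channel mismatches are reported
  expect_error(net_forward(net, rand_fm(60, 60, 3, seed = 6)), "divisible by 32")
  expect_error(net_forward(net, rand_fm(64, 64, 4, seed = 7)), "channels")
})

test_that("the head adapts to n_classes and input size (fully convolutional)", {
  set.seed(8)
  net3 <- build_network(network_config("tiny", n_classes = 3L))
  out <- net_forward(net3, rand_fm(64, 64, 3, seed = 9, fun = runif))
  expect_equal(dim(out$probabilities), c(64, 64, 3, 1))

  set.seed(10)
  net <- build_network(network_config("tiny"))
  p0 <- count_parameters(net)
  out96 <- net_forward(net, rand_fm(96, 96, 3, seed = 11, fun = runif))
  expect_equal(dim(out96$probabilities)[1:2], c(96, 96))
  expect_equal(count_parameters(net), p0)      # size change costs no weights
})

test_that("count_parameters sums trainable arrays exactly", {
  set.seed(12)
  head <- mambaseg:::nn_dense(4, 2, bias = TRUE)  # a 1x1 convolution
  expect_equal(count_parameters(head), 10L)        # 4*2 + 2 by hand

  net <- build_network(network_config("tiny"))
  manual <- sum(vapply(mambaseg:::walk_layers(net$root),
                       function(l) sum(vapply(l$p, length, 1L)), 1))
  expect_equal(count_parameters(net), manual)

  net$root$frozen <- TRUE
  expect_equal(count_parameters(net), 0L)          # frozen network
})

test_that("one optimization step leaves no dead branch", {
  set.seed(1)
  net <- build_network(network_config("tiny"))
  x <- rand_fm(64, 64, 3, n = 4, seed = 101, fun = runif)
  g <- array(0, c(64, 64, 4)); g[20:40, 20:40, ] <- 1
  out <- net_forward(net, x, train = TRUE)
  r <- mambaseg:::batch_loss_grad(out$prob_fm, g, loss_config())
  mambaseg:::net_backward(net, r$dlogits, wrt = "logits")
  for (l in mambaseg:::walk_layers(net$root))
    for (nm in names(l$p))
      expect_gt(max(abs(l$g[[nm]])), 0)
  mambaseg:::adamw_step(net$root, 1e-3, 1e-5, 1)
  out2 <- net_forward(net, x, train = TRUE)
  expect_false(identical(out$probabilities, out2$probabilities))
})

test_that("network backward matches finite differences through a smooth head", {
  set.seed(22)
  net <- build_network(network_config("tiny", input_size = 32L))
  x <- rand_fm(32, 32, 3, seed = 23, fun = runif)
  set.seed(24)
  W <- matrix(rnorm(32 * 32 * 2), 32 * 32, 2)
  lossf <- function() sum(net_forward(net, x, train = TRUE)$prob_fm$x * W)
  out <- net_forward(net, x, train = TRUE)
  mambaseg:::net_backward(net, mambaseg:::fmap_like(out$prob_fm, W))
  layers <- mambaseg:::walk_layers(net$root)
  set.seed(25)
  for (li in sample(length(layers), 6)) {
    l <- layers[[li]]
    nm <- sample(names(l$p), 1)
    i <- sample(length(l$p[[nm]]), 1)
    eps <- 1e-5
    p0 <- l$p[[nm]][i]
    l$p[[nm]][i] <- p0 + eps; lp <- lossf()
    l$p[[nm]][i] <- p0 - eps; lm <- lossf()
    l$p[[nm]][i] <- p0
    num <- (lp - lm) / (2 * eps)
    expect_equal(l$g[[nm]][i], num, tolerance = 2e-3)
  }
})

test_that("the summary table mirrors the configured architecture", {
  tab <- network_summary(network_config("default"))
  expect_equal(nrow(tab), 11)
  expect_equal(tab$channels, c(3, 32, 48, 80, 112, 192, 112, 80, 48, 32, 2))
  expect_equal(tab$resolution[6], "7x7")
  expect_equal(tab$sab_cab[6:10], rep("Yes", 5))
  expect_equal(tab$sab_cab[2:5], rep("No", 4))
})
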