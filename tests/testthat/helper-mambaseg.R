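# Shared fixtures and oracles for the test suite.

# deterministic random feature map
rand_fm <- function(h, w, c, n = 1L, seed = 1L, fun = rnorm) {
  set.seed(seed)
  feature_map(array(fun(h * w * c * n), c(h, w, c, n)))
}

# brute-force reference for the 1D state-space recurrence (R loop)
unrolled_scan <- function(x, A, B, C, D) {
  x <- as.matrix(x)
  S <- ncol(A)
  y <- matrix(0, nrow(x), ncol(x))
  for (ch in seq_len(ncol(x))) {
    h <- rep(0, S)
    for (t in seq_len(nrow(x))) {
      h <- A[ch, ] * h + B[ch, ] * x[t, ch]
      y[t, ch] <- sum(C[ch, ] * h) + D[ch] * x[t, ch]
    }
  }
  y
}

# finite-difference gradient check of a layer (input + sampled parameters)
fd_layer_check <- function(layer, x_fm, eps = 1e-5, nprobe = 5, seed = 99) {
  set.seed(seed)
  y0 <- layer$fwd(x_fm, TRUE)
  W <- matrix(rnorm(length(y0$x)), nrow(y0$x), ncol(y0$x))
  lossf <- function() sum(layer$fwd(x_fm, TRUE)$x * W)
  mambaseg:::zero_grads(layer)
  y <- layer$fwd(x_fm, TRUE)
  dx <- layer$bwd(mambaseg:::fmap_like(y, W))
  errs <- c()
  for (i in sample(length(x_fm$x), min(nprobe, length(x_fm$x)))) {
    x0 <- x_fm$x[i]
    x_fm$x[i] <- x0 + eps; lp <- lossf()
    x_fm$x[i] <- x0 - eps; lm <- lossf()
    x_fm$x[i] <- x0
    errs <- c(errs, abs((lp - lm) / (2 * eps) - dx$x[i]) / max(1, abs(dx$x[i])))
  }
  for (l in mambaseg:::walk_layers(layer)) for (nm in names(l$p)) {
    for (i in sample(length(l$p[[nm]]), min(2, length(l$p[[nm]])))) {
      p0 <- l$p[[nm]][i]
      l$p[[nm]][i] <- p0 + eps; lp <- lossf()
      l$p[[nm]][i] <- p0 - eps; lm <- lossf()
      l$p[[nm]][i] <- p0
      errs <- c(errs, abs((lp - lm) / (2 * eps) - l$g[[nm]][i]) / max(1, abs(l$g[[nm]][i])))
    }
  }
  max(errs)
}

# tiny slice fixture: bright square lesion on a noisy background, C channels
toy_slice <- function(h = 16L, w = 16L, c = 3L, seed = 5L) {
  set.seed(seed)
  img <- array(runif(h * w * c, 0, 0.4), c(h, w, c))
  msk <- array(0, c(h, w))
  msk[5:9, 6:10] <- 1
  for (ch in seq_len(c)) img[, , ch] <- pmin(1, img[, , ch] + msk * 0.5)
  structure(list(image = img, mask = msk,
                 source = list(volume_id = "toy", slice = 1L)),
            class = "mm_slice")
}

# shared tiny synthetic dataset on disk (built once per test run)
shared_dataset <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "mambaseg-shared-ds")
      if (!dir.exists(dir)) {
        spec <- synthetic_spec(volume_shape = c(32L, 32L, 8L),
                               lesion_radius_range = c(3, 6),
                               smooth_field_scale = 6)
        generate_dataset(spec, 8, dir, seed = 42)
      }
    }
    dir
  }
})
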