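test_that("active contour loss matches hand-computed discretizations", {
  cfg <- loss_config(lambda_length = 1, lambda_region = 1)
  flat <- matrix(1, 4, 4)
  expect_equal(active_contour_loss(flat, flat, cfg), 0)   # flat perfect prediction

  phi <- matrix(c(1, 1, 0, 0), 2, 2)  # columns (1,1) and (0,0)
  expect_equal(active_contour_loss(phi, phi, cfg), 0.5)   # |grad| total 2 over 4 px

  set.seed(1)
  g <- matrix(rbinom(36, 1, 0.4), 6, 6)
  cfg0 <- loss_config(lambda_length = 0, lambda_region = 2.5)
  # phi = 1 - g: (phi - g)^2 = 1 at every pixel (exhaustive-loop oracle)
  brute <- mean(vapply(seq_along(g), function(i) ((1 - g[i]) - g[i])^2, 1))
  expect_equal(brute, 1)
  expect_equal(active_contour_loss(1 - g, g, cfg0), 2.5)
})

test_that("active contour loss is nonnegative and zero only for flat perfect maps", {
  cfg <- loss_config()
  set.seed(2)
  for (i in 1:5) {
    phi <- matrix(runif(25), 5, 5)
    g <- matrix(rbinom(25, 1, 0.3), 5, 5)
    expect_gte(active_contour_loss(phi, g, cfg), 0)
  }
  expect_gt(active_contour_loss(matrix(0.5, 3, 3), matrix(0, 3, 3), cfg), 0)
  expect_equal(active_contour_loss(matrix(0, 3, 3), matrix(0, 3, 3), cfg), 0)
})

test_that("focal loss reproduces closed-form values and the cross-entropy limit", {
  # single pixel, p_t = 0.9, alpha 0.25, gamma 2
  cfg <- loss_config(alpha = 0.25, gamma = 2)
  val <- focal_loss(matrix(0.9), matrix(1), cfg)
  expect_equal(val, 0.25 * 0.01 * -log(0.9), tolerance = 1e-10)
  expect_equal(val, 2.634e-4, tolerance = 1e-3)

  # gamma 0, alpha 1 is exactly binary cross-entropy
  cfg_ce <- loss_config(alpha = 1, gamma = 0)
  expect_equal(focal_loss(matrix(0.5), matrix(1), cfg_ce), log(2), tolerance = 1e-12)
  set.seed(3)
  phi <- matrix(runif(64, 0.05, 0.95), 8, 8)
  g <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_equal(focal_loss(phi, g, cfg_ce), mambaseg:::bce_loss(phi, g),
               tolerance = 1e-7)

  # perfectly confident prediction has (numerically) zero loss
  eps <- loss_config()$epsilon
  expect_lt(focal_loss(matrix(1 - eps), matrix(1), loss_config()), 1e-10)
})

test_that("hybrid loss combines components with weight beta", {
  set.seed(4)
  phi <- matrix(runif(64), 8, 8)
  g <- matrix(rbinom(64, 1, 0.3), 8, 8)
  cfg <- loss_config(beta = 0.3)
  l <- hybrid_loss(phi, g, cfg)
  expect_equal(l$total, l$ac + 0.3 * l$focal)
  # combination arithmetic: components (1, 2) with beta 0.3 combine to 1.6
  expect_equal(1.0 + 0.3 * 2.0, 1.6)

  l0 <- hybrid_loss(phi, g, loss_config(beta = 0))
  expect_equal(l0$total, l0$ac)                 # beta = 0 collapses to ACL

  flat <- matrix(1, 6, 6)
  expect_lt(hybrid_loss(flat, flat)$total, 1e-9)

  # monotone nondecreasing in beta while the focal component is positive
  betas <- c(0, 0.1, 0.3, 0.5, 1)
  tots <- vapply(betas, function(b) hybrid_loss(phi, g, loss_config(beta = b))$total, 1)
  expect_true(all(diff(tots) >= 0))
  expect_gt(l$focal, 0)
})

test_that("loss gradients match finite differences away from clamps and kinks", {
  set.seed(5)
  cfg <- loss_config()
  phi <- matrix(runif(36, 0.15, 0.85), 6, 6)
  g <- matrix(rbinom(36, 1, 0.4), 6, 6)
  r <- mambaseg:::hybrid_loss_grad(phi, g, cfg)
  eps <- 1e-6
  for (i in sample(36, 8)) {
    p0 <- phi[i]
    phi[i] <- p0 + eps; lp <- hybrid_loss(phi, g, cfg)$total
    phi[i] <- p0 - eps; lm <- hybrid_loss(phi, g, cfg)$total
    phi[i] <- p0
    expect_equal(r$grad[i], (lp - lm) / (2 * eps), tolerance = 1e-3)
  }
})

test_that("logit-space gradient equals the phi-space chain away from saturation", {
  set.seed(6)
  cfg <- loss_config()
  phi <- matrix(runif(64, 0.1, 0.9), 8, 8)
  g <- matrix(rbinom(64, 1, 0.4), 8, 8)
  r_phi <- mambaseg:::hybrid_loss_grad(phi, g, cfg)
  r_z <- mambaseg:::hybrid_logit_grad(phi, g, cfg)
  expect_equal(r_z$total_grad, r_phi$grad * phi * (1 - phi), tolerance = 1e-10)
  expect_equal(r_z$ac + cfg$beta * r_z$focal, r_phi$total, tolerance = 1e-10)

  # at saturation the logit gradient stays finite and keeps pushing
  # misclassified foreground upwards
  phi_sat <- matrix(1e-12, 2, 2)
  g_fg <- matrix(1, 2, 2)
  rz <- mambaseg:::hybrid_logit_grad(phi_sat, g_fg, cfg)
  expect_true(all(is.finite(rz$total_grad)))
  expect_true(all(rz$total_grad < 0))   # descent increases the fg logit
})

test_that("invalid prediction pairs are rejected", {
  expect_error(hybrid_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(focal_loss(matrix(1.2, 2, 2), matrix(1, 2, 2)), "\\[0, 1\\]")
  expect_error(active_contour_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2)), "binary")
  expect_error(loss_config(alpha = 0), "alpha")
  expect_error(loss_config(beta = -1), "beta")
})
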