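# Segmentation losses.
#
# Active Contour Loss penalises boundary length (L1 norm of the forward
# finite-difference gradient of the predicted probability map, replicated
# border) and region inconsistency ((phi - g)^2); both integrals are taken as
# means over the pixel grid so the default weights are resolution
# independent. Focal Loss down-weights well-classified pixels. The hybrid
# training objective is L_AC + beta * L_Focal.

#' Loss configuration
#'
#' @param lambda_length,lambda_region Nonnegative weights of the boundary and
#'   region terms of the Active Contour Loss. The boundary term is a
#'   total-variation regulariser whose subgradient has unit magnitude even on
#'   visually flat regions; its default weight therefore sits an order of
#'   magnitude below the data-fit terms.
#' @param alpha Focal Loss class-balance factor in (0, 1]; the default 0.75
#'   favours the (rare) lesion foreground.
#' @param gamma Focal Loss focusing exponent (>= 0).
#' @param beta Hybrid weight on the Focal term (>= 0).
#' @param epsilon Probability clamp used inside the Focal logarithm.
#' @return A named list of class `seg_loss_config`.
#' @export
loss_config <- function(lambda_length = 0.05, lambda_region = 1, alpha = 0.75,
                        gamma = 2, beta = 0.3, epsilon = 1e-7) {
  stopifnot(lambda_length >= 0, lambda_region >= 0,
            alpha > 0, alpha <= 1, gamma >= 0, beta >= 0, epsilon > 0)
  structure(list(lambda_length = lambda_length, lambda_region = lambda_region,
                 alpha = alpha, gamma = gamma, beta = beta, epsilon = epsilon),
            class = "seg_loss_config")
}

check_pair <- function(phi, g) {
  if (is.null(dim(phi))) phi <- as.matrix(phi)
  if (is.null(dim(g))) g <- as.matrix(g)
  if (!all(dim(phi) == dim(g)))
    stop("prediction and ground truth must share shape")
  if (any(phi < 0 | phi > 1)) stop("predicted probabilities must lie in [0, 1]")
  if (!all(g %in% c(0, 1))) stop("ground truth must be binary")
  list(phi = phi, g = g)
}

#' Active Contour Loss
#'
#' `lambda_length * mean(|grad phi|) + lambda_region * mean((phi - g)^2)`,
#' where `|grad phi|` is the L1 norm of forward differences with a replicated
#' border and both means run over all pixels.
#'
#' @param phi Predicted foreground-probability map (matrix, values in
#'   `[0, 1]`).
#' @param g Binary ground-truth mask of the same shape.
#' @param config A [loss_config()].
#' @return Scalar loss.
#' @examples
#' phi <- matrix(c(1, 1, 0, 0), 2, 2)
#' active_contour_loss(phi, phi)  # region term 0, mean |grad| = 0.5
#' @export
active_contour_loss <- function(phi, g, config = loss_config()) {
  p <- check_pair(phi, g)
  acl_terms(p$phi, p$g, config)$loss
}

acl_terms <- function(phi, g, cfg, grad = FALSE) {
  h <- nrow(phi); w <- ncol(phi); n <- h * w
  dxh <- if (w > 1L) phi[, -1L, drop = FALSE] - phi[, -w, drop = FALSE] else matrix(0, h, 0)
  dxv <- if (h > 1L) phi[-1L, , drop = FALSE] - phi[-h, , drop = FALSE] else matrix(0, 0, w)
  len <- (sum(abs(dxh)) + sum(abs(dxv))) / n
  reg <- mean((phi - g)^2)
  loss <- cfg$lambda_length * len + cfg$lambda_region * reg
  if (!grad) return(list(loss = loss, length = len, region = reg))
  gr <- 2 * cfg$lambda_region * (phi - g) / n
  if (w > 1L) {
    s <- sign(dxh) * cfg$lambda_length / n
    gr[, -w] <- gr[, -w] - s
    gr[, -1L] <- gr[, -1L] + s
  }
  if (h > 1L) {
    s <- sign(dxv) * cfg$lambda_length / n
    gr[-h, ] <- gr[-h, ] - s
    gr[-1L, ] <- gr[-1L, ] + s
  }
  list(loss = loss, length = len, region = reg, grad = gr)
}

#' Focal Loss
#'
#' Mean over pixels of `-alpha * (1 - p_t)^gamma * log(p_t)` with
#' `p_t = phi` on foreground and `1 - phi` on background; probabilities are
#' clamped to `[epsilon, 1 - epsilon]` before the logarithm. With
#' `gamma = 0, alpha = 1` this reduces exactly to mean binary cross-entropy.
#'
#' @inheritParams active_contour_loss
#' @return Scalar loss.
#' @export
focal_loss <- function(phi, g, config = loss_config()) {
  p <- check_pair(phi, g)
  focal_terms(p$phi, p$g, config)$loss
}

focal_terms <- function(phi, g, cfg, grad = FALSE) {
  phic <- pmin(pmax(phi, cfg$epsilon), 1 - cfg$epsilon)
  pt <- ifelse(g == 1, phic, 1 - phic)
  omp <- 1 - pt
  loss <- mean(-cfg$alpha * omp^cfg$gamma * log(pt))
  if (!grad) return(list(loss = loss))
  n <- length(phi)
  dpt <- if (cfg$gamma == 0) -cfg$alpha / pt
         else cfg$alpha * (cfg$gamma * omp^(cfg$gamma - 1) * log(pt) - omp^cfg$gamma / pt)
  dphi <- dpt * ifelse(g == 1, 1, -1) / n
  dphi[phi < cfg$epsilon | phi > 1 - cfg$epsilon] <- 0  # clamped region
  list(loss = loss, grad = dphi)
}

#' Hybrid Active-Contour + Focal Loss
#'
#' The training objective `L_AC + beta * L_Focal`.
#'
#' @inheritParams active_contour_loss
#' @return List with `total`, `ac` and `focal` components.
#' @examples
#' g <- matrix(rbinom(64, 1, 0.2), 8, 8)
#' phi <- matrix(runif(64), 8, 8)
#' l <- hybrid_loss(phi, g)
#' all.equal(l$total, l$ac + 0.3 * l$focal)
#' @export
hybrid_loss <- function(phi, g, config = loss_config()) {
  p <- check_pair(phi, g)
  ac <- acl_terms(p$phi, p$g, config)$loss
  fl <- focal_terms(p$phi, p$g, config)$loss
  list(total = ac + config$beta * fl, ac = ac, focal = fl)
}

# loss + gradient w.r.t. phi for one slice (used by the training loop and the
# finite-difference gradient tests)
hybrid_loss_grad <- function(phi, g, cfg) {
  a <- acl_terms(phi, g, cfg, grad = TRUE)
  f <- focal_terms(phi, g, cfg, grad = TRUE)
  list(total = a$loss + cfg$beta * f$loss, ac = a$loss, focal = f$loss,
       grad = a$grad + cfg$beta * f$grad)
}

# mean binary cross-entropy, logged alongside the hybrid loss during training
bce_loss <- function(phi, g, eps = 1e-7) {
  phic <- pmin(pmax(phi, eps), 1 - eps)
  -mean(g * log(phic) + (1 - g) * log(1 - phic))
}

# Gradient of the hybrid loss w.r.t. the foreground *logit* (the difference of
# the two softmax logits). The focal term's 1/p_t singularity cancels against
# the softmax Jacobian phi*(1-phi) analytically; evaluating the cancelled form
# keeps a nonvanishing training signal on misclassified pixels even when the
# softmax has saturated (phi ~ 0 or 1), where the phi-space chain underflows.
hybrid_logit_grad <- function(phi, g, cfg) {
  n <- length(phi)
  xlogx <- function(p) ifelse(p <= 0, 0, p * log(p))
  fg <- g == 1
  omp <- 1 - phi
  dz_focal <- matrix(0, nrow(phi), ncol(phi))
  # d/dz of -alpha (1-p)^g log p  for foreground pixels
  dz_focal[fg] <- cfg$alpha * omp[fg]^cfg$gamma *
    (cfg$gamma * xlogx(phi[fg]) - omp[fg])
  # d/dz of -alpha p^g log(1-p)  for background pixels
  dz_focal[!fg] <- -cfg$alpha * phi[!fg]^cfg$gamma *
    (cfg$gamma * xlogx(omp[!fg]) - phi[!fg])
  dz_focal <- dz_focal / n
  # region + length terms: phi-space gradient times the softmax Jacobian
  a <- acl_terms(phi, g, cfg, grad = TRUE)
  dz_acl <- a$grad * phi * omp
  list(total_grad = dz_acl + cfg$beta * dz_focal,
       ac = a$loss, focal = focal_terms(phi, g, cfg)$loss)
}
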