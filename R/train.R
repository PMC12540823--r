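# Training loop (AdamW + cosine annealing + early stopping on validation
# hybrid loss), slice-wise volume inference, and dataset-level evaluation.

#' Training configuration
#'
#' Defaults follow the reference training recipe: AdamW with initial learning rate
#' 1e-4 and decoupled weight decay 1e-5, cosine annealing over 100 epochs to
#' 1e-6, batch size 8, early stopping with patience 10 monitored on the
#' validation hybrid loss every epoch.
#'
#' @param lr0 Initial learning rate.
#' @param lr_min Final learning rate of the cosine schedule.
#' @param weight_decay Decoupled weight decay.
#' @param epochs Length of the cosine schedule (and maximum epochs).
#' @param batch_size Slices per optimization step.
#' @param patience Early-stopping patience, epochs.
#' @param max_steps Optional cap on total optimization steps.
#' @param loss A [loss_config()].
#' @param augment Apply random augmentation to training slices.
#' @param seed Seed for shuffling/augmentation/initialisation bookkeeping.
#' @return Named list of class `seg_train_config`.
#' @export
train_config <- function(lr0 = 1e-4, lr_min = 1e-6, weight_decay = 1e-5,
                         epochs = 100L, batch_size = 8L, patience = 10L,
                         max_steps = Inf, loss = loss_config(), augment = TRUE,
                         seed = 1L) {
  stopifnot(lr_min < lr0, patience >= 1, batch_size >= 1, epochs >= 1)
  structure(list(lr0 = lr0, lr_min = lr_min, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 patience = as.integer(patience), max_steps = max_steps,
                 loss = loss, augment = augment, seed = as.integer(seed)),
            class = "seg_train_config")
}

#' Cosine annealing learning rate
#'
#' `lr(e) = lr_min + (lr0 - lr_min) * (1 + cos(pi * e / epochs)) / 2`.
#'
#' @param epoch Epoch index (0-based; `epoch = epochs` gives `lr_min`).
#' @param lr0,lr_min,epochs Schedule endpoints and length.
#' @return Learning rate.
#' @export
cosine_lr <- function(epoch, lr0 = 1e-4, lr_min = 1e-6, epochs = 100L) {
  lr_min + (lr0 - lr_min) * (1 + cos(pi * epoch / epochs)) / 2
}

#' Early-stopping epoch for a validation-loss history
#'
#' Training halts after `patience` consecutive epochs without strict
#' improvement over the best validation loss seen so far.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Number of non-improving epochs tolerated.
#' @return The 1-based epoch index at which training stops, or `NA` if the
#'   history never triggers stopping.
#' @export
early_stopping_epoch <- function(val_losses, patience = 10L) {
  best <- Inf; bad <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) { best <- val_losses[e]; bad <- 0L }
    else {
      bad <- bad + 1L
      if (bad >= patience) return(e)
    }
  }
  NA_integer_
}

adamw_step <- function(root, lr, weight_decay, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (l in walk_layers(root)) {
    if (is.null(l$opt)) l$opt <- lapply(l$p, function(a)
      list(m = array(0, dim(a) %||% length(a)), v = array(0, dim(a) %||% length(a))))
    for (nm in names(l$p)) {
      g <- l$g[[nm]]
      st <- l$opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l$p[[nm]] <- l$p[[nm]] - lr * mhat / (sqrt(vhat) + eps) -
        lr * weight_decay * l$p[[nm]]
      l$opt[[nm]] <- st
    }
  }
  invisible(root)
}

snapshot_params <- function(root) {
  lapply(walk_layers(root), function(l)
    list(p = l$p, rm = l$rm, rv = l$rv))
}

restore_params <- function(root, snap) {
  ls <- walk_layers(root)
  stopifnot(length(ls) == length(snap))
  for (i in seq_along(ls)) {
    ls[[i]]$p <- snap[[i]]$p
    if (!is.null(snap[[i]]$rm)) { ls[[i]]$rm <- snap[[i]]$rm; ls[[i]]$rv <- snap[[i]]$rv }
  }
  invisible(root)
}

# Load, normalise, stack and slice every volume of one manifest split.
prepare_split_slices <- function(manifest, split, input_size, lesion_only = TRUE) {
  dir <- attr(manifest, "dir") %||% "."
  sub <- manifest[manifest$split == split, , drop = FALSE]
  vols <- unique(sub$volume_id)
  slices <- list()
  for (vid in vols) {
    rows <- sub[sub$volume_id == vid, , drop = FALSE]
    img_rows <- rows[rows$role == "image", , drop = FALSE]
    img_rows <- img_rows[order(img_rows$modality), , drop = FALSE]
    mods <- lapply(seq_len(nrow(img_rows)), function(i)
      normalize_volume(load_nifti_volume(file.path(dir, img_rows$file[i]),
                                         paste0("mod", img_rows$modality[i]))))
    mask <- load_nifti_volume(file.path(dir, rows$file[rows$role == "mask"][1]), "mask")
    mmv <- stack_modalities(mods)
    sl <- extract_axial_slices(mmv, mask, lesion_only = lesion_only, volume_id = vid)
    sl <- lapply(sl, resize_slice, size = c(input_size, input_size))
    slices <- c(slices, sl)
  }
  slices
}

slices_to_batch <- function(slices) {
  h <- dim(slices[[1]]$image)[1]; w <- dim(slices[[1]]$image)[2]
  cc <- dim(slices[[1]]$image)[3]; n <- length(slices)
  x <- array(0, c(h, w, cc, n)); g <- array(0, c(h, w, n))
  for (i in seq_len(n)) { x[, , , i] <- slices[[i]]$image; g[, , i] <- slices[[i]]$mask }
  list(x = feature_map(x), g = g)
}

# phi (foreground probability) per sample from the output probability map
prob_to_phi <- function(prob_fm) {
  hw <- prob_fm$h * prob_fm$w
  lapply(seq_len(prob_fm$n), function(i)
    matrix(prob_fm$x[(i - 1) * hw + seq_len(hw), 2L], prob_fm$h, prob_fm$w, byrow = TRUE))
}

# Batch loss (mean of per-slice losses) and its gradient w.r.t. the logits.
batch_loss_grad <- function(prob_fm, g, loss_cfg) {
  n <- prob_fm$n; hw <- prob_fm$h * prob_fm$w
  phis <- prob_to_phi(prob_fm)
  dz <- matrix(0, nrow(prob_fm$x), ncol(prob_fm$x))
  tot <- ac <- fl <- bce <- 0
  for (i in seq_len(n)) {
    gi <- array(g[, , i], c(prob_fm$h, prob_fm$w))
    r <- hybrid_logit_grad(phis[[i]], gi, loss_cfg)
    tot <- tot + (r$ac + loss_cfg$beta * r$focal) / n
    ac <- ac + r$ac / n; fl <- fl + r$focal / n
    bce <- bce + bce_loss(phis[[i]], gi) / n
    dzi <- as.vector(t(r$total_grad)) / n
    dz[(i - 1) * hw + seq_len(hw), 2L] <- dzi
    dz[(i - 1) * hw + seq_len(hw), 1L] <- -dzi
  }
  list(total = tot, ac = ac, focal = fl, bce = bce,
       dlogits = fmap_like(prob_fm, dz))
}

batch_eval_loss <- function(net, slices, batch_size, loss_cfg) {
  tot <- ac <- fl <- bce <- 0; nb <- 0
  for (s in seq(1, length(slices), by = batch_size)) {
    b <- slices_to_batch(slices[s:min(s + batch_size - 1, length(slices))])
    out <- net_forward(net, b$x, train = FALSE)
    r <- batch_loss_grad(out$prob_fm, b$g, loss_cfg)
    tot <- tot + r$total; ac <- ac + r$ac; fl <- fl + r$focal; bce <- bce + r$bce
    nb <- nb + 1
  }
  c(total = tot / nb, ac = ac / nb, focal = fl / nb, bce = bce / nb)
}

#' Train the segmentation network
#'
#' Optimises the hybrid Active-Contour + Focal loss with AdamW under a cosine
#' learning-rate schedule, validating every epoch and stopping early after
#' `patience` epochs without improvement; the best-validation weights are
#' restored at the end.
#'
#' @param net A `seg_network` (weights are updated in place).
#' @param manifest A dataset manifest data.frame from [generate_dataset()] /
#'   [read_manifest()], or the dataset directory. Must contain `train` and
#'   `val` splits; training uses lesion-bearing slices only.
#' @param cfg A [train_config()].
#' @param quiet Suppress per-epoch progress messages.
#' @return List with the trained `net`, `history` (per-epoch data.frame),
#'   `best_epoch` and total `steps`; class `seg_fit`.
#' @export
train_network <- function(net, manifest, cfg = train_config(), quiet = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  set.seed(cfg$seed)
  tr <- prepare_split_slices(manifest, "train", net$config$input_size)
  va <- prepare_split_slices(manifest, "val", net$config$input_size)
  if (!length(tr)) stop("training split is empty")
  if (!length(va)) stop("validation split is empty")
  hist_rows <- list()
  step <- 0L; best <- Inf; best_snap <- NULL; best_epoch <- NA_integer_
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch - 1L, cfg$lr0, cfg$lr_min, cfg$epochs)
    ord <- sample(length(tr))
    ep_tot <- ep_ac <- ep_fl <- 0; nb <- 0L
    for (s in seq(1, length(tr), by = cfg$batch_size)) {
      if (step >= cfg$max_steps) break
      idx <- ord[s:min(s + cfg$batch_size - 1, length(tr))]
      sl <- tr[idx]
      if (isTRUE(cfg$augment)) sl <- lapply(sl, augment_slice)
      b <- slices_to_batch(sl)
      out <- net_forward(net, b$x, train = TRUE)
      r <- batch_loss_grad(out$prob_fm, b$g, cfg$loss)
      net_backward(net, r$dlogits, wrt = "logits")
      step <- step + 1L
      adamw_step(net$root, lr, cfg$weight_decay, step)
      zero_grads(net$root)
      ep_tot <- ep_tot + r$total; ep_ac <- ep_ac + r$ac; ep_fl <- ep_fl + r$focal
      nb <- nb + 1L
    }
    if (nb == 0L) break
    vl <- batch_eval_loss(net, va, cfg$batch_size, cfg$loss)
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, step = step, lr = lr,
      train_total = ep_tot / nb, train_ac = ep_ac / nb, train_focal = ep_fl / nb,
      val_total = vl["total"], val_ac = vl["ac"], val_focal = vl["focal"],
      val_bce = vl["bce"], row.names = NULL)
    if (!quiet)
      message(sprintf("epoch %3d | lr %.2e | train %.4f | val %.4f",
                      epoch, lr, ep_tot / nb, vl["total"]))
    if (vl["total"] < best) {
      best <- vl["total"]; best_snap <- snapshot_params(net$root); best_epoch <- epoch
    }
    history <- do.call(rbind, hist_rows)
    if (!is.na(early_stopping_epoch(history$val_total, cfg$patience))) {
      if (!quiet) message("early stopping at epoch ", epoch)
      break
    }
    if (step >= cfg$max_steps) break
  }
  if (!is.null(best_snap)) restore_params(net$root, best_snap)
  structure(list(net = net, history = do.call(rbind, hist_rows),
                 best_epoch = best_epoch, steps = step),
            class = "seg_fit")
}

#' @export
print.seg_fit <- function(x, ...) {
  cat(sprintf("<seg_fit: %d epochs, %d steps, best epoch %s (val loss %.4f)>\n",
              nrow(x$history), x$steps, x$best_epoch,
              min(x$history$val_total)))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' Checkpoints embed the network configuration, all weights and batch-norm
#' statistics, plus optional history/seed provenance and package versions.
#'
#' @param net A `seg_network`.
#' @param path Output `.rds` path.
#' @param history,seed Optional provenance stored alongside the weights.
#' @return `path` invisibly (`save_checkpoint`); a rebuilt `seg_network`
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(net, path, history = NULL, seed = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  obj <- list(config = net$config, params = snapshot_params(net$root),
              history = history, seed = seed,
              versions = list(mambaseg = as.character(utils::packageVersion("mambaseg")),
                              R = R.version.string))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  net <- build_network(do.call(network_config,
                               c(list(preset = obj$config$preset),
                                 obj$config[setdiff(names(obj$config), "preset")])))
  net$config <- obj$config
  restore_params(net$root, obj$params)
  net
}

#' Predict the lesion mask of one volume
#'
#' Normalises and stacks the modality volumes, runs the network slice by
#' slice in evaluation mode (resizing to the network input size and back)
#' and reassembles a binary 3D mask aligned with the input grid.
#'
#' @param net A trained `seg_network`.
#' @param image_paths Character vector of per-modality NIfTI paths, in
#'   training modality order; or a prebuilt `seg_mm_volume`.
#' @param out_path Optional NIfTI output path for the predicted mask.
#' @param batch_size Slices per forward pass.
#' @return The predicted mask as a `seg_volume` (values 0/1).
#' @export
predict_volume <- function(net, image_paths, out_path = NULL, batch_size = 8L) {
  mmv <- if (inherits(image_paths, "seg_mm_volume")) image_paths
  else stack_modalities(lapply(image_paths, function(p)
    normalize_volume(load_nifti_volume(p))))
  d <- dim(mmv$data)
  if (d[4] != net$config$input_channels)
    stop(sprintf("volume has %d modalities but the network expects %d",
                 d[4], net$config$input_channels))
  isz <- net$config$input_size
  dummy_mask <- array(0, d[1:3])
  slices <- extract_axial_slices(mmv, dummy_mask, lesion_only = FALSE)
  slices <- lapply(slices, resize_slice, size = c(isz, isz))
  labs <- array(0L, d[1:3])
  for (s in seq(1, length(slices), by = batch_size)) {
    idx <- s:min(s + batch_size - 1, length(slices))
    b <- slices_to_batch(slices[idx])
    out <- net_forward(net, b$x, train = FALSE)
    for (j in seq_along(idx)) {
      lab <- array(out$labels[, , j], c(isz, isz))
      if (!all(d[1:2] == c(isz, isz)))
        lab <- array(EBImage::resize(lab, w = d[1], h = d[2], filter = "none"), d[1:2])
      labs[, , idx[j]] <- as.integer(lab != 0)
    }
  }
  vol <- new_volume(labs, mmv$spacing, "prediction")
  if (!is.null(out_path)) write_nifti(vol, out_path)
  vol
}

#' Evaluate a trained network on a dataset split
#'
#' Runs slice-wise inference per volume and assembles the full metric report
#' (volume-level DSC, precision, recall, F1, mIoU, ASSD, HD in mm, plus the
#' mean slice-level DSC), with a mean/sd summary.
#'
#' @param net A trained `seg_network`.
#' @param manifest Manifest data.frame or dataset directory.
#' @param split Which split to evaluate (`"test"`, `"val"` or `"train"`).
#' @param file Optional CSV output path.
#' @return List with `cases` and `summary` data.frames.
#' @export
evaluate_dataset <- function(net, manifest, split = "test", file = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir <- attr(manifest, "dir") %||% "."
  sub <- manifest[manifest$split == split, , drop = FALSE]
  if (!nrow(sub)) stop("no volumes in split '", split, "'")
  vols <- unique(sub$volume_id)
  preds <- list(); gts <- list(); slice_dsc <- numeric(0)
  spacing <- NULL
  for (vid in vols) {
    rows <- sub[sub$volume_id == vid, , drop = FALSE]
    img_rows <- rows[rows$role == "image", , drop = FALSE]
    img_rows <- img_rows[order(img_rows$modality), , drop = FALSE]
    mask <- load_nifti_volume(file.path(dir, rows$file[rows$role == "mask"][1]))
    pred <- predict_volume(net, file.path(dir, img_rows$file))
    spacing <- mask$spacing
    preds[[vid]] <- pred$data; gts[[vid]] <- mask$data
    per_slice <- vapply(seq_len(dim(mask$data)[3]), function(z) {
      overlap_metrics(confusion_counts(pred$data[, , z], mask$data[, , z]))$dsc
    }, 1)
    slice_dsc <- c(slice_dsc, mean(per_slice))
  }
  res <- evaluate_cases(preds, gts, ids = vols, spacing = spacing)
  res$cases$slice_dsc <- slice_dsc
  if (!is.null(file)) {
    num <- res$cases[, -1L, drop = FALSE]
    summ <- rbind(
      data.frame(case = "mean", as.list(colMeans(num)), stringsAsFactors = FALSE),
      data.frame(case = "sd", as.list(apply(num, 2L, stats::sd)), stringsAsFactors = FALSE))
    write.csv(rbind(res$cases, summ), file, row.names = FALSE)
  }
  res
}

#' Hyperparameter sweep over the loss grids
#'
#' Re-trains a fresh model for each value of the Focal `alpha` grid (at fixed
#' `beta`) and the hybrid `beta` grid (at fixed `alpha`) on a synthetic
#' dataset and tabulates validation mIoU and foreground F1, mirroring the
#' reference ablation tables.
#'
#' @param manifest Dataset manifest or directory.
#' @param alphas,betas Grids to sweep.
#' @param net_config Network configuration used for every run.
#' @param cfg Base [train_config()]; each run copies it with the swept value.
#' @param quiet Passed to [train_network()].
#' @return data.frame with columns `parameter`, `value`, `miou`, `f1`.
#' @export
loss_sweep <- function(manifest,
                       alphas = c(0.25, 0.5, 0.75, 0.9),
                       betas = c(0.1, 0.3, 0.5, 0.7, 1.0),
                       net_config = network_config("tiny"),
                       cfg = train_config(lr0 = 5e-3, max_steps = 100,
                                          augment = FALSE, patience = 30L),
                       quiet = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  run_one <- function(param, value) {
    lc <- cfg$loss
    if (param == "alpha") lc$alpha <- value else lc$beta <- value
    cfg2 <- cfg; cfg2$loss <- lc
    set.seed(cfg$seed)
    net <- build_network(net_config)
    fit <- train_network(net, manifest, cfg2, quiet = quiet)
    ev <- evaluate_dataset(fit$net, manifest, "val")
    data.frame(parameter = param, value = value,
               miou = mean(ev$cases$miou), f1 = mean(ev$cases$f1),
               stringsAsFactors = FALSE)
  }
  rows <- c(lapply(alphas, function(a) run_one("alpha", a)),
            lapply(betas, function(b) run_one("beta", b)))
  do.call(rbind, rows)
}
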