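test_that("cosine schedule matches its closed form at the checkpoints", {
  lr <- function(e) cosine_lr(e, 1e-4, 1e-6, 100)
  expect_equal(lr(0), 1e-4)
  expect_equal(lr(100), 1e-6)
  expect_equal(lr(50), 1e-6 + (1e-4 - 1e-6) / 2)
  for (e in c(0, 25, 50, 75, 100))
    expect_equal(lr(e), 1e-6 + (1e-4 - 1e-6) * (1 + cos(pi * e / 100)) / 2)
  expect_true(all(diff(vapply(0:100, lr, 1)) < 0))  # monotone decay
})

test_that("early stopping fires after exactly `patience` non-improving epochs", {
  # constant validation loss: first epoch sets the best, then 10 bad epochs
  expect_equal(early_stopping_epoch(rep(1, 20), patience = 10), 11L)
  # monotone improvement never stops
  expect_true(is.na(early_stopping_epoch(seq(1, 0.1, length.out = 30), 10)))
  # improvement resets the counter
  v <- c(1, 0.9, rep(0.95, 9), 0.8, rep(0.85, 3))
  expect_equal(early_stopping_epoch(v, 3), 5L)
  expect_equal(early_stopping_epoch(c(0.5, rep(0.6, 2)), 2), 3L)
})

test_that("training on a tiny dataset reduces the loss and stops on rigged conditions", {
  dir <- shared_dataset()
  set.seed(31)
  net <- build_network(network_config("tiny", input_size = 32L))
  cfg <- train_config(lr0 = 1e-3, max_steps = 30, batch_size = 4, seed = 31)
  fit <- train_network(net, dir, cfg, quiet = TRUE)
  expect_s3_class(fit, "seg_fit")
  expect_lte(fit$steps, 30)
  # seeded convergence smoke: the loss after 30 steps is below the first batch
  expect_lt(tail(fit$history$train_total, 1), fit$history$train_total[1])
  expect_true(all(c("epoch", "lr", "train_total", "val_total", "val_bce") %in%
                    names(fit$history)))

  # manifest without a validation split aborts before training
  man <- read_manifest(dir)
  man_tr <- man[man$split == "train", ]
  attr(man_tr, "dir") <- attr(man, "dir")
  expect_error(train_network(net, man_tr, cfg), "validation split")
})

test_that("identical config and seed reproduce the training history exactly", {
  dir <- shared_dataset()
  run <- function() {
    set.seed(77)
    net <- build_network(network_config("tiny", input_size = 32L))
    train_network(net, dir,
                  train_config(lr0 = 1e-3, max_steps = 6, batch_size = 4, seed = 77),
                  quiet = TRUE)$history
  }
  expect_identical(run(), run())
})

test_that("the loss sweep tabulates mIoU and F1 per grid value", {
  dir <- shared_dataset()
  tab <- loss_sweep(dir, alphas = 0.75, betas = 0.3,
                    net_config = network_config("tiny", input_size = 32L),
                    cfg = train_config(lr0 = 1e-3, max_steps = 4, batch_size = 4))
  expect_equal(tab$parameter, c("alpha", "beta"))
  expect_equal(tab$value, c(0.75, 0.3))
  expect_true(all(tab$miou >= 0 & tab$miou <= 1))
  expect_true(all(tab$f1 >= 0 & tab$f1 <= 1))
})

test_that("checkpoints round-trip the weights and reproduce predictions", {
  dir <- shared_dataset()
  set.seed(32)
  net <- build_network(network_config("tiny", input_size = 32L))
  man <- read_manifest(dir)
  img_rows <- man[man$volume_id == "vol001" & man$role == "image", ]
  paths <- file.path(attr(man, "dir"), img_rows$file[order(img_rows$modality)])

  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f, seed = 32)
  p1 <- predict_volume(net, paths)
  net2 <- load_checkpoint(f)
  p2 <- predict_volume(net2, paths)
  expect_identical(p1$data, p2$data)
  expect_equal(dim(p1$data), c(32, 32, 8))       # output grid equals input grid
  expect_true(all(p1$data %in% c(0, 1)))
  p3 <- predict_volume(net, paths)
  expect_identical(p1$data, p3$data)             # eval-mode determinism
  expect_error(predict_volume(net, paths[1:2]), "modalities")

  out_nii <- tempfile(fileext = ".nii.gz")
  predict_volume(net, paths, out_path = out_nii)
  expect_true(all(load_nifti_volume(out_nii)$data == p1$data))
})

test_that("dataset evaluation matches the per-pair metric oracles", {
  dir <- shared_dataset()
  set.seed(33)
  net <- build_network(network_config("tiny", input_size = 32L))
  man <- read_manifest(dir)
  f <- tempfile(fileext = ".csv")
  res <- evaluate_dataset(net, dir, split = "test", file = f)
  expect_true(file.exists(f))
  expect_equal(nrow(res$cases), length(unique(man$volume_id[man$split == "test"])))

  # recompute the first case independently
  vid <- res$cases$case[1]
  rows <- man[man$volume_id == vid, ]
  img_rows <- rows[rows$role == "image", ]
  paths <- file.path(attr(man, "dir"), img_rows$file[order(img_rows$modality)])
  gt <- load_nifti_volume(file.path(attr(man, "dir"), rows$file[rows$role == "mask"][1]))
  pred <- predict_volume(net, paths)
  ref <- evaluate_pair(pred$data, gt$data, gt$spacing)
  expect_equal(res$cases$dsc[1], ref$dsc)
  expect_equal(res$cases$assd_mm[1], ref$assd_mm)
  expect_error(evaluate_dataset(net, dir, split = "nope"), "no volumes")
})
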