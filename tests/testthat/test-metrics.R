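test_that("confusion counts match an exhaustive per-pixel loop", {
  set.seed(1)
  pred <- matrix(rbinom(64, 1, 0.4), 8, 8)
  gt <- matrix(rbinom(64, 1, 0.4), 8, 8)
  cc <- confusion_counts(pred, gt)
  ref <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) ref["tp"] <- ref["tp"] + 1
    if (pred[i] == 1 && gt[i] == 0) ref["fp"] <- ref["fp"] + 1
    if (pred[i] == 0 && gt[i] == 1) ref["fn"] <- ref["fn"] + 1
    if (pred[i] == 0 && gt[i] == 0) ref["tn"] <- ref["tn"] + 1
  }
  expect_equal(unlist(cc), ref, ignore_attr = TRUE)
  expect_equal(sum(unlist(cc)), 64)

  same <- confusion_counts(gt, gt)
  expect_equal(same$fp + same$fn, 0)
  comp <- confusion_counts(1 - gt, gt)
  expect_equal(comp$tp + comp$tn, 0)
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("overlap metrics follow the closed formulas and DSC equals F1", {
  m <- overlap_metrics(list(tp = 3, fp = 1, fn = 2))
  expect_equal(m$recall, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$dsc, 6 / 9)
  expect_equal(m$f1, m$dsc)

  expect_equal(unlist(overlap_metrics(list(tp = 5, fp = 0, fn = 0))),
               c(recall = 1, precision = 1, f1 = 1, dsc = 1))
  m2 <- overlap_metrics(list(tp = 8, fp = 0, fn = 2))
  expect_equal(m2$recall, 0.8)
  expect_equal(m2$precision, 1)

  set.seed(2)
  for (i in 1:5) {
    pred <- matrix(rbinom(36, 1, 0.5), 6, 6)
    gt <- matrix(rbinom(36, 1, 0.5), 6, 6)
    om <- overlap_metrics(confusion_counts(pred, gt))
    # F1 via precision/recall harmonic mean must equal DSC exactly
    if (om$precision + om$recall > 0)
      expect_equal(om$f1, 2 * om$precision * om$recall / (om$precision + om$recall))
    expect_true(all(unlist(om) >= 0 & unlist(om) <= 1))
  }
})

test_that("mIoU averages per-class IoU with absent classes skipped", {
  gt <- matrix(0, 4, 4); gt[1:2, 1:2] <- 1       # 4 foreground pixels
  pred <- matrix(0, 4, 4); pred[1:2, 1] <- 1; pred[3:4, 1] <- 1
  # fg: inter 2, union 6 -> 1/3; bg: inter 10, union 14 -> 5/7
  expect_equal(miou(pred, gt), (2 / 6 + 10 / 14) / 2)
  expect_equal(miou(gt, gt), 1)

  disj_a <- matrix(0, 3, 3); disj_a[1, 1] <- 1
  disj_b <- matrix(0, 3, 3); disj_b[3, 3] <- 1
  # foreground IoU 0 pulls the mean down
  expect_equal(miou(disj_a, disj_b), (0 + 7 / 9) / 2)
  expect_error(miou(matrix(2, 2, 2), matrix(0, 2, 2), k = 1), "range")
})

test_that("surface extraction finds boundary pixels with border-as-background", {
  single <- matrix(0, 5, 5); single[3, 3] <- 1
  s <- surface_extract(single)
  expect_equal(nrow(s$points), 1)
  expect_equal(s$points[1, ], c(2, 2))           # 0-based, spacing 1

  sq <- matrix(0, 6, 6); sq[2:5, 2:5] <- 1       # filled 4x4 square
  expect_equal(nrow(surface_extract(sq)$points), 12)

  full <- matrix(1, 4, 4)                        # border counts as background
  expect_equal(nrow(surface_extract(full)$points), 12)

  expect_equal(nrow(surface_extract(matrix(0, 4, 4))$points), 0)
})

test_that("surface distances match brute-force nearest-neighbour oracles", {
  a <- matrix(c(0, 0), 1, 2)
  b <- matrix(c(3, 4), 1, 2)
  d <- surface_distances(a, b)
  expect_equal(d$assd, 5); expect_equal(d$hd, 5)

  A <- rbind(c(0, 0), c(1, 0))
  B <- rbind(c(0, 0), c(0, 3))
  d2 <- surface_distances(A, B)
  expect_equal(d2$asd_ab, 0.5)
  expect_equal(d2$asd_ba, 1.5)
  expect_equal(d2$assd, 1.0)
  expect_equal(d2$hd, 3.0)

  expect_equal(surface_distances(A, A)$hd, 0)

  set.seed(3)
  for (i in 1:4) {
    X <- matrix(rnorm(12), 6, 2); Y <- matrix(rnorm(8), 4, 2)
    # all-pairs brute force
    dm <- as.matrix(dist(rbind(X, Y)))[1:6, 7:10]
    ref_ab <- mean(apply(dm, 1, min)); ref_ba <- mean(apply(dm, 2, min))
    dd <- surface_distances(X, Y)
    expect_equal(dd$asd_ab, ref_ab); expect_equal(dd$asd_ba, ref_ba)
    expect_equal(dd$assd, (ref_ab + ref_ba) / 2)
    expect_equal(dd$hd, max(apply(dm, 1, min), apply(dm, 2, min)))
    # symmetry
    sw <- surface_distances(Y, X)
    expect_equal(sw$assd, dd$assd); expect_equal(sw$hd, dd$hd)
    expect_gte(dd$hd, dd$assd)
  }

  expect_warning(d3 <- surface_distances(matrix(0, 0, 2), A), "empty")
  expect_equal(d3$hd, Inf)
})

test_that("distances scale linearly with voxel spacing", {
  set.seed(4)
  pred <- matrix(0, 8, 8); pred[2:4, 2:4] <- 1
  gt <- matrix(0, 8, 8); gt[3:6, 3:6] <- 1
  r1 <- evaluate_pair(pred, gt, spacing = c(1, 1))
  r2 <- evaluate_pair(pred, gt, spacing = c(2, 2))
  expect_equal(r2$assd_mm, 2 * r1$assd_mm)
  expect_equal(r2$hd_mm, 2 * r1$hd_mm)
  expect_equal(r2$dsc, r1$dsc)                   # overlap unaffected by spacing
})

test_that("evaluate_pair assembles all metrics consistently", {
  set.seed(5)
  gt <- matrix(0, 10, 10); gt[3:6, 4:8] <- 1
  r <- evaluate_pair(gt, gt)
  expect_equal(unlist(r[c("dsc", "precision", "recall", "f1", "miou")]),
               rep(1, 5), ignore_attr = TRUE)
  expect_equal(r$assd_mm, 0); expect_equal(r$hd_mm, 0)

  pred <- matrix(rbinom(100, 1, 0.3), 10, 10)
  rr <- evaluate_pair(pred, gt)
  om <- overlap_metrics(confusion_counts(pred, gt))
  sd_ <- surface_distances(surface_extract(pred), surface_extract(gt))
  expect_equal(rr$dsc, om$dsc)
  expect_equal(rr$precision, om$precision)
  expect_equal(rr$miou, miou(pred, gt))
  expect_equal(rr$assd_mm, sd_$assd)
  expect_equal(rr$hd_mm, sd_$hd)

  empty <- matrix(0, 4, 4)
  re <- evaluate_pair(empty, empty)
  expect_equal(re$dsc, 1); expect_equal(re$assd_mm, 0)

  rhalf <- evaluate_pair(empty, gt[1:4, 1:4])
  expect_equal(rhalf$dsc, 0)
  expect_equal(rhalf$hd_mm, Inf)
  expect_true(rhalf$warn_empty)
})

test_that("batch evaluation writes per-case rows plus mean and sd", {
  set.seed(6)
  gts <- lapply(1:3, function(i) matrix(rbinom(64, 1, 0.3), 8, 8))
  preds <- lapply(gts, function(g) { g[1, ] <- 0; g })
  f <- tempfile(fileext = ".csv")
  res <- mambaseg:::evaluate_cases(preds, gts, file = f)
  expect_equal(nrow(res$cases), 3)
  csv <- read.csv(f)
  expect_equal(nrow(csv), 5)
  expect_equal(csv$case[4:5], c("mean", "sd"))
  expect_equal(csv$dsc[4], mean(res$cases$dsc), tolerance = 1e-12)
})
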