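# Evaluation metrics: pixel-overlap scores (recall, precision, F1, DSC,
# mIoU) and surface-distance scores (ASSD, Hausdorff) in millimetres.
#
# Conventions for degenerate masks: if prediction and ground truth are both
# empty, overlap scores are 1 and distances 0 (a vacuously perfect match);
# if exactly one is empty, overlap scores are 0 and distances +Inf with a
# warning flag in the report.

#' Pixelwise confusion counts
#'
#' @param pred,gt Binary masks (vectors, matrices or arrays) of equal shape.
#' @return List with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, gt) {
  if (!all((dim(pred) %||% length(pred)) == (dim(gt) %||% length(gt))))
    stop("pred and gt must share shape")
  p <- as.logical(pred); g <- as.logical(gt)
  list(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g), tn = sum(!p & !g))
}

#' Overlap metrics from confusion counts
#'
#' Recall `TP/(TP+FN)`, precision `TP/(TP+FP)`, `F1 = 2TP/(2TP+FP+FN)` and the
#' Dice similarity coefficient `2TP/((FP+TP)+(TP+FN))`; the last two are
#' algebraically identical for binary masks.
#'
#' @param counts A [confusion_counts()] list.
#' @return Named list `recall`, `precision`, `f1`, `dsc`, each in `[0, 1]`.
#' @export
overlap_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp + fn == 0)
    return(list(recall = 1, precision = 1, f1 = 1, dsc = 1))
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  dsc <- 2 * tp / (2 * tp + fp + fn)
  list(recall = recall, precision = precision, f1 = dsc, dsc = dsc)
}

#' Mean intersection over union
#'
#' Averages `tp / (tp + fp + fn)` over classes `0..k`; classes absent from
#' both maps are skipped.
#'
#' @param pred,gt Integer label maps of equal shape with labels in `0..k`.
#' @param k Largest class label (binary segmentation: `k = 1`).
#' @return Scalar mIoU in `[0, 1]`.
#' @export
miou <- function(pred, gt, k = 1L) {
  if (!all((dim(pred) %||% length(pred)) == (dim(gt) %||% length(gt))))
    stop("pred and gt must share shape")
  if (any(pred < 0 | pred > k) || any(gt < 0 | gt > k))
    stop("labels out of range [0, k]")
  ious <- c()
  for (i in 0:k) {
    tp <- sum(pred == i & gt == i)
    fp <- sum(pred == i & gt != i)
    fn <- sum(gt == i & pred != i)
    if (tp + fp + fn == 0) next
    ious <- c(ious, tp / (tp + fp + fn))
  }
  if (!length(ious)) return(1)
  mean(ious)
}

#' Extract the boundary surface of a binary mask
#'
#' Boundary pixels are foreground pixels with at least one background
#' face-neighbour (4-connectivity in 2D, 6-connectivity in 3D); the image
#' border counts as background. Coordinates are scaled by the voxel spacing,
#' giving physical (mm) positions.
#'
#' @param mask Binary matrix (2D) or 3D array.
#' @param spacing Numeric vector of mm per axis (default 1 mm isotropic).
#' @return Object of class `surface_set`: list with `points` (n x d matrix of
#'   mm coordinates) and `spacing`.
#' @export
surface_extract <- function(mask, spacing = NULL) {
  d <- dim(mask) %||% length(mask)
  nd <- length(d)
  if (!nd %in% c(2L, 3L)) stop("mask must be 2D or 3D")
  if (is.null(spacing)) spacing <- rep(1, nd)
  if (length(spacing) != nd || any(spacing <= 0)) stop("bad spacing")
  m <- array(as.numeric(mask != 0), d)
  # neighbour-of-background test via shifted copies; outside counts as 0
  shift <- function(a, axis, by) {
    out <- array(0, d)
    idx_src <- idx_dst <- lapply(d, seq_len)
    if (by == 1L) { idx_src[[axis]] <- seq_len(d[axis] - 1L); idx_dst[[axis]] <- 2:d[axis] }
    else { idx_src[[axis]] <- 2:d[axis]; idx_dst[[axis]] <- seq_len(d[axis] - 1L) }
    do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(a), idx_src)))))
  }
  has_bg <- array(FALSE, d)
  for (ax in seq_len(nd)) for (by in c(1L, -1L)) {
    nb <- shift(m, ax, by)
    edge <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    idx[[ax]] <- if (by == 1L) 1L else d[ax]
    edge <- do.call(`[<-`, c(list(edge), idx, list(TRUE)))
    has_bg <- has_bg | (nb == 0 & !edge) | edge
  }
  on_surface <- (m == 1) & has_bg
  coords <- which(on_surface, arr.ind = TRUE)
  pts <- sweep(coords - 1, 2L, spacing, `*`)
  structure(list(points = unname(pts), spacing = spacing), class = "surface_set")
}

#' Directed and symmetric surface distances
#'
#' Computes the directed average surface distances `ASD(A,B)` and `ASD(B,A)`
#' (mean nearest-neighbour Euclidean distance), their average ASSD, and the
#' Hausdorff distance (max of the two directed maxima).
#'
#' @param A,B `surface_set` objects (or bare n x d coordinate matrices).
#' @return List `asd_ab`, `asd_ba`, `assd`, `hd` (mm); all `Inf` with a
#'   warning if either surface is empty.
#' @export
surface_distances <- function(A, B) {
  pa <- if (inherits(A, "surface_set")) A$points else as.matrix(A)
  pb <- if (inherits(B, "surface_set")) B$points else as.matrix(B)
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    warning("empty surface set; distances reported as Inf")
    return(list(asd_ab = Inf, asd_ba = Inf, assd = Inf, hd = Inf))
  }
  nn_min <- function(X, Y) {
    # per-row min distance from X to Y, chunked to bound memory
    ny2 <- rowSums(Y^2)
    out <- numeric(nrow(X))
    step <- max(1L, 2e6 %/% max(1L, nrow(Y)))
    for (s in seq(1L, nrow(X), by = step)) {
      e <- min(s + step - 1L, nrow(X))
      Xc <- X[s:e, , drop = FALSE]
      d2 <- outer(rowSums(Xc^2), ny2, `+`) - 2 * Xc %*% t(Y)
      out[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
    }
    out
  }
  dab <- nn_min(pa, pb)
  dba <- nn_min(pb, pa)
  list(asd_ab = mean(dab), asd_ba = mean(dba),
       assd = (mean(dab) + mean(dba)) / 2, hd = max(max(dab), max(dba)))
}

#' Full metric report for a predicted/ground-truth mask pair
#'
#' Assembles DSC, precision, recall, F1, mIoU and the surface distances
#' (ASSD, Hausdorff) for one case.
#'
#' @param pred,gt Binary masks (2D or 3D arrays) of equal shape.
#' @param spacing mm per axis (default 1 mm isotropic).
#' @return List of class `metric_report` with fields `dsc`, `precision`,
#'   `recall`, `f1`, `miou`, `assd_mm`, `hd_mm` and the logical `warn_empty`.
#' @export
evaluate_pair <- function(pred, gt, spacing = NULL) {
  cc <- confusion_counts(pred, gt)
  om <- overlap_metrics(cc)
  stopifnot(isTRUE(all.equal(om$dsc, om$f1)))
  mi <- miou(array(as.integer(pred != 0), dim(pred) %||% length(pred)),
             array(as.integer(gt != 0), dim(gt) %||% length(gt)), 1L)
  np <- sum(pred != 0); ng <- sum(gt != 0)
  warn_empty <- FALSE
  if (np == 0 && ng == 0) {
    sd_ <- list(assd = 0, hd = 0)
  } else if (np == 0 || ng == 0) {
    sd_ <- list(assd = Inf, hd = Inf)
    warn_empty <- TRUE
  } else {
    sa <- surface_extract(pred, spacing)
    sb <- surface_extract(gt, spacing)
    sd_ <- surface_distances(sa, sb)
  }
  structure(list(dsc = om$dsc, precision = om$precision, recall = om$recall,
                 f1 = om$f1, miou = mi, assd_mm = sd_$assd, hd_mm = sd_$hd,
                 warn_empty = warn_empty),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "DSC %.4f | precision %.4f | recall %.4f | F1 %.4f | mIoU %.4f | ASSD %.3f mm | HD %.3f mm\n",
    x$dsc, x$precision, x$recall, x$f1, x$miou, x$assd_mm, x$hd_mm))
  invisible(x)
}

# Batch evaluation: per-case rows plus mean/sd summary; optionally written as
# a CSV (cases, then `mean` and `sd` rows).
evaluate_cases <- function(preds, gts, ids = NULL, spacing = NULL, file = NULL) {
  stopifnot(length(preds) == length(gts))
  if (is.null(ids)) ids <- sprintf("case%03d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    r <- evaluate_pair(preds[[i]], gts[[i]], spacing)
    data.frame(case = ids[i], dsc = r$dsc, precision = r$precision,
               recall = r$recall, f1 = r$f1, miou = r$miou,
               assd_mm = r$assd_mm, hd_mm = r$hd_mm,
               stringsAsFactors = FALSE)
  })
  cases <- do.call(rbind, rows)
  num <- cases[, -1L, drop = FALSE]
  summary <- rbind(
    data.frame(case = "mean", as.list(colMeans(num)), stringsAsFactors = FALSE),
    data.frame(case = "sd", as.list(apply(num, 2L, stats::sd)), stringsAsFactors = FALSE))
  if (!is.null(file)) write.csv(rbind(cases, summary), file, row.names = FALSE)
  list(cases = cases, summary = summary)
}
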