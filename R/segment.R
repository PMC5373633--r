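# Nucleus identification from the DAPI channel. Thresholding (Otsu or
# fixed), hole filling, optional watershed splitting of touching nuclei on
# the distance transform, and area filtering; built on EBImage.

#' Segment nuclei in a DAPI image
#'
#' Smooths the DAPI channel, thresholds it (Otsu's method by default),
#' fills holes, optionally splits touching nuclei by a watershed on the
#' distance transform, and removes objects outside the configured area
#' range. Labels in the returned mask are consecutive positive integers in
#' raster order; background is 0.
#'
#' @param dapi Numeric or integer matrix of nonnegative DAPI intensities
#'   (rows = image rows).
#' @param params A [segmentation_params()] object.
#' @return Integer label matrix of the same dimensions.
#' @export
segment_nuclei <- function(dapi, params = segmentation_params()) {
  stopifnot(is.matrix(dapi), inherits(params, "segmentation_params"))
  if (any(dapi < 0)) stop("DAPI intensities must be nonnegative")
  x <- dapi * 1.0
  top <- max(x)
  if (top == 0 || stats::sd(x) == 0) {
    if (params$threshold_method == "otsu") {
      warning("constant DAPI image: no objects found")
      return(matrix(0L, nrow(dapi), ncol(dapi)))
    }
  }
  smoothed <- if (params$smoothing_sigma > 0)
    as.matrix(EBImage::gblur(EBImage::Image(x), sigma = params$smoothing_sigma))
  else x
  thr <- if (params$threshold_method == "otsu") {
    t_norm <- EBImage::otsu(EBImage::Image(smoothed / max(smoothed)),
                            range = c(0, 1))
    t_norm * max(smoothed)
  } else params$fixed_threshold
  mask <- smoothed > thr
  if (!any(mask)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  mask_img <- EBImage::fillHull(EBImage::Image(mask * 1))
  labels <- if (params$split_touching) {
    EBImage::watershed(EBImage::distmap(mask_img), tolerance = 0.5, ext = 1)
  } else {
    EBImage::bwlabel(mask_img)
  }
  labels <- as.matrix(EBImage::imageData(labels))
  storage.mode(labels) <- "integer"
  # area filter + consecutive relabelling
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= params$min_area & areas <= params$max_area)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0L
  out[nz] <- remap[labels[nz]]
  out
}

#' Match predicted objects to ground-truth objects by IoU
#'
#' Greedy one-to-one matching of predicted to truth labels by descending
#' intersection-over-union. Pairs with IoU below `min_iou` are reported as
#' unmatched, as are labels left over on either side.
#'
#' @param pred_mask,truth_mask Integer label matrices of equal dimensions.
#' @param min_iou Minimum IoU for a pair to count as matched (default 0.5).
#' @return A `data.frame` with columns `pred_id`, `truth_id`, `iou`,
#'   `matched`. Unmatched predicted labels have `truth_id = NA` and vice
#'   versa.
#' @export
match_to_truth <- function(pred_mask, truth_mask, min_iou = 0.5) {
  if (!all(dim(pred_mask) == dim(truth_mask)))
    stop("pred_mask and truth_mask must have identical dimensions")
  pred_ids <- sort(unique(pred_mask[pred_mask > 0]))
  truth_ids <- sort(unique(truth_mask[truth_mask > 0]))
  if (length(pred_ids) == 0 && length(truth_ids) == 0)
    return(data.frame(pred_id = integer(), truth_id = integer(),
                      iou = numeric(), matched = logical()))
  both <- pred_mask > 0 & truth_mask > 0
  inter <- as.data.frame(table(pred = pred_mask[both],
                               truth = truth_mask[both]),
                         stringsAsFactors = FALSE)
  inter <- inter[inter$Freq > 0, ]
  area_p <- tabulate(pred_mask[pred_mask > 0], max(pred_mask))
  area_t <- tabulate(truth_mask[truth_mask > 0], max(truth_mask))
  inter$pred <- as.integer(inter$pred)
  inter$truth <- as.integer(inter$truth)
  inter$iou <- inter$Freq /
    (area_p[inter$pred] + area_t[inter$truth] - inter$Freq)
  inter <- inter[order(-inter$iou, inter$pred, inter$truth), ]
  used_p <- logical(max(pred_mask)); used_t <- logical(max(truth_mask))
  rows <- list()
  for (i in seq_len(nrow(inter))) {
    p <- inter$pred[i]; t <- inter$truth[i]
    if (used_p[p] || used_t[t] || inter$iou[i] < min_iou) next
    used_p[p] <- TRUE; used_t[t] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(pred_id = p, truth_id = t,
                                            iou = inter$iou[i],
                                            matched = TRUE)
  }
  matched <- if (length(rows)) do.call(rbind, rows)
  else data.frame(pred_id = integer(), truth_id = integer(),
                  iou = numeric(), matched = logical())
  un_p <- setdiff(pred_ids, matched$pred_id)
  un_t <- setdiff(truth_ids, matched$truth_id)
  out <- rbind(matched,
               if (length(un_p)) data.frame(pred_id = un_p, truth_id = NA,
                                            iou = NA_real_, matched = FALSE),
               if (length(un_t)) data.frame(pred_id = NA, truth_id = un_t,
                                            iou = NA_real_, matched = FALSE))
  rownames(out) <- NULL
  out
}
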