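# Region-level correspondence analysis: connected components of reference
# and predicted masks are matched by intersection-over-union.

#' Label 4-connected foreground regions
#'
#' @param mask Binary (0/1) matrix.
#' @return A `region_set`: list with `labels` (integer matrix, 0 =
#'   background, regions numbered in raster-scan order of their first pixel)
#'   and `areas` (pixel area per region).
#' @export
label_regions <- function(mask) {
  stopifnot_binary(mask)
  lab <- cpp_label(matrix(as.integer(mask), nrow(mask)), 4L)
  n <- max(lab)
  areas <- if (n > 0) tabulate(lab[lab > 0], nbins = n) else integer(0)
  structure(list(labels = lab, areas = areas, n = n), class = "region_set")
}

#' Match reference and predicted regions by IoU
#'
#' A reference and a predicted region correspond when their intersection
#' over union exceeds 0.5; this threshold makes the correspondence a partial
#' matching (each region has at most one partner). Reference regions smaller
#' than `min_ref_area` pixels are discarded beforehand as artefacts of the
#' background segmentation.
#'
#' @param ref_regions,pred_regions [label_regions()] results on masks of the
#'   same geometry.
#' @param iou_threshold Correspondence threshold (strictly greater than;
#'   default 0.5).
#' @param min_ref_area Minimum reference-region area in pixels (default
#'   1600).
#' @return List with `pairs` (data frame: `ref`, `pred`, `iou`, `TP`, `FN`,
#'   `FP` pixel counts per pair), `tp_ref`, `fn_ref`, `tp_pred`, `fp_pred`
#'   (region label vectors), and `n_ref_retained`.
#' @export
correspond_regions <- function(ref_regions, pred_regions,
                               iou_threshold = 0.5, min_ref_area = 1600L) {
  stopifnot(inherits(ref_regions, "region_set"), inherits(pred_regions, "region_set"))
  rl <- ref_regions$labels
  pl <- pred_regions$labels
  if (!all(dim(rl) == dim(pl))) stop("shape mismatch")
  keep_ref <- which(ref_regions$areas >= min_ref_area)
  ra <- ref_regions$areas
  pa <- pred_regions$areas
  both <- rl > 0 & pl > 0
  pairs <- data.frame(ref = integer(0), pred = integer(0), iou = numeric(0),
                      TP = integer(0), FN = integer(0), FP = integer(0))
  if (any(both)) {
    ov <- table(ref = rl[both], pred = pl[both])
    ov <- as.data.frame(ov, stringsAsFactors = FALSE)
    ov <- ov[ov$Freq > 0, ]
    ov$ref <- as.integer(ov$ref); ov$pred <- as.integer(ov$pred)
    ov <- ov[ov$ref %in% keep_ref, , drop = FALSE]
    if (nrow(ov) > 0) {
      inter <- ov$Freq
      union <- ra[ov$ref] + pa[ov$pred] - inter
      iou <- inter / union
      sel <- iou > iou_threshold
      if (any(sel)) {
        pairs <- data.frame(ref = ov$ref[sel], pred = ov$pred[sel],
                            iou = iou[sel], TP = inter[sel],
                            FN = ra[ov$ref[sel]] - inter[sel],
                            FP = pa[ov$pred[sel]] - inter[sel])
      }
    }
  }
  list(pairs = pairs,
       tp_ref = pairs$ref,
       fn_ref = setdiff(keep_ref, pairs$ref),
       tp_pred = pairs$pred,
       fp_pred = setdiff(seq_len(pred_regions$n), pairs$pred),
       n_ref_retained = length(keep_ref))
}

#' Per-image DSC over corresponding regions
#'
#' For each image, the contingency tables of all corresponding region pairs
#' are summed and a single DSC computed; images without any pair contribute
#' no value. The cohort average runs over images with at least one pair.
#'
#' @param correspondences List of [correspond_regions()] results, one per
#'   image.
#' @return List with `per_image` (DSC or `NA` per image), `mean_dsc` (over
#'   images with pairs), and `frac_with_tp` (fraction of images with at
#'   least one corresponding pair).
#' @export
tp_region_dsc <- function(correspondences) {
  per_image <- vapply(correspondences, function(co) {
    if (nrow(co$pairs) == 0) return(NA_real_)
    tp <- sum(co$pairs$TP); fn <- sum(co$pairs$FN); fp <- sum(co$pairs$FP)
    2 * tp / (2 * tp + fn + fp)
  }, 0)
  list(per_image = per_image,
       mean_dsc = mean(per_image, na.rm = TRUE),
       frac_with_tp = mean(!is.na(per_image)))
}

#' Region-size distribution of a cohort of masks
#'
#' Areas are converted to mm^2 with [pixels_to_mm()]; regions below 1 mm^2
#' are flagged as "small" (the fragmented-sample failure regime).
#'
#' @param masks List of binary masks at `mpp` resolution.
#' @param mpp Mask resolution (default 5 micrometres per pixel).
#' @param breaks Histogram breaks in mm^2 passed to [hist()]; the default
#'   spans 0 to the largest observed area.
#' @return List with `areas_mm2` (all region areas), `small_fraction`
#'   (fraction below 1 mm^2) and `histogram` (a `hist` object, or `NULL` for
#'   an empty cohort).
#' @importFrom graphics hist
#' @export
region_size_distribution <- function(masks, mpp = 5, breaks = "Sturges") {
  areas <- unlist(lapply(masks, function(m) label_regions(m)$areas))
  if (length(areas) == 0) {
    return(list(areas_mm2 = numeric(0), small_fraction = NA_real_, histogram = NULL))
  }
  mm2 <- pixels_to_mm(areas, mpp, area = TRUE)
  list(areas_mm2 = mm2,
       small_fraction = mean(mm2 < 1),
       histogram = hist(mm2, breaks = breaks, plot = FALSE))
}
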