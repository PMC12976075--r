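# End-to-end pipeline stages: whole-slide segmentation with a trained
# network, cohort evaluation, and the desk-scale training recipe.

#' Run configuration for whole-slide segmentation
#'
#' Defaults mirror the published operating point: inference tiles of
#' 7680 px with at least 1024 px overlap at 1 MPP, tissue masking and
#' post-processing at 5 MPP. The mini settings (2048/256) are appropriate
#' for the 4096 px synthetic slides.
#'
#' @param tile,min_overlap Inference tiling at `target_mpp`.
#' @param target_mpp Network input resolution (default 1).
#' @param mask_mpp Tissue-mask / post-processing resolution (default 5).
#' @param postprocess A [postprocess_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(tile = 7680L, min_overlap = 1024L, target_mpp = 1,
                       mask_mpp = 5, postprocess = postprocess_config()) {
  if (min_overlap >= tile) stop("min_overlap must be smaller than tile")
  structure(list(tile = as.integer(tile), min_overlap = as.integer(min_overlap),
                 target_mpp = target_mpp, mask_mpp = mask_mpp,
                 postprocess = postprocess),
            class = "run_config")
}

#' Segment one slide with a trained network
#'
#' Reads the slide at the target resolution tile by tile, applies the
#' network, stitches the overlapping score tiles into a probability mosaic
#' with distance weights, computes the tissue mask at 5 MPP, and
#' post-processes into the final binary tumour mask.
#'
#' @param slide A [slide_pyramid()].
#' @param net Trained network (e.g. from [train_network()]).
#' @param moments The training [dataset_moments()].
#' @param cfg A [run_config()].
#' @param progress Emit per-stage timing messages.
#' @return List with `mask` (binary 5 MPP mask), `mosaic` (1 MPP 0..255
#'   probability image), `smoothed`, `tissue` (5 MPP tissue mask), `grid`,
#'   and `timings` (seconds per stage).
#' @export
segment_slide <- function(slide, net, moments, cfg = run_config(),
                          progress = FALSE) {
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  note <- function(stage, t0) {
    timings[[stage]] <<- tic() - t0
    if (progress) message(sprintf("  %-12s %6.1f s", stage, timings[[stage]]))
  }
  t0 <- tic()
  dims <- slide_dims_at_mpp(slide, cfg$target_mpp)
  grid <- tile_grid(dims["width"], dims["height"], cfg$tile, cfg$min_overlap)
  score_tiles <- vector("list", nrow(grid$tiles))
  for (i in seq_len(nrow(grid$tiles))) {
    t <- grid$tiles[i, ]
    tile_img <- read_region_at_mpp(slide, cfg$target_mpp, t$x, t$y, t$w, t$h)
    score_tiles[[i]] <- infer_tile(net, tile_img$pixels, moments)
  }
  note("inference", t0)
  t0 <- tic()
  mosaic <- merge_tiles(score_tiles, grid)
  rm(score_tiles)
  note("stitching", t0)
  t0 <- tic()
  plane5 <- read_full_at_mpp(slide, cfg$mask_mpp)
  tissue <- tissue_mask_from_image(plane5)
  note("tissue_mask", t0)
  t0 <- tic()
  pp <- postprocess_mosaic(mosaic, tissue, cfg$postprocess)
  note("postprocess", t0)
  list(mask = pp$mask, mosaic = mosaic, smoothed = pp$smoothed,
       tissue = tissue, grid = grid, timings = unlist(timings))
}

#' Evaluate predicted masks against references over a cohort
#'
#' Computes the background-excluded contingency table and the 12 summary
#' statistics per scan, cohort means with t confidence intervals for DSC
#' and MCC, and the region-level correspondence analysis.
#'
#' @param pred_masks,ref_masks,tissue_masks Lists of binary 5 MPP masks with
#'   matching geometries; `tissue_masks` define the white background
#'   (complement) that is excluded from evaluation.
#' @param ids Scan identifiers (default sequential).
#' @return List with `per_scan` (data frame of all metrics), `cohort`
#'   (mean/CI for each metric), `region` (output of [tp_region_dsc()] plus
#'   detected-region fraction), `excluded` (ids of scans with an empty
#'   reference, which are left out of cohort averages).
#' @export
evaluate_cohort <- function(pred_masks, ref_masks, tissue_masks,
                            ids = seq_along(pred_masks)) {
  n <- length(pred_masks)
  stopifnot(length(ref_masks) == n, length(tissue_masks) == n)
  rows <- vector("list", n)
  correspondences <- vector("list", n)
  n_ref_regions <- 0L
  n_tp_regions <- 0L
  for (i in seq_len(n)) {
    cc <- confusion_counts(pred_masks[[i]], ref_masks[[i]],
                           (tissue_masks[[i]] == 0) * 1L)
    ms <- metric_set(cc)
    rows[[i]] <- data.frame(scan_id = ids[i], t(ms), RP = cc$RP, N = cc$N)
    co <- correspond_regions(label_regions(ref_masks[[i]]),
                             label_regions(pred_masks[[i]]))
    correspondences[[i]] <- co
    n_ref_regions <- n_ref_regions + co$n_ref_retained
    n_tp_regions <- n_tp_regions + nrow(co$pairs)
  }
  per_scan <- do.call(rbind, rows)
  excluded <- per_scan$scan_id[per_scan$RP == 0]
  keep <- per_scan$RP > 0
  cohort <- lapply(c("DSC", "MCC", "TPR", "PPV"), function(m) {
    v <- per_scan[[m]][keep]
    if (sum(!is.na(v)) >= 2) cohort_mean_ci(v) else c(mean = mean(v, na.rm = TRUE),
                                                      ci_low = NA, ci_high = NA,
                                                      n = sum(!is.na(v)))
  })
  names(cohort) <- c("DSC", "MCC", "TPR", "PPV")
  region <- tp_region_dsc(correspondences)
  region$n_ref_regions <- n_ref_regions
  region$n_tp_regions <- n_tp_regions
  region$detected_fraction <- if (n_ref_regions > 0) n_tp_regions / n_ref_regions else NA_real_
  list(per_scan = per_scan, cohort = cohort, region = region,
       correspondences = correspondences, excluded = excluded)
}

#' Write per-scan and cohort evaluation CSVs
#'
#' @param ev Result of [evaluate_cohort()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_evaluation <- function(ev, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(ev$per_scan, file.path(dir, "per_scan_metrics.csv"), row.names = FALSE)
  coh <- do.call(rbind, lapply(names(ev$cohort), function(m) {
    data.frame(metric = m, t(ev$cohort[[m]]))
  }))
  write.csv(coh, file.path(dir, "cohort_summary.csv"), row.names = FALSE)
  invisible(dir)
}

#' Desk-scale training on synthetic slides
#'
#' Generates a training cohort, prepares the balanced tile corpus (tissue
#' masking, background-tile exclusion, channel moments), and trains the
#' default small backbone. The published setup runs 500,000 steps with
#' batch 24 on 1536 px crops; this recipe scales every count down so the
#' whole run stays in the minutes range on one CPU core while exercising
#' exactly the same code path.
#'
#' @param n_slides Number of training slides (default 4).
#' @param preset Fixture preset (default `"mini"`).
#' @param steps,batch_size Optimisation settings (defaults 600 and 8).
#' @param max_tiles Cap on the corpus size; kept tiles beyond the cap are
#'   subsampled uniformly (seeded). Bounds the memory footprint of the run.
#' @param seed Master seed for generation, sampling and initialisation.
#' @param progress Emit progress messages.
#' @return List with `net`, `moments`, `trace`, `corpus_size`.
#' @export
train_toy <- function(n_slides = 4L, preset = "mini", steps = 600L,
                      batch_size = 8L, max_tiles = 260L, seed = 1L,
                      progress = FALSE) {
  seeds <- derive_seeds(seed, 4 + n_slides)
  tl <- preset_tiling(preset)
  counts <- with_seed(seeds[1], sample(1:3, n_slides, replace = TRUE))
  corpus <- list()
  # slides are generated, tiled and discarded one at a time to bound memory
  for (i in seq_len(n_slides)) {
    if (progress) message(sprintf("slide %d/%d: generating and tiling...",
                                  i, n_slides))
    sp <- slide_preset(preset, seed = seeds[4 + i], n_lesions = counts[i])
    fx <- generate_slide(sp)
    tissue <- tissue_mask_from_image(read_full_at_mpp(fx$slide, 5))
    prep <- prepare_tiles(fx$slide, fx$annotation, tissue,
                          tile_px = tl$train_tile, target_mpp = 1, mask_mpp = 5)
    corpus <- c(corpus, prep$tiles)
    rm(fx, prep, tissue)
    gc(FALSE)
  }
  if (length(corpus) == 0) stop("empty corpus")
  if (length(corpus) > max_tiles) {
    keep <- with_seed(seeds[2], sample(length(corpus), max_tiles))
    corpus <- corpus[keep]
  }
  moments <- dataset_moments(lapply(corpus, `[[`, "img"))
  net <- small_segnet(seed = seeds[3])
  if (progress) message(sprintf("training on %d tiles...", length(corpus)))
  # desk-scale schedule: same warm-up/cosine shape, compressed into the run,
  # with a peak step length scaled down for the tiny batch and network
  sched <- schedule_spec(total_steps = steps, warmup_init = 3e-5,
                         warmup_increment = 3e-5, warmup_period = 1L,
                         warmup_end = 100L, peak = 3e-3)
  tr <- train_network(corpus, net, moments, steps = steps,
                      batch_size = batch_size, crop = tl$train_crop,
                      schedule = sched, seed = seeds[4])
  list(net = tr$net, moments = moments, trace = tr$trace,
       corpus_size = length(corpus))
}
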