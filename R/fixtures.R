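# Deterministic synthetic-slide generation. The renderer produces an
# H&E-like appearance that is deliberately stylised: pink stroma with
# sparse small dark nuclei and fine speckle, tumour areas with denser and
# larger nuclei on a slightly more purple base, and a near-white glass
# background. The classes are separable by local texture, which is what the
# segmentation network needs; photorealism is not attempted.

#' Synthetic slide specification
#'
#' @param seed Integer seed; identical specs produce byte-identical slides.
#' @param canvas_px Canvas side at 1 MPP (square slides).
#' @param mpp Level-0 resolution (micrometres per pixel, default 1).
#' @param tissue_type `"en_bloc"` (one large section) or `"fragmented"`
#'   (many small pieces, the transurethral-resection regime).
#' @param n_lesions Number of tumour lesions (en-bloc slides).
#' @param lesion_radius_mm Lesion radius range in mm.
#' @param n_fragments,fragment_radius_mm,tumour_fragment_frac Fragmented
#'   slides: piece count, piece radius range, fraction of pieces that are
#'   tumour.
#' @param texture Texture parameter list; see defaults in the source. The
#'   defaults are chosen so that the structure detector marks tissue
#'   reliably and tumour texture is learnable from small tile corpora.
#' @return A `synthetic_slide_spec` list.
#' @export
synthetic_slide_spec <- function(seed = 1L, canvas_px = 4096L, mpp = 1,
                                 tissue_type = c("en_bloc", "fragmented"),
                                 n_lesions = 2L,
                                 lesion_radius_mm = c(0.35, 0.65),
                                 n_fragments = 12L,
                                 fragment_radius_mm = c(0.12, 0.3),
                                 tumour_fragment_frac = 0.7,
                                 texture = list()) {
  tissue_type <- match.arg(tissue_type)
  tex <- list(
    white_base = 246, white_noise = 2,
    stroma_rgb = c(233, 198, 212), tumour_rgb = c(216, 180, 208),
    noise_sd = 6,
    speckle_frac = 0.35, speckle_depth = c(25, 110),
    stroma_nuclei_per_mm2 = 350, tumour_nuclei_per_mm2 = 1200,
    stroma_nucleus_px = c(2.2, 3.2), tumour_nucleus_px = c(3.5, 5.0),
    nucleus_rgb = c(110, 75, 150), tumour_nucleus_rgb = c(95, 60, 140),
    nucleus_rgb_sd = 10,
    tissue_radius_frac = c(0.30, 0.38), lesion_margin_mm = 0.15
  )
  tex[names(texture)] <- texture
  structure(list(seed = as.integer(seed), canvas_px = as.integer(canvas_px),
                 mpp = mpp, tissue_type = tissue_type,
                 n_lesions = as.integer(n_lesions),
                 lesion_radius_mm = lesion_radius_mm,
                 n_fragments = as.integer(n_fragments),
                 fragment_radius_mm = fragment_radius_mm,
                 tumour_fragment_frac = tumour_fragment_frac,
                 texture = tex),
            class = "synthetic_slide_spec")
}

# Place n non-overlapping disks by rejection sampling. `inside` is a
# predicate on (cy, cx, r) in level-0 pixels. Early placements can block
# later ones, so the whole placement is restarted from scratch when a round
# stalls; an error is raised only when every restart fails.
place_disks <- function(n, r_range_px, inside, min_gap_px,
                        max_tries = 4000L, max_restarts = 25L) {
  if (n == 0) return(data.frame(cy = numeric(0), cx = numeric(0), r = numeric(0)))
  for (round in seq_len(max_restarts)) {
    placed <- data.frame(cy = numeric(0), cx = numeric(0), r = numeric(0))
    tries <- 0L
    while (nrow(placed) < n && tries < max_tries) {
      tries <- tries + 1L
      r <- runif(1, r_range_px[1], r_range_px[2])
      cand <- inside(r)
      if (is.null(cand)) next
      if (nrow(placed) > 0) {
        d <- sqrt((placed$cy - cand[1])^2 + (placed$cx - cand[2])^2)
        if (any(d < placed$r + r + min_gap_px)) next
      }
      placed <- rbind(placed, data.frame(cy = cand[1], cx = cand[2], r = r))
    }
    if (nrow(placed) == n) return(placed)
  }
  stop("lesions do not fit the canvas")
}

#' Generate a synthetic slide
#'
#' Renders the slide at 1 MPP, builds a three-level pyramid (factors 1, 4,
#' 16), and rasterises the tumour annotation on the 5 MPP grid. The region
#' table is exactly consistent with the mask: lesions are placed with a
#' minimum separation so each lesion is one 4-connected region whose pixel
#' area is counted directly from the mask.
#'
#' @param spec A [synthetic_slide_spec()].
#' @param dir If non-`NULL`, the slide (pyramidal TIFF + MPP sidecar), the
#'   5 MPP annotation mask (PNG) and the region table (CSV) are written
#'   there.
#' @param id Slide identifier used for file names.
#' @return List with `slide` ([slide_pyramid()]), `annotation` (binary 5 MPP
#'   mask), `tissue_gt` (geometric tissue mask at 5 MPP), `regions` (data
#'   frame: `region_id`, `cx_um`, `cy_um`, `radius_mm`, `area_px`,
#'   `area_mm2`), `spec`, and (when written) `paths`.
#' @export
generate_slide <- function(spec, dir = NULL, id = "slide") {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  n <- spec$canvas_px
  tex <- spec$texture
  px_per_mm <- 1000 / spec$mpp
  out <- with_seed(spec$seed, {
    # --- geometry (all in level-0 pixels = micrometres at 1 MPP) ---
    if (spec$tissue_type == "en_bloc") {
      a <- runif(1, tex$tissue_radius_frac[1], tex$tissue_radius_frac[2]) * n
      b <- runif(1, tex$tissue_radius_frac[1], tex$tissue_radius_frac[2]) * n
      cy0 <- n / 2 + runif(1, -0.02, 0.02) * n
      cx0 <- n / 2 + runif(1, -0.02, 0.02) * n
      tissue_fun <- function(y, x) {
        ((y - cy0) / a)^2 + ((x - cx0) / b)^2 <= 1
      }
      margin <- tex$lesion_margin_mm * px_per_mm
      inside <- function(r) {
        if (a - r - margin <= 0 || b - r - margin <= 0) {
          return(NULL)    # this radius cannot fit; caller retries
        }
        for (k in 1:50) {
          cy <- runif(1, cy0 - a, cy0 + a)
          cx <- runif(1, cx0 - b, cx0 + b)
          if (((cy - cy0) / (a - r - margin))^2 +
              ((cx - cx0) / (b - r - margin))^2 <= 1) {
            return(c(cy, cx))
          }
        }
        NULL
      }
      lesions <- place_disks(spec$n_lesions,
                             spec$lesion_radius_mm * px_per_mm,
                             inside, min_gap_px = 0.12 * px_per_mm)
      fragments <- NULL
    } else {
      border <- max(spec$fragment_radius_mm) * px_per_mm + 80
      inside <- function(r) c(runif(1, border, n - border),
                              runif(1, border, n - border))
      fragments <- place_disks(spec$n_fragments,
                               spec$fragment_radius_mm * px_per_mm,
                               inside, min_gap_px = 0.12 * px_per_mm)
      n_tum <- round(spec$tumour_fragment_frac * nrow(fragments))
      tum_idx <- if (n_tum > 0) sample(nrow(fragments), n_tum) else integer(0)
      lesions <- fragments[sort(tum_idx), , drop = FALSE]
      tissue_fun <- function(y, x) {
        m <- matrix(FALSE, length(y), 1)
        inm <- rep(FALSE, length(y))
        for (i in seq_len(nrow(fragments))) {
          inm <- inm | ((y - fragments$cy[i])^2 + (x - fragments$cx[i])^2 <=
                          fragments$r[i]^2)
        }
        inm
      }
    }

    # --- 1 MPP tissue / tumour index masks ---
    # tissue via separable coordinate terms; lesions rasterised inside their
    # bounding boxes only
    cy_px <- seq_len(n) - 0.5
    if (spec$tissue_type == "en_bloc") {
      tissue1 <- outer(((cy_px - cy0) / a)^2, ((cy_px - cx0) / b)^2, `+`) <= 1
    } else {
      tissue1 <- matrix(FALSE, n, n)
    }
    tumour1 <- matrix(FALSE, n, n)
    rasterise_disk <- function(mask, cy, cx, r) {
      y0 <- max(1, floor(cy - r)); y1 <- min(n, ceiling(cy + r))
      x0 <- max(1, floor(cx - r)); x1 <- min(n, ceiling(cx + r))
      sub <- outer((cy_px[y0:y1] - cy)^2, (cy_px[x0:x1] - cx)^2, `+`) <= r^2
      mask[y0:y1, x0:x1] <- mask[y0:y1, x0:x1] | sub
      mask
    }
    if (spec$tissue_type == "fragmented") {
      for (i in seq_len(nrow(fragments))) {
        tissue1 <- rasterise_disk(tissue1, fragments$cy[i], fragments$cx[i],
                                  fragments$r[i])
      }
    }
    if (nrow(lesions) > 0) {
      for (i in seq_len(nrow(lesions))) {
        tumour1 <- rasterise_disk(tumour1, lesions$cy[i], lesions$cx[i],
                                  lesions$r[i])
      }
    }
    tumour1 <- tumour1 & tissue1

    # --- render ---
    # one shared (luminance-like) noise field keeps the per-channel work low
    canvas <- array(0, c(n, n, 3))
    idx_t <- which(tissue1)
    tum_t <- tumour1[idx_t]
    n_t <- length(idx_t)
    noise <- rnorm(n * n)
    speckle_sel <- idx_t[runif(n_t) < tex$speckle_frac]
    speckle_d <- runif(length(speckle_sel), tex$speckle_depth[1], tex$speckle_depth[2])
    for (c in 1:3) {
      ch <- tex$white_base + tex$white_noise * noise
      ch[idx_t] <- tex$stroma_rgb[c] +
        (tex$tumour_rgb[c] - tex$stroma_rgb[c]) * tum_t +
        tex$noise_sd * noise[idx_t]
      ch[speckle_sel] <- ch[speckle_sel] - speckle_d
      canvas[, , c] <- ch
    }
    # nuclei
    area_mm2 <- function(npx) npx / px_per_mm^2
    stamp <- function(sel_mask, per_mm2, r_range, rgb) {
      idx <- which(sel_mask)
      k <- round(per_mm2 * area_mm2(length(idx)))
      if (k == 0 || length(idx) == 0) return(NULL)
      pos <- sample(idx, k, replace = TRUE)
      cy <- (pos - 1) %% n
      cx <- (pos - 1) %/% n
      col <- matrix(rep(rgb, each = k), k, 3) +
        matrix(rnorm(3 * k, 0, tex$nucleus_rgb_sd), k, 3)
      canvas <<- array(cpp_stamp_disks(as.vector(canvas), n, n, 3L,
                                       cy, cx, runif(k, r_range[1], r_range[2]),
                                       col),
                       c(n, n, 3))
      NULL
    }
    stamp(tissue1 & !tumour1, tex$stroma_nuclei_per_mm2,
          tex$stroma_nucleus_px, tex$nucleus_rgb)
    stamp(tumour1, tex$tumour_nuclei_per_mm2,
          tex$tumour_nucleus_px, tex$tumour_nucleus_rgb)
    level0 <- round(pmin(pmax(canvas, 0), 255))
    rm(canvas)

    # --- pyramid (factors 1, 4, 16) ---
    mk_level <- function(src, f) {
      d0 <- dim(src)
      d <- d0[1:2] %/% f
      out <- cpp_area_resample_multi(src, d0[1], d0[2], 3L, 0, 0,
                                     d0[1], d0[2], d[1], d[2])
      round(array(out, c(d[1], d[2], 3)))
    }
    level1 <- mk_level(level0, 4L)
    slide <- slide_pyramid(list(level0, level1, mk_level(level1, 4L)),
                           mpp_x = spec$mpp, mpp_y = spec$mpp)

    # --- 5 MPP ground truth ---
    n5 <- floor(n * spec$mpp / 5)
    c5 <- (seq_len(n5) - 0.5) * 5 / spec$mpp   # level-0 px coordinates
    ys5 <- matrix(c5, n5, n5); xs5 <- t(ys5)
    ann5 <- matrix(0L, n5, n5)
    regions <- data.frame(region_id = integer(0), cx_um = numeric(0),
                          cy_um = numeric(0), radius_mm = numeric(0),
                          area_px = integer(0), area_mm2 = numeric(0))
    if (nrow(lesions) > 0) {
      for (i in seq_len(nrow(lesions))) {
        inside_i <- (ys5 - lesions$cy[i])^2 + (xs5 - lesions$cx[i])^2 <=
          lesions$r[i]^2
        ann5[inside_i] <- 1L
        regions <- rbind(regions, data.frame(
          region_id = i, cx_um = lesions$cx[i] * spec$mpp,
          cy_um = lesions$cy[i] * spec$mpp,
          radius_mm = lesions$r[i] * spec$mpp / 1000,
          area_px = sum(inside_i),
          area_mm2 = pixels_to_mm(sum(inside_i), 5, area = TRUE)))
      }
    }
    tis5 <- matrix(as.integer(tissue_fun(as.vector(ys5), as.vector(xs5))), n5, n5)
    list(slide = slide, annotation = ann5, tissue_gt = tis5,
         regions = regions)
  })
  out$spec <- spec
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      slide = file.path(dir, paste0(id, ".tif")),
      mask = file.path(dir, paste0(id, "_mask.png")),
      regions = file.path(dir, paste0(id, "_regions.csv"))
    )
    write_slide(out$slide, paths$slide)
    write_mask_png(out$annotation, paths$mask)
    write.csv(out$regions, paths$regions, row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Preset slide specifications
#'
#' `"mini"`: 4096 px (4.1 x 4.1 mm) canvas for fast end-to-end runs, meant
#' to be tiled with 2048 px tiles and 256 px minimum overlap. `"standard"`:
#' 16,384 px (16.4 x 16.4 mm) canvas exercising the published 7680/1024
#' tiling. `"fragmented"`: many small tumour pieces (all below 1 mm^2),
#' emulating transurethral-resection material.
#'
#' @param name Preset name.
#' @param seed Seed for the spec.
#' @param n_lesions Lesion count for en-bloc presets.
#' @return A [synthetic_slide_spec()].
#' @export
slide_preset <- function(name = c("mini", "standard", "fragmented"),
                         seed = 1L, n_lesions = 2L) {
  name <- match.arg(name)
  switch(name,
    mini = synthetic_slide_spec(seed = seed, canvas_px = 4096L,
                                n_lesions = n_lesions),
    standard = synthetic_slide_spec(seed = seed, canvas_px = 16384L,
                                    n_lesions = n_lesions,
                                    lesion_radius_mm = c(1, 2.5)),
    fragmented = synthetic_slide_spec(seed = seed, canvas_px = 4096L,
                                      tissue_type = "fragmented",
                                      n_lesions = 0L)
  )
}

#' Tiling parameters matching a preset
#'
#' @param name Preset name as in [slide_preset()].
#' @return List with `tile` and `min_overlap` (inference settings) and
#'   `train_tile`, `train_crop` (training settings).
#' @export
preset_tiling <- function(name = c("mini", "standard", "fragmented")) {
  name <- match.arg(name)
  if (name == "standard") {
    list(tile = 7680L, min_overlap = 1024L, train_tile = 2048L, train_crop = 1536L)
  } else {
    list(tile = 2048L, min_overlap = 256L, train_tile = 128L, train_crop = 96L)
  }
}

#' Generate a cohort of synthetic slides
#'
#' Slides are generated independently with seeds derived from `seed`;
#' en-bloc cohorts vary the lesion count over `n_lesions_range`.
#'
#' @param n_slides Number of slides.
#' @param preset Preset name as in [slide_preset()].
#' @param seed Master seed.
#' @param n_lesions_range Inclusive lesion-count range for en-bloc slides.
#' @param dir Optional output directory (slides and masks are written).
#' @return List with `slides` (list of [generate_slide()] results) and
#'   `manifest` (data frame: `slide_id`, `seed`, `n_regions`,
#'   `tumour_area_mm2`).
#' @export
generate_cohort <- function(n_slides, preset = "mini", seed = 1L,
                            n_lesions_range = c(1L, 3L), dir = NULL) {
  seeds <- derive_seeds(seed, n_slides + 1)
  counts <- with_seed(seeds[n_slides + 1], {
    sample(seq(n_lesions_range[1], n_lesions_range[2]), n_slides, replace = TRUE)
  })
  slides <- lapply(seq_len(n_slides), function(i) {
    sp <- slide_preset(preset, seed = seeds[i], n_lesions = counts[i])
    generate_slide(sp, dir = dir, id = sprintf("%s_%03d", preset, i))
  })
  manifest <- data.frame(
    slide_id = sprintf("%s_%03d", preset, seq_len(n_slides)),
    seed = seeds[seq_len(n_slides)],
    n_regions = vapply(slides, function(s) nrow(s$regions), 0L),
    tumour_area_mm2 = vapply(slides, function(s) sum(s$regions$area_mm2), 0)
  )
  list(slides = slides, manifest = manifest)
}
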