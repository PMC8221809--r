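#' Confocal voxel stack
#'
#' Multi-channel 3-D intensity stack (z, y, x per channel) with the voxel
#' geometry needed for volume quantification. The axial step must not exceed
#' the optical-section thickness (the oversampling regime the volume formula
#' corrects for).
#'
#' @param channels named list of 3-D arrays `[z, y, x]`, identical dims.
#' @param pixel_size_um lateral pixel size, micrometres.
#' @param optical_section_um optical section thickness (axial resolution), um.
#' @param step_um z-step between slices, um; `step_um <= optical_section_um`.
#' @return object of class `voxel_stack`.
#' @export
voxel_stack <- function(channels, pixel_size_um, optical_section_um, step_um) {
  stopifnot(is.list(channels), length(channels) >= 1L, !is.null(names(channels)))
  dims <- dim(channels[[1]])
  if (length(dims) != 3L) stop("channels must be 3-D arrays [z, y, x]")
  for (nm in names(channels)) {
    if (!identical(dim(channels[[nm]]), dims)) {
      stop(sprintf("channel '%s' dimensions differ", nm))
    }
  }
  if (pixel_size_um <= 0 || optical_section_um <= 0 || step_um <= 0) {
    stop("all geometry values must be > 0")
  }
  if (step_um > optical_section_um) {
    stop("step_um must be <= optical_section_um (oversampling regime)")
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 optical_section_um = optical_section_um, step_um = step_um),
            class = "voxel_stack")
}

#' Steps per optical section
#'
#' N = optical section thickness / step size, rounded to the nearest integer,
#' floored at 1.
#' @param stack a [voxel_stack].
#' @return integer N >= 1.
#' @export
steps_per_section <- function(stack) {
  max(1L, as.integer(round(stack$optical_section_um / stack$step_um)))
}

#' Huang fuzzy-entropy auto-threshold
#'
#' Selects the threshold minimizing Huang's fuzzy-membership entropy over the
#' intensity histogram. For a candidate threshold the image is split into
#' background/foreground with class means `mu0`, `mu1`; each grey level g gets
#' membership `u(g) = 1 / (1 + |g - mu_class| / C)` (C = intensity range) and
#' the criterion is the summed Shannon entropy `-u log u - (1-u) log(1-u)`
#' weighted by the histogram. Integer-valued images up to 16-bit are binned at
#' native levels; anything else is min-max scaled onto 256 bins.
#'
#' @param x numeric array (2-D or 3-D) with >= 2 distinct values.
#' @return threshold on the original intensity scale; the foreground mask is
#'   `x > threshold`. The value falls strictly between the last background and
#'   first foreground level.
#' @export
huang_threshold <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite intensities")
  rng <- range(v)
  if (rng[1] == rng[2]) stop("constant image: no threshold exists")
  native <- all(v == round(v)) && (rng[2] - rng[1]) <= 65535
  if (native) {
    levels <- seq(rng[1], rng[2])
    h <- tabulate(v - rng[1] + 1L, nbins = length(levels))
  } else {
    nb <- 256L
    bin <- pmin(nb, floor((v - rng[1]) / (rng[2] - rng[1]) * nb) + 1L)
    h <- tabulate(bin, nbins = nb)
    levels <- rng[1] + (seq_len(nb) - 0.5) * (rng[2] - rng[1]) / nb
  }
  k <- .huang_best_split(h, levels)
  # threshold between level k (last background) and the next occupied level
  occ <- which(h > 0)
  nxt <- occ[occ > k][1]
  (levels[k] + levels[nxt]) / 2
}

# index (into levels) of the last background level of the best split
.huang_best_split <- function(h, levels) {
  w <- h * levels
  cw <- cumsum(h); cwl <- cumsum(w)
  n <- sum(h); tot <- sum(w)
  C <- levels[length(levels)] - levels[1]
  occ <- which(h > 0)
  # candidate split after each occupied level except the last
  cands <- occ[-length(occ)]
  best <- Inf; best_k <- cands[1]
  for (k in cands) {
    mu0 <- cwl[k] / cw[k]
    mu1 <- (tot - cwl[k]) / (n - cw[k])
    mu <- ifelse(seq_along(levels) <= k, mu0, mu1)
    u <- 1 / (1 + abs(levels - mu) / C)
    ent <- -u * log(u) - (1 - u) * log1p(-u)
    ent[u >= 1 - 1e-15] <- 0
    s <- sum(h * ent)
    if (s < best) { best <- s; best_k <- k }
  }
  best_k
}

#' Signal volume from masked areas
#'
#' `SignalVolume (um^3) = A * Z / N` where `A` is the summed signal-positive
#' area across retained slices (um^2), `Z` the optical-section thickness (um)
#' and `N` the number of z-steps per optical section. Dividing by N corrects
#' for axial oversampling.
#'
#' @param area_um2 per-slice signal-positive areas (um^2), summed internally,
#'   or a single pre-summed area.
#' @param z_um optical section thickness, > 0.
#' @param n_steps steps per optical section, integer >= 1.
#' @return volume in um^3.
#' @export
signal_volume <- function(area_um2, z_um, n_steps) {
  if (z_um <= 0) stop("z_um must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  sum(area_um2) * z_um / n_steps
}

#' Circular ROI table
#'
#' @param cell_id identifiers.
#' @param cx,cy lateral centre in pixel coordinates (1-based).
#' @param radius_px circle radius in pixels.
#' @param z_min,z_max retained slice range (1-based, inclusive); slices above
#'   the lowest monolayer are excluded upstream by restricting this range.
#' @return data.frame of class `roi_table`.
#' @export
roi_table <- function(cell_id, cx, cy, radius_px, z_min = 1L, z_max = NA_integer_) {
  out <- data.frame(cell_id = cell_id, cx = cx, cy = cy, radius_px = radius_px,
                    z_min = z_min, z_max = z_max)
  class(out) <- c("roi_table", "data.frame")
  out
}

#' Per-ROI signal volumes
#'
#' For each ROI and channel, a Huang threshold is computed from the ROI's own
#' voxels and the signal-positive area per retained slice is converted to a
#' volume with [signal_volume()]. Whole-cell filter: ROIs whose circle touches
#' or crosses the lateral image border are excluded (volume `NA`,
#' `excluded_border = TRUE`).
#'
#' @param stack a [voxel_stack].
#' @param rois a [roi_table].
#' @param channels channels to quantify (default all).
#' @return data.frame of class `volume_results`: `cell_id`, `channel`,
#'   `volume_um3`, `threshold`, `excluded_border`.
#' @export
measure_rois <- function(stack, rois, channels = names(stack$channels)) {
  stopifnot(inherits(stack, "voxel_stack"), is.data.frame(rois))
  dims <- dim(stack$channels[[1]])
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  n_steps <- steps_per_section(stack)
  px_area <- stack$pixel_size_um^2
  res <- list()
  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    zmin <- if (is.na(r$z_min)) 1L else max(1L, r$z_min)
    zmax <- if (is.na(r$z_max)) nz else min(nz, r$z_max)
    border <- (r$cx - r$radius_px) < 1 || (r$cx + r$radius_px) > nx ||
      (r$cy - r$radius_px) < 1 || (r$cy + r$radius_px) > ny
    # lateral disc mask
    xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
    ys <- matrix(rep(seq_len(ny), times = nx), ny, nx)
    disc <- (xs - r$cx)^2 + (ys - r$cy)^2 <= r$radius_px^2
    for (ch in channels) {
      if (border) {
        res[[length(res) + 1L]] <- data.frame(
          cell_id = r$cell_id, channel = ch, volume_um3 = NA_real_,
          threshold = NA_real_, excluded_border = TRUE)
        next
      }
      zs <- zmin:zmax
      vox <- vapply(zs, function(z) {
        sl <- stack$channels[[ch]][z, , ]
        sl[disc]
      }, numeric(sum(disc)))                       # npix x nslices
      vox <- matrix(vox, nrow = sum(disc))
      if (length(unique(as.numeric(vox))) < 2L) {
        # contrast-free ROI: nothing to segment, zero signal volume
        res[[length(res) + 1L]] <- data.frame(
          cell_id = r$cell_id, channel = ch, volume_um3 = 0,
          threshold = NA_real_, excluded_border = FALSE)
        next
      }
      thr <- huang_threshold(as.numeric(vox))
      areas <- colSums(vox > thr) * px_area
      res[[length(res) + 1L]] <- data.frame(
        cell_id = r$cell_id, channel = ch,
        volume_um3 = signal_volume(areas, stack$optical_section_um, n_steps),
        threshold = thr, excluded_border = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("volume_results", "data.frame")
  out
}

#' Connected-component ROI detection (fallback for synthetic stacks)
#'
#' 6-connected components of the thresholded reference channel; each component
#' becomes a circular ROI (centroid + radius covering its lateral extent).
#'
#' @param stack a [voxel_stack].
#' @param channel reference channel for detection.
#' @param threshold optional; defaults to the channel's Huang threshold.
#' @return a [roi_table].
#' @export
detect_rois <- function(stack, channel = names(stack$channels)[1], threshold = NULL) {
  arr <- stack$channels[[channel]]
  if (is.null(threshold)) threshold <- huang_threshold(arr)
  mask <- arr > threshold
  dims <- dim(mask)
  lab <- array(0L, dims)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      co <- arrayInd(p, dims)
      for (d in 1:3) for (s in c(-1L, 1L)) {
        nb <- co; nb[d] <- nb[d] + s
        if (nb[d] < 1L || nb[d] > dims[d]) next
        q <- nb[1] + (nb[2] - 1L) * dims[1] + (nb[3] - 1L) * dims[1] * dims[2]
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  if (cur == 0L) return(roi_table(character(0), numeric(0), numeric(0), numeric(0)))
  rows <- lapply(seq_len(cur), function(k) {
    co <- arrayInd(which(lab == k), dims)
    cx <- mean(co[, 3]); cy <- mean(co[, 2])
    rad <- max(sqrt((co[, 3] - cx)^2 + (co[, 2] - cy)^2)) + 0.5
    data.frame(cell_id = paste0("cc", k), cx = cx, cy = cy, radius_px = rad,
               z_min = min(co[, 1]), z_max = max(co[, 1]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("roi_table", "data.frame")
  out
}

#' Mitochondrial-to-nuclear volume ratio
#'
#' @param mito_volume,nuclear_volume volumes (um^3) for one cell ROI.
#' @return dimensionless ratio.
#' @export
volume_ratio <- function(mito_volume, nuclear_volume) {
  if (any(nuclear_volume <= 0)) stop("nuclear_volume must be > 0")
  mito_volume / nuclear_volume
}

#' Respiratory-deficiency index
#'
#' Compares respiratory capacity (protein-normalized maximal flux) to
#' mitochondrial content (mitochondrial signal volume), normalized to a
#' reference group's capacity/content quotient, which is 1 by construction.
#'
#' @param capacity protein-normalized maximal JO2, > 0.
#' @param content mitochondrial volume (e.g. TMRM), > 0.
#' @param ref_capacity,ref_content reference group means, > 0.
#' @return dimensionless index (reference group = 1).
#' @export
respiratory_deficiency <- function(capacity, content, ref_capacity, ref_content) {
  if (any(c(capacity, content, ref_capacity, ref_content) <= 0)) {
    stop("all inputs must be > 0")
  }
  (capacity / content) / (ref_capacity / ref_content)
}

#' Read/write a voxel stack as plain-text CSV
#'
#' Long-format CSV with columns `channel,z,y,x,intensity` plus a sidecar-free
#' header encoding of the geometry in the first comment line:
#' `# pixel_size_um=..,optical_section_um=..,step_um=..,dims=z:y:x`.
#' This is the text-only interchange format used by the CLI in place of TIFF.
#'
#' @param stack a [voxel_stack] (for writing).
#' @param path file path.
#' @return [read_stack_csv()] returns a [voxel_stack].
#' @export
write_stack_csv <- function(stack, path) {
  dims <- dim(stack$channels[[1]])
  hdr <- sprintf("# pixel_size_um=%g,optical_section_um=%g,step_um=%g,dims=%d:%d:%d",
                 stack$pixel_size_um, stack$optical_section_um, stack$step_um,
                 dims[1], dims[2], dims[3])
  rows <- do.call(rbind, lapply(names(stack$channels), function(ch) {
    a <- stack$channels[[ch]]
    co <- arrayInd(seq_along(a), dims)
    data.frame(channel = ch, z = co[, 1], y = co[, 2], x = co[, 3],
               intensity = as.numeric(a))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# ")) stop("missing geometry header line")
  kv <- strsplit(sub("^# ", "", hdr), ",")[[1]]
  meta <- setNames(lapply(strsplit(kv, "="), `[`, 2),
                   vapply(strsplit(kv, "="), `[`, 1, FUN.VALUE = character(1)))
  dims <- as.integer(strsplit(meta$dims, ":")[[1]])
  d <- read.csv(path, skip = 1L)
  chans <- lapply(split(d, d$channel), function(g) {
    a <- array(0, dims)
    a[cbind(g$z, g$y, g$x)] <- g$intensity
    a
  })
  voxel_stack(chans, as.numeric(meta$pixel_size_um),
              as.numeric(meta$optical_section_um), as.numeric(meta$step_um))
}
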