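#' Simulate a two-channel array-tomography image stack
#'
#' Plants punctate objects (2x2x2-voxel bright blobs) in two channels of
#' a serial-section voxel grid. A configurable fraction of channel-B
#' puncta is placed directly opposed to a channel-A punctum (within
#' `opposition_nm` of its centroid), emulating pre/postsynaptic marker
#' pairs; the rest are placed uniformly at random. Same-channel puncta
#' keep at least two empty voxels between footprints so they can never
#' merge under 26-connectivity. Optional Gaussian point-spread blurring
#' and additive Gaussian noise follow placement.
#'
#' @param shape integer vector (slices, rows, cols); at least 3 slices.
#' @param voxel_size numeric (dz, dy, dx) in nm; dz is the section
#'   thickness (70 nm sections by default).
#' @param n_puncta integer vector (channel A count, channel B count).
#' @param coloc_fraction fraction of B puncta planted opposed to an A
#'   punctum.
#' @param opposition_nm maximum planted centroid distance for an opposed
#'   pair.
#' @param psf_sigma point-spread sigma in nm (0 = no blur).
#' @param noise_sd SD of additive Gaussian noise (intensity units;
#'   amplitude of a planted punctum is 1).
#' @param seed integer seed.
#' @return list with `channels` (list of two 3D arrays `A`, `B`),
#'   `voxel_size`, and `truth` (data.frame: `channel`, planted centroid
#'   `z_nm`, `y_nm`, `x_nm`, `colocalized`).
#' @export
simulate_image_stack <- function(shape = c(12L, 64L, 64L),
                                 voxel_size = c(70, 100, 100),
                                 n_puncta = c(30L, 30L),
                                 coloc_fraction = 0.5,
                                 opposition_nm = 300,
                                 psf_sigma = 0, noise_sd = 0,
                                 seed = 1L) {
  if (length(shape) != 3L || shape[1] < 3L || any(shape < 1L)) {
    stop("shape must be (slices, rows, cols) with >= 3 slices")
  }
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (any(n_puncta < 0L)) stop("puncta counts must be >= 0")
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    stop("coloc_fraction must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  d <- as.integer(shape)
  # base voxel (1-based) of the 2x2x2 footprint; kept one voxel off edges
  max_base <- d - 1L
  sep <- 4L  # Chebyshev separation of base voxels within a channel

  place_random <- function(existing) {
    for (try in seq_len(2000L)) {
      cand <- c(sample.int(max_base[1], 1L), sample.int(max_base[2], 1L),
                sample.int(max_base[3], 1L))
      if (is_separated(cand, existing, sep)) return(cand)
    }
    stop("could not place punctum: volume too crowded")
  }

  bases_a <- matrix(0L, 0L, 3L)
  for (i in seq_len(n_puncta[1])) {
    bases_a <- rbind(bases_a, place_random(bases_a))
  }

  # candidate voxel shifts whose physical centroid distance fits the
  # opposition radius
  offs <- as.matrix(expand.grid(dz = -3:3, dy = -3:3, dx = -3:3))
  phys <- sqrt((offs[, 1] * voxel_size[1])^2 +
                 (offs[, 2] * voxel_size[2])^2 +
                 (offs[, 3] * voxel_size[3])^2)
  offs <- offs[phys > 0 & phys <= opposition_nm, , drop = FALSE]
  if (nrow(offs) == 0L && n_puncta[2] > 0L && coloc_fraction > 0 &&
      n_puncta[1] > 0L) {
    stop("opposition_nm smaller than one voxel; no opposed placement exists")
  }

  n_coloc <- round(coloc_fraction * n_puncta[2])
  if (n_puncta[1] == 0L) n_coloc <- 0L
  bases_b <- matrix(0L, 0L, 3L)
  coloc_flag <- logical(0)
  for (i in seq_len(n_puncta[2])) {
    placed <- FALSE
    if (i <= n_coloc) {
      for (try in seq_len(2000L)) {
        anchor <- bases_a[sample.int(nrow(bases_a), 1L), ]
        cand <- anchor + offs[sample.int(nrow(offs), 1L), ]
        if (all(cand >= 1L) && all(cand <= max_base) &&
            is_separated(cand, bases_b, sep)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place opposed punctum")
      coloc_flag <- c(coloc_flag, TRUE)
    } else {
      # uniform placement, kept clear of channel-A anchors so it is not
      # colocalized by construction
      for (try in seq_len(2000L)) {
        cand <- c(sample.int(max_base[1], 1L), sample.int(max_base[2], 1L),
                  sample.int(max_base[3], 1L))
        if (!is_separated(cand, bases_b, sep)) next
        if (nrow(bases_a) > 0L) {
          dist_a <- sqrt(colSums((t(bases_a) - cand)^2 * voxel_size^2))
          if (min(dist_a) <= opposition_nm + 2 * max(voxel_size)) next
        }
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place punctum: volume too crowded")
      coloc_flag <- c(coloc_flag, FALSE)
    }
    bases_b <- rbind(bases_b, cand)
  }

  render <- function(bases) {
    a <- array(0, d)
    for (i in seq_len(nrow(bases))) {
      b <- bases[i, ]
      a[b[1]:(b[1] + 1L), b[2]:(b[2] + 1L), b[3]:(b[3] + 1L)] <- 1
    }
    if (psf_sigma > 0) a <- gaussian_blur_3d(a, psf_sigma / voxel_size)
    if (noise_sd > 0) {
      a <- a + array(stats::rnorm(prod(d), sd = noise_sd), d)
      a[a < 0] <- 0
    }
    a
  }
  chan_a <- render(bases_a)
  chan_b <- render(bases_b)

  centroid_nm <- function(bases) {
    if (nrow(bases) == 0L) {
      return(matrix(numeric(0), 0L, 3L))
    }
    # footprint occupies 0-based indices (b-1, b); centroid (b-1)+0.5
    sweep(bases - 0.5, 2L, voxel_size, `*`)
  }
  ca <- centroid_nm(bases_a)
  cb <- centroid_nm(bases_b)
  truth <- data.frame(
    channel = c(rep("A", nrow(ca)), rep("B", nrow(cb))),
    z_nm = c(ca[, 1], cb[, 1]),
    y_nm = c(ca[, 2], cb[, 2]),
    x_nm = c(ca[, 3], cb[, 3]),
    colocalized = c(rep(NA, nrow(ca)), coloc_flag),
    stringsAsFactors = FALSE
  )
  list(channels = list(A = chan_a, B = chan_b),
       voxel_size = voxel_size, truth = truth)
}

is_separated <- function(cand, existing, sep) {
  if (nrow(existing) == 0L) return(TRUE)
  cheb <- apply(abs(sweep(existing, 2L, cand)), 1L, max)
  all(cheb >= sep)
}

gaussian_blur_3d <- function(a, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    a <- apply_along(a, axis, function(v) {
      stats::filter(c(rep(0, r), v, rep(0, r)), k,
                    sides = 2)[(r + 1):(r + length(v))]
    })
  }
  a
}

apply_along <- function(a, axis, f) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  m <- apply(m, 2L, f)
  ap <- array(m, dim(ap))
  aperm(ap, order(perm))
}

#' Segment puncta in one channel
#'
#' Binarizes each slice at its own mean + k.SD intensity (per-slice, to
#' tolerate section-to-section staining variation), labels the binary
#' volume by 3D 26-connectivity across sections, and keeps components
#' within the size and slice-span bounds. Centroids are reported in
#' physical nm respecting the anisotropic voxel size.
#'
#' @param stack 3D numeric array (slices, rows, cols).
#' @param voxel_size numeric (dz, dy, dx) in nm.
#' @param threshold_k threshold multiplier k in mean + k.SD.
#' @param min_voxels,max_voxels component volume bounds in voxels.
#' @param min_slices minimum number of sections a component must span.
#' @return data.frame of puncta: `id`, `z_nm`, `y_nm`, `x_nm`, `voxels`,
#'   `slices`, `volume_um3`.
#' @export
segment_puncta <- function(stack, voxel_size = c(70, 100, 100),
                           threshold_k = 2.0, min_voxels = 2L,
                           max_voxels = Inf, min_slices = 1L) {
  if (!is.array(stack) || length(dim(stack)) != 3L || prod(dim(stack)) == 0) {
    stop("stack must be a non-empty 3D array")
  }
  if (any(!is.finite(stack))) stop("non-finite intensities")
  d <- dim(stack)
  mask <- array(FALSE, d)
  for (s in seq_len(d[1])) {
    sl <- stack[s, , ]
    thr <- mean(sl) + threshold_k * stats::sd(sl)
    mask[s, , ] <- sl > thr
  }
  lab <- label_components_3d(mask)
  empty <- data.frame(id = integer(0), z_nm = numeric(0),
                      y_nm = numeric(0), x_nm = numeric(0),
                      voxels = integer(0), slices = integer(0),
                      volume_um3 = numeric(0))
  if (lab$n == 0L) return(empty)
  vox_um3 <- prod(voxel_size) * 1e-9
  rows <- vector("list", lab$n)
  keep <- 0L
  for (i in seq_len(lab$n)) {
    idx <- which(lab$labels == i, arr.ind = TRUE)
    nv <- nrow(idx)
    nslices <- diff(range(idx[, 1])) + 1L
    if (nv < min_voxels || nv > max_voxels || nslices < min_slices) next
    keep <- keep + 1L
    cen <- colMeans(idx) - 1  # 0-based voxel centroid
    rows[[keep]] <- data.frame(id = keep,
                               z_nm = cen[1] * voxel_size[1],
                               y_nm = cen[2] * voxel_size[2],
                               x_nm = cen[3] * voxel_size[3],
                               voxels = nv, slices = nslices,
                               volume_um3 = nv * vox_um3)
  }
  if (keep == 0L) return(empty)
  out <- do.call(rbind, rows[seq_len(keep)])
  rownames(out) <- NULL
  out
}

# 3D connected-component labelling, 26-connectivity, pure BFS over
# foreground voxels (no installed package labels 3D arrays).
label_components_3d <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(list(labels = labels, n = 0L))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  n <- 0L
  for (i in seq_len(nrow(fg))) {
    v <- fg[i, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    n <- n + 1L
    stack_ <- list(v)
    labels[v[1], v[2], v[3]] <- n
    while (length(stack_)) {
      cur <- stack_[[length(stack_)]]
      stack_[[length(stack_)]] <- NULL
      for (j in seq_len(nrow(offs))) {
        nb <- cur + offs[j, ]
        if (any(nb < 1L) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && labels[nb[1], nb[2], nb[3]] == 0L) {
          labels[nb[1], nb[2], nb[3]] <- n
          stack_[[length(stack_) + 1L]] <- nb
        }
      }
    }
  }
  list(labels = labels, n = n)
}

#' Puncta density per unit volume
#'
#' @param puncta puncta data.frame from [segment_puncta()] (only its row
#'   count is used).
#' @param shape stack dimensions (slices, rows, cols).
#' @param voxel_size numeric (dz, dy, dx) in nm.
#' @return Density in puncta per cubic micron.
#' @export
puncta_density <- function(puncta, shape, voxel_size = c(70, 100, 100)) {
  vol_um3 <- prod(shape) * prod(voxel_size) * 1e-9
  if (vol_um3 <= 0) stop("zero analyzed volume")
  NROW(puncta) / vol_um3
}

#' Opposed-puncta colocalization fraction
#'
#' Fraction of channel-B puncta whose centroid lies within
#' `max_distance_nm` of the centroid of at least one channel-A punctum
#' (physical distance, anisotropic voxel size already folded into the
#' nm coordinates). One A punctum may partner several B puncta.
#'
#' @param puncta_a,puncta_b puncta data.frames with `z_nm`, `y_nm`,
#'   `x_nm`, segmented from the same aligned stack.
#' @param max_distance_nm colocalization radius in nm.
#' @return Fraction in [0, 1] (0 when either list is empty).
#' @export
colocalize <- function(puncta_a, puncta_b, max_distance_nm = 500) {
  if (max_distance_nm < 0) stop("max_distance_nm must be >= 0")
  if (nrow(puncta_b) == 0L || nrow(puncta_a) == 0L) return(0)
  pa <- as.matrix(puncta_a[, c("z_nm", "y_nm", "x_nm")])
  pb <- as.matrix(puncta_b[, c("z_nm", "y_nm", "x_nm")])
  hit <- vapply(seq_len(nrow(pb)), function(i) {
    min(sqrt(colSums((t(pa) - pb[i, ])^2))) <= max_distance_nm
  }, logical(1))
  mean(hit)
}

#' Percent change of group mean densities
#'
#' @param densities_a,densities_b numeric vectors of per-stack densities
#'   for the reference and comparison groups.
#' @return 100 * (mean(b) - mean(a)) / mean(a).
#' @export
group_percent_change <- function(densities_a, densities_b) {
  if (length(densities_a) == 0L || length(densities_b) == 0L) {
    stop("both groups must be non-empty")
  }
  ma <- mean(densities_a)
  if (ma == 0) stop("reference group mean is zero")
  100 * (mean(densities_b) - ma) / ma
}

#' Write an image stack as multi-page TIFF (one file per channel)
#'
#' Intensities are rescaled to [0, 1] by the stack maximum before
#' writing (32-bit float samples); the mean + k.SD segmentation is
#' invariant to this rescaling.
#'
#' @param stack a stack from [simulate_image_stack()].
#' @param dir output directory; files are `<channel>.tif`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_image_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    mx <- max(a)
    if (mx > 0) a <- a / mx
    pages <- lapply(seq_len(dim(a)[1]), function(s) a[s, , ])
    path <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    paths[ch] <- path
  }
  invisible(paths)
}

#' Read a multi-page TIFF into a 3D array
#'
#' @param path TIFF path.
#' @return 3D array (slices, rows, cols).
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  a <- array(0, c(length(pages), d[1], d[2]))
  for (s in seq_along(pages)) a[s, , ] <- pages[[s]]
  a
}
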