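# Seeded generator of a four-class texture image set whose classes differ by
# orientation- and frequency-specific content, so that every stage of the
# pipeline can be exercised without external data:
#   class 0  smooth low-frequency blobs (Gaussian-filtered noise)
#   class 1  horizontal stripes (rows constant; energy in the vertical-detail
#            Haar subband V under this package's filter convention)
#   class 2  vertical stripes (energy in H)
#   class 3  high-frequency diagonal checker (energy in D)

#' Specification of a synthetic texture dataset
#'
#' @param n_per_class Images per class.
#' @param image_size Square image side (default 64; 224 for protocol-faithful
#'   runs).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param stripe_period Nominal stripe period in pixels (jittered +-20% per
#'   image).
#' @param blob_scale Gaussian blur radius of the class-0 blobs.
#' @param checker_period Diagonal checker period of class 3 (1 = fastest
#'   alternation).
#' @param seed Integer; the whole dataset is a deterministic function of the
#'   spec including this seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_per_class = 50L, image_size = 64L, noise_sd = 0.05,
                       stripe_period = 8, blob_scale = 8, checker_period = 1L,
                       seed = 1L) {
  if (n_per_class < 1L) stop("n_per_class must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 noise_sd = noise_sd, stripe_period = stripe_period,
                 blob_scale = blob_scale,
                 checker_period = as.integer(checker_period),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# separable Gaussian blur with circular boundary
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- nrow(m)
  idx <- function(i) ((i - 1L) %% n) + 1L
  out <- matrix(0, n, ncol(m))
  for (j in -r:r) out <- out + k[j + r + 1L] * m[idx(seq_len(n) + j), , drop = FALSE]
  out2 <- matrix(0, n, ncol(m))
  for (j in -r:r) out2 <- out2 + k[j + r + 1L] * out[, idx(seq_len(ncol(m)) + j), drop = FALSE]
  out2
}

rescale01 <- function(m, lo = 0.15, hi = 0.85) {
  rg <- range(m)
  if (diff(rg) < 1e-12) return(matrix(mean(c(lo, hi)), nrow(m), ncol(m)))
  lo + (m - rg[1]) / diff(rg) * (hi - lo)
}

synth_image <- function(class_id, spec) {
  n <- spec$image_size
  base <- switch(as.character(class_id),
    "0" = {
      rescale01(gaussian_blur(matrix(stats::rnorm(n * n), n, n), spec$blob_scale))
    },
    "1" = {
      period <- spec$stripe_period * stats::runif(1, 0.8, 1.2)
      phase <- stats::runif(1, 0, 2 * pi)
      row_wave <- 0.5 + 0.35 * sin(2 * pi * seq_len(n) / period + phase)
      matrix(row_wave, n, n)            # rows constant along each row
    },
    "2" = {
      period <- spec$stripe_period * stats::runif(1, 0.8, 1.2)
      phase <- stats::runif(1, 0, 2 * pi)
      col_wave <- 0.5 + 0.35 * sin(2 * pi * seq_len(n) / period + phase)
      matrix(col_wave, n, n, byrow = TRUE)
    },
    "3" = {
      off <- sample.int(2L, 2L, replace = TRUE) - 1L
      cp <- spec$checker_period
      i <- (seq_len(n) - 1L + off[1]) %/% cp
      j <- (seq_len(n) - 1L + off[2]) %/% cp
      0.5 + 0.35 * outer(i, j, function(a, b) ifelse((a + b) %% 2L == 0L, 1, -1))
    },
    stop("class_id must be 0..3"))
  img <- array(rep(base, 3L), c(n, n, 3L))
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(n * n * 3L, sd = spec$noise_sd), c(n, n, 3L))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a synthetic texture dataset on disk
#'
#' Writes `4 * n_per_class` RGB PNG images into per-class subdirectories of
#' `out_dir`, a `manifest.csv` with columns `path,label`, and the spec itself
#' as a key/value YAML file. Deterministic: the same spec produces
#' byte-identical files.
#'
#' @param spec A [synth_spec()].
#' @param out_dir Writable output directory (created if missing).
#' @return Invisibly, the manifest as a data frame.
#' @export
generate_synthetic <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synth_spec"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  with_local_seed(spec$seed, function() {
    paths <- character(0); labels <- integer(0)
    for (cls in 0:3) {
      cdir <- file.path(out_dir, paste0("class", cls))
      dir.create(cdir, showWarnings = FALSE)
      for (i in seq_len(spec$n_per_class)) {
        img <- synth_image(cls, spec)
        p <- file.path(cdir, sprintf("img_%04d.png", i))
        png::writePNG(img, p)
        paths <- c(paths, p); labels <- c(labels, cls)
      }
    }
    manifest <- data.frame(path = paths, label = labels)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    yaml::write_yaml(unclass(spec), file.path(out_dir, "synth_spec.yaml"))
    invisible(manifest)
  })
}

read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(manifest) || !all(c("path", "label") %in% names(manifest))) {
    stop("manifest must be a CSV/data frame with columns path,label")
  }
  if (nrow(manifest) == 0L) stop("manifest is empty")
  manifest$label <- as.integer(manifest$label)
  manifest
}

#' Stratified train/test split of a manifest
#'
#' @param manifest Manifest data frame or path to a `path,label` CSV.
#' @param train_frac Fraction of each class assigned to the training split.
#' @param seed Integer seed; the split is a deterministic function of it.
#' @return List with `train` and `test` manifests (disjoint, union = input).
#' @export
split_manifest <- function(manifest, train_frac = 0.5, seed = 1L) {
  manifest <- read_manifest(manifest)
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  with_local_seed(seed, function() {
    tr <- logical(nrow(manifest))
    for (cls in sort(unique(manifest$label))) {
      idx <- which(manifest$label == cls)
      if (length(idx) < 2L) {
        stop("class ", cls, " has fewer than 2 images; cannot split")
      }
      ntr <- round(train_frac * length(idx))
      ntr <- min(max(ntr, 1L), length(idx) - 1L)
      tr[sample(idx, ntr)] <- TRUE
    }
    list(train = manifest[tr, , drop = FALSE],
         test = manifest[!tr, , drop = FALSE])
  })
}
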