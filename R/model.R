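# Full network assembly: patch embedding, four stages of frequency-aware
# blocks with patch merging, optional cross-scale state-space fusion, global
# average pooling and the linear classification head.

#' Model configuration
#'
#' Defaults follow the Swin-tier layout: patch size 4, base width 96 doubling
#' per stage, depths (2, 2, 6, 2), heads (3, 6, 12, 24). For 224-pixel inputs
#' the four stages then run at 56, 28, 14 and 7 tokens per side. A desk-scale
#' variant is available via [tiny_model_config()].
#'
#' @param image_size Input side length; must be divisible by
#'   `8 * patch_size` so all four stages are well-defined.
#' @param patch_size Patch embedding size `P`.
#' @param channels Stage-1 channel width `C_1` (doubles each stage).
#' @param depths Integer vector of blocks per stage.
#' @param heads Integer vector of attention heads per stage.
#' @param num_classes Number of output classes.
#' @param use_fgt If `FALSE`, every block is the plain windowed (Swin-style)
#'   baseline block instead of the wavelet-subband block.
#' @param use_csm If `FALSE`, the cross-scale fusion block is omitted and the
#'   head pools the stage-4 output directly.
#' @param window_big,window_small,stripe Attention window geometry.
#' @param ffn_ratio FFN hidden ratio.
#' @param state_dim,expansion,conv_width Selective-scan hyperparameters.
#' @param downsample Cross-scale resize mode, `"bilinear"` or `"strided"`.
#' @param ffn_residual Residual topology of the block FFN (`"pre_norm"` or
#'   the `"literal"` form without an outer identity path).
#' @param init_sd Random initialization scale.
#' @return An object of class `crcformer_config`.
#' @export
model_config <- function(image_size = 224L, patch_size = 4L, channels = 96L,
                         depths = c(2L, 2L, 6L, 2L), heads = c(3L, 6L, 12L, 24L),
                         num_classes = 4L, use_fgt = TRUE, use_csm = TRUE,
                         window_big = 8L, window_small = 2L, stripe = 2L,
                         ffn_ratio = 4, state_dim = 16L, expansion = 2,
                         conv_width = 4L,
                         downsample = c("bilinear", "strided"),
                         ffn_residual = c("pre_norm", "literal"),
                         init_sd = 0.02) {
  downsample <- match.arg(downsample)
  ffn_residual <- match.arg(ffn_residual)
  image_size <- as.integer(image_size); patch_size <- as.integer(patch_size)
  if (image_size %% patch_size != 0L) {
    stop("image_size must be divisible by patch_size")
  }
  if (image_size %% (8L * patch_size) != 0L) {
    stop("image_size must be divisible by 8 * patch_size for four stages")
  }
  if (length(depths) != 4L || any(depths < 1L)) stop("depths must be four integers >= 1")
  if (length(heads) != 4L) stop("heads must have length 4")
  ch <- channels * 2L^(0:3)
  if (any(ch %% heads != 0L)) stop("stage channels must be divisible by stage heads")
  structure(list(
    image_size = image_size, patch_size = patch_size, channels = as.integer(channels),
    depths = as.integer(depths), heads = as.integer(heads),
    num_classes = as.integer(num_classes),
    use_fgt = isTRUE(use_fgt), use_csm = isTRUE(use_csm),
    window_big = as.integer(window_big), window_small = as.integer(window_small),
    stripe = as.integer(stripe), ffn_ratio = ffn_ratio,
    state_dim = as.integer(state_dim), expansion = expansion,
    conv_width = as.integer(conv_width), downsample = downsample,
    ffn_residual = ffn_residual, init_sd = init_sd
  ), class = "crcformer_config")
}

#' Desk-scale model configuration
#'
#' A reduced configuration (64-pixel inputs, width 32, depths 1/1/2/1) whose
#' four stages run at 16, 8, 4 and 2 tokens per side; forward and backward
#' passes complete quickly on a CPU.
#'
#' @param ... Overrides passed to [model_config()].
#' @export
tiny_model_config <- function(...) {
  args <- list(image_size = 64L, patch_size = 4L, channels = 32L,
               depths = c(1L, 1L, 2L, 1L), heads = c(2L, 4L, 8L, 16L))
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}

#' Per-stage token resolutions of a configuration
#'
#' @param cfg A `crcformer_config` (or a model).
#' @return Integer vector of the four stage side lengths.
#' @export
stage_resolutions <- function(cfg) {
  if (inherits(cfg, "crcformer_model")) cfg <- cfg$cfg
  as.integer(cfg$image_size %/% (cfg$patch_size * 2L^(0:3)))
}

stage_channels <- function(cfg) as.integer(cfg$channels * 2L^(0:3))

# run fn with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Build a model from a configuration
#'
#' Initializes every parameter of the network (patch embedding, stage blocks
#' with alternating unshifted/shifted attention, patch merging, optional
#' cross-scale fusion, final norm and head) under a local seed.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the initialization.
#' @param zero_init Passed to the blocks: zero residual branches (identity
#'   network), mainly for diagnostics.
#' @return An object of class `crcformer_model` (config, parameter arrays,
#'   block metadata, seed).
#' @export
build_model <- function(cfg, seed = 1L, zero_init = FALSE) {
  stopifnot(inherits(cfg, "crcformer_config"))
  with_local_seed(seed, function() {
    P <- cfg$patch_size
    res <- stage_resolutions(cfg)
    ch <- stage_channels(cfg)
    params <- list(
      embed_w = matrix(stats::rnorm(ch[1] * 3L * P * P, sd = cfg$init_sd),
                       ch[1], 3L * P * P),
      embed_b = numeric(ch[1])
    )
    meta <- list(blocks = vector("list", 4L))
    params$stages <- vector("list", 4L)
    for (i in 1:4) {
      blocks <- vector("list", cfg$depths[i])
      bmeta <- vector("list", cfg$depths[i])
      for (j in seq_len(cfg$depths[i])) {
        bp <- fgt_block_params(
          channels = ch[i], height = res[i], width = res[i],
          heads = cfg$heads[i], shifted = (j %% 2L == 0L),
          window_big = cfg$window_big, window_small = cfg$window_small,
          stripe = cfg$stripe, ffn_ratio = cfg$ffn_ratio,
          use_wavelet = cfg$use_fgt, ffn_residual = cfg$ffn_residual,
          init_sd = cfg$init_sd, zero_init = zero_init)
        blocks[[j]] <- bp$arrays
        bmeta[[j]] <- bp$meta
      }
      st <- list(blocks = blocks)
      if (i < 4L) {
        st$merge_w <- matrix(stats::rnorm(ch[i + 1] * 4L * ch[i], sd = cfg$init_sd),
                             ch[i + 1], 4L * ch[i])
        st$merge_b <- numeric(ch[i + 1])
      }
      params$stages[[i]] <- st
      meta$blocks[[i]] <- bmeta
    }
    if (cfg$use_csm) {
      cp <- csm_params(ch, cfg$state_dim, cfg$conv_width, cfg$expansion,
                       cfg$downsample, cfg$init_sd, zero_out_proj = TRUE)
      params$csm <- cp$arrays
      meta$csm <- cp$meta
    }
    params$norm_g <- rep(1, ch[4])
    params$norm_b <- numeric(ch[4])
    params$head_w <- matrix(stats::rnorm(cfg$num_classes * ch[4], sd = cfg$init_sd),
                            cfg$num_classes, ch[4])
    params$head_b <- numeric(cfg$num_classes)
    structure(list(cfg = cfg, params = params, meta = meta, seed = seed),
              class = "crcformer_model")
  })
}

#' Number of trainable parameters
#'
#' @param model A `crcformer_model`.
#' @return Total count of scalar parameters.
#' @export
n_parameters <- function(model) {
  cnt <- function(p) {
    if (is.list(p)) sum(vapply(p, cnt, 0)) else length(p)
  }
  cnt(model$params)
}

# (3, H, W, B) image tensor -> logits tensor (K, B)
.model_forward_t <- function(pt, model, xT) {
  cfg <- model$cfg
  P <- cfg$patch_size
  d <- dims_of(xT$v)
  H <- d[2]; B <- d[4]
  r <- H %/% P
  x <- t_reshape(xT, c(3L, P, r, P, r, B))
  x <- t_aperm(x, c(1L, 2L, 4L, 3L, 5L, 6L))
  x <- t_reshape(x, c(3L * P * P, r, r, B))
  x <- t_linear(pt$embed_w, x, pt$embed_b)
  stage_out <- vector("list", 4L)
  for (i in 1:4) {
    for (j in seq_along(pt$stages[[i]]$blocks)) {
      x <- .fgt_block_t(x, pt$stages[[i]]$blocks[[j]], model$meta$blocks[[i]][[j]])
    }
    stage_out[[i]] <- x
    if (i < 4L) {
      x <- .t_space_to_depth(x, 2L)
      x <- t_linear(pt$stages[[i]]$merge_w, x, pt$stages[[i]]$merge_b)
    }
  }
  if (cfg$use_csm) {
    x <- .csm_block_t(stage_out, pt$csm, model$meta$csm)
  }
  x <- t_layernorm(x, pt$norm_g, pt$norm_b)
  pooled <- t_gap(x)
  t_linear(pt$head_w, pooled, pt$head_b)
}

images_to_internal <- function(images) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  d <- dim(images)
  if (length(d) != 4L || d[3] != 3L) {
    stop("images must be H x W x 3 (x batch) arrays")
  }
  array(aperm(images, c(3L, 1L, 2L, 4L)), c(3L, d[1], d[2], d[4]))
}

#' Forward pass
#'
#' Computes class logits for a batch of (already normalized) images.
#' Deterministic: the network has no stochastic layers.
#'
#' @param model A `crcformer_model`.
#' @param images `H x W x 3` array or `H x W x 3 x B` batch, `H` equal to the
#'   configured image size.
#' @return `B x num_classes` matrix of logits.
#' @export
model_forward <- function(model, images) {
  xv <- images_to_internal(images)
  if (dim(xv)[2] != model$cfg$image_size || dim(xv)[3] != model$cfg$image_size) {
    stop("image size ", dim(xv)[2], " does not match configured size ",
         model$cfg$image_size)
  }
  out <- .model_forward_t(wrap_tensors(model$params), model, tn(xv))
  t(out$v)
}

#' Class probabilities
#'
#' Softmax over [model_forward()] logits.
#'
#' @inheritParams model_forward
#' @return `B x num_classes` matrix of probabilities, rows summing to one.
#' @export
model_predict_proba <- function(model, images) {
  lg <- model_forward(model, images)
  e <- exp(lg - apply(lg, 1, max))
  e / rowSums(e)
}

## ---- checkpointing and config files ----

#' Save a model checkpoint
#'
#' Stores weights, the full configuration and the build seed in one archive;
#' [load_checkpoint()] restores it bit-for-bit.
#'
#' @param model A `crcformer_model`.
#' @param path Destination file.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "crcformer_model"))
  saveRDS(list(format = "crcformer_checkpoint", version = 1L,
               cfg = unclass(model$cfg), params = model$params,
               seed = model$seed), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return The restored `crcformer_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupted or unreadable checkpoint: ", path, " (", conditionMessage(e), ")")
  })
  if (!is.list(obj) || !identical(obj$format, "crcformer_checkpoint")) {
    stop("not a crcformer checkpoint: ", path)
  }
  cfg <- do.call(model_config, obj$cfg)
  model <- build_model(cfg, seed = obj$seed)
  model$params <- obj$params
  model
}

#' Write a configuration as a flat key/value YAML file
#'
#' @param cfg A `crcformer_config`.
#' @param path Destination file.
#' @export
write_model_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a configuration file
#'
#' @param path YAML file written by [write_model_config()] (or hand-edited
#'   with the same keys).
#' @return A validated `crcformer_config`.
#' @export
read_model_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(model_config, vals)
}
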