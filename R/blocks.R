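# Composite blocks: the frequency-aware global-local transformer block (Haar
# subbands + orientation-specific windowed attention + FFN) and the
# cross-scale selective-state-space fusion block.

## ---- bilinear resize as constant matrix contractions ----

# 1D bilinear interpolation matrix (n_out x n_in), half-pixel centers
bilinear_matrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  src <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- floor(src)
  i1 <- pmin(i0 + 1, n_in - 1)
  w1 <- src - i0
  for (i in seq_len(n_out)) {
    M[i, i0[i] + 1] <- M[i, i0[i] + 1] + (1 - w1[i])
    M[i, i1[i] + 1] <- M[i, i1[i] + 1] + w1[i]
  }
  M
}

# contract dimension `dm` of tensor x with constant matrix M (m x size_dm)
.t_dim_matmul <- function(x, M, dm) {
  nd <- length(dims_of(x$v))
  perm <- c(dm, setdiff(seq_len(nd), dm))
  xp <- t_aperm(x, perm)
  yp <- t_linear(tn(M), xp)
  t_aperm(yp, order(perm))
}

.t_resize_bilinear <- function(x, h2, w2) {
  d <- dims_of(x$v)
  if (d[2] != h2) x <- .t_dim_matmul(x, bilinear_matrix(h2, d[2]), 2L)
  if (dims_of(x$v)[3] != w2) x <- .t_dim_matmul(x, bilinear_matrix(w2, d[3]), 3L)
  x
}

## ---- FGT block ----

#' Parameters and specs for one frequency-aware transformer block
#'
#' Builds the layer-norm, four per-subband attention modules (big-window for
#' the approximation band, horizontal/vertical stripes for the two oriented
#' detail bands, small windows for the diagonal band) and the FFN of one
#' block. With `use_wavelet = FALSE` the block degenerates to a plain
#' (Swin-style) windowed attention block on the full-resolution map, the
#' baseline arm of the ablation.
#'
#' @param channels Channel count `C` of the block input.
#' @param height,width Spatial size of the block input.
#' @param heads Attention heads (shared by the four branches);
#'   `channels %% heads` must be 0.
#' @param shifted Logical; if `TRUE` all branches use the half-window cyclic
#'   shift (the odd-indexed blocks of a stage).
#' @param window_big,window_small,stripe Window side for the approximation
#'   branch, the diagonal branch, and stripe thickness for the oriented
#'   branches.
#' @param ffn_ratio Hidden width of the FFN as a multiple of `channels`.
#' @param use_wavelet `FALSE` selects the plain windowed baseline block.
#' @param ffn_residual `"pre_norm"` (default) adds the standard outer residual
#'   around the FFN; `"literal"` applies `FFN(LN(branch + x))` with no outer
#'   residual.
#' @param init_sd Random init scale.
#' @param zero_init If `TRUE`, attention output projections and FFN second
#'   layers start at zero, making the whole block an exact identity.
#' @return List with `arrays` (the trainable parameter tree) and `meta`
#'   (specs and geometry); accepted by [fgt_block()].
#' @export
fgt_block_params <- function(channels, height, width, heads = 4L,
                             shifted = FALSE, window_big = 8L,
                             window_small = 2L, stripe = 2L, ffn_ratio = 4,
                             use_wavelet = TRUE,
                             ffn_residual = c("pre_norm", "literal"),
                             init_sd = 0.02, zero_init = FALSE) {
  ffn_residual <- match.arg(ffn_residual)
  if (channels %% heads != 0L) stop("channels must be divisible by heads")
  hd <- channels %/% heads
  sh <- function(wsz) if (shifted) max(0L, wsz %/% 2L) else 0L
  rh <- max(1L, ceiling(height / 2)); rw <- max(1L, ceiling(width / 2))
  if (use_wavelet) {
    specs <- list(
      A = attention_spec("WB", window_big, sh(window_big), heads, hd),
      H = attention_spec("SH", stripe, sh(stripe), heads, hd),
      V = attention_spec("SV", stripe, sh(stripe), heads, hd),
      D = attention_spec("WS", window_small, sh(window_small), heads, hd))
    att <- lapply(specs, function(s)
      msa_params(channels, s, rh, rw, init_sd, zero_out_proj = zero_init))
  } else {
    specs <- list(full = attention_spec("WS", window_big, sh(window_big), heads, hd))
    att <- list(full = msa_params(channels, specs$full, height, width,
                                  init_sd, zero_out_proj = zero_init))
  }
  hidden <- as.integer(round(ffn_ratio * channels))
  arrays <- list(
    ln1_g = rep(1, channels), ln1_b = numeric(channels),
    ln2_g = rep(1, channels), ln2_b = numeric(channels),
    att = att,
    ffn_w1 = matrix(stats::rnorm(hidden * channels, sd = init_sd), hidden, channels),
    ffn_b1 = numeric(hidden),
    ffn_w2 = if (zero_init) matrix(0, channels, hidden)
             else matrix(stats::rnorm(channels * hidden, sd = init_sd), channels, hidden),
    ffn_b2 = numeric(channels)
  )
  list(arrays = arrays,
       meta = list(specs = specs, height = height, width = width,
                   channels = channels, use_wavelet = use_wavelet,
                   ffn_residual = ffn_residual))
}

# FGT block on a (C, H, W, B) tensor
.fgt_block_t <- function(x, pt, meta) {
  xn <- t_layernorm(x, pt$ln1_g, pt$ln1_b)
  if (meta$use_wavelet) {
    sb <- .t_haar_dwt2d(xn)
    sb$A <- .msa_t(sb$A, meta$specs$A, pt$att$A)
    sb$H <- .msa_t(sb$H, meta$specs$H, pt$att$H)
    sb$V <- .msa_t(sb$V, meta$specs$V, pt$att$V)
    sb$D <- .msa_t(sb$D, meta$specs$D, pt$att$D)
    branch <- .t_haar_idwt2d(sb)
  } else {
    branch <- .msa_t(xn, meta$specs$full, pt$att$full)
  }
  ffn <- function(z) {
    t_linear(pt$ffn_w2, t_gelu(t_linear(pt$ffn_w1, z, pt$ffn_b1)), pt$ffn_b2)
  }
  if (meta$ffn_residual == "literal") {
    ffn(t_layernorm(t_add(branch, x), pt$ln2_g, pt$ln2_b))
  } else {
    mid <- t_add(x, branch)
    t_add(mid, ffn(t_layernorm(mid, pt$ln2_g, pt$ln2_b)))
  }
}

#' Apply one frequency-aware transformer block to a feature map
#'
#' Layer-normalizes the input, decomposes it into the four Haar subbands,
#' attends each subband with its dedicated windowed attention variant,
#' reconstructs by the inverse transform, and applies the residual FFN.
#' Shape-preserving: output has the shape of `F_in`.
#'
#' @param F_in Numeric `H x W x C` feature map.
#' @param p Block parameters from [fgt_block_params()] (with matching `C`).
#' @return The transformed `H x W x C` array.
#' @export
fgt_block <- function(F_in, p) {
  F_in <- promote_map(F_in)
  if (dim(F_in)[3] != p$meta$channels) {
    stop("channel count ", dim(F_in)[3], " does not match block channels ",
         p$meta$channels)
  }
  xt <- tn(map_to_internal(F_in))
  out <- .fgt_block_t(xt, wrap_tensors(p$arrays), p$meta)
  internal_to_map(out$v)
}

## ---- CSM block ----

#' Parameters for the cross-scale state-space fusion block
#'
#' @param channels Integer vector `C_1..C_4` of per-stage channel counts.
#' @param state_dim,conv_width,expansion Selective-scan hyperparameters.
#' @param downsample `"bilinear"` (fixed interpolation, default) or
#'   `"strided"` (learned strided patch convolutions initialized to average
#'   pooling).
#' @param init_sd Random init scale.
#' @param zero_out_proj Zero-initialize the block's output projection
#'   (default), so the fusion is an exact residual identity at init.
#' @return List with `arrays` and `meta`, accepted by [csm_block()].
#' @export
csm_params <- function(channels, state_dim = 16L, conv_width = 4L,
                       expansion = 2, downsample = c("bilinear", "strided"),
                       init_sd = 0.02, zero_out_proj = TRUE) {
  downsample <- match.arg(downsample)
  stopifnot(length(channels) == 4L)
  d_model <- sum(channels)
  mam <- bi_mamba_params(d_model, state_dim, conv_width, expansion,
                         init_sd, zero_out_proj)
  arrays <- list(mamba = .ssm_arrays(mam))
  if (downsample == "strided") {
    # stage i is pooled by stride 2^(4-i); init equals average pooling
    ds <- list()
    for (i in 1:3) {
      k <- 2L^(4L - i)
      Ci <- channels[i]
      W <- matrix(0, Ci, Ci * k * k)
      for (cc in seq_len(Ci)) W[cc, seq.int(cc, Ci * k * k, by = Ci)] <- 1 / (k * k)
      ds[[paste0("s", i)]] <- list(W = W, b = numeric(Ci))
    }
    arrays$ds <- ds
  }
  list(arrays = arrays,
       meta = list(channels = channels, d_model = d_model,
                   downsample = downsample, mamba = ssm_meta(mam)))
}

# space-to-depth by factor k on a (C, H, W, B) tensor -> (C*k*k, H/k, W/k, B)
.t_space_to_depth <- function(x, k) {
  d <- dims_of(x$v)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  x <- t_reshape(x, c(C, k, H %/% k, k, W %/% k, B))
  x <- t_aperm(x, c(1L, 2L, 4L, 3L, 5L, 6L))
  t_reshape(x, c(C * k * k, H %/% k, W %/% k, B))
}

# CSM on four (C_i, H_i, W_i, B) tensors; returns a tensor shaped like F4
.csm_block_t <- function(Fs, pt, meta, stub_identity = FALSE) {
  d4 <- dims_of(Fs[[4]]$v)
  h4 <- d4[2]; w4 <- d4[3]; B <- d4[4]
  down <- vector("list", 4L)
  for (i in 1:4) {
    if (i == 4L) { down[[i]] <- Fs[[i]]; next }
    if (meta$downsample == "strided") {
      k <- 2L^(4L - i)
      s2d <- .t_space_to_depth(Fs[[i]], k)
      down[[i]] <- t_linear(pt$ds[[paste0("s", i)]]$W, s2d,
                            pt$ds[[paste0("s", i)]]$b)
    } else {
      down[[i]] <- .t_resize_bilinear(Fs[[i]], h4, w4)
    }
  }
  cat4 <- t_concat(down, 1L)                        # (D, h4, w4, B)
  D <- meta$d_model
  # row-major token order: width runs fastest
  z <- t_reshape(t_aperm(cat4, c(1L, 3L, 2L, 4L)), c(D, h4 * w4, B))
  zp <- if (stub_identity) z else .bi_mamba_t(z, pt$mamba, meta$mamba)
  fm <- t_aperm(t_reshape(zp, c(D, w4, h4, B)), c(1L, 3L, 2L, 4L))
  C4 <- meta$channels[4]
  slice <- t_slice1(fm, D - C4 + 1L, C4)
  t_add(Fs[[4]], slice)
}

#' Cross-scale selective-state-space fusion
#'
#' Resizes the four stage outputs to the coarsest resolution, concatenates
#' them along channels (stage 1 first, stage 4 last), runs the bidirectional
#' selective-scan layer over the flattened token sequence, and adds the last
#' `C_4` channels of the result back onto `F4`.
#'
#' @param F1,F2,F3,F4 Stage feature maps, `H_i x W_i x C_i` arrays at
#'   resolutions halving from `F1` to `F4`.
#' @param p Parameters from [csm_params()] with matching channel counts.
#' @param stub_identity For diagnostics: replace the sequence layer by the
#'   identity, so the output is `F4 + (last C_4 channels of the concat)`.
#' @return Array shaped like `F4`.
#' @export
csm_block <- function(F1, F2, F3, F4, p, stub_identity = FALSE) {
  Fs <- lapply(list(F1, F2, F3, F4), promote_map)
  ch <- vapply(Fs, function(f) dim(f)[3], 1L)
  if (!all(ch == p$meta$channels)) {
    stop("stage channel counts (", paste(ch, collapse = ","),
         ") do not match csm_params channels")
  }
  h4 <- dim(Fs[[4]])[1]; w4 <- dim(Fs[[4]])[2]
  for (i in 1:3) {
    k <- 2L^(4L - i)
    if (dim(Fs[[i]])[1] != h4 * k || dim(Fs[[i]])[2] != w4 * k) {
      stop("stage ", i, " resolution must be ", k, "x the coarsest map")
    }
  }
  ft <- lapply(Fs, function(f) tn(map_to_internal(f)))
  out <- .csm_block_t(ft, wrap_tensors(p$arrays), p$meta, stub_identity)
  internal_to_map(out$v)
}
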