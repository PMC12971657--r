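# Windowed multi-head self-attention in four orientations.
#
# Variants: WB (big square windows, degenerating to global attention when the
# map fits one window), WS (small square windows), SH (full-width horizontal
# stripes), SV (full-height vertical stripes). Shifted variants follow the
# Swin construction: the token grid is cyclically rolled by half a window,
# attention is masked so that tokens whose pre-roll regions differ never
# attend to each other, and outputs are rolled back. Ragged map sizes are
# padded with mask-excluded dummy tokens so the partition stays bijective on
# real tokens.

#' Specify a windowed attention variant
#'
#' @param variant One of `"WB"`, `"WS"` (square windows of side `window`),
#'   `"SH"` (full-width stripes of height `window`) or `"SV"` (full-height
#'   stripes of width `window`).
#' @param window Positive integer window side / stripe thickness. Clamped to
#'   the spatial extent it is applied to.
#' @param shift Non-negative integer cyclic shift, `0` or `floor(window / 2)`.
#' @param heads Number of attention heads.
#' @param head_dim Per-head channel width; `heads * head_dim` must equal the
#'   channel count of the map the spec is applied to.
#' @return An object of class `attention_spec`.
#' @export
attention_spec <- function(variant = c("WB", "WS", "SH", "SV"),
                           window, shift = 0L, heads = 1L, head_dim = 8L) {
  variant <- match.arg(variant)
  window <- as.integer(window)
  shift <- as.integer(shift)
  if (window < 1L) stop("window must be a positive integer")
  if (shift < 0L || shift >= window) stop("shift must be 0 or floor(window/2), below window")
  if (heads < 1L || head_dim < 1L) stop("heads and head_dim must be positive")
  structure(list(variant = variant, window = window, shift = shift,
                 heads = as.integer(heads), head_dim = as.integer(head_dim)),
            class = "attention_spec")
}

# Effective window geometry for a h x w grid: per-axis window and shift.
effective_geometry <- function(h, w, spec) {
  switch(spec$variant,
    WB = , WS = {
      wh <- min(spec$window, h); ww <- min(spec$window, w)
      sh <- if (spec$shift > 0L && wh < h) wh %/% 2L else 0L
      sw <- if (spec$shift > 0L && ww < w) ww %/% 2L else 0L
      list(wh = wh, ww = ww, sh = sh, sw = sw)
    },
    SH = {
      wh <- min(spec$window, h)
      sh <- if (spec$shift > 0L && wh < h) wh %/% 2L else 0L
      list(wh = wh, ww = w, sh = sh, sw = 0L)
    },
    SV = {
      ww <- min(spec$window, w)
      sw <- if (spec$shift > 0L && ww < w) ww %/% 2L else 0L
      list(wh = h, ww = ww, sh = 0L, sw = sw)
    })
}

# Pre-roll region id along one axis: bands [0, w-s), [w-s, 2w-s), ..., the
# final band of width s wrapping the top. Tokens in different bands must not
# attend after the cyclic roll -- the Swin mask.
region_id <- function(n_padded, win, shift) {
  i0 <- seq_len(n_padded) - 1L
  (i0 + shift) %/% win
}

#' Partition a token grid into attention groups
#'
#' Builds the (cyclically rolled) window partition of an `height x width`
#' token grid for an [attention_spec()], with Swin-style masking: the boolean
#' pair-admissibility matrix of each group forbids attention between tokens
#' whose pre-roll regions differ, and excludes padded dummy slots entirely.
#' Token linear indices are column-major: token `(i, j)` has index
#' `i + (j - 1) * height`.
#'
#' @param height,width Positive grid dimensions.
#' @param spec An [attention_spec()].
#' @return An object of class `window_partition`: list with `groups` (a list
#'   of integer vectors of token indices, `0` marking a dummy slot), `mask`
#'   (list of symmetric logical matrices), the effective per-axis geometry,
#'   and the flat slot index used internally.
#' @export
window_partition <- function(height, width, spec) {
  if (height < 1L || width < 1L) stop("grid dimensions must be positive")
  g <- effective_geometry(height, width, spec)
  Hp <- as.integer(ceiling(height / g$wh) * g$wh)
  Wp <- as.integer(ceiling(width / g$ww) * g$ww)
  ids <- matrix(0L, Hp, Wp)
  ids[seq_len(height), seq_len(width)] <- matrix(seq_len(height * width), height, width)
  rr <- region_id(Hp, g$wh, g$sh)
  rc <- region_id(Wp, g$ww, g$sw)
  reg <- outer(rr, rc, function(a, b) a * 1000L + b)
  roll <- function(m, sh, sw) {
    ri <- ((seq_len(Hp) - 1L + sh) %% Hp) + 1L
    ci <- ((seq_len(Wp) - 1L + sw) %% Wp) + 1L
    m[ri, ci, drop = FALSE]
  }
  ids_r <- roll(ids, g$sh, g$sw)
  reg_r <- roll(reg, g$sh, g$sw)
  nwr <- Hp %/% g$wh
  nwc <- Wp %/% g$ww
  Tn <- g$wh * g$ww
  G <- nwr * nwc
  groups <- vector("list", G)
  masks <- vector("list", G)
  k <- 0L
  for (b in seq_len(nwc)) {
    cj <- ((b - 1L) * g$ww + 1L):(b * g$ww)
    for (a in seq_len(nwr)) {
      ri <- ((a - 1L) * g$wh + 1L):(a * g$wh)
      k <- k + 1L
      tok <- as.vector(ids_r[ri, cj])
      rg <- as.vector(reg_r[ri, cj])
      real <- tok > 0L
      m <- outer(rg, rg, `==`) & outer(real, real, `&`)
      groups[[k]] <- tok
      masks[[k]] <- m
    }
  }
  structure(list(groups = groups, mask = masks, geometry = g,
                 height = height, width = width,
                 group_size = Tn, n_groups = G),
            class = "window_partition")
}

# Internal cached geometry for the tensor path: gather/scatter indices,
# additive mask and relative-position-bias index table.
.part_cache <- new.env(parent = emptyenv())

partition_geometry <- function(h, w, spec) {
  key <- paste(h, w, spec$variant, spec$window, spec$shift, sep = ":")
  hit <- .part_cache[[key]]
  if (!is.null(hit)) return(hit)
  wp <- window_partition(h, w, spec)
  Tn <- wp$group_size
  G <- wp$n_groups
  idx <- matrix(unlist(wp$groups), Tn, G)
  idx0 <- idx + 1L
  idx0[idx0 == 1L] <- 1L  # dummies -> zero slot of the augmented tensor
  inv <- integer(h * w)
  flat <- as.vector(idx)
  inv[flat[flat > 0L]] <- which(flat > 0L)
  mask_add <- array(0, c(Tn, Tn, G))
  for (gi in seq_len(G)) mask_add[, , gi] <- ifelse(wp$mask[[gi]], 0, -1e9)
  th <- wp$geometry$wh
  tw <- wp$geometry$ww
  # within-window coordinates of each slot (column-major over the window)
  p0 <- (seq_len(Tn) - 1L) %% th
  q0 <- (seq_len(Tn) - 1L) %/% th
  dp <- outer(p0, p0, `-`) + th - 1L
  dq <- outer(q0, q0, `-`) + tw - 1L
  rel_idx <- as.vector(dq * (2L * th - 1L) + dp + 1L)
  geo <- list(idx0 = as.vector(idx0), inv = inv, mask_add = mask_add,
              th = th, tw = tw, Tn = Tn, G = G,
              rel_idx = rel_idx, nrel = (2L * th - 1L) * (2L * tw - 1L))
  .part_cache[[key]] <- geo
  geo
}

#' Initialize parameters for one windowed attention module
#'
#' Creates query/key/value/output projections (with biases) and the per-head
#' relative-position bias table (zero-initialized) for an [attention_spec()]
#' applied to a map of the given size.
#'
#' @param channels Channel count; must equal `heads * head_dim` of the spec.
#' @param spec An [attention_spec()].
#' @param height,width Spatial size of the maps the module will see (fixes the
#'   effective window and hence the bias table size).
#' @param init_sd Standard deviation of the random normal initialization.
#' @param zero_out_proj If `TRUE`, the output projection starts at zero so the
#'   module is an exact no-op contributor at initialization.
#' @return A named list of parameter arrays.
#' @export
msa_params <- function(channels, spec, height, width, init_sd = 0.02,
                       zero_out_proj = FALSE) {
  if (channels != spec$heads * spec$head_dim) {
    stop("channels (", channels, ") must equal heads * head_dim (",
         spec$heads * spec$head_dim, ")")
  }
  geo <- partition_geometry(height, width, spec)
  rn <- function(r, c) matrix(stats::rnorm(r * c, sd = init_sd), r, c)
  list(
    Wq = rn(channels, channels), bq = numeric(channels),
    Wk = rn(channels, channels), bk = numeric(channels),
    Wv = rn(channels, channels), bv = numeric(channels),
    Wo = if (zero_out_proj) matrix(0, channels, channels) else rn(channels, channels),
    bo = numeric(channels),
    bias_table = matrix(0, geo$nrel, spec$heads)
  )
}

# Core attention on a (C, H, W, B) tensor. `pt` holds parameter tensors.
.msa_t <- function(x, spec, pt) {
  d <- dims_of(x$v)
  C <- d[1]; h <- d[2]; w <- d[3]; B <- d[4]
  if (C %% spec$heads != 0L || C != spec$heads * spec$head_dim) {
    stop("channel count ", C, " incompatible with heads * head_dim")
  }
  geo <- partition_geometry(h, w, spec)
  Tn <- geo$Tn; G <- geo$G
  Hh <- spec$heads; hd <- spec$head_dim
  L <- h * w
  xt <- t_reshape(x, c(C, L, B))
  zero <- tn(array(0, c(C, 1L, B)))
  aug <- t_concat(list(zero, xt), 2L)
  xg <- t_index(aug, 2L, geo$idx0)          # (C, Tn*G, B)
  xg <- t_reshape(xg, c(C, Tn, G, B))
  q <- t_linear(pt$Wq, xg, pt$bq)
  k <- t_linear(pt$Wk, xg, pt$bk)
  v <- t_linear(pt$Wv, xg, pt$bv)
  N <- Hh * G * B
  to_b <- function(z) {
    z <- t_reshape(z, c(hd, Hh, Tn, G, B))
    z <- t_aperm(z, c(3L, 1L, 2L, 4L, 5L))  # (Tn, hd, Hh, G, B)
    t_reshape(z, c(Tn, hd, N))
  }
  qb <- to_b(q); kb <- to_b(k); vb <- to_b(v)
  sc <- t_smul(t_bmm(qb, kb, transB = TRUE), 1 / sqrt(hd))  # (Tn, Tn, N)
  bias <- t_index(pt$bias_table, 1L, geo$rel_idx)           # (Tn*Tn, Hh)
  bias <- t_reshape(bias, c(Tn, Tn, Hh))
  sc <- t_add(sc, t_rep_trail(bias, G * B, c(Tn, Tn, N)))
  mfull <- extract_dim(array(geo$mask_add, c(Tn, Tn, G)), 3L,
                       rep(seq_len(G), times = 1L))
  mexp <- aperm(array(mfull, c(Tn, Tn, G, Hh)), c(1L, 2L, 4L, 3L))
  sc <- t_cadd(sc, array(rep(as.vector(mexp), times = B), c(Tn, Tn, N)))
  p <- t_softmax2(sc)
  ob <- t_bmm(p, vb)                        # (Tn, hd, N)
  ob <- t_reshape(ob, c(Tn, hd, Hh, G, B))
  ob <- t_aperm(ob, c(2L, 3L, 1L, 4L, 5L))  # (hd, Hh, Tn, G, B)
  ob <- t_reshape(ob, c(C, Tn * G, B))
  out <- t_index(ob, 2L, geo$inv)           # back to token order
  out <- t_linear(pt$Wo, out, pt$bo)
  t_reshape(out, c(C, h, w, B))
}

wrap_tensors <- function(p) {
  if (is.list(p)) lapply(p, wrap_tensors) else tn(p, req = TRUE)
}

map_to_internal <- function(x) {
  # H x W x C array -> (C, H, W, 1) tensor value
  x <- promote_map(x)
  array(aperm(x, c(3L, 1L, 2L)), c(dim(x)[3], dim(x)[1], dim(x)[2], 1L))
}

internal_to_map <- function(v) {
  d <- dim(v)
  aperm(array(v, d[1:3]), c(2L, 3L, 1L))
}

#' Apply windowed multi-head self-attention to a feature map
#'
#' Runs scaled dot-product attention (scale `1/sqrt(head_dim)`) with additive
#' relative-position bias independently within each group of the (possibly
#' shifted and masked) window partition, and restores the original token
#' order. Shape-preserving.
#'
#' @param x A numeric `H x W x C` feature map (a matrix is treated as one
#'   channel).
#' @param spec An [attention_spec()] with `heads * head_dim == C`.
#' @param params Parameters from [msa_params()].
#' @return The attended `H x W x C` array.
#' @export
window_msa <- function(x, spec, params) {
  x <- promote_map(x)
  if (!all(is.finite(x))) stop("feature map entries must be finite")
  xt <- tn(map_to_internal(x))
  pt <- wrap_tensors(params)
  out <- .msa_t(xt, spec, pt)
  internal_to_map(out$v)
}

# Dense attention on one explicit token group (rows of `tok`: tokens x C),
# with relative-position bias from the tokens' grid coordinates. Used by the
# shifted-equivalence check; deliberately straight-line code.
dense_group_attention <- function(tok, coords, spec, params, geo) {
  Hh <- spec$heads; hd <- spec$head_dim
  q <- tok %*% t(params$Wq) + rep(params$bq, each = nrow(tok))
  k <- tok %*% t(params$Wk) + rep(params$bk, each = nrow(tok))
  v <- tok %*% t(params$Wv) + rep(params$bv, each = nrow(tok))
  out <- matrix(0, nrow(tok), ncol(tok))
  for (hh in seq_len(Hh)) {
    cols <- ((hh - 1L) * hd + 1L):(hh * hd)
    s <- (q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE])) / sqrt(hd)
    dp <- outer(coords[, 1], coords[, 1], `-`) + geo$th - 1L
    dq <- outer(coords[, 2], coords[, 2], `-`) + geo$tw - 1L
    ridx <- dq * (2L * geo$th - 1L) + dp + 1L
    s <- s + matrix(params$bias_table[ridx, hh], nrow(tok), nrow(tok))
    e <- exp(s - apply(s, 1, max))
    p <- e / rowSums(e)
    out[, cols] <- p %*% v[, cols, drop = FALSE]
  }
  out %*% t(params$Wo) + rep(params$bo, each = nrow(tok))
}

#' Check the defining identity of shifted-window masking
#'
#' Verifies, for a given map and spec, that masked attention on the cyclically
#' rolled grid agrees token-for-token with unmasked dense attention run
#' separately on each pre-roll region group (the property that makes the
#' roll-and-mask implementation equivalent to ragged shifted windows).
#'
#' @param x A numeric `H x W x C` feature map.
#' @param spec An [attention_spec()].
#' @param params Parameters from [msa_params()] (created for `dim(x)[1:2]`).
#' @param tol Maximum absolute deviation tolerated.
#' @return `TRUE` if the identity holds within `tol`, else `FALSE`.
#' @export
shifted_equivalence_check <- function(x, spec, params, tol = 1e-5) {
  x <- promote_map(x)
  h <- dim(x)[1]; w <- dim(x)[2]; C <- dim(x)[3]
  fast <- window_msa(x, spec, params)
  g <- effective_geometry(h, w, spec)
  geo <- partition_geometry(h, w, spec)
  rr <- region_id(h, g$wh, g$sh)
  rc <- region_id(w, g$ww, g$sw)
  tokmat <- matrix(aperm(x, c(3L, 1L, 2L)), nrow = C)  # C x (h*w)
  ref <- matrix(0, C, h * w)
  # within-window coordinates under the roll, for bias lookup
  Hp <- as.integer(ceiling(h / g$wh) * g$wh)
  Wp <- as.integer(ceiling(w / g$ww) * g$ww)
  prow <- (((seq_len(h) - 1L - g$sh) %% Hp)) %% g$wh
  pcol <- (((seq_len(w) - 1L - g$sw) %% Wp)) %% g$ww
  for (ra in sort(unique(rr))) {
    for (rb in sort(unique(rc))) {
      ii <- which(rr == ra); jj <- which(rc == rb)
      lin <- as.vector(outer(ii, jj, function(a, b) a + (b - 1L) * h))
      coords <- cbind(rep(prow[ii], times = length(jj)),
                      rep(pcol[jj], each = length(ii)))
      att <- dense_group_attention(t(tokmat[, lin, drop = FALSE]), coords,
                                   spec, params, geo)
      ref[, lin] <- t(att)
    }
  }
  refmap <- aperm(array(ref, c(C, h, w)), c(2L, 3L, 1L))
  max(abs(fast - refmap)) < tol
}
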