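# Independent reference implementations used as oracles. Deliberately
# straight-line code with no shared machinery with the package internals.

# full dense multi-head attention over an explicit token matrix (tokens x C),
# zero relative-position bias unless a per-head bias matrix list is given
oracle_dense_attention <- function(tok, params, heads, head_dim,
                                   bias = NULL) {
  n <- nrow(tok)
  q <- tok %*% t(params$Wq) + rep(params$bq, each = n)
  k <- tok %*% t(params$Wk) + rep(params$bk, each = n)
  v <- tok %*% t(params$Wv) + rep(params$bv, each = n)
  out <- matrix(0, n, ncol(tok))
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * head_dim + 1):(h * head_dim)
    s <- (q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE])) / sqrt(head_dim)
    if (!is.null(bias)) s <- s + bias[[h]]
    e <- exp(s - apply(s, 1, max))
    p <- e / rowSums(e)
    out[, cols] <- p %*% v[, cols, drop = FALSE]
  }
  out %*% t(params$Wo) + rep(params$bo, each = n)
}

# feature map (H x W x C) to token matrix in the package's column-major
# linearization: token (i, j) -> row i + (j-1) * H
map_to_tokens <- function(x) {
  t(matrix(aperm(x, c(3, 1, 2)), nrow = dim(x)[3]))
}

tokens_to_map <- function(tok, h, w) {
  aperm(array(t(tok), c(ncol(tok), h, w)), c(2, 3, 1))
}

# enumerate pre-roll region ids for every token of an h x w grid
oracle_region_ids <- function(h, w, wh, ww, sh, sw) {
  rr <- ((seq_len(h) - 1 + sh) %/% wh)
  rc <- ((seq_len(w) - 1 + sw) %/% ww)
  outer(rr, rc, function(a, b) paste(a, b))
}

# AUC by trapezoidal integration of the empirical ROC curve
oracle_auc_trapezoid <- function(scores, pos) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), 0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# AUC by brute-force pairwise comparison (ties count one half)
oracle_auc_pairs <- function(scores, pos) {
  ps <- scores[pos]; ns <- scores[!pos]
  cmp <- outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# gray-scale subband-energy features + nearest-centroid classification
subband_features <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  e <- crcformer::haar_energy(img)
  e / sum(e)
}

nearest_centroid_accuracy <- function(train_manifest, test_manifest) {
  ftr <- t(vapply(train_manifest$path, subband_features, numeric(4)))
  fte <- t(vapply(test_manifest$path, subband_features, numeric(4)))
  cls <- sort(unique(train_manifest$label))
  cent <- t(vapply(cls, function(k) colMeans(ftr[train_manifest$label == k, , drop = FALSE]),
                   numeric(4)))
  pred <- cls[apply(fte, 1, function(f) which.min(colSums((t(cent) - f)^2)))]
  mean(pred == test_manifest$label)
}

# parameter paths of a wrapped tensor tree, in collect_tensors order
tensor_paths <- function(pt, pre = "") {
  if (crcformer:::is_tensor(pt)) return(pre)
  nms <- names(pt)
  if (is.null(nms)) nms <- as.character(seq_along(pt))
  unlist(lapply(seq_along(pt), function(i) {
    tensor_paths(pt[[i]], paste0(pre, "$", nms[i]))
  }))
}

# tiny synthetic dataset shared by training tests (created once per run)
synth_dir_cached <- local({
  cache <- new.env()
  function(n_per_class, seed, image_size = 64, noise_sd = 0.05) {
    key <- paste(n_per_class, seed, image_size, noise_sd, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    d <- file.path(tempdir(), paste0("crcf_synth_", key))
    if (!file.exists(file.path(d, "manifest.csv"))) {
      generate_synthetic(synth_spec(n_per_class = n_per_class,
                                    image_size = image_size,
                                    noise_sd = noise_sd, seed = seed), d)
    }
    cache[[key]] <- d
    d
  }
})
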