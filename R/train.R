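# Training engine: manifest/image IO, flip + ImageNet normalization, Adam
# with cosine-annealed learning rate, multi-seed runs with seed-averaged
# metrics, checkpointing, and batched evaluation.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

#' Training configuration
#'
#' Defaults mirror the reference protocol: 224-pixel inputs, random
#' horizontal flip and channel-wise ImageNet normalization as the only
#' augmentation, Adam at `1e-4`, cosine annealing without restarts with a
#' 10-epoch period, 300 epochs, batch size 32, three seeds averaged.
#'
#' @param image_size Side length images are resized to (bilinear).
#' @param flip_prob Probability of a horizontal flip per image per epoch.
#' @param norm_mean,norm_sd Channel-wise normalization constants.
#' @param lr Initial learning rate.
#' @param lr_min Learning-rate floor. The cosine itself anneals to 0; the
#'   floor keeps post-period training alive.
#' @param t_max Cosine annealing period in epochs.
#' @param schedule `"hold"` keeps the floor once the period completes;
#'   `"stretch"` uses `t_max = epochs` instead.
#' @param epochs,batch_size Optimization budget.
#' @param seeds Integer vector; one independent run per seed, metrics
#'   averaged across them.
#' @param beta1,beta2,eps Adam moment/stability constants.
#' @return An object of class `train_config`.
#' @export
train_config <- function(image_size = 224L, flip_prob = 0.5,
                         norm_mean = IMAGENET_MEAN, norm_sd = IMAGENET_SD,
                         lr = 1e-4, lr_min = 1e-6, t_max = 10L,
                         schedule = c("hold", "stretch"),
                         epochs = 300L, batch_size = 32L,
                         seeds = c(1L, 2L, 3L),
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  schedule <- match.arg(schedule)
  if (lr <= 0) stop("lr must be positive")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(image_size = as.integer(image_size), flip_prob = flip_prob,
                 norm_mean = norm_mean, norm_sd = norm_sd, lr = lr,
                 lr_min = lr_min, t_max = as.integer(t_max),
                 schedule = schedule, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seeds = as.integer(seeds),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = max(lr_min, 0.5 * lr0 * (1 + cos(pi * e / T_max)))` for
#' `e <= T_max`, held at `lr_min` afterwards (no restarts). With the
#' `"stretch"` schedule the period spans the full training budget instead.
#'
#' @param epoch Real-valued epoch position, `>= 0`.
#' @param cfg A [train_config()].
#' @return The learning rate at `epoch`.
#' @export
lr_schedule <- function(epoch, cfg) {
  if (any(epoch < 0)) stop("epoch must be non-negative")
  tm <- if (cfg$schedule == "stretch") cfg$epochs else cfg$t_max
  raw <- 0.5 * cfg$lr * (1 + cos(pi * pmin(epoch, tm) / tm))
  pmax(raw, cfg$lr_min)
}

## ---- image IO ----

load_image <- function(path) {
  if (!file.exists(path)) stop("unreadable image (file missing): ", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = , tiff = tiff::readTIFF(path),
      stop("unsupported image format '.", ext, "' (PNG and TIFF are supported)")),
    error = function(e) stop("unreadable image: ", path, " (", conditionMessage(e), ")"))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

resize_image <- function(img, size) {
  d <- dim(img)
  if (d[1] == size && d[2] == size) return(img)
  Mh <- bilinear_matrix(size, d[1])
  Mw <- bilinear_matrix(size, d[2])
  out <- array(0, c(size, size, d[3]))
  for (cc in seq_len(d[3])) out[, , cc] <- Mh %*% img[, , cc] %*% t(Mw)
  out
}

normalize_image <- function(img, mean, sd) {
  for (cc in 1:3) img[, , cc] <- (img[, , cc] - mean[cc]) / sd[cc]
  img
}

# load a manifest into a normalized (H, W, 3, N) array plus labels
load_dataset <- function(manifest, train_cfg, num_classes) {
  manifest <- read_manifest(manifest)
  if (any(manifest$label < 0L | manifest$label >= num_classes)) {
    bad <- manifest$label[manifest$label < 0L | manifest$label >= num_classes][1]
    stop("label ", bad, " outside [0, ", num_classes, "): class-count mismatch")
  }
  n <- nrow(manifest)
  sz <- train_cfg$image_size
  x <- array(0, c(sz, sz, 3L, n))
  for (i in seq_len(n)) {
    img <- resize_image(load_image(manifest$path[i]), sz)
    x[, , , i] <- normalize_image(img, train_cfg$norm_mean, train_cfg$norm_sd)
  }
  list(x = x, y = manifest$label, manifest = manifest)
}

## ---- optimizer over the parameter-tensor tree ----

collect_tensors <- function(pt) {
  if (is_tensor(pt)) return(list(pt))
  out <- list()
  for (p in pt) out <- c(out, collect_tensors(p))
  out
}

unwrap_tensors <- function(pt) {
  if (is_tensor(pt)) return(pt$v)
  lapply(pt, unwrap_tensors)
}

adam_init <- function(leaves) {
  list(m = lapply(leaves, function(l) array(0, dims_of(l$v))),
       v = lapply(leaves, function(l) array(0, dims_of(l$v))),
       t = 0L)
}

adam_step <- function(leaves, st, lr, b1, b2, eps) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t
  c2 <- 1 - b2^st$t
  for (i in seq_along(leaves)) {
    l <- leaves[[i]]
    g <- l$grad
    if (is.null(g)) next
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    l$v <- l$v - lr * (st$m[[i]] / c1) / (sqrt(st$v[[i]] / c2) + eps)
    l$grad <- NULL
  }
  st
}

## ---- training ----

log_line <- function(con, verbose, fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (verbose) cat(msg, "\n", sep = "")
  if (!is.null(con)) writeLines(msg, con)
}

# forward/eval over a dataset in batches with no tape
predict_proba_data <- function(model, x, batch_size = 32L) {
  n <- dim(x)[4]
  out <- matrix(0, n, model$cfg$num_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    out[i:j, ] <- model_predict_proba(model, x[, , , i:j, drop = FALSE])
    i <- j + 1L
  }
  out
}

.train_one_seed <- function(model_cfg, train_cfg, data, eval_data, seed,
                            max_steps, out_dir, verbose,
                            stop_at_train_acc = NULL) {
  model <- build_model(model_cfg, seed = seed)
  pt <- wrap_tensors(model$params)
  leaves <- collect_tensors(pt)
  st <- adam_init(leaves)
  n <- dim(data$x)[4]
  bs <- min(train_cfg$batch_size, n)
  con <- if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    file(file.path(out_dir, sprintf("train_seed%d.log", seed)), open = "a")
  } else NULL
  on.exit(if (!is.null(con)) close(con))
  hist <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0),
                     eval_accuracy = numeric(0))
  best_acc <- -Inf
  step <- 0L
  done <- FALSE
  with_local_seed(seed + 1000L, function() {
    for (epoch in seq_len(train_cfg$epochs)) {
      lr <- lr_schedule(epoch - 1, train_cfg)
      ord <- sample.int(n)
      flips <- stats::runif(n) < train_cfg$flip_prob
      losses <- numeric(0)
      i <- 1L
      while (i <= n) {
        jj <- ord[i:min(i + bs - 1L, n)]
        xb <- data$x[, , , jj, drop = FALSE]
        for (b in seq_along(jj)) {
          if (flips[jj[b]]) xb[, , , b] <- xb[, rev(seq_len(dim(xb)[2])), , b]
        }
        yb <- data$y[jj]
        tape_start()
        logits <- .model_forward_t(pt, model, tn(images_to_internal(xb)))
        loss <- t_cross_entropy(logits, yb)
        tape_backward(loss)
        tape_stop()
        st <<- adam_step(leaves, st, lr, train_cfg$beta1, train_cfg$beta2,
                         train_cfg$eps)
        step <<- step + 1L
        losses <- c(losses, as.numeric(loss$v))
        log_line(con, verbose, "seed %d epoch %d step %d loss %.4f lr %.3e",
                 seed, epoch, step, as.numeric(loss$v), lr)
        if (!is.null(max_steps) && step >= max_steps) { done <<- TRUE; break }
        i <- i + bs
      }
      model$params <- unwrap_tensors(pt)
      ea <- NA_real_
      if (!is.null(eval_data)) {
        pr <- predict_proba_data(model, eval_data$x, train_cfg$batch_size)
        ea <- mean((max.col(pr, ties.method = "first") - 1L) == eval_data$y)
        if (!is.null(out_dir) && ea > best_acc) {
          best_acc <<- ea
          save_checkpoint(model, file.path(out_dir, sprintf("best_seed%d.rds", seed)))
        }
      }
      hist <<- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                      lr = lr, eval_accuracy = ea))
      if (!done && !is.null(stop_at_train_acc)) {
        pr <- predict_proba_data(model, data$x, train_cfg$batch_size)
        ta <- mean((max.col(pr, ties.method = "first") - 1L) == data$y)
        if (ta >= stop_at_train_acc) done <<- TRUE
      }
      if (done) break
    }
  })
  model$params <- unwrap_tensors(pt)
  if (!is.null(out_dir)) {
    save_checkpoint(model, file.path(out_dir, sprintf("final_seed%d.rds", seed)))
  }
  # final metrics on the evaluation split (training split when absent)
  fin_data <- if (!is.null(eval_data)) eval_data else data
  pr <- predict_proba_data(model, fin_data$x, train_cfg$batch_size)
  rep <- evaluate_scores(pr, fin_data$y)
  tr_pr <- predict_proba_data(model, data$x, train_cfg$batch_size)
  tr_acc <- mean((max.col(tr_pr, ties.method = "first") - 1L) == data$y)
  list(model = model, history = hist, metrics = rep, train_accuracy = tr_acc,
       steps = step)
}

#' Train the classifier
#'
#' Runs one training per seed under the given protocol (cross-entropy, Adam,
#' cosine annealing, flip + normalize augmentation only) and reports both the
#' per-seed records and the seed-averaged summary (arithmetic mean of the
#' per-seed final metrics).
#'
#' @param model_cfg A [model_config()]. Its `image_size` should match the
#'   training configuration.
#' @param train_cfg A [train_config()].
#' @param manifest Training manifest (`path,label` CSV or data frame).
#' @param eval_manifest Optional held-out manifest; enables per-epoch
#'   evaluation and best-accuracy checkpointing.
#' @param out_dir Optional directory for logs and checkpoints.
#' @param max_steps Optional hard cap on optimizer steps per seed (the epoch
#'   loop stops once reached).
#' @param stop_at_train_acc Optional early-stopping threshold: after each
#'   epoch the training-set accuracy is measured and the run ends once it is
#'   reached (used e.g. for over-fit sanity checks).
#' @param verbose Print structured `epoch/step/loss/lr` log lines.
#' @return An object of class `train_record`: per-seed histories, final
#'   metrics reports, trained models, and the seed-averaged `summary`.
#' @export
train <- function(model_cfg, train_cfg, manifest, eval_manifest = NULL,
                  out_dir = NULL, max_steps = NULL, stop_at_train_acc = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(model_cfg, "crcformer_config"),
            inherits(train_cfg, "train_config"))
  if (train_cfg$image_size != model_cfg$image_size) {
    stop("train_cfg and model_cfg disagree on image_size")
  }
  data <- load_dataset(manifest, train_cfg, model_cfg$num_classes)
  eval_data <- if (!is.null(eval_manifest)) {
    load_dataset(eval_manifest, train_cfg, model_cfg$num_classes)
  } else NULL
  runs <- lapply(train_cfg$seeds, function(s) {
    .train_one_seed(model_cfg, train_cfg, data, eval_data, s,
                    max_steps, out_dir, verbose, stop_at_train_acc)
  })
  names(runs) <- paste0("seed", train_cfg$seeds)
  per_seed <- data.frame(
    seed = train_cfg$seeds,
    accuracy = vapply(runs, function(r) r$metrics$accuracy, 0),
    macro_f1 = vapply(runs, function(r) r$metrics$macro$f1, 0),
    macro_precision = vapply(runs, function(r) r$metrics$macro$precision, 0),
    macro_recall = vapply(runs, function(r) r$metrics$macro$recall, 0),
    macro_auc = vapply(runs, function(r) r$metrics$macro$auc, 0),
    train_accuracy = vapply(runs, function(r) r$train_accuracy, 0)
  )
  summary <- as.list(colMeans(per_seed[, -1, drop = FALSE]))
  structure(list(runs = runs, per_seed = per_seed, summary = summary,
                 train_cfg = train_cfg, model_cfg = model_cfg),
            class = "train_record")
}

#' Evaluate a checkpoint on a manifest
#'
#' Deterministic batched evaluation; optionally writes the flat metrics
#' report and per-class ROC CSVs.
#'
#' @param checkpoint Path to a [save_checkpoint()] file.
#' @param manifest Evaluation manifest (`path,label`).
#' @param out_dir Optional report directory.
#' @param batch_size Evaluation batch size.
#' @return A `metrics_report`.
#' @export
evaluate_checkpoint <- function(checkpoint, manifest, out_dir = NULL,
                                batch_size = 32L) {
  model <- load_checkpoint(checkpoint)
  tc <- train_config(image_size = model$cfg$image_size, epochs = 1L)
  data <- load_dataset(manifest, tc, model$cfg$num_classes)
  pr <- predict_proba_data(model, data$x, batch_size)
  rep <- evaluate_scores(pr, data$y)
  if (!is.null(out_dir)) write_metrics_report(rep, out_dir)
  rep
}

#' Predict classes for images
#'
#' @param checkpoint Path to a checkpoint.
#' @param images Character vector of image paths, or a directory (all
#'   PNG/TIFF files inside).
#' @param batch_size Batch size.
#' @return Data frame with `path`, predicted `label`, and one probability
#'   column per class.
#' @export
predict_images <- function(checkpoint, images, batch_size = 32L) {
  model <- load_checkpoint(checkpoint)
  if (length(images) == 1L && dir.exists(images)) {
    images <- list.files(images, pattern = "\\.(png|tif|tiff)$",
                         ignore.case = TRUE, full.names = TRUE, recursive = TRUE)
  }
  if (length(images) == 0L) stop("no images to predict")
  tc <- train_config(image_size = model$cfg$image_size, epochs = 1L)
  sz <- model$cfg$image_size
  x <- array(0, c(sz, sz, 3L, length(images)))
  for (i in seq_along(images)) {
    x[, , , i] <- normalize_image(resize_image(load_image(images[i]), sz),
                                  tc$norm_mean, tc$norm_sd)
  }
  pr <- predict_proba_data(model, x, batch_size)
  out <- data.frame(path = images, label = max.col(pr, ties.method = "first") - 1L)
  colnames(pr) <- paste0("prob", seq_len(ncol(pr)) - 1L)
  cbind(out, pr)
}
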