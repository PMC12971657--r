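test_that("configuration arithmetic and validation behave", {
  cfg <- model_config()
  expect_equal(stage_resolutions(cfg), c(56L, 28L, 14L, 7L))
  tiny <- tiny_model_config()
  expect_equal(stage_resolutions(tiny), c(16L, 8L, 4L, 2L))
  expect_error(model_config(image_size = 225), "divisible")
  expect_error(model_config(image_size = 224, patch_size = 5), "divisible")
  expect_error(model_config(depths = c(1, 1)), "depths")
})

test_that("the default 224 model yields four-class logits at stage res 56/28/14/7", {
  cfg <- model_config()
  m <- build_model(cfg, seed = 1)
  expect_true(is.finite(n_parameters(m)))
  set.seed(501)
  x <- array(runif(224 * 224 * 3), c(224, 224, 3))
  lg <- model_forward(m, x)
  expect_equal(dim(lg), c(1L, 4L))
  expect_true(all(is.finite(lg)))
})

test_that("forward is deterministic and batch-consistent", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 2)
  set.seed(502)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  batch <- array(0, c(64, 64, 3, 2))
  batch[, , , 1] <- x; batch[, , , 2] <- x
  lg <- model_forward(m, batch)
  expect_equal(lg[1, ], lg[2, ])
  expect_equal(model_forward(m, x)[1, ], lg[1, ])
  expect_error(model_forward(m, array(0, c(64, 64, 4))), "H x W x 3")
  expect_error(model_forward(m, array(0, c(32, 32, 3))), "size")
})

test_that("forward+backward touches every parameter after one update", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 3)
  pt <- crcformer:::wrap_tensors(m$params)
  leaves <- crcformer:::collect_tensors(pt)
  set.seed(503)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  y <- c(0L, 2L)
  run_step <- function() {
    crcformer:::tape_start()
    lg <- crcformer:::.model_forward_t(pt, m, crcformer:::tn(crcformer:::images_to_internal(x)))
    loss <- crcformer:::t_cross_entropy(lg, y)
    crcformer:::tape_backward(loss)
    g <- vapply(leaves, function(l) if (is.null(l$grad)) NA_real_ else max(abs(l$grad)), 0)
    crcformer:::tape_stop()
    g
  }
  g1 <- run_step()
  # every gradient is defined and finite; parameters behind the
  # zero-initialized fusion output projection are legitimately zero here
  expect_false(any(is.na(g1)))
  expect_true(all(is.finite(g1)))
  expect_gt(mean(g1 > 0), 0.8)
  st <- crcformer:::adam_init(leaves)
  # one Adam step un-gates the zero-initialized projection ...
  crcformer:::tape_start()
  lg <- crcformer:::.model_forward_t(pt, m, crcformer:::tn(crcformer:::images_to_internal(x)))
  loss <- crcformer:::t_cross_entropy(lg, y)
  crcformer:::tape_backward(loss)
  st <- crcformer:::adam_step(leaves, st, 1e-3, 0.9, 0.999, 1e-8)
  crcformer:::tape_stop()
  # ... after which every parameter receives nonzero gradient, except the
  # query/key/bias parameters of stage-4 branches whose subbands are 1x1:
  # softmax over a singleton is constant, so their gradient is exactly zero
  # in any correct implementation
  g2 <- run_step()
  paths <- tensor_paths(pt)
  inert <- grepl("^\\$stages\\$4\\$blocks\\$[0-9]+\\$att\\$[AHVD]\\$(Wq|bq|Wk|bk|bias_table)$",
                 paths)
  expect_true(all(g2[!inert] > 0))
  expect_true(all(g2[inert] == 0))
})

test_that("no parameter is dead when every attention group has >1 token", {
  cfg <- tiny_model_config(image_size = 128L)
  m <- build_model(cfg, seed = 6)
  pt <- crcformer:::wrap_tensors(m$params)
  leaves <- crcformer:::collect_tensors(pt)
  set.seed(506)
  x <- array(runif(128 * 128 * 3), c(128, 128, 3, 1))
  st <- crcformer:::adam_init(leaves)
  g <- NULL
  for (k in 1:2) {
    crcformer:::tape_start()
    lg <- crcformer:::.model_forward_t(pt, m, crcformer:::tn(crcformer:::images_to_internal(x)))
    loss <- crcformer:::t_cross_entropy(lg, 1L)
    crcformer:::tape_backward(loss)
    g <- vapply(leaves, function(l) max(abs(l$grad)), 0)
    st <- crcformer:::adam_step(leaves, st, 1e-3, 0.9, 0.999, 1e-8)
    crcformer:::tape_stop()
  }
  expect_true(all(is.finite(g)))
  expect_true(all(g > 0))
})

test_that("checkpoint round trip reproduces logits bit-for-bit", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 4)
  set.seed(504)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  lg <- model_forward(m, x)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(model_forward(m2, x), lg)
  # corrupted checkpoints fail cleanly
  writeLines("not a checkpoint", f)
  expect_error(load_checkpoint(f), "checkpoint")
})

test_that("config files round-trip through YAML", {
  cfg <- tiny_model_config(use_csm = FALSE, window_big = 4L)
  f <- tempfile(fileext = ".yaml")
  write_model_config(cfg, f)
  cfg2 <- read_model_config(f)
  expect_equal(cfg2, cfg)
})

test_that("parameter counts are strictly ordered across ablation arms", {
  nb <- n_parameters(build_model(tiny_model_config(use_fgt = FALSE, use_csm = FALSE), 1))
  ncsm <- n_parameters(build_model(tiny_model_config(use_fgt = FALSE, use_csm = TRUE), 1))
  nfull <- n_parameters(build_model(tiny_model_config(), 1))
  expect_lt(nb, ncsm)
  expect_lt(ncsm, nfull)
})

test_that("the ablated model keeps the stage/depth/channel skeleton", {
  cfg <- tiny_model_config(use_fgt = FALSE, use_csm = FALSE)
  m <- build_model(cfg, seed = 5)
  expect_equal(stage_resolutions(cfg), stage_resolutions(tiny_model_config()))
  expect_equal(lengths(lapply(m$params$stages, `[[`, "blocks")), cfg$depths,
               ignore_attr = TRUE)
  for (i in 1:4) {
    expect_named(m$params$stages[[i]]$blocks[[1]]$att, "full")
  }
  set.seed(505)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_equal(dim(model_forward(m, x)), c(1L, 4L))
})
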