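test_that("zero-initialized branches make the block an exact identity", {
  set.seed(401)
  p <- fgt_block_params(8, 16, 16, heads = 2, zero_init = TRUE)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  expect_equal(fgt_block(x, p), x)
  # literal residual topology has no identity path: not the identity even
  # with zero branches feeding the FFN input
  pl <- fgt_block_params(8, 16, 16, heads = 2, zero_init = TRUE,
                         ffn_residual = "literal")
  expect_gt(max(abs(fgt_block(x, pl) - x)), 1e-3)
})

test_that("the block preserves shape, including the stage-1 contract", {
  set.seed(402)
  p <- fgt_block_params(96, 56, 56, heads = 3)
  x <- array(rnorm(56 * 56 * 96, sd = 0.5), c(56, 56, 96))
  out <- fgt_block(x, p)
  expect_equal(dim(out), c(56L, 56L, 96L))
  expect_true(all(is.finite(out)))
  expect_error(fgt_block(array(0, c(16, 16, 12)), p), "channel")
})

test_that("a striped input routes its detail energy through one branch", {
  # horizontal stripes (rows constant) put their pre-attention detail energy
  # into the vertical-difference subband, the branch served by the
  # vertical-stripe attention variant under this package's convention
  img <- array(0, c(16, 16, 8))
  img[seq(1, 16, 2), , ] <- 1
  sb <- haar_dwt2d(img)
  detail <- c(H = sum(sb$H^2), V = sum(sb$V^2), D = sum(sb$D^2))
  expect_gt(detail[["V"]] / sum(detail), 0.9)
  # and the transposed image routes through the other stripe branch
  sbt <- haar_dwt2d(aperm(img, c(2, 1, 3)))
  detail_t <- c(H = sum(sbt$H^2), V = sum(sbt$V^2), D = sum(sbt$D^2))
  expect_gt(detail_t[["H"]] / sum(detail_t), 0.9)
})

test_that("baseline flag reduces the block to plain windowed attention", {
  set.seed(403)
  p <- fgt_block_params(8, 16, 16, heads = 2, use_wavelet = FALSE)
  expect_named(p$arrays$att, "full")
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  expect_equal(dim(fgt_block(x, p)), dim(x))
})

test_that("cross-scale fusion is a residual identity at initialization", {
  set.seed(404)
  cp <- csm_params(c(4, 8, 16, 32))
  F1 <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  F2 <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  F3 <- array(rnorm(4 * 4 * 16), c(4, 4, 16))
  F4 <- array(rnorm(2 * 2 * 32), c(2, 2, 32))
  expect_equal(csm_block(F1, F2, F3, F4, cp), F4)
})

test_that("the channel slice added to F4 is the last block of the concat", {
  set.seed(405)
  cp <- csm_params(c(4, 8, 16, 32))
  F1 <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  F2 <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  F3 <- array(rnorm(4 * 4 * 16), c(4, 4, 16))
  F4 <- array(1, c(2, 2, 32))
  out <- csm_block(F1, F2, F3, F4, cp, stub_identity = TRUE)
  expect_equal(out, 2 * F4)
  expect_error(csm_block(F2, F2, F3, F4, cp), "channel")
  expect_error(csm_block(F1, F2, F3, array(0, c(3, 3, 32)), cp), "resolution")
})

test_that("default stage widths give the documented token depth", {
  cp <- csm_params(c(96, 192, 384, 768))
  expect_equal(cp$meta$d_model, 1440)
  cfg <- model_config()
  expect_equal((cfg$image_size / 32)^2, 49)
})

test_that("strided downsampling starts as average pooling", {
  set.seed(406)
  cp <- csm_params(c(4, 8, 16, 32), downsample = "strided")
  F1 <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  F2 <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  F3 <- array(rnorm(4 * 4 * 16), c(4, 4, 16))
  F4 <- array(0, c(2, 2, 32))
  out <- csm_block(F1, F2, F3, F4, cp, stub_identity = TRUE)
  # identity stub + zero F4: output = pooled F4-slice of the concat = 0,
  # while the pooled F1 block must equal plain 8x8 average pooling
  expect_equal(out, F4)
  # check the learned-pool init directly on stage 1 via the internal path
  ft <- lapply(list(F1, F2, F3, F4),
               function(f) crcformer:::tn(crcformer:::map_to_internal(f)))
  pt <- crcformer:::wrap_tensors(cp$arrays)
  s2d <- crcformer:::.t_space_to_depth(ft[[1]], 8L)
  pooled <- crcformer:::t_linear(pt$ds$s1$W, s2d, pt$ds$s1$b)
  manual <- apply(F1, 3, function(m) {
    sapply(0:1, function(j) sapply(0:1, function(i) {
      mean(m[(i * 8 + 1):(i * 8 + 8), (j * 8 + 1):(j * 8 + 8)])
    }))
  })
  expect_equal(as.vector(aperm(pooled$v[, , , 1], c(2, 3, 1))),
               as.vector(manual), tolerance = 1e-12)
})

test_that("gradients reach every parameter of both blocks", {
  set.seed(407)
  p <- fgt_block_params(4, 8, 8, heads = 2)
  x <- crcformer:::tn(array(rnorm(4 * 8 * 8), c(4, 8, 8, 1)))
  pt <- crcformer:::wrap_tensors(p$arrays)
  crcformer:::tape_start()
  out <- crcformer:::.fgt_block_t(x, pt, p$meta)
  # reduce to a scalar through a sum
  s <- crcformer:::node(sum(out$v), list(out),
                        function(g) list(array(as.numeric(g), crcformer:::dims_of(out$v))))
  crcformer:::tape_backward(s)
  leaves <- crcformer:::collect_tensors(pt)
  gr <- vapply(leaves, function(l) if (is.null(l$grad)) NA_real_ else max(abs(l$grad)), 0)
  crcformer:::tape_stop()
  expect_false(any(is.na(gr)))
  expect_true(all(gr > 0))

  cp <- csm_params(c(2, 4, 8, 16), zero_out_proj = FALSE)
  Fs <- list(array(rnorm(16 * 16 * 2), c(16, 16, 2)),
             array(rnorm(8 * 8 * 4), c(8, 8, 4)),
             array(rnorm(4 * 4 * 8), c(4, 4, 8)),
             array(rnorm(2 * 2 * 16), c(2, 2, 16)))
  ft <- lapply(Fs, function(f) crcformer:::tn(crcformer:::map_to_internal(f)))
  ptc <- crcformer:::wrap_tensors(cp$arrays)
  crcformer:::tape_start()
  outc <- crcformer:::.csm_block_t(ft, ptc, cp$meta)
  sc <- crcformer:::node(sum(outc$v), list(outc),
                         function(g) list(array(as.numeric(g), crcformer:::dims_of(outc$v))))
  crcformer:::tape_backward(sc)
  leaves <- crcformer:::collect_tensors(ptc)
  grc <- vapply(leaves, function(l) if (is.null(l$grad)) NA_real_ else max(abs(l$grad)), 0)
  crcformer:::tape_stop()
  expect_false(any(is.na(grc)))
  expect_true(all(grc > 0))
})
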