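test_that("unshifted partitions tile the grid as specified", {
  p <- window_partition(4, 4, attention_spec("WS", 2, 0, 1, 4))
  expect_length(p$groups, 4)
  expect_true(all(vapply(p$groups, length, 1L) == 4))
  expect_true(all(unlist(p$mask)))
  expect_setequal(unlist(p$groups), 1:16)

  p <- window_partition(4, 4, attention_spec("SH", 2, 0, 1, 4))
  expect_length(p$groups, 2)
  expect_true(all(vapply(p$groups, length, 1L) == 8))
  # first stripe covers grid rows 1-2 (column-major ids i + (j-1)*4)
  expect_setequal(p$groups[[1]], as.vector(outer(1:2, 0:3 * 4, `+`)))
  expect_error(window_partition(0, 4, attention_spec("WS", 2)), "positive")
})

test_that("shifted masks match the enumerated pre-roll region oracle", {
  p <- window_partition(4, 4, attention_spec("WS", 2, 1, 1, 4))
  expect_length(p$groups, 4)
  reg <- oracle_region_ids(4, 4, 2, 2, 1, 1)
  for (g in seq_along(p$groups)) {
    tok <- p$groups[[g]]
    m <- p$mask[[g]]
    for (a in seq_along(tok)) for (b in seq_along(tok)) {
      if (tok[a] == 0 || tok[b] == 0) {
        expect_false(m[a, b])
      } else {
        ia <- (tok[a] - 1) %% 4 + 1; ja <- (tok[a] - 1) %/% 4 + 1
        ib <- (tok[b] - 1) %% 4 + 1; jb <- (tok[b] - 1) %/% 4 + 1
        expect_equal(m[a, b], reg[ia, ja] == reg[ib, jb])
      }
    }
  }
})

test_that("partition is a bijection on real tokens for randomized shapes", {
  set.seed(201)
  variants <- c("WB", "WS", "SH", "SV")
  for (i in seq_len(50)) {
    h <- sample(1:13, 1); w <- sample(1:13, 1)
    vr <- sample(variants, 1)
    win <- sample(1:8, 1)
    sp <- attention_spec(vr, win, shift = if (win > 1 && i %% 2 == 0) win %/% 2 else 0,
                         heads = 1, head_dim = 4)
    p <- window_partition(h, w, sp)
    real <- unlist(p$groups)
    real <- real[real > 0]
    expect_setequal(real, seq_len(h * w))
    expect_length(real, h * w)
  }
})

test_that("single-token and constant-value fixed points hold", {
  set.seed(202)
  sp <- attention_spec("WS", 1, 0, 2, 3)
  pr <- msa_params(6, sp, 3, 3)
  x <- array(rnorm(3 * 3 * 6), c(3, 3, 6))
  out <- window_msa(x, sp, pr)
  # window 1: each token attends only to itself -> Wo(Wv x + bv) + bo
  tok <- map_to_tokens(x)
  ref <- (tok %*% t(pr$Wv) + rep(pr$bv, each = 9)) %*% t(pr$Wo) +
    rep(pr$bo, each = 9)
  expect_lt(max(abs(map_to_tokens(out) - ref)), 1e-10)

  # all value rows equal: every output row is the projected common value
  sp2 <- attention_spec("WB", 4, 0, 2, 3)
  pr2 <- msa_params(6, sp2, 4, 4)
  xc <- array(rep(rnorm(6), each = 16), c(4, 4, 6))
  outc <- window_msa(xc, sp2, pr2)
  expect_lt(max(abs(outc - array(rep(as.vector(outc[1, 1, ]), each = 16),
                                 c(4, 4, 6)))), 1e-10)
})

test_that("one whole-map window equals the dense attention oracle", {
  set.seed(203)
  sp <- attention_spec("WB", 4, 0, 2, 4)
  pr <- msa_params(8, sp, 4, 4)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  out <- window_msa(x, sp, pr)
  ref <- oracle_dense_attention(map_to_tokens(x), pr, 2, 4)
  expect_lt(max(abs(map_to_tokens(out) - ref)), 1e-5)

  # SH with stripe = map height and SV with stripe = map width are the same
  # dense attention
  for (v in c("SH", "SV")) {
    spv <- attention_spec(v, 4, 0, 2, 4)
    prv <- pr
    outv <- window_msa(x, spv, prv)
    expect_lt(max(abs(map_to_tokens(outv) - ref)), 1e-5)
  }
})

test_that("all four variants match a per-group dense oracle, shifted or not", {
  set.seed(204)
  cases <- list(
    list(v = "WB", win = 4, shift = 0), list(v = "WB", win = 4, shift = 2),
    list(v = "WS", win = 2, shift = 0), list(v = "WS", win = 2, shift = 1),
    list(v = "SH", win = 2, shift = 0), list(v = "SH", win = 2, shift = 1),
    list(v = "SV", win = 2, shift = 0), list(v = "SV", win = 2, shift = 1))
  for (cs in cases) {
    sp <- attention_spec(cs$v, cs$win, cs$shift, heads = 2, head_dim = 2)
    pr <- msa_params(4, sp, 8, 8)
    pr$bias_table[] <- rnorm(length(pr$bias_table), sd = 0.2)
    x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
    expect_true(shifted_equivalence_check(x, sp, pr, tol = 1e-5),
                label = paste(cs$v, "window", cs$win, "shift", cs$shift))
  }
})

test_that("shift 0 equivalence is trivially true and ragged sizes work", {
  set.seed(205)
  sp <- attention_spec("WS", 2, 0, 2, 2)
  pr <- msa_params(4, sp, 7, 7)
  x <- array(rnorm(7 * 7 * 4), c(7, 7, 4))
  expect_true(shifted_equivalence_check(x, sp, pr))
  sps <- attention_spec("WS", 2, 1, 2, 2)
  prs <- msa_params(4, sps, 7, 7)
  expect_true(shifted_equivalence_check(x, sps, prs))
})

test_that("attention is set-equivariant within a single window", {
  set.seed(206)
  sp <- attention_spec("WB", 4, 0, 2, 4)
  pr <- msa_params(8, sp, 4, 4)
  pr$bias_table[] <- 0   # permutation invariance needs permuted bias; use zero
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  tok <- map_to_tokens(x)
  perm <- sample(16)
  xp <- tokens_to_map(tok[perm, ], 4, 4)
  out <- map_to_tokens(window_msa(x, sp, pr))
  outp <- map_to_tokens(window_msa(xp, sp, pr))
  expect_lt(max(abs(outp - out[perm, ])), 1e-10)
})

test_that("large-magnitude inputs produce finite outputs", {
  set.seed(207)
  sp <- attention_spec("WS", 2, 1, 2, 4)
  pr <- msa_params(8, sp, 8, 8)
  x <- array(runif(8 * 8 * 8, -1e3, 1e3), c(8, 8, 8))
  expect_true(all(is.finite(window_msa(x, sp, pr))))
})

test_that("mismatched channels and bad specs raise errors", {
  sp <- attention_spec("WS", 2, 0, 2, 4)
  pr <- msa_params(8, sp, 4, 4)
  expect_error(window_msa(array(0, c(4, 4, 6)), sp, pr), "head")
  expect_error(attention_spec("WS", 2, shift = 2), "shift")
  expect_error(msa_params(6, sp, 4, 4), "heads")
})
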