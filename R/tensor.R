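# Reverse-mode autodiff on plain R arrays.
#
# Tensors are environments holding a value (`v`, always a dim-ed array), a
# gradient slot (`grad`) and a requires-grad flag (`req`). Operations record
# themselves on a global tape when one is active; `tape_backward()` walks the
# tape in reverse creation order (a valid topological order) and accumulates
# gradients into the leaves. With no tape active every op is plain numeric
# code, which is what inference uses.

.tape <- new.env(parent = emptyenv())
.tape$nodes <- NULL
.tape$n <- 0L
.tape$on <- FALSE

tape_start <- function() {
  .tape$nodes <- vector("list", 2048L)
  .tape$n <- 0L
  .tape$on <- TRUE
  invisible(NULL)
}

tape_stop <- function() {
  .tape$on <- FALSE
  .tape$nodes <- NULL
  .tape$n <- 0L
  invisible(NULL)
}

tape_active <- function() .tape$on

dims_of <- function(x) {
  d <- dim(x)
  if (is.null(d)) length(x) else d
}

as_dimmed <- function(x) {
  if (is.null(dim(x))) dim(x) <- length(x)
  x
}

# leaf tensor; req = TRUE marks a trainable parameter
tn <- function(v, req = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$v <- as_dimmed(v)
  nd$req <- req
  nd$grad <- NULL
  nd
}

is_tensor <- function(x) is.environment(x) && !is.null(x$v)

# interior node; bk(g) must return a list of gradients aligned with parents
node <- function(v, parents, bk) {
  nd <- new.env(parent = emptyenv())
  nd$v <- as_dimmed(v)
  req <- FALSE
  for (p in parents) if (p$req) { req <- TRUE; break }
  nd$req <- req
  nd$grad <- NULL
  if (.tape$on && req) {
    nd$parents <- parents
    nd$bk <- bk
    n <- .tape$n + 1L
    if (n > length(.tape$nodes)) {
      .tape$nodes <- c(.tape$nodes, vector("list", length(.tape$nodes)))
    }
    .tape$nodes[[n]] <- nd
    .tape$n <- n
  }
  nd
}

tape_backward <- function(root) {
  if (!.tape$on) stop("no active tape: call tape_start() before the forward pass")
  root$grad <- array(1, dims_of(root$v))
  if (.tape$n == 0L) return(invisible(NULL))
  for (i in seq(.tape$n, 1L)) {
    nd <- .tape$nodes[[i]]
    if (is.null(nd$grad)) next
    gs <- nd$bk(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      if (!p$req) next
      p$grad <- if (is.null(p$grad)) as_dimmed(gj) else p$grad + gj
    }
    nd$grad <- NULL
  }
  invisible(NULL)
}

## ---- elementwise ----

t_add <- function(a, b) {
  node(a$v + b$v, list(a, b), function(g) list(g, g))
}

t_sub <- function(a, b) {
  node(a$v - b$v, list(a, b), function(g) list(g, -g))
}

t_mul <- function(a, b) {
  av <- a$v; bv <- b$v
  node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

t_smul <- function(a, k) {
  node(a$v * k, list(a), function(g) list(g * k))
}

# add a constant array (e.g. an attention mask)
t_cadd <- function(a, const) {
  node(a$v + const, list(a), function(g) list(g))
}

t_neg <- function(a) t_smul(a, -1)

t_exp <- function(a) {
  ev <- exp(a$v)
  node(ev, list(a), function(g) list(g * ev))
}

t_sigmoid <- function(a) {
  sv <- 1 / (1 + exp(-a$v))
  node(sv, list(a), function(g) list(g * sv * (1 - sv)))
}

t_silu <- function(a) {
  av <- a$v
  sv <- 1 / (1 + exp(-av))
  node(av * sv, list(a), function(g) list(g * (sv * (1 + av * (1 - sv)))))
}

t_softplus <- function(a) {
  av <- a$v
  v <- ifelse(av > 30, av, log1p(exp(pmin(av, 30))))
  dim(v) <- dims_of(av)
  node(v, list(a), function(g) list(g / (1 + exp(-av))))
}

t_gelu <- function(a) {
  av <- a$v
  pv <- stats::pnorm(av)
  node(av * pv, list(a), function(g) list(g * (pv + av * stats::dnorm(av))))
}

## ---- shape ----

t_reshape <- function(a, d) {
  d0 <- dims_of(a$v)
  v <- a$v
  dim(v) <- d
  node(v, list(a), function(g) { dim(g) <- d0; list(g) })
}

t_aperm <- function(a, perm) {
  inv <- order(perm)
  node(aperm(a$v, perm), list(a), function(g) list(aperm(g, inv)))
}

# concatenate along dimension `dm`
t_concat <- function(xs, dm) {
  nd <- length(dims_of(xs[[1]]$v))
  perm <- c(dm, setdiff(seq_len(nd), dm))
  inv <- order(perm)
  mats <- lapply(xs, function(x) {
    p <- aperm(x$v, perm)
    matrix(p, nrow = dim(p)[1])
  })
  sizes <- vapply(mats, nrow, 1L)
  bound <- do.call(rbind, mats)
  dfront <- dims_of(aperm(xs[[1]]$v, perm))
  dfront[1] <- sum(sizes)
  out <- aperm(array(bound, dfront), inv)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  node(out, xs, function(g) {
    gp <- aperm(g, perm)
    gm <- matrix(gp, nrow = dim(gp)[1])
    lapply(seq_along(xs), function(i) {
      di <- dfront
      di[1] <- sizes[i]
      aperm(array(gm[starts[i]:ends[i], , drop = FALSE], di), inv)
    })
  })
}

# slice `len` entries of dim 1 starting at `from`
t_slice1 <- function(a, from, len) {
  d <- dims_of(a$v)
  idx <- seq.int(from, length.out = len)
  m <- matrix(a$v, nrow = d[1])
  dout <- d; dout[1] <- len
  node(array(m[idx, , drop = FALSE], dout), list(a), function(g) {
    gm <- matrix(0, d[1], prod(d[-1]))
    gm[idx, ] <- matrix(g, nrow = len)
    list(array(gm, d))
  })
}

# extract along one dimension with an arbitrary (possibly repeating) index
extract_dim <- function(x, dm, idx) {
  args <- rep(list(quote(expr = )), length(dims_of(x)))
  args[[dm]] <- idx
  do.call(`[`, c(list(as_dimmed(x)), args, list(drop = FALSE)))
}

# gather along dimension `dm`; backward is scatter-add (handles repeats)
t_index <- function(a, dm, idx) {
  d <- dims_of(a$v)
  nd <- length(d)
  v <- extract_dim(a$v, dm, idx)
  perm <- c(dm, setdiff(seq_len(nd), dm))
  invp <- order(perm)
  node(v, list(a), function(g) {
    gp <- aperm(g, perm)
    gm <- matrix(gp, nrow = length(idx))
    acc <- rowsum(gm, group = idx, reorder = TRUE)
    z <- matrix(0, d[dm], ncol(gm))
    z[sort(unique(idx)), ] <- acc
    dfront <- d[perm]
    list(aperm(array(z, dfront), invp))
  })
}

## ---- linear algebra ----

# W %*% x over dim 1 of x; W is (Cout x Cin), x is (Cin, ...)
t_linear <- function(W, x, b = NULL) {
  d <- dims_of(x$v)
  cin <- d[1]
  xm <- matrix(x$v, nrow = cin)
  vm <- W$v %*% xm
  if (!is.null(b)) vm <- vm + as.vector(b$v)
  dout <- d; dout[1] <- nrow(W$v)
  parents <- if (is.null(b)) list(W, x) else list(W, x, b)
  node(array(vm, dout), parents, function(g) {
    gm <- matrix(g, nrow = dout[1])
    gW <- gm %*% t(xm)
    gx <- array(crossprod(W$v, gm), d)
    if (is.null(b)) list(gW, gx) else list(gW, gx, rowSums(gm))
  })
}

# add a bias vector along dim 1
t_bias1 <- function(x, b) {
  d <- dims_of(x$v)
  node(x$v + as.vector(b$v), list(x, b), function(g) {
    list(g, rowSums(matrix(g, nrow = d[1])))
  })
}

# multiply by a vector along dim 1
t_scale1 <- function(x, w) {
  d <- dims_of(x$v)
  wv <- as.vector(w$v)
  xv <- x$v
  node(xv * wv, list(x, w), function(g) {
    list(g * wv, rowSums(matrix(g * xv, nrow = d[1])))
  })
}

# batched matmul on (r x c x n) stacks, via the compiled kernel
t_bmm <- function(a, b, transA = FALSE, transB = FALSE) {
  av <- a$v; bv <- b$v
  v <- cpp_bmm(av, bv, transA, transB)
  node(v, list(a, b), function(g) {
    if (!transA && !transB) {
      list(cpp_bmm(g, bv, FALSE, TRUE), cpp_bmm(av, g, TRUE, FALSE))
    } else if (!transA && transB) {
      list(cpp_bmm(g, bv, FALSE, FALSE), cpp_bmm(g, av, TRUE, FALSE))
    } else if (transA && !transB) {
      list(cpp_bmm(bv, g, FALSE, TRUE), cpp_bmm(av, g, FALSE, FALSE))
    } else {
      stop("t_bmm: double transpose not used")
    }
  })
}

# replicate the whole array `k` times along a new trailing dimension block
t_rep_trail <- function(a, k, dout) {
  av <- a$v
  n <- length(av)
  node(array(rep(as.vector(av), times = k), dout), list(a), function(g) {
    list(array(rowSums(matrix(g, nrow = n)), dims_of(av)))
  })
}

## ---- normalization / attention pieces ----

# LayerNorm over dim 1 (the channel axis), eps matching common practice
t_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dims_of(x$v)
  C <- d[1]
  xm <- matrix(x$v, nrow = C)
  mu <- .colMeans(xm, C, ncol(xm))
  xc <- xm - rep(mu, each = C)
  va <- .colMeans(xc * xc, C, ncol(xm))
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(istd, each = C)
  gv <- as.vector(gamma$v)
  vm <- xhat * gv + as.vector(beta$v)
  node(array(vm, d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = C)
    ghat <- gm * gv
    m1 <- .colMeans(ghat, C, ncol(gm))
    m2 <- .colMeans(ghat * xhat, C, ncol(gm))
    gx <- (ghat - rep(m1, each = C) - xhat * rep(m2, each = C)) *
      rep(istd, each = C)
    list(array(gx, d), rowSums(gm * xhat), rowSums(gm))
  })
}

# softmax over dim 2 of a (T1 x T2 x n) array
t_softmax2 <- function(x) {
  d <- dims_of(x$v)
  T2 <- d[2]
  xv <- x$v
  mx <- extract_dim(xv, 2, 1L)
  if (T2 > 1L) for (j in 2:T2) mx <- pmax(mx, extract_dim(xv, 2, j))
  e <- exp(xv - extract_dim(mx, 2, rep(1L, T2)))
  s <- extract_dim(e, 2, 1L)
  if (T2 > 1L) for (j in 2:T2) s <- s + extract_dim(e, 2, j)
  p <- e / extract_dim(s, 2, rep(1L, T2))
  node(p, list(x), function(g) {
    tpg <- p * g
    ssum <- extract_dim(tpg, 2, 1L)
    if (T2 > 1L) for (j in 2:T2) ssum <- ssum + extract_dim(tpg, 2, j)
    list(p * (g - extract_dim(ssum, 2, rep(1L, T2))))
  })
}

## ---- reductions / losses ----

# global average over dims 2..(nd-1) of (C, ..., B) -> (C, B)
t_gap <- function(x) {
  d <- dims_of(x$v)
  nd <- length(d)
  C <- d[1]; B <- d[nd]
  M <- prod(d[-c(1, nd)])
  a2 <- aperm(x$v, c(2:(nd - 1), 1L, nd))
  v <- matrix(.colMeans(matrix(a2, nrow = M), M, C * B), C, B)
  node(v, list(x), function(g) {
    ga2 <- array(rep(as.vector(g) / M, each = M), c(d[-c(1, nd)], C, B))
    list(aperm(ga2, order(c(2:(nd - 1), 1L, nd))))
  })
}

# mean cross-entropy of logits (K x B) against integer labels in 0..K-1
t_cross_entropy <- function(logits, y) {
  lv <- logits$v
  K <- nrow(lv); B <- ncol(lv)
  mx <- apply(lv, 2, max)
  e <- exp(lv - rep(mx, each = K))
  Z <- colSums(e)
  P <- e / rep(Z, each = K)
  iy <- y + 1L
  picked <- lv[cbind(iy, seq_len(B))]
  loss <- mean(log(Z) + mx - picked)
  node(loss, list(logits), function(g) {
    gl <- P
    gl[cbind(iy, seq_len(B))] <- gl[cbind(iy, seq_len(B))] - 1
    list(gl * (as.numeric(g) / B))
  })
}

# selective scan as a differentiable op (see src/kernels.cpp)
t_sscan <- function(x, delta, Bm, Cm, A, D) {
  fw <- cpp_sscan_fwd(x$v, delta$v, Bm$v, Cm$v, A$v, as.vector(D$v))
  H <- fw$H
  node(fw$y, list(x, delta, Bm, Cm, A, D), function(g) {
    bw <- cpp_sscan_bwd(x$v, delta$v, Bm$v, Cm$v, A$v, as.vector(D$v), H, g)
    list(bw$gx, bw$gdelta, bw$gB, bw$gC, bw$gA, as.vector(bw$gD))
  })
}
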