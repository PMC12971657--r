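# Orthonormal single-level Haar transforms.
#
# Filter convention (fixed by the 2x2 worked case [[1,2],[3,4]] -> A=5, H=-1,
# V=-2, D=0): the 1D step is applied first along the horizontal axis (columns)
# and then along the vertical axis (rows), so
#   A = low/low, H = vertical-low x horizontal-high (responds to variation
#   along the horizontal axis, e.g. vertical stripes), V = vertical-high x
#   horizontal-low (horizontal stripes), D = high/high (diagonal texture).
# Each 1D step scales by 1/sqrt(2), so the transform is orthonormal and the
# four subbands conserve energy exactly for even-sized inputs.

SQRT2 <- sqrt(2)

#' Single-level 1D Haar analysis
#'
#' Splits an even-length signal into approximation (scaling) and detail
#' (wavelet) coefficients with orthonormal `1/sqrt(2)` weights:
#' `approx[n] = (s[2n] + s[2n+1]) / sqrt(2)`,
#' `detail[n] = (s[2n] - s[2n+1]) / sqrt(2)`.
#'
#' @param s Numeric vector of even length with finite entries.
#' @return A list with components `approx` and `detail`, each of length
#'   `length(s) / 2`.
#' @examples
#' haar_dwt1d(c(1, 1, 1, 1))  # constant signal: zero detail
#' @seealso [haar_idwt1d()] for the exact inverse.
#' @export
haar_dwt1d <- function(s) {
  s <- as.numeric(s)
  n <- length(s)
  if (n < 1L) stop("signal must have length >= 1")
  if (!all(is.finite(s))) stop("signal entries must be finite")
  if (n %% 2L != 0L) {
    stop("signal length ", n, " is odd: pad to even length before haar_dwt1d()")
  }
  odd <- seq.int(1L, n, by = 2L)
  even <- odd + 1L
  list(approx = (s[odd] + s[even]) / SQRT2,
       detail = (s[odd] - s[even]) / SQRT2)
}

#' Single-level 1D Haar synthesis
#'
#' Exact inverse of [haar_dwt1d()]:
#' `s[2n] = (approx[n] + detail[n]) / sqrt(2)`,
#' `s[2n+1] = (approx[n] - detail[n]) / sqrt(2)`.
#'
#' @param approx,detail Numeric vectors of equal length.
#' @return The reconstructed signal, of length `2 * length(approx)`.
#' @export
haar_idwt1d <- function(approx, detail) {
  if (length(approx) != length(detail)) {
    stop("approx and detail must have equal length")
  }
  n2 <- length(approx)
  out <- numeric(2L * n2)
  odd <- seq.int(1L, 2L * n2, by = 2L)
  out[odd] <- (approx + detail) / SQRT2
  out[odd + 1L] <- (approx - detail) / SQRT2
  out
}

promote_map <- function(x) {
  if (is.null(dim(x))) stop("feature map must be a matrix or H x W x C array")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("feature map must be H x W (x C)")
  if (any(dim(x) == 0L)) stop("feature map is empty")
  x
}

#' Single-level 2D Haar analysis of a feature map
#'
#' Applies the orthonormal 1D Haar step along the horizontal axis and then the
#' vertical axis, channel-wise, yielding the four half-resolution subbands
#' `A` (approximation), `H` (horizontal-axis detail), `V` (vertical-axis
#' detail) and `D` (diagonal detail). Odd spatial dimensions are padded by one
#' row/column of edge replication before the transform; the padding is recorded
#' in `pad_spec` and removed again by [haar_idwt2d()].
#'
#' @param x A numeric `H x W` matrix or `H x W x C` array.
#' @return An object of class `haar_subbands`: a list with the four subband
#'   arrays `A`, `H`, `V`, `D` (each `ceiling(H/2) x ceiling(W/2) x C`),
#'   `pad_spec = c(rows_added, cols_added)` and the original spatial size
#'   `orig_dim`.
#' @examples
#' sb <- haar_dwt2d(matrix(c(1, 3, 2, 4), 2, 2))  # A = 5, H = -1, V = -2, D = 0
#' sb$A
#' @export
haar_dwt2d <- function(x) {
  x <- promote_map(x)
  d <- dim(x)
  h <- d[1]; w <- d[2]
  pad <- c(h %% 2L, w %% 2L)
  if (pad[1] == 1L) x <- x[c(seq_len(h), h), , , drop = FALSE]
  if (pad[2] == 1L) x <- x[, c(seq_len(w), w), , drop = FALSE]
  hp <- dim(x)[1]; wp <- dim(x)[2]
  oc <- seq.int(1L, wp, by = 2L)
  Lw <- (x[, oc, , drop = FALSE] + x[, oc + 1L, , drop = FALSE]) / SQRT2
  Hw <- (x[, oc, , drop = FALSE] - x[, oc + 1L, , drop = FALSE]) / SQRT2
  or <- seq.int(1L, hp, by = 2L)
  out <- list(
    A = (Lw[or, , , drop = FALSE] + Lw[or + 1L, , , drop = FALSE]) / SQRT2,
    H = (Hw[or, , , drop = FALSE] + Hw[or + 1L, , , drop = FALSE]) / SQRT2,
    V = (Lw[or, , , drop = FALSE] - Lw[or + 1L, , , drop = FALSE]) / SQRT2,
    D = (Hw[or, , , drop = FALSE] - Hw[or + 1L, , , drop = FALSE]) / SQRT2,
    pad_spec = pad,
    orig_dim = c(h, w)
  )
  class(out) <- "haar_subbands"
  out
}

#' Single-level 2D Haar synthesis
#'
#' Exact inverse of [haar_dwt2d()], including removal of any edge-replication
#' padding recorded in `pad_spec`.
#'
#' @param sb A `haar_subbands` object (or a plain list with components `A`,
#'   `H`, `V`, `D` and optionally `pad_spec`/`orig_dim`).
#' @return The reconstructed `H x W x C` array (a matrix input is returned as
#'   an `H x W x 1` array).
#' @export
haar_idwt2d <- function(sb) {
  for (nm in c("A", "H", "V", "D")) {
    if (is.null(sb[[nm]])) stop("subband set must contain A, H, V and D")
    sb[[nm]] <- promote_map(sb[[nm]])
  }
  dA <- dim(sb$A)
  for (nm in c("H", "V", "D")) {
    if (!identical(dim(sb[[nm]]), dA)) {
      stop("inconsistent subband shapes: all four subbands must match")
    }
  }
  h2 <- dA[1]; w2 <- dA[2]; C <- dA[3]
  Lw <- array(0, c(2L * h2, w2, C))
  Hw <- array(0, c(2L * h2, w2, C))
  or <- seq.int(1L, 2L * h2, by = 2L)
  Lw[or, , ] <- (sb$A + sb$V) / SQRT2
  Lw[or + 1L, , ] <- (sb$A - sb$V) / SQRT2
  Hw[or, , ] <- (sb$H + sb$D) / SQRT2
  Hw[or + 1L, , ] <- (sb$H - sb$D) / SQRT2
  x <- array(0, c(2L * h2, 2L * w2, C))
  oc <- seq.int(1L, 2L * w2, by = 2L)
  x[, oc, ] <- (Lw + Hw) / SQRT2
  x[, oc + 1L, ] <- (Lw - Hw) / SQRT2
  pad <- sb$pad_spec
  if (!is.null(pad)) {
    if (pad[1] == 1L) x <- x[-dim(x)[1], , , drop = FALSE]
    if (pad[2] == 1L) x <- x[, -dim(x)[2], , drop = FALSE]
  }
  x
}

#' Per-subband energy of a feature map
#'
#' Convenience wrapper returning the squared Frobenius norm of each Haar
#' subband, the quantity used to characterise orientation-specific texture
#' (e.g. stripe images concentrate detail energy in a single subband).
#'
#' @param x A numeric `H x W` matrix or `H x W x C` array.
#' @return Named numeric vector with components `A`, `H`, `V`, `D`.
#' @export
haar_energy <- function(x) {
  sb <- haar_dwt2d(x)
  vapply(sb[c("A", "H", "V", "D")], function(b) sum(b^2), 0)
}

## ---- differentiable versions on (C, H, W, B) tensors ----

# pad dim `dm` by replicating the trailing row/column
.t_pad_edge <- function(x, dm) {
  n <- dims_of(x$v)[dm]
  t_index(x, dm, c(seq_len(n), n))
}

# single-level 2D Haar on a (C,H,W,B) tensor; returns list(A,H,V,D, pad, dim)
.t_haar_dwt2d <- function(x) {
  d <- dims_of(x$v)
  h <- d[2]; w <- d[3]
  pad <- c(h %% 2L, w %% 2L)
  if (pad[1] == 1L) x <- .t_pad_edge(x, 2L)
  if (pad[2] == 1L) x <- .t_pad_edge(x, 3L)
  dp <- dims_of(x$v)
  oc <- seq.int(1L, dp[3], by = 2L)
  xo <- t_index(x, 3L, oc)
  xe <- t_index(x, 3L, oc + 1L)
  Lw <- t_smul(t_add(xo, xe), 1 / SQRT2)
  Hw <- t_smul(t_sub(xo, xe), 1 / SQRT2)
  or <- seq.int(1L, dp[2], by = 2L)
  lo <- t_index(Lw, 2L, or); le <- t_index(Lw, 2L, or + 1L)
  ho <- t_index(Hw, 2L, or); he <- t_index(Hw, 2L, or + 1L)
  list(A = t_smul(t_add(lo, le), 1 / SQRT2),
       H = t_smul(t_add(ho, he), 1 / SQRT2),
       V = t_smul(t_sub(lo, le), 1 / SQRT2),
       D = t_smul(t_sub(ho, he), 1 / SQRT2),
       pad = pad, orig = c(h, w))
}

# interleave two (C, n, W, B)-shaped tensors along dimension `dm`
.t_interleave <- function(a, b, dm) {
  d <- dims_of(a$v)
  da <- append(d, 1L, after = dm - 1L)
  a2 <- t_reshape(a, da)
  b2 <- t_reshape(b, da)
  m <- t_concat(list(a2, b2), dm)
  dout <- d
  dout[dm] <- 2L * d[dm]
  t_reshape(m, dout)
}

# inverse of .t_haar_dwt2d
.t_haar_idwt2d <- function(sb) {
  Lw <- .t_interleave(t_smul(t_add(sb$A, sb$V), 1 / SQRT2),
                      t_smul(t_sub(sb$A, sb$V), 1 / SQRT2), 2L)
  Hw <- .t_interleave(t_smul(t_add(sb$H, sb$D), 1 / SQRT2),
                      t_smul(t_sub(sb$H, sb$D), 1 / SQRT2), 2L)
  x <- .t_interleave(t_smul(t_add(Lw, Hw), 1 / SQRT2),
                     t_smul(t_sub(Lw, Hw), 1 / SQRT2), 3L)
  if (sb$pad[1] == 1L) x <- t_index(x, 2L, seq_len(sb$orig[1]))
  if (sb$pad[2] == 1L) x <- t_index(x, 3L, seq_len(sb$orig[2]))
  x
}
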