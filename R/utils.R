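# Internal numeric helpers shared across modules.

# Truncate to the normalised colour range [0, 1].
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# BT.601 luma weights; documented in render_monochrome().
.luma_weights <- c(0.299, 0.587, 0.114)

luma <- function(frame) {
  stopifnot(length(dim(frame)) == 3L, dim(frame)[3] == 3L)
  frame[, , 1] * .luma_weights[1] +
    frame[, , 2] * .luma_weights[2] +
    frame[, , 3] * .luma_weights[3]
}

# Bilinear resampling of a 2-d matrix onto an (out_h x out_w) grid.
#
# Convention (fixed and relied upon by resize_with_annotations and the
# block-matching flow upsampler): pixel centres sit at half-integer
# positions, output centre (i + 0.5) maps to input position
# (i + 0.5) * in/out, and samples beyond the border clamp to the edge
# pixel.  Under this convention a 2x downsample of a period-2
# checkerboard averages each 2x2 block exactly.
bilinear_resample <- function(mat, out_h, out_w) {
  in_h <- nrow(mat)
  in_w <- ncol(mat)
  if (in_h == out_h && in_w == out_w) {
    return(mat)
  }
  sy <- in_h / out_h
  sx <- in_w / out_w
  yc <- (seq_len(out_h) - 0.5) * sy - 0.5
  xc <- (seq_len(out_w) - 0.5) * sx - 0.5
  y0 <- pmin(pmax(floor(yc), 0), in_h - 1)
  x0 <- pmin(pmax(floor(xc), 0), in_w - 1)
  y1 <- pmin(y0 + 1, in_h - 1)
  x1 <- pmin(x0 + 1, in_w - 1)
  wy <- pmin(pmax(yc - y0, 0), 1)
  wx <- pmin(pmax(xc - x0, 0), 1)
  a <- mat[y0 + 1, x0 + 1, drop = FALSE]
  b <- mat[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- mat[y1 + 1, x0 + 1, drop = FALSE]
  d <- mat[y1 + 1, x1 + 1, drop = FALSE]
  wym <- matrix(wy, out_h, out_w)
  wxm <- matrix(wx, out_h, out_w, byrow = TRUE)
  a * (1 - wym) * (1 - wxm) + b * (1 - wym) * wxm +
    c_ * wym * (1 - wxm) + d * wym * wxm
}

# Resample an h x w x L array channel by channel.
bilinear_resample_frame <- function(frame, out_h, out_w) {
  L <- dim(frame)[3]
  out <- array(0, dim = c(out_h, out_w, L))
  for (l in seq_len(L)) {
    out[, , l] <- bilinear_resample(frame[, , l], out_h, out_w)
  }
  out
}

# Run code under a temporary RNG state; restores .Random.seed afterwards
# so generators are deterministic without clobbering the caller's stream.
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

# HSV -> RGB on vectorised h (degrees, [0, 360)), s, v in [0, 1].
# Returns a list of r, g, b vectors.  Standard hexcone model.
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t_ <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  idx <- function(k) i == k
  r[idx(0)] <- v[idx(0)]; g[idx(0)] <- t_[idx(0)]; b[idx(0)] <- p[idx(0)]
  r[idx(1)] <- q[idx(1)]; g[idx(1)] <- v[idx(1)]; b[idx(1)] <- p[idx(1)]
  r[idx(2)] <- p[idx(2)]; g[idx(2)] <- v[idx(2)]; b[idx(2)] <- t_[idx(2)]
  r[idx(3)] <- p[idx(3)]; g[idx(3)] <- q[idx(3)]; b[idx(3)] <- v[idx(3)]
  r[idx(4)] <- t_[idx(4)]; g[idx(4)] <- p[idx(4)]; b[idx(4)] <- v[idx(4)]
  r[idx(5)] <- v[idx(5)]; g[idx(5)] <- p[idx(5)]; b[idx(5)] <- q[idx(5)]
  list(r = r, g = g, b = b)
}
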