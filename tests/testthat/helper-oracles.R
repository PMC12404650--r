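# Independent oracles used across test files. These deliberately avoid the
# code paths they check.

# Brute-force convex-hull area: a point is a hull vertex iff it lies inside
# no (closed) triangle formed by three other points; vertices are then
# ordered by angle about their centroid and the shoelace formula applied.
brute_hull_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  cross2 <- function(ux, uy, vx, vy) ux * vy - uy * vx
  is_vertex <- logical(n)
  for (i in seq_len(n)) {
    o <- pts[-i, , drop = FALSE]
    tri <- utils::combn(nrow(o), 3L)
    ax <- o[tri[1, ], 1]; ay <- o[tri[1, ], 2]
    bx <- o[tri[2, ], 1]; by <- o[tri[2, ], 2]
    cx <- o[tri[3, ], 1]; cy <- o[tri[3, ], 2]
    px <- pts[i, 1]; py <- pts[i, 2]
    s1 <- cross2(bx - ax, by - ay, px - ax, py - ay)
    s2 <- cross2(cx - bx, cy - by, px - bx, py - by)
    s3 <- cross2(ax - cx, ay - cy, px - cx, py - cy)
    inside <- (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
    is_vertex[i] <- !any(inside)
  }
  v <- pts[is_vertex, , drop = FALSE]
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  m <- nrow(v); j <- c(2:m, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# Full conditional binomial pmf by multiplicative recurrence (no dbinom),
# for exhaustive checking of the exact rate test.
enum_binom_pmf <- function(n, p) {
  if (n == 0L) return(1)
  pmf <- numeric(n + 1L)
  pmf[1L] <- (1 - p)^n
  odds <- p / (1 - p)
  for (k in 0:(n - 1L)) pmf[k + 2L] <- pmf[k + 1L] * (n - k) / (k + 1L) * odds
  pmf
}

# Reference CIELAB through grDevices: encode linear RGB with the sRGB
# transfer curve, then convertColor from display sRGB to Lab (D65).
reference_lab <- function(rgb_linear) {
  enc <- ifelse(rgb_linear <= 0.0031308, 12.92 * rgb_linear,
                1.055 * rgb_linear^(1 / 2.4) - 0.055)
  grDevices::convertColor(matrix(enc, ncol = 3L), from = "sRGB", to = "Lab")
}

# Reference CIELAB from scikit-image's rgb2lab (the standard colorimetry
# implementation in this field), driven through the system python. Input is
# linear RGB; the sRGB transfer curve is applied before rgb2lab, which
# expects display-encoded values.
skimage_lab <- function(rgb_linear) {
  tf <- tempfile(fileext = ".csv"); of <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tf, of)))
  write.table(rgb_linear, tf, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- sprintf(paste0(
    "import numpy as np; from skimage.color import rgb2lab; ",
    "x = np.loadtxt(%s, delimiter=','); ",
    "enc = np.where(x <= 0.0031308, 12.92*x, 1.055*x**(1/2.4) - 0.055); ",
    "np.savetxt(%s, rgb2lab(enc.reshape(-1,1,3)).reshape(-1,3), delimiter=',')"),
    shQuote(tf), shQuote(of))
  status <- system2("python", c("-c", shQuote(code)))
  if (status != 0L) stop("python/skimage oracle failed")
  unname(as.matrix(utils::read.csv(of, header = FALSE)))
}
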