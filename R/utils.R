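#' @keywords internal
"_PACKAGE"

#' @importFrom stats sd median rbinom rexp rgamma rlnorm rnorm runif fft
#'   chisq.test pchisq setNames predict coef var
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(sprintf(...), call. = FALSE)

# polygon area by the shoelace formula (positive regardless of winding)
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(poly, closed = TRUE) {
  d <- sqrt(rowSums(diff(poly)^2))
  p <- sum(d)
  if (closed) p <- p + sqrt(sum((poly[1, ] - poly[nrow(poly), ])^2))
  p
}

is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  ax <- poly[, 1]; ay <- poly[, 2]
  nxt <- c(seq_len(n)[-1], 1L)
  bx <- ax[nxt]; by <- ay[nxt]
  ij <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  adjacent <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (!length(i)) return(TRUE)
  crossp <- function(ox, oy, px, py, qx, qy)
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  sgn <- function(v) ifelse(abs(v) < 1e-12, 0L, sign(v))
  d1 <- sgn(crossp(ax[j], ay[j], bx[j], by[j], ax[i], ay[i]))
  d2 <- sgn(crossp(ax[j], ay[j], bx[j], by[j], bx[i], by[i]))
  d3 <- sgn(crossp(ax[i], ay[i], bx[i], by[i], ax[j], ay[j]))
  d4 <- sgn(crossp(ax[i], ay[i], bx[i], by[i], bx[j], by[j]))
  if (any(d1 != d2 & d3 != d4 & d1 * d2 != 0 & d3 * d4 != 0)) return(FALSE)
  # collinear / endpoint-touching: a zero orientation with the point inside
  # the other edge's bounding box counts as an intersection
  on_box <- function(px, py, x1, y1, x2, y2)
    px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
    py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
  touch <-
    (d1 == 0 & on_box(ax[i], ay[i], ax[j], ay[j], bx[j], by[j])) |
    (d2 == 0 & on_box(bx[i], by[i], ax[j], ay[j], bx[j], by[j])) |
    (d3 == 0 & on_box(ax[j], ay[j], ax[i], ay[i], bx[i], by[i])) |
    (d4 == 0 & on_box(bx[j], by[j], ax[i], ay[i], bx[i], by[i]))
  !any(touch)
}

# Even-odd scanline rasterization; a pixel belongs to the polygon iff its
# center (integer coordinates, 0-based, x = column) is inside. Returns a
# logical matrix [rows = y, cols = x] plus the (x0, y0) offset of its corner.
rasterize_polygon <- function(poly) {
  xs <- poly[, 1]; ys <- poly[, 2]
  x0 <- floor(min(xs)); y0 <- floor(min(ys))
  x1 <- ceiling(max(xs)); y1 <- ceiling(max(ys))
  w <- x1 - x0 + 1L; h <- y1 - y0 + 1L
  mask <- matrix(FALSE, nrow = h, ncol = w)
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1], 1L)
  for (y in y0:y1) {
    # half-open edge rule in y avoids double-counting shared vertices
    cross <- numeric(0)
    for (i in seq_len(n)) {
      ya <- ys[i]; yb <- ys[nxt[i]]
      if ((ya <= y && yb > y) || (yb <= y && ya > y)) {
        t <- (y - ya) / (yb - ya)
        cross <- c(cross, xs[i] + t * (xs[nxt[i]] - xs[i]))
      }
    }
    if (length(cross) < 2) next
    cross <- sort(cross)
    for (k in seq(1, length(cross) - 1, by = 2)) {
      a <- cross[k]; b <- cross[k + 1]
      px <- seq.int(ceiling(a), ceiling(b) - 1L)
      px <- px[px >= a & px < b]
      if (length(px)) mask[y - y0 + 1L, px - x0 + 1L] <- TRUE
    }
  }
  list(mask = mask, offset = c(x0, y0))
}

# mask pixel coordinates (0-based x, y) given local mask + offset
mask_coords <- function(mask, offset) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1L + offset[1], y = idx[, 1] - 1L + offset[2])
}

# paint a set of local masks into a field-sized integer label raster
paint_labels <- function(glands, dim_hw) {
  lab <- matrix(0L, nrow = dim_hw[1], ncol = dim_hw[2])
  for (g in glands) {
    co <- mask_coords(g$mask, g$offset)
    keep <- co[, 1] >= 0 & co[, 1] < dim_hw[2] & co[, 2] >= 0 & co[, 2] < dim_hw[1]
    co <- co[keep, , drop = FALSE]
    lab[cbind(co[, 2] + 1L, co[, 1] + 1L)] <- g$id
  }
  lab
}
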