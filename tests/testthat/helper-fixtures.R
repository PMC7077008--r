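# shared geometric fixtures and oracles, built in code

ellipse_poly <- function(a, b, angle_deg = 0, center = c(60, 60), n = 128) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  ct <- cos(angle_deg * pi / 180); st <- sin(angle_deg * pi / 180)
  cbind(ct * x - st * y + center[1], st * x + ct * y + center[2])
}

# standard Koch curve polyline: `iter` iterations over a [0, span] baseline
koch_polyline <- function(iter = 4, span = 729) {
  p <- rbind(c(0, 0), c(span, 0))
  for (k in seq_len(iter)) {
    out <- NULL
    for (i in seq_len(nrow(p) - 1)) {
      a <- p[i, ]; b <- p[i + 1, ]
      d <- (b - a) / 3
      p1 <- a + d; p2 <- a + 2 * d
      ang <- -pi / 3
      rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      apex <- p1 + as.numeric(rot %*% d)
      out <- rbind(out, a, p1, apex, p2)
    }
    p <- rbind(out, p[nrow(p), ])
  }
  p
}

# match each truth gland to the segmented gland of maximal overlap and
# return the per-truth-gland Dice coefficients
dice_vs_truth <- function(truth_set, seg_set, field) {
  lab_t <- glandrisk:::paint_labels(truth_set$glands, c(field, field))
  lab_s <- glandrisk:::paint_labels(seg_set$glands, c(field, field))
  vapply(seq_along(truth_set$glands), function(i) {
    ti <- lab_t == i
    ov <- table(lab_s[ti])
    ov <- ov[names(ov) != "0"]
    if (!length(ov)) return(0)
    j <- as.integer(names(ov)[which.max(ov)])
    si <- lab_s == j
    2 * sum(ti & si) / (sum(ti) + sum(si))
  }, numeric(1))
}

# independent double-loop evaluation of every tensor measure (oracle kept
# deliberately naive; the package implementation is vectorized)
tensor_measures_oracle <- function(p, B) {
  cd <- function(i, j) min(abs(i - j), B - abs(i - j))
  ca <- 0; ce <- 0
  for (i in 1:B) for (j in 1:B) {
    d <- cd(i - 1, j - 1)
    ca <- ca + d * p[i, j]
    ce <- ce + d^2 * p[i, j]
  }
  cv <- 0
  for (i in 1:B) for (j in 1:B) cv <- cv + (cd(i - 1, j - 1) - ca)^2 * p[i, j]
  ent <- 0
  for (i in 1:B) for (j in 1:B) if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
  eng <- sum(p^2)
  px <- rowSums(p); py <- colSums(p)
  hx <- 0; for (i in 1:B) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
  hy <- 0; for (j in 1:B) if (py[j] > 0) hy <- hy - py[j] * log2(py[j])
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:B) for (j in 1:B) {
    pp <- px[i] * py[j]
    if (p[i, j] > 0 && pp > 0) hxy1 <- hxy1 - p[i, j] * log2(pp)
    if (pp > 0) hxy2 <- hxy2 - pp * log2(pp)
  }
  im1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  im2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  mux <- sum((0:(B - 1)) * px); muy <- sum((0:(B - 1)) * py)
  sx <- sqrt(sum(((0:(B - 1)) - mux)^2 * px))
  sy <- sqrt(sum(((0:(B - 1)) - muy)^2 * py))
  corr <- 0
  if (sx > 0 && sy > 0) {
    for (i in 1:B) for (j in 1:B)
      corr <- corr + (i - 1 - mux) * (j - 1 - muy) * p[i, j]
    corr <- corr / (sx * sy)
  }
  list(contrast_energy = ce, contrast_average = ca, contrast_variance = cv,
       entropy = ent, energy = eng, correlation = corr,
       intensity_average = mux,
       intensity_variance = sum(((0:(B - 1)) - mux)^2 * px),
       intensity_entropy = hx, info_measure1 = im1, info_measure2 = im2,
       max_probability = max(p), diag_dominance = sum(diag(p)))
}

random_cooc <- function(B, symmetric = TRUE) {
  m <- matrix(stats::runif(B * B), B, B)
  if (symmetric) m <- m + t(m)
  m <- m / sum(m)
  structure(list(B = B, p = m, empty_edges = FALSE),
            class = "cooccurrence_matrix")
}

# layout of identical aligned discs on a grid (homogeneous limit)
aligned_disc_set <- function(n_side = 4, r = 10, pitch = 40) {
  glands <- list()
  id <- 0
  for (i in seq_len(n_side)) for (j in seq_len(n_side)) {
    id <- id + 1
    glands[[id]] <- gland(id, ellipse_poly(r, r, 0, c(i * pitch, j * pitch)))
  }
  gland_set("grid", glands, provenance = "synthetic")
}
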