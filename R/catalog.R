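#' Feature catalog configuration
#'
#' Defines the named morphometric feature vector computed per image/core:
#' (a) image-level aggregations of per-gland shape descriptors, (b) the same
#' aggregations of neighborhood ("local") statistics of each descriptor,
#' and (c) mean/SD orientation co-occurrence tensor measures. With the
#' defaults this yields [catalog_size()] features, including the five
#' classifier features by name: `mean_tensor_info_measure1`,
#' `mean_tensor_contrast_average`, `mean_circularity_entropy`,
#' `mean_tensor_contrast_energy`, `sd_fractal_dimension_energy`.
#'
#' @param descriptors shape-descriptor names; `fourier_energy` expands to
#'   10 harmonic columns.
#' @param local_stats subset of mean, sd, entropy, energy.
#' @param aggregations subset of mean, sd, median, range.
#' @param tensor list with `k`, `B`, `radius_hops` for the co-occurrence
#'   features.
#' @param nbins_entropy bins for local entropy/energy statistics.
#' @return list of class `catalog_config`.
#' @export
catalog_config <- function(descriptors = c("area", "perimeter", "circularity",
                                           "eccentricity", "solidity",
                                           "axis_ratio", "equivalent_diameter",
                                           "fractal_dimension", "fourier_energy"),
                           local_stats = c("mean", "sd", "entropy", "energy"),
                           aggregations = c("mean", "sd", "median", "range"),
                           tensor = list(k = 5L, B = 18L, radius_hops = 1L),
                           nbins_entropy = 10L) {
  if (!length(descriptors) || !length(local_stats) || !length(aggregations))
    stop_domain("catalog selections must be non-empty")
  structure(list(descriptors = descriptors, local_stats = local_stats,
                 aggregations = aggregations, tensor = tensor,
                 nbins_entropy = as.integer(nbins_entropy)),
            class = "catalog_config")
}

expand_descriptor_names <- function(descriptors) {
  unlist(lapply(descriptors, function(d) {
    if (d == "fourier_energy") paste0("fourier_energy_", 1:10) else d
  }))
}

aggregate_stat <- function(v, agg) {
  switch(agg,
    mean = mean(v),
    sd = if (length(v) > 1) sd(v) else 0,
    median = median(v),
    range = diff(range(v)))
}

#' Extract the full named feature vector of a gland set
#'
#' Deterministic and invariant to gland order: per-gland descriptors are
#' computed once, local statistics use the k-nearest-neighbor gland graph
#' (each gland's neighborhood is itself plus its graph neighbors), and the
#' orientation tensor features come from [image_tensor_features()]. An empty
#' gland set returns an all-zero vector with attribute `empty = TRUE`.
#'
#' @param glands a [gland_set()].
#' @param cfg a [catalog_config()].
#' @return named numeric vector of class `feature_vector` with attribute
#'   `image_id`.
#' @export
extract_features <- function(glands, cfg = catalog_config()) {
  stopifnot(inherits(glands, "gland_set"), inherits(cfg, "catalog_config"))
  man <- feature_manifest(cfg)
  n <- length(glands$glands)
  if (n == 0) {
    out <- setNames(numeric(nrow(man)), man$name)
    attr(out, "empty") <- TRUE
    attr(out, "image_id") <- glands$image_id
    class(out) <- c("feature_vector", class(out))
    warning("empty gland set: returning a zero feature vector")
    return(out)
  }
  # canonical gland order: by id, so permuting list order changes nothing
  gl <- glands$glands[order(vapply(glands$glands, function(g) g$id, integer(1)))]
  gs <- gland_set(glands$image_id, gl, glands$provenance)
  desc_names <- expand_descriptor_names(cfg$descriptors)
  dmat <- matrix(0, nrow = n, ncol = length(desc_names),
                 dimnames = list(NULL, desc_names))
  for (i in seq_len(n)) {
    sdsc <- shape_descriptors(gl[[i]])
    for (d in cfg$descriptors) {
      if (d == "fourier_energy") {
        dmat[i, paste0("fourier_energy_", 1:10)] <- sdsc$fourier_energy
      } else dmat[i, d] <- sdsc[[d]]
    }
  }
  vals <- numeric(0)
  for (d in desc_names) {
    for (agg in cfg$aggregations) {
      vals[paste(agg, d, sep = "_")] <- aggregate_stat(dmat[, d], agg)
    }
  }
  cent <- t(vapply(gl, function(g) g$centroid, numeric(2)))
  graph <- build_graph(cent, k = cfg$tensor$k)
  nbhd <- lapply(seq_len(n), function(i) c(i, graph$adj[[i]]))
  for (d in desc_names) {
    for (st in cfg$local_stats) {
      loc <- local_statistic(dmat[, d], nbhd, stat = st,
                             nbins = cfg$nbins_entropy)
      for (agg in cfg$aggregations) {
        vals[paste(agg, d, st, sep = "_")] <- aggregate_stat(loc, agg)
      }
    }
  }
  tf <- image_tensor_features(gs, k = cfg$tensor$k, B = cfg$tensor$B,
                              radius_hops = cfg$tensor$radius_hops)
  vals[names(tf)] <- tf
  out <- vals[man$name]  # manifest order is the contract
  attr(out, "image_id") <- glands$image_id
  class(out) <- c("feature_vector", class(out))
  out
}

#' Manifest of the feature catalog
#'
#' One row per feature, in the exact order [extract_features()] emits them,
#' with the family and generating parameters of each — the audit trail for
#' a locked model's selected feature names.
#'
#' @param cfg a [catalog_config()].
#' @return data.frame with columns name, family, parameters.
#' @export
feature_manifest <- function(cfg = catalog_config()) {
  stopifnot(inherits(cfg, "catalog_config"))
  desc_names <- expand_descriptor_names(cfg$descriptors)
  # (a) image aggregations of per-gland descriptors, inner loop = aggregation
  a_desc <- rep(desc_names, each = length(cfg$aggregations))
  a_agg <- rep(cfg$aggregations, times = length(desc_names))
  # (b) aggregations of local statistics, loops: descriptor > stat > agg
  b_desc <- rep(desc_names, each = length(cfg$local_stats) * length(cfg$aggregations))
  b_st <- rep(rep(cfg$local_stats, each = length(cfg$aggregations)),
              times = length(desc_names))
  b_agg <- rep(cfg$aggregations,
               times = length(desc_names) * length(cfg$local_stats))
  # (c) mean/sd tensor measures
  tm <- tensor_measure_names()
  c_pre <- rep(c("mean", "sd"), each = length(tm))
  c_m <- rep(tm, 2)
  man <- data.frame(
    name = c(paste(a_agg, a_desc, sep = "_"),
             paste(b_agg, b_desc, b_st, sep = "_"),
             paste(c_pre, "tensor", c_m, sep = "_")),
    family = rep(c("shape_aggregate", "shape_local", "orientation_tensor"),
                 c(length(a_desc), length(b_desc), length(c_m))),
    parameters = c(
      sprintf("agg=%s;descriptor=%s", a_agg, a_desc),
      sprintf("agg=%s;descriptor=%s;local=%s;nbins=%d", b_agg, b_desc, b_st,
              cfg$nbins_entropy),
      sprintf("agg=%s;measure=%s;k=%d;B=%d;hops=%d", c_pre, c_m,
              cfg$tensor$k, cfg$tensor$B, cfg$tensor$radius_hops)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(man$name)) stop_domain("duplicate feature names in catalog")
  man
}

#' Size of the default feature catalog
#'
#' Single source of truth for the number of features the default
#' [catalog_config()] produces.
#'
#' @return integer count.
#' @export
catalog_size <- function() nrow(feature_manifest(catalog_config()))

#' Extract features for many gland sets into a table
#'
#' @param gland_sets list of [gland_set()] objects.
#' @param cfg a [catalog_config()].
#' @return data.frame: first column `image_id`, then one column per feature.
#' @export
extract_feature_table <- function(gland_sets, cfg = catalog_config()) {
  rows <- lapply(gland_sets, function(gs)
    suppressWarnings(extract_features(gs, cfg)))
  df <- as.data.frame(do.call(rbind, lapply(rows, as.numeric)))
  names(df) <- feature_manifest(cfg)$name
  cbind(data.frame(image_id = vapply(gland_sets, function(g) g$image_id,
                                     character(1)),
                   stringsAsFactors = FALSE), df)
}
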