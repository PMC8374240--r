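# Independent brute-force oracles for the texture matrix families, plus
# shared small fixtures. The 13 unique direction offsets (sign-folded) are
# fixed data shared with the implementation.

DIRS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# wrap an integer level array (0 = outside ROI) as a discretized_roi
dro_from_levels <- function(lev, n_bins = max(lev)) {
  lev <- array(as.integer(lev), dim(lev))
  structure(list(
    levels = lev, roi_mask = lev > 0, n_bins = as.integer(n_bins),
    bin_edges = seq(0, 1, length.out = n_bins + 1),
    bounding_box = rbind(min = c(1L, 1L, 1L), max = dim(lev)),
    voxel_size_mm = c(1, 1, 1)), class = "discretized_roi")
}

# all-voxel-pair enumeration of symmetric co-occurrence counts
bf_glcm <- function(lev, ng) {
  d <- dim(lev)
  vox <- which(lev > 0, arr.ind = TRUE)
  out <- array(0, c(ng, ng, 13))
  for (a in seq_len(nrow(vox))) {
    for (b in seq_len(nrow(vox))) {
      if (a == b) next
      dd <- vox[b, ] - vox[a, ]
      for (k in 1:13) {
        if (all(dd == DIRS13[k, ]) || all(dd == -DIRS13[k, ])) {
          la <- lev[vox[a, 1], vox[a, 2], vox[a, 3]]
          lb <- lev[vox[b, 1], vox[b, 2], vox[b, 3]]
          out[la, lb, k] <- out[la, lb, k] + 1
        }
      }
    }
  }
  out
}

# run enumeration: group voxels into maximal lines per direction, then rle
bf_glrlm <- function(lev, ng) {
  d <- dim(lev)
  lmax <- max(d)
  out <- array(0, c(ng, lmax, 13))
  inside <- function(p) all(p >= 1) && all(p <= d)
  for (k in 1:13) {
    dir <- DIRS13[k, ]
    starts <- list()
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if (!inside(c(x, y, z) - dir)) starts[[length(starts) + 1]] <- c(x, y, z)
    }
    for (s in starts) {
      p <- s
      vals <- integer(0)
      while (inside(p)) {
        vals <- c(vals, lev[p[1], p[2], p[3]])
        p <- p + dir
      }
      r <- rle(vals)
      for (i in seq_along(r$lengths)) {
        if (r$values[i] > 0) {
          out[r$values[i], r$lengths[i], k] <- out[r$values[i], r$lengths[i], k] + 1
        }
      }
    }
  }
  out
}

# zones via igraph connected components on the 26-adjacency graph
bf_glszm <- function(lev) {
  vox <- which(lev > 0, arr.ind = TRUE)
  n <- nrow(vox)
  if (n == 0) return(matrix(integer(0), 0, 2))
  vals <- lev[vox]
  edges <- c()
  if (n > 1) {
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (vals[a] == vals[b] && max(abs(vox[a, ] - vox[b, ])) <= 1) {
        edges <- c(edges, a, b)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  zones <- t(vapply(seq_len(comp$no), function(cid) {
    members <- which(comp$membership == cid)
    c(vals[members[1]], length(members))
  }, integer(2)))
  zones
}

# per-voxel neighbourhood loops
bf_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  out <- matrix(0, ng, 2)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    l <- lev[x, y, z]
    if (l == 0) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- c(x + dx, y + dy, z + dz)
      if (all(p >= 1) && all(p <= d) && lev[p[1], p[2], p[3]] > 0) {
        nb <- c(nb, lev[p[1], p[2], p[3]])
      }
    }
    out[l, 1] <- out[l, 1] + 1
    if (length(nb)) out[l, 2] <- out[l, 2] + abs(l - mean(nb))
  }
  out
}

bf_gldm <- function(lev, ng, alpha = 0) {
  d <- dim(lev)
  out <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    l <- lev[x, y, z]
    if (l == 0) next
    dep <- 1
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- c(x + dx, y + dy, z + dz)
      if (all(p >= 1) && all(p <= d)) {
        l2 <- lev[p[1], p[2], p[3]]
        if (l2 > 0 && abs(l2 - l) <= alpha) dep <- dep + 1
      }
    }
    out[l, dep] <- out[l, dep] + 1
  }
  out
}

# internal matrix builders of the installed package (not exported)
cpp_mat <- function(name, ...) {
  getFromNamespace(name, "msradiomics")(...)
}

random_level_grid <- function(dim3 = c(5, 5, 5), n_levels = 4,
                              p_roi = 0.85) {
  lev <- array(sample(0:n_levels, prod(dim3), replace = TRUE,
                      prob = c(1 - p_roi, rep(p_roi / n_levels, n_levels))),
               dim3)
  if (!any(lev > 0)) lev[1] <- 1L
  lev
}

# ---- shared cohort fixtures (memoized across test files) -------------------

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    spec <- cohort_spec(n_hcs = 3, n_msp = 3, channels = c("T1w", "MT"),
                        grid_shape = c(32, 32, 32),
                        lesion_count_range = c(2, 2),
                        lesion_radius_range_mm = c(4, 5), seed = 42)
    .fixture_env$small <- preprocess_cohort(generate_cohort(spec))
  }
  .fixture_env$small
}

small_feature_table <- function() {
  if (is.null(.fixture_env$small_ft)) {
    .fixture_env$small_ft <- extract_all(small_cohort())
  }
  .fixture_env$small_ft
}
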