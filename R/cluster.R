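#' Pointwise two-sample t-map between groups of TFRs
#'
#' Pooled-variance two-sample t-statistic (`df = nA + nB - 2`) at every
#' time-frequency pixel, oriented A minus B.
#'
#' @param group_a,group_b Lists of `tfr` objects on a shared grid, >= 2 per
#'   group.
#' @return Numeric time x frequency t-map.
#' @export
pointwise_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_invalid("need at least 2 subjects per group")
  st <- stack_tfrs(c(group_a, group_b))
  na <- length(group_a); nb <- length(group_b)
  t_flat <- t_stat_rows(st$X, seq_len(na), (na + 1):(na + nb))
  matrix(t_flat, nrow = st$n_time, ncol = st$n_freq)
}

# Vectorized pooled-variance t over columns of X for row index sets ia, ib.
t_stat_rows <- function(X, ia, ib) {
  na <- length(ia); nb <- length(ib)
  ma <- colMeans(X[ia, , drop = FALSE])
  mb <- colMeans(X[ib, , drop = FALSE])
  va <- (colSums(X[ia, , drop = FALSE]^2) - na * ma^2) / (na - 1)
  vb <- (colSums(X[ib, , drop = FALSE]^2) - nb * mb^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  d <- ma - mb
  ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
}

#' Suprathreshold clusters of a t-map
#'
#' Pixels with `|t| > t_crit(df, two-tailed alpha_pixel)` are partitioned
#' into maximal 4-connected components of equal sign; each cluster's mass is
#' the sum of its t-values.
#'
#' @param t_map Numeric time x frequency matrix of t-statistics.
#' @param alpha_pixel Uncorrected pixel-level threshold (default 0.05,
#'   two-tailed).
#' @param df Degrees of freedom of the t statistics (>= 1).
#' @return List of clusters, each a list with `pixels` (matrix of
#'   row/col indices), `sign` (+1/-1), `mass`. Empty list when no pixel is
#'   suprathreshold.
#' @export
form_clusters <- function(t_map, alpha_pixel = 0.05, df) {
  if (df < 1) stop_invalid("`df` must be >= 1")
  t_crit <- stats::qt(1 - alpha_pixel / 2, df)
  clusters <- list()
  for (sgn in c(1, -1)) {
    mask <- (sgn * t_map) > t_crit
    comp <- label_components(mask)
    if (comp$n == 0L) next
    for (k in seq_len(comp$n)) {
      idx <- which(comp$labels == k)
      clusters[[length(clusters) + 1L]] <- list(
        pixels = cbind(row = ((idx - 1L) %% nrow(t_map)) + 1L,
                       col = ((idx - 1L) %/% nrow(t_map)) + 1L),
        sign = sgn,
        mass = sum(t_map[idx]))
    }
  }
  clusters
}

# 4-connected component labelling of a logical matrix (flood fill).
# Returns list(labels = integer matrix-shaped vector, n = #components).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- integer(nr * nc)
  idx_all <- which(mask)
  if (length(idx_all) == 0L) return(list(labels = labels, n = 0L))
  n_comp <- 0L
  stack <- integer(length(idx_all))
  for (start in idx_all) {
    if (labels[start] != 0L) next
    n_comp <- n_comp + 1L
    top <- 1L
    stack[1L] <- start
    labels[start] <- n_comp
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      for (nb in c(if (r > 1L) cur - 1L, if (r < nr) cur + 1L,
                   if (cc > 1L) cur - nr, if (cc < nc) cur + nr)) {
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- n_comp
          top <- top + 1L
          stack[top] <- nb
        }
      }
    }
  }
  list(labels = labels, n = n_comp)
}

# Max |cluster mass| of a t-map (0 when no suprathreshold pixel).
max_cluster_mass <- function(t_map, t_crit) {
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- (sgn * t_map) > t_crit
    comp <- label_components(mask)
    if (comp$n == 0L) next
    masses <- abs(vapply(seq_len(comp$n), function(k)
      sum(t_map[comp$labels == k]), numeric(1)))
    best <- max(best, masses)
  }
  best
}

#' Cluster-based permutation test on group TFRs
#'
#' Non-parametric family-wise control for time-frequency group comparisons:
#' pointwise pooled t-maps, suprathreshold 4-connected same-sign clusters
#' scored by their summed t (cluster mass), and a max-statistic null built
#' from random permutations of the group labels (both signs pooled,
#' two-tailed). Cluster p-values use the add-one estimator
#' `p = (1 + #\{null >= |mass|\}) / (n_perm + 1)`, so p is never 0 and the
#' smallest achievable p is `1 / (n_perm + 1)`. Permutations are drawn
#' uniformly with replacement from the label-assignment space, excluding the
#' observed labelling; identical seeds give identical p-values.
#'
#' @inheritParams pointwise_t
#' @param n_perm Number of permutations (default 1000).
#' @param alpha_pixel Uncorrected pixel threshold (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `cluster_result`: list with `clusters` (each
#'   with `pixels`, `sign`, `mass`, `p_cluster`), `t_map`, `null_masses`,
#'   `n_perm`, `df`, `seed`, `times`, `freqs`.
#' @export
permutation_test <- function(group_a, group_b, n_perm = 1000, seed = 1,
                             alpha_pixel = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_invalid("need at least 2 subjects per group")
  st <- stack_tfrs(c(group_a, group_b))
  na <- length(group_a); nb <- length(group_b)
  n <- na + nb
  if (choose(n, na) < 2)
    stop_invalid("too few subjects for any distinct permutation")
  df <- n - 2
  t_crit <- stats::qt(1 - alpha_pixel / 2, df)
  obs_flat <- t_stat_rows(st$X, seq_len(na), (na + 1):n)
  t_map <- matrix(obs_flat, nrow = st$n_time, ncol = st$n_freq)
  clusters <- form_clusters(t_map, alpha_pixel, df)

  observed <- seq_len(na)
  null_masses <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      repeat {
        ia <- sort(sample.int(n, na))
        if (!identical(ia, observed)) break
      }
      pm <- matrix(t_stat_rows(st$X, ia, setdiff(seq_len(n), ia)),
                   nrow = st$n_time, ncol = st$n_freq)
      max_cluster_mass(pm, t_crit)
    }, numeric(1))
  })
  for (k in seq_along(clusters))
    clusters[[k]]$p_cluster <-
      (1 + sum(null_masses >= abs(clusters[[k]]$mass))) / (n_perm + 1)
  structure(list(clusters = clusters, t_map = t_map,
                 null_masses = null_masses, n_perm = n_perm, df = df,
                 seed = seed, alpha_pixel = alpha_pixel,
                 times = st$times, freqs = st$freqs),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations, df = %d\n",
              length(x$clusters), x$n_perm, x$df))
  for (k in seq_along(x$clusters)) {
    cl <- x$clusters[[k]]
    cat(sprintf("  cluster %d: sign %+d, %d pixels, mass %.2f, p = %.4g\n",
                k, cl$sign, nrow(cl$pixels), cl$mass, cl$p_cluster))
  }
  invisible(x)
}

#' Tidy summary of a cluster result
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return Data frame with one row per cluster: sign, pixel count, extent in
#'   seconds and Hz, mass, p_cluster.
#' @export
summary.cluster_result <- function(object, ...) {
  if (length(object$clusters) == 0L)
    return(data.frame(sign = integer(0), n_pixels = integer(0),
                      t_min = numeric(0), t_max = numeric(0),
                      f_min = numeric(0), f_max = numeric(0),
                      mass = numeric(0), p_cluster = numeric(0)))
  do.call(rbind, lapply(object$clusters, function(cl) {
    data.frame(sign = cl$sign, n_pixels = nrow(cl$pixels),
               t_min = min(object$times[cl$pixels[, "row"]]),
               t_max = max(object$times[cl$pixels[, "row"]]),
               f_min = min(object$freqs[cl$pixels[, "col"]]),
               f_max = max(object$freqs[cl$pixels[, "col"]]),
               mass = cl$mass, p_cluster = cl$p_cluster)
  }))
}
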