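#' All permutations of 1..m
#' @keywords internal
all_permutations <- function(m) {
  if (m == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(m - 1L))
    for (pos in 0:(m - 1L))
      out[[length(out) + 1L]] <- append(p, m, after = pos)
  out
}

# Cached map from base-m rank codes to pattern index, plus pattern names,
# in a fixed enumeration order of the m! rank vectors.
.ordinal_cache <- new.env(parent = emptyenv())
pattern_table <- function(m) {
  key <- as.character(m)
  tab <- .ordinal_cache[[key]]
  if (is.null(tab)) {
    perms <- all_permutations(m)
    codes <- vapply(perms, function(p) sum((p - 1L) * m^(seq_len(m) - 1L)),
                    numeric(1))
    lookup <- rep(NA_integer_, m^m)
    lookup[codes + 1L] <- seq_along(perms)
    tab <- list(lookup = lookup,
                names = vapply(perms, function(p) paste(p - 1L, collapse = "-"),
                               character(1)))
    .ordinal_cache[[key]] <- tab
  }
  tab
}

#' Ordinal pattern distribution of a signal
#'
#' Maps every length-`m` delay vector of the signal to the permutation that
#' sorts it ascending, with ties broken by position order (the earlier sample
#' ranks lower), and counts pattern occurrences over all
#' `n - (m - 1) * tau` windows. The counting is vectorized via pairwise
#' comparisons; the tie rule makes constant signals map to the identity
#' pattern.
#'
#' @param signal Numeric vector of length at least `(m - 1) * tau + 1`.
#' @param m Embedding dimension, 2-6.
#' @param tau Delay in samples (>= 1).
#' @return An object of class `ordinal_distribution`: list with `m`, `tau`,
#'   `counts` (named integer vector over all `m!` patterns, names are rank
#'   sequences like `"0-1-2"`) and `n_windows`.
#' @export
ordinal_patterns <- function(signal, m = 3, tau = 1) {
  if (!is.numeric(signal)) stop_invalid("`signal` must be numeric")
  if (m < 2 || m > 6) stop_invalid("`m` must be in 2..6")
  if (tau < 1) stop_invalid("`tau` must be >= 1")
  m <- as.integer(m); tau <- as.integer(tau)
  nw <- length(signal) - (m - 1L) * tau
  if (nw < 1L)
    stop_invalid("signal too short for the requested embedding (empty data)")
  emb <- vapply(0:(m - 1L), function(j) signal[(1L + j * tau):(nw + j * tau)],
                numeric(nw))
  if (nw == 1L) emb <- matrix(emb, nrow = 1L)
  # rank of element j within its window: number of elements ordered before it
  # (strictly smaller, or equal but earlier in time)
  code <- integer(nw)
  for (j in seq_len(m)) {
    rj <- integer(nw)
    for (k in seq_len(m)) {
      if (k == j) next
      rj <- rj + (emb[, k] < emb[, j] | (emb[, k] == emb[, j] & k < j))
    }
    code <- code + rj * m^(j - 1L)
  }
  pt <- pattern_table(m)
  counts <- tabulate(pt$lookup[code + 1L], nbins = length(pt$names))
  names(counts) <- pt$names
  structure(list(m = m, tau = tau, counts = counts, n_windows = nw),
            class = "ordinal_distribution")
}

#' Permutation entropy of an ordinal distribution
#'
#' Shannon entropy of the ordinal pattern relative frequencies; normalized by
#' `log(m!)` so the value lies in `[0, 1]` (1 = all patterns equally likely,
#' 0 = a single pattern, e.g. a monotone or constant signal).
#'
#' @param dist An `ordinal_distribution` from [ordinal_patterns()], or a raw
#'   count vector.
#' @param normalize Divide by `log(m!)`? Default `TRUE`.
#' @return Scalar entropy value.
#' @export
permutation_entropy <- function(dist, normalize = TRUE) {
  counts <- if (inherits(dist, "ordinal_distribution")) dist$counts else dist
  total <- sum(counts)
  if (total < 1) stop_invalid("distribution has no windows")
  p <- counts[counts > 0] / total
  h <- -sum(p * log(p))
  if (normalize) h <- h / log(length(counts))
  h
}

#' Permutation entropy of a signal
#'
#' Convenience wrapper: [ordinal_patterns()] then [permutation_entropy()].
#'
#' @inheritParams ordinal_patterns
#' @inheritParams permutation_entropy
#' @return Scalar entropy value.
#' @export
pe <- function(signal, m = 3, tau = 1, normalize = TRUE) {
  permutation_entropy(ordinal_patterns(signal, m, tau), normalize)
}

#' Permutation entropy timecourse over an epoch set
#'
#' Normalized PE per channel per epoch window, plus the channel-mean global
#' timecourse. PE shares the connectivity epoch grid so complexity and
#' connectivity stay time-aligned.
#'
#' @param epochs An `epoch_set`.
#' @param m,tau Embedding dimension and delay.
#' @return An object of class `pe_timecourse`: list with `times` (window
#'   start times, seconds), `values` (window x channel matrix), `global`
#'   (channel mean per window), `m`, `tau`.
#' @export
pe_timecourse <- function(epochs, m = 3, tau = 1) {
  if (!inherits(epochs, "epoch_set")) stop_invalid("`epochs` must be an epoch_set")
  d <- dim(epochs$epochs)
  if (d[1] < 1) stop_invalid("no epochs (empty data)")
  values <- matrix(NA_real_, nrow = d[1], ncol = d[2])
  for (e in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      values[e, ch] <- pe(epochs$epochs[e, ch, ], m, tau)
  colnames(values) <- epochs$channel_labels
  structure(list(times = epochs$starts, values = values,
                 global = rowMeans(values), m = m, tau = tau),
            class = "pe_timecourse")
}

#' Group comparison of per-subject PE values
#'
#' Routes through the normality-gated two-sample machinery
#' ([shapiro_route()]): pooled-variance t-test when both groups pass
#' Shapiro-Wilk at 0.05, Mann-Whitney U otherwise. FDR adjustment across
#' time-points/phases is applied by the caller over the returned raw p-values
#' (see [benjamini_hochberg()]).
#'
#' @param group_a,group_b Numeric vectors of per-subject PE values (>= 2 per
#'   group).
#' @param label Optional label (e.g. the phase) recorded in the result.
#' @return A `stat_result` (see [two_sample_t()]).
#' @export
compare_pe <- function(group_a, group_b, label = NULL) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_invalid("need at least 2 subjects per group")
  res <- compare_groups(group_a, group_b)
  res$label <- label
  res
}
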