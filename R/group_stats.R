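#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Shapiro-Wilk test with explicit input
#' validation. In the banded workflow normality is assessed per group per
#' band and reported; since profile data are typically non-normal, the
#' group comparison itself always uses rank-based tests.
#'
#' @param sample numeric vector, 3 <= n <= 5000, not constant.
#' @return list with \code{W} and \code{p}.
#' @export
shapiro_wilk <- function(sample) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  if (n < 3L) stop("Shapiro-Wilk requires at least 3 observations")
  if (n > 5000L) stop("Shapiro-Wilk supports at most 5000 observations")
  if (length(unique(sample)) == 1L)
    stop("W is undefined for a constant sample")
  ht <- shapiro.test(sample)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based k-sample test of identical distributions. Mid-ranks are used
#' for ties and H is divided by the usual tie-correction factor
#' \code{1 - sum(t^3 - t) / (N^3 - N)}. The p-value comes from the
#' chi-square approximation with \code{k - 1} degrees of freedom; for tiny
#' pooled samples (N <= 8) the exact permutation p-value over all
#' assignments of the pooled values to the group sizes is also computed.
#' If every pooled value is identical the statistic is defined as 0 with
#' p = 1 (the tie correction degenerates).
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 1, pooled
#'   n >= 3).
#' @param exact_max_n pooled-size cutoff below which the exact permutation
#'   p is computed (default 8).
#' @return list with \code{H}, \code{df}, \code{p} (chi-square),
#'   \code{p_exact} (NULL unless computed), \code{n} per group.
#' @export
kruskal_wallis <- function(groups, exact_max_n = 8L) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  n <- lengths(groups)
  if (any(n < 1L)) stop("every group needs at least one observation")
  x <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(x))) stop("non-finite values in groups")
  N <- length(x)
  if (N < 3L) stop("pooled sample must have at least 3 observations")
  g <- rep(seq_along(groups), n)
  k <- length(groups)

  H <- kw_statistic(x, g, n)
  if (is.na(H)) {  # all pooled values identical
    return(list(H = 0, df = k - 1L, p = 1, p_exact = NULL, n = n))
  }
  p <- pchisq(H, df = k - 1L, lower.tail = FALSE)
  p_exact <- NULL
  if (N <= exact_max_n)
    p_exact <- kw_exact_p(x, n, H)
  list(H = H, df = k - 1L, p = p, p_exact = p_exact, n = n)
}

# H from pooled values and group ids; NA when the tie correction is
# degenerate (all values equal).
kw_statistic <- function(x, g, n) {
  N <- length(x)
  r <- rank(x)  # mid-ranks
  Rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(n * (Rbar - (N + 1) / 2)^2)
  t <- table(x)
  C <- 1 - sum(t^3 - t) / (N^3 - N)
  if (C <= 0) return(NA_real_)
  H / C
}

# Exact permutation p-value: enumerate all distinct assignments of the
# pooled observations to the given group sizes and count H >= H_obs.
kw_exact_p <- function(x, n, H_obs) {
  N <- length(x)
  k <- length(n)
  count <- 0L
  total <- 0L
  recurse <- function(avail, gi, gvec) {
    if (gi > k) {
      H <- kw_statistic(x, gvec, n)
      if (is.na(H)) H <- 0
      total <<- total + 1L
      if (H >= H_obs - 1e-10) count <<- count + 1L
      return(invisible())
    }
    cmb <- combn(avail, n[gi])
    for (j in seq_len(ncol(cmb))) {
      gv <- gvec
      gv[cmb[, j]] <- gi
      recurse(setdiff(avail, cmb[, j]), gi + 1L, gv)
    }
  }
  recurse(seq_len(N), 1L, integer(N))
  count / total
}

#' Dunn's post-hoc test with Bonferroni adjustment
#'
#' Pairwise follow-up to a significant Kruskal-Wallis result. For groups i
#' and j, \code{z = (Rbar_i - Rbar_j) / sqrt(V * (1/n_i + 1/n_j))} with
#' \code{V = N(N+1)/12 - sum(t^3 - t) / (12 (N - 1))} (mid-ranks, standard
#' tie correction). Raw two-sided normal p-values are Bonferroni-adjusted
#' over the \code{k(k-1)/2} comparisons: \code{p_adj = min(1, p_raw * m)}.
#'
#' @param groups named list of numeric vectors (>= 3 groups, all
#'   non-empty).
#' @param alpha significance level for the \code{significant} flag.
#' @return data.frame with one row per pair: \code{group_i, group_j, z,
#'   p_raw, p_adj, significant}.
#' @export
dunn_bonferroni <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups))
  if (length(groups) < 3L) stop("Dunn's test needs at least 3 groups")
  if (any(lengths(groups) == 0L)) stop("empty group supplied to Dunn's test")
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  if (is.null(names(groups))) names(groups) <- nm
  x <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(x))) stop("non-finite values in groups")
  n <- lengths(groups)
  N <- length(x)
  g <- rep(seq_along(groups), n)
  r <- rank(x)
  Rbar <- tapply(r, g, mean)
  t <- table(x)
  V <- N * (N + 1) / 12 - sum(t^3 - t) / (12 * (N - 1))
  m <- length(groups) * (length(groups) - 1) / 2
  pairs <- combn(seq_along(groups), 2L)
  res <- data.frame(
    group_i = nm[pairs[1, ]], group_j = nm[pairs[2, ]],
    z = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
    stringsAsFactors = FALSE)
  for (c_ in seq_len(ncol(pairs))) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    se <- sqrt(V * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (Rbar[i] - Rbar[j]) / se else 0
    res$z[c_] <- z
    res$p_raw[c_] <- 2 * pnorm(-abs(z))
  }
  res$p_adj <- pmin(1, res$p_raw * m)
  res$significant <- res$p_adj < alpha
  res
}

#' Per-band group comparison (Kruskal-Wallis + Dunn-Bonferroni)
#'
#' Runs the full per-distance statistical battery on aggregated profile
#' samples: at every band, a tie-corrected Kruskal-Wallis test across the
#' surface groups and — where it is significant (gate configurable) —
#' Dunn's pairwise post-hoc tests with Bonferroni adjustment. Tests are
#' performed independently per band (no across-band correction by default,
#' matching a per-distance testing design); \code{across_band_bonferroni}
#' enables a conservative sensitivity variant.
#'
#' @param aggregate a \code{\link{aggregate_profiles}} result.
#' @param alpha significance level (default 0.05).
#' @param gate_on_kw run post-hoc tests only where the Kruskal-Wallis p is
#'   below alpha (default TRUE).
#' @param across_band_bonferroni if TRUE, multiply each band's KW p by the
#'   number of tested bands before gating/reporting.
#' @return An object of class \code{gb_band_comparison}: list of per-band
#'   results, each with \code{band}, \code{interval_um}, \code{n} per
#'   group, \code{H}, \code{p_kw}, \code{posthoc} (data.frame or NULL),
#'   \code{significant_pairs}, \code{testable}. Use \code{as.data.frame}
#'   for the flat stats table.
#' @export
compare_bands <- function(aggregate, alpha = 0.05, gate_on_kw = TRUE,
                          across_band_bonferroni = FALSE) {
  stopifnot(inherits(aggregate, "gb_aggregate"), alpha > 0, alpha < 1)
  s <- aggregate$samples
  bands <- sort(unique(s$band))
  res <- lapply(bands, function(b) {
    sb <- s[s$band == b, ]
    grp <- split(sb$value, sb$group)
    grp <- grp[lengths(grp) > 0L]
    iv <- c(sb$band_lo_um[1], sb$band_hi_um[1])
    if (length(grp) < 2L) {
      return(list(band = b, interval_um = iv, n = lengths(grp),
                  H = NA_real_, p_kw = NA_real_, posthoc = NULL,
                  significant_pairs = character(), testable = FALSE))
    }
    kw <- kruskal_wallis(grp)
    p_kw <- kw$p
    if (across_band_bonferroni) p_kw <- min(1, p_kw * length(bands))
    posthoc <- NULL
    sig <- character()
    if (length(grp) >= 3L && (!gate_on_kw || p_kw < alpha)) {
      posthoc <- dunn_bonferroni(grp, alpha = alpha)
      sig <- with(posthoc, paste(group_i, group_j, sep = " vs "))[
        posthoc$significant]
    }
    list(band = b, interval_um = iv, n = lengths(grp), H = kw$H,
         p_kw = p_kw, posthoc = posthoc, significant_pairs = sig,
         testable = TRUE)
  })
  structure(list(bands = res, alpha = alpha, gate_on_kw = gate_on_kw,
                 kind = aggregate$kind),
            class = "gb_band_comparison")
}

#' @export
as.data.frame.gb_band_comparison <- function(x, ...) {
  rows <- lapply(x$bands, function(b) {
    base <- data.frame(band = b$band, band_lo_um = b$interval_um[1],
                       band_hi_um = b$interval_um[2],
                       H = b$H, p_kw = b$p_kw, testable = b$testable,
                       stringsAsFactors = FALSE)
    if (is.null(b$posthoc) || !nrow(b$posthoc)) {
      cbind(base, data.frame(pair = NA_character_, z = NA_real_,
                             p_raw = NA_real_, p_adj = NA_real_,
                             significant = NA))
    } else {
      ph <- b$posthoc
      cbind(base[rep(1L, nrow(ph)), , drop = FALSE],
            data.frame(pair = paste(ph$group_i, ph$group_j, sep = " vs "),
                       z = ph$z, p_raw = ph$p_raw, p_adj = ph$p_adj,
                       significant = ph$significant))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.gb_band_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  kwt <- unique(df[, c("band", "band_lo_um", "band_hi_um", "H", "p_kw")])
  cat(sprintf("<gb_band_comparison> kind=%s, alpha=%g\n", x$kind, x$alpha))
  print(kwt, row.names = FALSE)
  nsig <- sum(vapply(x$bands, function(b) length(b$significant_pairs),
                     integer(1)))
  cat(sprintf("significant post-hoc pairs: %d\n", nsig))
  invisible(x)
}
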