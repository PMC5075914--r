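test_that("Shapiro-Wilk wrapper enforces its domain", {
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
  expect_error(shapiro_wilk(rep(5, 10)), "constant")
  r <- shapiro_wilk(c(1.2, 3.4, 2.2, 5.5, 0.1))
  expect_true(r$W > 0 && r$W <= 1)
})

test_that("Shapiro-Wilk is calibrated on normal data and powerful on skewed", {
  set.seed(101)
  reps <- 1000
  p_norm <- replicate(reps, shapiro_wilk(rnorm(500))$p)
  rate <- mean(p_norm < 0.05)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 4 * se)
  p_exp <- replicate(reps, shapiro_wilk(rexp(500))$p)
  expect_gt(mean(p_exp < 0.05), 0.99)
})

test_that("Kruskal-Wallis reproduces the closed-form no-ties example", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2L)
})

test_that("degenerate and identical groups yield H = 0, p = 1", {
  kw <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)
  kw2 <- kruskal_wallis(list(c(1, 5, 3), c(1, 5, 3)))
  expect_equal(kw2$H, 0, tolerance = 1e-12)
})

test_that("tie-corrected H and p match stats::kruskal.test on random data", {
  set.seed(55)
  for (rep_i in 1:40) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(i)
      sample(1:6, sample(3:12, 1), replace = TRUE))  # heavy ties
    if (length(unique(unlist(groups))) == 1L) next
    kw <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(groups)
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact permutation p agrees with a Monte-Carlo permutation oracle", {
  set.seed(77)
  for (rep_i in 1:5) {
    n <- c(3, 3, 2)
    x <- round(runif(sum(n), 0, 10), 1)
    groups <- split(x, rep(seq_along(n), n))
    kw <- kruskal_wallis(groups)
    expect_false(is.null(kw$p_exact))
    # independent MC oracle over random permutations of the pooled data
    B <- 4000
    h_obs <- kw$H
    hits <- 0L
    for (b in seq_len(B)) {
      xp <- sample(x)
      gp <- split(xp, rep(seq_along(n), n))
      hb <- tryCatch(stats::kruskal.test(gp)$statistic,
                     error = function(e) 0)
      if (hb >= h_obs - 1e-10) hits <- hits + 1L
    }
    p_mc <- hits / B
    se <- sqrt(max(p_mc * (1 - p_mc), 1e-4) / B)
    expect_lt(abs(kw$p_exact - p_mc), 4 * se)
    # chi-square approximation is in the right neighbourhood at tiny n
    expect_lt(abs(kw$p - kw$p_exact), 0.15)
  }
})

test_that("Dunn z and p match hand-computed values on a no-ties example", {
  # groups {1,2}, {3,4}, {5,6}: mean ranks 1.5, 3.5, 5.5; V = 6*7/12 = 3.5
  res <- dunn_bonferroni(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  z_ab <- -2 / sqrt(3.5)
  expect_equal(res$z[res$group_i == "a" & res$group_j == "b"], z_ab,
               tolerance = 1e-12)
  expect_equal(res$z[res$group_i == "a" & res$group_j == "c"], 2 * z_ab,
               tolerance = 1e-12)
  expect_equal(res$p_raw, 2 * pnorm(-abs(res$z)), tolerance = 1e-12)
  expect_equal(res$p_adj, pmin(1, res$p_raw * 3), tolerance = 1e-12)
})

test_that("Bonferroni adjustment multiplies by the comparison count and caps", {
  set.seed(9)
  groups <- lapply(1:4, function(i) rnorm(8, mean = i))
  res <- dunn_bonferroni(groups)
  expect_equal(nrow(res), 6L)
  expect_equal(res$p_adj, pmin(1, res$p_raw * 6), tolerance = 1e-15)
  expect_true(all(res$p_adj >= res$p_raw))
  expect_true(all(res$p_adj <= 1))
  flat <- dunn_bonferroni(list(a = c(1, 1, 2), b = c(1, 2, 2),
                               c = c(1, 2, 1)))
  expect_true(all(flat$p_adj == 1))  # p_raw ~ 0.3-1 -> capped
  expect_error(dunn_bonferroni(list(a = 1:3, b = 2:4)), "3 groups")
  expect_error(dunn_bonferroni(list(a = 1:3, b = 2:4, c = numeric())),
               "empty")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(31)
  groups <- lapply(1:4, function(i) rnorm(10, i / 2))
  h1 <- kruskal_wallis(groups)$H
  h2 <- kruskal_wallis(lapply(groups, exp))$H
  h3 <- kruskal_wallis(lapply(groups, function(v) 5 * v - 3))$H
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("per-band comparison gates post-hocs and flags untestable bands", {
  # identical samples at every band: KW never significant, no post hoc
  samples <- expand.grid(section_id = paste0("s", 1:6),
                         group = FACE_LABELS, band = 0:3,
                         stringsAsFactors = FALSE)
  samples$band_lo_um <- samples$band * 50
  samples$band_hi_um <- samples$band_lo_um + 50
  samples$value <- rep(c(1.0, 1.1, 0.9, 1.2, 1.05, 0.95), times = 16)
  agg <- structure(list(samples = samples, summary = NULL,
                        kind = "intensity", value = "normalized"),
                   class = "gb_aggregate")
  cmp <- compare_bands(agg)
  expect_true(all(vapply(cmp$bands, function(b)
    length(b$significant_pairs) == 0L, logical(1))))
  expect_true(all(vapply(cmp$bands, function(b) is.null(b$posthoc),
                         logical(1))))

  # drop all but one group at band 3 -> untestable
  s2 <- samples[!(samples$band == 3 & samples$group != "nanoSi"), ]
  agg2 <- structure(list(samples = s2, summary = NULL, kind = "intensity",
                         value = "normalized"), class = "gb_aggregate")
  cmp2 <- compare_bands(agg2)
  b3 <- Filter(function(b) b$band == 3, cmp2$bands)[[1]]
  expect_false(b3$testable)
  expect_true(is.na(b3$p_kw))

  # ungated variant always runs the post hoc where >= 3 groups exist
  cmp3 <- compare_bands(agg, gate_on_kw = FALSE)
  expect_true(all(vapply(cmp3$bands, function(b) !is.null(b$posthoc),
                         logical(1))))
  df <- as.data.frame(cmp3)
  expect_true(all(c("band", "H", "p_kw", "pair", "z", "p_raw", "p_adj",
                    "significant") %in% names(df)))
})

test_that("a strong single-band group shift is detected only in that band", {
  set.seed(71)
  samples <- expand.grid(section_id = paste0("s", 1:12),
                         group = FACE_LABELS, band = 0:4,
                         stringsAsFactors = FALSE)
  samples$band_lo_um <- samples$band * 50
  samples$band_hi_um <- samples$band_lo_um + 50
  samples$value <- rnorm(nrow(samples), 1, 0.05)
  shift <- samples$band == 0 & samples$group == "micro-polymer"
  samples$value[shift] <- samples$value[shift] - 0.5
  agg <- structure(list(samples = samples, summary = NULL,
                        kind = "density", value = "normalized"),
                   class = "gb_aggregate")
  cmp <- compare_bands(agg)
  b0 <- cmp$bands[[1]]
  expect_lt(b0$p_kw, 0.05)
  expect_true(any(grepl("micro-polymer", b0$significant_pairs)))
  for (b in cmp$bands[-1]) {
    expect_equal(length(b$significant_pairs), 0L)
  }
})
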