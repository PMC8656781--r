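test_that("signed-rank test handles the worked small-sample cases", {
  # n = 5, all differences positive, no ties: two one-sided extremes of 2^5
  r <- wilcoxon_signed_rank(c(2, 4, 7, 11, 16), c(1, 2, 4, 7, 11))
  expect_equal(r$W, 15)
  expect_equal(r$p, 2 / 32)
  expect_true(r$exact)
  # identical vectors: degenerate, p = 1
  r2 <- wilcoxon_signed_rank(rep(0.4, 6), rep(0.4, 6))
  expect_true(r2$degenerate)
  expect_equal(r2$p, 1)
  expect_equal(r2$W, 0)
  # zero differences are dropped before ranking
  r3 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 4), c(1, 1, 1, 1, 4))
  expect_equal(r3$n_used, 3)
})

test_that("exact p equals full sign-pattern enumeration on random draws", {
  set.seed(41)
  for (rep in 1:200) {
    n <- 8
    d <- round(rnorm(n), 3)
    while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(n), 3)
    x <- d; y <- rep(0, n)
    got <- wilcoxon_signed_rank(x, y)
    expect_true(got$exact)
    expect_equal(got$p, oracle_wilcoxon_exact(d), tolerance = 1e-12)
  }
})

test_that("large samples and ties fall back to the corrected normal approximation", {
  set.seed(43)
  x <- rnorm(30); y <- rnorm(30)
  r <- wilcoxon_signed_rank(x, y)
  expect_false(r$exact)
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(r$p, ref$p.value)
})

test_that("maxT with a single probe reduces to that probe's permutation p", {
  set.seed(47)
  t1 <- matrix(rnorm(10, mean = 1), 1, 10)
  n1 <- matrix(rnorm(10), 1, 10)
  p <- maxt_adjust(t1, n1, n_perm = 2000, seed = 5)
  # exhaustive: 2^10 = 1024 <= 2000, so the p-value is the exact sign-flip
  # tail probability of the standardized statistic
  d <- t1 - n1
  r <- rank(abs(d)); mu <- sum(r) / 2; sig <- sqrt(sum(r^2) / 4)
  z_obs <- abs(sum(r[d > 0]) - mu) / sig
  cnt <- 0
  for (mask in 0:(2^10 - 1)) {
    s <- bitwAnd(bitwShiftR(mask, 0:9), 1L) == 1L
    keep <- ifelse(s, d, -d)
    z <- abs(sum(r[keep > 0]) - mu) / sig
    if (z >= z_obs - 1e-12) cnt <- cnt + 1
  }
  expect_equal(p, cnt / 1024)
})

test_that("exhaustive enumeration makes maxT seed-independent", {
  set.seed(53)
  tm <- matrix(rnorm(5 * 4), 5, 4)
  nm <- matrix(rnorm(5 * 4), 5, 4)
  p1 <- maxt_adjust(tm, nm, n_perm = 100, seed = 1)
  p2 <- maxt_adjust(tm, nm, n_perm = 100, seed = 999)
  expect_identical(p1, p2)
})

test_that("maxT adjusted p dominates raw p and is monotone along the ordering", {
  set.seed(59)
  tm <- matrix(rbeta(80 * 12, 2, 2), 80, 12)
  nm <- matrix(rbeta(80 * 12, 2, 2), 80, 12)
  tm[1:5, ] <- tm[1:5, ] + 0.35
  p_adj <- maxt_adjust(tm, nm, n_perm = 500, seed = 61)
  p_raw <- vapply(1:80, function(i)
    wilcoxon_signed_rank(tm[i, ], nm[i, ])$p, numeric(1))
  expect_true(all(p_adj >= p_raw - 1e-9))
  # monotone non-decreasing when sorted by observed statistic = by raw p
  z <- vapply(1:80, function(i) {
    d <- tm[i, ] - nm[i, ]; d <- d[d != 0]
    r <- rank(abs(d)); mu <- sum(r) / 2; sig <- sqrt(sum(r^2) / 4)
    abs(sum(r[d > 0]) - mu) / sig
  }, numeric(1))
  expect_true(all(diff(p_adj[order(z, decreasing = TRUE)]) >= -1e-12))
  expect_error(maxt_adjust(tm, nm, n_perm = 500), "seed")
  expect_warning(maxt_adjust(tm[1:3, ], nm[1:3, ], n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("fold change reproduces the signed ratio-of-medians convention", {
  expect_equal(compute_fold_change(0.79, 0.04), 16)
  expect_equal(compute_fold_change(0.19, 0.57), -2.9)
  expect_equal(compute_fold_change(0.5, 0.5), 1)    # equality reported +1
  expect_equal(compute_fold_change(0, 0), 1)
  expect_true(all(abs(compute_fold_change(runif(50), runif(50))) >= 1))
})

test_that("site calls combine medians, p-values and directions deterministically", {
  cfg <- sim_config(seed = 67, n_islands = 2, genome_length = 40000,
                    n_probes = 100, n_pairs = 24, n_true_hyper = 5,
                    n_true_hypo = 5, effect_delta = 0.3, noise_kappa = 50)
  st <- simulate_study(cfg)
  res <- call_sites(st$betas$tumor, st$betas$normal)
  expect_equal(nrow(res), 100)
  tr <- st$betas$truth[match(res$probe_id, st$betas$truth$probe_id), ]
  planted <- tr$true_direction != "null"
  expect_true(all(res$direction[planted] == tr$true_direction[planted]))
  # direction consistency with the sign of the median difference
  sig <- res$direction != "none"
  expect_true(all(res$median_diff[res$direction == "hyper"] > 0))
  expect_true(all(res$median_diff[res$direction == "hypo"] < 0))
  expect_true(all(sign(res$fold_change[res$direction == "hyper"]) == 1))
  # sorted by gating p then probe id
  expect_true(!is.unsorted(res$p_raw))
  # empty input gives an empty table
  empty <- call_sites(st$betas$tumor[0, , drop = FALSE],
                      st$betas$normal[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
})

test_that("swapping tumor and normal flips effect signs but not p-values", {
  set.seed(71)
  tm <- matrix(rbeta(40 * 10, 2, 2), 40, 10,
               dimnames = list(sprintf("p%02d", 1:40), NULL))
  nm <- matrix(rbeta(40 * 10, 2, 2), 40, 10,
               dimnames = dimnames(tm))
  a <- call_sites(tm, nm)
  b <- call_sites(nm, tm)
  b <- b[match(a$probe_id, b$probe_id), ]
  expect_equal(a$median_diff, -b$median_diff)
  expect_equal(a$p_raw, b$p_raw)
  expect_equal(sign(a$fold_change[abs(a$fold_change) > 1]),
               -sign(b$fold_change[abs(b$fold_change) > 1]))
})

test_that("fold-change selection keeps both directions at the threshold", {
  res <- data.frame(probe_id = paste0("p", 1:4),
                    fold_change = c(16, -2.9, 1.5, -1.9),
                    direction = c("hyper", "hypo", "hyper", "hypo"),
                    stringsAsFactors = FALSE)
  sel <- select_fold_candidates(res)
  expect_setequal(sel$probe_id, c("p1", "p2"))
  expect_equal(nrow(select_fold_candidates(res[0, ])), 0)
  # brute-force filter on random tables
  set.seed(73)
  rnd <- data.frame(probe_id = sprintf("r%03d", 1:100),
                    fold_change = ifelse(runif(100) < 0.5, 1, -1) *
                      (1 + rexp(100)),
                    direction = sample(c("hyper", "hypo", "none"), 100,
                                       replace = TRUE),
                    stringsAsFactors = FALSE)
  sel2 <- select_fold_candidates(rnd, min_abs_fc = 2)
  want <- rnd[rnd$direction != "none" & abs(rnd$fold_change) >= 2, ]
  expect_equal(sel2$probe_id, want$probe_id)
})
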