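#' Paired Wilcoxon signed-rank test
#'
#' Classic signed-rank treatment of paired differences: zero differences
#' are dropped (reducing the effective sample size to `n'`), the absolute
#' differences are midranked, and `W` is the sum of ranks of positive
#' differences. The two-sided p-value is exact (full enumeration of sign
#' assignments) when `n' <= 25` and the non-zero `|d|` are tie-free,
#' otherwise a normal approximation with tie-corrected variance and a 0.5
#' continuity correction is used. All differences zero is flagged
#' degenerate with `p = 1` and `W = 0`.
#'
#' @param tumor,normal Paired numeric vectors of equal length (pairing by
#'   index).
#' @return List: `W`, `p`, `n_used` (non-zero differences), `exact`,
#'   `degenerate`.
#' @export
wilcoxon_signed_rank <- function(tumor, normal) {
  if (length(tumor) != length(normal)) stop("unequal vector lengths")
  if (length(tumor) < 2) stop("need at least 2 pairs")
  d <- tumor - normal
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(W = 0, p = 1, n_used = 0L, exact = FALSE, degenerate = TRUE))
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= 25 && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    d, mu = 0, alternative = "two.sided", exact = exact, correct = TRUE))
  list(W = unname(ht$statistic), p = min(1, ht$p.value), n_used = n,
       exact = exact, degenerate = FALSE)
}

#' Westfall-Young step-down maxT adjusted p-values
#'
#' Strong family-wise error control for the per-probe signed-rank tests
#' under the paired sign-flip null: each permutation flips the sign of
#' every pair's difference vector independently, with the same flip applied
#' across all probes of that pair so inter-probe correlation is preserved.
#' The per-probe statistic is the absolute standardized signed-rank
#' statistic `|W - mu| / sigma` (mu = S/2, sigma^2 = sum of squared ranks
#' / 4, which is tie-corrected because midranks are used). Probes are
#' ordered by decreasing observed statistic; for each permutation,
#' successive maxima over the ordered tail give the step-down reference
#' distribution, and adjusted p-values are the tail-max exceedance
#' proportions with the +1 correction in numerator and denominator,
#' monotonized to be non-decreasing along the ordering. When `2^n_pairs <=
#' n_perm` the full set of sign assignments is enumerated instead of
#' sampled and the result is seed-independent.
#'
#' @param tumor,normal Probes x pairs beta matrices, paired by column.
#' @param n_perm Number of sign-flip permutations (warning below 100).
#' @param seed Mandatory integer seed for the sampled regime.
#' @return Numeric vector of adjusted p-values, one per probe (row order of
#'   the input).
#' @export
maxt_adjust <- function(tumor, normal, n_perm = 10000L, seed) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is required: permutation results must be reproducible")
  if (!identical(dim(tumor), dim(normal)))
    stop("tumor and normal must have identical dimensions")
  m <- nrow(tumor); n <- ncol(tumor)
  if (m < 1 || n < 2) stop("need >= 1 probe and >= 2 pairs")
  if (n_perm < 100) warning("n_perm < 100 gives very coarse adjusted p-values")

  D <- tumor - normal
  A <- abs(D)
  # per-probe midranks of non-zero |d|; zero differences get rank 0
  R <- t(apply(A, 1L, function(a) {
    r <- numeric(length(a)); nz <- a != 0
    r[nz] <- rank(a[nz]); r
  }))
  if (m == 1) R <- matrix(R, 1L, n)
  mu <- rowSums(R) / 2
  sig <- sqrt(rowSums(R^2) / 4)
  Pmat <- R * (D > 0)                    # ranks of positive differences
  Nmat <- R * (D < 0)
  W_obs <- rowSums(Pmat)
  z_obs <- ifelse(sig > 0, abs(W_obs - mu) / sig, 0)

  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    B <- as.integer(2^n)
    F <- vapply(seq_len(B) - 1L,
                function(b) as.integer(bitwAnd(bitwShiftR(b, 0:(n - 1L)), 1L)),
                integer(n))               # n x B matrix of 0/1 (1 = keep sign)
  } else {
    B <- as.integer(n_perm)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    F <- matrix(stats::rbinom(n * B, 1L, 0.5), n, B)
  }
  # W under flip pattern f: pairs with kept sign contribute their positive
  # ranks, flipped pairs contribute their negative ranks
  W_perm <- Pmat %*% F + Nmat %*% (1 - F)
  Z <- abs(W_perm - mu) / ifelse(sig > 0, sig, 1)
  Z[sig == 0, ] <- 0

  o <- order(z_obs, decreasing = TRUE)
  Zo <- Z[o, , drop = FALSE]
  # successive maxima from the least significant probe upwards
  U <- apply(Zo, 2L, function(col) rev(cummax(rev(col))))
  if (m == 1) U <- matrix(U, 1L, B)
  eps <- 1e-12
  cnt <- rowSums(U >= matrix(z_obs[o], m, B) - eps)
  p_adj <- if (exhaustive) cnt / B else (cnt + 1) / (B + 1)
  p_adj <- cummax(p_adj)                 # enforce step-down monotonicity
  out <- numeric(m)
  out[o] <- pmin(p_adj, 1)
  out
}

#' Signed fold change of beta medians
#'
#' Ratio of pseudo-counted medians `r = (median_tumor + pseudo) /
#' (median_normal + pseudo)`, reported as `r` when `r >= 1` (hyper) and
#' `-1/r` otherwise (hypo), so the magnitude is always at least 1 and the
#' sign tracks the direction of methylation change. The pseudo-count keeps
#' ratios finite when a median sits at 0.
#'
#' @param median_tumor,median_normal Beta medians in \[0, 1\] (vectorized).
#' @param pseudo Small positive pseudo-count. Default 0.01.
#' @return Signed fold change(s).
#' @examples
#' compute_fold_change(0.79, 0.04)   # +16
#' compute_fold_change(0.19, 0.57)   # -2.9
#' @export
compute_fold_change <- function(median_tumor, median_normal, pseudo = 0.01) {
  r <- (median_tumor + pseudo) / (median_normal + pseudo)
  ifelse(r >= 1, r, -1 / r)
}

#' Per-site differential methylation calls
#'
#' Computes, for every probe of a paired tumor/normal beta matrix pair, the
#' tumor and normal medians, their difference, the signed fold change, the
#' raw paired Wilcoxon p-value and (optionally) the maxT-adjusted p-value,
#' and calls the direction: `hyper` when the site is selected (p at or
#' below `alpha` on the gating p column) with a positive median difference,
#' `hypo` with a negative one, `none` otherwise. The gate defaults to the
#' raw p-value, with the adjusted p-value reported alongside; set
#' `gate_maxt = TRUE` to gate on the adjusted column instead.
#'
#' @param tumor,normal Probes x pairs beta matrices with matching rownames.
#' @param alpha Significance threshold. Default 0.05.
#' @param use_maxt Compute maxT-adjusted p-values. Default `FALSE`.
#' @param gate_maxt Gate direction calls on `p_maxt` instead of `p_raw`
#'   (requires `use_maxt`). Default `FALSE`.
#' @param n_perm,seed Passed to [maxt_adjust()] when `use_maxt`.
#' @param pseudo Pseudo-count for [compute_fold_change()].
#' @return Data frame (one row per probe, sorted by gating p then
#'   `probe_id`): `probe_id`, `median_tumor`, `median_normal`,
#'   `median_diff`, `fold_change`, `w_statistic`, `p_raw`, `p_maxt` (NA
#'   when not computed), `direction`.
#' @export
call_sites <- function(tumor, normal, alpha = 0.05, use_maxt = FALSE,
                       gate_maxt = FALSE, n_perm = 10000L, seed = NULL,
                       pseudo = 0.01) {
  if (!identical(dim(tumor), dim(normal)))
    stop("tumor and normal must have identical dimensions")
  m <- nrow(tumor)
  if (m == 0)
    return(data.frame(probe_id = character(), median_tumor = numeric(),
                      median_normal = numeric(), median_diff = numeric(),
                      fold_change = numeric(), w_statistic = numeric(),
                      p_raw = numeric(), p_maxt = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  if (gate_maxt && !use_maxt) stop("gate_maxt requires use_maxt = TRUE")
  probe_id <- rownames(tumor)
  if (is.null(probe_id)) probe_id <- sprintf("probe_%d", seq_len(m))

  med_t <- apply(tumor, 1L, stats::median)
  med_n <- apply(normal, 1L, stats::median)
  wt <- lapply(seq_len(m), function(i)
    wilcoxon_signed_rank(tumor[i, ], normal[i, ]))
  p_raw <- vapply(wt, `[[`, numeric(1), "p")
  W <- vapply(wt, `[[`, numeric(1), "W")
  p_maxt <- if (use_maxt)
    maxt_adjust(tumor, normal, n_perm = n_perm, seed = seed)
  else rep(NA_real_, m)

  p_gate <- if (gate_maxt) p_maxt else p_raw
  diff <- med_t - med_n
  direction <- ifelse(p_gate <= alpha & diff > 0, "hyper",
                      ifelse(p_gate <= alpha & diff < 0, "hypo", "none"))
  out <- data.frame(probe_id = probe_id, median_tumor = med_t,
                    median_normal = med_n, median_diff = diff,
                    fold_change = compute_fold_change(med_t, med_n, pseudo),
                    w_statistic = W, p_raw = p_raw, p_maxt = p_maxt,
                    direction = direction, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(p_gate, out$probe_id), , drop = FALSE]
}

#' Select fold-change candidates among significant sites
#'
#' Keeps the significant sites (direction called) whose absolute fold
#' change meets the threshold; hyper- and hypomethylated sites are both
#' retained.
#'
#' @param results Site-result table from [call_sites()].
#' @param min_abs_fc Minimum absolute fold change. Default 2.
#' @return The filtered site-result table.
#' @export
select_fold_candidates <- function(results, min_abs_fc = 2.0) {
  results[results$direction != "none" &
            abs(results$fold_change) >= min_abs_fc, , drop = FALSE]
}
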