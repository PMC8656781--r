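# Independent brute-force oracles. These deliberately share no code with
# the package implementation: plain substring scans, full enumerations and
# naive loops, kept slow and obvious.

# every qualifying window of a sequence, by direct substring inspection,
# then a naive interval union
oracle_scan_islands <- function(seq, window = 200L, min_gc = 0.5,
                                min_oe = 0.6) {
  L <- nchar(seq)
  if (L < window) return(data.frame(start = integer(), end = integer()))
  qualifying <- integer()
  for (i in 1:(L - window + 1L)) {
    w <- substr(seq, i, i + window - 1L)
    if (grepl("[^ACGT]", w)) next
    nc <- lengths(regmatches(w, gregexpr("C", w)))
    ng <- lengths(regmatches(w, gregexpr("G", w)))
    ncg <- lengths(regmatches(w, gregexpr("(?=CG)", w, perl = TRUE)))
    gc <- (nc + ng) / window
    oe <- if (nc > 0 && ng > 0) ncg * window / (nc * ng) else 0
    if (gc > min_gc && oe >= min_oe) qualifying <- c(qualifying, i - 1L)
  }
  if (!length(qualifying))
    return(data.frame(start = integer(), end = integer()))
  covered <- rep(FALSE, L)
  for (s in qualifying) covered[(s + 1):(s + window)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  EW <- sum(r) / 2
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    W <- sum(r[signs])
    if (abs(W - EW) >= abs(W_obs - EW) - 1e-12) count <- count + 1L
  }
  count / 2^n
}

# nearest-island neighborhood class by scanning every island
oracle_neighborhood <- function(islands, pos) {
  if (nrow(islands) == 0) return("OpenSea")
  best_d <- Inf; best_side <- NA; best_start <- Inf
  for (k in seq_len(nrow(islands))) {
    s <- islands$start[k]; e <- islands$end[k]
    if (pos >= s && pos < e) return("Island")
    if (pos < s) { d <- s - pos - 1L; side <- "N_" }
    else { d <- pos - e; side <- "S_" }
    if (d < best_d || (d == best_d && s < best_start)) {
      best_d <- d; best_side <- side; best_start <- s
    }
  }
  if (best_d <= 2000) paste0(best_side, "Shore")
  else if (best_d <= 4000) paste0(best_side, "Shelf")
  else "OpenSea"
}

# hypergeometric upper tail by summing binomial-coefficient terms
oracle_hypergeom_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# per-gene functional class by direct interval checks on one gene row
oracle_gene_class <- function(g, pos) {
  up <- if (g$strand == "+") g$tss - pos else pos - g$tss
  if (up >= 1 && up <= 200) return("TSS200")
  if (up > 200 && up <= 1500) return("TSS1500")
  if (up >= 1) return(NA_character_)
  if (pos < g$start || pos >= g$end) return(NA_character_)
  if (!is.na(g$utr5_start) && pos >= g$utr5_start && pos < g$utr5_end)
    return("UTR5")
  ex <- strsplit(g$exons, ";")[[1]]
  if (length(ex) && nzchar(ex[1])) {
    sp <- lapply(strsplit(ex, "-"), as.integer)
    first <- if (g$strand == "+") sp[[which.min(sapply(sp, `[`, 1))]]
             else sp[[which.max(sapply(sp, `[`, 2))]]
    if (pos >= first[1] && pos < first[2]) return("FirstExon")
  }
  if (!is.na(g$utr3_start) && pos >= g$utr3_start && pos < g$utr3_end)
    return("UTR3")
  "Body"
}
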