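#' Detect CpG islands in a DNA sequence
#'
#' Slides a fixed-width window along the sequence at 1-bp steps and marks a
#' window as island-like when its GC fraction is strictly greater than
#' `min_gc` and its observed/expected CpG ratio is at least `min_oe`
#' (Gardiner-Garden ratio: `n_CpG * L / (n_C * n_G)`). Overlapping or
#' book-ended qualifying windows are merged into maximal islands, whose GC
#' fraction and obs/exp ratio are then recomputed over the full merged
#' interval. Windows containing any `N` never qualify.
#'
#' @param sequence DNA sequence: a character string or a
#'   [Biostrings::DNAString] over the alphabet A/C/G/T/N.
#' @param chrom Chromosome name attached to the reported intervals.
#' @param min_gc Minimum GC fraction (strict inequality). Default 0.5.
#' @param min_oe Minimum observed/expected CpG ratio (inclusive). Default 0.6.
#' @param window Window width in bp. Default 200.
#' @return A data frame with one row per island: `chrom`, `start`, `end`
#'   (0-based half-open), `length`, `gc_fraction`, `obs_exp_ratio`, sorted by
#'   `start`. Zero rows when the sequence is shorter than `window` or no
#'   window qualifies.
#' @examples
#' detect_cpg_islands(strrep("CG", 200))
#' @export
detect_cpg_islands <- function(sequence, chrom = "chr1", min_gc = 0.5,
                               min_oe = 0.6, window = 200L) {
  if (window < 2) stop("`window` must be >= 2")
  s <- .as_base_vector(sequence)
  L <- length(s)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      length = integer(), gc_fraction = numeric(),
                      obs_exp_ratio = numeric(), stringsAsFactors = FALSE)
  if (L < window) return(empty)

  is_c <- s == "C"
  is_g <- s == "G"
  is_n <- !(s %in% c("A", "C", "G", "T"))
  # CpG dinucleotide starting at i (fully inside the sequence)
  is_cg <- c(is_c[-L] & is_g[-1], FALSE)

  cum_c  <- cumsum(is_c)
  cum_g  <- cumsum(is_g)
  cum_n  <- cumsum(is_n)
  cum_cg <- cumsum(is_cg)

  n_win <- L - window + 1L
  i <- seq_len(n_win)                       # 1-based window starts
  wsum <- function(cum, lo, hi) cum[hi] - c(0, cum)[lo]
  nc <- wsum(cum_c, i, i + window - 1L)
  ng <- wsum(cum_g, i, i + window - 1L)
  nn <- wsum(cum_n, i, i + window - 1L)
  # dinucleotides fully inside [i, i+window): starts i .. i+window-2
  ncg <- wsum(cum_cg, i, i + window - 2L)

  gc <- (nc + ng) / window
  oe <- ifelse(nc > 0 & ng > 0, ncg * window / (nc * ng), 0)
  ok <- nn == 0 & gc > min_gc & oe >= min_oe
  if (!any(ok)) return(empty)

  # merge qualifying windows [i-1, i-1+window) — overlapping or book-ended
  starts0 <- i[ok] - 1L
  runs <- .merge_intervals(starts0, starts0 + window)

  gcf <- numeric(nrow(runs)); oer <- numeric(nrow(runs))
  for (k in seq_len(nrow(runs))) {
    lo <- runs$start[k] + 1L; hi <- runs$end[k]
    len <- hi - lo + 1L
    kc <- wsum(cum_c, lo, hi); kg <- wsum(cum_g, lo, hi)
    kcg <- if (hi - 1L >= lo) wsum(cum_cg, lo, hi - 1L) else 0
    gcf[k] <- (kc + kg) / len
    oer[k] <- if (kc > 0 && kg > 0) kcg * len / (kc * kg) else 0
  }
  data.frame(chrom = chrom, start = runs$start, end = runs$end,
             length = runs$end - runs$start, gc_fraction = gcf,
             obs_exp_ratio = oer, stringsAsFactors = FALSE)
}

#' Classify positions relative to CpG islands
#'
#' Partitions every genomic position into one of six mutually exclusive
#' neighborhood classes: inside an island (`Island`); within 2 kb of an
#' island edge (`N_Shore`/`S_Shore`); 2-4 kb away (`N_Shelf`/`S_Shelf`);
#' more than 4 kb from every island, or on a chromosome without islands
#' (`OpenSea`). `N_` (north) means the nearest island lies at a higher
#' coordinate than the position, `S_` (south) at a lower coordinate; a tie
#' between two equidistant islands is broken toward the island with the
#' lower start. The distance `d` counts the bases strictly between the
#' position and the island, so the base adjacent to an island has `d = 0`;
#' shores cover `d <= 2000` and shelves `2000 < d <= 4000` inclusively.
#'
#' @param islands Data frame of islands (as from [detect_cpg_islands()]):
#'   columns `start`, `end`, sorted, non-overlapping, one chromosome.
#' @param pos Integer vector of 0-based positions.
#' @return Character vector, one class per position, levels
#'   `Island`, `N_Shore`, `S_Shore`, `N_Shelf`, `S_Shelf`, `OpenSea`.
#' @export
classify_neighborhood <- function(islands, pos) {
  if (nrow(islands) == 0)
    return(rep("OpenSea", length(pos)))
  st <- as.integer(islands$start); en <- as.integer(islands$end)
  if (is.unsorted(st, strictly = TRUE) || any(st[-1] < en[-length(en)]))
    stop("`islands` must be sorted by start and non-overlapping")
  if (any(st >= en)) stop("island with end <= start")

  out <- character(length(pos))
  for (j in seq_along(pos)) {
    p <- pos[j]
    # inside?
    k <- findInterval(p, st)
    if (k >= 1 && p < en[k]) { out[j] <- "Island"; next }
    # distance = number of bases strictly between pos and the island
    d_s <- if (k >= 1) p - en[k] else NA_integer_
    d_n <- if (k < length(st)) st[k + 1L] - p - 1L else NA_integer_
    if (is.na(d_s) || (!is.na(d_n) && d_n < d_s)) {
      d <- d_n; side <- "N_"
    } else if (is.na(d_n) || d_s < d_n) {
      d <- d_s; side <- "S_"
    } else {
      # equidistant: prefer the island with the lower start (the south one)
      d <- d_s; side <- "S_"
    }
    out[j] <- if (d <= 2000L) paste0(side, "Shore")
              else if (d <= 4000L) paste0(side, "Shelf")
              else "OpenSea"
  }
  out
}

#' Write islands as a 6-column BED file
#'
#' BED uses 0-based half-open coordinates; the name is the island index and
#' the score is `round(1000 * obs_exp_ratio)` capped at 1000.
#'
#' @param islands Island data frame from [detect_cpg_islands()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(islands, path) {
  score <- pmin(1000L, as.integer(round(1000 * islands$obs_exp_ratio)))
  bed <- data.frame(islands$chrom, islands$start, islands$end,
                    paste0("island_", seq_len(nrow(islands))),
                    score, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- internal helpers ------------------------------------------------------

# TRUE iff every window of the sequence qualifies under the island criterion
# (used by the simulator to certify planted islands by construction)
.all_windows_qualify <- function(sequence, window = 200L, min_gc = 0.5,
                                 min_oe = 0.6) {
  s <- .as_base_vector(sequence)
  L <- length(s)
  if (L < window) return(FALSE)
  is_c <- s == "C"; is_g <- s == "G"
  is_cg <- c(is_c[-L] & is_g[-1], FALSE)
  cum_c <- cumsum(is_c); cum_g <- cumsum(is_g); cum_cg <- cumsum(is_cg)
  i <- seq_len(L - window + 1L)
  wsum <- function(cum, lo, hi) cum[hi] - c(0, cum)[lo]
  nc <- wsum(cum_c, i, i + window - 1L)
  ng <- wsum(cum_g, i, i + window - 1L)
  ncg <- wsum(cum_cg, i, i + window - 2L)
  gc <- (nc + ng) / window
  oe <- ifelse(nc > 0 & ng > 0, ncg * window / (nc * ng), 0)
  all(gc > min_gc & oe >= min_oe) && !any(!(s %in% c("A", "C", "G", "T")))
}

.as_base_vector <- function(sequence) {
  if (inherits(sequence, "XString")) sequence <- as.character(sequence)
  toupper(strsplit(sequence, "", fixed = TRUE)[[1]])
}

# union of possibly overlapping/book-ended [start, end) intervals
.merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (k in seq_along(start)[-1]) {
    if (start[k] <= me) me <- max(me, end[k])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[k]; me <- end[k] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}
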