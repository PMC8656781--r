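# Shared fixture builders (all generated in code; nothing binary).

fixture_path <- function() {
  p <- system.file("extdata", "table1_table2_fixture.tsv",
                   package = "methseas")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata",
                                 "table1_table2_fixture.tsv")
  p
}

# expand one table of the printed-count fixture into per-site results and
# annotations, so the cross-tab operations can be exercised on it
expand_fixture <- function(which_table = c("t1", "t2")) {
  which_table <- match.arg(which_table)
  fx <- read.table(fixture_path(), header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  fx <- fx[fx$table == which_table, ]
  # concrete member of each collapsed group (N/S split is irrelevant here)
  region_of <- c(OpenSea = "OpenSea", Island = "Island",
                 Shelf = "N_Shelf", Shore = "S_Shore")
  rows <- list()
  for (i in seq_len(nrow(fx))) {
    for (grp in names(region_of)) {
      cnt <- fx[[grp]][i]
      if (cnt > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = fx$chrom[i], direction = fx$status[i],
          region = region_of[[grp]], n = cnt, stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  long <- long[rep(seq_len(nrow(long)), long$n), c("chrom", "direction",
                                                   "region")]
  long$probe_id <- sprintf("%s_site_%06d", which_table, seq_len(nrow(long)))
  results <- data.frame(probe_id = long$probe_id,
                        direction = long$direction,
                        stringsAsFactors = FALSE)
  ann <- data.frame(probe_id = long$probe_id, chrom = long$chrom,
                    pos = seq_len(nrow(long)), region = long$region,
                    is_mir = which_table == "t2", stringsAsFactors = FALSE)
  list(results = results, annotations = ann)
}

# small toy gene-model table: four overlapping genes on both strands
toy_gene_models <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC", "gM"),
    chrom = "chr1",
    start = c(5000L, 5600L, 7000L, 6500L),
    end = c(8000L, 6800L, 9500L, 6900L),
    strand = c("+", "+", "-", "+"),
    tss = c(5000L, 5600L, 9499L, 6500L),
    biotype = c("coding", "noncoding", "coding", "miR"),
    exons = c("5000-5400;6000-6400", "5600-5900", "9000-9500;7200-7600",
              "6500-6900"),
    utr5_start = c(5000L, NA, 9300L, NA),
    utr5_end = c(5200L, NA, 9500L, NA),
    utr3_start = c(7800L, NA, 7000L, NA),
    utr3_end = c(8000L, NA, 7150L, NA),
    stringsAsFactors = FALSE)
}

# random CpG-bearing sequence for island-detector oracle comparisons
random_dna <- function(len, p_cg = 0.15) {
  chunks <- character(0); n <- 0
  while (n < len) {
    if (runif(1) < p_cg) { chunks <- c(chunks, "CG"); n <- n + 2 }
    else {
      b <- sample(c("A", "C", "G", "T"), 1)
      chunks <- c(chunks, b); n <- n + 1
    }
  }
  substr(paste(chunks, collapse = ""), 1, len)
}
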