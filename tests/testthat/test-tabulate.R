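test_that("genome-wide fixture reproduces the printed column totals and percentages", {
  fx <- expand_fixture("t1")
  ct <- crosstab_region(fx$results, fx$annotations, subset = "all")
  expect_equal(ct$grand, 25341)
  expect_equal(ct$col_totals[["OpenSea_hypo"]], 9342)
  expect_equal(ct$col_totals[["OpenSea_hyper"]], 643)
  expect_equal(ct$col_totals[["Island_hyper"]], 8321)
  expect_equal(ct$col_totals[["Island_hypo"]], 495)
  expect_equal(ct$col_totals[["Shelf_hypo"]], 1747)
  expect_equal(ct$col_totals[["Shelf_hyper"]], 189)
  expect_equal(ct$col_totals[["Shore_hyper"]], 2360)
  expect_equal(ct$col_totals[["Shore_hypo"]], 2244)
  expect_equal(sum(ct$col_totals[grep("hyper", names(ct$col_totals))]),
               11513)
  expect_equal(sum(ct$col_totals[grep("hypo", names(ct$col_totals))]),
               13828)
  pct <- summarize_percentages(ct)
  expect_equal(pct$region_pct,
               c(OpenSea = 39.4, Island = 34.8, Shelf = 7.6,
                 Shore = 18.2)[names(pct$region_pct)])
  expect_equal(round(unname(pct$direction_pct["hyper"])), 45)
  expect_equal(round(unname(pct$direction_pct["hypo"])), 55)
})

test_that("miR fixture reproduces the reconciling margins", {
  fx <- expand_fixture("t2")
  ct <- crosstab_region(fx$results, fx$annotations, subset = "mir_only")
  expect_equal(ct$grand, 170)
  expect_equal(sum(ct$col_totals[grep("hypo", names(ct$col_totals))]), 115)
  expect_equal(sum(ct$col_totals[grep("hyper", names(ct$col_totals))]), 55)
})

test_that("cross-tabulation equals a brute-force group-and-count", {
  set.seed(79)
  n <- 200
  ann <- data.frame(
    probe_id = sprintf("p%03d", 1:n),
    chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
    pos = 1:n,
    region = sample(c("Island", "N_Shore", "S_Shore", "N_Shelf",
                      "S_Shelf", "OpenSea"), n, replace = TRUE),
    is_mir = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
  res <- data.frame(probe_id = ann$probe_id,
                    direction = sample(c("hyper", "hypo", "none"), n,
                                       replace = TRUE),
                    stringsAsFactors = FALSE)
  ct <- crosstab_region(res, ann, subset = "all")
  for (ch in unique(ann$chrom)) for (g in c("OpenSea", "Island", "Shelf",
                                            "Shore"))
    for (d in c("hyper", "hypo")) {
      want <- sum(ann$chrom == ch & sub("^[NS]_", "", ann$region) == g &
                    res$direction == d)
      expect_equal(ct$counts[ch, paste(g, d, sep = "_")], want)
    }
  expect_equal(ct$grand, sum(res$direction != "none"))
  expect_equal(sum(ct$row_totals), ct$grand)
  # restricting the all-sites table to miR rows equals the mir_only table
  ct_mir <- crosstab_region(res, ann, subset = "mir_only")
  ct_rest <- crosstab_region(res[ann$is_mir[match(res$probe_id,
                                                    ann$probe_id)], ],
                               ann, subset = "all")
  expect_equal(ct_mir$counts, ct_rest$counts)
  # unannotated sites are rejected, not counted
  res2 <- rbind(res, data.frame(probe_id = "ghost", direction = "hyper"))
  ct2 <- crosstab_region(res2, ann)
  expect_equal(attr(ct2, "rejects"), "ghost")
  expect_equal(ct2$grand, ct$grand)
})

test_that("feature tabulation counts each site once per distinct class", {
  ann <- data.frame(probe_id = c("a", "b"), chrom = "chr1", pos = 1:2,
                    region = "OpenSea", is_mir = FALSE,
                    stringsAsFactors = FALSE)
  ann$classes <- list(c("TSS200", "Body"), character())
  ann$genes <- list(c("g1", "g2"), character())
  res <- data.frame(probe_id = c("a", "b"),
                    direction = c("hyper", "hypo"),
                    stringsAsFactors = FALSE)
  ft <- crosstab_features(res, ann)
  expect_equal(ft["TSS200", "hyper"], 1)
  expect_equal(ft["Body", "hyper"], 1)
  expect_equal(ft["Intergenic", "hypo"], 1)
  expect_equal(sum(ft$hyper), 2)   # one site, two distinct classes
  # duplicate classes via two genes still count once
  ann$classes[[1]] <- c("Body", "Body")
  ft2 <- crosstab_features(res, ann)
  expect_equal(ft2["Body", "hyper"], 1)
})

test_that("a body-class fixture reproduces the printed body totals", {
  n_hyper <- 4899; n_hypo <- 6933
  ann <- data.frame(
    probe_id = sprintf("b%05d", seq_len(n_hyper + n_hypo)),
    chrom = "chr1", pos = seq_len(n_hyper + n_hypo),
    region = "OpenSea", is_mir = FALSE, stringsAsFactors = FALSE)
  ann$classes <- rep(list("Body"), n_hyper + n_hypo)
  ann$genes <- rep(list("g"), n_hyper + n_hypo)
  res <- data.frame(probe_id = ann$probe_id,
                    direction = rep(c("hyper", "hypo"), c(n_hyper, n_hypo)),
                    stringsAsFactors = FALSE)
  ft <- crosstab_features(res, ann)
  expect_equal(ft["Body", "total"], 11832)
})

test_that("percentages normalize to 100 within rounding", {
  set.seed(83)
  fx <- expand_fixture("t1")
  keep <- sample(nrow(fx$results), 500)
  ct <- crosstab_region(fx$results[keep, ], fx$annotations)
  pct <- summarize_percentages(ct)
  expect_lt(abs(sum(pct$region_pct) - 100), 0.2 + 1e-9)
  expect_lt(abs(sum(pct$direction_pct) - 100), 0.1 + 1e-9)
  # single-cell table: 100% in that cell
  one <- crosstab_region(fx$results[1, , drop = FALSE], fx$annotations)
  expect_equal(sum(summarize_percentages(one)$region_pct == 100), 1)
  empty <- crosstab_region(fx$results[0, , drop = FALSE], fx$annotations)
  expect_error(summarize_percentages(empty), "no sites")
})

test_that("heat-map matrix is gene-grouped and carries fold changes", {
  ann <- data.frame(probe_id = c("p1", "p2", "p3"), chrom = "chr1",
                    pos = c(500L, 100L, 300L),
                    region = "Island", is_mir = TRUE,
                    stringsAsFactors = FALSE)
  ann$classes <- list("TSS200", "TSS200", "Body")
  ann$genes <- list("MIRB", "MIRA", "MIRB")
  ann$biotypes <- list("miR", "miR", "miR")
  sel <- data.frame(probe_id = c("p1", "p2", "p3"),
                    fold_change = c(16, -2.9, 2.5),
                    direction = c("hyper", "hypo", "hyper"),
                    stringsAsFactors = FALSE)
  hm <- export_heatmap_matrix(sel, ann)
  expect_equal(nrow(hm), 3)
  expect_equal(hm$genes, c("MIRA", "MIRB", "MIRB"))   # gene then position
  expect_equal(hm$pos, c(100L, 300L, 500L))
  expect_equal(hm$fold_change[hm$probe_id == "p1"], 16)
  # empty selection -> header-only file
  tf <- tempfile(fileext = ".tsv")
  export_heatmap_matrix(sel[0, ], ann, tf)
  expect_equal(length(readLines(tf)), 1)
})
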