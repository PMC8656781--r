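.REGION_GROUPS <- c("OpenSea", "Island", "Shelf", "Shore")
.DIRECTIONS <- c("hyper", "hypo")

# collapse the six neighborhood classes into the four table groups
.region_group <- function(region) {
  g <- sub("^[NS]_", "", region)
  if (any(!g %in% .REGION_GROUPS))
    stop("unknown region class: ",
         paste(unique(g[!g %in% .REGION_GROUPS]), collapse = ", "))
  g
}

#' Chromosome-by-neighborhood cross-tabulation of significant sites
#'
#' Counts significant sites (direction `hyper` or `hypo`) per chromosome,
#' neighborhood group and direction. North/south shores collapse into
#' `Shore` and shelves into `Shelf`, giving the four groups `OpenSea`,
#' `Island`, `Shelf`, `Shore`; every site is counted exactly once by its
#' single neighborhood class. `subset = "mir_only"` restricts to sites in
#' miR genes (`is_mir`). Sites without an annotation row are excluded and
#' listed in the `rejects` attribute.
#'
#' @param results Site-result table from [call_sites()] (or any data frame
#'   with `probe_id` and `direction`).
#' @param annotations Probe annotations from [annotate_probes()] (needs
#'   `probe_id`, `chrom`, `region`, `is_mir`).
#' @param subset `"all"` or `"mir_only"`.
#' @return Object of class `meth_crosstab`: list with `counts` (data frame,
#'   chromosome rows x group:direction columns), `col_totals`,
#'   `row_totals`, `grand`; attribute `rejects` holds unannotated probe
#'   ids.
#' @export
crosstab_region <- function(results, annotations,
                            subset = c("all", "mir_only")) {
  subset <- match.arg(subset)
  sig <- results[results$direction %in% .DIRECTIONS, , drop = FALSE]
  idx <- match(sig$probe_id, annotations$probe_id)
  rejects <- sig$probe_id[is.na(idx)]
  sig <- sig[!is.na(idx), , drop = FALSE]
  ann <- annotations[idx[!is.na(idx)], , drop = FALSE]
  if (subset == "mir_only") {
    keep <- ann$is_mir
    sig <- sig[keep, , drop = FALSE]
    ann <- ann[keep, , drop = FALSE]
  }
  chroms <- unique(annotations$chrom)
  cols <- as.vector(outer(.REGION_GROUPS, .DIRECTIONS, paste, sep = "_"))
  counts <- matrix(0L, length(chroms), length(cols),
                   dimnames = list(chroms, cols))
  if (nrow(sig)) {
    grp <- .region_group(ann$region)
    key <- paste(grp, sig$direction, sep = "_")
    tab <- table(factor(ann$chrom, levels = chroms),
                 factor(key, levels = cols))
    counts <- counts + unclass(tab)
  }
  out <- list(counts = as.data.frame.matrix(counts),
              col_totals = colSums(counts),
              row_totals = rowSums(counts),
              grand = sum(counts))
  class(out) <- "meth_crosstab"
  attr(out, "rejects") <- rejects
  out
}

#' @export
print.meth_crosstab <- function(x, ...) {
  cat("Significant sites by chromosome, neighborhood and direction\n")
  print(x$counts)
  cat("Column totals:\n"); print(x$col_totals)
  cat("Grand total:", x$grand, "\n")
  invisible(x)
}

#' Functional-region-by-direction tabulation of significant sites
#'
#' Counts unique significant sites per functional class and direction. A
#' site assigned to several genes increments each of its distinct classes
#' once; a site with no gene assignment counts as `Intergenic`.
#'
#' @inheritParams crosstab_region
#' @return Data frame with rows `TSS200`, `TSS1500`, `UTR5`, `FirstExon`,
#'   `UTR3`, `Body`, `Intergenic` and columns `hyper`, `hypo`, `total`.
#' @export
crosstab_features <- function(results, annotations) {
  sig <- results[results$direction %in% .DIRECTIONS, , drop = FALSE]
  idx <- match(sig$probe_id, annotations$probe_id)
  sig <- sig[!is.na(idx), , drop = FALSE]
  ann <- annotations[idx[!is.na(idx)], , drop = FALSE]
  classes <- c(.FUNCTIONAL_CLASSES, "Intergenic")
  counts <- matrix(0L, length(classes), 2L,
                   dimnames = list(classes, .DIRECTIONS))
  for (j in seq_len(nrow(sig))) {
    cl <- unique(ann$classes[[j]])
    if (length(cl) == 0) cl <- "Intergenic"
    counts[cl, sig$direction[j]] <- counts[cl, sig$direction[j]] + 1L
  }
  out <- as.data.frame.matrix(counts)
  out$total <- out$hyper + out$hypo
  out
}

# one-decimal half-up rounding, the convention used in reported percentages
.round1_half_up <- function(x) floor(x * 10 + 0.5) / 10

#' Percentage summary of a region cross-tabulation
#'
#' Expresses each neighborhood group, and each direction, as a percentage
#' of all significant sites, rounded to one decimal (half-up).
#'
#' @param crosstab A `meth_crosstab` from [crosstab_region()].
#' @return List with `region_pct` (named: OpenSea, Island, Shelf, Shore)
#'   and `direction_pct` (named: hyper, hypo).
#' @export
summarize_percentages <- function(crosstab) {
  if (crosstab$grand == 0) stop("cross-tabulation has no sites")
  ct <- crosstab$col_totals
  region <- vapply(.REGION_GROUPS, function(g)
    sum(ct[paste(g, .DIRECTIONS, sep = "_")]), numeric(1))
  direction <- vapply(.DIRECTIONS, function(d)
    sum(ct[paste(.REGION_GROUPS, d, sep = "_")]), numeric(1))
  list(region_pct = .round1_half_up(100 * region / crosstab$grand),
       direction_pct = .round1_half_up(100 * direction / crosstab$grand))
}

#' Export the site-by-fold-change matrix behind a methylation heat map
#'
#' One row per selected CpG site, labelled with the probe id and every
#' assigned miR gene (genes with overlapping reading frames are all
#' listed), with the signed fold change as the single value column. Rows
#' are ordered by (first) gene, then genomic position, so sites of one gene
#' group together.
#'
#' @param selected Site-result table (e.g. from
#'   [select_fold_candidates()]).
#' @param annotations Probe annotations from [annotate_probes()].
#' @param path Optional TSV output path.
#' @return Data frame `probe_id`, `genes`, `chrom`, `pos`, `fold_change`;
#'   written to `path` when given.
#' @export
export_heatmap_matrix <- function(selected, annotations, path = NULL) {
  idx <- match(selected$probe_id, annotations$probe_id)
  ann <- annotations[idx, , drop = FALSE]
  mir_labels <- vapply(seq_len(nrow(selected)), function(j) {
    g <- ann$genes[[j]]
    b <- ann$biotypes[[j]]
    mir <- if (!is.null(b)) g[b == "miR"] else character()
    paste(if (length(mir)) mir else g, collapse = ",")
  }, character(1))
  if (nrow(selected) == 0) mir_labels <- character()
  out <- data.frame(probe_id = selected$probe_id, genes = mir_labels,
                    chrom = ann$chrom, pos = ann$pos,
                    fold_change = selected$fold_change,
                    stringsAsFactors = FALSE)
  first_gene <- vapply(strsplit(out$genes, ",", fixed = TRUE), function(g)
    if (length(g)) g[1] else "", character(1))
  if (nrow(out)) out <- out[order(first_gene, out$pos), , drop = FALSE]
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
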