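#' Read pathway gene sets from a GMT file
#'
#' Thin wrapper over [fgsea::gmtPathways()] returning a named list of
#' character vectors.
#'
#' @param path GMT file path.
#' @return Named list of gene sets.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Hypergeometric over-representation analysis of one target set
#'
#' For each pathway, tests whether the overlap `k` between the target set
#' (size `n`) and the pathway (size `K`) within the gene universe (size
#' `N`) is larger than expected by chance, with the exact hypergeometric
#' upper tail `P[X >= k]`. P-values are Benjamini-Hochberg adjusted across
#' the pathways of this one target set. Target genes outside the universe
#' are dropped (their count is reported in the `n_dropped` attribute); the
#' default universe is the union of all pathway genes.
#'
#' @param target_set Character vector of gene identifiers (e.g. the
#'   predicted targets of one miR).
#' @param pathways Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Optional character vector overriding the default
#'   universe.
#' @return Data frame sorted by p-value: `pathway`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`.
#' @export
hypergeom_ora <- function(target_set, pathways, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(pathways))
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  if (any(lengths(pathways) == 0)) stop("empty pathway set")
  targets <- unique(target_set)
  n_dropped <- sum(!targets %in% universe)
  targets <- targets[targets %in% universe]
  n <- length(targets); N <- length(universe)
  rows <- lapply(names(pathways), function(pw) {
    genes <- unique(pathways[[pw]])
    genes <- genes[genes %in% universe]
    K <- length(genes)
    k <- sum(targets %in% genes)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, K = K, n = n, N = N,
               p_value = min(1, p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Pathway-per-miR and miR-per-pathway significance counts
#'
#' Given per-miR enrichment results, counts for every miR the number of
#' pathways significant at `alpha`, and for every pathway the number of
#' miRs significant for it. Both tables are sorted by decreasing count
#' with lexicographic tie-breaks. MiRs whose pathway count reaches
#' `broad_min` are flagged `broad` (regulators of a wide pathway swath).
#'
#' @param per_mir_results Named list: miR id -> result data frame from
#'   [hypergeom_ora()].
#' @param alpha Per-miR significance threshold on the raw p-value.
#'   Default 0.05.
#' @param broad_min Minimum pathway count for the `broad` flag.
#'   Default 11.
#' @return List of data frames `per_mir` (`mir`, `n_pathways`, `broad`)
#'   and `per_pathway` (`pathway`, `n_mirs`).
#' @export
pathway_mir_counts <- function(per_mir_results, alpha = 0.05,
                               broad_min = 11L) {
  mirs <- names(per_mir_results)
  n_path <- vapply(per_mir_results, function(res)
    sum(res$p_value < alpha), integer(1))
  per_mir <- data.frame(mir = mirs, n_pathways = unname(n_path),
                        stringsAsFactors = FALSE)
  per_mir$broad <- per_mir$n_pathways >= broad_min
  per_mir <- per_mir[order(-per_mir$n_pathways, per_mir$mir), , drop = FALSE]

  all_pw <- unique(unlist(lapply(per_mir_results, `[[`, "pathway")))
  n_mir <- vapply(all_pw, function(pw)
    sum(vapply(per_mir_results, function(res)
      any(res$pathway == pw & res$p_value < alpha), logical(1))),
    integer(1))
  per_pathway <- data.frame(pathway = all_pw, n_mirs = unname(n_mir),
                            stringsAsFactors = FALSE)
  per_pathway <- per_pathway[order(-per_pathway$n_mirs,
                                   per_pathway$pathway), , drop = FALSE]
  rownames(per_mir) <- rownames(per_pathway) <- NULL
  list(per_mir = per_mir, per_pathway = per_pathway)
}

#' Read a two-column miR-to-target map
#'
#' @param path TSV with columns `mir_id`, `gene_id` (header optional but
#'   recommended).
#' @return Named list: miR id -> character vector of target genes.
#' @export
read_target_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  split(tab[[2]], tab[[1]])
}
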