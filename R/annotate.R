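#' @name gene_models
#' @title Gene-model table format
#' @description
#' Gene models are plain data frames in 0-based half-open coordinates with
#' columns: `gene_id`, `chrom`, `start`, `end`, `strand` (`+`/`-`), `tss`
#' (base coordinate of the first transcribed base: `start` on `+`,
#' `end - 1` on `-`), `biotype` (`coding`, `noncoding`, `miR`), `exons`
#' (semicolon-separated `start-end` spans in transcription order),
#' `utr5_start`/`utr5_end` and `utr3_start`/`utr3_end` (NA when absent).
NULL

.FUNCTIONAL_CLASSES <- c("TSS200", "TSS1500", "UTR5", "FirstExon",
                         "UTR3", "Body")

.validate_gene_models <- function(gene_models) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "tss", "biotype")
  miss <- setdiff(need, names(gene_models))
  if (length(miss))
    stop("gene model table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(gene_models$end <= gene_models$start))
    stop("gene with end <= start: ",
         paste(gene_models$gene_id[gene_models$end <= gene_models$start],
               collapse = ", "))
  bad <- !gene_models$biotype %in% c("coding", "noncoding", "miR")
  if (any(bad))
    stop("unknown biotype: ",
         paste(unique(gene_models$biotype[bad]), collapse = ", "))
  invisible(gene_models)
}

.parse_exons <- function(exons) {
  if (is.na(exons) || !nzchar(exons)) return(NULL)
  parts <- strsplit(strsplit(exons, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p)
    data.frame(start = as.integer(p[1]), end = as.integer(p[2]))))
}

# functional class of position `pos` for one gene-model row, or NA if the
# position lies outside the gene and its 1500-bp promoter window
.classify_for_gene <- function(g, pos) {
  up <- if (g$strand == "+") g$tss - pos else pos - g$tss
  if (up >= 1) {
    if (up <= 200) return("TSS200")
    if (up <= 1500) return("TSS1500")
    return(NA_character_)
  }
  if (pos < g$start || pos >= g$end) return(NA_character_)
  if (!is.na(g$utr5_start) && pos >= g$utr5_start && pos < g$utr5_end)
    return("UTR5")
  ex <- .parse_exons(g$exons)
  if (!is.null(ex)) {
    first <- if (g$strand == "+") ex[which.min(ex$start), ]
             else ex[which.max(ex$end), ]
    if (pos >= first$start && pos < first$end) return("FirstExon")
  }
  if (!is.na(g$utr3_start) && pos >= g$utr3_start && pos < g$utr3_end)
    return("UTR3")
  "Body"
}

#' Assign functional gene regions to positions
#'
#' For every gene whose span (extended 1500 bp upstream of the TSS,
#' strand-aware) covers a position, exactly one functional class is
#' emitted with precedence
#' `TSS200 > TSS1500 > UTR5 > FirstExon > UTR3 > Body`:
#' upstream distance `u` (`u >= 1`) of at most 200 bp gives `TSS200`,
#' 200 < u <= 1500 gives `TSS1500`; positions inside the gene fall into the
#' annotated 5' UTR, first exon, 3' UTR or gene body. Positions covered by
#' no gene contribute no row.
#'
#' @param gene_models Gene-model data frame (see [gene_models]).
#' @param pos Integer vector of 0-based positions.
#' @param chrom Chromosome of the positions (single name) or a vector
#'   parallel to `pos`.
#' @return Data frame with columns `pos`, `chrom`, `gene_id`, `class`,
#'   `biotype`; zero rows when nothing maps.
#' @export
assign_functional_regions <- function(gene_models, pos, chrom = "chr1") {
  .validate_gene_models(gene_models)
  chrom <- rep_len(chrom, length(pos))
  rows <- vector("list", 0L)
  for (j in seq_along(pos)) {
    gm <- gene_models[gene_models$chrom == chrom[j], , drop = FALSE]
    for (i in seq_len(nrow(gm))) {
      cls <- .classify_for_gene(gm[i, ], pos[j])
      if (!is.na(cls))
        rows[[length(rows) + 1L]] <-
          data.frame(pos = pos[j], chrom = chrom[j],
                     gene_id = gm$gene_id[i], class = cls,
                     biotype = gm$biotype[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pos = integer(), chrom = character(),
                      gene_id = character(), class = character(),
                      biotype = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Classify the gene context of a set of per-gene assignments
#'
#' Returns `coding` when any assigned gene is protein-coding, otherwise
#' `noncoding` when any assigned gene is a non-coding RNA or miR gene,
#' otherwise `intergenic` (empty assignment set).
#'
#' @param assignments Data frame with columns `gene_id` and `biotype`
#'   (one row per assigned gene), e.g. from [assign_functional_regions()].
#' @return List with `context` (one of `coding`, `noncoding`, `intergenic`)
#'   and `gene_ids` (character vector of assigned genes).
#' @export
classify_gene_context <- function(assignments) {
  if (nrow(assignments) == 0)
    return(list(context = "intergenic", gene_ids = character()))
  bad <- !assignments$biotype %in% c("coding", "noncoding", "miR")
  if (any(bad)) stop("unknown biotype: ",
                     paste(unique(assignments$biotype[bad]), collapse = ", "))
  ctx <- if (any(assignments$biotype == "coding")) "coding" else "noncoding"
  list(context = ctx, gene_ids = unique(assignments$gene_id))
}

#' Annotate a probe manifest with neighborhood, gene region and context
#'
#' Joins the island-neighborhood classifier, the functional-region
#' assigner and the gene-context rule onto every probe of a manifest.
#' Probes on chromosomes absent from the island/gene tables are reported in
#' the `rejects` attribute, not silently dropped (their region falls back to
#' `OpenSea` and their context to `intergenic`).
#'
#' @param manifest Data frame with columns `probe_id`, `chrom`, `pos`.
#' @param islands Island table (per chromosome handled internally).
#' @param gene_models Gene-model data frame (see [gene_models]).
#' @param known_chroms Optional character vector of chromosomes present in
#'   the genome; probes outside it are listed in the rejects report.
#' @return Data frame with one row per probe: `probe_id`, `chrom`, `pos`,
#'   `region` (neighborhood class), `gene_context`, `is_mir`, `gene_ids`
#'   (comma-joined), plus list-columns `classes` and `genes` holding the
#'   per-gene functional assignments. Attribute `rejects` lists probes on
#'   unknown chromosomes.
#' @export
annotate_probes <- function(manifest, islands, gene_models,
                            known_chroms = NULL) {
  if (nrow(manifest) == 0) {
    out <- data.frame(probe_id = character(), chrom = character(),
                      pos = integer(), region = character(),
                      gene_context = character(), is_mir = logical(),
                      gene_ids = character(), stringsAsFactors = FALSE)
    out$classes <- list(); out$genes <- list(); out$biotypes <- list()
    attr(out, "rejects") <- character()
    return(out)
  }
  .validate_gene_models(gene_models)
  rejects <- if (is.null(known_chroms)) character()
             else manifest$probe_id[!manifest$chrom %in% known_chroms]

  region <- character(nrow(manifest))
  for (ch in unique(manifest$chrom)) {
    sel <- manifest$chrom == ch
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    region[sel] <- classify_neighborhood(isl, manifest$pos[sel])
  }

  asg <- assign_functional_regions(gene_models, manifest$pos, manifest$chrom)
  key <- paste(manifest$chrom, manifest$pos)
  akey <- paste(asg$chrom, asg$pos)

  ctx <- character(nrow(manifest)); is_mir <- logical(nrow(manifest))
  gene_ids <- character(nrow(manifest))
  classes <- vector("list", nrow(manifest))
  genes <- vector("list", nrow(manifest))
  biotypes <- vector("list", nrow(manifest))
  for (j in seq_len(nrow(manifest))) {
    a <- asg[akey == key[j], , drop = FALSE]
    cc <- classify_gene_context(a)
    ctx[j] <- cc$context
    is_mir[j] <- any(a$biotype == "miR")
    gene_ids[j] <- paste(cc$gene_ids, collapse = ",")
    classes[[j]] <- a$class
    genes[[j]] <- a$gene_id
    biotypes[[j]] <- a$biotype
  }
  out <- data.frame(probe_id = manifest$probe_id, chrom = manifest$chrom,
                    pos = manifest$pos, region = region, gene_context = ctx,
                    is_mir = is_mir, gene_ids = gene_ids,
                    stringsAsFactors = FALSE)
  out$classes <- classes
  out$genes <- genes
  out$biotypes <- biotypes
  attr(out, "rejects") <- rejects
  out
}
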