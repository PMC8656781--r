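#' Compute beta values from intensity matrices
#'
#' The methylation fraction at each probe/sample is the methylated signal
#' over the total locus signal, with a stabilizing offset in the
#' denominator: `beta = meth / (meth + unmeth + offset)`. With the default
#' offset of 100 (the conventional choice for array intensities on the
#' scale of hundreds to thousands) betas lie in `[0, 1)` and near-zero
#' totals are damped; offset 0 gives the literal ratio. Cells whose
#' denominator is exactly zero become `NA` and are counted in the
#' `n_missing` attribute.
#'
#' @param meth,unmeth Non-negative matrices with identical dimnames
#'   (probes x samples).
#' @param offset Non-negative scalar added to the denominator. Default 100.
#' @return Beta matrix with the same dimnames; attribute `n_missing` counts
#'   zero-denominator cells.
#' @export
compute_beta <- function(meth, unmeth, offset = 100) {
  if (offset < 0) stop("offset must be non-negative")
  if (!identical(dim(meth), dim(unmeth)) ||
      !identical(dimnames(meth), dimnames(unmeth)))
    stop("meth and unmeth must have identical dimensions and labels")
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stop("negative intensities")
  denom <- meth + unmeth + offset
  beta <- meth / denom
  zero <- denom == 0
  beta[zero] <- NA_real_
  attr(beta, "n_missing") <- sum(zero, na.rm = TRUE)
  beta
}

#' Filter probes by the standard exclusion rules
#'
#' Excludes, in order: probes on the X or Y chromosome (with or without a
#' `chr` prefix), probes with a common SNP within 5 bp of the targeted CpG
#' (`snp_within_5bp` flag), and probes that do not map uniquely to the
#' reference (`unique_mapping` flag false). Each excluded probe is
#' attributed to the first rule it trips, so the report counts sum with the
#' kept count to the input size. SNP and mapping evidence are consumed as
#' manifest flags; recomputing them needs external resources and is out of
#' scope here.
#'
#' @param manifest Data frame with columns `probe_id`, `chrom`,
#'   `snp_within_5bp`, `unique_mapping`.
#' @return List: `kept` (character vector of probe ids) and `report`
#'   (named counts `sex_chromosome`, `snp_within_5bp`, `non_unique_mapping`,
#'   `kept`).
#' @export
filter_probes <- function(manifest) {
  need <- c("probe_id", "chrom", "snp_within_5bp", "unique_mapping")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  sex <- sub("^chr", "", manifest$chrom, ignore.case = TRUE) %in%
    c("X", "Y", "x", "y")
  snp <- !sex & manifest$snp_within_5bp
  nonuniq <- !sex & !snp & !manifest$unique_mapping
  keep <- !(sex | snp | nonuniq)
  list(kept = manifest$probe_id[keep],
       report = c(sex_chromosome = sum(sex),
                  snp_within_5bp = sum(snp),
                  non_unique_mapping = sum(nonuniq),
                  kept = sum(keep)))
}
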