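#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic study generator.
#' The defaults emulate the design this package targets: 24 tumor/normal
#' pairs, beta-distributed methylation fractions with a low baseline at
#' island/promoter probes and a high baseline in open seas, and planted
#' hyper-/hypomethylation shifts of known direction.
#'
#' @param genome_length Genome size in bp.
#' @param n_islands Number of CpG islands to plant.
#' @param island_length Length of each planted island (bp, >= 200).
#' @param n_probes Number of probes in the generated manifest.
#' @param n_pairs Number of tumor/normal sample pairs.
#' @param n_true_hyper,n_true_hypo Number of probes carrying planted
#'   hyper-/hypomethylation effects.
#' @param effect_delta Beta-scale shift of planted effects, in (0, 1).
#' @param noise_kappa Concentration of the Beta noise (larger = less noise).
#' @param seed Integer seed; every artifact derives its RNG stream from it.
#' @param island_mean,opensea_mean Baseline normal-tissue beta means for
#'   island/promoter and open-sea probes.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 150000L, n_islands = 8L,
                       island_length = 600L, n_probes = 400L, n_pairs = 24L,
                       n_true_hyper = 0L, n_true_hypo = 0L,
                       effect_delta = 0.3, noise_kappa = 50, seed = 1L,
                       island_mean = 0.15, opensea_mean = 0.75) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_islands = as.integer(n_islands),
              island_length = as.integer(island_length),
              n_probes = as.integer(n_probes),
              n_pairs = as.integer(n_pairs),
              n_true_hyper = as.integer(n_true_hyper),
              n_true_hypo = as.integer(n_true_hypo),
              effect_delta = effect_delta, noise_kappa = noise_kappa,
              seed = as.integer(seed),
              island_mean = island_mean, opensea_mean = opensea_mean)
  if (cfg$n_true_hyper + cfg$n_true_hypo > cfg$n_probes)
    stop("n_true_hyper + n_true_hypo exceeds n_probes")
  if (cfg$effect_delta <= 0 || cfg$effect_delta >= 1)
    stop("effect_delta must lie in (0, 1)")
  if (cfg$n_islands > 0 &&
      cfg$genome_length < cfg$n_islands * (cfg$island_length + 8000L))
    stop("genome too short: need >= n_islands * (island_length + 8000) bp")
  if (cfg$island_length < 200L) stop("island_length must be >= 200")
  class(cfg) <- "sim_config"
  cfg
}

# run expr under a private RNG stream derived from (seed, stream); the
# caller's RNG state is untouched
.with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed * 131L + stream) %% .Machine$integer.max)
  force(expr)
}

# CpG-rich island sequence of exactly `len` bases: mostly CG dinucleotides
# with occasional A/T, re-sampled until every window passes the island
# criterion (truth labels are then correct by construction)
.make_island_seq <- function(len, window = 200L) {
  for (attempt in 1:25) {
    chunks <- character(0); n <- 0L
    while (n < len) {
      if (stats::runif(1) < 0.8) { chunks <- c(chunks, "CG"); n <- n + 2L }
      else { b <- sample(c("A", "T", "C"), 1); chunks <- c(chunks, b); n <- n + 1L }
    }
    s <- substr(paste(chunks, collapse = ""), 1L, len)
    if (.all_windows_qualify(s, window)) return(s)
  }
  stop("failed to synthesize a fully qualifying island sequence")
}

# CpG-depleted AT-rich background with no CG dinucleotide at all
.make_background_seq <- function(len) {
  b <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
              prob = c(0.42, 0.08, 0.08, 0.42))
  cg <- which(b[-len] == "C" & b[-1] == "G")
  while (length(cg)) {
    b[cg + 1L] <- "T"
    cg <- which(b[-len] == "C" & b[-1] == "G")
  }
  paste(b, collapse = "")
}

#' Generate a synthetic genome with planted CpG islands and gene models
#'
#' Plants `n_islands` non-overlapping CpG-rich segments, each at least
#' `island_length` bp and satisfying the island criterion (GC > 50%,
#' obs/exp CpG >= 0.6) in every 200-bp window, into a CpG-depleted AT-rich
#' background in which no window qualifies. Islands are separated by more
#' than 8 kb so open-sea positions exist. Gene models include coding,
#' non-coding and miR genes: each island hosts a gene whose promoter
#' (TSS200/TSS1500) and 5' end lie in the island, and additional genes sit
#' mid-gap in open-sea territory.
#'
#' @param config A [sim_config()].
#' @return List with `sequence` (character), `chrom` (name), `islands`
#'   (planted truth intervals, 0-based half-open) and `gene_models`
#'   (see [gene_models]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length; nI <- config$n_islands
  iw <- config$island_length
  gap <- if (nI > 0) (L - nI * iw) %/% (nI + 1L) else L
  if (nI > 0 && gap <= 8000L)
    stop("islands cannot be placed with > 8 kb separation; enlarge genome")

  .with_stream(config$seed, 1L, {
    starts <- if (nI > 0) gap + (0:(nI - 1L)) * (iw + gap) else integer()
    pieces <- character(0); cursor <- 0L
    for (s in starts) {
      pieces <- c(pieces, .make_background_seq(s - cursor),
                  .make_island_seq(iw))
      cursor <- s + iw
    }
    pieces <- c(pieces, .make_background_seq(L - cursor))
    sequence <- paste(pieces, collapse = "")

    islands <- data.frame(chrom = rep("chr1", length(starts)),
                          start = starts, end = starts + iw)

    gm <- list()
    biocycle <- c("coding", "coding", "miR", "noncoding")
    for (k in seq_len(nI)) {
      s <- starts[k]
      tss <- s + 100L                       # promoter inside the island
      glen <- 3000L
      gend <- min(tss + glen, L)
      gm[[length(gm) + 1L]] <- data.frame(
        gene_id = sprintf("GENE_ISL_%02d", k), chrom = "chr1",
        start = tss, end = gend, strand = "+", tss = tss,
        biotype = biocycle[(k - 1L) %% 4L + 1L],
        exons = sprintf("%d-%d;%d-%d", tss, tss + 300L,
                        tss + 1000L, tss + 1300L),
        utr5_start = tss, utr5_end = tss + 150L,
        utr3_start = gend - 200L, utr3_end = gend,
        stringsAsFactors = FALSE)
    }
    # open-sea genes at gap centers (> 4 kb from flanking islands)
    gap_centers <- if (nI > 0) c(starts, L) - gap %/% 2L else L %/% 2L
    for (k in seq_along(gap_centers)) {
      c0 <- gap_centers[k]
      glen <- 2000L
      s0 <- max(0L, c0 - glen %/% 2L); e0 <- s0 + glen
      bio <- if (k %% 3L == 0L) "miR" else "coding"
      gm[[length(gm) + 1L]] <- data.frame(
        gene_id = sprintf("GENE_SEA_%02d", k), chrom = "chr1",
        start = s0, end = e0, strand = "-", tss = e0 - 1L, biotype = bio,
        exons = sprintf("%d-%d", e0 - 400L, e0),
        utr5_start = NA_integer_, utr5_end = NA_integer_,
        utr3_start = NA_integer_, utr3_end = NA_integer_,
        stringsAsFactors = FALSE)
    }
    gene_models <- do.call(rbind, gm)
    list(sequence = sequence, chrom = "chr1", islands = islands,
         gene_models = gene_models)
  })
}

#' Generate a probe manifest on a synthetic genome
#'
#' Places probes at actual CpG sites of the genome, split between island
#' interiors and open-sea gene bodies / intergenic background, and attaches
#' the filter flags downstream preprocessing consumes (all clean by
#' default). The `island_probe` column records the baseline group used by
#' [generate_paired_betas()].
#'
#' @param genome Output of [simulate_genome()].
#' @param config The same [sim_config()].
#' @return Data frame: `probe_id`, `chrom`, `pos` (0-based C of the CpG),
#'   `snp_within_5bp`, `unique_mapping`, `island_probe`.
#' @export
simulate_manifest <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  s <- .as_base_vector(genome$sequence)
  cg_pos <- which(s[-length(s)] == "C" & s[-1] == "G") - 1L  # 0-based
  in_island <- rep(FALSE, length(cg_pos))
  for (k in seq_len(nrow(genome$islands)))
    in_island <- in_island | (cg_pos >= genome$islands$start[k] &
                              cg_pos < genome$islands$end[k])
  .with_stream(config$seed, 2L, {
    n_isl <- min(sum(in_island), config$n_probes %/% 2L)
    n_sea <- config$n_probes - n_isl
    isl_pool <- cg_pos[in_island]
    sea_pool <- cg_pos[!in_island]
    if (length(sea_pool) < n_sea) {
      # CpG-free background: fall back to arbitrary open-sea positions
      # > 4 kb from every island
      cand <- sort(sample.int(config$genome_length, 5L * n_sea) - 1L)
      cls <- classify_neighborhood(genome$islands, cand)
      sea_pool <- cand[cls == "OpenSea"]
    }
    pick <- function(x, k) x[sample.int(length(x), k)]  # safe for length 1
    pos <- sort(c(pick(isl_pool, n_isl),
                  pick(sea_pool, min(n_sea, length(sea_pool)))))
    data.frame(probe_id = sprintf("cg%08d", seq_along(pos)),
               chrom = genome$chrom, pos = pos,
               snp_within_5bp = FALSE, unique_mapping = TRUE,
               island_probe = pos %in% isl_pool,
               stringsAsFactors = FALSE)
  })
}

#' Generate paired tumor/normal beta matrices with planted effects
#'
#' Normal-sample betas are drawn per probe from a Beta distribution with a
#' two-component baseline mean (`island_mean` for island/promoter probes,
#' `opensea_mean` for open-sea probes) and concentration `noise_kappa`.
#' Tumor betas are drawn around the baseline shifted by `+effect_delta`
#' (planted hyper), `-effect_delta` (planted hypo) or 0 (null), with means
#' clipped to (0.001, 0.999); the number of clipped means is reported.
#' Hyper effects are planted preferentially on island probes and hypo
#' effects on open-sea probes, mirroring the island-hyper / open-sea-hypo
#' asymmetry of tumor methylomes.
#'
#' @param manifest Probe manifest (needs `probe_id` and, if present,
#'   `island_probe`; otherwise all probes use `opensea_mean`).
#' @param config A [sim_config()]; `n_true_hyper`/`n_true_hypo` probes get
#'   planted effects.
#' @return List: `tumor` and `normal` (probes x pairs matrices with
#'   dimnames), `pairing` (data frame tumor_id/normal_id), `truth` (data
#'   frame `probe_id`, `true_direction`, `true_effect`), `n_clipped`.
#' @export
generate_paired_betas <- function(manifest, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(manifest) == 0) stop("manifest is empty")
  if (config$n_pairs < 2) stop("need n_pairs >= 2")
  m <- nrow(manifest); n <- config$n_pairs
  island_probe <- if ("island_probe" %in% names(manifest))
    manifest$island_probe else rep(FALSE, m)

  .with_stream(config$seed, 3L, {
    dir <- rep("null", m)
    hyper_pool <- order(!island_probe)      # island probes first
    hypo_pool <- order(island_probe)        # open-sea probes first
    take_hyper <- utils::head(hyper_pool, config$n_true_hyper)
    take_hypo <- utils::head(setdiff(hypo_pool, take_hyper),
                             config$n_true_hypo)
    dir[take_hyper] <- "hyper"; dir[take_hypo] <- "hypo"

    mu0 <- ifelse(island_probe, config$island_mean, config$opensea_mean)
    shift <- ifelse(dir == "hyper", config$effect_delta,
                    ifelse(dir == "hypo", -config$effect_delta, 0))
    mu1_raw <- mu0 + shift
    mu1 <- pmin(pmax(mu1_raw, 0.001), 0.999)
    n_clipped <- sum(mu1 != mu1_raw)

    k <- config$noise_kappa
    rbeta_mu <- function(mu) {
      x <- stats::rbeta(length(mu), mu * k, (1 - mu) * k)
      pmin(pmax(x, 0.001), 0.999)
    }
    normal <- matrix(rbeta_mu(rep(mu0, n)), m, n)
    tumor <- matrix(rbeta_mu(rep(mu1, n)), m, n)
    rownames(normal) <- rownames(tumor) <- manifest$probe_id
    colnames(tumor) <- sprintf("tumor_%02d", seq_len(n))
    colnames(normal) <- sprintf("normal_%02d", seq_len(n))

    list(tumor = tumor, normal = normal,
         pairing = data.frame(tumor_id = colnames(tumor),
                              normal_id = colnames(normal),
                              stringsAsFactors = FALSE),
         truth = data.frame(probe_id = manifest$probe_id,
                            true_direction = dir, true_effect = shift,
                            stringsAsFactors = FALSE),
         n_clipped = n_clipped)
  })
}

#' Invert beta values into methylated/unmethylated intensity matrices
#'
#' Produces non-negative intensity matrices whose beta computation (with the
#' same `offset`) recovers the input betas to within 1e-9: for attainable
#' betas the total `meth + unmeth + offset` equals `total_intensity`;
#' betas too large to reach with that total at the given offset are realized
#' with `unmeth = 0` and an inflated methylated signal.
#'
#' @param betas Matrix of beta values in \[0, 1).
#' @param total_intensity Target total signal per cell (must exceed
#'   `offset`).
#' @param offset Offset used in the beta denominator.
#' @return List with matrices `meth` and `unmeth`.
#' @export
generate_intensities <- function(betas, total_intensity = 1000,
                                 offset = 100) {
  if (total_intensity <= offset)
    stop("total_intensity must exceed offset")
  if (any(betas < 0 | betas > 1)) stop("betas must lie in [0, 1]")
  if (any(betas >= 1 & offset > 0))
    stop("beta = 1 is not attainable with a positive offset")
  meth <- betas * total_intensity
  unmeth <- total_intensity - offset - meth
  # betas above (T - offset)/T: keep unmeth at 0, solve meth directly
  hi <- unmeth < 0
  if (any(hi)) {
    meth[hi] <- betas[hi] * offset / (1 - betas[hi])
    unmeth[hi] <- 0
  }
  dimnames(meth) <- dimnames(unmeth) <- dimnames(betas)
  list(meth = meth, unmeth = unmeth)
}

#' Run the full synthetic-study generator
#'
#' Convenience wrapper producing genome, manifest, paired betas and truth in
#' one call; a pure function of the configuration.
#'
#' @param config A [sim_config()].
#' @return List: `genome`, `manifest`, `betas` (see
#'   [generate_paired_betas()]).
#' @export
simulate_study <- function(config) {
  genome <- simulate_genome(config)
  manifest <- simulate_manifest(genome, config)
  betas <- generate_paired_betas(manifest, config)
  list(genome = genome, manifest = manifest, betas = betas)
}
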