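# Synthetic multi-omics cohort generator.
#
# Emulates the study design: four genotypes with graded H3K27me3 retention
# (wild type, a Suz12 gene-trap hypomorph, a Suz12 truncation, an Eed null)
# by two timepoints (day 0 ESC, day 5 spinal-motor-neuron-differentiated)
# with >= 2 RRBS replicates. PRC2-target promoters carry bivalent
# H3K4me3/H3K27me3 regions; mutants retain each wild-type H3K27me3 region
# independently with the genotype's retention fraction; CpGs in lost
# regions gain a planted methylation delta; expression change is coupled
# inversely to H3K27me3 change with a planted slope. Every planted label is
# recorded in truth tables so downstream stages can be scored.
#
# Each stage and sample draws from its own RNG stream keyed by
# (seed, label), so adding samples does not perturb existing ones and an
# identical configuration yields a bit-identical cohort.

#' Simulation configuration
#'
#' Defaults describe the emulated study: genotypes wt / Suz12GT / Suz12D /
#' Eednull with H3K27me3 retention fractions 1 / 0.5 / 0.02 / 0,
#' timepoints d0 and d5, two RRBS replicates, a planted methylation gain of
#' 15 percentage points at CpGs in lost regions, beta-binomial counts at
#' mean coverage 30 with dispersion 0.02, and an inverse
#' expression/H3K27me3 coupling with slope 0.5.
#'
#' @param seed Master seed (integer).
#' @param n_genes,n_prc2_targets Number of genes and of PRC2 target genes.
#' @param genome_length Simulated chromosome length in bp.
#' @param cpg_density CpGs per kb.
#' @param genotypes Named numeric vector of H3K27me3 retention fractions
#'   in \[0, 1\]; must contain `wt = 1`.
#' @param timepoints Timepoint labels (first = ESC day 0, second = day 5).
#' @param n_rrbs_replicates RRBS replicates per genotype x timepoint (>= 2).
#' @param meth_gain_delta Percentage points of methylation added at CpGs
#'   inside regions lost in a mutant.
#' @param meth_beta_dispersion Beta-binomial overdispersion (0 = binomial);
#'   the beta precision is `1 / dispersion`.
#' @param mean_coverage Mean reads per CpG (Poisson).
#' @param reads_per_sample ChIP library size per sample and mark.
#' @param expr_slope Planted slope of expression log2 fold change on
#'   (-1) x H3K27me3 log2 fold change at PRC2 targets.
#' @param expr_noise_sd Gaussian sd of expression noise (log2 scale).
#' @param derepression_lfc log2 expression increase in a mutant at genes
#'   whose H3K27me3 region is lost (0 plants methylation/expression
#'   independence).
#' @param frac_gain_k27,frac_lose_k27 Fractions of PRC2 targets gaining /
#'   losing H3K27me3 over differentiation in wild type.
#' @param background_read_frac Fraction of ChIP reads that are uniform
#'   background.
#' @param meth_low,meth_high Baseline methylation proportion inside /
#'   outside wild-type H3K27me3 regions.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 200, n_prc2_targets = 60,
                       genome_length = 2e6, cpg_density = 10,
                       genotypes = c(wt = 1.0, Suz12GT = 0.5,
                                     Suz12D = 0.02, Eednull = 0.0),
                       timepoints = c("d0", "d5"),
                       n_rrbs_replicates = 2,
                       meth_gain_delta = 15, meth_beta_dispersion = 0.02,
                       mean_coverage = 30, reads_per_sample = 2e5,
                       expr_slope = 0.5, expr_noise_sd = 0.3,
                       derepression_lfc = 1,
                       frac_gain_k27 = 0.2, frac_lose_k27 = 0.2,
                       background_read_frac = 0.3,
                       meth_low = 0.05, meth_high = 0.85) {
  cfg <- as.list(environment())
  if (is.null(names(genotypes)) || any(names(genotypes) == ""))
    .stopf("genotypes must be a named vector of retention fractions")
  if (any(genotypes < 0 | genotypes > 1))
    .stopf("retention fractions must lie in [0, 1]")
  if (n_prc2_targets > n_genes)
    .stopf("n_prc2_targets must not exceed n_genes")
  if (mean_coverage <= 0) .stopf("mean_coverage must be positive")
  if (n_rrbs_replicates < 2) .stopf("need at least 2 RRBS replicates")
  for (f in c("frac_gain_k27", "frac_lose_k27", "background_read_frac",
              "meth_low", "meth_high"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) .stopf("%s must lie in [0, 1]", f)
  if (frac_gain_k27 + frac_lose_k27 > 1)
    .stopf("frac_gain_k27 + frac_lose_k27 must not exceed 1")
  if (meth_gain_delta < 0 || meth_gain_delta > 100)
    .stopf("meth_gain_delta is in percentage points [0, 100]")
  if (length(timepoints) != 2) .stopf("exactly two timepoints expected")
  structure(cfg, class = "sim_config")
}

.gene_len_range <- c(2000L, 6000L)
.min_gap <- 200L

#' Simulate gene annotation and CpG positions
#'
#' Places non-overlapping gene bodies with random strand on a single
#' chromosome, designates PRC2 targets, and scatters CpGs at the requested
#' density with CpG-island-like clustering near PRC2-target TSSs (30% of
#' CpGs drawn from Gaussians of sd 500 bp around target TSSs).
#'
#' @param config A [sim_config()].
#' @return List `annotation` (data.frame `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `prc2_target`), `cpgs` (data.frame `chrom`, `pos`),
#'   `prc2_targets` (character).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- as.integer(config$genome_length)
  n <- config$n_genes
  if (n == 0) {
    ann <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), prc2_target = logical())
    return(list(annotation = ann,
                cpgs = data.frame(chrom = character(), pos = integer()),
                prc2_targets = character()))
  }
  set.seed(.sub_seed(config$seed, "genome"))
  len <- sample(seq(.gene_len_range[1], .gene_len_range[2]), n, replace = TRUE)
  if (sum(len) + (n + 1L) * .min_gap > L)
    .stopf("genome too small: %d genes (~%d bp + gaps) exceed %d bp",
           n, sum(len), L)
  slack <- L - sum(len) - (n + 1L) * .min_gap
  w <- stats::runif(n + 1L)
  gaps <- .min_gap + floor(w / sum(w) * slack)
  starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0L, len[-n]))
  ids <- sprintf("g%04d", seq_len(n))
  prc2 <- sort(sample(ids, config$n_prc2_targets))
  ann <- data.frame(gene_id = ids, chrom = "chr1",
                    start = as.integer(starts),
                    end = as.integer(starts + len),
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    prc2_target = ids %in% prc2)
  n_cpg <- round(L / 1000 * config$cpg_density)
  n_clust <- if (length(prc2)) round(0.3 * n_cpg) else 0L
  bg <- sample.int(L - 1L, n_cpg - n_clust, replace = TRUE) - 1L
  pos <- bg
  if (n_clust > 0) {
    tss <- gene_tss(ann[ann$prc2_target, , drop = FALSE])
    centers <- sample(tss, n_clust, replace = TRUE)
    cl <- round(centers + stats::rnorm(n_clust, sd = 500))
    pos <- c(bg, pmin(pmax(cl, 0), L - 2L))
  }
  cpgs <- data.frame(chrom = "chr1", pos = sort(unique(as.integer(pos))))
  list(annotation = ann, cpgs = cpgs, prc2_targets = prc2)
}

# per-gene wild-type mark weights and d5 dynamics class
.gene_truth <- function(genome, config) {
  ann <- genome$annotation
  n <- nrow(ann)
  set.seed(.sub_seed(config$seed, "chromatin_truth"))
  d5_class <- rep("non_target", n)
  ti <- which(ann$prc2_target)
  nt <- length(ti)
  cls <- rep("stable", nt)
  ng <- round(config$frac_gain_k27 * nt)
  nl <- round(config$frac_lose_k27 * nt)
  pick <- sample(nt)
  cls[pick[seq_len(ng)]] <- "gain"
  if (nl > 0) cls[pick[ng + seq_len(nl)]] <- "loss"
  d5_class[ti] <- cls
  # d5 gain weight 16: after reads-per-million renormalization against the
  # inflated d5 library, measured TSS ratios land near 5-6x, comfortably
  # over the 4-fold resolution threshold
  base_d5 <- c(gain = 16, loss = 0.25, stable = 1, non_target = 0)
  jitter <- 2^stats::rnorm(n, sd = 0.25)
  w27_d0 <- ifelse(ann$prc2_target, 1, 0)
  w27_d5 <- unname(base_d5[d5_class]) * ifelse(ann$prc2_target, jitter, 1)
  w4_d0 <- rep(1, n)  # all promoters active or poised; targets bivalent
  w4_d5 <- ifelse(d5_class == "gain", 0.3, ifelse(d5_class == "loss", 3, 1))
  data.frame(gene_id = ann$gene_id, prc2_target = ann$prc2_target,
             d5_class = d5_class, w27_d0 = w27_d0, w27_d5 = w27_d5,
             w4_d0 = w4_d0, w4_d5 = w4_d5)
}

#' Simulate ChIP enriched regions and mapped reads
#'
#' Wild-type PRC2 targets carry an H3K27me3 region over TSS +/- 2 kb and an
#' H3K4me3 region over TSS +/- 1 kb (bivalent promoters). Each mutant
#' genotype retains each wild-type H3K27me3 region independently with its
#' retention fraction (recorded in `region_truth`). At day 5, designated
#' target subsets gain or lose H3K27me3 (with the opposite H3K4me3 move,
#' planting resolution classes). Reads are single-base 5' positions:
#' a uniform background fraction plus in-region reads proportional to
#' region width x signal weight.
#'
#' @param genome Output of [simulate_genome()].
#' @param config The [sim_config()].
#' @return List `samples` (data.frame `sample`, `genotype`, `timepoint`),
#'   `regions` / `reads` (per sample label: list with `k27`, `k4`
#'   data.frames), `region_truth` (per genotype x target gene: `retained`,
#'   `status`), `gene_truth` (per-gene wild-type weights and d5 class).
#' @export
simulate_chromatin <- function(genome, config) {
  ann <- genome$annotation
  if (nrow(ann) == 0L) .stopf("annotation is empty")
  gt <- .gene_truth(genome, config)
  tss <- gene_tss(ann)
  L <- as.integer(config$genome_length)
  ti <- which(ann$prc2_target)
  k27_reg <- data.frame(gene_id = ann$gene_id[ti], chrom = ann$chrom[ti],
                        start = pmax(tss[ti] - 2000L, 0L),
                        end = pmin(tss[ti] + 2000L, L))
  k4_reg <- data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                       start = pmax(tss - 1000L, 0L),
                       end = pmin(tss + 1000L, L))
  genos <- names(config$genotypes)
  retained <- list()
  for (g in genos) {
    set.seed(.sub_seed(config$seed, paste0("retention_", g)))
    retained[[g]] <- stats::rbinom(nrow(k27_reg), 1L,
                                   config$genotypes[[g]]) == 1L
  }
  region_truth <- do.call(rbind, lapply(genos, function(g)
    data.frame(genotype = g, k27_reg[c("gene_id", "chrom", "start", "end")],
               retained = retained[[g]],
               status = ifelse(retained[[g]], "maintained", "lost"))))
  samples <- expand.grid(genotype = genos, timepoint = config$timepoints,
                         stringsAsFactors = FALSE)
  samples$sample <- paste(samples$genotype, samples$timepoint, sep = "_")
  regions <- list(); reads <- list()
  present_cut <- 0.3  # weight above which a region is emitted as a peak
  for (i in seq_len(nrow(samples))) {
    g <- samples$genotype[i]; tp <- samples$timepoint[i]
    d5 <- tp == config$timepoints[2]
    w27 <- (if (d5) gt$w27_d5 else gt$w27_d0)[ti] * retained[[g]]
    w4 <- if (d5) gt$w4_d5 else gt$w4_d0
    lab <- samples$sample[i]
    regions[[lab]] <- list(
      k27 = k27_reg[w27 > present_cut, c("chrom", "start", "end", "gene_id")],
      k4 = k4_reg[w4 > present_cut, c("chrom", "start", "end", "gene_id")])
    reads[[lab]] <- list(
      k27 = .sim_reads(k27_reg, w27, config, paste0("reads_", lab, "_k27"),
                       ref_width = sum(k27_reg$end - k27_reg$start)),
      k4 = .sim_reads(k4_reg, w4, config, paste0("reads_", lab, "_k4"),
                      ref_width = sum(k4_reg$end - k4_reg$start)))
  }
  list(samples = samples[c("sample", "genotype", "timepoint")],
       regions = regions, reads = reads,
       region_truth = region_truth, gene_truth = gt)
}

# Reads: a fixed uniform background plus per-region Poisson counts at a
# per-base rate anchored to the wild-type day-0 region set at weight 1, so
# planted weight ratios carry through to read-count ratios (library sizes
# then differ a little between samples, as they do in practice).
.sim_reads <- function(reg, weights, config, key, ref_width) {
  set.seed(.sub_seed(config$seed, key))
  n <- config$reads_per_sample
  L <- as.integer(config$genome_length)
  n_bg <- round(config$background_read_frac * n)
  pos <- sample.int(L, n_bg, replace = TRUE) - 1L
  if (nrow(reg) > 0 && ref_width > 0) {
    rate <- (1 - config$background_read_frac) * n / ref_width
    width <- reg$end - reg$start
    cnt <- stats::rpois(nrow(reg), rate * width * weights)
    for (r in which(cnt > 0)) {
      pos <- c(pos, reg$start[r] + sample.int(width[r], cnt[r],
                                              replace = TRUE) - 1L)
    }
  }
  data.frame(chrom = "chr1", pos = as.integer(pos))
}

#' Simulate RRBS methylation counts
#'
#' Each CpG gets a baseline methylation proportion: low (beta around
#' `meth_low`) inside wild-type H3K27me3 regions, high (beta around
#' `meth_high`) outside. In a mutant genotype, CpGs inside regions that
#' genotype lost get baseline + `meth_gain_delta` percentage points
#' (capped at 98%). Replicates share the true proportion of their
#' genotype x timepoint; counts are beta-binomial (precision
#' `1/meth_beta_dispersion`) at Poisson(`mean_coverage`) coverage.
#'
#' @param genome Output of [simulate_genome()].
#' @param chromatin Output of [simulate_chromatin()].
#' @param config The [sim_config()].
#' @return List `table` (a [meth_table()] with one sample per genotype x
#'   timepoint x replicate, labelled `geno_tp_rN`), `cpg_truth`
#'   (per CpG: `in_k27_region`, `region_gene`, plus `gains_meth_<geno>`
#'   flags), `samples` (sample sheet).
#' @export
simulate_methylation <- function(genome, chromatin, config) {
  cpgs <- genome$cpgs
  if (nrow(cpgs) == 0L) .stopf("no CpG positions defined")
  wt_reg <- chromatin$region_truth[
    chromatin$region_truth$genotype == "wt", , drop = FALSE]
  ov <- GenomicRanges::findOverlaps(.gr_points(cpgs), .gr_regions(wt_reg),
                                    select = "first")
  in_reg <- !is.na(ov)
  region_gene <- ifelse(in_reg, wt_reg$gene_id[ov], NA_character_)
  set.seed(.sub_seed(config$seed, "meth_baseline"))
  n <- nrow(cpgs)
  prec <- 40
  base <- ifelse(in_reg,
                 stats::rbeta(n, config$meth_low * prec,
                              (1 - config$meth_low) * prec),
                 stats::rbeta(n, config$meth_high * prec,
                              (1 - config$meth_high) * prec))
  genos <- names(config$genotypes)
  truth <- data.frame(chrom = cpgs$chrom, pos = cpgs$pos,
                      in_k27_region = in_reg, region_gene = region_gene,
                      baseline = base)
  m_geno <- list()
  for (g in genos) {
    rt <- chromatin$region_truth[chromatin$region_truth$genotype == g, ,
                                 drop = FALSE]
    lost_gene <- rt$gene_id[rt$status == "lost"]
    gains <- in_reg & region_gene %in% lost_gene
    m <- base + ifelse(gains, config$meth_gain_delta / 100, 0)
    m_geno[[g]] <- pmin(m, 0.98)
    truth[[paste0("gains_meth_", g)]] <- gains
  }
  s_prec <- if (config$meth_beta_dispersion > 0)
    1 / config$meth_beta_dispersion else Inf
  sample_rows <- list(); sheet <- list()
  for (g in genos) for (tp in config$timepoints)
    for (r in seq_len(config$n_rrbs_replicates)) {
      lab <- paste(g, tp, paste0("r", r), sep = "_")
      set.seed(.sub_seed(config$seed, paste0("meth_", lab)))
      cov <- stats::rpois(n, config$mean_coverage)
      m <- m_geno[[g]]
      p <- if (is.finite(s_prec))
        stats::rbeta(n, pmax(m, 1e-6) * s_prec, pmax(1 - m, 1e-6) * s_prec)
      else m
      meth <- stats::rbinom(n, cov, p)
      sample_rows[[lab]] <- data.frame(chrom = cpgs$chrom, pos = cpgs$pos,
                                       cov = cov, meth = meth)
      sheet[[lab]] <- data.frame(sample = lab, genotype = g, timepoint = tp,
                                 replicate = r)
    }
  list(table = meth_table(sample_rows), cpg_truth = truth,
       samples = do.call(rbind, sheet))
}

#' Simulate per-gene expression (FPKM)
#'
#' Baseline log2 FPKM is drawn per gene (PRC2 targets repressed, around 1
#' FPKM; other genes around 8 FPKM). At day 5 each gene's log2 FPKM moves
#' by `expr_slope` x (-(log2 H3K27me3 change)) for PRC2 targets (the
#' planted inverse relation) plus Gaussian noise; non-targets only get
#' noise. In a mutant, genes whose H3K27me3 region is lost are derepressed
#' by `derepression_lfc` at both timepoints.
#'
#' @param genome Output of [simulate_genome()].
#' @param chromatin Output of [simulate_chromatin()].
#' @param config The [sim_config()].
#' @return List `table` (data.frame `gene_id` + `fpkm.<geno>_<tp>`
#'   columns), `truth` (per gene x genotype: `k27_lfc_true`,
#'   `expr_lfc_true`, `derepressed`).
#' @export
simulate_expression <- function(genome, chromatin, config) {
  ann <- genome$annotation
  gt <- chromatin$gene_truth
  set.seed(.sub_seed(config$seed, "expression"))
  n <- nrow(ann)
  base <- ifelse(ann$prc2_target, stats::rnorm(n, 0, 1), stats::rnorm(n, 3, 1.5))
  eps <- 0.01
  out <- data.frame(gene_id = ann$gene_id)
  truth <- list()
  for (g in names(config$genotypes)) {
    rt <- chromatin$region_truth[chromatin$region_truth$genotype == g, ,
                                 drop = FALSE]
    ret <- stats::setNames(rt$retained, rt$gene_id)[ann$gene_id]
    ret[is.na(ret)] <- TRUE
    derep <- ann$prc2_target & !ret
    k27_lfc <- log2((gt$w27_d5 * ret + eps) / (gt$w27_d0 * ret + eps))
    delta <- ifelse(ann$prc2_target, -config$expr_slope * k27_lfc, 0)
    set.seed(.sub_seed(config$seed, paste0("expr_", g)))
    l0 <- base + config$derepression_lfc * derep +
      stats::rnorm(n, 0, config$expr_noise_sd)
    l5 <- base + config$derepression_lfc * derep + delta +
      stats::rnorm(n, 0, config$expr_noise_sd)
    out[[paste0("fpkm.", g, "_", config$timepoints[1])]] <- 2^l0
    out[[paste0("fpkm.", g, "_", config$timepoints[2])]] <- 2^l5
    truth[[g]] <- data.frame(gene_id = ann$gene_id, genotype = g,
                             k27_lfc_true = k27_lfc, expr_lfc_true = delta,
                             derepressed = derep)
  }
  list(table = out, truth = do.call(rbind, truth))
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_genome()], [simulate_chromatin()],
#' [simulate_methylation()] and [simulate_expression()] under one
#' configuration and bundles the results with all truth tables.
#'
#' @param config A [sim_config()].
#' @return List of class `prc_cohort`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  chromatin <- simulate_chromatin(genome, config)
  methylation <- simulate_methylation(genome, chromatin, config)
  expression <- simulate_expression(genome, chromatin, config)
  structure(list(config = config, annotation = genome$annotation,
                 cpgs = genome$cpgs, prc2_targets = genome$prc2_targets,
                 chromatin = chromatin, methylation = methylation,
                 expression = expression),
            class = "prc_cohort")
}
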