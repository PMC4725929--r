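#' Configuration for the synthetic three-library experiment
#'
#' Defaults describe the desk-scale stated world the package is validated
#' on: 2,000 genes carrying 1-3 transcript isoforms of 300-3,000 bp, three
#' unreplicated libraries (tolerant-ungrazed TU, tolerant-grazed TG,
#' intolerant-grazed IG) of 2e6 clean reads each, baseline expression
#' log-normal around 15 FPKM, planted log2 effects of +/-2 (twice the DE
#' calling threshold), ten suppressed-advantage and ten upregulated-advantage
#' candidate genes expressed at 500 FPKM (candidate transcripts in this kind
#' of study are abundantly expressed), three planted enriched terms per
#' ontology with 40% DEG membership against a ~10% background, and twenty
#' planted consistency-satisfying SNPs plus decoys covering every violation
#' class of the filter.
#'
#' @param seed Integer random seed.
#' @param n_genes Number of genes.
#' @param isoforms_range Min/max isoforms per gene (uniform).
#' @param length_range Min/max transcript length in bp (uniform).
#' @param lib_sizes Named clean-read totals for TU, TG, IG.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal baseline FPKM parameters.
#' @param frac_de_response,frac_de_tolerance Background fractions of genes
#'   with a planted effect in each contrast.
#' @param de_log2fc Magnitude of planted log2 effects.
#' @param n_suppressed,n_upregulated Planted candidate-pattern gene counts.
#' @param candidate_fpkm Baseline FPKM of planted candidate genes.
#' @param n_terms_go,n_terms_kegg Terms per ontology.
#' @param term_size_range Min/max genes per background term.
#' @param n_enriched_terms Planted dual-context enriched terms per ontology.
#' @param enriched_term_size Genes per planted term.
#' @param enriched_deg_frac Fraction of a planted term's genes given the
#'   dual-context DE signature.
#' @param enriched_min_fpkm Floor on baseline FPKM of planted-term DE genes.
#' @param n_snps Planted consistency-satisfying SNPs.
#' @param n_decoys Planted filter-violating positions (cycled over the
#'   violation classes).
#' @param coverage_range Min/max per-sample coverage at SNP positions.
#' @param error_rate Per-base sequencing error rate.
#' @param overdispersion Gamma over-dispersion of expected counts
#'   (0 = pure Poisson, the model's own null; default off).
#' @param phenotype List of two groups, each `list(mean, sd, n)`, defaults
#'   to the shoot-canopy-area contrast of the study's phenotype table.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       isoforms_range = c(1L, 3L),
                       length_range = c(300L, 3000L),
                       lib_sizes = c(TU = 2e6, TG = 2e6, IG = 2e6),
                       fpkm_meanlog = log(15),
                       fpkm_sdlog = 1,
                       frac_de_response = 0.08,
                       frac_de_tolerance = 0.08,
                       de_log2fc = 2,
                       n_suppressed = 10L,
                       n_upregulated = 10L,
                       candidate_fpkm = 500,
                       n_terms_go = 40L,
                       n_terms_kegg = 30L,
                       term_size_range = c(10L, 100L),
                       n_enriched_terms = 3L,
                       enriched_term_size = 100L,
                       enriched_deg_frac = 0.4,
                       enriched_min_fpkm = 50,
                       n_snps = 20L,
                       n_decoys = 12L,
                       coverage_range = c(20L, 60L),
                       error_rate = 0.01,
                       overdispersion = 0,
                       phenotype = list(
                         tolerant = list(mean = 9669.70, sd = 5890.62, n = 10L),
                         intolerant = list(mean = 602.60, sd = 249.45, n = 10L))) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes > 0, all(cfg$lib_sizes > 0),
            cfg$frac_de_response >= 0, cfg$frac_de_response <= 1,
            cfg$frac_de_tolerance >= 0, cfg$frac_de_tolerance <= 1,
            cfg$enriched_deg_frac >= 0, cfg$enriched_deg_frac <= 1,
            cfg$de_log2fc > 0, cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$overdispersion >= 0)
  if (cfg$n_suppressed + cfg$n_upregulated > cfg$n_genes)
    stop("infeasible config: more planted pattern genes than genes")
  if (cfg$enriched_term_size > cfg$n_genes ||
      cfg$term_size_range[2] > cfg$n_genes)
    stop("infeasible config: planted term larger than the gene universe")
  structure(cfg, class = "sim_config")
}

# random DNA sequence of length n
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# base-composition counts for one sample at one position.
# Heterozygous allele dosage is deterministic (the libraries are RNA bulks
# pooled over ten plants, so per-position dosage sits near expectation);
# sequencing errors are drawn stochastically.
genotype_counts <- function(genotype, coverage, error_rate) {
  bases <- c("A", "C", "G", "T")
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  alleles <- iupac_alleles(genotype)
  n_err <- stats::rbinom(1L, coverage, error_rate)
  err_bases <- setdiff(bases, alleles)
  if (n_err > 0) {
    err <- table(sample(err_bases, n_err, replace = TRUE))
    counts[names(err)] <- counts[names(err)] + as.numeric(err)
  }
  good <- coverage - n_err
  if (length(alleles) == 1L) {
    counts[alleles] <- counts[alleles] + good
  } else {
    half <- ceiling(good / 2)
    counts[alleles[1L]] <- counts[alleles[1L]] + half
    counts[alleles[2L]] <- counts[alleles[2L]] + good - half
  }
  counts
}

#' Simulate a full three-library grazing experiment with known truth
#'
#' Generates every input surface of the pipeline: a count table with Poisson
#' noise around FPKM-derived means, isoform groups, GO and KEGG annotation
#' maps with planted dual-context enriched terms, transcript sequences with
#' CDS coordinates, per-position base compositions with planted SNPs and
#' filter-violating decoys, and the ground-truth tables needed to score
#' recovery.  Effects are planted per gene as a multiplier chain
#' `FPKM_TU = g`, `FPKM_TG = g * 2^e_r`, `FPKM_IG = g * 2^(e_r + e_t)` so the
#' grazing-response contrast carries exactly `e_r` and the tolerance contrast
#' exactly `e_t`.  Expected counts are
#' `FPKM * length_kb * library_size / 1e6`; mapped counts stay well below the
#' configured clean-read totals.
#'
#' @param config A [sim_config()].
#' @return A `grazing_sim` list: `counts` ([count_table()]), `groups`
#'   (isoform grouping), `annotations` (list of [annotation_map()]s `GO`,
#'   `KEGG`), `transcripts` ([transcript_set()]), `basecomp`
#'   (base-composition data.frame), `truth` (list of data.frames
#'   `transcripts`, `genes`, `terms`, `snps`) and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(ng))

  ## --- gene effects -------------------------------------------------------
  e_r <- numeric(ng)   # log2 effect, TG vs TU
  e_t <- numeric(ng)   # log2 effect, IG vs TG
  base_fpkm <- stats::rlnorm(ng, config$fpkm_meanlog, config$fpkm_sdlog)
  E <- config$de_log2fc

  idx <- sample.int(ng, config$n_suppressed + config$n_upregulated)
  sup_genes <- idx[seq_len(config$n_suppressed)]
  up_genes <- setdiff(idx, sup_genes)
  e_r[sup_genes] <- -E; e_t[sup_genes] <- -E
  e_r[up_genes] <- E;  e_t[up_genes] <- -E
  base_fpkm[idx] <- config$candidate_fpkm

  ## --- annotation with planted enriched terms -----------------------------
  make_ontology <- function(n_terms, prefix, ontology) {
    term_ids <- sprintf(prefix, seq_len(n_terms))
    planted <- term_ids[seq_len(config$n_enriched_terms)]
    members <- lapply(term_ids, function(tid) {
      size <- if (tid %in% planted) config$enriched_term_size
              else sample(config$term_size_range[1]:config$term_size_range[2], 1L)
      sample(gene_ids, size)
    })
    names(members) <- term_ids
    # candidate-pattern genes belong to the planted terms (the study's
    # candidates were drawn from the selected pathways)
    for (tid in planted)
      members[[tid]] <- unique(c(members[[tid]], gene_ids[idx]))
    list(members = members, planted = planted)
  }
  go <- make_ontology(config$n_terms_go, "GO:%07d", "GO")
  kegg <- make_ontology(config$n_terms_kegg, "ko%05d", "KEGG")

  planted_term_genes <- setdiff(
    unique(unlist(c(go$members[go$planted], kegg$members[kegg$planted]))),
    gene_ids[idx])
  enriched_de <- sample(planted_term_genes,
                        round(config$enriched_deg_frac * length(planted_term_genes)))
  ei <- match(enriched_de, gene_ids)
  e_r[ei] <- E; e_t[ei] <- -E   # up by grazing in tolerant plants only
  base_fpkm[ei] <- pmax(base_fpkm[ei], config$enriched_min_fpkm)

  ## --- background DE ------------------------------------------------------
  free <- setdiff(seq_len(ng), c(idx, ei))
  bg_r <- sample(free, round(config$frac_de_response * length(free)))
  e_r[bg_r] <- E * sample(c(-1, 1), length(bg_r), replace = TRUE)
  bg_t <- sample(free, round(config$frac_de_tolerance * length(free)))
  e_t[bg_t] <- E * sample(c(-1, 1), length(bg_t), replace = TRUE)

  ## --- transcripts and counts --------------------------------------------
  n_iso <- sample(config$isoforms_range[1]:config$isoforms_range[2], ng,
                  replace = TRUE)
  gene_of_tx <- rep(seq_len(ng), n_iso)
  tx_ids <- paste0(gene_ids[gene_of_tx], ".t",
                   unlist(lapply(n_iso, seq_len)))
  len <- sample(config$length_range[1]:config$length_range[2],
                length(tx_ids), replace = TRUE)
  fpkm_TU <- base_fpkm[gene_of_tx]
  fpkm_TG <- fpkm_TU * 2^e_r[gene_of_tx]
  fpkm_IG <- fpkm_TU * 2^(e_r[gene_of_tx] + e_t[gene_of_tx])
  len_kb <- len / 1000
  mu <- cbind(TU = fpkm_TU * len_kb * config$lib_sizes[["TU"]] / 1e6,
              TG = fpkm_TG * len_kb * config$lib_sizes[["TG"]] / 1e6,
              IG = fpkm_IG * len_kb * config$lib_sizes[["IG"]] / 1e6)
  if (config$overdispersion > 0) {
    shape <- 1 / config$overdispersion
    mu <- mu * matrix(stats::rgamma(length(mu), shape = shape, rate = shape),
                      nrow = nrow(mu))
  }
  counts <- apply(mu, 2, function(m) stats::rpois(length(m), m))
  ct <- count_table(
    data.frame(transcript_id = tx_ids, length = len,
               TU = counts[, "TU"], TG = counts[, "TG"], IG = counts[, "IG"],
               stringsAsFactors = FALSE),
    config$lib_sizes)
  groups <- data.frame(transcript_id = tx_ids,
                       gene_id = gene_ids[gene_of_tx],
                       stringsAsFactors = FALSE)

  ## --- sequences with CDS -------------------------------------------------
  seqs <- vapply(len, random_dna, "")
  names(seqs) <- tx_ids
  utr5 <- sample(30:150, length(tx_ids), replace = TRUE)
  cds_len <- 3 * ((len - utr5 - 50) %/% 3)
  has_cds <- cds_len >= 90
  cds <- data.frame(transcript_id = tx_ids[has_cds],
                    cds_start = utr5[has_cds] + 1,
                    cds_end = utr5[has_cds] + cds_len[has_cds],
                    stringsAsFactors = FALSE)
  transcripts <- transcript_set(seqs, cds)

  ## --- SNP planting -------------------------------------------------------
  bases <- c("A", "C", "G", "T")
  decoy_classes <- c("tolerant_discordant", "all_het",
                     "low_coverage_tolerant", "all_reference")
  n_pos <- config$n_snps + config$n_decoys
  snp_tx <- sample(cds$transcript_id, n_pos, replace = n_pos > nrow(cds))
  snp_pos <- vapply(snp_tx, function(t) sample.int(nchar(seqs[[t]]), 1L), 0L)
  classes <- c(rep("consistent", config$n_snps),
               decoy_classes[(seq_len(config$n_decoys) - 1L) %% 4L + 1L])
  bc_rows <- list(); truth_rows <- list()
  cov_rng <- config$coverage_range
  for (i in seq_len(n_pos)) {
    tid <- snp_tx[i]; pos <- snp_pos[i]
    ref <- substr(seqs[[tid]], pos, pos)
    alt <- sample(setdiff(bases, ref), 1L)
    het <- unname(IUPAC2[paste(sort(c(ref, alt)), collapse = "")])
    geno <- switch(classes[i],
      consistent = c(TU = ref, TG = ref, IG = het),
      tolerant_discordant = c(TU = ref, TG = het, IG = het),
      all_het = c(TU = het, TG = het, IG = het),
      low_coverage_tolerant = c(TU = ref, TG = ref, IG = het),
      all_reference = c(TU = ref, TG = ref, IG = ref))
    cov <- sample(cov_rng[1]:cov_rng[2], 3L, replace = TRUE)
    names(cov) <- c("TU", "TG", "IG")
    if (classes[i] == "low_coverage_tolerant") cov[c("TU", "TG")] <- 2L
    for (s in c("TU", "TG", "IG")) {
      cc <- genotype_counts(geno[[s]], cov[[s]], config$error_rate)
      bc_rows[[length(bc_rows) + 1L]] <- data.frame(
        transcript_id = tid, pos = pos, sample = s,
        nA = cc[["A"]], nC = cc[["C"]], nG = cc[["G"]], nT = cc[["T"]],
        stringsAsFactors = FALSE)
    }
    truth_rows[[i]] <- data.frame(
      transcript_id = tid, pos = pos, class = classes[i],
      ref = ref, alt = alt,
      geno_TU = geno[["TU"]], geno_TG = geno[["TG"]], geno_IG = geno[["IG"]],
      expected_kept = classes[i] == "consistent",
      stringsAsFactors = FALSE)
  }
  empty_bc <- data.frame(transcript_id = character(), pos = numeric(),
                         sample = character(), nA = numeric(), nC = numeric(),
                         nG = numeric(), nT = numeric(),
                         stringsAsFactors = FALSE)
  empty_truth <- data.frame(transcript_id = character(), pos = numeric(),
                            class = character(), ref = character(),
                            alt = character(), geno_TU = character(),
                            geno_TG = character(), geno_IG = character(),
                            expected_kept = logical(),
                            stringsAsFactors = FALSE)
  basecomp <- if (length(bc_rows)) do.call(rbind, bc_rows) else empty_bc
  snp_truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else empty_truth

  ## --- truth tables -------------------------------------------------------
  gene_pattern <- ifelse(e_r < 0 & e_t < 0, "suppressed_tolerant_advantage",
                  ifelse(e_r > 0 & e_t < 0, "upregulated_tolerant_advantage",
                         "other"))
  truth <- list(
    transcripts = data.frame(
      transcript_id = tx_ids, gene_id = gene_ids[gene_of_tx],
      fpkm_TU = fpkm_TU, fpkm_TG = fpkm_TG, fpkm_IG = fpkm_IG,
      e_response = e_r[gene_of_tx], e_tolerance = e_t[gene_of_tx],
      stringsAsFactors = FALSE),
    genes = data.frame(
      gene_id = gene_ids, base_fpkm = base_fpkm,
      e_response = e_r, e_tolerance = e_t, pattern = gene_pattern,
      planted_candidate = seq_len(ng) %in% idx,
      stringsAsFactors = FALSE),
    terms = data.frame(
      term_id = c(names(go$members), names(kegg$members)),
      ontology = rep(c("GO", "KEGG"),
                     c(length(go$members), length(kegg$members))),
      planted = c(names(go$members) %in% go$planted,
                  names(kegg$members) %in% kegg$planted),
      stringsAsFactors = FALSE),
    snps = snp_truth
  )

  structure(list(
    counts = ct,
    groups = groups,
    annotations = list(
      GO = annotation_map(unlist(go$members, use.names = FALSE),
                          rep(names(go$members), lengths(go$members)), "GO"),
      KEGG = annotation_map(unlist(kegg$members, use.names = FALSE),
                            rep(names(kegg$members), lengths(kegg$members)),
                            "KEGG")),
    transcripts = transcripts,
    basecomp = basecomp,
    truth = truth,
    config = config
  ), class = "grazing_sim")
}

#' @export
print.grazing_sim <- function(x, ...) {
  cat("grazing_sim: seed", x$config$seed, "-", nrow(x$counts$counts),
      "transcripts /", x$config$n_genes, "genes, 3 libraries\n")
  cat("planted:", x$config$n_suppressed, "suppressed +",
      x$config$n_upregulated, "upregulated candidate genes,",
      x$config$n_enriched_terms, "enriched terms/ontology,",
      x$config$n_snps, "SNPs +", x$config$n_decoys, "decoys\n")
  invisible(x)
}

#' Simulate a two-group phenotype table
#'
#' Normal draws per group, emulating the study's trait measurements (two
#' populations of ten plants).
#'
#' @param groups List of two groups, each `list(mean, sd, n)`, named by
#'   group label.
#' @param seed Integer seed.
#' @return data.frame `label`, `value`; group parameters in attribute
#'   `"params"`.
#' @export
simulate_phenotypes <- function(groups, seed = 1L) {
  stopifnot(length(groups) == 2L)
  if (any(vapply(groups, `[[`, 0, "n") < 2)) stop("group n must be >= 2")
  set.seed(seed)
  out <- do.call(rbind, lapply(names(groups), function(lab) {
    g <- groups[[lab]]
    data.frame(label = lab, value = stats::rnorm(g$n, g$mean, g$sd),
               stringsAsFactors = FALSE)
  }))
  attr(out, "params") <- groups
  out
}

#' Run the full analysis pipeline on a simulated (or assembled) experiment
#'
#' Executes, in order: the exact DE test for the grazing-response contrast
#' (TG vs TU, baseline TU) and the tolerance contrast (IG vs TG, baseline
#' TG); gene-level DEG sets; GO and KEGG over-representation in both
#' contexts with dual-context selection; transcript profiles, gene pattern
#' calls and the candidate intersection against the selected KEGG pathways;
#' and the SNP stage.
#'
#' @param sim A `grazing_sim` (or a list with the same elements built from
#'   real inputs).
#' @param config Pipeline configuration, see [default_config()].
#' @return list with `de_response`, `de_tolerance`, `enrichment` (per
#'   ontology: `response`, `tolerance`, `selection`), `profiles`,
#'   `gene_calls`, `candidates`, `snps`.
#' @export
run_pipeline <- function(sim, config = default_config()) {
  th <- config$thresholds
  roles <- config$roles
  de_resp <- de_test(sim$counts, roles$tolerant_ungrazed,
                     roles$tolerant_grazed, fdr = th$fdr, lfc = th$lfc)
  de_tol <- de_test(sim$counts, roles$tolerant_grazed,
                    roles$intolerant_grazed, fdr = th$fdr, lfc = th$lfc)
  enr <- lapply(sim$annotations, function(ann) {
    resp <- enrich(ann, deg_genes(de_resp, sim$groups), "response")
    tol <- enrich(ann, deg_genes(de_tol, sim$groups), "tolerance")
    list(response = resp, tolerance = tol,
         selection = dual_context_select(resp, tol, alpha = th$alpha))
  })
  profiles <- build_profiles(de_resp, de_tol, sim$groups)
  gene_calls <- aggregate_gene(profiles)
  candidates <- intersect_candidates(gene_calls, enr$KEGG$selection,
                                     sim$annotations$KEGG)
  snp_cfg <- config$snp
  snps <- call_snps(sim$basecomp, roles, sim$transcripts,
                    min_frac = snp_cfg$min_frac, min_count = snp_cfg$min_count,
                    min_allele_count = snp_cfg$min_allele_count)
  list(de_response = de_resp, de_tolerance = de_tol, enrichment = enr,
       profiles = profiles, gene_calls = gene_calls, candidates = candidates,
       snps = snps)
}
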