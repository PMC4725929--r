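test_that("IUPAC consensus calling applies coverage and frequency thresholds", {
  expect_equal(iupac_call(base_counts(G = 10)), "G")
  expect_equal(iupac_call(base_counts(G = 6, T = 4)), "K")
  expect_equal(iupac_call(base_counts(G = 19, T = 1)), "G")  # below min_frac
  expect_equal(iupac_call(base_counts(G = 8, T = 1)), "G")   # below min count
  expect_true(is.na(iupac_call(base_counts(G = 2, T = 1)))) # coverage < 4
  # three strong alleles: drop the rarest
  expect_equal(iupac_call(base_counts(A = 10, C = 9, G = 5)), "M")
  # tie among the rarest when only two can stay: reject
  expect_true(is.na(iupac_call(base_counts(A = 10, C = 5, G = 5))))
  expect_error(iupac_call(c(A = 1, C = 1)), "named")
})

test_that("two-base IUPAC codes decode to exactly their two alleles", {
  codes <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")
  for (code in names(codes)) {
    expect_equal(sort(iupac_alleles(code)),
                 strsplit(codes[[code]], "")[[1]])
  }
  expect_equal(iupac_alleles("A"), "A")
  expect_error(iupac_alleles("N"), "unknown")
})

test_that("consistency filter keeps tolerant-monomorphic, intolerant-polymorphic sites", {
  # the published worked case: G/G in both tolerant libraries, K (G/T) in
  # the intolerant library -> kept with variant alleles G:T
  keep <- consistency_filter(c(tolerant_grazed = "G", tolerant_ungrazed = "G",
                               intolerant_grazed = "K"))
  expect_true(keep$keep)
  expect_equal(keep$variant, "G:T")

  reject_cases <- list(
    c(tolerant_grazed = "G", tolerant_ungrazed = "G", intolerant_grazed = "G"),
    c(tolerant_grazed = "R", tolerant_ungrazed = "G", intolerant_grazed = "A"),
    c(tolerant_grazed = "R", tolerant_ungrazed = "R", intolerant_grazed = "A"),
    c(tolerant_grazed = "G", tolerant_ungrazed = "G", intolerant_grazed = NA)
  )
  for (calls in reject_cases)
    expect_false(consistency_filter(calls)$keep)

  # intolerant with a different single base is polymorphic with respect to
  # the tolerant transcriptomes
  alt <- consistency_filter(c(tolerant_grazed = "G", tolerant_ungrazed = "G",
                              intolerant_grazed = "A"))
  expect_true(alt$keep)
  expect_equal(alt$variant, "G:A")
  expect_error(consistency_filter(c(a = "G")), "roles")
})

test_that("effect annotation locates the SNP and translates the codon", {
  #         123456789012345
  seq15 <- "GGGAATCCCTTTGGG"   # CDS 4..12: AAT CCC TTT -> Asn Pro Phe
  expect_equal(annotate_effect(seq15, 4, 12, 14, "G", "A"),
               list(region = "3'UTR", effect = "UTR"))
  expect_equal(annotate_effect(seq15, 4, 12, 2, "G", "A"),
               list(region = "5'UTR", effect = "UTR"))
  expect_equal(annotate_effect(seq15, NA, NA, 2, "G", "A"),
               list(region = "noncoding", effect = "noncoding"))
  # AAT -> AAC: both Asn
  expect_equal(annotate_effect(seq15, 4, 12, 6, "T", "C"),
               list(region = "CDS", effect = "synonymous"))
  # AAT -> ATT (Ile) and AGT (Ser), the dual-allele reporting format
  expect_equal(annotate_effect(seq15, 4, 12, 5, "A", c("T", "G")),
               list(region = "CDS", effect = "Asn->Ile (T); Asn->Ser (G)"))
  expect_error(annotate_effect(seq15, 4, 12, 5, "C", "T"), "mismatch")
})

test_that("codon-level effects agree with a full-CDS translation oracle", {
  set.seed(17)
  for (i in 1:200) {
    n_codons <- sample(4:40, 1)
    utr5 <- sample(0:9, 1); utr3 <- sample(0:9, 1)
    len <- utr5 + 3 * n_codons + utr3
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    cds_start <- utr5 + 1; cds_end <- utr5 + 3 * n_codons
    pos <- sample(cds_start:cds_end, 1)
    ref <- substr(s, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- annotate_effect(s, cds_start, cds_end, pos, ref, alt)
    want <- oracle_effect(s, cds_start, cds_end, pos, alt)
    expect_equal(got$region, "CDS")
    if (want == "synonymous") expect_equal(got$effect, "synonymous")
    else expect_match(got$effect, "->")
  }
})

test_that("call_snps reproduces calls, filter and annotation end to end", {
  seqs <- c(tx1 = "GGGAATCCCTTTGGG")
  ts <- transcript_set(seqs, data.frame(transcript_id = "tx1",
                                        cds_start = 4, cds_end = 12))
  bc <- rbind(
    data.frame(transcript_id = "tx1", pos = 14, sample = "s_tu",
               nA = 0, nC = 0, nG = 30, nT = 0),
    data.frame(transcript_id = "tx1", pos = 14, sample = "s_tg",
               nA = 0, nC = 0, nG = 28, nT = 0),
    data.frame(transcript_id = "tx1", pos = 14, sample = "s_ig",
               nA = 0, nC = 0, nG = 15, nT = 15),
    # decoy: all three libraries agree
    data.frame(transcript_id = "tx1", pos = 2, sample = c("s_tu", "s_tg", "s_ig"),
               nA = 0, nC = 0, nG = 20, nT = 0)
  )
  roles <- list(tolerant_ungrazed = "s_tu", tolerant_grazed = "s_tg",
                intolerant_grazed = "s_ig")
  rep <- call_snps(bc, roles, ts)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$pos, 14)
  expect_equal(rep$consensus, "G")
  expect_equal(rep$call_intolerant_grazed, "K")
  expect_equal(rep$variant, "G:T")
  expect_equal(rep$region, "3'UTR")
  all_rows <- call_snps(bc, roles, ts, keep_all = TRUE)
  expect_equal(nrow(all_rows), 2L)
  expect_equal(sum(all_rows$kept), 1L)
  expect_error(call_snps(bc, list(tolerant_ungrazed = "s_tu"), ts), "roles")
})

test_that("planted SNPs are all reported and every decoy class is rejected", {
  for (seed in c(31, 32, 33, 34)) {
    sim <- simulate_experiment(small_sim_config(seed = seed))
    rep <- call_snps(sim$basecomp,
                     list(tolerant_ungrazed = "TU", tolerant_grazed = "TG",
                          intolerant_grazed = "IG"),
                     sim$transcripts)
    truth <- sim$truth$snps
    got <- paste(rep$transcript_id, rep$pos)
    want <- paste(truth$transcript_id[truth$expected_kept],
                  truth$pos[truth$expected_kept])
    expect_setequal(got, want)
  }
})
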