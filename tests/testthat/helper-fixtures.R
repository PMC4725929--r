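# Small in-code fixtures shared across test files.

tiny_count_table <- function() {
  count_table(
    data.frame(
      transcript_id = c("t1", "t2", "t3"),
      length = c(1000L, 500L, 2000L),
      A = c(10L, 0L, 40L),
      B = c(20L, 5L, 0L),
      C = c(15L, 2L, 10L),
      stringsAsFactors = FALSE
    ),
    c(A = 1e6, B = 2e6, C = 1e6)
  )
}

# minimal transcript-profile rows for the pattern classifier
profile_row <- function(tu, tg, ig, de_r, de_t,
                        tid = "tx1", gene = "g1") {
  data.frame(
    transcript_id = tid, gene_id = gene,
    fpkm_TU = tu, fpkm_TG = tg, fpkm_IG = ig,
    de_response = de_r, lfc_response = log2_fold_change(tu, tg),
    de_tolerance = de_t, lfc_tolerance = log2_fold_change(tg, ig),
    stringsAsFactors = FALSE
  )
}

base_counts <- function(A = 0, C = 0, G = 0, T = 0) c(A = A, C = C, G = G, T = T)

# a fast, small simulation for tests that only need structure
small_sim_config <- function(seed = 1L) {
  sim_config(
    seed = seed, n_genes = 300L, n_suppressed = 4L, n_upregulated = 4L,
    n_terms_go = 12L, n_terms_kegg = 10L, n_enriched_terms = 2L,
    enriched_term_size = 40L, term_size_range = c(5L, 30L),
    n_snps = 6L, n_decoys = 8L
  )
}
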