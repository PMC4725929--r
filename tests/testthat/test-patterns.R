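test_that("transcript classification matches the three canonical shapes", {
  # suppressed by grazing, even lower in the grazed intolerant plants
  p1 <- profile_row(100, 40, 10, TRUE, TRUE)
  # upregulated by grazing, higher in tolerant than intolerant
  p2 <- profile_row(10, 50, 15, TRUE, TRUE)
  # intolerant higher: no tolerant advantage
  p3 <- profile_row(10, 50, 60, TRUE, TRUE)
  expect_equal(classify_transcript(rbind(p1, p2, p3)),
               c("suppressed_tolerant_advantage",
                 "upregulated_tolerant_advantage",
                 "other"))
  # non-DE transcripts are never candidates
  expect_equal(classify_transcript(profile_row(100, 40, 10, FALSE, TRUE)), "other")
  expect_equal(classify_transcript(profile_row(100, 40, 10, TRUE, FALSE)), "other")
  # every transcript maps to exactly one pattern
  set.seed(3)
  many <- do.call(rbind, lapply(1:50, function(i)
    profile_row(rlnorm(1, 3), rlnorm(1, 3), rlnorm(1, 3),
                sample(c(TRUE, FALSE), 1), sample(c(TRUE, FALSE), 1))))
  pats <- classify_transcript(many)
  expect_true(all(pats %in% c("suppressed_tolerant_advantage",
                              "upregulated_tolerant_advantage", "other")))
  bad <- profile_row(1, 2, 3, NA, TRUE)
  expect_error(classify_transcript(bad), "DE flags")
})

test_that("gene aggregation applies the consistency rule", {
  sup <- function(tid) profile_row(100, 40, 10, TRUE, TRUE, tid = tid)
  up <- function(tid) profile_row(10, 50, 15, TRUE, TRUE, tid = tid)
  oth <- function(tid) profile_row(10, 11, 12, FALSE, FALSE, tid = tid)

  g <- aggregate_gene(rbind(sup("a"), sup("b"), sup("c")))
  expect_equal(g$pattern, "suppressed_tolerant_advantage")
  expect_equal(g$n_supporting, 3L)
  expect_equal(g$n_transcripts, 3L)

  # an "other" isoform does not break consistency
  g2 <- aggregate_gene(rbind(up("a"), up("b"), oth("c")))
  expect_equal(g2$pattern, "upregulated_tolerant_advantage")
  expect_equal(g2$n_supporting, 2L)

  # directional conflict vetoes the gene
  g3 <- aggregate_gene(rbind(sup("a"), up("b")))
  expect_equal(g3$pattern, "other")
  expect_equal(g3$n_supporting, 0L)
})

test_that("candidate intersection keeps only genes annotated to selected terms", {
  calls <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    pattern = c("suppressed_tolerant_advantage",
                "upregulated_tolerant_advantage", "other"),
    n_transcripts = c(2L, 1L, 1L), n_supporting = c(2L, 1L, 0L),
    stringsAsFactors = FALSE
  )
  ann <- annotation_map(c("g1", "g2", "g3", "g1"),
                        c("sel", "unsel", "sel", "also_sel"))
  selection <- data.frame(
    term_id = c("sel", "also_sel", "unsel"),
    response_p = c(0.01, 0.01, 0.01),
    tolerance_p = c(0.01, 0.01, 0.9),
    selected = c(TRUE, TRUE, FALSE)
  )
  out <- intersect_candidates(calls, selection, ann)
  # g1: pattern + selected terms; g2: only unselected annotation; g3: no pattern
  expect_equal(out$gene_id, "g1")
  expect_equal(out$supporting_terms, "also_sel;sel")
  expect_error(intersect_candidates(calls, selection[0, ], ann), "empty")
})

test_that("pattern calls are invariant to rescaling FPKM by a constant", {
  sim <- simulate_experiment(small_sim_config(seed = 8))
  de_r <- de_test(sim$counts, "TU", "TG")
  de_t <- de_test(sim$counts, "TG", "IG")
  calls <- aggregate_gene(build_profiles(de_r, de_t, sim$groups))

  # halving lengths doubles every FPKM but leaves counts and totals alone,
  # so DE statistics and hence every pattern call must be unchanged
  ct2 <- sim$counts
  ct2$counts$length <- ct2$counts$length * 2L
  de_r2 <- de_test(ct2, "TU", "TG")
  de_t2 <- de_test(ct2, "TG", "IG")
  calls2 <- aggregate_gene(build_profiles(de_r2, de_t2, sim$groups))
  expect_equal(calls2, calls)
})

test_that("planted candidate genes are recovered with the right direction", {
  hits <- 0; genes <- 0; wrong <- 0
  for (seed in c(101, 202, 303)) {
    sim <- simulate_experiment(small_sim_config(seed = seed))
    de_r <- de_test(sim$counts, "TU", "TG")
    de_t <- de_test(sim$counts, "TG", "IG")
    calls <- aggregate_gene(build_profiles(de_r, de_t, sim$groups))
    truth <- sim$truth$genes
    planted <- truth[truth$planted_candidate, ]
    called <- calls$pattern[match(planted$gene_id, calls$gene_id)]
    hits <- hits + sum(called == planted$pattern)
    genes <- genes + nrow(planted)
    tp <- truth$pattern[match(calls$gene_id, truth$gene_id)]
    wrong <- wrong + sum(calls$pattern != "other" & tp != "other" &
                           calls$pattern != tp)
  }
  expect_gte(hits / genes, 0.9)
  expect_equal(wrong, 0)
})
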