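#' Build per-transcript expression profiles across the three transcriptomes
#'
#' Joins the two contrast-level DE tables into one profile per transcript:
#' FPKM in the tolerant-ungrazed (TU), tolerant-grazed (TG) and
#' intolerant-grazed (IG) libraries, plus DE flag and direction for the
#' grazing-response contrast (TG vs TU) and the tolerance contrast
#' (IG vs TG).
#'
#' @param de_response `de_result` for TG vs TU (baseline TU).
#' @param de_tolerance `de_result` for IG vs TG (baseline TG).
#' @param groups Isoform grouping data.frame (`transcript_id`, `gene_id`).
#' @return A `transcript_profiles` data.frame with columns `transcript_id`,
#'   `gene_id`, `fpkm_TU`, `fpkm_TG`, `fpkm_IG`, `de_response`,
#'   `lfc_response`, `de_tolerance`, `lfc_tolerance`.
#' @export
build_profiles <- function(de_response, de_tolerance, groups) {
  if (!setequal(de_response$transcript_id, de_tolerance$transcript_id))
    stop("the two DE tables cover different transcripts")
  i <- match(de_response$transcript_id, de_tolerance$transcript_id)
  gene <- groups$gene_id[match(de_response$transcript_id, groups$transcript_id)]
  if (anyNA(gene))
    stop("transcript(s) missing from the isoform grouping: ",
         de_response$transcript_id[which(is.na(gene))[1L]])
  structure(data.frame(
    transcript_id = de_response$transcript_id,
    gene_id = gene,
    fpkm_TU = de_response$fpkm_a,
    fpkm_TG = de_response$fpkm_b,
    fpkm_IG = de_tolerance$fpkm_b[i],
    de_response = de_response$is_de,
    lfc_response = de_response$log2fc,
    de_tolerance = de_tolerance$is_de[i],
    lfc_tolerance = de_tolerance$log2fc[i],
    stringsAsFactors = FALSE
  ), class = c("transcript_profiles", "data.frame"))
}

#' Classify transcripts into candidate expression patterns
#'
#' Two patterns of interest across the three transcriptomes:
#' * `suppressed_tolerant_advantage` — suppressed by grazing in the tolerant
#'   plants (DE down, TG vs TU) and expressed at an even lower level in the
#'   grazed intolerant plants (DE with IG < TG);
#' * `upregulated_tolerant_advantage` — upregulated by grazing in the
#'   tolerant plants (DE up, TG vs TU) and more strongly expressed in the
#'   tolerant than the intolerant grazed plants (DE with TG > IG).
#' Everything else is `other`.  Each transcript maps to exactly one pattern.
#'
#' @param profiles A `transcript_profiles` data.frame (see
#'   [build_profiles()]).
#' @return Character vector of patterns, one per row of `profiles`.
#' @export
classify_transcript <- function(profiles) {
  need <- c("de_response", "lfc_response", "de_tolerance", "lfc_tolerance")
  if (!all(need %in% names(profiles)) ||
      anyNA(profiles[need]))
    stop("profiles must carry evaluated DE flags for both contrasts")
  advantage <- profiles$de_tolerance & profiles$lfc_tolerance < 0  # IG < TG
  ifelse(profiles$de_response & profiles$lfc_response < 0 & advantage,
         "suppressed_tolerant_advantage",
         ifelse(profiles$de_response & profiles$lfc_response > 0 & advantage,
                "upregulated_tolerant_advantage", "other"))
}

#' Aggregate transcript patterns to gene-level candidate calls
#'
#' A gene receives a non-`other` pattern when at least one of its transcript
#' isoforms shows that pattern and no isoform shows the opposite non-`other`
#' pattern ("consistently"); `other` isoforms do not break consistency, a
#' directional conflict does.
#'
#' @param profiles A `transcript_profiles` data.frame.
#' @return data.frame `gene_id`, `pattern`, `n_transcripts`, `n_supporting`,
#'   one row per gene, ordered by `gene_id`.
#' @export
aggregate_gene <- function(profiles) {
  pat <- classify_transcript(profiles)
  split_pat <- split(pat, profiles$gene_id)
  calls <- vapply(split_pat, function(p) {
    sup <- sum(p == "suppressed_tolerant_advantage")
    up <- sum(p == "upregulated_tolerant_advantage")
    if (sup > 0 && up > 0) "other"
    else if (sup > 0) "suppressed_tolerant_advantage"
    else if (up > 0) "upregulated_tolerant_advantage"
    else "other"
  }, "")
  n_sup <- vapply(split_pat, function(p) {
    sup <- sum(p == "suppressed_tolerant_advantage")
    up <- sum(p == "upregulated_tolerant_advantage")
    if (sup > 0 && up > 0) 0L else max(sup, up)
  }, 0L)
  out <- data.frame(
    gene_id = names(split_pat),
    pattern = unname(calls),
    n_transcripts = unname(lengths(split_pat)),
    n_supporting = unname(n_sup),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Intersect candidate genes with dual-context selected terms
#'
#' Restricts gene-level candidate calls to genes annotated to at least one
#' term/pathway retained by [dual_context_select()], listing the supporting
#' terms.  This is the final candidate-gene table: a gene must both show a
#' tolerant-advantage expression pattern and belong to a grazing-responsive,
#' differentially regulated term.
#'
#' @param gene_calls Output of [aggregate_gene()].
#' @param selection Output of [dual_context_select()].
#' @param annotation The [annotation_map()] the selection was computed on.
#' @return data.frame `gene_id`, `pattern`, `n_transcripts`, `n_supporting`,
#'   `supporting_terms` (semicolon-joined), ordered by `gene_id`.  May have
#'   zero rows.
#' @export
intersect_candidates <- function(gene_calls, selection, annotation) {
  if (nrow(selection) == 0L) stop("empty selection")
  sel_terms <- selection$term_id[selection$selected]
  cand <- gene_calls[gene_calls$pattern != "other", , drop = FALSE]
  term_of_gene <- lapply(cand$gene_id, function(g) {
    sort(names(Filter(function(members) g %in% members,
                      annotation$terms[sel_terms])))
  })
  keep <- lengths(term_of_gene) > 0L
  out <- cand[keep, , drop = FALSE]
  out$supporting_terms <- vapply(term_of_gene[keep], paste, "", collapse = ";")
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Write a candidate-gene table
#' @param candidates Output of [intersect_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
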