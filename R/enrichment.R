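#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of seeing at least `m` annotated genes among the
#' differentially expressed genes:
#' `P = 1 - sum_{i=0}^{m-1} C(M, i) C(N - M, n - i) / C(N, n)`,
#' where `N` is the number of genes with any annotation in the ontology, `n`
#' the number of DEGs among them, `M` the genes annotated to the term and `m`
#' the DEGs annotated to the term.
#'
#' @param N,n,M,m Non-negative integers with `m <= min(n, M)`, `n <= N`,
#'   `M <= N` (vectorised in parallel).
#' @return p-values in (0, 1]; `m = 0` gives 1.
#' @export
hypergeom_p <- function(N, n, M, m) {
  bad <- m < 0 | n < 0 | M < 0 | N < 0 | m > pmin(n, M) | n > N | M > N
  if (any(bad)) stop("invalid enrichment input: need 0 <= m <= min(n, M), n <= N, M <= N")
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Bonferroni multiple-testing correction
#'
#' @param p p-values in (0, 1].
#' @param alpha Family-wise significance threshold (default 0.05).
#' @return data.frame with `p`, `corrected_p = min(1, k p)` for `k = length(p)`
#'   tests, and `significant = corrected_p <= alpha`.
#' @export
bonferroni_correct <- function(p, alpha = 0.05) {
  if (length(p) == 0L) stop("empty p-value list")
  if (any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  corrected <- pmin(1, length(p) * p)
  data.frame(p = p, corrected_p = corrected,
             significant = corrected <= alpha)
}

#' Term/pathway over-representation in a DEG set
#'
#' Counts, for every term of the annotation map, the number of annotated
#' genes (`M`) and annotated DEGs (`m`) against the ontology universe (`N`
#' genes with at least one annotation, of which `n` are DEGs), and computes
#' the hypergeometric upper-tail p-value plus Bonferroni-corrected p and BH
#' q-value across terms.  DEGs outside the universe are dropped (with a
#' message giving the count).  The unit is the gene (isoform group), not the
#' transcript.
#'
#' @param annotation An [annotation_map()].
#' @param deg_genes Character vector of differentially expressed gene ids.
#' @param contrast_label Label stored on the result (e.g. `"response"`).
#' @return An `enrichment_result` data.frame with columns `term_id`, `N`,
#'   `n`, `M`, `m`, `p`, `p_bonf`, `q`, ordered by `p` then `term_id`.
#' @export
enrich <- function(annotation, deg_genes, contrast_label = "contrast") {
  stopifnot(inherits(annotation, "annotation_map"))
  if (length(annotation$universe) == 0L) stop("empty annotation universe")
  deg <- unique(deg_genes)
  outside <- setdiff(deg, annotation$universe)
  if (length(outside))
    message(length(outside), " DEG(s) outside the ", annotation$ontology,
            " universe were dropped")
  deg <- intersect(deg, annotation$universe)
  N <- length(annotation$universe)
  n <- length(deg)
  M <- lengths(annotation$terms)
  m <- vapply(annotation$terms, function(g) length(intersect(g, deg)), 0L)
  res <- data.frame(
    term_id = names(annotation$terms),
    N = N, n = n, M = as.integer(M), m = as.integer(m),
    p = hypergeom_p(N, n, M, m),
    stringsAsFactors = FALSE
  )
  res$p_bonf <- pmin(1, nrow(res) * res$p)
  res$q <- bh_qvalues(res$p)
  res <- res[order(res$p, res$term_id), ]
  rownames(res) <- NULL
  attr(res, "ontology") <- annotation$ontology
  attr(res, "contrast") <- contrast_label
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result [", attr(x, "ontology"), ", ", attr(x, "contrast"),
      "]: ", nrow(x), " terms, universe ", x$N[1L], " genes, ", x$n[1L],
      " DEGs\n", sep = "")
  NextMethod()
}

#' Dual-context selection of enriched terms
#'
#' Retains terms that are significantly enriched both in the grazing-response
#' context (grazed vs ungrazed tolerant) and in the differential-tolerance
#' context (grazed intolerant vs grazed tolerant): `selected` iff both
#' p-values are `<= alpha`.  A term present in only one context receives
#' p = 1 for the missing context, with a warning.  Output is ordered by
#' tolerance p ascending, ties broken by `term_id`.
#'
#' @param response_results,tolerance_results `enrichment_result` objects for
#'   the two contexts over the same ontology.
#' @param alpha Significance threshold applied in both contexts (default
#'   0.05, inclusive).
#' @param p_column Which p-value column the threshold applies to:
#'   `"p_bonf"` (Bonferroni-corrected, default), `"p"` (raw) or `"q"` (BH).
#' @return data.frame `term_id`, `response_p`, `tolerance_p`, `selected`.
#' @export
dual_context_select <- function(response_results, tolerance_results,
                                alpha = 0.05,
                                p_column = c("p_bonf", "p", "q")) {
  p_column <- match.arg(p_column)
  ids <- union(response_results$term_id, tolerance_results$term_id)
  only <- c(setdiff(response_results$term_id, tolerance_results$term_id),
            setdiff(tolerance_results$term_id, response_results$term_id))
  if (length(only))
    warning("term(s) present in one context only (missing p set to 1): ",
            paste(only, collapse = ", "))
  rp <- response_results[[p_column]][match(ids, response_results$term_id)]
  tp <- tolerance_results[[p_column]][match(ids, tolerance_results$term_id)]
  rp[is.na(rp)] <- 1
  tp[is.na(tp)] <- 1
  out <- data.frame(term_id = ids, response_p = rp, tolerance_p = tp,
                    selected = rp <= alpha & tp <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$tolerance_p, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Write a dual-context enrichment report
#'
#' Machine-readable twin of the study's enriched-term tables: one row per
#' term with counts and p/q values for both contexts and the selection flag.
#'
#' @param response_results,tolerance_results `enrichment_result` objects.
#' @param selection Output of [dual_context_select()] on the same pair.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(response_results, tolerance_results,
                                    selection, path) {
  ids <- selection$term_id
  ri <- match(ids, response_results$term_id)
  ti <- match(ids, tolerance_results$term_id)
  out <- data.frame(
    term_id = ids,
    N = response_results$N[ri], n = response_results$n[ri],
    M = response_results$M[ri], m = response_results$m[ri],
    response_p = response_results$p_bonf[ri],
    response_q = response_results$q[ri],
    tolerance_p = tolerance_results$p_bonf[ti],
    tolerance_q = tolerance_results$q[ti],
    selected = selection$selected
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene-level DEG set from a transcript-level DE table
#'
#' A gene counts as differentially expressed for a contrast when at least one
#' of its transcripts is DE; this avoids inflating enrichment counts with
#' isoform multiplicity.
#'
#' @param de A `de_result` (see [de_test()]).
#' @param groups Isoform grouping data.frame (`transcript_id`, `gene_id`).
#' @return Character vector of DEG gene ids.
#' @export
deg_genes <- function(de, groups) {
  tx <- de$transcript_id[de$is_de]
  sort(unique(groups$gene_id[match(tx, groups$transcript_id)]))
}
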