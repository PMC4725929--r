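# two-base IUPAC ambiguity codes, keyed by the sorted allele pair
IUPAC2 <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")
IUPAC2_ALLELES <- strsplit(names(IUPAC2), "")
names(IUPAC2_ALLELES) <- unname(IUPAC2)

# one-letter -> three-letter amino acid names; stop codons reported as "X"
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "X")

#' Decode an IUPAC nucleotide code into its alleles
#'
#' @param code Single-character code from `{A,C,G,T,R,Y,S,W,K,M}`.
#' @return Character vector of one or two bases.
#' @export
iupac_alleles <- function(code) {
  if (code %in% c("A", "C", "G", "T")) return(code)
  if (code %in% names(IUPAC2_ALLELES)) return(IUPAC2_ALLELES[[code]])
  stop("unknown IUPAC code: ", code)
}

#' IUPAC consensus call for one sample at one position
#'
#' Calls the genotype of one library at one transcript position from its
#' base composition.  Alleles must reach both a minimum fraction of the
#' coverage and a minimum absolute count to be retained; one retained allele
#' yields that base, two yield the corresponding two-base ambiguity code.
#' With more than two retained alleles the rarest are dropped one at a time;
#' a tie at the dropping step rejects the position.  The study names no
#' SNP caller, so these thresholds are declared package defaults.
#'
#' @param counts Named numeric vector with elements `A`, `C`, `G`, `T`.
#' @param min_frac Minimum allele frequency (default 0.2).
#' @param min_count Minimum total coverage to attempt a call (default 4).
#' @param min_allele_count Minimum reads supporting a retained allele
#'   (default 2).
#' @return A single IUPAC code, or `NA_character_` for no call.
#' @export
iupac_call <- function(counts, min_frac = 0.2, min_count = 4,
                       min_allele_count = 2) {
  counts <- counts[c("A", "C", "G", "T")]
  if (anyNA(counts) || any(counts < 0)) stop("counts must be named non-negative values for A, C, G, T")
  total <- sum(counts)
  if (total < min_count) return(NA_character_)
  kept <- counts[counts / total >= min_frac & counts >= min_allele_count]
  while (length(kept) > 2L) {
    lo <- min(kept)
    if (sum(kept == lo) > 1L && length(kept) - sum(kept == lo) < 2L)
      return(NA_character_)  # tie among the rarest: ambiguous, reject
    kept <- kept[-which.min(kept)]
  }
  if (length(kept) == 0L) return(NA_character_)
  if (length(kept) == 1L) return(names(kept))
  unname(IUPAC2[paste(sort(names(kept)), collapse = "")])
}

#' Tolerance-consistency filter for one SNP position
#'
#' Implements the reporting rule of the study's SNP tables: a SNP is kept
#' when the transcriptomes of the grazed and ungrazed tolerant plants are
#' monomorphic (identical single-base calls) while the grazed intolerant
#' transcriptome is polymorphic with respect to them (a different single
#' base, or any ambiguity code).  A missing call at any role rejects the
#' position.
#'
#' @param calls Named character vector of IUPAC calls with names
#'   `tolerant_grazed`, `tolerant_ungrazed`, `intolerant_grazed`
#'   (`NA` = no call).
#' @return list with `keep` (logical), `ref` (the shared tolerant base or
#'   `NA`), `alt` (character vector of intolerant-specific alleles) and
#'   `variant` (string `"ref:alt"`, comma-joining multiple alts).
#' @export
consistency_filter <- function(calls) {
  roles <- c("tolerant_grazed", "tolerant_ungrazed", "intolerant_grazed")
  if (!all(roles %in% names(calls)))
    stop("calls must be named by the roles: ", paste(roles, collapse = ", "))
  tg <- calls[["tolerant_grazed"]]
  tu <- calls[["tolerant_ungrazed"]]
  ig <- calls[["intolerant_grazed"]]
  rej <- list(keep = FALSE, ref = NA_character_, alt = character(),
              variant = NA_character_)
  if (anyNA(c(tg, tu, ig))) return(rej)
  if (tg != tu || !(tg %in% c("A", "C", "G", "T"))) return(rej)
  ig_alleles <- iupac_alleles(ig)
  alt <- setdiff(ig_alleles, tg)
  if (length(alt) == 0L) return(rej)  # intolerant identical to tolerant
  list(keep = TRUE, ref = tg, alt = alt,
       variant = paste0(tg, ":", paste(alt, collapse = ",")))
}

#' Locate a SNP and annotate its coding effect
#'
#' Positions are 1-based from the transcript 5' end.  Positions before the
#' CDS are `5'UTR`, after it `3'UTR`, and transcripts without a CDS are
#' `noncoding`.  Inside the CDS the affected codon is translated with each
#' alternative allele under the standard genetic code: an unchanged amino
#' acid is `synonymous`, otherwise the effect lists per-allele
#' `From->To (allele)` substitutions (three-letter amino acid names, stop
#' as `X`), semicolon-joined.
#'
#' @param sequence Transcript sequence (single character string, sense
#'   strand).
#' @param cds_start,cds_end 1-based inclusive CDS bounds, or `NA` for no CDS.
#' @param pos 1-based SNP position.
#' @param ref_base Reference base expected at `pos`; a mismatch with the
#'   sequence is a data-inconsistency error.
#' @param alt_bases Character vector of alternative alleles.
#' @return list with `region` (`"5'UTR"`, `"CDS"`, `"3'UTR"` or
#'   `"noncoding"`) and `effect` (`"synonymous"`, a substitution string,
#'   `"UTR"` or `"noncoding"`).
#' @export
annotate_effect <- function(sequence, cds_start, cds_end, pos, ref_base,
                            alt_bases) {
  sequence <- toupper(sequence)
  if (pos < 1 || pos > nchar(sequence)) stop("pos outside the sequence")
  if (substr(sequence, pos, pos) != ref_base)
    stop("reference base mismatch at position ", pos, ": sequence has ",
         substr(sequence, pos, pos), ", expected ", ref_base)
  if (is.na(cds_start) || is.na(cds_end))
    return(list(region = "noncoding", effect = "noncoding"))
  if (pos < cds_start) return(list(region = "5'UTR", effect = "UTR"))
  if (pos > cds_end) return(list(region = "3'UTR", effect = "UTR"))
  offset <- pos - cds_start              # 0-based offset into the CDS
  codon_start <- cds_start + 3 * (offset %/% 3)
  within <- offset %% 3 + 1              # position inside the codon, 1..3
  codon <- substr(sequence, codon_start, codon_start + 2)
  aa_from <- Biostrings::GENETIC_CODE[[codon]]
  changes <- vapply(alt_bases, function(alt) {
    alt_codon <- codon
    substr(alt_codon, within, within) <- alt
    Biostrings::GENETIC_CODE[[alt_codon]]
  }, "")
  if (all(changes == aa_from))
    return(list(region = "CDS", effect = "synonymous"))
  eff <- paste0(AA3[[aa_from]], "->", unname(AA3[changes]),
                " (", alt_bases, ")")
  # a mix of synonymous and nonsynonymous alts is reported by its
  # nonsynonymous substitutions only
  eff <- eff[changes != aa_from]
  list(region = "CDS", effect = paste(eff, collapse = "; "))
}

#' Call, filter and annotate SNPs from base compositions
#'
#' Runs the full SNP stage: per-sample IUPAC consensus calls at every
#' position of the base-composition table, the tolerance-consistency filter,
#' and region/amino-acid-effect annotation against the transcript sequences.
#' The consensus base reported per position is the majority allele of the
#' pooled (all-sample) base counts, ties broken alphabetically.
#'
#' @param basecomp Base-composition data.frame (see
#'   [read_base_composition()]).
#' @param roles Named list/vector mapping the roles `tolerant_ungrazed`,
#'   `tolerant_grazed`, `intolerant_grazed` to sample names used in
#'   `basecomp`.
#' @param transcripts A [transcript_set()] supplying sequences and CDS
#'   intervals.
#' @param min_frac,min_count,min_allele_count Calling thresholds, see
#'   [iupac_call()].
#' @param keep_all If `TRUE`, also return positions that failed the filter
#'   (`kept = FALSE` rows).
#' @return A `snp_report` data.frame with columns `transcript_id`, `pos`,
#'   `consensus`, one IUPAC call column per role (`call_<role>`), `variant`,
#'   `region`, `effect`, `kept`.
#' @export
call_snps <- function(basecomp, roles, transcripts,
                      min_frac = 0.2, min_count = 4, min_allele_count = 2,
                      keep_all = FALSE) {
  stopifnot(inherits(transcripts, "transcript_set"))
  roles <- unlist(roles)
  need <- c("tolerant_ungrazed", "tolerant_grazed", "intolerant_grazed")
  if (!all(need %in% names(roles)))
    stop("roles must map: ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(basecomp$sample), roles)
  if (length(unknown))
    stop("sample(s) in base composition not mapped to a role: ",
         paste(unknown, collapse = ", "))

  key <- paste(basecomp$transcript_id, basecomp$pos)
  rows <- lapply(split(seq_len(nrow(basecomp)), key), function(idx) {
    sub <- basecomp[idx, ]
    tid <- sub$transcript_id[1L]
    pos <- sub$pos[1L]
    calls <- vapply(need, function(role) {
      i <- which(sub$sample == roles[[role]])
      if (length(i) == 0L) return(NA_character_)
      cc <- c(A = sub$nA[i], C = sub$nC[i], G = sub$nG[i], T = sub$nT[i])
      iupac_call(cc, min_frac, min_count, min_allele_count)
    }, "")
    pooled <- c(A = sum(sub$nA), C = sum(sub$nC), G = sum(sub$nG), T = sum(sub$nT))
    consensus <- names(pooled)[which.max(pooled)]
    flt <- consistency_filter(calls)
    region <- NA_character_; effect <- NA_character_
    if (flt$keep) {
      seq_i <- match(tid, names(transcripts$seqs))
      if (is.na(seq_i)) stop("no sequence for transcript ", tid)
      cds <- transcripts$cds[match(tid, transcripts$cds$transcript_id), ]
      ann <- annotate_effect(transcripts$seqs[[seq_i]], cds$cds_start,
                             cds$cds_end, pos, flt$ref, flt$alt)
      region <- ann$region; effect <- ann$effect
    }
    data.frame(transcript_id = tid, pos = pos, consensus = consensus,
               call_tolerant_ungrazed = calls[["tolerant_ungrazed"]],
               call_tolerant_grazed = calls[["tolerant_grazed"]],
               call_intolerant_grazed = calls[["intolerant_grazed"]],
               variant = flt$variant, region = region, effect = effect,
               kept = flt$keep, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$pos), ]
  rownames(out) <- NULL
  if (!keep_all) out <- out[out$kept, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_report", "data.frame")
  out
}

#' Write a SNP report
#' @param report A `snp_report` from [call_snps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
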