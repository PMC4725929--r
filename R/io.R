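#' Read a per-transcript count table
#'
#' The count table is a tab-separated UTF-8 file with one header line naming
#' the columns `transcript_id`, `length` and then one column per sample, plus
#' a single `#totals` line (anywhere after the header) carrying the
#' library-level clean-read totals for each sample in header order.  Totals
#' are supplied explicitly rather than inferred by summation because the
#' library total is the number of *clean* reads, which normally exceeds the
#' number of reads mapped to assembled transcripts.
#'
#' @param path Path to the tab-separated count file.
#' @return A `count_table` object: a list with elements `counts` (data.frame
#'   with `transcript_id`, `length` and one integer column per sample),
#'   `totals` (named numeric vector of clean-read totals) and `sample_ids`.
#' @seealso [write_count_table()], [count_table()]
#' @export
read_count_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  totals_line <- grep("^#totals\t", lines)
  if (length(totals_line) != 1L)
    stop("count table must contain exactly one '#totals' line: ", path)
  body <- lines[-totals_line]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "transcript_id" || header[2L] != "length")
    stop("count table header must be 'transcript_id\\tlength\\t<samples...>'")
  samples <- header[-(1:2)]
  tot <- strsplit(lines[totals_line], "\t", fixed = TRUE)[[1L]][-1L]
  if (length(tot) != length(samples))
    stop("#totals line must carry one total per sample column")
  totals <- as.numeric(tot)
  names(totals) <- samples

  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    stop("malformed count line ", bad[1L] + 1L, ": wrong number of fields")
  mat <- do.call(rbind, rows)
  counts <- data.frame(
    transcript_id = mat[, 1L],
    length = suppressWarnings(as.numeric(mat[, 2L])),
    stringsAsFactors = FALSE
  )
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(mat[, j + 2L]))
    counts[[samples[j]]] <- v
  }
  count_table(counts, totals)
}

#' Construct and validate a count table
#'
#' @param counts data.frame with columns `transcript_id`, `length`, then one
#'   non-negative integer count column per sample.
#' @param totals Named numeric vector of per-library clean-read totals; names
#'   must match the sample columns of `counts`.
#' @return A validated `count_table` object.
#' @export
count_table <- function(counts, totals) {
  stopifnot(is.data.frame(counts), all(c("transcript_id", "length") %in% names(counts)))
  samples <- setdiff(names(counts), c("transcript_id", "length"))
  if (length(samples) == 0L) stop("count table has no sample columns")
  if (!all(samples %in% names(totals)))
    stop("missing library total for sample(s): ",
         paste(setdiff(samples, names(totals)), collapse = ", "))
  totals <- totals[samples]
  dup <- counts$transcript_id[duplicated(counts$transcript_id)]
  if (length(dup))
    stop("duplicated transcript_id: ", paste(unique(dup), collapse = ", "))
  if (anyNA(counts$length) || any(counts$length <= 0) ||
      any(counts$length != round(counts$length)))
    stop("transcript lengths must be positive integers")
  for (s in samples) {
    v <- counts[[s]]
    if (anyNA(v) || any(v < 0) || any(v != round(v)))
      stop("counts for sample '", s, "' must be non-negative integers")
  }
  if (anyNA(totals) || any(totals <= 0))
    stop("library totals must be positive")
  structure(
    list(counts = counts, totals = totals, sample_ids = samples),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "transcripts,",
      length(x$sample_ids), "samples\n")
  cat("samples:", paste(x$sample_ids, collapse = ", "), "\n")
  cat("clean-read totals:", paste(format(x$totals, big.mark = ","), collapse = ", "), "\n")
  invisible(x)
}

#' Write a count table
#'
#' Inverse of [read_count_table()]; `read_count_table(write_count_table(x, p))`
#' reproduces `x`.
#'
#' @param x A `count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  header <- paste(c("transcript_id", "length", x$sample_ids), collapse = "\t")
  totals <- paste(c("#totals", format(x$totals, scientific = FALSE, trim = TRUE)),
                  collapse = "\t")
  body <- do.call(paste, c(unname(as.list(
    data.frame(x$counts$transcript_id,
               format(x$counts$length, scientific = FALSE, trim = TRUE),
               lapply(x$counts[x$sample_ids],
                      function(v) format(v, scientific = FALSE, trim = TRUE)),
               stringsAsFactors = FALSE))), sep = "\t"))
  writeLines(c(header, totals, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene-to-term annotation map
#'
#' Expects a two-column tab-separated file `gene_id<TAB>term_id` with a single
#' header line; repeated (gene, term) pairs collapse to set semantics.  The
#' annotation universe is the set of distinct genes carrying at least one term
#' in this ontology.
#'
#' @param path Path to the annotation file.
#' @param ontology Label for the ontology (e.g. `"GO"` or `"KEGG"`).
#' @return An `annotation_map`: list with `ontology`, `terms` (named list of
#'   character vectors of gene ids) and `universe` (character vector).
#' @export
read_annotation <- function(path, ontology = "GO") {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("annotation file is empty: ", path)
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("malformed annotation line ", bad[1L] + 1L, " in ", path)
  gene <- vapply(fields, `[[`, "", 1L)
  term <- vapply(fields, `[[`, "", 2L)
  annotation_map(gene, term, ontology)
}

#' Construct an annotation map from paired gene/term vectors
#'
#' @param gene_id,term_id Character vectors of equal length.
#' @inheritParams read_annotation
#' @return An `annotation_map`.
#' @export
annotation_map <- function(gene_id, term_id, ontology = "GO") {
  stopifnot(length(gene_id) == length(term_id), length(gene_id) > 0L)
  terms <- lapply(split(gene_id, term_id), function(g) sort(unique(g)))
  terms <- terms[order(names(terms))]
  structure(
    list(ontology = ontology, terms = terms,
         universe = sort(unique(gene_id))),
    class = "annotation_map"
  )
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map [", x$ontology, "]: ", length(x$terms), " terms, ",
      length(x$universe), " annotated genes\n", sep = "")
  invisible(x)
}

#' Write an annotation map
#'
#' @param x An `annotation_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(x, path) {
  stopifnot(inherits(x, "annotation_map"))
  gene <- unlist(x$terms, use.names = FALSE)
  term <- rep(names(x$terms), lengths(x$terms))
  writeLines(c("gene_id\tterm_id", paste(gene, term, sep = "\t")), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read transcript-to-gene isoform grouping
#'
#' @param path Two-column tab-separated file `transcript_id<TAB>gene_id` with
#'   a header line.
#' @return data.frame with columns `transcript_id`, `gene_id`.
#' @export
read_isoform_groups <- function(path) {
  g <- utils::read.delim(path, colClasses = "character")
  if (!identical(names(g), c("transcript_id", "gene_id")))
    stop("isoform group file must have columns transcript_id, gene_id")
  if (anyDuplicated(g$transcript_id))
    stop("transcript mapped to more than one gene: ",
         g$transcript_id[duplicated(g$transcript_id)][1L])
  g
}

#' Write transcript-to-gene isoform grouping
#' @param groups data.frame with columns `transcript_id`, `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isoform_groups <- function(groups, path) {
  utils::write.table(groups[c("transcript_id", "gene_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript sequences with CDS coordinates
#'
#' Sequences come from a FASTA file; coding-region coordinates come from a
#' tab-separated table with columns `transcript_id`, `cds_start`, `cds_end`
#' (1-based inclusive on the transcript 5'->3' strand).  Transcripts absent
#' from the CDS table are retained without a CDS and treated as noncoding.
#'
#' @param fasta_path Path to the FASTA file.
#' @param cds_table_path Path to the CDS coordinate table.
#' @return A `transcript_set`: list with `seqs` (upper-cased character vector
#'   named by transcript id) and `cds` (data.frame `transcript_id`,
#'   `cds_start`, `cds_end`, `NA` for transcripts without a CDS).
#' @export
read_fasta_with_cds <- function(fasta_path, cds_table_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  seqs <- toupper(as.character(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  cds <- utils::read.delim(cds_table_path, colClasses = c("character", "numeric", "numeric"))
  if (!identical(names(cds), c("transcript_id", "cds_start", "cds_end")))
    stop("CDS table must have columns transcript_id, cds_start, cds_end")
  transcript_set(seqs, cds)
}

#' Construct a transcript set from sequences and a CDS table
#'
#' @param seqs Named character vector of transcript sequences.
#' @param cds data.frame with `transcript_id`, `cds_start`, `cds_end`; may
#'   omit transcripts (they become noncoding).
#' @return A validated `transcript_set`.
#' @export
transcript_set <- function(seqs, cds) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  seqs <- toupper(seqs)
  missing_seq <- setdiff(cds$transcript_id, names(seqs))
  if (length(missing_seq))
    stop("CDS table names transcripts absent from FASTA: ",
         paste(missing_seq, collapse = ", "))
  for (i in seq_len(nrow(cds))) {
    len <- nchar(seqs[[cds$transcript_id[i]]])
    s <- cds$cds_start[i]; e <- cds$cds_end[i]
    if (is.na(s) || is.na(e) || s < 1 || s > e || e > len)
      stop("CDS out of bounds for ", cds$transcript_id[i])
    if ((e - s + 1) %% 3 != 0)
      stop("CDS length not divisible by 3 for ", cds$transcript_id[i])
  }
  full <- data.frame(transcript_id = names(seqs), stringsAsFactors = FALSE)
  full <- merge(full, cds, by = "transcript_id", all.x = TRUE, sort = FALSE)
  full <- full[match(names(seqs), full$transcript_id), ]
  rownames(full) <- NULL
  structure(list(seqs = seqs, cds = full), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", length(x$seqs), "sequences,",
      sum(!is.na(x$cds$cds_start)), "with a CDS\n")
  invisible(x)
}

#' Write a transcript set to FASTA + CDS table
#' @param x A `transcript_set`.
#' @param fasta_path,cds_table_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_fasta_with_cds <- function(x, fasta_path, cds_table_path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$seqs), fasta_path)
  cds <- x$cds[!is.na(x$cds$cds_start), ]
  utils::write.table(cds, cds_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta_path)
}

#' Read a per-position base-composition table
#'
#' Long-format tab-separated table with header columns `transcript_id`,
#' `pos`, `sample`, `nA`, `nC`, `nG`, `nT`: the number of reads supporting
#' each nucleotide at a 1-based transcript position in one library.
#'
#' @param path Path to the table.
#' @return data.frame with those columns.
#' @export
read_base_composition <- function(path) {
  bc <- utils::read.delim(path, colClasses = c("character", "numeric", "character",
                                               rep("numeric", 4)))
  need <- c("transcript_id", "pos", "sample", "nA", "nC", "nG", "nT")
  if (!identical(names(bc), need))
    stop("base composition table must have columns ", paste(need, collapse = ", "))
  if (any(bc$pos < 1) || any(bc[c("nA", "nC", "nG", "nT")] < 0))
    stop("invalid base composition values")
  bc
}

#' Write a base-composition table
#' @param bc data.frame as returned by [read_base_composition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_base_composition <- function(bc, path) {
  utils::write.table(bc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a pipeline configuration
#'
#' The configuration is a JSON object with nested sections, e.g. `thresholds`
#' (`fdr`, `lfc`, `alpha`), `roles` (mapping of sample names to the roles
#' `tolerant_ungrazed`, `tolerant_grazed`, `intolerant_grazed`) and `seed`.
#'
#' @param path Path to the JSON configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_config
#' @param config Named list to serialise.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Thresholds follow the study design: differential expression is called at
#' FDR <= 0.001 and |log2 fold change| >= 1; enrichment significance at
#' alpha = 0.05 in both contexts.
#'
#' @param seed Integer seed echoed into outputs for provenance.
#' @return Named list understood by the pipeline runners and the CLI.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    thresholds = list(fdr = 0.001, lfc = 1, alpha = 0.05),
    roles = list(tolerant_ungrazed = "TU", tolerant_grazed = "TG",
                 intolerant_grazed = "IG"),
    snp = list(min_count = 4, min_frac = 0.2, min_allele_count = 2)
  )
}
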