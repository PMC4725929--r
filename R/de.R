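#' FPKM from a raw count
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `count / ((length_bp/1000) * (total_reads/1e6))`.  Single-end reads are
#' counted as fragments.
#'
#' @param count Non-negative read count (vectorised).
#' @param length_bp Transcript length in base pairs, > 0.
#' @param total_reads Library clean-read total, > 0.
#' @return Numeric FPKM values.
#' @export
compute_fpkm <- function(count, length_bp, total_reads) {
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count / ((length_bp / 1000) * (total_reads / 1e6))
}

#' Log2 fold change between two FPKM values
#'
#' Zero FPKM values are replaced by 0.01 before taking the ratio, so a
#' transcript absent from one library still yields a finite fold change.
#' Antisymmetric under swapping the two samples.
#'
#' @param fpkm_a Baseline-sample FPKM (vectorised).
#' @param fpkm_b Treatment-sample FPKM.
#' @param zero_sub Substitution value for zero FPKM (default 0.01).
#' @return `log2(fpkm_b' / fpkm_a')` after zero substitution.
#' @export
log2_fold_change <- function(fpkm_a, fpkm_b, zero_sub = 0.01) {
  if (any(fpkm_a < 0) || any(fpkm_b < 0)) stop("FPKM values must be >= 0")
  a <- ifelse(fpkm_a == 0, zero_sub, fpkm_a)
  b <- ifelse(fpkm_b == 0, zero_sub, fpkm_b)
  log2(b / a)
}

# log pmf of the conditional distribution of the second count given the
# first: P(Y = y | x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1)).
# Computed entirely through log-gamma so counts up to ~1e6 are safe.
ac_log_pmf <- function(y, x, N1, N2) {
  r <- N2 / N1
  y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
}

#' Conditional Poisson probability of a count pair
#'
#' Exact null distribution for comparing one transcript's counts in two
#' unreplicated libraries: conditional on observing `x` reads in library 1
#' (total `N1` clean reads), the count `Y` in library 2 (total `N2`) follows
#' `P(Y = y | x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))` under the
#' null hypothesis of no differential expression.
#'
#' @param y Observed count in library 2 (vectorised over `y`).
#' @param x Observed count in library 1.
#' @param N1,N2 Library clean-read totals, > 0.
#' @return `P(Y = y | x)`.
#' @export
ac_pmf <- function(y, x, N1, N2) {
  stopifnot(N1 > 0, N2 > 0)
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  exp(ac_log_pmf(y, x, N1, N2))
}

# log(sum(exp(lx))) without overflow
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# Both tails of the conditional distribution, summing the shorter side in
# log space.  Returns c(lower = P(Y <= y), upper = P(Y > y)); the strict
# upper tail equals P(X <= x | y) in the swapped conditioning direction,
# which is what makes the two-sided rule exactly symmetric.
ac_tails <- function(x, y, N1, N2) {
  r <- N2 / N1
  centre <- r * (x + 1)  # mean of the conditional distribution
  if (y <= centre) {
    lower <- min(exp(logsumexp(ac_log_pmf(0:y, x, N1, N2))), 1)
    upper <- 1 - lower
  } else {
    # open-ended strict upper tail from y + 1: accumulate chunks until the
    # remainder is negligible; terms decay geometrically beyond the centre
    chunk <- 512L
    total <- -Inf
    k0 <- y + 1L
    repeat {
      ks <- k0:(k0 + chunk - 1L)
      total <- logsumexp(c(total, ac_log_pmf(ks, x, N1, N2)))
      last <- ac_log_pmf(k0 + chunk - 1L, x, N1, N2)
      # bound the missed mass by a geometric series with the current ratio
      ratio <- r / (1 + r) * (x + k0 + chunk) / (k0 + chunk)
      if (ratio < 1 && last + log(ratio / (1 - ratio)) < total + log(1e-15)) break
      k0 <- k0 + chunk
      if (k0 > y + 1e7) break  # safety net, never reached in practice
    }
    upper <- min(exp(total), 1)
    lower <- 1 - upper
  }
  c(lower = min(max(lower, 0), 1), upper = min(max(upper, 0), 1))
}

#' Cumulative conditional probability P(Y <= y | x)
#'
#' @inheritParams ac_pmf
#' @return The lower-tail probability of the conditional distribution.
#' @export
ac_cumulative <- function(y, x, N1, N2) {
  stopifnot(N1 > 0, N2 > 0, x >= 0, y >= 0)
  unname(mapply(function(yy, xx) ac_tails(xx, yy, N1, N2)[["lower"]], y, x))
}

#' Two-sided exact p-value for a pair of unreplicated counts
#'
#' The probability of the transcript being expressed more differentially than
#' observed, under the conditional Poisson null: the smaller of the two
#' one-sided tails is doubled and capped at 1,
#' `p = min(1, 2 * min(P(Y <= y | x), P(X <= x | y)))`.
#' Each one-sided component is the inclusive lower tail in its own
#' conditioning direction, and `P(X <= x | y) = P(Y > y | x)` exactly, so
#' the rule is exactly symmetric in the two libraries:
#' `ac_two_sided_p(x, y, N1, N2) == ac_two_sided_p(y, x, N2, N1)`.
#' Underflow for extremely differential pairs is clamped to the smallest
#' positive double so p-values stay in (0, 1].
#'
#' @param x,y Observed counts in libraries 1 and 2 (vectorised in parallel).
#' @param N1,N2 Library clean-read totals.
#' @return p-values in (0, 1].
#' @export
ac_two_sided_p <- function(x, y, N1, N2) {
  stopifnot(N1 > 0, N2 > 0)
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  unname(mapply(function(xx, yy) {
    t <- ac_tails(xx, yy, N1, N2)
    max(min(1, 2 * min(t[["lower"]], t[["upper"]])), .Machine$double.xmin)
  }, x, y))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values: sort ascending, take
#' `q_(i) = min_(j >= i) m p_(j) / j`, restore input order.  Monotone in p
#' and order-equivariant.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values in (0, 1], same order as `p`.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0L) stop("empty p-value list")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Apply differential-expression thresholds
#'
#' A record is called differentially expressed when its q-value is at most
#' `fdr` and its |log2 fold change| is at least `lfc` (defaults 0.001 and 1).
#'
#' @param records data.frame with columns `q` and `log2fc` (e.g. from
#'   [de_test()]).
#' @param fdr FDR threshold on the BH q-value.
#' @param lfc Minimum absolute log2 fold change.
#' @return `records` with a logical `is_de` column (re)set.
#' @export
call_de <- function(records, fdr = 0.001, lfc = 1) {
  stopifnot(all(c("q", "log2fc") %in% names(records)))
  records$is_de <- records$q <= fdr & abs(records$log2fc) >= lfc
  records
}

#' Exact differential-expression test between two unreplicated libraries
#'
#' For every transcript, computes FPKM in both samples, the log2 fold change
#' with the 0.01 zero substitution, the two-sided exact conditional Poisson
#' p-value using the library clean-read totals, BH q-values over all
#' transcripts, and the DE call at the given thresholds.  Transcripts with
#' zero counts in both libraries are retained with `p = 1`, `log2fc = 0`.
#'
#' @param ct A [count_table()].
#' @param sample_a Baseline sample name (e.g. ungrazed tolerant for the
#'   grazing-response contrast; grazed tolerant for the tolerance contrast).
#' @param sample_b Treatment sample name; fold changes are
#'   `log2(FPKM_b / FPKM_a)`.
#' @param fdr,lfc DE-calling thresholds, see [call_de()].
#' @return A `de_result` data.frame with columns `transcript_id`, `x`, `y`,
#'   `fpkm_a`, `fpkm_b`, `log2fc`, `p`, `q`, `is_de`; the contrast is stored
#'   in attributes `sample_a` / `sample_b`.
#' @export
de_test <- function(ct, sample_a, sample_b, fdr = 0.001, lfc = 1) {
  stopifnot(inherits(ct, "count_table"))
  if (!all(c(sample_a, sample_b) %in% ct$sample_ids))
    stop("unknown sample name(s): ",
         paste(setdiff(c(sample_a, sample_b), ct$sample_ids), collapse = ", "))
  x <- ct$counts[[sample_a]]
  y <- ct$counts[[sample_b]]
  N1 <- ct$totals[[sample_a]]
  N2 <- ct$totals[[sample_b]]
  fpkm_a <- compute_fpkm(x, ct$counts$length, N1)
  fpkm_b <- compute_fpkm(y, ct$counts$length, N2)
  res <- data.frame(
    transcript_id = ct$counts$transcript_id,
    x = x, y = y,
    fpkm_a = fpkm_a, fpkm_b = fpkm_b,
    log2fc = ifelse(x == 0 & y == 0, 0, log2_fold_change(fpkm_a, fpkm_b)),
    p = ac_two_sided_p(x, y, N1, N2),
    stringsAsFactors = FALSE
  )
  res$q <- bh_qvalues(res$p)
  res <- call_de(res, fdr = fdr, lfc = lfc)
  attr(res, "sample_a") <- sample_a
  attr(res, "sample_b") <- sample_b
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result: ", attr(x, "sample_b"), " vs ", attr(x, "sample_a"),
      " (baseline)\n", sep = "")
  cat(nrow(x), "transcripts,", sum(x$is_de), "differentially expressed\n")
  NextMethod()
}

#' Write / read a differential-expression result table
#'
#' Tab-separated with a `#contrast` provenance line recording baseline and
#' treatment sample names.
#'
#' @param de A `de_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(de, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#contrast\t", attr(de, "sample_a"), "\t",
                    attr(de, "sample_b")), con)
  utils::write.table(as.data.frame(de), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_result
#' @export
read_de_result <- function(path) {
  lines <- readLines(path, n = 1L)
  contrast <- strsplit(lines, "\t", fixed = TRUE)[[1L]]
  de <- utils::read.delim(path, skip = 1L,
                          colClasses = c("character", rep("numeric", 7), "logical"))
  attr(de, "sample_a") <- contrast[2L]
  attr(de, "sample_b") <- contrast[3L]
  class(de) <- c("de_result", "data.frame")
  de
}
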