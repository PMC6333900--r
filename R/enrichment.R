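# Enrichment ranking: two-proportion Z statistic comparing a peptide's
# frequency in the target-selected pool against the control-selected pool.

#' Two-proportion Z statistic
#'
#' Pooled-variance form (the textbook default, satisfying the identity
#' Z^2 = 1-df chi-square of the 2x2 table without continuity correction):
#' \deqn{Z = (p_1 - p_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' with \eqn{p_1 = x_1/n_1}, \eqn{p_2 = x_2/n_2} and pooled
#' \eqn{\hat p = (x_1+x_2)/(n_1+n_2)}. Positive Z means target-enriched.
#' When \eqn{x_1 + x_2 = 0} or the pooled proportion is 1 the statistic is
#' undefined and \code{NaN} is returned (such records are excluded from
#' rankings).
#'
#' @param x1,n1 target-arm count and total.
#' @param x2,n2 control-arm count and total.
#' @param pooled use the pooled variance estimate (default); otherwise the
#'   unpooled (Welch-type) form.
#' @return numeric vector of Z scores (vectorised over the inputs).
#' @examples
#' two_proportion_z(40, 40000, 4, 40000)
#' @export
two_proportion_z <- function(x1, n1, x2, n2, pooled = TRUE) {
  stopifnot(all(n1 > 0), all(n2 > 0), all(x1 >= 0), all(x2 >= 0),
            all(x1 <= n1), all(x2 <= n2))
  p1 <- x1 / n1
  p2 <- x2 / n2
  if (pooled) {
    pb <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pb * (1 - pb) * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  }
  z <- (p1 - p2) / se
  und <- (x1 + x2) == 0 | (x1 + x2) == (n1 + n2)
  z[und] <- NaN
  z
}

#' Rank peptides by enrichment Z score
#'
#' Computes the two-proportion Z statistic for every peptide in a count
#' table and returns the top records sorted by Z descending, ties broken
#' by target count descending then peptide lexicographically. Records
#' with undefined Z are excluded from the ranking (with a warning when
#' all are). A small pseudo-count can be added to every cell for
#' sensitivity analysis; the default is none, so a peptide absent from
#' the control arm legitimately obtains a large finite Z.
#'
#' @param table a \code{peptide_count_table} (see [count_peptides()]).
#' @param top_n number of top records to return (the full ranked table is
#'   kept in attribute \code{full_ranking}).
#' @param pooled see [two_proportion_z()].
#' @param pseudocount added to x1, x2 (and twice to n1, n2) before the
#'   test; default 0.
#' @return data.frame of class \code{enrichment_ranking}: top
#'   \code{min(top_n, valid records)} rows with columns \code{peptide},
#'   \code{z}, \code{x1}, \code{n1}, \code{x2}, \code{n2}, \code{p1},
#'   \code{p2}; attribute \code{full_ranking} holds all valid records.
#' @export
rank_peptides <- function(table, top_n = 50, pooled = TRUE, pseudocount = 0) {
  stopifnot(nrow(table) > 0, top_n >= 1)
  n1 <- attr(table, "n_target")
  n2 <- attr(table, "n_control")
  if (is.null(n1) || is.null(n2)) {
    n1 <- sum(table$x_target)
    n2 <- sum(table$x_control)
  }
  x1 <- table$x_target + pseudocount
  x2 <- table$x_control + pseudocount
  N1 <- n1 + 2 * pseudocount
  N2 <- n2 + 2 * pseudocount
  z <- two_proportion_z(x1, N1, x2, N2, pooled = pooled)
  rec <- data.frame(peptide = table$peptide, z = z,
                    x1 = table$x_target, n1 = n1,
                    x2 = table$x_control, n2 = n2,
                    p1 = table$x_target / n1, p2 = table$x_control / n2,
                    stringsAsFactors = FALSE)
  valid <- is.finite(rec$z)
  if (!any(valid)) {
    warning("no valid enrichment records")
    out <- rec[0, , drop = FALSE]
    attr(out, "full_ranking") <- out
    class(out) <- c("enrichment_ranking", "data.frame")
    return(out)
  }
  rec <- rec[valid, , drop = FALSE]
  rec <- rec[order(-rec$z, -rec$x1, rec$peptide), , drop = FALSE]
  rownames(rec) <- NULL
  out <- head(rec, top_n)
  attr(out, "full_ranking") <- rec
  class(out) <- c("enrichment_ranking", "data.frame")
  out
}

#' Top peptides for motif input
#'
#' The top-ranked peptides observed at least once in the target arm;
#' control-only records (x1 = 0, negative Z) are retained in the ranking
#' but never fed into motif discovery.
#'
#' @param ranking an \code{enrichment_ranking}.
#' @param n maximum number of peptides.
#' @return character vector of peptide sequences.
#' @export
top_peptides <- function(ranking, n = nrow(ranking)) {
  head(ranking$peptide[ranking$x1 > 0], n)
}

#' Write / read a ranked enrichment report
#'
#' Fixed column order \code{peptide, z, x1, n1, x2, n2, p1, p2}; an empty
#' record set yields a header-only file. Reading the written TSV
#' reproduces the records.
#'
#' @param records an \code{enrichment_ranking} (or compatible data.frame).
#' @param path TSV path.
#' @param header optional comment lines (each written prefixed "# ").
#' @rdname enrichment_report
#' @export
enrichment_report <- function(records, path, header = NULL) {
  cols <- c("peptide", "z", "x1", "n1", "x2", "n2", "p1", "p2")
  df <- as.data.frame(records)[, cols, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname enrichment_report
#' @export
read_enrichment_report <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  class(df) <- c("enrichment_ranking", "data.frame")
  df
}

#' Write peptides as FASTA
#'
#' @param peptides character vector of peptide sequences.
#' @param path FASTA path.
#' @param prefix record-name prefix.
#' @export
write_peptide_fasta <- function(peptides, path, prefix = "pep") {
  x <- Biostrings::AAStringSet(peptides)
  names(x) <- sprintf("%s%04d", prefix, seq_along(peptides))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read peptides from FASTA
#' @param path FASTA path.
#' @return character vector of peptide sequences.
#' @export
read_peptide_fasta <- function(path) {
  as.character(Biostrings::readAAStringSet(path))
}
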