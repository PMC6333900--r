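# FASTQ -> per-sample peptide count tables: demultiplex by exact 5'
# barcode, translate each read in the three forward frames, and keep
# inserts flanked by the conserved gpVIII anchor sequences.

#' Read and validate a barcode sheet
#'
#' TSV with columns \code{sample_id}, \code{barcode}, \code{panning_round},
#' \code{condition} (\code{target} or \code{control}). Barcodes must be
#' unique and each (round, condition) pair may appear at most once.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_barcode_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_barcode_sheet(sheet)
}

validate_barcode_sheet <- function(sheet) {
  need <- c("sample_id", "barcode", "panning_round", "condition")
  if (!all(need %in% names(sheet)))
    stop("barcode sheet needs columns: ", paste(need, collapse = ", "))
  if (nrow(sheet) == 0L) stop("barcode sheet is empty")
  if (anyDuplicated(sheet$barcode))
    stop("duplicate barcodes in sheet")
  if (anyDuplicated(sheet[c("panning_round", "condition")]))
    stop("each (round, condition) pair may appear at most once")
  if (!all(sheet$condition %in% c("target", "control")))
    stop("condition must be 'target' or 'control'")
  if (!all(grepl("^[ACGT]+$", sheet$barcode)))
    stop("barcodes must be A/C/G/T strings")
  sheet
}

# read a FASTQ as named character vector of sequences; empty file -> empty
read_fastq_seqs <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTQ: ", path)
    return(character())
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Demultiplex a FASTQ by 5' barcode
#'
#' A read is assigned to the unique sample whose barcode matches the
#' read's 5' prefix; the barcode is trimmed from assigned reads.
#' The default policy is exact matching (0 mismatches); with
#' \code{max_mismatch > 0} a read is assigned to the unique barcode
#' within that Hamming distance of its prefix (ties stay unassigned).
#' Unassigned reads are counted, never silently dropped.
#'
#' @param fastq_path FASTQ file (Phred+33).
#' @param sheet barcode sheet data.frame (see [read_barcode_sheet()]).
#' @param max_mismatch allowed barcode mismatches (default 0).
#' @return list with \code{samples} (named list, per sample a named
#'   character vector of barcode-trimmed read sequences),
#'   \code{unassigned} (count) and \code{total}.
#' @export
demultiplex <- function(fastq_path, sheet, max_mismatch = 0) {
  sheet <- validate_barcode_sheet(sheet)
  reads <- read_fastq_seqs(fastq_path)
  samples <- setNames(vector("list", nrow(sheet)), sheet$sample_id)
  if (length(reads) == 0L) {
    warning("no reads to demultiplex")
    for (i in seq_len(nrow(sheet))) samples[[i]] <- character()
    return(list(samples = samples, unassigned = 0L, total = 0L))
  }
  bc <- sheet$barcode
  nb <- nchar(bc)
  # mismatch count of each read's prefix against each barcode
  mm <- matrix(NA_integer_, length(reads), length(bc))
  for (j in seq_along(bc)) {
    pre <- substr(reads, 1L, nb[j])
    if (max_mismatch == 0) {
      mm[, j] <- ifelse(pre == bc[j], 0L, nb[j])
    } else {
      bcj <- strsplit(bc[j], "", fixed = TRUE)[[1]]
      prm <- matrix(unlist(strsplit(pre, "", fixed = TRUE)), nrow = nb[j])
      mm[, j] <- colSums(prm != bcj)
    }
    mm[nchar(reads) < nb[j], j] <- nb[j] # too short to carry the barcode
  }
  best <- max.col(-mm, ties.method = "first")
  bestmm <- mm[cbind(seq_along(reads), best)]
  n_best <- rowSums(mm == bestmm)
  ok <- bestmm <= max_mismatch & n_best == 1L
  for (j in seq_along(bc)) {
    sel <- ok & best == j
    trimmed <- substr(reads[sel], nb[j] + 1L, nchar(reads[sel]))
    names(trimmed) <- names(reads)[sel]
    samples[[j]] <- trimmed
  }
  list(samples = samples, unassigned = sum(!ok), total = length(reads))
}

# translate a character vector of DNA reads in the three forward frames;
# returns list of 3 character vectors (N codons -> X, stops -> *)
translate_frames <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  w <- Biostrings::width(x)
  lapply(0:2, function(f) {
    w3 <- pmax((w - f) %/% 3L, 0L) * 3L
    st <- pmin(f + 1L, w + 1L)
    s <- Biostrings::subseq(x, start = st, width = w3)
    as.character(Biostrings::translate(s, if.fuzzy.codon = "X"))
  })
}

#' Translate a DNA sequence in the three forward frames
#'
#' Frames start at offsets 0, 1, 2 of the given strand only
#' (reverse-complement frames are not produced). Codons containing N
#' translate to \code{X}, stop codons to \code{*}, and trailing 1--2 nt
#' are dropped.
#'
#' @param dna a single DNA string over A/C/G/T/N.
#' @return character vector of length 3, names \code{frame0..frame2}.
#' @examples
#' translate_three_frames("ATGGCA") # "MA", "W", "G"
#' @export
translate_three_frames <- function(dna) {
  stopifnot(length(dna) == 1L)
  out <- vapply(translate_frames(dna), `[`, character(1), 1L)
  setNames(out, paste0("frame", 0:2))
}

#' Extract the insert peptide between conserved flanks
#'
#' Returns the substring strictly between the first occurrence of
#' \code{up_flank} and the subsequent first occurrence of
#' \code{down_flank}. Returns \code{NA} if either anchor is absent, if
#' the insert contains a stop (\code{*}) or ambiguous (\code{X}) symbol,
#' or -- in fixed-length mode -- if its length differs from
#' \code{insert_length}.
#'
#' @param protein amino-acid string(s); vectorised.
#' @param up_flank,down_flank conserved anchor sequences (gpVIII defaults).
#' @param insert_length expected insert length in residues, or \code{NULL}
#'   for variable-length mode.
#' @return character vector of inserts (\code{NA} where extraction fails).
#' @examples
#' extract_insert("MAEGEFYKLKIRTPQDPAKAAG") # "YKLKIRTPQ"
#' @export
extract_insert <- function(protein, up_flank = UP_FLANK_AA,
                           down_flank = DOWN_FLANK_AA, insert_length = 9) {
  stopifnot(nchar(up_flank) > 0, nchar(down_flank) > 0)
  res <- rep(NA_character_, length(protein))
  up_pos <- regexpr(up_flank, protein, fixed = TRUE)
  has_up <- up_pos > 0L
  if (!any(has_up)) return(res)
  rest <- substr(protein, up_pos + nchar(up_flank), nchar(protein))
  down_pos <- regexpr(down_flank, rest, fixed = TRUE)
  ok <- has_up & down_pos > 0L
  ins <- substr(rest, 1L, down_pos - 1L)
  ok <- ok & !grepl("*", ins, fixed = TRUE) & !grepl("X", ins, fixed = TRUE)
  if (!is.null(insert_length)) ok <- ok & nchar(ins) == insert_length
  res[ok] <- ins[ok]
  res
}

#' Extract insert peptides from a set of reads
#'
#' Translates every read in the three forward frames and applies
#' [extract_insert()] to each frame. Reads whose anchors appear in more
#' than one frame contribute one extract per matching frame (with
#' error-free data at most one frame can match).
#'
#' @param reads named character vector of (barcode-trimmed) DNA reads.
#' @inheritParams extract_insert
#' @return data.frame with columns \code{read_id}, \code{frame} (0--2),
#'   \code{peptide}; one row per successful extraction.
#' @export
extract_peptides <- function(reads, up_flank = UP_FLANK_AA,
                             down_flank = DOWN_FLANK_AA, insert_length = 9) {
  if (length(reads) == 0L)
    return(data.frame(read_id = character(), frame = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  ids <- if (is.null(names(reads))) as.character(seq_along(reads)) else names(reads)
  frames <- translate_frames(unname(reads))
  out <- lapply(0:2, function(f) {
    ins <- extract_insert(frames[[f + 1L]], up_flank, down_flank, insert_length)
    keep <- !is.na(ins)
    data.frame(read_id = ids[keep], frame = rep.int(f, sum(keep)),
               peptide = ins[keep], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(match(res$read_id, ids), res$frame), , drop = FALSE]
}

#' Build a paired target-vs-control peptide count table
#'
#' Takes the multisets of peptides extracted from a target-selected and a
#' control-selected sample and tabulates, over the union of observed
#' peptides, the copy number in each arm. Totals are the numbers of
#' extracted peptides per sample (not raw reads). Rows are ordered by
#' descending target count, then lexicographically -- a deterministic
#' serialisation order.
#'
#' @param target,control character vectors of extracted peptides (one
#'   entry per extracted read).
#' @return data.frame of class \code{peptide_count_table} with columns
#'   \code{peptide}, \code{x_target}, \code{x_control},
#'   \code{freq_target}, \code{freq_control} and attributes
#'   \code{n_target}, \code{n_control}.
#' @export
count_peptides <- function(target, control) {
  all_pep <- sort(unique(c(target, control)))
  xt <- as.integer(table(factor(target, levels = all_pep)))
  xc <- as.integer(table(factor(control, levels = all_pep)))
  nt <- length(target); nc <- length(control)
  tab <- data.frame(peptide = all_pep, x_target = xt, x_control = xc,
                    freq_target = if (nt > 0) xt / nt else numeric(length(xt)),
                    freq_control = if (nc > 0) xc / nc else numeric(length(xc)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$x_target, tab$peptide), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_target") <- nt
  attr(tab, "n_control") <- nc
  class(tab) <- c("peptide_count_table", "data.frame")
  tab
}

#' @export
print.peptide_count_table <- function(x, ...) {
  cat("Peptide count table:", nrow(x), "unique peptides;",
      "n_target =", attr(x, "n_target"),
      "n_control =", attr(x, "n_control"), "\n")
  print.data.frame(head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Write / read a peptide count table as TSV
#'
#' Sample totals are recoverable as the column sums (an invariant of the
#' table), so the TSV carries only the count and frequency columns.
#'
#' @param tab a \code{peptide_count_table}.
#' @param path TSV path.
#' @rdname count_table_io
#' @export
write_count_table <- function(tab, path) {
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname count_table_io
#' @export
read_count_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  attr(tab, "n_target") <- sum(tab$x_target)
  attr(tab, "n_control") <- sum(tab$x_control)
  class(tab) <- c("peptide_count_table", "data.frame")
  tab
}

#' Process one demultiplexed sample to extracted peptides
#'
#' Convenience wrapper: [extract_peptides()] plus per-stage counts.
#'
#' @param reads named character vector of barcode-trimmed reads.
#' @inheritParams extract_insert
#' @return list with \code{peptides} (character vector, one per extract),
#'   \code{extracts} (data.frame) and \code{counts} (reads in / extracted).
#' @export
process_sample <- function(reads, up_flank = UP_FLANK_AA,
                           down_flank = DOWN_FLANK_AA, insert_length = 9) {
  ex <- extract_peptides(reads, up_flank, down_flank, insert_length)
  list(peptides = ex$peptide, extracts = ex,
       counts = c(reads_in = length(reads), extracted = nrow(ex)))
}
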