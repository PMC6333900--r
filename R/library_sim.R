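# Synthetic phage-display library, panning, and read-set generation.
# Emulates a PC89VIII-style gpVIII display library: random nonapeptide
# inserts carried between the conserved vector-encoded flanks AEGEF
# (upstream) and DPAKAA (downstream) at the protein level.

#' Standard amino-acid alphabet
#'
#' The 20 standard residues, in the conventional one-letter ordering used
#' throughout the package (PWM columns, background vectors).
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA4 <- c("A", "C", "G", "T")

# Conserved gpVIII flank sequences at the protein level and one fixed DNA
# encoding for each (the vector region is a fixed sequence, so a single
# codon choice is the realistic model).
UP_FLANK_AA <- "AEGEF"
DOWN_FLANK_AA <- "DPAKAA"
UP_FLANK_DNA <- "GCTGAAGGTGAATTT"
DOWN_FLANK_DNA <- "GATCCAGCTAAAGCTGCT"

# codon -> amino acid lookup split by residue (standard genetic code)
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# random DNA strings, vectorised: n strings of length len
rand_dna <- function(n, len) {
  if (len == 0L || n == 0L) return(rep("", n))
  m <- matrix(sample(DNA4, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Back-translate peptides to DNA
#'
#' Each residue is encoded by a synonymous codon drawn uniformly at random
#' (the library's codon scheme is randomised; stop codons never occur
#' because only sense codons encode residues). Uses the current RNG state.
#'
#' @param peptides character vector of peptide sequences over the 20
#'   standard residues.
#' @return character vector of DNA sequences, 3x the peptide length.
#' @export
back_translate <- function(peptides) {
  tab <- codon_table()[AA_STANDARD]
  flat <- unlist(tab, use.names = FALSE)
  ncod <- lengths(tab)
  starts <- cumsum(c(0L, ncod[-length(ncod)]))
  names(starts) <- names(ncod)
  aa <- strsplit(peptides, "", fixed = TRUE)
  lens <- lengths(aa)
  aa_vec <- unlist(aa, use.names = FALSE)
  bad <- setdiff(unique(aa_vec), AA_STANDARD)
  if (length(bad)) stop("non-standard residues: ", paste(bad, collapse = ","))
  pick <- ceiling(runif(length(aa_vec)) * ncod[aa_vec])
  codons <- flat[starts[aa_vec] + pick]
  grp <- rep.int(seq_along(peptides), lens)
  vapply(split(codons, grp), paste, character(1), collapse = "")
}

#' Generate a random-peptide display library
#'
#' Draws \code{n_clones} independent inserts with residues uniform over the
#' 20 standard amino acids (the null model for an unselected randomised
#' library) and back-translates each with uniformly sampled synonymous
#' codons.
#'
#' @param n_clones number of library clones.
#' @param insert_length insert length in residues (default 9, a
#'   nonapeptide gpVIII fusion library).
#' @param seed optional integer seed; the library is reproducible given it.
#' @return data.frame with columns \code{clone}, \code{peptide},
#'   \code{dna}.
#' @examples
#' lib <- build_library(5, seed = 1)
#' nchar(lib$dna) # 27 nt per 9-mer
#' @export
build_library <- function(n_clones, insert_length = 9, seed = NULL) {
  stopifnot(n_clones >= 1, insert_length >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(AA_STANDARD, n_clones * insert_length, replace = TRUE),
              nrow = n_clones)
  peptide <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  dna <- back_translate(peptide)
  data.frame(clone = sprintf("clone%06d", seq_len(n_clones)),
             peptide = peptide, dna = dna, stringsAsFactors = FALSE)
}

#' Simulate multi-round biopanning of target and control arms
#'
#' Starting from a uniform clone distribution, each selection round
#' multiplies every clone's abundance by a lognormal amplification-noise
#' factor (mean 1, coefficient of variation \code{amplification_noise_cv});
#' in the target arm, clones whose insert is in \code{binders} are
#' additionally multiplied by \code{enrichment_factor}. The control arm
#' sees amplification noise only. Frequencies are renormalised after every
#' round.
#'
#' @param library data.frame from [build_library()].
#' @param binders character vector of true-binder insert peptides (subset
#'   of the library; may be empty for a null simulation).
#' @param enrichment_factor per-round multiplicative enrichment of binders
#'   in the target arm (> 0; 1 gives a null run).
#' @param rounds number of selection rounds (>= 1).
#' @param amplification_noise_cv coefficient of variation of the lognormal
#'   clone-amplification noise.
#' @param seed optional integer seed.
#' @return an object of class \code{panning_sim}: list with frequency
#'   matrices \code{target} and \code{control} (rows \code{round0} ..
#'   \code{roundR}, columns clones), the cumulative unnormalised
#'   amplification weights \code{weights_target}/\code{weights_control}
#'   after the final round, and the logical \code{is_binder} per clone.
#' @export
simulate_panning <- function(library, binders = character(),
                             enrichment_factor = 10, rounds = 3,
                             amplification_noise_cv = 0.3, seed = NULL) {
  stopifnot(rounds >= 1, enrichment_factor > 0, amplification_noise_cv >= 0)
  if (length(binders) && !all(binders %in% library$peptide))
    stop("binders must be insert peptides present in the library")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(library)
  is_binder <- library$peptide %in% binders
  sigma <- sqrt(log(1 + amplification_noise_cv^2))
  target <- control <- matrix(NA_real_, rounds + 1L, n,
                              dimnames = list(paste0("round", 0:rounds),
                                              library$clone))
  init <- rep(1 / n, n)
  target[1, ] <- control[1, ] <- init
  w_t <- w_c <- rep(1, n)
  for (r in seq_len(rounds)) {
    noise_t <- if (sigma > 0) rlnorm(n, -sigma^2 / 2, sigma) else rep(1, n)
    noise_c <- if (sigma > 0) rlnorm(n, -sigma^2 / 2, sigma) else rep(1, n)
    w_t <- w_t * noise_t * ifelse(is_binder, enrichment_factor, 1)
    w_c <- w_c * noise_c
    target[r + 1L, ] <- init * w_t / sum(init * w_t)
    control[r + 1L, ] <- init * w_c / sum(init * w_c)
  }
  structure(list(target = target, control = control,
                 weights_target = w_t, weights_control = w_c,
                 is_binder = is_binder, library = library,
                 enrichment_factor = enrichment_factor, rounds = rounds),
            class = "panning_sim")
}

#' @export
print.panning_sim <- function(x, ...) {
  cat("Panning simulation:", ncol(x$target), "clones,", x$rounds, "rounds,",
      sum(x$is_binder), "true binders (factor", x$enrichment_factor, ")\n")
  invisible(x)
}

# substitute bases in place at per-base rate; substitutions only
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  nc <- nchar(seqs)
  n_err <- rbinom(length(seqs), nc, rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nc[i], n_err[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA4, cur), 1L)
    }
  }
  seqs
}

# optional single indel per affected read (Ion Torrent homopolymer errors
# break frame; off by default, exists to exercise frame tolerance)
apply_indels <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  nc <- nchar(seqs)
  hit <- which(rbinom(length(seqs), nc, rate) > 0L)
  for (i in hit) {
    p <- sample.int(nc[i], 1L)
    if (runif(1) < 0.5) { # deletion
      seqs[i] <- paste0(substr(seqs[i], 1L, p - 1L),
                        substr(seqs[i], p + 1L, nc[i]))
    } else {             # insertion
      seqs[i] <- paste0(substr(seqs[i], 1L, p), sample(DNA4, 1L),
                        substr(seqs[i], p + 1L, nc[i]))
    }
  }
  seqs
}

#' Write a synthetic barcoded amplicon FASTQ sample
#'
#' Samples \code{n_reads} reads from the given clone frequencies
#' (multinomially) and writes Ion Torrent-style single-end amplicon reads:
#' \code{barcode + frame-offset pad + AEGEF-flank DNA + insert DNA +
#' DPAKAA-flank DNA + trailing vector context}, with i.i.d. substitution
#' errors at \code{per_base_error_rate}. Quality strings are constant Q30
#' (Phred+33 \code{"?"}); the downstream pipeline never uses qualities.
#'
#' @param frequencies clone frequency vector (sums to 1), one entry per
#'   library row.
#' @param library data.frame from [build_library()].
#' @param path output FASTQ path.
#' @param barcode DNA barcode prepended to every read.
#' @param n_reads number of reads to emit.
#' @param per_base_error_rate substitution probability per base.
#' @param frame_offset_weights sampling weights for 0/1/2-nt pads before
#'   the upstream flank (normalised internally).
#' @param indel_rate per-base rate at which a read receives one indel
#'   (default 0: substitutions only).
#' @param trailing_length random vector-context bases appended after the
#'   downstream flank.
#' @param read_prefix read-id prefix.
#' @param append append to an existing file (multiplexed FASTQ).
#' @param seed optional integer seed; identical seeds give byte-identical
#'   files.
#' @return (invisibly) data.frame of per-read truth: \code{read_id},
#'   \code{clone}, \code{peptide}, \code{offset}.
#' @export
emit_fastq <- function(frequencies, library, path, barcode,
                       n_reads = 40000, per_base_error_rate = 0.005,
                       frame_offset_weights = c(1, 1, 1),
                       indel_rate = 0, trailing_length = 20,
                       read_prefix = "read", append = FALSE, seed = NULL) {
  stopifnot(length(frequencies) == nrow(library), n_reads >= 1,
            per_base_error_rate >= 0, per_base_error_rate < 1,
            length(frame_offset_weights) == 3L)
  if (abs(sum(frequencies) - 1) > 1e-6)
    stop("frequencies must be normalised")
  if (!is.null(seed)) set.seed(seed)
  counts <- rmultinom(1L, n_reads, frequencies)[, 1L]
  idx <- sample(rep.int(seq_along(frequencies), counts))
  offs <- sample(0:2, n_reads, replace = TRUE,
                 prob = frame_offset_weights / sum(frame_offset_weights))
  pad2 <- rand_dna(n_reads, 2L)
  pads <- substr(pad2, 1L, offs)
  trail <- rand_dna(n_reads, trailing_length)
  seqs <- paste0(barcode, pads, UP_FLANK_DNA, library$dna[idx],
                 DOWN_FLANK_DNA, trail)
  seqs <- apply_substitutions(seqs, per_base_error_rate)
  seqs <- apply_indels(seqs, indel_rate)
  ids <- sprintf("%s.%06d", read_prefix, seq_len(n_reads))
  quals <- strrep("?", nchar(seqs))
  rec <- as.vector(rbind(paste0("@", ids), seqs, "+", quals))
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(data.frame(read_id = ids, clone = library$clone[idx],
                       peptide = library$peptide[idx], offset = offs,
                       stringsAsFactors = FALSE))
}

#' Simulate a complete NGPD dataset on disk
#'
#' Runs [build_library()], [simulate_panning()] and [emit_fastq()] for the
#' final-round target and control arms, writing a multiplexed FASTQ, a
#' barcode sheet TSV and a ground-truth sidecar TSV (clone, peptide,
#' binder flag, generating frequency per round and arm).
#'
#' @param outdir output directory (created if missing).
#' @param n_clones library size.
#' @param n_binders number of spiked true binders (first clones of the
#'   library are used).
#' @param enrichment_factor,rounds,amplification_noise_cv see
#'   [simulate_panning()].
#' @param n_reads reads per arm.
#' @param per_base_error_rate,frame_offset_weights,indel_rate see
#'   [emit_fastq()].
#' @param insert_length insert length in residues.
#' @param barcodes named character vector with elements \code{target} and
#'   \code{control}.
#' @param seed integer seed governing every random choice.
#' @return list with file \code{paths}, the \code{truth} data.frame, the
#'   \code{panning} object and the barcode \code{sheet}.
#' @export
simulate_ngpd_dataset <- function(outdir, n_clones = 10000, n_binders = 5,
                                  enrichment_factor = 10, rounds = 3,
                                  amplification_noise_cv = 0.3,
                                  n_reads = 40000,
                                  per_base_error_rate = 0.005,
                                  frame_offset_weights = c(1, 1, 1),
                                  indel_rate = 0, insert_length = 9,
                                  barcodes = c(target = "AACCGGTTAG",
                                               control = "GGTTAACCTC"),
                                  seed = 1) {
  stopifnot(n_binders <= n_clones, all(c("target", "control") %in% names(barcodes)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lib <- build_library(n_clones, insert_length, seed = seed)
  binders <- lib$peptide[seq_len(n_binders)]
  pan <- simulate_panning(lib, binders, enrichment_factor, rounds,
                          amplification_noise_cv, seed = seed + 1L)
  fastq <- file.path(outdir, "reads.fastq")
  tr_t <- emit_fastq(pan$target[rounds + 1L, ], lib, fastq,
                     barcode = barcodes[["target"]], n_reads = n_reads,
                     per_base_error_rate = per_base_error_rate,
                     frame_offset_weights = frame_offset_weights,
                     indel_rate = indel_rate, read_prefix = "t",
                     append = FALSE, seed = seed + 2L)
  tr_c <- emit_fastq(pan$control[rounds + 1L, ], lib, fastq,
                     barcode = barcodes[["control"]], n_reads = n_reads,
                     per_base_error_rate = per_base_error_rate,
                     frame_offset_weights = frame_offset_weights,
                     indel_rate = indel_rate, read_prefix = "c",
                     append = TRUE, seed = seed + 3L)
  sheet <- data.frame(sample_id = c("target_r3", "control_r3"),
                      barcode = unname(barcodes[c("target", "control")]),
                      panning_round = rounds,
                      condition = c("target", "control"),
                      stringsAsFactors = FALSE)
  sheet_path <- file.path(outdir, "barcodes.tsv")
  write.table(sheet, sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(clone = lib$clone, peptide = lib$peptide,
                      is_binder = pan$is_binder, stringsAsFactors = FALSE)
  for (r in 0:rounds) {
    truth[[paste0("freq_target_r", r)]] <- pan$target[r + 1L, ]
    truth[[paste0("freq_control_r", r)]] <- pan$control[r + 1L, ]
  }
  truth_path <- file.path(outdir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(paths = list(fastq = fastq, sheet = sheet_path, truth = truth_path),
       truth = truth, panning = pan, sheet = sheet,
       reads_target = tr_t, reads_control = tr_c)
}
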