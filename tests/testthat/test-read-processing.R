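# Demultiplexing, three-frame translation, flank-anchored extraction,
# and count-table construction.

make_sheet <- function(barcodes = c("ACGTACGTAA", "TGCATGCAGG"),
                       conditions = c("target", "control")) {
  data.frame(sample_id = paste0("s_", conditions), barcode = barcodes,
             panning_round = 3, condition = conditions,
             stringsAsFactors = FALSE)
}

write_fastq_records <- function(path, seqs) {
  ids <- sprintf("@r%03d", seq_along(seqs))
  writeLines(as.vector(rbind(ids, seqs, "+", strrep("?", nchar(seqs)))), path)
}

test_that("demultiplexing assigns exact-prefix reads and counts the rest", {
  sheet <- make_sheet()
  tf <- tempfile(fileext = ".fastq")
  payload <- "GCTGAAGGTGAATTTAAAAAAAAA"
  seqs <- c(paste0("ACGTACGTAA", payload),  # exact match sample 1
            paste0("TGCATGCAGG", payload),  # exact match sample 2
            paste0("ACGTACGTAC", payload),  # 1 mismatch -> unassigned
            paste0("GGGGGGGGGG", payload))  # garbage -> unassigned
  write_fastq_records(tf, seqs)
  dm <- demultiplex(tf, sheet)
  expect_equal(length(dm$samples$s_target), 1)
  expect_equal(unname(dm$samples$s_target[1]), payload) # barcode trimmed
  expect_equal(length(dm$samples$s_control), 1)
  expect_equal(dm$unassigned, 2)
  # conservation: assigned + unassigned = total
  expect_equal(sum(lengths(dm$samples)) + dm$unassigned, dm$total)
  # 1-mismatch read is recovered when the policy allows it
  dm1 <- demultiplex(tf, sheet, max_mismatch = 1)
  expect_equal(length(dm1$samples$s_target), 2)
  expect_equal(dm1$unassigned, 1)
})

test_that("demultiplexing rejects bad sheets and tolerates empty input", {
  sheet_dup <- make_sheet(barcodes = c("ACGTACGTAA", "ACGTACGTAA"))
  expect_error(demultiplex(tempfile(), sheet_dup), "duplicate")
  tf <- tempfile(fileext = ".fastq")
  file.create(tf)
  w <- capture_warnings(dm <- demultiplex(tf, make_sheet()))
  expect_true(any(grepl("empty|no reads", w)))
  expect_equal(dm$total, 0L)
  expect_equal(lengths(dm$samples), c(s_target = 0L, s_control = 0L))
})

test_that("demultiplexed counts match generator truth at zero error rate", {
  lib <- build_library(30, seed = 21)
  tf <- tempfile(fileext = ".fastq")
  n_t <- 150; n_c <- 90
  emit_fastq(rep(1 / 30, 30), lib, tf, barcode = "ACGTACGTAA", n_reads = n_t,
             per_base_error_rate = 0, seed = 22, read_prefix = "t")
  emit_fastq(rep(1 / 30, 30), lib, tf, barcode = "TGCATGCAGG", n_reads = n_c,
             per_base_error_rate = 0, seed = 23, read_prefix = "c",
             append = TRUE)
  dm <- demultiplex(tf, make_sheet())
  expect_equal(length(dm$samples$s_target), n_t)
  expect_equal(length(dm$samples$s_control), n_c)
  expect_equal(dm$unassigned, 0)
})

test_that("three-frame translation matches the codon-table oracle", {
  expect_equal(translate_three_frames("ATGGCA"),
               c(frame0 = "MA", frame1 = "W", frame2 = "G"))
  expect_equal(translate_three_frames(""),
               c(frame0 = "", frame1 = "", frame2 = ""))
  # N codons -> X; stops -> *
  expect_equal(unname(translate_three_frames("ATGNNNTAA")[1]), "MX*")
  set.seed(24)
  for (len in c(3, 10, 31, 100)) {
    dna <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                        prob = c(24, 24, 24, 24, 4)), collapse = "")
    got <- translate_three_frames(dna)
    want <- vapply(0:2, function(f) oracle_translate(dna, f), character(1))
    expect_equal(unname(got), want, info = dna)
  }
})

test_that("insert extraction honours anchors, stops, X and fixed length", {
  expect_equal(extract_insert("MAEGEFYKLKIRTPQDPAKAAG"), "YKLKIRTPQ")
  expect_equal(extract_insert("AEGEFLELLKASRWDPAKAA"), "LELLKASRW")
  expect_true(is.na(extract_insert("AEGEFYK*KIRTPQDPAKAA")))  # internal stop
  expect_true(is.na(extract_insert("AEGEFYKXKIRTPQDPAKAA")))  # ambiguous
  expect_true(is.na(extract_insert("AEGEFYKLKIRTPQ")))        # no down anchor
  expect_true(is.na(extract_insert("YKLKIRTPQDPAKAA")))       # no up anchor
  expect_true(is.na(extract_insert("AEGEFYKLKIRTDPAKAA")))    # wrong length
  expect_equal(extract_insert("AEGEFYKLKIRTDPAKAA", insert_length = NULL),
               "YKLKIRT")                                     # variable mode
  # first-occurrence semantics: first AEGEF, then nearest DPAKAA
  expect_equal(extract_insert(
    "AEGEFAAAAAAAAADPAKAAXXAEGEFYKLKIRTPQDPAKAA"), "AAAAAAAAA")
})

test_that("extraction over random reads equals the regex brute-force oracle", {
  lib <- build_library(400, seed = 25)
  tr <- emit_fastq(rep(1 / 400, 400), lib, tf <- tempfile(fileext = ".fastq"),
                   barcode = "", n_reads = 10000,
                   per_base_error_rate = 0.01, seed = 26)
  reads <- readLines(tf)[seq(2, 40000, 4)]
  got <- sort(extract_peptides(setNames(reads, paste0("r", 1:10000)))$peptide)
  want <- oracle_extract_multiset(reads)
  expect_identical(got, want)
  expect_lt(length(got), 9900)  # errors must knock some extractions out
  expect_gt(length(got), 5000)  # ~0.99^60 of reads survive intact
})

test_that("raising the error rate never increases expected extraction yield", {
  lib <- build_library(50, seed = 27)
  yield <- function(rate) {
    mean(vapply(1:5, function(s) {
      tr <- emit_fastq(rep(1 / 50, 50), lib,
                       tf <- tempfile(fileext = ".fastq"), barcode = "",
                       n_reads = 800, per_base_error_rate = rate,
                       seed = 500 + s)
      nrow(extract_peptides(setNames(readLines(tf)[seq(2, 3200, 4)],
                                     paste0("r", 1:800))))
    }, numeric(1)))
  }
  y <- vapply(c(0, 0.01, 0.04), yield, numeric(1))
  expect_true(all(diff(y) <= 0))
})

test_that("indel mode breaks frame and reduces extraction yield", {
  lib <- build_library(40, seed = 28)
  tf <- tempfile(fileext = ".fastq")
  emit_fastq(rep(1 / 40, 40), lib, tf, barcode = "", n_reads = 500,
             per_base_error_rate = 0, indel_rate = 0.01, seed = 29)
  reads <- setNames(readLines(tf)[seq(2, 2000, 4)], paste0("r", 1:500))
  ex <- extract_peptides(reads)
  expect_lt(nrow(ex), 500)
  expect_gt(nrow(ex), 0)
  # extracted inserts are still exact library peptides (anchors re-found
  # in a shifted frame or the unshifted prefix)
  expect_true(all(ex$peptide %in% lib$peptide))
})

test_that("count tables satisfy their invariants and serialisation contract", {
  tab <- count_peptides(c("AAA", "AAA", "AAA"), character())
  expect_equal(tab$x_target, 3L)
  expect_equal(tab$x_control, 0L)
  expect_equal(attr(tab, "n_target"), 3L)
  expect_equal(attr(tab, "n_control"), 0L)

  set.seed(30)
  tgt <- sample(c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"), 60, TRUE)
  ctl <- sample(c("AAAAAAAAA", "EEEEEEEEE"), 40, TRUE)
  tab <- count_peptides(tgt, ctl)
  expect_equal(sum(tab$x_target), attr(tab, "n_target"))
  expect_equal(sum(tab$x_control), attr(tab, "n_control"))
  expect_setequal(tab$peptide, union(tgt, ctl))
  # deterministic order: descending x_target then lexicographic
  expect_equal(tab$peptide,
               tab$peptide[order(-tab$x_target, tab$peptide)])
  # TSV round trip restores counts and totals
  tf <- tempfile(fileext = ".tsv")
  write_count_table(tab, tf)
  back <- read_count_table(tf)
  expect_equal(back$x_target, tab$x_target)
  expect_equal(attr(back, "n_target"), attr(tab, "n_target"))
})

test_that("counts equal generator multiplicities exactly at zero error rate", {
  lib <- build_library(25, seed = 31)
  tf <- tempfile(fileext = ".fastq")
  tr_t <- emit_fastq(rep(1 / 25, 25), lib, tf, barcode = "ACGTACGTAA",
                     n_reads = 200, per_base_error_rate = 0, seed = 32)
  tr_c <- emit_fastq(rep(1 / 25, 25), lib, tf, barcode = "TGCATGCAGG",
                     n_reads = 150, per_base_error_rate = 0, seed = 33,
                     append = TRUE)
  dm <- demultiplex(tf, make_sheet())
  tab <- count_peptides(process_sample(dm$samples$s_target)$peptides,
                        process_sample(dm$samples$s_control)$peptides)
  want_t <- table(tr_t$peptide)
  expect_equal(setNames(tab$x_target, tab$peptide)[names(want_t)],
               setNames(as.integer(want_t), names(want_t)))
  expect_equal(attr(tab, "n_target"), 200L)
  expect_equal(attr(tab, "n_control"), 150L)
})
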