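# Configuration-driven orchestration of the NGPD workflow:
# simulate -> demultiplex/extract/rank -> motif discovery -> ITC fits.
# A single config (list or YAML) drives all stages; each stage is also
# runnable on its own against intermediate files.

#' Build a pipeline configuration
#'
#' Returns the default configuration, with any supplied values merged
#' over it. Sections: \code{paths} (fastq, barcode sheet, output dir),
#' \code{simulate} (generator settings), \code{extract} (flanks, insert
#' length), \code{rank} (top_n, pooled), \code{motif} (widths, n_motifs,
#' n_starts), \code{itc} (heat CSVs, protocol, fit options), and a global
#' \code{seed} recorded in every output header.
#'
#' @param ... named sections overriding the defaults (nested lists are
#'   merged element-wise).
#' @return list of class \code{ngpd_config}.
#' @export
ngpd_config <- function(...) {
  default <- list(
    seed = 1,
    paths = list(outdir = "ngpd_out", fastq = NULL, barcode_sheet = NULL),
    simulate = list(n_clones = 10000, n_binders = 5, enrichment_factor = 10,
                    rounds = 3, amplification_noise_cv = 0.3,
                    n_reads = 40000, per_base_error_rate = 0.005,
                    insert_length = 9),
    extract = list(up_flank = UP_FLANK_AA, down_flank = DOWN_FLANK_AA,
                   insert_length = 9, barcode_mismatch = 0),
    rank = list(top_n = 50, pooled = TRUE, pseudocount = 0),
    motif = list(n_motifs = 2, widths = 6:8, n_starts = 10,
                 max_iter = 500, tol = 1e-6),
    itc = list(heat_files = character(), cell_volume = 1.4e-3,
               cell_conc = 30e-6, syringe_conc = 300e-6,
               n_injections = 30, injection_volume = 8e-6,
               temperature = 298.15, exclude_first = TRUE, float_N = TRUE))
  user <- list(...)
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(default[[nm]]))
      default[[nm]] <- modifyList(default[[nm]], user[[nm]])
    else default[[nm]] <- user[[nm]]
  }
  structure(default, class = c("ngpd_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [ngpd_config()].
#' @return list of class \code{ngpd_config}.
#' @export
read_config <- function(path) {
  do.call(ngpd_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  # hash the scientific settings only: file locations do not change results
  cfg <- unclass(config)
  cfg$paths <- NULL
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

stage_header <- function(config, stage) {
  sprintf("ngpd stage=%s seed=%s config=%s", stage, config$seed,
          config_hash(config))
}

stage_log <- function(stage, ...) {
  kv <- c(...)
  message("ngpd ", stage, ": ",
          paste(names(kv), unname(kv), sep = "=", collapse = " "))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the simulation stage
#'
#' Wraps [simulate_ngpd_dataset()]; writes the multiplexed FASTQ, barcode
#' sheet, ground-truth sidecar and a manifest of output checksums.
#'
#' @param config an \code{ngpd_config} (or YAML path).
#' @return the [simulate_ngpd_dataset()] result plus \code{manifest}.
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- read_config(config)
  outdir <- config$paths$outdir
  s <- config$simulate
  res <- simulate_ngpd_dataset(
    outdir, n_clones = s$n_clones, n_binders = s$n_binders,
    enrichment_factor = s$enrichment_factor, rounds = s$rounds,
    amplification_noise_cv = s$amplification_noise_cv,
    n_reads = s$n_reads, per_base_error_rate = s$per_base_error_rate,
    insert_length = s$insert_length, seed = config$seed)
  manifest <- data.frame(file = basename(unlist(res$paths)),
                         md5 = unname(tools::md5sum(unlist(res$paths))),
                         stringsAsFactors = FALSE)
  write_tsv_with_header(manifest, file.path(outdir, "manifest.tsv"),
                        stage_header(config, "simulate"))
  stage_log("simulate", n_clones = s$n_clones, n_binders = s$n_binders,
            reads_per_arm = s$n_reads)
  res$manifest <- manifest
  invisible(res)
}

#' Run the processing and ranking stage
#'
#' Demultiplex, translate in three frames, extract flank-anchored
#' inserts, count, and rank by the two-proportion Z statistic. Writes the
#' count table, the ranked enrichment report and the top-N FASTA; logs
#' per-stage read counts.
#'
#' @param config an \code{ngpd_config} (or YAML path); uses
#'   \code{paths$fastq} and \code{paths$barcode_sheet}, falling back to
#'   the simulation stage's outputs in \code{paths$outdir}.
#' @return list with the \code{ranking}, count \code{table}, demux
#'   summary and per-stage \code{counts}.
#' @export
run_rank <- function(config) {
  if (is.character(config)) config <- read_config(config)
  outdir <- config$paths$outdir
  fastq <- config$paths$fastq %||% file.path(outdir, "reads.fastq")
  sheet_path <- config$paths$barcode_sheet %||% file.path(outdir, "barcodes.tsv")
  sheet <- read_barcode_sheet(sheet_path)
  dm <- demultiplex(fastq, sheet,
                    max_mismatch = config$extract$barcode_mismatch)
  ex <- config$extract
  proc <- lapply(dm$samples, process_sample, up_flank = ex$up_flank,
                 down_flank = ex$down_flank, insert_length = ex$insert_length)
  tgt <- sheet$sample_id[sheet$condition == "target"][1]
  ctl <- sheet$sample_id[sheet$condition == "control"][1]
  if (is.na(tgt) || is.na(ctl))
    stop("need one target and one control sample")
  tab <- count_peptides(proc[[tgt]]$peptides, proc[[ctl]]$peptides)
  counts <- c(reads_total = dm$total, unassigned = dm$unassigned,
              target_reads = length(dm$samples[[tgt]]),
              control_reads = length(dm$samples[[ctl]]),
              target_extracted = attr(tab, "n_target"),
              control_extracted = attr(tab, "n_control"),
              unique_peptides = nrow(tab))
  if (nrow(tab) == 0L) {
    warning("no peptides extracted; writing empty outputs")
    ranking <- structure(
      data.frame(peptide = character(), z = numeric(), x1 = integer(),
                 n1 = integer(), x2 = integer(), n2 = integer(),
                 p1 = numeric(), p2 = numeric(), stringsAsFactors = FALSE),
      class = c("enrichment_ranking", "data.frame"))
  } else {
    ranking <- rank_peptides(tab, top_n = config$rank$top_n,
                             pooled = config$rank$pooled,
                             pseudocount = config$rank$pseudocount)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(tab, file.path(outdir, "counts.tsv"))
  enrichment_report(attr(ranking, "full_ranking") %||% ranking,
                    file.path(outdir, "ranking.tsv"),
                    header = stage_header(config, "rank"))
  write_peptide_fasta(top_peptides(ranking),
                      file.path(outdir, "top_peptides.fasta"))
  stage_log("rank", counts)
  invisible(list(ranking = ranking, table = tab, demux = dm[c("unassigned", "total")],
                 counts = counts))
}

#' Run the motif-discovery stage
#'
#' Sequential two-motif ZOOPS discovery on the top-ranked peptide FASTA,
#' with erasure of the first motif's members before the second search,
#' plus a degenerate-pattern match report against the two USP11 consensus
#' motifs.
#'
#' @param config an \code{ngpd_config} (or YAML path).
#' @param peptides optional peptide vector (defaults to the top-peptide
#'   FASTA in the output directory).
#' @return list with the \code{motif_set} and the pattern-\code{matches}
#'   data.frame.
#' @export
run_motif <- function(config, peptides = NULL) {
  if (is.character(config)) config <- read_config(config)
  outdir <- config$paths$outdir
  if (is.null(peptides))
    peptides <- read_peptide_fasta(file.path(outdir, "top_peptides.fasta"))
  if (length(peptides) < 2L) stop("need at least 2 peptides for motif discovery")
  mc <- config$motif
  ms <- discover_motifs(peptides, n_motifs = mc$n_motifs,
                        widths = mc$widths, n_starts = mc$n_starts,
                        max_iter = mc$max_iter, tol = mc$tol,
                        seed = config$seed)
  pats <- motif_patterns()
  matches <- data.frame(
    peptide = peptides,
    motif1_offset = pattern_offsets(peptides, pats$motif1),
    motif2_offset = pattern_offsets(peptides, pats$motif2),
    stringsAsFactors = FALSE)
  for (i in seq_along(ms$motifs)) {
    write_motif_tsv(ms$motifs[[i]],
                    file.path(outdir, sprintf("motif%d_pwm.tsv", i)))
    write_tsv_with_header(ms$motifs[[i]]$members,
                          file.path(outdir, sprintf("motif%d_members.tsv", i)),
                          stage_header(config, "motif"))
  }
  write_tsv_with_header(matches, file.path(outdir, "pattern_matches.tsv"),
                        stage_header(config, "motif"))
  stage_log("motif", n_peptides = length(peptides),
            n_motifs = length(ms$motifs))
  invisible(list(motifs = ms, matches = matches))
}

#' Run the ITC fitting stage
#'
#' Fits the one-site model to each configured heat CSV; non-convergence
#' in one experiment is reported without aborting the batch. Writes a
#' parameter table with standard errors and c-values.
#'
#' @param config an \code{ngpd_config} (or YAML path);
#'   \code{config$itc$heat_files} lists the input CSVs.
#' @return list of \code{onesite_fit} objects (NULL for failures), plus
#'   the parameter table.
#' @export
run_itcfit <- function(config) {
  if (is.character(config)) config <- read_config(config)
  ic <- config$itc
  protocol <- itc_protocol(cell_volume = ic$cell_volume,
                           cell_conc = ic$cell_conc,
                           syringe_conc = ic$syringe_conc,
                           injection_volumes = rep(ic$injection_volume,
                                                   ic$n_injections),
                           temperature = ic$temperature)
  fits <- setNames(vector("list", length(ic$heat_files)),
                   basename(ic$heat_files))
  rows <- list()
  for (f in ic$heat_files) {
    h <- read_injection_heats(f, protocol)
    fit <- tryCatch(fit_one_site(h, protocol,
                                 exclude_first = ic$exclude_first,
                                 float_N = ic$float_N),
                    error = function(e) {
                      warning("fit failed for ", f, ": ", conditionMessage(e))
                      NULL
                    })
    fits[[basename(f)]] <- fit
    if (!is.null(fit)) {
      co <- fit$coefficients
      rows[[basename(f)]] <- data.frame(
        experiment = basename(f), N = co[["N"]], se_N = fit$se[["N"]],
        K_D_uM = co[["K_D"]] * 1e6, se_K_D_uM = fit$se[["K_D"]] * 1e6,
        dH_kcal = co[["dH"]], se_dH = fit$se[["dH"]],
        q_dil = co[["q_dil"]], c_value = fit$c_value,
        converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  partab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(experiment = character())
  outdir <- config$paths$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_with_header(partab, file.path(outdir, "itc_fits.tsv"),
                        stage_header(config, "itcfit"))
  stage_log("itcfit", n_experiments = length(ic$heat_files),
            n_converged = sum(vapply(fits, function(f)
              !is.null(f) && f$converged, logical(1))))
  invisible(list(fits = fits, table = partab))
}

#' Run the full pipeline
#'
#' Simulate (when no FASTQ is configured), rank, and discover motifs;
#' ITC fitting runs when heat files are configured.
#'
#' @param config an \code{ngpd_config} (or YAML path).
#' @return list with the per-stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  sim <- NULL
  if (is.null(config$paths$fastq) &&
      !file.exists(file.path(config$paths$outdir, "reads.fastq")))
    sim <- run_simulate(config)
  rk <- run_rank(config)
  mt <- if (length(top_peptides(rk$ranking)) >= 2L) run_motif(config) else NULL
  it <- if (length(config$itc$heat_files)) run_itcfit(config) else NULL
  invisible(list(simulate = sim, rank = rk, motif = mt, itc = it))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
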