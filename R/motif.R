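# ZOOPS EM motif discovery on short peptide sets, plus degenerate
# consensus-pattern matching. The EM machinery is the package's own
# implementation of the zero-or-one-occurrence-per-sequence mixture model
# used by MEME-style motif elicitation.

RESIDUES_NONPOLAR <- c("A", "V", "L", "I", "M", "F", "W", "P", "G", "C")
RESIDUES_CHARGED <- c("D", "E", "K", "R", "H")

# ---- degenerate consensus patterns ----------------------------------------

#' Construct a degenerate residue-class pattern
#'
#' Pattern strings are hyphen-separated position tokens:
#' \describe{
#'   \item{an uppercase letter}{fixed residue, e.g. \code{L};}
#'   \item{\code{X}}{wildcard (any residue);}
#'   \item{\code{h}}{nonpolar residue (phi class):
#'     A, V, L, I, M, F, W, P, G, C;}
#'   \item{\code{c}}{charged residue (+/- class): D, E, K, R, H;}
#'   \item{\code{[ABC]}}{explicit alternative set.}
#' }
#' For example \code{"[YNHC]-c-L-c-h-R"} is a 6-position pattern whose
#' first position admits Y, N, H or C, second any charged residue, and so
#' on. At least one position must be non-wildcard.
#'
#' @param pattern pattern string as above, or a list of per-position
#'   allowed-residue character vectors (\code{NULL} entries = wildcard).
#' @return object of class \code{degenerate_pattern}: list of allowed
#'   residue sets per position.
#' @examples
#' degenerate_pattern("L-X-L-h-X-X-S-[RP]")
#' @export
degenerate_pattern <- function(pattern) {
  if (is.character(pattern) && length(pattern) == 1L) {
    toks <- strsplit(pattern, "-", fixed = TRUE)[[1]]
    pos <- lapply(toks, function(tk) {
      if (tk == "X") return(AA_STANDARD)
      if (tk == "h") return(RESIDUES_NONPOLAR)
      if (tk == "c") return(RESIDUES_CHARGED)
      if (grepl("^\\[[A-Z]+\\]$", tk))
        return(strsplit(substr(tk, 2L, nchar(tk) - 1L), "")[[1]])
      if (grepl("^[A-Z]$", tk)) return(tk)
      stop("unrecognised pattern token: ", tk)
    })
  } else if (is.list(pattern)) {
    pos <- lapply(pattern, function(p) if (is.null(p)) AA_STANDARD else p)
  } else stop("pattern must be a string or a list")
  if (all(lengths(pos) == length(AA_STANDARD)))
    stop("pattern must have at least one non-wildcard position")
  structure(pos, class = "degenerate_pattern", source = pattern)
}

#' @export
print.degenerate_pattern <- function(x, ...) {
  cat("Degenerate pattern (", length(x), " positions): ",
      paste(vapply(x, function(p)
        if (length(p) == 1L) p
        else if (length(p) == length(AA_STANDARD)) "X"
        else paste0("[", paste(p, collapse = ""), "]"), character(1)),
        collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' The two USP11-binding consensus motifs
#'
#' Degenerate patterns for the two consensus motifs recovered from
#' USP11-selected nonapeptide libraries: motif 1,
#' \code{(YNHC)-(+/-)-L-(+/-)-phi-R}, and motif 2,
#' \code{L-X-L-phi-X-X-S-(RP)}, where X is any residue, +/- a charged
#' residue (D, E, K, R, H) and phi a nonpolar residue
#' (A, V, L, I, M, F, W, P, G, C).
#'
#' @return named list of two \code{degenerate_pattern} objects.
#' @export
motif_patterns <- function() {
  list(motif1 = degenerate_pattern("[YNHC]-c-L-c-h-R"),
       motif2 = degenerate_pattern("L-X-L-h-X-X-S-[RP]"))
}

#' Match a peptide against a degenerate pattern
#'
#' True iff some offset aligns every pattern position to a residue
#' satisfying its class or set; the first matching offset (1-based) is
#' attached as attribute \code{offset} (NA when no match).
#'
#' @param peptide a single peptide string.
#' @param pattern a \code{degenerate_pattern}.
#' @return logical scalar with attribute \code{offset}.
#' @examples
#' match_degenerate("YKLKIRTPQ", motif_patterns()$motif1)
#' @export
match_degenerate <- function(peptide, pattern) {
  off <- pattern_offsets(peptide, pattern)
  structure(!is.na(off), offset = off)
}

#' First matching offsets for a set of peptides
#'
#' Vectorised form of [match_degenerate()].
#'
#' @param peptides character vector.
#' @param pattern a \code{degenerate_pattern}.
#' @return integer vector of first matching offsets (NA when none).
#' @export
pattern_offsets <- function(peptides, pattern) {
  stopifnot(inherits(pattern, "degenerate_pattern"))
  w <- length(pattern)
  vapply(peptides, function(p) {
    L <- nchar(p)
    if (L < w) return(NA_integer_)
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    for (o in seq_len(L - w + 1L)) {
      hit <- TRUE
      for (k in seq_len(w)) {
        if (!(ch[o + k - 1L] %in% pattern[[k]])) { hit <- FALSE; break }
      }
      if (hit) return(o)
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

# ---- ZOOPS EM --------------------------------------------------------------

# encode peptides as list of integer vectors over 1..20
encode_peptides <- function(peptides) {
  lapply(strsplit(peptides, "", fixed = TRUE), function(ch) {
    ix <- match(ch, AA_STANDARD)
    if (anyNA(ix)) stop("peptides must use the 20 standard residues")
    ix
  })
}

# one EM run from a given initial pwm; returns converged model pieces.
# Objective traced is the Dirichlet-regularised log likelihood (observed
# log likelihood + fixed pseudo-count prior terms), which EM increases
# monotonically.
zoops_em_run <- function(enc, w, pwm0, lambda0, bg0, max_iter, tol,
                         model = "zoops", pc_pwm = 0.01 / 20,
                         pc_bg = 0.1 / 20) {
  n <- length(enc)
  m <- vapply(enc, length, integer(1)) - w + 1L
  tot_counts <- tabulate(unlist(enc), nbins = 20L)
  n_pos_total <- sum(vapply(enc, length, integer(1)))
  # window residue indices: for each seq, matrix w x m of codes
  windows <- lapply(enc, function(v) {
    mm <- length(v) - w + 1L
    matrix(v[outer(seq_len(w), seq_len(mm) - 1L, `+`)], nrow = w)
  })
  pwm <- pwm0; lambda <- lambda0; bg <- bg0
  trace <- numeric(0)
  obj_prev <- -Inf
  for (it in seq_len(max_iter)) {
    lpw <- log(pwm); lbg <- log(bg)
    ll <- 0
    post <- vector("list", n) # per-seq offset posteriors
    for (i in seq_len(n)) {
      win <- windows[[i]]
      # log LR of motif-at-j vs background for the window residues
      llr <- colSums(matrix(lpw[cbind(rep(seq_len(w), ncol(win)),
                                      as.vector(win))], nrow = w) -
                     matrix(lbg[as.vector(win)], nrow = w))
      bg_ll <- sum(lbg[enc[[i]]])
      if (model == "zoops") {
        r <- (lambda / m[i]) * exp(llr)
        denom <- (1 - lambda) + sum(r)
        post[[i]] <- r / denom
        ll <- ll + bg_ll + log(denom)
      } else { # oops: exactly one occurrence
        r <- exp(llr) / m[i]
        denom <- sum(r)
        post[[i]] <- r / denom
        ll <- ll + bg_ll + log(denom)
      }
    }
    # M-step: expected motif counts
    cnt <- matrix(0, w, 20L)
    q_sum <- 0
    for (i in seq_len(n)) {
      z <- post[[i]]
      q_sum <- q_sum + sum(z)
      win <- windows[[i]]
      for (j in seq_along(z)) {
        if (z[j] > 0)
          cnt[cbind(seq_len(w), win[, j])] <-
            cnt[cbind(seq_len(w), win[, j])] + z[j]
      }
    }
    pwm <- cnt + pc_pwm
    pwm <- pwm / rowSums(pwm)
    if (model == "zoops") lambda <- min(max(q_sum / n, 1e-6), 1 - 1e-9)
    bg_cnt <- pmax(tot_counts - colSums(cnt), 0) + pc_bg
    bg <- bg_cnt / sum(bg_cnt)
    obj <- ll + pc_pwm * sum(log(pwm)) + pc_bg * sum(log(bg))
    trace <- c(trace, obj)
    if (it > 1L && abs(obj - obj_prev) < tol * abs(obj_prev)) break
    obj_prev <- obj
  }
  # final posteriors and plain log likelihood under converged parameters
  lpw <- log(pwm); lbg <- log(bg)
  ll <- 0
  q_i <- numeric(n); best_off <- integer(n); best_p <- numeric(n)
  for (i in seq_len(n)) {
    win <- windows[[i]]
    llr <- colSums(matrix(lpw[cbind(rep(seq_len(w), ncol(win)),
                                    as.vector(win))], nrow = w) -
                   matrix(lbg[as.vector(win)], nrow = w))
    bg_ll <- sum(lbg[enc[[i]]])
    if (model == "zoops") {
      r <- (lambda / m[i]) * exp(llr)
      denom <- (1 - lambda) + sum(r)
    } else {
      r <- exp(llr) / m[i]
      denom <- sum(r)
    }
    z <- r / denom
    ll <- ll + bg_ll + log(denom)
    q_i[i] <- sum(z)
    best_off[i] <- which.max(z)
    best_p[i] <- z[best_off[i]]
  }
  list(pwm = pwm, lambda = lambda, background = bg, log_likelihood = ll,
       objective_trace = trace, iterations = length(trace),
       q = q_i, best_offset = best_off, best_offset_post = best_p)
}

#' Fit a ZOOPS motif model by expectation-maximisation
#'
#' Fits the zero-or-one-occurrence-per-sequence (ZOOPS) mixture model: each
#' peptide either contains one motif occurrence (probability
#' \code{lambda}, offset uniform over its admissible positions) drawn from
#' a width-\code{width} position weight matrix, or is pure background. EM
#' alternates posterior occurrence/offset computation with re-estimation
#' of the PWM (Dirichlet pseudo-counts), lambda, and the background
#' composition from non-motif positions. The run is repeated from
#' \code{n_starts} initialisations, each seeded from one observed
#' width-length subsequence smoothed toward the background, and the
#' highest-objective model is returned. The traced objective (the
#' pseudo-count-regularised log likelihood) is non-decreasing across
#' iterations within each start.
#'
#' @param peptides character vector of peptides (each at least
#'   \code{width} residues long, standard alphabet).
#' @param width motif width in residues.
#' @param n_starts number of seeded initialisations.
#' @param max_iter maximum EM iterations per start.
#' @param tol relative objective-change convergence threshold.
#' @param seed optional integer seed for the initialisation schedule.
#' @param model \code{"zoops"} (default) or \code{"oops"} (exactly one
#'   occurrence per sequence).
#' @return object of class \code{motif_model}: PWM (\code{width} x 20),
#'   background, lambda, log likelihood, objective trace, consensus, and
#'   \code{members} (peptides with posterior occurrence probability >
#'   0.5, with their best offsets). Degenerate input (a single distinct
#'   peptide) converges to a trivial motif and is flagged via
#'   \code{degenerate = TRUE}.
#' @examples
#' set.seed(1)
#' peps <- c(replicate(12, paste0(paste(sample(c("A","G","S"), 2, TRUE),
#'            collapse = ""), "LKLLAAS")),
#'           replicate(6, paste(sample(AA_STANDARD, 9, TRUE), collapse = "")))
#' m <- em_fit(peps, width = 7, n_starts = 4, seed = 1)
#' m
#' @export
em_fit <- function(peptides, width, n_starts = 10, max_iter = 500,
                   tol = 1e-6, seed = NULL, model = c("zoops", "oops")) {
  model <- match.arg(model)
  stopifnot(length(peptides) >= 2, n_starts >= 1, width >= 2)
  if (width > min(nchar(peptides)))
    stop("width exceeds the shortest peptide")
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_peptides(peptides)
  bg0 <- tabulate(unlist(enc), nbins = 20L) + 1
  bg0 <- bg0 / sum(bg0)
  # candidate start subsequences: all (sequence, offset) pairs
  cand <- do.call(rbind, lapply(seq_along(enc), function(i) {
    mm <- length(enc[[i]]) - width + 1L
    cbind(i, seq_len(mm))
  }))
  pick <- cand[sample.int(nrow(cand), min(n_starts, nrow(cand))), ,
               drop = FALSE]
  best <- NULL
  for (s in seq_len(nrow(pick))) {
    sub <- enc[[pick[s, 1L]]][pick[s, 2L] + seq_len(width) - 1L]
    pwm0 <- matrix(rep(bg0, each = width) * 0.4, width, 20L)
    pwm0[cbind(seq_len(width), sub)] <- pwm0[cbind(seq_len(width), sub)] + 0.6
    pwm0 <- pwm0 / rowSums(pwm0)
    run <- zoops_em_run(enc, width, pwm0, lambda0 = 0.5, bg0 = bg0,
                        max_iter = max_iter, tol = tol, model = model)
    if (is.null(best) ||
        run$objective_trace[length(run$objective_trace)] >
        best$objective_trace[length(best$objective_trace)])
      best <- run
  }
  members <- data.frame(index = which(best$q > 0.5),
                        peptide = peptides[best$q > 0.5],
                        offset = best$best_offset[best$q > 0.5],
                        posterior = best$q[best$q > 0.5],
                        stringsAsFactors = FALSE)
  rownames(members) <- NULL
  colnames(best$pwm) <- AA_STANDARD
  names(best$background) <- AA_STANDARD
  # background-only (null) log likelihood with empirical composition
  emp <- tabulate(unlist(enc), nbins = 20L)
  ll0 <- sum(emp * log(emp / sum(emp) + (emp == 0)))
  structure(list(width = width, pwm = best$pwm,
                 background = best$background, lambda = best$lambda,
                 log_likelihood = best$log_likelihood,
                 null_log_likelihood = ll0,
                 objective_trace = best$objective_trace,
                 iterations = best$iterations, members = members,
                 n_sequences = length(peptides), model = model,
                 degenerate = length(unique(peptides)) == 1L,
                 peptides = peptides),
            class = "motif_model")
}

#' Per-position information content of a motif
#'
#' Relative entropy of each PWM row against the background:
#' \eqn{IC_i = \sum_a p_{ia} \log_2(p_{ia}/b_a)} (bits, >= 0; 0 iff the
#' row equals the background). These are the column heights of a
#' relative-entropy sequence logo.
#'
#' @param model a \code{motif_model}, or a PWM matrix (positions x 20).
#' @param background background probabilities (taken from the model when
#'   given one).
#' @return numeric vector of per-position bits.
#' @export
information_content <- function(model, background = NULL) {
  if (inherits(model, "motif_model")) {
    pwm <- model$pwm
    background <- model$background
  } else pwm <- model
  stopifnot(is.matrix(pwm), ncol(pwm) == 20L, length(background) == 20L)
  apply(pwm, 1L, function(p) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / background[nz]))
  })
}

motif_consensus <- function(pwm) {
  paste(AA_STANDARD[apply(pwm, 1L, which.max)], collapse = "")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("ZOOPS motif model (width ", x$width, ", ", x$n_sequences,
      " sequences)\n", sep = "")
  cat("  consensus:       ", motif_consensus(x$pwm), "\n")
  cat("  lambda:          ", signif(x$lambda, 4), "\n")
  cat("  members (>0.5):  ", nrow(x$members), "\n")
  cat("  log likelihood:  ", signif(x$log_likelihood, 8),
      " (null ", signif(x$null_log_likelihood, 8), ")\n", sep = "")
  cat("  information:     ", paste(sprintf("%.2f", information_content(x)),
                                   collapse = " "), "bits\n")
  if (isTRUE(x$degenerate))
    cat("  NOTE: degenerate input (single distinct peptide)\n")
  invisible(x)
}

#' @export
summary.motif_model <- function(object, ...) {
  print(object)
  cat("\nPWM (rows = positions):\n")
  print(round(object$pwm, 3))
  invisible(object)
}

#' @export
logLik.motif_model <- function(object, ...) {
  structure(object$log_likelihood,
            df = object$width * 19 + 1 + 19, class = "logLik")
}

#' Plot a motif as a simple sequence logo
#'
#' Relative-entropy logo drawn with base graphics: at each position,
#' residues are stacked with heights proportional to
#' \code{pwm * information content}.
#'
#' @param x a \code{motif_model}.
#' @param min_prob residues below this probability are not drawn.
#' @param ... ignored.
#' @export
plot.motif_model <- function(x, min_prob = 0.02, ...) {
  ic <- information_content(x)
  w <- x$width
  plot(NA, xlim = c(0.5, w + 0.5), ylim = c(0, max(ic, 1e-3) * 1.05),
       xlab = "position", ylab = "bits", xaxt = "n",
       main = paste("motif:", motif_consensus(x$pwm)))
  axis(1, at = seq_len(w))
  for (i in seq_len(w)) {
    p <- x$pwm[i, ]
    ord <- order(p)
    y0 <- 0
    for (a in ord) {
      h <- p[a] * ic[i]
      if (p[a] >= min_prob && h > 0) {
        text(i, y0 + h / 2, AA_STANDARD[a], cex = 0.5 + 3 * p[a],
             col = if (AA_STANDARD[a] %in% RESIDUES_CHARGED) "firebrick"
                   else if (AA_STANDARD[a] %in% RESIDUES_NONPOLAR) "navy"
                   else "darkgreen")
      }
      y0 <- y0 + h
    }
  }
  invisible(x)
}

#' Sequential discovery of multiple motifs
#'
#' Discovers \code{n_motifs} motifs one after another. For each motif the
#' candidate widths are scanned and the width maximising the likelihood
#' ratio against the background-only model is kept; member sequences of
#' the accepted motif are then erased (removed) before the next round of
#' discovery -- the simplest faithful variant of MEME-style sequential
#' elicitation.
#'
#' @param peptides character vector of peptides.
#' @param n_motifs how many motifs to report.
#' @param widths candidate motif widths (default 6--8).
#' @param n_starts,max_iter,tol,seed,model passed to [em_fit()].
#' @return list of class \code{motif_set}: \code{motifs} (list of
#'   \code{motif_model}) and \code{remaining} peptides after erasure.
#' @export
discover_motifs <- function(peptides, n_motifs = 2, widths = 6:8,
                            n_starts = 10, max_iter = 500, tol = 1e-6,
                            seed = NULL, model = "zoops") {
  if (!is.null(seed)) set.seed(seed)
  motifs <- list()
  pool <- peptides
  pool_idx <- seq_along(peptides) # map back to the input after erasure
  for (k in seq_len(n_motifs)) {
    widths_k <- widths[widths <= min(nchar(pool))]
    if (length(pool) < 2L || length(widths_k) == 0L) break
    fits <- lapply(widths_k, function(w)
      em_fit(pool, w, n_starts = n_starts, max_iter = max_iter, tol = tol,
             seed = sample.int(.Machine$integer.max, 1L), model = model))
    lr <- vapply(fits, function(f) f$log_likelihood - f$null_log_likelihood,
                 numeric(1))
    best <- fits[[which.max(lr)]]
    local <- best$members$index
    best$members$index <- pool_idx[local]
    motifs[[k]] <- best
    if (length(local) == 0L) break
    pool <- pool[-local]
    pool_idx <- pool_idx[-local]
  }
  structure(list(motifs = motifs, remaining = pool, input = peptides),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat("Motif set:", length(x$motifs), "motifs from",
      length(x$input), "peptides\n")
  for (i in seq_along(x$motifs)) {
    cat("\n-- motif", i, "--\n")
    print(x$motifs[[i]])
  }
  invisible(x)
}

#' Write a motif PWM as TSV (rows = positions, columns = residues)
#'
#' @param model a \code{motif_model}.
#' @param path TSV path.
#' @export
write_motif_tsv <- function(model, path) {
  df <- data.frame(position = seq_len(model$width), round(model$pwm, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate peptides with a planted motif core
#'
#' Generates \code{n_signal} peptides carrying the consensus core at a
#' uniformly random admissible offset (each core position reproduces the
#' consensus residue with probability \code{fidelity}, otherwise a random
#' residue) among \code{n_background} fully random peptides. Ground-truth
#' offsets (NA for background) are attached.
#'
#' @param n_signal,n_background numbers of motif-bearing and background
#'   peptides.
#' @param consensus consensus core sequence to plant.
#' @param peptide_length total peptide length.
#' @param fidelity per-position probability of the consensus residue.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{peptide}, \code{is_signal},
#'   \code{offset}.
#' @export
simulate_motif_peptides <- function(n_signal, n_background,
                                    consensus = "LKLLAASR",
                                    peptide_length = 9, fidelity = 0.9,
                                    seed = NULL) {
  stopifnot(nchar(consensus) <= peptide_length, fidelity >= 0, fidelity <= 1)
  if (!is.null(seed)) set.seed(seed)
  w <- nchar(consensus)
  core <- strsplit(consensus, "", fixed = TRUE)[[1]]
  n_off <- peptide_length - w + 1L
  make_one <- function(signal) {
    ch <- sample(AA_STANDARD, peptide_length, replace = TRUE)
    off <- NA_integer_
    if (signal) {
      off <- sample.int(n_off, 1L)
      keep <- runif(w) < fidelity
      ch[off + seq_len(w) - 1L] <- ifelse(keep, core,
                                          sample(AA_STANDARD, w, TRUE))
    }
    list(paste(ch, collapse = ""), off)
  }
  sig <- lapply(seq_len(n_signal), function(i) make_one(TRUE))
  bgp <- lapply(seq_len(n_background), function(i) make_one(FALSE))
  all <- c(sig, bgp)
  data.frame(peptide = vapply(all, `[[`, character(1), 1L),
             is_signal = rep(c(TRUE, FALSE), c(n_signal, n_background)),
             offset = vapply(all, function(z) as.integer(z[[2]]), integer(1)),
             stringsAsFactors = FALSE)
}
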