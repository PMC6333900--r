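# One-site ITC binding model: perfusion-cell concentration bookkeeping,
# mass-action complex concentration, injection-heat prediction with the
# displaced-volume correction, synthetic titrations, and weighted
# nonlinear least-squares fitting. Calories are used internally
# (MicroCal convention); user-facing enthalpies are kcal/mol.

#' Define an ITC titration protocol
#'
#' @param cell_volume active cell volume V0 in litres (default 1.4 mL,
#'   a VP-ITC cell).
#' @param cell_conc initial cell (protein) concentration M0 in molar.
#' @param syringe_conc syringe (titrant) concentration in molar.
#' @param injection_volumes per-injection volumes in litres.
#' @param temperature kelvin.
#' @return object of class \code{itc_protocol}.
#' @examples
#' itc_protocol() # 30 uM protein, 300 uM peptide, 30 x 8 uL at 25 C
#' @export
itc_protocol <- function(cell_volume = 1.4e-3, cell_conc = 30e-6,
                         syringe_conc = 300e-6,
                         injection_volumes = rep(8e-6, 30),
                         temperature = 298.15) {
  stopifnot(cell_volume > 0, cell_conc > 0, syringe_conc > 0,
            all(injection_volumes > 0), temperature > 0)
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes = injection_volumes,
                 temperature = temperature),
            class = "itc_protocol")
}

#' @export
print.itc_protocol <- function(x, ...) {
  cat(sprintf(
    "ITC protocol: %.3g uM cell (V0 = %.3g mL), %.3g uM syringe, %d injections (%.3g uL), %.2f K\n",
    x$cell_conc * 1e6, x$cell_volume * 1e3, x$syringe_conc * 1e6,
    length(x$injection_volumes), mean(x$injection_volumes) * 1e6,
    x$temperature))
  invisible(x)
}

#' Effective cell concentrations after injection i
#'
#' Standard continuous (exponential) correction for an overfilled
#' perfusion cell: with cumulative injected volume \eqn{\Delta V_i},
#' \eqn{M_i = M_0 e^{-\Delta V_i/V_0}} and
#' \eqn{X_i = X_s (1 - e^{-\Delta V_i/V_0})}.
#'
#' @param protocol an \code{itc_protocol}.
#' @param i injection indices (default all).
#' @return data.frame with columns \code{M} (cell species) and \code{X}
#'   (titrant), molar.
#' @export
effective_concentrations <- function(protocol,
                                     i = seq_along(protocol$injection_volumes)) {
  stopifnot(all(i >= 1), all(i <= length(protocol$injection_volumes)))
  dv <- cumsum(protocol$injection_volumes)[i]
  f <- exp(-dv / protocol$cell_volume)
  data.frame(M = protocol$cell_conc * f,
             X = protocol$syringe_conc * (1 - f))
}

#' Equilibrium complex concentration for one-site binding
#'
#' Physical root of the mass-action quadratic
#' \eqn{[c]^2 - [c](N M_t + X_t + K_D) + N M_t X_t = 0}; always within
#' \code{[0, min(N*M_t, X_t)]}. Evaluated in the numerically stable form
#' \eqn{2 N M_t X_t / (b + \sqrt{b^2 - 4 N M_t X_t})}.
#'
#' @param M_t total cell-species concentration (molar).
#' @param X_t total titrant concentration (molar, may be 0).
#' @param K_D dissociation constant (molar, > 0).
#' @param N stoichiometry (sites per cell-species molecule).
#' @return complex concentration (molar); vectorised.
#' @export
bound_fraction <- function(M_t, X_t, K_D, N = 1) {
  stopifnot(all(M_t > 0), all(X_t >= 0), all(K_D > 0), all(N > 0))
  b <- N * M_t + X_t + K_D
  disc <- b^2 - 4 * N * M_t * X_t
  2 * N * M_t * X_t / (b + sqrt(pmax(disc, 0)))
}

#' Predict per-injection ITC heats under the one-site model
#'
#' Cumulative heat content after injection i is
#' \eqn{Q_i = V_0 \Delta H [c]_i} with post-injection concentrations from
#' [effective_concentrations()]. The measured per-injection heat applies
#' the displaced-volume correction
#' \deqn{\delta Q_i = Q_i - Q_{i-1} + \frac{v_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2}}
#' and is normalised by the moles injected, plus the dilution-heat offset
#' \code{q_dil}.
#'
#' @param protocol an \code{itc_protocol}.
#' @param N stoichiometry.
#' @param K_D dissociation constant (molar).
#' @param dH binding enthalpy, kcal/mol.
#' @param q_dil constant dilution-heat offset, kcal per mole of injectant.
#' @return object of class \code{injection_heats}: data.frame with columns
#'   \code{injection}, \code{volume_l}, \code{heat_cal} (measured heat,
#'   calories, including dilution), \code{normalized_kcal_per_mol}; the
#'   protocol and generating parameters are kept as attributes.
#' @export
predict_heats <- function(protocol, N, K_D, dH, q_dil = 0) {
  stopifnot(inherits(protocol, "itc_protocol"), K_D > 0, N > 0)
  v <- protocol$injection_volumes
  conc <- effective_concentrations(protocol)
  cplx <- bound_fraction(conc$M, conc$X, K_D, N)
  dH_cal <- dH * 1000
  q_cum <- protocol$cell_volume * dH_cal * cplx
  q_prev <- c(0, q_cum[-length(q_cum)])
  dq <- q_cum - q_prev + (v / protocol$cell_volume) * (q_cum + q_prev) / 2
  moles <- protocol$syringe_conc * v
  norm <- dq / (moles * 1000) + q_dil
  out <- data.frame(injection = seq_along(v), volume_l = v,
                    heat_cal = dq + q_dil * 1000 * moles,
                    normalized_kcal_per_mol = norm)
  structure(out, class = c("injection_heats", "data.frame"),
            protocol = protocol,
            params = c(N = N, K_D = K_D, dH = dH, q_dil = q_dil))
}

#' Simulate a noisy ITC titration
#'
#' [predict_heats()] plus i.i.d. Gaussian noise on the normalised heats.
#' The noise standard deviation may be given absolutely
#' (\code{noise_sd}, kcal/mol) or as a fraction of the peak model heat
#' (\code{noise_frac}; sd = \code{noise_frac * max|model - q_dil|}).
#'
#' @inheritParams predict_heats
#' @param noise_sd absolute noise sd, kcal/mol (ignored when
#'   \code{noise_frac} given).
#' @param noise_frac optional noise sd as a fraction of the peak heat.
#' @param seed optional integer seed; same seed, same output.
#' @return an \code{injection_heats} object.
#' @export
simulate_titration <- function(protocol, N, K_D, dH, q_dil = 0,
                               noise_sd = 0, noise_frac = NULL,
                               seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  h <- predict_heats(protocol, N, K_D, dH, q_dil)
  if (!is.null(noise_frac))
    noise_sd <- noise_frac * max(abs(h$normalized_kcal_per_mol - q_dil))
  if (noise_sd > 0) {
    eps <- rnorm(nrow(h), 0, noise_sd)
    h$normalized_kcal_per_mol <- h$normalized_kcal_per_mol + eps
    moles <- attr(h, "protocol")$syringe_conc * h$volume_l
    h$heat_cal <- h$heat_cal + eps * 1000 * moles
  }
  attr(h, "noise_sd") <- noise_sd
  h
}

#' Write / read per-injection heats as CSV
#'
#' Columns \code{injection_index}, \code{volume_ul}, \code{heat_ucal},
#' \code{normalized_kcal_per_mol} (microlitre / microcalorie units at
#' I/O).
#'
#' @param heats an \code{injection_heats} object.
#' @param path CSV path.
#' @rdname heats_io
#' @export
write_injection_heats <- function(heats, path) {
  df <- data.frame(injection_index = heats$injection,
                   volume_ul = heats$volume_l * 1e6,
                   heat_ucal = heats$heat_cal * 1e6,
                   normalized_kcal_per_mol = heats$normalized_kcal_per_mol)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param protocol an \code{itc_protocol} to attach (cell volume and
#'   concentrations are not stored in the CSV).
#' @rdname heats_io
#' @export
read_injection_heats <- function(path, protocol) {
  df <- read.csv(path, comment.char = "#")
  out <- data.frame(injection = df$injection_index,
                    volume_l = df$volume_ul / 1e6,
                    heat_cal = df$heat_ucal / 1e6,
                    normalized_kcal_per_mol = df$normalized_kcal_per_mol)
  structure(out, class = c("injection_heats", "data.frame"),
            protocol = protocol)
}

#' Fit the one-site binding model to injection heats
#'
#' Nonlinear least squares on the normalised heats over
#' (N, log K_a, dH, q_dil), Levenberg-Marquardt, multi-started over a
#' log-spaced K_a grid; uniform residual weights. Standard errors come
#' from the Jacobian at the optimum; the K_D error is obtained from the
#' log K_a error by the delta method. When the Wiseman c-value
#' \code{N*M0/K_D} falls outside [0.1, 1000] the K_D standard error is
#' suppressed (NA) unless \code{force_se = TRUE}, since the isotherm
#' shape no longer constrains K_D. The first injection is excluded by
#' default (syringe-tip diffusion).
#'
#' @param heats an \code{injection_heats} object (or data.frame with the
#'   same columns).
#' @param protocol the titration protocol (defaults to the one attached
#'   to \code{heats}).
#' @param exclude_first drop injection 1 from the fit (default TRUE).
#' @param float_N estimate stoichiometry N (default) or fix it at
#'   \code{N_fixed}.
#' @param N_fixed value of N when not floated.
#' @param Ka_grid multi-start association-constant grid (1/M).
#' @param force_se report the K_D standard error even outside the
#'   informative c-value range.
#' @return object of class \code{onesite_fit} with components
#'   \code{coefficients} (N, K_D, dH, q_dil), \code{se}, \code{K_a},
#'   \code{c_value}, \code{rss}, \code{sigma}, \code{fitted},
#'   \code{residuals}, \code{identifiable}, \code{converged}.
#' @examples
#' pr <- itc_protocol()
#' h <- simulate_titration(pr, N = 1, K_D = 8.86e-6, dH = -8, q_dil = -0.05,
#'                         noise_frac = 0.02, seed = 7)
#' fit <- fit_one_site(h)
#' fit
#' @export
fit_one_site <- function(heats, protocol = attr(heats, "protocol"),
                         exclude_first = TRUE, float_N = TRUE, N_fixed = 1,
                         Ka_grid = 10^seq(3, 9, by = 1), force_se = FALSE) {
  stopifnot(inherits(protocol, "itc_protocol"))
  y <- heats$normalized_kcal_per_mol
  idx <- seq_along(y)
  if (exclude_first) idx <- idx[-1]
  if (length(idx) < 6L) stop("need at least 6 usable injections")
  yy <- y[idx]
  model_norm <- function(N, K_D, dH, q_dil)
    predict_heats(protocol, N, K_D, dH, q_dil)$normalized_kcal_per_mol[idx]
  dH0 <- yy[1] - yy[length(yy)]
  if (abs(dH0) < 1e-8) dH0 <- 1e-8
  q0 <- yy[length(yy)]
  resid_fun <- function(par) {
    N <- if (float_N) par[["N"]] else N_fixed
    if (N <= 0) return(rep(1e6, length(yy)))
    K_D <- exp(-par[["lKa"]])
    yy - model_norm(N, K_D, par[["dH"]], par[["q_dil"]])
  }
  best <- NULL
  for (Ka0 in Ka_grid) {
    par0 <- c(dH = dH0, q_dil = q0, lKa = log(Ka0))
    if (float_N) par0 <- c(N = 1, par0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("one-site fit failed to converge from every start")
  par <- best$par
  N_hat <- if (float_N) par[["N"]] else N_fixed
  K_D <- exp(-par[["lKa"]])
  K_a <- 1 / K_D
  p <- length(par)
  dof <- length(yy) - p
  rss <- best$deviance
  sigma2 <- if (dof > 0) rss / dof else NA_real_
  vc <- tryCatch(sigma2 * solve(best$hessian), error = function(e) NULL)
  identifiable <- !is.null(vc) && all(is.finite(diag(vc))) &&
    all(diag(vc) >= 0)
  se_par <- if (identifiable) sqrt(diag(vc)) else
    setNames(rep(NA_real_, p), names(par))
  se <- c(N = if (float_N) unname(se_par[["N"]]) else 0,
          K_D = unname(K_D * se_par[["lKa"]]), # delta method on log Ka
          dH = unname(se_par[["dH"]]),
          q_dil = unname(se_par[["q_dil"]]))
  c_value <- N_hat * protocol$cell_conc / K_D
  if ((c_value < 0.1 || c_value > 1000) && !force_se) {
    if (!is.na(se[["K_D"]]))
      warning(sprintf(
        "c-value %.3g outside [0.1, 1000]; K_D standard error suppressed (force_se = TRUE to keep)",
        c_value))
    se[["K_D"]] <- NA_real_
  }
  fitted_all <- predict_heats(protocol, N_hat, K_D, par[["dH"]],
                              par[["q_dil"]])$normalized_kcal_per_mol
  structure(list(coefficients = c(N = N_hat, K_D = K_D,
                                  dH = unname(par[["dH"]]),
                                  q_dil = unname(par[["q_dil"]])),
                 se = se, K_a = K_a, c_value = c_value, rss = rss,
                 sigma = sqrt(sigma2), df = dof, fitted = fitted_all,
                 residuals = y - fitted_all, excluded = setdiff(seq_along(y), idx),
                 identifiable = identifiable,
                 converged = best$info %in% 1:4,
                 protocol = protocol, heats = heats, float_N = float_N),
            class = "onesite_fit")
}

#' @export
print.onesite_fit <- function(x, ...) {
  co <- x$coefficients
  se <- x$se
  fmt <- function(v, s, scale = 1, unit = "") {
    if (is.na(s)) sprintf("%.4g%s (SE n/a)", v * scale, unit)
    else sprintf("%.4g +/- %.2g%s", v * scale, s * scale, unit)
  }
  cat("One-site ITC fit", if (!x$converged) " (NOT converged)" else "", "\n",
      sep = "")
  cat("  N      =", fmt(co[["N"]], se[["N"]]), "\n")
  cat("  K_D    =", fmt(co[["K_D"]], se[["K_D"]], 1e6, " uM"), "\n")
  cat("  dH     =", fmt(co[["dH"]], se[["dH"]], 1, " kcal/mol"), "\n")
  cat("  q_dil  =", fmt(co[["q_dil"]], se[["q_dil"]], 1, " kcal/mol"), "\n")
  cat(sprintf("  c-value = %.3g; RSS = %.4g; sigma = %.3g kcal/mol\n",
              x$c_value, x$rss, x$sigma))
  if (!x$identifiable)
    cat("  WARNING: parameters not identifiable from these data\n")
  invisible(x)
}

#' @export
summary.onesite_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  out <- list(coefficients = tab, c_value = object$c_value,
              rss = object$rss, sigma = object$sigma, df = object$df,
              identifiable = object$identifiable)
  class(out) <- "summary.onesite_fit"
  out
}

#' @export
print.summary.onesite_fit <- function(x, ...) {
  printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("\nc-value %.3g, residual sd %.3g kcal/mol on %d df\n",
              x$c_value, x$sigma, x$df))
  invisible(x)
}

#' @export
coef.onesite_fit <- function(object, ...) object$coefficients

#' @export
vcov.onesite_fit <- function(object, ...) {
  d <- object$se
  warning("vcov from marginal standard errors (diagonal only)")
  diag(d^2, nrow = length(d))
}

#' @export
fitted.onesite_fit <- function(object, ...) object$fitted

#' @export
residuals.onesite_fit <- function(object, ...) object$residuals

#' @export
predict.onesite_fit <- function(object, protocol = object$protocol, ...) {
  co <- object$coefficients
  predict_heats(protocol, co[["N"]], co[["K_D"]], co[["dH"]], co[["q_dil"]])
}

#' @export
simulate.onesite_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  co <- object$coefficients
  lapply(seq_len(nsim), function(i)
    simulate_titration(object$protocol, co[["N"]], co[["K_D"]], co[["dH"]],
                       co[["q_dil"]], noise_sd = object$sigma))
}

#' Plot an ITC binding isotherm with its one-site fit
#'
#' Normalised heats against the molar ratio titrant/protein, with the
#' fitted isotherm overlaid.
#'
#' @param x a \code{onesite_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.onesite_fit <- function(x, ...) {
  conc <- effective_concentrations(x$protocol)
  ratio <- conc$X / conc$M
  y <- x$heats$normalized_kcal_per_mol
  plot(ratio, y, pch = 19, xlab = "molar ratio [X]/[M]",
       ylab = "kcal/mol of injectant", ...)
  lines(ratio, x$fitted, col = "firebrick", lwd = 2)
  if (length(x$excluded))
    points(ratio[x$excluded], y[x$excluded], pch = 1, col = "grey50")
  invisible(x)
}

#' Integrate a power trace into per-injection heats
#'
#' Trapezoidal integration of a (synthetic) differential-power trace
#' between injection boundaries. Peak integration of real instrument
#' traces with baseline estimation is out of scope; this helper exists
#' for synthetic traces only.
#'
#' @param time time points (s).
#' @param power differential power (ucal/s).
#' @param boundaries injection start times (s); each injection integrates
#'   to the next boundary (or the end of the trace).
#' @return numeric vector of per-injection heats (ucal).
#' @export
integrate_power <- function(time, power, boundaries) {
  stopifnot(length(time) == length(power), !is.unsorted(time))
  ends <- c(boundaries[-1], Inf)
  vapply(seq_along(boundaries), function(i) {
    # half-open [b_i, b_{i+1}): the next peak's onset sample belongs to
    # the next injection
    sel <- time >= boundaries[i] & time < ends[i]
    tt <- time[sel]; pp <- power[sel]
    if (length(tt) < 2L) return(0)
    sum(diff(tt) * (pp[-1] + pp[-length(pp)]) / 2)
  }, numeric(1))
}
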