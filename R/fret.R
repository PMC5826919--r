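# Donor-photobleaching FRET: energy transfer to an acceptor slows the
# donor's photobleaching, so the interaction is read out as
# E = 1 - tau_PB / tau'_PB, where tau_PB is the donor-only photobleaching
# time constant and tau'_PB the time constant in the presence of the
# acceptor fusion. Negative estimates are reported as-is (faster bleaching
# with the acceptor present), never clipped.

#' Extract a bleach trace from an image stack
#'
#' Per-frame mean intensity over an ROI mask.
#'
#' @param stack 3-D array `[frame, y, x]`.
#' @param roi_mask logical matrix `[y, x]`, non-empty, same frame shape.
#' @param ... labels passed to [bleach_trace()].
#' @return A [bleach_trace()].
#' @export
extract_trace <- function(stack, roi_mask, ...) {
  stopifnot(length(dim(stack)) == 3L, is.logical(roi_mask))
  if (!all(dim(roi_mask) == dim(stack)[2:3])) {
    stopf("ROI mask shape %dx%d does not match frames %dx%d",
          nrow(roi_mask), ncol(roi_mask), dim(stack)[2], dim(stack)[3])
  }
  if (!any(roi_mask)) stopf("ROI mask is empty")
  flat <- matrix(stack, nrow = dim(stack)[1])
  intensity <- rowMeans(flat[, as.logical(roi_mask), drop = FALSE])
  bleach_trace(intensity, ...)
}

#' Fit a mono-exponential photobleaching decay
#'
#' Least-squares fit of `I(t) = A * exp(-t / tau) + B` (offset optional) by
#' Levenberg-Marquardt, initialised from a log-linear regression of the
#' baseline-subtracted early frames. Frames at the quantisation floor are
#' trimmed from the tail. Non-converged fits are returned flagged, never
#' silently.
#'
#' @param trace a [bleach_trace()] (or numeric vector of intensities).
#' @param offset logical: include the baseline term B (default TRUE; fixed
#'   cells on slides retain non-bleaching background).
#' @param floor_threshold intensities at or below this are treated as the
#'   quantisation floor and trimmed from the tail (default 0).
#' @return Object of class `cocciq_decay_fit`: `tau_frames`, `amplitude`,
#'   `offset`, `residual_rms`, `converged`, `diagnostic`, `n_frames_used`.
#' @export
fit_decay <- function(trace, offset = TRUE, floor_threshold = 0) {
  I <- if (inherits(trace, "cocciq_bleach_trace")) trace$intensity
       else as.numeric(trace)
  n <- length(I)
  if (n < 10) stopf("decay fit needs >= 10 frames")
  keep <- n
  while (keep > 1 && I[keep] <= floor_threshold) keep <- keep - 1
  I <- I[seq_len(keep)]
  t <- seq_len(keep) - 1
  fail <- function(msg) {
    structure(list(tau_frames = NA_real_, amplitude = NA_real_,
                   offset = NA_real_, residual_rms = NA_real_,
                   converged = FALSE, diagnostic = msg,
                   n_frames_used = keep),
              class = "cocciq_decay_fit")
  }
  if (keep < 10) return(fail("fewer than 10 frames above the floor"))
  if (max(I) - min(I) <= 0) return(fail("constant trace"))
  slope <- coef(lm(I ~ t))[2]
  if (!is.finite(slope) || slope >= 0) {
    return(fail("trace is not decreasing"))
  }
  # Profiled least squares: at fixed tau the model is linear in (A, B), so
  # the amplitude and offset are solved in closed form and tau is found by
  # 1-D minimisation of the profiled RSS over log(tau). A log-linear
  # regression on the baseline-subtracted early frames brackets the search;
  # a Levenberg-Marquardt polish is applied when it improves the fit.
  lin_fit <- function(tau) {
    x <- exp(-t / tau)
    X <- if (offset) cbind(x, 1) else cbind(x)
    cf <- tryCatch(qr.coef(qr(X), I), error = function(e) rep(NA_real_, ncol(X)))
    if (anyNA(cf)) return(list(rss = Inf, A = NA_real_, B = NA_real_))
    r <- I - X %*% cf
    list(rss = sum(r^2), A = unname(cf[1]), B = if (offset) unname(cf[2]) else 0)
  }
  B0 <- if (offset) max(0, min(I) - 1e-12) else 0
  y <- pmax(I - B0, max(I) * 1e-9)
  n_early <- suppressWarnings(min(which(y < 0.05 * y[1])) - 1)
  if (!is.finite(n_early)) n_early <- keep
  early <- seq_len(min(keep, max(10, n_early)))
  ll <- coef(lm(log(y[early]) ~ t[early]))
  tau0 <- if (is.finite(ll[2]) && ll[2] < 0) -1 / ll[2] else keep / 3
  lo <- log(max(min(tau0 / 50, 1), 1e-2))
  hi <- log(max(tau0 * 50, 50 * keep))
  opt <- stats::optimize(function(lt) lin_fit(exp(lt))$rss, c(lo, hi),
                         tol = 1e-10)
  tau_hat <- exp(opt$minimum)
  prof <- lin_fit(tau_hat)
  if (!is.finite(prof$rss) || prof$A <= 0) {
    return(fail("profiled least squares degenerate"))
  }
  # LM polish from the profiled solution
  polish <- tryCatch({
    if (offset) {
      minpack.lm::nlsLM(I ~ A * exp(-t / tau) + B,
                        start = list(A = prof$A, tau = tau_hat, B = max(prof$B, 0)),
                        lower = c(A = 0, tau = 1e-3, B = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 100))
    } else {
      minpack.lm::nlsLM(I ~ A * exp(-t / tau),
                        start = list(A = prof$A, tau = tau_hat),
                        lower = c(A = 0, tau = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 100))
    }
  }, error = function(e) NULL)
  if (!is.null(polish) && sum(residuals(polish)^2) <= prof$rss) {
    cf <- coef(polish)
    tau_hat <- unname(cf[["tau"]])
    prof <- list(rss = sum(residuals(polish)^2), A = unname(cf[["A"]]),
                 B = if (offset) unname(cf[["B"]]) else 0)
  }
  if (!is.finite(tau_hat) || tau_hat <= 0) {
    return(fail("fitted time constant not positive"))
  }
  structure(list(tau_frames = tau_hat,
                 amplitude = unname(prof$A),
                 offset = unname(prof$B),
                 residual_rms = sqrt(prof$rss / keep),
                 converged = TRUE, diagnostic = "ok",
                 n_frames_used = keep),
            class = "cocciq_decay_fit")
}

converged_taus <- function(fits, arm) {
  if (inherits(fits, "cocciq_decay_fit")) fits <- list(fits)
  taus <- vapply(fits, function(f) {
    stopifnot(inherits(f, "cocciq_decay_fit"))
    if (isTRUE(f$converged)) f$tau_frames else NA_real_
  }, numeric(1))
  taus <- taus[is.finite(taus)]
  if (!length(taus)) stopf("no converged decay fits in the %s arm", arm)
  taus
}

#' FRET efficiency from two arms of decay fits
#'
#' Each arm's time constant is the arithmetic mean of its converged per-cell
#' time constants (the alternative — efficiency per acceptor cell against the
#' donor-arm mean, then averaged — is available via `aggregate`), and
#' `E = 1 - tau_donor_only / tau_with_acceptor`, reported as a percentage.
#' Uncertainty is a seeded percentile bootstrap resampling cells within each
#' arm.
#'
#' @param donor_only_fits list of [fit_decay()] results for the donor-only
#'   arm (tau_PB).
#' @param with_acceptor_fits list of fits for the donor-plus-acceptor arm
#'   (tau'_PB).
#' @param n_boot bootstrap resamples (default 1000; 0 disables).
#' @param seed bootstrap seed.
#' @param aggregate `"mean_tau"` (default) or `"per_cell"`.
#' @param compartment optional label carried into the result.
#' @return Object of class `cocciq_fret_result`: `efficiency` (fraction,
#'   may be negative), `efficiency_pct`, `tau_donor_only`,
#'   `tau_with_acceptor`, `ci_pct` (bootstrap 95%), `n_cells_each_arm`,
#'   `compartment`.
#' @export
fret_efficiency <- function(donor_only_fits, with_acceptor_fits,
                            n_boot = 1000, seed = NULL,
                            aggregate = c("mean_tau", "per_cell"),
                            compartment = NA_character_) {
  aggregate <- match.arg(aggregate)
  tau_d <- converged_taus(donor_only_fits, "donor-only")
  tau_a <- converged_taus(with_acceptor_fits, "donor-plus-acceptor")
  eff <- function(td, ta) {
    if (aggregate == "mean_tau") 1 - mean(td) / mean(ta)
    else mean(1 - mean(td) / ta)
  }
  E <- eff(tau_d, tau_a)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot <- with_seed_if(seed, {
      vapply(seq_len(n_boot), function(i) {
        eff(sample(tau_d, replace = TRUE), sample(tau_a, replace = TRUE))
      }, numeric(1))
    })
    ci <- unname(quantile(boot, c(0.025, 0.975)))
  }
  structure(list(efficiency = E, efficiency_pct = 100 * E,
                 tau_donor_only = mean(tau_d),
                 tau_with_acceptor = mean(tau_a),
                 ci_pct = 100 * ci,
                 n_cells_each_arm = c(donor_only = length(tau_d),
                                      with_acceptor = length(tau_a)),
                 compartment = compartment),
            class = "cocciq_fret_result")
}

#' Subcellular FRET analysis
#'
#' Splits labelled traces by compartment (division_state x roi_label), fits
#' every trace, and computes one FRET efficiency per compartment of the
#' design. Compartments with no traces at all are reported absent; a
#' compartment missing its donor-only arm is reported as an error row while
#' the remaining compartments are still analysed. Dividing cells are
#' conventionally dissected into septum and periphery ROIs.
#'
#' @param traces list of labelled [bleach_trace()] objects (attributes
#'   `roi_label`, `division_state`, `condition`).
#' @param n_boot,seed bootstrap settings, see [fret_efficiency()].
#' @param offset passed to [fit_decay()].
#' @return data.frame with one row per (division_state x roi_label):
#'   taus, `efficiency_pct`, bootstrap CI, arm sizes and a `status` column
#'   (`"ok"`, `"absent"`, or an error message).
#' @export
subcellular_fret <- function(traces, n_boot = 1000, seed = NULL,
                             offset = TRUE) {
  stopifnot(is.list(traces), length(traces) > 0)
  lab <- function(tr, a) attr(tr, a) %||% NA_character_
  keys <- data.frame(
    division_state = vapply(traces, lab, character(1), a = "division_state"),
    roi_label = vapply(traces, lab, character(1), a = "roi_label"),
    condition = vapply(traces, lab, character(1), a = "condition"),
    stringsAsFactors = FALSE)
  if (anyNA(keys)) stopf("every trace must carry roi_label, division_state and condition labels")
  design <- unique(keys[c("division_state", "roi_label")])
  design <- design[order(design$division_state, design$roi_label), ]
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    ds <- design$division_state[i]; roi <- design$roi_label[i]
    in_comp <- keys$division_state == ds & keys$roi_label == roi
    row <- data.frame(division_state = ds, roi_label = roi,
                      tau_donor_only = NA_real_, tau_with_acceptor = NA_real_,
                      efficiency_pct = NA_real_, ci_lo_pct = NA_real_,
                      ci_hi_pct = NA_real_, n_donor = 0L, n_acceptor = 0L,
                      status = "absent", stringsAsFactors = FALSE)
    if (any(in_comp)) {
      don <- traces[in_comp & keys$condition == "donor_only"]
      acc <- traces[in_comp & keys$condition == "donor_plus_acceptor"]
      res <- tryCatch({
        if (!length(don)) stopf("compartment %s/%s lacks a donor-only arm", ds, roi)
        if (!length(acc)) stopf("compartment %s/%s lacks an acceptor arm", ds, roi)
        fd <- lapply(don, fit_decay, offset = offset)
        fa <- lapply(acc, fit_decay, offset = offset)
        fret_efficiency(fd, fa, n_boot = n_boot,
                        seed = if (is.null(seed)) NULL else seed + i,
                        compartment = paste(ds, roi, sep = "/"))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$status <- conditionMessage(res)
      } else {
        row$tau_donor_only <- res$tau_donor_only
        row$tau_with_acceptor <- res$tau_with_acceptor
        row$efficiency_pct <- res$efficiency_pct
        row$ci_lo_pct <- res$ci_pct[1]; row$ci_hi_pct <- res$ci_pct[2]
        row$n_donor <- unname(res$n_cells_each_arm["donor_only"])
        row$n_acceptor <- unname(res$n_cells_each_arm["with_acceptor"])
        row$status <- "ok"
      }
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
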