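#' Injection schedule for SPR experiments
#'
#' Ordered, contiguous, non-overlapping segments of constant analyte
#' concentration, as in single-cycle kinetics: several ascending
#' injections followed by a dissociation phase at concentration 0.
#'
#' @param start,end segment boundaries in seconds (each segment
#'   `[start, end)`; `start[i+1]` must equal `end[i]`).
#' @param concentration analyte concentration per segment, molar
#'   (0 for dissociation segments).
#' @return an `injection_schedule` data frame.
#' @export
injection_schedule <- function(start, end, concentration) {
  if (!(length(start) == length(end) && length(end) == length(concentration)))
    stop("start, end and concentration must have equal lengths")
  if (any(end <= start)) stop("segment times must be increasing")
  if (length(start) > 1L && any(abs(start[-1] - end[-length(end)]) > 1e-9))
    stop("schedule segments must be contiguous and non-overlapping")
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  structure(data.frame(start = start, end = end,
                       concentration = concentration),
            class = c("injection_schedule", "data.frame"))
}

schedule_concentration <- function(schedule, times) {
  conc <- numeric(length(times))
  for (i in seq_len(nrow(schedule))) {
    inseg <- times >= schedule$start[i] &
      (times < schedule$end[i] | (i == nrow(schedule) & times <= schedule$end[i]))
    conc[inseg] <- schedule$concentration[i]
  }
  conc
}

#' Equilibrium binding curve container
#'
#' @param concentrations analyte concentrations, molar, >= 0.
#' @param responses responses (RU or normalized absorbance).
#' @param replicate optional replicate labels.
#' @return a `binding_curve` data frame.
#' @export
binding_curve <- function(concentrations, responses, replicate = NULL) {
  if (length(concentrations) != length(responses))
    stop("concentrations and responses must have equal lengths")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  out <- data.frame(concentration = concentrations, response = responses)
  if (!is.null(replicate)) out$replicate <- replicate
  class(out) <- c("binding_curve", "data.frame")
  out
}

#' One-site binding hyperbola fit
#'
#' Nonlinear least squares of `Y = Bmax * X / (KD + X)`, where Y is the
#' response, X the analyte concentration, Bmax the response at maximal
#' binding and KD the equilibrium affinity constant. Positivity is
#' enforced by bounded (port) optimization with a Levenberg-Marquardt
#' fallback; KD is initialized at the concentration of half-maximal
#' observed response. Replicates can be pre-normalized to a reference
#' maximum via `normalize_to`.
#'
#' @param curve a [binding_curve()] (or data frame with columns
#'   `concentration`, `response`).
#' @param normalize_to optional reference value: responses are divided
#'   by it and multiplied by 100 before fitting.
#' @param start optional named list `list(bmax=, kd=)`.
#' @return a `hyperbola_fit` with `bmax`, `kd` (molar), standard
#'   errors, residual sum of squares and a convergence flag. A constant
#'   response is flagged non-identifiable instead of erroring.
#' @seealso [coef.hyperbola_fit()], [predict.hyperbola_fit()]
#' @export
fit_hyperbola <- function(curve, normalize_to = NULL, start = NULL) {
  X <- curve$concentration
  Y <- curve$response
  if (!is.null(normalize_to)) Y <- 100 * Y / normalize_to
  if (length(unique(X)) < 3L)
    stop("need at least 3 distinct concentrations")
  out <- structure(list(bmax = NA_real_, kd = NA_real_,
                        se = c(bmax = NA_real_, kd = NA_real_),
                        rss = NA_real_, converged = FALSE,
                        message = "", data = binding_curve(X, Y)),
                   class = "hyperbola_fit")
  if (stats::sd(Y) < 1e-12 * max(abs(Y), 1)) {
    out$message <- "constant response: non-identifiable"
    return(out)
  }
  if (is.null(start)) {
    ymax <- max(Y)
    half <- X[which.min(abs(Y - ymax / 2))]
    start <- list(bmax = ymax, kd = max(half, min(X[X > 0], na.rm = TRUE) / 10))
  }
  fit <- tryCatch(
    stats::nls(Y ~ bmax * X / (kd + X), start = start, algorithm = "port",
               lower = c(bmax = 1e-12, kd = 1e-15),
               control = stats::nls.control(maxiter = 500, warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error"))
    fit <- tryCatch(
      minpack.lm::nlsLM(Y ~ bmax * X / (kd + X), start = start,
                        lower = c(1e-12, 1e-15),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(out)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(bmax = NA_real_, kd = NA_real_))
  out$bmax <- unname(cf["bmax"]); out$kd <- unname(cf["kd"])
  out$se <- c(bmax = unname(se["bmax"]), kd = unname(se["kd"]))
  out$rss <- sum(stats::resid(fit)^2)
  out$converged <- TRUE
  out$fit <- fit
  out
}

#' @export
print.hyperbola_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hyperbola_fit> did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("<hyperbola_fit> Bmax = %.4g (SE %.2g), K_D = %.4g M (SE %.2g), RSS = %.3g\n",
              x$bmax, x$se["bmax"], x$kd, x$se["kd"], x$rss))
  invisible(x)
}

#' @export
coef.hyperbola_fit <- function(object, ...)
  c(bmax = object$bmax, kd = object$kd)

#' Predicted hyperbola responses
#' @param object a `hyperbola_fit`.
#' @param newdata optional data frame with a `concentration` column.
#' @param ... unused.
#' @export
predict.hyperbola_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$data$concentration else newdata$concentration
  object$bmax * X / (object$kd + X)
}

# Exact solution of dR/dt = kon C (Rmax - R) - koff R with
# piecewise-constant C(t): within each segment R relaxes exponentially
# to Rss = kon C Rmax / (kon C + koff) with rate kon C + koff.
langmuir_response <- function(times, kon, koff, rmax, schedule) {
  R <- numeric(length(times))
  r0 <- 0; t0 <- schedule$start[1]
  for (i in seq_len(nrow(schedule))) {
    C <- schedule$concentration[i]
    k <- kon * C + koff
    rss <- if (k > 0) kon * C * rmax / k else 0
    last <- i == nrow(schedule)
    sel <- times >= schedule$start[i] &
      (times < schedule$end[i] | (last & times <= schedule$end[i]))
    R[sel] <- rss + (r0 - rss) * exp(-k * (times[sel] - schedule$start[i]))
    r0 <- rss + (r0 - rss) * exp(-k * (schedule$end[i] - schedule$start[i]))
  }
  R
}

#' 1:1 Langmuir kinetic fit of an SPR sensorgram
#'
#' Least-squares fit of the 1:1 Langmuir binding model
#' `dR/dt = kon C(t) (Rmax - R) - koff R`, `R(0) = 0`, to a sensorgram
#' with a known injection schedule. The bulk refractive-index
#' contribution is fixed at 0 and mass transport is taken as
#' non-limiting (pure 1:1 kinetics), the standard constraints for
#' single-cycle kinetics evaluation. Positivity of (kon, koff, Rmax) is
#' enforced by fitting on the log scale with Levenberg-Marquardt
#' (trust-region) least squares; the model curve uses the exact
#' piecewise-exponential solution. K_D = koff/kon is derived.
#'
#' @param sensorgram data frame with columns `time` (s) and `response`
#'   (RU), e.g. from [simulate_sensorgram()].
#' @param schedule an [injection_schedule()].
#' @param start optional named list `list(kon=, koff=, rmax=)`;
#'   defaults: kon 1e5 M^-1 s^-1, K_D at the concentration of
#'   half-maximal response, Rmax 1.5x the observed maximum.
#' @return a `langmuir_fit` with `kon`, `koff`, `rmax`, derived `kd`,
#'   approximate standard errors, RSS and convergence/boundary flags. A
#'   flat zero sensorgram is flagged non-identifiable.
#' @export
fit_langmuir <- function(sensorgram, schedule, start = NULL) {
  tt <- sensorgram$time
  R <- sensorgram$response
  out <- structure(list(kon = NA_real_, koff = NA_real_, rmax = NA_real_,
                        kd = NA_real_, se = c(kon = NA, koff = NA, rmax = NA),
                        rss = NA_real_, converged = FALSE, boundary = FALSE,
                        message = "", schedule = schedule,
                        data = sensorgram),
                   class = "langmuir_fit")
  if (max(abs(R)) < 1e-12) {
    out$message <- "flat zero sensorgram: non-identifiable"
    return(out)
  }
  if (is.null(start)) {
    concs <- schedule$concentration[schedule$concentration > 0]
    if (length(concs) == 0L) {
      out$message <- "schedule has no injection segments"
      return(out)
    }
    # per-segment terminal responses vs concentration -> crude K_D guess
    plateau <- vapply(which(schedule$concentration > 0), function(i) {
      sel <- tt >= schedule$end[i] - 0.1 * (schedule$end[i] - schedule$start[i]) &
        tt <= schedule$end[i]
      if (!any(sel)) NA_real_ else mean(R[sel])
    }, numeric(1))
    rmax0 <- 1.5 * max(R)
    half <- concs[which.min(abs(plateau - max(plateau, na.rm = TRUE) / 2))]
    kon0 <- 1e5
    start <- list(kon = kon0, koff = kon0 * max(half, min(concs) / 10),
                  rmax = rmax0)
  }
  resid_fn <- function(theta)
    langmuir_response(tt, exp(theta[1]), exp(theta[2]), exp(theta[3]),
                      schedule) - R
  fit <- tryCatch(
    minpack.lm::nls.lm(par = log(unlist(start)), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(out)
  }
  th <- unname(fit$par)
  out$kon <- exp(th[1]); out$koff <- exp(th[2]); out$rmax <- exp(th[3])
  out$kd <- out$koff / out$kon
  out$rss <- sum(fit$fvec^2)
  out$converged <- fit$info %in% 1:4
  out$boundary <- any(abs(th) > log(1e12))
  if (out$boundary) out$message <- "parameter at boundary of plausible range"
  cov <- tryCatch({
    n <- length(R); p <- 3L
    s2 <- out$rss / max(n - p, 1L)
    s2 * solve(fit$hessian / 2)  # hessian ~ 2 J'J; covariance on log scale
  }, error = function(e) NULL)
  if (!is.null(cov)) {
    rel <- sqrt(pmax(diag(cov), 0))     # relative (delta method)
    out$se <- c(kon = out$kon, koff = out$koff, rmax = out$rmax) * rel
  }
  out
}

#' @export
print.langmuir_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<langmuir_fit> did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("<langmuir_fit> kon = %.3g M^-1 s^-1, koff = %.3g s^-1, Rmax = %.3g RU\n",
              x$kon, x$koff, x$rmax))
  cat(sprintf("  K_D = koff/kon = %.4g M, RSS = %.3g%s\n", x$kd, x$rss,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' @export
coef.langmuir_fit <- function(object, ...)
  c(kon = object$kon, koff = object$koff, rmax = object$rmax, kd = object$kd)

#' Predicted sensorgram at the fitted parameters
#' @param object a `langmuir_fit`.
#' @param newdata optional data frame with a `time` column.
#' @param ... unused.
#' @export
predict.langmuir_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$data$time else newdata$time
  langmuir_response(tt, object$kon, object$koff, object$rmax, object$schedule)
}

#' Steady-state responses from a sensorgram
#'
#' For each injection segment, averages the terminal `plateau_fraction`
#' of the segment as the equilibrium response at that concentration.
#' The resulting concentration-response curve can be fed to
#' [fit_hyperbola()] for steady-state affinity analysis of fast-exchange
#' interactions.
#'
#' @param sensorgram data frame with `time` and `response`.
#' @param schedule an [injection_schedule()].
#' @param plateau_fraction terminal fraction of each injection averaged
#'   (default 0.1).
#' @return a [binding_curve()] of per-concentration plateau responses.
#' @export
steady_state_responses <- function(sensorgram, schedule, plateau_fraction = 0.1) {
  inj <- which(schedule$concentration > 0)
  if (length(inj) == 0L) stop("schedule has no injection segments")
  resp <- vapply(inj, function(i) {
    t0 <- schedule$end[i] - plateau_fraction * (schedule$end[i] - schedule$start[i])
    sel <- sensorgram$time >= t0 & sensorgram$time <= schedule$end[i]
    if (!any(sel))
      stop(sprintf("injection segment %d has no samples in the plateau span", i))
    mean(sensorgram$response[sel])
  }, numeric(1))
  binding_curve(schedule$concentration[inj], resp)
}
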