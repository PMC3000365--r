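#' Gaussian peak constructor
#'
#' One fitted normal component of an electropherogram: mean and standard
#' deviation in bp, amplitude in intensity units, and the analytic area
#' `amplitude * sigma_bp * sqrt(2*pi)`.
#'
#' @param mean_bp Peak mean, bp.
#' @param sigma_bp Peak standard deviation, bp (> 0).
#' @param amplitude Peak height, intensity units (> 0).
#' @return An object of class `"gaussian_peak"`.
#' @export
gaussian_peak <- function(mean_bp, sigma_bp, amplitude) {
  if (sigma_bp <= 0) stop("sigma_bp must be positive")
  if (amplitude <= 0) stop("amplitude must be positive")
  structure(list(mean_bp = mean_bp, sigma_bp = sigma_bp,
                 amplitude = amplitude,
                 area = amplitude * sigma_bp * sqrt(2 * pi)),
            class = "gaussian_peak")
}

#' @export
print.gaussian_peak <- function(x, ...) {
  cat(sprintf(
    "<gaussian_peak> mean %.2f bp (%.2f repeats), sigma %.2f bp, area %.4g\n",
    x$mean_bp, repeats_from_size(x$mean_bp), x$sigma_bp, x$area))
  invisible(x)
}

gauss_curve <- function(grid, mean_bp, sigma_bp, amplitude) {
  amplitude * exp(-0.5 * ((grid - mean_bp) / sigma_bp)^2)
}

# Nelder-Mead least-squares fit of a single Gaussian to (x, y).
# Parameters optimised on (mean, log sigma, log amplitude).
nm_fit_gauss <- function(x, y, init, maxit = 2000, reltol = 1e-12) {
  obj <- function(p) {
    mu <- p[[1L]]; sg <- exp(p[[2L]]); am <- exp(p[[3L]])
    sum((y - gauss_curve(x, mu, sg, am))^2)
  }
  p0 <- c(init$mean_bp, log(init$sigma_bp), log(init$amplitude))
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  list(mean_bp = fit$par[[1L]], sigma_bp = exp(fit$par[[2L]]),
       amplitude = exp(fit$par[[3L]]), sse = fit$value,
       converged = fit$convergence == 0L)
}

# Moment/FWHM-based initial guess for the dominant lobe of (x, y).
# Ties in the argmax are broken toward lower bp. Sigma comes from the
# narrower one-sided half width, so a shoulder from an overlapping
# neighbour does not inflate the estimate.
init_guess <- function(x, y) {
  i <- which(y == max(y))[1L]
  amp <- y[[i]]
  half <- amp / 2
  lo <- i; while (lo > 1L && y[[lo]] > half) lo <- lo - 1L
  hi <- i; while (hi < length(y) && y[[hi]] > half) hi <- hi + 1L
  hw <- c(if (lo < i) x[[i]] - x[[lo]] else Inf,
          if (hi > i) x[[hi]] - x[[i]] else Inf)
  hw <- hw[is.finite(hw)]
  fwhm <- if (length(hw)) 2 * min(hw) else x[[length(x)]] - x[[1L]]
  sigma <- max(fwhm / 2.355, (x[[2L]] - x[[1L]]) / 2, 1e-3)
  list(mean_bp = x[[i]], sigma_bp = sigma, amplitude = max(amp, 1e-12),
       index = i)
}

# Contiguous lobe of the residual around the argmax: expand outward while
# the signal keeps falling (tracking the running minimum, with a 10% rise
# tolerance for noise) and stop at a valley or once below 2% of the apex.
# The masked fit window is this lobe clipped to +/- 4 sigma estimates.
lobe_window <- function(x, r, ini) {
  i <- ini$index
  rmax <- r[[i]]
  step_out <- function(idx_seq) {
    runmin <- rmax
    last <- i
    for (j in idx_seq) {
      if (r[[j]] > runmin + 0.1 * rmax || r[[j]] < 0.02 * rmax) break
      runmin <- min(runmin, r[[j]])
      last <- j
    }
    last
  }
  lo <- step_out(rev(seq_len(i - 1L)))
  hi <- step_out(if (i < length(x)) seq.int(i + 1L, length(x))
                 else integer(0))
  win <- x >= max(x[[lo]], ini$mean_bp - 4 * ini$sigma_bp) &
         x <= min(x[[hi]], ini$mean_bp + 4 * ini$sigma_bp)
  if (sum(win) < 5L) win <- rank(abs(x - ini$mean_bp)) <= 5
  win
}

#' Fit a single normal distribution to a trace
#'
#' Least-squares fit of one Gaussian by Nelder-Mead simplex, initialised at
#' the trace maximum with sigma from the FWHM. On failure to converge the fit
#' is restarted (default 3 times) with 10\% parameter jitter.
#'
#' @param trace A [cag_trace()].
#' @param restarts Number of jittered restarts on non-convergence.
#' @param seed Optional seed controlling restart jitter.
#' @return A [gaussian_peak()].
#' @examples
#' g <- seq(420, 470, by = 0.5)
#' tr <- cag_trace(g, gauss_curve(g, 443, 5.94, 1000))
#' fit_single_gaussian(tr)
#' @export
fit_single_gaussian <- function(trace, restarts = 3, seed = NULL) {
  stopifnot(inherits(trace, "cag_trace"))
  x <- trace$size_bp; y <- trace$intensity
  if (trace_area(trace) <= 0) stop("trace has zero area")
  contrast <- max(y) - min(y)
  if (contrast <= sqrt(.Machine$double.eps) * max(max(y), 1))
    stop(errorCondition("no distinguishable peak in trace",
                        class = c("cagdyn_fit_error", "error", "condition")))
  init <- init_guess(x, y)
  best <- NULL
  with_seed(seed, {
    for (k in seq_len(restarts + 1L)) {
      ini <- init
      if (k > 1L) {  # +/-10% jitter on restart
        ini$mean_bp <- ini$mean_bp * stats::runif(1, 0.9, 1.1)
        ini$sigma_bp <- ini$sigma_bp * stats::runif(1, 0.9, 1.1)
        ini$amplitude <- ini$amplitude * stats::runif(1, 0.9, 1.1)
      }
      fit <- nm_fit_gauss(x, y, ini)
      if (is.null(best) || fit$sse < best$sse) best <- fit
      if (fit$converged) break
    }
  })
  if (!best$converged)
    stop(errorCondition("single-Gaussian fit did not converge",
                        class = c("cagdyn_fit_error", "error", "condition"),
                        best = best))
  gaussian_peak(best$mean_bp, best$sigma_bp, best$amplitude)
}

peaks_to_df <- function(means, sigmas, amps) {
  area <- amps * sigmas * sqrt(2 * pi)
  data.frame(mean_bp = means, sigma_bp = sigmas, amplitude = amps,
             area = area,
             mean_repeats = repeats_from_size(pmax(means, FLANK_BP)),
             area_fraction = area / sum(area))
}

model_curve <- function(grid, peaks) {
  out <- numeric(length(grid))
  for (i in seq_len(nrow(peaks)))
    out <- out + gauss_curve(grid, peaks$mean_bp[[i]], peaks$sigma_bp[[i]],
                             peaks$amplitude[[i]])
  out
}

#' Decompose a trace into consecutive normal distributions
#'
#' Masked Nelder-Mead simplex fitting: the highest residual lobe is located,
#' one Gaussian is fitted to a window of +/- 4 sigma-estimates around it with
#' the rest of the trace masked, the component is subtracted, and the cycle
#' repeats until the fitted model accounts for at least `min_explained` of the
#' trapezoidal trace area (or `max_peaks` is reached). A final joint simplex
#' refinement of all parameters follows, and peaks contributing less than
#' `min_area_fraction` of the fitted area are discarded as noise.
#'
#' @param trace A [cag_trace()].
#' @param min_explained Required explained-area fraction (default 0.98).
#' @param max_peaks Maximum number of components (default 12).
#' @param min_area_fraction Smallest retained per-peak share of the fitted
#'   area (default 0.01).
#' @param restarts Jittered restarts per component on non-convergence.
#' @param seed Optional seed controlling restart jitter.
#' @return An object of class `"peak_decomposition"` with elements `peaks`
#'   (data frame: `mean_bp`, `sigma_bp`, `amplitude`, `area`, `mean_repeats`,
#'   `area_fraction`, sorted by ascending mean), `n_peaks`,
#'   `explained_fraction` (share of the raw trace area accounted for by the
#'   fitted curve, `1 - integral(|data - model|)/integral(data)`),
#'   `area_ratio` (total model area over trace area), `explained_path`
#'   (per-iteration explained fraction during the greedy phase),
#'   `reached_target` (logical), and the fitting grid. Supports `print`,
#'   `summary`, `coef`, `fitted`, `predict`, `plot` and `residuals`.
#' @examples
#' g <- seq(410, 520, by = 0.5)
#' y <- gauss_curve(g, 443, 5.94, 1000) + gauss_curve(g, 464, 5.94, 1000)
#' d <- decompose(cag_trace(g, y))
#' d
#' coef(d)
#' @export
decompose <- function(trace, min_explained = 0.98, max_peaks = 12,
                      min_area_fraction = 0.01, restarts = 3, seed = NULL) {
  stopifnot(inherits(trace, "cag_trace"))
  if (!(min_explained > 0 && min_explained <= 1))
    stop("min_explained must be in (0, 1]")
  x <- trace$size_bp; y <- trace$intensity
  total_area <- trace_area(trace)
  if (total_area <= 0) stop("trace has zero area")

  means <- sigmas <- amps <- numeric(0)
  explained_path <- numeric(0)
  resid <- y
  noise_floor <- sqrt(.Machine$double.eps) * max(y)

  with_seed(seed, {
    for (k in seq_len(max_peaks)) {
      if (max(resid) <= noise_floor) break
      ini <- init_guess(x, resid)
      win <- lobe_window(x, resid, ini)
      fit <- nm_fit_gauss(x[win], resid[win], ini)
      if (!fit$converged) {
        for (r in seq_len(restarts)) {
          ini2 <- ini
          ini2$mean_bp <- ini$mean_bp * stats::runif(1, 0.9, 1.1)
          ini2$sigma_bp <- ini$sigma_bp * stats::runif(1, 0.9, 1.1)
          ini2$amplitude <- ini$amplitude * stats::runif(1, 0.9, 1.1)
          fit2 <- nm_fit_gauss(x[win], resid[win], ini2)
          if (fit2$sse < fit$sse) fit <- fit2
          if (fit$converged) break
        }
      }
      means <- c(means, fit$mean_bp)
      sigmas <- c(sigmas, fit$sigma_bp)
      amps <- c(amps, fit$amplitude)
      # joint refinement after every added component: the masked
      # single-peak fit is contaminated by overlapping neighbours, and the
      # explained fraction is only meaningful for the refined set
      ref <- joint_refine(x, y, means, sigmas, amps)
      means <- ref$mean_bp; sigmas <- ref$sigma_bp; amps <- ref$amplitude
      model <- model_curve(x, ref)
      resid <- y - model
      explained_path <- c(explained_path,
                          explained_coverage(x, y, model, total_area))
      if (explained_path[[k]] >= min_explained) break
    }
  })
  if (!length(means))
    stop(errorCondition("no component could be fitted",
                        class = c("cagdyn_fit_error", "error", "condition")))

  refined <- joint_refine(x, y, means, sigmas, amps)

  # drop sub-threshold noise peaks, then refine once more if any were dropped
  keep <- refined$area / sum(refined$area) >= min_area_fraction
  if (!all(keep) && any(keep)) {
    refined <- refined[keep, , drop = FALSE]
    refined <- joint_refine(x, y, refined$mean_bp, refined$sigma_bp,
                            refined$amplitude)
  }
  refined <- refined[order(refined$mean_bp), , drop = FALSE]
  refined <- merge_degenerate(refined)
  peaks <- peaks_to_df(refined$mean_bp, refined$sigma_bp, refined$amplitude)
  model <- model_curve(x, peaks)
  explained <- explained_coverage(x, y, model, total_area)
  area_ratio <- trapz(x, model) / total_area
  reached <- explained >= min_explained
  if (!reached)
    warning(sprintf(
      "explained fraction %.4f below target %.3f after %d peaks",
      explained, min_explained, nrow(peaks)))
  structure(
    list(peaks = peaks, n_peaks = nrow(peaks),
         explained_fraction = explained, area_ratio = area_ratio,
         explained_path = explained_path,
         reached_target = reached, min_explained = min_explained,
         grid = x, observed = y, trace_meta = trace$meta),
    class = "peak_decomposition")
}

# Fraction of the raw trace area accounted for by the model:
# 1 - integral(|data - model|) / integral(data). Equals 1 for a perfect
# fit and, unlike the bare model-to-data area ratio, penalises a model
# whose total area is right but whose shape is wrong.
explained_coverage <- function(x, y, model, total_area) {
  max(0, 1 - trapz(x, abs(y - model)) / total_area)
}

# Joint least-squares refinement of all components by Levenberg-Marquardt
# on (mean, log sigma, log amplitude), with the analytic Jacobian. The
# greedy masked simplex fits supply the starting point; the joint polish is
# a plain nonlinear least-squares problem in 3k parameters, which LM solves
# to machine precision where a 3k-dimensional simplex stalls. Falls back to
# the incoming parameters if refinement fails to improve the fit or drifts
# to a degenerate (trace-spanning) component.
joint_refine <- function(x, y, means, sigmas, amps) {
  k <- length(means)
  span <- x[[length(x)]] - x[[1L]]
  p0 <- c(means, log(sigmas), log(amps))
  # components model PCR-broadened length classes of similar width, so a
  # single component must not stretch to swallow several classes: sigma is
  # bounded within a band around the typical (median) component width
  sig_mid <- stats::median(sigmas)
  lower <- c(rep(-Inf, k), rep(log(sig_mid / 2.5), k), rep(-Inf, k))
  upper <- c(rep(Inf, k), rep(log(sig_mid * 2), k), rep(Inf, k))
  p0 <- pmin(pmax(p0, lower), upper)
  unpack <- function(p)
    list(m = p[1:k], s = exp(p[(k + 1):(2 * k)]),
         a = exp(p[(2 * k + 1):(3 * k)]))
  fn <- function(p) {
    q <- unpack(p)
    mod <- numeric(length(x))
    for (i in seq_len(k))
      mod <- mod + gauss_curve(x, q$m[[i]], q$s[[i]], q$a[[i]])
    y - mod
  }
  jac <- function(p) {
    q <- unpack(p)
    J <- matrix(0, length(x), 3 * k)
    for (i in seq_len(k)) {
      z <- (x - q$m[[i]]) / q$s[[i]]
      g <- q$a[[i]] * exp(-0.5 * z^2)
      J[, i] <- -g * z / q$s[[i]]
      J[, k + i] <- -g * z^2
      J[, 2 * k + i] <- -g
    }
    J
  }
  # iteration-limit warnings are irrelevant here: fit quality is policed
  # below by comparing the refined SSE against the incoming parameters
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = fn,
                         jac = jac,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15))),
    error = function(e) NULL)
  out <- data.frame(mean_bp = means, sigma_bp = sigmas, amplitude = amps)
  if (!is.null(fit)) {
    q <- unpack(fit$par)
    cand <- data.frame(mean_bp = q$m, sigma_bp = q$s, amplitude = q$a)
    if (sum(fn(fit$par)^2) <= sum(fn(p0)^2) && all(cand$sigma_bp <= span))
      out <- cand
  }
  out$area <- out$amplitude * out$sigma_bp * sqrt(2 * pi)
  out
}

# Collapse components that are not mutually resolvable: two Gaussians
# closer than the narrower component's sigma describe one length class
# split across two components, an artefact of over-parameterisation.
merge_degenerate <- function(df) {
  if (nrow(df) < 2L) return(df)
  repeat {
    d <- diff(df$mean_bp)
    tol <- pmin(df$sigma_bp[-nrow(df)], df$sigma_bp[-1L])
    i <- which(d < tol)
    if (!length(i)) return(df)
    i <- i[[1L]]
    a <- df$area[[i]] + df$area[[i + 1L]]
    w <- df$area[[i]] / a
    df$mean_bp[[i]] <- w * df$mean_bp[[i]] + (1 - w) * df$mean_bp[[i + 1L]]
    df$sigma_bp[[i]] <- w * df$sigma_bp[[i]] + (1 - w) * df$sigma_bp[[i + 1L]]
    df$area[[i]] <- a
    df$amplitude[[i]] <- a / (df$sigma_bp[[i]] * sqrt(2 * pi))
    df <- df[-(i + 1L), , drop = FALSE]
  }
}

#' @export
print.peak_decomposition <- function(x, ...) {
  cat(sprintf("<peak_decomposition> %d peak(s), explained %.4f%s\n",
              x$n_peaks, x$explained_fraction,
              if (x$reached_target) "" else " (target not reached)"))
  print(format(x$peaks, digits = 6), row.names = FALSE)
  invisible(x)
}

#' @export
summary.peak_decomposition <- function(object, ...) {
  ints <- peak_intervals(object)
  out <- list(n_peaks = object$n_peaks,
              explained_fraction = object$explained_fraction,
              reached_target = object$reached_target,
              peaks = object$peaks,
              intervals_repeats = ints$intervals)
  class(out) <- "summary.peak_decomposition"
  out
}

#' @export
print.summary.peak_decomposition <- function(x, ...) {
  cat(sprintf("Peak decomposition: %d peak(s), explained fraction %.4f\n",
              x$n_peaks, x$explained_fraction))
  print(format(x$peaks, digits = 6), row.names = FALSE)
  if (length(x$intervals_repeats))
    cat("consecutive intervals (repeats):",
        paste(sprintf("%.2f", x$intervals_repeats), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.peak_decomposition <- function(object, ...) {
  as.matrix(object$peaks[, c("mean_bp", "sigma_bp", "amplitude", "area")])
}

#' @export
fitted.peak_decomposition <- function(object, ...) {
  model_curve(object$grid, object$peaks)
}

#' @export
residuals.peak_decomposition <- function(object, ...) {
  object$observed - fitted(object)
}

#' @export
predict.peak_decomposition <- function(object, grid = object$grid, ...) {
  model_curve(grid, object$peaks)
}

#' @export
plot.peak_decomposition <- function(x, ...) {
  graphics::plot(x$grid, x$observed, type = "l", col = "grey40",
                 xlab = "fragment size (bp)", ylab = "intensity", ...)
  for (i in seq_len(x$n_peaks))
    graphics::lines(x$grid,
                    gauss_curve(x$grid, x$peaks$mean_bp[[i]],
                                x$peaks$sigma_bp[[i]],
                                x$peaks$amplitude[[i]]),
                    col = "black", lty = 2)
  graphics::lines(x$grid, fitted(x), col = "red")
  invisible(x)
}

#' Render a fitted model as a trace
#'
#' Evaluates the sum of all Gaussian components of a decomposition on a
#' fragment-size grid.
#'
#' @param decomposition A `"peak_decomposition"`.
#' @param grid Strictly increasing fragment sizes, bp; defaults to the
#'   decomposition's own fitting grid.
#' @return A [cag_trace()] holding the model curve.
#' @export
render_model <- function(decomposition, grid = decomposition$grid) {
  stopifnot(inherits(decomposition, "peak_decomposition"))
  if (decomposition$n_peaks < 1L) stop("empty peak list")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  cag_trace(grid, model_curve(grid, decomposition$peaks))
}

#' Write a peak table to delimited text
#'
#' One row per fitted peak with columns `mean_bp`, `sigma_bp`, `amplitude`,
#' `area`, `mean_repeats`, `area_fraction`.
#'
#' @param decomposition A `"peak_decomposition"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(decomposition, path) {
  stopifnot(inherits(decomposition, "peak_decomposition"))
  utils::write.table(decomposition$peaks, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak table written by [write_peak_table()]
#'
#' @param path Path to the table.
#' @return A `"peak_decomposition"`-compatible peak data frame wrapped with
#'   minimal structure (no grid or residuals).
#' @export
read_peak_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  structure(list(peaks = df, n_peaks = nrow(df),
                 explained_fraction = NA_real_, reached_target = NA,
                 grid = NULL, observed = NULL, trace_meta = NULL),
            class = "peak_decomposition")
}
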