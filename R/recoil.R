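#' Kelvin-Voigt fit of a laser-ablation recoil trace
#'
#' Fits the vertex-vertex distance following ablation with the step response
#' of a Kelvin-Voigt (spring and dashpot in parallel) element,
#' \deqn{d(t) = d_0 + D\,(1 - e^{-k t}),}
#' by nonlinear least squares. `k` (per second) is the ratio of junctional
#' elasticity to cytoplasmic viscosity; the initial recoil velocity is
#' \eqn{d'(0) = D k}. By default the pre-ablation baseline \eqn{d_0} is fixed
#' to the mean of the pre-ablation samples (`time_s <= 0`); it can instead be
#' fitted as a free parameter.
#'
#' @param trace data.frame with numeric columns `time_s` (seconds, strictly
#'   increasing, `t = 0` at the ablation frame, at least one point at
#'   `t <= 0`) and `distance` (vertex-vertex separation, any consistent
#'   length unit). At least 5 post-ablation points are required.
#' @param fix_baseline fix `d0` to the pre-ablation mean (default) or fit it.
#' @param k_bounds allowed range for `k`, per second.
#' @return object of class `kelvin_voigt_fit`: list with `d0`, `D`, `k`,
#'   `initial_recoil` (`= D * k`), `residual_rms`, `converged`, `n_points`
#'   and `negative_D` (flag: junction under compression or failed ablation).
#'   Non-convergence raises an error carrying the best-so-far parameters in
#'   its `data` field.
#' @export
fit_kelvin_voigt <- function(trace, fix_baseline = TRUE,
                             k_bounds = c(1e-4, 10)) {
  stopifnot(is.data.frame(trace), all(c("time_s", "distance") %in%
                                        names(trace)))
  trace <- trace[order(trace$time_s), ]
  if (any(diff(trace$time_s) <= 0)) stop("time must be strictly increasing")
  pre <- trace$time_s < 0
  post <- trace[trace$time_s >= 0, ]
  if (!any(pre)) stop("need at least one pre-ablation point (time_s < 0)")
  if (nrow(post) < 5L) stop("need at least 5 post-ablation points")
  t <- post$time_s
  y <- post$distance
  d0 <- mean(trace$distance[pre])
  D0 <- y[length(y)] - y[1]
  # initial k: inverse time of half-rise
  half <- y[1] + 0.5 * (y[length(y)] - y[1])
  thalf <- if (D0 >= 0) t[which(y >= half)[1]] else t[which(y <= half)[1]]
  if (is.na(thalf) || thalf <= 0) thalf <- t[max(2L, length(t) %/% 2L)]
  k0 <- min(max(1 / thalf, k_bounds[1]), k_bounds[2])
  if (abs(D0) < 1e-12) D0 <- 1e-8
  model <- function(par) {
    b <- if (fix_baseline) d0 else par[["b0"]]
    b + par[["D"]] * (1 - exp(-par[["k"]] * t))
  }
  resid_fn <- function(par) y - model(par)
  start <- if (fix_baseline) c(D = D0, k = k0) else c(b0 = d0, D = D0,
                                                      k = k0)
  lower <- c(b0 = -Inf, D = -Inf, k = k_bounds[1])
  upper <- c(b0 = Inf, D = Inf, k = k_bounds[2])
  if (fix_baseline) {
    lower <- lower[c("D", "k")]
    upper <- upper[c("D", "k")]
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                       upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error") || !fit$info %in% 1:4) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
    err <- simpleError(sprintf("Kelvin-Voigt fit did not converge: %s", msg))
    err$data <- if (inherits(fit, "error")) list(d0 = d0, D = D0, k = k0)
    else as.list(fit$par)
    stop(err)
  }
  cf <- fit$par
  if (!fix_baseline) d0 <- cf[["b0"]]
  D <- cf[["D"]]
  k <- cf[["k"]]
  structure(
    list(d0 = d0, D = D, k = k, initial_recoil = D * k,
         residual_rms = sqrt(mean(fit$fvec^2)),
         converged = TRUE, n_points = nrow(post), negative_D = D < 0),
    class = "kelvin_voigt_fit")
}

#' @export
print.kelvin_voigt_fit <- function(x, ...) {
  cat("Kelvin-Voigt recoil fit\n")
  cat(sprintf("  d0 = %.4g, D = %.4g, k = %.4g /s\n", x$d0, x$D, x$k))
  cat(sprintf("  initial recoil = %.4g per second (residual rms %.3g, n = %d)\n",
              x$initial_recoil, x$residual_rms, x$n_points))
  if (x$negative_D)
    cat("  note: negative D (junction under compression or failed ablation)\n")
  invisible(x)
}

#' Fit every trace in a recoil table
#'
#' @param traces data.frame with columns `trace_id, group, time_s, distance`
#'   (or a CSV path).
#' @param ... passed to [fit_kelvin_voigt()].
#' @return data.frame with one row per trace: `trace_id, group, d0, D, k,
#'   initial_recoil, residual_rms, converged`.
#' @export
fit_recoil_table <- function(traces, ...) {
  if (is.character(traces)) traces <- read.csv(traces,
                                               stringsAsFactors = FALSE)
  stopifnot(all(c("trace_id", "group", "time_s", "distance") %in%
                  names(traces)))
  ids <- unique(traces$trace_id)
  rows <- lapply(ids, function(id) {
    tr <- traces[traces$trace_id == id, ]
    f <- tryCatch(fit_kelvin_voigt(tr[, c("time_s", "distance")], ...),
                  error = function(e) e)
    if (inherits(f, "error"))
      data.frame(trace_id = id, group = tr$group[1], d0 = NA, D = NA, k = NA,
                 initial_recoil = NA, residual_rms = NA, converged = FALSE)
    else
      data.frame(trace_id = id, group = tr$group[1], d0 = f$d0, D = f$D,
                 k = f$k, initial_recoil = f$initial_recoil,
                 residual_rms = f$residual_rms, converged = TRUE)
  })
  do.call(rbind, rows)
}

#' Per-group initial-recoil summary
#'
#' Group means, standard errors and counts of the initial recoil velocity
#' (and of `k`), for comparison across cluster / wild-type / boundary
#' groups. Raw values are returned alongside for external statistics.
#'
#' @param fits data.frame as returned by [fit_recoil_table()], or a list of
#'   `kelvin_voigt_fit` objects with a parallel `groups` vector.
#' @param groups group labels (only when `fits` is a list).
#' @return list with `summary` (data.frame: group, n, mean_initial_recoil,
#'   sem_initial_recoil, mean_k, sem_k) and `values` (raw per-trace values).
#' @export
initial_recoil_summary <- function(fits, groups = NULL) {
  if (is.list(fits) && !is.data.frame(fits)) {
    stopifnot(!is.null(groups), length(groups) == length(fits))
    fits <- data.frame(
      trace_id = seq_along(fits), group = groups,
      initial_recoil = vapply(fits, `[[`, numeric(1), "initial_recoil"),
      k = vapply(fits, `[[`, numeric(1), "k"),
      converged = vapply(fits, `[[`, logical(1), "converged"))
  }
  fits <- fits[!is.na(fits$initial_recoil), ]
  if (!nrow(fits)) {
    warning("no converged fits")
    return(list(summary = data.frame(), values = fits))
  }
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  grp <- split(fits, fits$group)
  summ <- do.call(rbind, lapply(grp, function(g) data.frame(
    group = g$group[1], n = nrow(g),
    mean_initial_recoil = mean(g$initial_recoil),
    sem_initial_recoil = sem(g$initial_recoil),
    mean_k = mean(g$k), sem_k = sem(g$k))))
  rownames(summ) <- NULL
  list(summary = summ, values = fits)
}
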