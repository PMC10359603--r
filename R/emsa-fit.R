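# EMSA quantitation: constant co-purified band exclusion and
# least-squares fitting of the specific-binding-with-Hill-slope model
# Y = Bmax * X^h / (KD^h + X^h).

#' Exclude a constant co-purified unbound band
#'
#' Co-purified probe DNA that remains equally unbound at every protein
#' concentration is excluded before fitting: if the designated band's
#' coefficient of variation across lanes is below `cv_threshold`, its
#' mean intensity is subtracted from each lane's unbound signal and
#' recorded as `excluded_baseline`. Subtraction never drives unbound
#' below zero (clipped, with a warning count).
#'
#' @param lanes data.frame with columns `concentration_nM`, `rep`,
#'   `bound`, `unbound`, and the designated band column (>= 3 lanes).
#' @param band name of the designated band column (default
#'   `"copurified"`); lanes without such a column are returned
#'   unchanged.
#' @param cv_threshold CV below which the band is deemed constant.
#' @return the lanes with corrected `unbound`; attributes
#'   `excluded_baseline` (mean intensity, or `NULL` when not excluded)
#'   and `n_clipped`.
#' @export
exclude_constant_unbound <- function(lanes, band = "copurified",
                                     cv_threshold = 0.10) {
  if (nrow(lanes) < 3L) stop("need at least 3 lanes")
  if (!band %in% names(lanes)) return(lanes)
  v <- lanes[[band]]
  m <- mean(v)
  cv <- if (m > 0) sd(v) / m else Inf
  if (!is.finite(cv) || cv >= cv_threshold || m <= 0) {
    attr(lanes, "excluded_baseline") <- NULL
    return(lanes)
  }
  corrected <- lanes$unbound - m
  n_clip <- sum(corrected < 0)
  if (n_clip > 0L)
    warning(sprintf("baseline subtraction clipped %d unbound value(s) to 0",
                    n_clip))
  lanes$unbound <- pmax(corrected, 0)
  attr(lanes, "excluded_baseline") <- m
  attr(lanes, "n_clipped") <- n_clip
  lanes
}

hill_rss <- function(logpar, x, y) {
  kd <- exp(logpar[1L]); h <- exp(logpar[2L]); bmax <- exp(logpar[3L])
  r <- y - bmax * x^h / (kd^h + x^h)
  sum(r * r)
}

#' Fit the specific-binding-with-Hill-slope model
#'
#' Least-squares fit of `Y = Bmax * X^h / (KD^h + X^h)` to per-lane
#' responses. By default the response is the bound fraction
#' `bound / (bound + unbound)` (a ratio-based response bounded in
#' `[0, 1]`); `response = "ratio"` fits the raw bound/unbound ratio
#' instead. Optimisation is multi-start (log-parameterised BFGS from a
#' deterministic jitter grid around `kd0 =` X nearest half-max,
#' `h0 = 1`, `bmax0 = max(Y)`), and the convergence flag is honest: on
#' failure from every start the parameters are `NA`, never fabricated.
#'
#' @param lanes data.frame with columns `concentration_nM`, `bound`,
#'   `unbound` (>= 4 distinct concentrations), e.g. from
#'   [gen_emsa()]/[read_emsa_tsv()], typically after
#'   [exclude_constant_unbound()].
#' @param response `"fraction"` (default) or `"ratio"`.
#' @param n_starts number of multi-starts (jitter factors spanning
#'   0.25x to 4x around the initial KD).
#' @return object of class `binding_fit`: list with `kd`, `hill`,
#'   `bmax`, `rss`, `converged`, `n_points`, `response`, and `fitted`
#'   (data.frame of X, observed and fitted Y).
#' @export
fit_hill <- function(lanes, response = c("fraction", "ratio"),
                     n_starts = 8L) {
  response <- match.arg(response)
  x <- lanes$concentration_nM
  if (any(!is.finite(x)) || any(x <= 0))
    stop("concentrations must all be positive")
  if (length(unique(x)) < 4L) stop("need >= 4 distinct concentrations")
  y <- if (response == "fraction") lanes$bound / (lanes$bound + lanes$unbound)
    else lanes$bound / lanes$unbound
  if (any(!is.finite(y))) stop("non-finite response values")
  ybar <- tapply(y, x, mean)
  xs <- as.numeric(names(ybar))
  kd0 <- xs[which.min(abs(ybar - max(ybar) / 2))]
  bmax0 <- max(y)
  jitter <- exp(seq(log(0.25), log(4), length.out = n_starts))
  best <- NULL
  for (f in jitter) {
    start <- log(c(kd0 * f, 1, max(bmax0, 1e-6)))
    fit <- tryCatch(
      optim(start, hill_rss, x = x, y = y, method = "BFGS",
            control = list(maxit = 500L, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(kd = NA_real_, hill = NA_real_, bmax = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          n_points = length(y), response = response,
                          fitted = NULL, diagnostics = "all starts failed"),
                     class = "binding_fit"))
  }
  # Nelder-Mead polish guards against BFGS stalling on flat plateaus
  pol <- optim(best$par, hill_rss, x = x, y = y, method = "Nelder-Mead",
               control = list(maxit = 2000L, reltol = 1e-15))
  if (pol$value < best$value) best <- pol
  kd <- exp(best$par[1L]); h <- exp(best$par[2L]); bmax <- exp(best$par[3L])
  yfit <- bmax * x^h / (kd^h + x^h)
  structure(list(kd = kd, hill = h, bmax = bmax, rss = best$value,
                 converged = best$convergence == 0 && all(is.finite(best$par)),
                 n_points = length(y), response = response,
                 fitted = data.frame(concentration_nM = x, observed = y,
                                     fitted = yfit)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "<binding_fit> KD = %.4g nM, Hill = %.3g, Bmax = %.4g (RSS %.3g, %s, n = %d)\n",
    x$kd, x$hill, x$bmax, x$rss,
    if (isTRUE(x$converged)) "converged" else "NOT converged", x$n_points))
  invisible(x)
}
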