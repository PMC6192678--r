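# Upper-envelope richness binning and Laplace / Gaussian constraint fits.

#' Binned upper percentile of richness along a covariate
#'
#' Equal-width bins over the observed covariate range (the survey
#' convention: 100 bins for pH, 120 for temperature); per occupied bin the
#' richness percentile (default 99th, linear interpolation / type 7).
#' Bins with fewer than \code{minOccupancy} points are dropped and
#' reported — a 99th percentile of a handful of points is degenerate.
#'
#' @param covariate,richness paired numeric vectors (pairs with a missing
#'   value are dropped).
#' @param nBins number of bins (>= 2).
#' @param percentile percentile to take per bin (default 99).
#' @param minOccupancy minimum points per retained bin (default 5).
#' @return data.frame: bin centre \code{x}, \code{value}, \code{n};
#'   attributes \code{"edges"} and \code{"dropped"} (bins removed for low
#'   occupancy).
#' @export
binPercentile <- function(covariate, richness, nBins, percentile = 99,
                          minOccupancy = 5) {
  stopifnot(length(covariate) == length(richness), nBins >= 2)
  ok <- is.finite(covariate) & is.finite(richness)
  covariate <- covariate[ok]; richness <- richness[ok]
  if (length(unique(covariate)) < 2)
    .stopf("need at least 2 distinct covariate values")
  edges <- seq(min(covariate), max(covariate), length.out = nBins + 1)
  bin <- findInterval(covariate, edges, rightmost.closed = TRUE)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  occ <- tabulate(bin, nbins = nBins)
  keep <- which(occ >= minOccupancy)
  dropped <- which(occ > 0 & occ < minOccupancy)
  out <- data.frame(
    x = centres[keep],
    value = vapply(keep, function(b)
      unname(quantile(richness[bin == b], percentile / 100, type = 7)), 0),
    n = occ[keep])
  attr(out, "edges") <- edges
  attr(out, "dropped") <- data.frame(x = centres[dropped], n = occ[dropped])
  out
}

envelopeCurve <- function(x, family, mu, scale, amplitude) {
  if (family == "laplace") amplitude * exp(-abs(x - mu) / scale)
  else amplitude * exp(-(x - mu)^2 / (2 * scale^2))
}

#' Fit a peaked envelope to binned percentiles
#'
#' Least-squares fit of \eqn{S_0 \exp(-|x-\mu|/b)} (Laplace / two-sided
#' exponential) or \eqn{S_0 \exp(-(x-\mu)^2/(2\sigma^2))} (Gaussian) to
#' the (bin centre, percentile) points, by multi-start Nelder-Mead over
#' \eqn{(\mu, \log b, \log S_0)} — the \eqn{|x-\mu|} kink rules out
#' gradient methods. Initialised at the argmax bin, the max percentile,
#' and the half-width at \eqn{S_0/e}, with a small restart grid around
#' them.
#'
#' @param envelope data.frame from \code{\link{binPercentile}} (columns
#'   \code{x}, \code{value}); at least 4 occupied bins.
#' @param family \code{"laplace"} or \code{"gaussian"}.
#' @return an \linkS4class{EnvelopeFit}.
#' @export
fitEnvelope <- function(envelope, family = c("laplace", "gaussian")) {
  family <- match.arg(family)
  x <- envelope$x; y <- envelope$value
  if (length(x) < 4) .stopf("need at least 4 occupied bins")
  mu0 <- x[which.max(y)]
  S0 <- max(y)
  above <- x[y >= S0 / exp(1)]
  b0 <- max((max(above) - min(above)) / 2, diff(range(x)) / 20)
  sse <- function(par) {
    pred <- envelopeCurve(x, family, par[1], exp(par[2]), exp(par[3]))
    sum((y - pred)^2)
  }
  starts <- expand.grid(mu = mu0 + c(-1, 0, 1) * b0 / 2,
                        b = b0 * c(0.5, 1, 2), S = S0 * c(1, 1.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(c(starts$mu[i], log(starts$b[i]), log(starts$S[i])), sse,
            method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    .stopf("envelope fit failed to converge (%s, %d bins)", family,
           length(x))
  methods::new("EnvelopeFit", family = family, mu = best$par[1],
               scale = exp(best$par[2]), amplitude = exp(best$par[3]),
               sse = best$value, nPoints = length(x))
}

#' Compare Laplace and Gaussian envelope fits
#'
#' Fits both families and declares the winner by lower SSE (both have
#' three parameters, so the SSE comparison is AIC-equivalent).
#'
#' @param envelope data.frame from \code{\link{binPercentile}}.
#' @return list with \code{laplace}, \code{gaussian}
#'   (\linkS4class{EnvelopeFit}s) and \code{winner}.
#' @export
compareFits <- function(envelope) {
  fl <- fitEnvelope(envelope, "laplace")
  fg <- fitEnvelope(envelope, "gaussian")
  list(laplace = fl, gaussian = fg,
       winner = if (fl@sse <= fg@sse) "laplace" else "gaussian")
}
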