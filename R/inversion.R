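# Generalized-least-squares inversion: moment-change covariance ->
# per-layer absorption-change uncertainty -> chromophore-concentration
# uncertainty through the Beer-Lambert law.

.checkConditioning <- function(M, what) {
  rc <- tryCatch(rcond(M), error = function(e) 0)
  if (rc == 0) stop(what, " is singular (identifiability lost)")
  kappa <- 1 / rc
  if (kappa > 1e12)
    warning(what, sprintf(" badly conditioned (condition number %.3g)", kappa))
  kappa
}

#' Standard deviation of recovered absorption changes
#'
#' Propagates the moment-change covariance Z through the linear
#' moments-method model: cov(dmua) = (X' Z^-1 X)^-1, and returns the
#' element-wise square roots of its diagonal.  A subset of the moments
#' (A alone, A+T, or A+T+V) can be selected by row.
#'
#' @param X sensitivity matrix with rows `A`, `T`, `V` and one column per
#'   recoverable layer (see [twoLayerX()]).
#' @param Z 3 x 3 covariance of (dA, dT, dV) from [covarianceZ()].
#' @param moments character subset of `c("A", "T", "V")` to use.
#' @return list with `sigma` (named per layer, mm^-1), `cov` (the full
#'   covariance matrix) and `condition` (condition number of the normal
#'   matrix).
#' @export
sigmaDmua <- function(X, Z, moments = c("A", "T", "V")) {
  moments <- match.arg(moments, several.ok = TRUE)
  Xs <- X[moments, , drop = FALSE]
  Zs <- Z[moments, moments, drop = FALSE]
  if (nrow(Xs) < ncol(Xs))
    stop("fewer moments than layers: under-determined")
  # equilibrate: A, T, V live on wildly different unit scales (1, ps^2,
  # ps^4), so normalise each moment by its own standard deviation before
  # factorising; the normal matrix is unchanged mathematically
  s <- sqrt(diag(Zs))
  if (any(s <= 0)) stop("moment covariance Z is singular")
  Xs <- Xs / s
  Zs <- Zs / tcrossprod(s)
  .checkConditioning(Zs, "moment covariance Z")
  ZiX <- solve(Zs, Xs)
  M <- crossprod(Xs, ZiX)
  kappa <- .checkConditioning(M, "normal matrix X' Z^-1 X")
  C <- solve(M)
  sigma <- sqrt(diag(C))
  names(sigma) <- colnames(X)
  dimnames(C) <- list(colnames(X), colnames(X))
  list(sigma = sigma, cov = C, condition = kappa)
}

#' Recover absorption changes from moment changes
#'
#' Generalized least squares: dmua = (X' Z^-1 X)^-1 X' Z^-1 (dA, dT, dV)'.
#' Unbiased under the linear sensitivity model, with covariance equal to
#' the matrix returned by [sigmaDmua()].
#'
#' @param dm named vector `c(A=, T=, V=)` from [momentChange()].
#' @inheritParams sigmaDmua
#' @return list with `dmua` (named per layer, mm^-1), `sigma`, `cov`.
#' @export
recoverDmua <- function(dm, X, Z, moments = c("A", "T", "V")) {
  moments <- match.arg(moments, several.ok = TRUE)
  prop <- sigmaDmua(X, Z, moments)
  s <- sqrt(diag(Z)[moments])
  Xs <- X[moments, , drop = FALSE] / s
  Zs <- Z[moments, moments, drop = FALSE] / tcrossprod(s)
  rhs <- crossprod(Xs, solve(Zs, dm[moments] / s))
  est <- as.vector(prop$cov %*% rhs)
  names(est) <- colnames(X)
  list(dmua = est, sigma = prop$sigma, cov = prop$cov)
}

#' Default per-layer chromophore sets
#'
#' Two chromophores in the scalp (HbO2, Hb) and three in the brain (HbO2,
#' Hb, oxidised cytochrome-c-oxidase difference spectrum).
#'
#' @return named list of character vectors.
#' @export
defaultLayerChromophores <- function() {
  list(scalp = c("HbO2", "Hb"), brain = c("HbO2", "Hb", "oxCCO"))
}

#' Concentration-change uncertainty through the Beer-Lambert law
#'
#' For each layer, with E the (wavelength x chromophore) extinction matrix
#' and W = diag(1/sigma_dmua(lambda)^2), the covariance of the recovered
#' concentration changes is cov(dC) = (E' W E)^-1 (inverse-variance
#' weighted least squares; the default).  The unweighted variant solves
#' ordinary least squares and propagates the per-wavelength variances
#' through its pseudo-inverse; the two coincide when E is square.
#'
#' @param sigma matrix of absorption-change standard deviations with one
#'   row per wavelength and named columns per layer (mm^-1), e.g. built
#'   from repeated [sigmaDmua()] calls.
#' @param wavelengths nm, matching the rows of `sigma`.
#' @param spectra named list of [SpectralCurve-class]; the convention the
#'   curves carry must match the one used to build the forward model.
#' @param layerChromophores named list mapping layer -> chromophores.
#' @param weighted logical; inverse-variance weighting (default TRUE).
#' @return data.frame with columns `layer`, `chromophore`, `sigma_uM`,
#'   with the per-layer covariance matrices attached as attribute `cov`.
#' @export
sigmaDC <- function(sigma, wavelengths, spectra,
                    layerChromophores = defaultLayerChromophores(),
                    weighted = TRUE) {
  stopifnot(nrow(sigma) == length(wavelengths))
  rows <- list()
  covs <- list()
  for (layer in names(layerChromophores)) {
    chroms <- layerChromophores[[layer]]
    if (length(wavelengths) < length(chroms))
      stop("fewer wavelengths than chromophores for layer '", layer, "'")
    E <- extinctionMatrix(spectra, wavelengths, chroms)
    if (qr(E)$rank < ncol(E))
      stop("extinction matrix rank-deficient for layer '", layer, "'")
    s2 <- sigma[, layer]^2
    if (any(!is.finite(s2)) || any(s2 <= 0))
      stop("sigma_dmua must be positive and finite")
    if (weighted) {
      M <- crossprod(E / s2, E)  # E' W E with W = diag(1/s2)
      .checkConditioning(M, paste0("E' W E (", layer, ")"))
      C <- solve(M)
    } else {
      P <- solve(crossprod(E), t(E))  # OLS pseudo-inverse
      C <- P %*% (s2 * t(P))
    }
    dimnames(C) <- list(chroms, chroms)
    covs[[layer]] <- C
    rows[[layer]] <- data.frame(layer = layer, chromophore = chroms,
                                sigma_uM = sqrt(diag(C)),
                                row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cov") <- covs
  out
}
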