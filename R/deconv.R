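#' DSB-location kernel on a profile bin grid
#'
#' Probability mass of the true break position's offset from the hotspot
#' center, discretized on the profile bin grid. Aggregate profiles are the
#' per-break footprint blurred by this within-hotspot break-position
#' spread; deconvolution inverts it. The Gaussian constructor integrates a
#' normal density over each bin and truncates at `radius` bins before
#' renormalizing to exactly 1.
#'
#' @param sd standard deviation of the break position about the center (bp);
#'   `sd = 0` gives a delta kernel.
#' @param binsize bin width (bp), matching the profile grid.
#' @param radius half-width of the kernel support in bins (default 4 sd).
#' @return numeric vector of masses, named by bin-start offset; sums to 1.
#' @examples
#' k <- dsbLocationKernel(0, 40)   # delta kernel
#' @export
dsbLocationKernel <- function(sd, binsize, radius = NULL) {
  stopifnot(sd >= 0, binsize >= 1)
  if (sd == 0) {
    k <- 1
    offs <- 0
  } else {
    if (is.null(radius)) radius <- ceiling(4 * sd / binsize)
    offs <- (-radius:radius) * binsize
    lo <- offs - binsize / 2
    hi <- offs + binsize / 2
    k <- pnorm(hi, 0, sd) - pnorm(lo, 0, sd)
    k <- k / sum(k)
  }
  structure(k, names = as.character(offs))
}

#' Convolution (design) matrix of a DSB-location kernel
#'
#' Builds the matrix H with `H[i, j]` equal to the kernel mass at offset
#' `i - j` bins, so that an observed profile is `y = H s` for a per-break
#' footprint `s` on the same grid. Edges are truncated: interior columns
#' sum to 1, edge columns to less.
#'
#' @param kernel kernel from [dsbLocationKernel()] (names are bp offsets on
#'   the bin grid).
#' @param nBins number of profile bins.
#' @param binsize bin width (bp), to interpret the kernel offsets.
#' @return `nBins x nBins` matrix.
#' @export
buildKernelMatrix <- function(kernel, nBins, binsize) {
  offs <- as.numeric(names(kernel))
  if (any(offs %% binsize != 0))
    stop("kernel offsets must lie on the profile bin grid", call. = FALSE)
  ob <- as.integer(offs / binsize)
  if (length(kernel) > nBins)
    stop("kernel is wider than the profile window", call. = FALSE)
  H <- matrix(0, nBins, nBins)
  for (t in seq_along(ob)) {
    o <- ob[t]
    j <- seq_len(nBins)
    i <- j + o
    ok <- i >= 1L & i <= nBins
    H[cbind(i[ok], j[ok])] <- H[cbind(i[ok], j[ok])] + kernel[t]
  }
  H
}

# Lawson-Hanson active-set nonnegative least squares:
#   min ||b - A x||^2  s.t.  x >= 0
# Returns the KKT point: x >= 0, gradient w = A'(b - A x) <= tol outside the
# passive set, |w| <= tol on it.
.nnlsLH <- function(A, b, tol = 1e-10, maxIter = NULL) {
  p <- ncol(A)
  if (is.null(maxIter)) maxIter <- 10L * p
  x <- numeric(p)
  passive <- logical(p)
  w <- drop(crossprod(A, b))
  iter <- 0L
  resHist <- numeric(0)
  scale <- max(1, max(abs(w)))
  while (any(!passive) && max(w[!passive]) > tol * scale) {
    iter <- iter + 1L
    if (iter > maxIter) {
      err <- simpleError("NNLS failed to converge within the iteration cap")
      err$residualHistory <- resHist
      stop(err)
    }
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(p)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > 0)) break
      neg <- passive & z <= 0
      alpha <- suppressWarnings(min(x[neg] / (x[neg] - z[neg]), na.rm = TRUE))
      if (!is.finite(alpha)) alpha <- 0
      x <- x + alpha * (z - x)
      passive <- passive & x > tol * 1e-4
      x[!passive] <- 0
    }
    x <- z
    r <- b - drop(A %*% x)
    w <- drop(crossprod(A, r))
    resHist <- c(resHist, sqrt(sum(r^2)))
  }
  list(x = x, residual = sqrt(sum((b - drop(A %*% x))^2)), iterations = iter)
}

#' Nonnegative (optionally ridge-regularized) least-squares deconvolution
#'
#' Solves `argmin ||y - H s||^2 + lambda ||s||^2` subject to `s >= 0` with
#' a Lawson-Hanson active-set solver (ridge handled by augmenting the
#' system with `sqrt(lambda) I`). The solution satisfies the KKT conditions
#' to within `tol`; the fit is deterministic.
#'
#' @param y observed profile values (finite numeric vector).
#' @param H convolution matrix from [buildKernelMatrix()].
#' @param lambda ridge penalty (default 0); a small ridge is useful when
#'   edge truncation ill-conditions H.
#' @param tol KKT tolerance (default 1e-10, comfortably inside the 1e-8
#'   contract).
#' @return list with `s` (nonnegative solution), `residual` (Euclidean norm
#'   of `y - H s`), `iterations`.
#' @examples
#' H <- diag(4)
#' deconvolve(c(1, 0, 2, 3), H)$s   # identity kernel returns y
#' @export
deconvolve <- function(y, H, lambda = 0, tol = 1e-10) {
  stopifnot(is.matrix(H), length(y) == nrow(H), all(is.finite(y)),
            lambda >= 0)
  A <- H
  b <- y
  if (lambda > 0) {
    A <- rbind(H, sqrt(lambda) * diag(ncol(H)))
    b <- c(y, numeric(ncol(H)))
  }
  fit <- .nnlsLH(A, b, tol = tol)
  list(s = fit$x, residual = sqrt(sum((y - drop(H %*% fit$x))^2)),
       iterations = fit$iterations)
}

#' Deconvolve a full aggregate profile into per-break footprints
#'
#' Runs [deconvolve()] panel by panel (strand x homolog role) on a
#' [StrandProfile-class], after subtracting an optional flat background
#' level, yielding the per-DSB binding footprint of the assayed protein.
#' With a delta kernel the footprint equals the background-subtracted
#' profile.
#'
#' @param profile a [StrandProfile-class].
#' @param kernel DSB-location kernel from [dsbLocationKernel()], on the
#'   profile's bin grid.
#' @param lambda ridge penalty (default 0).
#' @param background flat background level to subtract from each bin
#'   (fragments per hotspot per bin; scalar or one value per panel).
#' @return a [FootprintModel-class].
#' @export
footprintPipeline <- function(profile, kernel, lambda = 0, background = 0) {
  stopifnot(is(profile, "StrandProfile"))
  v <- profileValues(profile)
  H <- buildKernelMatrix(kernel, nrow(v), profile@binsize)
  bg <- rep(background, length.out = ncol(v))
  fits <- lapply(seq_len(ncol(v)), function(j)
    deconvolve(v[, j] - bg[j], H, lambda = lambda))
  vals <- vapply(fits, `[[`, numeric(nrow(v)), "s")
  colnames(vals) <- colnames(v)
  res <- vapply(fits, `[[`, numeric(1), "residual")
  names(res) <- colnames(v)
  new("FootprintModel", values = vals, residuals = res, lambda = lambda,
      binsize = profile@binsize, halfWidth = profile@halfWidth)
}
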