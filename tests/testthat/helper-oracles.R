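# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Exhaustive active-set NNLS: try every support set, solve the restricted
# unconstrained least-squares problem, keep feasible solutions, return the
# one with the smallest objective. Exact for small p.
oracleNnlsEnum <- function(A, b, lambda = 0) {
  if (lambda > 0) {
    A <- rbind(A, sqrt(lambda) * diag(ncol(A)))
    b <- c(b, numeric(ncol(A)))
  }
  p <- ncol(A)
  best <- numeric(p)
  bestObj <- sum(b^2)
  for (m in seq_len(2^p) - 1L) {
    S <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) > 0L)
    if (length(S) == 0L) next
    xs <- tryCatch(qr.coef(qr(A[, S, drop = FALSE]), b),
                   error = function(e) NULL)
    if (is.null(xs) || anyNA(xs) || any(xs < 0)) next
    x <- numeric(p)
    x[S] <- xs
    obj <- sum((b - A %*% x)^2)
    if (obj < bestObj - 1e-12) {
      bestObj <- obj
      best <- x
    }
  }
  best
}

# Clopper-Pearson interval by direct root-finding on the binomial tails
# (independent of the qbeta identity used in the implementation)
oracleClopperPearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else
    uniroot(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

# per-base brute-force coverage, aggregated to bins
oracleCoverage <- function(fragments, binsize, len) {
  nb <- as.integer(ceiling(len / binsize))
  out <- matrix(0L, nb, 2L, dimnames = list(NULL, c("F", "R")))
  st <- GenomicRanges::start(fragments)
  en <- GenomicRanges::end(fragments)
  sd <- as.character(GenomicRanges::strand(fragments))
  for (i in seq_along(fragments)) {
    for (bin in seq_len(nb)) {
      b1 <- (bin - 1L) * binsize + 1L
      b2 <- min(bin * binsize, len)
      if (st[i] <= b2 && en[i] >= b1)
        out[bin, if (sd[i] == "+") "F" else "R"] <-
          out[bin, if (sd[i] == "+") "F" else "R"] + 1L
    }
  }
  out
}

# direct convolution sum (loop form)
oracleConvolve <- function(kernel, binsize, s) {
  offs <- as.integer(as.numeric(names(kernel)) / binsize)
  n <- length(s)
  y <- numeric(n)
  for (i in seq_len(n))
    for (t in seq_along(offs)) {
      j <- i - offs[t]
      if (j >= 1 && j <= n) y[i] <- y[i] + kernel[t] * s[j]
    }
  y
}

# per-fragment brute-force profile binning, mirroring the documented rules
oracleProfile <- function(fragments, calls, hotspots, symmetry, binsize,
                          halfWidth) {
  mc <- S4Vectors::mcols(hotspots)
  asym <- which(symmetry$label %in% c("asymmetric_B6", "asymmetric_CAST") &
                !mc$onXNonPar)
  nb <- 2L * halfWidth %/% binsize
  panels <- c("F.dsb_initiating", "R.dsb_initiating",
              "F.repair_template", "R.repair_template")
  out <- matrix(0, nb, 4, dimnames = list(NULL, panels))
  mid <- (GenomicRanges::start(fragments) + GenomicRanges::end(fragments) +
          1L) %/% 2L
  frChrom <- as.character(GenomicRanges::seqnames(fragments))
  frStrand <- as.character(GenomicRanges::strand(fragments))
  nFrag <- 0L
  for (i in seq_along(fragments)) {
    if (!calls$call[i] %in% c("B6", "CAST")) next
    for (h in asym) {
      if (frChrom[i] != as.character(GenomicRanges::seqnames(hotspots))[h])
        next
      d <- mid[i] - mc$center[h]
      fwd <- frStrand[i] == "+"
      if (as.character(GenomicRanges::strand(hotspots))[h] == "-") {
        d <- -d
        fwd <- !fwd
      }
      if (d < -halfWidth || d >= halfWidth) next
      dsb <- if (symmetry$label[h] == "asymmetric_B6")
        calls$call[i] == "B6" else calls$call[i] == "CAST"
      panel <- paste0(if (fwd) "F" else "R",
                      if (dsb) ".dsb_initiating" else ".repair_template")
      bin <- (d + halfWidth) %/% binsize + 1L
      out[bin, panel] <- out[bin, panel] + 1
      nFrag <- nFrag + 1L
      break
    }
  }
  list(values = out / length(asym), nFragments = nFrag)
}

# expected probability that a simulated fragment covers a grid SNP,
# integrating the truncated/rounded length model numerically
oracleInformativeProb <- function(mean, sd, minLen, spacing) {
  lens <- seq(ceiling(mean - 8 * sd), floor(mean + 8 * sd))
  wt <- dnorm(lens, mean, sd)
  wt <- wt / sum(wt)
  eff <- pmax(lens, minLen)
  sum(wt * pmin(eff / spacing, 1))
}
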