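#' Biweight midcorrelation
#'
#' Robust correlation based on the median and median absolute deviation
#' (MAD): observations are weighted by a bisquare function of their distance
#' from the median in units of 9 MADs, so outliers beyond 9 MADs receive zero
#' weight. Computation is restricted to pairwise-complete entries. A variable
#' whose MAD is zero (more than half its values tied) has no robust scale, so
#' the calculation falls back to Pearson weighting for that variable.
#'
#' @param x,y numeric vectors of equal length; NAs allowed.
#' @param minOverlap minimum number of jointly observed entries required;
#'   below it the result is NA (flagged, never silently 0).
#' @return correlation in \[-1, 1\], or NA when overlap is insufficient or a
#'   variable has no spread.
#' @examples
#' bicor(1:10, (1:10)^2)
#' @export
bicor <- function(x, y, minOverlap = 10) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < max(3, minOverlap)) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  xw <- .bicorTransform(x)
  yw <- .bicorTransform(y)
  if (is.null(xw) || is.null(yw)) return(NA_real_)
  num <- sum(xw * yw)
  den <- sqrt(sum(xw^2)) * sqrt(sum(yw^2))
  if (den == 0) return(NA_real_)
  max(-1, min(1, num / den))
}

# bisquare-weighted, median-centered transform of one variable; NULL if the
# variable has no spread at all
.bicorTransform <- function(x) {
  med <- median(x)
  madx <- mad(x, constant = 1)
  if (madx == 0) {
    # Pearson fallback: mean-centered, unit weights
    xc <- x - mean(x)
    if (all(xc == 0)) return(NULL)
    return(xc)
  }
  u <- (x - med) / (9 * madx)
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  (x - med) * w
}

#' Biweight midcorrelation matrix between rows
#'
#' Computes all pairwise biweight midcorrelations between the rows of a
#' matrix (protein profiles) or, with two matrices, between rows of the first
#' and rows of the second. Each row is robust-transformed once on its
#' observed entries; pairs are then combined on jointly observed positions
#' with per-pair renormalization. This single-pass treatment of missing data
#' is the standard fast approximation for pairwise-complete robust
#' correlation on large matrices; the two-vector [bicor()] recomputes
#' median/MAD on the joint subset and is the reference definition.
#'
#' @param x numeric matrix, variables in rows.
#' @param y optional second matrix with the same number of columns.
#' @param minOverlap minimum jointly observed entries per pair; pairs below
#'   it get NA.
#' @return correlation matrix, rows of \code{x} by rows of \code{y} (or
#'   \code{x} by \code{x}).
#' @export
bicorMatrix <- function(x, y = NULL, minOverlap = 10) {
  x <- as.matrix(x)
  Zx <- t(apply(x, 1L, .bicorTransformNA))
  if (is.null(y)) { Zy <- Zx; y <- x } else {
    y <- as.matrix(y)
    stopifnot(ncol(x) == ncol(y))
    Zy <- t(apply(y, 1L, .bicorTransformNA))
  }
  Mx <- is.finite(x) * 1; My <- is.finite(y) * 1
  Zx0 <- Zx; Zx0[!is.finite(Zx0)] <- 0
  Zy0 <- Zy; Zy0[!is.finite(Zy0)] <- 0
  num <- Zx0 %*% t(Zy0)
  # per-pair norms over jointly observed entries
  nx <- (Zx0^2) %*% t(My)
  ny <- Mx %*% t(Zy0^2)
  den <- sqrt(nx * ny)
  r <- num / den
  r[den == 0] <- NA
  overlap <- Mx %*% t(My)
  r[overlap < minOverlap] <- NA
  r[r > 1] <- 1; r[r < -1] <- -1
  rownames(r) <- rownames(x); colnames(r) <- rownames(y)
  r
}

# like .bicorTransform but keeps NA positions (transform computed on the
# observed entries only)
.bicorTransformNA <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x)
  if (sum(ok) < 2) return(out)
  xt <- .bicorTransform(x[ok])
  if (is.null(xt)) return(out)
  out[ok] <- xt
  out
}

#' Correlation p-value from the Student t approximation
#'
#' Two-sided p-value for a correlation coefficient on n observations using
#' the t distribution with n - 2 degrees of freedom.
#'
#' @param r correlation value(s).
#' @param n number of observations.
#' @return p-value(s) in (0, 1].
#' @export
corPvalue <- function(r, n) {
  r2 <- pmin(1 - 1e-15, r^2)
  tstat <- abs(r) * sqrt((n - 2) / (1 - r2))
  2 * pt(tstat, df = n - 2, lower.tail = FALSE)
}
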