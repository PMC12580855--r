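#' Median polish decomposition of a two-way table
#'
#' Decomposes a grid into \code{overall + row + col + residual} by
#' alternately sweeping out row medians and column medians of the residuals
#' (rows first), until the largest absolute adjustment in a full sweep falls
#' below \code{tol} or \code{maxIter} sweeps are reached. Missing cells are
#' ignored by the medians and left missing in the residuals. At convergence
#' the median of residuals along every row and every column is within
#' \code{tol} of zero.
#'
#' @param grid numeric matrix, missing values allowed; every row and column
#'   must contain at least one observed value.
#' @param tol convergence tolerance on the largest absolute adjustment.
#' @param maxIter maximum number of full sweeps.
#' @return list with \code{overall}, \code{row} (row effects), \code{col}
#'   (column effects), \code{residuals} and \code{converged}; a
#'   non-converged run warns and returns the partial decomposition.
#' @examples
#' g <- outer(c(0, 1, 2, 5), c(0, 3, 4), "+")
#' mp <- medianPolish(g)
#' max(abs(mp$residuals))
#' @export
medianPolish <- function(grid, tol = 1e-4, maxIter = 20) {
  grid <- as.matrix(grid)
  if (any(rowSums(is.finite(grid)) == 0) || any(colSums(is.finite(grid)) == 0))
    stop("every row and column must contain at least one observed value")
  r <- numeric(nrow(grid))
  cl <- numeric(ncol(grid))
  overall <- 0
  res <- grid
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    rmed <- rowMedians2(res)
    res <- res - rmed
    r <- r + rmed
    # the median of the row effects migrates into the overall term
    rshift <- median(r)
    r <- r - rshift
    overall <- overall + rshift
    cmed <- colMedians2(res)
    res <- sweep(res, 2L, cmed)
    cl <- cl + cmed
    cshift <- median(cl)
    cl <- cl - cshift
    overall <- overall + cshift
    delta <- max(abs(rmed), abs(cmed), na.rm = TRUE)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("median polish did not converge in ", maxIter, " sweeps")
  names(r) <- rownames(grid)
  names(cl) <- colnames(grid)
  list(overall = overall, row = r, col = cl, residuals = res,
       converged = converged)
}
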