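#' k-nearest-neighbour imputation over protein profiles
#'
#' Replaces each missing cell by the average of the observed values, at that
#' sample, of the k proteins nearest to the target protein (Euclidean
#' distance over jointly observed samples, scaled to a per-sample average so
#' different overlaps are comparable). Observed entries are never changed.
#' Intended only for analyses requiring a complete matrix (variance
#' partition, per-module PCA); network construction and subtyping operate on
#' the unimputed data.
#'
#' @param x abundance matrix or SummarizedExperiment; every protein needs at
#'   least one observed value.
#' @param k number of neighbour proteins, default 10; must be below the
#'   protein count.
#' @return object of the input type with missing cells filled (cells with no
#'   observed neighbour fall back to the protein mean).
#' @export
knnImpute <- function(x, k = 10) {
  X <- .abundance(x)
  if (k >= nrow(X)) stop("k must be smaller than the number of proteins")
  if (any(rowSums(is.finite(X)) == 0))
    stop("every protein needs at least one observed value")
  out <- X
  missRows <- which(rowSums(!is.finite(X)) > 0)
  if (length(missRows)) {
    M <- is.finite(X)
    X0 <- X; X0[!M] <- 0
    # squared distances over shared observed samples, per-sample average
    xx <- (X0^2) %*% t(M)
    cross <- X0 %*% t(X0)
    overlap <- M %*% t(M * 1)
    d2 <- (xx + t(xx) - 2 * cross) / pmax(overlap, 1)
    d2[overlap == 0] <- Inf
    diag(d2) <- Inf
    for (p in missRows) {
      nb <- order(d2[p, ])[seq_len(k)]
      missCols <- which(!M[p, ])
      for (j in missCols) {
        vals <- X[nb, j]
        vals <- vals[is.finite(vals)]
        out[p, j] <- if (length(vals)) mean(vals)
                     else mean(X[p, ], na.rm = TRUE)
      }
    }
  }
  if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::`assay<-`(x, value = out)
  else out
}
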