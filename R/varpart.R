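#' Per-protein variance fractions across experimental factors
#'
#' Decomposes each protein's variance into fractions attributable to a set
#' of factors plus a residual, using fixed-effect sequential sums of squares
#' averaged over all factor orderings (the Lindeman-Merenda-Gold
#' decomposition), so the fractions are order-independent and sum to one.
#' Requires a complete matrix (run [knnImpute()] first).
#'
#' @param x complete abundance matrix or SummarizedExperiment.
#' @param traits traits data.frame when \code{x} is a matrix.
#' @param factors character, trait columns to decompose over (at most 5;
#'   the orderings grow factorially).
#' @return data.frame, one row per protein, columns = factor fractions plus
#'   \code{residual}, each in \[0, 1\], rows summing to 1.
#' @export
varianceFractions <- function(x, traits = NULL, factors) {
  X <- .abundance(x)
  if (anyNA(X)) stop("matrix must be complete; impute first")
  if (is.null(traits)) traits <- .traits(x)
  traits <- traits[match(colnames(X), traits$sample_id), , drop = FALSE]
  stopifnot(all(factors %in% names(traits)))
  if (length(factors) > 5) stop("at most 5 factors supported")

  df <- traits[, factors, drop = FALSE]
  for (v in factors) if (!is.numeric(df[[v]])) df[[v]] <- factor(df[[v]])
  # detect aliased (collinear) factors up front
  mmAll <- model.matrix(~ ., data = df)
  if (qr(mmAll)$rank < ncol(mmAll)) {
    for (a in seq_along(factors)) for (b in seq_along(factors)) {
      if (a >= b) next
      mm2 <- model.matrix(~ ., data = df[, c(a, b), drop = FALSE])
      if (qr(mm2)$rank < ncol(mm2))
        stop("collinear factors: ", factors[a], " and ", factors[b])
    }
    stop("design matrix is rank deficient")
  }

  Yc <- t(scale(t(X), center = TRUE, scale = FALSE))
  tss <- rowSums(Yc^2)

  # orthonormal bases for every ordering prefix; explained SS per protein is
  # a crossproduct, shared across proteins because the design is common
  orderings <- .permutations(seq_along(factors))
  k <- length(factors)
  ssFactor <- matrix(0, nrow(X), k, dimnames = list(rownames(X), factors))
  for (ord in orderings) {
    prev <- 0
    for (step in seq_len(k)) {
      mm <- model.matrix(~ ., data = df[, ord[seq_len(step)], drop = FALSE])
      Q <- qr.Q(qr(mm))
      expl <- rowSums((Yc %*% Q)^2)
      ssFactor[, ord[step]] <- ssFactor[, ord[step]] +
        (expl - prev) / length(orderings)
      prev <- expl
    }
  }
  fr <- ssFactor / tss
  fr[tss == 0, ] <- 0
  res <- pmax(0, 1 - rowSums(fr))
  out <- data.frame(fr, residual = res, check.names = FALSE)
  # guard tiny numerical drift
  out <- out / rowSums(out)
  out
}

.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
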