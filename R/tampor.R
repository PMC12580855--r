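#' Two-round median-polish harmonization anchored to reference channels
#'
#' Removes batch and set structure from a multi-set abundance matrix by two
#' rounds of median polish on reference-anchored log2 ratios. Round 1 runs
#' within each set: every protein is expressed as the log2 ratio to the
#' median over that batch's GIS (pooled reference) channels, then the
#' (protein x sample) grid is median-polished and its residuals plus protein
#' effects kept. Round 2 concatenates the sets, re-anchors every protein to
#' its median over non-Hispanic White control samples, and polishes again.
#' GIS columns are dropped from the final matrix. Missingness is preserved
#' exactly.
#'
#' @param cohort SummarizedExperiment with traits in colData (needs
#'   \code{set_label}, \code{batch_label}, \code{is_gis}, \code{diagnosis},
#'   \code{race}), or a list of per-set matrices plus a \code{traits}
#'   data.frame.
#' @param traits traits data.frame when \code{cohort} is a matrix.
#' @param tol,maxIter median-polish convergence controls (log2 scale).
#' @return SummarizedExperiment of harmonized log2 ratios (GIS columns
#'   removed), with metadata field \code{scale_tag = "harmonized"}.
#' @export
tamporTwoRound <- function(cohort, traits = NULL, tol = 1e-4, maxIter = 20) {
  X <- .abundance(cohort)
  if (is.null(traits)) traits <- .traits(cohort)
  traits <- traits[match(colnames(X), traits$sample_id), , drop = FALSE]
  isGis <- traits$is_gis

  sets <- unique(traits$set_label[!isGis])
  roundOne <- list()
  for (s in sets) {
    inSet <- which(traits$set_label == s)
    sub <- X[, inSet, drop = FALSE]
    subTraits <- traits[inSet, , drop = FALSE]
    # anchor each batch to its GIS reference median
    ratio <- sub
    for (b in unique(subTraits$batch_label)) {
      gisCols <- which(subTraits$batch_label == b & subTraits$is_gis)
      if (!length(gisCols))
        stop("batch '", b, "' has no GIS reference channel")
      ref <- rowMedians2(sub[, gisCols, drop = FALSE])
      bCols <- which(subTraits$batch_label == b)
      ratio[, bCols] <- sub[, bCols, drop = FALSE] - ref
    }
    keep <- !subTraits$is_gis
    mp <- medianPolish(ratio[, keep, drop = FALSE], tol = tol,
                       maxIter = maxIter)
    # keep protein (row) effects with the residuals: they carry the
    # biological abundance profile; sample and overall effects are nuisance
    roundOne[[s]] <- mp$residuals + mp$row
  }
  combined <- do.call(cbind, roundOne)
  combined <- combined[, match(traits$sample_id[!isGis], colnames(combined)),
                       drop = FALSE]
  sampleTraits <- traits[!isGis, , drop = FALSE]

  nhwControl <- which(!is.na(sampleTraits$diagnosis) &
                        sampleTraits$diagnosis == "control" &
                        sampleTraits$race == "NHW")
  if (!length(nhwControl)) stop("no non-Hispanic White control samples found")
  ref2 <- rowMedians2(combined[, nhwControl, drop = FALSE])
  mp2 <- medianPolish(combined - ref2, tol = tol, maxIter = maxIter)
  out <- mp2$residuals + mp2$row

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = out),
    colData = S4Vectors::DataFrame(sampleTraits))
  S4Vectors::metadata(se)$scale_tag <- "harmonized"
  se
}

#' Remove nuisance covariate effects by bootstrap regression
#'
#' Per protein, fits a linear model with the nuisance and preserved factors
#' on bootstrap resamples of the samples, averages the fitted coefficients
#' over resamples, and subtracts only the nuisance component. Effects of the
#' preserved factors (e.g. diagnosis, race, sex, age) are untouched, and
#' missing cells stay missing.
#'
#' @param cohort SummarizedExperiment or matrix of log2 abundances.
#' @param traits traits data.frame when \code{cohort} is a matrix.
#' @param nuisance character, factor names to regress out (e.g.
#'   \code{c("set_label", "batch_label")}).
#' @param preserve character, factor names whose effects must be retained.
#' @param n_boot bootstrap resamples, default 100.
#' @param seed integer seed.
#' @param min_obs minimum observed samples per protein; proteins below it
#'   are skipped with a warning.
#' @return object of the input type with nuisance effects removed.
#' @export
bootstrapRegressCovariates <- function(cohort, traits = NULL,
                                       nuisance, preserve = character(),
                                       n_boot = 100, seed = 1L,
                                       min_obs = 10) {
  X <- .abundance(cohort)
  if (is.null(traits)) traits <- .traits(cohort)
  traits <- traits[match(colnames(X), traits$sample_id), , drop = FALSE]
  miss <- setdiff(c(nuisance, preserve), names(traits))
  if (length(miss)) stop("factors not in traits: ", paste(miss, collapse = ", "))

  vars <- c(nuisance, preserve)
  df <- traits[, vars, drop = FALSE]
  for (v in vars) if (!is.numeric(df[[v]])) df[[v]] <- factor(df[[v]])
  mm <- model.matrix(~ ., data = df)
  nuisCols <- unlist(lapply(nuisance, function(v) grep(paste0("^", v), colnames(mm))))
  nuisCols <- setdiff(unique(nuisCols), 1L)

  out <- X
  skipped <- 0L
  withSeed(seed, {
    for (p in seq_len(nrow(X))) {
      obs <- which(is.finite(X[p, ]))
      if (length(obs) < min_obs) { skipped <- skipped + 1L; next }
      Zp <- mm[obs, , drop = FALSE]
      yp <- X[p, obs]
      if (qr(Zp)$rank < ncol(Zp)) { skipped <- skipped + 1L; next }
      coefSum <- numeric(ncol(Zp))
      nb <- 0L
      for (b in seq_len(n_boot)) {
        i <- sample.int(length(obs), replace = TRUE)
        co <- stats::lm.fit(Zp[i, , drop = FALSE], yp[i])$coefficients
        if (anyNA(co)) next
        coefSum <- coefSum + co
        nb <- nb + 1L
      }
      if (nb == 0L) { skipped <- skipped + 1L; next }
      beta <- coefSum / nb
      out[p, obs] <- yp - Zp[, nuisCols, drop = FALSE] %*% beta[nuisCols]
    }
  })
  if (skipped > 0L)
    warning(skipped, " protein(s) skipped (too few observations or ",
            "rank-deficient design)")
  if (methods::is(cohort, "SummarizedExperiment"))
    SummarizedExperiment::`assay<-`(cohort, value = out)
  else out
}
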