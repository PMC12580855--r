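#' Filter proteins by minimum presence across samples
#'
#' Retains exactly the proteins observed (non-missing) in at least
#' \code{min_presence} of the non-GIS samples; the comparison is inclusive.
#' Protein order is preserved.
#'
#' @param x abundance matrix or SummarizedExperiment.
#' @param min_presence required fraction of samples with an observed value,
#'   default 0.5.
#' @param is_gis optional logical per column; GIS columns are excluded from
#'   the denominator (taken from colData when \code{x} is a
#'   SummarizedExperiment).
#' @return object of the same type with failing proteins dropped.
#' @export
filterMinPresence <- function(x, min_presence = 0.5, is_gis = NULL) {
  .checkFraction(min_presence, "min_presence")
  X <- .abundance(x)
  if (is.null(is_gis) && methods::is(x, "SummarizedExperiment")) {
    cd <- .traits(x)
    if ("is_gis" %in% names(cd)) is_gis <- cd$is_gis
  }
  if (is.null(is_gis)) is_gis <- rep(FALSE, ncol(X))
  sub <- X[, !is_gis, drop = FALSE]
  frac <- rowMeans(is.finite(sub))
  keep <- frac >= min_presence
  if (!any(keep))
    stop("no protein passes the presence filter of ", min_presence)
  if (methods::is(x, "SummarizedExperiment")) x[keep, ] else X[keep, , drop = FALSE]
}

#' Exclude samples with biomarker-discordant diagnoses
#'
#' Applies the diagnostic QC rule: an AD-labelled sample is kept only when
#' its immunoassay t-tau / abeta42 ratio is at least \code{ratio_threshold}
#' (the comparison is inclusive). Controls are not subject to the ratio
#' rule. An optional extra predicate can exclude further samples (e.g. a
#' cognition-score incongruence rule); it receives the traits table and must
#' return a logical exclusion vector.
#'
#' @param traits traits data.frame with \code{diagnosis}, \code{t_tau},
#'   \code{abeta42} (GIS rows, if present, are passed through untouched).
#' @param ratio_threshold minimum t-tau/abeta42 ratio for AD confirmation,
#'   default 0.226.
#' @param extra_predicate optional \code{function(traits) -> logical}.
#' @return list with \code{kept} (sample ids) and \code{excluded}
#'   (data.frame of sample id and reason).
#' @export
qcExcludeDiscordant <- function(traits, ratio_threshold = 0.226,
                                extra_predicate = NULL) {
  traits <- .traits(traits)
  isGis <- if ("is_gis" %in% names(traits)) traits$is_gis else rep(FALSE, nrow(traits))
  ad <- !isGis & !is.na(traits$diagnosis) & traits$diagnosis == "AD"
  if (any(ad & (is.na(traits$t_tau) | is.na(traits$abeta42))))
    stop("t_tau and abeta42 must be present for AD-labelled samples")
  bad0 <- ad & traits$abeta42 == 0
  if (any(bad0))
    stop("undefined t-tau/abeta42 ratio (abeta42 = 0) for sample(s): ",
         paste(traits$sample_id[bad0], collapse = ", "))
  ratio <- traits$t_tau / traits$abeta42
  exclRatio <- ad & ratio < ratio_threshold
  reasons <- ifelse(exclRatio, "ratio", NA_character_)
  if (!is.null(extra_predicate)) {
    extra <- extra_predicate(traits) & !isGis
    reasons[is.na(reasons) & extra] <- "predicate"
  }
  excluded <- !is.na(reasons)
  list(
    kept = traits$sample_id[!excluded],
    excluded = data.frame(sample_id = traits$sample_id[excluded],
                          reason = reasons[excluded],
                          stringsAsFactors = FALSE)
  )
}

#' Z-score values independently within each set
#'
#' Standardizes a per-sample quantity (typically an immunoassay biomarker
#' measured on a different platform per set) to mean 0 and sample sd 1 within
#' each set. Missing values propagate.
#'
#' @param values numeric vector.
#' @param set_labels set label per entry.
#' @return numeric vector of within-set z-scores.
#' @export
zscorePerSet <- function(values, set_labels) {
  stopifnot(length(values) == length(set_labels))
  out <- rep(NA_real_, length(values))
  for (s in unique(set_labels)) {
    i <- which(set_labels == s)
    v <- values[i]
    obs <- v[!is.na(v)]
    if (length(obs) < 2) stop("set '", s, "' has fewer than 2 observed values")
    if (sd(obs) == 0) stop("set '", s, "' has zero variance")
    out[i] <- (v - mean(obs)) / sd(obs)
  }
  out
}

#' APOE allele risk score
#'
#' Additive allele score: +1 for each epsilon-4 allele, -1 for each
#' epsilon-2 allele; epsilon-3 contributes 0. Range -2 to +2.
#'
#' @param e2_count,e4_count allele counts in 0..2, jointly at most 2
#'   (vectorized).
#' @return integer score(s).
#' @examples
#' apoeRiskScore(0, 2) # e4/e4 homozygote
#' apoeRiskScore(1, 1) # e2/e4 heterozygote
#' @export
apoeRiskScore <- function(e2_count, e4_count) {
  if (any(e2_count < 0 | e2_count > 2 | e4_count < 0 | e4_count > 2,
          na.rm = TRUE) ||
      any(e2_count + e4_count > 2, na.rm = TRUE))
    stop("allele counts must be in 0..2 and sum to at most 2")
  as.integer(e4_count - e2_count)
}

#' Multi-factor ANOVA with Tukey post hoc comparisons
#'
#' Omnibus F tests for up to three categorical factors (main-effects ANOVA)
#' plus Tukey honestly-significant-difference pairwise p-values across the
#' crossed factor groups. Missing values are dropped listwise; empty crossed
#' cells trigger a warning and the analysis proceeds on the available cells.
#'
#' @param values numeric response per sample.
#' @param factors data.frame (or list) of 1-3 categorical factors.
#' @return list with \code{omnibus} (data.frame of factor, F, p) and
#'   \code{tukey} (data.frame of comparison, estimate, p_adj).
#' @export
anovaTukey <- function(values, factors) {
  factors <- as.data.frame(factors, stringsAsFactors = TRUE)
  stopifnot(ncol(factors) >= 1, ncol(factors) <= 3)
  ok <- !is.na(values) & complete.cases(factors)
  values <- values[ok]
  factors <- droplevels(as.data.frame(lapply(factors[ok, , drop = FALSE],
                                             factor)))
  if (any(vapply(factors, nlevels, 1L) < 2))
    stop("every factor needs at least 2 levels")
  crossed <- interaction(factors, drop = FALSE)
  if (any(table(crossed) == 0)) {
    warning("empty crossed cells; proceeding on available cells")
    crossed <- droplevels(crossed)
  }
  dat <- cbind(.y = values, factors)
  form <- stats::as.formula(paste(".y ~", paste(names(factors), collapse = " + ")))
  fit <- aov(form, data = dat)
  an <- summary(fit)[[1]]
  rows <- trimws(rownames(an)) != "Residuals"
  omnibus <- data.frame(factor = trimws(rownames(an))[rows],
                        F = an[rows, "F value"], p = an[rows, "Pr(>F)"],
                        stringsAsFactors = FALSE)
  gfit <- aov(values ~ crossed, data = data.frame(values = values,
                                                  crossed = droplevels(crossed)))
  tk <- TukeyHSD(gfit)$crossed
  tukey <- data.frame(comparison = rownames(tk), estimate = tk[, "diff"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE,
                      row.names = NULL)
  list(omnibus = omnibus, tukey = tukey)
}
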