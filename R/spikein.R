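#' Percent-of-baseline trajectories for a dilution series
#'
#' Per protein and condition: the linear-scale mean abundance (log2 values
#' exponentiated before averaging) divided by the baseline linear-scale mean,
#' times 100. The baseline condition is 100 exactly for every protein by
#' construction.
#'
#' @param series a \linkS4class{DilutionSeries}.
#' @return proteins x conditions percentage matrix (columns named by
#'   concentration, increasing).
#' @export
percentOfBaseline <- function(series) {
  stopifnot(methods::is(series, "DilutionSeries"))
  ab <- series@abundance
  conds <- series@concentrations
  out <- matrix(NA_real_, nrow(ab), length(conds),
                dimnames = list(rownames(ab), as.character(conds)))
  lin <- 2^ab
  baseMean <- rowMeans(lin[, series@condition == 0, drop = FALSE], na.rm = TRUE)
  if (any(!is.finite(baseMean) | baseMean == 0))
    warning("protein(s) with undefined baseline flagged NA")
  for (ci in seq_along(conds)) {
    condMean <- rowMeans(lin[, series@condition == conds[ci], drop = FALSE],
                         na.rm = TRUE)
    out[, ci] <- 100 * condMean / baseMean
  }
  out[!is.finite(baseMean) | baseMean == 0, ] <- NA
  out
}

#' Related-measures ANOVA on module hub trajectories
#'
#' Tests, per module, whether hub-protein percent-of-baseline values differ
#' between the baseline and top-dose conditions, treating the protein as the
#' repeated unit (one-way ANOVA on condition with protein as a block) with
#' Tukey adjustment over condition comparisons; Benjamini-Hochberg adjusted
#' p across modules is reported as a secondary column.
#'
#' @param percent proteins x conditions percentage matrix from
#'   [percentOfBaseline()].
#' @param module_hubs named list of hub protein id vectors per module.
#' @param baseline,top column names (concentrations) to compare; default
#'   first and last column.
#' @param min_proteins modules with fewer hubs present are skipped (logged),
#'   default 3.
#' @return data.frame of (module, n_proteins, mean_change_pct, p, p_bh).
#' @export
moduleDoseAnova <- function(percent, module_hubs,
                            baseline = colnames(percent)[1],
                            top = colnames(percent)[ncol(percent)],
                            min_proteins = 3) {
  if (identical(baseline, top))
    stop("need two distinct conditions to compare")
  rows <- list()
  for (m in names(module_hubs)) {
    prots <- intersect(module_hubs[[m]], rownames(percent))
    prots <- prots[is.finite(percent[prots, baseline]) &
                     is.finite(percent[prots, top])]
    if (length(prots) < min_proteins) {
      message("module ", m, " skipped: only ", length(prots),
              " hub protein(s) in the series")
      next
    }
    y <- c(percent[prots, baseline], percent[prots, top])
    cond <- factor(rep(c("baseline", "top"), each = length(prots)))
    prot <- factor(rep(prots, 2))
    fit <- aov(y ~ cond + prot)
    tk <- TukeyHSD(fit, which = "cond")$cond
    rows[[m]] <- data.frame(
      module = m, n_proteins = length(prots),
      mean_change_pct = mean(percent[prots, top] - percent[prots, baseline]),
      p = tk[1, "p adj"], stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no module had enough hub proteins")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_bh <- p.adjust(out$p, method = "BH")
  out
}

#' Exclude extreme hub values by leave-one-out standard deviation
#'
#' Flags values more than \code{threshold_sd} standard deviations from the
#' module mean, where mean and sd are computed excluding the candidate value
#' so a single extreme point cannot mask itself. Flagged values are removed
#' from the returned analysis vector but retained in the exclusion log for
#' plotting.
#'
#' @param values named numeric vector (percent values of one module's hubs).
#' @param threshold_sd exclusion threshold, default 5.
#' @return list with \code{kept}, \code{excluded} (named values) and
#'   \code{log} (data.frame of id, value, z).
#' @export
excludeExtremeHub <- function(values, threshold_sd = 5) {
  stopifnot(length(values) >= 4)
  z <- vapply(seq_along(values), function(i) {
    rest <- values[-i]
    s <- sd(rest)
    if (s == 0) return(Inf * sign(values[i] - mean(rest)))
    (values[i] - mean(rest)) / s
  }, numeric(1))
  out <- abs(z) > threshold_sd
  list(kept = values[!out], excluded = values[out],
       log = data.frame(id = names(values)[out], value = values[out],
                        z = z[out], row.names = NULL))
}

#' Per-module dose-response regression
#'
#' Ordinary least squares of protein-level log2 abundance on the ordered
#' dose index (0 = baseline, 1, 2, ...), pooling a module's proteins as
#' replicates. The ordered index is used as the predictor because the
#' concentrations are log-spaced; \code{log_dose = TRUE} regresses on
#' log10(concentration) over the non-baseline conditions instead.
#'
#' @param series a \linkS4class{DilutionSeries}.
#' @param module_assignments named character vector mapping proteins to
#'   modules (proteins absent from the series are ignored).
#' @param log_dose use log10(concentration) as the predictor, dropping the
#'   baseline, default FALSE.
#' @return data.frame of (module, slope, se, p, n_proteins).
#' @export
moduleDoseRegression <- function(series, module_assignments, log_dose = FALSE) {
  stopifnot(methods::is(series, "DilutionSeries"))
  if (length(series@concentrations) < 3)
    stop("need at least 3 conditions for a regression")
  ab <- series@abundance
  doseIndex <- match(series@condition, series@concentrations) - 1
  mods <- sort(unique(module_assignments))
  rows <- list()
  for (m in mods) {
    prots <- intersect(names(module_assignments)[module_assignments == m],
                       rownames(ab))
    if (!length(prots)) next
    Y <- ab[prots, , drop = FALSE]
    if (log_dose) {
      keep <- series@condition > 0
      xv <- rep(log10(series@condition[keep]), each = length(prots))
      yv <- as.vector(Y[, keep, drop = FALSE])
    } else {
      xv <- rep(doseIndex, each = length(prots))
      yv <- as.vector(Y)
    }
    ok <- is.finite(yv)
    if (length(unique(xv[ok])) < 2) stop("singular dose design")
    fit <- lm(yv ~ xv, subset = ok)
    cf <- summary(fit)$coefficients
    rows[[m]] <- data.frame(module = m, slope = cf["xv", "Estimate"],
                            se = cf["xv", "Std. Error"],
                            p = cf["xv", "Pr(>|t|)"],
                            n_proteins = length(prots),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
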