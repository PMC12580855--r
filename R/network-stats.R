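#' Module-trait correlations
#'
#' Biweight midcorrelation between each module eigenprotein and each numeric
#' or binary-encoded trait, with a Student-t p-value on n - 2 degrees of
#' freedom over pairwise-complete samples. Set-2 members of replicate pairs
#' are excluded first so each participant contributes once. Binary traits
#' are encoded 0/1 (male = 1, AA = 1, AD = 1); the encoding is recorded in
#' the output.
#'
#' @param eigen modules x samples eigenprotein matrix.
#' @param traits traits data.frame.
#' @param trait_names columns of \code{traits} to correlate.
#' @return data.frame of (module, trait, bicor, p, n, encoding).
#' @export
moduleTraitCorrelations <- function(eigen, traits, trait_names) {
  traits <- .traits(traits)
  traits <- traits[match(colnames(eigen), traits$sample_id), , drop = FALSE]
  # drop Set-2 replicate-pair members: the Set-1 member represents the case
  drop <- !is.na(traits$replicate_pair_id) & traits$set_label == "Set2"
  eigen <- eigen[, !drop, drop = FALSE]
  traits <- traits[!drop, , drop = FALSE]
  out <- list()
  for (tr in trait_names) {
    v <- traits[[tr]]
    enc <- "numeric"
    if (!is.numeric(v)) {
      lv <- sort(unique(na.omit(as.character(v))))
      if (length(lv) != 2) {
        out[[tr]] <- data.frame(module = rownames(eigen), trait = tr,
                                bicor = NA_real_, p = NA_real_, n = NA_integer_,
                                encoding = "non-binary: skipped")
        next
      }
      enc <- paste0(lv[2], "=1")
      # code the level that reads as the risk/male/AA level as 1 where known
      one <- intersect(c("male", "AA", "AD"), lv)
      if (length(one)) { enc <- paste0(one[1], "=1"); v <- as.integer(v == one[1]) }
      else v <- as.integer(v == lv[2])
    }
    rows <- lapply(rownames(eigen), function(m) {
      ok <- is.finite(eigen[m, ]) & !is.na(v)
      n <- sum(ok)
      if (n < 3 || length(unique(v[ok])) < 2)
        return(data.frame(module = m, trait = tr, bicor = NA_real_,
                          p = NA_real_, n = n, encoding = enc))
      r <- bicor(eigen[m, ], as.numeric(v), minOverlap = 3)
      data.frame(module = m, trait = tr, bicor = r,
                 p = if (is.na(r)) NA_real_ else corPvalue(r, n),
                 n = n, encoding = enc)
    })
    out[[tr]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cell-type marker enrichment of modules
#'
#' One-tailed (over-representation) Fisher exact test of each module's
#' membership against each marker set, over the supplied protein universe,
#' with Benjamini-Hochberg adjustment across all (module, set) tests.
#'
#' @param labels module labels per protein.
#' @param marker_sets named list of protein id vectors (e.g. read from a GMT
#'   file with [readGmt()]).
#' @param background protein universe; defaults to the labelled proteins.
#' @return data.frame of (module, set, overlap, p, p_adj).
#' @export
celltypeEnrichment <- function(labels, marker_sets, background = names(labels)) {
  mods <- .moduleOrder(labels)
  rows <- list()
  for (m in mods) {
    inMod <- names(labels)[labels == m]
    inMod <- intersect(inMod, background)
    for (s in names(marker_sets)) {
      set <- intersect(marker_sets[[s]], background)
      if (!length(set)) { warning("marker set '", s, "' has no overlap with ",
                                  "the universe; skipped"); next }
      a <- length(intersect(inMod, set))
      tab <- matrix(c(a, length(inMod) - a,
                      length(set) - a,
                      length(background) - length(inMod) - length(set) + a),
                    2, 2)
      p <- fisher.test(tab, alternative = "greater")$p.value
      rows[[paste(m, s)]] <- data.frame(module = m, set = s, overlap = a,
                                        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Per-protein differential abundance across groups
#'
#' For each protein: group means on the log2 scale, pairwise differences
#' (log2 fold changes), one-way ANOVA omnibus p, and Tukey-adjusted pairwise
#' p-values. When Tukey is undefined for a pair (a degenerate cell),
#' a Bonferroni-adjusted Welch t-test p is substituted and flagged.
#'
#' @param x abundance matrix or SummarizedExperiment.
#' @param group factor per sample (at least 2 groups).
#' @param min_per_group minimum observed values per group per protein,
#'   default 3; proteins below it get missing statistics.
#' @return data.frame, one row per (protein, pair): \code{log2fc},
#'   \code{omnibus_p}, \code{pairwise_p}, \code{fallback} flag.
#' @export
differentialAbundance <- function(x, group, min_per_group = 3) {
  X <- .abundance(x)
  group <- factor(group)
  stopifnot(length(group) == ncol(X), nlevels(group) >= 2)
  lv <- levels(group)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- list()
  for (p in seq_len(nrow(X))) {
    y <- X[p, ]
    ok <- is.finite(y)
    counts <- table(group[ok])
    present <- names(counts)[counts >= min_per_group]
    if (length(present) < 2) {
      for (pr in pairs)
        rows[[length(rows) + 1L]] <- data.frame(
          protein = rownames(X)[p], group1 = pr[1], group2 = pr[2],
          log2fc = NA_real_, omnibus_p = NA_real_, pairwise_p = NA_real_,
          fallback = NA)
      next
    }
    gg <- droplevels(group[ok & group %in% present])
    yy <- y[ok & group %in% present]
    fit <- aov(yy ~ gg)
    omni <- summary(fit)[[1]][1, "Pr(>F)"]
    tk <- TukeyHSD(fit)$gg
    means <- tapply(yy, gg, mean)
    for (pr in pairs) {
      fc <- if (all(pr %in% names(means))) means[[pr[2]]] - means[[pr[1]]] else NA_real_
      key <- paste(pr[2], pr[1], sep = "-")
      if (key %in% rownames(tk) && is.finite(tk[key, "p adj"])) {
        pw <- tk[key, "p adj"]; fb <- FALSE
      } else if (all(pr %in% levels(gg))) {
        tt <- t.test(yy[gg == pr[2]], yy[gg == pr[1]])$p.value
        pw <- min(1, tt * length(pairs)); fb <- TRUE
      } else { pw <- NA_real_; fb <- NA }
      rows[[length(rows) + 1L]] <- data.frame(
        protein = rownames(X)[p], group1 = pr[1], group2 = pr[2],
        log2fc = fc, omnibus_p = omni, pairwise_p = pw, fallback = fb)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
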