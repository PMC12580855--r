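#' Generate a synthetic spike-in dilution series
#'
#' Simulates log2 protein abundances across a spike-in dilution of plasma
#' (or human serum albumin, HSA) into pooled CSF. Conditions are the
#' baseline (0 percent) plus the supplied concentrations; the planted log2
#' change of a protein at dose index d (1..D, ordered by concentration) is
#' \code{effect[class] * d / D}, i.e. linear on the ordered (log-spaced)
#' dose scale, reaching the class's full effect at the top dose. Replicate
#' noise is Gaussian on the log2 scale. An HSA control series is obtained by
#' passing zero effects.
#'
#' @param baseline_profile named numeric vector of baseline log2 abundances.
#' @param class_labels named character vector per protein, e.g.
#'   \code{"plasma_module"}, \code{"neuronal_module"},
#'   \code{"protected_module"}, \code{"background"}.
#' @param concentrations increasing spike concentrations (percent v/v),
#'   excluding the baseline 0 (added automatically), default
#'   \code{c(0.001, 0.01, 0.1, 1)}.
#' @param effects named numeric vector of full log2 changes at the top dose,
#'   one entry per class present in \code{class_labels}.
#' @param n_reps replicates per condition, default 3.
#' @param noise_sd replicate noise sd (log2), default 0.05.
#' @param spike_type \code{"plasma"} or \code{"HSA"}.
#' @param seed integer seed.
#' @return a \linkS4class{DilutionSeries}.
#' @examples
#' prof <- setNames(rnorm(6), paste0("P", 1:6))
#' cls <- setNames(rep(c("plasma_module", "background"), each = 3), names(prof))
#' generateDilutionSeries(prof, cls, effects = c(plasma_module = 1.93,
#'                                               background = 0))
#' @export
generateDilutionSeries <- function(baseline_profile, class_labels,
                                   concentrations = c(0.001, 0.01, 0.1, 1),
                                   effects, n_reps = 3, noise_sd = 0.05,
                                   spike_type = c("plasma", "HSA"),
                                   seed = 1L) {
  spike_type <- match.arg(spike_type)
  stopifnot(length(baseline_profile) == length(class_labels))
  if (any(concentrations <= 0)) stop("supply positive spike concentrations; ",
                                     "the 0 baseline is added automatically")
  concentrations <- sort(concentrations)
  missingCls <- setdiff(unique(class_labels), names(effects))
  if (length(missingCls))
    stop("effects missing for class(es): ", paste(missingCls, collapse = ", "))
  nP <- length(baseline_profile)
  conds <- c(0, concentrations)
  D <- length(concentrations)
  cols <- expand.grid(rep = seq_len(n_reps), cond = conds)
  withSeed(seed, {
    ab <- matrix(NA_real_, nP, nrow(cols),
                 dimnames = list(names(baseline_profile),
                                 sprintf("c%g.r%d", cols$cond, cols$rep)))
    for (ci in seq_len(nrow(cols))) {
      d <- match(cols$cond[ci], conds) - 1L  # 0 = baseline
      delta <- effects[class_labels] * d / D
      ab[, ci] <- baseline_profile + delta + rnorm(nP, 0, noise_sd)
    }
    methods::new("DilutionSeries",
                 spikeType = spike_type,
                 concentrations = conds,
                 abundance = ab,
                 condition = cols$cond,
                 replicate = as.integer(cols$rep),
                 proteinClass = setNames(as.character(class_labels),
                                         names(baseline_profile)))
  })
}
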