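#' Configuration for the synthetic CSF cohort generator
#'
#' Assembles and validates the parameters of the additive Gaussian factor
#' model on the log2 scale that the generator uses: each planted module m has
#' a per-sample factor score, each module protein loads on its module's
#' factor, subtypes shift module factors by fixed offsets, batches add
#' per-(batch, protein) offsets, and demographic covariates add module-linked
#' effects. Defaults describe the standard study-sized cohort: 400 samples by
#' 1000 proteins, 10 modules, 6 subtypes, 2 sets of 4 batches with pooled
#' reference (GIS) channels, 20 same-case replicate pairs and 10 percent
#' missingness.
#'
#' @param n_samples,n_proteins cohort dimensions.
#' @param module_sizes planted module sizes (largest first); proteins beyond
#'   their sum are unstructured background.
#' @param n_subtypes number of planted sample subtypes.
#' @param subtype_module_shifts modules x subtypes matrix of log2 mean
#'   offsets applied to module factor scores; NULL builds a default pattern
#'   in which every subtype raises two modules and lowers two others by
#'   \code{shift_amplitude}.
#' @param shift_amplitude amplitude of the default shift pattern (log2).
#' @param loading_sd spread of within-module factor loadings around 1.
#' @param noise_sd residual noise sd (log2).
#' @param n_sets,batches_per_set batch structure.
#' @param batch_offset_sd sd of per-(batch, protein) offsets (log2).
#' @param gis_per_batch pooled reference channels appended per batch.
#' @param missing_rate fraction of sample cells set missing at random.
#' @param n_replicate_pairs same-case sample pairs re-measured in Set 2.
#' @param replicate_noise_sd technical noise added to replicate columns.
#' @param demographic_effects modules x covariates matrix (columns
#'   \code{diagnosis}, \code{race}, \code{sex}, \code{age}) of factor-score
#'   offsets; NULL uses a default with a diagnosis effect on module 2, race
#'   and sex effects on module 1 and an age slope on module 3.
#' @param seed integer seed making generation deterministic.
#' @param protein_seed separate seed for the protein-level ground truth
#'   (baselines and loadings); defaults to \code{seed}. Two cohorts built
#'   with the same \code{protein_seed} but different \code{seed} share
#'   identical planted protein structure while drawing independent samples.
#' @return validated configuration list of class \code{cohortConfig}.
#' @export
cohortConfig <- function(n_samples = 400, n_proteins = 1000,
                         module_sizes = c(200, 120, 100, 90, 80, 70, 60, 50, 40, 30),
                         n_subtypes = 6,
                         subtype_module_shifts = NULL,
                         shift_amplitude = 3,
                         loading_sd = 0.3,
                         noise_sd = 0.5,
                         n_sets = 2, batches_per_set = 4,
                         batch_offset_sd = 0.4,
                         gis_per_batch = 1,
                         missing_rate = 0.1,
                         n_replicate_pairs = 20,
                         replicate_noise_sd = 0.2,
                         demographic_effects = NULL,
                         seed = 1L, protein_seed = NULL) {
  nMod <- length(module_sizes)
  if (sum(module_sizes) > n_proteins)
    stop("configuration error in 'module_sizes': sum exceeds n_proteins")
  if (n_subtypes < 1) stop("configuration error in 'n_subtypes': must be >= 1")
  for (nm in c("loading_sd", "noise_sd", "batch_offset_sd", "replicate_noise_sd"))
    if (get(nm) < 0) stop("configuration error in '", nm, "': must be >= 0")
  .checkFraction(missing_rate, "missing_rate", openTop = TRUE)
  if (n_replicate_pairs > n_samples)
    stop("configuration error in 'n_replicate_pairs': exceeds n_samples")
  if (is.null(subtype_module_shifts))
    subtype_module_shifts <- .defaultSubtypeShifts(nMod, n_subtypes, shift_amplitude)
  stopifnot(nrow(subtype_module_shifts) == nMod,
            ncol(subtype_module_shifts) == n_subtypes)
  if (is.null(demographic_effects)) {
    demographic_effects <- matrix(0, nMod, 4,
      dimnames = list(NULL, c("diagnosis", "race", "sex", "age")))
    # diagnosis raises one module and lowers another so the proteome-wide
    # median is dx-neutral, as with a real up/down disease signature
    if (nMod >= 2) demographic_effects[2, "diagnosis"] <- 0.8
    if (nMod >= 5) demographic_effects[5, "diagnosis"] <- -0.8
    if (nMod >= 1) {
      demographic_effects[1, "race"] <- 0.5
      demographic_effects[1, "sex"] <- 0.3
    }
    if (nMod >= 3) demographic_effects[3, "age"] <- 0.02
  }
  structure(list(
    n_samples = n_samples, n_proteins = n_proteins,
    module_sizes = module_sizes, n_subtypes = n_subtypes,
    subtype_module_shifts = subtype_module_shifts,
    loading_sd = loading_sd, noise_sd = noise_sd,
    n_sets = n_sets, batches_per_set = batches_per_set,
    batch_offset_sd = batch_offset_sd, gis_per_batch = gis_per_batch,
    missing_rate = missing_rate, n_replicate_pairs = n_replicate_pairs,
    replicate_noise_sd = replicate_noise_sd,
    demographic_effects = demographic_effects, seed = as.integer(seed),
    protein_seed = as.integer(if (is.null(protein_seed)) seed else protein_seed)
  ), class = "cohortConfig")
}

# fixed, deterministic shift pattern: subtype t raises module t and lowers
# module t+1 (cyclic over the first min(nSub, nMod) modules) by `amp` log2
# units; adjacent modules then share at most a negative factor correlation,
# so planted modules stay distinct under signed-network merging
.defaultSubtypeShifts <- function(nMod, nSub, amp = 3) {
  S <- matrix(0, nMod, nSub)
  colnames(S) <- paste0("S", seq_len(nSub))
  if (nMod > 0) rownames(S) <- paste0("M", seq_len(nMod))
  K <- min(nSub, nMod)
  if (K == 0) return(S)
  for (t in seq_len(nSub)) {
    up <- (t - 1L) %% K + 1L
    dn <- t %% K + 1L
    S[up, t] <- S[up, t] + amp
    S[dn, t] <- S[dn, t] - amp
  }
  S
}

#' Generate a synthetic two-set CSF proteomic cohort
#'
#' Draws a cohort from the additive factor model described in
#' [cohortConfig()]: planted co-expression modules, planted sample subtypes,
#' per-(batch, protein) offsets, pooled reference (GIS) channels per batch,
#' same-case replicate pairs re-labelled as Set 2, missing-at-random cells,
#' and a traits table with demographics and immunoassay biomarkers that are
#' linear in designated module factor scores (total tau and p-tau181 track
#' module 2, amyloid-beta 42 negatively tracks module 1, with per-set
#' platform scale differences). GIS columns are the exact per-batch median
#' profile (no added noise, no missingness).
#'
#' @param config a [cohortConfig()].
#' @return list with \code{cohort}, a
#'   \linkS4class{SummarizedExperiment} (assay \code{"log2"}, traits in
#'   \code{colData}), and \code{truth}, a list with
#'   \code{true_module_of_protein}, \code{true_subtype_of_sample},
#'   \code{batch_offsets}, \code{factor_scores}, \code{loadings},
#'   \code{planted_covariate_effects} and \code{subtype_module_shifts}.
#' @examples
#' cfg <- cohortConfig(n_samples = 60, n_proteins = 120,
#'                     module_sizes = c(30, 20, 15), n_subtypes = 3,
#'                     n_replicate_pairs = 4, seed = 7)
#' gen <- generateCohort(cfg)
#' gen$cohort
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  withSeed(config$seed, .generateCohortImpl(config))
}

.generateCohortImpl <- function(cfg) {
  nP <- cfg$n_proteins; nS <- cfg$n_samples
  nMod <- length(cfg$module_sizes)
  proteinIds <- sprintf("P%04d", seq_len(nP))
  moduleOf <- rep("background", nP)
  idx <- 1L
  for (m in seq_len(nMod)) {
    moduleOf[idx:(idx + cfg$module_sizes[m] - 1L)] <- paste0("M", m)
    idx <- idx + cfg$module_sizes[m]
  }
  names(moduleOf) <- proteinIds

  sampleIds <- sprintf("S%04d", seq_len(nS))
  subtype <- sample(rep_len(paste0("S", seq_len(cfg$n_subtypes)), nS))
  names(subtype) <- sampleIds

  # demographics; diagnosis is stratified within subtype so planted subtype
  # shifts and the diagnosis effect stay unconfounded
  race <- ifelse(runif(nS) < 0.27, "AA", "NHW")
  sex <- ifelse(runif(nS) < 0.4, "male", "female")
  age <- round(rnorm(nS, 70, 8), 1)
  dx <- character(nS)
  for (st in unique(subtype)) {
    i <- which(subtype == st)
    dx[i] <- sample(rep_len(c("AD", "control"), length(i)))
  }

  # sets and batches: diagnosis-stratified randomized blocks, as multiplexed
  # designs randomize case/control across plexes
  setOf <- rep_len(paste0("Set", seq_len(cfg$n_sets)), nS)[sample.int(nS)]
  batchIds <- unlist(lapply(seq_len(cfg$n_sets), function(s)
    paste0("Set", s, ".B", seq_len(cfg$batches_per_set))))
  batchOf <- character(nS)
  for (s in seq_len(cfg$n_sets)) {
    inSet <- which(setOf == paste0("Set", s))
    inSet <- inSet[order(dx[inSet])]
    batchOf[inSet] <- rep_len(paste0("Set", s, ".B",
                                     seq_len(cfg$batches_per_set)),
                              length(inSet))
  }
  names(setOf) <- names(batchOf) <- sampleIds

  # factor scores per (module, sample)
  eff <- cfg$demographic_effects
  Fscores <- matrix(rnorm(nMod * nS), nMod, nS)
  colnames(Fscores) <- sampleIds
  if (nMod > 0) rownames(Fscores) <- paste0("M", seq_len(nMod))
  subIdx <- as.integer(sub("^S", "", subtype))
  for (m in seq_len(nMod)) {
    Fscores[m, ] <- Fscores[m, ] + cfg$subtype_module_shifts[m, subIdx] +
      eff[m, "diagnosis"] * (dx == "AD") +
      eff[m, "race"] * (race == "AA") +
      eff[m, "sex"] * (sex == "male") +
      eff[m, "age"] * (age - 70)
  }

  # protein-level ground truth (baselines, loadings) under its own seed so
  # two cohorts can share identical planted structure while drawing
  # independent samples
  # offset decorrelates the protein stream from the sample stream when
  # protein_seed equals seed
  pp <- withSeed(cfg$protein_seed + 77003L,
                 list(baseline = rnorm(nP, 0, 0.5),
                                        loading = 1 + rnorm(nP, 0, cfg$loading_sd)))
  baseline <- pp$baseline
  loading <- pp$loading
  batchOffsets <- matrix(rnorm(length(batchIds) * nP, 0, cfg$batch_offset_sd),
                         length(batchIds), nP,
                         dimnames = list(batchIds, proteinIds))

  X <- matrix(rnorm(nP * nS, 0, cfg$noise_sd), nP, nS,
              dimnames = list(proteinIds, sampleIds))
  X <- X + baseline
  for (m in seq_len(nMod)) {
    rows <- which(moduleOf == paste0("M", m))
    X[rows, ] <- X[rows, ] + outer(loading[rows], Fscores[m, ])
  }
  X <- X + t(batchOffsets[batchOf, , drop = FALSE])

  # immunoassay biomarkers linked to designated module factors,
  # with per-set platform scale differences
  f1 <- if (nMod >= 1) Fscores[1, ] else numeric(nS)
  f2 <- if (nMod >= 2) Fscores[2, ] else f1
  tTau <- 200 + 150 * (dx == "AD") + 60 * f2 + rnorm(nS, 0, 25)
  pTau <- tTau / 10 + rnorm(nS, 0, 4)
  abeta <- 420 - 150 * (dx == "AD") - 40 * f1 + rnorm(nS, 0, 35)
  abeta <- pmax(abeta, 40)
  moca <- pmin(30, pmax(0, round(26 - 5 * (dx == "AD") - 1.5 * f2 +
                                   rnorm(nS, 0, 2))))
  # per-set platform scale difference; a common multiplier keeps the
  # diagnostic t-tau/abeta ratio comparable across platforms
  isSet2 <- setOf == "Set2"
  tTau[isSet2] <- tTau[isSet2] * 0.45
  pTau[isSet2] <- pTau[isSet2] * 0.45
  abeta[isSet2] <- abeta[isSet2] * 0.45

  e4 <- rbinom(nS, 2, ifelse(dx == "AD", 0.35, 0.15))
  e2 <- rbinom(nS, 2 - e4, 0.06)

  traits <- data.frame(
    sample_id = sampleIds, set_label = setOf, batch_label = batchOf,
    is_gis = FALSE, diagnosis = dx, race = race, sex = sex, age = age,
    abeta42 = abeta, t_tau = tTau, p_tau181 = pTau, moca = moca,
    apoe_e2_count = e2, apoe_e4_count = e4,
    replicate_pair_id = NA_character_,
    stringsAsFactors = FALSE, row.names = sampleIds
  )

  # replicate pairs: Set-1 samples re-measured with technical noise,
  # labelled Set 2 and spread over Set-2 batches
  if (cfg$n_replicate_pairs > 0) {
    rp <- .addReplicatePairs(X, traits, cfg$n_replicate_pairs,
                             cfg$replicate_noise_sd)
    X <- rp$matrix; traits <- rp$traits
  }

  # GIS: exact per-batch median profile, appended per batch
  if (cfg$gis_per_batch > 0) {
    gisCols <- list(); gisTraits <- list()
    for (b in batchIds) {
      inB <- which(traits$batch_label == b & !traits$is_gis)
      if (!length(inB)) next
      ref <- rowMedians2(X[, inB, drop = FALSE])
      for (g in seq_len(cfg$gis_per_batch)) {
        id <- paste0("GIS.", b, ".", g)
        gisCols[[id]] <- ref
        gisTraits[[id]] <- data.frame(
          sample_id = id, set_label = sub("\\.B.*$", "", b), batch_label = b,
          is_gis = TRUE, diagnosis = NA_character_, race = NA_character_,
          sex = NA_character_, age = NA_real_, abeta42 = NA_real_,
          t_tau = NA_real_, p_tau181 = NA_real_, moca = NA_real_,
          apoe_e2_count = NA_integer_, apoe_e4_count = NA_integer_,
          replicate_pair_id = NA_character_,
          stringsAsFactors = FALSE, row.names = id)
      }
    }
    X <- cbind(X, do.call(cbind, gisCols))
    traits <- rbind(traits, do.call(rbind, gisTraits))
  }

  # missingness on sample columns only; GIS channels stay complete
  if (cfg$missing_rate > 0) {
    keep <- traits$is_gis
    sub <- X[, !keep, drop = FALSE]
    sub <- .injectMissingnessImpl(sub, cfg$missing_rate)
    X[, !keep] <- sub
  }

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = X),
    colData = S4Vectors::DataFrame(traits)
  )
  truth <- list(
    true_module_of_protein = moduleOf,
    true_subtype_of_sample = subtype,
    batch_offsets = batchOffsets,
    factor_scores = Fscores,
    loadings = setNames(loading, proteinIds),
    planted_covariate_effects = eff,
    subtype_module_shifts = cfg$subtype_module_shifts
  )
  list(cohort = se, truth = truth)
}

.addReplicatePairs <- function(X, traits, nPairs, noiseSd) {
  set1 <- rownames(traits)[traits$set_label == "Set1" & !traits$is_gis]
  if (nPairs > length(set1))
    stop("n_replicate_pairs exceeds the number of Set-1 samples")
  chosen <- sort(sample(set1, nPairs))
  set2batches <- unique(traits$batch_label[traits$set_label == "Set2"])
  if (!length(set2batches)) set2batches <- unique(traits$batch_label)
  newIds <- paste0(chosen, ".rep")
  repX <- X[, chosen, drop = FALSE] +
    matrix(rnorm(nrow(X) * nPairs, 0, noiseSd), nrow(X), nPairs)
  colnames(repX) <- newIds
  pairIds <- sprintf("pair%02d", seq_len(nPairs))
  traits$replicate_pair_id[match(chosen, traits$sample_id)] <- pairIds
  newTraits <- traits[match(chosen, traits$sample_id), , drop = FALSE]
  newTraits$sample_id <- newIds
  newTraits$set_label <- "Set2"
  newTraits$batch_label <- rep_len(set2batches, nPairs)
  newTraits$replicate_pair_id <- pairIds
  rownames(newTraits) <- newIds
  list(matrix = cbind(X, repX), traits = rbind(traits, newTraits))
}

#' Add same-case replicate pairs to an existing cohort
#'
#' Duplicates \code{n_pairs} Set-1 samples with Normal technical noise,
#' labels the duplicates as Set 2 and links each original/duplicate pair with
#' a shared \code{replicate_pair_id} in the traits.
#'
#' @param cohort a SummarizedExperiment as produced by [generateCohort()].
#' @param n_pairs number of pairs; must not exceed the Set-1 sample count.
#' @param noise_sd technical noise sd (log2).
#' @param seed integer seed.
#' @return SummarizedExperiment with the duplicate columns appended.
#' @export
makeReplicatePairs <- function(cohort, n_pairs, noise_sd = 0.2, seed = 1L) {
  X <- .abundance(cohort)
  traits <- .traits(cohort)
  res <- withSeed(seed, .addReplicatePairs(X, traits, n_pairs, noise_sd))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = res$matrix),
    colData = S4Vectors::DataFrame(res$traits))
}

.injectMissingnessImpl <- function(X, rate) {
  mask <- matrix(runif(length(X)) < rate, nrow(X), ncol(X))
  X[mask] <- NA
  X
}

#' Set matrix entries missing completely at random
#'
#' @param x abundance matrix or SummarizedExperiment.
#' @param rate fraction of cells set missing, in \[0, 1).
#' @param seed integer seed; the same seed reproduces the same mask.
#' @return object of the same type with missing cells injected.
#' @export
injectMissingness <- function(x, rate, seed = 1L) {
  .checkFraction(rate, "rate", openTop = TRUE)
  if (methods::is(x, "SummarizedExperiment")) {
    m <- withSeed(seed, .injectMissingnessImpl(SummarizedExperiment::assay(x), rate))
    SummarizedExperiment::`assay<-`(x, value = m)
  } else {
    withSeed(seed, .injectMissingnessImpl(as.matrix(x), rate))
  }
}
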