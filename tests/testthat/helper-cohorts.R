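# Shared fixtures. The standard study-sized cohort pipeline is expensive, so
# it is built lazily once per session and cached.

.fixtures <- new.env(parent = emptyenv())

# small cohort for structural tests: 60 samples x 120 proteins, 3 modules
smallConfig <- function(seed = 7, missing_rate = 0.05, ...) {
  cohortConfig(n_samples = 60, n_proteins = 120,
               module_sizes = c(30, 20, 15), n_subtypes = 3,
               n_sets = 2, batches_per_set = 2,
               n_replicate_pairs = 4, missing_rate = missing_rate,
               seed = seed, ...)
}

# the standard synthetic cohort: 400 samples x 1000 proteins, 10 modules,
# 6 subtypes, 2 sets x 4 batches, 20 replicate pairs, fixed seed
standardPipeline <- function() {
  if (!is.null(.fixtures$std)) return(.fixtures$std)
  gen <- generateCohort(cohortConfig(seed = 11))
  filt <- filterMinPresence(gen$cohort, 0.5)
  harm <- suppressWarnings(tamporTwoRound(filt))
  X <- SummarizedExperiment::assay(harm)
  net <- buildNetwork(X)
  hubs <- selectHubFeatures(kme(net), moduleLabels(net), 30)
  traits <- as.data.frame(SummarizedExperiment::colData(harm))
  pairs <- do.call(rbind, lapply(split(traits$sample_id,
                                       traits$replicate_pair_id),
                                 function(s) s[1:2]))
  .fixtures$std <- list(gen = gen, harm = harm, X = X, net = net,
                        hubs = hubs, traits = traits, pairs = pairs)
  .fixtures$std
}

# raw (pre-harmonization) group-mean difference for a module's proteins
moduleGroupEffect <- function(M, proteins, groups, a, b) {
  mean(rowMeans(M[proteins, groups == a, drop = FALSE], na.rm = TRUE) -
       rowMeans(M[proteins, groups == b, drop = FALSE], na.rm = TRUE))
}

# two perfectly separated correlation blocks for module-detection tests
twoBlockMatrix <- function(nPer = 20, nSamples = 50, seed = 3) {
  set.seed(seed)
  f1 <- rnorm(nSamples); f2 <- rnorm(nSamples)
  X <- rbind(outer(rep(1, nPer), f1), outer(rep(1, nPer), f2)) +
    matrix(rnorm(2 * nPer * nSamples, 0, 0.05), 2 * nPer)
  dimnames(X) <- list(sprintf("P%03d", seq_len(2 * nPer)),
                      sprintf("S%03d", seq_len(nSamples)))
  X
}
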