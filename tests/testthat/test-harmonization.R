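test_that("presence filter counts observations inclusively over non-GIS samples", {
  M <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:10)))
  M[1, 1:4] <- NA   # 60% observed
  M[2, 1:5] <- NA   # 50% observed
  M[3, 1:6] <- NA   # 40% observed
  M[4, ] <- NA      # 0% observed
  out <- filterMinPresence(M, 0.5)
  expect_identical(rownames(out), c("p1", "p2"))

  Mc <- matrix(rnorm(40), 4, 10,
               dimnames = list(paste0("p", 1:4), paste0("s", 1:10)))
  expect_identical(filterMinPresence(Mc, 0.5), Mc)
  Mc[2, 1] <- NA
  expect_identical(rownames(filterMinPresence(Mc, 1)), c("p1", "p3", "p4"))
  expect_error(filterMinPresence(M, 0.99), "presence")
})

test_that("QC exclusion applies the diagnostic ratio rule to AD samples only", {
  tr <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    diagnosis = c("AD", "AD", "control", "AD"),
    t_tau = c(226, 100, 50, 113),
    abeta42 = c(1000, 500, 500, 500),
    is_gis = FALSE)
  res <- qcExcludeDiscordant(tr, 0.226)
  expect_true("a" %in% res$kept)                  # ratio exactly 0.226: kept
  expect_true("b" %in% res$excluded$sample_id)    # 0.20: excluded
  expect_true("c" %in% res$kept)                  # control with low ratio: kept
  expect_identical(res$excluded$reason[res$excluded$sample_id == "b"], "ratio")
  tr$abeta42[1] <- 0
  expect_error(qcExcludeDiscordant(tr), "a")

  # pluggable extra predicate
  tr$abeta42[1] <- 1000
  res2 <- qcExcludeDiscordant(tr, 0.226,
                              extra_predicate = function(t) t$sample_id == "c")
  expect_identical(res2$excluded$reason[res2$excluded$sample_id == "c"],
                   "predicate")
})

test_that("per-set z-scoring standardizes each platform independently", {
  expect_equal(zscorePerSet(c(1, 2, 3), rep("A", 3)), c(-1, 0, 1))
  set.seed(4)
  v <- c(rnorm(50, 100, 10), rnorm(40, 5, 1))
  s <- rep(c("A", "B"), c(50, 40))
  z <- zscorePerSet(v, s)
  for (g in c("A", "B")) {
    expect_equal(mean(z[s == g]), 0, tolerance = 1e-12)
    expect_equal(sd(z[s == g]), 1, tolerance = 1e-12)
  }
  expect_lt(abs(mean(z[s == "A"]) - mean(z[s == "B"])), 1e-10)
  expect_error(zscorePerSet(c(1, 1, 1), rep("A", 3)), "variance")
  # missing values propagate
  z2 <- zscorePerSet(c(1, NA, 3, 5), rep("A", 4))
  expect_true(is.na(z2[2]))
})

test_that("APOE risk score adds e4 and subtracts e2 alleles", {
  expect_identical(apoeRiskScore(0, 0), 0L)
  expect_identical(apoeRiskScore(0, 2), 2L)
  expect_identical(apoeRiskScore(1, 1), 0L)
  expect_identical(apoeRiskScore(2, 0), -2L)
  expect_identical(apoeRiskScore(c(0, 1), c(1, 0)), c(1L, -1L))
  expect_error(apoeRiskScore(2, 1), "at most 2")
})

test_that("two-round polish removes batch structure and keeps missingness", {
  gen <- generateCohort(smallConfig(seed = 21))
  se <- gen$cohort
  harm <- suppressWarnings(tamporTwoRound(se))
  X <- SummarizedExperiment::assay(harm)
  tr <- as.data.frame(SummarizedExperiment::colData(harm))
  expect_false(any(tr$is_gis))
  expect_identical(S4Vectors::metadata(harm)$scale_tag, "harmonized")

  # missingness pattern untouched
  raw <- SummarizedExperiment::assay(se)[, colnames(X)]
  expect_identical(is.na(X), is.na(raw))

  # idempotence within tolerance: re-harmonizing (GIS-free round 2 only
  # applies) changes little; check via a second full run on a GIS-carrying
  # reconstruction is not defined, so verify residual batch variance instead
  imp <- knnImpute(X)
  vf <- varianceFractions(imp, tr, c("batch_label", "diagnosis"))
  expect_lt(mean(vf$batch_label), 0.05)

  expect_error(tamporTwoRound(se[, !as.data.frame(
    SummarizedExperiment::colData(se))$is_gis]), "GIS")
})

test_that("planted additive batch offsets are removed exactly without noise", {
  cfg <- cohortConfig(n_samples = 24, n_proteins = 40,
                      module_sizes = integer(0), n_subtypes = 1,
                      noise_sd = 0, batch_offset_sd = 0.8,
                      missing_rate = 0, n_replicate_pairs = 0,
                      n_sets = 2, batches_per_set = 2, seed = 3)
  gen <- generateCohort(cfg)
  harm <- suppressWarnings(tamporTwoRound(gen$cohort))
  X <- SummarizedExperiment::assay(harm)
  tr <- as.data.frame(SummarizedExperiment::colData(harm))
  # constant-per-batch blocks: post-round values independent of batch
  for (p in seq_len(nrow(X))) {
    bm <- tapply(X[p, ], tr$batch_label, mean)
    expect_lt(diff(range(bm)), 1e-6)
  }
})

test_that("bootstrap regression removes nuisance and preserves biology", {
  set.seed(8)
  n <- 200
  tr <- data.frame(sample_id = paste0("s", 1:n),
                   set_label = rep(c("A", "B"), each = n / 2),
                   sex = sample(c("male", "female"), n, TRUE))
  M <- matrix(rnorm(60 * n), 60, n,
              dimnames = list(paste0("p", 1:60), tr$sample_id))
  sexEff <- 1.5
  M <- M + 1 * (rep(1, 60) %o% as.integer(tr$set_label == "B")) +
    sexEff * (rep(1, 60) %o% as.integer(tr$sex == "male"))

  out <- bootstrapRegressCovariates(M, tr, nuisance = "set_label",
                                    preserve = "sex", n_boot = 100, seed = 2)
  setDiff <- mean(rowMeans(out[, tr$set_label == "B"]) -
                    rowMeans(out[, tr$set_label == "A"]))
  expect_lt(abs(setDiff), 0.05)
  sexDiff <- mean(rowMeans(out[, tr$sex == "male"]) -
                    rowMeans(out[, tr$sex == "female"]))
  expect_lt(abs(sexDiff - sexEff) / sexEff, 0.05)

  # null nuisance effect: output close to input
  M0 <- matrix(rnorm(30 * n), 30, n,
               dimnames = list(paste0("q", 1:30), tr$sample_id))
  out0 <- bootstrapRegressCovariates(M0, tr, nuisance = "set_label",
                                     n_boot = 200, seed = 3)
  expect_lt(mean(abs(out0 - M0)), 0.15)
  # missing cells stay missing
  M0[1, 1] <- NA
  outNA <- bootstrapRegressCovariates(M0, tr, nuisance = "set_label",
                                      n_boot = 20, seed = 3)
  expect_true(is.na(outNA[1, 1]))
})

test_that("kNN imputation beats column-mean imputation and respects observed cells", {
  set.seed(12)
  f <- rnorm(40)
  M <- outer(rnorm(30, 1, 0.2), f) + matrix(rnorm(1200, 0, 0.3), 30)
  dimnames(M) <- list(paste0("p", 1:30), paste0("s", 1:40))
  expect_identical(knnImpute(M, 5), M)

  # protein identical to 3 complete neighbours except one missing cell:
  # imputed value equals the neighbours' value there
  M2 <- rbind(M, n1 = M[1, ], n2 = M[1, ], n3 = M[1, ], dup = M[1, ])
  M2["dup", 3] <- NA
  imp2 <- knnImpute(M2, 3)
  expect_equal(imp2["dup", 3], M[1, 3], tolerance = 1e-12)

  hole <- M
  mask <- matrix(runif(length(M)) < 0.1, nrow(M))
  hole[mask] <- NA
  imp <- knnImpute(hole, 5)
  expect_identical(imp[!mask], M[!mask])
  rmseKnn <- sqrt(mean((imp[mask] - M[mask])^2))
  colMeanImp <- hole
  for (j in seq_len(ncol(hole)))
    colMeanImp[is.na(hole[, j]), j] <- mean(hole[, j], na.rm = TRUE)
  rmseCol <- sqrt(mean((colMeanImp[mask] - M[mask])^2))
  expect_lt(rmseKnn, rmseCol)
  expect_error(knnImpute(M, 30), "smaller")
})

test_that("variance fractions decompose R2 and flag collinearity", {
  set.seed(6)
  n <- 60
  tr <- data.frame(sample_id = paste0("s", 1:n),
                   batch = rep(c("b1", "b2", "b3"), each = n / 3),
                   dx = rep_len(c("AD", "control"), n))
  M <- matrix(rnorm(20 * n, 0, 0.2), 20, n,
              dimnames = list(paste0("p", 1:20), tr$sample_id))
  M[1, ] <- as.integer(tr$batch == "b2") * 3 + rnorm(n, 0, 0.01)
  vf <- varianceFractions(M, tr, c("batch", "dx"))
  expect_gt(vf$batch[1], 0.95)
  expect_equal(unname(rowSums(vf)), rep(1, 20), tolerance = 1e-9)
  expect_true(all(vf >= 0 & vf <= 1))
  # pure-noise proteins: small factor fractions
  expect_lt(mean(vf$batch[-1]), 0.15)

  tr$alias <- tr$batch
  expect_error(varianceFractions(M, tr, c("batch", "alias")), "collinear")
  M[1, 1] <- NA
  expect_error(varianceFractions(M, tr, c("batch", "dx")), "complete")
})

test_that("three-way ANOVA with Tukey reduces to the t-test for two groups", {
  set.seed(9)
  y <- rnorm(40)
  g <- rep(c("a", "b"), each = 20)
  res <- anovaTukey(y, data.frame(g = g))
  tt <- t.test(y[g == "b"], y[g == "a"], var.equal = TRUE)$p.value
  expect_equal(res$tukey$p_adj[1], tt, tolerance = 1e-6)

  # planted shift: three-factor omnibus detects the shifted factor
  n <- 120
  f <- data.frame(dx = sample(c("AD", "ctl"), n, TRUE),
                  sex = sample(c("m", "f"), n, TRUE),
                  race = sample(c("AA", "NHW"), n, TRUE))
  y2 <- rnorm(n) + 2 * (f$dx == "AD")
  res2 <- anovaTukey(y2, f)
  expect_lt(res2$omnibus$p[res2$omnibus$factor == "dx"], 1e-10)
  expect_gt(min(res2$omnibus$p[res2$omnibus$factor != "dx"]), 1e-4)
  expect_error(anovaTukey(y2, f[, c("dx", "sex", "race")][, c(1, 1, 1, 1)]))
})
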