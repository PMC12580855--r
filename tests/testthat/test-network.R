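test_that("two separable correlation blocks yield exactly two modules", {
  X <- twoBlockMatrix()
  labels <- detectModules(X, networkParamsDefault(min_module_size = 5))
  expect_identical(sort(unique(labels)), c("M1", "M2"))
  expect_identical(unname(table(labels)[c("M1", "M2")]),
                   c(20L, 20L), ignore_attr = TRUE)
  # block membership is contiguous by construction
  expect_identical(length(unique(labels[1:20])), 1L)
  expect_identical(length(unique(labels[21:40])), 1L)
})

test_that("pure noise yields mostly unassigned proteins", {
  set.seed(33)
  X <- matrix(rnorm(200 * 100), 200, 100,
              dimnames = list(sprintf("p%03d", 1:200), sprintf("s%03d", 1:100)))
  labels <- tryCatch(detectModules(X), error = function(e) {
    expect_match(conditionMessage(e), "unassigned")
    rep("unassigned", 200)
  })
  expect_gte(mean(labels == "unassigned"), 0.9)
})

test_that("eigenproteins follow the PCA oracle, sign and variance conventions", {
  set.seed(21)
  f <- rnorm(40)
  # rank-1 module: identical standardized profiles
  M <- outer(c(2, 2, 2), f) + 1
  dimnames(M) <- list(paste0("p", 1:3), paste0("s", 1:40))
  labs <- setNames(rep("M1", 3), rownames(M))
  res <- moduleEigenproteins(M, labs)
  expect_equal(unname(res$varExplained["M1"]), 1)
  zf <- (f - mean(f)) / sd(f)
  expect_equal(unname(res$eigenproteins["M1", ]) / sd(res$eigenproteins["M1", ]),
               zf, tolerance = 1e-8)

  # 5-protein toy vs an independent covariance-eigendecomposition oracle
  M2 <- outer(rnorm(5, 1, 0.3), f) + matrix(rnorm(200, 0, 0.4), 5)
  dimnames(M2) <- list(paste0("q", 1:5), paste0("s", 1:40))
  labs2 <- setNames(rep("M1", 5), rownames(M2))
  res2 <- moduleEigenproteins(M2, labs2)
  Z <- t(scale(t(M2)))
  ev <- eigen(crossprod(t(Z)) / (ncol(Z)))       # protein x protein covariance
  scoresOracle <- as.numeric(t(Z) %*% ev$vectors[, 1])
  scoresOracle <- scoresOracle / sd(scoresOracle)
  got <- res2$eigenproteins["M1", ]
  agree <- min(max(abs(got - scoresOracle)), max(abs(got + scoresOracle)))
  expect_lt(agree, 1e-10)
  # sign convention: positive bicor with the module mean profile
  expect_gt(bicor(got, colMeans(Z), minOverlap = 3), 0)

  expect_error(moduleEigenproteins(rbind(M, const = 1), c(labs,
    const = "M1")), "constant")
})

test_that("module merging follows the eigenprotein dissimilarity rule", {
  set.seed(13)
  f1 <- rnorm(60)
  f2mer <- 0.55 * f1 + sqrt(1 - 0.55^2) * rnorm(60)   # cor ~ 0.55 > 0.3
  f3sep <- -0.1 * f1 + rnorm(60)                       # cor ~ 0
  mk <- function(f, n, pre) {
    M <- outer(rep(1, n), f) + matrix(rnorm(n * 60, 0, 0.1), n)
    rownames(M) <- paste0(pre, seq_len(n)); M
  }
  X <- rbind(mk(f1, 12, "a"), mk(f2mer, 12, "b"), mk(f3sep, 12, "c"))
  colnames(X) <- paste0("s", 1:60)
  labs <- setNames(rep(c("M1", "M2", "M3"), each = 12), rownames(X))
  merged <- mergeModules(X, labs, merge_cut_height = 0.7)
  expect_identical(length(unique(merged[1:24])), 1L)     # a+b merged
  expect_identical(length(unique(merged)), 2L)           # c stays apart
  # idempotence
  expect_identical(mergeModules(X, merged, 0.7), merged)
})

test_that("kME is the bicor to the eigenprotein with correct sign", {
  std <- standardPipeline()
  net <- std$net
  K <- kme(net)
  labs <- moduleLabels(net)
  # a protein tracking its module eigenprotein has kME near 1; planted
  # proteins rank their own module highest for nearly all proteins
  assigned <- names(labs)[labs != "unassigned"]
  own <- K[cbind(assigned, labs[assigned])]
  best <- colnames(K)[apply(K[assigned, ], 1, which.max)]
  expect_gte(mean(best == labs[assigned]), 0.95)
  expect_gt(median(own), 0.5)

  # exact cases
  ep <- eigenproteins(net)
  direct <- rbind(ep["M1", ], -ep["M1", ])
  rownames(direct) <- c("same", "anti")
  K2 <- kmeTable(direct, ep)
  expect_equal(unname(K2["same", "M1"]), 1, tolerance = 1e-12)
  expect_equal(unname(K2["anti", "M1"]), -1, tolerance = 1e-12)
})

test_that("module-trait correlations recover planted links and drop replicates", {
  std <- standardPipeline()
  net <- std$net
  res <- moduleTraitCorrelations(eigenproteins(std$net), std$traits,
                                 c("t_tau", "age", "sex"))
  expect_true(all(res$p > 0 & res$p <= 1, na.rm = TRUE))
  # trait equal to an eigenprotein correlates perfectly
  tr2 <- std$traits
  tr2$fake <- eigenproteins(net)["M1", match(tr2$sample_id,
                                             colnames(eigenproteins(net)))]
  resF <- moduleTraitCorrelations(eigenproteins(net), tr2, "fake")
  expect_equal(resF$bicor[resF$module == "M1"], 1, tolerance = 1e-9)
  expect_lt(resF$p[resF$module == "M1"], 1e-100)

  # replicate Set-2 members excluded from n
  nUsed <- resF$n[1]
  expect_equal(nUsed, sum(is.na(std$traits$replicate_pair_id)) +
                 sum(!is.na(std$traits$replicate_pair_id) &
                       std$traits$set_label == "Set1"))
})

test_that("permuted traits give uniform correlation p-values", {
  set.seed(10)
  ep <- matrix(rnorm(2 * 150), 2, 150,
               dimnames = list(c("M1", "M2"), paste0("s", 1:150)))
  tr <- data.frame(sample_id = colnames(ep), set_label = "Set1",
                   replicate_pair_id = NA_character_)
  ps <- replicate(300, {
    tr$x <- rnorm(150)
    moduleTraitCorrelations(ep, tr, "x")$p[1]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cell-type enrichment equals the hypergeometric oracle", {
  labs <- setNames(rep(c("M1", "M2"), c(10, 90)), sprintf("g%03d", 1:100))
  sets <- list(markers = names(labs)[1:10])
  res <- celltypeEnrichment(labs, sets)
  pOracle <- 1 / choose(100, 10)     # module identical to the marker set
  expect_equal(res$p[res$module == "M1"], pOracle, tolerance = 1e-12)
  # full enumeration oracle: P(overlap >= observed)
  hyperOracle <- function(q, m, n, k)
    sum(dhyper(q:min(m, k), m, n, k))
  expect_equal(res$p[res$module == "M1"], hyperOracle(10, 10, 90, 10),
               tolerance = 1e-12)
  expect_equal(res$p[res$module == "M2"], hyperOracle(0, 10, 90, 90),
               tolerance = 1e-12)
  # overlap at expectation: one-tailed p >= 0.5
  labs2 <- setNames(rep(c("A", "B"), each = 50), sprintf("h%03d", 1:100))
  sets2 <- list(s = c(names(labs2)[labs2 == "A"][1:5],
                      names(labs2)[labs2 == "B"][1:5]))
  res2 <- celltypeEnrichment(labs2, sets2)
  expect_gte(min(res2$p), 0.5)
  # BH never reduces p and is monotone in rank
  expect_true(all(res$p_adj >= res$p - 1e-15))
})

test_that("differential abundance reduces to the t-test for two groups", {
  set.seed(3)
  X <- matrix(rnorm(5 * 40), 5, 40,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:40)))
  g <- rep(c("a", "b"), each = 20)
  X[1, g == "b"] <- X[1, g == "b"] + 2
  res <- differentialAbundance(X, g)
  for (p in rownames(X)) {
    r <- res[res$protein == p, ]
    tt <- t.test(X[p, g == "b"], X[p, g == "a"], var.equal = TRUE)$p.value
    expect_equal(r$pairwise_p, tt, tolerance = 1e-6)
    expect_equal(r$log2fc,
                 mean(X[p, g == "b"]) - mean(X[p, g == "a"]),
                 tolerance = 1e-12)
  }
  expect_lt(res$omnibus_p[res$protein == "p1"], 1e-6)
  # protein observed in fewer than 2 groups: missing statistics
  X[2, g == "b"] <- NA
  res2 <- differentialAbundance(X, g)
  expect_true(all(is.na(res2$pairwise_p[res2$protein == "p2"])))
})
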