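#' Signed soft-threshold adjacency
#'
#' Maps a correlation to network adjacency by the signed transform
#' \code{a = ((1 + cor) / 2)^beta}: perfectly anti-correlated pairs get 0,
#' perfectly correlated pairs get 1, and the soft power beta suppresses weak
#' correlations. Monotone increasing in \code{cor}.
#'
#' @param cor correlation value(s) in \[-1, 1\].
#' @param beta soft-threshold power (>= 1), default 6.
#' @return adjacency value(s) in \[0, 1\].
#' @examples
#' signedAdjacency(0, beta = 6)   # 0.5^6
#' @export
signedAdjacency <- function(cor, beta = 6) {
  stopifnot(beta >= 1)
  ((1 + cor) / 2)^beta
}

#' Topological overlap matrix with mean denominator
#'
#' For a symmetric adjacency with unit diagonal, the topological overlap of
#' proteins i and j combines their direct adjacency with their shared
#' neighbourhood: \code{TOM_ij = (sum_u a_iu a_uj + a_ij) /
#' (mean(k_i, k_j) + 1 - a_ij)}, where the sum runs over u distinct from i
#' and j and \code{k_i = sum_u a_iu} (u != i). The diagonal is 1.
#'
#' @param adjacency symmetric numeric matrix, values in \[0, 1\], unit
#'   diagonal.
#' @return symmetric TOM matrix in \[0, 1\].
#' @export
tomSimilarity <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (!isSymmetric(unname(A), tol = 1e-10)) stop("adjacency must be symmetric")
  diag(A) <- 0
  k <- rowSums(A)
  num <- A %*% A   # includes u = i or j only via diagonal, which is 0
  num <- num + A
  den <- outer(k, k, function(a, b) (a + b) / 2) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Default network construction parameters
#'
#' @param beta soft power, default 6.
#' @param deep_split split sensitivity 0-4, default 2 (higher cuts the
#'   dendrogram lower, producing more, smaller modules).
#' @param min_module_size smallest allowed module, default 10.
#' @param merge_cut_height eigenprotein dissimilarity below which modules are
#'   merged, default 0.7.
#' @param min_pairwise_overlap minimum jointly observed samples for a
#'   correlation, default 10.
#' @param min_cohesion cohesion floor: detected branches whose mean pairwise
#'   member bicor falls below this are dissolved to unassigned, default 0.3
#'   (a branch of chance-correlated background proteins rarely exceeds it,
#'   while a genuine module comfortably does).
#' @return parameter list.
#' @export
networkParamsDefault <- function(beta = 6, deep_split = 2, min_module_size = 10,
                                 merge_cut_height = 0.7,
                                 min_pairwise_overlap = 10,
                                 min_cohesion = 0.3) {
  stopifnot(beta >= 1, merge_cut_height > 0, merge_cut_height < 1,
            deep_split %in% 0:4)
  list(beta = beta, deep_split = deep_split,
       min_module_size = min_module_size,
       merge_cut_height = merge_cut_height,
       tom_denom = "mean", network_type = "signed",
       min_pairwise_overlap = min_pairwise_overlap,
       min_cohesion = min_cohesion)
}

#' Detect protein co-expression modules
#'
#' Builds the signed bicor network (adjacency = signed soft-threshold of the
#' biweight midcorrelation), computes topological overlap, clusters proteins
#' by average-linkage hierarchical clustering on \code{1 - TOM}, and cuts the
#' dendrogram with a simplified dynamic-hybrid rule: a static cut at a height
#' set by \code{deep_split}, recursive bisection of branches that still
#' contain dissimilar sub-modules, dissolution of branches smaller than
#' \code{min_module_size}, and a cohesion filter that sends branches whose
#' mean pairwise bicor falls below \code{min_cohesion} to
#' \code{"unassigned"}.
#' Labels are \code{"M1"}, \code{"M2"}, ... ordered by decreasing size.
#'
#' @param x harmonized abundance matrix or SummarizedExperiment (proteins in
#'   rows).
#' @param params parameter list from [networkParamsDefault()].
#' @return named character vector of module labels per protein.
#' @export
detectModules <- function(x, params = networkParamsDefault()) {
  X <- .abundance(x)
  if (nrow(X) < 2 * params$min_module_size)
    stop("need at least 2 * min_module_size proteins")
  cor <- bicorMatrix(X, minOverlap = params$min_pairwise_overlap)
  cor[is.na(cor)] <- 0
  adj <- signedAdjacency(cor, params$beta)
  diag(adj) <- 1
  tom <- tomSimilarity(adj)
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  # deep_split in 0..4 maps to progressively lower static cut heights
  hmax <- max(hc$height)
  hmin <- min(hc$height)
  frac <- c(0.99, 0.97, 0.95, 0.92, 0.90)[params$deep_split + 1]
  cutH <- hmin + frac * (hmax - hmin)
  raw <- cutree(hc, h = cutH)

  labels <- rep("unassigned", nrow(X))
  names(labels) <- rownames(X)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= params$min_module_size])
  # per-branch refinement: a static-cut branch may still contain distinct
  # modules; recursively bisect while the two halves' eigenproteins are
  # dissimilar enough that merging would not rejoin them
  kept <- list()
  for (cl in keep) {
    members <- rownames(X)[raw == cl]
    for (part in .refineBranch(X, members, diss, params))
      kept[[length(kept) + 1L]] <- part
  }
  # cohesion filter: a genuine module's members are mutually correlated;
  # loosely-merged background branches are not
  cohesive <- list()
  for (members in kept) {
    sub <- cor[members, members]
    meanCor <- mean(sub[upper.tri(sub)])
    if (meanCor >= params$min_cohesion)
      cohesive[[length(cohesive) + 1L]] <- members
  }
  if (!length(cohesive))
    stop("all proteins unassigned; consider lowering min_cohesion or deep_split")
  ord <- order(vapply(cohesive, length, 1L), decreasing = TRUE)
  for (i in seq_along(ord))
    labels[cohesive[[ord[i]]]] <- paste0("M", i)
  labels
}

# recursively split a branch in two while the halves' eigenproteins are
# dissimilar (1 - cor > merge_cut_height) and both satisfy the size floor
.refineBranch <- function(X, members, diss, params) {
  if (length(members) < 2 * params$min_module_size) return(list(members))
  hc <- hclust(as.dist(diss[members, members]), method = "average")
  halves <- split(members, cutree(hc, k = 2))
  if (any(lengths(halves) < params$min_module_size)) return(list(members))
  eps <- lapply(halves, function(h) .eigenproteinOne(X[h, , drop = FALSE])$scores)
  r <- suppressWarnings(cor(eps[[1]], eps[[2]]))
  if (is.na(r) || (1 - r) <= params$merge_cut_height) return(list(members))
  c(.refineBranch(X, halves[[1]], diss, params),
    .refineBranch(X, halves[[2]], diss, params))
}

# first principal component of a protein-standardized submatrix, sign-aligned
# to the module mean profile; missing cells imputed within the module first
.eigenproteinOne <- function(sub, k = 10) {
  if (anyNA(sub)) sub <- knnImpute(sub, k = min(k, nrow(sub) - 1))
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) stop("module contains constant protein(s)")
  Z <- t(scale(t(sub)))
  pc <- prcomp(t(Z), center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  meanProfile <- colMeans(Z)
  r <- bicor(scores, meanProfile, minOverlap = 3)
  if (!is.na(r) && r < 0) scores <- -scores
  scores <- scores / sd(scores)
  varExpl <- pc$sdev[1]^2 / sum(pc$sdev^2)
  list(scores = scores, varExplained = varExpl)
}

#' Module eigenproteins
#'
#' Per module, the first principal component of the protein-standardized
#' module submatrix, scored per sample and scaled to unit sd. The sign is
#' aligned so the eigenprotein correlates positively with the module mean
#' profile. Missing cells are imputed within the module (kNN, k = 10) before
#' the PCA.
#'
#' @param x abundance matrix or SummarizedExperiment.
#' @param labels module labels per protein (from [detectModules()]).
#' @return list with \code{eigenproteins} (modules x samples) and
#'   \code{varExplained}.
#' @export
moduleEigenproteins <- function(x, labels) {
  X <- .abundance(x)
  mods <- .moduleOrder(labels)
  eig <- matrix(NA_real_, length(mods), ncol(X),
                dimnames = list(mods, colnames(X)))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    members <- names(labels)[labels == m]
    if (length(members) < 2) stop("module ", m, " has fewer than 2 proteins")
    res <- .eigenproteinOne(X[members, , drop = FALSE])
    eig[m, ] <- res$scores
    ve[m] <- res$varExplained
  }
  list(eigenproteins = eig, varExplained = ve)
}

# module names sorted by numeric suffix, excluding unassigned
.moduleOrder <- function(labels) {
  mods <- setdiff(unique(labels), "unassigned")
  mods[order(as.integer(sub("^M", "", mods)))]
}

#' Merge modules with similar eigenproteins
#'
#' Iteratively clusters module eigenproteins (average linkage on
#' \code{1 - cor}), merges groups whose dissimilarity falls below
#' \code{merge_cut_height}, recomputes eigenproteins, and repeats until
#' stable. Labels are renamed by decreasing size after merging.
#'
#' @param x abundance matrix or SummarizedExperiment.
#' @param labels module labels per protein.
#' @param merge_cut_height eigenprotein dissimilarity threshold, default 0.7.
#' @return merged, size-ordered label vector.
#' @export
mergeModules <- function(x, labels, merge_cut_height = 0.7) {
  X <- .abundance(x)
  repeat {
    mods <- .moduleOrder(labels)
    if (length(mods) < 2) break
    eig <- moduleEigenproteins(X, labels)$eigenproteins
    d <- 1 - cor(t(eig), use = "pairwise.complete.obs")
    hc <- hclust(as.dist(d), method = "average")
    grp <- cutree(hc, h = merge_cut_height)
    if (max(grp) == length(mods)) break  # nothing below the cut
    newLabels <- labels
    for (g in unique(grp)) {
      members <- names(grp)[grp == g]
      newLabels[labels %in% members] <- members[1]
    }
    labels <- newLabels
  }
  .relabelBySize(labels)
}

.relabelBySize <- function(labels) {
  mods <- setdiff(unique(labels), "unassigned")
  sizes <- vapply(mods, function(m) sum(labels == m), 1L)
  map <- setNames(paste0("M", seq_along(mods)),
                  mods[order(sizes, decreasing = TRUE)])
  out <- labels
  for (m in names(map)) out[labels == m] <- map[[m]]
  out
}

#' kME (module membership) table
#'
#' Biweight midcorrelation of every protein profile with every module
#' eigenprotein, on pairwise-complete samples.
#'
#' @param x abundance matrix or SummarizedExperiment.
#' @param eigen modules x samples eigenprotein matrix.
#' @param minOverlap minimum jointly observed samples, default 10.
#' @return proteins x modules numeric matrix.
#' @export
kmeTable <- function(x, eigen, minOverlap = 10) {
  X <- .abundance(x)
  bicorMatrix(X, eigen, minOverlap = minOverlap)
}

#' Build the full co-expression network
#'
#' Convenience wrapper running [detectModules()], [mergeModules()],
#' [moduleEigenproteins()] and [kmeTable()] and returning a
#' \linkS4class{CoexpressionNetwork}.
#'
#' @param x harmonized abundance matrix or SummarizedExperiment.
#' @param params parameter list from [networkParamsDefault()].
#' @return a \linkS4class{CoexpressionNetwork}.
#' @export
buildNetwork <- function(x, params = networkParamsDefault()) {
  X <- .abundance(x)
  labels <- detectModules(X, params)
  labels <- mergeModules(X, labels, params$merge_cut_height)
  eig <- moduleEigenproteins(X, labels)
  kmeM <- kmeTable(X, eig$eigenproteins, params$min_pairwise_overlap)
  methods::new("CoexpressionNetwork",
               params = params, moduleLabels = labels,
               eigenproteins = eig$eigenproteins, kme = kmeM,
               varExplained = eig$varExplained)
}
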