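#' Default subtyping parameters
#'
#' Grid-search and network settings for modularity-based sample subtyping.
#'
#' @param n_hubs_per_module hub proteins taken per module, default 30.
#' @param sample_beta soft power for the sample-sample signed adjacency,
#'   default 13.
#' @param grid_min_size candidate minimum cluster sizes i, default
#'   \code{c(10, 15, 20, 25)}.
#' @param grid_max_size candidate maximum cluster sizes j, default
#'   \code{c(100, 150, 200, 250, 300, 350, 400)}.
#' @param grid_avg_degree candidate target average degrees k, default
#'   \code{c(25, 50)}.
#' @param seed integer seed for the seeded community detection.
#' @return parameter list.
#' @export
subtypeParamsDefault <- function(n_hubs_per_module = 30, sample_beta = 13,
                                 grid_min_size = c(10, 15, 20, 25),
                                 grid_max_size = c(100, 150, 200, 250, 300, 350, 400),
                                 grid_avg_degree = c(25, 50),
                                 seed = 1L) {
  stopifnot(all(outer(grid_min_size, grid_max_size, "<")))
  list(n_hubs_per_module = n_hubs_per_module, sample_beta = sample_beta,
       grid_min_size = grid_min_size, grid_max_size = grid_max_size,
       grid_avg_degree = grid_avg_degree, seed = as.integer(seed))
}

#' Select module hub proteins as subtyping features
#'
#' Per module, the \code{n} proteins with the highest kME to their own
#' module (all of them when the module is smaller than \code{n}), with a
#' deterministic tie-break on the protein id; concatenated across modules in
#' module order.
#'
#' @param kmeTable proteins x modules kME matrix.
#' @param labels module labels per protein.
#' @param n_hubs_per_module hubs per module, default 30.
#' @return ordered character vector of hub protein ids.
#' @export
selectHubFeatures <- function(kmeTable, labels, n_hubs_per_module = 30) {
  mods <- .moduleOrder(labels)
  hubs <- character()
  for (m in mods) {
    members <- names(labels)[labels == m]
    if (!length(members)) stop("module ", m, " is empty")
    k <- kmeTable[members, m]
    ord <- order(-k, members)  # ties broken by lexicographic id
    hubs <- c(hubs, members[ord][seq_len(min(n_hubs_per_module, length(members)))])
  }
  hubs
}

#' Sample-sample signed adjacency over hub proteins
#'
#' Biweight midcorrelation between samples over the hub-protein features,
#' soft-thresholded with the signed transform at \code{sample_beta}. The
#' diagonal is zeroed for clustering.
#'
#' @param x abundance matrix or SummarizedExperiment (proteins x samples).
#' @param hub_features hub protein ids (rows of \code{x}).
#' @param sample_beta soft power, default 13.
#' @param minOverlap minimum jointly observed hub features per sample pair.
#' @return symmetric samples x samples adjacency in \[0, 1\], zero diagonal.
#' @export
sampleAdjacency <- function(x, hub_features, sample_beta = 13, minOverlap = 3) {
  X <- .abundance(x)
  missing <- setdiff(hub_features, rownames(X))
  if (length(missing)) stop("hub features absent from matrix: ",
                            paste(head(missing, 5), collapse = ", "))
  sub <- X[hub_features, , drop = FALSE]
  bad <- colSums(is.finite(sub)) == 0
  if (any(bad)) stop("sample(s) with no observed hub values: ",
                     paste(colnames(sub)[bad], collapse = ", "))
  r <- bicorMatrix(t(sub), minOverlap = minOverlap)
  r[is.na(r)] <- 0
  a <- signedAdjacency(r, sample_beta)
  diag(a) <- 0
  a
}

#' Modularity clustering of samples under size and degree constraints
#'
#' Sparsifies the weighted sample network to a target average degree by
#' keeping each node's strongest edges (symmetrized union of each node's top
#' \code{ceiling(k/2)} edges), detects communities by seeded Louvain
#' modularity maximization, recursively re-splits communities larger than
#' \code{j} on their induced subgraph (raising the resolution when a split
#' refuses), and dissolves communities smaller than \code{i} to
#' \code{"unassigned"}. Deterministic given the seed.
#'
#' @param adjacency symmetric non-negative samples x samples matrix, zero
#'   diagonal.
#' @param i minimum cluster size.
#' @param j maximum cluster size.
#' @param k target average degree; must be below the sample count.
#' @param seed integer seed.
#' @return named character labels (\code{"C1"}, ... by decreasing size, or
#'   \code{"unassigned"}), with attributes \code{modularity} and
#'   \code{realized_degree}.
#' @export
modularityCluster <- function(adjacency, i = 15, j = 200, k = 25, seed = 1L) {
  A <- as.matrix(adjacency)
  n <- ncol(A)
  if (k >= n) stop("average degree k must be below the number of samples")
  ids <- colnames(A)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  keepA <- .sparsifyTopK(A, k)
  if (all(keepA == 0)) stop("graph is empty after sparsification")
  g <- igraph::graph_from_adjacency_matrix(keepA, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- withSeed(seed, .louvainRecursive(g, j))
  memb <- .refinePartition(keepA, memb[ids], maxSize = j)
  labels <- rep("unassigned", n)
  names(labels) <- ids
  sizes <- table(memb)
  # hard size constraints: undersized dissolve; rare unsplittable oversized
  # communities dissolve as well so emitted clusters always satisfy [i, j]
  good <- names(sizes)[sizes >= i & sizes <= j]
  cid <- 0L
  for (cl in good[order(-sizes[good])]) {
    cid <- cid + 1L
    labels[memb == cl] <- paste0("C", cid)
  }
  mod <- igraph::modularity(g, membership = as.integer(factor(memb)),
                            weights = igraph::E(g)$weight)
  attr(labels, "modularity") <- mod
  attr(labels, "realized_degree") <- mean(rowSums(keepA > 0))
  labels
}

# keep each node's ceil(k/2) strongest edges, symmetrized by union
.sparsifyTopK <- function(A, k) {
  n <- ncol(A)
  keep <- matrix(FALSE, n, n)
  topk <- ceiling(k / 2)
  for (v in seq_len(n)) {
    ord <- order(A[v, ], decreasing = TRUE)
    ord <- ord[A[v, ord] > 0]
    sel <- head(ord, topk)
    keep[v, sel] <- TRUE
  }
  keep <- keep | t(keep)
  out <- A * keep
  dimnames(out) <- dimnames(A)
  out
}

# deterministic local refinement: sweep nodes in fixed order, moving each to
# the neighbouring community with the largest positive modularity gain
# (Louvain phase 1 restarted on the final partition); moves that would push a
# community past maxSize are skipped
.refinePartition <- function(S, memb, maxSize = Inf, maxSweeps = 20) {
  memb <- as.integer(factor(memb))
  n <- length(memb)
  m <- sum(S) / 2
  if (m == 0) return(memb)
  k <- rowSums(S)
  sigma <- tapply(k, memb, sum)
  commSize <- tabulate(memb)
  for (sweep in seq_len(maxSweeps)) {
    moved <- FALSE
    for (v in seq_len(n)) {
      own <- memb[v]
      w <- tapply(S[v, ], memb, sum)  # weight from v to each community
      cands <- as.integer(names(w))
      gains <- vapply(seq_along(cands), function(ci) {
        cc <- cands[ci]
        if (cc == own) return(0)
        if (commSize[cc] + 1 > maxSize) return(-Inf)
        dW <- w[[ci]] - (w[[as.character(own)]])
        dSig <- sigma[[as.character(cc)]] - (sigma[[as.character(own)]] - k[v])
        dW / m - k[v] * dSig / (2 * m^2)
      }, numeric(1))
      best <- which.max(gains)
      if (gains[best] > 1e-12) {
        tgt <- cands[best]
        sigma[[as.character(own)]] <- sigma[[as.character(own)]] - k[v]
        sigma[[as.character(tgt)]] <- sigma[[as.character(tgt)]] + k[v]
        commSize[own] <- commSize[own] - 1L
        commSize[tgt] <- commSize[tgt] + 1L
        memb[v] <- tgt
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  memb
}

.louvainRecursive <- function(g, j, prefix = "", resolution = 1, depth = 0) {
  n <- igraph::vcount(g)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                resolution = resolution)
  memb <- igraph::membership(cl)
  out <- paste0(prefix, memb)
  names(out) <- igraph::V(g)$name
  if (length(unique(memb)) == 1 && n > j) {
    if (depth >= 6) return(out)  # unsplittable; caller dissolves by size
    return(.louvainRecursive(g, j, prefix, resolution * 1.6, depth + 1))
  }
  for (cid in unique(memb)) {
    members <- which(memb == cid)
    if (length(members) > j) {
      sub <- igraph::induced_subgraph(g, members)
      subLab <- .louvainRecursive(sub, j, paste0(prefix, cid, "."),
                                  1, depth + 1)
      out[names(subLab)] <- subLab
    }
  }
  out
}

#' Grid search over subtyping constraints
#'
#' Clusters the sample network at every (i, j, k) combination, scores each
#' partition lexicographically by fraction of samples assigned, modularity,
#' and replicate-pair consistency, and returns the winning assignment with
#' the full score table.
#'
#' @param x abundance matrix or SummarizedExperiment.
#' @param hub_features hub proteins from [selectHubFeatures()].
#' @param params parameter list from [subtypeParamsDefault()].
#' @param replicate_pairs optional 2-column matrix/data.frame of paired
#'   sample ids for the consistency score.
#' @return a \linkS4class{SubtypeAssignment}.
#' @export
gridSearchSubtypes <- function(x, hub_features, params = subtypeParamsDefault(),
                               replicate_pairs = NULL) {
  A <- sampleAdjacency(x, hub_features, params$sample_beta)
  grid <- expand.grid(i = params$grid_min_size, j = params$grid_max_size,
                      k = params$grid_avg_degree)
  best <- NULL; bestScore <- c(-Inf, -Inf, -Inf)
  scores <- list()
  for (r in seq_len(nrow(grid))) {
    gi <- grid$i[r]; gj <- grid$j[r]; gk <- grid$k[r]
    labels <- tryCatch(
      modularityCluster(A, i = gi, j = gj, k = gk, seed = params$seed),
      error = function(e) NULL)
    if (is.null(labels)) {
      scores[[r]] <- data.frame(i = gi, j = gj, k = gk, n_subtypes = 0,
                                frac_assigned = 0, modularity = NA,
                                replicate_consistency = NA)
      next
    }
    frac <- mean(labels != "unassigned")
    modV <- attr(labels, "modularity")
    rc <- if (!is.null(replicate_pairs))
      replicateConsistency(labels, replicate_pairs)$fraction else NA_real_
    nClust <- length(setdiff(unique(labels), "unassigned"))
    scores[[r]] <- data.frame(i = gi, j = gj, k = gk, n_subtypes = nClust,
                              frac_assigned = frac, modularity = modV,
                              replicate_consistency = rc)
    if (nClust < 2) next
    sc <- c(frac, modV, ifelse(is.na(rc), 0, rc))
    if (.lexGreater(sc, bestScore)) {
      bestScore <- sc
      best <- list(labels = labels, i = gi, j = gj, k = gk, mod = modV, rc = rc)
    }
  }
  if (is.null(best)) stop("no grid combination produced at least 2 clusters")
  methods::new("SubtypeAssignment",
               labels = setNames(as.character(best$labels), names(best$labels)),
               chosenParams = c(i = best$i, j = best$j, k = best$k),
               modularity = best$mod,
               replicateConsistency = best$rc,
               gridScores = do.call(rbind, scores),
               hubFeatures = hub_features)
}

.lexGreater <- function(a, b) {
  for (q in seq_along(a)) {
    if (a[q] > b[q] + 1e-12) return(TRUE)
    if (a[q] < b[q] - 1e-12) return(FALSE)
  }
  FALSE
}

#' Replicate-pair subtype consistency
#'
#' Fraction of same-case sample pairs whose two members carry the same
#' non-unassigned subtype label. A pair with an unassigned member counts as
#' discordant (conservative).
#'
#' @param labels subtype labels per sample (named), or a
#'   \linkS4class{SubtypeAssignment}.
#' @param pairs 2-column matrix/data.frame of paired sample ids.
#' @return list with \code{fraction}, \code{n_concordant}, \code{n_pairs}
#'   and \code{discordant} (pair rows).
#' @export
replicateConsistency <- function(labels, pairs) {
  if (methods::is(labels, "SubtypeAssignment")) labels <- subtypeLabels(labels)
  pairs <- as.matrix(pairs)
  missing <- setdiff(c(pairs), names(labels))
  if (length(missing)) stop("pair member(s) missing from labels: ",
                            paste(head(missing, 5), collapse = ", "))
  l1 <- labels[pairs[, 1]]; l2 <- labels[pairs[, 2]]
  conc <- l1 == l2 & l1 != "unassigned" & l2 != "unassigned"
  list(fraction = mean(conc), n_concordant = sum(conc),
       n_pairs = nrow(pairs),
       discordant = pairs[!conc, , drop = FALSE])
}

#' Demographic enrichment of subtypes
#'
#' Per subtype and trait level, a 2x2 chi-squared test of subtype membership
#' against the remaining cohort; when an expected cell count falls below 5
#' the Fisher exact test is substituted and flagged.
#'
#' @param labels subtype labels per sample (named), or a
#'   \linkS4class{SubtypeAssignment}.
#' @param traits traits data.frame.
#' @param trait categorical trait column name.
#' @return data.frame of (subtype, level, observed proportion, cohort
#'   proportion, p, exact flag).
#' @export
subtypeEnrichment <- function(labels, traits, trait) {
  if (methods::is(labels, "SubtypeAssignment")) labels <- subtypeLabels(labels)
  traits <- .traits(traits)
  traits <- traits[match(names(labels), traits$sample_id), , drop = FALSE]
  v <- traits[[trait]]
  assigned <- labels != "unassigned" & !is.na(v)
  labels <- labels[assigned]; v <- factor(v[assigned])
  if (nlevels(v) < 2) stop("trait '", trait, "' has a single level")
  rows <- list()
  for (st in sort(unique(labels))) {
    inSt <- labels == st
    for (lv in levels(v)) {
      tab <- table(inSt, v == lv)
      if (!all(dim(tab) == c(2, 2))) next
      expCounts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expCounts < 5)) {
        p <- fisher.test(tab)$p.value; exact <- TRUE
      } else {
        p <- chisq.test(tab, correct = FALSE)$p.value; exact <- FALSE
      }
      rows[[paste(st, lv)]] <- data.frame(
        subtype = st, level = lv,
        prop_subtype = mean(v[inSt] == lv),
        prop_cohort = mean(v == lv),
        p = p, exact = exact, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
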