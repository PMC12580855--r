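#' Fit a supervised 2-D embedding of subtyped samples
#'
#' Embeds labelled training samples into two dimensions with a
#' deterministic, class-supervised map designed for out-of-sample
#' projection. Each subtype receives a fixed anchor on a circle of radius
#' \code{anchor_radius}; a sample's coordinate is the softmax-weighted mean
#' of the anchors, with weights decaying in the sample's feature-space
#' distance to each subtype centroid, multiplied by a radial shrinkage term
#' that pulls samples far from every centroid toward the origin (so
#' out-of-distribution profiles land far from every cluster), plus a small
#' seeded random projection of the sample's residual from its weighted
#' centroid (within-class scatter). The map is fully determined by the
#' training data and the seed.
#'
#' @param x abundance matrix or SummarizedExperiment (training cohort).
#' @param labels named subtype labels (no \code{"unassigned"}), or a
#'   \linkS4class{SubtypeAssignment} (unassigned samples are dropped).
#' @param features proteins to use (e.g. hubs overlapping an external
#'   cohort); must meet \code{min_features}.
#' @param max_assign_dist unassignment threshold in embedding units,
#'   default 3.
#' @param target_weight supervision strength in \[0, 1\): the fraction by
#'   which a training sample's coordinate is pulled toward its own label's
#'   anchor (analogous to the target weight of supervised neighbour
#'   embeddings), default 0.6. Projection of unlabelled external samples
#'   never uses it.
#' @param anchor_radius radius of the subtype anchor circle, default 10.
#' @param min_features minimum feature overlap, default 50.
#' @param seed integer seed, default 42.
#' @return an \linkS4class{EmbeddingModel}.
#' @export
fitSupervisedEmbedding <- function(x, labels, features,
                                   max_assign_dist = 3, anchor_radius = 10,
                                   min_features = 50, seed = 42L,
                                   target_weight = 0.6) {
  stopifnot(target_weight >= 0, target_weight < 1)
  if (methods::is(labels, "SubtypeAssignment")) labels <- subtypeLabels(labels)
  X <- .abundance(x)
  features <- intersect(features, rownames(X))
  if (length(features) < min_features)
    stop("feature overlap (", length(features), ") below the floor of ",
         min_features)
  labels <- labels[labels != "unassigned"]
  labels <- labels[names(labels) %in% colnames(X)]
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 subtype labels")
  M <- t(X[features, names(labels), drop = FALSE])  # samples x features
  featureMeans <- colMeans(M, na.rm = TRUE)
  for (f in seq_len(ncol(M))) M[!is.finite(M[, f]), f] <- featureMeans[f]

  centroids <- do.call(rbind, lapply(classes, function(cl)
    colMeans(M[labels == cl, , drop = FALSE])))
  rownames(centroids) <- classes

  D <- .rowDistToCentroids(M, centroids)
  own <- D[cbind(seq_len(nrow(M)), match(labels, classes))]
  # softmax temperature from the class-gap statistic: the runner-up class of
  # a typical training sample gets weight ~1%, so coordinates sit at their
  # class anchor rather than between anchors
  gaps <- apply(D^2, 1, function(d) sort(d)[2] - min(d))
  bandwidth <- sqrt(max(median(gaps), 1e-8) / (2 * log(100)))
  radialCutoff <- as.numeric(quantile(own, 0.99))

  anchors <- anchor_radius * cbind(cos(2 * pi * (seq_along(classes) - 1) /
                                         length(classes)),
                                   sin(2 * pi * (seq_along(classes) - 1) /
                                         length(classes)))
  rownames(anchors) <- classes

  projection <- withSeed(seed,
    matrix(rnorm(2 * ncol(M)), 2, ncol(M),
           dimnames = list(NULL, colnames(M))))

  model <- methods::new("EmbeddingModel",
    features = features,
    trainingCoordinates = matrix(0, nrow(M), 2,
                                 dimnames = list(rownames(M), NULL)),
    trainingLabels = labels,
    centroids = anchors,  # replaced by realized coordinate means below
    featureCentroids = centroids,
    featureMeans = featureMeans,
    bandwidth = bandwidth,
    radialCutoff = radialCutoff,
    anchorRadius = anchor_radius,
    projection = projection,
    scatterScale = 1,
    hyperparams = list(n_components = 2, metric = "euclidean", seed = seed,
                       target_weight = target_weight),
    maxAssignDist = max_assign_dist)

  coords <- .embedCoords(model, M, anchors)
  # supervised pull: blend each training coordinate toward its label anchor
  coords$base <- (1 - target_weight) * coords$base +
    target_weight * anchors[labels, , drop = FALSE]
  # scale within-class scatter so class clouds have sd about 0.5
  resid <- coords$scatter
  sc <- stats::sd(resid)
  model@scatterScale <- if (is.finite(sc) && sc > 0) 0.5 / sc else 0
  coordsFinal <- coords$base + model@scatterScale * coords$scatter
  model@trainingCoordinates <- coordsFinal
  model@centroids <- do.call(rbind, lapply(classes, function(cl)
    colMeans(coordsFinal[labels == cl, , drop = FALSE])))
  rownames(model@centroids) <- classes
  methods::validObject(model)
  model
}

.rowDistToCentroids <- function(M, centroids) {
  d2 <- outer(rowSums(M^2), rep(1, nrow(centroids))) -
    2 * M %*% t(centroids) +
    outer(rep(1, nrow(M)), rowSums(centroids^2))
  sqrt(pmax(d2, 0))
}

# core of the map: softmax anchor mixing + radial shrinkage + scatter term
.embedCoords <- function(model, M, anchors = NULL) {
  if (is.null(anchors)) {
    classes <- rownames(model@featureCentroids)
    anchors <- model@anchorRadius *
      cbind(cos(2 * pi * (seq_along(classes) - 1) / length(classes)),
            sin(2 * pi * (seq_along(classes) - 1) / length(classes)))
  }
  D <- .rowDistToCentroids(M, model@featureCentroids)
  W <- exp(-(D^2 - apply(D^2, 1, min)) / (2 * model@bandwidth^2))
  W <- W / rowSums(W)
  dmin <- apply(D, 1, min)
  shrink <- exp(-pmax(0, dmin - model@radialCutoff) /
                  (model@radialCutoff / 2))
  base <- (W %*% anchors) * shrink
  xhat <- W %*% model@featureCentroids
  scatter <- (M - xhat) %*% t(model@projection) * shrink
  rownames(base) <- rownames(M)
  list(base = base, scatter = scatter)
}

#' Project external samples and assign subtypes
#'
#' Projects external samples into a trained embedding and assigns each to
#' the nearest subtype centroid in Euclidean embedding space, unless the
#' nearest centroid is farther than the model's \code{maxAssignDist}, in
#' which case the sample is unassigned. Model features missing from the
#' external matrix are imputed with training feature means (count reported);
#' a sample missing more than half the features is unassigned with reason.
#' Distance ties break by label order.
#'
#' @param model an \linkS4class{EmbeddingModel}.
#' @param x external abundance matrix or SummarizedExperiment.
#' @return data.frame of (sample, subtype, distance, reason) where subtype
#'   is \code{"unassigned"} beyond the threshold; attribute
#'   \code{imputed_features} carries the imputation count.
#' @export
projectAssign <- function(model, x) {
  X <- .abundance(x)
  present <- intersect(model@features, rownames(X))
  nImputed <- length(model@features) - length(present)
  M <- matrix(rep(model@featureMeans, each = ncol(X)), ncol(X),
              length(model@features),
              dimnames = list(colnames(X), model@features))
  M[, present] <- t(X[present, , drop = FALSE])
  fracMissing <- rowMeans(!is.finite(M)) + nImputed / length(model@features)
  for (f in seq_len(ncol(M)))
    M[!is.finite(M[, f]), f] <- model@featureMeans[f]

  coords <- .embedCoords(model, M)
  pts <- coords$base + model@scatterScale * coords$scatter
  D <- .rowDistToCentroids(pts, model@centroids)
  nearest <- apply(D, 1, which.min)  # which.min takes the first on ties
  dmin <- D[cbind(seq_len(nrow(D)), nearest)]
  subtype <- rownames(model@centroids)[nearest]
  reason <- rep(NA_character_, nrow(M))
  tooFar <- dmin > model@maxAssignDist
  subtype[tooFar] <- "unassigned"; reason[tooFar] <- "distance"
  manyMissing <- fracMissing > 0.5
  subtype[manyMissing] <- "unassigned"; reason[manyMissing] <- "missing_features"
  out <- data.frame(sample = rownames(M), subtype = subtype,
                    distance = dmin, reason = reason,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "imputed_features") <- nImputed
  out
}

#' Reference-centered subtype signatures
#'
#' Per protein, computes subtype mean expression, subtracts the reference
#' subtype's mean, and z-scores the centered values per protein across the
#' non-reference subtypes. The reference column is dropped. Proteins whose
#' centered values are constant have no z-scale and are flagged missing.
#'
#' @param x abundance matrix or SummarizedExperiment.
#' @param labels named subtype labels per sample.
#' @param reference_subtype label used as the control reference.
#' @return proteins x (non-reference subtypes) signature matrix.
#' @export
referenceCenteredSignatures <- function(x, labels, reference_subtype) {
  X <- .abundance(x)
  labels <- labels[names(labels) %in% colnames(X)]
  labels <- labels[labels != "unassigned"]
  classes <- sort(unique(labels))
  if (!reference_subtype %in% classes)
    stop("reference subtype '", reference_subtype, "' not present")
  if (any(table(labels) < 2)) stop("every subtype needs at least 2 samples")
  means <- vapply(classes, function(cl)
    rowMeans(X[, names(labels)[labels == cl], drop = FALSE], na.rm = TRUE),
    numeric(nrow(X)))
  centered <- means - means[, reference_subtype]
  centered <- centered[, setdiff(classes, reference_subtype), drop = FALSE]
  sds <- apply(centered, 1, sd)
  z <- (centered - rowMeans(centered)) / sds
  z[sds == 0, ] <- NA
  z
}

#' Correlate subtype signatures between cohorts
#'
#' Biweight midcorrelation between every pair of signature columns over the
#' protein intersection, with Student-t p-values.
#'
#' @param sigA,sigB protein x subtype signature matrices (rownames are
#'   protein ids).
#' @param min_shared minimum shared proteins, default 30.
#' @return list with \code{bicor} and \code{p} matrices (rows = columns of
#'   \code{sigA}, cols = columns of \code{sigB}).
#' @export
signatureCorrelation <- function(sigA, sigB, min_shared = 30) {
  shared <- intersect(rownames(sigA), rownames(sigB))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " shared proteins; need ", min_shared)
  A <- sigA[shared, , drop = FALSE]
  B <- sigB[shared, , drop = FALSE]
  r <- bicorMatrix(t(A), t(B), minOverlap = min(min_shared, 10))
  n <- length(shared)
  list(bicor = r, p = corPvalue(r, n))
}
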