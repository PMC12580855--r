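#' @import methods
#' @importFrom stats median mad sd quantile var prcomp hclust cutree as.dist
#'   aov TukeyHSD fisher.test p.adjust chisq.test pt pf lm coef anova
#'   complete.cases rnorm runif rbinom model.matrix setNames dist na.omit
#'   t.test phyper cor
#' @importFrom utils head read.delim write.table combn
NULL

#' Signed co-expression network of protein modules
#'
#' Holds the result of building a signed biweight-midcorrelation network:
#' per-protein module labels (with the reserved label \code{"unassigned"}),
#' module eigenproteins (first principal component of each module's
#' standardized submatrix, scored per sample), the kME (module membership)
#' table, per-module variance explained, and the parameters used.
#'
#' @slot params list of network parameters (see [networkParams()]).
#' @slot moduleLabels named character vector, one label per protein.
#' @slot eigenproteins numeric matrix, modules x samples.
#' @slot kme numeric matrix, proteins x modules, biweight midcorrelation of
#'   each protein profile with each module eigenprotein.
#' @slot varExplained named numeric vector, proportion of module variance
#'   captured by the eigenprotein.
#'
#' @seealso [buildNetwork()], [detectModules()], [moduleEigenproteins()]
#' @export
setClass("CoexpressionNetwork",
  representation(
    params = "list",
    moduleLabels = "character",
    eigenproteins = "matrix",
    kme = "matrix",
    varExplained = "numeric"
  )
)

setValidity("CoexpressionNetwork", function(object) {
  msg <- NULL
  labs <- object@moduleLabels
  mods <- setdiff(unique(labs), "unassigned")
  if (length(mods) && nrow(object@eigenproteins) != length(mods))
    msg <- c(msg, "eigenprotein rows must match the number of modules")
  if (nrow(object@kme) && !identical(rownames(object@kme), names(labs)))
    msg <- c(msg, "kme rows must be named by protein, matching moduleLabels")
  if (is.null(msg)) TRUE else msg
})

#' Subtype assignment of cohort samples
#'
#' Result of modularity-based sample clustering on module hub proteins:
#' per-sample subtype label (or \code{"unassigned"}), the grid-search
#' parameters selected, achieved modularity, replicate-pair consistency and
#' the hub features used.
#'
#' @slot labels named character vector, one subtype label per sample.
#' @slot chosenParams named numeric vector with elements \code{i} (minimum
#'   cluster size), \code{j} (maximum cluster size), \code{k} (target average
#'   degree).
#' @slot modularity numeric, Newman modularity of the chosen partition.
#' @slot replicateConsistency numeric fraction of replicate pairs concordant
#'   (NA when no pairs supplied).
#' @slot gridScores data.frame of per-combination grid-search scores.
#' @slot hubFeatures character vector of the hub proteins used as features.
#'
#' @seealso [gridSearchSubtypes()], [modularityCluster()]
#' @export
setClass("SubtypeAssignment",
  representation(
    labels = "character",
    chosenParams = "numeric",
    modularity = "numeric",
    replicateConsistency = "numeric",
    gridScores = "data.frame",
    hubFeatures = "character"
  )
)

setValidity("SubtypeAssignment", function(object) {
  sizes <- table(object@labels[object@labels != "unassigned"])
  p <- object@chosenParams
  if (length(sizes) && all(c("i", "j") %in% names(p))) {
    if (any(sizes < p[["i"]]) || any(sizes > p[["j"]]))
      return("assigned subtype sizes must lie within [i, j]")
  }
  TRUE
})

#' Supervised 2-D embedding model for cross-cohort subtype transfer
#'
#' A deterministic supervised embedding of labelled training samples into two
#' dimensions. Each subtype receives a fixed anchor on a circle; a sample's
#' coordinate is the softmax-weighted combination of anchors (weights from
#' distances to subtype centroids in feature space), shrunk toward the origin
#' when the sample is far from every centroid, plus a small projected
#' within-class scatter. External samples are projected by the same map and
#' assigned to the nearest subtype centroid in the embedding, or left
#' unassigned beyond \code{maxAssignDist}.
#'
#' @slot features character, the protein features the model was trained on.
#' @slot trainingCoordinates numeric matrix, training samples x 2.
#' @slot trainingLabels named character vector of training subtype labels.
#' @slot centroids numeric matrix, subtypes x 2, per-label coordinate means.
#' @slot featureCentroids numeric matrix, subtypes x features (feature space).
#' @slot featureMeans numeric, per-feature training means (imputation values).
#' @slot bandwidth numeric, softmax bandwidth (feature-space units).
#' @slot radialCutoff numeric, in-distribution distance cutoff.
#' @slot anchorRadius numeric, radius of the anchor circle.
#' @slot projection numeric matrix, 2 x features, scatter projection.
#' @slot scatterScale numeric, scaling of the within-class scatter term.
#' @slot hyperparams list of embedding hyperparameters, including the seed.
#' @slot maxAssignDist numeric, unassignment threshold in embedding units.
#'
#' @seealso [fitSupervisedEmbedding()], [projectAssign()]
#' @export
setClass("EmbeddingModel",
  representation(
    features = "character",
    trainingCoordinates = "matrix",
    trainingLabels = "character",
    centroids = "matrix",
    featureCentroids = "matrix",
    featureMeans = "numeric",
    bandwidth = "numeric",
    radialCutoff = "numeric",
    anchorRadius = "numeric",
    projection = "matrix",
    scatterScale = "numeric",
    hyperparams = "list",
    maxAssignDist = "numeric"
  )
)

setValidity("EmbeddingModel", function(object) {
  if (!length(object@features)) return("feature list must be non-empty")
  if (ncol(object@trainingCoordinates) != 2)
    return("training coordinates must be 2-D")
  TRUE
})

#' Plasma/HSA dilution series into pooled CSF
#'
#' Log2 abundances of proteins across a spike-in dilution series: a baseline
#' condition (0 percent spike) plus increasing spike concentrations, each with
#' replicates, and a per-protein class label describing the planted behaviour
#' (or, for real data, the module annotation).
#'
#' @slot spikeType character, \code{"plasma"} or \code{"HSA"}.
#' @slot concentrations numeric, ordered spike concentrations (percent v/v)
#'   including 0 exactly once.
#' @slot abundance numeric matrix, proteins x (condition x replicate), log2.
#' @slot condition numeric vector, the concentration of each column.
#' @slot replicate integer vector, replicate index of each column.
#' @slot proteinClass named character vector per protein.
#'
#' @seealso [generateDilutionSeries()], [percentOfBaseline()]
#' @export
setClass("DilutionSeries",
  representation(
    spikeType = "character",
    concentrations = "numeric",
    abundance = "matrix",
    condition = "numeric",
    replicate = "integer",
    proteinClass = "character"
  )
)

setValidity("DilutionSeries", function(object) {
  conc <- object@concentrations
  if (sum(conc == 0) != 1) return("baseline concentration 0 must appear exactly once")
  if (is.unsorted(conc, strictly = TRUE)) return("concentrations must be strictly increasing")
  if (length(object@condition) != ncol(object@abundance))
    return("condition vector must match abundance columns")
  if (any(!is.finite(object@abundance) & !is.na(object@abundance)))
    return("abundance must be finite where observed")
  TRUE
})

## ---- accessors ----

#' @describeIn CoexpressionNetwork-class per-protein module labels
#' @param object a \code{CoexpressionNetwork}
#' @export
moduleLabels <- function(object) object@moduleLabels

#' @describeIn CoexpressionNetwork-class module eigenprotein matrix
#' @export
eigenproteins <- function(object) object@eigenproteins

#' @describeIn CoexpressionNetwork-class protein x module kME table
#' @export
kme <- function(object) object@kme

#' @describeIn CoexpressionNetwork-class network parameter list
#' @export
networkParams <- function(object) object@params

#' @describeIn CoexpressionNetwork-class module sizes, decreasing
#' @export
moduleSizes <- function(object) {
  labs <- object@moduleLabels[object@moduleLabels != "unassigned"]
  sort(table(labs), decreasing = TRUE)
}

#' @describeIn SubtypeAssignment-class per-sample subtype labels
#' @param object a \code{SubtypeAssignment}
#' @export
subtypeLabels <- function(object) object@labels

#' @describeIn SubtypeAssignment-class grid-search score table
#' @export
gridScores <- function(object) object@gridScores

#' @describeIn SubtypeAssignment-class hub proteins used as features
#' @export
hubFeatures <- function(object) object@hubFeatures

setMethod("show", "CoexpressionNetwork", function(object) {
  sizes <- moduleSizes(object)
  cat("CoexpressionNetwork:", length(object@moduleLabels), "proteins,",
      length(sizes), "modules\n")
  cat("  beta =", object@params$beta, "| minModuleSize =",
      object@params$min_module_size, "| mergeCutHeight =",
      object@params$merge_cut_height, "\n")
  if (length(sizes)) {
    cat("  module sizes:", paste(names(sizes), sizes, sep = "=",
        collapse = ", "), "\n")
  }
  cat("  unassigned:", sum(object@moduleLabels == "unassigned"), "\n")
})

setMethod("show", "SubtypeAssignment", function(object) {
  sizes <- table(object@labels[object@labels != "unassigned"])
  cat("SubtypeAssignment:", length(object@labels), "samples,",
      length(sizes), "subtypes\n")
  p <- object@chosenParams
  cat(sprintf("  chosen (i, j, k) = (%d, %d, %d); modularity = %.3f\n",
              p[["i"]], p[["j"]], p[["k"]], object@modularity))
  if (!is.na(object@replicateConsistency))
    cat(sprintf("  replicate consistency = %.1f%%\n",
                100 * object@replicateConsistency))
  cat("  sizes:", paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "EmbeddingModel", function(object) {
  cat("EmbeddingModel:", length(object@features), "features,",
      nrow(object@centroids), "subtypes\n")
  cat("  maxAssignDist =", object@maxAssignDist,
      "| anchorRadius =", object@anchorRadius, "\n")
})

setMethod("show", "DilutionSeries", function(object) {
  cat("DilutionSeries (", object@spikeType, "): ",
      nrow(object@abundance), " proteins x ", ncol(object@abundance),
      " columns\n", sep = "")
  cat("  concentrations (% v/v):",
      paste(object@concentrations, collapse = ", "), "\n")
  cat("  classes:", paste(names(table(object@proteinClass)),
      table(object@proteinClass), sep = "=", collapse = ", "), "\n")
})
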