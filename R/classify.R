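# Discriminant function analysis with a pooled within-group covariance, and
# single-linkage clustering with a normalized linkage cutoff for species
# delimitation.

#' Fit a discriminant function analysis
#'
#' Estimates per-group mean vectors and the pooled within-group covariance;
#' observations are classified to the group minimizing squared Mahalanobis
#' distance under the pooled covariance minus twice the log prior (the
#' linear discriminant rule). When the pooled covariance is numerically
#' singular an escalating ridge is added to the diagonal and recorded on the
#' model.
#'
#' @param x numeric matrix or data.frame of features (rows = individuals).
#' @param labels group (species) label per row; every group needs >= 2
#'   members.
#' @param prior \code{"equal"} (default; the design is near-balanced) or
#'   \code{"proportional"} to group sizes.
#' @return a [DfaModel-class] object.
#' @export
fitDfa <- function(x, labels, prior = c("equal", "proportional")) {
  prior <- match.arg(prior)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  counts <- table(labels)
  if (length(counts) < 2L) stop("at least 2 groups required")
  if (any(counts < 2L))
    stop("every group needs >= 2 members; offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  groups <- names(counts)
  p <- ncol(x)
  means <- do.call(rbind, lapply(groups, function(g)
    colMeans(x[labels == g, , drop = FALSE])))
  rownames(means) <- groups
  centered <- x - means[match(labels, groups), , drop = FALSE]
  pooled <- crossprod(centered) / (nrow(x) - length(groups))
  ridge <- 0
  repeat {
    ok <- tryCatch({chol(pooled + diag(ridge, p)); TRUE},
                   error = function(e) FALSE)
    if (ok) break
    ridge <- if (ridge == 0) 1e-8 * mean(diag(pooled)) else ridge * 10
  }
  if (ridge > 0) {
    pooled <- pooled + diag(ridge, p)
    message("pooled covariance singular; ridge ", signif(ridge, 3),
            " added to the diagonal")
  }
  pr <- if (prior == "equal") rep(1 / length(groups), length(groups))
        else as.numeric(counts) / nrow(x)
  names(pr) <- groups
  if (is.null(colnames(means))) colnames(means) <- colnames(x)
  new("DfaModel", groups = groups, means = means,
      pooledCov = (pooled + t(pooled)) / 2, priors = pr, ridge = ridge)
}

#' Classify observations with a fitted DFA
#'
#' @param object a [DfaModel-class].
#' @param newdata matrix or data.frame with the model's feature columns.
#' @param ... unused.
#' @return character vector of predicted group labels.
#' @export
setMethod("predict", "DfaModel", function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  Sinv <- chol2inv(chol(object@pooledCov))
  scores <- vapply(seq_along(object@groups), function(g) {
    d <- x - matrix(object@means[g, ], nrow(x), ncol(x), byrow = TRUE)
    rowSums((d %*% Sinv) * d) - 2 * log(object@priors[g])
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) scores <- matrix(scores, nrow = 1L)
  object@groups[max.col(-scores, ties.method = "first")]
})

#' Resubstitution classification matrix
#'
#' Confusion matrix of true against predicted groups and the percentage of
#' correctly classified individuals (100 * trace / total). Resubstitution
#' scoring: the same individuals the model was fitted on are classified.
#'
#' @param model a [DfaModel-class].
#' @param x feature matrix conformable with the model.
#' @param labels true group label per row; every label must be known to the
#'   model.
#' @return list with \code{counts} (true x predicted matrix) and
#'   \code{percentCorrect}.
#' @export
classificationMatrix <- function(model, x, labels) {
  labels <- as.character(labels)
  unseen <- setdiff(unique(labels), model@groups)
  if (length(unseen))
    stop("label(s) unseen by the model: ", paste(unseen, collapse = ", "))
  pred <- predict(model, x)
  counts <- table(factor(labels, levels = model@groups),
                  factor(pred, levels = model@groups))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("true", "predicted")
  list(counts = counts,
       percentCorrect = 100 * sum(diag(counts)) / sum(counts))
}

#' Pairwise Euclidean distances
#'
#' Symmetric matrix of Euclidean distances between rows; intended for
#' standardized feature tables (see [standardizeFeatures()]).
#'
#' @param x numeric matrix or data.frame (rows = individuals).
#' @return a dense symmetric distance matrix with zero diagonal.
#' @export
pairwiseEuclidean <- function(x) {
  as.matrix(stats::dist(as.matrix(x), method = "euclidean"))
}

#' Single-linkage dendrogram
#'
#' Agglomerative single-linkage clustering of a distance matrix; merge
#' heights are non-decreasing and equal the sorted edge weights of the
#' minimum spanning tree.
#'
#' @param distances distance matrix (dense symmetric or \code{"dist"}).
#' @return an [stats::hclust] tree.
#' @export
singleLinkage <- function(distances) {
  d <- if (inherits(distances, "dist")) distances else
    stats::as.dist(distances)
  stats::hclust(d, method = "single")
}

#' Delimit species by cutting a dendrogram
#'
#' Cuts the single-linkage tree at a fixed linkage distance. By default the
#' merge heights are first divided by the maximum height, so the cutoff is a
#' fraction in (0, 1] of the deepest split; raw Euclidean heights on
#' standardized features depend on the number of characters, and the 0.4
#' criterion is only meaningful on the normalized scale. Individuals joined
#' below the cutoff form one putative species.
#'
#' @param dendrogram an [stats::hclust] tree from [singleLinkage()].
#' @param cutoff linkage cutoff; in (0, 1] when \code{normalize} is TRUE.
#' @param normalize divide heights by the maximum merge height first.
#' @return integer cluster assignment per individual.
#' @export
delimitSpecies <- function(dendrogram, cutoff = 0.4, normalize = TRUE) {
  stopifnot(inherits(dendrogram, "hclust"))
  if (normalize) {
    if (cutoff <= 0 || cutoff > 1)
      stop("cutoff must be in (0, 1] in normalized mode")
    h <- cutoff * max(dendrogram$height)
  } else h <- cutoff
  stats::cutree(dendrogram, h = h)
}

#' Taxon-level correctness of a cluster assignment
#'
#' A taxon is resolved correctly iff some cluster contains all of its
#' individuals and no others (pure and complete). The proportion of correct
#' taxa is always a multiple of 1 / (number of taxa), matching the
#' granularity of the published cluster percentages.
#'
#' @param assignment cluster id per individual (e.g. from
#'   [delimitSpecies()]).
#' @param labels true species label per individual.
#' @return list with \code{flags} (named logical per taxon) and
#'   \code{proportion} of correctly resolved taxa.
#' @export
scoreClusterCorrectness <- function(assignment, labels) {
  labels <- as.character(labels)
  stopifnot(length(assignment) == length(labels))
  taxa <- unique(labels)
  flags <- vapply(taxa, function(sp) {
    cl <- unique(assignment[labels == sp])
    length(cl) == 1L && all(labels[assignment == cl] == sp)
  }, logical(1))
  list(flags = flags, proportion = mean(flags))
}

#' Corrupt a fraction of group labels
#'
#' Emulates a-priori misidentification: \code{round(fraction * N)}
#' individuals, drawn at random, are reassigned to one randomly chosen
#' other group (individuals already in the target group are drawn from the
#' remaining groups). Used to probe the robustness of DFA to erroneous
#' morphological classification.
#'
#' @param labels group label per individual.
#' @param fraction fraction of individuals to misclassify.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return list with \code{labels} (corrupted), \code{changed} (indices
#'   reassigned) and \code{target} (the receiving group).
#' @export
misclassifyLabels <- function(labels, fraction, seed = NULL) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2L) stop("at least 2 groups required")
  stopifnot(fraction >= 0, fraction <= 1)
  m <- round(fraction * length(labels))
  .withSeed(seed, {
    target <- sample(groups, 1L)
    eligible <- which(labels != target)
    changed <- if (m > 0) sample(eligible, min(m, length(eligible)))
               else integer(0)
    labels[changed] <- target
    list(labels = labels, changed = sort(changed), target = target)
  })
}
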