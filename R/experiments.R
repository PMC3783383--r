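# The randomized evaluation: random taxa subsets crossed with character
# sets, scored by DFA and by single-linkage clustering on identical
# subsets, plus the inferential statistics run on the outcomes (binomial
# GLM, arcsine bootstrap, two-proportion tests).

.characterSet <- function(nCharacters) {
  switch(as.character(nCharacters),
         "5" = standardCharacters(),
         "7" = allCharacters(),
         stop("character set must be 5 or 7"))
}

# evaluate one species subset with one character set by both methods
.evaluateSubset <- function(table, speciesSubset, chars, cutoff = 0.4) {
  sub <- table[table$species %in% speciesSubset, , drop = FALSE]
  x <- as.matrix(sub[, chars, drop = FALSE])
  model <- fitDfa(x, sub$species)
  dfaPct <- classificationMatrix(model, x, sub$species)$percentCorrect
  std <- standardizeFeatures(sub, columns = chars)
  hc <- singleLinkage(pairwiseEuclidean(std[, chars, drop = FALSE]))
  assign <- delimitSpecies(hc, cutoff = cutoff, normalize = TRUE)
  score <- scoreClusterCorrectness(assign, sub$species)
  list(dfa = dfaPct, cluster = 100 * score$proportion,
       clusterFlags = score$flags)
}

#' Run the randomized subset evaluation
#'
#' For each taxa-group size and replicate, draws one random species subset
#' and evaluates it with both character sets (5 standard characters; 5 plus
#' the two superstructure statistics) and both methods -- resubstitution
#' DFA (individual-level percent correct) and single-linkage clustering
#' with the normalized 0.4 linkage cutoff (taxon-level percent correct) --
#' on the identical subset, so method and character-set effects are
#' compared on the same draws.
#'
#' @param table a feature table holding all candidate species.
#' @param taxaCounts taxa-group sizes to evaluate (default 5 to 13).
#' @param replicates random subsets per taxa-group size (default 10).
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @param cutoff linkage cutoff for species delimitation.
#' @return data.frame with one row per (taxa_count, replicate,
#'   n_characters, method): columns \code{taxa_count}, \code{replicate},
#'   \code{n_characters}, \code{method}, \code{percent}, \code{species}
#'   (semicolon-joined subset).
#' @export
runRandomization <- function(table, taxaCounts = 5:13, replicates = 10,
                             seed = NULL, cutoff = 0.4) {
  species <- unique(table$species)
  if (max(taxaCounts) > length(species))
    stop("taxa count exceeds the number of available species")
  .withSeed(seed, {
    out <- list()
    for (tc in taxaCounts) {
      for (r in seq_len(replicates)) {
        subset <- sample(species, tc)
        for (nc in c(5, 7)) {
          ev <- .evaluateSubset(table, subset, .characterSet(nc), cutoff)
          out[[length(out) + 1L]] <- data.frame(
            taxa_count = tc, replicate = r, n_characters = nc,
            method = c("dfa", "cluster"),
            percent = c(ev$dfa, ev$cluster),
            species = paste(sort(subset), collapse = ";"),
            stringsAsFactors = FALSE)
        }
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Summarize outcomes in the published table layout
#'
#' One row per (method, taxa_count, n_characters) with the ten replicate
#' percentages and their rounded mean, mirroring the layout of the
#' published replicate tables.
#'
#' @param outcomes data.frame from [runRandomization()], or any data.frame
#'   with \code{taxa_count}, \code{n_characters}, \code{replicate},
#'   \code{percent} and optionally \code{method}.
#' @return data.frame with columns \code{method} (if present),
#'   \code{taxa_count}, \code{n_characters}, \code{r1}..\code{rK},
#'   \code{average}.
#' @export
summarizeOutcomes <- function(outcomes) {
  if (!"method" %in% names(outcomes)) outcomes$method <- "all"
  cells <- unique(outcomes[, c("method", "taxa_count", "n_characters")])
  cells <- cells[order(cells$method, cells$taxa_count,
                       -cells$n_characters), ]
  nrep <- max(outcomes$replicate)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- outcomes$method == cells$method[i] &
      outcomes$taxa_count == cells$taxa_count[i] &
      outcomes$n_characters == cells$n_characters[i]
    pct <- outcomes$percent[sel][order(outcomes$replicate[sel])]
    if (length(pct) != nrep)
      warning("incomplete cell: ", cells$taxa_count[i], " taxa, ",
              cells$n_characters[i], " characters (", cells$method[i], ")")
    row <- as.data.frame(as.list(round(pct, 1)))
    names(row) <- paste0("r", seq_along(pct))
    cbind(cells[i, , drop = FALSE], row,
          average = round(mean(pct)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Superstructure resolution experiment
#'
#' Quantifies how much the two chirp-superstructure statistics help the
#' cluster analysis resolve the two species with chirp-group song structure.
#' For each taxa-group size, both focal species are retained in every
#' random subset and the remaining taxa are drawn at random; for each
#' character set the number of randomizations in which each focal species
#' forms a pure, complete cluster is counted.
#'
#' @param table a feature table holding all candidate species.
#' @param taxaCounts subset sizes (default 6, 7 and 10).
#' @param replicates randomizations per subset size (default 10).
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @param retained the two focal species retained in every subset.
#' @param cutoff linkage cutoff for species delimitation.
#' @return data.frame with columns \code{taxa_count}, \code{n_characters},
#'   \code{species}, \code{successes}, \code{trials}.
#' @export
runSuperstructureExperiment <- function(table, taxaCounts = c(6, 7, 10),
                                        replicates = 10, seed = NULL,
                                        retained = c("Coiblemmus",
                                                     "Velarifictorus_sp2"),
                                        cutoff = 0.4) {
  species <- unique(table$species)
  if (!all(retained %in% species))
    stop("retained species missing from the table: ",
         paste(setdiff(retained, species), collapse = ", "))
  others <- setdiff(species, retained)
  .withSeed(seed, {
    counts <- list()
    for (tc in taxaCounts) {
      succ <- matrix(0L, nrow = 2L, ncol = length(retained),
                     dimnames = list(c("5", "7"), retained))
      for (r in seq_len(replicates)) {
        subset <- c(retained, sample(others, tc - length(retained)))
        for (nc in c(5, 7)) {
          ev <- .evaluateSubset(table, subset, .characterSet(nc), cutoff)
          ok <- ev$clusterFlags[retained]
          succ[as.character(nc), ] <- succ[as.character(nc), ] +
            as.integer(ok)
        }
      }
      for (nc in c("5", "7")) for (sp in retained)
        counts[[length(counts) + 1L]] <- data.frame(
          taxa_count = tc, n_characters = as.integer(nc), species = sp,
          successes = succ[nc, sp], trials = replicates,
          stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, counts)
    rownames(out) <- NULL
    out
  })
}

#' Rebuild GLM counts from the published cluster percentages
#'
#' Inverts every printed replicate percentage of the cluster table to its
#' unique success count (see [invertPercentage()]), giving the 180
#' successes/trials observations the two-way binomial GLM is fitted to.
#'
#' @param tableId passed to [loadPrintedResults()] (default
#'   \code{"table3"}, the cluster percentages).
#' @return data.frame with \code{taxa_count}, \code{n_characters},
#'   \code{replicate}, \code{successes}, \code{trials}.
#' @export
glmDataFromPrinted <- function(tableId = "table3") {
  long <- loadPrintedResults(tableId)
  long$successes <- vapply(seq_len(nrow(long)), function(i)
    invertPercentage(long$percent[i], long$taxa_count[i]), integer(1))
  long$trials <- long$taxa_count
  long[, c("taxa_count", "n_characters", "replicate", "successes",
           "trials")]
}

#' Two-way binomial GLM on classification successes
#'
#' Fits successes/failures per replicate with a logit link and the full
#' taxa-group by character-set interaction, using treatment coding against
#' explicit reference levels. The character factor is labelled so that the
#' reference set prints as \code{character1}; the seven-character set is
#' the default reference, which is the parameterization under which the
#' published coefficient tables reproduce. Wald z and two-sided p values
#' are reported per term, with the residual deviance, residual df and AIC
#' (standard binomial log-likelihood including the combinatorial terms).
#'
#' @param counts data.frame with \code{taxa_count}, \code{n_characters},
#'   \code{successes}, \code{trials} (e.g. from [glmDataFromPrinted()] or
#'   aggregated [runRandomization()] outcomes).
#' @param refTaxa reference taxa-group level, e.g. \code{"taxa5"}.
#' @param refCharacters reference character set, 5 or 7 (default 7).
#' @return a [BinomialGlmFit-class] object.
#' @examples
#' fit <- fitBinomialGlm(glmDataFromPrinted("table3"))
#' fit
#' @export
fitBinomialGlm <- function(counts, refTaxa = "taxa5", refCharacters = 7) {
  stopifnot(all(c("taxa_count", "n_characters", "successes", "trials")
                %in% names(counts)))
  taxaLevels <- paste0("taxa", sort(unique(counts$taxa_count)))
  taxa <- factor(paste0("taxa", counts$taxa_count), levels = taxaLevels)
  if (!refTaxa %in% taxaLevels)
    stop("refTaxa must be one of: ", paste(taxaLevels, collapse = ", "))
  taxa <- stats::relevel(taxa, ref = refTaxa)
  refCharacters <- as.integer(refCharacters)
  sets <- sort(unique(counts$n_characters))
  if (!refCharacters %in% sets)
    stop("refCharacters must be one of: ", paste(sets, collapse = ", "))
  ordered <- c(refCharacters, setdiff(sets, refCharacters))
  chars <- factor(paste0("character",
                         match(counts$n_characters, ordered)),
                  levels = paste0("character", seq_along(ordered)))
  dat <- data.frame(successes = counts$successes,
                    failures = counts$trials - counts$successes,
                    taxa = taxa, chars = chars)
  fit <- tryCatch(
    stats::glm(cbind(successes, failures) ~ taxa * chars,
               family = stats::binomial(link = "logit"), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop("separation detected: some cells are all-success or ",
             "all-failure; the Wald statistics would be meaningless")
      suppressWarnings(
        stats::glm(cbind(successes, failures) ~ taxa * chars,
                   family = stats::binomial(link = "logit"), data = dat))
    })
  co <- summary(fit)$coefficients
  terms <- rownames(co)
  terms[terms == "(Intercept)"] <- paste0(refTaxa, " (intercept)")
  terms <- gsub("taxataxa", "taxa", gsub("charscharacter", "character",
                                         terms))
  coefTab <- data.frame(term = terms, estimate = co[, "Estimate"],
                        se = co[, "Std. Error"], z = co[, "z value"],
                        p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE)
  rownames(coefTab) <- NULL
  new("BinomialGlmFit",
      coefficients = coefTab,
      residualDeviance = fit$deviance,
      residualDf = as.integer(fit$df.residual),
      aic = stats::AIC(fit),
      referenceLevels = c(taxa = refTaxa,
                          characters = paste0(refCharacters,
                                              " characters")),
      fit = fit)
}

#' Wald z statistic of a GLM term
#'
#' Convenience accessor: looks a term up in the coefficient table of a
#' [BinomialGlmFit-class] by name (e.g. \code{"taxa11"} or
#' \code{"taxa11:character2"}).
#'
#' @param fit a [BinomialGlmFit-class].
#' @param term term name; the intercept is \code{"<refTaxa> (intercept)"}.
#' @return the Wald z value.
#' @export
waldZ <- function(fit, term) {
  stopifnot(is(fit, "BinomialGlmFit"))
  i <- match(term, fit@coefficients$term)
  if (is.na(i)) stop("term not found: ", term, "; available: ",
                     paste(fit@coefficients$term, collapse = ", "))
  fit@coefficients$z[i]
}

#' Arcsine bootstrap confidence interval for replicate proportions
#'
#' Resamples the replicate-level proportions with replacement, transforms
#' each bootstrap mean by \code{asin(sqrt(p))}, and forms a normal interval
#' (mean +/- 1.96 bootstrap SE) on the transformed scale, back-transformed
#' through \code{sin^2}; endpoints are therefore always in \[0, 1\].
#'
#' @param proportions replicate proportions in \[0, 1\].
#' @param iterations bootstrap iterations (default 100).
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return list with \code{mean}, \code{lower}, \code{upper}.
#' @export
bootstrapCi <- function(proportions, iterations = 100, seed = NULL) {
  stopifnot(all(proportions >= 0), all(proportions <= 1),
            length(proportions) >= 1L)
  .withSeed(seed, {
    bootMeans <- vapply(seq_len(iterations), function(i)
      mean(asin(sqrt(sample(proportions, replace = TRUE)))), numeric(1))
    m <- mean(bootMeans)
    se <- stats::sd(bootMeans)
    if (!is.finite(se)) se <- 0
    lim <- pmin(pmax(m + c(-1.96, 1.96) * se, 0), pi / 2)
    list(mean = sin(m)^2, lower = sin(lim[1])^2, upper = sin(lim[2])^2)
  })
}

#' Two-proportion test with continuity correction
#'
#' Chi-squared test of equality of two binomial proportions on the 2x2
#' table, with Yates continuity correction and 1 df (two-sided). Degenerate
#' margins (both samples all-success or both all-failure) return statistic
#' 0 and p = 1.
#'
#' @param k1,n1 successes and trials of the first sample.
#' @param k2,n2 successes and trials of the second sample.
#' @return list with \code{statistic} (chi-squared) and \code{p.value}.
#' @examples
#' twoProportionTest(1, 10, 8, 10)  # chi-squared ~ 7.27
#' @export
twoProportionTest <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2, n1 > 0, n2 > 0)
  if ((k1 + k2 == 0) || (k1 + k2 == n1 + n2))
    return(list(statistic = 0, p.value = 1))
  ht <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
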