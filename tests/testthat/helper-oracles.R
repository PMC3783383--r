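# Independent oracles and fixture builders used across the suite.

# brute-force Mahalanobis classifier: explicit per-observation loop,
# independent of the DfaModel code path
bruteMahalanobisAssign <- function(x, labels, newdata,
                                   prior = "equal") {
  x <- as.matrix(x); newdata <- as.matrix(newdata)
  groups <- sort(unique(as.character(labels)))
  means <- lapply(groups, function(g)
    colMeans(x[labels == g, , drop = FALSE]))
  centered <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    rows <- x[labels == groups[gi], , drop = FALSE]
    sweep(rows, 2, means[[gi]])
  }))
  S <- crossprod(centered) / (nrow(x) - length(groups))
  pr <- if (prior == "equal") rep(1 / length(groups), length(groups))
        else as.numeric(table(labels)[groups]) / nrow(x)
  apply(newdata, 1, function(row) {
    d2 <- vapply(seq_along(groups), function(gi) {
      d <- row - means[[gi]]
      as.numeric(t(d) %*% solve(S, d)) - 2 * log(pr[gi])
    }, numeric(1))
    groups[which.min(d2)]
  })
}

# Prim's algorithm on a dense distance matrix; returns the MST edge weights
bruteMstWeights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  inTree <- c(TRUE, rep(FALSE, n - 1))
  weights <- numeric(0)
  while (sum(inTree) < n) {
    best <- Inf
    for (i in which(inTree)) for (j in which(!inTree))
      if (d[i, j] < best) { best <- d[i, j]; pick <- j }
    weights <- c(weights, best)
    inTree[pick] <- TRUE
  }
  weights
}

# well-separated gaussian feature table: species means far apart relative
# to the within-species SD
makeSeparatedTable <- function(nSpecies, nPer, p = 5, gap = 50, sd = 1,
                               seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(nSpecies), function(s) {
    mu <- rnorm(p, mean = s * gap, sd = 5)
    vals <- matrix(rnorm(nPer * p, rep(mu, each = nPer), sd), nPer, p)
    df <- as.data.frame(vals)
    names(df) <- paste0("f", seq_len(p))
    df$species <- paste0("sp", s)
    df
  })
  out <- do.call(rbind, rows)
  out$temperature <- 25
  out
}

# single-row species profile for sampler edge cases
makeProfileRow <- function(species = "toy", n = 5, means = NULL,
                           ses = NULL) {
  feats <- allCharacters()
  if (is.null(means)) means <- setNames(rep(100, 7), feats)
  if (is.null(ses)) ses <- setNames(rep(1, 7), feats)
  row <- data.frame(species = species, collection_site = "lab",
                    n_individuals = n, superstructured = FALSE,
                    stringsAsFactors = FALSE)
  for (f in feats) {
    row[[paste0(f, "_mean")]] <- means[[f]]
    row[[paste0(f, "_se")]] <- ses[[f]]
  }
  row
}

roundHalfUp <- function(x) floor(x + 0.5)
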