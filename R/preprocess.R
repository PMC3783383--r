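# Temperature correction to a 25 degC reference and pooled standardization
# of feature columns.

#' Correct song features to a reference temperature
#'
#' Crickets are poikilothermic, so several song features drift with ambient
#' temperature. For each feature (within each species by default) the
#' feature is regressed on recording temperature by ordinary least squares;
#' when the slope is significant at \code{alpha}, every value is shifted
#' parallel to the fitted line to the target temperature
#' (\code{v + b * (targetTemp - T)}), which preserves individual residual
#' variation. Non-significant features are left untouched. Regression scopes
#' with fewer than 3 distinct temperatures are skipped with a warning.
#'
#' @param table a feature table (data.frame with \code{species},
#'   \code{temperature} and feature columns).
#' @param targetTemp reference temperature, degrees C (default 25).
#' @param alpha significance gate for the slope (default 0.05).
#' @param scope \code{"species"} to fit one regression per species per
#'   feature, \code{"pooled"} for one per feature over all individuals.
#' @param features feature columns to consider (default all seven).
#' @return the corrected table, with the per-regression report (slope,
#'   p-value, corrected flag) attached as attribute
#'   \code{"correctionReport"}; retrieve it with [correctionReport()].
#' @export
temperatureCorrect <- function(table, targetTemp = 25, alpha = 0.05,
                               scope = c("species", "pooled"),
                               features = allCharacters()) {
  scope <- match.arg(scope)
  stopifnot("temperature" %in% names(table),
            all(features %in% names(table)))
  groups <- if (scope == "species") split(seq_len(nrow(table)),
                                          table$species)
            else list(pooled = seq_len(nrow(table)))
  report <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    temps <- table$temperature[idx]
    if (length(unique(temps)) < 3L) {
      warning("scope '", g, "': fewer than 3 distinct temperatures; ",
              "regression skipped")
      next
    }
    for (f in features) {
      fit <- stats::lm(table[[f]][idx] ~ temps)
      co <- summary(fit)$coefficients
      b <- co["temps", "Estimate"]
      p <- co["temps", "Pr(>|t|)"]
      corrected <- is.finite(p) && p < alpha
      if (corrected)
        table[[f]][idx] <- table[[f]][idx] + b * (targetTemp - temps)
      report[[length(report) + 1L]] <-
        data.frame(scope = g, feature = f, slope = b, p_value = p,
                   corrected = corrected, stringsAsFactors = FALSE)
    }
  }
  attr(table, "correctionReport") <- if (length(report))
    do.call(rbind, report) else
    data.frame(scope = character(0), feature = character(0),
               slope = numeric(0), p_value = numeric(0),
               corrected = logical(0))
  table
}

#' @rdname temperatureCorrect
#' @param x a table returned by [temperatureCorrect()].
#' @export
correctionReport <- function(x) attr(x, "correctionReport")

#' Standardize feature columns
#'
#' Centers and scales the selected columns to mean 0 and SD 1 over all
#' pooled individuals (not per species): the clustering operates on overall
#' call similarity, so standardization must share one scale across taxa.
#'
#' @param table a feature table.
#' @param columns columns to standardize (default all seven features).
#' @return the table with standardized columns; per-column means and SDs
#'   are attached as attributes \code{"center"} and \code{"scale"}.
#' @export
standardizeFeatures <- function(table, columns = allCharacters()) {
  stopifnot(all(columns %in% names(table)))
  ctr <- vapply(table[columns], mean, numeric(1))
  scl <- vapply(table[columns], stats::sd, numeric(1))
  zero <- columns[!is.finite(scl) | scl == 0]
  if (length(zero))
    stop("zero-variance column(s): ", paste(zero, collapse = ", "))
  for (f in columns) table[[f]] <- (table[[f]] - ctr[[f]]) / scl[[f]]
  attr(table, "center") <- ctr
  attr(table, "scale") <- scl
  table
}
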