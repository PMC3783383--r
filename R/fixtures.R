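#' Names of the acoustic characters
#'
#' The five standard song features are call period, call duration, syllable
#' period, syllable duration (all ms) and dominant frequency (kHz). The
#' seven-character set adds the two chirp-superstructure statistics,
#' relative variance and constancy factor.
#'
#' @return character vector of feature column names.
#' @export
standardCharacters <- function() {
  c("call_period", "call_duration", "syllable_period", "syllable_duration",
    "dominant_frequency")
}

#' @rdname standardCharacters
#' @export
allCharacters <- function() {
  c(standardCharacters(), "relative_variance", "constancy_factor")
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "cricketsong",
                      mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    stop("fixture file not found: ", file, call. = FALSE)
  path
}

#' Reference song-feature profiles of the 14 study species
#'
#' Per-species means and standard errors of the seven acoustic characters,
#' with the number of recorded individuals and the collection site, for the
#' 14 Gryllinae call types the analyses are parameterized from. The two
#' species whose songs carry a chirp-group superstructure (very large
#' constancy factor and relative variance) are flagged.
#'
#' @return data.frame with one row per species and columns \code{species},
#'   \code{collection_site}, \code{<feature>_mean} and \code{<feature>_se}
#'   for each of the seven characters, \code{n_individuals}, and
#'   \code{superstructured}.
#' @examples
#' profiles <- loadReferenceProfiles()
#' nrow(profiles)            # 14 species
#' sum(profiles$n_individuals)  # 85 recorded individuals
#' @export
loadReferenceProfiles <- function() {
  prof <- utils::read.csv(.extdata("table1_song_features.csv"),
                          stringsAsFactors = FALSE)
  needed <- c("species", "collection_site",
              paste0(rep(allCharacters(), each = 2), c("_mean", "_se")),
              "n_individuals")
  missing <- setdiff(needed, names(prof))
  if (length(missing))
    stop("corrupted profile fixture; missing field(s): ",
         paste(missing, collapse = ", "))
  means <- prof[, paste0(allCharacters(), "_mean")]
  ses <- prof[, paste0(allCharacters(), "_se")]
  if (any(!is.finite(as.matrix(means))) || any(as.matrix(means) <= 0))
    stop("corrupted profile fixture: non-positive or missing feature mean")
  if (any(!is.finite(as.matrix(ses))) || any(as.matrix(ses) < 0))
    stop("corrupted profile fixture: negative or missing standard error")
  if (any(is.na(prof$n_individuals)) || any(prof$n_individuals < 1))
    stop("corrupted profile fixture: invalid n_individuals")
  # superstructured songs: chirp groups make the constancy factor several
  # times the mean chirp period
  prof$superstructured <- prof$species %in%
    c("Coiblemmus", "Velarifictorus_sp2")
  prof
}

#' Published per-replicate classification percentages
#'
#' The per-replicate percent-correct values of the randomized evaluation:
#' 9 taxa-group sizes (5-13) by 2 character sets (5 or 7 characters) by 10
#' replicates, for either the discriminant-function-analysis run
#' (\code{"table2"}) or the single-linkage cluster run (\code{"table3"}).
#'
#' @param tableId \code{"table2"} (DFA percentages) or \code{"table3"}
#'   (cluster-analysis percentages).
#' @return data.frame with columns \code{taxa_count}, \code{n_characters},
#'   \code{replicate}, \code{percent} (long format, 180 rows) plus the
#'   published row average in \code{printed_average}.
#' @examples
#' t3 <- loadPrintedResults("table3")
#' subset(t3, taxa_count == 5 & n_characters == 5)$percent
#' @export
loadPrintedResults <- function(tableId = c("table2", "table3")) {
  tableId <- match.arg(tableId)
  file <- switch(tableId,
                 table2 = "table2_dfa_percent.csv",
                 table3 = "table3_cluster_percent.csv")
  wide <- utils::read.csv(.extdata(file), stringsAsFactors = FALSE)
  repcols <- paste0("r", 1:10)
  if (!all(c("taxa_count", "n_characters", repcols) %in% names(wide)) ||
      nrow(wide) != 18L)
    stop("corrupted results fixture: ", file)
  long <- do.call(rbind, lapply(seq_len(nrow(wide)), function(i) {
    data.frame(taxa_count = wide$taxa_count[i],
               n_characters = wide$n_characters[i],
               replicate = 1:10,
               percent = as.numeric(wide[i, repcols]),
               printed_average = wide$printed_average[i])
  }))
  rownames(long) <- NULL
  long
}

#' Recover a success count from a rounded percentage
#'
#' The published cluster percentages are taxon-level proportions k/n rounded
#' to whole percent. For n at most 13 the rounding is injective, so the
#' underlying success count k can be recovered exactly; this rebuilds the
#' binomial successes/trials data the GLM is fitted to. Rounding is half-up
#' (62.5 prints as 63), matching the published tables.
#'
#' @param percent printed percentage, 0-100.
#' @param nTaxa number of taxa in the subset (the binomial trials), <= 13.
#' @return the unique integer k with \code{round(100 k / nTaxa) == percent}.
#' @examples
#' invertPercentage(60, 5)   # 3 of 5 taxa correct
#' invertPercentage(63, 8)   # 5 of 8 (62.5 printed as 63)
#' @export
invertPercentage <- function(percent, nTaxa) {
  stopifnot(length(percent) == 1L, length(nTaxa) == 1L,
            nTaxa >= 1, nTaxa <= 13)
  k <- which(floor(100 * (0:nTaxa) / nTaxa + 0.5) == percent) - 1L
  if (length(k) != 1L)
    stop("no success count k in 0..", nTaxa, " rounds to ", percent,
         "% - possible transcription error")
  k
}
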