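#' Daily laying records
#'
#' An N x 161 binary matrix of daily laying indicators over weeks 21-43
#' of age; day d belongs to week 21 + (d - 1) %/% 7.
#'
#' @param samples character vector of N sample identifiers.
#' @param matrix N x D matrix of 0/1 daily indicators (D = 161 for the
#'   full cycle).
#' @return an object of class \code{laying_records}.
#' @export
laying_records <- function(samples, matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(samples))
    stop("matrix rows must match samples")
  if (!all(matrix %in% c(0L, 1L))) stop("laying records must be binary")
  storage.mode(matrix) <- "integer"
  colnames(matrix) <- paste0("day_", seq_len(ncol(matrix)))
  structure(list(samples = as.character(samples), matrix = matrix),
            class = "laying_records")
}

#' @export
#' @method print laying_records
print.laying_records <- function(x, ...) {
  cat("laying_records:", length(x$samples), "individuals x",
      ncol(x$matrix), "days; overall laying rate",
      round(mean(x$matrix), 3), "\n")
  invisible(x)
}

# Day indices (within the 161-day cycle) covered by a vector of weeks of
# age: week w covers days 7(w-21)+1 ... 7(w-21)+7.
stage_days <- function(weeks) {
  unlist(lapply(weeks, function(w) (7L * (w - 21L) + 1L):(7L * (w - 21L) + 7L)))
}

#' Clutch and interval structure of a daily laying vector
#'
#' A clutch is a maximal run of consecutive laying days; an interval is a
#' maximal run of non-laying days strictly between the first and last
#' egg (leading and trailing zero runs are neither clutches nor
#' intervals).
#'
#' @param day_vector binary vector of daily laying indicators for one
#'   individual over one stage.
#' @return list with \code{clutches} (run lengths of 1s) and
#'   \code{intervals} (run lengths of 0s between first and last egg);
#'   both empty for an all-zero vector.
#' @export
detect_clutches <- function(day_vector) {
  stopifnot(all(day_vector %in% c(0, 1)))
  if (!any(day_vector == 1))
    return(list(clutches = integer(0), intervals = integer(0)))
  r <- rle(as.integer(day_vector))
  clutches <- r$lengths[r$values == 1L]
  inner <- seq_along(r$values)
  ones <- which(r$values == 1L)
  inner <- inner[inner > min(ones) & inner < max(ones)]
  intervals <- r$lengths[inner][r$values[inner] == 0L]
  list(clutches = as.integer(clutches), intervals = as.integer(intervals))
}

#' The thirteen derived egg-laying traits
#'
#' Names and desirable directions of the derived traits: five production
#' traits (EV, WMLR, WEV, BWMLR, BWEV), three clutch traits (CPN, TCS,
#' ECI) and five interval traits (LIT, AILI, TILI, MILI, II).
#' Direction +1 means higher is better (e.g. ECI), -1 lower is better
#' (e.g. TILI); variability traits are coded lower-is-better.
#'
#' @return data.frame with columns \code{trait} and \code{direction}.
#' @export
trait_directions <- function() {
  data.frame(
    trait = c("EV", "WMLR", "WEV", "BWMLR", "BWEV",
              "CPN", "TCS", "ECI",
              "LIT", "AILI", "TILI", "MILI", "II"),
    direction = c(-1, 1, -1, 1, -1,
                  -1, 1, 1,
                  1, -1, -1, -1, -1))
}

# Compute the 13 derived traits for one individual over one stage's days.
derive_one <- function(v) {
  nd <- length(v)
  weeks <- ceiling(seq_len(nd) / 7)
  wk_counts <- tapply(v, weeks, sum)
  n_wk <- length(wk_counts)
  out <- c(EV = NA, WMLR = NA, WEV = NA, BWMLR = NA, BWEV = NA,
           CPN = NA, TCS = NA, ECI = NA,
           LIT = NA, AILI = NA, TILI = NA, MILI = NA, II = NA)
  out["EV"] <- if (n_wk > 1) var(wk_counts) else NA
  out["WMLR"] <- max(wk_counts) / 7
  out["WEV"] <- if (n_wk > 1) var(wk_counts / 7) else NA
  if (n_wk >= 2) {
    nbw <- n_wk %/% 2
    bw <- vapply(seq_len(nbw), function(k)
      wk_counts[2 * k - 1] + wk_counts[2 * k], numeric(1))
    out["BWMLR"] <- max(bw) / 14
    out["BWEV"] <- if (nbw > 1) var(bw / 14) else NA
  }
  cs <- detect_clutches(v)
  out["CPN"] <- length(cs$clutches)
  out["TCS"] <- sum(cs$clutches)
  eligible <- cs$clutches[cs$clutches >= 2]
  if (length(eligible) > 0) {
    out["ECI"] <- sum(eligible) / length(eligible)
    out["II"] <- length(cs$intervals) / length(eligible)
  }
  eggs <- which(v == 1)
  out["LIT"] <- if (length(eggs)) max(eggs) - min(eggs) + 1 else 0
  out["TILI"] <- sum(cs$intervals)
  out["MILI"] <- if (length(cs$intervals)) max(cs$intervals) else 0
  out["AILI"] <- if (length(cs$intervals)) mean(cs$intervals) else 0
  out
}

#' Derive the 13 egg-laying traits per stage
#'
#' For each stage of the cycle, computes per individual: egg-production
#' variance EV (variance of weekly egg counts), weekly maximum laying
#' rate WMLR (max weekly eggs / 7), weekly egg-production variance WEV
#' (variance of weekly laying rate), their bi-weekly analogues BWMLR and
#' BWEV (consecutive week pairs; a trailing odd week is dropped), clutch
#' period number CPN, total clutch size TCS, effective clutch intensity
#' ECI = total eggs in clutches of length >= 2 divided by the number of
#' such clutches, laying interval time LIT (days from first to last egg,
#' inclusive), and the interval traits AILI / TILI / MILI (mean / total /
#' maximum interval length) and interclutch interval II (number of
#' intervals divided by the number of eligible clutches). Individuals
#' with no clutch of length >= 2 get missing ECI and II.
#'
#' @param records a \code{\link{laying_records}} object.
#' @param stages a \code{\link{segment_stages}} stage definition.
#' @return data.frame of traits, one row per individual (rownames =
#'   samples), columns named \code{<stage>-<trait>} (e.g.
#'   \code{"up-ECI"}).
#' @export
derive_traits <- function(records, stages) {
  stopifnot(inherits(records, "laying_records"),
            inherits(stages, "stage_definition"))
  n_days <- ncol(records$matrix)
  cols <- list()
  for (s in names(stages)) {
    days <- stage_days(stages[[s]])
    if (max(days) > n_days)
      stop("stage ", s, " extends past the recorded days")
    if (length(days) < 14)
      warning("stage ", s, " shorter than 14 days; bi-weekly traits missing")
    tt <- t(apply(records$matrix[, days, drop = FALSE], 1L, derive_one))
    colnames(tt) <- paste(s, colnames(tt), sep = "-")
    cols[[s]] <- tt
  }
  out <- as.data.frame(do.call(cbind, cols))
  rownames(out) <- records$samples
  out
}

#' Single-pass 3-sigma outlier filter
#'
#' Per trait column, values outside mean +/- 3 SD (computed on the
#' non-missing values) are set to missing. A single pass only; columns
#' with zero SD are left untouched.
#'
#' @param table data.frame of numeric trait columns.
#' @return the filtered data.frame; the number of values removed per
#'   column is attached as attribute \code{"n_removed"}.
#' @export
remove_outliers_3sigma <- function(table) {
  removed <- integer(ncol(table))
  names(removed) <- colnames(table)
  for (j in seq_len(ncol(table))) {
    x <- table[[j]]
    if (!is.numeric(x)) next
    m <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) next
    out <- !is.na(x) & abs(x - m) > 3 * s
    table[[j]][out] <- NA
    removed[j] <- sum(out)
  }
  attr(table, "n_removed") <- removed
  table
}

#' Fill missing trait values with the column mean
#'
#' A deliberately simple completion utility for downstream analyses that
#' need complete columns; it makes no claim to the statistical fidelity
#' of a model-based imputation.
#'
#' @param table data.frame of numeric trait columns.
#' @return the table with missing numeric values replaced by column means.
#' @export
mean_fill <- function(table) {
  for (j in seq_len(ncol(table))) {
    x <- table[[j]]
    if (is.numeric(x) && anyNA(x)) table[[j]][is.na(x)] <- mean(x, na.rm = TRUE)
  }
  table
}
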