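#' Interview-based severity score for attenuated positive symptoms
#'
#' Five attenuated-positive-symptom interview ratings on a 0--6 scale are
#' dichotomized (0--2 absent, 3--6 present) and summed, giving a severity
#' score from 0 to 5.
#'
#' @param ratings integer vector of length 5 with values in 0..6.
#' @return integer severity score in 0..5.
#' @examples
#' aps_severity(c(4, 2, 3, 0, 6)) # 3
#' @export
aps_severity <- function(ratings) {
  if (length(ratings) != 5)
    stop("expected 5 attenuated-positive-symptom ratings, got ",
         length(ratings), call. = FALSE)
  bad <- which(is.na(ratings) | ratings != round(ratings) |
                 ratings < 0 | ratings > 6)
  if (length(bad))
    stop("rating out of range 0..6 at position ",
         paste(bad, collapse = ", "), call. = FALSE)
  as.integer(sum(ratings >= 3))
}

#' Interview-based severity score for basic symptoms
#'
#' Fourteen basic-symptom interview ratings (0--6 frequency scale plus the
#' special codes 7 trait, 8 present with unknown frequency, 9 undecidable)
#' are dichotomized -- codes 0, 7 and 9 count as absent, codes 1--6 and 8 as
#' present -- and summed, giving a severity score from 0 to 14.
#'
#' @param ratings integer vector of length 14 with values in 0..9.
#' @return integer severity score in 0..14.
#' @examples
#' bs_severity(c(7, 9, 1, 6, 8, rep(0, 9))) # 3
#' @export
bs_severity <- function(ratings) {
  if (length(ratings) != 14)
    stop("expected 14 basic-symptom ratings, got ", length(ratings),
         call. = FALSE)
  bad <- which(is.na(ratings) | ratings != round(ratings) |
                 ratings < 0 | ratings > 9)
  if (length(bad))
    stop("rating out of range 0..9 at position ",
         paste(bad, collapse = ", "), call. = FALSE)
  as.integer(sum(ratings %in% c(1:6, 8)))
}

#' Default EMA item catalog
#'
#' The 21 momentary symptom items: 14 basic-symptom (BS) items and 7
#' attenuated/brief-psychotic (APS/B(L)IPS) items, each labelled perceptive or
#' nonperceptive.  The instrument split (14 + 7) follows the protocol; the
#' perceptive/nonperceptive labelling here is a synthetic default (the study's
#' exact item mapping is not part of the published tables) and should be
#' overridden with a study-specific catalog where available.
#'
#' @return data.frame with columns `item_id`, `instrument` ("SPI" for BS
#'   items, "SIPS" for APS/B(L)IPS items) and `partition` ("perceptive" or
#'   "nonperceptive").
#' @export
default_item_catalog <- function() {
  data.frame(
    item_id = sprintf("item_%02d", 1:21),
    instrument = c(rep("SPI", 14), rep("SIPS", 7)),
    partition = c(rep("nonperceptive", 10), rep("perceptive", 4), # BS
                  rep("nonperceptive", 5), rep("perceptive", 2))  # APS
  )
}

check_catalog <- function(catalog) {
  stopifnot(all(c("item_id", "instrument", "partition") %in% names(catalog)))
  if (nrow(catalog) != 21)
    stop("item catalog must describe 21 items", call. = FALSE)
  if (sum(catalog$instrument == "SPI") != 14 ||
      sum(catalog$instrument == "SIPS") != 7)
    stop("item catalog must contain 14 SPI (BS) and 7 SIPS (APS/B(L)IPS) ",
         "items", call. = FALSE)
  if (!all(catalog$partition %in% c("perceptive", "nonperceptive")))
    stop("partition labels must be 'perceptive' or 'nonperceptive'",
         call. = FALSE)
  invisible(catalog)
}

#' Momentary composite scores
#'
#' Computes, for each observation, the mean over all 21 momentary symptom
#' items (`mchr`), the means over the APS/B(L)IPS and BS items, and the means
#' over the perceptive and nonperceptive items.  By construction
#' `(7 * aps + 14 * bs) / 21 == mchr`.
#'
#' @param items numeric vector of length 21 or a matrix/data.frame with 21
#'   columns in catalog order (one row per observation).
#' @param catalog an item catalog, see [default_item_catalog()].
#' @param allow_partial if `FALSE` (default) any missing item is an error,
#'   mirroring an app that enforces complete responses; if `TRUE` composites
#'   are means of the available items.
#' @return a data.frame with columns `mchr`, `aps`, `bs`, `perc`, `nonp`.
#' @export
ema_composites <- function(items, catalog = default_item_catalog(),
                           allow_partial = FALSE) {
  check_catalog(catalog)
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  if (ncol(items) != 21)
    stop("expected 21 items per observation, got ", ncol(items),
         call. = FALSE)
  if (!allow_partial && anyNA(items))
    stop("missing item ratings; set allow_partial = TRUE to average over ",
         "available items", call. = FALSE)
  grp_mean <- function(sel) rowMeans(items[, sel, drop = FALSE],
                                     na.rm = allow_partial)
  data.frame(
    mchr = grp_mean(rep(TRUE, 21)),
    aps  = grp_mean(catalog$instrument == "SIPS"),
    bs   = grp_mean(catalog$instrument == "SPI"),
    perc = grp_mean(catalog$partition == "perceptive"),
    nonp = grp_mean(catalog$partition == "nonperceptive")
  )
}

#' Root mean of squared successive differences
#'
#' Instability statistic over the successive observed values of a momentary
#' series; missing values are dropped first, so the statistic ignores the
#' length of gaps between observations.
#'
#' @param x numeric vector in temporal order, `NA` for missing.
#' @return nonnegative scalar; `NA` if fewer than two observed values.
#' @export
rmssd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sqrt(mean(diff(x)^2))
}

#' Individual summary statistics of EMA variables
#'
#' Per-person mean, median, standard deviation and RMSSD of each EMA
#' variable, computed over that person's observed prompts in temporal order,
#' plus group-level "i"-statistics: the unweighted mean (and SD) over persons
#' of each individual statistic (e.g. the iMedian is the mean over the
#' person-wise medians).
#'
#' @param data long data.frame with a `person_id` column, an ordering column
#'   (`slot`, or `day` + `time`), and the variables in `vars`.
#' @param vars character vector of variable names to summarize.
#' @return a list with `person` (one row per person and variable) and `group`
#'   (one row per variable and statistic, columns `mean` and `sd`). Persons
#'   with fewer than two observed values of a variable are excluded from that
#'   variable's summaries with a warning.
#' @export
individual_summaries <- function(data, vars) {
  stopifnot("person_id" %in% names(data), all(vars %in% names(data)))
  if ("slot" %in% names(data)) {
    data <- data[order(data$person_id, data$slot), ]
  } else if (all(c("day", "time") %in% names(data))) {
    data <- data[order(data$person_id, data$day, data$time), ]
  }
  rows <- list()
  dropped <- character()
  for (v in vars) {
    for (pid in unique(data$person_id)) {
      x <- data[[v]][data$person_id == pid]
      xo <- x[!is.na(x)]
      if (length(xo) < 2) {
        dropped <- c(dropped, paste0(pid, "/", v))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        person_id = pid, variable = v, n = length(xo),
        mean = mean(xo), median = stats::median(xo), sd = stats::sd(xo),
        rmssd = rmssd(x))
    }
  }
  if (length(dropped))
    warning("excluded (fewer than 2 observations): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) " ..." else "", call. = FALSE)
  person <- do.call(rbind, rows)
  stats_n <- c("mean", "median", "sd", "rmssd")
  group <- do.call(rbind, lapply(vars, function(v) {
    sub <- person[person$variable == v, , drop = FALSE]
    do.call(rbind, lapply(stats_n, function(s) {
      data.frame(variable = v, statistic = paste0("i", s),
                 mean = mean(sub[[s]]), sd = stats::sd(sub[[s]]))
    }))
  }))
  list(person = person, group = group)
}
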