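#' Construct an ordinal response matrix
#'
#' The raw input of the pipeline: an n-subjects by p-items integer matrix of
#' category scores in \code{1..K} with no missing values.
#'
#' @param values integer matrix (subjects in rows, items in columns)
#' @param item_codes character vector of item codes (defaults to column names)
#' @param K number of response categories (7 for the BPRS)
#' @return the matrix with class \code{ordinal_matrix} and attribute \code{K}
#' @export
ordinal_matrix <- function(values, item_codes = colnames(values), K = 7L) {
  values <- as.matrix(values)
  if (is.null(item_codes)) {
    item_codes <- paste0("V", seq_len(ncol(values)))
  }
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("need at least 2 subjects and 2 items")
  }
  if (anyNA(values)) stop("ordinal matrix must not contain missing values")
  if (!all(values == round(values))) stop("all entries must be integers")
  if (any(values < 1 | values > K)) {
    bad <- which(values < 1 | values > K, arr.ind = TRUE)[1, ]
    stop(sprintf("value out of range [1, %d] at row %d, column %s",
                 K, bad[1], item_codes[bad[2]]))
  }
  storage.mode(values) <- "integer"
  colnames(values) <- item_codes
  structure(values, K = as.integer(K), class = c("ordinal_matrix", "matrix"))
}

#' Load ordinal responses from CSV
#'
#' Reads a comma-separated file with a header row whose column names match
#' the catalog's item codes (any order); columns are reordered to catalog
#' order. Rows containing missing cells or values outside \code{[1, K]} are
#' handled per \code{policy}: \code{"reject-file"} (default) fails with the
#' offending cell; \code{"drop-row"} removes them and records the count in
#' attribute \code{dropped_rows}.
#'
#' @param path CSV path
#' @param catalog an \code{item_catalog} (defaults to the packaged BPRS one)
#' @param K number of categories
#' @param policy missing/out-of-range handling, \code{"reject-file"} or
#'   \code{"drop-row"}
#' @return an \code{ordinal_matrix}
#' @export
load_responses <- function(path, catalog = bprs_catalog(), K = 7L,
                           policy = c("reject-file", "drop-row")) {
  policy <- match.arg(policy)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(catalog$code, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(df), catalog$code)
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  }
  df <- df[, catalog$code, drop = FALSE]
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop(sprintf("non-integer cell at row %d, column %s",
                   if (is.na(bad)) 1L else bad, names(df)[j]))
    }
    nonint <- which(!is.na(col) & col != round(col))
    if (length(nonint)) {
      stop(sprintf("non-integer cell at row %d, column %s",
                   nonint[1], names(df)[j]))
    }
  }
  m <- as.matrix(df)
  bad_cell <- is.na(m) | m < 1 | m > K
  if (any(bad_cell)) {
    if (policy == "reject-file") {
      idx <- which(bad_cell, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "invalid value at row %d, column %s (must be an integer in [1, %d])",
        idx[1], colnames(m)[idx[2]], K))
    }
    keep <- rowSums(bad_cell) == 0
    n_drop <- sum(!keep)
    message(sprintf("dropped %d row(s) with missing/out-of-range values",
                    n_drop))
    m <- m[keep, , drop = FALSE]
  } else {
    n_drop <- 0L
  }
  out <- ordinal_matrix(m, catalog$code, K)
  attr(out, "dropped_rows") <- as.integer(n_drop)
  out
}

#' Per-item frequency table with means and standard deviations
#'
#' Tabulates category counts per item and derives the mean and SD (n - 1
#' denominator) of each item, either from raw responses or directly from a
#' pre-tabulated items-by-categories count matrix. Percentages, and the
#' reporting columns used by [write_item_summary()], are rounded half up to
#' one decimal in the style of clinical frequency tables.
#'
#' @param x an \code{ordinal_matrix}, or an items-by-K matrix of counts with
#'   item codes as row names
#' @param K number of categories (taken from \code{x} when it is an
#'   \code{ordinal_matrix})
#' @return a data frame of class \code{item_frequency_table} with columns
#'   \code{code}, \code{mean}, \code{sd} (full precision),
#'   \code{count_1..count_K} and \code{pct_1..pct_K}; attribute \code{n}
#'   holds the per-item total.
#' @export
#' @examples
#' counts <- rbind(A = c(840, 258, 199, 87, 37, 13, 4),
#'                 B = c(530, 234, 259, 196, 118, 80, 21))
#' s <- summarize_items(counts)
#' round_half_up(s$mean, 1)
summarize_items <- function(x, K = NULL) {
  if (inherits(x, "ordinal_matrix")) {
    K <- attr(x, "K")
    counts <- t(apply(unclass(x), 2, function(col) {
      tabulate(col, nbins = K)
    }))
    rownames(counts) <- colnames(x)
  } else {
    counts <- as.matrix(x)
    K <- K %||% ncol(counts)
    if (is.null(rownames(counts))) {
      rownames(counts) <- paste0("V", seq_len(nrow(counts)))
    }
  }
  n <- rowSums(counts)
  cats <- seq_len(K)
  tot <- counts %*% cats
  mean_i <- as.numeric(tot / n)
  ssq <- counts %*% (cats^2)
  var_i <- as.numeric((ssq - n * mean_i^2) / (n - 1))
  var_i[var_i < 0] <- 0  # guard float noise for degenerate items
  sd_i <- sqrt(var_i)
  pct <- round_half_up(100 * counts / n, 1)
  out <- data.frame(code = rownames(counts), mean = mean_i, sd = sd_i,
                    stringsAsFactors = FALSE, row.names = NULL)
  cn <- as.data.frame(counts)
  names(cn) <- paste0("count_", cats)
  pc <- as.data.frame(pct)
  names(pc) <- paste0("pct_", cats)
  out <- cbind(out, cn, pc)
  attr(out, "n") <- n
  class(out) <- c("item_frequency_table", "data.frame")
  out
}

#' Write an item summary as TSV
#'
#' Columns: \code{item} (code), \code{mean} and \code{sd} rounded half up to
#' one decimal, then \code{count_1..count_K}.
#'
#' @param tab an \code{item_frequency_table}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_item_summary <- function(tab, path) {
  cc <- grep("^count_", names(tab), value = TRUE)
  out <- data.frame(item = tab$code,
                    mean = sprintf("%.1f", round_half_up(tab$mean, 1)),
                    sd = sprintf("%.1f", round_half_up(tab$sd, 1)),
                    tab[, cc, drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an item summary TSV
#' @param path TSV path written by [write_item_summary()]
#' @return data frame
#' @export
read_item_summary <- function(path) {
  read.csv(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
}

#' Flag high-dose antipsychotic treatment
#'
#' A prescription is flagged high-dose when the chlorpromazine-equivalent
#' cumulative dose is at least 1000 mg/day, or the ratio of prescribed daily
#' dose to defined daily dose is at least 1.5. Both thresholds are inclusive.
#'
#' @param cpz_equivalent chlorpromazine-equivalent dose in mg/day
#' @param pdd_ddd_ratio prescribed/defined daily dose ratio (dimensionless)
#' @return logical vector
#' @export
#' @examples
#' flag_high_dose(1000, 0.5)  # TRUE
#' flag_high_dose(999, 1.49)  # FALSE
flag_high_dose <- function(cpz_equivalent, pdd_ddd_ratio) {
  if (any(cpz_equivalent < 0) || any(pdd_ddd_ratio < 0)) {
    stop("doses and dose ratios must be nonnegative")
  }
  cpz_equivalent >= 1000 | pdd_ddd_ratio >= 1.5
}

#' Packaged BPRS category-frequency counts (reference cohort, n = 1438)
#'
#' Item-by-category counts of the 18 BPRS items in the multinational
#' schizophrenia cohort the packaged marginals are calibrated to. Rows are
#' items in catalog order; columns are categories 1..7. Every row sums
#' to 1438.
#'
#' @return an 18 x 7 integer matrix with item codes as row names
#' @export
bprs_reference_counts <- function() {
  counts <- rbind(
    SOM = c(840, 258, 199,  87,  37, 13,  4),
    ANX = c(596, 348, 290, 143,  44, 16,  1),
    EMO = c(511, 274, 294, 221,  85, 42, 11),
    CON = c(599, 251, 265, 176, 102, 32, 13),
    GUI = c(1016, 237, 140, 32,   7,  4,  2),
    TEN = c(656, 336, 286, 121,  31,  8,  0),
    MAN = c(1090, 148, 117, 56,  18,  9,  0),
    GRA = c(1107, 140,  97, 63,  14, 12,  5),
    DEP = c(804, 301, 233,  74,  14,  9,  3),
    HOS = c(807, 256, 169, 136,  47, 15,  8),
    SUS = c(587, 248, 269, 201,  81, 41, 11),
    HAL = c(530, 234, 259, 196, 118, 80, 21),
    MOT = c(898, 244, 158,  82,  37, 15,  4),
    UNC = c(814, 273, 182, 103,  38, 22,  6),
    THO = c(578, 239, 251, 181, 118, 54, 17),
    BLU = c(572, 285, 285, 162,  84, 43,  7),
    EXC = c(1001, 184, 113, 77,  49, 13,  1),
    DIS = c(1144, 162,  87, 30,   7,  3,  5)
  )
  colnames(counts) <- as.character(1:7)
  storage.mode(counts) <- "integer"
  counts
}

#' Packaged cohort descriptive counts (reference cohort, n = 1438)
#'
#' Counts of the discrete descriptive variables of the reference cohort,
#' from which percentages (of n = 1438) are recomputed.
#'
#' @return named integer vector, with attribute \code{n}
#' @export
cohort_reference_counts <- function() {
  x <- c(
    sex_male = 830L, sex_female = 608L,
    country_india = 400L, country_indonesia = 261L, country_japan = 98L,
    country_malaysia = 299L, country_taiwan = 380L,
    dur_illness_lt3m = 52L, dur_illness_3_6m = 38L, dur_illness_6_12m = 46L,
    dur_illness_1_5y = 274L, dur_illness_5_10y = 240L,
    dur_illness_10_20y = 429L, dur_illness_gt20y = 359L,
    dup_lt3m = 524L, dup_3_12m = 492L, dup_1_5y = 270L, dup_gt5y = 152L,
    inpatient = 664L, unemployed = 237L,
    antipsychotic_polypharmacy = 536L, adjunctive_mood_stabilizer = 142L,
    adjunctive_antidepressant = 129L, adjunctive_antiparkinsonian = 560L,
    high_dose_antipsychotic = 161L, long_acting_injectable = 305L,
    clozapine = 293L, electroconvulsive_therapy = 42L,
    cannabis_use_lifetime = 119L
  )
  attr(x, "n") <- 1438L
  x
}
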