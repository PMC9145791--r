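# Event-table (NONMEM-style CSV) reading/writing and data utilities.

.kpd_cov_cols <- c(SEX = "sex", DM = "dm", BSA = "bsa", AGE = "age",
                   ALT = "alt", CLCR = "clcr", HTN = "htn", TB = "tb",
                   SMOK = "smoking", ECOG = "ecog")

#' Absolute neutrophil count from a differential blood count
#'
#' `ANC = WBC * neutrophil% / 100`.
#'
#' @param wbc white blood cell count, 1e9 cells/L.
#' @param neut_pct neutrophil percentage, 0-100.
#' @return ANC, 1e9 cells/L.
#' @examples
#' compute_anc(7.93, 65)
#' @export
compute_anc <- function(wbc, neut_pct) {
  if (any(wbc < 0)) stop("wbc must be non-negative", call. = FALSE)
  if (any(neut_pct < 0 | neut_pct > 100))
    stop("neut_pct must be within [0, 100]", call. = FALSE)
  wbc * neut_pct / 100
}

#' Convert subject records to an event table
#'
#' One row per dose (`EVID = 1`, `AMT`, `DRUG`) or observation (`EVID = 0`,
#' `DV`, `MDV = 0`), sorted by subject and time with observations before
#' doses at equal times (pre-dose sampling). Covariates are repeated on
#' every row.
#'
#' @param dataset list of subject records.
#' @return `data.frame` with columns `ID`, `TIME`, `EVID`, `AMT`, `DRUG`,
#'   `DV`, `MDV` and available covariate columns.
#' @export
as_event_table <- function(dataset) {
  rows <- lapply(dataset, function(s) {
    nd <- nrow(s$doses)
    no <- nrow(s$observations)
    d <- data.frame(
      ID = s$id,
      TIME = c(s$observations$time, s$doses$time),
      EVID = c(rep(0L, no), rep(1L, nd)),
      AMT = c(rep(NA_real_, no), s$doses$amount),
      DRUG = c(rep(NA_character_, no), s$doses$drug),
      DV = c(s$observations$anc, rep(NA_real_, nd)),
      MDV = c(rep(0L, no), rep(1L, nd)),
      stringsAsFactors = FALSE)
    for (col in names(.kpd_cov_cols)) {
      v <- s$covariates[[.kpd_cov_cols[[col]]]]
      if (!is.null(v)) d[[col]] <- v
    }
    d[order(d$TIME, d$EVID), ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

validate_event_table <- function(df) {
  req <- c("ID", "TIME", "EVID", "AMT", "DRUG", "DV", "MDV")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (id in unique(df$ID)) {
    rows <- which(df$ID == id)
    tt <- df$TIME[rows]
    if (is.unsorted(tt))
      stop("unsorted times for subject ", id, " (row ",
           rows[which(diff(tt) < 0)[1] + 1L], ")", call. = FALSE)
  }
  key <- paste(df$ID, df$TIME, df$EVID, df$DRUG)
  if (anyDuplicated(key)) {
    stop("duplicate (id, time, evid) row at line ",
         which(duplicated(key))[1], call. = FALSE)
  }
  dose <- df$EVID == 1L
  if (any(dose & (is.na(df$AMT) | df$AMT <= 0)))
    stop("dose row with missing or non-positive AMT at line ",
         which(dose & (is.na(df$AMT) | df$AMT <= 0))[1], call. = FALSE)
  if (any(dose & !(df$DRUG %in% names(.kpd_drug_codes))))
    stop("dose row with unknown drug label '",
         df$DRUG[which(dose & !(df$DRUG %in% names(.kpd_drug_codes)))[1]],
         "'", call. = FALSE)
  obs <- df$EVID == 0L
  if (any(obs & df$MDV == 0L & is.na(df$DV)))
    stop("observation row with MDV = 0 but missing DV at line ",
         which(obs & df$MDV == 0L & is.na(df$DV))[1], call. = FALSE)
  if (any(obs & df$MDV == 0L & df$DV < 0))
    stop("negative DV at line ",
         which(obs & df$MDV == 0L & df$DV < 0)[1], call. = FALSE)
  invisible(df)
}

#' Convert an event table back to subject records
#'
#' @param df event table (see [as_event_table()]); validated first.
#' @return List of subject records (class `"kpd_dataset"`).
#' @export
as_subject_records <- function(df) {
  validate_event_table(df)
  ids <- unique(df$ID)
  subjects <- lapply(ids, function(id) {
    rows <- df[df$ID == id, , drop = FALSE]
    dose <- rows[rows$EVID == 1L, , drop = FALSE]
    obs <- rows[rows$EVID == 0L & rows$MDV == 0L, , drop = FALSE]
    cov <- list()
    for (col in names(.kpd_cov_cols)) {
      if (!is.null(rows[[col]])) cov[[.kpd_cov_cols[[col]]]] <- rows[[col]][1]
    }
    structure(list(
      id = id,
      covariates = as.data.frame(cov),
      doses = data.frame(time = dose$TIME, drug = dose$DRUG,
                         amount = dose$AMT, stringsAsFactors = FALSE),
      observations = data.frame(time = obs$TIME, anc = obs$DV),
      etas_true = NULL), class = "kpd_subject")
  })
  structure(subjects, class = "kpd_dataset")
}

#' Write a dataset to the event CSV format
#'
#' Comma-separated with a header row; missing cells written as `"."`; times
#' rounded to 1e-6 day resolution.
#'
#' @param dataset list of subject records (or an event-table data.frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  df <- if (is.data.frame(dataset)) dataset else as_event_table(dataset)
  df$TIME <- round(df$TIME, 6)
  out <- as.data.frame(lapply(df, function(col) {
    s <- as.character(col)
    s[is.na(col)] <- "."
    s
  }), stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset from the event CSV format
#'
#' Reads, validates (row numbers reported on failure) and converts to
#' subject records. `"."` denotes missing.
#'
#' @param path CSV file path.
#' @param impute apply [impute_covariates()] to fill missing covariate cells.
#' @return List of subject records (class `"kpd_dataset"`).
#' @export
read_dataset <- function(path, impute = FALSE) {
  df <- read.csv(path, na.strings = ".", stringsAsFactors = FALSE)
  num <- intersect(c("ID", "TIME", "AMT", "DV", "MDV", "EVID",
                     names(.kpd_cov_cols)), names(df))
  for (col in num) if (!col %in% "DRUG") df[[col]] <- as.numeric(df[[col]])
  df$EVID <- as.integer(df$EVID)
  df$MDV <- as.integer(df$MDV)
  if (impute) df <- impute_covariates(df)
  as_subject_records(df)
}

#' Impute missing covariate values within subject
#'
#' Interior gaps are replaced by the mean of the nearest previous and next
#' non-missing values; trailing gaps are carried forward; leading gaps are
#' carried backward. A covariate that is missing on every row of a subject
#' is an error naming the subject and column.
#'
#' @param df event table with covariate columns.
#' @param cols covariate columns to impute (default: all recognised ones
#'   present).
#' @return The table with no missing values in the imputed columns;
#'   non-missing cells are never altered.
#' @export
impute_covariates <- function(df, cols = intersect(names(.kpd_cov_cols),
                                                   names(df))) {
  for (id in unique(df$ID)) {
    rows <- which(df$ID == id)
    for (col in cols) {
      x <- df[[col]][rows]
      if (!anyNA(x)) next
      if (all(is.na(x)))
        stop("covariate '", col, "' entirely missing for subject ", id,
             call. = FALSE)
      ok <- which(!is.na(x))
      for (i in which(is.na(x))) {
        prev <- ok[ok < i]
        nxt <- ok[ok > i]
        x[i] <- if (length(prev) && length(nxt))
          (x[max(prev)] + x[min(nxt)]) / 2
        else if (length(prev)) x[max(prev)]
        else x[min(nxt)]
      }
      df[[col]][rows] <- x
    }
  }
  df
}
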