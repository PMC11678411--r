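#' Sparse therapeutic drug monitoring PK datasets
#'
#' A `pk_dataset` holds one or more subjects, each with an oral dosing
#' history, concentration observations, and a covariate record. Times are
#' hours since the subject's first recorded dose (the origin is shifted at
#' read time), doses are mg, concentrations are ug/mL (mg and L give mg/L,
#' identical to ug/mL, so no unit conversion ever happens).
#'
#' @param subjects list of subjects as built by [pk_subject()]
#' @param provenance free-text note on where the data came from
#' @return an object of class `pk_dataset`
#' @seealso [read_pk_dataset()], [write_pk_dataset()], [validate_pk_dataset()]
#' @export
pk_dataset <- function(subjects, provenance = "") {
  if (!length(subjects)) {
    stop_gabapk("a pk_dataset needs at least one subject",
                class = "gabapk_validation_error")
  }
  ids <- vapply(subjects, function(s) s$id, character(1))
  if (anyDuplicated(ids)) {
    stop_gabapk("duplicate subject ids: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "),
                class = "gabapk_validation_error")
  }
  names(subjects) <- ids
  structure(
    list(subjects = subjects,
         units = c(dose = "mg", time = "h", conc = "ug/mL"),
         provenance = provenance),
    class = "pk_dataset")
}

#' Build a single subject record
#'
#' @param id subject identifier (coerced to character)
#' @param doses data.frame with columns `time` (h) and `amount` (mg),
#'   sorted ascending in time
#' @param observations data.frame with columns `time` (h), `conc` (ug/mL)
#'   and optionally `bloq` (below limit of quantification flag)
#' @param covariates one-row data.frame of covariate values (AGE, SEX,
#'   RACE, WT, HT, SCR, FPG, DM, plus any derived columns)
#' @export
pk_subject <- function(id, doses, observations, covariates = NULL) {
  id <- as.character(id)
  if (!nrow(doses)) {
    stop_gabapk("subject ", id, " has no dose events",
                class = "gabapk_validation_error")
  }
  if (!nrow(observations)) {
    stop_gabapk("subject ", id, " has no observations",
                class = "gabapk_validation_error")
  }
  if (is.unsorted(doses$time)) {
    stop_gabapk("subject ", id, ": dose times are not ascending",
                class = "gabapk_validation_error")
  }
  if (any(observations$time < doses$time[1])) {
    stop_gabapk("subject ", id, ": observation precedes the first dose",
                class = "gabapk_validation_error")
  }
  if (is.null(observations$bloq)) observations$bloq <- FALSE
  if (is.null(covariates)) covariates <- data.frame(row.names = 1L)
  list(id = id,
       doses = doses[, c("time", "amount")],
       observations = observations[, c("time", "conc", "bloq")],
       covariates = covariates)
}

#' @export
print.pk_dataset <- function(x, ...) {
  n_obs <- sum(vapply(x$subjects, function(s) nrow(s$observations), 0))
  n_dose <- sum(vapply(x$subjects, function(s) nrow(s$doses), 0))
  cat("pk_dataset:", length(x$subjects), "subjects,", n_dose, "dose events,",
      n_obs, "observations\n")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of subjects / observations
#' @param x a `pk_dataset`
#' @export
n_subjects <- function(x) length(x$subjects)

#' @rdname n_subjects
#' @export
n_observations <- function(x) {
  sum(vapply(x$subjects, function(s) nrow(s$observations), 0))
}

.required_cols <- c("ID", "TIME", "AMT", "DV", "EVID")
.covariate_cols <- c("AGE", "SEX", "RACE", "WT", "HT", "SCR", "FPG", "DM")
.derived_cols <- c("BMI", "IBW", "ABW", "LBW", "EGFR", "CRCL",
                   "AKI", "OBESE", "METCAT")

.decode_sex <- function(x) {
  if (is.numeric(x)) ifelse(x == 1, "female", "male") else as.character(x)
}
.encode_sex <- function(x) ifelse(x == "female", 1L, 0L)

#' Read a NONMEM-style event-record file
#'
#' Accepts comma- or tab-delimited files with columns ID, TIME, AMT, DV,
#' EVID, optional MDV, and covariate columns (AGE, SEX, RACE, WT, HT, SCR,
#' FPG, DM, ...). Dose rows (EVID = 1) become dose events; observation rows
#' (EVID = 0 with MDV = 0 or absent) become observations. Covariates are
#' taken from each subject's first row. Event times are shifted so that
#' time 0 is the subject's first recorded dose. SEX is encoded 0/1
#' (male/female) in files, RACE as a lower-case token, DM/AKI/OBESE as 0/1.
#'
#' @param path file to read
#' @param column_map optional named character vector mapping required names
#'   to the file's column names, e.g. `c(ID = "subject")`
#' @return a [pk_dataset()]
#' @export
read_pk_dataset <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    stop_gabapk("file not found: ", path, class = "gabapk_io_error")
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("NA", "."),
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      names(tab)[names(tab) == column_map[[std]]] <- std
    }
  }
  missing <- setdiff(.required_cols, names(tab))
  if (length(missing)) {
    stop_gabapk("missing required column(s): ", paste(missing, collapse = ", "),
                class = "gabapk_format_error")
  }
  for (num in c("TIME", "AMT", "DV")) tab[[num]] <- as.numeric(tab[[num]])
  if (is.null(tab$MDV)) tab$MDV <- ifelse(tab$EVID == 0, 0, 1)
  tab$MDV[is.na(tab$MDV)] <- ifelse(tab$EVID[is.na(tab$MDV)] == 0, 0, 1)

  cov_present <- intersect(c(.covariate_cols, .derived_cols), names(tab))
  subjects <- lapply(split(tab, factor(tab$ID, levels = unique(tab$ID))),
                     function(rows) {
    id <- as.character(rows$ID[1])
    if (is.unsorted(rows$TIME)) {
      stop_gabapk("subject ", id, ": event times are not monotone",
                  class = "gabapk_validation_error")
    }
    dose_rows <- rows[rows$EVID == 1, , drop = FALSE]
    obs_rows <- rows[rows$EVID == 0 & rows$MDV == 0, , drop = FALSE]
    if (!nrow(dose_rows)) {
      stop_gabapk("subject ", id, " has observation rows but no dose rows",
                  class = "gabapk_validation_error")
    }
    t0 <- dose_rows$TIME[1]
    if (any(obs_rows$TIME < t0)) {
      stop_gabapk("subject ", id, ": observation before any dose",
                  class = "gabapk_validation_error")
    }
    cov <- rows[1, cov_present, drop = FALSE]
    row.names(cov) <- NULL
    if (!is.null(cov$SEX)) cov$SEX <- .decode_sex(cov$SEX)
    if (!is.null(cov$RACE)) cov$RACE <- tolower(as.character(cov$RACE))
    for (lg in c("DM", "AKI", "OBESE")) {
      if (!is.null(cov[[lg]])) cov[[lg]] <- as.logical(cov[[lg]] == 1 | cov[[lg]] == TRUE)
    }
    pk_subject(
      id = id,
      doses = data.frame(time = dose_rows$TIME - t0,
                         amount = dose_rows$AMT),
      observations = data.frame(time = obs_rows$TIME - t0,
                                conc = obs_rows$DV,
                                bloq = FALSE),
      covariates = cov)
  })
  pk_dataset(unname(subjects), provenance = paste("read from", path))
}

#' Write a dataset in the event-record dialect `read_pk_dataset` consumes
#'
#' Numeric fields are written at full (17 significant digit) precision so a
#' write/read round trip reproduces every value bit-identically. Column
#' order is ID, TIME, AMT, DV, EVID, MDV, then covariates.
#'
#' @param dataset a valid [pk_dataset()]
#' @param path output file; `.tsv` extension selects tab delimiting
#' @param sep field separator, `","` or `"\t"`
#' @export
write_pk_dataset <- function(dataset, path,
                             sep = if (grepl("\\.tsv$", path)) "\t" else ",") {
  stopifnot(inherits(dataset, "pk_dataset"))
  if (!length(dataset$subjects)) {
    stop_gabapk("refusing to write a dataset with no subjects",
                class = "gabapk_validation_error")
  }
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "." else sprintf("%.17g", v)
    }, character(1))
    out
  }
  cov_present <- intersect(c(.covariate_cols, .derived_cols),
                           names(dataset$subjects[[1]]$covariates))
  rows <- lapply(dataset$subjects, function(s) {
    cov <- s$covariates
    if (!is.null(cov$SEX)) cov$SEX <- .encode_sex(cov$SEX)
    for (lg in c("DM", "AKI", "OBESE")) {
      if (!is.null(cov[[lg]])) cov[[lg]] <- as.integer(cov[[lg]])
    }
    ev <- rbind(
      data.frame(TIME = s$doses$time, AMT = s$doses$amount, DV = NA_real_,
                 EVID = 1L, MDV = 1L),
      data.frame(TIME = s$observations$time, AMT = NA_real_,
                 DV = s$observations$conc, EVID = 0L, MDV = 0L))
    ev <- ev[order(ev$TIME, -ev$EVID), , drop = FALSE]
    out <- data.frame(ID = s$id, TIME = fmt(ev$TIME), AMT = fmt(ev$AMT),
                      DV = fmt(ev$DV), EVID = ev$EVID, MDV = ev$MDV,
                      stringsAsFactors = FALSE)
    for (cc in cov_present) {
      v <- cov[[cc]]
      out[[cc]] <- if (is.numeric(v)) fmt(rep(v, nrow(out))) else as.character(v)
    }
    out
  })
  tab <- do.call(rbind, rows)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_gabapk("cannot write ", path,
                                                  class = "gabapk_io_error"))
  on.exit(close(con))
  utils::write.table(tab, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Report data-quality issues without repairing them
#'
#' Checks the cohort inclusion rules and structural sanity: adults only
#' (age >= 18), serum creatinine present, no observation before the first
#' dose, strictly positive dose amounts, non-negative observed
#' concentrations. Returns a character vector of human-readable issues; an
#' empty vector means the dataset is clean. The input is never modified.
#'
#' @param dataset a [pk_dataset()]
#' @return character vector of issue descriptions
#' @export
validate_pk_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "pk_dataset"))
  issues <- character(0)
  for (s in dataset$subjects) {
    cov <- s$covariates
    if (!is.null(cov$AGE) && !is.na(cov$AGE) && cov$AGE < 18) {
      issues <- c(issues, paste0("subject ", s$id, ": age ", cov$AGE,
                                 " violates the adult (>= 18 years) inclusion rule"))
    }
    if (is.null(cov$SCR) || is.na(cov$SCR)) {
      issues <- c(issues, paste0("subject ", s$id, ": missing serum creatinine"))
    }
    if (any(s$observations$time < s$doses$time[1])) {
      issues <- c(issues, paste0("subject ", s$id,
                                 ": observation precedes the first dose"))
    }
    if (any(s$doses$amount <= 0)) {
      issues <- c(issues, paste0("subject ", s$id, ": nonpositive dose amount"))
    }
    if (any(s$observations$conc < 0, na.rm = TRUE)) {
      issues <- c(issues, paste0("subject ", s$id,
                                 ": negative observed concentration"))
    }
  }
  issues
}

#' Flatten a dataset to a long event-record data.frame
#' @param x a `pk_dataset`
#' @param row.names,optional,... ignored (S3 signature)
#' @export
as.data.frame.pk_dataset <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- lapply(x$subjects, function(s) {
    rbind(data.frame(ID = s$id, TIME = s$doses$time, AMT = s$doses$amount,
                     DV = NA_real_, EVID = 1L),
          data.frame(ID = s$id, TIME = s$observations$time, AMT = NA_real_,
                     DV = s$observations$conc, EVID = 0L))
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$ID, names(x$subjects)), out$TIME, -out$EVID), ]
  row.names(out) <- NULL
  out
}

#' Covariate table, one row per subject
#' @param dataset a `pk_dataset`
#' @return data.frame with an `ID` column followed by covariates
#' @export
covariate_table <- function(dataset) {
  rows <- lapply(dataset$subjects, function(s) {
    cbind(data.frame(ID = s$id, stringsAsFactors = FALSE), s$covariates)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
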