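#' Subject record
#'
#' One subject's dose events, observation events and covariates.
#' Fit-eligible observations are rows of `obs` with `mdv == 0`; `mdv == 1`
#' rows (e.g. pre-dose samples in generated cohorts) are carried but never
#' fitted.
#'
#' @param id subject identifier (coerced to character)
#' @param doses data.frame(time h, amt micrograms)
#' @param obs data.frame(time h, dv ng/mL, mdv 0/1); `mdv` defaults to 0
#' @param covariates named vector: WT (kg), SEX (0 female / 1 male), AGE (y),
#'   ALT (U/L), AST (U/L), SCR (mg/dL), INF (0 uninfected / 1 LF-infected)
#' @return a `subject_record` object
#' @export
subject_record <- function(id, doses, obs, covariates) {
  if (is.null(obs$mdv)) obs$mdv <- 0L
  obs <- obs[c("time", "dv", "mdv")]
  structure(
    list(id = as.character(id),
         doses = doses[c("time", "amt")],
         obs = obs,
         covariates = unlist(covariates)),
    class = "subject_record"
  )
}

fit_obs <- function(s) s$obs[s$obs$mdv == 0, , drop = FALSE]

#' Pharmacometric dataset
#'
#' @param subjects list of [subject_record] objects
#' @param lloq lower limit of quantification (ng/mL)
#' @param name free-text label
#' @return a `pk_dataset` object
#' @export
pk_dataset <- function(subjects, lloq = 0.1, name = "") {
  ds <- structure(list(subjects = subjects, lloq = lloq, name = name),
                  class = "pk_dataset")
  ds
}

#' @export
print.pk_dataset <- function(x, ...) {
  nobs <- sum(vapply(x$subjects, function(s) nrow(fit_obs(s)), 0L))
  cat(sprintf("PK dataset '%s': %d subjects, %d fit-eligible observations, LLOQ %g ng/mL\n",
              x$name, length(x$subjects), nobs, x$lloq))
  invisible(x)
}

#' Number of fit-eligible observations
#' @param ds a [pk_dataset]
#' @return integer count of `EVID=0, MDV=0` records
#' @export
n_observations <- function(ds) {
  sum(vapply(ds$subjects, function(s) nrow(fit_obs(s)), 0L))
}

event_columns <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV")
covariate_columns <- c("WT", "SEX", "AGE", "ALT", "AST", "SCR", "INF")

#' Read an event-record CSV dataset
#'
#' Reads a comma-separated event-record table in the de facto pharmacometric
#' convention: columns `ID, TIME, AMT, DV, EVID, MDV` plus the covariates
#' `WT, SEX, AGE, ALT, AST, SCR, INF`. `EVID=1` rows are dose events carrying
#' `AMT` (micrograms, so that amount/volume in litres is ng/mL); `EVID=0`
#' rows are observations carrying `DV` (ng/mL); `MDV=1` observation rows are
#' parsed but excluded from fitting.
#'
#' @param path CSV file path (header mandatory, decimal point, UTF-8)
#' @param column_map optional named character vector renaming file columns to
#'   the standard names, e.g. `c(SUBJ = "ID")` maps file column `SUBJ` to `ID`
#' @param lloq lower limit of quantification (ng/mL); every fit-eligible DV
#'   must be at or above it
#' @param name dataset label (defaults to the file name)
#' @return a [pk_dataset]
#' @export
read_dataset <- function(path, column_map = NULL, lloq = 0.1,
                         name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(raw))
    names(raw)[idx[!is.na(idx)]] <- column_map[!is.na(idx)]
  }
  missing_cols <- setdiff(c(event_columns, covariate_columns), names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num <- raw
  for (col in c("TIME", "AMT", "DV", "EVID", "MDV", covariate_columns)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    blank <- !nzchar(trimws(raw[[col]]))
    bad <- which(is.na(v) & !blank)
    if (length(bad)) {
      stop(sprintf("non-numeric value in column %s at data row %d: '%s'",
                   col, bad[1], raw[[col]][bad[1]]), call. = FALSE)
    }
    num[[col]] <- v
  }
  subjects <- lapply(split(num, factor(raw$ID, levels = unique(raw$ID))),
                     function(d) {
    dose_rows <- d[d$EVID == 1, , drop = FALSE]
    obs_rows <- d[d$EVID == 0, , drop = FALSE]
    if (nrow(obs_rows) > 0 && nrow(dose_rows) == 0) {
      stop("subject ", d$ID[1], " has observations but no dose event",
           call. = FALSE)
    }
    subject_record(
      id = d$ID[1],
      doses = data.frame(time = dose_rows$TIME, amt = dose_rows$AMT),
      obs = data.frame(time = obs_rows$TIME, dv = obs_rows$DV,
                       mdv = as.integer(obs_rows$MDV)),
      covariates = vapply(covariate_columns, function(cn) d[[cn]][1], 0)
    )
  })
  names(subjects) <- NULL
  ds <- pk_dataset(subjects, lloq = lloq, name = name)
  findings <- validate_dataset(ds)
  if (nrow(findings)) {
    stop("dataset failed validation:\n",
         paste(sprintf("  [%s] %s", findings$subject_id, findings$finding),
               collapse = "\n"), call. = FALSE)
  }
  ds
}

#' Validate a dataset against the type invariants
#'
#' Checks subject-id uniqueness, time ordering, positivity of amounts and
#' weight, 0/1 coding of SEX and INF, dose-before-observation ordering and the
#' LLOQ floor on fit-eligible observations. Returns findings rather than
#' raising, one row per violation.
#'
#' @param ds a [pk_dataset]
#' @return data.frame(subject_id, finding); zero rows iff the dataset is valid
#' @export
validate_dataset <- function(ds) {
  out <- list()
  note <- function(id, msg) out[[length(out) + 1]] <<- data.frame(
    subject_id = id, finding = msg, stringsAsFactors = FALSE)
  ids <- vapply(ds$subjects, function(s) s$id, "")
  for (dup in unique(ids[duplicated(ids)])) {
    note(dup, "duplicate subject id")
  }
  if (is.na(ds$lloq) || ds$lloq <= 0) note("", "lloq must be positive")
  for (s in ds$subjects) {
    cv <- s$covariates
    if (anyNA(cv)) note(s$id, paste("missing covariate value:",
                                    paste(names(cv)[is.na(cv)], collapse = ", ")))
    if (!is.na(cv[["WT"]]) && cv[["WT"]] <= 0) note(s$id, "WT must be > 0")
    for (cc in c("SEX", "INF")) {
      if (!is.na(cv[[cc]]) && !cv[[cc]] %in% c(0, 1)) {
        note(s$id, paste(cc, "must be 0 or 1"))
      }
    }
    if (nrow(s$doses)) {
      if (any(s$doses$amt <= 0)) note(s$id, "dose amount must be > 0")
      if (any(s$doses$time < 0)) note(s$id, "dose time must be >= 0")
      if (is.unsorted(s$doses$time)) note(s$id, "dose times must be non-decreasing")
    }
    if (nrow(s$obs)) {
      if (any(s$obs$time < 0)) note(s$id, "observation time must be >= 0")
      if (is.unsorted(s$obs$time)) note(s$id, "observation times must be non-decreasing")
      fo <- fit_obs(s)
      if (nrow(fo)) {
        if (!nrow(s$doses)) {
          note(s$id, "observations present but no dose event")
        } else {
          post <- fo$time[fo$time > min(s$doses$time)]
          if (nrow(fo) && length(post) < nrow(fo) &&
              any(fo$time <= min(s$doses$time))) {
            note(s$id, "fit-eligible observation at or before first dose")
          }
        }
        low <- which(fo$dv < ds$lloq)
        if (length(low)) {
          note(s$id, sprintf("DV below LLOQ (%g ng/mL) at time(s) %s", ds$lloq,
                             paste(fo$time[low], collapse = ", ")))
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(subject_id = character(), finding = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write a dataset as an event-record CSV
#'
#' Inverse of [read_dataset]: emits one dose row (`EVID=1`) per dose event
#' and one observation row (`EVID=0`) per observation, covariates repeated on
#' every row. Numeric cells are printed with 17 significant digits so that
#' `read_dataset(write_dataset(ds))` reproduces `ds` exactly.
#'
#' @param ds a [pk_dataset]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_dataset <- function(ds, path) {
  rows <- lapply(ds$subjects, function(s) {
    cv <- as.list(s$covariates[covariate_columns])
    dose <- data.frame(ID = s$id, TIME = s$doses$time, AMT = s$doses$amt,
                       DV = NA_real_, EVID = 1L, MDV = 1L)
    obs <- data.frame(ID = s$id, TIME = s$obs$time, AMT = NA_real_,
                      DV = s$obs$dv, EVID = 0L, MDV = s$obs$mdv)
    tab <- rbind(dose, obs)
    tab <- tab[order(tab$TIME, -tab$EVID), ]
    cbind(tab, as.data.frame(cv))
  })
  tab <- do.call(rbind, rows)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out <- data.frame(ID = tab$ID, TIME = fmt(tab$TIME), AMT = fmt(tab$AMT),
                    DV = fmt(tab$DV), EVID = tab$EVID, MDV = tab$MDV)
  for (cn in covariate_columns) out[[cn]] <- fmt(tab[[cn]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write dataset to ", path, call. = FALSE)
  invisible(path)
}
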