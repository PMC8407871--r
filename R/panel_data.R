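#' Panel dataset for joint longitudinal / event-time modelling
#'
#' The single container every fitter in the package consumes: a long-format
#' table of subject visits (one row per observed outcome), a table of
#' time-fixed baseline covariates, and a one-row-per-subject event table
#' recording the follow-up/censoring time and a status indicator per cause
#' (one cause, e.g. dementia, or two competing causes, e.g. dementia and
#' death).  Missing outcomes are represented by the *absence* of a visit
#' row; no explicit missingness indicator column is stored.
#'
#' Invariants enforced at construction:
#' \itemize{
#'   \item subject ids are unique and consistent across the three tables;
#'   \item visit times are non-negative and strictly increasing within
#'     subject;
#'   \item no visit occurs strictly after the subject's event/censoring
#'     time;
#'   \item at most one cause has status 1 for any subject;
#'   \item subjects with zero visits are allowed (they carry event
#'     information only).
#' }
#'
#' @param visits data.frame with columns \code{id}, \code{time} (years since
#'   index visit), \code{y} (outcome).  Rows with \code{NA} outcome are
#'   dropped (their absence is the missingness indicator).
#' @param baseline data.frame with column \code{id} plus one column per
#'   baseline covariate; one row per subject.
#' @param events data.frame with columns \code{id}, \code{time} (event or
#'   censoring time, years) and \code{status} (0 censored / 1 event), plus
#'   optionally \code{status2} for a second competing cause.
#' @param waves optional numeric vector of scheduled visit times (years),
#'   used by \code{\link{summarize_cohort}} to define completers and by the
#'   GEE fitter to index visit occasions.
#' @return An object of class \code{"panel_data"}.
#' @seealso \code{\link{read_panel}}, \code{\link{summarize_cohort}}
#' @export
panel_data <- function(visits, baseline, events, waves = NULL) {
  visits <- as.data.frame(visits)
  baseline <- as.data.frame(baseline)
  events <- as.data.frame(events)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop_config("%s table is missing required column(s): %s",
                  what, paste(miss, collapse = ", "))
  }
  need(visits, c("id", "time", "y"), "visit")
  need(baseline, "id", "baseline")
  need(events, c("id", "time", "status"), "event")

  visits <- visits[!is.na(visits$y), c("id", "time", "y")]
  n_causes <- if ("status2" %in% names(events)) 2L else 1L
  status_cols <- c("status", if (n_causes == 2L) "status2")
  events <- events[, c("id", "time", status_cols)]

  if (anyDuplicated(events$id))
    stop("duplicate subject id(s) in event table: ",
         paste(unique(events$id[duplicated(events$id)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(baseline$id))
    stop("duplicate subject id(s) in baseline table", call. = FALSE)

  ids <- events$id
  if (!all(baseline$id %in% ids) || !all(ids %in% baseline$id))
    stop("baseline and event tables must cover the same subjects",
         call. = FALSE)
  orphans <- setdiff(visits$id, ids)
  if (length(orphans))
    stop("visit rows for subject(s) with no event record: ",
         paste(utils::head(orphans, 5L), collapse = ", "), call. = FALSE)

  key <- paste(visits$id, visits$time)
  if (anyDuplicated(key))
    stop("duplicate (id, time) visit row(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 5L), collapse = "; "),
         call. = FALSE)
  if (any(visits$time < 0))
    stop("negative visit time(s)", call. = FALSE)
  if (any(events$time < 0))
    stop("negative event time(s)", call. = FALSE)

  smat <- as.matrix(events[, status_cols, drop = FALSE])
  if (!all(smat %in% c(0, 1)))
    stop("event status values must be 0 or 1", call. = FALSE)
  if (n_causes == 2L && any(rowSums(smat) > 1))
    stop("at most one cause may have status 1 per subject", call. = FALSE)

  visits <- visits[order(match(visits$id, ids), visits$time), , drop = FALSE]
  rownames(visits) <- NULL
  last_visit <- tapply(visits$time, factor(visits$id, levels = ids),
                       max, default = -Inf)
  bad <- ids[!is.na(last_visit) & last_visit > events$time + 1e-9]
  bad <- bad[!is.na(bad)]
  if (length(bad))
    stop("event/censoring time earlier than a visit for subject(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)

  baseline <- baseline[match(ids, baseline$id), , drop = FALSE]
  rownames(baseline) <- NULL

  structure(list(
    visits = visits,
    baseline = baseline,
    events = events,
    covariate_names = setdiff(names(baseline), "id"),
    n_causes = n_causes,
    waves = waves
  ), class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  cat(sprintf(
    "Panel dataset: %d subjects, %d visits, %d covariate(s), %d cause(s)\n",
    nrow(x$events), nrow(x$visits), length(x$covariate_names), x$n_causes))
  if (length(x$covariate_names))
    cat("  covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  ev <- colSums(x$events[, grep("^status", names(x$events)), drop = FALSE])
  cat("  events per cause:", paste(ev, collapse = ", "), "\n")
  if (!is.null(x$waves))
    cat("  wave schedule (years):", paste(x$waves, collapse = ", "), "\n")
  invisible(x)
}

#' Number of subjects in a panel dataset
#' @param data a \code{panel_data} object.
#' @return integer subject count.
#' @export
n_subjects <- function(data) nrow(data$events)

#' Read a panel dataset from delimited text files
#'
#' Reads the long-format visit/covariate file and the one-row-per-subject
#' event file and returns a validated \code{\link{panel_data}} object.
#' Rows whose outcome cell is empty or \code{NA} are dropped from the visit
#' list (row absence encodes missingness); their covariate values are still
#' used for the subject's baseline record.
#'
#' @param panel_path path to the panel CSV (columns: id, time, outcome,
#'   covariates ...).
#' @param event_path path to the event CSV (columns: id, event time, status,
#'   optionally a second status column).
#' @param columns optional named list remapping column names; recognized
#'   entries \code{id}, \code{time}, \code{y}, \code{etime}, \code{status},
#'   \code{status2}, \code{covariates} (character vector; default: all
#'   remaining panel columns).
#' @param waves optional scheduled visit times (years), stored on the
#'   dataset.
#' @return a \code{\link{panel_data}} object.
#' @export
read_panel <- function(panel_path, event_path, columns = list(), waves = NULL) {
  cn <- utils::modifyList(
    list(id = "id", time = "time", y = "y",
         etime = "etime", status = "status", status2 = "status2"),
    columns)
  pan <- utils::read.csv(panel_path, stringsAsFactors = FALSE)
  ev <- utils::read.csv(event_path, stringsAsFactors = FALSE)

  for (col in c("id", "time", "y"))
    if (!cn[[col]] %in% names(pan))
      stop_config("panel file lacks column '%s'", cn[[col]])
  for (col in c("id", "etime", "status"))
    if (!cn[[col]] %in% names(ev))
      stop_config("event file lacks column '%s'", cn[[col]])

  covs <- cn$covariates %||%
    setdiff(names(pan), c(cn$id, cn$time, cn$y))
  miss <- setdiff(covs, names(pan))
  if (length(miss))
    stop_config("panel file lacks covariate column(s): %s",
                paste(miss, collapse = ", "))

  visits <- data.frame(id = pan[[cn$id]], time = pan[[cn$time]],
                       y = pan[[cn$y]])
  base <- pan[!duplicated(pan[[cn$id]]), c(cn$id, covs), drop = FALSE]
  names(base) <- c("id", covs)
  events <- data.frame(id = ev[[cn$id]], time = ev[[cn$etime]],
                       status = ev[[cn$status]])
  if (cn$status2 %in% names(ev)) events$status2 <- ev[[cn$status2]]

  # subjects present only in the event file get an empty covariate row
  only_ev <- setdiff(events$id, base$id)
  if (length(only_ev)) {
    pad <- base[rep(NA_integer_, length(only_ev)), , drop = FALSE]
    pad$id <- only_ev
    base <- rbind(base, pad)
  }
  panel_data(visits, base, events, waves = waves)
}

#' Write a panel dataset to delimited text files
#'
#' Inverse of \code{\link{read_panel}}: emits the long-format panel file
#' (visit rows joined with the subject's baseline covariates) and the
#' one-row-per-subject event file.  Subjects with zero observed visits are
#' written as a single panel row at time 0 with an empty outcome cell so
#' that their covariates survive the round trip.
#'
#' @param data a \code{\link{panel_data}} object.
#' @param panel_path,event_path output paths.
#' @return invisibly, \code{data}.
#' @export
write_panel <- function(data, panel_path, event_path) {
  stopifnot(inherits(data, "panel_data"))
  pan <- merge(data$visits, data$baseline, by = "id", sort = FALSE)
  no_visit <- setdiff(data$events$id, data$visits$id)
  if (length(no_visit)) {
    pad <- merge(data.frame(id = no_visit, time = 0, y = NA_real_),
                 data$baseline, by = "id", sort = FALSE)
    pan <- rbind(pan, pad)
  }
  pan <- pan[order(match(pan$id, data$events$id), pan$time), , drop = FALSE]
  utils::write.csv(pan, panel_path, row.names = FALSE, quote = FALSE)
  ev <- data$events
  names(ev)[names(ev) == "time"] <- "etime"
  utils::write.csv(ev, event_path, row.names = FALSE, quote = FALSE)
  invisible(data)
}

#' Cohort completion and baseline summary
#'
#' Tabulates study retention: how many subjects are completers (observed at
#' every scheduled wave), how many were lost to follow-up, optionally
#' broken down by a grouping covariate, plus means/SDs of the baseline
#' covariates and of the baseline outcome.
#'
#' A visit is matched to a scheduled wave when it lies within \code{tol}
#' years of it (visit schedules are jittered in practice).
#'
#' @param data a \code{\link{panel_data}} object.
#' @param group optional name of a (categorical/binary) baseline covariate.
#' @param waves scheduled visit times; defaults to the schedule stored on
#'   the dataset, else \code{c(0, 6, 15, 18, 20)}.
#' @param tol half-width (years) for matching visits to waves.
#' @return an object of class \code{"cohort_summary"}: list with \code{n},
#'   \code{n_completer}, \code{pct_completer}, \code{pct_lost},
#'   \code{by_group} (data.frame or NULL), \code{baseline_stats}.
#' @export
summarize_cohort <- function(data, group = NULL, waves = NULL, tol = 1.5) {
  stopifnot(inherits(data, "panel_data"))
  waves <- waves %||% data$waves %||% c(0, 6, 15, 18, 20)
  ids <- data$events$id
  if (!is.null(group) && !group %in% data$covariate_names)
    stop_config("unknown grouping covariate '%s'", group)

  idf <- factor(data$visits$id, levels = ids)
  hit <- matrix(FALSE, length(ids), length(waves))
  for (w in seq_along(waves)) {
    at_w <- abs(data$visits$time - waves[w]) <= tol
    hit[, w] <- tabulate(idf[at_w], nbins = length(ids)) > 0
  }
  complete <- rowSums(hit) == length(waves)
  n <- length(ids)
  nc <- sum(complete)

  by_group <- NULL
  if (!is.null(group)) {
    g <- data$baseline[[group]]
    tab <- table(g, factor(complete, levels = c(FALSE, TRUE)))
    by_group <- data.frame(
      group = rownames(tab),
      n = as.integer(rowSums(tab)),
      n_lost = as.integer(tab[, "FALSE"]),
      pct_lost = round(100 * tab[, "FALSE"] / rowSums(tab)),
      row.names = NULL)
  }

  num <- data$covariate_names[vapply(data$baseline[data$covariate_names],
                                     is.numeric, logical(1))]
  base_y <- data$visits$y[data$visits$time <= tol][
    !duplicated(data$visits$id[data$visits$time <= tol])]
  stats <- data.frame(
    variable = c(num, "baseline outcome"),
    mean = c(vapply(data$baseline[num], mean, numeric(1), na.rm = TRUE),
             mean(base_y, na.rm = TRUE)),
    sd = c(vapply(data$baseline[num], stats::sd, numeric(1), na.rm = TRUE),
           stats::sd(base_y, na.rm = TRUE)))

  structure(list(n = n, n_completer = nc,
                 pct_completer = round(100 * nc / n),
                 pct_lost = round(100 * (n - nc) / n),
                 by_group = by_group, baseline_stats = stats,
                 waves = waves),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: N = %d; completers %d (%d%%); lost to follow-up %d (%d%%)\n",
              x$n, x$n_completer, x$pct_completer,
              x$n - x$n_completer, x$pct_lost))
  cat("  scheduled waves (years):", paste(x$waves, collapse = ", "), "\n")
  if (!is.null(x$by_group)) {
    cat("  loss by group:\n")
    print(x$by_group, row.names = FALSE)
  }
  cat("  baseline covariates:\n")
  print(x$baseline_stats, row.names = FALSE, digits = 4)
  invisible(x)
}
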