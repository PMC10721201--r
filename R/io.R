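#' Canonical column mapping for event logs
#'
#' The canonical event schema is long/tidy: one row per solicitation. A
#' schema maps canonical names to whatever headers a particular CSV dialect
#' uses, so deposited files with arbitrary headers can be adapted without
#' editing them.
#'
#' @param group_id,female_id,offspring_id,start_time,end_time,duration_s,outcome,is_filial
#'   Column names in the file for each canonical field. `end_time`,
#'   `duration_s` and `is_filial` may be `NA` if absent (the filial flag is
#'   then derived from the mother table).
#' @return Named character vector (canonical -> file column).
#' @export
event_schema <- function(group_id = "group_id", female_id = "female_id",
                         offspring_id = "offspring_id",
                         start_time = "start_time", end_time = "end_time",
                         duration_s = "duration_s", outcome = "outcome",
                         is_filial = "is_filial") {
  c(group_id = group_id, female_id = female_id, offspring_id = offspring_id,
    start_time = start_time, end_time = end_time, duration_s = duration_s,
    outcome = outcome, is_filial = is_filial)
}

parse_iso_time <- function(x) {
  x <- ifelse(x == "", NA_character_, x)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  fallback <- is.na(out) & !is.na(x)
  out[fallback] <- as.POSIXct(x[fallback], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  out
}

#' Read a solicitation event log
#'
#' Parses a CSV of solicitations into the canonical event tibble. Rows
#' that cannot be parsed are rejected collectively with a line-numbered
#' report, so a malformed file never yields a silently truncated stream.
#' Timestamps are ISO 8601 with seconds resolution, one clock per group.
#'
#' @param path CSV file.
#' @param schema Column mapping from [event_schema()].
#' @return Tibble with columns `group_id`, `female_id`, `offspring_id`,
#'   `start_time`, `end_time` (POSIXct, `NA` allowed), `duration_s`,
#'   `outcome` (`bout`/`rejection`/`attempt`), `is_filial` (logical or
#'   `NA`), sorted stably by `start_time` within group.
#' @export
read_events <- function(path, schema = event_schema()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("group_id", "female_id", "offspring_id", "start_time", "outcome")
  for (canon in required) {
    if (is.na(schema[[canon]]) || !schema[[canon]] %in% names(raw)) {
      stop("schema error: required column '", schema[[canon]] %||% canon,
           "' (", canon, ") not found in ", path)
    }
  }
  pick <- function(canon) {
    col <- schema[[canon]]
    if (is.na(col) || !col %in% names(raw)) rep(NA_character_, nrow(raw)) else raw[[col]]
  }
  n <- nrow(raw)
  if (n == 0) {
    return(tibble::tibble(group_id = character(), female_id = character(),
                          offspring_id = character(),
                          start_time = as.POSIXct(character(), tz = "UTC"),
                          end_time = as.POSIXct(character(), tz = "UTC"),
                          duration_s = numeric(), outcome = character(),
                          is_filial = logical()))
  }
  errs <- character()
  line <- seq_len(n) + 1L  # header is line 1

  start_raw <- pick("start_time")
  start_time <- parse_iso_time(start_raw)
  bad <- is.na(start_time)
  if (any(bad)) errs <- c(errs, sprintf("line %d: unparseable start_time '%s'",
                                        line[bad], start_raw[bad]))

  end_raw <- pick("end_time")
  end_time <- parse_iso_time(end_raw)
  bad <- is.na(end_time) & !is.na(end_raw) & end_raw != ""
  if (any(bad)) errs <- c(errs, sprintf("line %d: unparseable end_time '%s'",
                                        line[bad], end_raw[bad]))

  outcome <- pick("outcome")
  bad <- !outcome %in% c("bout", "rejection", "attempt")
  if (any(bad)) errs <- c(errs, sprintf("line %d: unknown outcome token '%s'",
                                        line[bad], outcome[bad]))

  duration_s <- suppressWarnings(as.numeric(pick("duration_s")))
  filial_raw <- pick("is_filial")
  is_filial <- rep(NA, n)
  is_filial[filial_raw %in% c("TRUE", "true", "1")] <- TRUE
  is_filial[filial_raw %in% c("FALSE", "false", "0")] <- FALSE

  both <- !is.na(start_time) & !is.na(end_time)
  bad <- both & end_time < start_time
  if (any(bad)) errs <- c(errs, sprintf("line %d: end_time before start_time", line[bad]))

  if (length(errs) > 0) {
    stop("row errors in ", path, ":\n", paste(errs, collapse = "\n"))
  }
  out <- tibble::tibble(
    group_id = pick("group_id"), female_id = pick("female_id"),
    offspring_id = pick("offspring_id"), start_time = start_time,
    end_time = end_time, duration_s = duration_s, outcome = outcome,
    is_filial = is_filial
  )
  out[order(out$group_id, as.numeric(out$start_time)), , drop = FALSE]
}

#' Write events back to the canonical CSV
#' @param events Canonical event tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- events
  out$start_time <- format(out$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out$end_time <- format(out$end_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read the mother attribute table
#'
#' @param path CSV with columns `mother_id`, `group_id`, `age_years`,
#'   `rank`, `offspring_id`, `offspring_sex`, `offspring_birth_mass`,
#'   `offspring_birth_date`.
#' @return Tibble; ranks are checked to be a permutation of `1..N` within
#'   each group.
#' @export
read_mothers <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(
    mother_id = "c", group_id = "c", age_years = "d", rank = "i",
    offspring_id = "c", offspring_sex = "c", offspring_birth_mass = "d",
    offspring_birth_date = readr::col_date()
  ), progress = FALSE)
  validate_mothers(m)
  m
}

validate_mothers <- function(m) {
  stopifnot(all(m$age_years > 0), all(m$offspring_sex %in% c("M", "F")))
  for (g in unique(m$group_id)) {
    rk <- sort(m$rank[m$group_id == g])
    if (!identical(rk, seq_along(rk))) {
      stop("ranks in group ", g, " are not a permutation of 1..N")
    }
  }
  invisible(m)
}

#' Read an agonistic-interaction log
#'
#' @param path CSV with `group_id`, `individual_a`, `individual_b`,
#'   `winner` (empty when unresolved), `resolved`.
#' @return Tibble with a logical `resolved` column.
#' @export
read_agonistic <- function(path) {
  a <- readr::read_csv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  a$resolved <- a$resolved %in% c("TRUE", "true", "1")
  a$winner[!is.na(a$winner) & a$winner == ""] <- NA_character_
  bad <- a$resolved & (is.na(a$winner) |
                         (a$winner != a$individual_a & a$winner != a$individual_b))
  if (any(bad)) {
    stop("resolved interaction rows with missing or non-participant winner: ",
         paste(which(bad), collapse = ", "))
  }
  a
}

#' Read a pairwise relatedness matrix
#'
#' Accepts either a wide square table (first column = ids, remaining
#' columns one per id) or a long table of `(id_a, id_b, r)` triples.
#' Asymmetric wide input is symmetrized only when `|r_ij - r_ji| <= tol`;
#' duplicate long-format pairs with conflicting values are an error. The
#' diagonal is set to `NA` (self-relatedness is not defined here).
#'
#' @param path CSV file.
#' @param tol Symmetry / duplicate tolerance (default 1e-9).
#' @return Symmetric numeric matrix with id dimnames and `NA` diagonal.
#' @export
read_relatedness <- function(path, tol = 1e-9) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  if (ncol(raw) == 3) {
    ids <- sort(unique(c(raw[[1]], raw[[2]])))
    m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    vals <- as.numeric(raw[[3]])
    for (k in seq_len(nrow(raw))) {
      i <- raw[[1]][k]; j <- raw[[2]][k]
      for (cell in list(c(i, j), c(j, i))) {
        old <- m[cell[1], cell[2]]
        if (!is.na(old) && abs(old - vals[k]) > tol) {
          stop("conflicting relatedness for pair ", i, "-", j,
               ": ", old, " vs ", vals[k])
        }
        m[cell[1], cell[2]] <- vals[k]
      }
    }
    diag(m) <- NA_real_
    return(m)
  }
  ids <- raw[[1]]
  m <- as.matrix(as.data.frame(lapply(raw[-1], as.numeric)))
  if (nrow(m) != ncol(m)) stop("wide relatedness table is not square")
  dimnames(m) <- list(ids, ids)
  off <- row(m) != col(m)
  if (any(abs(m - t(m))[off] > tol, na.rm = TRUE)) {
    stop("relatedness matrix is asymmetric beyond tolerance ", tol)
  }
  m[off] <- ((m + t(m)) / 2)[off]
  if (any(!is.finite(m[off]))) stop("non-finite off-diagonal relatedness values")
  diag(m) <- NA_real_
  m
}

#' Write a relatedness matrix in the wide CSV layout
#' @param m Symmetric relatedness matrix with id dimnames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_relatedness <- function(m, path) {
  df <- tibble::as_tibble(m)
  df <- tibble::add_column(df, id = rownames(m), .before = 1)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Bundle per-group results for serialization
#'
#' @param group_id Group label.
#' @param fits Named list of serializable fit summaries (see [tidy_fit()]),
#'   keyed by prediction.
#' @param latency Optional latency summary list.
#' @param diagnostics Optional named list of diagnostics reports.
#' @param extra Optional named list of additional tables (dyads, ranks...).
#' @return A `results_bundle` list.
#' @export
results_bundle <- function(group_id, fits = list(), latency = NULL,
                           diagnostics = NULL, extra = NULL) {
  structure(list(group_id = group_id, fits = fits, latency = latency,
                 diagnostics = diagnostics, extra = extra),
            class = "results_bundle")
}

#' Write a results bundle to a directory
#'
#' Emits one machine-readable JSON file per fitted model, a bundle-level
#' JSON, a human-readable `summary.txt` with one coefficient table per
#' fitted prediction, and a `manifest.csv` listing each file's MD5
#' checksum.
#'
#' @param bundle A [results_bundle()].
#' @param dir Output directory (created if needed).
#' @return Tibble manifest (file, md5), invisibly the same as written.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  paths <- character()
  for (nm in names(bundle$fits)) {
    p <- file.path(dir, paste0("fit_", nm, ".json"))
    jsonlite::write_json(bundle$fits[[nm]], p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "bundle.json")
  jsonlite::write_json(unclass(bundle), p, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  paths <- c(paths, p)

  sm <- file.path(dir, "summary.txt")
  con <- file(sm, "w")
  writeLines(sprintf("Group %s: %d fitted model(s)", bundle$group_id,
                     length(bundle$fits)), con)
  for (nm in names(bundle$fits)) {
    fit <- bundle$fits[[nm]]
    writeLines(c("", paste0("== ", nm, " =="),
                 sprintf("family: %s   converged: %s", fit$family,
                         fit$converged)), con)
    co <- as.data.frame(fit$coefficients)
    writeLines(paste(utils::capture.output(print(co, row.names = FALSE)),
                     collapse = "\n"), con)
  }
  close(con)
  paths <- c(paths, sm)

  manifest <- tibble::tibble(file = basename(paths),
                             md5 = unname(tools::md5sum(paths)))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(manifest)
}

#' Read a results bundle back from a directory
#' @param dir Directory written by [write_results()].
#' @return A `results_bundle`.
#' @export
read_results <- function(dir) {
  b <- jsonlite::read_json(file.path(dir, "bundle.json"), simplifyVector = TRUE)
  structure(b, class = "results_bundle")
}
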