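#' File formats
#'
#' All files are long-format (tidy) CSV with a header, decimal points and
#' UTF-8 encoding. Comment lines starting with \code{#} are ignored on read
#' and used on write for provenance (package version, seed). Writes are
#' atomic: a temporary file in the destination directory is renamed into
#' place.
#'
#' \itemize{
#'   \item cross-sections: \code{time,age,prevalence[,sigma][,n]}
#'   \item mortality: \code{time,age,m,R}
#'   \item incidence estimates: \code{time,age,incidence,lower,upper,clamped}
#'   \item bootstrap results: \code{time,age,median,lower,upper}
#' }
#'
#' @name incitrend_io
#' @keywords internal
NULL

.read_csv <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  d <- tryCatch(
    utils::read.csv(path, comment.char = "#", fileEncoding = "UTF-8"),
    error = function(e) stop(sprintf("malformed CSV %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in names(d)) {
    if (!is.numeric(d[[col]]) && col != "clamped") {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[col]]))) &
                   !is.na(d[[col]]))[1L]
      stop(sprintf("%s: non-numeric value in column `%s` (data line %d)",
                   path, col, if (is.na(bad)) NA_integer_ else bad),
           call. = FALSE)
    }
  }
  d
}

.write_atomic <- function(df, path, header_lines = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  con <- file(tmp, open = "w", encoding = "UTF-8")
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  for (h in header_lines) writeLines(paste0("# ", h), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
  on.exit()
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE); unlink(tmp)
  }
  invisible(path)
}

.version_header <- function(extra = NULL) {
  c(sprintf("incitrend %s",
            tryCatch(as.character(utils::packageVersion("incitrend")),
                     error = function(e) "dev")),
    extra)
}

#' Read prevalence cross-sections from CSV
#'
#' Expects columns \code{time,age,prevalence} and optionally \code{sigma}
#' and \code{n}. Rows are grouped by time and sorted by age; duplicate
#' (time, age) cells are rejected.
#'
#' @param path CSV file path.
#' @return List of [cross_section()]s ordered by time.
#' @export
read_cross_sections <- function(path) {
  d <- .read_csv(path, c("time", "age", "prevalence"))
  if (anyDuplicated(d[c("time", "age")])) {
    dup <- d[duplicated(d[c("time", "age")]), , drop = FALSE][1L, ]
    stop(sprintf("%s: duplicate cell (time=%g, age=%g)", path, dup$time, dup$age),
         call. = FALSE)
  }
  lapply(sort(unique(d$time)), function(t) {
    s <- d[d$time == t, , drop = FALSE]
    s <- s[order(s$age), , drop = FALSE]
    cross_section(time = t, ages = s$age, prevalence = s$prevalence,
                  sigma = if ("sigma" %in% names(s)) s$sigma,
                  n = if ("n" %in% names(s)) s$n)
  })
}

#' Write prevalence cross-sections to CSV
#'
#' @param cross_sections list of [cross_section()]s.
#' @param path destination file.
#' @param header extra comment lines (e.g. \code{"seed=7"}).
#' @return The path, invisibly.
#' @export
write_cross_sections <- function(cross_sections, path, header = NULL) {
  df <- do.call(rbind, lapply(cross_sections, as.data.frame))
  .write_atomic(df, path, .version_header(header))
}

#' Read mortality inputs from CSV
#'
#' Expects columns \code{time,age,m,R}; rows are grouped by time.
#'
#' @param path CSV file path.
#' @return List of [mortality_input()]s ordered by time.
#' @export
read_mortality <- function(path) {
  d <- .read_csv(path, c("time", "age", "m", "R"))
  lapply(sort(unique(d$time)), function(t) {
    s <- d[d$time == t, , drop = FALSE]
    s <- s[order(s$age), , drop = FALSE]
    mortality_input(time = t, ages = s$age, m = s$m, R = s$R)
  })
}

#' Write mortality inputs to CSV
#'
#' @param mortality list of [mortality_input()]s.
#' @param path destination file.
#' @param header extra comment lines.
#' @return The path, invisibly.
#' @export
write_mortality <- function(mortality, path, header = NULL) {
  df <- do.call(rbind, lapply(mortality, function(m) {
    data.frame(time = m$time, age = m$ages, m = m$m, R = m$R)
  }))
  .write_atomic(df, path, .version_header(header))
}

#' Write a prevalence surface to long-format CSV
#'
#' Columns \code{time,age,prevalence}, one row per grid node.
#'
#' @param surface a [simulate_prevalence()] result.
#' @param path destination file.
#' @param header extra comment lines.
#' @return The path, invisibly.
#' @export
write_prevalence_surface <- function(surface, path, header = NULL) {
  stopifnot(inherits(surface, "prevalence_surface"))
  df <- data.frame(
    time = rep(surface$times, times = length(surface$ages)),
    age = rep(surface$ages, each = length(surface$times)),
    prevalence = as.vector(surface$p))
  df <- df[order(df$time, df$age), , drop = FALSE]
  .write_atomic(df, path, .version_header(header))
}

#' Write incidence estimates to CSV
#'
#' Columns \code{time,age,incidence,lower,upper,clamped}.
#'
#' @param estimates list of [incidence_estimate()]s (or a single one).
#' @param path destination file.
#' @param header extra comment lines.
#' @return The path, invisibly.
#' @export
write_incidence_estimates <- function(estimates, path, header = NULL) {
  if (inherits(estimates, "incidence_estimate")) estimates <- list(estimates)
  df <- do.call(rbind, lapply(estimates, as.data.frame))
  .write_atomic(df, path, .version_header(header))
}

#' Write a bootstrap result to CSV
#'
#' Columns \code{time,age,median,lower,upper}.
#'
#' @param result a [bootstrap_incidence()] result.
#' @param path destination file.
#' @param header extra comment lines.
#' @return The path, invisibly.
#' @export
write_bootstrap_result <- function(result, path, header = NULL) {
  stopifnot(inherits(result, "bootstrap_result"))
  .write_atomic(as.data.frame(result), path, .version_header(header))
}
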