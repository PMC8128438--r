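# File formats and provenance: the canonical CSV trial table, JSON fit
# documents, and flat key=value config files.

trial_schema_version <- "1.0"

trial_cols_pre <- c("subject", "trial", "condition", "vr0_a", "vr0_b",
                    "vcr0_a", "vcr0_b", "choice", "rt_s", "confidence",
                    "effort")
trial_cols_post <- c("vr1_a", "vr1_b", "vcr1_a", "vcr1_b")
rating_cols <- c("vr0_a", "vr0_b", "vcr0_a", "vcr0_b",
                 "confidence", "effort", "vr1_a", "vr1_b", "vcr1_a",
                 "vcr1_b")

#' Write a trial table to CSV
#'
#' Writes the canonical comma-separated trial table (latent simulator
#' columns are dropped). A `# mcd-trials v<schema>` comment line records the
#' schema version.
#'
#' @param trials Trial data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- intersect(c(trial_cols_pre, trial_cols_post), names(trials))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mcd-trials v%s", trial_schema_version), con)
  utils::write.csv(trials[, cols, drop = FALSE], con, row.names = FALSE)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Parses the canonical CSV trial table and validates it: required columns,
#' ratings within `[0, 1]`, positive RTs, known condition labels, known
#' choice labels. Tables without post-choice rating columns are accepted and
#' flagged pre-only (attribute `pre_only`); such tables support fitting of
#' effort-related variables only. Validation failures name the offending
#' rows and columns. A schema comment line with a different major version is
#' rejected.
#'
#' @param path CSV file path.
#' @return Validated data frame (attribute `pre_only` set accordingly).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (startsWith(first, "# mcd-trials")) {
    ver <- sub("^# mcd-trials v", "", first)
    if (strsplit(ver, ".", fixed = TRUE)[[1]][1] !=
        strsplit(trial_schema_version, ".", fixed = TRUE)[[1]][1]) {
      stop("incompatible trial-table schema version: ", ver, call. = FALSE)
    }
  }
  tr <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(trial_cols_pre, names(tr))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pre_only <- !all(trial_cols_post %in% names(tr))
  for (cl in intersect(rating_cols, names(tr))) {
    bad <- which(!is.finite(tr[[cl]]) | tr[[cl]] < 0 | tr[[cl]] > 1)
    if (length(bad)) {
      stop(sprintf("column `%s`: value out of [0,1] at row(s) %s", cl,
                   paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad <- which(!is.finite(tr$rt_s) | tr$rt_s <= 0)
  if (length(bad)) {
    stop("column `rt_s`: non-positive RT at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!tr$condition %in% mcd_conditions)
  if (length(bad)) {
    stop("column `condition`: unknown label at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!tr$choice %in% c("a", "b"))
  if (length(bad)) {
    stop("column `choice`: labels must be 'a' or 'b'; bad row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  attr(tr, "pre_only") <- pre_only
  tr
}

#' Serialize a subject fit to JSON
#'
#' Writes a structured JSON document with full provenance: package version,
#' schema version, fit options (including seed), prior specification,
#' posterior mode, Laplace covariance, evidence, diagnostics, and
#' postdictions.
#'
#' @param fit An [fit_subject()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  doc <- list(
    schema = list(name = "mcd-fit", version = trial_schema_version),
    package_version = as.character(utils::packageVersion("mcdecide")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    fitted_vars = fit$fitted_vars,
    options = fit$options,
    priors = list(location = as.list(fit$priors$location),
                  scale = as.list(fit$priors$scale),
                  kAlpha_offset = fit$priors$kAlpha_offset),
    theta_log = as.list(fit$theta),
    core = fit$core[c("alpha", "beta", "gamma", "R", "kR", "kAlpha")],
    obs = if (!is.null(fit$obs)) list(
      maps = lapply(fit$obs$maps, function(m) m[c("intercept", "slope")]),
      noise_sd = as.list(fit$obs$noise_sd)) else NULL,
    vcov = fit$vcov,
    log_evidence = fit$log_evidence,
    diagnostics = fit$diagnostics,
    postdictions = fit$postdictions
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a subject fit written by [write_fit()]
#'
#' @param path JSON path.
#' @return A list mirroring the `mcd_fit` structure (class `mcd_fit_doc`).
#' @export
read_fit <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema$name, "mcd-fit")) {
    stop("not an mcd-fit document: ", path, call. = FALSE)
  }
  major <- strsplit(as.character(doc$schema$version), ".", fixed = TRUE)[[1]][1]
  if (major != strsplit(trial_schema_version, ".", fixed = TRUE)[[1]][1]) {
    stop("incompatible fit schema version: ", doc$schema$version,
         call. = FALSE)
  }
  structure(doc, class = "mcd_fit_doc")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are parsed
#' as numeric when possible, else kept as strings. Unknown keys are passed
#' through so callers can validate.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
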