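#' Read a right-censored survival dataset
#'
#' Reads a CSV (RFC-4180 dialect) or ARFF file — chosen by extension — into a
#' data frame ready for [survrules()]: nominal covariates as factors, numeric
#' covariates as numbers, plus validated `time`/`status` (and optional
#' weight) columns. For CSV, a column whose non-missing entries all parse as
#' numbers is numeric, anything else nominal; `kinds` overrides the
#' inference. Missing-value tokens map to `NA`. Rows with missing time or
#' status, non-\{0,1\} status, negative times or non-positive weights are
#' rejected with row-numbered errors.
#'
#' @param path file path ending in `.csv` or `.arff`.
#' @param time_col,status_col names of the time and status columns.
#' @param weight_col optional name of a positive weight column.
#' @param kinds optional named character vector overriding inferred column
#'   kinds, values `"nominal"` or `"numeric"` (CSV only).
#' @param na_tokens strings treated as missing (default `""`, `"?"`, `"NA"`).
#' @return A data frame; covariates first, then `time`, `status` (and
#'   `weight` if present), under those standard names.
#' @export
read_survival_data <- function(path, time_col = "time", status_col = "status",
                               weight_col = NULL,
                               kinds = NULL,
                               na_tokens = c("", "?", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (time_col == status_col)
    stop("time and status columns must be distinct")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    csv = read_csv_typed(path, na_tokens, kinds),
    arff = foreign::read.arff(path),
    stop("unknown dataset format '.", ext, "' (expected .csv or .arff)"))

  for (col in c(time_col, status_col, weight_col))
    if (!col %in% names(raw))
      stop("missing mandatory column '", col, "'")

  time <- as_numeric_column(raw[[time_col]], time_col)
  if (anyNA(time))
    stop("missing time in row(s) ", row_list(which(is.na(time))))
  if (any(time < 0))
    stop("negative time in row(s) ", row_list(which(time < 0)))

  status_raw <- raw[[status_col]]
  status <- suppressWarnings(as.integer(as.character(status_raw)))
  if (any(is.na(status)))
    stop("missing or non-numeric status '", status_col, "' in row(s) ",
         row_list(which(is.na(status))))
  if (!all(status %in% c(0L, 1L)))
    stop("status '", status_col, "' must be 0 or 1; bad row(s) ",
         row_list(which(!status %in% c(0L, 1L))))

  out <- raw[, setdiff(names(raw), c(time_col, status_col, weight_col)),
             drop = FALSE]
  out$time <- time
  out$status <- status
  if (!is.null(weight_col)) {
    w <- as_numeric_column(raw[[weight_col]], weight_col)
    if (anyNA(w) || any(w <= 0))
      stop("weight '", weight_col, "' must be positive in row(s) ",
           row_list(which(is.na(w) | w <= 0)))
    out$weight <- w
  }
  out
}

row_list <- function(idx) paste(utils::head(idx, 5), collapse = ", ")

as_numeric_column <- function(x, name) {
  out <- suppressWarnings(as.numeric(as.character(x)))
  if (any(is.na(out) & !is.na(x)))
    stop("non-numeric value in column '", name, "', row(s) ",
         row_list(which(is.na(out) & !is.na(x))))
  out
}

read_csv_typed <- function(path, na_tokens, kinds) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (nrow(raw) == 0) stop("empty dataset: ", path)
  for (j in seq_along(raw)) {
    x <- raw[[j]]
    x[x %in% na_tokens] <- NA
    nm <- names(raw)[j]
    kind <- if (!is.null(kinds) && nm %in% names(kinds)) kinds[[nm]] else NULL
    num <- suppressWarnings(as.numeric(x))
    inferred <- if (all(is.na(num) == is.na(x))) "numeric" else "nominal"
    kind <- if (is.null(kind)) inferred else match.arg(kind, c("nominal", "numeric"))
    if (kind == "numeric" && inferred == "nominal")
      stop("column '", nm, "' declared numeric but has non-numeric values")
    raw[[j]] <- if (kind == "numeric") num else factor(x)
  }
  raw
}

#' Write a survival dataset as CSV
#'
#' Plain CSV with missing values written as empty strings; numbers are
#' written with 17 significant digits so a read/write round trip preserves
#' them exactly.
#'
#' @param data data frame (covariates plus `time`/`status`).
#' @param path output path.
#' @export
write_survival_data <- function(data, path) {
  out <- data
  out[] <- lapply(out, function(col) {
    if (is.numeric(col)) ifelse(is.na(col), "", fmt_num(col))
    else as.character(col)
  })
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# rule-set model files: a line-oriented plain-text format.
#
#   survrules-model 1
#   mincov <number>
#   attributes <p>
#   <name> numeric                     | <name> nominal <v1,v2,...>
#   default <n_effective> <k>
#   <time> <prob>                      (k lines)
#   rules <m>
#   rule <i>
#   premise <format_rule() text>
#   stats <quality> <coverage_count> <p_value>
#   curve <n_effective> <k>
#   <time> <prob>                      (k lines)
#
# All numbers use 17 significant digits, so files round-trip bit-exactly.
# Nominal values must not contain commas; attribute names must not contain
# whitespace.
# ---------------------------------------------------------------------------

#' Save and load fitted rule sets
#'
#' Serializes a fitted [survrules()] model to a line-oriented plain-text
#' format (schema, default curve, then one premise/statistics/conclusion
#' block per rule; grammar documented in the function source). Numbers are
#' written with 17 significant digits, so
#' `read_ruleset(write_ruleset(fit, path))` reproduces premises, conclusion
#' curves and the default curve exactly.
#'
#' @param object a fitted [survrules()] model.
#' @param path file path.
#' @return `write_ruleset()` returns `path` invisibly; `read_ruleset()`
#'   returns a `survrules` object (without training-only fields such as the
#'   coverage matrix).
#' @export
write_ruleset <- function(object, path) {
  stopifnot(inherits(object, "survrules"))
  lines <- c("survrules-model 1", paste("mincov", fmt_num(object$mincov)),
             paste("attributes", length(object$attributes)))
  for (nm in names(object$attributes)) {
    a <- object$attributes[[nm]]
    if (grepl("\\s", nm)) stop("attribute names must not contain whitespace")
    lines <- c(lines, if (a$kind == "numeric") paste(nm, "numeric")
               else {
                 if (any(grepl(",", a$domain)))
                   stop("nominal values must not contain commas")
                 paste(nm, "nominal", paste(a$domain, collapse = ","))
               })
  }
  lines <- c(lines, curve_lines("default", object$default_curve),
             paste("rules", length(object$rules)))
  for (i in seq_along(object$rules)) {
    r <- object$rules[[i]]
    lines <- c(lines,
               paste("rule", i),
               paste("premise", format_rule(r)),
               paste("stats", fmt_num(r$quality), fmt_num(r$coverage_count),
                     fmt_num(r$p_value)),
               curve_lines("curve", r$conclusion))
  }
  writeLines(lines, path)
  invisible(path)
}

curve_lines <- function(tag, curve) {
  c(paste(tag, fmt_num(curve$n_effective), length(curve$times)),
    paste(fmt_num(curve$times), fmt_num(curve$probs)))
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "survrules-model 1")
    stop("not a survrules model file: ", path)
  pos <- 2
  take <- function() { line <- lines[pos]; pos <<- pos + 1; line }
  expect_field <- function(key) {
    parts <- strsplit(take(), " ", fixed = TRUE)[[1]]
    if (parts[1] != key) stop("malformed model file: expected '", key, "'")
    parts[-1]
  }
  mincov <- as.numeric(expect_field("mincov"))
  p <- as.integer(expect_field("attributes"))
  attrs <- list()
  for (i in seq_len(p)) {
    parts <- strsplit(take(), " ", fixed = TRUE)[[1]]
    attrs[[parts[1]]] <- if (parts[2] == "numeric")
      list(kind = "numeric", domain = NULL)
    else list(kind = "nominal", domain = strsplit(parts[3], ",")[[1]])
  }
  read_curve <- function(tag) {
    head <- expect_field(tag)
    n_eff <- as.numeric(head[1]); k <- as.integer(head[2])
    times <- probs <- numeric(k)
    for (i in seq_len(k)) {
      v <- as.numeric(strsplit(take(), " ", fixed = TRUE)[[1]])
      times[i] <- v[1]; probs[i] <- v[2]
    }
    km_curve(times, probs, n_eff)
  }
  default_curve <- read_curve("default")
  m <- as.integer(expect_field("rules"))
  rules <- vector("list", m)
  for (i in seq_len(m)) {
    expect_field("rule")
    premise <- sub("^premise ", "", take())
    st <- as.numeric(expect_field("stats"))
    conclusion <- read_curve("curve")
    rules[[i]] <- structure(list(
      conditions = parse_rule(premise, attrs),
      conclusion = conclusion,
      quality = st[1], quality_grown = NA_real_,
      coverage_count = st[2], p_value = st[3]
    ), class = "survrules_rule")
  }
  structure(list(rules = rules, default_curve = default_curve,
                 attributes = attrs, mincov = mincov,
                 n = NA_integer_, n_effective = default_curve$n_effective,
                 coverage = NULL),
            class = "survrules")
}
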