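#' Elementary rule conditions
#'
#' A condition tests a single attribute: equality for nominal attributes
#' (`op = "="`), a strict upper or non-strict lower threshold for numeric
#' attributes (`op = "<"` / `op = ">="`), or membership of a left-closed
#' right-open interval (`op = "in"`, produced by condition merging).
#'
#' @param attribute attribute name.
#' @param op one of `"="`, `"<"`, `">="`, `"in"`.
#' @param value the nominal value, the numeric threshold, or for `"in"` the
#'   interval bounds `c(low, high)` with `low < high`.
#' @return An object of class `survrules_condition`.
#' @export
condition <- function(attribute, op, value) {
  op <- match.arg(op, c("=", "<", ">=", "in"))
  if (op == "in") {
    if (length(value) != 2 || !is.numeric(value) || value[1] >= value[2])
      stop("interval condition needs numeric bounds c(low, high) with low < high")
  } else if (op %in% c("<", ">=")) {
    if (length(value) != 1 || !is.numeric(value))
      stop("threshold condition needs a single numeric value")
  } else {
    if (length(value) != 1) stop("equality condition needs a single value")
    value <- as.character(value)
  }
  structure(list(attribute = as.character(attribute), op = op, value = value),
            class = "survrules_condition")
}

#' Does a condition cover records?
#'
#' A record is covered when its value for the tested attribute is known and
#' satisfies the operator; records with a missing value of the attribute are
#' never covered (the ignored-value strategy for missing data).
#'
#' @param cond a [condition()].
#' @param data data frame of covariates containing the tested attribute.
#' @return Logical vector, one element per row of `data`.
#' @export
condition_covers <- function(cond, data) {
  if (!cond$attribute %in% names(data))
    stop("unknown attribute: ", cond$attribute)
  x <- data[[cond$attribute]]
  out <- switch(cond$op,
    "="  = as.character(x) == cond$value,
    "<"  = x < cond$value,
    ">=" = x >= cond$value,
    "in" = x >= cond$value[1] & x < cond$value[2])
  out & !is.na(out) & !is.na(x)
}

#' Does a rule cover records?
#'
#' Conjunction of [condition_covers()] over the rule's premise. An empty
#' premise (which only exists transiently during rule growing) covers every
#' record.
#'
#' @param rule a `survrules_rule`, or a plain list of conditions.
#' @param data data frame of covariates.
#' @return Logical vector, one element per row of `data`.
#' @export
rule_covers <- function(rule, data) {
  conds <- if (inherits(rule, "survrules_rule")) rule$conditions else rule
  out <- rep(TRUE, nrow(data))
  for (cond in conds) out <- out & condition_covers(cond, data)
  out
}

#' Merge numeric conditions of a rule
#'
#' Post-processes a finalized rule for readability: all conditions on the
#' same numeric attribute are replaced by their intersection, so
#' `A >= x AND A < y` becomes `A in [x, y)` and repeated same-direction
#' thresholds collapse to the tightest one. Coverage is unchanged.
#'
#' @param rule a `survrules_rule` or list of conditions.
#' @return Object of the same kind with at most one condition per attribute.
#' @export
merge_numeric_conditions <- function(rule) {
  conds <- if (inherits(rule, "survrules_rule")) rule$conditions else rule
  attrs <- vapply(conds, function(cn) cn$attribute, "")
  merged <- list()
  for (a in unique(attrs)) {
    sub <- conds[attrs == a]
    if (all(vapply(sub, function(cn) cn$op == "=", TRUE))) {
      vals <- unique(vapply(sub, function(cn) cn$value, ""))
      if (length(vals) > 1)
        stop("contradictory premise: '", a, "' equal to several values")
      merged[[length(merged) + 1]] <- sub[[1]]
      next
    }
    lo <- -Inf; hi <- Inf
    for (cn in sub) {
      if (cn$op == ">=") lo <- max(lo, cn$value)
      else if (cn$op == "<") hi <- min(hi, cn$value)
      else if (cn$op == "in") { lo <- max(lo, cn$value[1]); hi <- min(hi, cn$value[2]) }
      else stop("cannot merge '=' with numeric conditions on '", a, "'")
    }
    if (lo >= hi)
      stop("contradictory premise: empty interval for '", a, "'")
    merged[[length(merged) + 1]] <-
      if (is.infinite(lo)) condition(a, "<", hi)
      else if (is.infinite(hi)) condition(a, ">=", lo)
      else condition(a, "in", c(lo, hi))
  }
  if (inherits(rule, "survrules_rule")) { rule$conditions <- merged; rule }
  else merged
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Format and parse rule premises
#'
#' `format_rule()` renders a rule premise as text, e.g.
#' `"pnodes >= 4.5 AND progrec < 28.5"` or `"estrec in [0.5, 37)"`; numbers
#' are written with 17 significant digits so `parse_rule(format_rule(r))`
#' reproduces the premise exactly. `parse_rule()` validates attribute names,
#' operator/kind compatibility and nominal domains against the attribute
#' metadata.
#'
#' @param rule a `survrules_rule` or list of conditions.
#' @param text premise text: conditions joined by `" AND "`.
#' @param attributes attribute metadata as stored in a fitted model
#'   (`fit$attributes`): a named list with `kind` (`"nominal"`/`"numeric"`)
#'   and, for nominal attributes, `domain`.
#' @return `format_rule()`: a character scalar. `parse_rule()`: a list of
#'   [condition()] objects.
#' @export
format_rule <- function(rule) {
  conds <- if (inherits(rule, "survrules_rule")) rule$conditions else rule
  if (length(conds) == 0) return("")
  paste(vapply(conds, function(cn) {
    switch(cn$op,
      "="  = paste(cn$attribute, "=", cn$value),
      "<"  = paste(cn$attribute, "<", fmt_num(cn$value)),
      ">=" = paste(cn$attribute, ">=", fmt_num(cn$value)),
      "in" = sprintf("%s in [%s, %s)", cn$attribute,
                     fmt_num(cn$value[1]), fmt_num(cn$value[2])))
  }, ""), collapse = " AND ")
}

#' @rdname format_rule
#' @export
parse_rule <- function(text, attributes) {
  parts <- strsplit(trimws(text), " AND ", fixed = TRUE)[[1]]
  if (length(parts) == 0 || !nzchar(trimws(text)))
    stop("empty rule premise")
  lapply(parts, parse_condition, attributes = attributes)
}

parse_condition <- function(txt, attributes) {
  txt <- trimws(txt)
  m <- regmatches(txt, regexec(
    "^(\\S+) in \\[\\s*([^,]+),\\s*([^)]+)\\)$", txt))[[1]]
  if (length(m) == 4) {
    check_attr(m[2], "numeric", attributes)
    return(condition(m[2], "in", c(parse_number(m[3]), parse_number(m[4]))))
  }
  m <- regmatches(txt, regexec("^(\\S+)\\s*(>=|<|=)\\s*(.+)$", txt))[[1]]
  if (length(m) != 4) stop("cannot parse condition: '", txt, "'")
  attr_name <- m[2]; op <- m[3]; val <- trimws(m[4])
  if (op == "=") {
    check_attr(attr_name, "nominal", attributes)
    if (!val %in% attributes[[attr_name]]$domain)
      stop("value '", val, "' not in the domain of '", attr_name, "'")
    condition(attr_name, "=", val)
  } else {
    check_attr(attr_name, "numeric", attributes)
    condition(attr_name, op, parse_number(val))
  }
}

check_attr <- function(name, kind, attributes) {
  if (!name %in% names(attributes))
    stop("unknown attribute: '", name, "'")
  if (attributes[[name]]$kind != kind)
    stop("attribute '", name, "' is ", attributes[[name]]$kind,
         " but the operator requires a ", kind, " attribute")
  invisible(TRUE)
}

parse_number <- function(s) {
  x <- suppressWarnings(as.numeric(trimws(s)))
  if (is.na(x)) stop("not a number: '", s, "'")
  x
}

#' @export
print.survrules_condition <- function(x, ...) {
  cat(format_rule(list(x)), "\n")
  invisible(x)
}
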