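#' Enumerate candidate elementary conditions
#'
#' The candidate pool of rule growing, built from the records currently
#' covered by the rule: for a nominal attribute, one equality condition per
#' domain value observed among the covered records; for a numeric attribute,
#' the distinct non-missing covered values are sorted, split points are the
#' arithmetic means of adjacent values, and both `A < a` and `A >= a` are
#' emitted per split point (ascending, `<` before `>=`). Missing values are
#' skipped, so an attribute entirely missing among the covered records
#' contributes no conditions.
#'
#' @param data data frame of the covariates of the currently covered records
#'   (factors are nominal, everything else numeric).
#' @return A list of [condition()] objects in deterministic order: attribute
#'   declaration order, then domain / split-point order.
#' @export
enumerate_conditions <- function(data) {
  if (nrow(data) == 0) stop("no covered records to enumerate conditions from")
  out <- list()
  for (nm in names(data)) {
    x <- data[[nm]]
    if (is.factor(x) || is.character(x)) {
      dom <- if (is.factor(x)) levels(x) else sort(unique(x[!is.na(x)]))
      observed <- dom[dom %in% as.character(x[!is.na(x)])]
      for (v in observed)
        out[[length(out) + 1]] <- condition(nm, "=", v)
    } else {
      vals <- sort(unique(x[!is.na(x)]))
      if (length(vals) >= 2) {
        splits <- (vals[-length(vals)] + vals[-1]) / 2
        for (s in splits) {
          out[[length(out) + 1]] <- condition(nm, "<", s)
          out[[length(out) + 1]] <- condition(nm, ">=", s)
        }
      }
    }
  }
  out
}
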