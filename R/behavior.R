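#' Default emotion item-to-composite mapping
#'
#' Twelve emotion items on a 0-20 scale: six negative and six positive.
#' The negative-affect composite is the mean of the six negative items; the
#' fear and anger composites are means of designated negative-item subsets.
#' The exact item composition of the subscales is study-specific
#' configuration, not code: supply your own mapping to
#' [composite_scores()] when your instrument differs.
#'
#' @return list with `negative_items`, `positive_items`, `fear`, `anger`.
#' @export
panas_mapping <- function() {
  list(negative_items = c("afraid", "scared", "upset", "distressed",
                          "irritable", "angry"),
       positive_items = c("interested", "excited", "strong", "enthusiastic",
                          "alert", "inspired"),
       fear = c("afraid", "scared"),
       anger = c("angry", "irritable"))
}

#' Composite emotion scores
#'
#' Appends `negative_affect`, `positive_affect`, `fear` and `anger` columns,
#' each the mean of its item set.
#'
#' @param table survey data.frame containing all twelve emotion items.
#' @param mapping item mapping, see [panas_mapping()].
#' @return the table with four composite columns appended.
#' @export
composite_scores <- function(table, mapping = panas_mapping()) {
  items <- c(mapping$negative_items, mapping$positive_items)
  missing_items <- setdiff(items, names(table))
  if (length(missing_items) > 0)
    stop("missing emotion items: ", paste(missing_items, collapse = ", "))
  table$negative_affect <- rowMeans(table[mapping$negative_items])
  table$positive_affect <- rowMeans(table[mapping$positive_items])
  table$fear <- rowMeans(table[mapping$fear])
  table$anger <- rowMeans(table[mapping$anger])
  table
}

#' Framing-effect linear model
#'
#' Least-squares regression of an outcome on the frame condition (neutral as
#' reference) plus covariates. For within-subject tables the participant is
#' absorbed as a fixed effect (equivalent to participant demeaning), the
#' dependency-light stand-in for a random participant intercept.
#' Rows with missing values in the model variables are dropped.
#'
#' @param table survey data.frame with a `frame` column (levels neutral,
#'   threat, blame) and, for `within_subject = TRUE`, a `participant_id`.
#' @param outcome outcome column name.
#' @param covariates covariate column names (may be empty).
#' @param within_subject absorb a participant fixed effect.
#' @return object of class `framing_model`: coefficient table (term, estimate,
#'   se, t, p, ci_lo, ci_hi; participant dummies omitted), n used, formula,
#'   and the underlying `lm` fit.
#' @export
fit_framing_model <- function(table, outcome, covariates = character(0),
                              within_subject = FALSE) {
  need <- c(outcome, "frame", covariates,
            if (within_subject) "participant_id")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0)
    stop("table missing columns: ", paste(missing_cols, collapse = ", "))
  tab <- table[stats::complete.cases(table[need]), need, drop = FALSE]
  tab$frame <- relevel(factor(tab$frame), ref = "neutral")
  if (any(table(tab$frame) == 0))
    stop("empty frame cells: ",
         paste(names(which(table(tab$frame) == 0)), collapse = ", "))
  rhs <- c("frame", covariates,
           if (within_subject) "factor(participant_id)")
  fml <- as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  fit <- lm(fml, data = tab)
  if (any(is.na(coef(fit)))) {
    dropped <- names(coef(fit))[is.na(coef(fit))]
    stop("collinear design; aliased terms: ", paste(dropped, collapse = ", "))
  }
  framing_model_result(fit, outcome, fml, nrow(tab))
}

framing_model_result <- function(fit, outcome, fml, n) {
  sm <- summary(fit)$coefficients
  keep <- !grepl("^factor\\(participant_id\\)", rownames(sm))
  sm <- sm[keep, , drop = FALSE]
  ci <- sm[, "Estimate"] + qt(0.975, df = fit$df.residual) *
    sm[, "Std. Error"] %o% c(-1, 1)
  coefficients <- data.frame(term = rownames(sm),
                             estimate = sm[, "Estimate"],
                             se = sm[, "Std. Error"],
                             t = sm[, "t value"],
                             p = sm[, "Pr(>|t|)"],
                             ci_lo = ci[, 1], ci_hi = ci[, 2],
                             row.names = NULL, stringsAsFactors = FALSE)
  structure(list(outcome = outcome, coefficients = coefficients, n = n,
                 formula = deparse(fml), fit = fit),
            class = "framing_model")
}

#' @export
print.framing_model <- function(x, digits = 3, ...) {
  cat(sprintf("Framing model for '%s' (n = %d)\n  %s\n",
              x$outcome, x$n, x$formula))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.framing_model <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.framing_model <- function(object, ...) object$coefficients

#' Interaction model with enforced marginality
#'
#' Fits an outcome on a set of model terms that may include interactions
#' (e.g. `"importance:frame:negative_affect"`). Every interaction must be
#' accompanied by all of its lower-order margins; requesting a three-way term
#' without its two-way terms and main effects is an error.
#'
#' @param table survey data.frame.
#' @param outcome outcome column name.
#' @param terms character vector of model terms; `a:b` denotes an
#'   interaction, `a*b` expands to the full crossing.
#' @param within_subject absorb a participant fixed effect.
#' @return a `framing_model`.
#' @export
interaction_model <- function(table, outcome, terms,
                              within_subject = FALSE) {
  expanded <- unique(unlist(lapply(terms, function(tm) {
    if (grepl("*", tm, fixed = TRUE)) {
      parts <- trimws(strsplit(tm, "*", fixed = TRUE)[[1]])
      unlist(lapply(seq_along(parts), function(k)
        apply(utils::combn(parts, k), 2, paste, collapse = ":")))
    } else tm
  })))
  for (tm in expanded[grepl(":", expanded, fixed = TRUE)]) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    margins <- unlist(lapply(seq_len(length(parts) - 1), function(k)
      apply(utils::combn(parts, k), 2, paste, collapse = ":")))
    canon <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                                function(p) paste(sort(p), collapse = ":"), "")
    absent <- setdiff(canon(margins), canon(expanded))
    if (length(absent) > 0)
      stop("interaction ", tm, " requested without its margins: ",
           paste(absent, collapse = ", "))
  }
  vars <- unique(unlist(strsplit(expanded, ":", fixed = TRUE)))
  need <- c(outcome, vars, if (within_subject) "participant_id")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0)
    stop("table missing columns: ", paste(missing_cols, collapse = ", "))
  tab <- table[stats::complete.cases(table[need]), need, drop = FALSE]
  if ("frame" %in% names(tab))
    tab$frame <- relevel(factor(tab$frame), ref = "neutral")
  rhs <- c(expanded, if (within_subject) "factor(participant_id)")
  fml <- as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  fit <- lm(fml, data = tab)
  if (any(is.na(coef(fit))))
    stop("collinear design; aliased terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  framing_model_result(fit, outcome, fml, nrow(tab))
}
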