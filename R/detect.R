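# Logistic model of molecular confirmation against observed
# co-occurrence counts, with an optional body-size covariate.

#' Per-larva detection records
#'
#' For every classified larva: x is the total number of observed
#' occurrences of its insect species on its collection host species
#' across the dataset, and y = 1 iff the molecular diet confirmed the
#' host (mismatch category "match"). Records are per larva, not per
#' unique pair, so a pair observed five times with two confirmations
#' yields five records with x = 5 of which two have y = 1.
#'
#' @param classified a [classify_diets()]-style table joined with the
#'   insect label and collection host; needs columns `insect`, `host`,
#'   `category`, optionally `body_size_mm`.
#' @return data.frame (insect, host, x, y, body_size_mm) per larva.
#' @export
occurrence_counts <- function(classified) {
  if (!nrow(classified)) {
    return(data.frame(insect = character(), host = character(),
                      x = integer(), y = integer(),
                      body_size_mm = numeric()))
  }
  stopifnot(all(c("insect", "host", "category") %in% names(classified)))
  key <- paste(classified$insect, classified$host, sep = "\r")
  x <- as.integer(table(key)[key])
  data.frame(
    insect = classified$insect, host = classified$host,
    x = x, y = as.integer(classified$category == "match"),
    body_size_mm = classified$body_size_mm %||% rep(NA_real_, nrow(classified)),
    stringsAsFactors = FALSE
  )
}

#' Fit the logistic detection model
#'
#' Maximum-likelihood logistic regression of confirmation on the
#' observed occurrence count (plus optional covariates), via iteratively
#' reweighted least squares with a 1e-8 deviance tolerance; Wald
#' z-statistics and p-values per coefficient.
#'
#' @param records an [occurrence_counts()] table.
#' @param covariates model terms (default `"x"`); e.g.
#'   `c("x", "body_size_mm")` adds the body-size check.
#' @return List of class `logistic_fit` with `coefficients`, `se`, `z`,
#'   `p_value`, `log_likelihood`, `converged`, `n` and the underlying
#'   `glm` object.
#' @export
fit_logistic <- function(records, covariates = "x") {
  if (!nrow(records) || length(unique(records$y)) < 2) {
    stopf("need both confirmed and unconfirmed records to fit")
  }
  fml <- stats::as.formula(paste("y ~", paste(covariates, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = records,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stopf("IRLS did not converge (separation?)")
  # complete separation shows up as fitted probabilities pinned at 0/1
  if (any(fit$fitted.values > 1 - 1e-10) && any(fit$fitted.values < 1e-10)) {
    stopf("complete separation: coefficients unbounded")
  }
  s <- summary(fit)$coefficients
  structure(list(
    coefficients = stats::setNames(s[, 1], rownames(s)),
    se = stats::setNames(s[, 2], rownames(s)),
    z = stats::setNames(s[, 3], rownames(s)),
    p_value = stats::setNames(s[, 4], rownames(s)),
    log_likelihood = as.numeric(stats::logLik(fit)),
    converged = fit$converged,
    n = nrow(records),
    glm = fit
  ), class = "logistic_fit")
}

#' Predicted confirmation probability
#'
#' exp(b0 + b1 x) / (1 + exp(b0 + b1 x)) for a fitted model or
#' user-supplied intercept and slope.
#'
#' @param fit a [fit_logistic()] object, or a numeric vector
#'   `c(intercept, slope)`.
#' @param x observed occurrence counts.
#' @return Probabilities in (0, 1).
#' @export
predict_probability <- function(fit, x) {
  if (inherits(fit, "logistic_fit")) {
    b0 <- fit$coefficients[["(Intercept)"]]
    b1 <- fit$coefficients[["x"]]
  } else {
    b0 <- fit[[1]]
    b1 <- fit[[2]]
  }
  stats::plogis(b0 + b1 * x)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic detection model (n = %d, logLik = %.2f)\n",
              x$n, x$log_likelihood))
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$z,
                   p = signif(x$p_value, 3)))
  invisible(x)
}

#' Serialize a logistic fit with a prediction table
#'
#' @param fit a [fit_logistic()] object.
#' @param path output path.
#' @param x_max largest occurrence count tabulated.
#' @return Invisibly, `path`.
#' @export
write_fit <- function(fit, path, x_max = 30) {
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients), se = as.list(fit$se),
         p_value = as.list(fit$p_value),
         log_likelihood = fit$log_likelihood, n = fit$n,
         predictions = data.frame(
           x = seq_len(x_max),
           probability = predict_probability(fit, seq_len(x_max))
         )),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
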