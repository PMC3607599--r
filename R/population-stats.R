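# Population-level statistics: fate fractions, distribution fits, and the
# two-condition F-then-t comparison protocol.

.TIMING_METRICS <- c(start_of_germination_min = "t_start_min",
                     germination_time_min = "germ_duration_min",
                     outgrowth_time_min = "outgrowth_time_min",
                     generation_time_min = "generation_time_min")

#' Classify spore fates and compute population fractions
#'
#' Assessed spores are all records not manually excluded. Germinated =
#' outgrowing + germinated-but-not-outgrowing (+ spores already phase-dark
#' at t = 0); outgrown = spores with a first division. Fractions are
#' percentages of the assessed denominator, which is reported alongside.
#'
#' @param records record data.frame (see [emptyRecords()]).
#' @param movieDurationMin movie length in minutes (reported for context:
#'   dormancy means "did not germinate within this observation window").
#' @return list: `n_assessed`, `counts` (per fate), `n_germinated`,
#'   `n_outgrown`, `fraction_germinated`, `fraction_outgrown` (percent),
#'   `movie_duration_min`.
#' @export
classifyFates <- function(records, movieDurationMin = NA_real_) {
  stopifnot(is.data.frame(records))
  assessed <- records[records$fate != "excluded", , drop = FALSE]
  n <- nrow(assessed)
  counts <- table(factor(assessed$fate,
                         levels = setdiff(.FATES, "excluded")))
  n_germ <- sum(assessed$fate %in%
                  c("outgrow", "germinate_only", "pre_germinated"))
  n_out <- sum(assessed$fate == "outgrow" |
                 (assessed$fate == "pre_germinated" &
                    is.finite(assessed$t_division_min)))
  list(n_assessed = n, counts = counts,
       n_germinated = n_germ, n_outgrown = n_out,
       fraction_germinated = if (n) 100 * n_germ / n else NA_real_,
       fraction_outgrown = if (n) 100 * n_out / n else NA_real_,
       movie_duration_min = movieDurationMin)
}

#' Fit a normal or lognormal distribution by maximum likelihood
#'
#' Location/scale are the MLEs (`mean`/`sd` with 1/n on the natural or the
#' log scale); the goodness metric is the log-likelihood, intended for
#' family selection. A degenerate sample (zero scale) is flagged.
#'
#' @param values numeric vector, `n >= 3`; strictly positive for the
#'   lognormal family.
#' @param family `"normal"` or `"lognormal"`.
#' @return list: `family`, `location`, `scale`, `logLik`, `n`, `flagged`.
#' @export
fitDistribution <- function(values, family = c("normal", "lognormal")) {
  family <- match.arg(family)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 values to fit a distribution")
  if (family == "lognormal" && any(values <= 0))
    stop("lognormal fit requires strictly positive values")
  x <- if (family == "lognormal") log(values) else values
  loc <- mean(x)
  sc <- sqrt(sum((x - loc)^2) / n)
  flagged <- sc == 0
  ll <- if (flagged) NA_real_ else if (family == "normal")
    sum(dnorm(values, loc, sc, log = TRUE)) else
    sum(dlnorm(values, loc, sc, log = TRUE))
  list(family = family, location = loc, scale = sc, logLik = ll, n = n,
       flagged = flagged)
}

#' Compare one metric between two conditions (F-test, then t-test)
#'
#' The protocol: a two-sided F-test on the variances at alpha = 0.05; if the
#' variances do not differ significantly, a pooled (equal-variance) t-test,
#' otherwise Welch's t-test. `mean_diff = mean_b - mean_a`.
#'
#' @param valuesA,valuesB numeric vectors (n >= 2 each).
#' @param metricName label carried into the output.
#' @param alpha significance level (fixed at 0.05 in the protocol).
#' @return one-row data.frame: `metric_name, mean_a, sd_a, n_a, mean_b,
#'   sd_b, n_b, f_statistic, f_p_value, t_statistic, t_p_value, t_variant,
#'   mean_diff, alpha`.
#' @export
compareConditions <- function(valuesA, valuesB, metricName = "metric",
                              alpha = 0.05) {
  valuesA <- valuesA[is.finite(valuesA)]
  valuesB <- valuesB[is.finite(valuesB)]
  if (length(valuesA) < 2 || length(valuesB) < 2)
    stop("need at least 2 values per condition")
  if (var(valuesA) == 0 && var(valuesB) == 0)
    stop("degenerate (zero-variance) inputs in both conditions")
  ft <- var.test(valuesA, valuesB)
  pooled <- ft$p.value >= alpha
  tt <- t.test(valuesB, valuesA, var.equal = pooled)
  data.frame(metric_name = metricName,
             mean_a = mean(valuesA), sd_a = sd(valuesA),
             n_a = length(valuesA),
             mean_b = mean(valuesB), sd_b = sd(valuesB),
             n_b = length(valuesB),
             f_statistic = unname(ft$statistic), f_p_value = ft$p.value,
             t_statistic = unname(tt$statistic), t_p_value = tt$p.value,
             t_variant = if (pooled) "pooled" else "welch",
             mean_diff = mean(valuesB) - mean(valuesA),
             alpha = alpha, stringsAsFactors = FALSE)
}

#' Summarize one condition's records
#'
#' Fate fractions plus mean/sd/n of each timing metric over the spores for
#' which it is defined (dormant and undetected spores contribute to the
#' fractions but not to the timing distributions).
#'
#' @param records record data.frame.
#' @param condition label carried into the output.
#' @param movieDurationMin movie length in minutes.
#' @return list: `condition`, the [classifyFates()] fields, and per metric
#'   `mean`, `sd`, `n`.
#' @export
summarizeCondition <- function(records, condition = "condition",
                               movieDurationMin = NA_real_) {
  cf <- classifyFates(records, movieDurationMin)
  metrics <- lapply(.TIMING_METRICS, function(col) {
    v <- records[[col]][records$fate != "excluded"]
    v <- v[is.finite(v)]
    list(mean = if (length(v)) mean(v) else NA_real_,
         sd = if (length(v) > 1) sd(v) else NA_real_, n = length(v))
  })
  c(list(condition = condition), cf, list(metrics = metrics))
}

#' Per-metric differences between two condition summaries
#'
#' Fraction deltas are percentage points `a - b` (how many fewer spores of
#' condition b germinate / grow out, the convention used when condition a
#' is the untreated reference); timing deltas are minutes `b - a` (how much
#' later or longer condition b is).
#'
#' @param summaryA,summaryB lists from [summarizeCondition()]; `summaryA`
#'   is the reference (control).
#' @return data.frame `(metric, value_a, value_b, delta, unit)`.
#' @export
conditionDeltas <- function(summaryA, summaryB) {
  rows <- list(
    data.frame(metric = "fraction_germinated",
               value_a = summaryA$fraction_germinated,
               value_b = summaryB$fraction_germinated,
               delta = summaryA$fraction_germinated -
                 summaryB$fraction_germinated,
               unit = "percentage_points", stringsAsFactors = FALSE),
    data.frame(metric = "fraction_outgrown",
               value_a = summaryA$fraction_outgrown,
               value_b = summaryB$fraction_outgrown,
               delta = summaryA$fraction_outgrown -
                 summaryB$fraction_outgrown,
               unit = "percentage_points", stringsAsFactors = FALSE))
  for (mn in names(.TIMING_METRICS)) {
    ma <- summaryA$metrics[[mn]]; mb <- summaryB$metrics[[mn]]
    rows[[length(rows) + 1L]] <- data.frame(
      metric = mn, value_a = ma$mean, value_b = mb$mean,
      delta = mb$mean - ma$mean, unit = "min", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
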