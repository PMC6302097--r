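#' Regression of offspring count on an adjusted phenotype
#'
#' Ordinary least squares of the number of children on the (age-adjusted)
#' phenotype, after excluding implausible offspring counts, plus the
#' Pearson correlation with a Fisher-z confidence interval.
#'
#' @param children non-negative offspring counts.
#' @param adjusted_pheno adjusted phenotype, same individuals.
#' @param max_children records above this count are excluded from the fit.
#' @return An object of class `selection_estimate` with `slope_b`,
#'   `se_slope`, `p_slope`, `pearson_r`, `r_ci`, `sd_pheno`,
#'   `mean_children`, `n`; `per_sd` and `gradient` are completed by
#'   [selection_gradient()].
#' @export
fertility_regression <- function(children, adjusted_pheno, max_children = 20) {
  ok <- !is.na(children) & !is.na(adjusted_pheno) & children <= max_children
  ch <- children[ok]; ph <- adjusted_pheno[ok]
  if (sd(ph) == 0) stop("zero phenotype variance", call. = FALSE)
  fit <- lm(ch ~ ph)
  co <- summary(fit)$coefficients
  rr <- repeatability(ch, ph)    # Pearson r with Fisher-z CI
  structure(list(slope_b = unname(co["ph", "Estimate"]),
                 se_slope = unname(co["ph", "Std. Error"]),
                 p_slope = unname(co["ph", "Pr(>|t|)"]),
                 pearson_r = rr$r, r_ci = rr$ci,
                 sd_pheno = sd(ph), mean_children = mean(ch),
                 n = sum(ok), per_sd = NA_real_, gradient = NA_real_),
            class = "selection_estimate")
}

#' Linear selection gradient from a fertility regression
#'
#' Scales the children-per-score slope by the phenotype SD and divides by
#' mean offspring count, so the gradient is the change in relative fitness
#' (offspring count standardized by its mean) per phenotype standard
#' deviation.
#'
#' @param slope_b children per phenotype unit, or a `selection_estimate`
#'   from [fertility_regression()] (then the other arguments default to
#'   its fields).
#' @param sd_pheno phenotype standard deviation.
#' @param mean_children mean offspring count (must be positive).
#' @return A completed `selection_estimate` with `per_sd` (children per
#'   phenotype SD) and `gradient`.
#' @export
selection_gradient <- function(slope_b, sd_pheno = NULL, mean_children = NULL) {
  if (inherits(slope_b, "selection_estimate")) {
    est <- slope_b
    sd_pheno <- sd_pheno %||% est$sd_pheno
    mean_children <- mean_children %||% est$mean_children
    slope_b <- est$slope_b
  } else {
    est <- structure(list(slope_b = slope_b, se_slope = NA_real_,
                          p_slope = NA_real_, pearson_r = NA_real_,
                          r_ci = c(NA_real_, NA_real_)),
                     class = "selection_estimate")
  }
  if (is.null(mean_children) || mean_children <= 0)
    stop("mean_children must be positive", call. = FALSE)
  est$sd_pheno <- sd_pheno
  est$mean_children <- mean_children
  est$per_sd <- slope_b * sd_pheno
  est$gradient <- est$per_sd / mean_children
  est
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf("selection_estimate: slope = %.4f children/unit, r = %.3f\n",
              x$slope_b, x$pearson_r))
  if (!is.na(x$per_sd))
    cat(sprintf("  per SD = %.4f children; gradient = %.4f per SD\n",
                x$per_sd, x$gradient))
  invisible(x)
}

#' Expected offspring-count contrast between two scores
#'
#' @param slope_b children per score unit.
#' @param score_a,score_b scores to contrast (default 4 vs 1).
#' @return `slope_b * (score_a - score_b)`.
#' @export
score_contrast <- function(slope_b, score_a = 4, score_b = 1) {
  slope_b * (score_a - score_b)
}
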