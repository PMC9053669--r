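#' Assemble the carrier 2x2 table from a cohort
#'
#' @param cohort a `cnv_cohort`.
#' @param carrier named logical vector over the cohort's sample ids.
#' @return A [contingency_2x2()] with margins equal to the group sizes.
#' @export
burden_table <- function(cohort, carrier) {
  stopifnot(all(cohort$sample_id %in% names(carrier)))
  carr <- carrier[cohort$sample_id]
  case <- cohort$group == "CASE"
  contingency_2x2(sum(carr & case), sum(!carr & case),
                  sum(carr & !case), sum(!carr & !case))
}

#' Multivariable logistic burden model
#'
#' Maximum-likelihood logistic regression of case status on: carrier status
#' (a miRNA target gene overlapped by an additional rare CNV), the summed
#' size in bp of all rare CNVs (scaled to Mb internally, reported per bp
#' effect via the Mb-scale OR), the number of protein-coding genes
#' overlapped, and sex (FEMALE = 0, MALE = 1, so male sex carries a positive
#' coefficient when cases are more often male).
#'
#' @param cohort a `cnv_cohort` with covariate columns from
#'   [cohort_covariates()].
#' @param carrier named logical vector over the cohort's sample ids.
#' @param alpha Wald CI level complement.
#' @return A `logistic_burden` object: coefficient table (term, estimate, se,
#'   OR, CI, p), convergence flag, and the fitted `glm`.
#' @export
fit_logistic_burden <- function(cohort, carrier, alpha = 0.05) {
  stopifnot(all(c("total_cnv_bp", "n_genes_overlapped") %in% names(cohort)))
  carr <- as.numeric(carrier[cohort$sample_id])
  if (all(carr == 1) || all(carr == 0))
    stop("need at least one carrier and one non-carrier")
  dat <- data.frame(y = as.numeric(cohort$group == "CASE"),
                    carrier = carr,
                    cnv_mb = cohort$total_cnv_bp / 1e6,
                    n_genes = cohort$n_genes_overlapped,
                    sex_male = as.numeric(cohort$sex == "MALE"))
  fit <- stats::glm(y ~ carrier + cnv_mb + n_genes + sex_male,
                    family = stats::binomial(), data = dat)
  # Complete separation shows up as fitted probabilities pinned to 0/1 and
  # runaway coefficients; report the offending covariate instead of a silent
  # divergent fit.
  eps <- 1e-8
  if (any(abs(stats::coef(fit)[-1]) > 15) &&
      all(fit$fitted.values > 1 - eps | fit$fitted.values < eps)) {
    bad <- names(which.max(abs(stats::coef(fit)[-1])))
    stop("complete separation detected on covariate: ", bad)
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - alpha / 2)
  terms <- rownames(sm)
  res <- data.frame(term = terms,
                    estimate = sm[, 1], se = sm[, 2],
                    or = exp(sm[, 1]),
                    ci_low = exp(sm[, 1] - z * sm[, 2]),
                    ci_high = exp(sm[, 1] + z * sm[, 2]),
                    p = sm[, 4],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(list(coefficients = res,
                 converged = fit$converged,
                 max_abs_score = max(abs(stats::coef(fit))),
                 alpha = alpha,
                 fit = fit),
            class = "logistic_burden")
}

#' @export
print.logistic_burden <- function(x, ...) {
  tab <- x$coefficients
  tab$or <- round(tab$or, 2)
  tab$ci_low <- round(tab$ci_low, 2); tab$ci_high <- round(tab$ci_high, 2)
  tab$p <- round(tab$p, 4)
  print(tab[, c("term", "or", "ci_low", "ci_high", "p")], row.names = FALSE)
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' Carrier odds ratio row of a logistic burden fit
#' @param fit a `logistic_burden`.
#' @export
carrier_effect <- function(fit) {
  fit$coefficients[fit$coefficients$term == "carrier", , drop = FALSE]
}
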