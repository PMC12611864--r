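# Multivariable logistic model of death classification: per vaccine class,
# the log-odds of a report being classified as death are modelled on age
# group (reference: 6 weeks to 4 months), sex (reference: male) and
# co-administration (reference: vaccine given alone).

#' Build the regression design for the death model
#'
#' Subsets one vaccine class, excludes reports with unknown sex (the model
#' contrasts female vs male; the exclusion count is messaged), drops
#' factors that are constant in the subset with a warning, and checks each
#' remaining covariate level for outcome separation (a level whose reports
#' are all deaths or all non-deaths), which is warned about by name.
#'
#' @param reports analysis-ready report tibble.
#' @param class `"penta"` or `"hexa"`.
#' @return a `death_design` list: `data` (model frame), `formula`, and
#'   `n_excluded_unknown_sex`.
#' @export
build_design <- function(reports, class = c("penta", "hexa")) {
  class <- match.arg(class)
  sub <- reports[reports$vaccine_class == class, ]
  if (!nrow(sub)) stop("build_design: no reports for class ", class)
  n_unknown <- sum(sub$sex == "unknown")
  if (n_unknown > 0) {
    message("build_design: excluding ", n_unknown,
      " report(s) with unknown sex from the ", class, " regression")
  }
  sub <- sub[sub$sex != "unknown", ]
  if (sum(sub$died) == 0) stop("build_design: zero deaths in class ", class)
  if (sum(!sub$died) == 0) stop("build_design: zero non-deaths in class ", class)

  df <- data.frame(
    died = sub$died,
    age_group = droplevels(factor(sub$age_group, levels = AGE_GROUPS)),
    sex = droplevels(factor(as.character(sub$sex), levels = c("male", "female"))),
    coadmin = factor(ifelse(sub$vaccine_alone, "no", "yes"), levels = c("no", "yes"))
  )
  terms <- c("age_group", "sex", "coadmin")
  keep <- vapply(terms, function(t) nlevels(droplevels(df[[t]])) > 1, logical(1))
  for (t in terms[!keep]) {
    warning("build_design: covariate '", t, "' is constant in the ", class,
      " subset and was dropped", call. = FALSE)
  }
  terms <- terms[keep]
  if (!length(terms)) stop("build_design: no usable covariates for class ", class)
  df[terms] <- lapply(df[terms], droplevels)

  for (t in terms) {
    for (lv in levels(df[[t]])) {
      outcomes <- df$died[df[[t]] == lv]
      if (length(outcomes) && (all(outcomes) || !any(outcomes))) {
        warning("build_design: possible outcome separation at ", t, " = ", lv,
          " (", if (all(outcomes)) "all deaths" else "no deaths", ")",
          call. = FALSE)
      }
    }
  }
  structure(list(
    data = df,
    formula = stats::reformulate(terms, response = "died"),
    vaccine_class = class,
    n_excluded_unknown_sex = n_unknown
  ), class = "death_design")
}

#' Fit the logistic death model
#'
#' Maximum-likelihood binomial fit by iteratively reweighted least squares
#' (convergence tolerance 1e-10 on the relative deviance change, at most
#' 100 iterations), with odds ratios, Wald 95% intervals
#' `exp(beta +/- 1.96 SE)` and two-sided Wald p-values per non-reference
#' level. Non-convergence or an aliased (rank-deficient) design is an
#' error.
#'
#' @param design a `death_design` from [build_design()].
#' @return a `logistic_fit`: tibble `terms` (term, level, reference,
#'   estimate, se, or, or_lo, or_hi, p, significant) plus `n_used`,
#'   `iterations`, `converged`, `deviance` and the underlying `glm` object.
#' @export
fit_logistic <- function(design) {
  if (!inherits(design, "death_design")) {
    stop("fit_logistic: design must come from build_design()")
  }
  fit <- stats::glm(design$formula, family = stats::binomial(),
    data = design$data,
    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    stop("fit_logistic: IRLS did not converge in ", fit$iter,
      " iterations (deviance ", format(fit$deviance), ")")
  }
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("fit_logistic: design is rank deficient; aliased term(s): ",
      paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))

  # map coefficient names back to (term, level, reference)
  labels <- names(beta)
  meta <- lapply(labels, function(lb) {
    if (lb == "(Intercept)") return(c("(Intercept)", "", ""))
    for (t in attr(stats::terms(design$formula), "term.labels")) {
      if (startsWith(lb, t)) {
        return(c(t, sub(paste0("^", t), "", lb),
          levels(design$data[[t]])[1]))
      }
    }
    c(lb, "", "")
  })
  meta <- do.call(rbind, meta)

  terms_tbl <- tibble::tibble(
    term = meta[, 1], level = meta[, 2], reference = meta[, 3],
    estimate = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    or_lo = exp(unname(beta) - 1.96 * unname(se)),
    or_hi = exp(unname(beta) + 1.96 * unname(se)),
    p = unname(p),
    significant = unname(p) < 0.05
  )
  structure(list(
    terms = terms_tbl,
    vaccine_class = design$vaccine_class,
    n_used = stats::nobs(fit),
    n_excluded_unknown_sex = design$n_excluded_unknown_sex,
    iterations = fit$iter,
    converged = fit$converged,
    deviance = fit$deviance,
    glm = fit
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic model of death classification (", x$vaccine_class,
    " class), n = ", x$n_used, "\n", sep = "")
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' Fit the death model for one vaccine class
#'
#' Convenience wrapper: [build_design()] then [fit_logistic()].
#'
#' @inheritParams build_design
#' @return a `logistic_fit`.
#' @export
fit_death_model <- function(reports, class = c("penta", "hexa")) {
  fit_logistic(build_design(reports, class))
}
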