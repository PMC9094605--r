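#' Factorial mixed-model specification
#'
#' Declares the model fit to any pipeline readout: Gaussian linear mixed
#' model with the listed main effects, the full k-way interaction product
#' of `interaction_factors` (including all lower-order terms), and a
#' random intercept per animal, estimated by maximum likelihood (so that
#' fixed-effect structures are comparable by likelihood ratio). In the
#' canonical study the interaction factors are age at injection,
#' genotype, treatment, timepoint and brain region (histology) or
#' electrode (electrophysiology); sex enters as a main effect only.
#'
#' @param outcome name of the outcome column.
#' @param main_effects factor columns entering as main effects.
#' @param interaction_factors factor columns whose full factorial product
#'   forms the interaction set (must be a subset of `main_effects`).
#' @param random grouping column for the random intercept, default
#'   `"animal_id"`.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(outcome = "value",
                       main_effects = c("sex", "age", "genotype",
                                        "treatment", "timepoint", "region"),
                       interaction_factors = c("age", "genotype",
                                               "treatment", "timepoint",
                                               "region"),
                       random = "animal_id") {
  if (!all(interaction_factors %in% main_effects)) {
    abort("`interaction_factors` must be a subset of `main_effects`")
  }
  structure(list(outcome = outcome, main_effects = main_effects,
                 interaction_factors = interaction_factors, random = random),
            class = "model_spec")
}

# Observed-level bookkeeping: factors with < 2 observed levels cannot be
# estimated and are dropped with a warning.
usable_factors <- function(table, factors) {
  nlev <- vapply(factors, function(f) {
    if (!f %in% names(table)) {
      abort(sprintf("factor `%s` not found in the table", f))
    }
    length(unique(table[[f]][!is.na(table[[f]])]))
  }, integer(1))
  dropped <- factors[nlev < 2]
  if (length(dropped)) {
    warn(paste0("dropping single-level factor(s): ",
                paste(dropped, collapse = ", ")))
  }
  factors[nlev >= 2]
}

# All interaction term labels (order >= 2) of the factorial product, in
# the canonical expansion order used by terms().
interaction_terms <- function(factors) {
  if (length(factors) < 2) return(character(0))
  unlist(lapply(2:length(factors), function(k) {
    combn(factors, k, paste, collapse = ":")
  }))
}

build_formula <- function(spec, table, drop_terms = character(),
                          random = TRUE) {
  mains <- usable_factors(table, spec$main_effects)
  inter <- intersect(spec$interaction_factors, mains)
  rhs <- c(setdiff(mains, inter),
           if (length(inter) >= 2) paste(inter, collapse = " * ")
           else inter)
  rhs <- paste(rhs, collapse = " + ")
  if (length(drop_terms)) {
    rhs <- paste(rhs, "-", paste(drop_terms, collapse = " - "))
  }
  if (rhs == "") rhs <- "1"
  if (random) rhs <- paste0(rhs, " + (1 | ", spec$random, ")")
  stats::as.formula(paste(spec$outcome, "~", rhs))
}

#' Fit the factorial linear mixed model
#'
#' Gaussian LMM with animal random intercept, fit by maximum likelihood
#' via [lme4::lmer()] (deterministic optimizer start, so fits are
#' reproducible given the data). Singular random-effect fits are
#' tolerated; optimizer non-convergence is flagged and such fits are
#' refused by the likelihood-ratio machinery.
#'
#' @param table study tibble (see [simulate_study_table()] for the layout).
#' @param spec a [model_spec()].
#' @param drop_terms interaction term labels excluded from the fixed
#'   structure (used by the likelihood-ratio machinery).
#' @return An object of class `lfpath_fit`: list with the `lme4` model,
#'   `loglik`, `n_fixed`, `df_residual` (observations minus fixed-effect
#'   parameters), `converged`, and the formula. Supports [tidy()] and
#'   [glance()].
#' @export
fit_lmm <- function(table, spec, drop_terms = character()) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$outcome %in% names(table)) {
    abort(sprintf("outcome `%s` not found in the table", spec$outcome))
  }
  # the random intercept is unidentifiable with one row per animal, and a
  # noiseless (zero-residual) mixed fit has a degenerate covariance; both
  # cases drop to ordinary least squares on the same fixed structure
  use_lmm <- length(unique(table[[spec$random]])) < nrow(table)
  fit <- NULL
  if (use_lmm) {
    form <- suppressWarnings(build_formula(spec, table, drop_terms))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = table, REML = FALSE)
    ))
    if (stats::sigma(fit) < 1e-8) fit <- NULL
  }
  if (is.null(fit)) {
    form <- suppressWarnings(build_formula(spec, table, drop_terms,
                                           random = FALSE))
    fit <- stats::lm(form, data = table)
    conv <- TRUE
    nf <- sum(!is.na(coef(fit)))
  } else {
    conv <- fit@optinfo$conv$opt == 0
    nf <- length(lme4::fixef(fit))
  }
  structure(list(model = fit, formula = form, loglik = as.numeric(logLik(fit)),
                 n_fixed = nf, df_residual = nobs(fit) - nf,
                 converged = isTRUE(conv), spec = spec,
                 drop_terms = drop_terms),
            class = "lfpath_fit")
}

#' @export
print.lfpath_fit <- function(x, ...) {
  cat("<lfpath_fit> ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  ML logLik %.3f | %d fixed parameters | residual df %d | %s\n",
              x$loglik, x$n_fixed, x$df_residual,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of a fitted mixed model
#' @param x an `lfpath_fit`.
#' @param ... unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `t_ratio`.
#' @export
#' @exportS3Method generics::tidy
tidy.lfpath_fit <- function(x, ...) {
  cf <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(term = rownames(cf), estimate = unname(cf[, 1]),
                 std_error = unname(cf[, 2]), t_ratio = unname(cf[, 3]))
}

#' One-row model summary
#' @param x an `lfpath_fit`.
#' @param ... unused.
#' @return Tibble with log-likelihood, parameter counts, sigma and
#'   convergence flag.
#' @export
#' @exportS3Method generics::glance
glance.lfpath_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_fixed = x$n_fixed,
                 df_residual = x$df_residual,
                 sigma = stats::sigma(x$model),
                 converged = x$converged,
                 n_obs = nobs(x$model))
}

#' Degrees of freedom of an interaction term
#'
#' The product over the term's factors of (observed levels - 1): the
#' number of coefficients the term adds to a full-factorial design. A
#' term containing a single-level factor has 0 df (with a warning).
#'
#' @param table study tibble supplying the observed levels.
#' @param term interaction term as `"a:b:c"` or a character vector of
#'   factor names.
#' @return Integer df.
#' @examples
#' tbl <- simulate_study_table(study_spec())
#' interaction_df(tbl, "age:genotype:treatment:timepoint:region")
#' @export
interaction_df <- function(table, term) {
  factors <- if (length(term) == 1) strsplit(term, ":", fixed = TRUE)[[1]]
  else term
  missing <- setdiff(factors, names(table))
  if (length(missing)) {
    abort(paste0("unknown factor(s) in term: ",
                 paste(missing, collapse = ", ")))
  }
  nlev <- vapply(factors,
                 function(f) length(unique(table[[f]][!is.na(table[[f]])])),
                 integer(1))
  if (any(nlev < 2)) {
    warn(paste0("term contains single-level factor(s): ",
                paste(factors[nlev < 2], collapse = ", "), "; df = 0"))
    return(0L)
  }
  as.integer(prod(nlev - 1L))
}

#' Likelihood-ratio test of one interaction term
#'
#' Compares the model containing all terms against the null model with
#' `term` removed (both by maximum likelihood):
#' `chi2 = 2 (logLik_full - logLik_null)`, df from [interaction_df()],
#' p from the upper chi-square tail.
#'
#' @param table study tibble.
#' @param spec a [model_spec()].
#' @param term interaction term label, e.g.
#'   `"age:genotype:treatment:timepoint:region"`.
#' @param base_drop terms already removed from both models (the
#'   drop-and-refit trail uses this).
#' @return Tibble with `term`, `chi2`, `df`, `p`.
#' @export
lrt_interaction <- function(table, spec, term, base_drop = character()) {
  full <- fit_lmm(table, spec, drop_terms = base_drop)
  null <- fit_lmm(table, spec, drop_terms = union(base_drop, term))
  if (!full$converged || !null$converged) {
    abort(sprintf("non-converged fit in LRT for term `%s`", term))
  }
  if (null$n_fixed > full$n_fixed) {
    abort("null model is not nested in the full model")
  }
  chi2 <- max(0, 2 * (full$loglik - null$loglik))
  df <- suppressWarnings(interaction_df(table, term))
  p <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  tibble::tibble(term = term, chi2 = chi2, df = df, p = p)
}

#' Drop-and-refit likelihood-ratio trail over interaction orders
#'
#' Tests the highest-order interaction term of the factorial product; if
#' it is not significant at `alpha`, removes it, refits, and tests each
#' term of the next lower order against its own null (the refitted model
#' without that term), continuing downward while entire orders test
#' non-significant. The full decision trail is returned.
#'
#' @param table study tibble.
#' @param spec a [model_spec()].
#' @param alpha significance threshold, default 0.05.
#' @param min_order lowest interaction order to test, default 2.
#' @return Tibble with `term`, `order`, `chi2`, `df`, `p`, `significant`,
#'   `dropped`; zero rows when the spec has no interactions.
#' @export
drop_and_refit <- function(table, spec, alpha = 0.05, min_order = 2) {
  factors <- suppressWarnings(
    intersect(spec$interaction_factors,
              usable_factors(table, spec$main_effects)))
  if (length(factors) < 2) {
    return(tibble::tibble(term = character(), order = integer(),
                          chi2 = numeric(), df = integer(), p = numeric(),
                          significant = logical(), dropped = logical()))
  }
  trail <- list()
  dropped <- character(0)
  for (ord in seq(length(factors), min_order)) {
    terms_k <- combn(factors, ord, paste, collapse = ":")
    res <- purrr::map_dfr(terms_k, function(tm) {
      out <- lrt_interaction(table, spec, tm, base_drop = dropped)
      out$order <- ord
      out$significant <- !is.na(out$p) && out$p < alpha
      out
    })
    any_sig <- any(res$significant)
    res$dropped <- !any_sig
    trail[[length(trail) + 1]] <- res
    if (any_sig) break
    dropped <- c(dropped, terms_k)
  }
  dplyr::bind_rows(trail)[, c("term", "order", "chi2", "df", "p",
                              "significant", "dropped")]
}

#' Pairwise contrasts of predicted marginal means
#'
#' Predicted marginal means per cell of the `contrast` factor (within
#' levels of the `by` factors, averaging over all other fixed factors
#' with equal cell weights - sex in particular is averaged over), with
#' pairwise differences, SEs from the coefficient covariance, t ratios at
#' a constant residual df (observations minus fixed-effect parameters;
#' `df_method = "asymptotic"` uses normal-theory z instead), raw
#' two-sided p-values and Benjamini-Hochberg q-values across the table.
#'
#' @param fit an [fit_lmm()] result.
#' @param contrast factor whose levels are compared pairwise.
#' @param by optional conditioning factors (one contrast table per cell).
#' @param df_method `"residual"` (default) or `"asymptotic"`.
#' @return A `contrast_table` tibble: `comparison`, any `by` columns,
#'   `estimate`, `se`, `df`, `t_ratio`, `p`, `q`.
#' @export
marginal_contrasts <- function(fit, contrast, by = NULL,
                               df_method = c("residual", "asymptotic")) {
  stopifnot(inherits(fit, "lfpath_fit"))
  df_method <- match.arg(df_method)
  if (!fit$converged) abort("cannot form contrasts from a non-converged fit")
  emm <- if (inherits(fit$model, "merMod")) {
    suppressMessages(
      emmeans::emmeans(fit$model, specs = contrast, by = by,
                       lmer.df = "asymptotic", data = fit$model@frame))
  } else {
    # noiseless least-squares fits trip the "essentially perfect fit"
    # warning inside vcov(); SE = 0 is the intended answer there
    suppressWarnings(suppressMessages(
      emmeans::emmeans(fit$model, specs = contrast, by = by)))
  }
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "none"),
                 infer = FALSE)
  out <- tibble::as_tibble(prs)
  names(out)[names(out) == "contrast"] <- "comparison"
  names(out)[names(out) == "SE"] <- "se"
  out$comparison <- as.character(out$comparison)
  df <- if (df_method == "residual") fit$df_residual else Inf
  out$df <- df
  out$t_ratio <- ifelse(out$se > 0, out$estimate / out$se,
                        ifelse(out$estimate == 0, 0, sign(out$estimate) * Inf))
  out$p <- 2 * pt(-abs(out$t_ratio), df)
  out$q <- bh_adjust(out$p)
  keep <- c("comparison", by, "estimate", "se", "df", "t_ratio", "p", "q")
  structure(out[, keep], class = c("contrast_table", class(out)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Maps raw p-values to q-values controlling the false discovery rate:
#' on the sorted scale `q_(i) = min_{j >= i} m p_(j) / j`, mapped back to
#' the input order. Elementwise `q >= p`, and the output is permutation
#' -equivariant.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("all p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
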