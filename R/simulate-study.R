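#' Specification for a synthetic factorial study table
#'
#' Emulates the outcome table of a longitudinal two-by-two factorial
#' seeding study: between-animal factors sex, genotype (TG/WT), treatment
#' (tau/buffer) and age at injection (3mo/6mo), crossed within animal with
#' timepoint and region (brain region or electrode). Outcomes are drawn
#' from a Gaussian linear mixed model with known fixed-effect coefficients,
#' an animal-level random intercept and residual noise, so downstream fits
#' can be checked against ground truth.
#'
#' Fixed effects are declared by name against the columns of the treatment
#' -contrast model matrix of
#' `~ sex + age * genotype * treatment * timepoint * region`
#' (e.g. `"genotypeWT"`, `"treatmenttau:regionRSC"`); unnamed columns get
#' coefficient 0. Use [study_term_names()] to list the valid names.
#'
#' @param n_per_cell animals per sex x genotype x treatment x age cell.
#' @param timepoints character vector of timepoint labels (>= 1).
#' @param regions character vector of region/electrode labels (>= 1).
#' @param coefficients named numeric vector/list of true fixed effects,
#'   including `"(Intercept)"`; unknown names are an error.
#' @param random_intercept_sd animal-level SD (>= 0).
#' @param residual_sd observation-level SD (>= 0).
#' @param sexes,genotypes,treatments,ages factor levels; each needs >= 1
#'   level, defaults are the full study design.
#' @param seed integer seed.
#' @return A list of class `study_spec`.
#' @seealso [simulate_study_table()]
#' @export
study_spec <- function(n_per_cell = 2,
                       timepoints = c("1mpi", "3mpi", "5mpi"),
                       regions = c("HPC", "RSC", "MEC", "Tha"),
                       coefficients = c("(Intercept)" = 0),
                       random_intercept_sd = 0, residual_sd = 1,
                       sexes = c("F", "M"), genotypes = c("TG", "WT"),
                       treatments = c("buffer", "tau"),
                       ages = c("3mo", "6mo"), seed = 1) {
  assert_scalar_num(n_per_cell, "n_per_cell", lower = 1)
  assert_scalar_num(random_intercept_sd, "random_intercept_sd", lower = 0)
  assert_scalar_num(residual_sd, "residual_sd", lower = 0)
  stopifnot(length(timepoints) >= 1, length(regions) >= 1)
  structure(list(n_per_cell = as.integer(n_per_cell),
                 timepoints = timepoints, regions = regions,
                 coefficients = unlist(coefficients),
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd, sexes = sexes,
                 genotypes = genotypes, treatments = treatments,
                 ages = ages, seed = seed),
            class = "study_spec")
}

study_design_grid <- function(spec) {
  animals <- expand.grid(sex = spec$sexes, genotype = spec$genotypes,
                         treatment = spec$treatments, age = spec$ages,
                         rep = seq_len(spec$n_per_cell),
                         stringsAsFactors = FALSE)
  animals$animal_id <- sprintf("a%03d", seq_len(nrow(animals)))
  tbl <- tidyr::expand_grid(animals,
                            timepoint = spec$timepoints,
                            region = spec$regions)
  tbl$rep <- NULL
  for (f in c("sex", "genotype", "treatment", "age", "timepoint", "region")) {
    lev <- switch(f, sex = spec$sexes, genotype = spec$genotypes,
                  treatment = spec$treatments, age = spec$ages,
                  timepoint = spec$timepoints, region = spec$regions)
    tbl[[f]] <- factor(tbl[[f]], levels = lev)
  }
  tibble::as_tibble(tbl)
}

study_model_matrix <- function(tbl) {
  # single-level factors cannot enter a model matrix; hold them out
  varying <- vapply(c("sex", "age", "genotype", "treatment", "timepoint",
                      "region"),
                    function(f) nlevels(droplevels(tbl[[f]])) >= 2, logical(1))
  fixed <- names(varying)[varying]
  inter <- setdiff(fixed, "sex")
  rhs <- c(intersect("sex", fixed),
           if (length(inter)) paste(inter, collapse = " * "))
  form <- stats::reformulate(if (length(rhs)) rhs else "1")
  stats::model.matrix(form, data = tbl)
}

#' Valid fixed-effect term names for a study spec
#' @param spec a [study_spec()].
#' @return Character vector of model-matrix column names.
#' @export
study_term_names <- function(spec) {
  colnames(study_model_matrix(study_design_grid(spec)))
}

#' Simulate a factorial study outcome table
#'
#' One row per animal x timepoint x region; `value` is the declared linear
#' predictor plus the animal random intercept and residual noise. The true
#' coefficient vector (aligned to the full model matrix), the realized
#' random intercepts and the spec are attached as attribute `truth`.
#'
#' @param spec a [study_spec()].
#' @param outcome name of the outcome column, default `"value"`.
#' @return A tibble with columns `animal_id`, `sex`, `genotype`,
#'   `treatment`, `age`, `timepoint`, `region` and the outcome.
#' @examples
#' tbl <- simulate_study_table(study_spec(
#'   coefficients = c("(Intercept)" = 1, "genotypeWT" = -0.5)))
#' attr(tbl, "truth")$beta[1:3]
#' @export
simulate_study_table <- function(spec, outcome = "value") {
  stopifnot(inherits(spec, "study_spec"))
  tbl <- study_design_grid(spec)
  mm <- study_model_matrix(tbl)
  beta <- setNames(numeric(ncol(mm)), colnames(mm))
  declared <- spec$coefficients
  unknown <- setdiff(names(declared), names(beta))
  if (length(unknown)) {
    abort(paste0("unknown coefficient term(s): ",
                 paste(unknown, collapse = ", "),
                 "\nvalid terms are: ", paste(names(beta), collapse = ", ")))
  }
  beta[names(declared)] <- declared
  with_seed(spec$seed, {
    ids <- unique(tbl$animal_id)
    b <- setNames(rnorm(length(ids), 0, spec$random_intercept_sd), ids)
    eps <- rnorm(nrow(tbl), 0, spec$residual_sd)
    tbl[[outcome]] <- as.numeric(mm %*% beta) + b[tbl$animal_id] + eps
  })
  attr(tbl, "truth") <- list(beta = beta, random_intercepts = b, spec = spec)
  tbl
}
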