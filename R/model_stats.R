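.pyro_model_vars <- c("Position", "Seq.type", "Homopolymer", "Dist.region",
                      "Dist.plate", "Seq.length", "Region")

# per-plate, per-type response subset: rows of this error type (1) and
# error-free rows (0); rows carrying a different error type are excluded so
# the two response classes are not conflated.
model_subset <- function(table, plate, error_type) {
  stopifnot(error_type %in% .pyro_error_types)
  d <- table[table$plate == plate &
               (table$error == 0L | table$error_type == error_type), ,
             drop = FALSE]
  if (!any(d$error == 1L) || !any(d$error == 0L))
    stop("plate ", plate, " / ", error_type,
         ": need both response classes to fit")
  d
}

# drop factor terms with fewer than two observed levels (they are
# unestimable and would abort model.matrix); returns the pruned term vector
prune_terms <- function(d, vars) {
  keep <- vapply(vars, function(v) {
    x <- d[[v]]
    if (is.factor(x)) length(unique(droplevels(x))) >= 2L else TRUE
  }, TRUE)
  if (!all(keep))
    warning("dropping single-level term(s): ",
            paste(vars[!keep], collapse = ", "))
  vars[keep]
}

glm_fit <- function(d, vars) {
  d <- droplevels(d)
  fml <- if (length(vars) == 0L) error ~ 1
  else as.formula(paste("error ~", paste(sprintf("`%s`", vars), collapse = " + ")))
  suppressWarnings(
    glm(fml, family = binomial(), data = d,
        control = glm.control(epsilon = 1e-8, maxit = 100))
  )
}

#' Per-plate logistic model of the error probability
#'
#' Fits, by iteratively reweighted least squares (maximum likelihood),
#' `error ~ Position + Seq.type + Homopolymer + Dist.region + Dist.plate +
#' Seq.length + Region` on the balanced table restricted to one plate and
#' one error type (qualitative variables dummy-coded). Coefficient tests
#' are Wald statistics (estimate / standard error), the logistic-regression
#' analogue of the per-coefficient t tests reported in this literature.
#' Perfect separation is flagged, and aliased (rank-deficient) columns are
#' dropped with a warning.
#'
#' @param table a [build_covariate_table()] result.
#' @param plate plate identifier.
#' @param error_type one of `insertion`, `deletion`, `mismatch`,
#'   `ambiguous`.
#' @param vars explanatory variables (default: the seven standard ones).
#' @param formula optional explicit model formula overriding `vars`
#'   (response must be `error`).
#' @return An object of class `pyro_logfit`: the underlying `glm`, the
#'   coefficient table (`estimate`, `se`, `statistic`, `p`), deviances,
#'   `n`, and flags `separation` and `aliased`.
#' @export
fit_logistic <- function(table, plate, error_type,
                         vars = .pyro_model_vars, formula = NULL) {
  d <- model_subset(table, plate, error_type)
  d <- droplevels(d)
  fit <- if (is.null(formula)) {
    glm_fit(d, prune_terms(d, vars))
  } else {
    suppressWarnings(glm(formula, family = binomial(), data = d,
                         control = glm.control(epsilon = 1e-8, maxit = 100)))
  }
  cf <- coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased))
    warning("aliased column(s) dropped: ", paste(aliased, collapse = ", "))
  ok <- !is.na(cf)
  se <- rep(NA_real_, length(cf))
  se[ok] <- sqrt(diag(vcov(fit)))[names(cf)[ok]]
  separation <- !fit$converged || any(se[ok] > 1e3) ||
    any(fitted(fit) > 1 - 1e-10) && any(fitted(fit) < 1e-10)
  if (separation) {
    warning("possible separation / non-convergence for plate ", plate,
            " / ", error_type)
    se[ok & se > 1e3] <- Inf
  }
  stat <- cf / se
  coefs <- data.frame(term = names(cf), estimate = unname(cf),
                      se = unname(se), statistic = unname(stat),
                      p = unname(2 * pnorm(-abs(stat))),
                      stringsAsFactors = FALSE)
  structure(list(glm = fit, plate = plate, error_type = error_type,
                 coefficients = coefs, deviance = fit$deviance,
                 null_deviance = fit$null.deviance, n = nrow(d),
                 separation = separation, aliased = aliased),
            class = "pyro_logfit")
}

#' @export
print.pyro_logfit <- function(x, ...) {
  cat("Logistic error model: plate", x$plate, "/", x$error_type,
      "(n =", x$n, ")\n")
  cat(sprintf("deviance %.2f (null %.2f), explained %.2f%%\n",
              x$deviance, x$null_deviance, 100 * deviance_explained(x)))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Fraction of the null deviance explained by a fit
#'
#' `(null deviance - residual deviance) / null deviance`, in `[0, 1]`.
#'
#' @param fit a `pyro_logfit`.
#' @return A single fraction.
#' @export
deviance_explained <- function(fit) {
  (fit$null_deviance - fit$deviance) / fit$null_deviance
}

#' Three-term deviance decomposition for one explanatory variable
#'
#' Writes the complete model's deviance as the sum of a part exclusive to
#' the variable, a part exclusive to the remaining variables, and a shared
#' part: with `dev(comp)` the deviance of the complete model, `dev(sub)`
#' that of the model without the variable, and `dev(solo)` that of the
#' variable-only model,
#' `part_xi = (dev(sub) - dev(comp)) / dev(comp)`,
#' `part_rest = (dev(solo) - dev(comp)) / dev(comp)`, and
#' `shared = 1 - part_xi - part_rest`. Both parts are non-negative by
#' nesting; values below `-1e-6` (beyond IRLS convergence noise) raise an
#' internal consistency error, smaller negative round-off is clamped to 0.
#'
#' @inheritParams fit_logistic
#' @param variable the variable whose contribution is decomposed.
#' @return A one-row `data.frame`: `variable`, `part_xi`, `part_rest`,
#'   `shared`, and the three deviances used.
#' @export
decompose_deviance <- function(table, plate, error_type, variable,
                               vars = .pyro_model_vars) {
  if (!variable %in% vars) stop("variable must be one of the model variables")
  d <- model_subset(table, plate, error_type)
  d <- droplevels(d)
  vars <- prune_terms(d, vars)
  run <- function(v, label) {
    f <- tryCatch(glm_fit(d, v), error = function(e)
      stop("decomposition: ", label, " fit failed: ", conditionMessage(e),
           call. = FALSE))
    f$deviance
  }
  dev_comp <- run(vars, "complete-model")
  dev_sub <- run(setdiff(vars, variable), "sub-model")
  dev_solo <- if (variable %in% vars) run(variable, "variable-only")
  else run(character(0), "variable-only")
  part_xi <- (dev_sub - dev_comp) / dev_comp
  part_rest <- (dev_solo - dev_comp) / dev_comp
  if (part_xi < -1e-6 || part_rest < -1e-6)
    stop("internal consistency error: negative deviance part (",
         format(min(part_xi, part_rest)), ") for ", variable)
  part_xi <- max(part_xi, 0)
  part_rest <- max(part_rest, 0)
  data.frame(variable = variable, part_xi = part_xi, part_rest = part_rest,
             shared = 1 - part_xi - part_rest, dev_comp = dev_comp,
             dev_sub = dev_sub, dev_solo = dev_solo,
             stringsAsFactors = FALSE)
}

#' @rdname decompose_deviance
#' @details `decompose_all()` decomposes every model variable for one
#'   plate/error type, fitting the complete model once and reusing its
#'   deviance across variables.
#' @export
decompose_all <- function(table, plate, error_type,
                          vars = .pyro_model_vars) {
  d <- model_subset(table, plate, error_type)
  d <- droplevels(d)
  kept <- prune_terms(d, vars)
  dev_comp <- glm_fit(d, kept)$deviance
  rows <- lapply(vars, function(v) {
    dev_sub <- glm_fit(d, setdiff(kept, v))$deviance
    dev_solo <- glm_fit(d, intersect(kept, v))$deviance
    part_xi <- (dev_sub - dev_comp) / dev_comp
    part_rest <- (dev_solo - dev_comp) / dev_comp
    if (part_xi < -1e-6 || part_rest < -1e-6)
      stop("internal consistency error: negative deviance part for ", v)
    part_xi <- max(part_xi, 0)
    part_rest <- max(part_rest, 0)
    data.frame(variable = v, part_xi = part_xi, part_rest = part_rest,
               shared = 1 - part_xi - part_rest, dev_comp = dev_comp,
               dev_sub = dev_sub, dev_solo = dev_solo,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation tests of pairwise correlation among the seven variables
#'
#' Bravais-Pearson correlation for each of the 21 unordered pairs, with a
#' two-sided permutation p-value
#' `(1 + #\{|r_perm| >= |r_obs|\}) / (n_perm + 1)` and Benjamini-Hochberg
#' adjustment across the pairs at alpha = 0.05. Qualitative variables
#' enter through numeric codes (`Homopolymer` by its code value,
#' `Seq.type` and `Region` by level index). Pairs involving a
#' zero-variance variable are skipped with a warning.
#'
#' @param table a covariate table.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param alpha significance level for the `significant` flag.
#' @return A `data.frame`: `var1`, `var2`, `r`, `p`, `p_adj`,
#'   `significant`.
#' @export
correlation_tests <- function(table, n_perm = 999L, seed = 1L, alpha = 0.05) {
  if (nrow(table) < 3L) stop("need at least 3 rows")
  if (n_perm < 99L) stop("n_perm must be >= 99")
  set.seed(as.integer(seed))
  num <- list(
    Position = table$Position,
    Seq.type = as.numeric(factor(table$Seq.type)),
    Homopolymer = as.numeric(as.character(table$Homopolymer)),
    Dist.region = table$Dist.region,
    Dist.plate = table$Dist.plate,
    Seq.length = as.numeric(table$Seq.length),
    Region = as.numeric(factor(table$Region)))
  vars <- names(num)
  sds <- vapply(num, sd, 0)
  pairs <- combn(vars, 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    v1 <- pairs[1, j]; v2 <- pairs[2, j]
    if (sds[v1] == 0 || sds[v2] == 0) {
      warning("skipping pair ", v1, " / ", v2, ": zero variance")
      next
    }
    x <- num[[v1]]; y <- num[[v2]]
    r_obs <- cor(x, y)
    r_perm <- vapply(seq_len(n_perm),
                     function(i) cor(x, y[sample.int(length(y))]), 0)
    p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_perm + 1)
    rows[[length(rows) + 1L]] <- data.frame(
      var1 = v1, var2 = v2, r = r_obs, p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj <= alpha
  out
}

#' Chi-square test of error-rate homogeneity across plates
#'
#' Pearson chi-square on the plates-by-outcome contingency table of
#' erroneous and error-free base counts (no continuity correction);
#' df = number of plates - 1.
#'
#' @param error_counts a matrix or data.frame with one row per plate and
#'   columns `errors` and `non_errors`.
#' @return A list with `chi2`, `df` and `p`.
#' @export
plate_homogeneity <- function(error_counts) {
  m <- as.matrix(as.data.frame(error_counts)[, c("errors", "non_errors")])
  if (nrow(m) < 2L) stop("need at least two plates")
  if (any(m < 0) || any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("invalid contingency table (zero marginal or negative count)")
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  if (any(ht$expected <= 0)) stop("expected count of zero")
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' @importFrom stats pnorm fitted
NULL
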