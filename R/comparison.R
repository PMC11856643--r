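#' Paired t-test on item-level MAD values
#'
#' Compares two reconstruction methods on the same items.  Cohen's d
#' for paired data uses the standard deviation of the differences.
#'
#' @param mads_a,mads_b per-item MAD values matched by position (or by
#'   names when both are named).
#' @return List with `t`, `df`, `p_value`, `d` (Cohen's d), and
#'   `mean_diff` (a minus b).
#' @export
paired_mad_test <- function(mads_a, mads_b) {
  if (!is.null(names(mads_a)) && !is.null(names(mads_b))) {
    if (!setequal(names(mads_a), names(mads_b)))
      stop("MAD vectors cover different items")
    mads_b <- mads_b[names(mads_a)]
  }
  if (length(mads_a) != length(mads_b) || length(mads_a) < 3)
    stop("need matched vectors of length >= 3")
  dif <- mads_a - mads_b
  if (sd(dif) < 1e-12) {
    if (abs(mean(dif)) < 1e-12)
      return(list(t = 0, df = length(dif) - 1L, p_value = 1, d = 0,
                  mean_diff = 0))
    return(list(t = sign(mean(dif)) * Inf, df = length(dif) - 1L,
                p_value = 0, d = sign(mean(dif)) * Inf,
                mean_diff = mean(dif)))
  }
  tt <- t.test(mads_a, mads_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, d = mean(dif) / sd(dif), mean_diff = mean(dif))
}

#' Agreement between model-implied and empirical item difficulties
#'
#' Pearson correlation with a Fisher-z 95% confidence interval.
#'
#' @param sigma_model,sigma_empirical matched per-item difficulty
#'   vectors, length >= 4.
#' @return List with `r`, `ci` (length-2), `n`.
#' @export
difficulty_agreement <- function(sigma_model, sigma_empirical) {
  if (length(sigma_model) != length(sigma_empirical) ||
      length(sigma_model) < 4)
    stop("need matched vectors of length >= 4")
  if (sd(sigma_model) < 1e-12 || sd(sigma_empirical) < 1e-12)
    stop("correlation undefined for a zero-variance vector")
  ct <- cor.test(sigma_model, sigma_empirical, method = "pearson")
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       n = length(sigma_model))
}

#' Steiger's Z test for two dependent overlapping correlations
#'
#' Tests whether `r_a = cor(x, y)` and `r_b = cor(x, z)` -- two
#' correlations sharing the variable `x` (here, the empirical
#' difficulty vector) -- differ, accounting for the dependence induced
#' by `r_ab = cor(y, z)`.  Uses Fisher z transforms and the
#' shared-variable covariance term evaluated at the mean correlation.
#'
#' @param r_a,r_b the two correlations sharing one variable.
#' @param r_ab correlation between the two non-shared variables.
#' @param n sample size (>= 10).
#' @return List with `z` and two-sided `p_value`.
#' @export
steiger_z <- function(r_a, r_b, r_ab, n) {
  rs <- c(r_a, r_b, r_ab)
  if (any(abs(rs) >= 1)) stop("correlations must lie strictly in (-1, 1)")
  if (n < 10) stop("n must be at least 10")
  rbar <- (r_a + r_b) / 2
  psi <- r_ab * (1 - 2 * rbar^2) -
    0.5 * rbar^2 * (1 - 2 * rbar^2 - r_ab^2)
  sbar <- psi / (1 - rbar^2)^2
  z <- (atanh(r_a) - atanh(r_b)) * sqrt((n - 3) / (2 - 2 * sbar))
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Rank-order agreement between component parameter vectors
#'
#' Spearman correlation with average ranks for ties.
#'
#' @param params_a,params_b matched per-component values, length >= 3
#'   (matched by names when both are named).
#' @return Spearman correlation coefficient.
#' @export
rank_agreement <- function(params_a, params_b) {
  if (!is.null(names(params_a)) && !is.null(names(params_b))) {
    if (!setequal(names(params_a), names(params_b)))
      stop("parameter vectors cover different components")
    params_b <- params_b[names(params_a)]
  }
  if (length(params_a) != length(params_b) || length(params_a) < 3)
    stop("need matched vectors of length >= 3")
  if (sd(params_a) < 1e-12 || sd(params_b) < 1e-12)
    stop("rank correlation undefined for a constant vector")
  cor(rank(params_a), rank(params_b))
}

#' Regression robustness check for additive vs interactive structure
#'
#' Regresses item difficulties on selected Q-matrix component columns
#' (main effects), then adds all pairwise change-rule-by-design-
#' principle product terms among the selected components, and tests the
#' increase in explained variance with a hierarchical F-test.
#' Interaction columns that are collinear with the existing design are
#' dropped with a warning and listed.
#'
#' @param difficulties per-item difficulty vector, matched to the rows
#'   of `q`.
#' @param q a [qmatrix()].
#' @param selected_components component ids to use as predictors.
#' @return List with `r2_main`, `r2_interaction`, `delta_r2`, `F`,
#'   `df`, `p_value`, and `dropped` (dropped interaction terms).
#' @export
regression_robustness <- function(difficulties, q, selected_components) {
  tax <- q_taxonomy(q)
  if (!all(selected_components %in% colnames(q)))
    stop("selected components not present in the Q-matrix")
  Qm <- unclass(q)[, selected_components, drop = FALSE]
  storage.mode(Qm) <- "double"
  if (length(difficulties) != nrow(Qm))
    stop("difficulties must match the Q-matrix items")
  kinds <- tax$kind[match(selected_components, tax$id)]
  rules <- selected_components[kinds == "change_rule"]
  dps <- selected_components[kinds == "design_principle"]
  inter <- list()
  for (a in rules) for (b in dps)
    inter[[paste0(a, ":", b)]] <- Qm[, a] * Qm[, b]
  Imat <- if (length(inter)) do.call(cbind, inter) else
    matrix(numeric(0), nrow(Qm), 0)
  if (nrow(Qm) < ncol(Qm) + ncol(Imat) + 2)
    stop("too few items for the requested predictor set")
  df_main <- data.frame(y = difficulties, Qm, check.names = FALSE)
  m1 <- lm(y ~ ., data = df_main)
  df_full <- data.frame(y = difficulties, Qm, Imat, check.names = FALSE)
  m2 <- lm(y ~ ., data = df_full)
  dropped <- names(coef(m2))[is.na(coef(m2))]
  if (length(dropped))
    warning("collinear interaction term(s) dropped: ",
            paste(dropped, collapse = ", "))
  r2_1 <- summary(m1)$r.squared
  r2_2 <- summary(m2)$r.squared
  av <- anova(m1, m2)
  list(r2_main = r2_1, r2_interaction = r2_2, delta_r2 = r2_2 - r2_1,
       F = av$F[2], df = c(av$Df[2], av$Res.Df[2]),
       p_value = av$`Pr(>F)`[2], dropped = dropped)
}

## pick the two hardest change rules and design principles from the
## LLTM base parameter ranking (higher eta = harder)
select_hardest_components <- function(lltm, n_per_kind = 2L) {
  tab <- lltm_component_table(lltm)
  pick <- function(kind) {
    sub <- tab[tab$kind == kind, ]
    sub$component[order(sub$eta, decreasing = TRUE)][
      seq_len(min(n_per_kind, nrow(sub)))]
  }
  c(pick("change_rule"), pick("design_principle"))
}

#' Run the full additive-vs-multiplicative model comparison
#'
#' Executes the four-step comparison on a calibration sample and an
#' independent cross-validation sample sharing the same items and
#' Q-matrix: (1) Rasch calibration with item-fit screening and a 2PL
#' fit on the conforming subset; (2) LLTM reconstruction of the
#' response data and LSDM reconstruction of the Rasch and 2PL ICCs;
#' (3) MAD diagnostics, predictive and cross-validation difficulty
#' correlations, paired t-tests on item MADs, and Steiger's Z tests of
#' the dependent predictive correlations; (4) component parameter
#' tables, rank-order agreement, and the regression robustness check.
#'
#' @param responses_fit calibration-sample [response_matrix()].
#' @param responses_cv cross-validation-sample [response_matrix()]
#'   over the same items.
#' @param q a [qmatrix()] covering the items.
#' @param grid [theta_grid()] of ability focal points.
#' @param quad_nodes quadrature nodes for 2PL estimation.
#' @param alpha item-fit screening level; `screen = FALSE` skips
#'   screening and uses all items.
#' @param screen apply item-fit screening before the CDM stage.
#' @param constrained LSDM constraint flag (see
#'   [solve_attribute_logprobs()]).
#' @param epsilon probability clipping bound.
#' @param selected_components predictors for the regression robustness
#'   check; `NULL` selects the two hardest change rules and design
#'   principles from the LLTM ranking.
#' @return A `comparison_report`; its `table` element mirrors the
#'   model-comparison layout (one row per model/IRT-source combination
#'   with mean MAD, Cohen's d against the comparison model, predictive
#'   r, and cross-validation r).
#' @export
run_full_comparison <- function(responses_fit, responses_cv, q,
                                grid = theta_grid(), quad_nodes = 21L,
                                alpha = 0.05, screen = TRUE,
                                constrained = TRUE, epsilon = 1e-6,
                                selected_components = NULL) {
  if (!identical(colnames(responses_fit), colnames(responses_cv)))
    stop("both samples must share the same item set")
  ## -- step 1: calibration ------------------------------------------------
  rasch_all <- fit_rasch(responses_fit)
  if (screen) {
    screen_report <- item_fit_screen(rasch_all, responses_fit,
                                     alpha = alpha)
    items <- screen_report$retained
    if (length(items) < ncol(q))
      stop("item-fit screening retained fewer items (", length(items),
           ") than components (", ncol(q), "); components unidentified")
  } else {
    screen_report <- NULL
    items <- colnames(responses_fit)
  }
  rf <- response_matrix(unclass(responses_fit)[, items, drop = FALSE])
  rc <- response_matrix(unclass(responses_cv)[, items, drop = FALSE])
  qs <- subset_qmatrix(q, items)
  rasch_fit <- if (screen) fit_rasch(rf) else rasch_all
  twopl_fit <- fit_2pl(rf, quad_nodes = quad_nodes)
  rasch_cv <- fit_rasch(rc)
  twopl_cv <- fit_2pl(rc, quad_nodes = quad_nodes)
  lrt <- compare_model_fit(rasch_fit, twopl_fit)
  ## -- step 2: reconstruction --------------------------------------------
  icc_rasch <- evaluate_iccs(rasch_fit, grid, epsilon)
  icc_2pl <- evaluate_iccs(twopl_fit, grid, epsilon)
  lltm <- fit_lltm(rf, qs)
  icc_lltm <- lltm_icc_table(lltm, grid, epsilon)
  lsdm_rasch <- solve_attribute_logprobs(icc_rasch, qs,
                                         constrained = constrained,
                                         epsilon = epsilon)
  lsdm_2pl <- solve_attribute_logprobs(icc_2pl, qs,
                                       constrained = constrained,
                                       epsilon = epsilon)
  ## -- step 3: evaluation and comparison ---------------------------------
  mads <- list(
    lltm = mad_diagnostics(icc_rasch, icc_lltm),
    lsdm_rasch = mad_diagnostics(icc_rasch, lsdm_rasch$reconstructed),
    lsdm_2pl = mad_diagnostics(icc_2pl, lsdm_2pl$reconstructed))
  sig_emp <- rasch_fit$difficulties
  sig_emp_2pl <- twopl_fit$b
  sig_cv <- rasch_cv$difficulties
  sig_cv_2pl <- twopl_cv$b
  sig_model <- list(
    lltm = lltm$difficulties,
    lsdm_rasch = setNames(implied_item_difficulty(
      lsdm_rasch$reconstructed)$difficulty, items),
    lsdm_2pl = setNames(implied_item_difficulty(
      lsdm_2pl$reconstructed)$difficulty, items))
  pred <- list(
    lltm = difficulty_agreement(sig_model$lltm, sig_emp),
    lsdm_rasch = difficulty_agreement(sig_model$lsdm_rasch, sig_emp),
    lsdm_2pl = difficulty_agreement(sig_model$lsdm_2pl, sig_emp_2pl))
  cv <- list(
    lltm = difficulty_agreement(sig_model$lltm, sig_cv),
    lsdm_rasch = difficulty_agreement(sig_model$lsdm_rasch, sig_cv),
    lsdm_2pl = difficulty_agreement(sig_model$lsdm_2pl, sig_cv_2pl))
  mad_tests <- list(
    lltm_vs_lsdm_rasch = paired_mad_test(
      setNames(mads$lltm$items$mad, items),
      setNames(mads$lsdm_rasch$items$mad, items)),
    lsdm_rasch_vs_lsdm_2pl = paired_mad_test(
      setNames(mads$lsdm_rasch$items$mad, items),
      setNames(mads$lsdm_2pl$items$mad, items)))
  n_items <- length(items)
  steiger <- list(
    lltm_vs_lsdm_rasch_fit = steiger_z(
      pred$lltm$r, pred$lsdm_rasch$r,
      cor(sig_model$lltm, sig_model$lsdm_rasch), n_items),
    lltm_vs_lsdm_rasch_cv = steiger_z(
      cv$lltm$r, cv$lsdm_rasch$r,
      cor(sig_model$lltm, sig_model$lsdm_rasch), n_items),
    lsdm_rasch_vs_lsdm_2pl_fit = steiger_z(
      pred$lsdm_rasch$r, pred$lsdm_2pl$r,
      cor(sig_model$lsdm_rasch, sig_model$lsdm_2pl), n_items))
  ## -- step 4: parameter inspection --------------------------------------
  comp_lltm <- lltm_component_table(lltm)
  attr_rasch <- attribute_curve_summary(lsdm_rasch)
  attr_2pl <- attribute_curve_summary(lsdm_2pl)
  ## rank orders are compared over the components both models estimate
  ## (LSDM attribute difficulties can be degenerate, e.g. a component
  ## mastered everywhere on the grid)
  usable <- !is.na(attr_rasch$difficulty)
  rank_cor <- if (sum(usable) >= 3) tryCatch(rank_agreement(
    setNames(comp_lltm$eta[match(attr_rasch$component[usable],
                                 comp_lltm$component)],
             attr_rasch$component[usable]),
    setNames(attr_rasch$difficulty[usable],
             attr_rasch$component[usable])),
    error = function(e) NA_real_) else NA_real_
  if (is.null(selected_components))
    selected_components <- select_hardest_components(lltm)
  regression <- list(
    rasch = regression_robustness(sig_emp, qs, selected_components),
    twopl = regression_robustness(sig_emp_2pl, qs, selected_components))
  table <- data.frame(
    model = c("LLTM", "LSDM", "LSDM"),
    irt_model = c("Rasch", "Rasch", "2PL"),
    mad = c(mads$lltm$mean, mads$lsdm_rasch$mean, mads$lsdm_2pl$mean),
    comparison = c(NA, 1, 2),
    cohens_d = c(NA, mad_tests$lltm_vs_lsdm_rasch$d,
                 mad_tests$lsdm_rasch_vs_lsdm_2pl$d),
    predictive_r = c(pred$lltm$r, pred$lsdm_rasch$r, pred$lsdm_2pl$r),
    cross_validation_r = c(cv$lltm$r, cv$lsdm_rasch$r, cv$lsdm_2pl$r),
    stringsAsFactors = FALSE)
  structure(list(table = table, items = items,
                 screen = screen_report, lrt = lrt,
                 rasch = rasch_fit, twopl = twopl_fit,
                 rasch_cv = rasch_cv, twopl_cv = twopl_cv,
                 lltm = lltm, lsdm_rasch = lsdm_rasch, lsdm_2pl = lsdm_2pl,
                 mads = mads, predictive = pred, cross_validation = cv,
                 mad_tests = mad_tests, steiger = steiger,
                 component_table = list(lltm = comp_lltm,
                                        lsdm_rasch = attr_rasch,
                                        lsdm_2pl = attr_2pl),
                 rank_agreement = rank_cor,
                 regression = regression,
                 selected_components = selected_components),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Model comparison over", length(x$items), "retained items\n\n")
  tab <- transform(x$table, mad = round(mad, 3),
                   cohens_d = round(cohens_d, 2),
                   predictive_r = round(predictive_r, 2),
                   cross_validation_r = round(cross_validation_r, 2))
  print(tab, row.names = FALSE)
  cat("\nPaired t (LSDM-Rasch vs LLTM MADs): t = ",
      round(x$mad_tests$lltm_vs_lsdm_rasch$t, 2), ", p = ",
      format.pval(x$mad_tests$lltm_vs_lsdm_rasch$p_value, digits = 2),
      "\nSteiger Z (LLTM vs LSDM-Rasch, calibration sample): Z = ",
      round(x$steiger$lltm_vs_lsdm_rasch_fit$z, 2), ", p = ",
      format.pval(x$steiger$lltm_vs_lsdm_rasch_fit$p_value, digits = 2),
      "\nComponent rank agreement (LLTM vs LSDM-Rasch): r = ",
      round(x$rank_agreement, 2), "\n", sep = "")
  invisible(x)
}
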