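# Statistical validation of direct and indirect predictions: scaled
# regressions, all-subsets information-criterion selection, overdispersion
# handling, variance-decomposition R2, multiple-test Bernoulli probability,
# and leverage-based outlier screening.
#
# Models with grouping factors are fitted as random-intercept GLMMs via
# lme4; models without grouping factors fall back to stats::glm. The
# inferential contract throughout is the sign and significance of the focal
# slope plus information-criterion ranking.

#' Centre and scale a predictor to mean 0, sd 1
#' @param x numeric vector of length >= 2 with non-zero sample sd.
#' @export
scale_center <- function(x) {
  if (length(x) < 2) stop("need at least two values to scale")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot scale a constant vector")
  (x - mean(x)) / s
}

#' Fit a (mixed) generalised linear model
#'
#' With `groups`, a random-intercept GLMM (lme4::glmer); otherwise an
#' ordinary GLM. `olre = TRUE` adds an observation-level random factor (one
#' level per row) to absorb extra-Poisson/binomial dispersion. Binomial
#' responses should be passed as `cbind(events, trials - events)` so the
#' likelihood is exact.
#'
#' @param formula fixed-effects formula (response ~ terms).
#' @param data data.frame.
#' @param family "poisson", "binomial" or "gaussian".
#' @param groups character vector of grouping-factor column names.
#' @param olre add an observation-level random factor.
#' @return object of class `apc_fit`: the fitted model plus a coefficient
#'   table, AIC/AICc, sample size, parameter count and a convergence flag.
#' @export
fit_glm <- function(formula, data, family = c("poisson", "binomial", "gaussian"),
                    groups = character(0), olre = FALSE) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  groups <- setdiff(groups, ".obs")
  if (olre) {
    data$.obs <- factor(seq_len(nrow(data)))
    all_groups <- c(groups, ".obs")
  } else {
    all_groups <- groups
  }
  fam <- switch(family, poisson = stats::poisson(),
                binomial = stats::binomial(), gaussian = stats::gaussian())
  msgs <- character(0)
  catch <- function(expr) withCallingHandlers(expr, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  lhs <- paste(deparse(formula[[2]]), collapse = " ")
  rhs <- paste(deparse(formula[[3]]), collapse = " ")
  if (length(all_groups) > 0) {
    f <- stats::as.formula(paste(
      lhs, "~", rhs, "+",
      paste(sprintf("(1 | %s)", all_groups), collapse = " + ")))
    model <- tryCatch(
      if (family == "gaussian") {
        catch(lme4::lmer(f, data = data, REML = FALSE))
      } else {
        catch(lme4::glmer(f, data = data, family = fam))
      },
      error = function(e) {
        msgs <<- c(msgs, paste("mixed fit failed:", conditionMessage(e)))
        NULL
      })
    if (is.null(model)) {
      # flagged fallback: fixed-effects fit so selection can still compare
      model <- catch(stats::glm(formula, data = data, family = fam))
      converged <- FALSE
    } else {
      conv_msgs <- model@optinfo$conv$lme4$messages %||% character(0)
      converged <- length(conv_msgs) == 0
    }
    co <- as.data.frame(summary(model)$coefficients)
  } else {
    model <- catch(stats::glm(formula, data = data, family = fam))
    converged <- isTRUE(model$converged)
    co <- as.data.frame(summary(model)$coefficients)
  }
  # normalise the coefficient table: z and p columns may be t-based
  coefs <- data.frame(term = rownames(co),
                      estimate = co[[1]], std_error = co[[2]],
                      z = co[[3]],
                      p = if (ncol(co) >= 4) co[[4]]
                          else 2 * stats::pnorm(-abs(co[[3]])),
                      stringsAsFactors = FALSE, row.names = NULL)
  ll <- stats::logLik(model)
  k <- attr(ll, "df")
  n <- stats::nobs(model)
  aic <- stats::AIC(model)
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(list(model = model, formula = formula, family = family,
                 groups = groups, olre = olre, data = data,
                 coefficients = coefs, aic = aic, aicc = aicc,
                 n = n, npar = k, converged = converged, messages = msgs),
            class = "apc_fit")
}

#' @export
print.apc_fit <- function(x, ...) {
  cat(sprintf("apc_fit: %s %s, n = %d, AIC = %.2f, AICc = %.2f%s\n",
              x$family,
              if (length(x$groups) || x$olre) "GLMM" else "GLM",
              x$n, x$aic, x$aicc,
              if (x$converged) "" else " [not converged]"))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Coefficient row for a single term
#' @param fit an `apc_fit`.
#' @param term term name as it appears in the coefficient table.
#' @export
slope_of <- function(fit, term) {
  row <- fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
  if (nrow(row) == 0) stop("term not in fit: ", term)
  row
}

#' Overdispersion check via Pearson residuals
#'
#' Ratio of the sum of squared Pearson residuals to the residual degrees of
#' freedom, with a chi-squared tail test. The flag is set when the ratio is
#' >= 2 or the test is significant at 0.05; the pipeline then refits with an
#' observation-level random factor.
#'
#' @param fit an `apc_fit`.
#' @export
overdispersion_check <- function(fit) {
  stopifnot(inherits(fit, "apc_fit"))
  r <- stats::residuals(fit$model, type = "pearson")
  df <- stats::df.residual(fit$model)
  if (is.na(df) || df <= 0) stop("no residual degrees of freedom")
  ratio <- sum(r^2) / df
  p <- stats::pchisq(sum(r^2), df, lower.tail = FALSE)
  list(ratio = ratio, p_value = p, flag = (ratio >= 2) || (p < 0.05), df = df)
}

#' Refit a model with an observation-level random factor
#' @param fit an `apc_fit`.
#' @export
refit_with_olre <- function(fit) {
  fit_glm(fit$formula, fit$data[setdiff(names(fit$data), ".obs")],
          fit$family, fit$groups, olre = TRUE)
}

#' Marginal and conditional R2 by variance decomposition (delta method)
#'
#' Marginal R2 is the fixed-effect share of the latent-scale variance;
#' conditional R2 adds the grouping (random-intercept) variances. The
#' distribution-specific observation-level variance uses the delta method:
#' 1/lambda for Poisson (log link; lambda evaluated at the intercept plus
#' half the summed random variance, so predictors should be centred) and
#' 1/(p(1-p)) for binomial (logit link, p at the intercept); for Gaussian
#' fits it is the residual variance, so the marginal value of a no-grouping
#' Gaussian fit equals classical R2.
#'
#' @param fit a converged `apc_fit`.
#' @return list with `marginal` and `conditional`.
#' @export
nakagawa_r2 <- function(fit) {
  stopifnot(inherits(fit, "apc_fit"))
  mod <- fit$model
  if (inherits(mod, "merMod")) {
    X <- lme4::getME(mod, "X")
    beta <- lme4::fixef(mod)
    eta_f <- as.numeric(X %*% beta)
    vc <- lme4::VarCorr(mod)
    var_a <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
    b0 <- if ("(Intercept)" %in% names(beta)) unname(beta["(Intercept)"]) else 0
    resid_var <- if (fit$family == "gaussian") attr(vc, "sc")^2 else NA_real_
  } else {
    eta_f <- as.numeric(stats::model.matrix(mod) %*% stats::coef(mod))
    var_a <- 0
    cf <- stats::coef(mod)
    b0 <- if ("(Intercept)" %in% names(cf)) unname(cf["(Intercept)"]) else 0
    resid_var <- if (fit$family == "gaussian")
      stats::var(stats::residuals(mod, type = "response")) else NA_real_
  }
  var_f <- stats::var(eta_f)
  var_e <- switch(fit$family,
    gaussian = resid_var,
    poisson = {
      lambda <- exp(b0 + 0.5 * var_a)
      if (!is.finite(lambda) || lambda <= 0) stop("R2 undefined: degenerate rate")
      1 / lambda
    },
    binomial = {
      pbar <- stats::plogis(b0)
      1 / (pbar * (1 - pbar))
    })
  tot <- var_f + var_a + var_e
  if (!is.finite(tot) || tot <= 0) stop("R2 undefined for degenerate response")
  list(marginal = var_f / tot, conditional = (var_f + var_a) / tot)
}

#' Probability of k or more significant tests by chance (Bernoulli process)
#'
#' Exact binomial tail P(X >= k) for X ~ Binomial(N, alpha): the probability
#' that at least k of N independent tests reach significance at level alpha
#' under the global null.
#'
#' @param n_tests number of tests N.
#' @param k_significant observed number of significant tests.
#' @param alpha per-test significance level.
#' @export
bernoulli_multiple_tests <- function(n_tests, k_significant, alpha = 0.05) {
  if (n_tests < 0 || k_significant < 0 || k_significant > n_tests)
    stop("need 0 <= k <= N")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  if (k_significant == 0) return(1)
  sum(stats::dbinom(seq.int(k_significant, n_tests), n_tests, alpha))
}

#' Leverage (hat-value) screening for influential observations
#'
#' Hat-matrix diagonal from the final weighted least-squares step of a GLM;
#' observations with h_i > 2p/n (p = fitted parameters) are flagged. For
#' mixed fits, screen the fixed-effects refit.
#'
#' @param fit an `apc_fit` without grouping factors.
#' @param threshold override the 2p/n flag threshold.
#' @return object of class `leverage_report`: hat values, flagged indices,
#'   threshold, parameter count.
#' @export
leverage_outliers <- function(fit, threshold = NULL) {
  stopifnot(inherits(fit, "apc_fit"))
  mod <- fit$model
  if (inherits(mod, "merMod"))
    stop("leverage screening operates on the fixed-effects GLM; refit without grouping factors")
  mm <- stats::model.matrix(mod)
  if (mod$rank < ncol(mm)) stop("rank-deficient design matrix")
  h <- stats::hatvalues(mod)
  p <- mod$rank
  n <- length(h)
  thr <- if (is.null(threshold)) 2 * p / n else threshold
  structure(list(hat = h, flagged = which(h > thr), threshold = thr,
                 n_params = p),
            class = "leverage_report")
}

# ---- all-subsets selection -------------------------------------------------

marginality_subsets <- function(term_labels) {
  # all subsets of fixed-effect terms in which every interaction is
  # accompanied by all of its lower-order relatives present in the full set
  nt <- length(term_labels)
  comps <- lapply(strsplit(term_labels, ":", fixed = TRUE), sort)
  requires <- lapply(seq_len(nt), function(i) {
    which(vapply(seq_len(nt), function(j) {
      j != i && length(comps[[j]]) < length(comps[[i]]) &&
        all(comps[[j]] %in% comps[[i]])
    }, logical(1)))
  })
  subs <- list()
  for (b in 0:(2^nt - 1)) {
    s <- which(bitwAnd(b, bitwShiftL(1, seq_len(nt) - 1)) > 0)
    ok <- all(vapply(s, function(i) all(requires[[i]] %in% s), logical(1)))
    if (ok) subs[[length(subs) + 1L]] <- s
  }
  subs[order(lengths(subs))]
}

#' All-subsets fixed-effect selection by AIC or AICc
#'
#' Enumerates every marginality-respecting subset of the full model's fixed
#' terms (interactions never appear without their main effects), refits each
#' with the full model's random structure, and ranks by the chosen
#' criterion. Also reports the delta < 2 candidate set and per-term
#' inclusion fractions within it (the collinearity audit).
#'
#' @param fit the full-model `apc_fit`.
#' @param criterion "AIC" or "AICc".
#' @param max_terms guard on exhaustive enumeration.
#' @return object of class `subset_selection`.
#' @export
all_subsets_selection <- function(fit, criterion = c("AIC", "AICc"),
                                  max_terms = 12L) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(fit, "apc_fit"))
  tl <- attr(stats::terms(fit$formula), "term.labels")
  if (length(tl) > max_terms)
    stop("refusing exhaustive enumeration over ", length(tl), " terms")
  subs <- marginality_subsets(tl)
  lhs <- paste(deparse(fit$formula[[2]]), collapse = " ")
  fits <- lapply(subs, function(s) {
    rhs <- if (length(s) == 0) "1" else paste(tl[s], collapse = " + ")
    f <- stats::as.formula(paste(lhs, "~", rhs))
    fit_glm(f, fit$data[setdiff(names(fit$data), ".obs")], fit$family,
            fit$groups, olre = fit$olre)
  })
  ics <- vapply(fits, function(f) if (criterion == "AIC") f$aic else f$aicc,
                numeric(1))
  best <- which.min(ics)  # subsets ordered by size, so ties go to the simpler model
  delta <- ics - min(ics)
  cand <- which(delta < 2)
  inclusion <- vapply(seq_along(tl), function(i)
    mean(vapply(cand, function(ci) i %in% subs[[ci]], logical(1))), numeric(1))
  names(inclusion) <- tl
  structure(list(terms = tl, subsets = subs, ics = ics, criterion = criterion,
                 best = fits[[best]], best_terms = tl[subs[[best]]],
                 delta = delta, candidate_set = cand, inclusion = inclusion,
                 fits = fits),
            class = "subset_selection")
}

#' @export
print.subset_selection <- function(x, ...) {
  cat(sprintf("subset_selection over %d terms (%d subsets, %s): best = {%s}\n",
              length(x$terms), length(x$subsets), x$criterion,
              paste(x$best_terms, collapse = ", ")))
  cat("inclusion fractions (delta < 2 set):\n")
  print(round(x$inclusion, 3))
  invisible(x)
}

# ---- validation wrappers ---------------------------------------------------

select_random_structure <- function(formula, data, family, groups) {
  # the paper's first step: choose the random-effect structure by AIC
  sets <- list(character(0))
  for (m in seq_along(groups))
    sets <- c(sets, utils::combn(groups, m, simplify = FALSE))
  fits <- lapply(sets, function(g)
    suppressMessages(fit_glm(formula, data, family, groups = g)))
  fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
}

#' Validate direct predictions against observed test-site networks
#'
#' Builds the long pair table (one row per host-parasitoid pair per site),
#' scales the focal predictor, and fits a Poisson model of observed
#' interaction frequency on the prediction, with parasitoid identity and
#' site as candidate random intercepts (structure chosen by AIC), an
#' observation-level random factor on overdispersion, all-subsets selection
#' and variance-decomposition R2. With `moderators`, host/parasitoid ND and
#' abundance and forest type enter as interacting fixed effects (no forest x
#' ND and no abundance x ND interactions).
#'
#' @param predictions named list (by site id) of prediction matrices at time t.
#' @param observed named list (by site id) of observed `site_network`s at time t.
#' @param traits trait table (needed with `moderators = TRUE`).
#' @param site_habitat named character vector mapping site id to habitat
#'   (needed with `moderators = TRUE`).
#' @param moderators include the moderated model.
#' @param criterion "AIC" or "AICc".
#' @param groups candidate random factors (columns of the pair table).
#' @return list with the pair `table`, the chosen `fit`, `selection`,
#'   `dispersion` and `r2`.
#' @export
validate_direct <- function(predictions, observed, traits = NULL,
                            site_habitat = NULL, moderators = FALSE,
                            criterion = "AIC",
                            groups = c("parasitoid_id", "site_id")) {
  if (length(predictions) == 0) stop("no predictions supplied")
  tabs <- lapply(names(predictions), function(s) {
    pm <- predictions[[s]]
    on <- observed[[s]]
    if (is.null(on)) stop("no observed network for site ", s)
    om <- on$count_matrix
    hosts <- rownames(pm); paras <- colnames(pm)
    if (!all(hosts %in% rownames(om)) || !all(paras %in% colnames(om)))
      stop("prediction/observation key mismatch at site ", s)
    grid <- expand.grid(parasitoid_id = paras, host_id = hosts,
                        stringsAsFactors = FALSE)
    data.frame(site_id = s, host_id = grid$host_id,
               parasitoid_id = grid$parasitoid_id,
               observed = om[cbind(grid$host_id, grid$parasitoid_id)],
               predicted = pm[cbind(grid$host_id, grid$parasitoid_id)],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  tab$predicted_s <- scale_center(tab$predicted)
  f <- observed ~ predicted_s
  if (moderators) {
    if (is.null(traits) || is.null(site_habitat))
      stop("moderated model needs traits and site habitats")
    tr <- validate_traits(traits)
    rownames(tr) <- tr$species_id
    tab$host_nd_s    <- scale_center(tr[tab$host_id, "nd"])
    tab$para_nd_s    <- scale_center(tr[tab$parasitoid_id, "nd"])
    tab$host_abund_s <- scale_center(tr[tab$host_id, "total_abundance"])
    tab$para_abund_s <- scale_center(tr[tab$parasitoid_id, "total_abundance"])
    tab$forest <- factor(site_habitat[tab$site_id])
    f <- observed ~ predicted_s + host_nd_s + para_nd_s + host_abund_s +
      para_abund_s + forest + predicted_s:host_nd_s + predicted_s:para_nd_s +
      host_nd_s:para_nd_s + predicted_s:host_abund_s +
      predicted_s:para_abund_s + predicted_s:forest
  }
  base <- select_random_structure(f, tab, "poisson", groups)
  disp <- overdispersion_check(base)
  if (disp$flag) {
    base <- refit_with_olre(base)
    disp <- c(disp, list(after_olre = overdispersion_check(base)))
  }
  sel <- all_subsets_selection(base, criterion)
  r2 <- tryCatch(nakagawa_r2(base), error = function(e) NULL)
  list(table = tab, fit = base, selection = sel, dispersion = disp, r2 = r2)
}

#' Pooled occurrence AUC of site-level predictions
#'
#' Ranks predicted interaction scores against observed interaction
#' occurrence (count > 0) over all host x parasitoid pairs of all sites -
#' the held-out discrimination of a model trained on other sites.
#'
#' @param predictions named list (by site) of prediction matrices.
#' @param observed named list (by site) of observed `site_network`s.
#' @return the ranking AUC (numeric scalar).
#' @export
pair_occurrence_auc <- function(predictions, observed) {
  scores <- numeric(0)
  labels <- numeric(0)
  for (s in names(predictions)) {
    pm <- predictions[[s]]
    om <- observed[[s]]$count_matrix
    hosts <- rownames(pm); paras <- colnames(pm)
    if (!all(hosts %in% rownames(om)) || !all(paras %in% colnames(om)))
      stop("prediction/observation key mismatch at site ", s)
    scores <- c(scores, as.numeric(pm))
    labels <- c(labels, as.numeric(om[hosts, paras, drop = FALSE] > 0))
  }
  if (length(unique(labels)) < 2) stop("observed occurrences are single-class")
  cv_auc(labels, scores)
}

#' Validate expected against observed parasitism rates
#'
#' Joins eligible expected-parasitism records to observed parasitism on
#' site x host and fits an events-of-trials binomial model of observed
#' parasitism on the scaled expected rate, with site as a candidate random
#' intercept. Leverage screening (on the fixed-effects fit) flags
#' high-influence points; the fit without them is reported alongside.
#'
#' @param expected data.frame from [expected_parasitism()] (possibly several
#'   sites bound together).
#' @param observed data.frame from [observed_parasitism()].
#' @param criterion "AIC" or "AICc".
#' @param groups candidate random factors.
#' @return list with the joined `table`, `fit`, `fit_no_outliers`,
#'   `selection`, `dispersion`, `leverage` and `r2`.
#' @export
validate_indirect <- function(expected, observed, criterion = "AIC",
                              groups = "site_id") {
  el <- expected[expected$eligible, c("site_id", "host_id", "E")]
  tab <- merge(el, observed[, c("site_id", "host_id", "events", "sampled")],
               by = c("site_id", "host_id"))
  if (nrow(tab) == 0) stop("no eligible host records joined observed parasitism")
  if (any(tab$events > tab$sampled)) stop("events exceed sampled hosts")
  tab$E_s <- scale_center(tab$E)
  f <- cbind(events, sampled - events) ~ E_s
  base <- select_random_structure(f, tab, "binomial", groups)
  disp <- overdispersion_check(base)
  if (disp$flag) {
    base <- refit_with_olre(base)
    disp <- c(disp, list(after_olre = overdispersion_check(base)))
  }
  sel <- all_subsets_selection(base, criterion)
  r2 <- tryCatch(nakagawa_r2(base), error = function(e) NULL)
  fe <- fit_glm(f, tab, "binomial")
  lev <- leverage_outliers(fe)
  fit_wo <- NULL
  if (length(lev$flagged) > 0 && nrow(tab) - length(lev$flagged) > 2) {
    tab2 <- tab[-lev$flagged, , drop = FALSE]
    tab2$E_s <- scale_center(tab2$E)
    fit_wo <- fit_glm(f, tab2, "binomial", base$groups, olre = base$olre)
  }
  list(table = tab, fit = base, fit_no_outliers = fit_wo, selection = sel,
       dispersion = disp, leverage = lev, r2 = r2)
}
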