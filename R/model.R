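#' Mixed-effects model for aggression direction
#'
#' Fits the interaction score (recipient minus aggressor standardized Elo,
#' bounded in `[-1, 1]`) on aggression intensity (reference `mild`), the
#' numbers of adult males and females in the group, the aggressor's
#' reproductive state (reference `cycling`), and species (reference
#' `mountain`), with four crossed random intercepts: aggressor identity,
#' recipient identity, dyad, and group.
#'
#' A bounded response and a "logit" mean structure admit several
#' formalizations; three families are provided and the choice is surfaced,
#' not hidden:
#' \describe{
#'   \item{`beta_logit` (default)}{the score is mapped to `(0, 1)` via
#'     `y' = (y + 1) / 2` and the boundary-squeeze
#'     `y'' = (y' (n - 1) + 0.5) / n`, then modelled with a beta family and
#'     logit link. Estimates are reported on the logit scale.}
#'   \item{`linear_logit`}{a Gaussian linear mixed model on
#'     `qlogis(y'')`.}
#'   \item{`linear`}{a Gaussian linear mixed model on the raw score; its
#'     estimates are on the score scale and directly comparable to score
#'     differences.}
#' }
#'
#' Estimation is maximum likelihood (Laplace approximation via
#' \pkg{glmmTMB}) and deterministic given data and specification.
#' Non-convergence is an explicit error; variance components estimated at
#' (or numerically indistinguishable from) zero raise a warning and stay
#' pinned at the boundary. Categorical fixed effects with a single observed
#' level are dropped with a warning.
#'
#' @param data a `"scored_aggression"` table from [score_interactions()]
#'   (or any data frame with columns `score`, `intensity`, `n_males`,
#'   `n_females`, `state`, `species`, `aggressor`, `recipient`, `dyad`,
#'   `group`).
#' @param family response family, see Details.
#' @param fixed optional one-sided formula overriding the default fixed
#'   part `~ intensity + n_males + n_females + state + species`.
#' @param squeeze_n divisor of the boundary squeeze; defaults to the number
#'   of observations.
#' @return An object of class `"direction_model"` with methods `print`,
#'   `summary`, `coef`, `vcov`, `predict`, `simulate`, `residuals`,
#'   `anova` (Type-II Wald tests) and `plot`.
#' @seealso [type2_wald_tests()], [tukey_contrasts()], [vif_terms()],
#'   [residual_diagnostics()], [predict_effects()]
#' @export
direction_model <- function(data,
                            family = c("beta_logit", "linear_logit", "linear"),
                            fixed = NULL, squeeze_n = NULL) {
  family <- match.arg(family)
  dat <- as.data.frame(data)
  need <- c("score", "aggressor", "recipient", "dyad", "group")
  miss <- setdiff(need, names(dat))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(dat$score < -1 | dat$score > 1)) stop("scores must lie in [-1, 1]")
  for (cc in c("aggressor", "recipient", "dyad", "group"))
    dat[[cc]] <- factor(dat[[cc]])
  # factor covariates with fixed reference levels; unobserved levels dropped
  fct_defs <- list(intensity = intensity_levels,
                   state = setdiff(reproductive_states, "unknown"),
                   species = c("mountain", "western"))
  for (cc in names(fct_defs)) {
    if (is.null(dat[[cc]])) next
    dat[[cc]] <- factor(as.character(dat[[cc]]), levels = fct_defs[[cc]])
    obs <- levels(droplevels(dat[[cc]]))
    if (length(obs) < length(levels(dat[[cc]]))) {
      warning("dropping unobserved ", cc, " level(s): ",
              paste(setdiff(levels(dat[[cc]]), obs), collapse = ", "))
      dat[[cc]] <- factor(as.character(dat[[cc]]),
                          levels = intersect(fct_defs[[cc]], obs))
    }
  }
  if (is.null(fixed)) {
    terms_avail <- c("intensity", "n_males", "n_females", "state", "species")
    terms_avail <- terms_avail[terms_avail %in% names(dat)]
    drop_f <- vapply(terms_avail, function(tt)
      is.factor(dat[[tt]]) && nlevels(dat[[tt]]) < 2, logical(1))
    if (any(drop_f))
      warning("dropping fixed term(s) with fewer than 2 observed levels: ",
              paste(terms_avail[drop_f], collapse = ", "))
    terms_avail <- terms_avail[!drop_f]
    fixed <- stats::reformulate(terms_avail)
  }
  n <- nrow(dat)
  if (is.null(squeeze_n)) squeeze_n <- n
  y1 <- (dat$score + 1) / 2
  y2 <- (y1 * (squeeze_n - 1) + 0.5) / squeeze_n
  dat$.resp <- switch(family,
                      beta_logit = y2,
                      linear_logit = stats::qlogis(y2),
                      linear = dat$score)
  full <- stats::update(fixed, .resp ~ . +
                          (1 | aggressor) + (1 | recipient) +
                          (1 | dyad) + (1 | group))
  fam <- if (family == "beta_logit") glmmTMB::beta_family() else stats::gaussian()
  re_terms <- c("aggressor", "recipient", "dyad", "group")
  sds <- stats::setNames(rep(0, length(re_terms)), re_terms)
  keep <- re_terms
  repeat {
    full <- stats::update(fixed, .resp ~ .)
    for (tt in keep)
      full <- stats::update(full, stats::as.formula(paste0("~ . + (1|", tt, ")")))
    fit <- glmmTMB::glmmTMB(full, data = dat, family = fam)
    vc <- glmmTMB::VarCorr(fit)$cond
    fit_sds <- vapply(vc, function(v) attr(v, "stddev"), numeric(1))
    healthy <- fit$fit$convergence == 0 && isTRUE(fit$sdr$pdHess) &&
      !anyNA(vcov(fit)$cond)
    if (healthy) {
      sds[keep] <- fit_sds[keep]
      break
    }
    # a variance component collapsing onto the zero boundary can break
    # convergence or leave the Hessian uninvertible; pin it at exactly
    # zero by refitting without that term
    tiny <- names(fit_sds)[fit_sds < 1e-3]
    if (!length(tiny) && length(keep) > 1L)
      tiny <- names(fit_sds)[which.min(fit_sds)]
    if (!length(tiny) || length(keep) <= 1L)
      stop("model did not converge: convergence code ", fit$fit$convergence,
           ", pdHess = ", isTRUE(fit$sdr$pdHess),
           "; message: ", fit$fit$message)
    warning("variance component(s) pinned at the zero boundary: ",
            paste(tiny, collapse = ", "))
    keep <- setdiff(keep, tiny)
  }
  tiny0 <- names(sds)[sds < 1e-6]
  if (length(tiny0))
    warning("variance component(s) estimated at the zero boundary: ",
            paste(tiny0, collapse = ", "))
  structure(list(model = fit, family = family, data = dat,
                 fixed = fixed, squeeze_n = squeeze_n,
                 var_comp = sds, call = match.call()),
            class = "direction_model")
}

# map model-scale response values back to the score scale
unsqueeze_score <- function(object, y2) {
  n <- object$squeeze_n
  y1 <- (y2 * n - 0.5) / (n - 1)
  2 * y1 - 1
}
link_to_score <- function(object, eta) {
  switch(object$family,
         beta_logit = unsqueeze_score(object, stats::plogis(eta)),
         linear_logit = unsqueeze_score(object, stats::plogis(eta)),
         linear = eta)
}

#' @export
coef.direction_model <- function(object, ...) {
  glmmTMB::fixef(object$model)$cond
}

#' @export
vcov.direction_model <- function(object, ...) {
  vcov(object$model)$cond
}

#' @export
print.direction_model <- function(x, ...) {
  cat("Aggression-direction mixed model (", x$family, " family)\n", sep = "")
  cat("  fixed:", deparse(x$fixed[[2]]), "\n")
  cat("  random intercepts: aggressor, recipient, dyad, group\n")
  cat("  n =", nrow(x$data), "events\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.direction_model <- function(object, level = 0.95, ...) {
  b <- coef(object)
  se <- sqrt(diag(vcov(object)))
  # the conventional 1.96 multiplier at the default level
  z <- if (identical(level, 0.95)) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  est <- data.frame(term = names(b), estimate = b, std_error = se,
                    ci_lower = b - z * se, ci_upper = b + z * se,
                    row.names = NULL)
  out <- list(family = object$family,
              scale = switch(object$family,
                             beta_logit = "logit (beta family)",
                             linear_logit = "logit (Gaussian on qlogis score)",
                             linear = "interaction score"),
              coefficients = est,
              wald = type2_wald_tests(object),
              var_comp = object$var_comp,
              n = nrow(object$data), level = level)
  class(out) <- "summary.direction_model"
  out
}

#' @export
print.summary.direction_model <- function(x, ...) {
  cat("Aggression-direction mixed model —", x$family, "family\n")
  cat("Estimates on the", x$scale, "scale;", x$n, "events\n\n")
  print(cbind(x$coefficients[1], round(x$coefficients[-1], 4)),
        row.names = FALSE)
  cat("\nType-II Wald tests:\n")
  print(cbind(x$wald[1], round(x$wald[-1], 4)), row.names = FALSE)
  cat("\nRandom-intercept SDs:\n")
  print(round(x$var_comp, 4))
  invisible(x)
}

#' @export
predict.direction_model <- function(object, newdata = NULL,
                                    type = c("score", "response", "link"),
                                    se.fit = FALSE, ...) {
  type <- match.arg(type)
  pr <- stats::predict(object$model, newdata = newdata,
                       re.form = if (is.null(newdata)) NULL else NA,
                       se.fit = se.fit, type = "link",
                       allow.new.levels = TRUE)
  eta <- if (se.fit) pr$fit else pr
  out <- switch(type,
                link = eta,
                response = switch(object$family,
                                  linear = eta,
                                  stats::plogis(eta)),
                score = link_to_score(object, eta))
  if (se.fit) list(fit = out, se.fit = pr$se.fit, eta = eta) else out
}

#' @export
simulate.direction_model <- function(object, nsim = 1, seed = NULL, ...) {
  sims <- stats::simulate(object$model, nsim = nsim, seed = seed)
  as.data.frame(lapply(sims, function(s) switch(object$family,
    beta_logit = unsqueeze_score(object, s),
    linear_logit = unsqueeze_score(object, stats::plogis(s)),
    linear = s)))
}

#' @export
residuals.direction_model <- function(object, type = c("response", "pearson"),
                                      ...) {
  stats::residuals(object$model, type = match.arg(type))
}

#' @export
anova.direction_model <- function(object, ...) {
  type2_wald_tests(object)
}

#' @export
plot.direction_model <- function(x, variable = "state", ...) {
  eff <- predict_effects(x, variable)
  v <- eff[[variable]]
  if (is.numeric(v)) {
    plot(v, eff$score, type = "l", ylim = range(eff$lower, eff$upper),
         xlab = variable, ylab = "predicted interaction score", ...)
    graphics::lines(v, eff$lower, lty = 2)
    graphics::lines(v, eff$upper, lty = 2)
  } else {
    at <- seq_along(v)
    plot(at, eff$score, xaxt = "n", ylim = range(eff$lower, eff$upper),
         pch = 16, xlab = variable, ylab = "predicted interaction score", ...)
    graphics::axis(1, at = at, labels = as.character(v))
    graphics::arrows(at, eff$lower, at, eff$upper, angle = 90, code = 3,
                     length = 0.05)
  }
  graphics::abline(h = 0, col = "grey60", lty = 3)
  invisible(eff)
}

#' Type-II Wald chi-square tests of the fixed terms
#'
#' For each fixed-effect term, the joint Wald chi-square of all its
#' coefficients, with degrees of freedom equal to the number of
#' coefficients; with no interactions in the model this coincides with the
#' Type-II (marginality-respecting) test. P-values come from the
#' chi-square upper tail.
#'
#' @param object a [direction_model()] fit.
#' @return data frame `term`, `chisq`, `df`, `p_value`.
#' @export
type2_wald_tests <- function(object) {
  stopifnot(inherits(object, "direction_model"))
  b <- coef(object)
  V <- vcov(object)
  X <- stats::model.matrix(object$fixed, object$data)
  asg <- attr(X, "assign")
  labels <- attr(stats::terms(object$fixed), "term.labels")
  out <- lapply(seq_along(labels), function(ti) {
    idx <- which(asg == ti)
    bi <- b[idx]; Vi <- V[idx, idx, drop = FALSE]
    w <- tryCatch(drop(t(bi) %*% solve(Vi, bi)), error = function(e) NULL)
    df <- length(idx)
    if (is.null(w)) {
      sv <- svd(Vi)
      pos <- sv$d > max(sv$d) * 1e-10
      warning("rank-deficient coefficient block for term '", labels[ti],
              "'; df reduced to ", sum(pos))
      pinv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      w <- drop(t(bi) %*% pinv %*% bi)
      df <- sum(pos)
    }
    data.frame(term = labels[ti], chisq = w, df = df,
               p_value = stats::pchisq(w, df, lower.tail = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("wald_tests", "data.frame")
  res
}

# single-step max-|T| tail probabilities by Monte Carlo: contrast stats
# T = K X / se with X ~ N(0, Vs); p_i = P(max_j |T_j| >= z_i). NULL when
# Vs is not positive definite (caller falls back to Bonferroni).
single_step_maxT <- function(z_abs, se, K, Vs, mc_draws, seed) {
  ch <- tryCatch(chol(Vs), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  with_seed(seed, {
    G <- matrix(stats::rnorm(mc_draws * ncol(K)), mc_draws) %*% ch
    Tm <- abs(sweep(tcrossprod(G, K), 2, se, "/"))
    mx <- do.call(pmax, as.data.frame(Tm))
    vapply(z_abs, function(zi) mean(mx >= zi), numeric(1))
  })
}

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Single-step (Tukey-type) pairwise contrasts of a fixed factor
#'
#' All pairwise differences among the estimated levels of a categorical
#' fixed effect, with single-step adjusted p-values
#' `p_i = P(max_j |Z_j| >= |z_i|)` under the joint normal distribution of
#' the contrast statistics, whose correlation comes from the fitted
#' fixed-effect covariance. The tail probability is estimated by Monte
#' Carlo with a fixed seed (reproducible bit-for-bit given `seed` and
#' `mc_draws`), then clamped into its analytic envelope
#' `[p_raw, min(1, m * p_raw)]` (single-step adjusted p-values always lie
#' between the unadjusted and the Bonferroni p; clamping removes Monte
#' Carlo noise at the envelope edges). A degenerate contrast covariance
#' falls back to Bonferroni with a warning.
#'
#' @param object a [direction_model()] fit.
#' @param factor name of the categorical fixed effect (default
#'   `"state"`).
#' @param mc_draws Monte Carlo sample size (default 1e5, about 1e-3
#'   resolution on adjusted p-values).
#' @param seed RNG seed for the Monte Carlo draw.
#' @return data frame of class `"contrast_table"`: `comparison`,
#'   `estimate`, `std_error`, `z_value`, `p_value` (unadjusted),
#'   `p_adjusted`.
#' @export
tukey_contrasts <- function(object, factor = "state", mc_draws = 1e5,
                            seed = 1) {
  stopifnot(inherits(object, "direction_model"))
  f <- object$data[[factor]]
  if (is.null(f) || !is.factor(f)) stop("no factor '", factor, "' in the model")
  lv <- levels(f)
  k <- length(lv)
  if (k < 2) stop("factor '", factor, "' has fewer than 2 estimated levels")
  b <- coef(object); V <- vcov(object)
  cn <- paste0(factor, lv[-1])
  if (!all(cn %in% names(b)))
    stop("coefficients for factor '", factor, "' not found in the fit")
  bs <- c(0, b[cn])                      # level effects, reference = 0
  Vs <- V[cn, cn, drop = FALSE]
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  K <- matrix(0, m, k - 1)               # contrasts on the (k-1) coef space
  comparison <- character(m)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (i2 > 1) K[j, i2 - 1] <- 1
    if (i1 > 1) K[j, i1 - 1] <- -1
    comparison[j] <- paste(lv[i2], "-", lv[i1])
  }
  est <- drop(K %*% bs[-1]) + 0          # reference column contributes 0
  se <- sqrt(diag(K %*% Vs %*% t(K)))
  z <- est / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_mc <- single_step_maxT(abs(z), se, K, Vs, mc_draws, seed)
  if (is.null(p_mc)) {
    warning("degenerate contrast covariance; falling back to Bonferroni")
    p_adj <- pmin(1, m * p_raw)
  } else {
    p_adj <- pmin(pmax(p_mc, p_raw), pmin(1, m * p_raw))
  }
  res <- data.frame(comparison = comparison, estimate = est, std_error = se,
                    z_value = z, p_value = p_raw, p_adjusted = p_adj,
                    stringsAsFactors = FALSE)
  attr(res, "seed") <- seed
  attr(res, "mc_draws") <- mc_draws
  attr(res, "factor") <- factor
  class(res) <- c("contrast_table", "data.frame")
  res
}

#' Generalized variance-inflation factors of the fixed effects
#'
#' Collinearity diagnostics computed from the correlation structure of the
#' fixed-effect design matrix: for each term,
#' `GVIF = det(R11) det(R22) / det(R)` (Fox & Monette), with the
#' df-corrected `GVIF^(1/(2 df))` comparable across terms of different
#' dimension. A GVIF of 1 means the term is orthogonal to the rest; exact
#' collinearity yields an infinite GVIF with the offending terms named in a
#' warning.
#'
#' @param x a [direction_model()] fit, or a data frame.
#' @param fixed one-sided formula for the fixed effects (required when `x`
#'   is a data frame without a model).
#' @return data frame `term`, `df`, `gvif`, `gvif_scaled`.
#' @export
vif_terms <- function(x, fixed = NULL) {
  if (inherits(x, "direction_model")) {
    dat <- x$data
    if (is.null(fixed)) fixed <- x$fixed
  } else {
    dat <- as.data.frame(x)
    if (is.null(fixed))
      fixed <- stats::reformulate(intersect(
        c("intensity", "n_males", "n_females", "state", "species"),
        names(dat)))
  }
  X <- stats::model.matrix(fixed, dat)
  asg <- attr(X, "assign")
  labels <- attr(stats::terms(fixed), "term.labels")
  X <- X[, asg != 0, drop = FALSE]
  asg <- asg[asg != 0]
  if (length(labels) < 2)
    stop("at least two fixed terms are needed for VIFs")
  R <- stats::cor(X)
  detR <- det(R)
  gvif <- df <- numeric(length(labels))
  for (ti in seq_along(labels)) {
    a <- which(asg == ti)
    df[ti] <- length(a)
    if (detR < 1e-12) { gvif[ti] <- Inf; next }
    gvif[ti] <- det(R[a, a, drop = FALSE]) *
      det(R[-a, -a, drop = FALSE]) / detR
  }
  if (any(!is.finite(gvif))) {
    cr <- abs(R); diag(cr) <- 0
    off <- which(cr > 1 - 1e-8, arr.ind = TRUE)
    nm <- unique(labels[asg[unique(as.vector(off))]])
    warning("exact collinearity among fixed effects; offending term(s): ",
            paste(if (length(nm)) nm else labels, collapse = ", "))
  }
  data.frame(term = labels, df = df, gvif = gvif,
             gvif_scaled = gvif^(1 / (2 * df)), row.names = NULL)
}

#' Simulation-based residual diagnostics
#'
#' Scaled (PIT) residuals in the style of simulation-based model checking:
#' each observation's response is ranked among `n_sim` responses simulated
#' from the fitted model (ties randomized), giving residuals that are
#' uniform on (0, 1) when the model is adequate. Uniformity is tested with
#' a one-sample Kolmogorov-Smirnov test; dispersion with the ratio of the
#' observed residual variance to the simulated residual variances, with a
#' two-sided Monte Carlo p-value.
#'
#' @param object a [direction_model()] fit.
#' @param data optional replacement data (same columns as the fitting
#'   data); when supplied, its `score` column is diagnosed against the
#'   fitted model, e.g. to probe suspected overdispersion.
#' @param n_sim number of simulated response vectors; fewer than 50 is
#'   refused as unstable.
#' @param seed RNG seed for the simulations and tie randomization.
#' @return An object of class `"residual_check"`: list with `uniformity`
#'   (KS statistic and p-value), `dispersion` (variance ratio and Monte
#'   Carlo p-value), and the `scaled_residuals`.
#' @export
residual_diagnostics <- function(object, data = NULL, n_sim = 250, seed = 1) {
  stopifnot(inherits(object, "direction_model"))
  if (n_sim < 50)
    stop("n_sim must be at least 50; fewer simulations give unstable ",
         "scaled residuals")
  if (is.null(data)) {
    y <- object$data$.resp
  } else {
    sc <- as.data.frame(data)$score
    n <- object$squeeze_n
    y1 <- (sc + 1) / 2
    y2 <- (y1 * (n - 1) + 0.5) / n
    y <- switch(object$family, beta_logit = y2,
                linear_logit = stats::qlogis(y2), linear = sc)
  }
  sims <- as.matrix(stats::simulate(object$model, nsim = n_sim, seed = seed))
  u <- with_seed(seed + 1L, {
    lo <- rowSums(sims < y)
    ties <- rowSums(sims == y)
    (lo + stats::runif(length(y)) * (ties + 1)) / (n_sim + 1)
  })
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  ctr <- rowMeans(sims)
  obs_stat <- stats::var(y - ctr)
  sim_stat <- apply(sims - ctr, 2, stats::var)
  ratio <- obs_stat / mean(sim_stat)
  p_hi <- (1 + sum(sim_stat >= obs_stat)) / (n_sim + 1)
  p_lo <- (1 + sum(sim_stat <= obs_stat)) / (n_sim + 1)
  structure(list(
    uniformity = list(statistic = unname(ks$statistic),
                      p_value = ks$p.value),
    dispersion = list(ratio = ratio, p_value = min(1, 2 * min(p_hi, p_lo))),
    scaled_residuals = u, n_sim = n_sim, seed = seed),
    class = "residual_check")
}

#' @export
print.residual_check <- function(x, ...) {
  cat(sprintf("Simulation-based residual check (%d simulations)\n", x$n_sim))
  cat(sprintf("  uniformity: KS D = %.4f, p = %.4f\n",
              x$uniformity$statistic, x$uniformity$p_value))
  cat(sprintf("  dispersion: ratio = %.3f, p = %.4f\n",
              x$dispersion$ratio, x$dispersion$p_value))
  invisible(x)
}

#' Marginal-effect predictions on the interaction-score scale
#'
#' Predicted interaction score with 95% confidence band along a grid of one
#' fixed-effect variable, all other covariates held at their reference
#' level (factors) or mean (numerics). Predictions are population-level
#' (random effects at zero) and mapped back to the score scale in
#' `[-1, 1]`; the confidence band transforms the Wald band on the link
#' scale through the monotone inverse link.
#'
#' @param object a [direction_model()] fit.
#' @param variable name of a fixed-effect variable.
#' @param grid values of `variable` at which to predict; defaults to the
#'   observed levels (factor) or an evenly spaced grid over the observed
#'   range (numeric). Values outside the observed range draw a warning but
#'   are still computed.
#' @param level confidence level.
#' @return data frame with the grid variable, `score`, `lower`, `upper`.
#' @export
predict_effects <- function(object, variable, grid = NULL, level = 0.95) {
  stopifnot(inherits(object, "direction_model"))
  dat <- object$data
  if (is.null(dat[[variable]])) stop("unknown variable: ", variable)
  v <- dat[[variable]]
  if (is.null(grid))
    grid <- if (is.factor(v)) levels(v) else
      seq(min(v), max(v), length.out = 25)
  if (!is.factor(v) && (any(grid < min(v)) || any(grid > max(v))))
    warning("grid extends outside the observed range of ", variable)
  nd <- dat[rep(1L, length(grid)), , drop = FALSE]
  for (cc in names(nd)) {
    if (cc == variable) next
    if (is.factor(nd[[cc]]))
      nd[[cc]] <- factor(levels(dat[[cc]])[1], levels = levels(dat[[cc]]))
    else if (is.numeric(nd[[cc]]))
      nd[[cc]] <- mean(dat[[cc]])
  }
  nd[[variable]] <- if (is.factor(v)) factor(grid, levels = levels(v)) else grid
  pr <- predict(object, newdata = nd, type = "link", se.fit = TRUE)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  lo <- pr$eta - zq * pr$se.fit
  hi <- pr$eta + zq * pr$se.fit
  out <- data.frame(grid, score = link_to_score(object, pr$eta),
                    lower = link_to_score(object, lo),
                    upper = link_to_score(object, hi))
  names(out)[1] <- variable
  rownames(out) <- NULL
  out
}
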