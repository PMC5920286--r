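#' Convert an interval probability to a monthly probability
#'
#' Uses the constant-hazard assumption: a probability `p` of an event over
#' `interval_months` months corresponds to a monthly probability
#' `1 - (1 - p)^(1/interval_months)`, so that compounding the monthly
#' probability over the interval reproduces `p` exactly.
#'
#' @param p_interval probability over the interval, in \[0, 1\].
#' @param interval_months length of the interval in months (>= 1).
#' @return monthly probability.
#' @export
interval_to_monthly <- function(p_interval, interval_months = 24L) {
  if (any(is.na(p_interval)) || any(p_interval < 0 | p_interval > 1))
    .domain_error("interval probability outside [0, 1]")
  if (interval_months < 1) .domain_error("interval_months must be >= 1")
  1 - (1 - p_interval)^(1 / interval_months)
}

# index of each individual's current state in model$states
current_state_index <- function(model, pop, idx = NULL) {
  g <- function(col) if (is.null(idx)) pop[[col]] else pop[[col]][idx]
  switch(model$family,
    binary_logit = 1L + as.integer(g(model$name)),
    ordinal_logit = if (model$name == "mmse_band") mmse_band_index(g("mmse"))
                    else as.integer(g(model$name)),
    generalised_logit = {
      i <- match(g(model$name), model$states)
      if (anyNA(i)) .schema_error(paste0("state outside registry for ", model$name))
      i
    })
}

#' Per-state interval probabilities from a fitted transition model
#'
#' Builds the linear predictor(s) from the individual's current covariates
#' and returns the distribution over wave-2 states implied by the fitted
#' 2-year model.
#'
#' @param model a `transition_model`.
#' @param pop population data frame (or list of columns).
#' @param idx optional row indices to evaluate.
#' @return numeric matrix, one row per (selected) individual, one column per
#'   state; rows sum to 1.
#' @export
predict_interval_probs <- function(model, pop, idx = NULL) {
  cols <- design_columns(pop, model$predictors, idx)
  K <- length(model$states)
  switch(model$family,
    binary_logit = {
      p <- stats::plogis(linear_predictor(cols, model$coef))
      cbind(absent = 1 - p, present = p)
    },
    ordinal_logit = {
      beta <- model$coef$beta
      eta <- linear_predictor(cols, c("(Intercept)" = 0, beta))
      out <- matrix(0, length(eta), K, dimnames = list(NULL, model$states))
      prev <- 0
      for (k in seq_len(K - 1)) {
        cum <- stats::plogis(model$coef$zeta[k] - eta)
        out[, k] <- cum - prev
        prev <- cum
      }
      out[, K] <- 1 - prev
      out
    },
    generalised_logit = {
      n <- length(cols[[1]])
      expeta <- matrix(1, n, K, dimnames = list(NULL, model$states))
      for (k in 2:K)
        expeta[, k] <- exp(linear_predictor(cols, model$coef[k - 1, ]))
      expeta / rowSums(expeta)
    })
}

#' Monthly transition probabilities for one characteristic
#'
#' The fitted interval (2-year) distribution over destination states is
#' converted move-by-move with [interval_to_monthly()]; the stay-probability
#' takes the remainder so each row sums to 1. Individuals already in the
#' present state of an absorbing characteristic stay with probability 1.
#'
#' @inheritParams predict_interval_probs
#' @return matrix of monthly probabilities (rows sum to 1), one column per
#'   state.
#' @export
monthly_transition_probabilities <- function(model, pop, idx = NULL) {
  P <- predict_interval_probs(model, pop, idx)
  cur <- current_state_index(model, pop, idx)
  M <- 1 - (1 - P)^(1 / model$interval_months)
  i <- seq_len(nrow(M))
  diag_idx <- cbind(i, cur)
  M[diag_idx] <- 0
  M[diag_idx] <- 1 - rowSums(M)
  if (isTRUE(model$absorbing)) {
    pres <- cur == 2L
    if (any(pres)) {
      M[pres, 1L] <- 0
      M[pres, 2L] <- 1
    }
  }
  M
}

# Lightly ridge-penalised logistic regression (intercept unpenalised),
# fitted by penalised IRLS. Used as the separation fallback: a small fixed
# L2 penalty keeps the maximum-penalised-likelihood estimate finite while a
# no-event stratum still gets an essentially vanishing predicted
# probability (the intercept remains free to go strongly negative).
ridge_logit <- function(X, y, lambda = 0.01, maxit = 200L, tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)  # column 1 is the intercept
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-10)
    I <- crossprod(X * W, X) + pen
    U <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    step <- solve(I, U)
    # dampen large Newton steps for stability under near-separation
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  Iinv <- solve(I)
  list(coef = stats::setNames(beta, colnames(X)),
       se = stats::setNames(sqrt(diag(Iinv)), colnames(X)),
       iterations = it)
}

# outcome factor for fitting, from wave-2 rows
outcome_factor <- function(spec, w2, idx = NULL) {
  g <- function(col) if (is.null(idx)) w2[[col]] else w2[[col]][idx]
  switch(spec$model_family,
    binary_logit = factor(as.integer(g(spec$name)), levels = 0:1),
    ordinal_logit = {
      code <- if (spec$name == "mmse_band") mmse_band_index(g("mmse"))
              else as.integer(g(spec$name))
      factor(spec$states[code], levels = spec$states, ordered = TRUE)
    },
    generalised_logit = factor(g(spec$name), levels = spec$states))
}

#' Fit one characteristic's transition model to a two-wave panel
#'
#' The outcome is the wave-2 state among wave-2 survivors; covariates are
#' the wave-1 characteristics named in the spec (the model's own lagged
#' state enters through its predictor list; absorbing characteristics are
#' fitted on the at-risk subset only). Families: binary logistic
#' ([stats::glm()]), proportional-odds ordinal ([MASS::polr()]) and
#' generalised/multinomial ([nnet::multinom()]).
#'
#' @param panel two-wave panel data frame (`wave` column coded 1/2, two rows
#'   per surviving individual; wave-2 rows of decedents have `alive = FALSE`).
#' @param spec the [characteristic_spec()] to fit.
#' @param interval_months elapsed months between the waves.
#' @return an object of class `transition_model` with coefficients, standard
#'   errors, covariate schema and fit metadata.
#' @export
fit_transition_model <- function(panel, spec, interval_months = 24L) {
  if (spec$model_family == "none")
    .config_error(paste0(spec$name, " carries no transition model"))
  w1 <- panel[panel$wave == 1L, , drop = FALSE]
  w2 <- panel[panel$wave == 2L, , drop = FALSE]
  w2 <- w2[match(w1$id, w2$id), , drop = FALSE]
  keep <- !is.na(w2$id) & w2$alive
  w1 <- w1[keep, , drop = FALSE]
  w2 <- w2[keep, , drop = FALSE]
  if (isTRUE(spec$absorbing)) {
    at_risk <- !w1[[spec$name]]
    w1 <- w1[at_risk, , drop = FALSE]
    w2 <- w2[at_risk, , drop = FALSE]
  }
  y <- outcome_factor(spec, w2)
  if (length(unique(y)) < 2L)
    .msim_error(paste0("outcome constant in panel for ", spec$name),
                "morbsim_degenerate_fit_error")
  X <- build_design(w1, spec$predictors)
  df <- data.frame(.y = y, X, check.names = FALSE)
  penalised <- FALSE
  if (spec$model_family == "binary_logit") {
    fit <- stats::glm(.y ~ ., family = stats::binomial(), data = df)
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    if (!fit$converged || any(abs(cf) > 15)) {
      warning("possible separation in transition model for ", spec$name,
              "; refitting with a light ridge penalty", call. = FALSE)
      ff <- ridge_logit(cbind(`(Intercept)` = 1, X),
                        as.integer(y) - 1L)
      cf <- ff$coef
      se <- ff$se
      penalised <- TRUE
    }
    coef_out <- cf
    se_out <- se
    ll <- as.numeric(stats::logLik(fit))
  } else if (spec$model_family == "ordinal_logit") {
    fit <- MASS::polr(.y ~ ., data = df, Hess = TRUE)
    coef_out <- list(zeta = fit$zeta, beta = stats::coef(fit))
    se_all <- sqrt(diag(stats::vcov(fit)))
    se_out <- list(zeta = se_all[names(fit$zeta)],
                   beta = se_all[names(stats::coef(fit))])
    ll <- as.numeric(stats::logLik(fit))
  } else {
    fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300)
    cf <- stats::coef(fit)
    if (is.null(dim(cf)))
      cf <- matrix(cf, nrow = 1,
                   dimnames = list(spec$states[2], names(cf)))
    sm <- summary(fit)$standard.errors
    if (is.null(dim(sm)))
      sm <- matrix(sm, nrow = 1, dimnames = dimnames(cf))
    rownames(cf) <- rownames(sm) <- spec$states[-1]
    coef_out <- cf
    se_out <- sm
    ll <- -fit$value
  }
  structure(list(name = spec$name, family = spec$model_family,
                 states = spec$states, absorbing = isTRUE(spec$absorbing),
                 predictors = spec$predictors, schema = colnames(X),
                 coef = coef_out, se = se_out, n = length(y), loglik = ll,
                 interval_months = as.integer(interval_months),
                 penalised = penalised),
            class = "transition_model")
}

#' Fit the full transition-model bundle
#'
#' Fits every stochastic characteristic that carries a model family (all
#' except dementia, which is allocated outside the simulation).
#'
#' @inheritParams fit_transition_model
#' @param registry a `characteristic_registry`.
#' @return `transition_bundle`: named list of `transition_model`s in
#'   registry (update) order.
#' @export
fit_transition_bundle <- function(panel, registry = default_registry(),
                                  interval_months = 24L) {
  specs <- modelled_characteristics(registry)
  models <- lapply(specs, fit_transition_model, panel = panel,
                   interval_months = interval_months)
  structure(models, class = "transition_bundle",
            interval_months = as.integer(interval_months))
}

#' Build a transition model from explicit coefficients
#'
#' Used for ground-truth bundles in synthetic-data generation and for
#' deserialisation; no fitting is involved.
#'
#' @param spec the [characteristic_spec()].
#' @param coef coefficients in the family's shape: binary, a named vector
#'   including `"(Intercept)"`; ordinal, `list(zeta=, beta=)`; generalised,
#'   a matrix with one row per non-reference state.
#' @param interval_months interval the coefficients refer to.
#' @return a `transition_model`.
#' @export
manual_transition_model <- function(spec, coef, interval_months = 24L) {
  schema <- unique(unlist(lapply(spec$predictors, function(p)
    switch(p,
      age = "age_c", sex = "sexfemale", education = "education_c",
      ses = "ses_c", smoking = c("smoking_former", "smoking_current"),
      marital = c("marital_married", "marital_widowed"),
      bmi_cat = "bmi_score", mmse_band = "mmse_band_score", p))))
  structure(list(name = spec$name, family = spec$model_family,
                 states = spec$states, absorbing = isTRUE(spec$absorbing),
                 predictors = spec$predictors, schema = schema,
                 coef = coef, se = NULL, n = NA_integer_, loglik = NA_real_,
                 interval_months = as.integer(interval_months),
                 penalised = FALSE),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> ", x$name, " (", x$family,
      if (x$absorbing) ", absorbing" else "", "), n = ", x$n,
      ", interval = ", x$interval_months, " months\n", sep = "")
  invisible(x)
}

#' @export
print.transition_bundle <- function(x, ...) {
  cat("<transition_bundle> ", length(x), " models, interval ",
      attr(x, "interval_months"), " months\n", sep = "")
  for (m in x) cat("  ", m$name, " [", m$family, "]\n", sep = "")
  invisible(x)
}

#' Serialise / load a transition bundle as JSON
#'
#' @param bundle a `transition_bundle`.
#' @param path file path.
#' @param registry registry used to rebuild specs on load.
#' @return `read_bundle` returns a `transition_bundle`.
#' @export
write_bundle <- function(bundle, path) {
  ser <- lapply(bundle, function(m) {
    cf <- m$coef
    if (m$family == "ordinal_logit")
      cf <- list(zeta = as.list(cf$zeta), beta = as.list(cf$beta))
    else if (m$family == "generalised_logit")
      cf <- list(rows = rownames(cf), cols = colnames(cf),
                 values = unname(split(cf, row(cf))))
    else cf <- as.list(cf)
    list(name = m$name, family = m$family, states = m$states,
         absorbing = m$absorbing, predictors = m$predictors,
         schema = m$schema, coef = cf, n = m$n, loglik = m$loglik,
         interval_months = m$interval_months, penalised = m$penalised)
  })
  jsonlite::write_json(
    list(interval_months = attr(bundle, "interval_months"), models = ser),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path, registry = default_registry()) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(raw$models, function(m) {
    spec <- registry[[m$name]]
    if (is.null(spec)) .config_error(paste0("unknown characteristic ", m$name))
    cf <- if (m$family == "ordinal_logit")
      list(zeta = unlist(m$coef$zeta), beta = unlist(m$coef$beta))
    else if (m$family == "generalised_logit") {
      v <- do.call(rbind, lapply(m$coef$values, unlist))
      dimnames(v) <- list(unlist(m$coef$rows), unlist(m$coef$cols))
      v
    } else unlist(m$coef)
    mm <- manual_transition_model(spec, cf, m$interval_months)
    mm$n <- m$n
    mm$loglik <- if (is.null(m$loglik)) NA_real_ else m$loglik
    mm$penalised <- isTRUE(m$penalised)
    mm
  })
  names(models) <- vapply(models, `[[`, "", "name")
  structure(models, class = "transition_bundle",
            interval_months = as.integer(raw$interval_months))
}
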