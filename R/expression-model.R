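# --- internal helpers -------------------------------------------------------

# concentrations: named list of axis_profile / numeric -> TF x B matrix
conc_matrix <- function(concentrations, n_bins = 100L) {
  if (is.matrix(concentrations)) {
    if (ncol(concentrations) != n_bins) stop("concentration matrix must have ",
                                             n_bins, " columns")
    return(concentrations)
  }
  if (is.null(names(concentrations))) stop("concentrations must be named by TF")
  m <- do.call(rbind, lapply(concentrations, profile_values, n_bins = n_bins))
  rownames(m) <- names(concentrations)
  m
}

# default covariate spec: one first-order term per TF
default_covariate_spec <- function(tf_names) {
  data.frame(tf = tf_names, order = 1L, stringsAsFactors = FALSE)
}

validate_covariate_spec <- function(spec, tf_names) {
  if (is.null(spec)) spec <- default_covariate_spec(tf_names)
  if (!all(c("tf", "order") %in% names(spec))) {
    stop("covariate spec needs columns 'tf' and 'order'")
  }
  if (!all(spec$order %in% c(1L, 2L))) stop("covariate order must be 1 or 2")
  if (!all(spec$tf %in% tf_names)) {
    stop("covariate spec names unknown TF: ",
         paste(setdiff(spec$tf, tf_names), collapse = ", "))
  }
  second <- spec$tf[spec$order == 2]
  if (!all(second %in% spec$tf[spec$order == 1])) {
    stop("every order-2 term needs a matching order-1 term")
  }
  if (anyDuplicated(paste(spec$tf, spec$order))) stop("duplicate covariate terms")
  spec
}

term_labels <- function(spec) {
  ifelse(spec$order == 2, paste0(spec$tf, "^2"), spec$tf)
}

# named score row of a CRM x TF matrix (drop=TRUE loses names for 1 column)
row_of <- function(S, l) setNames(as.numeric(S[l, ]), colnames(S))

# covariate block for one CRM: B x n_terms matrix of (c_{i,b} * S_{i,l})^order
covariate_block <- function(spec, S_row, C) {
  miss <- setdiff(unique(spec$tf), names(S_row))
  if (length(miss)) stop("missing motif score for TF: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(unique(spec$tf), rownames(C))
  if (length(miss)) stop("missing concentration profile for TF: ",
                         paste(miss, collapse = ", "))
  X <- vapply(seq_len(nrow(spec)), function(t) {
    (C[spec$tf[t], ] * S_row[spec$tf[t]])^spec$order[t]
  }, numeric(ncol(C)))
  colnames(X) <- term_labels(spec)
  X
}

bernoulli_loglik <- function(y, mu) {
  eps <- 1e-12
  mu <- pmin(pmax(mu, eps), 1 - eps)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# --- model object -----------------------------------------------------------

#' Construct a CRM expression regression model
#'
#' The model predicts the expression of CRM `l` in axis bin `b` as
#' `sig(alpha_l + sum_i w_i (c_{i,b} S_{i,l})^{order_i})` where `sig` is the
#' logistic function, `c_{i,b}` the concentration of factor `i` in bin `b`,
#' `S_{i,l}` its motif score in the CRM, `w_i` the factor's regression weight
#' (positive for activators, negative for repressors) and `alpha_l` a
#' CRM-specific basal level. Second-order terms square the covariate (used
#' for the anterior activator whose response is non-monotone).
#'
#' Normally produced by [fit_model()]; the constructor is exported so models
#' with known weights can be built directly (e.g. for simulation).
#'
#' @param weights Named numeric vector of term weights; second-order terms
#'   are named `"<tf>^2"`.
#' @param baselines Named numeric vector of per-CRM basal levels.
#' @param covariate_spec Data frame with columns `tf`, `order`.
#' @param se_weights,se_baselines Optional standard errors.
#' @param loglik,lambda,converged,separation Fit metadata.
#' @return An object of class `regression_model`.
#' @export
regression_model <- function(weights, baselines, covariate_spec,
                             se_weights = NULL, se_baselines = NULL,
                             loglik = NA_real_, lambda = NA_real_,
                             converged = NA, separation = NA) {
  covariate_spec <- validate_covariate_spec(covariate_spec,
                                            unique(covariate_spec$tf))
  if (!identical(sort(names(weights)), sort(term_labels(covariate_spec)))) {
    stop("weights must be named by the covariate terms")
  }
  structure(list(weights = weights, baselines = baselines,
                 covariate_spec = covariate_spec, se_weights = se_weights,
                 se_baselines = se_baselines, loglik = loglik,
                 lambda = lambda, converged = converged,
                 separation = separation),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf("<regression_model> %d terms, %d CRM baselines\n",
              length(x$weights), length(x$baselines)))
  print(round(x$weights, 4))
  invisible(x)
}

#' Predict a CRM's expression profile
#'
#' Evaluates the logistic model for one CRM given its motif scores and the
#' TF concentration profiles.
#'
#' @param model A [regression_model()].
#' @param S_row Named numeric vector of motif scores for this CRM (one per
#'   TF in the covariate spec).
#' @param concentrations Named list of continuous [axis_profile()]s (or a
#'   TF x bins matrix).
#' @param crm CRM name whose trained baseline to use, or
#' @param alpha an explicit baseline (used when scanning windows that have no
#'   trained baseline; defaults to the mean trained baseline).
#' @return A continuous [axis_profile()] with values in (0, 1).
#' @export
predict_expression <- function(model, S_row, concentrations, crm = NULL,
                               alpha = NULL) {
  C <- conc_matrix(concentrations)
  if (is.null(alpha)) {
    alpha <- if (!is.null(crm)) {
      if (!crm %in% names(model$baselines)) stop("unknown CRM: ", crm)
      model$baselines[[crm]]
    } else mean(model$baselines)
  }
  X <- covariate_block(model$covariate_spec, S_row, C)
  eta <- alpha + as.numeric(X %*% model$weights[colnames(X)])
  axis_profile(plogis(eta), "continuous",
               label = if (is.null(crm)) "prediction" else crm,
               n_bins = ncol(C))
}

#' Fit the expression model by iteratively reweighted least squares
#'
#' Maximizes the Bernoulli log-likelihood of the binary target profiles under
#' the logistic model via IWLS with a small ridge penalty (`lambda`, default
#' `1e-6`) that keeps coefficients finite when the data are separable. The
#' fit is deterministic. Covariates with zero variance across all CRM x bin
#' cells are dropped with a warning. Standard errors come from the inverse
#' of the (penalized) Fisher information.
#'
#' @param S CRM x TF matrix of motif scores with row/column names.
#' @param concentrations Named list of continuous [axis_profile()]s per TF.
#' @param targets Named list of binary [axis_profile()]s, one per row of `S`.
#' @param covariate_spec Data frame with columns `tf` and `order` (1 or 2);
#'   default: one first-order term per TF.
#' @param lambda Ridge stabilizer (default 1e-6).
#' @param max_iter,tol IWLS iteration cap (default 100) and relative
#'   log-likelihood convergence tolerance (default 1e-8).
#' @return A list with elements `model` (a [regression_model()]) and
#'   `report` (a fit report from [goodness_of_fit()]).
#' @export
fit_model <- function(S, concentrations, targets, covariate_spec = NULL,
                      lambda = 1e-6, max_iter = 100L, tol = 1e-8) {
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    stop("S must have CRM rownames and TF colnames")
  }
  if (nrow(S) < 1) stop("need at least one CRM")
  if (!all(rownames(S) %in% names(targets))) stop("missing target profiles")
  C <- conc_matrix(concentrations)
  spec <- validate_covariate_spec(covariate_spec, colnames(S))
  B <- ncol(C)
  crms <- rownames(S)
  n_crm <- length(crms)

  Xt <- do.call(rbind, lapply(crms, function(l) {
    covariate_block(spec, row_of(S, l), C)
  }))
  y <- unlist(lapply(crms, function(l) {
    v <- profile_values(targets[[l]], B)
    if (!all(v %in% c(0, 1))) stop("target profiles must be binary")
    v
  }), use.names = FALSE)

  keep <- apply(Xt, 2, function(col) stats::var(col) > 0)
  dropped <- colnames(Xt)[!keep]
  if (length(dropped)) {
    warning("dropping zero-variance covariate(s): ",
            paste(dropped, collapse = ", "))
    Xt <- Xt[, keep, drop = FALSE]
    spec <- spec[keep, , drop = FALSE]
  }
  if (ncol(Xt) == 0) stop("no usable covariates")

  # full design: covariate terms then one indicator per CRM baseline
  D <- matrix(0, n_crm * B, n_crm)
  for (i in seq_len(n_crm)) D[((i - 1) * B + 1):(i * B), i] <- 1
  X <- cbind(Xt, D)
  p <- ncol(X)
  n_terms <- ncol(Xt)

  beta <- rep(0, p)
  pen_ll <- function(b) {
    mu <- plogis(as.numeric(X %*% b))
    bernoulli_loglik(y, mu) - lambda * sum(b^2) / 2
  }
  ll_old <- pen_ll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X + diag(lambda, p)
    beta_new <- as.numeric(solve(H, XtW %*% z))
    # step-halving if the penalized likelihood would decrease
    ll_new <- pen_ll(beta_new)
    step <- 1
    while (ll_new < ll_old && step > 1e-4) {
      step <- step / 2
      beta_new <- beta + step * (beta_new - beta)
      ll_new <- pen_ll(beta_new)
    }
    beta <- beta_new
    if (abs(ll_new - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  eta <- as.numeric(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- t(X * w) %*% X + diag(lambda, p)
  se <- sqrt(diag(solve(H)))
  separation <- max(abs(eta)) > 30

  weights <- setNames(beta[seq_len(n_terms)], colnames(Xt))
  baselines <- setNames(beta[n_terms + seq_len(n_crm)], crms)
  model <- regression_model(
    weights, baselines, spec,
    se_weights = setNames(se[seq_len(n_terms)], colnames(Xt)),
    se_baselines = setNames(se[n_terms + seq_len(n_crm)], crms),
    loglik = bernoulli_loglik(y, mu), lambda = lambda,
    converged = converged, separation = separation)
  list(model = model,
       report = goodness_of_fit(model, S, concentrations, targets))
}

#' Coefficient z-scores and p-values
#'
#' The ratio of each trained weight to its estimated standard error is
#' treated as a z-score; two-sided p-values come from the standard normal.
#'
#' @param model A fitted [regression_model()].
#' @return Data frame with columns `term`, `estimate`, `se`, `z`, `p`.
#'   Terms with zero standard error get `NA` z and p.
#' @export
coefficient_significance <- function(model) {
  if (is.null(model$se_weights)) stop("model carries no standard errors")
  est <- model$weights
  se <- model$se_weights[names(est)]
  z <- ifelse(se > 0, est / se, NA_real_)
  data.frame(term = names(est), estimate = as.numeric(est),
             se = as.numeric(se), z = as.numeric(z),
             p = 2 * pnorm(-abs(as.numeric(z))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Goodness-of-fit report
#'
#' Computes, over all CRM x bin cells: the root mean squared error between
#' predicted and target expression; the mean over CRMs of the per-CRM
#' Pearson correlation between prediction and target across bins (CRMs with
#' zero variance in either vector are excluded and counted); and
#' `AIC = 2k - 2 logLik` with `k` = number of TF terms plus number of
#' baselines.
#'
#' @inheritParams fit_model
#' @param model A fitted [regression_model()].
#' @return A list of class `fit_report`: `rmse`, `mean_cc`, `n_cc_used`,
#'   `n_cc_excluded`, `aic`, `k`, `loglik`.
#' @export
goodness_of_fit <- function(model, S, concentrations, targets) {
  C <- conc_matrix(concentrations)
  B <- ncol(C)
  crms <- rownames(S)
  sq <- 0; n <- 0; ll <- 0
  ccs <- numeric(0); excl <- 0L
  for (l in crms) {
    pred <- predict_expression(model, row_of(S, l), C, crm = l)$values
    yv <- profile_values(targets[[l]], B)
    sq <- sq + sum((pred - yv)^2); n <- n + B
    ll <- ll + bernoulli_loglik(yv, pred)
    if (sd(pred) > 0 && sd(yv) > 0) ccs <- c(ccs, cor(pred, yv))
    else excl <- excl + 1L
  }
  k <- length(model$weights) + length(model$baselines)
  structure(list(rmse = sqrt(sq / n),
                 mean_cc = if (length(ccs)) mean(ccs) else NA_real_,
                 n_cc_used = length(ccs), n_cc_excluded = excl,
                 aic = 2 * k - 2 * ll, k = k, loglik = ll),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> RMSE %.4f | mean CC %.3f (%d CRMs, %d excluded) | AIC %.1f\n",
              x$rmse, x$mean_cc, x$n_cc_used, x$n_cc_excluded, x$aic))
  invisible(x)
}

#' Replicated two-fold cross-validation of the expression model
#'
#' Each replicate randomly splits the CRM x bin cells in half, trains the
#' model on one half and records the test RMSE on the other, for both halves
#' (their mean is the replicate's value). With `shuffle = TRUE` the
#' CRM-to-expression-profile assignment is randomly permuted before
#' splitting, which destroys the sequence-to-pattern signal and yields the
#' null distribution to compare against.
#'
#' @inheritParams fit_model
#' @param folds Number of folds (fixed at 2).
#' @param reps Number of replicates.
#' @param shuffle Permute the CRM-profile matching first?
#' @param seed Integer seed; the run is fully reproducible.
#' @return Numeric vector of test RMSEs, length `reps`.
#' @export
cross_validate <- function(S, concentrations, targets, covariate_spec = NULL,
                           folds = 2L, reps = 1000L, shuffle = FALSE,
                           seed = 1L, lambda = 1e-6) {
  if (reps < 1) stop("reps must be >= 1")
  if (folds != 2L) stop("only 2-fold cross-validation is supported")
  if (nrow(S) < 4) stop("need at least 4 CRMs")
  C <- conc_matrix(concentrations)
  B <- ncol(C)
  crms <- rownames(S)
  spec <- validate_covariate_spec(covariate_spec, colnames(S))
  withr::local_seed(seed)
  vapply(seq_len(reps), function(r) {
    tg <- targets[crms]
    if (shuffle) tg <- setNames(tg[sample(length(tg))], crms)
    Y <- do.call(rbind, lapply(tg, profile_values, n_bins = B))
    half <- sample(length(Y), floor(length(Y) / 2))
    mask <- matrix(FALSE, nrow(Y), ncol(Y)); mask[half] <- TRUE
    rmse <- vapply(c(TRUE, FALSE), function(train_in_mask) {
      fit <- fit_cells(S, C, Y, spec, if (train_in_mask) mask else !mask,
                       lambda = lambda)
      test <- if (train_in_mask) !mask else mask
      sqrt(mean((fit$mu[test] - Y[test])^2))
    }, numeric(1))
    mean(rmse)
  }, numeric(1))
}

# IWLS on a cell subset; returns fitted probabilities for ALL cells.
# Y, mask: CRM x bin matrices.
fit_cells <- function(S, C, Y, spec, mask, lambda = 1e-6, max_iter = 50L,
                      tol = 1e-8) {
  B <- ncol(C)
  n_crm <- nrow(Y)
  Xt <- do.call(rbind, lapply(seq_len(n_crm), function(i) {
    covariate_block(spec, row_of(S, i), C)
  }))
  D <- matrix(0, n_crm * B, n_crm)
  for (i in seq_len(n_crm)) D[((i - 1) * B + 1):(i * B), i] <- 1
  X <- cbind(Xt, D)
  # crm-major ordering to match X
  y <- unlist(lapply(seq_len(n_crm), function(i) Y[i, ]), use.names = FALSE)
  sel <- unlist(lapply(seq_len(n_crm), function(i) mask[i, ]),
                use.names = FALSE)
  Xs <- X[sel, , drop = FALSE]; ys <- y[sel]
  p <- ncol(X)
  beta <- rep(0, p)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xs %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (ys - mu) / w
    XtW <- t(Xs * w)
    beta <- as.numeric(solve(XtW %*% Xs + diag(lambda, p), XtW %*% z))
    ll <- bernoulli_loglik(ys, plogis(as.numeric(Xs %*% beta))) -
      lambda * sum(beta^2) / 2
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  mu_all <- matrix(plogis(as.numeric(X %*% beta)), n_crm, B, byrow = TRUE)
  list(beta = beta, mu = mu_all)
}

#' In-silico knockdown of a transcription factor
#'
#' Re-predicts a CRM's expression with the named TF's concentration profile
#' replaced by zeros everywhere, leaving everything else unchanged.
#'
#' @inheritParams predict_expression
#' @param tf Name of the TF to knock down.
#' @return A continuous [axis_profile()].
#' @export
knockdown <- function(model, tf, S_row, concentrations, crm = NULL,
                      alpha = NULL) {
  C <- conc_matrix(concentrations)
  if (!tf %in% rownames(C)) stop("unknown TF: ", tf)
  C[tf, ] <- 0
  predict_expression(model, S_row, C, crm = crm, alpha = alpha)
}

#' Serialize / restore a regression model as JSON
#'
#' @param model A [regression_model()].
#' @param path Output / input file path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(weights = as.list(model$weights),
         baselines = as.list(model$baselines),
         se_weights = as.list(model$se_weights),
         se_baselines = as.list(model$se_baselines),
         covariate_spec = model$covariate_spec,
         loglik = model$loglik, lambda = model$lambda),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  regression_model(unlist(x$weights), unlist(x$baselines),
                   as.data.frame(x$covariate_spec),
                   se_weights = unlist(x$se_weights),
                   se_baselines = unlist(x$se_baselines),
                   loglik = x$loglik, lambda = x$lambda)
}
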