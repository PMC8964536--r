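# Build the numeric arrays the optimiser works on from a long-format
# choices table. Within-index (lambda-scaled) columns: 27 free attribute
# levels (cont4 reference), optional taste-interaction and worst-stage ASC
# columns; position columns for rows 2..7 of each stage type; scale
# covariate columns Z.
build_model_data <- function(choices, respondents = NULL,
                             scale_covars = character(),
                             interactions = NULL,
                             include_worst_asc = FALSE,
                             scale_applies = "all",
                             first_seq_len = 4L) {
  oi <- occasion_index(choices)
  ch <- choices[oi$order, , drop = FALSE]
  occ <- oi$occ
  N <- nrow(ch)
  lab <- paste0(ch$attribute, ch$level)
  type <- stage_type(ch$stage)
  sgn <- ifelse(type == "B", 1, -1)
  ridx <- if (!is.null(respondents)) match(ch$respondent_id, respondents$id)

  labs27 <- setdiff(level_labels(), "cont4")
  cols <- list()
  scaled <- logical()
  add_col <- function(name, values, is_scaled) {
    cols[[name]] <<- values
    scaled[name] <<- is_scaled
  }
  for (j in seq_along(labs27))
    add_col(labs27[j], sgn * (lab == labs27[j]), TRUE)
  if (!is.null(interactions) && nrow(interactions)) {
    if (is.null(respondents))
      stop("interactions require a respondents table")
    for (i in seq_len(nrow(interactions))) {
      v <- interactions$covariate[i]
      if (is.null(respondents[[v]]))
        stop("collinearity/na: interaction covariate '", v,
             "' missing from the cohort")
      nm <- paste0(interactions$level[i], ":", v)
      add_col(nm, sgn * (lab == interactions$level[i]) *
                as.numeric(respondents[[v]][ridx]), TRUE)
    }
  }
  if (include_worst_asc) {
    codes <- tolower(ascot_scheme()$codes)
    for (a in codes[-1])
      add_col(paste0("ascW_", a), as.numeric(type == "W" & ch$attribute == a),
              TRUE)
  }
  pos_scaled <- identical(scale_applies, "all")
  for (r in 2:7) {
    add_col(paste0("pos", r, "_B"), as.numeric(type == "B" & ch$row == r),
            pos_scaled)
    add_col(paste0("pos", r, "_W"), as.numeric(type == "W" & ch$row == r),
            pos_scaled)
  }
  M <- matrix(unlist(cols, use.names = FALSE), nrow = N,
              dimnames = list(NULL, names(cols)))
  drop_cols <- colnames(M)[colSums(M != 0) == 0]
  keep <- setdiff(colnames(M), drop_cols)
  M <- M[, keep, drop = FALSE]
  scaled <- scaled[keep]

  Z <- NULL
  if (length(scale_covars)) {
    if (is.null(respondents)) stop("scale covariates require a respondents table")
    Z <- vapply(scale_covars, function(v) {
      if (v == "learning") as.numeric(ch$task > first_seq_len)
      else {
        if (is.null(respondents[[v]]))
          stop("scale covariate '", v, "' missing from the cohort")
        as.numeric(respondents[[v]][ridx])
      }
    }, numeric(N))
    colnames(Z) <- scale_covars
  }
  list(M = M, Z = Z, scaled = scaled, occ = occ,
       y = ch$chosen == 1L, cluster = ch$respondent_id,
       n_occ = max(occ), sizes = as.integer(table(occ)))
}

# Safeguarded Newton ascent: Levenberg-style ridge keeps the step an ascent
# direction where the likelihood is not locally concave; step-halving line
# search guarantees monotone log-likelihood.
newton_maximize <- function(par, dat, gtol = 1e-6, maxit = 500L) {
  npar <- length(par)
  ev <- smnl_eval(par, dat, hessian = TRUE)
  iter <- 0L
  converged <- max(abs(ev$grad)) < gtol
  while (!converged && iter < maxit) {
    iter <- iter + 1L
    ridge <- 0
    improved <- FALSE
    repeat {
      Hr <- if (ridge > 0) ev$H - ridge * diag(npar) else ev$H
      step <- tryCatch(solve(Hr, -ev$grad), error = function(e) NULL)
      ok_dir <- !is.null(step) && all(is.finite(step)) &&
        sum(step * ev$grad) > 0
      if (ok_dir) {
        alpha <- 1
        gmax <- max(abs(ev$grad))
        while (alpha >= 1e-10) {
          cand <- par + alpha * step
          ev_new <- tryCatch(smnl_eval(cand, dat, hessian = FALSE),
                             error = function(e) NULL)
          # accept on log-likelihood ascent, or — near the optimum, where
          # LL changes fall below double precision — on a halved gradient
          ok <- !is.null(ev_new) && is.finite(ev_new$ll) &&
            (ev_new$ll > ev$ll + 1e-11 * (1 + abs(ev$ll)) ||
             (max(abs(ev_new$grad)) < 0.5 * gmax &&
              ev_new$ll > ev$ll - 1e-9 * (1 + abs(ev$ll))))
          if (ok) {
            par <- cand
            improved <- TRUE
            break
          }
          alpha <- alpha / 2
        }
      }
      if (improved) break
      ridge <- if (ridge == 0) 1e-4 * max(1, max(abs(diag(ev$H)))) else ridge * 10
      if (ridge > 1e12 * max(1, max(abs(diag(ev$H)))))
        stop("non-convergence: no ascent direction at iteration ", iter,
             " (|grad| = ", format(max(abs(ev$grad))), ")")
    }
    ev <- smnl_eval(par, dat, hessian = TRUE)
    converged <- max(abs(ev$grad)) < gtol
  }
  list(par = par, ev = ev, iterations = iter, converged = converged)
}

# groupwise max over sorted integer groups, overflow-safe softmax shift
occ_max <- function(V, occ) {
  gm <- max(V)
  if (gm - min(V) < 600) return(rep(gm, length(V)))
  stats::ave(V, occ, FUN = max)
}

# log-likelihood, probabilities, gradient and (optionally) Hessian at par
smnl_eval <- function(par, dat, hessian = FALSE) {
  k_w <- ncol(dat$M)
  k_t <- if (is.null(dat$Z)) 0L else ncol(dat$Z)
  bw <- par[seq_len(k_w)]
  th <- if (k_t) par[k_w + seq_len(k_t)] else numeric()
  s_idx <- which(dat$scaled)
  u_s <- as.vector(dat$M[, s_idx, drop = FALSE] %*% bw[s_idx])
  u_u <- if (length(s_idx) < k_w)
    as.vector(dat$M[, -s_idx, drop = FALSE] %*% bw[-s_idx]) else 0
  lam <- if (k_t) exp(as.vector(dat$Z %*% th)) else rep(1, nrow(dat$M))
  V <- lam * u_s + u_u
  shift <- occ_max(V, dat$occ)
  e <- exp(V - shift)
  denom <- as.vector(rowsum(e, dat$occ))
  p <- e / denom[dat$occ]
  ll <- sum(log(p[dat$y]))
  r <- as.numeric(dat$y) - p

  # J = dV/dpar, row-wise
  J <- dat$M
  if (length(s_idx)) J[, s_idx] <- J[, s_idx, drop = FALSE] * lam
  if (k_t) J <- cbind(J, dat$Z * (lam * u_s))
  g <- as.vector(crossprod(J, r))
  names(g) <- c(colnames(dat$M), colnames(dat$Z))
  out <- list(ll = ll, grad = g, p = p, r = r, lam = lam, u_s = u_s, J = J)
  if (hessian) {
    Jp <- J * p
    Jbar <- rowsum(Jp, dat$occ)
    H <- -(crossprod(J, Jp) - crossprod(Jbar))
    if (k_t) {
      # curvature of V itself: d2V/db_s dtheta and d2V/dtheta dtheta'
      rl <- r * lam
      for (k in seq_len(k_t)) {
        zk <- dat$Z[, k]
        hbt <- as.vector(crossprod(dat$M[, s_idx, drop = FALSE], rl * zk))
        H[s_idx, k_w + k] <- H[s_idx, k_w + k] + hbt
        H[k_w + k, s_idx] <- H[k_w + k, s_idx] + hbt
      }
      w <- r * lam * u_s
      H[k_w + seq_len(k_t), k_w + seq_len(k_t)] <-
        H[k_w + seq_len(k_t), k_w + seq_len(k_t)] +
        crossprod(dat$Z, dat$Z * w)
    }
    out$H <- H
  }
  out
}

#' Fit an exploded best-worst choice model by maximum likelihood
#'
#' Fits the exploded sequential logit to long-format BWS choice data:
#' plain MNL (attribute-level utilities plus best/worst position constants),
#' S-MNL (adding multiplicative scale factors `gamma = exp(theta)` on
#' respondent covariates and the learning indicator), optionally with
#' attribute-level x subgroup taste interactions and worst-stage
#' attribute-specific constants. Estimation is Newton-Raphson with analytic
#' gradient and Hessian and step-halving line search; reference constraints
#' (`cont4 = 0`, row-1 position constants = 0, reference scale group
#' `lambda = 1`) are structural. Standard errors are cluster-robust
#' (sandwich) over respondents.
#'
#' @param choices an `ascot_choices` long-format data frame.
#' @param respondents cohort table (required for scale covariates or
#'   interactions).
#' @param model `"mnl"` or `"smnl"`.
#' @param scale_covars scale covariates for `"smnl"`; default
#'   `c("hgood", "eduhigh", "tmlong", "learning")`.
#' @param interactions optional data frame with columns `level`,
#'   `covariate` defining taste terms (a `delta` column, if present, is
#'   ignored: coefficients are estimated).
#' @param include_worst_asc add attribute-specific constants for worst-type
#'   stages (first attribute is the reference)?
#' @param start optional named start vector; defaults to zeros.
#' @param gtol convergence tolerance on the gradient max-norm (default 1e-6).
#' @param maxit maximum Newton iterations (default 500).
#' @param scale_applies,first_seq_len see [stage_utilities].
#' @return a `bws_fit` object: list with `model`, `estimates`, `vcov`
#'   (cluster-robust), `vcov_hessian`, `se`, `loglik`, `loglik_null`,
#'   `rho2_0`, `n_occasions`, `n_clusters`, `gradient_norm`, `iterations`,
#'   `converged`, `gamma` (scale factors with delta-method SEs, S-MNL only),
#'   and the fitting options.
#' @examples
#' \donttest{
#' coh <- simulate_respondents(60, seed = 2)
#' plan <- generate_omep(seed = 2)
#' ch <- simulate_dataset(coh, plan, finnish_carer_estimates("I"), seed = 2)
#' fit <- fit_model(ch, coh, model = "mnl")
#' fit$rho2_0
#' }
#' @export
fit_model <- function(choices, respondents = NULL,
                      model = c("smnl", "mnl"),
                      scale_covars = c("hgood", "eduhigh", "tmlong", "learning"),
                      interactions = NULL,
                      include_worst_asc = FALSE,
                      start = NULL, gtol = 1e-6, maxit = 500L,
                      scale_applies = c("all", "beta"),
                      first_seq_len = 4L) {
  model <- match.arg(model)
  scale_applies <- match.arg(scale_applies)
  if (model == "mnl") scale_covars <- character()
  dat <- build_model_data(choices, respondents, scale_covars, interactions,
                          include_worst_asc, scale_applies, first_seq_len)
  npar <- ncol(dat$M) + (if (is.null(dat$Z)) 0L else ncol(dat$Z))
  par_names <- c(colnames(dat$M), colnames(dat$Z))
  qr_M <- qr(crossprod(dat$M))
  if (qr_M$rank < ncol(dat$M)) {
    bad <- colnames(dat$M)[qr_M$pivot[(qr_M$rank + 1):ncol(dat$M)]]
    stop("singular design: collinear columns ", paste(bad, collapse = ", "))
  }
  par <- stats::setNames(numeric(npar), par_names)
  if (!is.null(start)) {
    if (is.null(names(start))) {
      stopifnot(length(start) == npar)
      par[] <- start
    } else par[names(start)] <- start
  }

  # warm start: with scale factors present the likelihood is only locally
  # concave, so first solve the concave conditional-logit subproblem
  # (theta = 0), then run full Newton from there
  if (!is.null(dat$Z) && is.null(start)) {
    dat0 <- dat
    dat0$Z <- NULL
    ns0 <- newton_maximize(par[seq_len(ncol(dat$M))], dat0,
                           gtol = max(gtol, 1e-4), maxit = maxit)
    par[seq_len(ncol(dat$M))] <- ns0$par
  }
  ns <- newton_maximize(par, dat, gtol = gtol, maxit = maxit)
  par <- ns$par
  ev <- ns$ev
  iter <- ns$iterations
  converged <- ns$converged
  if (!converged)
    warning("non-convergence: gradient max-norm ", format(max(abs(ev$grad))),
            " after ", iter, " iterations")

  G <- rowsum(ev$J * ev$r, dat$cluster)
  bread <- solve(-ev$H)
  vcov_rob <- bread %*% crossprod(G) %*% bread
  dimnames(vcov_rob) <- list(par_names, par_names)
  vcov_hess <- bread
  dimnames(vcov_hess) <- list(par_names, par_names)

  ll0 <- -sum(log(dat$sizes))
  k_t <- if (is.null(dat$Z)) 0L else ncol(dat$Z)
  gamma <- NULL
  if (k_t) {
    th <- par[ncol(dat$M) + seq_len(k_t)]
    se_th <- sqrt(diag(vcov_rob))[ncol(dat$M) + seq_len(k_t)]
    gamma <- data.frame(covariate = colnames(dat$Z),
                        gamma = exp(th), se = exp(th) * se_th,
                        row.names = NULL)
  }
  structure(list(
    model = if (k_t) "smnl" else "mnl",
    estimates = par,
    vcov = vcov_rob,
    vcov_hessian = vcov_hess,
    se = sqrt(diag(vcov_rob)),
    loglik = ev$ll,
    loglik_null = ll0,
    rho2_0 = 1 - ev$ll / ll0,
    n_occasions = dat$n_occ,
    n_clusters = length(unique(dat$cluster)),
    gradient_norm = max(abs(ev$grad)),
    iterations = iter,
    converged = converged,
    gamma = gamma,
    options = list(scale_covars = scale_covars, interactions = interactions,
                   include_worst_asc = include_worst_asc,
                   scale_applies = scale_applies,
                   first_seq_len = first_seq_len)
  ), class = "bws_fit")
}

#' @export
print.bws_fit <- function(x, ...) {
  cat(sprintf("Exploded BWS %s fit: %d occasions, %d respondents\n",
              toupper(x$model), x$n_occasions, x$n_clusters))
  cat(sprintf("  log-likelihood %.2f (null %.2f), rho2(0) = %.3f\n",
              x$loglik, x$loglik_null, x$rho2_0))
  cat(sprintf("  %d free parameters, %d Newton iterations, |grad| = %.2e\n",
              length(x$estimates), x$iterations, x$gradient_norm))
  if (!is.null(x$gamma)) {
    cat("  scale factors:\n")
    for (i in seq_len(nrow(x$gamma)))
      cat(sprintf("    %-9s gamma = %.3f (se %.3f)\n", x$gamma$covariate[i],
                  x$gamma$gamma[i], x$gamma$se[i]))
  }
  invisible(x)
}

#' @export
coef.bws_fit <- function(object, ...) object$estimates

#' @export
vcov.bws_fit <- function(object, ...) object$vcov

#' @export
logLik.bws_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates),
            nobs = object$n_occasions, class = "logLik")
}

#' Extract a fitted parameter set
#'
#' Repackages a `bws_fit` as a [bws_params] object (28 beta with the cont4
#' reference restored, position vectors, scale factors, interaction terms)
#' for use with the simulator, likelihood and weighting functions.
#'
#' @param fit a `bws_fit`.
#' @return a [bws_params].
#' @export
fitted_params <- function(fit) {
  est <- fit$estimates
  labs <- level_labels()
  beta <- est[intersect(names(est), labs)]
  pb <- pw <- numeric(7)
  for (r in 2:7) {
    pb[r] <- est[paste0("pos", r, "_B")] %||% 0
    pw[r] <- est[paste0("pos", r, "_W")] %||% 0
  }
  pb[is.na(pb)] <- 0; pw[is.na(pw)] <- 0
  scale <- numeric()
  if (!is.null(fit$gamma))
    scale <- stats::setNames(fit$gamma$gamma, fit$gamma$covariate)
  inter <- NULL
  if (!is.null(fit$options$interactions) && nrow(fit$options$interactions)) {
    inter <- fit$options$interactions[, c("level", "covariate")]
    inter$delta <- est[paste0(inter$level, ":", inter$covariate)]
  }
  bws_params(beta = beta, pos_best = pb, pos_worst = pw, scale = scale,
             interactions = inter)
}

#' Cluster-robust sandwich covariance of a fitted model
#'
#' Recomputes `H^-1 (sum_c g_c g_c') H^-1` at the fitted estimates, with
#' per-cluster score sums `g_c` and the analytic Hessian `H`, clustering on
#' the supplied id (default: respondent). This is the covariance already
#' stored in the fit; exposing the computation lets alternative clusterings
#' be examined.
#'
#' @param fit a `bws_fit`.
#' @param choices,respondents the data the model was fitted to.
#' @param cluster vector of cluster ids aligned with `choices` rows, or NULL
#'   for the respondent id.
#' @return robust covariance matrix.
#' @export
sandwich_covariance <- function(fit, choices, respondents = NULL,
                                cluster = NULL) {
  dat <- build_model_data(choices, respondents, fit$options$scale_covars,
                          fit$options$interactions,
                          fit$options$include_worst_asc,
                          fit$options$scale_applies, fit$options$first_seq_len)
  if (!is.null(cluster)) {
    oi <- occasion_index(choices)
    dat$cluster <- cluster[oi$order]
  }
  ev <- smnl_eval(fit$estimates[c(colnames(dat$M), colnames(dat$Z))], dat,
                  hessian = TRUE)
  if (inherits(tryCatch(solve(ev$H), error = function(e) e), "error"))
    stop("singular Hessian")
  G <- rowsum(ev$J * ev$r, dat$cluster)
  bread <- solve(-ev$H)
  out <- bread %*% crossprod(G) %*% bread
  dimnames(out) <- list(names(fit$estimates), names(fit$estimates))
  out
}

#' Likelihood-ratio test of nested fits
#'
#' `statistic = -2 (LL_restricted - LL_full)` referred to the chi-square
#' distribution with `df` = difference in free-parameter counts.
#'
#' @param fit_restricted,fit_full fitted models (`bws_fit`), or lists with
#'   elements `loglik` and `df`/`estimates`.
#' @return list with `statistic`, `df`, `p_value`.
#' @examples
#' lr_test(list(loglik = -38475.50, df = 43), list(loglik = -38469.54, df = 47))
#' @export
lr_test <- function(fit_restricted, fit_full) {
  getdf <- function(f) if (!is.null(f$df)) f$df else length(f$estimates)
  ll_r <- fit_restricted$loglik; ll_f <- fit_full$loglik
  df <- getdf(fit_full) - getdf(fit_restricted)
  if (df < 0) stop("nesting violation: full model has fewer parameters")
  if (ll_f < ll_r - 1e-8)
    stop("nesting violation: full-model log-likelihood below restricted")
  stat <- -2 * (ll_r - ll_f)
  list(statistic = stat, df = df,
       p_value = if (df == 0) as.numeric(stat <= 0) else
         stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Pseudo-R-squared against the uniform-choice null
#'
#' `rho2(0) = 1 - LL / LL0` with `LL0` the exploded uniform-choice
#' log-likelihood on the same occasions.
#'
#' @param fit a `bws_fit`, or a list with `loglik` and `loglik_null`.
#' @param digits rounding of the reported value (default 3, as published).
#' @return scalar.
#' @export
pseudo_r2 <- function(fit, digits = 3) {
  round(1 - fit$loglik / fit$loglik_null, digits)
}
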