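attr_of <- function(labels) sub("[1-4]$", "", labels)
level_of <- function(labels) as.integer(sub("^[a-z]+", "", labels))

check_beta28 <- function(beta) {
  labs <- level_labels()
  if (is.null(names(beta)) || !all(labs %in% names(beta)))
    stop("beta must be a named vector covering all 28 attribute levels")
  beta[labs]
}

#' Post-stratification taste adjustment of attribute-level coefficients
#'
#' Adjusts fitted attribute-level coefficients toward the general population
#' by replacing each sample-specific interaction with its population-share
#' weighted contribution: `beta*_jk = beta_jk + sum_m s_g(m) * delta_m` over
#' the interaction terms `m` touching level `jk`, with `s_g` the population
#' share of subgroup `g`. Standard errors come from the fixed-weight linear
#' combination `w' Sigma w` of the robust covariance (weight 1 on the level
#' coefficient, `s_g` on each of its interactions). Levels untouched by any
#' interaction pass through unchanged.
#'
#' @param fit a `bws_fit` estimated with taste interactions.
#' @param margins margins table with `subgroup` and `population` columns.
#' @return list with `beta` (named 28-vector including the cont4 reference)
#'   and `se` (NA for the reference).
#' @examples
#' \donttest{
#' coh <- simulate_respondents(60, seed = 3)
#' ch <- simulate_dataset(coh, generate_omep(seed = 3),
#'                        finnish_carer_estimates("I"), seed = 3)
#' fit <- fit_model(ch, coh, model = "mnl",
#'                  interactions = default_interactions())
#' adj <- adjust_for_population(fit, default_margins())
#' }
#' @export
adjust_for_population <- function(fit, margins) {
  est <- fit$estimates
  V <- fit$vcov
  inter <- fit$options$interactions
  labs <- level_labels()
  beta <- stats::setNames(rep(0, 28), labs)
  se <- stats::setNames(rep(NA_real_, 28), labs)
  free <- intersect(labs, names(est))
  beta[free] <- est[free]
  se[free] <- sqrt(diag(V))[free]
  if (!is.null(inter) && nrow(inter)) {
    for (lv in unique(inter$level)) {
      rows <- inter[inter$level == lv, ]
      w <- stats::setNames(numeric(0), character(0))
      w[lv] <- 1
      for (i in seq_len(nrow(rows))) {
        g <- rows$covariate[i]
        s <- margins$population[match(g, margins$subgroup)]
        if (length(s) == 0 || is.na(s))
          stop("population share for subgroup '", g, "' missing from margins")
        w[paste0(lv, ":", g)] <- s
      }
      idx <- match(names(w), names(est))
      if (anyNA(idx)) stop("fit lacks parameter(s): ",
                           paste(names(w)[is.na(idx)], collapse = ", "))
      beta[lv] <- sum(w * est[idx])
      se[lv] <- sqrt(drop(t(w) %*% V[idx, idx] %*% w))
    }
  }
  beta["cont4"] <- 0
  list(beta = beta, se = se)
}

#' Normalise attribute-level coefficients
#'
#' Divides every coefficient by the largest attribute-level coefficient, so
#' the most-valued state takes the value 1 and the reference level 0.
#'
#' @param beta named numeric of attribute-level coefficients.
#' @return named numeric of normalised values.
#' @examples
#' p <- finnish_carer_estimates("III*")
#' round(normalize_weights(p$beta)[["occu1"]], 3)
#' @export
normalize_weights <- function(beta) {
  if (all(beta == 0)) stop("degenerate input: all coefficients are zero")
  mx <- max(beta)
  if (mx <= 0) stop("degenerate input: no strictly positive maximum")
  beta / mx
}

#' Anchor attribute-level coefficients to the 0-1 index
#'
#' Affine rescaling of the 28 coefficients so that the best attainable state
#' (the seven per-attribute maxima together) scores 1 and the worst
#' attainable state (the seven minima) scores 0, keeping relative
#' differences unchanged: `v_jk = (beta_jk - mu) * alpha` with
#' `mu = sum_j min_k(beta_jk) / 7` and
#' `alpha = 1 / (sum_j max_k - sum_j min_k)`. Individual level values may be
#' negative (a level below the average worst level).
#'
#' @param beta named numeric covering all 28 attribute levels.
#' @return named numeric of index values, with attribute `constants`
#'   (a list: `sum_max`, `sum_min`, `mu`, `alpha`).
#' @examples
#' v <- anchor_index(finnish_carer_estimates("III*")$beta)
#' round(v[["cont4"]], 3)
#' @export
anchor_index <- function(beta) {
  beta <- check_beta28(beta)
  att <- attr_of(names(beta))
  mx <- tapply(beta, att, max)
  mn <- tapply(beta, att, min)
  sum_max <- sum(mx); sum_min <- sum(mn)
  if (abs(sum_max - sum_min) < 1e-12)
    stop("degenerate input: best and worst states coincide")
  mu <- sum_min / 7
  alpha <- 1 / (sum_max - sum_min)
  v <- (beta - mu) * alpha
  attr(v, "constants") <- list(sum_max = sum_max, sum_min = sum_min,
                               mu = mu, alpha = alpha)
  v
}

#' Assemble a preference-weight table
#'
#' Chains normalisation and anchoring on a vector of (possibly
#' population-adjusted) attribute-level coefficients and applies any level
#' switches to the published values. The default switch exchanges the
#' self-care (PERC) levels 1 and 2, whose estimated coefficients came out in
#' reversed need order; switching the published weights (never the fitted
#' model) restores the instrument's level ordering for use in practice.
#'
#' @param beta named numeric covering all 28 attribute levels.
#' @param se optional named numeric of standard errors.
#' @param switch_pairs list of `c(attribute, level, level)` triples to
#'   exchange, e.g. `list(c("PERC", 1, 2))` (the default); `list()` for none.
#' @return an `ascot_weights` object: a list with `table` (data frame:
#'   `attribute`, `level`, `label`, `raw`, `se`, `normalized`, `index`),
#'   `constants` (`max_coef`, `sum_max`, `sum_min`, `mu`, `alpha`), and
#'   `switched` (log of applied switches).
#' @examples
#' w <- preference_weights(finnish_carer_estimates("III*")$beta)
#' score_state(w, "3442434")
#' @export
preference_weights <- function(beta, se = NULL,
                               switch_pairs = list(c("PERC", 1, 2))) {
  beta <- check_beta28(beta)
  v <- anchor_index(beta)
  const <- attr(v, "constants")
  tab <- data.frame(
    attribute = toupper(attr_of(names(beta))),
    level = level_of(names(beta)),
    label = names(beta),
    raw = unname(beta),
    se = if (is.null(se)) NA_real_ else unname(se[names(beta)]),
    normalized = unname(normalize_weights(beta)),
    index = unname(v)
  )
  out <- structure(list(table = tab,
                        constants = c(list(max_coef = max(beta)), const),
                        switched = list()),
                   class = "ascot_weights")
  apply_level_switch(out, switch_pairs)
}

#' Exchange the published weights of two levels
#'
#' Swaps the value columns (`raw`, `se`, `normalized`, `index`) of two
#' levels within an attribute and records the swap. Applying the same switch
#' twice restores the original weights.
#'
#' @param weights an `ascot_weights` object.
#' @param pairs list of `c(attribute, level, level)` triples; empty list is
#'   the identity.
#' @return the modified `ascot_weights`.
#' @export
apply_level_switch <- function(weights, pairs = list(c("PERC", 1, 2))) {
  tab <- weights$table
  for (p in pairs) {
    a <- toupper(p[1]); l1 <- as.integer(p[2]); l2 <- as.integer(p[3])
    i <- which(tab$attribute == a & tab$level == l1)
    j <- which(tab$attribute == a & tab$level == l2)
    if (length(i) != 1L || length(j) != 1L)
      stop("switch pair references unknown level: ", a, " ", l1, "/", l2)
    for (cl in c("raw", "se", "normalized", "index"))
      tab[c(i, j), cl] <- tab[c(j, i), cl]
    weights$switched <- c(weights$switched,
                          list(list(attribute = a, levels = c(l1, l2))))
  }
  weights$table <- tab
  weights
}

#' @export
print.ascot_weights <- function(x, digits = 3, ...) {
  cat("ASCOT-Carer preference weights\n")
  cat(sprintf("  anchoring: mu = %.4f, alpha = %.4f (best-state sum 1, worst 0)\n",
              x$constants$mu, x$constants$alpha))
  if (length(x$switched))
    for (s in x$switched)
      cat(sprintf("  switched: %s levels %d <-> %d\n", s$attribute,
                  s$levels[1], s$levels[2]))
  tab <- x$table
  tab$raw <- round(tab$raw, digits)
  tab$normalized <- round(tab$normalized, digits)
  tab$index <- round(tab$index, digits)
  print(tab[, c("label", "raw", "normalized", "index")], row.names = FALSE)
  invisible(x)
}

#' Score a quality-of-life state
#'
#' Computes the additive ASCOT-Carer value of a state written as a 7-digit
#' string (one level per attribute in instrument order OCCU, CONT, PERC,
#' SAFE, SOCI, SPAC, SUPP, e.g. `"3442434"`). The sum uses the unrounded
#' internal weights and is rounded at the end.
#'
#' @param weights an `ascot_weights` object.
#' @param state 7-character string of digits 1-4.
#' @param scale `"index"` (0-1 anchored, default) or `"normalized"`.
#' @param digits rounding of the final sum (default 3); `NA` for unrounded.
#' @return scalar value.
#' @examples
#' w <- preference_weights(finnish_carer_estimates("III*")$beta)
#' score_state(w, "1231321")
#' @export
score_state <- function(weights, state, scale = c("index", "normalized"),
                        digits = 3) {
  scale <- match.arg(scale)
  if (!is.character(state) || length(state) != 1L || nchar(state) != 7L)
    stop("state must be a 7-character string of digits 1-4")
  digitsv <- strsplit(state, "")[[1]]
  lev <- suppressWarnings(as.integer(digitsv))
  bad <- which(is.na(lev) | lev < 1L | lev > 4L)
  if (length(bad))
    stop("invalid state digit '", digitsv[bad[1]], "' at position ", bad[1])
  codes <- ascot_scheme()$codes
  tab <- weights$table
  val <- vapply(seq_len(7), function(a) {
    tab[tab$attribute == codes[a] & tab$level == lev[a], scale]
  }, 0)
  s <- sum(val)
  if (is.na(digits)) s else round(s, digits)
}

#' Export radar-chart data comparing two states
#'
#' Per-attribute weight values of two states on the chosen scale, the data
#' behind the usual radar comparison of a poorer and a better state.
#'
#' @param weights an `ascot_weights`.
#' @param state_a,state_b 7-digit state strings.
#' @param scale `"index"` or `"normalized"`.
#' @return data frame with `attribute`, `level_a`, `value_a`, `level_b`,
#'   `value_b`.
#' @export
radar_data <- function(weights, state_a, state_b,
                       scale = c("index", "normalized")) {
  scale <- match.arg(scale)
  codes <- ascot_scheme()$codes
  la <- as.integer(strsplit(state_a, "")[[1]])
  lb <- as.integer(strsplit(state_b, "")[[1]])
  tab <- weights$table
  get <- function(a, l) tab[tab$attribute == codes[a] & tab$level == l, scale]
  data.frame(
    attribute = codes,
    level_a = la, value_a = vapply(1:7, function(a) get(a, la[a]), 0),
    level_b = lb, value_b = vapply(1:7, function(a) get(a, lb[a]), 0)
  )
}
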