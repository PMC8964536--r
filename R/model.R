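STAGES <- c("best", "worst", "second_best", "second_worst")
STAGE_SIZES <- c(best = 7L, worst = 6L, second_best = 5L, second_worst = 4L)

stage_type <- function(stage) ifelse(stage %in% c("best", "second_best"), "B", "W")

#' Explode one best-worst task into sequential choice occasions
#'
#' A profile-case BWS task asks for the best, worst, second-best and
#' second-worst attribute level of one seven-attribute profile. The partial
#' ranking is "exploded" into four independent logit choices over shrinking
#' availability sets of sizes 7, 6, 5 and 4: each pick removes the chosen
#' item from the next stage's set.
#'
#' @param profile integer(7) levels in 1..4, instrument attribute order.
#' @param picks integer(4) attribute indices (1..7) in elicitation order
#'   best, worst, second-best, second-worst; must be distinct.
#' @param display_order integer permutation of 1..7 giving the display row of
#'   each attribute; defaults to instrument order.
#' @param respondent_id,task identifiers copied into the output.
#' @return an `ascot_choices` data frame with one row per available
#'   alternative per occasion: `respondent_id`, `task`, `stage`, `attribute`
#'   (lowercase code), `level`, `row`, `available`, `chosen`.
#' @examples
#' occ <- explode_task(c(1, 4, 2, 3, 1, 4, 2), picks = c(1, 2, 5, 6))
#' table(occ$stage)
#' @export
explode_task <- function(profile, picks, display_order = 1:7,
                         respondent_id = 1L, task = 1L) {
  profile <- as.integer(profile)
  picks <- as.integer(picks)
  if (length(profile) != 7L || any(profile < 1L) || any(profile > 4L))
    stop("malformed task: profile must be 7 levels in 1..4")
  if (length(picks) != 4L || anyDuplicated(picks) ||
      any(picks < 1L) || any(picks > 7L))
    stop("malformed task: picks must be 4 distinct attribute indices in 1..7")
  if (!identical(sort(as.integer(display_order)), 1:7))
    stop("display_order must be a permutation of 1..7")
  codes <- tolower(ascot_scheme()$codes)
  avail <- 1:7
  out <- vector("list", 4L)
  for (k in 1:4) {
    if (!(picks[k] %in% avail))
      stop("malformed task: pick ", k, " not in the remaining set")
    out[[k]] <- data.frame(
      respondent_id = respondent_id, task = as.integer(task),
      stage = STAGES[k],
      attribute = codes[avail],
      level = profile[avail],
      row = as.integer(display_order[avail]),
      available = 1L,
      chosen = as.integer(avail == picks[k])
    )
    avail <- setdiff(avail, picks[k])
  }
  res <- do.call(rbind, out)
  class(res) <- c("ascot_choices", "data.frame")
  res
}

#' Multiplicative scale of a respondent-task
#'
#' In the scale-heterogeneity MNL the systematic utility is multiplied by
#' `lambda = prod(gamma_k ^ z_k)`, equivalently `exp(sum theta_k z_k)` with
#' `theta = log(gamma)`, where `z` are the respondent's scale covariates plus
#' the learning indicator (second sequence of tasks). `lambda = 1` for the
#' reference group. A `gamma > 1` means less error variance, i.e. more
#' consistent choices.
#'
#' @param params a [bws_params].
#' @param covars named list / one-row data frame of 0/1 covariates (any
#'   scale covariate absent from `covars` other than `learning` is an error).
#' @param task_index task position 1..8.
#' @param first_seq_len tasks after this position carry `learning = 1`
#'   (default 4, i.e. the second sequence of four tasks; alternative splits
#'   1/7, 2/6, 3/5 are obtained by changing this).
#' @return positive scalar `lambda`.
#' @examples
#' p <- finnish_carer_estimates("III*")
#' respondent_scale(p, list(hgood = 1, eduhigh = 0, tmlong = 1), task_index = 2)
#' @export
respondent_scale <- function(params, covars, task_index, first_seq_len = 4L) {
  if (!length(params$scale)) return(1)
  z <- scale_covariate_values(names(params$scale), covars, task_index,
                              first_seq_len)
  prod(params$scale^z)
}

scale_covariate_values <- function(vars, covars, task_index, first_seq_len = 4L) {
  vapply(vars, function(v) {
    if (v == "learning") as.numeric(task_index > first_seq_len)
    else {
      val <- covars[[v]]
      if (is.null(val)) stop("scale covariate '", v, "' missing from covariates")
      as.numeric(val)
    }
  }, 0)
}

#' Systematic utilities of one choice occasion
#'
#' For best-type stages the utility of an item is
#' `lambda * (beta + pi_B[row] + taste)`; for worst-type stages the sign of
#' the preference components flips: `lambda * (-beta + pi_W[row] - taste)`.
#' Taste terms are attribute-level x subgroup interactions and ride with
#' `beta` (they adjust the level's utility, so they flip sign together with
#' it). Setting `scale_applies = "beta"` restricts the multiplier to the
#' preference components, leaving the position constants unscaled — an
#' alternative algebraic placement of the scale factor.
#'
#' @param params a [bws_params].
#' @param occasion rows of an `ascot_choices` data frame belonging to one
#'   occasion (single stage).
#' @param covars respondent covariates (see [respondent_scale]); also
#'   supplies the interaction covariates.
#' @param task_index task position 1..8.
#' @param scale_applies `"all"` (default) or `"beta"`.
#' @param first_seq_len see [respondent_scale].
#' @return list with `lambda` and the utility vector `V` (one per available
#'   alternative, in occasion row order).
#' @export
stage_utilities <- function(params, occasion, covars = list(), task_index = 1L,
                            scale_applies = c("all", "beta"),
                            first_seq_len = 4L) {
  scale_applies <- match.arg(scale_applies)
  stage <- unique(occasion$stage)
  if (length(stage) != 1L) stop("occasion must contain a single stage")
  type <- stage_type(stage)
  sgn <- if (type == "B") 1 else -1
  lab <- paste0(occasion$attribute, occasion$level)
  b <- params$beta[lab]
  pos <- if (type == "B") params$pos_best[occasion$row]
         else params$pos_worst[occasion$row]
  taste <- numeric(length(lab))
  if (!is.null(params$interactions) && nrow(params$interactions)) {
    for (i in seq_len(nrow(params$interactions))) {
      ia <- params$interactions[i, ]
      x <- covars[[ia$covariate]]
      if (is.null(x)) stop("interaction covariate '", ia$covariate,
                           "' missing from covariates")
      taste <- taste + ia$delta * as.numeric(x) * (lab == ia$level)
    }
  }
  lambda <- respondent_scale(params, covars, task_index, first_seq_len)
  V <- if (scale_applies == "all") lambda * (sgn * (b + taste) + pos)
       else lambda * sgn * (b + taste) + pos
  list(lambda = lambda, V = unname(V))
}

#' Choice probabilities of one occasion
#'
#' Multinomial-logit (softmax) probabilities over the available set,
#' computed with max-subtraction for overflow safety.
#'
#' @param utilities numeric utility vector, or the list returned by
#'   [stage_utilities].
#' @return probability vector summing to one.
#' @examples
#' occasion_probability(c(log(2), 0))
#' @export
occasion_probability <- function(utilities) {
  V <- if (is.list(utilities)) utilities$V else utilities
  if (any(!is.finite(V))) stop("non-finite utility")
  e <- exp(V - max(V))
  e / sum(e)
}

# --- vectorised internals over a long-format choices table -----------------

# canonical occasion ordering + integer occasion index
occasion_index <- function(choices) {
  stage_ord <- match(choices$stage, STAGES)
  o <- order(choices$respondent_id, choices$task, stage_ord)
  key <- paste(choices$respondent_id[o], choices$task[o], stage_ord[o])
  occ <- cumsum(!duplicated(key))
  list(order = o, occ = occ)
}

# per-row lambda given params and a cohort lookup
row_lambda <- function(params, choices, respondents, first_seq_len = 4L) {
  if (!length(params$scale)) return(rep(1, nrow(choices)))
  ridx <- match(choices$respondent_id, respondents$id)
  if (anyNA(ridx)) stop("choices reference respondents absent from the cohort")
  logl <- rep(0, nrow(choices))
  for (v in names(params$scale)) {
    z <- if (v == "learning") as.numeric(choices$task > first_seq_len)
         else {
           if (is.null(respondents[[v]]))
             stop("scale covariate '", v, "' missing from the cohort")
           as.numeric(respondents[[v]][ridx])
         }
    logl <- logl + log(params$scale[[v]]) * z
  }
  exp(logl)
}

# per-row systematic index (before lambda) given params
row_base_utility <- function(params, choices, respondents = NULL) {
  lab <- paste0(choices$attribute, choices$level)
  sgn <- ifelse(stage_type(choices$stage) == "B", 1, -1)
  b <- params$beta[lab]
  pos <- ifelse(stage_type(choices$stage) == "B",
                params$pos_best[choices$row], params$pos_worst[choices$row])
  taste <- numeric(nrow(choices))
  if (!is.null(params$interactions) && nrow(params$interactions)) {
    ridx <- match(choices$respondent_id, respondents$id)
    for (i in seq_len(nrow(params$interactions))) {
      ia <- params$interactions[i, ]
      x <- as.numeric(respondents[[ia$covariate]][ridx])
      taste <- taste + ia$delta * x * (lab == ia$level)
    }
  }
  unname(sgn * (b + taste) + pos)
}

#' Log-likelihood of an exploded choice dataset
#'
#' Sum over all occasions of the log softmax probability of the chosen item,
#' treating the four stages of a task as independent conditional-logit
#' choices (the exploded-logit assumption).
#'
#' @param params a [bws_params].
#' @param choices an `ascot_choices` long-format data frame.
#' @param respondents cohort table supplying scale / interaction covariates
#'   (required when `params` has scale factors or interactions).
#' @param scale_applies,first_seq_len see [stage_utilities].
#' @return scalar log-likelihood.
#' @export
dataset_loglik <- function(params, choices, respondents = NULL,
                           scale_applies = c("all", "beta"),
                           first_seq_len = 4L) {
  scale_applies <- match.arg(scale_applies)
  if (nrow(choices) == 0L) return(0)
  oi <- occasion_index(choices)
  ch <- choices[oi$order, ]
  occ <- oi$occ
  base <- row_base_utility(params, ch, respondents)
  lam <- row_lambda(params, ch, respondents, first_seq_len)
  V <- if (scale_applies == "all") lam * base else {
    sgnpos <- ifelse(stage_type(ch$stage) == "B",
                     params$pos_best[ch$row], params$pos_worst[ch$row])
    lam * (base - sgnpos) + sgnpos
  }
  if (any(!is.finite(V))) {
    bad <- which(!is.finite(V))[1]
    stop("non-finite utility at respondent ", ch$respondent_id[bad],
         " task ", ch$task[bad], " stage ", ch$stage[bad])
  }
  Vmax <- stats::ave(V, occ, FUN = max)
  e <- exp(V - Vmax)
  denom <- rowsum(e, occ)
  chosen <- ch$chosen == 1L
  sum(log(e[chosen] / denom[occ[chosen]]))
}

#' Null (uniform-choice) log-likelihood
#'
#' Log-likelihood of the zero-parameter model in which every available
#' alternative is equally likely: `-sum(log(set size))` over occasions.
#' For a full task of set sizes 7/6/5/4 this is `-(log 7 + log 6 + log 5 +
#' log 4) = -6.7334`.
#'
#' @param choices an `ascot_choices` data frame.
#' @return scalar log-likelihood of the null model.
#' @export
null_loglik <- function(choices) {
  if (nrow(choices) == 0L) return(0)
  oi <- occasion_index(choices)
  sizes <- as.integer(table(oi$occ))
  -sum(log(sizes))
}
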