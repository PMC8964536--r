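# inverse-CDF draw from softmax probabilities of one stage
sample_stage <- function(V, u) {
  p <- occasion_probability(V)
  cp <- cumsum(p)
  # guard against cumulative rounding leaving cp[n] slightly below u
  cp[length(cp)] <- 1
  which(u <= cp)[1]
}

# simulate the 4 sequential picks of one task; returns attribute indices in
# elicitation order. beta_adj: taste-adjusted 28-level utilities for this
# respondent; lambda: task scale; rows: display row per attribute.
simulate_picks <- function(beta_adj, params, profile, rows, lambda, u4,
                           scale_applies = "all") {
  codes <- names(beta_adj$by_attr)
  lab_u <- beta_adj$values[(seq_len(7) - 1L) * 4L + profile]
  avail <- 1:7
  picks <- integer(4)
  for (k in 1:4) {
    type <- stage_type(STAGES[k])
    pos <- if (type == "B") params$pos_best[rows[avail]]
           else params$pos_worst[rows[avail]]
    sgn <- if (type == "B") 1 else -1
    V <- if (scale_applies == "all") lambda * (sgn * lab_u[avail] + pos)
         else lambda * sgn * lab_u[avail] + pos
    j <- sample_stage(V, u4[k])
    picks[k] <- avail[j]
    avail <- avail[-j]
  }
  picks
}

# respondent-specific taste-adjusted level utilities (length 28, attribute-major)
respondent_beta <- function(params, covars) {
  vals <- params$beta
  if (!is.null(params$interactions) && nrow(params$interactions)) {
    for (i in seq_len(nrow(params$interactions))) {
      ia <- params$interactions[i, ]
      x <- covars[[ia$covariate]]
      if (is.null(x)) stop("interaction covariate '", ia$covariate,
                           "' missing from covariates")
      vals[ia$level] <- vals[ia$level] + ia$delta * as.numeric(x)
    }
  }
  list(values = unname(vals), by_attr = stats::setNames(1:7, tolower(ascot_scheme()$codes)))
}

#' Simulate one best-worst task
#'
#' Draws the best, worst, second-best and second-worst picks of one profile
#' stage by stage: each pick is sampled from the softmax probabilities of
#' the current availability set (inverse-CDF sampling, equivalent to
#' stage-wise Gumbel-utility argmax), then removed. Reproducible given
#' `(seed, respondent_id, task_index)`.
#'
#' @param profile integer(7) levels.
#' @param respondent one-row cohort data frame (supplies covariates, id and
#'   display order) or a list with at least `id`; missing display order
#'   defaults to instrument order.
#' @param params a [bws_params] used as the generating truth.
#' @param task_index task position 1..8.
#' @param seed integer root seed.
#' @param scale_applies,first_seq_len see [stage_utilities].
#' @return an `ascot_choices` data frame of 4 occasions (22 rows).
#' @export
simulate_task <- function(profile, respondent, params, task_index = 1L,
                          seed = 1L, scale_applies = c("all", "beta"),
                          first_seq_len = 4L) {
  scale_applies <- match.arg(scale_applies)
  id <- respondent$id %||% 1L
  ord <- if (!is.null(respondent$display_order))
    parse_display_order(respondent$display_order) else 1:7
  lambda <- respondent_scale(params, respondent, task_index, first_seq_len)
  badj <- respondent_beta(params, respondent)
  u4 <- withr::with_seed(substream_seed(seed, "choices", id),
                         stats::runif(4L * task_index))
  u4 <- u4[(4L * (task_index - 1L) + 1L):(4L * task_index)]
  picks <- simulate_picks(badj, params, as.integer(profile), ord, lambda, u4,
                          scale_applies)
  explode_task(profile, picks, ord, respondent_id = id, task = task_index)
}

#' Simulate a full exploded BWS dataset
#'
#' Each respondent evaluates the eight profiles of their assigned design
#' block in randomised profile order, producing 8 tasks x 4 occasions = 32
#' choice occasions per respondent (32,160 for the full 1005-respondent
#' study). Each respondent's picks are driven by an RNG substream derived
#' from `(seed, respondent id)`, so the dataset is reproducible under
#' cohort reordering.
#'
#' @param cohort an `ascot_cohort` from [simulate_respondents].
#' @param plan an `ascot_design` from [generate_omep].
#' @param params generating truth, a [bws_params].
#' @param seed integer root seed.
#' @param scale_applies,first_seq_len see [stage_utilities].
#' @return an `ascot_choices` long-format data frame.
#' @examples
#' coh <- simulate_respondents(4, seed = 1)
#' plan <- generate_omep(seed = 1)
#' ch <- simulate_dataset(coh, plan, finnish_carer_estimates("II"), seed = 1)
#' nrow(ch)
#' @export
simulate_dataset <- function(cohort, plan, params, seed = 1L,
                             scale_applies = c("all", "beta"),
                             first_seq_len = 4L) {
  scale_applies <- match.arg(scale_applies)
  codes <- tolower(ascot_scheme()$codes)
  attr_cols <- intersect(codes, colnames(plan))
  if (length(attr_cols) != 7L) stop("plan must contain the 7 attribute columns")
  pmat <- as.matrix(plan[, attr_cols])
  n_resp <- nrow(cohort)
  n_tasks <- 8L
  rows_per_task <- sum(STAGE_SIZES)
  N <- n_resp * n_tasks * rows_per_task
  col_rid <- integer(N); col_task <- integer(N); col_stage <- character(N)
  col_attr <- character(N); col_level <- integer(N); col_row <- integer(N)
  col_chosen <- integer(N)
  stage_rep <- rep(STAGES, times = STAGE_SIZES)
  ptr <- 0L
  for (i in seq_len(n_resp)) {
    resp <- cohort[i, ]
    id <- resp$id
    ord <- parse_display_order(resp$display_order)
    badj <- respondent_beta(params, resp)
    block_rows <- which(plan$block == resp$block)
    if (length(block_rows) != n_tasks)
      stop("block ", resp$block, " does not contain ", n_tasks, " profiles")
    stream <- substream_seed(seed, "choices", id)
    us <- withr::with_seed(stream, stats::runif(4L * n_tasks + n_tasks))
    # first n_tasks uniforms shuffle the block's profile order
    task_profiles <- block_rows[order(us[seq_len(n_tasks)])]
    u_choice <- us[-seq_len(n_tasks)]
    for (t in seq_len(n_tasks)) {
      lambda <- respondent_scale(params, resp, t, first_seq_len)
      profile <- pmat[task_profiles[t], ]
      u4 <- u_choice[(4L * (t - 1L) + 1L):(4L * t)]
      picks <- simulate_picks(badj, params, profile, ord, lambda, u4,
                              scale_applies)
      avail <- 1:7
      for (k in 1:4) {
        nk <- length(avail)
        idx <- ptr + seq_len(nk)
        col_rid[idx] <- id
        col_task[idx] <- t
        col_stage[idx] <- STAGES[k]
        col_attr[idx] <- codes[avail]
        col_level[idx] <- profile[avail]
        col_row[idx] <- ord[avail]
        col_chosen[idx] <- as.integer(avail == picks[k])
        ptr <- ptr + nk
        avail <- setdiff(avail, picks[k])
      }
    }
  }
  out <- data.frame(respondent_id = col_rid, task = col_task,
                    stage = col_stage, attribute = col_attr,
                    level = col_level, row = col_row,
                    available = 1L, chosen = col_chosen)
  class(out) <- c("ascot_choices", "data.frame")
  out
}
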