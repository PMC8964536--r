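#' Default covariate margins for the synthetic cohort
#'
#' Marginal shares of the respondent indicators used by the simulator and
#' the post-stratification adjustment, as reported for the valuation study's
#' analysis sample (n = 1005) and the Finnish general adult population:
#' renters 0.464 sample / 0.274 population; lower-secondary education or
#' below 0.108 / 0.188; no religion 0.379 / 0.267; and the scale covariates
#' good self-assessed health 0.539, bachelor-or-higher education 0.302, and
#' completion time over 6.5 minutes 0.750 (sample shares, used for
#' simulation).
#'
#' @param path optional YAML file with entries `subgroup: {sample: s,
#'   population: p}`; defaults to the bundled configuration.
#' @return data frame with columns `subgroup`, `sample`, `population`
#'   (population NA where not applicable).
#' @export
default_margins <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "margins_fi.yaml", package = "ascotbws")
  raw <- yaml::read_yaml(path)
  out <- data.frame(
    subgroup = names(raw),
    sample = vapply(raw, function(x) as.numeric(x$sample %||% NA), 0),
    population = vapply(raw, function(x) as.numeric(x$population %||% NA), 0),
    row.names = NULL
  )
  bad <- stats::na.omit(c(out$sample, out$population))
  if (any(bad < 0 | bad > 1)) stop("margin shares must lie in [0, 1]")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a synthetic respondent cohort
#'
#' Draws `n` respondents whose binary covariates are independent Bernoulli
#' variables at the configured sample shares, assigns each respondent a
#' design block uniformly at random, and gives each respondent a fixed
#' attribute display order via [randomize_attribute_order]. The covariates
#' are drawn independently because only marginal shares are reported for the
#' study sample; pass `joint` to impose a dependence structure instead.
#'
#' @param n cohort size (the study analysed 1005 respondents).
#' @param margins margins table as from [default_margins]; the `sample`
#'   column supplies the Bernoulli rates.
#' @param seed integer seed.
#' @param n_blocks number of design blocks (default 4).
#' @param joint optional data frame of pre-drawn covariate columns (one row
#'   per respondent) overriding the independent draws for its columns.
#' @return An `ascot_cohort` data frame: `id`, one 0/1 column per subgroup
#'   in `margins`, `block`, and `display_order` (dash-joined display row of
#'   each attribute in instrument order).
#' @examples
#' coh <- simulate_respondents(50, seed = 7)
#' table(coh$block)
#' @export
simulate_respondents <- function(n, margins = default_margins(), seed = 1L,
                                 n_blocks = 4L, joint = NULL) {
  stopifnot(n >= 1)
  need <- c("hgood", "eduhigh", "tmlong", "renter", "lowedu", "noreligion")
  missing <- setdiff(need, margins$subgroup)
  if (length(missing))
    stop("margins are missing subgroup(s): ", paste(missing, collapse = ", "))
  out <- data.frame(id = seq_len(n))
  withr::local_seed(substream_seed(seed, "cohort"))
  for (i in seq_len(nrow(margins))) {
    sg <- margins$subgroup[i]
    p <- margins$sample[i]
    if (is.na(p)) next
    out[[sg]] <- if (!is.null(joint) && sg %in% colnames(joint))
      as.integer(joint[[sg]]) else stats::rbinom(n, 1L, p)
  }
  out$block <- sample.int(n_blocks, n, replace = TRUE)
  out$display_order <- vapply(out$id, function(id)
    paste(randomize_attribute_order(id, seed), collapse = "-"), "")
  class(out) <- c("ascot_cohort", "data.frame")
  out
}

#' Summarise cohort covariate margins
#'
#' Computes the count and share of each binary indicator in the cohort and,
#' when population margins are supplied, the absolute sample-population
#' difference with a divergence flag at the conventional 10-percentage-point
#' threshold used to pick the post-stratification subgroups.
#'
#' @param respondents an `ascot_cohort`.
#' @param margins optional margins table with a `population` column.
#' @param threshold absolute-difference flag threshold (default 0.10).
#' @return data frame with `subgroup`, `count`, `share` and, if population
#'   margins are given, `population`, `difference`, `divergent`.
#' @export
summarize_margins <- function(respondents, margins = NULL, threshold = 0.10) {
  stopifnot(nrow(respondents) >= 1)
  skip <- c("id", "block", "display_order")
  vars <- setdiff(colnames(respondents), skip)
  vars <- vars[vapply(vars, function(v) all(respondents[[v]] %in% 0:1), TRUE)]
  out <- data.frame(
    subgroup = vars,
    count = vapply(vars, function(v) sum(respondents[[v]]), 0),
    share = vapply(vars, function(v) mean(respondents[[v]]), 0),
    row.names = NULL
  )
  if (!is.null(margins) && "population" %in% colnames(margins)) {
    out$population <- margins$population[match(out$subgroup, margins$subgroup)]
    out$difference <- abs(out$share - out$population)
    out$divergent <- !is.na(out$difference) & out$difference > threshold
  }
  out
}

#' Read / write a cohort CSV
#'
#' Schema: `id,hgood,eduhigh,tmlong,renter,lowedu,noreligion,block,display_order`
#' with `display_order` dash-joined.
#'
#' @param respondents an `ascot_cohort`.
#' @param path file path.
#' @export
write_cohort <- function(respondents, path) {
  utils::write.csv(as.data.frame(respondents), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, colClasses = c(display_order = "character"))
  if (!all(c("id", "block", "display_order") %in% colnames(df)))
    stop("cohort CSV must contain id, block, display_order")
  class(df) <- c("ascot_cohort", "data.frame")
  df
}

# display_order string -> integer permutation (row of each attribute)
parse_display_order <- function(s) {
  as.integer(strsplit(s, "-", fixed = TRUE)[[1]])
}
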