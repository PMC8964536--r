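#' The ASCOT-Carer attribute scheme
#'
#' The ASCOT-Carer instrument describes an informal carer's social
#' care-related quality of life (SCRQoL) with seven attributes, each observed
#' at four ordered need-intensity levels: level 1 is the "ideal state" and
#' level 4 is "high needs".
#'
#' @return An object of class `ascot_scheme`: a list with
#'   \describe{
#'     \item{codes}{character(7), the attribute codes in instrument order:
#'       OCCU, CONT, PERC, SAFE, SOCI, SPAC, SUPP.}
#'     \item{names}{character(7), human-readable attribute names.}
#'     \item{levels}{a 7 x 4 character matrix of level wordings,
#'       rows named by attribute code.}
#'   }
#' @examples
#' sch <- ascot_scheme()
#' sch$codes
#' sch$levels["CONT", 4]
#' @export
ascot_scheme <- function() {
  codes <- c("OCCU", "CONT", "PERC", "SAFE", "SOCI", "SPAC", "SUPP")
  names <- c(
    "Occupation",
    "Control over daily life",
    "Looking after yourself",
    "Personal safety",
    "Social participation and involvement",
    "Space and time to be yourself",
    "Feeling supported and encouraged"
  )
  levels <- rbind(
    OCCU = c(
      "I am able to spend my time as I want, doing things I value or enjoy.",
      "I am able do enough of the things I value or enjoy with my time.",
      "I do some of the things I value or enjoy with my time, but not enough.",
      "I do not do anything I value or enjoy with my time."
    ),
    CONT = c(
      "I have as much control over my daily life as I want.",
      "I have adequate control over my daily life.",
      "I have some control over my daily life, but not enough.",
      "I have no control over my daily life."
    ),
    PERC = c(
      "I look after myself as well as I want.",
      "I look after myself well enough.",
      "Sometimes I cannot look after myself well enough.",
      "I feel I am neglecting myself."
    ),
    SAFE = c(
      "I feel as safe as I want.",
      "Generally I feel adequately safe, but not as safe as I would like.",
      "I feel less than adequately safe.",
      "I do not feel at all safe."
    ),
    SOCI = c(
      "I have as much social contact as I want with people I like.",
      "I have adequate social contact with people.",
      "I have some social contact with people, but not enough.",
      "I have little social contact with people and feel socially isolated."
    ),
    SPAC = c(
      "I have all the space and time I need to be myself.",
      "I have adequate space and time to be myself.",
      "I have some of the space and time I need to be myself, but not enough.",
      "I do not have any space or time to be myself."
    ),
    SUPP = c(
      "I feel I have the encouragement and support I want.",
      "I feel I have adequate encouragement and support.",
      "I feel I have some encouragement and support, but not enough.",
      "I feel I have no encouragement and support."
    )
  )
  colnames(levels) <- paste0("level", 1:4)
  structure(list(codes = codes, names = names, levels = levels),
            class = "ascot_scheme")
}

#' @export
print.ascot_scheme <- function(x, ...) {
  cat("ASCOT-Carer attribute scheme: 7 attributes x 4 levels\n")
  for (i in seq_along(x$codes)) {
    cat(sprintf("  %s  %s\n", x$codes[i], x$names[i]))
  }
  invisible(x)
}

#' Attribute-level labels in estimation order
#'
#' Lowercase labels `occu1 ... supp4` used to name coefficients; `cont4`
#' (the reference level, "I have no control over my daily life") is included.
#'
#' @return character(28)
#' @keywords internal
level_labels <- function() {
  codes <- tolower(ascot_scheme()$codes)
  as.vector(t(outer(codes, 1:4, paste0)))
}

#' Mirror a profile (foldover)
#'
#' Maps every attribute level `l` to `5 - l`, producing the foldover image of
#' a profile. Pairing each design profile with its mirror avoids dominated
#' ("easy") choice tasks. The map is an involution.
#'
#' @param profile integer vector of levels in 1..4 (any length).
#' @return integer vector of the same length.
#' @examples
#' foldover_mirror(c(1, 1, 1, 1, 1, 1, 1))
#' foldover_mirror(foldover_mirror(c(3, 4, 4, 2, 4, 3, 4)))
#' @export
foldover_mirror <- function(profile) {
  profile <- as.integer(profile)
  if (any(is.na(profile)) || any(profile < 1L) || any(profile > 4L))
    stop("profile levels must be integers in 1..4")
  5L - profile
}

#' Per-respondent attribute display order
#'
#' The display position of the seven attributes is randomised between (but
#' not within) respondents: one respondent sees the same attribute order in
#' all of their tasks, different respondents see different orders. The
#' permutation is a deterministic function of `(seed, respondent_id)`, so
#' regenerating a respondent's order never depends on how many other
#' respondents were drawn before them.
#'
#' @param respondent_id integer id (>= 1).
#' @param seed integer root seed.
#' @param n_attributes number of display rows, default 7.
#' @return an integer permutation `ord` of `1:n_attributes`; `ord[a]` is the
#'   display row (1 = top) of attribute `a` in instrument order.
#' @examples
#' randomize_attribute_order(17, seed = 1)
#' @export
randomize_attribute_order <- function(respondent_id, seed, n_attributes = 7L) {
  withr::local_seed(substream_seed(seed, "order", respondent_id))
  sample.int(n_attributes)
}

# Deterministic 31-bit substream seed from (root seed, stream label, unit id).
# A small multiplicative hash keeps streams for different respondents and
# pipeline stages disjoint in practice while staying below 2^31.
substream_seed <- function(seed, stream, id = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  x <- (as.double(seed) %% 2147483647) + 1
  x <- (x * 48271) %% 2147483647
  x <- (x + h * 69621 + as.double(id) * 16807) %% 2147483647
  as.integer((x * 48271) %% 2147483629 + 1)
}
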