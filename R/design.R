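#' Generate an orthogonal main-effects plan (OMEP)
#'
#' Constructs a strength-2 orthogonal array with `n_attributes` columns at
#' `n_levels` levels in `n_runs` runs, the fractional-factorial design used
#' to pick which quality-of-life profiles respondents evaluate. For the
#' ASCOT-Carer geometry (7 attributes x 4 levels) the default is the 32-run
#' plan, blocked into 4 blocks of 8 profiles.
#'
#' Four-level columns are built by expansive replacement over the regular
#' two-level design indexed by GF(2)^m (`n_runs = 2^m`): each attribute is
#' assigned a closed triple \{a, b, a+b\} of nonzero vectors, pairwise
#' disjoint across attributes, and the two-level pair (x_a, x_b) is recoded
#' to a level in 1..4. Because the triples are disjoint closed sets, any four
#' defining vectors drawn from two different triples are linearly
#' independent, which forces every pairwise level combination to appear
#' exactly `n_runs / n_levels^2` times (strength 2 by construction).
#'
#' @param n_attributes number of attribute columns (default 7).
#' @param n_levels levels per attribute; 4 (expansive replacement) or 2.
#' @param n_runs number of profiles; must be a power of 2 divisible by
#'   `n_levels^2`.
#' @param seed integer seed; the plan (triple packing, level recoding, and
#'   blocking) is deterministic given the seed.
#' @param n_blocks number of equal-size blocks profiles are randomly divided
#'   into (default 4; use 1 for no blocking).
#' @return An `ascot_design`: a data frame with columns `profile_id`, `block`
#'   and one integer level column per attribute (named `occu`...`supp` for
#'   the 7-attribute scheme, `attr1`... otherwise).
#' @examples
#' plan <- generate_omep(seed = 1)
#' verify_design(plan)$pass
#' @export
generate_omep <- function(n_attributes = 7L, n_levels = 4L, n_runs = 32L,
                          seed = 1L, n_blocks = 4L) {
  n_attributes <- as.integer(n_attributes)
  n_levels <- as.integer(n_levels)
  n_runs <- as.integer(n_runs)
  # pairwise (strength-2) balance needs n_levels^2 | n_runs; a single column
  # only needs level balance
  if (n_attributes >= 2L && n_runs %% (n_levels^2) != 0L)
    stop("design-infeasible: n_runs must be divisible by n_levels^2")
  if (n_runs %% n_levels != 0L)
    stop("design-infeasible: n_runs must be divisible by n_levels")
  m <- as.integer(round(log2(n_runs)))
  if (2L^m != n_runs)
    stop("design-infeasible: n_runs must be a power of 2 for this construction")

  # rows of the full GF(2)^m run index, one run per row
  runs <- as.matrix(expand.grid(rep(list(0:1), m)))[, m:1, drop = FALSE]

  if (n_levels == 4L) {
    if (3L * n_attributes > 2L^m - 1L)
      stop("design-infeasible: cannot supply ", n_attributes,
           " mutually disjoint generator triples from ", 2L^m - 1L,
           " nonzero vectors")
    triples <- withr::with_seed(substream_seed(seed, "design"),
                                find_disjoint_triples(n_attributes, m))
    cols <- lapply(triples, function(tr) {
      xa <- (runs %*% tr$a) %% 2L
      xb <- (runs %*% tr$b) %% 2L
      as.integer(2L * xa + xb + 1L)
    })
    # a random bijective relabelling of 1..4 per column preserves strength 2
    cols <- withr::with_seed(substream_seed(seed, "relabel"), lapply(cols, function(cl) {
      perm <- sample.int(4L)
      perm[cl]
    }))
  } else if (n_levels == 2L) {
    if (n_attributes > 2L^m - 1L)
      stop("design-infeasible: too many two-level columns")
    vecs <- gf2_vectors(m)
    cols <- lapply(seq_len(n_attributes), function(j)
      as.integer((runs %*% vecs[[j]]) %% 2L + 1L))
  } else {
    stop("design-infeasible: only 2- or 4-level attributes are supported")
  }

  mat <- do.call(cbind, cols)
  colnames(mat) <- design_attr_names(n_attributes)

  if (n_runs %% n_blocks != 0L) stop("n_runs must be divisible by n_blocks")
  block <- withr::with_seed(substream_seed(seed, "blocks"),
                            sample(rep(seq_len(n_blocks), n_runs / n_blocks)))

  out <- data.frame(profile_id = seq_len(n_runs), block = as.integer(block), mat)
  class(out) <- c("ascot_design", "data.frame")
  out
}

design_attr_names <- function(n_attributes) {
  if (n_attributes == 7L) tolower(ascot_scheme()$codes)
  else paste0("attr", seq_len(n_attributes))
}

# all nonzero vectors of GF(2)^m as integer m-vectors
gf2_vectors <- function(m) {
  lapply(seq_len(2L^m - 1L), function(k) as.integer(intToBits(k)[1:m]))
}

# restart-greedy packing of n pairwise-disjoint closed triples {a, b, a+b}
# among the nonzero points of GF(2)^m (a partial line packing in PG(m-1, 2))
find_disjoint_triples <- function(n, m, max_restarts = 200L) {
  vecs <- gf2_vectors(m)
  nv <- length(vecs)
  xor_idx <- function(i, j) {
    v <- (vecs[[i]] + vecs[[j]]) %% 2L
    sum(v * 2L^(seq_len(m) - 1L))
  }
  shuffle <- function(x) x[sample.int(length(x))]
  for (r in seq_len(max_restarts)) {
    free <- rep(TRUE, nv)
    triples <- vector("list", n)
    ok <- TRUE
    for (t in seq_len(n)) {
      placed <- FALSE
      cand_a <- shuffle(which(free))
      for (ia in cand_a) {
        cand_b <- shuffle(setdiff(which(free), ia))
        for (ib in cand_b) {
          ic <- xor_idx(ia, ib)
          if (free[ic] && ic != ia && ic != ib) {
            free[c(ia, ib, ic)] <- FALSE
            triples[[t]] <- list(a = vecs[[ia]], b = vecs[[ib]])
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(triples)
  }
  stop("design-infeasible: could not find ", n,
       " mutually disjoint generator triples")
}

#' Verify level balance and pairwise orthogonality of a design plan
#'
#' Brute-force check of the orthogonal main-effects properties: every level
#' of every attribute appears `n_runs / n_levels` times, and for every pair
#' of attributes every ordered level combination appears
#' `n_runs / n_levels^2` times. Blocking, if present, must partition the
#' profiles into equal blocks. Violations are reported, never raised.
#'
#' @param plan an `ascot_design` or data frame with attribute level columns
#'   (and optionally `profile_id`, `block`).
#' @param n_levels levels per attribute (default 4).
#' @return list with elements `pass` (logical), `level_counts` (attribute x
#'   level matrix), `pair_counts` (data frame of ordered pairwise combination
#'   counts), `block_sizes`, and `violations` (character vector, empty when
#'   the plan passes).
#' @export
verify_design <- function(plan, n_levels = 4L) {
  mat <- as.matrix(plan[, setdiff(colnames(plan), c("profile_id", "block")),
                        drop = FALSE])
  storage.mode(mat) <- "integer"
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 1L) stop("plan must contain at least one profile")
  violations <- character()

  lev <- seq_len(n_levels)
  level_counts <- t(apply(mat, 2, function(cl) tabulate(cl, nbins = n_levels)))
  colnames(level_counts) <- paste0("level", lev)
  target_lev <- n / n_levels
  bad <- which(level_counts != target_lev, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    violations <- c(violations, sprintf(
      "level balance: %s level %d appears %d times (expected %g)",
      rownames(level_counts)[bad[, 1]], bad[, 2],
      level_counts[bad], target_lev))
  }

  target_pair <- n / n_levels^2
  pair_counts <- NULL
  if (k >= 2) {
    pairs <- utils::combn(k, 2)
    pc <- vector("list", ncol(pairs))
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1, q]; j <- pairs[2, q]
      tab <- table(factor(mat[, i], levels = lev),
                   factor(mat[, j], levels = lev))
      off <- which(tab != target_pair, arr.ind = TRUE)
      if (nrow(off) > 0) {
        violations <- c(violations, sprintf(
          "orthogonality: (%s,%s) combination (%d,%d) appears %d times (expected %g)",
          colnames(mat)[i], colnames(mat)[j], off[, 1], off[, 2],
          tab[off], target_pair))
      }
      pc[[q]] <- data.frame(attr_i = colnames(mat)[i], attr_j = colnames(mat)[j],
                            level_i = as.integer(rep(lev, n_levels)),
                            level_j = as.integer(rep(lev, each = n_levels)),
                            count = as.vector(tab))
    }
    pair_counts <- do.call(rbind, pc)
  }

  block_sizes <- NULL
  if ("block" %in% colnames(plan)) {
    block_sizes <- table(plan$block)
    if (length(unique(as.integer(block_sizes))) != 1L)
      violations <- c(violations, sprintf(
        "blocking: unequal block sizes (%s)",
        paste(as.integer(block_sizes), collapse = ", ")))
  }

  list(pass = length(violations) == 0L,
       level_counts = level_counts,
       pair_counts = pair_counts,
       block_sizes = block_sizes,
       violations = violations)
}

#' Pair design profiles with their foldover mirrors
#'
#' Reports, for each profile in the plan, whether its mirror image
#' (levels `l -> 5 - l`) is also present in the plan. The published design
#' strategy applies a foldover to avoid dominated tasks; this check makes the
#' property inspectable without constraining the generator.
#'
#' @param plan an `ascot_design`.
#' @return data frame with `profile_id`, `mirror_id` (NA when the mirror is
#'   absent), and `has_mirror`.
#' @export
foldover_pairs <- function(plan) {
  mat <- as.matrix(plan[, setdiff(colnames(plan), c("profile_id", "block")),
                        drop = FALSE])
  key <- apply(mat, 1, paste, collapse = "")
  mirror_key <- apply(5L - mat, 1, paste, collapse = "")
  idx <- match(mirror_key, key)
  data.frame(profile_id = plan$profile_id,
             mirror_id = plan$profile_id[idx],
             has_mirror = !is.na(idx))
}

#' Read / write a design plan CSV
#'
#' CSV schema: `profile_id,block,occu,cont,perc,safe,soci,spac,supp` with
#' integer levels 1-4.
#'
#' @param plan an `ascot_design`.
#' @param path file path.
#' @return `read_design` returns an `ascot_design`; `write_design` returns
#'   `path` invisibly.
#' @export
write_design <- function(plan, path) {
  utils::write.csv(as.data.frame(plan), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path)
  need <- c("profile_id", "block")
  if (!all(need %in% colnames(df)))
    stop("design CSV must contain columns: ", paste(need, collapse = ", "))
  lev_cols <- setdiff(colnames(df), need)
  for (cl in lev_cols) {
    if (any(is.na(df[[cl]])) || any(df[[cl]] < 1) || any(df[[cl]] > 4))
      stop("design CSV column '", cl, "' has levels outside 1..4")
    df[[cl]] <- as.integer(df[[cl]])
  }
  class(df) <- c("ascot_design", "data.frame")
  df
}
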