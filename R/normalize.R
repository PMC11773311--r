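#' Estimate input-library frequencies from a control ligation
#'
#' A near-complete enzymatic control ligation of the randomized overhang
#' pool measures the input sequence distribution; its read counts give
#' the per-sequence frequencies `f_i = (c_i + pseudocount) /
#' sum(c_j + pseudocount)` over all 256 overhangs.
#'
#' @param counts Named counts over overhangs (zeros allowed), or a tibble
#'   with columns `overhang` and `count`.
#' @param pseudocount Added to every category before normalizing
#'   (default 0). With pseudocount 0, zero-count sequences trigger a
#'   warning: their normalization factor is undefined and will error on
#'   use.
#' @return An `input_distribution` tibble with columns overhang, count,
#'   f; frequencies sum to 1.
#' @export
input_frequencies <- function(counts, pseudocount = 0) {
  v <- as_overhang_vector(counts)
  if (sum(v) == 0) stop("control table is empty: no reads to estimate from")
  stopifnot(pseudocount >= 0)
  if (pseudocount == 0 && any(v == 0)) {
    warning(sum(v == 0), " overhang(s) have zero control counts; their ",
            "normalization factors are undefined (use a pseudocount)")
  }
  f <- (v + pseudocount) / sum(v + pseudocount)
  structure(
    tibble::tibble(overhang = names(v), count = as.integer(v), f = unname(f)),
    total_reads = sum(v),
    class = c("input_distribution", class(tibble::tibble()))
  )
}

#' Per-sequence normalization factors
#'
#' `alpha_i = f_i / (1/256) = 256 * f_i`: the ratio of a sequence's
#' observed input frequency to the hypothetical even distribution, so
#' `alpha_i = 1` when the observed frequency is exactly 1/256. Product
#' counts are divided by alpha to correct for input-library composition
#' bias.
#'
#' @param dist An [input_frequencies()] result (or tibble with columns
#'   `overhang`, `f`).
#' @return Tibble with columns overhang, alpha; mean alpha is 1.
#' @export
alpha_factors <- function(dist) {
  f <- as_overhang_vector(dist, value_col = "f")
  if (any(f == 0)) {
    bad <- names(f)[f == 0]
    stop("alpha undefined for zero-frequency sequence(s): ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "")
  }
  tibble::tibble(overhang = names(f), alpha = unname(length(f) * f))
}

#' Normalize product counts into a frequency profile
#'
#' Counts for one (reaction, product class) are divided by the
#' per-sequence alpha factors of the strand contributing the overhang and
#' renormalized to sum to 1. Ranks are assigned by descending normalized
#' frequency with ties (including all zero-count sequences) broken
#' lexicographically by sequence, so rankings are deterministic.
#'
#' @param counts Named counts over overhangs, a tibble with `overhang`
#'   and `count` columns, or a `product_count_table` restricted to one
#'   product class.
#' @param alpha An [alpha_factors()] table; every sequence with a nonzero
#'   count must have an alpha.
#' @param reaction,product,closing_pair Optional metadata recorded on the
#'   profile.
#' @return A `frequency_profile` tibble with columns overhang, count,
#'   alpha, norm_freq, raw_freq, rank, raw_rank.
#' @export
normalize_counts <- function(counts, alpha, reaction = NA_character_,
                             product = NA_character_,
                             closing_pair = NA_character_) {
  if (inherits(counts, "product_count_table")) {
    prods <- unique(counts$product)
    if (length(prods) != 1) {
      stop("counts span multiple product classes; filter to one first")
    }
    if (is.na(product)) product <- prods
    if (is.na(reaction) && length(unique(counts$reaction)) == 1) {
      reaction <- counts$reaction[1]
    }
    if (is.na(closing_pair) && length(unique(counts$closing_pair)) == 1) {
      closing_pair <- counts$closing_pair[1]
    }
  }
  v <- as_overhang_vector(counts)
  if (sum(v) == 0) stop("all counts are zero: nothing to normalize")
  a <- as_overhang_vector(alpha, value_col = "alpha")
  undefined <- v > 0 & a <= 0
  if (any(undefined)) {
    stop("alpha undefined for sequence(s) with nonzero counts: ",
         paste(head(names(v)[undefined], 5), collapse = ", "))
  }
  w <- ifelse(a > 0, v / a, 0)
  norm <- w / sum(w)
  raw <- v / sum(v)
  rank_of <- function(x) {
    ord <- order(-x, names(v))
    r <- integer(length(x))
    r[ord] <- seq_along(x)
    r
  }
  structure(
    tibble::tibble(
      overhang = names(v), count = as.integer(v), alpha = unname(a),
      norm_freq = unname(norm), raw_freq = unname(raw),
      rank = rank_of(unname(norm)), raw_rank = rank_of(unname(raw))
    ),
    reaction = reaction, product = product, closing_pair = closing_pair,
    class = c("frequency_profile", class(tibble::tibble()))
  )
}

#' Fold-range of a frequency profile
#'
#' Maximum frequency divided by the minimum nonzero frequency. Sequences
#' with zero frequency are excluded from the denominator; their number is
#' attached as attribute `n_zero`.
#'
#' @param profile A [normalize_counts()] profile (or any tibble with a
#'   `norm_freq` column).
#' @param column Frequency column to use (default `"norm_freq"`).
#' @return Ratio >= 1 with attribute `n_zero`.
#' @export
fold_range <- function(profile, column = "norm_freq") {
  x <- profile[[column]]
  if (is.null(x)) stop("no column '", column, "' in profile")
  pos <- x[x > 0]
  if (length(pos) == 0) stop("no positive frequencies: fold range undefined")
  structure(max(pos) / min(pos), n_zero = sum(x == 0))
}

#' Frequency-weighted positional base composition
#'
#' The 4 x 4 matrix of base frequencies at overhang positions 1-4,
#' weighted by each sequence's frequency (sequence-logo semantics), plus
#' the per-position information content in bits.
#'
#' @param profile A `frequency_profile` or `input_distribution` (or any
#'   tibble with an `overhang` column and the weight column).
#' @param column Weight column; defaults to `norm_freq` for profiles and
#'   `f` for input distributions.
#' @return A `position_profile`: list with `composition` (4x4 matrix,
#'   rows = positions, rows sum to 1) and `information` (bits, in
#'   `[0, 2]`).
#' @export
position_composition <- function(profile, column = NULL) {
  if (is.null(column)) {
    column <- if ("norm_freq" %in% names(profile)) "norm_freq" else "f"
  }
  w <- profile[[column]]
  if (is.null(w)) stop("no weight column '", column, "' in profile")
  seqs <- profile$overhang
  stopifnot(!is.null(seqs), all(nchar(seqs) == 4))
  if (sum(w) <= 0) stop("weights sum to zero")
  w <- w / sum(w)
  mat <- matrix(0, nrow = 4, ncol = 4,
                dimnames = list(paste0("pos", 1:4), rna_bases()))
  for (j in 1:4) {
    b <- substring(seqs, j, j)
    mat[j, ] <- vapply(rna_bases(), function(base) sum(w[b == base]),
                       numeric(1))
  }
  structure(list(composition = mat, information = information_content(mat)),
            class = "position_profile")
}

#' Per-position information content in bits
#'
#' `IC_j = 2 + sum_b p_bj * log2(p_bj)` with `0 * log 0 = 0`: 0 bits for
#' a uniform position, 2 bits for an invariant one.
#'
#' @param positions A `position_profile` or a positions-by-bases
#'   frequency matrix whose rows sum to 1.
#' @return Numeric vector of bits per position, each in `[0, 2]`.
#' @export
information_content <- function(positions) {
  mat <- if (inherits(positions, "position_profile")) {
    positions$composition
  } else {
    as.matrix(positions)
  }
  if (any(mat < 0) || any(abs(rowSums(mat) - 1) > 1e-9)) {
    stop("each row must be a base-frequency distribution summing to 1")
  }
  plogp <- ifelse(mat > 0, mat * log2(mat), 0)
  unname(log2(ncol(mat)) + rowSums(plogp))
}

#' Classify the top-k ranked sequences into consensus groups
#'
#' Takes the `k` top-ranked sequences of a profile and assigns each to
#' the first matching pattern (ordered, first match wins) or `"other"`.
#'
#' @param profile A [normalize_counts()] profile.
#' @param patterns Character vector of consensus patterns, in priority
#'   order.
#' @param k Number of top-ranked sequences to classify (0 <= k <= 256).
#' @param rank_column `"rank"` (alpha-normalized, default) or
#'   `"raw_rank"`.
#' @return List with `assignments` (tibble overhang, rank, norm_freq,
#'   group), `group_counts` (named integer vector over patterns and
#'   "other"), and `top_share` (cumulative normalized read share of the
#'   top k).
#' @export
classify_top_k <- function(profile, patterns, k, rank_column = "rank") {
  stopifnot(k >= 0, k <= 256, rank_column %in% c("rank", "raw_rank"))
  top <- profile[profile[[rank_column]] <= k, , drop = FALSE]
  top <- top[order(top[[rank_column]]), , drop = FALSE]
  group <- rep("other", nrow(top))
  assigned <- rep(FALSE, nrow(top))
  for (p in patterns) {
    hit <- !assigned & match_pattern(top$overhang, p)
    group[hit] <- p
    assigned <- assigned | hit
  }
  counts <- vapply(c(patterns, "other"), function(g) sum(group == g),
                   integer(1))
  freq_col <- if (rank_column == "rank") "norm_freq" else "raw_freq"
  list(
    assignments = tibble::tibble(
      overhang = top$overhang, rank = top[[rank_column]],
      norm_freq = top[[freq_col]], group = group
    ),
    group_counts = counts,
    top_share = sum(top[[freq_col]]),
    k = k
  )
}

#' Ranked loop sequences of a profile
#'
#' @param profile A `frequency_profile`.
#' @param rank_column `"rank"` or `"raw_rank"`.
#' @return Character vector of overhangs in rank order (best first).
#' @export
ranked_sequences <- function(profile, rank_column = "rank") {
  profile$overhang[order(profile[[rank_column]])]
}
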