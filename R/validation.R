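#' Spearman rank correlation with midrank ties
#'
#' Pearson correlation of average ranks (midranks assigned to ties).
#' Constant input vectors make the statistic undefined and raise an
#' error rather than returning NaN.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return A `spearman_result` list: `rho`, `n`, `ties_x`, `ties_y`
#'   (number of tied groups in each variable).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("rank correlation undefined for a constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  structure(
    list(
      rho = cor(rx, ry),
      n = length(x),
      ties_x = sum(table(x) > 1),
      ties_y = sum(table(y) > 1)
    ),
    class = "spearman_result"
  )
}

#' @export
print.spearman_result <- function(x, ...) {
  cat("<spearman_result> rho = ", signif(x$rho, 4), " (n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' Mean yield of a consensus group
#'
#' Unweighted mean yield over the records whose overhang matches the
#' consensus pattern.
#'
#' @param records Tibble with columns `overhang` and `yield` (fractions
#'   in `[0, 1]`).
#' @param pattern A consensus pattern, e.g. `"UNCG"`.
#' @return Mean yield (fraction).
#' @export
group_mean_yield <- function(records, pattern) {
  stopifnot(all(c("overhang", "yield") %in% names(records)))
  hit <- match_pattern(records$overhang, pattern)
  if (!any(hit)) stop("no record matches pattern '", pattern, "'")
  mean(records$yield[hit])
}

#' Fold difference between two means
#'
#' @param mean_a Numerator mean.
#' @param mean_b Denominator mean (> 0).
#' @return `mean_a / mean_b`.
#' @export
fold_difference <- function(mean_a, mean_b) {
  if (!is.numeric(mean_b) || mean_b <= 0) {
    stop("denominator mean must be positive")
  }
  mean_a / mean_b
}

#' Correlate measured yields with sequencing rank order
#'
#' Restricts the profile to the tested overhangs and correlates measured
#' yields against the sequencing ranking, with the rank order reversed
#' before correlating so that higher yield at a better (numerically
#' smaller) rank reports a positive rho.
#'
#' @param profile A [normalize_counts()] profile.
#' @param records Yield records (columns `overhang`, `yield`).
#' @param rank_column `"rank"` or `"raw_rank"`.
#' @return A [spearman_rho()] result.
#' @export
rank_yield_correlation <- function(profile, records, rank_column = "rank") {
  stopifnot(all(c("overhang", "yield") %in% names(records)))
  idx <- match(records$overhang, profile$overhang)
  if (anyNA(idx)) {
    stop("overhang(s) absent from the profile: ",
         paste(head(records$overhang[is.na(idx)], 5), collapse = ", "))
  }
  rk <- profile[[rank_column]][idx]
  spearman_rho(records$yield, max(rk) + 1 - rk)
}

#' Read a yield table
#'
#' Tab-separated columns `overhang`, `yield_pct`, `sd_pct`, `n`
#' (yields in percent); returned with yields as fractions.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns overhang, yield, sd, n.
#' @export
read_yield_table <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("overhang", "yield_pct", "sd_pct", "n") %in% names(d)))
  if (any(d$yield_pct < 0 | d$yield_pct > 100)) {
    stop("yields must be percentages in [0, 100]")
  }
  tibble::tibble(
    overhang = to_rna(d$overhang),
    yield = d$yield_pct / 100,
    sd = d$sd_pct / 100,
    n = as.integer(d$n)
  )
}

#' Packaged synthetic validation panel
#'
#' A 34-overhang yield panel emulating a triplicate validation
#' experiment: per-sequence values are synthetic, constructed so that the
#' consensus-group means equal the measured group means (UNCG 62 %,
#' CNNG 30 %, GNNA 28 %, UNNC 20 %, RNNY 0.2 %), with a few
#' middle-ranking sequences.
#'
#' @return Tibble as from [read_yield_table()].
#' @export
validation_panel <- function() {
  read_yield_table(
    system.file("extdata", "validation_yields_synthetic.tsv",
                package = "looplig", mustWork = TRUE)
  )
}
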