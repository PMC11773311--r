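#' @importFrom rlang .data
#' @importFrom stats setNames rmultinom rnorm rpois runif cor median quantile
#' @importFrom utils head packageVersion write.table read.delim
NULL

#' RNA alphabet
#'
#' The internal alphabet is RNA `{A, C, G, U}`; `T` is mapped to `U` on
#' input so DNA-alphabet reads are accepted transparently.
#'
#' @return Character vector of the four RNA bases.
#' @export
rna_bases <- function() c("A", "C", "G", "U")

# IUPAC-style degenerate codes used in consensus patterns.
iupac_sets <- function() {
  list(
    A = "A", C = "C", G = "G", U = "U",
    N = c("A", "C", "G", "U"),
    R = c("A", "G"),
    Y = c("C", "U")
  )
}

#' The six allowed closing base pairs
#'
#' The stem base pair immediately adjacent to the loop: the four
#' Watson-Crick pairs plus the two wobble pairs, each giving one parallel
#' reaction.
#'
#' @return Character vector of length 6, e.g. `"C:G"`.
#' @export
closing_pairs <- function() c("C:G", "G:C", "U:A", "A:U", "U:G", "G:U")

#' All 256 tetranucleotide overhang sequences
#'
#' @return Character vector of the 256 4-mers over `{A,C,G,U}` in
#'   lexicographic order.
#' @export
all_overhangs <- function() {
  b <- rna_bases()
  g <- expand.grid(p4 = b, p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3, g$p4))
}

#' Enumerate the full variant space of the assay
#'
#' Every combination of randomized 4-nt overhang (256) and closing base
#' pair (6), i.e. the 1536 hairpin variants profiled across the six
#' parallel reactions.
#'
#' @return A tibble with columns `closing_pair` and `overhang` (1536 rows).
#' @export
variant_space <- function() {
  tibble::tibble(
    closing_pair = rep(closing_pairs(), each = 256L),
    overhang = rep(all_overhangs(), times = 6L)
  )
}

#' Per-variant concentration of a randomized pool
#'
#' At a total strand concentration `total_nM`, each unique overhang
#' sequence in an `n_variants`-membered randomized pool is present at
#' `total_nM / n_variants` (e.g. 0.02 nM per sequence for a 5 nM NNNN
#' pool).
#'
#' @param total_nM Total strand concentration in nM.
#' @param n_variants Number of equimolar sequence variants (default 256).
#' @return Concentration per unique sequence, in nM.
#' @export
per_variant_concentration <- function(total_nM, n_variants = 256L) {
  stopifnot(is.numeric(total_nM), total_nM > 0, n_variants >= 1)
  total_nM / n_variants
}

#' Reverse complement of RNA sequences
#'
#' @param x Character vector of RNA sequences over `{A,C,G,U}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(s) paste(rev(s), collapse = ""),
    character(1)
  )
}

#' Match sequences against an IUPAC-style consensus pattern
#'
#' Positionwise set membership over the alphabet `{A,C,G,U,N,R,Y}`
#' (N = any base, R = purine A/G, Y = pyrimidine C/U). Both sequence and
#' pattern must have the same length.
#'
#' @param seqs Character vector of sequences (RNA alphabet).
#' @param pattern A single consensus pattern, e.g. `"UNNG"` or `"RNNY"`.
#' @return Logical vector, one element per sequence.
#' @export
match_pattern <- function(seqs, pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  sets <- iupac_sets()
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (!all(pat %in% names(sets))) {
    stop("pattern '", pattern, "' contains symbols outside {A,C,G,U,N,R,Y}")
  }
  ok <- nchar(seqs) == length(pat)
  res <- ok
  for (j in seq_along(pat)) {
    res <- res & substring(seqs, j, j) %in% sets[[pat[j]]]
  }
  res
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# Mismatch count of each window against a fixed tag; windows of the wrong
# length count as fully mismatched.
mismatch_count <- function(windows, tag) {
  n <- nchar(tag)
  res <- rep.int(n, length(windows))
  ok <- !is.na(windows) & nchar(windows) == n
  if (any(ok)) {
    mat <- matrix(
      unlist(strsplit(windows[ok], "", fixed = TRUE), use.names = FALSE),
      nrow = n
    )
    res[ok] <- colSums(mat != strsplit(tag, "", fixed = TRUE)[[1]])
  }
  res
}

# Named-vector coercion: accept a named vector or a two-column table over
# the 256 overhangs, return a full named vector in all_overhangs() order.
as_overhang_vector <- function(x, value_col = "count", fill = 0) {
  seqs <- all_overhangs()
  if (is.data.frame(x)) {
    stopifnot(all(c("overhang", value_col) %in% names(x)))
    v <- setNames(x[[value_col]], x[["overhang"]])
  } else {
    v <- x
  }
  if (is.null(names(v))) {
    stop("overhang-indexed values must be named by sequence")
  }
  bad <- setdiff(names(v), seqs)
  if (length(bad) > 0) {
    stop("unknown overhang sequence(s): ", paste(head(bad, 5), collapse = ", "))
  }
  out <- setNames(rep.int(as.numeric(fill), 256L), seqs)
  agg <- tapply(as.numeric(v), names(v), sum)
  out[names(agg)] <- agg
  out
}
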