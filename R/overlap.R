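#' Pairwise identity and coverage of two context sequences
#'
#' Global ends-free (overlap) alignment with unit match score and
#' configurable mismatch and gap penalties. Identity is matches divided
#' by aligned columns (end gaps excluded by the overlap alignment);
#' coverage is the aligned span divided by the length of the shorter
#' sequence, capped at 1.
#'
#' @param a,b RNA context sequences (non-empty, over `{A,C,G,U}`).
#' @param match Match score (default 1).
#' @param mismatch Mismatch score (default -1).
#' @param gap Per-gap penalty (default -1).
#' @return Named numeric vector `c(identity =, coverage =)`.
#' @export
pairwise_similarity <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  stopifnot(length(a) == 1, length(b) == 1)
  if (is.na(a) || is.na(b) || nchar(a) == 0 || nchar(b) == 0) {
    stop("context sequences must be non-empty")
  }
  a <- to_rna(a); b <- to_rna(b)
  if (!grepl("^[ACGU]+$", a) || !grepl("^[ACGU]+$", b)) {
    stop("context sequences must be over {A,C,G,U}")
  }
  bases <- rna_bases()
  sm <- matrix(mismatch, 4, 4, dimnames = list(bases, bases))
  diag(sm) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::RNAString(a), Biostrings::RNAString(b),
    type = "overlap", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = abs(gap)
  )
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  if (cols == 0) {
    return(c(identity = 0, coverage = 0))
  }
  c(identity = Biostrings::nmatch(aln) / cols,
    coverage = min(1, cols / min(nchar(a), nchar(b))))
}

# Unique k-mers of a sequence; used to pre-screen dedup candidates.
kmer_set <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(x)
  unique(substring(x, 1:(n - k + 1), k:n))
}

#' Deduplicate a tetraloop reference by context similarity
#'
#' Greedy scan in descending entry frequency (ties broken
#' lexicographically by context): an entry is dropped when its context
#' aligns to an already-kept entry with identity above
#' `identity_threshold` and coverage at least `coverage_threshold`
#' (defaults 0.90 / 0.70). Dropped entries' frequencies are discarded,
#' not merged. The operation is idempotent.
#'
#' Candidate pairs are pre-screened by shared 8-mers when `prescreen` is
#' `TRUE`: substitution-level similarity above 90 % identity over at
#' least 70 % of a >= 30-nt context forces a shared exact 8-mer, so the
#' screen only skips alignments that could not reach the thresholds.
#'
#' @param entries Tibble with columns loop, closing_pair, context,
#'   frequency (see [generate_reference()] for the layout).
#' @param identity_threshold,coverage_threshold Fractions in (0, 1].
#' @param prescreen Use the shared-8-mer screen (default TRUE).
#' @return The kept entries, sorted by descending frequency.
#' @export
dedup_reference <- function(entries, identity_threshold = 0.90,
                            coverage_threshold = 0.70, prescreen = TRUE) {
  stopifnot(nrow(entries) > 0,
            all(c("loop", "closing_pair", "context", "frequency") %in%
                  names(entries)),
            identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1)
  ord <- order(-entries$frequency, entries$context)
  entries <- entries[ord, , drop = FALSE]
  ctx <- entries$context
  n <- length(ctx)
  kept <- logical(n)
  kmers <- if (prescreen) lapply(ctx, kmer_set, k = 8L) else NULL
  index <- new.env(parent = emptyenv()) # kmer -> kept entry ids
  kept_ids <- integer(0)
  for (i in seq_len(n)) {
    cand <- if (prescreen) {
      found <- unlist(lapply(kmers[[i]], function(k) index[[k]]),
                      use.names = FALSE)
      sort(unique(found))
    } else {
      kept_ids
    }
    dup <- FALSE
    for (j in cand) {
      s <- pairwise_similarity(ctx[i], ctx[j])
      if (s[["identity"]] > identity_threshold &&
          s[["coverage"]] >= coverage_threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      kept[i] <- TRUE
      kept_ids <- c(kept_ids, i)
      if (prescreen) {
        for (k in kmers[[i]]) index[[k]] <- c(index[[k]], i)
      }
    }
  }
  entries[kept, , drop = FALSE]
}

#' Group and rank reference loops by closing pair
#'
#' Entries are grouped by their closing base pair; within each group,
#' loop sequences are aggregated by summed frequency and ranked in
#' descending order (ties broken lexicographically by loop).
#'
#' @param entries Reference tibble (loop, closing_pair, frequency, ...).
#' @return Tibble with columns closing_pair, loop, frequency, rank.
#' @export
group_rank <- function(entries) {
  stopifnot(all(c("loop", "closing_pair", "frequency") %in% names(entries)))
  bad <- setdiff(unique(entries$closing_pair), closing_pairs())
  if (length(bad) > 0) {
    stop("unknown closing pair(s): ", paste(bad, collapse = ", "))
  }
  agg <- dplyr::summarise(
    dplyr::group_by(entries, .data$closing_pair, .data$loop),
    frequency = sum(.data$frequency), .groups = "drop"
  )
  agg <- agg[order(agg$closing_pair, -agg$frequency, agg$loop), , drop = FALSE]
  agg <- dplyr::mutate(dplyr::group_by(agg, .data$closing_pair),
                       rank = dplyr::row_number())
  dplyr::ungroup(agg)
}

#' Observed overlap of two top-k ranked sets
#'
#' @param ranked_a,ranked_b Character vectors of loop sequences in rank
#'   order (best first).
#' @param k Set size.
#' @return Size of the intersection of the two top-k sets.
#' @export
overlap_top_k <- function(ranked_a, ranked_b, k) {
  stopifnot(k >= 0)
  length(intersect(head(ranked_a, k), head(ranked_b, k)))
}

#' Expected overlap under the hypergeometric null
#'
#' For two independent size-`K`/size-`n` subsets of an `N`-membered
#' population (one treated as a fixed reference), the expected overlap is
#' `n * K / N`: 6.25 for two top-40 sets from a 256-sequence population.
#'
#' @param N Population size.
#' @param K,n Sizes of the two subsets.
#' @return The expectation `n * K / N`.
#' @export
hypergeom_expected <- function(N, K, n) {
  stopifnot(N >= 1, K >= 0, n >= 0)
  if (K > N || n > N) stop("subset sizes cannot exceed the population size")
  n * K / N
}

# log hypergeometric pmf via log binomial coefficients.
log_hyper_pmf <- function(k, N, K, n) {
  lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Exact hypergeometric tail probability
#'
#' Inclusive tail sum of the hypergeometric pmf, accumulated in log
#' space: `direction = "enrichment"` gives `P(X >= k_obs)`,
#' `"depletion"` gives `P(X <= k_obs)`.
#'
#' @param k_obs Observed overlap, in `[max(0, n-(N-K)), min(K, n)]`
#'   bounds-checked against `0 <= k_obs <= min(K, n)`.
#' @inheritParams hypergeom_expected
#' @param direction `"enrichment"` (upper tail) or `"depletion"` (lower
#'   tail).
#' @return Exact tail p-value in `[0, 1]`.
#' @export
hypergeom_tail <- function(k_obs, N, K, n,
                           direction = c("enrichment", "depletion")) {
  direction <- match.arg(direction)
  stopifnot(N >= 1, K >= 0, n >= 0)
  if (K > N || n > N) stop("subset sizes cannot exceed the population size")
  if (k_obs < 0 || k_obs > min(K, n)) {
    stop("k_obs must lie in [0, min(K, n)]")
  }
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  if (direction == "enrichment") {
    ks <- seq(max(k_obs, lo), hi)
  } else {
    if (k_obs < lo) return(0)
    ks <- seq(lo, k_obs)
  }
  min(1, exp(logsumexp(log_hyper_pmf(ks, N, K, n))))
}

#' Fold enrichment or depletion of an observed overlap
#'
#' @param k_obs Observed overlap count.
#' @param expected Expected overlap under the null (> 0).
#' @return List with `direction` (`"enriched"`, `"depleted"`, or
#'   `"equal"`) and `fold`: `k_obs / expected` when enriched,
#'   `expected / k_obs` when depleted (so depletion is reported as an
#'   x-fold under-representation).
#' @export
enrichment <- function(k_obs, expected) {
  stopifnot(expected > 0, k_obs >= 0)
  ratio <- k_obs / expected
  if (ratio > 1) {
    list(direction = "enriched", fold = ratio)
  } else if (ratio < 1) {
    list(direction = "depleted", fold = expected / k_obs)
  } else {
    list(direction = "equal", fold = 1)
  }
}

#' Full overlap analysis of two ranked sets
#'
#' Combines [overlap_top_k()], [hypergeom_expected()], [enrichment()]
#' and [hypergeom_tail()] into one result.
#'
#' @inheritParams overlap_top_k
#' @param N Population size (default 256, all tetraloops of one
#'   closing-pair group).
#' @param direction `"auto"` (enrichment tail when the observed overlap
#'   is at least the expectation, depletion tail otherwise),
#'   `"enrichment"`, or `"depletion"`.
#' @return An `overlap_result` list: `k`, `N`, `k_obs`, `expected`,
#'   `fold`, `direction`, `p_value`, `tail`.
#' @export
overlap_analysis <- function(ranked_a, ranked_b, k = 40, N = 256,
                             direction = c("auto", "enrichment", "depletion")) {
  direction <- match.arg(direction)
  k_obs <- overlap_top_k(ranked_a, ranked_b, k)
  kA <- min(k, length(ranked_a))
  kB <- min(k, length(ranked_b))
  expected <- hypergeom_expected(N, kA, kB)
  enr <- enrichment(k_obs, expected)
  tail <- if (direction == "auto") {
    if (k_obs >= expected) "enrichment" else "depletion"
  } else {
    direction
  }
  structure(
    list(k = k, N = N, k_obs = k_obs, expected = expected,
         fold = enr$fold, direction = enr$direction,
         p_value = hypergeom_tail(k_obs, N, kA, kB, tail), tail = tail),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> top-", x$k, " overlap: observed ", x$k_obs,
      ", expected ", signif(x$expected, 4), " (", x$direction, " ",
      signif(x$fold, 3), "-fold); exact ", x$tail, " p = ",
      signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}
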