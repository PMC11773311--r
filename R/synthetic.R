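#' Positional base frequencies of the randomized library
#'
#' The randomized NNNN overhangs produced by solid-phase synthesis are not
#' evenly distributed: the observed marginal base composition is
#' A > G > U > C at the first three positions and C > A > G > U at the
#' fourth (the only position coupled directly to the solid support).
#' Sequences are modelled as positionally independent draws from these
#' marginals.
#'
#' @param mat A 4x4 numeric matrix, rows = overhang positions 1-4 (from
#'   the 5' end), columns named `A,C,G,U`; each row must sum to 1.
#'   Defaults to the measured library composition.
#' @return An object of class `position_base_frequencies`.
#' @export
position_base_frequencies <- function(mat = default_input_composition()) {
  mat <- as.matrix(mat)
  if (!all(dim(mat) == c(4L, 4L))) stop("frequency matrix must be 4 x 4")
  if (is.null(colnames(mat)) || !setequal(colnames(mat), rna_bases())) {
    stop("frequency matrix columns must be named A, C, G, U")
  }
  mat <- mat[, rna_bases(), drop = FALSE]
  if (any(mat < 0)) stop("frequencies must be non-negative")
  if (any(abs(rowSums(mat) - 1) > 1e-9)) {
    stop("each positional frequency row must sum to 1 (within 1e-9)")
  }
  rownames(mat) <- paste0("pos", 1:4)
  structure(mat, class = c("position_base_frequencies", "matrix"))
}

#' Default library base composition
#'
#' A 0.33, G 0.26, U 0.22, C 0.19 at positions 1-3; C 0.33, A 0.28,
#' G 0.21, U 0.18 at position 4.
#'
#' @return 4x4 matrix suitable for [position_base_frequencies()].
#' @export
default_input_composition <- function() {
  p123 <- c(A = 0.33, C = 0.19, G = 0.26, U = 0.22)
  p4 <- c(A = 0.28, C = 0.33, G = 0.21, U = 0.18)
  rbind(p123, p123, p123, p4)
}

# P(sequence) under positional independence, over all 256 overhangs.
sequence_probabilities <- function(freqs) {
  freqs <- position_base_frequencies(unclass(freqs))
  seqs <- all_overhangs()
  p <- rep(1, length(seqs))
  for (j in 1:4) p <- p * freqs[j, substring(seqs, j, j)]
  setNames(p / sum(p), seqs)
}

#' Sample a randomized input library
#'
#' Multinomial draw of `n_molecules` molecules over the 256 overhangs with
#' `P(seq)` the product of positional base frequencies.
#'
#' @param freqs A [position_base_frequencies()] object (or matrix).
#' @param n_molecules Number of molecules to draw (> 0).
#' @param seed Integer seed; the draw is a pure function of
#'   `(freqs, n_molecules, seed)`.
#' @return Named integer vector of counts over all 256 overhangs (zeros
#'   retained).
#' @export
sample_input_library <- function(freqs, n_molecules, seed) {
  if (!is.numeric(n_molecules) || length(n_molecules) != 1 || n_molecules <= 0) {
    stop("n_molecules must be a positive count")
  }
  p <- sequence_probabilities(freqs)
  counts <- withr::with_seed(seed, rmultinom(1, size = n_molecules, prob = p)[, 1])
  setNames(as.integer(counts), names(p))
}

#' Sequence-dependent loop-closing efficiency model
#'
#' Ordered consensus patterns with group-mean efficiencies; the first
#' matching pattern wins, unmatched sequences fall back to
#' `fallback`. Per-sequence efficiencies are the group mean perturbed by
#' multiplicative lognormal noise and clipped to (0, 1].
#'
#' Default group means follow the measured yields of the validated
#' consensus groups: UNCG 62 %, CNNG 30 %, GNNA 28 %, UNNC 20 %, and the
#' disfavored RNNY group at 0.2 % (a 310-fold spread).
#'
#' @param patterns Data frame with columns `pattern` and `mean`
#'   (fractions in (0,1]); order matters.
#' @param fallback Efficiency for sequences matching no pattern.
#' @param noise_sd Standard deviation of the lognormal perturbation
#'   (on the log scale); 0 gives exactly the group means.
#' @param seed Integer seed used when resolving per-sequence values.
#' @return An object of class `efficiency_model`.
#' @export
efficiency_model <- function(patterns = default_efficiency_patterns(),
                             fallback = 0.05, noise_sd = 0.25, seed = 1L) {
  patterns <- tibble::as_tibble(patterns)
  stopifnot(
    all(c("pattern", "mean") %in% names(patterns)),
    all(patterns$mean > 0), all(patterns$mean <= 1),
    fallback > 0, fallback <= 1, noise_sd >= 0
  )
  for (p in patterns$pattern) match_pattern("AAAA", p) # validates symbols
  structure(
    list(patterns = patterns, fallback = fallback,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "efficiency_model"
  )
}

#' Default consensus-group efficiencies
#' @return Tibble of ordered (pattern, mean) rows.
#' @export
default_efficiency_patterns <- function() {
  tibble::tibble(
    pattern = c("UNCG", "CNNG", "GNNA", "UNNC", "RNNY"),
    mean = c(0.62, 0.30, 0.28, 0.20, 0.002)
  )
}

#' Resolve per-sequence loop-closing efficiencies
#'
#' @param model An [efficiency_model()].
#' @return Named numeric vector over all 256 overhangs, values in (0, 1];
#'   deterministic given the model's seed.
#' @export
resolve_efficiencies <- function(model) {
  stopifnot(inherits(model, "efficiency_model"))
  seqs <- all_overhangs()
  eff <- rep(model$fallback, length(seqs))
  assigned <- rep(FALSE, length(seqs))
  for (i in seq_len(nrow(model$patterns))) {
    hit <- !assigned & match_pattern(seqs, model$patterns$pattern[i])
    eff[hit] <- model$patterns$mean[i]
    assigned <- assigned | hit
  }
  if (model$noise_sd > 0) {
    noise <- withr::with_seed(model$seed, rnorm(length(seqs), 0, model$noise_sd))
    eff <- eff * exp(noise)
  }
  eff <- pmin(pmax(eff, 1e-6), 1)
  setNames(eff, seqs)
}

#' Splinted-ligation propensity model
#'
#' The propensity of an overhang to direct splinted (nicked-duplex)
#' ligation is the product of per-base-pair annealing weights over the
#' 4-bp splint (Watson-Crick complements only, no wobble), scaled
#' linearly by total duplex concentration: C:G pairs are weighted more
#' strongly than A:U pairs, which makes splinted ligation favor CG-rich
#' overhangs.
#'
#' @param w_gc,w_au Per-base-pair weights for C:G and A:U pairs (> 0).
#' @param conc_scale Concentration scale factor converting
#'   `weight * nM * partner_frequency` into a rate comparable to the
#'   loop-closing rate; usually set by [calibrate_splint_scale()].
#' @return An object of class `splint_model`.
#' @export
splint_model <- function(w_gc = 3, w_au = 1, conc_scale = 1) {
  stopifnot(w_gc > 0, w_au > 0, conc_scale >= 0)
  structure(list(w_gc = w_gc, w_au = w_au, conc_scale = conc_scale),
            class = "splint_model")
}

# Product of per-pair weights over the 4-bp splint formed by an overhang.
splint_weights <- function(seqs, model) {
  stopifnot(inherits(model, "splint_model"))
  w <- rep(1, length(seqs))
  for (j in 1:4) {
    gc <- substring(seqs, j, j) %in% c("C", "G")
    w <- w * ifelse(gc, model$w_gc, model$w_au)
  }
  w
}

# Mass-action partition terms for one duplex type: per-overhang rates of
# loop closing, same-duplex splinting, cross-duplex splinting, hydrolysis.
partition_terms <- function(eff, f_same, f_cross, splint, concentration,
                            k_loop, k_hyd) {
  seqs <- all_overhangs()
  rc <- revcomp(seqs)
  w <- splint_weights(seqs, splint)
  list(
    loop = k_loop * eff[seqs],
    spl_same = splint$conc_scale * w * concentration * f_same[rc],
    spl_cross = splint$conc_scale * w * concentration * f_cross[rc],
    hyd = rep(k_hyd, length(seqs))
  )
}

#' Expected splinted fractions under the mass-action partition
#'
#' Deterministic per-molecule enumeration over all 256 overhangs of both
#' duplex pools: each molecule partitions among loop closing, splinting
#' with a same-type partner, splinting with a cross-type partner, and
#' hydrolysis, with probabilities proportional to the four rate terms.
#'
#' @param efficiencies Named per-sequence loop-closing efficiencies.
#' @param freqs_a,freqs_b Named input frequency vectors (summing to 1) of
#'   the overhang-bearing strands of the two duplex pools.
#' @inheritParams simulate_reaction
#' @return List with elements `observed` (expected (P2+P3)/(P1+..+P4) read
#'   fraction), `true` (expected fraction of all ligation events that are
#'   splinted, including same-type events absorbed into P1/P4), and
#'   `ligated_yield` (expected ligated fraction of molecules).
#' @export
expected_splinted_fraction <- function(efficiencies, freqs_a, freqs_b, splint,
                                       concentration, k_loop = 1, k_hyd = 4) {
  fa <- as_overhang_vector(freqs_a, value_col = "f")
  fb <- as_overhang_vector(freqs_b, value_col = "f")
  fa <- fa / sum(fa)
  fb <- fb / sum(fb)
  tA <- partition_terms(efficiencies, fa, fb, splint, concentration, k_loop, k_hyd)
  tB <- partition_terms(efficiencies, fb, fa, splint, concentration, k_loop, k_hyd)
  zA <- tA$loop + tA$spl_same + tA$spl_cross + tA$hyd
  zB <- tB$loop + tB$spl_same + tB$spl_cross + tB$hyd
  cross <- sum(fa * tA$spl_cross / zA) + sum(fb * tB$spl_cross / zB)
  same <- sum(fa * tA$spl_same / zA) + sum(fb * tB$spl_same / zB)
  loop <- sum(fa * tA$loop / zA) + sum(fb * tB$loop / zB)
  lig <- cross + same + loop
  list(observed = cross / lig, true = (cross + same) / lig,
       ligated_yield = lig / 2)
}

#' Calibrate the splint concentration scale
#'
#' Chooses `conc_scale` by bisection against the analytic mass-action
#' partition so that the expected (P2+P3)/total read fraction matches the
#' calibration targets. With targets at two concentrations the scale
#' matching each is found separately and their geometric mean returned,
#' balancing the residual between the two regimes.
#'
#' @inheritParams expected_splinted_fraction
#' @param targets Named numeric vector: names are concentrations in nM,
#'   values the target observed splinted fractions. Default: 0.44 at
#'   250 nM and 0.03 at 5 nM.
#' @return A calibrated [splint_model()].
#' @export
calibrate_splint_scale <- function(efficiencies, freqs_a, freqs_b,
                                   splint = splint_model(),
                                   targets = c("250" = 0.44, "5" = 0.03),
                                   k_loop = 1, k_hyd = 4) {
  stopifnot(length(targets) >= 1, all(targets > 0), all(targets < 0.5))
  scale_for <- function(conc, target) {
    f <- function(log_s) {
      m <- splint_model(splint$w_gc, splint$w_au, exp(log_s))
      expected_splinted_fraction(efficiencies, freqs_a, freqs_b, m,
                                 conc, k_loop, k_hyd)$observed - target
    }
    lo <- log(1e-10); hi <- log(1e6)
    if (f(lo) > 0 || f(hi) < 0) stop("calibration target unattainable")
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    exp((lo + hi) / 2)
  }
  scales <- mapply(scale_for, as.numeric(names(targets)), targets)
  splint_model(splint$w_gc, splint$w_au, exp(mean(log(scales))))
}

#' Simulate one competing-ligation reaction
#'
#' Two duplex pools (A:a and B:b), each carrying a randomized 3'
#' overhang, react by loop-closing ligation (intramolecular), splinted
#' ligation across a nick held by annealing of Watson-Crick-complementary
#' overhangs (with a same-type or cross-type partner duplex), or
#' hydrolysis of the activated 5'-phosphate. Each molecule's fate is a
#' multinomial draw with probabilities proportional to the mass-action
#' rate terms; products are labelled P1 (A-a), P2 (A-b), P3 (B-a),
#' P4 (B-b), with P2/P3 arising only from cross-duplex splinting. Reads
#' are then sampled from the ligated product pool to `read_depth` by a
#' single multinomial draw.
#'
#' The overhang recorded for a product is the acceptor strand's overhang:
#' the loop sequence for loop closing, the splint partner's (reverse
#' complement) overhang for splinted events.
#'
#' @param library_a,library_b Named molecule counts over the 256
#'   overhangs for the two duplex pools (see [sample_input_library()]).
#' @param efficiencies Named per-sequence loop-closing efficiencies,
#'   see [resolve_efficiencies()].
#' @param splint A [splint_model()].
#' @param concentration Per-duplex strand concentration in nM (> 0).
#' @param read_depth Number of sequencing reads to emit (> 0).
#' @param seed Integer seed; the batch is a pure function of
#'   `(arguments, seed)`.
#' @param k_loop Rate constant multiplying the loop-closing efficiency.
#' @param k_hyd Hydrolysis rate constant (the unreacted sink); the
#'   default places total ligated yield in the observed few-percent
#'   range.
#' @return An object of class `synthetic_batch`: `read_counts` (tibble of
#'   product, overhang, pathway, events, reads), `true_splinted_fraction`,
#'   `true_efficiencies`, `ligated_yield`, `params`, `seed`.
#' @export
simulate_reaction <- function(library_a, library_b, efficiencies, splint,
                              concentration, read_depth, seed,
                              k_loop = 1, k_hyd = 4) {
  stopifnot(concentration > 0, read_depth > 0)
  na <- as_overhang_vector(library_a)
  nb <- as_overhang_vector(library_b)
  fa <- na / sum(na)
  fb <- nb / sum(nb)
  eff <- as_overhang_vector(efficiencies, value_col = "efficiency")
  seqs <- all_overhangs()
  rc <- revcomp(seqs)
  tA <- partition_terms(eff, fa, fb, splint, concentration, k_loop, k_hyd)
  tB <- partition_terms(eff, fb, fa, splint, concentration, k_loop, k_hyd)
  if (all(tA$loop + tA$spl_same + tA$spl_cross == 0) &&
      all(tB$loop + tB$spl_same + tB$spl_cross == 0)) {
    stop("degenerate input: zero total ligation propensity")
  }
  draw_events <- function(n, terms) {
    probs <- cbind(terms$loop, terms$spl_same, terms$spl_cross, terms$hyd)
    out <- matrix(0L, nrow = length(n), ncol = 4L)
    nz <- which(n > 0)
    for (i in nz) out[i, ] <- rmultinom(1, n[i], probs[i, ])[, 1]
    out
  }
  batch <- withr::with_seed(seed, {
    evA <- draw_events(na, tA)
    evB <- draw_events(nb, tB)
    events <- dplyr::bind_rows(
      tibble::tibble(product = "P1", overhang = seqs, pathway = "loop",   events = evA[, 1]),
      tibble::tibble(product = "P1", overhang = rc,   pathway = "splint", events = evA[, 2]),
      tibble::tibble(product = "P2", overhang = rc,   pathway = "splint", events = evA[, 3]),
      tibble::tibble(product = "P4", overhang = seqs, pathway = "loop",   events = evB[, 1]),
      tibble::tibble(product = "P4", overhang = rc,   pathway = "splint", events = evB[, 2]),
      tibble::tibble(product = "P3", overhang = rc,   pathway = "splint", events = evB[, 3])
    )
    events <- dplyr::summarise(
      dplyr::group_by(events, .data$product, .data$overhang, .data$pathway),
      events = sum(.data$events), .groups = "drop"
    )
    events <- events[events$events > 0, , drop = FALSE]
    total_lig <- sum(events$events)
    if (total_lig == 0) stop("degenerate input: no ligation events to sequence")
    reads <- rmultinom(1, read_depth, events$events)[, 1]
    events$reads <- as.integer(reads)
    events
  })
  n_splint <- sum(batch$events[batch$pathway == "splint"])
  structure(
    list(
      read_counts = batch,
      true_splinted_fraction = n_splint / sum(batch$events),
      true_efficiencies = eff,
      ligated_yield = sum(batch$events) / (sum(na) + sum(nb)),
      params = list(concentration = concentration, read_depth = read_depth,
                    splint = splint, k_loop = k_loop, k_hyd = k_hyd),
      seed = as.integer(seed)
    ),
    class = "synthetic_batch"
  )
}

#' @export
print.synthetic_batch <- function(x, ...) {
  cat("<synthetic_batch> ", sum(x$read_counts$reads), " reads at ",
      x$params$concentration, " nM; true splinted fraction ",
      signif(x$true_splinted_fraction, 3), "; ligated yield ",
      signif(x$ligated_yield, 3), "\n", sep = "")
  invisible(x)
}

#' Product read counts of a synthetic batch
#'
#' Collapses the per-pathway read table to the (reaction, closing pair,
#' product, overhang) count table that demultiplexing of the written
#' FASTQ would yield at zero mismatches.
#'
#' @param batch A [simulate_reaction()] result.
#' @param spec A [construct_spec()] (supplies the closing pair).
#' @param reaction Reaction identifier string.
#' @return A `product_count_table` tibble.
#' @export
batch_count_table <- function(batch, spec, reaction = "reaction1") {
  stopifnot(inherits(batch, "synthetic_batch"), inherits(spec, "construct_spec"))
  tab <- dplyr::summarise(
    dplyr::group_by(batch$read_counts, .data$product, .data$overhang),
    count = sum(.data$reads), .groups = "drop"
  )
  tab <- tab[tab$count > 0, , drop = FALSE]
  out <- tibble::tibble(
    reaction = reaction, closing_pair = spec$closing_pair,
    product = tab$product, overhang = tab$overhang,
    count = as.integer(tab$count)
  )
  new_product_count_table(out, rejections = empty_rejections())
}

#' Write a synthetic batch as FASTQ with a truth sidecar
#'
#' Each read is `handle5 + donor tag + overhang + acceptor tag + handle3`
#' per its product class, written in the DNA alphabet (U -> T) with
#' constant Phred+33 qualities. A tab-separated truth table
#' (read_id, reaction, product_class, overhang) is written alongside.
#'
#' @param batch A [simulate_reaction()] result.
#' @param spec A [construct_spec()].
#' @param path Output FASTQ path.
#' @param truth_path Output truth TSV path (default `<path>.truth.tsv`).
#' @param reaction Reaction identifier recorded in the truth table.
#' @param error_rate Optional uniform per-base substitution error rate
#'   applied to the written reads (default 0, no error model).
#' @param seed Seed for the error model (required if `error_rate > 0`).
#' @return Invisibly, the truth tibble.
#' @export
write_reads <- function(batch, spec, path,
                        truth_path = paste0(path, ".truth.tsv"),
                        reaction = "reaction1", error_rate = 0, seed = NULL) {
  stopifnot(inherits(batch, "synthetic_batch"), inherits(spec, "construct_spec"))
  tbl <- batch$read_counts[batch$read_counts$reads > 0, , drop = FALSE]
  product <- rep(tbl$product, tbl$reads)
  overhang <- rep(tbl$overhang, tbl$reads)
  n <- length(product)
  if (n > 0) {
    donor <- unname(spec$donor_tags[product_donor(product)])
    acceptor <- unname(spec$acceptor_tags[product_acceptor(product)])
    seqs <- paste0(spec$handle5, donor, overhang, acceptor, spec$handle3)
    if (error_rate > 0) {
      if (is.null(seed)) stop("seed is required when error_rate > 0")
      seqs <- withr::with_seed(seed, mutate_reads(seqs, error_rate))
    }
    dna <- chartr("U", "T", seqs)
  } else {
    dna <- character(0)
  }
  ids <- sprintf("read_%07d", seq_len(n))
  x <- Biostrings::DNAStringSet(dna)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(dna)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = qual)
  truth <- tibble::tibble(read_id = ids, reaction = reaction,
                          product_class = product, overhang = overhang)
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}

# Uniform substitution errors: each base flips to one of the other three.
mutate_reads <- function(seqs, rate) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(runif(length(flat)) < rate)
  if (length(hit) > 0) {
    alt <- vapply(flat[hit], function(b) sample(setdiff(rna_bases(), b), 1),
                  character(1))
    flat[hit] <- alt
  }
  idx <- rep(seq_along(lens), lens)
  vapply(split(flat, idx), paste, character(1), collapse = "")
}

#' Generate a mock biological tetraloop reference
#'
#' Emulates a redundant tetraloop table extracted from an automated RNA
#' secondary-structure annotation resource: entries are
#' (loop, closing_pair, context, frequency) with the canonical biological
#' tetraloop families (UNCG, GNRA, CUUG, and the broader UNNG group)
#' over-represented both in entry counts and in per-entry frequencies,
#' and a configurable fraction of near-duplicate contexts (>= 90 %
#' identity to an earlier entry) to exercise deduplication. This is a
#' synthetic stand-in, not data from any real database.
#'
#' @param n_entries Number of entries (> 0).
#' @param seed Integer seed; the table is byte-identical given
#'   `(parameters, seed)`.
#' @param enrichment Named numeric vector of consensus patterns to
#'   sampling weights (first match wins, remainder weight 1).
#' @param dup_fraction Fraction of entries that are near-duplicates of an
#'   earlier entry.
#' @param context_length Integer range of context lengths (nt).
#' @return Tibble with columns loop, closing_pair, context, frequency.
#' @export
generate_reference <- function(n_entries = 1200L, seed = 1L,
                               enrichment = c(UNCG = 40, GNRA = 25, CUUG = 10,
                                              UNNG = 4),
                               dup_fraction = 0.1,
                               context_length = c(30L, 80L)) {
  if (!is.numeric(n_entries) || n_entries <= 0) stop("n_entries must be > 0")
  stopifnot(dup_fraction >= 0, dup_fraction < 1,
            length(context_length) == 2, context_length[1] >= 10)
  seqs <- all_overhangs()
  w <- rep(1, length(seqs))
  assigned <- rep(FALSE, length(seqs))
  for (p in names(enrichment)) {
    hit <- !assigned & match_pattern(seqs, p)
    w[hit] <- enrichment[[p]]
    assigned <- assigned | hit
  }
  withr::with_seed(seed, {
    loop <- sample(seqs, n_entries, replace = TRUE, prob = w)
    pair <- sample(closing_pairs(), n_entries, replace = TRUE)
    wl <- w[match(loop, seqs)]
    frequency <- 1L + rpois(n_entries, lambda = 3 * wl)
    len <- sample(seq(context_length[1], context_length[2]), n_entries,
                  replace = TRUE)
    context <- vapply(seq_len(n_entries), function(i) {
      flank <- len[i] - 4L
      left <- sample(0:flank, 1)
      paste0(
        paste(sample(rna_bases(), left, replace = TRUE), collapse = ""),
        loop[i],
        paste(sample(rna_bases(), flank - left, replace = TRUE), collapse = "")
      )
    }, character(1))
    n_dup <- round(dup_fraction * n_entries)
    if (n_dup > 0 && n_entries >= 2) {
      dup_idx <- sample(2:n_entries, n_dup)
      for (i in dup_idx) {
        src <- sample(seq_len(i - 1L), 1)
        ctx <- strsplit(context[src], "", fixed = TRUE)[[1]]
        n_sub <- max(0L, min(floor(0.05 * length(ctx)), length(ctx)))
        if (n_sub > 0) {
          pos <- sample(seq_along(ctx), n_sub)
          ctx[pos] <- vapply(ctx[pos],
                             function(b) sample(setdiff(rna_bases(), b), 1),
                             character(1))
        }
        context[i] <- paste(ctx, collapse = "")
        loop[i] <- loop[src]
        pair[i] <- pair[src]
        frequency[i] <- max(1L, frequency[src] %/% 2L)
      }
    }
    tibble::tibble(loop = loop, closing_pair = pair,
                   context = context, frequency = as.integer(frequency))
  })
}
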