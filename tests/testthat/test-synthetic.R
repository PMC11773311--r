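test_that("input library sampling follows the positional product model", {
  # uniform limit: every sequence near n/256
  unif <- position_base_frequencies(
    matrix(0.25, 4, 4, dimnames = list(NULL, rna_bases()))
  )
  lib <- sample_input_library(unif, 256000L, seed = 11)
  expect_identical(sum(lib), 256000L)
  expect_length(lib, 256L)
  expect_lt(max(lib) / min(lib), 1.4)

  # biased defaults: analytic product of the printed marginals
  p_aaac <- 0.33^3 * 0.28   # A,A,A + A at position 4
  p_cccu <- 0.19^3 * 0.18
  p <- looplig:::sequence_probabilities(fix_freqs())
  expect_equal(p[["AAAC"]] / p[["CCCU"]], (0.33^3 * 0.33) / (0.19^3 * 0.18))
  expect_equal(p[["AAAA"]] / p[["CCCU"]], p_aaac / p_cccu)
  # most vs least common frequency differ ~10-fold, same order as the
  # measured 8-20-fold range
  expect_gt(max(p) / min(p), 8)
  expect_lt(max(p) / min(p), 20)

  big <- sample_input_library(fix_freqs(), 2e6, seed = 3)
  expect_gt(cor(as.numeric(big), as.numeric(p)), 0.999)

  expect_error(sample_input_library(fix_freqs(), 0, seed = 1), "positive")
  badmat <- matrix(c(0.5, 0.5, 0.5, 0.5), 4, 4,
                   dimnames = list(NULL, rna_bases()))
  expect_error(position_base_frequencies(badmat), "sum to 1")
  expect_identical(sample_input_library(fix_freqs(), 1e4, seed = 5),
                   sample_input_library(fix_freqs(), 1e4, seed = 5))
})

test_that("efficiency resolution honors pattern order, noise and clipping", {
  eff <- fix_eff()
  expect_equal(eff[["UUCG"]], 0.62)
  expect_equal(eff[["AAAC"]], 0.002)   # RNNY
  expect_equal(eff[["CAAG"]], 0.30)    # CNNG
  expect_equal(eff[["GAAA"]], 0.28)    # GNNA
  expect_equal(eff[["UAGC"]], 0.20)    # UNNC
  expect_true(all(eff > 0 & eff <= 1))

  # independent enumeration oracle for pattern sizes
  seqs <- all_overhangs()
  expect_identical(sum(startsWith(seqs, "U") & endsWith(seqs, "G")), 16L)
  expect_identical(sum(match_pattern(seqs, "UNNG")),
                   sum(startsWith(seqs, "U") & endsWith(seqs, "G")))

  # UNCG takes precedence over a later UNNG-style pattern
  m <- efficiency_model(
    patterns = data.frame(pattern = c("UNCG", "UNNG"), mean = c(0.62, 0.10)),
    noise_sd = 0
  )
  r <- resolve_efficiencies(m)
  expect_equal(r[["UGCG"]], 0.62)
  expect_equal(r[["UGGG"]], 0.10)

  noisy <- resolve_efficiencies(efficiency_model(noise_sd = 0.3, seed = 9))
  expect_identical(noisy,
                   resolve_efficiencies(efficiency_model(noise_sd = 0.3,
                                                         seed = 9)))
  expect_false(identical(noisy, fix_eff()))
})

test_that("reaction simulation partitions molecules and conserves reads", {
  lib_a <- sample_input_library(fix_freqs(), 2e5, seed = 21)
  lib_b <- sample_input_library(fix_freqs(), 2e5, seed = 22)

  # splint pathway disabled: no splinted events, only P1/P4
  off <- splint_model(conc_scale = 0)
  b0 <- simulate_reaction(lib_a, lib_b, fix_eff(), off, 5, 5e4, seed = 1)
  expect_equal(b0$true_splinted_fraction, 0)
  expect_setequal(unique(b0$read_counts$product), c("P1", "P4"))
  expect_identical(sum(b0$read_counts$reads), 50000L)

  # determinism: identical batches from identical (parameters, seed)
  b1 <- simulate_reaction(lib_a, lib_b, fix_eff(), fix_splint(), 250, 2e4,
                          seed = 7)
  b2 <- simulate_reaction(lib_a, lib_b, fix_eff(), fix_splint(), 250, 2e4,
                          seed = 7)
  expect_identical(b1$read_counts, b2$read_counts)

  # read-count conservation at any depth
  expect_identical(sum(b1$read_counts$reads), 20000L)

  # degenerate input: nothing can ligate
  expect_error(
    simulate_reaction(lib_a, lib_b, fix_eff(), off, 5, 100, seed = 1,
                      k_loop = 0),
    "degenerate"
  )
})

test_that("splinted fractions match calibration targets and the mass-action truth", {
  lib_a <- sample_input_library(fix_freqs(), 5e5, seed = 31)
  lib_b <- sample_input_library(fix_freqs(), 5e5, seed = 32)
  depth <- 1e5
  hi <- simulate_reaction(lib_a, lib_b, fix_eff(), fix_splint(), 250, depth,
                          seed = 41)
  lo <- simulate_reaction(lib_a, lib_b, fix_eff(), fix_splint(), 5, depth,
                          seed = 42)
  obs_hi <- splinted_fraction(batch_count_table(hi, fix_spec()))
  obs_lo <- splinted_fraction(batch_count_table(lo, fix_spec()))

  # recovered fractions match the simulated truth within 3 binomial sd;
  # the statistic observes cross-duplex events only (P2 + P3)
  for (pair in list(list(obs_hi, hi), list(obs_lo, lo))) {
    ev <- pair[[2]]$read_counts
    cross_truth <- sum(ev$events[ev$product %in% c("P2", "P3")]) /
      sum(ev$events)
    sd3 <- 3 * sqrt(cross_truth * (1 - cross_truth) / depth)
    expect_lt(abs(pair[[1]] - cross_truth), sd3)
    # lower-limit property: observed never exceeds the full splinted
    # fraction (same-type splinted events are absorbed into P1/P4)
    expect_lt(pair[[1]], pair[[2]]$true_splinted_fraction + sd3)
  }
  # high concentration sits in the strong-competition regime, low
  # concentration in the weak one
  expect_gt(obs_hi, 0.35)
  expect_lt(obs_lo, 0.08)
})

test_that("expected splinted fraction is monotone in concentration", {
  p <- looplig:::sequence_probabilities(fix_freqs())
  grid <- c(1, 5, 25, 50, 100, 250, 500, 1000)
  vals <- vapply(grid, function(C) {
    expected_splinted_fraction(fix_eff(), p, p, fix_splint(), C)$true
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("FASTQ round-trip recovers every synthetic label", {
  spec <- fix_spec()
  lib_a <- uniform_library(20000L)
  lib_b <- uniform_library(20000L)
  batch <- simulate_reaction(lib_a, lib_b, fix_eff(), fix_splint(), 250,
                             5000, seed = 5)
  fq <- withr::local_tempfile(fileext = ".fastq")
  truth <- write_reads(batch, spec, fq, reaction = "rt")
  tab <- tabulate_reads(fq, spec, max_mismatch = 0, reaction = "rt")
  expect_identical(sum(tab$count), nrow(truth))
  expect_identical(sum(rejections(tab)$n), 0L)

  # table equals the truth histogram exactly
  want <- as.data.frame(table(truth$product_class, truth$overhang),
                        stringsAsFactors = FALSE)
  names(want) <- c("product", "overhang", "count")
  want <- want[want$count > 0, ]
  got <- merge(want, as.data.frame(tab[, c("product", "overhang", "count")]),
               by = c("product", "overhang"), all = TRUE)
  expect_true(all(got$count.x == got$count.y))

  # single-read construction identity
  one <- fix_read(spec, "P1", "UUCG")
  expect_identical(classify_read(one, spec), "P1")
  expect_identical(extract_overhang(one, spec), "UUCG")
})

test_that("empty batches produce a valid empty FASTQ", {
  spec <- fix_spec()
  lib <- uniform_library(25600L)
  batch <- simulate_reaction(lib, lib, fix_eff(), fix_splint(), 5, 10,
                             seed = 2)
  batch$read_counts$reads <- 0L
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads(batch, spec, fq)
  expect_true(file.exists(fq))
  tab <- tabulate_reads(fq, spec)
  expect_identical(nrow(tab), 0L)
})

test_that("mock tetraloop reference is reproducible and enriched", {
  ref1 <- generate_reference(n_entries = 400, seed = 17)
  ref2 <- generate_reference(n_entries = 400, seed = 17)
  expect_identical(ref1, ref2)
  expect_true(all(nchar(ref1$loop) == 4))
  expect_true(all(ref1$frequency >= 1))
  expect_true(all(nchar(ref1$context) >= 30 & nchar(ref1$context) <= 80))

  # enrichment: UNCG/GNRA dominate the top frequency ranks, per the
  # generator's own sampling weights
  ranked <- group_rank(ref1)
  top10 <- ranked[ranked$rank <= 10, ]
  frac_common <- mean(match_pattern(top10$loop, "UNCG") |
                        match_pattern(top10$loop, "GNRA"))
  expect_gt(frac_common, 0.5)

  expect_error(generate_reference(n_entries = 0), "n_entries")

  # duplicate fraction 0: dedup removes nothing
  ref0 <- generate_reference(n_entries = 60, seed = 4, dup_fraction = 0)
  expect_identical(nrow(dedup_reference(ref0)), nrow(ref0))
})
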