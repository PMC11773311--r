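test_that("input frequencies and alpha factors follow the ratio definition", {
  eq <- input_frequencies(uniform_library(25600L))
  expect_equal(eq$f, rep(1 / 256, 256))
  a <- alpha_factors(eq)
  expect_equal(a$alpha, rep(1, 256))          # alpha = 1 at frequency 1/256
  expect_equal(mean(a$alpha), 1)

  # f = 1/128 on half the sequences -> alpha = 2 there
  half <- setNames(rep(c(2L, 0L), each = 128L), all_overhangs())
  expect_warning(d <- input_frequencies(half), "zero")
  expect_error(alpha_factors(d), "undefined")
  d2 <- suppressWarnings(input_frequencies(half, pseudocount = 0))
  expect_equal(d2$f[1], 1 / 128)

  expect_error(input_frequencies(setNames(rep(0L, 256), all_overhangs())),
               "empty")

  # pseudocount removes the zero problem
  d3 <- input_frequencies(half, pseudocount = 0.5)
  expect_true(all(alpha_factors(d3)$alpha > 0))
  expect_equal(sum(d3$f), 1)
})

test_that("normalization cancels input bias and ranks deterministically", {
  f <- looplig:::sequence_probabilities(fix_freqs())
  alpha <- alpha_factors(
    tibble::tibble(overhang = names(f), f = unname(f))
  )
  # counts exactly proportional to alpha -> perfectly flat profile
  counts <- setNames(as.integer(round(alpha$alpha * 1000)), alpha$overhang)
  prof <- normalize_counts(counts, alpha)
  expect_lt(as.numeric(fold_range(prof)), 1.01)
  expect_equal(sum(prof$norm_freq), 1, tolerance = 1e-9)

  # ranks: descending frequency, lexicographic ties, zeros last
  counts2 <- setNames(rep(0L, 256), all_overhangs())
  counts2[c("UUCG", "GAAA", "AAAA")] <- c(100L, 50L, 50L)
  uni <- alpha_factors(input_frequencies(uniform_library()))
  prof2 <- normalize_counts(counts2, uni)
  expect_identical(prof2$rank[prof2$overhang == "UUCG"], 1L)
  expect_identical(prof2$rank[prof2$overhang == "AAAA"], 2L) # tie, lex first
  expect_identical(prof2$rank[prof2$overhang == "GAAA"], 3L)
  expect_identical(min(prof2$rank[prof2$count == 0]), 4L)

  # rank determinism under input reordering
  shuf <- withr::with_seed(1, sample(256))
  prof3 <- normalize_counts(counts2[shuf], uni)
  expect_identical(prof2$rank, prof3$rank)

  expect_error(normalize_counts(setNames(rep(0L, 256), all_overhangs()), uni),
               "zero")
})

test_that("fold range reports max over min nonzero frequency", {
  uni <- alpha_factors(input_frequencies(uniform_library()))
  counts <- setNames(rep(0L, 256), all_overhangs())
  counts[c("UUCG", "AAAA")] <- c(90L, 10L)
  fr <- fold_range(normalize_counts(counts, uni))
  expect_equal(as.numeric(fr), 9)
  expect_identical(attr(fr, "n_zero"), 254L)

  flat <- normalize_counts(setNames(rep(5L, 256), all_overhangs()), uni)
  expect_equal(as.numeric(fold_range(flat)), 1)
})

test_that("positional composition and information content behave like logos", {
  uni <- alpha_factors(input_frequencies(uniform_library()))
  counts <- setNames(rep(0L, 256), all_overhangs())
  counts["UUCG"] <- 100L
  pp <- position_composition(normalize_counts(counts, uni))
  expect_equal(unname(pp$composition["pos1", "U"]), 1)
  expect_equal(pp$information, c(2, 2, 2, 2))

  flat <- normalize_counts(setNames(rep(3L, 256), all_overhangs()), uni)
  ppf <- position_composition(flat)
  expect_equal(unname(ppf$composition), matrix(0.25, 4, 4), tolerance = 1e-12)
  expect_equal(ppf$information, c(0, 0, 0, 0))

  # a sampled input-library profile recovers the printed marginals
  lib <- sample_input_library(fix_freqs(), 2e6, seed = 8)
  ppl <- position_composition(input_frequencies(lib))
  expect_equal(unname(ppl$composition["pos1", c("A", "G", "U", "C")]),
               c(0.33, 0.26, 0.22, 0.19), tolerance = 0.01)
  expect_equal(unname(ppl$composition["pos4", c("C", "A", "G", "U")]),
               c(0.33, 0.28, 0.21, 0.18), tolerance = 0.01)

  # closed forms and invariances
  expect_equal(information_content(rbind(c(A = 0.5, C = 0.5, G = 0, U = 0))), 1)
  perm <- rbind(c(A = 0, C = 0, G = 0.5, U = 0.5))
  expect_equal(information_content(perm), 1)  # relabeling invariance
  expect_error(information_content(rbind(c(A = 0.7, C = 0.7, G = 0, U = 0))),
               "sum")
})

test_that("top-k classification assigns ordered consensus groups", {
  uni <- alpha_factors(input_frequencies(uniform_library()))
  counts <- setNames(rep(1L, 256), all_overhangs())
  counts[c("UUCG", "CAAG", "GAAA", "AAAA")] <- c(500L, 400L, 300L, 200L)
  prof <- normalize_counts(counts, uni)

  all_in <- classify_top_k(prof, "NNNN", 256)
  expect_identical(unname(all_in$group_counts[["NNNN"]]), 256L)
  expect_equal(all_in$top_share, 1)

  none <- classify_top_k(prof, c("UNNG", "CNNG", "GNNA"), 0)
  expect_identical(nrow(none$assignments), 0L)

  top4 <- classify_top_k(prof, c("UNNG", "CNNG", "GNNA"), 4)
  expect_identical(unname(top4$group_counts),
                   c(1L, 1L, 1L, 1L))  # UUCG, CAAG, GAAA, AAAA->other
  expect_identical(top4$assignments$group[top4$assignments$overhang == "AAAA"],
                   "other")

  # brute-force pattern size oracle
  expect_identical(sum(match_pattern(all_overhangs(), "GNRA")), 8L)
  expect_false(match_pattern("UUCG", "RNNY"))
  expect_true(match_pattern("UUCG", "UNNG"))
})

test_that("normalized profiles recover simulated efficiencies", {
  lib_a <- sample_input_library(fix_freqs(), 1e6, seed = 51)
  lib_b <- sample_input_library(fix_freqs(), 1e6, seed = 52)
  control <- sample_input_library(fix_freqs(), 1e6, seed = 53)
  alpha <- alpha_factors(input_frequencies(control, pseudocount = 0.5))
  eff <- resolve_efficiencies(efficiency_model(noise_sd = 0.25, seed = 54))
  batch <- simulate_reaction(lib_a, lib_b, eff, fix_splint(), 5, 1e6,
                             seed = 55)
  tab <- batch_count_table(batch, fix_spec())
  prof <- normalize_counts(tab[tab$product == "P1", ], alpha)
  rho <- spearman_rho(prof$norm_freq, eff)$rho
  expect_gt(rho, 0.9)

  # high-contrast fold range: within 2-fold of the true efficiency ratio
  # (uniform deep library so the rarest products still accumulate events)
  eff0 <- fix_eff()
  ulib <- uniform_library(25600000L)
  b2 <- simulate_reaction(ulib, ulib, eff0, splint_model(conc_scale = 0),
                          5, 1e7, seed = 56)
  t2 <- batch_count_table(b2, fix_spec())
  p2 <- normalize_counts(t2[t2$product == "P1", ],
                         alpha_factors(input_frequencies(uniform_library())))
  fr <- as.numeric(fold_range(p2))
  true_ratio <- max(eff0) / min(eff0)
  expect_gt(fr, true_ratio / 2)
  expect_lt(fr, true_ratio * 2)
})
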