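# Shared fixtures: everything is generated in code at test time.

fix_spec <- function(pair = "C:G") construct_spec(closing_pair = pair)

# Noise-free efficiencies: exactly the consensus-group means.
fix_eff <- function() resolve_efficiencies(efficiency_model(noise_sd = 0))

fix_freqs <- function() position_base_frequencies()

# Uniform 256-category library of n molecules.
uniform_library <- function(n = 256000L) {
  setNames(rep.int(n %/% 256L, 256L), all_overhangs())
}

# A calibrated splint model under the default study conditions, cached
# per test run (calibration is deterministic).
fix_splint <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- setNames(
        as.numeric(sample_input_library(fix_freqs(), 1e6, 1) / 1e6),
        all_overhangs()
      )
      cache <<- calibrate_splint_scale(
        fix_eff(),
        tibble::tibble(overhang = all_overhangs(), f = unname(p)),
        tibble::tibble(overhang = all_overhangs(), f = unname(p))
      )
    }
    cache
  }
})

# Build a read string for a given product/overhang under a spec.
fix_read <- function(spec, product, overhang) {
  paste0(
    spec$handle5,
    spec$donor_tags[[product_donor_chr(product)]],
    overhang,
    spec$acceptor_tags[[product_acceptor_chr(product)]],
    spec$handle3
  )
}
product_donor_chr <- function(p) c(P1 = "A", P2 = "A", P3 = "B", P4 = "B")[[p]]
product_acceptor_chr <- function(p) c(P1 = "a", P2 = "b", P3 = "a", P4 = "b")[[p]]

# Substitute n_sub positions of a sequence deterministically.
substitute_bases <- function(x, positions) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  rot <- c(A = "C", C = "G", G = "U", U = "A")
  chars[positions] <- rot[chars[positions]]
  paste(chars, collapse = "")
}

random_context <- function(n, seed) {
  withr::with_seed(seed, paste(sample(rna_bases(), n, TRUE), collapse = ""))
}
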