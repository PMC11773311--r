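#' Default pipeline configuration
#'
#' One configuration object drives the whole pipeline: simulation,
#' demultiplexing, normalization/profiling, reference overlap, and
#' validation. The seed is mandatory; every stochastic stage derives its
#' seed deterministically from it.
#'
#' @param seed Integer seed (mandatory).
#' @param outdir Output directory for tables and the report (NULL to
#'   skip writing).
#' @param reactions Closing pairs to simulate (subset of
#'   [closing_pairs()]).
#' @param n_molecules Molecules per duplex pool per reaction.
#' @param read_depth Sequencing reads per reaction per concentration.
#' @param control_depth Reads per input-library control.
#' @param concentration_low,concentration_high Duplex concentrations
#'   (nM) for the two regimes.
#' @param top_k Top-ranked set size for consensus classification and
#'   overlap.
#' @param max_mismatch Demultiplexing tag mismatch tolerance.
#' @param pseudocount Pseudocount for input-frequency estimation.
#' @param write_fastq Round-trip reads through FASTQ and the
#'   demultiplexer (TRUE) or tabulate in memory (FALSE).
#' @param noise_sd Lognormal sd of per-sequence efficiencies.
#' @param fallback_efficiency Efficiency of sequences outside the named
#'   consensus groups.
#' @param splint List: `w_gc`, `w_au`, `targets` (named vector of
#'   calibration targets, concentration -> observed splinted fraction).
#' @param k_loop,k_hyd Loop-closing and hydrolysis rate constants.
#' @param reference List: `n_entries`, `dup_fraction` for the mock
#'   biological reference.
#' @param dedup List: `identity`, `coverage` thresholds.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed,
                            outdir = NULL,
                            reactions = closing_pairs(),
                            n_molecules = 1e6,
                            read_depth = 2e5,
                            control_depth = 1e6,
                            concentration_low = 5,
                            concentration_high = 250,
                            top_k = 40L,
                            max_mismatch = 0L,
                            pseudocount = 0,
                            write_fastq = FALSE,
                            noise_sd = 0.25,
                            fallback_efficiency = 0.05,
                            splint = list(w_gc = 3, w_au = 1,
                                          targets = c("250" = 0.44, "5" = 0.03)),
                            k_loop = 1,
                            k_hyd = 4,
                            reference = list(n_entries = 1200L,
                                             dup_fraction = 0.1),
                            dedup = list(identity = 0.9, coverage = 0.7)) {
  cfg <- list(
    seed = seed, outdir = outdir, reactions = reactions,
    n_molecules = n_molecules, read_depth = read_depth,
    control_depth = control_depth, concentration_low = concentration_low,
    concentration_high = concentration_high, top_k = top_k,
    max_mismatch = max_mismatch, pseudocount = pseudocount,
    write_fastq = write_fastq, noise_sd = noise_sd,
    fallback_efficiency = fallback_efficiency, splint = splint,
    k_loop = k_loop, k_hyd = k_hyd, reference = reference, dedup = dedup
  )
  validate_config(cfg)
}

config_schema <- function() {
  list(
    top = c("seed", "outdir", "reactions", "n_molecules", "read_depth",
            "control_depth", "concentration_low", "concentration_high",
            "top_k", "max_mismatch", "pseudocount", "write_fastq",
            "noise_sd", "fallback_efficiency", "splint", "k_loop", "k_hyd",
            "reference", "dedup"),
    splint = c("w_gc", "w_au", "targets"),
    reference = c("n_entries", "dup_fraction"),
    dedup = c("identity", "coverage")
  )
}

#' Validate a pipeline configuration
#'
#' Full schema check with actionable messages: unknown keys are
#' rejected, the seed is mandatory, and numeric fields are range-checked
#' (thresholds in (0, 1], concentrations and depths positive).
#'
#' @param config A named list (e.g. parsed from YAML).
#' @return The validated `pipeline_config` (invisibly usable downstream);
#'   errors name the offending field.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  fail <- function(...) stop("config error: ", ..., call. = FALSE)
  if (!is.list(config)) fail("configuration must be a named list")
  unknown <- setdiff(names(config), schema$top)
  if (length(unknown) > 0) {
    fail("unknown key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- formals(pipeline_config)
  for (key in setdiff(schema$top, c(names(config), "seed"))) {
    config[[key]] <- eval(defaults[[key]])
  }
  if (is.null(config$seed)) fail("'seed' is mandatory")
  if (!is.numeric(config$seed) || length(config$seed) != 1 ||
      config$seed != round(config$seed)) {
    fail("'seed' must be a single integer")
  }
  for (nested in c("splint", "reference", "dedup")) {
    unknown <- setdiff(names(config[[nested]]), schema[[nested]])
    if (length(unknown) > 0) {
      fail("unknown key(s) under '", nested, "': ",
           paste(unknown, collapse = ", "))
    }
    for (key in setdiff(schema[[nested]], names(config[[nested]]))) {
      config[[nested]][[key]] <- eval(defaults[[nested]])[[key]]
    }
  }
  if (is.list(config$splint$targets)) {
    config$splint$targets <- unlist(config$splint$targets)
  }
  bad <- setdiff(config$reactions, closing_pairs())
  if (length(bad) > 0) {
    fail("'reactions' contains unknown closing pair(s): ",
         paste(bad, collapse = ", "))
  }
  pos <- c("n_molecules", "read_depth", "control_depth",
           "concentration_low", "concentration_high", "k_loop", "k_hyd")
  for (key in pos) {
    if (!is.numeric(config[[key]]) || config[[key]] <= 0) {
      fail("'", key, "' must be positive")
    }
  }
  if (config$top_k < 0 || config$top_k > 256) {
    fail("'top_k' must lie in [0, 256]")
  }
  if (config$max_mismatch < 0) fail("'max_mismatch' must be >= 0")
  if (config$pseudocount < 0) fail("'pseudocount' must be >= 0")
  if (config$noise_sd < 0) fail("'noise_sd' must be >= 0")
  for (key in c("identity", "coverage")) {
    v <- config$dedup[[key]]
    if (!is.numeric(v) || v <= 0 || v > 1) {
      fail("'dedup$", key, "' must lie in (0, 1]")
    }
  }
  if (config$reference$n_entries <= 0) {
    fail("'reference$n_entries' must be > 0")
  }
  if (config$reference$dup_fraction < 0 || config$reference$dup_fraction >= 1) {
    fail("'reference$dup_fraction' must lie in [0, 1)")
  }
  structure(config[intersect(schema$top, names(config))],
            class = "pipeline_config")
}

#' Read and validate a YAML pipeline configuration
#'
#' @param path Path to a YAML file of configuration keys (see
#'   [pipeline_config()]); keys not present fall back to the defaults,
#'   unknown keys are rejected.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Write a demo YAML configuration
#'
#' A small-depth, fixed-seed configuration suitable for a quick
#' end-to-end run.
#'
#' @param path Output YAML path.
#' @param seed Seed to record.
#' @return The path, invisibly.
#' @export
write_demo_config <- function(path, seed = 1L) {
  cfg <- pipeline_config(
    seed = seed, reactions = c("C:G", "G:C"), n_molecules = 2e5,
    read_depth = 2e4, control_depth = 2e5, write_fastq = TRUE,
    reference = list(n_entries = 400L, dup_fraction = 0.1)
  )
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Deterministic stage seeds derived from the master seed (kept < 2^31).
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101 + offset) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> demultiplex -> normalize/profile -> reference
#' overlap -> validation in order for every configured reaction, at both
#' the low- and high-concentration regimes, and assembles a run report.
#' All outputs are recomputable from (config, seed); with an `outdir`
#' set, tables (TSV) and the report (JSON) are written atomically.
#'
#' @param config A `pipeline_config` (or plain list; it is validated
#'   first).
#' @return A `run_report` list.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  eff <- resolve_efficiencies(efficiency_model(
    fallback = cfg$fallback_efficiency, noise_sd = cfg$noise_sd,
    seed = stage_seed(cfg$seed, 1)
  ))
  freqs <- position_base_frequencies()
  p_theory <- sequence_probabilities(freqs)
  splint <- calibrate_splint_scale(
    eff, p_theory, p_theory,
    splint = splint_model(cfg$splint$w_gc, cfg$splint$w_au),
    targets = cfg$splint$targets, k_loop = cfg$k_loop, k_hyd = cfg$k_hyd
  )

  # Input-library controls, one per overhang-bearing strand (a and b).
  control_a <- sample_input_library(freqs, cfg$control_depth,
                                    stage_seed(cfg$seed, 2))
  control_b <- sample_input_library(freqs, cfg$control_depth,
                                    stage_seed(cfg$seed, 3))
  dist_a <- input_frequencies(control_a, cfg$pseudocount)
  dist_b <- input_frequencies(control_b, cfg$pseudocount)
  alpha_a <- alpha_factors(dist_a)
  alpha_b <- alpha_factors(dist_b)

  top_patterns <- c("UNNG", "CNNG", "GNNA")
  outdir <- cfg$outdir
  if (cfg$write_fastq && is.null(outdir)) outdir <- tempdir()
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }

  reactions <- list()
  profiles <- list()
  counts_all <- list()
  for (i in seq_along(cfg$reactions)) {
    pair <- cfg$reactions[i]
    spec <- construct_spec(closing_pair = pair)
    rxn_id <- paste0("rxn_", gsub(":", "", pair))
    lib_a <- sample_input_library(freqs, cfg$n_molecules,
                                  stage_seed(cfg$seed, 10 + 4 * i))
    lib_b <- sample_input_library(freqs, cfg$n_molecules,
                                  stage_seed(cfg$seed, 11 + 4 * i))
    run_one <- function(concentration, tag, offset) {
      batch <- simulate_reaction(
        lib_a, lib_b, eff, splint, concentration, cfg$read_depth,
        stage_seed(cfg$seed, offset), k_loop = cfg$k_loop, k_hyd = cfg$k_hyd
      )
      id <- paste0(rxn_id, "_", tag)
      counts <- if (cfg$write_fastq) {
        fq <- file.path(outdir, paste0(id, ".fastq"))
        write_reads(batch, spec, fq, reaction = id)
        tabulate_reads(fq, spec, cfg$max_mismatch, reaction = id)
      } else {
        batch_count_table(batch, spec, reaction = id)
      }
      list(batch = batch, counts = counts)
    }
    lo <- run_one(cfg$concentration_low, "low", 12 + 4 * i)
    hi <- run_one(cfg$concentration_high, "high", 13 + 4 * i)
    counts_all[[pair]] <- dplyr::bind_rows(lo$counts, hi$counts)

    prof_p1 <- normalize_counts(
      lo$counts[lo$counts$product == "P1", , drop = FALSE], alpha_a,
      reaction = paste0(rxn_id, "_low"), product = "P1", closing_pair = pair
    )
    prof_p2 <- normalize_counts(
      hi$counts[hi$counts$product == "P2", , drop = FALSE], alpha_b,
      reaction = paste0(rxn_id, "_high"), product = "P2", closing_pair = pair
    )
    profiles[[paste0(pair, "_P1")]] <- prof_p1
    profiles[[paste0(pair, "_P2")]] <- prof_p2
    top <- classify_top_k(prof_p1, top_patterns, cfg$top_k)
    pos <- position_composition(prof_p1)
    rej <- rejections(lo$counts)
    reactions[[pair]] <- list(
      closing_pair = pair,
      reads_low = sum(lo$counts$count),
      reads_high = sum(hi$counts$count),
      rejected_low = sum(rej$n),
      splinted_fraction_low = splinted_fraction(lo$counts),
      splinted_fraction_high = splinted_fraction(hi$counts),
      true_splinted_low = lo$batch$true_splinted_fraction,
      true_splinted_high = hi$batch$true_splinted_fraction,
      ligated_yield_low = lo$batch$ligated_yield,
      fold_range_p1 = as.numeric(fold_range(prof_p1)),
      information_bits_p1 = pos$information,
      top_group_counts = as.list(top$group_counts),
      top_share = top$top_share
    )
  }

  reference <- generate_reference(
    n_entries = cfg$reference$n_entries,
    seed = stage_seed(cfg$seed, 4),
    dup_fraction = cfg$reference$dup_fraction
  )
  deduped <- dedup_reference(reference, cfg$dedup$identity,
                             cfg$dedup$coverage)
  ranked_ref <- group_rank(deduped)

  overlaps <- list()
  for (pair in cfg$reactions) {
    bio <- ranked_ref$loop[ranked_ref$closing_pair == pair]
    loop_res <- overlap_analysis(
      ranked_sequences(profiles[[paste0(pair, "_P1")]]), bio,
      k = cfg$top_k, N = 256
    )
    splint_res <- overlap_analysis(
      ranked_sequences(profiles[[paste0(pair, "_P2")]]), bio,
      k = cfg$top_k, N = 256
    )
    overlaps[[pair]] <- list(loop = loop_res, splint = splint_res)
  }
  mean_loop_overlap <- mean(vapply(overlaps, function(o) o$loop$k_obs,
                                   numeric(1)))
  mean_splint_overlap <- mean(vapply(overlaps, function(o) o$splint$k_obs,
                                     numeric(1)))

  panel <- validation_panel()
  first_prof <- profiles[[paste0(cfg$reactions[1], "_P1")]]
  panel_in <- panel[panel$overhang %in% first_prof$overhang, , drop = FALSE]
  validation <- list(
    group_mean_yield = list(
      UNCG = group_mean_yield(panel, "UNCG"),
      CNNG = group_mean_yield(panel, "CNNG"),
      GNNA = group_mean_yield(panel, "GNNA"),
      UNNC = group_mean_yield(panel, "UNNC"),
      RNNY = group_mean_yield(panel, "RNNY")
    ),
    uncg_rnny_fold = fold_difference(group_mean_yield(panel, "UNCG"),
                                     group_mean_yield(panel, "RNNY")),
    spearman = unclass(rank_yield_correlation(first_prof, panel_in))
  )

  # Hash and serialize the analysis-relevant configuration: the output
  # location does not change any computed number.
  cfg_content <- unclass(cfg)
  cfg_content$outdir <- NULL
  cfg_json <- jsonlite::toJSON(cfg_content, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  report <- structure(
    list(
      package_version = as.character(packageVersion("looplig")),
      config = cfg_content,
      config_hash = unname(tools::md5sum(tmp)),
      splint_conc_scale = splint$conc_scale,
      expected_overlap = hypergeom_expected(256, cfg$top_k, cfg$top_k),
      reactions = reactions,
      mean_loop_overlap = mean_loop_overlap,
      mean_splint_overlap = mean_splint_overlap,
      overlaps = overlaps,
      validation = validation,
      reference_entries = nrow(reference),
      reference_after_dedup = nrow(deduped)
    ),
    class = "run_report"
  )
  unlink(tmp)
  if (!is.null(cfg$outdir)) {
    write_report(report, profiles, counts_all, ranked_ref, cfg$outdir)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", length(x$reactions), " reaction(s); mean top-",
      x$config$top_k, " loop overlap ", signif(x$mean_loop_overlap, 3),
      " (expected ", signif(x$expected_overlap, 4), ")\n", sep = "")
  invisible(x)
}

# Serialize report + tables; each file is written to a temp path in the
# same directory and renamed into place.
write_report <- function(report, profiles, counts_all, ranked_ref, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  atomically <- function(name, writer) {
    final <- file.path(outdir, name)
    tmp <- file.path(outdir, paste0(".tmp_", name))
    writer(tmp)
    file.rename(tmp, final)
  }
  atomically("report.json", function(p) {
    jsonlite::write_json(strip_classes(report), p, auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
  })
  prof_tbl <- dplyr::bind_rows(lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    tibble::tibble(profile = nm, reaction = attr(p, "reaction"),
                   product = attr(p, "product"),
                   closing_pair = attr(p, "closing_pair"),
                   p[, c("overhang", "count", "alpha", "norm_freq",
                         "raw_freq", "rank", "raw_rank")])
  }))
  atomically("profiles.tsv", function(p) {
    write.table(prof_tbl, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  atomically("product_counts.tsv", function(p) {
    write.table(dplyr::bind_rows(counts_all), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  atomically("reference_ranked.tsv", function(p) {
    write.table(ranked_ref, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  invisible(outdir)
}

# Recursively drop S3 classes so jsonlite serializes plain structures.
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}
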