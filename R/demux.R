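new_product_count_table <- function(tbl, rejections) {
  structure(
    tibble::as_tibble(tbl),
    rejections = rejections,
    class = c("product_count_table", class(tibble::tibble()))
  )
}

empty_rejections <- function() {
  tibble::tibble(
    reason = c("no_donor_tag", "no_acceptor_tag", "ambiguous", "bad_overhang"),
    n = 0L
  )
}

#' Rejection tallies of a count table
#'
#' @param table A `product_count_table`.
#' @return Tibble of rejection reasons and counts.
#' @export
rejections <- function(table) {
  attr(table, "rejections") %||% empty_rejections()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalize raw read strings to the internal RNA alphabet.
to_rna <- function(seqs) chartr("T", "U", toupper(seqs))

#' Classify reads into junction products P1-P4
#'
#' The donor-side tag (A vs B) and acceptor-side tag (a vs b) are each
#' matched at their fixed windows within `max_mismatch` Hamming distance;
#' the (donor, acceptor) pair maps to P1 (A-a), P2 (A-b), P3 (B-a),
#' P4 (B-b). A read matching both tags of a side is `ambiguous`; a read
#' matching neither is `no_donor_tag` / `no_acceptor_tag`; a classified
#' read whose overhang window contains a character outside `{A,C,G,U}`
#' (after T -> U mapping) or runs past the read end is `bad_overhang`.
#'
#' @param seqs Character vector of read sequences (RNA or DNA alphabet).
#' @param spec A [construct_spec()]; its tag pairs must be separated by
#'   Hamming distance greater than `2 * max_mismatch`, otherwise a
#'   configuration error is raised.
#' @param max_mismatch Maximum per-tag Hamming distance (default 0).
#' @return Tibble with columns `product` (NA when rejected), `reason`
#'   (NA when classified), and `overhang`.
#' @export
classify_reads <- function(seqs, spec, max_mismatch = 0L) {
  stopifnot(inherits(spec, "construct_spec"), max_mismatch >= 0)
  if (spec$donor_tag_distance <= 2 * max_mismatch ||
      spec$acceptor_tag_distance <= 2 * max_mismatch) {
    stop("configuration error: strand tags are not distinguishable at ",
         "Hamming distance > 2 * max_mismatch")
  }
  seqs <- to_rna(seqs)
  side <- function(window, tags) {
    win <- substring(seqs, window[["start"]], window[["end"]])
    mm <- vapply(tags, function(t) mismatch_count(win, t),
                 numeric(length(seqs)))
    mm <- matrix(mm, ncol = length(tags))
    hit <- mm <= max_mismatch
    call <- rep(NA_character_, length(seqs))
    nhit <- rowSums(hit)
    call[nhit == 1] <- names(tags)[apply(hit[nhit == 1, , drop = FALSE], 1,
                                         which)]
    list(call = call, ambiguous = nhit > 1)
  }
  donor <- side(spec$donor_window, spec$donor_tags)
  acceptor <- side(spec$acceptor_window, spec$acceptor_tags)
  overhang <- substring(seqs, spec$overhang_window[["start"]],
                        spec$overhang_window[["end"]])
  good_ovh <- grepl("^[ACGU]{4}$", overhang)

  reason <- rep(NA_character_, length(seqs))
  reason[!good_ovh] <- "bad_overhang"
  reason[is.na(acceptor$call) & !acceptor$ambiguous] <- "no_acceptor_tag"
  reason[is.na(donor$call) & !donor$ambiguous] <- "no_donor_tag"
  reason[donor$ambiguous | acceptor$ambiguous] <- "ambiguous"

  product <- rep(NA_character_, length(seqs))
  ok <- is.na(reason)
  key <- paste0(donor$call[ok], acceptor$call[ok])
  product[ok] <- c(Aa = "P1", Ab = "P2", Ba = "P3", Bb = "P4")[key]
  overhang[!is.na(reason)] <- NA_character_
  tibble::tibble(product = product, reason = reason, overhang = overhang)
}

#' Classify a single read
#'
#' @inheritParams classify_reads
#' @param seq One read sequence.
#' @return The product class (`"P1"`..`"P4"`) or the rejection reason.
#' @export
classify_read <- function(seq, spec, max_mismatch = 0L) {
  stopifnot(length(seq) == 1L)
  r <- classify_reads(seq, spec, max_mismatch)
  if (is.na(r$product[1])) r$reason[1] else r$product[1]
}

#' Extract the randomized overhang from a read
#'
#' Returns the 4-mer at the construct's overhang window (1-based,
#' inclusive), with T mapped to U. Reads shorter than the window or with
#' characters outside `{A,C,G,U}` yield `NA` (rejection reason
#' `bad_overhang`).
#'
#' @param seqs Character vector of read sequences.
#' @param spec A [construct_spec()].
#' @return Character vector of overhangs (NA where invalid).
#' @export
extract_overhang <- function(seqs, spec) {
  stopifnot(inherits(spec, "construct_spec"))
  ovh <- substring(to_rna(seqs), spec$overhang_window[["start"]],
                   spec$overhang_window[["end"]])
  ovh[!grepl("^[ACGU]{4}$", ovh)] <- NA_character_
  ovh
}

# Read sequences from a FASTQ/FASTA file (gzip allowed) as characters.
read_seqs <- function(path) {
  fmt <- if (grepl("\\.(fa|fasta)(\\.gz)?$", path, ignore.case = TRUE)) {
    "fasta"
  } else {
    "fastq"
  }
  as.character(Biostrings::readBStringSet(path, format = fmt))
}

#' Tabulate product reads into a count table
#'
#' One pass over a read stream: classify each read into P1-P4, extract
#' its overhang, and tally counts by (reaction, closing pair, product,
#' overhang); rejected reads are tallied by reason. Classification is
#' deterministic and order-independent.
#'
#' @param reads Character vector of read sequences, or a path to a
#'   FASTQ/FASTA file (optionally gzipped).
#' @param spec A [construct_spec()].
#' @param max_mismatch Maximum per-tag Hamming distance (default 0).
#' @param reaction Reaction identifier recorded in the table.
#' @return A `product_count_table` tibble with columns reaction,
#'   closing_pair, product, overhang, count; rejection tallies are
#'   available via [rejections()].
#' @export
tabulate_reads <- function(reads, spec, max_mismatch = 0L,
                           reaction = "reaction1") {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_seqs(reads)
  }
  if (length(reads) == 0) {
    return(new_product_count_table(
      tibble::tibble(reaction = character(0), closing_pair = character(0),
                     product = character(0), overhang = character(0),
                     count = integer(0)),
      rejections = empty_rejections()
    ))
  }
  cls <- classify_reads(reads, spec, max_mismatch)
  rej <- empty_rejections()
  tallied <- table(cls$reason)
  v <- as.numeric(tallied[rej$reason])
  v[is.na(v)] <- 0
  rej$n <- as.integer(v)
  keep <- !is.na(cls$product)
  tab <- dplyr::count(cls[keep, c("product", "overhang")],
                      .data$product, .data$overhang, name = "count")
  out <- tibble::tibble(
    reaction = reaction, closing_pair = spec$closing_pair,
    product = tab$product, overhang = tab$overhang,
    count = as.integer(tab$count)
  )
  new_product_count_table(out, rejections = rej)
}

#' Splinted-ligation contribution statistic
#'
#' The fraction (P2 + P3) / (P1 + P2 + P3 + P4) of classified reads,
#' summed over all overhangs within each reaction. Because same-type
#' nicked-duplex events also produce P1 and P4, this statistic is a
#' lower limit on the true splinted contribution to the ligated pool.
#'
#' @param table A `product_count_table`.
#' @return Named numeric vector of fractions, one per reaction (a bare
#'   scalar when the table holds a single reaction).
#' @export
splinted_fraction <- function(table) {
  stopifnot(all(c("reaction", "product", "count") %in% names(table)))
  by_rxn <- split(table, table$reaction)
  out <- vapply(by_rxn, function(t) {
    tot <- sum(t$count)
    if (tot == 0) stop("splinted fraction undefined: zero classified reads")
    sum(t$count[t$product %in% c("P2", "P3")]) / tot
  }, numeric(1))
  if (length(out) == 1L) unname(out) else out
}
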