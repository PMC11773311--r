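#' Construct layout for the four-strand ligation assay
#'
#' Describes how a sequenced ligation product is laid out: a 5' handle,
#' a 12-nt strand-tagged stem segment identifying the donor strand
#' (A or B), the randomized 4-nt overhang that became the loop (or the
#' splint junction), a 12-nt strand-tagged segment identifying the
#' acceptor strand (a or b), and a 3' handle. The donor/acceptor tag
#' combination identifies the junction product: P1 (A-a), P2 (A-b),
#' P3 (B-a), P4 (B-b); P2 and P3 can only arise from splinted
#' (nicked-duplex) ligation.
#'
#' The default handle/stem/tag sequences are invented plumbing chosen to
#' be mutually distinguishable; demultiplexing depends only on this spec,
#' never on any particular laboratory oligo set.
#'
#' @param closing_pair One of the six allowed closing base pairs,
#'   see [closing_pairs()].
#' @param handle5,handle3 Constant handle sequences (RNA alphabet).
#' @param donor_tags Named character vector `c(A=, B=)` of equal-length
#'   stem tags identifying the donor strand.
#' @param acceptor_tags Named character vector `c(a=, b=)` of equal-length
#'   stem tags identifying the acceptor strand (the strand contributing
#'   the overhang).
#' @return An object of class `construct_spec` with 1-based inclusive
#'   coordinates for the donor tag, overhang, and acceptor tag windows.
#' @export
construct_spec <- function(closing_pair = "C:G",
                           handle5 = "ACGUGCUA",
                           handle3 = "UAGCACGU",
                           donor_tags = c(A = "GGACUCGUACCG", B = "CCUGAGCAUGGC"),
                           acceptor_tags = c(a = "AGCCGUUAGGCA", b = "UCGGACAAUUGG")) {
  if (!closing_pair %in% closing_pairs()) {
    stop("closing_pair must be one of: ", paste(closing_pairs(), collapse = ", "))
  }
  chk_rna <- function(x, what) {
    if (any(!grepl("^[ACGU]+$", x))) stop(what, " must be over {A,C,G,U}")
  }
  stopifnot(
    identical(sort(names(donor_tags)), c("A", "B")),
    identical(sort(names(acceptor_tags)), c("a", "b"))
  )
  chk_rna(c(handle5, handle3), "handles")
  chk_rna(donor_tags, "donor_tags")
  chk_rna(acceptor_tags, "acceptor_tags")
  if (nchar(donor_tags[["A"]]) != nchar(donor_tags[["B"]])) {
    stop("donor tags must have equal length")
  }
  if (nchar(acceptor_tags[["a"]]) != nchar(acceptor_tags[["b"]])) {
    stop("acceptor tags must have equal length")
  }
  if (donor_tags[["A"]] == donor_tags[["B"]] ||
      acceptor_tags[["a"]] == acceptor_tags[["b"]]) {
    stop("strand tags must be pairwise distinct")
  }
  dlen <- nchar(donor_tags[["A"]])
  alen <- nchar(acceptor_tags[["a"]])
  h5 <- nchar(handle5)
  spec <- list(
    closing_pair = closing_pair,
    handle5 = handle5,
    handle3 = handle3,
    donor_tags = donor_tags,
    acceptor_tags = acceptor_tags,
    donor_window = c(start = h5 + 1L, end = h5 + dlen),
    overhang_window = c(start = h5 + dlen + 1L, end = h5 + dlen + 4L),
    acceptor_window = c(start = h5 + dlen + 5L, end = h5 + dlen + 4L + alen),
    read_length = h5 + dlen + 4L + alen + nchar(handle3),
    donor_tag_distance = hamming(donor_tags[["A"]], donor_tags[["B"]]),
    acceptor_tag_distance = hamming(acceptor_tags[["a"]], acceptor_tags[["b"]])
  )
  structure(spec, class = "construct_spec")
}

#' @export
print.construct_spec <- function(x, ...) {
  cat("<construct_spec> closing pair ", x$closing_pair,
      "; read length ", x$read_length, " nt\n",
      "  overhang window: ", x$overhang_window[["start"]], "-",
      x$overhang_window[["end"]], " (1-based, inclusive)\n", sep = "")
  invisible(x)
}

# Product class bookkeeping: donor strand and acceptor strand per class.
product_classes <- function() c("P1", "P2", "P3", "P4")
product_donor <- function(product) c(P1 = "A", P2 = "A", P3 = "B", P4 = "B")[product]
product_acceptor <- function(product) c(P1 = "a", P2 = "b", P3 = "a", P4 = "b")[product]
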