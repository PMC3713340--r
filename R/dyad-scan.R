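#' @useDynLib beldyad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The four literal core words. A plus-strand core means the window itself reads
# TGAC (or its extended form TTGAC); a minus-strand core means the window reads
# GTCA (or GTCAA), i.e. the TGAC core sits on the opposite strand.
.CORE_PLUS  <- "TGAC"
.CORE_MINUS <- "GTCA"

#' Find TGAC-core motifs on both strands of a sequence
#'
#' Locates every maximal occurrence of the BEL1/KNOX-type core motif in a
#' nucleotide sequence, on both strands. On the plus strand the core reads
#' \code{TGAC}, extended to the 5-mer \code{TTGAC} when the preceding base is a
#' T; on the minus strand the window reads \code{GTCA}, extended to
#' \code{GTCAA} when the following base is an A. A 4-mer hit is never reported
#' when its 5-mer extension is present (hits are maximal). Matching is
#' case-insensitive; ambiguity codes (N etc.) never match.
#'
#' @param sequence A single nucleotide string (or anything coercible via
#'   \code{as.character}, e.g. a \code{DNAString}).
#' @return A data frame with one row per core hit, sorted by \code{start}:
#'   \describe{
#'     \item{start, end}{1-based inclusive coordinates within the sequence.}
#'     \item{length}{4 or 5.}
#'     \item{strand}{\code{"+"} or \code{"-"}.}
#'     \item{text}{the matched substring, upper-cased (one of TGAC, TTGAC,
#'       GTCA, GTCAA).}
#'   }
#'   The scanned sequence is attached as \code{attr(, "sequence")} so that
#'   \code{\link{pair_cores}} can recover linker text.
#' @examples
#' find_cores("TGACTTGAC")    # a 4-mer core abutting an extended 5-mer core
#' find_cores("AAAACCCC")     # no cores
#' @seealso \code{\link{pair_cores}}, \code{\link{scan_sequences}}
#' @export
find_cores <- function(sequence) {
  seq <- toupper(as.character(sequence))
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      strand = character(), text = character(),
                      stringsAsFactors = FALSE)
  if (is.na(seq) || n < 4L) {
    attr(empty, "sequence") <- seq
    return(empty)
  }

  hit_rows <- function(pattern, strand) {
    m <- gregexpr(pattern, seq, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) return(empty[, 1:5])
    pos <- as.integer(m)
    if (strand == "+") {
      # extend to TTGAC when preceded by T
      ext <- pos > 1L & substring(seq, pos - 1L, pos - 1L) == "T"
      start <- ifelse(ext, pos - 1L, pos)
      len <- ifelse(ext, 5L, 4L)
      text <- ifelse(ext, "TTGAC", "TGAC")
    } else {
      # extend to GTCAA when followed by A
      ext <- (pos + 4L) <= n & substring(seq, pos + 4L, pos + 4L) == "A"
      start <- pos
      len <- ifelse(ext, 5L, 4L)
      text <- ifelse(ext, "GTCAA", "GTCA")
    }
    data.frame(start = as.integer(start), end = as.integer(start + len - 1L),
               length = as.integer(len), strand = strand, text = text,
               stringsAsFactors = FALSE)
  }

  hits <- rbind(hit_rows(.CORE_PLUS, "+"), hit_rows(.CORE_MINUS, "-"))
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "sequence") <- seq
  hits
}

#' Classify the relative orientation of two cores
#'
#' A core is drawn as an arrow pointing 5'->3' along the strand that reads
#' TGAC: a plus-strand core has its tail at its left end and its head at its
#' right end, a minus-strand core the reverse. The orientation label reads the
#' outermost ends of the two arrows left to right, giving the four classes
#' head-to-head (HtH), head-to-tail (HtT), tail-to-head (TtH) and tail-to-tail
#' (TtT).
#'
#' @param left_strand,right_strand Strand of the left and right core of each
#'   dyad, \code{"+"} or \code{"-"} (vectorised, recycled).
#' @return Character vector of orientation labels: \code{(+,+) -> "TtH"},
#'   \code{(+,-) -> "TtT"}, \code{(-,+) -> "HtH"}, \code{(-,-) -> "HtT"}.
#' @examples
#' classify_orientation("-", "+")  # HtH, e.g. GTCAAtgcTTGAC
#' classify_orientation("+", "+")  # TtH, e.g. TTGACcttaTTGAC
#' @export
classify_orientation <- function(left_strand, right_strand) {
  stopifnot(all(left_strand %in% c("+", "-")), all(right_strand %in% c("+", "-")))
  key <- paste0(left_strand, right_strand)
  map <- c("++" = "TtH", "+-" = "TtT", "-+" = "HtH", "--" = "HtT")
  unname(map[key])
}

#' Pair cores into tandem dyad elements
#'
#' Forms dyad elements from the core hits of one sequence: ordered pairs of
#' distinct cores whose linker (the nucleotides strictly between the end of the
#' left core and the start of the right core) is at most \code{max_linker} nt
#' long. Because maximal cores can never overlap, the linker length is always
#' non-negative; abutting cores have linker 0. By default all qualifying pairs
#' are reported (a window with three cores can hold three dyads);
#' \code{adjacent_only = TRUE} restricts pairing to consecutive cores.
#'
#' @param cores A core-hit data frame from \code{\link{find_cores}}.
#' @param max_linker Maximum linker length in nt (default 24, the longest
#'   linker among the published potato elements).
#' @param adjacent_only Only pair consecutive cores? Default \code{FALSE}.
#' @param sequence The scanned sequence; defaults to the attribute stored by
#'   \code{find_cores} and is used to recover linker and element text.
#' @return A data frame with one row per dyad: left/right core coordinates,
#'   strands and texts, \code{linker_length}, \code{linker_text},
#'   \code{element} (substring from left core start to right core end) and
#'   \code{orientation}.
#' @examples
#' pair_cores(find_cores("TGACTTGAC"))          # one dyad, linker 0, TtH
#' pair_cores(find_cores("TTGACaaGTCA"))        # one dyad, linker 2, TtT
#' @export
pair_cores <- function(cores, max_linker = 24L, adjacent_only = FALSE,
                       sequence = attr(cores, "sequence")) {
  stopifnot(is.data.frame(cores), max_linker >= 0L)
  empty <- data.frame(left_start = integer(), left_end = integer(),
                      left_strand = character(), left_text = character(),
                      right_start = integer(), right_end = integer(),
                      right_strand = character(), right_text = character(),
                      linker_length = integer(), linker_text = character(),
                      element = character(), orientation = character(),
                      stringsAsFactors = FALSE)
  n <- nrow(cores)
  if (n < 2L) return(empty)
  cores <- cores[order(cores$start), , drop = FALSE]
  idx <- utils::combn(n, 2L)
  if (adjacent_only) idx <- idx[, idx[2L, ] - idx[1L, ] == 1L, drop = FALSE]
  if (ncol(idx) == 0L) return(empty)
  i <- idx[1L, ]; j <- idx[2L, ]
  linker <- cores$start[j] - cores$end[i] - 1L
  keep <- linker >= 0L & linker <= max_linker
  if (!any(keep)) return(empty)
  i <- i[keep]; j <- j[keep]; linker <- linker[keep]
  has_seq <- !is.null(sequence) && !is.na(sequence)
  linker_text <- if (has_seq) {
    ifelse(linker > 0L,
           substring(sequence, cores$end[i] + 1L, cores$start[j] - 1L), "")
  } else NA_character_
  element <- if (has_seq) {
    substring(sequence, cores$start[i], cores$end[j])
  } else NA_character_
  out <- data.frame(
    left_start = cores$start[i], left_end = cores$end[i],
    left_strand = cores$strand[i], left_text = cores$text[i],
    right_start = cores$start[j], right_end = cores$end[j],
    right_strand = cores$strand[j], right_text = cores$text[j],
    linker_length = as.integer(linker), linker_text = linker_text,
    element = element,
    orientation = classify_orientation(cores$strand[i], cores$strand[j]),
    stringsAsFactors = FALSE)
  out <- out[order(out$left_start, out$right_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan an upstream region for tandem dyad elements
#'
#' Runs \code{\link{find_cores}} and \code{\link{pair_cores}} on one upstream
#' window and attaches the distance-upstream of each dyad. The distance is the
#' 1-based position of the dyad's 5'-most base counted from the right
#' (anchor-proximal) end of the window, so a dyad whose element begins 820 nt
#' before the anchor has \code{distance_upstream = 820}. Set
#' \code{distance_to = "3prime"} to measure to the element's 3'-most base
#' instead (sensitivity analysis).
#'
#' @param region One upstream region: either a one-row data frame as returned
#'   by \code{\link{extract_upstream}} (columns \code{gene_id},
#'   \code{sequence}) or a single named/unnamed character string.
#' @param max_linker,adjacent_only Passed to \code{\link{pair_cores}}.
#' @param max_distance Optional cap: dyads whose \code{distance_upstream}
#'   exceeds it are dropped.
#' @param distance_to Measure distance to the element's \code{"5prime"}
#'   (default) or \code{"3prime"} end.
#' @return A dyad data frame (see \code{\link{pair_cores}}) with additional
#'   columns \code{gene_id} and \code{distance_upstream}.
#' @export
scan_region <- function(region, max_linker = 24L, max_distance = NULL,
                        adjacent_only = FALSE,
                        distance_to = c("5prime", "3prime")) {
  distance_to <- match.arg(distance_to)
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L, all(c("gene_id", "sequence") %in% names(region)))
    gene_id <- region$gene_id
    seq <- region$sequence
  } else {
    gene_id <- if (!is.null(names(region))) names(region)[1L] else NA_character_
    seq <- unname(as.character(region))
    stopifnot(length(seq) == 1L)
  }
  dyads <- pair_cores(find_cores(seq), max_linker = max_linker,
                      adjacent_only = adjacent_only)
  L <- nchar(seq)
  dist <- if (distance_to == "5prime") L - dyads$left_start + 1L
          else L - dyads$right_end + 1L
  dyads$gene_id <- rep(gene_id, nrow(dyads))
  dyads$distance_upstream <- as.integer(dist)
  if (!is.null(max_distance)) {
    dyads <- dyads[dyads$distance_upstream <= max_distance, , drop = FALSE]
    rownames(dyads) <- NULL
  }
  dyads
}

#' Scan a collection of sequences for tandem dyad elements
#'
#' Convenience wrapper applying \code{\link{scan_region}} to each element of a
#' named character vector, \code{DNAStringSet}, or upstream-region data frame.
#'
#' @param x Named character vector, \code{Biostrings::DNAStringSet}, or a data
#'   frame with columns \code{gene_id} and \code{sequence}.
#' @inheritParams scan_region
#' @return A single dyad data frame with a \code{gene_id} column (zero rows if
#'   nothing is found).
#' @examples
#' scan_sequences(c(geneA = "TTGACcttaTTGAC", geneB = "ACGTACGT"))
#' @export
scan_sequences <- function(x, max_linker = 24L, max_distance = NULL,
                           adjacent_only = FALSE,
                           distance_to = c("5prime", "3prime")) {
  distance_to <- match.arg(distance_to)
  if (methods::is(x, "XStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("gene_id", "sequence") %in% names(x)))
    x <- stats::setNames(x$sequence, x$gene_id)
  }
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  out <- lapply(seq_along(x), function(i) {
    scan_region(stats::setNames(x[[i]], names(x)[i]), max_linker = max_linker,
                max_distance = max_distance, adjacent_only = adjacent_only,
                distance_to = distance_to)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write dyads as TSV, BED6 or GFF3
#'
#' \code{write_dyads_tsv} writes the dyad table as-is. \code{write_dyads_bed}
#' writes window-relative BED6 (0-based half-open, name = orientation,
#' score = linker length, strand = \code{"."} since a dyad spans both strands).
#' \code{write_dyads_gff3} writes genome-relative GFF3 when the dyads were
#' obtained from regions carrying source coordinates.
#'
#' @param dyads A dyad data frame from \code{\link{scan_sequences}} /
#'   \code{\link{scan_region}}.
#' @param path Output file path.
#' @param regions For \code{write_dyads_gff3}: the upstream-region data frame
#'   (from \code{\link{extract_upstream}}) supplying \code{source_contig},
#'   \code{source_start}, \code{source_end} and \code{source_strand} per gene.
#' @return The path, invisibly.
#' @export
write_dyads_tsv <- function(dyads, path) {
  utils::write.table(dyads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dyads_tsv
#' @export
write_dyads_bed <- function(dyads, path) {
  bed <- data.frame(chrom = ifelse(is.na(dyads$gene_id), ".", dyads$gene_id),
                    start = dyads$left_start - 1L,     # 0-based half-open
                    end = dyads$right_end,
                    name = dyads$orientation,
                    score = dyads$linker_length,
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dyads_tsv
#' @export
write_dyads_gff3 <- function(dyads, regions, path) {
  stopifnot(all(c("gene_id", "source_contig", "source_start", "source_end",
                  "source_strand") %in% names(regions)))
  m <- match(dyads$gene_id, regions$gene_id)
  if (anyNA(m)) stop("dyads refer to gene ids absent from `regions`")
  reg <- regions[m, , drop = FALSE]
  # window position p (1-based, 5'->3' in gene orientation) -> genome coordinate
  plus <- reg$source_strand == "+"
  gstart <- ifelse(plus, reg$source_start + dyads$left_start - 1L,
                         reg$source_end - dyads$right_end + 1L)
  gend   <- ifelse(plus, reg$source_start + dyads$right_end - 1L,
                         reg$source_end - dyads$left_start + 1L)
  gr <- GenomicRanges::GRanges(
    seqnames = reg$source_contig,
    ranges = IRanges::IRanges(start = gstart, end = gend),
    strand = "*",
    source = "beldyad", type = "nucleotide_motif",
    ID = sprintf("%s_dyad%02d", dyads$gene_id, stats::ave(gstart, dyads$gene_id,
                                                          FUN = seq_along)),
    orientation = dyads$orientation,
    linker_length = dyads$linker_length)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
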