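#' Load a genome FASTA with random access
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} that rejects
#' duplicate record ids (record names are truncated at the first whitespace,
#' the usual FASTA convention).
#'
#' @param fasta Path to a FASTA file, or an existing \code{DNAStringSet}.
#' @return A named \code{DNAStringSet}.
#' @export
load_genome <- function(fasta) {
  genome <- if (methods::is(fasta, "DNAStringSet")) fasta
            else Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate record ids in FASTA: ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  genome
}

#' Fetch a subsequence by contig and 1-based inclusive coordinates
#'
#' @param genome A \code{DNAStringSet} from \code{\link{load_genome}}.
#' @param contig Contig (record) id.
#' @param start,end 1-based inclusive coordinates; fetching beyond the record
#'   boundaries is an error.
#' @return A single character string.
#' @export
fetch_subseq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) stop("no such contig: ", contig)
  n <- length(genome[[contig]])
  if (start < 1L || end > n || start > end)
    stop(sprintf("coordinates [%d, %d] outside contig %s (1..%d)",
                 start, end, contig, n))
  as.character(Biostrings::subseq(genome[[contig]], start, end))
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 via \code{rtracklayer} and reduces it to one row per gene:
#' contig, strand, gene span, and the CDS span (union of CDS segments linked
#' to the gene directly or through its transcripts). The \code{ID} attribute
#' is used as the gene id.
#'
#' @param gff3 Path to a GFF3 file, or a \code{GRanges} as returned by
#'   \code{rtracklayer::import}.
#' @return A data frame: \code{gene_id}, \code{contig}, \code{strand},
#'   \code{gene_start}, \code{gene_end}, \code{cds_start}, \code{cds_end}
#'   (NA when the gene has no CDS).
#' @export
read_gene_models <- function(gff3) {
  gr <- if (methods::is(gff3, "GRanges")) gff3
        else rtracklayer::import(gff3, format = "GFF3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) stop("no gene features in GFF3")
  gene_ids <- as.character(genes$ID)
  if (anyNA(gene_ids)) stop("gene features must carry an ID attribute")

  # map every feature to its owning gene id by walking Parent links
  id2gene <- stats::setNames(gene_ids, gene_ids)
  parent_of <- function(x) {
    p <- x$Parent
    vapply(as.list(p), function(v) if (length(v)) v[[1L]] else NA_character_,
           character(1))
  }
  if (!is.null(gr$Parent)) {
    mrna <- gr[type %in% c("mRNA", "transcript")]
    if (length(mrna) > 0L) {
      mp <- parent_of(mrna)
      known <- !is.na(mp) & mp %in% names(id2gene)
      id2gene <- c(id2gene,
                   stats::setNames(id2gene[mp[known]],
                                   as.character(mrna$ID)[known]))
    }
  }
  cds <- gr[type == "CDS"]
  cds_gene <- if (length(cds) > 0L && !is.null(cds$Parent)) {
    cp <- parent_of(cds)
    unname(id2gene[cp])
  } else character(0)

  out <- data.frame(
    gene_id = gene_ids,
    contig = as.character(GenomicRanges::seqnames(genes)),
    strand = as.character(GenomicRanges::strand(genes)),
    gene_start = GenomicRanges::start(genes),
    gene_end = GenomicRanges::end(genes),
    cds_start = NA_integer_, cds_end = NA_integer_,
    stringsAsFactors = FALSE)
  if (length(cds) > 0L) {
    for (i in seq_len(nrow(out))) {
      k <- which(cds_gene == out$gene_id[i])
      if (length(k) > 0L) {
        out$cds_start[i] <- min(GenomicRanges::start(cds)[k])
        out$cds_end[i] <- max(GenomicRanges::end(cds)[k])
      }
    }
  }
  out
}

#' Extract strand-aware upstream windows
#'
#' For each gene, extracts the \code{window_length} bases 5' of the anchor, in
#' gene orientation: for plus-strand genes the bases left of the anchor as-is,
#' for minus-strand genes the bases right of the anchor, reverse-complemented.
#' The returned sequence is written 5'->3' in gene orientation, so its
#' rightmost base is the base immediately before the anchor, and "nt upstream"
#' equals the window position counted from the right, 1-based (the convention
#' \code{\link{scan_region}} uses for \code{distance_upstream}).
#'
#' Anchors: \code{TSS} is the 5' end of the gene feature; \code{AUG} is the
#' 5' end of the CDS in gene orientation. A gene without a CDS is an error
#' under \code{anchor = "AUG"}. Windows truncated at a contig edge are
#' returned shorter, with a warning.
#'
#' @param genome A \code{DNAStringSet} from \code{\link{load_genome}}.
#' @param gene_models Data frame from \code{\link{read_gene_models}} (or any
#'   data frame with those columns).
#' @param anchor \code{"TSS"} or \code{"AUG"}.
#' @param window_length Window length in nt (default 2000).
#' @return A data frame with one row per gene: \code{gene_id},
#'   \code{anchor_kind}, \code{window_length}, \code{sequence},
#'   \code{source_contig}, \code{source_start}, \code{source_end} (1-based
#'   inclusive genomic coordinates of the window), \code{source_strand}.
#' @export
extract_upstream <- function(genome, gene_models, anchor = c("TSS", "AUG"),
                             window_length = 2000) {
  anchor <- match.arg(anchor)
  stopifnot(window_length >= 1)
  gm <- gene_models
  rows <- lapply(seq_len(nrow(gm)), function(i) {
    g <- gm[i, ]
    if (!g$strand %in% c("+", "-"))
      stop("gene ", g$gene_id, " has no usable strand")
    if (anchor == "AUG" && (is.na(g$cds_start) || is.na(g$cds_end)))
      stop("gene ", g$gene_id, " has no CDS; cannot anchor at AUG")
    clen <- length(genome[[g$contig]])
    if (g$strand == "+") {
      a <- if (anchor == "TSS") g$gene_start else g$cds_start
      start <- a - window_length
      end <- a - 1L
      if (start < 1L) {
        warning("window for gene ", g$gene_id, " truncated at contig start")
        start <- 1L
      }
      if (end < 1L) return(NULL)
      seq <- fetch_subseq(genome, g$contig, start, end)
    } else {
      a <- if (anchor == "TSS") g$gene_end else g$cds_end
      start <- a + 1L
      end <- a + window_length
      if (end > clen) {
        warning("window for gene ", g$gene_id, " truncated at contig end")
        end <- clen
      }
      if (start > clen) return(NULL)
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(fetch_subseq(genome, g$contig, start, end))))
    }
    data.frame(gene_id = g$gene_id, anchor_kind = anchor,
               window_length = as.integer(window_length), sequence = seq,
               source_contig = g$contig, source_start = as.integer(start),
               source_end = as.integer(end), source_strand = g$strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write extracted windows as FASTA and metadata as TSV
#'
#' @param regions Data frame from \code{\link{extract_upstream}}.
#' @param fasta Output FASTA path (one record per gene, id = gene id).
#' @param metadata_tsv Optional TSV of the window metadata (everything except
#'   the sequence).
#' @return \code{fasta}, invisibly.
#' @export
write_upstream_regions <- function(regions, fasta, metadata_tsv = NULL) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(regions$sequence, regions$gene_id)),
    fasta)
  if (!is.null(metadata_tsv))
    utils::write.table(regions[, setdiff(names(regions), "sequence")],
                       metadata_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fasta)
}
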