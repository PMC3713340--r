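# Seed handling: every generator takes an explicit `seed`; the global RNG state
# is saved and restored so package calls never perturb a user's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

.base_probs <- function(gc_fraction) {
  stopifnot(is.numeric(gc_fraction), gc_fraction >= 0, gc_fraction <= 1)
  c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
    G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
}

.forbidden_positions <- function(seq) {
  # 1-based start positions of TGAC or GTCA on the plus-strand string.
  # Forbidding these two 4-mers forbids cores on both strands, since a
  # minus-strand core appears on the plus string as the reverse complement.
  pos <- integer(0)
  for (pat in c("TGAC", "GTCA")) {
    m <- gregexpr(pat, seq, fixed = TRUE)[[1L]]
    if (m[1L] != -1L) pos <- c(pos, as.integer(m))
  }
  sort(pos)
}

#' Generate a core-free random background sequence
#'
#' Draws an i.i.d. nucleotide sequence of the requested length and base
#' composition that is guaranteed to contain no TGAC core on either strand:
#' neither \code{TGAC} nor \code{GTCA} occurs as a substring. Cleanliness is
#' obtained by rejection: any window matching a forbidden 4-mer is redrawn
#' until the sequence is clean. Deterministic for a fixed seed.
#'
#' @param length Sequence length in nt (>= 1).
#' @param gc_fraction G+C fraction in [0, 1]; bases are drawn i.i.d. with
#'   P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2. Default 0.5.
#' @param seed Integer seed (optional; the caller's RNG state is preserved).
#' @return A single upper-case nucleotide string.
#' @examples
#' bg <- generate_corefree_background(200, gc_fraction = 0.36, seed = 7)
#' grepl("TGAC|GTCA", bg)  # FALSE
#' @export
generate_corefree_background <- function(length, gc_fraction = 0.5, seed = NULL) {
  stopifnot(length >= 1)
  probs <- .base_probs(gc_fraction)
  bases <- names(probs)
  with_seed(seed, {
    x <- sample(bases, length, replace = TRUE, prob = probs)
    repeat {
      seq <- paste(x, collapse = "")
      bad <- .forbidden_positions(seq)
      if (length(bad) == 0L) break
      for (p in bad) {
        idx <- p:min(p + 3L, length)
        x[idx] <- sample(bases, length(idx), replace = TRUE, prob = probs)
      }
    }
    seq
  })
}

#' Specify an element to embed in a synthetic promoter window
#'
#' @param gene_id Gene identifier (one window per gene).
#' @param element The dyad element string, embedded verbatim (case preserved;
#'   published elements print cores upper-case and linkers lower-case). Must
#'   contain at least two cores.
#' @param distance_upstream Distance in nt from the element's 5'-most base to
#'   the anchor end of the window (1-based, so an element at distance d ends
#'   d - nchar(element) + 1 nt upstream). Must be >= nchar(element).
#' @param anchor \code{"AUG"} or \code{"TSS"}; metadata recorded in the truth
#'   table.
#' @return A one-row data frame (rows can be \code{rbind}-ed into a plan set).
#' @export
embed_plan <- function(gene_id, element, distance_upstream, anchor = c("AUG", "TSS")) {
  anchor <- match.arg(anchor)
  stopifnot(is.character(gene_id), is.character(element),
            distance_upstream >= nchar(element))
  if (nrow(find_cores(element)) < 2L)
    stop("element must contain at least two TGAC cores: ", element)
  data.frame(gene_id = gene_id, element = element,
             distance_upstream = as.integer(distance_upstream),
             anchor = anchor, stringsAsFactors = FALSE)
}

#' Build a synthetic promoter set with embedded dyad elements
#'
#' Generates one core-free background window per gene and splices the planned
#' elements in by replacement (window length is preserved, so planned
#' distances are exact), each element placed with its 5'-most base exactly
#' \code{distance_upstream} nt from the anchor (right) end of the window.
#' After splicing, each window is re-scanned: if a splice junction created an
#' incidental core (or extended a planned one), the background is redrawn and
#' splicing repeated, so the scanner recovers exactly the planned dyads.
#'
#' @param plans A plan data frame (\code{rbind} of \code{\link{embed_plan}}
#'   rows), or \code{NULL} for an all-background set.
#' @param genes Gene ids to generate; defaults to the genes in \code{plans}.
#'   Genes without a plan get pure background.
#' @param window_length Window length in nt (default 2000; every
#'   \code{distance_upstream} must fit).
#' @param gc_fraction Background base composition (see
#'   \code{\link{generate_corefree_background}}).
#' @param seed Integer seed.
#' @return An object of class \code{"promoter_set"}: a list with
#'   \code{$sequences} (named character vector of windows, one per gene),
#'   \code{$truth} (data frame gene_id, element, distance_upstream, anchor)
#'   and \code{$window_length}.
#' @examples
#' ps <- build_promoter_set(
#'   embed_plan("StBEL5", "GTCAAtgcTTGAC", 820, "TSS"),
#'   window_length = 1000, seed = 1)
#' scan_sequences(ps$sequences)$distance_upstream  # 820
#' @export
build_promoter_set <- function(plans = NULL, genes = NULL, window_length = 2000,
                               gc_fraction = 0.5, seed = NULL) {
  if (is.null(plans)) {
    plans <- data.frame(gene_id = character(), element = character(),
                        distance_upstream = integer(), anchor = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "element", "distance_upstream", "anchor")
                %in% names(plans)))
  window_length <- as.integer(window_length)
  if (is.null(genes)) genes <- unique(plans$gene_id)
  if (length(genes) == 0L) genes <- character(0)
  if (nrow(plans) > 0L && any(plans$distance_upstream > window_length))
    stop("a planned distance_upstream exceeds window_length")

  with_seed(seed, {
    seqs <- vapply(genes, function(g) {
      gp <- plans[plans$gene_id == g, , drop = FALSE]
      if (nrow(gp) == 0L)
        return(generate_corefree_background(window_length, gc_fraction))
      # window position of each element: [start, end], 1-based
      el_start <- window_length - gp$distance_upstream + 1L
      el_end <- el_start + nchar(gp$element) - 1L
      o <- order(el_start)
      if (nrow(gp) > 1L && any(el_start[o][-1L] <= el_end[o][-nrow(gp)]))
        stop("embedded elements overlap in gene ", g)
      # expected maximal cores = cores of each element, offset into the window
      expected <- do.call(rbind, lapply(seq_len(nrow(gp)), function(k) {
        h <- find_cores(gp$element[k])
        h$start <- h$start + el_start[k] - 1L
        h[, c("start", "length", "strand")]
      }))
      expected <- expected[order(expected$start), , drop = FALSE]
      for (attempt in 1:100) {
        bg <- generate_corefree_background(window_length, gc_fraction)
        win <- bg
        for (k in seq_len(nrow(gp))) {
          win <- paste0(substring(win, 1L, el_start[k] - 1L), gp$element[k],
                        substring(win, el_end[k] + 1L, window_length))
        }
        got <- find_cores(win)[, c("start", "length", "strand")]
        rownames(got) <- rownames(expected) <- NULL
        if (identical(got, expected)) return(win)
      }
      stop("could not build a junction-clean window for gene ", g) # nocov
    }, character(1))
    truth <- plans[order(match(plans$gene_id, genes), plans$distance_upstream),
                   , drop = FALSE]
    rownames(truth) <- NULL
    structure(list(sequences = seqs, truth = truth,
                   window_length = as.integer(window_length)),
              class = "promoter_set")
  })
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d windows of %d nt, %d embedded element(s)\n",
              length(x$sequences), x$window_length, nrow(x$truth)))
  invisible(x)
}

#' Write a promoter set to FASTA (+ truth TSV, + companion GFF3)
#'
#' The optional companion GFF3 holds one gene feature per window (the whole
#' window, strand +, \code{ID} = gene id) so the windows can be fed through
#' the upstream-extraction interface end to end.
#'
#' @param x A \code{promoter_set}.
#' @param fasta,truth_tsv,gff3 Output paths (\code{truth_tsv}/\code{gff3}
#'   optional).
#' @return \code{fasta}, invisibly.
#' @export
write_promoter_set <- function(x, fasta, truth_tsv = NULL, gff3 = NULL) {
  stopifnot(inherits(x, "promoter_set"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$sequences), fasta)
  if (!is.null(truth_tsv))
    utils::write.table(x$truth, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(gff3)) {
    gr <- GenomicRanges::GRanges(
      seqnames = names(x$sequences),
      ranges = IRanges::IRanges(1L, nchar(x$sequences)),
      strand = "+", source = "beldyad", type = "gene",
      ID = names(x$sequences))
    rtracklayer::export(gr, gff3, format = "GFF3")
  }
  invisible(fasta)
}

#' Build a synthetic genome + gene models around a promoter set
#'
#' Assembles one contig per gene: the upstream window followed by a core-free
#' gene body, with the whole contig reverse-complemented for minus-strand
#' genes. Gene, mRNA and CDS features share one span whose 5' end is the
#' anchor, so extraction with either anchor (TSS or AUG) and
#' \code{window_length} recovers exactly the generated windows. Used to
#' exercise the FASTA/GFF3 extraction path end to end.
#'
#' @inheritParams build_promoter_set
#' @param strand Per-gene strand, recycled (default alternates \code{"+"} /
#'   \code{"-"}).
#' @param gene_length Length of the core-free gene body in nt (default 300).
#' @return A list: \code{$genome} (named character vector, one contig per
#'   gene, contig \code{<gene>_contig}), \code{$features} (a
#'   \code{GenomicRanges::GRanges} of gene/mRNA/CDS rows), \code{$windows}
#'   (the underlying \code{promoter_set}).
#' @export
build_synthetic_genome <- function(plans = NULL, genes = NULL,
                                   window_length = 2000, gc_fraction = 0.5,
                                   seed = NULL, strand = c("+", "-"),
                                   gene_length = 300) {
  ps <- build_promoter_set(plans, genes = genes, window_length = window_length,
                           gc_fraction = gc_fraction, seed = seed)
  genes <- names(ps$sequences)
  strand <- rep_len(strand, length(genes))
  seed2 <- if (is.null(seed)) NULL else seed + 1L
  bodies <- with_seed(seed2, vapply(seq_along(genes), function(i)
    generate_corefree_background(gene_length, gc_fraction), character(1)))
  contigs <- character(length(genes))
  gstart <- gend <- integer(length(genes))
  for (i in seq_along(genes)) {
    segment <- paste0(ps$sequences[[i]], bodies[[i]])
    if (strand[i] == "+") {
      contigs[i] <- segment
      gstart[i] <- window_length + 1L
      gend[i] <- window_length + gene_length
    } else {
      contigs[i] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(segment)))
      gstart[i] <- 1L
      gend[i] <- gene_length
    }
  }
  names(contigs) <- paste0(genes, "_contig")
  ids <- unlist(lapply(genes, function(g)
    c(g, paste0(g, ".t1"), paste0(g, ".t1.cds"))))
  parents <- unlist(lapply(genes, function(g)
    list(character(0), g, paste0(g, ".t1"))), recursive = FALSE)
  feat <- GenomicRanges::GRanges(
    seqnames = rep(names(contigs), each = 3L),
    ranges = IRanges::IRanges(rep(gstart, each = 3L), rep(gend, each = 3L)),
    strand = rep(strand, each = 3L),
    source = "beldyad",
    type = rep(c("gene", "mRNA", "CDS"), length(genes)),
    phase = rep(c(NA_integer_, NA_integer_, 0L), length(genes)),
    ID = ids,
    Parent = IRanges::CharacterList(parents))
  list(genome = contigs, features = feat, windows = ps)
}

#' Write a synthetic genome as FASTA + GFF3
#'
#' @param x Result of \code{\link{build_synthetic_genome}}.
#' @param fasta,gff3 Output paths.
#' @return \code{fasta}, invisibly.
#' @export
write_synthetic_genome <- function(x, fasta, gff3) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$genome), fasta)
  rtracklayer::export(x$features, gff3, format = "GFF3")
  invisible(fasta)
}

#' Specify a simulated qPCR experiment
#'
#' The simulation inverts the comparative-threshold-cycle (Livak) measurement
#' model: per replicate, target Ct = baseline - log2(expression) + Gaussian
#' noise, with expression 1 in the control (WT) condition and the true fold
#' change in the treatment condition; the reference (normalizer) gene Ct is
#' independent of condition.
#'
#' @param genes Character vector of target gene ids.
#' @param fold_change True linear fold changes (recycled along \code{genes});
#'   must be positive. The WT condition has fold change 1 by construction.
#' @param n_replicates Replicates per gene and condition (>= 2 for a t-test;
#'   >= 1 accepted).
#' @param ct_noise_sd Gaussian Ct noise standard deviation in cycles (>= 0),
#'   applied independently to target and reference wells.
#' @param reference_gene Name of the normalizer transcript (metadata only).
#' @param seed Integer seed.
#' @param baseline_ct,reference_ct Mean control-condition Ct of target and
#'   reference wells (cycles).
#' @return A list of class \code{"qpcr_sim_spec"}.
#' @export
qpcr_sim_spec <- function(genes, fold_change, n_replicates = 3,
                          ct_noise_sd = 0.3, reference_gene = "actin",
                          seed = NULL, baseline_ct = 25, reference_ct = 20) {
  fold_change <- rep_len(fold_change, length(genes))
  if (any(!is.finite(fold_change) | fold_change <= 0))
    stop("true fold changes must be positive and finite")
  stopifnot(n_replicates >= 1, ct_noise_sd >= 0)
  structure(list(genes = genes, fold_change = fold_change,
                 n_replicates = as.integer(n_replicates),
                 ct_noise_sd = ct_noise_sd, reference_gene = reference_gene,
                 seed = seed, baseline_ct = baseline_ct,
                 reference_ct = reference_ct),
            class = "qpcr_sim_spec")
}

#' Simulate a replicate Ct table
#'
#' @param spec A \code{\link{qpcr_sim_spec}}.
#' @return A data frame with one row per gene x condition x replicate:
#'   \code{gene}, \code{condition} (\code{"WT"} or \code{"transgenic"}),
#'   \code{replicate}, \code{target_ct}, \code{reference_ct}. With
#'   \code{ct_noise_sd = 0} the downstream 2^-ddCt estimate recovers the true
#'   fold change exactly.
#' @examples
#' ct <- simulate_ct_table(qpcr_sim_spec("g1", 2, ct_noise_sd = 0, seed = 1))
#' fold_change(ct, "g1")$fold_change  # exactly 2
#' @export
simulate_ct_table <- function(spec) {
  stopifnot(inherits(spec, "qpcr_sim_spec"))
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      condition = c("WT", "transgenic"),
                      gene = spec$genes, stringsAsFactors = FALSE)
  fc <- spec$fold_change[match(grid$gene, spec$genes)]
  expr <- ifelse(grid$condition == "transgenic", fc, 1)
  with_seed(spec$seed, {
    n <- nrow(grid)
    target_ct <- spec$baseline_ct - log2(expr) +
      stats::rnorm(n, 0, spec$ct_noise_sd)
    reference_ct <- spec$reference_ct + stats::rnorm(n, 0, spec$ct_noise_sd)
    data.frame(gene = grid$gene, condition = grid$condition,
               replicate = grid$replicate, target_ct = target_ct,
               reference_ct = reference_ct, stringsAsFactors = FALSE)
  })
}
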