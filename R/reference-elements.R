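.read_extdata <- function(file) {
  utils::read.table(system.file("extdata", file, package = "beldyad",
                                mustWork = TRUE),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", quote = "")
}

#' Published tandem TGAC elements upstream of StBEL5 target genes
#'
#' The curated set of tandem TGAC-core cis-elements reported in the upstream
#' sequences of potato StBEL5/POTH1 target genes (hormone-pathway genes such
#' as the PIN, YUCCA1, LAX, GA2ox, IPT, ARF and MADS-box genes, plus the
#' StBEL5 autoregulatory element itself), transcribed verbatim from the
#' published survey. Element strings print cores upper-case and linkers
#' lower-case; genes with two reported elements occupy two rows
#' (\code{n_reported} = 2). One row (StGA2ox1) is annotated as a double
#' palindromic motif whose element count is ambiguous in the source
#' annotation.
#'
#' @return A data frame: \code{gene}, \code{element}, \code{n_reported},
#'   \code{orientation} (published label), \code{distance_nt} (nt upstream of
#'   the anchor to the element's 5'-most base), \code{anchor} (TSS or AUG),
#'   \code{note}.
#' @examples
#' els <- bel5_target_elements()
#' scan_sequences(stats::setNames(els$element, els$gene))
#' @export
bel5_target_elements <- function() .read_extdata("bel5_target_elements.tsv")

#' Tandem TGAC element survey of the potato AUX/IAA gene family
#'
#' All 27 non-redundant potato AUX/IAA genes with, where present, the tandem
#' TGAC element found in their upstream sequence (14 of the 27 carry one),
#' plus the StBEL5 autoregulatory element for reference
#' (\code{gene_family = "BEL1-like"}). The \code{induction_assay} column
#' marks the genes whose root induction was assayed: four motif-bearing genes
#' scored as induced and two motif-free genes as uninduced (the negative
#' controls). One element (index 27) was published with its 20-nt linker
#' sequence unstated; it is represented here with a run of 20 N placeholders
#' (\code{linker_unspecified = TRUE}) -- N never matches a core, so the dyad
#' and its linker length are still recovered by the scanner.
#'
#' @return A data frame: \code{iaa_index}, \code{ortholog}, \code{gene_id},
#'   \code{element} (NA for motif-free genes), \code{orientation},
#'   \code{distance_from_aug}, \code{linker_unspecified},
#'   \code{induction_assay} (\code{"induced"}, \code{"uninduced"} or NA),
#'   \code{gene_family}.
#' @export
aux_iaa_elements <- function() {
  x <- .read_extdata("aux_iaa_elements.tsv")
  x$linker_unspecified <- as.logical(x$linker_unspecified)
  x
}

#' Gel-shift (EMSA) probe oligonucleotides
#'
#' The published double-stranded gel-shift probes for four dyad-bearing
#' target promoters (sense and antisense strands of each), used here as
#' scanner inputs only: the probes for YUCCA1c, IPT, StPIN1 and StPIN2 carry
#' the corresponding promoter elements, and the IPT probe genuinely contains
#' three cores (hence three dyads under all-pairs pairing).
#'
#' @return A data frame: \code{name}, \code{target}, \code{sequence}.
#' @examples
#' oligos <- gelshift_oligos()
#' scan_sequences(stats::setNames(oligos$sequence, oligos$name))
#' @export
gelshift_oligos <- function() .read_extdata("gelshift_oligos.tsv")
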