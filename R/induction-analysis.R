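#' Read a replicate Ct table from delimited text
#'
#' Expects columns \code{gene}, \code{condition}, \code{replicate},
#' \code{target_ct}, \code{reference_ct} (extra columns pass through). The
#' delimiter is sniffed from the first line (tab or comma).
#'
#' @param path Path to a TSV or CSV file.
#' @return A data frame.
#' @export
read_ct_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  ct <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("gene", "condition", "replicate", "target_ct", "reference_ct")
  missing <- setdiff(required, names(ct))
  if (length(missing) > 0L)
    stop("Ct table lacks columns: ", paste(missing, collapse = ", "))
  if (!all(is.finite(ct$target_ct)) || !all(is.finite(ct$reference_ct)))
    stop("Ct values must be finite")
  ct
}

.p_stars <- function(p) {
  ifelse(is.na(p), 0L,
         ifelse(p < 0.001, 3L, ifelse(p < 0.01, 2L, ifelse(p < 0.05, 1L, 0L))))
}

#' Comparative-threshold-cycle (2^-ddCt) fold change for one gene
#'
#' Implements the Livak relative-quantification method: per replicate,
#' \eqn{\Delta Ct} = target Ct - reference Ct; \eqn{\Delta\Delta Ct} = mean
#' \eqn{\Delta Ct}(treatment) - mean \eqn{\Delta Ct}(control); fold change =
#' \eqn{2^{-\Delta\Delta Ct}} (control = 1). Significance is a two-sided
#' two-sample Student's t-test on the per-replicate \eqn{\Delta Ct} values
#' (equal variances by default; set \code{var_equal = FALSE} for the Welch
#' variant). The \eqn{\Delta Ct} scale is used for testing because Ct
#' differences, not linear ratios, are approximately Gaussian under the
#' measurement model. Stars follow the 0.05 / 0.01 / 0.001 convention.
#'
#' An optional amplification-efficiency correction replaces base 2 with
#' \code{1 + efficiency} (an efficiency of 1 is a perfectly doubling primer
#' pair; published primer efficiencies are typically 0.97-1.10).
#'
#' @param ct A Ct table (see \code{\link{read_ct_table}} /
#'   \code{\link{simulate_ct_table}}).
#' @param gene Gene id, present in both conditions.
#' @param control,treatment Condition labels (defaults \code{"WT"} and
#'   \code{"transgenic"}).
#' @param var_equal Use the equal-variance Student's t-test (default) or
#'   Welch's.
#' @param efficiency Amplification efficiency E; fold change =
#'   \code{(1 + E)^-ddCt}. Default 1 (the standard 2^-ddCt).
#' @param conf_level Confidence level for the fold-change interval.
#' @return A one-row data frame: \code{gene}, \code{n_control},
#'   \code{n_treatment}, \code{delta_delta_ct}, \code{fold_change},
#'   \code{log2_fold_change}, \code{ci_lower}, \code{ci_upper},
#'   \code{p_value}, \code{stars}. With a single replicate in either
#'   condition the fold change is still computed but \code{p_value},
#'   \code{ci_lower} and \code{ci_upper} are \code{NA}.
#' @examples
#' ct <- simulate_ct_table(qpcr_sim_spec("g1", 2, ct_noise_sd = 0, seed = 1))
#' fold_change(ct, "g1")
#' @export
fold_change <- function(ct, gene, control = "WT", treatment = "transgenic",
                        var_equal = TRUE, efficiency = 1, conf_level = 0.95) {
  stopifnot(efficiency > 0)
  rows <- ct[ct$gene == gene, , drop = FALSE]
  dct_c <- rows$target_ct[rows$condition == control] -
    rows$reference_ct[rows$condition == control]
  dct_t <- rows$target_ct[rows$condition == treatment] -
    rows$reference_ct[rows$condition == treatment]
  if (length(dct_c) == 0L || length(dct_t) == 0L)
    stop("gene ", gene, " is not present in both conditions")
  ddct <- mean(dct_t) - mean(dct_c)
  base <- 1 + efficiency
  fc <- base^(-ddct)
  p <- ci <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (length(dct_c) >= 2L && length(dct_t) >= 2L &&
      (stats::sd(dct_c) > 0 || stats::sd(dct_t) > 0)) {
    tt <- stats::t.test(dct_t, dct_c, var.equal = var_equal,
                        conf.level = conf_level)
    p <- tt$p.value
    ci <- base^(-rev(tt$conf.int))       # invert: lower ddCt = higher FC
  }
  data.frame(gene = gene,
             n_control = length(dct_c), n_treatment = length(dct_t),
             delta_delta_ct = ddct, fold_change = fc,
             log2_fold_change = -ddct * log2(base),
             ci_lower = ci[1L], ci_upper = ci[2L],
             p_value = p, stars = .p_stars(p),
             stringsAsFactors = FALSE)
}

#' Fold changes for all genes in a Ct table
#'
#' @inheritParams fold_change
#' @param genes Genes to analyse (default: all genes in the table).
#' @return A data frame with one \code{\link{fold_change}} row per gene.
#' @export
fold_changes <- function(ct, genes = unique(ct$gene), ...) {
  out <- do.call(rbind, lapply(genes, function(g) fold_change(ct, g, ...)))
  rownames(out) <- NULL
  out
}

#' Correlation between dyad linker length and induction level
#'
#' Spearman rank correlation of per-gene fold changes against dyad linker
#' lengths, used to ask whether longer linkers go with weaker induction (a
#' negative rho).
#'
#' @param results A fold-change data frame (columns \code{gene},
#'   \code{fold_change}), e.g. from \code{\link{fold_changes}}.
#' @param linkers Named integer vector (names = gene ids) or a data frame
#'   with columns \code{gene_id}/\code{gene} and \code{linker_length}.
#' @return A list: \code{rho}, \code{p_value}, \code{n} (genes used). With
#'   fewer than 3 genes carrying both values this is an error; with constant
#'   fold changes or constant linkers the correlation is undefined and
#'   \code{rho}/\code{p_value} are returned as \code{NA}.
#' @examples
#' res <- data.frame(gene = c("a", "b", "c", "d"), fold_change = c(8, 6, 4, 2))
#' linker_induction_correlation(res, c(a = 0, b = 1, c = 4, d = 12))  # rho -1
#' @export
linker_induction_correlation <- function(results, linkers) {
  if (is.data.frame(linkers)) {
    gene_col <- if ("gene_id" %in% names(linkers)) "gene_id" else "gene"
    linkers <- stats::setNames(linkers$linker_length, linkers[[gene_col]])
  }
  common <- intersect(results$gene, names(linkers))
  fc <- results$fold_change[match(common, results$gene)]
  lk <- as.numeric(linkers[common])
  keep <- is.finite(fc) & is.finite(lk)
  fc <- fc[keep]; lk <- lk[keep]
  if (length(fc) < 3L)
    stop("need at least 3 genes with both a fold change and a linker length")
  if (stats::sd(fc) == 0 || stats::sd(lk) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(fc)))
  }
  ct <- suppressWarnings(
    stats::cor.test(fc, lk, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(fc))
}

#' Join dyad-scan output with induction results
#'
#' Per-gene table combining motif presence (dyad count, shortest linker,
#' orientations) with the fold-change analysis. Genes present in the
#' induction results but absent from the scan are reported as
#' \code{motif_present = FALSE} -- the expected negative-control pattern is
#' that such genes show no induction. Scan genes with no induction result are
#' kept with NA fold changes; a warning notes ids that did not join.
#'
#' @param dyads Dyad data frame from \code{\link{scan_sequences}} (may have
#'   zero rows).
#' @param results Fold-change data frame from \code{\link{fold_changes}}.
#' @return A data frame: \code{gene}, \code{motif_present}, \code{n_dyads},
#'   \code{min_linker}, \code{orientations}, \code{fold_change},
#'   \code{p_value}, \code{stars}.
#' @export
induction_report <- function(dyads, results) {
  if (nrow(dyads) > 0L) {
    summ <- do.call(rbind, lapply(split(dyads, dyads$gene_id), function(d) {
      data.frame(gene = d$gene_id[1L], n_dyads = nrow(d),
                 min_linker = min(d$linker_length),
                 orientations = paste(sort(unique(d$orientation)),
                                      collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  } else {
    summ <- data.frame(gene = character(), n_dyads = integer(),
                       min_linker = integer(), orientations = character(),
                       stringsAsFactors = FALSE)
  }
  only_scan <- setdiff(summ$gene, results$gene)
  if (length(only_scan) > 0L)
    warning("scanned genes with no induction result: ",
            paste(only_scan, collapse = ", "))
  out <- merge(summ, results[, intersect(c("gene", "fold_change", "p_value",
                                           "stars"), names(results))],
               by = "gene", all = TRUE)
  out$motif_present <- !is.na(out$n_dyads)
  out$n_dyads[is.na(out$n_dyads)] <- 0L
  out <- out[, c("gene", "motif_present", "n_dyads", "min_linker",
                 "orientations", "fold_change", "p_value", "stars")]
  out[order(out$gene), , drop = FALSE]
}
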