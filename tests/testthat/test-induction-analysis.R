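make_ct <- function(gene, dct_wt, dct_tg, ref = 20) {
  n <- length(dct_wt)
  m <- length(dct_tg)
  data.frame(gene = gene,
             condition = c(rep("WT", n), rep("transgenic", m)),
             replicate = c(seq_len(n), seq_len(m)),
             target_ct = ref + c(dct_wt, dct_tg),
             reference_ct = ref)
}

test_that("fold change follows the 2^-ddCt closed form", {
  # identical dCt in both conditions -> fold change 1
  ct <- make_ct("g", c(3, 3, 3), c(3, 3, 3))
  expect_equal(fold_change(ct, "g")$fold_change, 1)

  # ddCt = -1 -> fold change 2
  ct <- make_ct("g", c(3, 3, 3), c(2, 2, 2))
  r <- fold_change(ct, "g")
  expect_equal(r$delta_delta_ct, -1)
  expect_equal(r$fold_change, 2)
  expect_equal(r$log2_fold_change, 1)

  # replicate-mean form equals the ratio form on noiseless data
  ct <- make_ct("g", c(4, 4), c(1.5, 1.5))
  expect_equal(fold_change(ct, "g")$fold_change, 2^(4 - 1.5))

  # efficiency-adjusted mode changes the base
  ct <- make_ct("g", c(3, 3), c(2, 2))
  expect_equal(fold_change(ct, "g", efficiency = 0.9)$fold_change, 1.9^1)

  expect_error(fold_change(make_ct("g", 1, 1), "missing"), "both conditions")
})

test_that("single replicates give a fold change but no p-value", {
  ct <- make_ct("g", 3, 2)
  r <- fold_change(ct, "g")
  expect_equal(r$fold_change, 2)
  expect_true(is.na(r$p_value))
  expect_equal(r$stars, 0L)
})

test_that("stars are consistent with the p-value thresholds", {
  set.seed(71)
  for (i in 1:50) {
    ct <- simulate_ct_table(qpcr_sim_spec("g", sample(c(1, 2, 8), 1),
                                          n_replicates = 3,
                                          ct_noise_sd = 0.3, seed = i))
    r <- fold_change(ct, "g")
    want <- if (r$p_value < 0.001) 3L else if (r$p_value < 0.01) 2L
            else if (r$p_value < 0.05) 1L else 0L
    expect_equal(r$stars, want)
  }
})

test_that("a null comparison is centred on fold change 1", {
  # WT-vs-WT style: true fold change 1, estimate should be unbiased on the
  # log scale
  l2fc <- vapply(1:300, function(s) {
    ct <- simulate_ct_table(qpcr_sim_spec("g", 1, n_replicates = 3,
                                          ct_noise_sd = 0.3, seed = 1000 + s))
    fold_change(ct, "g")$log2_fold_change
  }, numeric(1))
  se <- stats::sd(l2fc) / sqrt(length(l2fc))
  expect_lt(abs(mean(l2fc)), 3 * se)
})

test_that("fold-change recovery error matches the measurement model", {
  # With per-well Ct noise sd s and n replicates, ddCt_hat - ddCt is
  # Normal(0, sigma^2) with sigma = s * 2 / sqrt(n): each dCt has variance
  # 2 s^2 and each condition mean 2 s^2 / n. The median absolute relative
  # error of the linear fold change is therefore around
  # 2^(sigma * qnorm(0.75)) - 1; the simulation must land near that
  # prediction, not at an arbitrary hard-coded bound.
  s <- 0.3; n <- 3
  sigma <- s * 2 / sqrt(n)
  are <- vapply(1:400, function(k) {
    ct <- simulate_ct_table(qpcr_sim_spec("g", 5, n_replicates = n,
                                          ct_noise_sd = s, seed = 2000 + k))
    abs(fold_change(ct, "g")$fold_change - 5) / 5
  }, numeric(1))
  med <- stats::median(are)
  upper <- 2^(sigma * stats::qnorm(0.75)) - 1
  lower <- 1 - 2^(-sigma * stats::qnorm(0.75))
  expect_lt(med, upper * 1.25)
  expect_gt(med, lower * 0.75)
})

test_that("Spearman correlation reports the linker-induction rank pattern", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    fold_change = c(8, 6, 4, 2))
  linkers <- c(a = 0, b = 1, c = 4, d = 12)
  out <- linker_induction_correlation(res, linkers)
  expect_equal(out$rho, -1)
  expect_equal(out$n, 4L)

  res$fold_change <- c(2, 4, 6, 8)
  expect_equal(linker_induction_correlation(res, linkers)$rho, 1)

  res$fold_change <- rep(3, 4)
  expect_warning(out <- linker_induction_correlation(res, linkers),
                 "constant")
  expect_true(is.na(out$rho))

  expect_error(linker_induction_correlation(res[1:2, ], linkers), "at least 3")

  # data-frame linker input
  res$fold_change <- c(8, 6, 4, 2)
  ldf <- data.frame(gene_id = names(linkers), linker_length = linkers)
  expect_equal(linker_induction_correlation(res, ldf)$rho, -1)
})

test_that("the induction sign is recovered reliably from noisy replicates", {
  genes <- c("a", "b", "c", "d")
  linkers <- c(a = 0, b = 1, c = 4, d = 12)
  ok <- vapply(1:300, function(s) {
    ct <- simulate_ct_table(qpcr_sim_spec(genes, c(8, 6, 4, 2),
                                          n_replicates = 3,
                                          ct_noise_sd = 0.3,
                                          seed = 3000 + s))
    linker_induction_correlation(fold_changes(ct), linkers)$rho < 0
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("induction reports flag motif-absent genes", {
  dyads <- scan_sequences(c(g1 = "TGACTTGAC", g2 = "AATTGACxxGTCAATT"))
  ct <- simulate_ct_table(qpcr_sim_spec(c("g1", "g2", "g3", "g4"),
                                        c(6, 4, 1, 1), ct_noise_sd = 0,
                                        seed = 1))
  rep <- induction_report(dyads, fold_changes(ct))
  expect_equal(rep$motif_present[rep$gene %in% c("g1", "g2")], c(TRUE, TRUE))
  expect_equal(rep$motif_present[rep$gene %in% c("g3", "g4")], c(FALSE, FALSE))
  expect_equal(rep$n_dyads[rep$gene == "g3"], 0L)

  # empty scan output -> motif absent for every gene
  empty <- scan_sequences(c(z = "ACGTACGT"))
  rep2 <- induction_report(empty, fold_changes(ct))
  expect_true(all(!rep2$motif_present))

  # ids that do not join are kept and warned about
  expect_warning(induction_report(dyads, fold_changes(ct)[3:4, ]),
                 "no induction result")
})

test_that("Ct tables round-trip through delimited text", {
  ct <- simulate_ct_table(qpcr_sim_spec(c("g1", "g2"), c(2, 5), seed = 4))
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(ct, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_ct_table(tsv)
  expect_equal(back$target_ct, ct$target_ct)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(ct, csv, row.names = FALSE)
  expect_equal(read_ct_table(csv)$reference_ct, ct$reference_ct)
  bad <- tempfile()
  utils::write.table(ct[, 1:3], bad, sep = "\t", row.names = FALSE)
  expect_error(read_ct_table(bad), "lacks columns")
})
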