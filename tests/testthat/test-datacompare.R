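# Toy gzip CSV fixture in the layout of a pairwise FDR-corrected p-value
# table: perturbation rows (first column = target gene ID), gene columns.
write_pvalue_fixture <- function(rows, path = tempfile(fileext = ".csv.gz")) {
  con <- gzfile(path, "w")
  writeLines(rows, con)
  close(con)
  path
}

test_that("p-value loader matches perturbations to measured genes", {
  path <- write_pvalue_fixture(c(
    "target,ENSG01,ENSG02,ENSG03",
    "ENSG01,0.001,0.2,0.9",
    "ENSG02,0.5,0.04,0.7",
    "ENSG99,0.1,0.1,0.1"   # targets an unmeasured gene -> dropped
  ))
  tab <- suppressMessages(load_pairwise_pvalues(path))
  expect_identical(rownames(tab), c("ENSG01", "ENSG02"))
  expect_identical(attr(tab, "n_dropped_unmatched"), 1L)
})

test_that("duplicate perturbations keep the self-significant one", {
  path <- write_pvalue_fixture(c(
    "target,ENSG01,ENSG02,ENSG03",
    "ENSG01,0.8,0.2,0.9",    # no significant effect on its own target
    "ENSG01,0.001,0.3,0.9",  # significant on itself -> kept
    "ENSG03,0.5,0.2,0.01"
  ))
  tab <- suppressMessages(load_pairwise_pvalues(path))
  expect_identical(nrow(tab), 2L)
  expect_equal(tab["ENSG01", "ENSG01"], 0.001)
  expect_identical(attr(tab, "n_dropped_duplicates"), 1L)
})

test_that("loader degrades cleanly without the external file", {
  err <- tryCatch(load_pairwise_pvalues("/nonexistent/replogle.csv.gz"),
                  condition = identity)
  expect_s3_class(err, "grnforge_external_data_unavailable")
  expect_match(conditionMessage(err), "external data unavailable")
})

test_that("loader warns and returns empty on a table with no matching IDs", {
  path <- write_pvalue_fixture(c(
    "target,ENSG01,ENSG02",
    "ENSGX,0.5,0.5"
  ))
  expect_warning(tab <- load_pairwise_pvalues(path), "no perturbations")
  expect_identical(nrow(tab), 0L)
})

test_that("effect fractions from p-values match hand counts", {
  path <- write_pvalue_fixture(c(
    "target,G1,G2,G3,G4",
    "G1,0.001,0.01,0.2,0.8",
    "G2,0.9,0.001,0.03,0.9",
    "G3,0.2,0.9,0.5,0.01",
    "G4,0.04,0.9,0.9,0.9"
  ))
  tab <- load_pairwise_pvalues(path)
  fr <- effect_fractions_from_pvalues(tab, alpha = 0.05)
  # hand count with the self cell excluded, denominator 4
  expect_equal(unname(fr$outgoing), c(1, 1, 1, 1) / 4)
  expect_equal(unname(fr$incoming), c(1, 1, 1, 1) / 4)

  all_one <- matrix(1, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  fr1 <- effect_fractions_from_pvalues(all_one)
  expect_true(all(fr1$outgoing == 0) && all(fr1$incoming == 0))
  all_zero <- matrix(0, 3, 3, dimnames = dimnames(all_one))
  fr0 <- effect_fractions_from_pvalues(all_zero)
  expect_true(all(fr0$outgoing == (3 - 1) / 3))
})

test_that("screen effect fractions hit the requested discovery rate", {
  sys <- random_fixture_system(n = 20, m = 35, seed = 23)
  base <- simulate_to_steady_state(sys$params, fast_config(), seed = 24)
  screen <- knockout_screen(sys$params, base, fast_config(), seed = 25)
  rate <- 0.1
  fr <- effect_fractions_from_screen(screen, significance_rate = rate)
  n <- fr$n_analyzed
  called <- sum(fr$outgoing) * n
  M <- n * (n - 1)
  expect_lte(abs(called - rate * M), 1)  # within one pair's resolution
  expect_equal(sum(fr$outgoing), sum(fr$incoming))
  # sort-based threshold oracle
  m <- abs(screen$log2fc[screen$expressed, screen$expressed])
  vals <- sort(m[!is.na(m)])
  expect_equal(fr$threshold, vals[length(vals) - ceiling(rate * length(vals))])

  fr_all <- effect_fractions_from_screen(screen, significance_rate = 1)
  expect_true(all(fr_all$outgoing == (n - 1) / n))
})

test_that("quantile arithmetic calls exactly one pair on a 2x2 off-diagonal set", {
  lf <- matrix(c(NA, 0.3, 0.1, NA), 2, 2, byrow = TRUE)
  screen <- structure(list(log2fc = lf, expressed = c(TRUE, TRUE)),
                      class = "grn_screen")
  fr <- effect_fractions_from_screen(screen, significance_rate = 0.25)
  expect_equal(sum(fr$outgoing) * fr$n_analyzed, 1)
})

test_that("KS comparison equals an exhaustive ECDF-gap oracle", {
  expect_equal(ks_compare(1:5, 1:5)$statistic, 0)
  expect_equal(ks_compare(1:3, 11:13)$statistic, 1)
  a <- c(1, 2, 3); b <- c(1.5, 2.5)
  grid <- sort(unique(c(a, b)))
  gap <- max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x),
                        numeric(1))))
  expect_equal(ks_compare(a, b)$statistic, gap)
  expect_error(ks_compare(numeric(0), 1:3), "non-empty")
})

test_that("best-match ranking agrees with exhaustive search over r", {
  p_out <- c(0.9, 0.2, 0.8, 0.1, 0.5, 0.3)
  p_in <- c(0.1, 0.8, 0.7, 0.2, 0.9, 0.4)
  rep2 <- rank_best_matches(p_out, p_in, k_select = 2)
  # exhaustive oracle
  r_out <- rank(-p_out); r_in <- rank(-p_in)
  oracle_r <- NA
  for (r in 1:6) {
    if (sum(r_out <= r & r_in <= r) >= 2) { oracle_r <- r; break }
  }
  expect_equal(rep2$r, oracle_r)
  expect_setequal(rep2$selected, which(r_out <= oracle_r & r_in <= oracle_r))

  # single dominating network selected at r = 1
  rep1 <- rank_best_matches(c(0.99, 0.1, 0.2), c(0.98, 0.2, 0.1), 1)
  expect_equal(rep1$r, 1)
  expect_equal(rep1$selected, 1L)
  # k_select = all networks selects everything
  repn <- rank_best_matches(p_out, p_in, 6)
  expect_setequal(repn$selected, 1:6)

  # invariance to monotone rescaling of p-values
  rep_resc <- rank_best_matches(p_out^3, p_in^3, 2)
  expect_equal(rep_resc$selected, rep2$selected)
})

test_that("match_report wires KS statistics into the ranking", {
  set.seed(5)
  ref <- new_fr <- NULL
  fracs <- lapply(1:4, function(i)
    grnforge:::new_effect_fractions(runif(30), runif(30), 30L))
  ref <- grnforge:::new_effect_fractions(runif(30), runif(30), 30L)
  rep <- match_report(fracs, ref, k_select = 2)
  expect_length(rep$p_outgoing, 4)
  expect_true(all(rep$selected %in% 1:4))
  expect_gte(length(rep$selected), 2)
})
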