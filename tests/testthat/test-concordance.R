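test_that("agreement categories implement the major/minor error definitions", {
  expect_identical(agreement_category("LBV", "pathogenic"), "major_error")
  expect_identical(agreement_category("PV", "benign"), "major_error")
  expect_identical(agreement_category("PV", "uncertain"), "minor_error")
  expect_identical(agreement_category("LBV", "uncertain"), "minor_error")
  expect_identical(agreement_category("VUS", "pathogenic"), "minor_error")
  expect_identical(agreement_category("VUS", "uncertain"), "concordant")
  expect_identical(agreement_category("LPV", "pathogenic"), "concordant")
  # IARC classes collapse to the same three-way scheme (1-2 benign, 3
  # uncertain, 4-5 pathogenic) and SGE categories are accepted as calls
  expect_identical(agreement_category("2", "pathogenic"), "major_error")
  expect_identical(agreement_category(5, -4), "major_error")
  expect_identical(agreement_category("3", 0), "concordant")
})

test_that("rate summaries reproduce all six printed triples", {
  t1 <- table1()
  triple <- function(r) c(r$major_pct, r$minor_pct, r$concordant_pct)
  cat_h <- agreement_category(t1$classification, functional_call(t1$sge_hap1))
  cat_m <- agreement_category(t1$classification, functional_call(t1$sge_mes))
  expect_identical(triple(rate_summary(cat_h)), c(15.4, 46.2, 38.5))
  expect_identical(triple(rate_summary(cat_m)), c(23.1, 38.5, 38.5))
  sel <- !is.na(t1$iarc)
  iarc <- iarc_class(t1$posterior[sel], t1$combined_lr[sel])
  ih <- agreement_category(iarc, functional_call(t1$sge_hap1[sel]))
  im <- agreement_category(iarc, functional_call(t1$sge_mes[sel]))
  expect_identical(triple(rate_summary(ih)), c(20.0, 20.0, 60.0))
  expect_identical(triple(rate_summary(im)), c(40.0, 20.0, 40.0))
})

test_that("rate percentages round half away from zero at one decimal", {
  # 5/400 = 1.25% must report 1.3, not banker's 1.2
  cats <- c(rep("major_error", 5), rep("concordant", 395))
  expect_identical(rate_summary(cats)$major_pct, 1.3)
  r <- rate_summary(rep("concordant", 7))
  expect_identical(c(r$major_pct, r$minor_pct, r$concordant_pct), c(0, 0, 100))
  expect_error(rate_summary(character(0)), "at least one")
})

test_that("cross-tabulation preserves both datasets' marginals", {
  expect_identical(crosstab_agreement(character(0), character(0)),
                   matrix(0L, 3, 3, dimnames = list(agreement_levels(),
                                                    agreement_levels())))
  t1 <- table1()
  sel <- !is.na(t1$iarc)
  iarc <- iarc_class(t1$posterior[sel], t1$combined_lr[sel])
  tab <- crosstab_agreement(
    agreement_category(iarc, functional_call(t1$sge_hap1[sel])),
    agreement_category(iarc, functional_call(t1$sge_mes[sel])))
  expect_identical(unname(rowSums(tab)), c(1, 1, 3))
  expect_identical(unname(colSums(tab)), c(2, 1, 2))
  tab <- crosstab_agreement(c("major_error", "minor_error"),
                            c("major_error", "minor_error"))
  expect_identical(unname(diag(tab)), c(1L, 1L, 0L))
})

test_that("marginally homogeneous tables give statistic 0 and p 1", {
  tab <- matrix(c(5, 2, 3, 2, 7, 1, 3, 1, 4), 3, 3) # symmetric
  res <- bhapkar_test(tab)
  expect_identical(res$statistic, 0)
  expect_identical(res$p_value, 1)
  expect_identical(bhapkar_test(diag(c(3, 3)))$p_value, 1)
})

test_that("the IARC-comparison pair table gives the published p of 0.84", {
  t1 <- table1()
  sel <- !is.na(t1$iarc)
  iarc <- iarc_class(t1$posterior[sel], t1$combined_lr[sel])
  tab <- crosstab_agreement(
    agreement_category(iarc, functional_call(t1$sge_hap1[sel])),
    agreement_category(iarc, functional_call(t1$sge_mes[sel])))
  res <- bhapkar_test(tab)
  # hand-computed: d = (-0.2, 0), V diagonal (0.56, 0.40), so the statistic
  # is 5 * 0.04 / 0.56 and p = exp(-stat / 2) with 2 df
  expect_equal(res$statistic, 5 * 0.04 / 0.56, tolerance = 1e-12)
  expect_identical(res$df, 2L)
  expect_equal(round(res$p_value, 2), 0.84)
})

test_that("the k=2 statistic agrees with the closed-form reduction", {
  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(bhapkar_test(tab)$statistic, bhapkar_2x2_oracle(tab),
                 tolerance = 1e-9)
  }
})

test_that("the chi-square p agrees with a parametric bootstrap on 3x3 tables", {
  set.seed(7)
  for (i in 1:3) {
    tab <- random_pair_table(3, 300)
    res <- bhapkar_test(tab)
    p_boot <- bhapkar_bootstrap_p(tab, B = 4000)
    expect_lt(abs(res$p_value - p_boot), 0.05)
  }
})

test_that("the statistic is label-permutation invariant and grows with replication", {
  set.seed(3)
  tab <- random_pair_table(4, 120)
  base <- bhapkar_test(tab)
  for (i in 1:5) {
    perm <- sample(4)
    res <- bhapkar_test(tab[perm, perm])
    expect_equal(res$statistic, base$statistic, tolerance = 1e-9)
  }
  # scaling a fixed asymmetry up makes it harder to attribute to chance
  asym <- matrix(c(4, 6, 1, 2, 3, 2, 3, 1, 5), 3, 3)
  p <- vapply(c(1, 2, 4, 8), function(f) bhapkar_test(asym * f)$p_value,
              numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("singular covariance falls back to a generalized inverse with reduced df", {
  # one category never used by either dataset
  tab <- matrix(0, 3, 3)
  tab[1, 1] <- 4; tab[1, 2] <- 3; tab[2, 1] <- 1; tab[2, 2] <- 2
  res <- bhapkar_test(tab)
  expect_identical(res$df, 1L)
  expect_equal(res$statistic, bhapkar_2x2_oracle(tab[1:2, 1:2]),
               tolerance = 1e-9)
  expect_error(bhapkar_test(matrix(0, 3, 3)), "at least one")
  expect_error(bhapkar_test(matrix(1, 2, 3)), "square")
})
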