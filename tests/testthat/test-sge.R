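test_that("SGE category levels and signed points are a bijection", {
  levels <- c("pathogenic_strong", "pathogenic_moderate", "pathogenic_supporting",
              "uncertain", "benign_supporting", "benign_moderate", "benign_strong")
  points <- c(4L, 2L, 1L, 0L, -1L, -2L, -4L)
  expect_identical(sge_category(levels), points)
  expect_identical(sge_category(points), points)
  expect_identical(sge_level(points), levels)
  expect_identical(sge_category("Benign_Strong"), -4L)   # case-insensitive
  expect_identical(sge_category("−4"), -4L)         # Unicode minus
  expect_identical(sge_category("-4"), sge_category("benign_strong"))
  expect_error(sge_category(3), "category points")
  expect_error(sge_category("mostly_benign"), "unrecognized")
})

test_that("functional call follows the sign of the category", {
  expect_identical(functional_call(2), "pathogenic")
  expect_identical(functional_call(0), "uncertain")
  expect_identical(functional_call(-4), "benign")
  expect_identical(functional_call(c(1, -1, NA)),
                   c("pathogenic", "benign", NA))
})

test_that("integration assigns PS3/BS3 for concordant pairs at the stronger level", {
  res <- integrate_sge(4, 4)
  expect_identical(res$status, "concordant_pathogenic")
  expect_identical(res$code, "PS3")
  res <- integrate_sge(-2, -4)
  expect_identical(res$status, "concordant_benign")
  expect_identical(res$code, "BS3")
  # supporting-level downgrade for a weakly concordant pair
  res <- integrate_sge(-1, -1)
  expect_identical(res$code, "BS3_P")
  expect_identical(integrate_sge(2, 1)$code, "PS3_M")
  # discordance: one uncertain, or opposite signs
  expect_identical(integrate_sge(4, 0)$status, "discordant")
  expect_identical(integrate_sge(-1, 2)$status, "discordant")
  expect_true(is.na(integrate_sge(4, 0)$code))
  # two uncertain calls carry no information but are not discordant
  res <- integrate_sge(0, 0)
  expect_identical(res$status, "uninformative")
  expect_true(is.na(res$code))
})

test_that("integration is symmetric and strength-monotone", {
  pts <- c(-4L, -2L, -1L, 0L, 1L, 2L, 4L)
  for (a in pts) {
    for (b in pts) {
      r1 <- integrate_sge(a, b)
      r2 <- integrate_sge(b, a)
      expect_identical(r1$status, r2$status)
      expect_identical(r1$code, r2$code)
    }
  }
  # upgrading either same-sign input never weakens the assigned strength
  strength_rank <- function(code) {
    c(supporting = 1, moderate = 2, strong = 4)[
      parse_evidence_code(code)$strength]
  }
  for (a in c(1L, 2L, 4L)) {
    for (b in c(1L, 2L, 4L)) {
      for (b2 in c(1L, 2L, 4L)) {
        if (b2 < b) next
        expect_gte(strength_rank(integrate_sge(a, b2)$code),
                   strength_rank(integrate_sge(a, b)$code))
      }
    }
  }
})

test_that("reclassification appends the integrated code to the evidence", {
  res <- apply_integration(c("PM2_P", "BP4"), -4, -4)
  expect_identical(res$pre$label, "VUS")
  expect_identical(sort(res$post$applied_codes$label),
                   sort(c("PM2_P", "BS3", "BP4")))
  expect_identical(res$post$total_points, -4L)
  expect_identical(res$post$label, "LBV")
  expect_true(res$reclassified)

  res <- apply_integration(c("PS1_M", "PP3"), 4, 2)
  expect_identical(res$post$total_points, 7L)
  expect_identical(res$post$label, "LPV")

  # discordant results add nothing
  res <- apply_integration("PM2_P", 4, 0)
  expect_identical(res$post$total_points, 1L)
  expect_identical(res$post$label, "VUS")
  expect_false(res$reclassified)

  expect_error(apply_integration(c("PM2_P", "BS3"), -4, -4), "PS3/BS3")
})

test_that("the 29 reassessed VUS rows reproduce printed evidence and final labels", {
  t2 <- table2()
  expect_identical(nrow(t2), 29L)
  for (i in seq_len(29)) {
    res <- apply_integration(t2$evidence[[i]], t2$sge_hap1[i], t2$sge_mes[i])
    expect_identical(res$pre$label, "VUS", label = t2$variant_id[i])
    expect_identical(res$integration$code, t2$integrated_evidence[i],
                     label = t2$variant_id[i])
    expect_identical(sort(res$post$applied_codes$label),
                     sort(strsplit(t2$final_criteria[i], ";")[[1]]),
                     label = t2$variant_id[i])
    expect_identical(res$post$label, t2$final_class[i],
                     label = t2$variant_id[i])
  }
})
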