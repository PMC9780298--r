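test_that("chi-square screen reproduces hand 2x2 arithmetic and BH", {
  # [[10,0],[0,10]]: chi2 = N(ad-bc)^2 / (row x col products) = 20
  states <- matrix(c(rep(1L, 10), rep(0L, 10)), 1,
                   dimnames = list("G1", paste0("s", 1:20)))
  condition <- rep(c("tumor", "normal"), each = 10)
  res <- cnv_chisquare_screen(states, condition)
  expect_equal(res$chi2, 20)

  # identical distributions: chi2 = 0, p = 1
  states2 <- matrix(rep(c(1L, 0L), 10), 1,
                    dimnames = list("G1", paste0("s", 1:20)))
  res2 <- cnv_chisquare_screen(states2, condition)
  expect_equal(res2$chi2, 0)
  expect_equal(res2$p, 1)

  # untestable gene (all neutral) reported as NA, not significant
  states3 <- rbind(states, G2 = rep(0L, 20))
  res3 <- cnv_chisquare_screen(states3, condition)
  expect_false(res3$testable[res3$gene == "G2"])
  expect_false(res3$significant[res3$gene == "G2"])

  expect_error(cnv_chisquare_screen(states, rep("tumor", 20)), "normal")

  # BH step-up on {0.01, 0.02, 0.03} -> all 0.03
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})

test_that("BH adjustment is monotone under input reordering", {
  set.seed(151)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(stats::p.adjust(p, "BH")[perm], stats::p.adjust(p[perm], "BH"))
})

test_that("dosage association picks the right test and hand statistics", {
  # three state groups {1,2},{3,4},{5,6}: Kruskal-Wallis H = 32/7
  expr <- c(1, 2, 3, 4, 5, 6)
  states <- c(-1L, -1L, 0L, 0L, 1L, 1L)
  res <- dosage_association(expr, states)
  expect_identical(res$test, "kruskal")
  expect_equal(res$statistic, 32 / 7)

  # two groups: Wilcoxon
  res2 <- dosage_association(c(1, 2, 5, 6), c(0L, 0L, 1L, 1L))
  expect_identical(res2$test, "wilcoxon")

  # constant expression: statistic 0, p = 1
  res3 <- dosage_association(rep(2, 6), states)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p, 1)

  # deep deletion merges into the deletion group
  res4 <- dosage_association(c(1, 2, 5, 6), c(-2L, -1L, 0L, 0L))
  expect_identical(sort(res4$groups_used), c("deletion", "normal"))

  # monotone dosage with vanishing noise: significant at n = 4 per group
  res5 <- dosage_association(c(1.0, 1.1, 1.2, 1.3, 5.0, 5.1, 5.2, 5.3),
                             rep(c(0L, 1L), each = 4))
  expect_lt(res5$p, 0.05)

  # fewer than two usable groups: untestable
  res6 <- dosage_association(1:3, c(0L, 0L, 1L))
  expect_identical(res6$test, "untestable")
})

test_that("dosage null p-values are uniform over 1000 genes", {
  set.seed(161)
  n <- 60; genes <- 1000
  states <- generate_cnv_states(genes, sprintf("s%02d", 1:n),
                                state_probs = c(0.1, 0.2, 0.4, 0.2, 0.1),
                                seed = 162)
  expr <- matrix(rnorm(genes * n), genes, n, dimnames = dimnames(states))
  scr <- dosage_screen(expr, states)
  p <- scr$p[scr$test != "untestable"]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("chi-square screen recovers planted associations at FDR 0.05", {
  n_rep <- 100
  sens <- vapply(seq_len(n_rep), function(i) {
    set.seed(6000 + i)
    n <- 40
    condition <- rep(c("tumor", "normal"), each = n / 2)
    genes <- 30; planted <- 1:6
    states <- matrix(0L, genes, n,
                     dimnames = list(sprintf("G%03d", 1:genes),
                                     sprintf("s%02d", 1:n)))
    # background alteration prob 0.15 everywhere; planted genes altered at
    # 0.75 in tumors (odds ratio >> 5)
    bg <- matrix(rbinom(genes * n, 1L, 0.15), genes, n)
    states[bg == 1L] <- 1L
    hot <- matrix(rbinom(length(planted) * n / 2, 1L, 0.75),
                  length(planted), n / 2)
    states[planted, condition == "tumor"] <- pmax(
      states[planted, condition == "tumor"], hot)
    res <- cnv_chisquare_screen(states, condition)
    mean(res$significant[planted])
  }, numeric(1))
  expect_gte(mean(sens), 0.9)
})

test_that("gene-set intersections cover all seven Venn regions", {
  v <- intersect_screens(c("x", "y"), c("y", "z"), "y")
  expect_identical(v$core, "Y")
  expect_identical(unname(v$counts[c("A_only", "B_only", "ABC")]),
                   c(1L, 1L, 1L))

  d <- intersect_screens("a", "b", "c")
  expect_identical(unname(d$counts[c("AB_not_C", "AC_not_B", "BC_not_A", "ABC")]),
                   rep(0L, 4))

  # brute-force enumeration oracle over the label universe
  set.seed(171)
  uni <- paste0("g", 1:40)
  a <- sample(uni, 15); b <- sample(uni, 20); c <- sample(uni, 10)
  v2 <- intersect_screens(a, b, c)
  brute <- sum(vapply(toupper(uni), function(g) {
    g %in% toupper(a) && g %in% toupper(b) && g %in% toupper(c)
  }, logical(1)))
  expect_identical(unname(v2$counts["ABC"]), brute)
  expect_lte(length(v2$core), min(length(a), length(b), length(c)))

  # empty sets allowed
  e <- intersect_screens(character(0), "x", "x")
  expect_identical(unname(e$counts["BC_not_A"]), 1L)
})

test_that("drug-sensitivity correlations match hand values and BH applies", {
  lines <- paste0("cl", 1:3)
  expr <- matrix(c(1, 2, 3), 1, dimnames = list("SRC", lines))
  pos <- matrix(c(2, 4, 6), 1, dimnames = list("drugA", lines))
  neg <- matrix(c(6, 4, 2), 1, dimnames = list("drugB", lines))
  mix <- matrix(c(1, 3, 2), 1, dimnames = list("drugC", lines))
  resp <- rbind(pos, neg, mix)
  res <- drug_sensitivity_correlation(expr, resp)
  expect_equal(res$r[res$drug == "drugA"], 1)
  expect_equal(res$r[res$drug == "drugB"], -1)
  expect_equal(res$r[res$drug == "drugC"], 0.5)
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))

  # affine invariance / sign flip under negative scaling
  set.seed(181)
  e2 <- matrix(rnorm(8), 1, dimnames = list("g", paste0("cl", 1:8)))
  r2 <- matrix(rnorm(8), 1, dimnames = list("d", paste0("cl", 1:8)))
  base_r <- drug_sensitivity_correlation(e2, r2)$r
  aff <- drug_sensitivity_correlation(e2 * 3 + 5, r2)$r
  expect_equal(aff, base_r, tolerance = 1e-12)
  flip <- drug_sensitivity_correlation(e2, -2 * r2)$r
  expect_equal(flip, -base_r, tolerance = 1e-12)

  # too few shared lines: untestable
  small <- matrix(1:2, 1, dimnames = list("g", paste0("cl", 1:2)))
  res3 <- drug_sensitivity_correlation(small,
                                       matrix(2:1, 1, dimnames = list("d", paste0("cl", 1:2))))
  expect_false(res3$testable)
  expect_error(drug_sensitivity_correlation(
    matrix(1, 1, dimnames = list("g", "a")),
    matrix(1, 1, dimnames = list("d", "b"))), "shared")
})
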