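test_that("running sum matches the hand-walked 5-gene example", {
  v <- c(g1 = 50, g2 = 40, g3 = 30, g4 = 20, g5 = 10)
  es <- ssgsea_es(v, c("g1", "g2"), alpha = 0.25)
  # positions 1..5 get weights (5,4,3,2,1)^0.25; only g1, g2 are in the
  # set, so P_in steps 5^.25/(5^.25+4^.25) then 1; P_out steps 1/3 each
  # from position 3: ES = P_in(1) + 1 + 2/3 + 1/3 + 0
  w1 <- 5^0.25; w2 <- 4^0.25
  expect_equal(es, w1 / (w1 + w2) + 1 + 2 / 3 + 1 / 3)
})

test_that("implementation equals the naive reference on random instances", {
  withr::with_seed(123, {
    for (i in 1:100) {
      n <- sample(5:20, 1)
      v <- random_sample_values(n)
      k <- sample(seq_len(n - 1), 1)
      set_genes <- sample(names(v), k)
      expect_equal(ssgsea_es(v, set_genes, alpha = 0.25),
                   naive_ssgsea(v, set_genes, alpha = 0.25),
                   tolerance = 1e-12)
    }
  })
})

test_that("single-gene set scores strictly decrease with worse rank", {
  v <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  es <- vapply(names(v), function(g) ssgsea_es(v, g), numeric(1))
  expect_true(all(diff(es) < 0))
})

test_that("gene input order and monotone transforms do not change ES", {
  withr::with_seed(21, {
    v <- random_sample_values(15)
    set_genes <- sample(names(v), 4)
    perm <- sample(15)
    expect_identical(ssgsea_es(v[perm], set_genes), ssgsea_es(v, set_genes))
    expect_identical(ssgsea_es(v * 2, set_genes), ssgsea_es(v, set_genes))
  })
})

test_that("degenerate sets are rejected", {
  v <- c(a = 3, b = 2, c = 1)
  expect_error(ssgsea_es(v, c("x", "y")), "no overlap")
  expect_error(ssgsea_es(v, c("a", "b", "c")), "every measured gene")
})

test_that("signature matrices normalize to unit range and respect ranks", {
  withr::with_seed(31, {
    m <- matrix(rexp(50 * 4, 0.1), 50, 4,
                dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
  })
  sets <- list(up = sprintf("g%02d", 1:10), down = sprintf("g%02d", 41:50))
  sig <- score_signatures(expr_tibble(m), sets)
  vals <- as.matrix(sig[-1])
  expect_equal(max(vals) - min(vals), 1)

  # rank invariance: doubling one sample's TPM leaves its scores unchanged
  m2 <- m
  m2[, 2] <- m2[, 2] * 2
  sig2 <- score_signatures(expr_tibble(m2), sets)
  expect_equal(sig2$s2, sig$s2)

  # identical samples give identical scores; zero range warns
  m3 <- cbind(s1 = m[, 1], s2 = m[, 1])
  expect_warning(sig3 <- score_signatures(expr_tibble(m3), sets["up"]),
                 "range is zero")
  expect_equal(sig3$s1, sig3$s2)
})

test_that("per-patient scores satisfy the C-score identity", {
  co <- simulate_cohort(small_design(seed = 6))
  ann <- co$annotation
  expr_c <- align_cohort(co$expression, ann, "C")
  expr_ln <- align_cohort(co$expression, ann, "Ln")
  sc <- compute_scores(expr_c, expr_ln, ann,
                       dhgp_set = co$truth$modules$emt_angio,
                       rhgp_set = co$truth$modules$metabolism_cellcycle,
                       ln_set = co$truth$modules$ln_fibrosis)
  expect_equal(sc$c_score, sc$dhgp_score - sc$rhgp_score, tolerance = 1e-15)
  expect_equal(nrow(sc), 35)

  # identical seed sets cancel exactly
  same <- compute_scores(expr_c, expr_ln, ann,
                         dhgp_set = co$truth$modules$emt_angio,
                         rhgp_set = co$truth$modules$emt_angio,
                         ln_set = co$truth$modules$ln_fibrosis)
  expect_equal(same$c_score, rep(0, 35))
})

test_that("patients missing a tissue get NA scores with a message", {
  co <- simulate_cohort(small_design(seed = 6))
  ann <- co$annotation
  drop_c <- ann$sample_id[ann$patient_id == "P01" & ann$tissue == "C"]
  expr_c <- align_cohort(co$expression, ann[ann$sample_id != drop_c, ], "C")
  expr_ln <- align_cohort(co$expression, ann, "Ln")
  expect_message(
    sc <- compute_scores(expr_c, expr_ln, ann[ann$sample_id != drop_c, ],
                         dhgp_set = co$truth$modules$emt_angio,
                         rhgp_set = co$truth$modules$metabolism_cellcycle,
                         ln_set = co$truth$modules$ln_fibrosis),
    "missing")
  expect_true(is.na(sc$c_score[sc$patient_id == "P01"]))
  expect_false(anyNA(sc$c_score[sc$patient_id != "P01"]))
})

test_that("planted cohorts separate the classes on both scores", {
  co <- simulate_cohort(small_design(seed = 10))
  ann <- co$annotation
  sc <- compute_scores(align_cohort(co$expression, ann, "C"),
                       align_cohort(co$expression, ann, "Ln"), ann,
                       dhgp_set = co$truth$modules$emt_angio,
                       rhgp_set = co$truth$modules$metabolism_cellcycle,
                       ln_set = co$truth$modules$ln_fibrosis)
  d <- sc[sc$hgp == "dHGP", ]
  r <- sc[sc$hgp == "rHGP", ]
  expect_gt(mean(d$c_score), mean(r$c_score))
  expect_lt(wilcox.test(d$c_score, r$c_score, alternative = "greater")$p.value,
            0.01)
  expect_lt(wilcox.test(d$ln_score, r$ln_score, alternative = "greater")$p.value,
            0.01)
})
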