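toy_expr <- function(m) expr_tibble(m)

test_that("direction requires both the fold-change and FDR gates", {
  # planted shift large in significance but below the log2FC gate
  withr::with_seed(1, {
    a <- matrix(rnorm(6 * 20, 100), 6, 20)
    b <- matrix(rnorm(6 * 20, 100), 6, 20)
    a[1, ] <- a[1, ] * 1.8  # log2fc ~ 0.85 < 1, p tiny
    m <- cbind(a, b)
    dimnames(m) <- list(paste0("g", 1:6), paste0("s", 1:40))
  })
  de <- run_de(toy_expr(m), paste0("s", 1:20), paste0("s", 21:40),
               lfc_threshold = 1, fdr_threshold = 0.05)
  g1 <- de[de$gene_id == "g1", ]
  expect_lt(g1$fdr, 0.05)
  expect_lt(abs(g1$log2fc), 1)
  expect_equal(g1$direction, "ns")
})

test_that("identical groups give log2fc 0, p 1, ns", {
  m <- matrix(rep(c(5, 7, 9), each = 6), 3, 6, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:6)))
  de <- run_de(toy_expr(m), paste0("s", 1:3), paste0("s", 4:6),
               lfc_threshold = 1, fdr_threshold = 0.05)
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$p_value, rep(1, 3))
  expect_equal(de$direction, rep("ns", 3))
})

test_that("vectorized rank-sum matches wilcox.test with tie correction", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      a <- matrix(round(rexp(30 * 8, 0.1), 1), 30, 8)
      b <- matrix(round(rexp(30 * 11, 0.1), 1), 30, 11)
      p_fast <- rowwise_wilcoxon_p(a, b)
      p_ref <- vapply(1:30, function(i) {
        suppressWarnings(wilcox.test(a[i, ], b[i, ], exact = FALSE,
                                     correct = TRUE))$p.value
      }, numeric(1))
      expect_equal(p_fast, p_ref, tolerance = 1e-12, ignore_attr = TRUE)
    }
  })
})

test_that("p-values are invariant under monotone transforms; swap negates", {
  withr::with_seed(3, {
    m <- matrix(rexp(40 * 10, 0.05), 40, 10,
                dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:10)))
  })
  ga <- paste0("s", 1:5); gb <- paste0("s", 6:10)
  de <- run_de(toy_expr(m), ga, gb)
  de_t <- run_de(toy_expr(sqrt(m) + 2), ga, gb)
  expect_equal(de_t$p_value, de$p_value, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(de_t$log2fc, de$log2fc)))

  de_sw <- run_de(toy_expr(m), gb, ga)
  expect_equal(de_sw$log2fc, -de$log2fc, tolerance = 1e-12)
  expect_equal(de_sw$p_value, de$p_value, tolerance = 1e-12)
  expect_equal(de_sw$direction == "up_in_A", de$direction == "up_in_B")
})

test_that("FDR values are monotone along the p-value ordering", {
  withr::with_seed(8, {
    m <- matrix(rexp(100 * 12, 0.05), 100, 12,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:12)))
  })
  de <- run_de(toy_expr(m), paste0("s", 1:6), paste0("s", 7:12))
  ord <- order(de$p_value)
  expect_true(all(diff(de$fdr[ord]) >= -1e-15))
})

test_that("group validation catches misuse", {
  m <- matrix(1:12, 3, 4, dimnames = list(letters[1:3], paste0("s", 1:4)))
  e <- toy_expr(m)
  expect_error(run_de(e, c("s1", "s2"), c("s2", "s3")), "disjoint")
  expect_error(run_de(e, "s1", c("s2", "s3")), "at least 2")
  expect_error(run_de(e, c("s1", "s2"), c("s3", "sX")), "absent")
})

test_that("intersection builds shared signatures from concordant DEGs", {
  fake_de <- function(up_a, up_b, universe) {
    tibble::tibble(
      gene_id = universe,
      log2fc = ifelse(universe %in% up_a, 2, ifelse(universe %in% up_b, -2, 0)),
      p_value = 0.001, fdr = 0.001,
      direction = ifelse(universe %in% up_a, "up_in_A",
                         ifelse(universe %in% up_b, "up_in_B", "ns")))
  }
  u <- sprintf("g%02d", 1:20)
  d1 <- fake_de(c("g01", "g02", "g03"), c("g10"), u)
  d2 <- fake_de(c("g02", "g03", "g04"), c("g11"), u)
  got <- intersect_up_sets(d1, d2, "up_in_A")
  expect_equal(got$set, "dHGP_shared")
  expect_setequal(got$genes[[1]], c("g02", "g03"))

  expect_message(empty <- intersect_up_sets(d1, d2, "up_in_B"), "empty")
  expect_length(empty$genes[[1]], 0)

  # self-intersection returns the significant genes unchanged
  self <- intersect_up_sets(d1, d1, "up_in_A")
  expect_setequal(self$genes[[1]], c("g01", "g02", "g03"))
})

test_that("shared planted modules are recovered by the intersection", {
  co <- simulate_cohort(small_design(seed = 4))
  ann <- co$annotation
  pick <- function(t, h) ann$sample_id[ann$tissue == t & ann$hgp == h]
  de_l <- run_de(align_cohort(co$expression, ann, "L"),
                 pick("L", "dHGP"), pick("L", "rHGP"))
  de_c <- run_de(align_cohort(co$expression, ann, "C"),
                 pick("C", "dHGP"), pick("C", "rHGP"))
  shared_d <- intersect_up_sets(de_c, de_l, "up_in_A")$genes[[1]]
  shared_r <- intersect_up_sets(de_c, de_l, "up_in_B")$genes[[1]]
  expect_gte(mean(co$truth$modules$emt_angio %in% shared_d), 0.9)
  expect_gte(mean(co$truth$modules$metabolism_cellcycle %in% shared_r), 0.9)
  # the immune module is planted in L only, so it must not enter the
  # shared seed signature
  expect_lt(mean(co$truth$modules$immune %in% shared_d), 0.2)
})
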