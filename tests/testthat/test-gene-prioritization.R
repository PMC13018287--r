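test_that("promoter mapping respects the upstream and symmetric windows", {
  ids <- sprintf("cg%02d", 1:6)
  ann <- make_annotation(ids,
                         nearest_gene = c("G1", "G1", "G2", "G2", "G3", "G3"),
                         tss_distance = c(-200L, -1500L, -1501L, 0L,
                                          800L, NA))
  expect_message(map <- map_promoter_esls(ids, ann), "skipped")
  expect_setequal(map$G1, c("cg01", "cg02"))  # -200 and -1500 inside
  expect_identical(map$G2, "cg04")            # -1501 outside, 0 inside
  expect_false("G3" %in% names(map))          # +800 outside upstream window

  map_sym <- suppressMessages(
    map_promoter_esls(ids, ann, window = "symmetric"))
  expect_identical(map_sym$G3, "cg05")        # +800 within +/-1500

  # interval-containment oracle on random annotations
  set.seed(91)
  ids2 <- sprintf("cg%03d", 1:200)
  d <- sample(-3000:3000, 200, replace = TRUE)
  ann2 <- make_annotation(ids2, nearest_gene = sprintf("g%03d", 1:200),
                          tss_distance = d)
  map2 <- map_promoter_esls(ids2, ann2)
  oracle <- ids2[d >= -1500 & d <= 0]
  expect_setequal(unlist(map2), oracle)
})

test_that("methylation-expression correlation handles exact and null cases", {
  set.seed(92)
  n <- 30
  beta <- make_beta(runif(3 * n), n_probes = 3,
                    probe_ids = c("cgA", "cgB", "cgC"))
  expr <- matrix(0, 2, n, dimnames = list(c("G1", "G2"), colnames(beta)))
  expr["G1", ] <- 10 - 8 * unclass(beta)["cgA", ]   # exact anti-correlation
  expr["G2", ] <- runif(n)
  map <- list(G1 = "cgA", G2 = c("cgB", "cgC"))
  rec <- correlate_meth_expr(beta, expr, map, log_transform = FALSE)
  expect_equal(rec$r_meth_expr[rec$gene == "G1"], -1, tolerance = 1e-10)
  expect_true(rec$significant_negative[rec$gene == "G1"])

  expect_error(correlate_meth_expr(beta[, 1:2], expr[, 1:2], map),
               "3 shared samples")
})

test_that("null methylation-expression pairs are significant at about the alpha rate", {
  set.seed(93)
  n_genes <- 150; n <- 40
  beta <- make_beta(runif(n_genes * n), n_probes = n_genes,
                    probe_ids = sprintf("cg%03d", 1:n_genes))
  expr <- matrix(runif(n_genes * n), n_genes, n,
                 dimnames = list(sprintf("g%03d", 1:n_genes),
                                 colnames(beta)))
  map <- setNames(as.list(rownames(beta)), rownames(expr))
  rec <- correlate_meth_expr(beta, expr, map, log_transform = FALSE)
  # Bonferroni keeps the family-wise null nearly clean
  expect_lte(sum(rec$significant_negative), 2)
  # raw null calibration: ~alpha of independent gene-age pairs significant
  ages <- runif(n, 20, 80)
  age_rec <- correlate_age_expr(expr, ages, log_transform = FALSE)
  expect_lt(abs(mean(age_rec$p_age_expr < 0.05) - 0.05), 0.05)
  expect_lte(sum(age_rec$significant_negative), 2)
})

test_that("age-expression correlation flags planted declining genes", {
  set.seed(94)
  n <- 50
  ages <- runif(n, 20, 80)
  expr <- rbind(
    dec1 = 100 - ages + rnorm(n, 0, 5),
    dec2 = 50 - 0.5 * ages + rnorm(n, 0, 3),
    flat = rnorm(n, 20, 3),
    const = rep(7, n)
  )
  colnames(expr) <- sprintf("s%02d", 1:n)
  expect_message(rec <- correlate_age_expr(expr, ages, log_transform = FALSE),
                 "constant")
  expect_false("const" %in% rec$gene)
  expect_true(all(rec$significant_negative[rec$gene %in% c("dec1", "dec2")]))
  expect_false(rec$significant_negative[rec$gene == "flat"])
  # strictly decreasing expression: r = -1
  expr2 <- matrix(100 - sort(ages), 1, n,
                  dimnames = list("g", colnames(expr)))
  rec2 <- correlate_age_expr(expr2, sort(ages), log_transform = FALSE)
  expect_equal(rec2$r_age_expr, -1, tolerance = 1e-10)
})

test_that("prioritization is the conjunction of the three criteria", {
  meth <- data.frame(gene = c("g1", "g2", "g3"), n_esls = 1,
                     r_meth_expr = c(-0.8, -0.8, -0.8),
                     p_meth_expr = 1e-6,
                     significant_negative = c(TRUE, TRUE, TRUE))
  age <- data.frame(gene = c("g1", "g2", "g3"),
                    r_age_expr = c(-0.7, -0.7, 0.7),
                    p_age_expr = 1e-6, p_age_expr_adj = 1e-4,
                    significant_negative = c(TRUE, TRUE, FALSE))
  mean_rec <- c(g1 = 0.2, g2 = 0.04, g3 = 0.2)
  out <- prioritize_genes(meth, age, mean_rec)
  # g2 fails only recurrence; g3 fails only the age criterion
  expect_identical(out$gene[out$prioritized], "g1")
  empty <- prioritize_genes(meth[0, ], age, mean_rec)
  expect_identical(nrow(empty), 0L)
})

test_that("planted silenced-with-age genes are recovered from a full simulation", {
  set.seed(95)
  n_genes <- 120; n <- 60
  genes <- sprintf("g%03d", 1:n_genes)
  probes <- sprintf("cg%03d", 1:n_genes)
  planted <- genes[1:20]
  ages <- runif(n, 20, 80)
  beta <- matrix(rbeta(n_genes * n, 1, 60), n_genes, n,
                 dimnames = list(probes, sprintf("s%02d", 1:n)))
  expr <- matrix(rnorm(n_genes * n, 50, 5), n_genes, n,
                 dimnames = list(genes, colnames(beta)))
  recurrence <- data.frame(probe_id = probes,
                           recurrence = runif(n_genes, 0, 0.04))
  for (i in 1:20) {
    # promoter methylation rises with age and silences expression
    b <- pmin(0.9, 0.02 + 0.006 * (ages - 20) + rnorm(n, 0, 0.02))
    beta[i, ] <- pmax(0, b)
    expr[i, ] <- pmax(0, 60 - 50 * beta[i, ] + rnorm(n, 0, 2))
    recurrence$recurrence[i] <- 0.3
  }
  map <- setNames(as.list(probes), genes)
  meth <- correlate_meth_expr(beta_matrix(beta), expr, map,
                              log_transform = FALSE)
  age_rec <- correlate_age_expr(expr, ages, log_transform = FALSE)
  mrec <- gene_mean_recurrence(map, recurrence)
  out <- prioritize_genes(meth, age_rec, mrec)
  got <- out$gene[out$prioritized]
  expect_gte(mean(got %in% planted), 0.9)     # precision
  expect_gte(mean(planted %in% got), 0.9)     # recall
})

test_that("context enrichment matches the brute-force cross-product ratio", {
  set.seed(96)
  ids <- sprintf("cg%04d", 1:2000)
  esl <- sample(ids, 300)
  is_esl <- ids %in% esl
  island <- ifelse(is_esl, runif(2000) < 0.7, runif(2000) < 0.2)
  ann <- make_annotation(ids,
                         cgi_relation = ifelse(island, "island", "open_sea"),
                         tss_distance = sample(c(-800L, 4000L), 2000, TRUE))
  enr <- context_enrichment(esl, ann)
  a <- sum(is_esl & island); b <- sum(is_esl & !island)
  cc <- sum(!is_esl & island); d <- sum(!is_esl & !island)
  expect_equal(enr$odds_ratio, (a * d) / (b * cc))
  expect_lt(enr$p, 1e-10)
  expect_equal(enr$tss_fraction,
               mean(ann$tss_distance[is_esl] == -800L))

  # identical island rates: OR near 1
  ann2 <- make_annotation(ids, cgi_relation = "island",
                          tss_distance = -100L)
  ann2$cgi_relation <- sample(rep(c("island", "open_sea"), 1000))
  enr2 <- context_enrichment(esl, ann2)
  expect_lt(abs(log(enr2$odds_ratio)), 0.7)
  expect_equal(enr2$tss_fraction, 1)   # all within the window
})
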