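make_records <- function(ids, fc, status = "up") {
  tibble::tibble(gene_id = ids, background = "x", log2fc = fc,
                 p_value = 0, adj_p = 0, status = status)
}

test_that("dependence points are x = fc1, y = fc1 - fc2 on the common genes", {
  ids <- paste0("g", 1:5)
  r1 <- make_records(ids, c(3, 2, 1.5, 2.5, 4))
  r2 <- make_records(ids, c(1, 2, 0, 2.5, 0))
  pts <- build_dependence_points(r1, r2, subset = ids)
  expect_equal(pts$x, r1$log2fc)
  expect_equal(pts$y, r1$log2fc - r2$log2fc)
  expect_equal(pts$y[pts$gene_id == "g1"], 2)  # fc 3 vs 1
  # identical fold changes in both backgrounds: all y = 0
  expect_true(all(build_dependence_points(r1, r1, subset = ids)$y == 0))
  # background 2 fold changes all zero: y = x
  r0 <- make_records(ids, rep(0, 5))
  pts0 <- build_dependence_points(r1, r0, subset = ids)
  expect_equal(pts0$y, pts0$x)
  # genes missing in background 2 are dropped with a warning
  expect_warning(
    dropped <- build_dependence_points(r1, r2[1:3, ], subset = ids),
    "2 gene")
  expect_equal(nrow(dropped), 3)
  expect_error(build_dependence_points(r1, r2, subset = character()), "empty")
})

test_that("the default subset is the background-1 up genes", {
  r1 <- make_records(paste0("g", 1:4), c(3, 2, -2, 0),
                     status = c("up", "up", "down", "ns"))
  r2 <- make_records(paste0("g", 1:4), c(0, 0, 0, 0))
  expect_equal(build_dependence_points(r1, r2)$gene_id, c("g1", "g2"))
  expect_equal(build_dependence_points(r1, r2, subset = "down")$gene_id, "g3")
})

test_that("split_sides partitions exhaustively and flips with the sign of y", {
  pts <- tibble::tibble(gene_id = c("a", "b", "c"), x = 1:3, y = c(1, -1, 0))
  s <- split_sides(pts)
  expect_equal(s$side, c("above", "below", "on_line"))
  flipped <- split_sides(dplyr::mutate(pts, y = -y))
  expect_equal(flipped$side, c("below", "above", "on_line"))
  all_zero <- split_sides(dplyr::mutate(pts, y = 0))
  expect_true(all(all_zero$side == "on_line"))
})

test_that("fit_line matches closed-form OLS and stats::lm", {
  ident <- fit_line(tibble::tibble(x = 1:3, y = 1:3))
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$r_squared, 1)
  expect_equal(ident$spearman_rho, 1)

  rev_mono <- fit_line(tibble::tibble(x = c(1, 2, 4), y = c(9, 3, 2)))
  expect_equal(rev_mono$spearman_rho, -1)

  # worked 3-point example: Sxy = 1.5, Sxx = 2, Syy = 7/6
  f <- fit_line(tibble::tibble(x = 1:3, y = c(0.5, 1.5, 2.0)))
  expect_equal(f$slope, 0.75)
  expect_equal(f$intercept, -1 / 6)
  expect_equal(f$r_squared, 1.5^2 / (2 * 7 / 6), tolerance = 1e-12)
  expect_equal(round(f$r_squared, 4), 0.9643)

  set.seed(33)
  d <- tibble::tibble(x = rnorm(50), y = rnorm(50))
  f2 <- fit_line(d)
  lmfit <- lm(y ~ x, data = d)
  expect_equal(f2$slope, unname(coef(lmfit)[2]))
  expect_equal(f2$intercept, unname(coef(lmfit)[1]))
  expect_equal(f2$r_squared, summary(lmfit)$r.squared)
  expect_equal(f2$spearman_rho, cor(d$x, d$y, method = "spearman"))

  expect_error(fit_line(tibble::tibble(x = c(1, 1), y = c(1, 2))),
               "insufficient")
  expect_error(fit_line(tibble::tibble(x = 1, y = 1)), "insufficient")
  flat <- fit_line(tibble::tibble(x = 1:4, y = rep(2, 4)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
})

test_that("bias tests follow their conventions and the F oracle", {
  zero <- tibble::tibble(x = 1:5, y = rep(0, 5))
  expect_equal(test_bias(zero, method = "ftest"), 1)
  expect_equal(test_bias(zero, method = "slope"), 1)
  diag <- tibble::tibble(x = c(1, 2, 3.5), y = c(1, 2, 3.5))
  expect_equal(test_bias(diag, method = "ftest"), 0)
  expect_equal(test_bias(diag, method = "slope"), 0)
  expect_error(test_bias(diag[1:2, ]), "at least 3")

  set.seed(55)
  pts <- tibble::tibble(x = runif(40, 1, 4), y = rnorm(40, 0.5, 0.4))
  f <- fit_line(pts)
  # oracle: hand-computed sums of squares through the F tail
  ss0 <- sum(pts$y^2)
  ss1 <- sum((pts$y - f$intercept - f$slope * pts$x)^2)
  fstat <- ((ss0 - ss1) / 2) / (ss1 / (40 - 2))
  expect_equal(test_bias(pts, method = "ftest"),
               pf(fstat, 2, 38, lower.tail = FALSE))
  # slope branch equals the lm coefficient test
  lm_p <- summary(lm(y ~ x, data = pts))$coefficients["x", 4]
  expect_equal(test_bias(pts, method = "slope"), lm_p)
})

test_that("iterative filter keeps collinear points and rejects a gross outlier", {
  collinear <- tibble::tibble(gene_id = paste0("g", 1:10),
                              x = 1:10, y = 0.5 * (1:10) + 1)
  fit <- iterative_filter(collinear, side = "above")
  expect_true(fit$converged)
  expect_equal(fit$n_iterations, 1)
  expect_setequal(fit$included_gene_ids, collinear$gene_id)
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$r_squared, 1)

  # 20 points exactly on y = x plus one displaced 10 units off the line
  base <- tibble::tibble(
    gene_id = paste0("g", 1:20),
    x = seq(1, 4, length.out = 20),
    y = seq(1, 4, length.out = 20)
  )
  outlier <- tibble::tibble(gene_id = "bad", x = 2.5, y = 12.5)
  pts <- dplyr::bind_rows(base, outlier)
  # oracle check of the first-iteration threshold: the outlier's
  # perpendicular distance exceeds k * 1.4826 * median distance
  f0 <- fit_line(pts)
  d <- abs(pts$y - f0$intercept - f0$slope * pts$x) / sqrt(1 + f0$slope^2)
  expect_gt(d[pts$gene_id == "bad"], 2.5 * 1.4826 * median(d))
  fit2 <- iterative_filter(pts, side = "above")
  expect_true(fit2$converged)
  expect_setequal(fit2$included_gene_ids, base$gene_id)
  expect_equal(fit2$slope, 1, tolerance = 0.01)

  # below the minimum point count the side yields no fit and no calls
  tiny <- collinear[1:2, ]
  fit3 <- iterative_filter(tiny, side = "above")
  expect_false(fit3$converged)
  expect_equal(fit3$included_gene_ids, character(0))
  expect_equal(fit3$bias_p, 1)
})

test_that("iterative filter is deterministic, scale-free and always terminates", {
  set.seed(91)
  for (i in 1:60) {
    n <- sample(10:60, 1)
    pts <- tibble::tibble(gene_id = paste0("g", 1:n),
                          x = runif(n, 0.5, 5),
                          y = abs(rnorm(n, 0.3, 0.5)) + 1e-6)
    a <- iterative_filter(pts, side = "above")
    b <- iterative_filter(pts, side = "above")
    expect_identical(a, b)
    expect_lte(a$n_iterations, 50)
    # common positive rescaling leaves the inclusion set and r^2 unchanged
    sc <- iterative_filter(dplyr::mutate(pts, x = 3.7 * x, y = 3.7 * y),
                           side = "above")
    expect_setequal(sc$included_gene_ids, a$included_gene_ids)
    if (a$n_points > 0) {
      expect_equal(sc$r_squared, a$r_squared)
      expect_equal(sc$spearman_rho, a$spearman_rho)
    }
  }
})

test_that("dependence calls recover the limiting behaviours", {
  # all points on the line: everyone independent
  ids <- paste0("g", 1:8)
  r <- make_records(ids, 1:8 / 2)
  dep0 <- dependence_analysis(r, r, subset = ids)
  expect_true(all(tidy(dep0)$call == "independent"))
  expect_false(dep0$fit_above$converged && dep0$fit_above$bias_p < 0.05)

  # perfect dependence (fc2 = 0): everyone dependent_impaired
  r0 <- make_records(ids, rep(0, 8))
  dep1 <- dependence_analysis(r, r0, subset = ids)
  expect_true(all(tidy(dep1)$call == "dependent_impaired"))
  expect_equal(dep1$fit_above$bias_p, 0)
  expect_equal(dep1$fit_above$r_squared, 1)

  # impaired calls only above the line, enhanced only below
  mixed <- dependence_analysis(
    make_records(ids, c(2, 2.5, 3, 3.5, 2, 2.5, 3, 3.5)),
    make_records(ids, c(0, 0, 0, 0, 4.2, 5.1, 6.3, 7.2)),
    subset = ids, min_points = 3
  )
  calls <- tidy(mixed)
  expect_true(all(calls$side[calls$call == "dependent_impaired"] == "above"))
  expect_true(all(calls$side[calls$call == "dependent_enhanced"] == "below"))
})

test_that("pure technical noise produces dependence calls at the nominal error rate", {
  set.seed(121)
  res <- replicate(200, {
    n <- 150
    pts <- tibble::tibble(gene_id = as.character(seq_len(n)),
                          x = runif(n, 1, 4), y = rnorm(n, 0, 0.3))
    s <- split_sides(pts)
    fa <- iterative_filter(s[s$side == "above", ], "above")
    fb <- iterative_filter(s[s$side == "below", ], "below")
    calls <- call_dependence(pts, fa, fb, alpha_bias = 0.05)
    c(sig_above = isTRUE(fa$converged && fa$bias_p < 0.05),
      frac_dependent = mean(calls$call != "independent"))
  })
  # the side-level rejection probability should sit near alpha = 0.05
  expect_lt(mean(res["sig_above", ]), 0.12)
  expect_gt(mean(res["sig_above", ]), 0.005)
  # and only a small fraction of genes get (spuriously) called dependent
  expect_lt(mean(res["frac_dependent", ]), 0.15)
})

test_that("tidy, glance and autoplot expose the dependence results", {
  sim <- simulate_experiment(n_genes = 300, n_replicates = 4,
                             frac_induced = 0.2, frac_dependent_impaired = 0.8,
                             dispersion = 0.05, seed = 17)
  run <- run_small_pipeline(sim)
  dep <- dependence_analysis(run$de1, run$de2)
  td <- tidy(dep)
  expect_named(td, c("gene_id", "x", "y", "side", "included", "call"))
  gl <- glance(dep)
  expect_equal(gl$side, c("above", "below"))
  expect_true(all(gl$r_squared >= 0 & gl$r_squared <= 1, na.rm = TRUE))
  expect_true(all(abs(gl$spearman_rho) <= 1, na.rm = TRUE))
  expect_s3_class(autoplot(dep), "ggplot")
})
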