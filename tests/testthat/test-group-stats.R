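test_that("photoreceptor selection samples without replacement per animal", {
  pool <- data.frame(animal_id = rep(c("a1", "a2"), c(5, 2)),
                     cell_id = paste0("c", 1:7))
  sel <- select_photoreceptors(pool, k = 3, seed = 1)
  expect_equal(sum(sel$animal_id == "a1"), 3)
  expect_equal(sum(sel$animal_id == "a2"), 2)  # pool smaller than k: all
  expect_false(anyDuplicated(sel$cell_id) > 0)
  expect_identical(sel, select_photoreceptors(pool, k = 3, seed = 1))
  expect_warning(sel0 <- select_photoreceptors(pool[0, ], k = 3, seed = 1),
                 "empty")
  expect_equal(nrow(sel0), 0)
})

test_that("selection is uniform over the pool", {
  pool <- data.frame(animal_id = "a1", cell_id = paste0("c", 1:5))
  counts <- integer(5)
  n_rep <- 4000
  for (s in seq_len(n_rep)) {
    sel <- select_photoreceptors(pool, k = 3, seed = s)
    counts[match(sel$cell_id, pool$cell_id)] <-
      counts[match(sel$cell_id, pool$cell_id)] + 1L
  }
  freq <- counts / n_rep
  se <- sqrt(0.6 * 0.4 / n_rep)
  expect_true(all(abs(freq - 0.6) < 3 * se + 0.02))
})

test_that("identical samples give t = 0, p = 1", {
  r <- compare_two(c(1, 2, 3), c(1, 2, 3), "student_t")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # degenerate zero-variance case
  r0 <- compare_two(c(2, 2), c(2, 2), "student_t")
  expect_equal(r0$p_value, 1)
})

test_that("exact Mann-Whitney reproduces the fully separated case", {
  r <- compare_two(c(1, 2, 3), c(4, 5, 6), "mann_whitney_u")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2 of the 20 labelings are as extreme
  expect_equal(r$method, "exact_enumeration")
})

test_that("exact Mann-Whitney equals full permutation enumeration", {
  set.seed(11)
  for (rep in 1:25) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    a <- sample(1:8, n1, replace = TRUE)  # ties likely
    b <- sample(1:8, n2, replace = TRUE)
    r <- compare_two(a, b, "mann_whitney_u")
    expect_equal(r$p_value, mwu_permutation_p(a, b), tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney p is symmetric and monotone-invariant", {
  set.seed(12)
  for (rep in 1:10) {
    a <- runif(4); b <- runif(5)
    p_ab <- compare_two(a, b, "mann_whitney_u")$p_value
    p_ba <- compare_two(b, a, "mann_whitney_u")$p_value
    expect_equal(p_ab, p_ba, tolerance = 1e-12)
    p_mono <- compare_two(exp(3 * a), exp(3 * b), "mann_whitney_u")$p_value
    expect_equal(p_ab, p_mono, tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney switches to the normal approximation", {
  set.seed(13)
  a <- rnorm(12); b <- rnorm(12, 1)
  r <- compare_two(a, b, "mann_whitney_u")
  expect_equal(r$method, "normal_approximation")
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE,
                                             exact = FALSE))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("ANOVA equals F = t^2 for two groups and handles degenerate input", {
  set.seed(14)
  a <- rnorm(8); b <- rnorm(8, 0.5)
  t_res <- compare_two(a, b, "student_t")
  f_res <- compare_many(list(a = a, b = b))
  expect_equal(f_res$statistic, t_res$statistic^2, tolerance = 1e-9)
  expect_equal(f_res$p_value, t_res$p_value, tolerance = 1e-9)
  expect_equal(compare_many(list(c(1, 1), c(1, 1), c(1, 1)))$statistic, 0)
  expect_equal(compare_many(list(c(1, 2), c(2, 1), c(1, 2)))$statistic, 0)
})

test_that("ANOVA F matches the textbook between/within ratio", {
  set.seed(15)
  groups <- list(g1 = rnorm(6), g2 = rnorm(7, 0.5), g3 = rnorm(5, 1))
  res <- compare_many(groups)
  all_v <- unlist(groups)
  k <- length(groups)
  n <- length(all_v)
  between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - mean(all_v))^2
  }, numeric(1))) / (k - 1)
  within <- sum(vapply(groups, function(g) {
    sum((g - mean(g))^2)
  }, numeric(1))) / (n - k)
  expect_equal(res$statistic, between / within, tolerance = 1e-9)
  # invariant to within-group ordering
  res2 <- compare_many(lapply(groups, rev))
  expect_equal(res2$statistic, res$statistic)
})

test_that("colocalization fraction covers mask and centroid modes", {
  mask <- matrix(FALSE, 10, 10)
  mask[3:6, 3:6] <- TRUE
  inside <- data.frame(x_px = c(3, 4), y_px = c(3, 5),
                       x_nm = c(3, 4) * 210, y_nm = c(3, 5) * 210)
  expect_equal(colocalization_fraction(inside, mask), 1)
  outside <- data.frame(x_px = c(0, 9), y_px = c(0, 9),
                        x_nm = c(0, 9) * 210, y_nm = c(0, 9) * 210)
  expect_equal(colocalization_fraction(outside, mask), 0)
  # centroid mode against an exhaustive distance check
  set.seed(16)
  a <- data.frame(x_nm = runif(20, 0, 4000), y_nm = runif(20, 0, 4000))
  b <- data.frame(x_nm = runif(10, 0, 4000), y_nm = runif(10, 0, 4000))
  got <- colocalization_fraction(a, b, radius_nm = 630)
  brute <- mean(vapply(seq_len(20), function(i) {
    any(sqrt((a$x_nm[i] - b$x_nm)^2 + (a$y_nm[i] - b$y_nm)^2) <= 630)
  }, logical(1)))
  expect_equal(got, brute)
  expect_warning(na <- colocalization_fraction(a[0, ], b), "undefined")
  expect_true(is.na(na))
})
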