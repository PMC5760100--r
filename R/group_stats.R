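#' Randomly select photoreceptors per animal
#'
#' Uniform sampling without replacement of `k` eligible cells per animal
#' (three to four per animal in the reproduced design, to avoid sampling
#' error carryover). Animals with fewer than `k` eligible cells contribute
#' all of them.
#'
#' @param pool data.frame with columns `animal_id` and `cell_id`, or a
#'   character vector of cell ids (treated as one animal).
#' @param k number of cells to select per animal (>= 1).
#' @param seed integer seed; selection is deterministic given seed.
#' @return data.frame `animal_id`, `cell_id` of the selected cells.
#' @export
select_photoreceptors <- function(pool, k = 3L, seed = 1L) {
  stopifnot(k >= 1)
  if (is.atomic(pool)) {
    pool <- data.frame(animal_id = "animal_1", cell_id = pool)
  }
  if (nrow(pool) == 0L) {
    warning("empty photoreceptor pool: nothing selected")
    return(pool[, c("animal_id", "cell_id")])
  }
  set.seed(seed)
  picked <- lapply(split(pool, pool$animal_id), function(d) {
    n <- nrow(d)
    idx <- if (n <= k) seq_len(n) else sample.int(n, k)
    d[sort(idx), c("animal_id", "cell_id"), drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

# Exact two-sided Mann-Whitney p by enumeration of all C(n1+n2, n1)
# group labelings of the combined midranks; handles ties.
mwu_exact <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- sqrt(.Machine$double.eps)
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - eps)
  list(statistic = u_obs, p_value = p)
}

# Normal approximation with tie correction and continuity correction.
mwu_approx <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  n <- n1 + n2
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u_obs, p_value = 1))
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  list(statistic = u_obs, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Two-sample comparison (Student's t or Mann-Whitney U)
#'
#' Two-sided tests as used for the study's pairwise comparisons: Student's
#' t-test (classical equal-variance form; Welch available via `welch`) for
#' kinetic parameters, Mann-Whitney U for non-normally distributed contact
#' parameters. The Mann-Whitney p-value is exact by enumeration of all
#' labelings when the combined sample size is at most 16, and uses the
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param a,b numeric samples.
#' @param test `"student_t"` or `"mann_whitney_u"`.
#' @param welch use the Welch (unequal-variance) t-test.
#' @param labels optional length-2 group labels.
#' @param exact_max_n combined sample size up to which the Mann-Whitney p is
#'   computed by exact enumeration.
#' @return a `comparison_result` list: `test_name`, `statistic`, `p_value`
#'   (two-sided), `n` (group sizes), `labels`, `method`.
#' @export
compare_two <- function(a, b, test = c("student_t", "mann_whitney_u"),
                        welch = FALSE, labels = c("a", "b"),
                        exact_max_n = 16L) {
  test <- match.arg(test)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (test == "student_t") {
    stopifnot(length(a) >= 2L, length(b) >= 2L)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: no variance in either sample
      equal <- isTRUE(all.equal(mean(a), mean(b)))
      res <- list(statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
                  p_value = if (equal) 1 else 0,
                  method = "student_t_degenerate")
    } else {
      ht <- stats::t.test(a, b, var.equal = !welch)
      res <- list(statistic = unname(ht$statistic), p_value = ht$p.value,
                  method = if (welch) "welch_t" else "student_t")
    }
  } else {
    stopifnot(length(a) >= 1L, length(b) >= 1L)
    if (length(a) + length(b) <= exact_max_n) {
      res <- mwu_exact(a, b)
      res$method <- "exact_enumeration"
    } else {
      res <- mwu_approx(a, b)
      res$method <- "normal_approximation"
    }
  }
  structure(list(test_name = test, statistic = res$statistic,
                 p_value = res$p_value, n = c(length(a), length(b)),
                 labels = labels, method = res$method),
            class = "comparison_result")
}

#' One-way fixed-effects ANOVA across groups
#'
#' Used to compare kinetic parameters across more than two conditions.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return a `comparison_result` with the F statistic and two-sided p.
#' @export
compare_many <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  stopifnot(all(vapply(groups, length, integer(1)) >= 2L))
  if (is.null(names(groups))) {
    names(groups) <- paste0("group_", seq_along(groups))
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  if (stats::var(values) == 0) {
    res <- list(statistic = 0, p_value = 1)
  } else {
    ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
    res <- list(statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  structure(list(test_name = "one_way_anova", statistic = res$statistic,
                 p_value = res$p_value,
                 n = vapply(groups, length, integer(1)),
                 labels = names(groups), method = "fixed_effects_f"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, two-sided p = %.4g, n = %s\n",
              x$test_name, x$method, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Fraction of puncta colocalizing with a second channel
#'
#' The fraction of A puncta whose centroid lies inside a B mask (mask mode:
#' `puncta_b` is a logical matrix) or within `radius_nm` of the nearest B
#' centroid (centroid mode: `puncta_b` is a centroid table). The centroid
#' radius defaults to 630 nm for consistency with the basal-body contact
#' radius.
#'
#' @param puncta_a data.frame of A centroids (`x_nm`, `y_nm`; mask mode also
#'   needs `x_px`, `y_px`).
#' @param puncta_b logical matrix (mask mode) or data.frame of centroids
#'   (`x_nm`, `y_nm`).
#' @param radius_nm centroid-mode colocalization radius, nm (> 0).
#' @return fraction in `[0, 1]`, or `NA` (with a warning) when A is empty.
#' @export
colocalization_fraction <- function(puncta_a, puncta_b, radius_nm = 630) {
  if (nrow(puncta_a) == 0L) {
    warning("no A puncta: colocalization fraction undefined")
    return(NA_real_)
  }
  if (is.matrix(puncta_b) && (is.logical(puncta_b) || all(puncta_b %in% c(0, 1)))) {
    stopifnot(all(c("x_px", "y_px") %in% names(puncta_a)))
    hits <- point_in_mask(cbind(puncta_a$x_px, puncta_a$y_px),
                          puncta_b != 0)
    return(mean(hits))
  }
  stopifnot(radius_nm > 0, nrow(puncta_b) >= 0)
  if (nrow(puncta_b) == 0L) return(0)
  d2 <- outer(puncta_a$x_nm, puncta_b$x_nm, "-")^2 +
    outer(puncta_a$y_nm, puncta_b$y_nm, "-")^2
  mean(sqrt(apply(d2, 1, min)) <= radius_nm)
}
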