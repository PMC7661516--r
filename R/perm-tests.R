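# Permutation-based one-way ANOVA across groups and pairwise permutation
# post-hoc tests with multiplicity adjustment and compact letter display.

# Sums of squares and F for a one-way layout. Returns F = 0 when both the
# between- and within-group sums of squares vanish (all values identical).
one_way_f <- function(values, group_index, n_groups) {
  n <- length(values)
  grand <- sum(values)
  group_sums <- rowsum_vec(values, group_index, n_groups)
  group_n <- tabulate(group_index, n_groups)
  ss_total <- sum(values^2) - grand^2 / n
  ss_between <- sum(group_sums^2 / group_n) - grand^2 / n
  ss_within <- ss_total - ss_between
  df_between <- n_groups - 1
  df_within <- n - n_groups
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  f <- if (ss_within <= 1e-12 * max(1, ss_total)) {
    if (ss_between <= 1e-12 * max(1, ss_total)) 0 else Inf
  } else {
    ms_between / ms_within
  }
  list(
    ss_between = ss_between, df_between = df_between,
    ms_between = ms_between,
    ss_within = ss_within, df_within = df_within,
    ms_within = ms_within, f = f
  )
}

rowsum_vec <- function(values, index, n_groups) {
  out <- numeric(n_groups)
  sums <- rowsum(values, index)
  out[as.integer(rownames(sums))] <- sums[, 1]
  out
}

#' Permutation-based one-way ANOVA
#'
#' Tests for differences in a response among groups without distributional
#' assumptions: group labels are permuted uniformly at random and the
#' p-value is the proportion of permutations whose F statistic is at least
#' the observed one, with the add-one convention
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + m)} so p is never exactly zero.
#'
#' @param data Data frame holding the response and grouping columns.
#' @param response,group Unquoted column names of the numeric response and
#'   the group label.
#' @param iterations Number of random label permutations (default 5000).
#' @param seed Integer seed; results are reproducible given a seed.
#' @return An object of class `perm_anova`: a list with the observed ANOVA
#'   decomposition (`ss_between`, `df_between`, `ms_between`, `ss_within`,
#'   `df_within`, `ms_within`, `f_obs`), `iterations`, and `p_value`.
#'   `tidy()` returns the ANOVA table as a tibble.
#' @examples
#' df <- tibble::tibble(
#'   g = rep(c("a", "b", "c"), each = 4),
#'   y = c(rnorm(4), rnorm(4, 1), rnorm(4, 2))
#' )
#' fit <- perm_anova(df, y, g, iterations = 200, seed = 1)
#' tidy(fit)
#' @export
perm_anova <- function(data, response, group, iterations = 5000, seed = NULL) {
  values <- rlang::eval_tidy(rlang::enquo(response), data)
  labels <- rlang::eval_tidy(rlang::enquo(group), data)
  stopifnot(is.numeric(values), length(values) == length(labels))
  if (iterations < 1) stop("`iterations` must be at least 1.", call. = FALSE)
  fg <- if (is.factor(labels)) labels else factor(labels)
  n_groups <- nlevels(fg)
  if (n_groups < 2) stop("need at least 2 groups.", call. = FALSE)
  counts <- tabulate(as.integer(fg), n_groups)
  if (any(counts == 0)) {
    stop(sprintf("group '%s' has no observations.",
                 levels(fg)[which(counts == 0)[1]]), call. = FALSE)
  }
  idx <- as.integer(fg)
  obs <- one_way_f(values, idx, n_groups)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  exceed <- 0L
  tol <- if (is.finite(obs$f)) 1e-12 * max(1, abs(obs$f)) else 0
  for (b in seq_len(iterations)) {
    perm_f <- one_way_f(values[sample.int(n)], idx, n_groups)$f
    if (perm_f >= obs$f - tol) exceed <- exceed + 1L
  }
  structure(
    list(
      ss_between = obs$ss_between, df_between = obs$df_between,
      ms_between = obs$ms_between,
      ss_within = obs$ss_within, df_within = obs$df_within,
      ms_within = obs$ms_within,
      f_obs = obs$f, iterations = iterations,
      p_value = (1 + exceed) / (iterations + 1),
      groups = levels(fg)
    ),
    class = "perm_anova"
  )
}

#' @export
print.perm_anova <- function(x, ...) {
  cat("Permutation-based one-way ANOVA\n")
  cat(sprintf("  groups: %d, iterations: %d\n",
              x$df_between + 1, x$iterations))
  cat(sprintf("  SS between = %.4g (df = %d, MSS = %.4g)\n",
              x$ss_between, x$df_between, x$ms_between))
  cat(sprintf("  F = %.4g, p = %.4g\n", x$f_obs, x$p_value))
  invisible(x)
}

#' @export
tidy.perm_anova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sumsq = c(x$ss_between, x$ss_within),
    meansq = c(x$ms_between, x$ss_within / x$df_within),
    statistic = c(x$f_obs, NA_real_),
    p.value = c(x$p_value, NA_real_)
  )
}

#' @export
glance.perm_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$f_obs, p.value = x$p_value,
    df = x$df_between, df.residual = x$df_within,
    iterations = x$iterations
  )
}

# Two-sample permutation test on the absolute difference of means.
two_sample_perm_p <- function(x, y, iterations) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  obs <- abs(mean(x) - mean(y))
  tol <- 1e-12 * max(1, obs)
  exceed <- 0L
  for (b in seq_len(iterations)) {
    take <- sample.int(n, n1)
    stat <- abs(mean(pooled[take]) - mean(pooled[-take]))
    if (stat >= obs - tol) exceed <- exceed + 1L
  }
  (1 + exceed) / (iterations + 1)
}

# Compact letter display: cliques of the "not significantly different"
# graph get shared letters, so two groups share a letter iff every pairwise
# contrast within the clique is non-significant.
letter_display <- function(group_levels, pair_a, pair_b, significant) {
  k <- length(group_levels)
  adj <- matrix(TRUE, k, k, dimnames = list(group_levels, group_levels))
  for (i in seq_along(pair_a)) {
    if (significant[i]) {
      adj[pair_a[i], pair_b[i]] <- FALSE
      adj[pair_b[i], pair_a[i]] <- FALSE
    }
  }
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(g)
  # deterministic letter order: by first member's position
  ord <- order(vapply(cliques, function(cl) min(as.integer(cl)), 1L))
  cliques <- cliques[ord]
  letters_per_group <- stats::setNames(rep("", k), group_levels)
  for (i in seq_along(cliques)) {
    members <- group_levels[as.integer(cliques[[i]])]
    letters_per_group[members] <- paste0(letters_per_group[members],
                                         letters[i])
  }
  # sort letters within each group for stable display
  unname(vapply(letters_per_group, function(s) {
    paste(sort(strsplit(s, "")[[1]]), collapse = "")
  }, character(1)))
}

#' Pairwise permutation post-hoc tests
#'
#' For every pair of groups, a two-sample permutation test on the absolute
#' difference of means; raw p-values are adjusted for multiplicity and a
#' compact letter display is derived at the chosen significance level
#' (groups sharing a letter are not significantly different).
#'
#' @inheritParams perm_anova
#' @param adjust Multiplicity adjustment: `"holm"` (default), `"BH"`, or
#'   `"none"`.
#' @param alpha Significance level for the letter display.
#' @return An object of class `pairwise_perm`: list with `pairs` (tibble of
#'   `group1, group2, estimate, p.value, p.adjusted`) and `letters` (tibble
#'   of `group, mean, letters`). `tidy()` returns the pair table.
#' @export
pairwise_perm_test <- function(data, response, group, iterations = 5000,
                               seed = NULL, adjust = c("holm", "BH", "none"),
                               alpha = 0.05) {
  adjust <- match.arg(adjust)
  values <- rlang::eval_tidy(rlang::enquo(response), data)
  labels <- rlang::eval_tidy(rlang::enquo(group), data)
  fg <- if (is.factor(labels)) labels else factor(labels)
  if (nlevels(fg) < 2) stop("need at least 2 groups.", call. = FALSE)
  counts <- table(fg)
  if (any(counts == 0)) {
    stop(sprintf("group '%s' has no observations.",
                 names(counts)[which(counts == 0)[1]]), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  lev <- levels(fg)
  combos <- utils::combn(lev, 2)
  pairs <- purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    xa <- values[fg == a]; xb <- values[fg == b]
    tibble::tibble(
      group1 = a, group2 = b,
      estimate = mean(xa) - mean(xb),
      p.value = two_sample_perm_p(xa, xb, iterations)
    )
  })
  pairs$p.adjusted <- stats::p.adjust(pairs$p.value, method = adjust)
  letters_tbl <- tibble::tibble(
    group = lev,
    mean = vapply(lev, function(g) mean(values[fg == g]), numeric(1)),
    letters = letter_display(lev, pairs$group1, pairs$group2,
                             pairs$p.adjusted <= alpha)
  )
  structure(
    list(pairs = pairs, letters = letters_tbl, alpha = alpha,
         adjust = adjust, iterations = iterations),
    class = "pairwise_perm"
  )
}

#' @export
print.pairwise_perm <- function(x, ...) {
  cat(sprintf("Pairwise permutation tests (%s-adjusted, alpha = %g)\n",
              x$adjust, x$alpha))
  print(x$pairs)
  cat("Letters:\n")
  print(x$letters)
  invisible(x)
}

#' @export
tidy.pairwise_perm <- function(x, ...) x$pairs
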