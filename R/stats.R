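# Group-comparison statistics used in song phenotyping. Stock R carries the
# classical tests (fisher.test, wilcox.test, aov, kruskal.test); the
# Dwass-Steel-Critchlow-Fligner all-pairs and Steel many-to-one procedures
# are implemented here directly.

significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 0.001) "***" else if (pp < 0.01) "**"
    else if (pp < 0.05) "*" else "NS"
  }, character(1))
}

new_test_report <- function(test_name, statistic, p_value, comparisons) {
  structure(
    list(test_name = test_name, statistic = statistic, p_value = p_value,
         comparisons = comparisons),
    class = "test_report"
  )
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s", x$test_name))
  if (!is.null(x$statistic)) {
    cat(sprintf(": statistic = %.4g", x$statistic))
  }
  if (!is.null(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  cat("\n")
  if (!is.null(x$comparisons) && nrow(x$comparisons) > 0L) {
    print(as.data.frame(x$comparisons), row.names = FALSE)
  }
  invisible(x)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Used to compare the incidence of polycyclic pulses between genotypes
#' (rows = genotypes, columns = monocyclic/polycyclic counts). Two-sided
#' p-values follow the standard convention: the sum of hypergeometric
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed one.
#'
#' @param table 2x2 matrix of nonnegative counts, or a length-4 vector
#'   `c(a, b, c, d)` filled by row.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A `test_report` with the odds-ratio estimate as statistic.
#' @export
fisher_exact <- function(table, alternative = "two.sided") {
  m <- as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("empty row or column margin", call. = FALSE)
  }
  ft <- stats::fisher.test(m, alternative = alternative)
  cmp <- tibble::tibble(
    comparison = "row1 vs row2",
    statistic = unname(ft$estimate),
    p_raw = ft$p.value,
    p_adj = ft$p.value,
    stars = significance_stars(ft$p.value)
  )
  new_test_report("Fisher's exact test", unname(ft$estimate), ft$p.value, cmp)
}

as_2x2 <- function(table) {
  if (is.matrix(table)) {
    if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
    m <- table
  } else if (length(table) == 4L) {
    m <- matrix(as.numeric(table), 2L, 2L, byrow = TRUE)
  } else {
    stop("need a 2x2 table", call. = FALSE)
  }
  if (any(m < 0) || sum(m) <= 0) {
    stop("counts must be nonnegative with a positive total", call. = FALSE)
  }
  m
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison with midranks for ties. The p-value is
#' exact (by enumeration of the rank-sum distribution) when the smaller
#' sample has at most 8 observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y Numeric samples.
#' @return A `test_report`; the statistic is the U of `x`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples need at least one observation", call. = FALSE)
  }
  ties <- any(duplicated(c(x, y)))
  use_exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = !use_exact)
  )
  u <- unname(wt$statistic)
  cmp <- tibble::tibble(
    comparison = "x vs y", statistic = u, p_raw = wt$p.value,
    p_adj = wt$p.value, stars = significance_stars(wt$p.value)
  )
  new_test_report("Mann-Whitney U test", u, wt$p.value, cmp)
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Omnibus F test across groups followed by all-pairs pooled-SD t tests
#' whose p-values are multiplied by the number of pairs (capped at 1).
#'
#' @param groups Named (or unnamed) list of >= 2 numeric vectors, each of
#'   length >= 2.
#' @return A `test_report`; `statistic` is F, `p_value` the omnibus p, and
#'   `comparisons` the per-pair adjusted results.
#' @export
anova_bonferroni <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (any(vapply(groups, stats::sd, numeric(1)) == 0)) {
    warning("a group has zero variance; F statistic may be unstable",
            call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  f_stat <- an[["F value"]][1]
  p_omni <- an[["Pr(>F)"]][1]

  pt <- suppressWarnings(
    stats::pairwise.t.test(y, g, p.adjust.method = "bonferroni",
                           pool.sd = TRUE)
  )
  pairs <- which(!is.na(pt$p.value), arr.ind = TRUE)
  cmp <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    a <- rownames(pt$p.value)[i]; b <- colnames(pt$p.value)[j]
    p_adj <- pt$p.value[i, j]
    tibble::tibble(
      comparison = paste(b, "vs", a), statistic = NA_real_,
      p_raw = NA_real_, p_adj = p_adj, stars = significance_stars(p_adj)
    )
  }))
  new_test_report("one-way ANOVA + Bonferroni", f_stat, p_omni, cmp)
}

# Standardized pairwise rank-sum statistic on the two groups' own midranks,
# with tie correction; returns z. Shared by the DSCF and Steel procedures.
pairwise_ranksum_z <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  e <- na * (N + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- na * nb / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(0)
  (w - e) / sqrt(v)
}

#' Kruskal-Wallis test with Dwass-Steel-Critchlow-Fligner all-pairs
#' comparisons
#'
#' Omnibus Kruskal-Wallis H (tie-corrected) followed by the DSCF procedure:
#' each pair of groups is re-ranked on its own, the standardized rank-sum
#' statistic is referred to the studentized range distribution with as many
#' means as groups (p from `ptukey` on `|z| * sqrt(2)`).
#'
#' @param groups Named (or unnamed) list of >= 2 numeric vectors, each n >= 2.
#' @return A `test_report`; `statistic` is H, `p_value` the omnibus p.
#' @export
kruskal_steel_dwass <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  k <- length(groups)
  kw <- stats::kruskal.test(groups)
  combs <- utils::combn(k, 2)
  cmp <- do.call(rbind, lapply(seq_len(ncol(combs)), function(c_idx) {
    i <- combs[1, c_idx]; j <- combs[2, c_idx]
    z <- pairwise_ranksum_z(groups[[i]], groups[[j]])
    stat <- abs(z) * sqrt(2)
    p <- stats::ptukey(stat, nmeans = k, df = Inf, lower.tail = FALSE)
    tibble::tibble(
      comparison = paste(names(groups)[i], "vs", names(groups)[j]),
      statistic = stat, p_raw = p, p_adj = p,
      stars = significance_stars(p)
    )
  }))
  new_test_report("Kruskal-Wallis + Steel-Dwass (DSCF)",
                  unname(kw$statistic), kw$p.value, cmp)
}

#' Kruskal-Wallis test with Steel's many-to-one comparisons
#'
#' Omnibus Kruskal-Wallis H followed by Steel's nonparametric many-to-one
#' procedure: each treatment group is compared with the designated control
#' on the ranks of that pair alone, and the family of standardized
#' statistics is referred to the maximum of correlated normals with the
#' Steel correlation `rho_jk = sqrt(n_j n_k / ((n0 + n_j)(n0 + n_k)))`
#' (0.5 at equal group sizes), evaluated with a seeded multivariate-normal
#' quadrature so results are reproducible.
#'
#' @param groups Named (or unnamed) list of >= 3 numeric vectors.
#' @param control_index Index of the control group within `groups`.
#' @return A `test_report` with one comparison per treatment group.
#' @export
kruskal_steel <- function(groups, control_index = 1L) {
  if (length(groups) < 3L) {
    stop("need a control and at least two treatment groups", call. = FALSE)
  }
  if (control_index < 1L || control_index > length(groups)) {
    stop("control_index out of range", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  kw <- stats::kruskal.test(groups)
  ctrl <- groups[[control_index]]
  n0 <- length(ctrl)
  treat_idx <- setdiff(seq_along(groups), control_index)
  m <- length(treat_idx)
  ns <- vapply(groups[treat_idx], length, integer(1))
  corr <- diag(m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) {
        corr[i, j] <- sqrt(ns[i] * ns[j] /
                             ((n0 + ns[i]) * (n0 + ns[j])))
      }
    }
  }
  zs <- vapply(treat_idx, function(ti) {
    pairwise_ranksum_z(groups[[ti]], ctrl)
  }, numeric(1))
  ps <- vapply(zs, function(z) {
    t_abs <- abs(z)
    if (t_abs == 0) return(1)
    pr <- with_local_seed(20231118L, mvtnorm::pmvnorm(
      lower = rep(-t_abs, m), upper = rep(t_abs, m),
      mean = rep(0, m), corr = corr
    ))
    min(max(1 - as.numeric(pr), 0), 1)
  }, numeric(1))
  cmp <- tibble::tibble(
    comparison = paste(names(groups)[treat_idx], "vs",
                       names(groups)[control_index]),
    statistic = zs, p_raw = ps, p_adj = ps,
    stars = significance_stars(ps)
  )
  new_test_report("Kruskal-Wallis + Steel many-to-one",
                  unname(kw$statistic), kw$p.value, cmp)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}
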