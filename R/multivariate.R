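# Permutation-based multivariate statistics, implemented from first
# principles on the distance matrix (one-way designs only).

align_labels <- function(D, labels) {
  ids <- attr(D, "Labels")
  if (is.null(ids)) ids <- rownames(as.matrix(D))
  if (!is.null(names(labels))) {
    miss <- setdiff(ids, names(labels))
    if (length(miss)) stop("labels missing for sample(s): ",
                           paste(miss, collapse = ", "))
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels must be named or match the distance matrix order")
  }
  factor(as.character(labels))
}

# sum of squares decomposition of a squared-distance matrix under a grouping
ss_decompose <- function(D2, g) {
  N <- nrow(D2)
  ss_tot <- sum(D2[upper.tri(D2)]) / N
  ss_w <- 0
  for (lv in levels(g)) {
    idx <- which(g == lv)
    if (length(idx) > 1L)
      ss_w <- ss_w + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
  }
  c(total = ss_tot, within = ss_w, between = ss_tot - ss_w)
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' the total sum of squared inter-point distances is partitioned into
#' within- and between-group components (SS_total = sum over pairs of
#' d^2 / N; SS_within = sum over groups of within-group pair d^2 / n_g),
#' giving pseudo-F = (SS_between / (a - 1)) / (SS_within / (N - a)) and
#' R^2 = SS_between / SS_total. Significance comes from free permutation of
#' sample labels with the add-one rule, so p is never 0 and never below
#' 1 / (n_perm + 1).
#'
#' @param D a `dist` object (e.g. [bray_curtis()]).
#' @param labels group label per sample: a named vector covering the
#'   distance labels, or an unnamed vector in matrix order. >= 2 groups.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return object of class `permanova_result`: `R2`, `pseudo_F`, `p_perm`,
#'   `n_permutations`, `df`, and the sums of squares.
#' @export
permanova <- function(D, labels, n_perm = 999, seed = NULL) {
  g <- align_labels(D, labels)
  a <- nlevels(g)
  N <- length(g)
  if (a < 2L) stop("need at least 2 groups (one group absorbs all samples)")
  D2 <- as.matrix(D)^2
  ss <- ss_decompose(D2, g)
  df1 <- a - 1L
  df2 <- N - a
  f_of <- function(ssv) (ssv[["between"]] / df1) / (ssv[["within"]] / df2)
  if (ss[["within"]] <= .Machine$double.eps * ss[["total"]]) {
    f_obs <- Inf
    p <- 1 / (n_perm + 1)
  } else {
    f_obs <- f_of(ss)
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        gp <- sample(g)
        f_of(ss_decompose(D2, gp))
      }, numeric(1)) >= f_obs)
    })
    p <- (1 + hits) / (n_perm + 1)
  }
  structure(list(R2 = unname(ss[["between"]] / ss[["total"]]),
                 pseudo_F = unname(f_obs), p_perm = p,
                 n_permutations = n_perm, df = c(df1, df2),
                 ss = ss, groups = table(g)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova> pseudo-F = %.3f (df %d, %d), R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$R2, x$p_perm, x$n_permutations))
  invisible(x)
}

# principal-coordinates embedding retaining negative-eigenvalue axes
pcoa_embed <- function(D) {
  m <- as.matrix(D)
  n <- nrow(m)
  A <- -0.5 * m^2
  G <- A - rowMeans(A)[row(A)] - colMeans(A)[col(A)] + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * n * .Machine$double.eps
  pos <- e$values > tol
  neg <- e$values < -tol
  list(pos = e$vectors[, pos, drop = FALSE] %*%
         diag(sqrt(e$values[pos]), sum(pos)),
       neg = e$vectors[, neg, drop = FALSE] %*%
         diag(sqrt(-e$values[neg]), sum(neg)),
       ids = rownames(m))
}

anova_f <- function(z, g) {
  N <- length(z)
  a <- nlevels(g)
  gm <- tapply(z, g, mean)
  n_g <- tabulate(g)
  ssb <- sum(n_g * (gm - mean(z))^2)
  ssw <- sum((z - gm[g])^2)
  (ssb / (a - 1)) / (ssw / (N - a))
}

#' Permutation test of multivariate dispersion homogeneity (PERMDISP)
#'
#' Embeds the distance matrix by principal-coordinates analysis (keeping
#' negative-eigenvalue axes, whose squared contributions are subtracted and
#' the result clamped at zero — the standard treatment for semi-metric
#' dissimilarities like Bray-Curtis), computes each sample's distance to
#' its group centroid, optionally applies the small-sample bias correction
#' (multiplying each group's distances by sqrt(n_g / (n_g - 1)), relevant
#' for strongly unequal group sizes), and tests the one-way ANOVA F on
#' those distances by permuting group labels over the distance values.
#'
#' @inheritParams permanova
#' @param bias_adjust apply the sqrt(n / (n - 1)) small-sample correction
#'   (default `TRUE`).
#' @return object of class `permdisp_result`: per-group mean
#'   distance-to-centroid, `F`, `p_perm`, and the per-sample distances.
#' @export
permdisp <- function(D, labels, bias_adjust = TRUE, n_perm = 999, seed = NULL) {
  g <- align_labels(D, labels)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  n_g <- table(g)
  if (any(n_g < 2L))
    stop("group(s) of size 1: ", paste(names(n_g)[n_g < 2], collapse = ", "))
  emb <- pcoa_embed(D)
  z <- numeric(length(g))
  for (lv in levels(g)) {
    idx <- which(g == lv)
    cp <- colMeans(emb$pos[idx, , drop = FALSE])
    cn <- if (ncol(emb$neg)) colMeans(emb$neg[idx, , drop = FALSE]) else numeric(0)
    d2 <- rowSums(sweep(emb$pos[idx, , drop = FALSE], 2L, cp)^2)
    if (ncol(emb$neg))
      d2 <- d2 - rowSums(sweep(emb$neg[idx, , drop = FALSE], 2L, cn)^2)
    z[idx] <- sqrt(pmax(d2, 0))
  }
  if (bias_adjust) {
    adj <- sqrt(as.numeric(n_g) / (as.numeric(n_g) - 1))
    z <- z * adj[as.integer(g)]
  }
  f_obs <- anova_f(z, g)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) anova_f(z, sample(g)),
               numeric(1)) >= f_obs)
  })
  p <- (1 + hits) / (n_perm + 1)
  means <- tapply(z, g, mean)
  structure(list(group_means = means, F = f_obs, p_perm = p,
                 n_permutations = n_perm, distances = stats::setNames(z, emb$ids),
                 bias_adjust = bias_adjust, groups = n_g),
            class = "permdisp_result")
}

#' @export
print.permdisp_result <- function(x, ...) {
  cat(sprintf("<permdisp> F = %.3f, p = %.4g (%d permutations%s)\n",
              x$F, x$p_perm, x$n_permutations,
              if (x$bias_adjust) ", bias-adjusted" else ""))
  print(round(x$group_means, 4))
  invisible(x)
}

indval_stat <- function(m, g) {
  n_g <- tabulate(g)
  mean_ab <- rowsum(m, g, reorder = TRUE) / n_g          # groups x taxa
  tot <- colSums(mean_ab)
  A <- sweep(mean_ab, 2L, ifelse(tot > 0, tot, 1), "/")
  B <- rowsum((m > 0) + 0, g, reorder = TRUE) / n_g
  IV <- A * B
  list(stat = apply(IV, 2L, max),
       group = rownames(IV)[apply(IV, 2L, which.max)])
}

#' Indicator species analysis (IndVal)
#'
#' The Dufrene-Legendre indicator value: for taxon i and group j,
#' A_ij = (mean abundance of i in j) / (sum of i's group mean abundances)
#' measures specificity and B_ij = (fraction of j's samples containing i)
#' measures fidelity; IndVal_ij = A_ij * B_ij, and the reported value is
#' the maximum over groups. Significance by free permutation of group
#' labels (add-one rule). The statistic is computed on the table as given
#' (normally group-mean relative abundances at phylum/class level);
#' rescaling one sample's row changes A unless the table is renormalised.
#'
#' @param table samples x taxa abundance matrix, possibly rank-aggregated
#'   ([aggregate_taxa()]).
#' @param labels group per sample (named, or in row order).
#' @param threshold indicator value cutoff (default 0.6).
#' @param alpha permutation p-value cutoff (default 0.01).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return data.frame of class `indval_result`: `taxon`, `group` (argmax),
#'   `indval`, `p_perm`, `is_indicator`. Taxa absent everywhere are
#'   excluded with a message.
#' @export
indval <- function(table, labels, threshold = 0.6, alpha = 0.01,
                   n_perm = 999, seed = NULL) {
  m <- unclass(table)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("taxon", seq_len(ncol(m)))
  if (!is.null(names(labels))) {
    miss <- setdiff(rownames(m), names(labels))
    if (length(miss)) stop("labels missing for sample(s): ",
                           paste(miss, collapse = ", "))
    labels <- labels[rownames(m)]
  } else if (length(labels) != nrow(m)) {
    stop("labels must be named or match the table's rows")
  }
  g <- factor(as.character(labels))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  absent <- colSums(m) == 0
  if (any(absent)) {
    message("excluding ", sum(absent), " taxa absent from every sample")
    m <- m[, !absent, drop = FALSE]
  }
  obs <- indval_stat(m, g)
  hits <- with_seed(seed, {
    acc <- numeric(ncol(m))
    for (i in seq_len(n_perm)) {
      acc <- acc + (indval_stat(m, sample(g))$stat >= obs$stat)
    }
    acc
  })
  p <- (1 + hits) / (n_perm + 1)
  out <- data.frame(taxon = colnames(m), group = obs$group,
                    indval = unname(obs$stat), p_perm = unname(p),
                    is_indicator = unname(obs$stat >= threshold & p < alpha),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("indval_result", "data.frame")
  out
}
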