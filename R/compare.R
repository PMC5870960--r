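#' @include selection.R
NULL

#' Pairwise correlations among codon-usage indices
#'
#' Pearson product-moment correlations with two-tailed significance between
#' every pair of index columns, using pairwise-complete observations
#' (undefined per-gene indices are dropped pair by pair). A column with zero
#' variance yields `NA` coefficients.
#'
#' @param profiles data.frame of numeric index columns (non-numeric columns
#'   such as `gene_id` are ignored), e.g. from [indexTable()].
#' @param method Correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @param minN Minimum pairwise-complete observations below which the pair
#'   is left `NA`; default 3. Pairs with fewer than 5 observations trigger a
#'   small-sample warning (whole-genome correlations over a handful of
#'   genomes are supported but fragile).
#' @return List of matrices `r`, `p`, `n` (class `"cubCorrelation"`), with
#'   unit diagonal on `r`.
#' @export
correlateIndices <- function(profiles, method = c("pearson", "spearman"),
                             minN = 3L) {
  method <- match.arg(method)
  num <- profiles[vapply(profiles, is.numeric, logical(1))]
  vars <- names(num)
  k <- length(vars)
  if (k < 2) stop("need at least two numeric index columns")
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    r[i, i] <- 1
    n[i, i] <- sum(!is.na(num[[i]]))
    for (j in seq_len(i - 1L)) {
      ok <- !is.na(num[[i]]) & !is.na(num[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < minN) next
      xi <- num[[i]][ok]; xj <- num[[j]][ok]
      if (sd(xi) == 0 || sd(xj) == 0) next
      ct <- stats::cor.test(xi, xj, method = method, exact = FALSE)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  small <- n[lower.tri(n)] < 5
  if (any(small, na.rm = TRUE))
    warning("some index pairs have fewer than 5 complete observations; ",
            "correlations are unstable at this sample size")
  structure(list(r = r, p = p, n = n, method = method),
            class = "cubCorrelation")
}

#' @export
print.cubCorrelation <- function(x, digits = 3, ...) {
  cat("Pairwise", x$method, "correlations (r):\n")
  print(round(x$r, digits))
  invisible(x)
}

# Duncan least significant range for span p:
# protection level 1-(1-alpha)^(p-1), studentized-range quantile
.duncanRange <- function(p, dfError, alpha, se) {
  alphaP <- 1 - (1 - alpha)^(p - 1)
  qtukey(1 - alphaP, nmeans = p, df = dfError) * se
}

# Letter assignment for a multiple range test over means sorted descending.
# Stepwise protocol: spans are examined from largest to smallest; a span
# whose range does not exceed its critical value is declared homogeneous
# and none of its sub-spans are tested.
.rangeLetters <- function(meansDesc, crit) {
  k <- length(meansDesc)
  if (k == 1L) return("a")
  ns <- diag(TRUE, k)
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      if (ns[i, j]) next
      if (meansDesc[i] - meansDesc[j] <= crit[span]) {
        ns[i:j, i:j] <- TRUE  # homogeneous block; protects sub-spans
      }
    }
  }
  # maximal homogeneous intervals, left to right
  intervals <- list()
  for (i in seq_len(k)) {
    j <- max(which(ns[i, ]))
    if (!length(intervals) ||
        intervals[[length(intervals)]][2] < j)
      intervals[[length(intervals) + 1L]] <- c(i, j)
  }
  letters_ <- rep("", k)
  for (li in seq_along(intervals)) {
    iv <- intervals[[li]]
    idx <- iv[1]:iv[2]
    letters_[idx] <- paste0(letters_[idx], letters[li])
  }
  letters_
}

#' One-way ANOVA with Duncan's multiple range test
#'
#' Fits a one-way ANOVA across groups, then compares group means with
#' Duncan's multiple range test: means are ordered, and the range of every
#' span of p consecutive means is compared with the least significant range
#' R_p = q(1 - alpha_p, p, df) * sqrt(MSE / nh), where
#' alpha_p = 1 - (1 - alpha)^(p - 1) is Duncan's protection level, q the
#' studentized-range quantile and nh the harmonic mean of group sizes.
#' Groups sharing a letter are not significantly different at `alpha`.
#' With exactly 2 groups the procedure coincides with the pooled-variance
#' t-test.
#'
#' @param groups Named list of numeric vectors (one per group, each with at
#'   least 2 values).
#' @param alpha Comparisonwise significance level, default 0.05.
#' @return List of class `"duncanTest"`: `table` (data.frame: group, n,
#'   mean, sd, letters, in input order), `F`, `pValue`, `dfError`, `MSE`,
#'   `alpha`, `criticalRanges`.
#' @export
#' @examples
#' set.seed(1)
#' g <- list(a = rnorm(10), b = rnorm(10, 5), c = rnorm(10, 5.2))
#' anovaDuncan(g)$table
anovaDuncan <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("groups must be uniquely named")
  groups <- lapply(groups, function(v) v[!is.na(v)])
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 non-missing values")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups)))
  fit <- aov(value ~ group, data = df)
  at <- anova(fit)
  mse <- at["Residuals", "Mean Sq"]
  dfErr <- at["Residuals", "Df"]
  if (mse == 0) stop("zero error mean square; Duncan ranges undefined")
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, sd, numeric(1))
  nh <- length(sizes) / sum(1 / sizes)
  se <- sqrt(mse / nh)
  k <- length(groups)
  crit <- c(NA_real_, vapply(2:k, .duncanRange, numeric(1),
                             dfError = dfErr, alpha = alpha, se = se))
  ord <- order(-means, names(means))  # descending mean, ties by label
  letts <- .rangeLetters(means[ord], crit)
  lettersByGroup <- setNames(letts, names(means)[ord])[names(groups)]
  structure(list(
    table = data.frame(group = names(groups), n = as.integer(sizes),
                       mean = unname(means), sd = unname(sds),
                       letters = unname(lettersByGroup),
                       row.names = NULL, stringsAsFactors = FALSE),
    F = at["group", "F value"], pValue = at["group", "Pr(>F)"],
    dfError = dfErr, MSE = mse, alpha = alpha,
    criticalRanges = crit), class = "duncanTest")
}

#' @export
print.duncanTest <- function(x, digits = 4, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g (df error %d)\n",
              x$F, x$pValue, x$dfError))
  cat(sprintf("Duncan's multiple range test at alpha = %g\n", x$alpha))
  tab <- x$table
  tab$mean <- round(tab$mean, digits)
  tab$sd <- round(tab$sd, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Hierarchical clustering of gene sets by RSCU
#'
#' Agglomerative clustering of labelled RSCU vectors (one per genome,
#' subgenome or other gene set) on Euclidean distance with average linkage
#' by default. Undefined RSCU entries are imputed with 1 (the no-bias
#' value) before distance computation. Labels are sorted lexicographically
#' before clustering so the result, including its Newick serialisation, is
#' invariant under input reordering.
#'
#' @param rscuBySet Numeric matrix with one row per labelled set (rownames
#'   required) and one column per synonymous codon, or a named list of
#'   equal-length RSCU vectors.
#' @param distMethod Distance passed to [stats::dist()], default
#'   `"euclidean"`.
#' @param linkage Linkage passed to [stats::hclust()], default
#'   `"average"`.
#' @return List of class `"rscuClusterTree"`: `hclust`, `phylo`
#'   (an [ape::as.phylo()] tree) and `newick` (serialised string).
#' @export
rscuCluster <- function(rscuBySet, distMethod = "euclidean",
                        linkage = "average") {
  if (is.list(rscuBySet) && !is.data.frame(rscuBySet))
    rscuBySet <- do.call(rbind, rscuBySet)
  rscuBySet <- as.matrix(rscuBySet)
  if (nrow(rscuBySet) < 2) stop("need at least 2 labelled RSCU vectors")
  if (is.null(rownames(rscuBySet)) || anyDuplicated(rownames(rscuBySet)))
    stop("RSCU vectors must carry unique labels (rownames)")
  rscuBySet[is.na(rscuBySet)] <- 1
  rscuBySet <- rscuBySet[order(rownames(rscuBySet)), , drop = FALSE]
  hc <- hclust(dist(rscuBySet, method = distMethod), method = linkage)
  ph <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = ph,
                 newick = ape::write.tree(ph)),
            class = "rscuClusterTree")
}

#' @export
print.rscuClusterTree <- function(x, ...) {
  cat("RSCU cluster tree over", length(x$hclust$labels), "sets:\n")
  cat(x$newick, "\n")
  invisible(x)
}
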