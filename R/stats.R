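#' One-way analysis of variance
#'
#' Classical fixed-effects one-way decomposition via the base linear model,
#' reported in the F(df1, df2) = F, p format. The degenerate case where every
#' observation is identical (zero between- and within-group variance) is
#' reported as F = 0, p = 1 rather than 0/0.
#'
#' @param values numeric response
#' @param groups grouping factor (>= 2 non-empty groups)
#' @return list: `f`, `df` (length 2), `p`, `n`, `k`, formatted `label` like
#'   "F2,9 = 0.107, p = 0.900"
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) == 0)) stop("a group has zero observations")
  n <- length(values)
  k <- nlevels(groups)
  if (n - k < 1) stop("no residual degrees of freedom")
  gm <- tapply(values, groups, mean)
  ss_between <- sum(table(groups) * (gm - mean(values))^2)
  if (ss_between < .Machine$double.eps * sum(values^2 + 1)) {
    f <- 0
    p <- 1
  } else {
    a <- stats::anova(stats::lm(values ~ groups))
    f <- a$`F value`[1]
    p <- a$`Pr(>F)`[1]
  }
  list(
    f = f, df = c(k - 1, n - k), p = p, n = n, k = k,
    label = sprintf("F%d,%d = %.3f, p = %.3f", k - 1, n - k, f, p)
  )
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation with average ranks for ties. The two-sided p-value is
#' computed by exhaustive enumeration over all permutations of one ranking
#' for n <= `exact_n` (counting permutations with |rho| >= |rho observed|),
#' and by the t approximation `t = rho sqrt((n-2)/(1-rho^2))` above that.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant
#' @param exact_n enumeration threshold (default 9; 9! = 362,880
#'   permutations)
#' @return list: `rho`, `p`, `n`, `method` ("exact" or "t-approximation"),
#'   formatted `label`
#' @export
spearman_correlation <- function(x, y, exact_n = 9) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance in a ranked vector")
  rho <- stats::cor(rx, ry)

  if (n <= exact_n) {
    # enumerate rho over all permutations of ry against fixed rx; rho is
    # affine in the permuted inner product, so only crossprods are needed
    perms <- permutations_of(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    ips <- as.vector(matrix(ryc[perms], nrow = nrow(perms)) %*% rxc)
    rhos <- ips / sqrt(sum(rxc^2) * sum(ryc^2))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method,
       label = sprintf("rho = %.3f, p = %.3f (n = %d, %s)",
                       rho, p, n, method))
}

# all n! permutations of 1..n as rows (n <= 9 by construction upstream)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(
      sub[, seq_len(pos - 1L), drop = FALSE],
      n,
      sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE]
    )
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Aggregate ASV relative abundances to a taxonomic rank
#'
#' Sums the relative abundance of all ASVs sharing the same classification at
#' the requested rank within each sample. Totals are conserved; an unassigned
#' fraction (per-sample sums below 1) is allowed and preserved under an
#' "unassigned" label when rank labels are missing.
#'
#' @param asv_table data.frame with `sample`, `rel_abund` and one column per
#'   rank (e.g. `family`, `genus`); NA rank labels become "unassigned"
#' @param rank name of the rank column to aggregate by
#' @return data.frame: sample, taxon, rel_abund
#' @export
aggregate_taxa <- function(asv_table, rank) {
  stopifnot(all(c("sample", "rel_abund") %in% names(asv_table)))
  if (!rank %in% names(asv_table))
    stop(sprintf("unknown rank '%s'", rank))
  sums <- tapply(asv_table$rel_abund, asv_table$sample, sum)
  if (any(sums > 1 + 1e-9))
    stop("per-sample relative abundances must sum to <= 1")
  lab <- as.character(asv_table[[rank]])
  lab[is.na(lab) | lab == ""] <- "unassigned"
  agg <- stats::aggregate(
    rel_abund ~ sample + taxon,
    data = data.frame(sample = asv_table$sample, taxon = lab,
                      rel_abund = asv_table$rel_abund),
    FUN = sum
  )
  agg[order(agg$sample, agg$taxon), , drop = FALSE]
}
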