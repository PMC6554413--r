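#' Spearman correlation matrix of index values
#'
#' Pairwise Spearman rank correlations (average-rank tie handling) between
#' the columns of a networks-by-indices table, as used to check whether the
#' neighbourhood degree sequence indices duplicate classical indices.
#' Because Spearman operates on ranks, any strictly monotone transform of a
#' column leaves the matrix unchanged. Constant columns have no rank spread;
#' their off-diagonal entries are \code{NA} and the column is flagged.
#'
#' @param x A numeric matrix or data frame (rows = networks, columns =
#'   indices); at least 3 rows.
#' @return An object of class \code{"spearman_matrix"}: list with \code{rho}
#'   (symmetric matrix, unit diagonal), \code{abs_mean} and \code{abs_sd}
#'   (mean/SD of off-diagonal absolute correlations), \code{flagged}
#'   (names of constant columns).
#' @export
spearman_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("index table must be numeric")
  if (nrow(x) < 3L) stop("need at least 3 networks (rows)")
  const <- apply(x, 2, function(col) stats::sd(col, na.rm = TRUE) == 0)
  rho <- suppressWarnings(stats::cor(x, method = "spearman",
                                     use = "pairwise.complete.obs"))
  diag(rho) <- 1
  off <- abs(rho[upper.tri(rho)])
  structure(list(rho = rho,
                 abs_mean = mean(off, na.rm = TRUE),
                 abs_sd = stats::sd(off, na.rm = TRUE),
                 flagged = colnames(x)[which(const)]),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 3, ...) {
  print(round(x$rho, digits))
  cat("mean |rho| off-diagonal:", round(x$abs_mean, digits),
      "(SD", round(x$abs_sd, digits), ")\n")
  if (length(x$flagged)) cat("constant columns:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

# Exact null distribution of the doubled signed-rank statistic 2*W+ under
# H0 (each pair's sign equally likely), by convolution over the (possibly
# tied, average) ranks. Doubling makes tied half-ranks integral. Returns the
# probability vector over 0 .. sum(2r).
signed_rank_null <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1:(total + 1L - r)]
    f <- g / 2
  }
  f
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences \code{x - y}. Zero
#' differences are dropped (Wilcoxon's original treatment; the count is
#' reported). For \code{n <= exact_limit} non-zero pairs the p-value is
#' exact, computed from the full null distribution of the statistic over all
#' \eqn{2^n} sign assignments (handled by convolution, valid under ties via
#' average ranks); larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @param exact_limit Largest n for which the exact branch is used
#'   (default 25).
#' @return A list with \code{statistic} (W+, the positive-rank sum),
#'   \code{p_value} (\code{NA} with \code{degenerate = TRUE} when all
#'   differences are zero), \code{n_used}, \code{n_zero}, \code{method}.
#' @export
wilcoxon_paired <- function(x, y, exact_limit = 25L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_, n_used = 0L,
                n_zero = n_zero, method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    null <- signed_rank_null(r2)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(null[1:(w2 + 1L)])
    p_ge <- sum(null[(w2 + 1L):length(null)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sig2)   # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "asymptotic"
  }
  list(statistic = W, p_value = p, n_used = n, n_zero = n_zero,
       method = method, degenerate = FALSE)
}

#' Matched-pairs rank-biserial effect size
#'
#' The signed effect size for the paired signed-rank test,
#' \deqn{r_{rb} = (W^+ - W^-) / (W^+ + W^-),} where \eqn{W^+} and \eqn{W^-}
#' are the rank sums of positive and negative differences \code{x - y}
#' (zeros dropped). Ranges over [−1, 1]; +1 when every \code{x} exceeds its
#' \code{y}, −1 in the reverse case, 0 when all differences are zero. The
#' sign convention: positive means \code{x} (e.g. the observed networks)
#' tends to exceed \code{y} (e.g. their configuration-model nulls).
#'
#' @inheritParams wilcoxon_paired
#' @return A number in [−1, 1].
#' @export
paired_rank_effect <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  if (length(d) == 0L) return(0)
  r <- rank(abs(d))
  wpos <- sum(r[d > 0]); wneg <- sum(r[d < 0])
  (wpos - wneg) / (wpos + wneg)
}

#' Corpus-level comparison of observed indices against null ensembles
#'
#' For each index (optionally within each network class), pairs every
#' network's observed value with the mean of its configuration-model
#' ensemble and runs a two-sided paired Wilcoxon signed-rank test with a
#' rank-biserial effect size. Strata with fewer than \code{min_n} usable
#' pairs are reported descriptively (effect size and median difference, no
#' p-value). Pairs with a missing observed or null value are excluded with a
#' message.
#'
#' @param tab A long-format data frame with columns \code{network},
#'   \code{index}, \code{observed}, \code{null_mean}, and optionally
#'   \code{class}.
#' @param by_class Stratify by the \code{class} column.
#' @param min_n Minimum pairs for testing (default 5).
#' @return An object of class \code{"null_comparison"}: a data frame with
#'   one row per index (and class), columns \code{index}, \code{class},
#'   \code{n}, \code{median_diff}, \code{statistic}, \code{p_value},
#'   \code{effect_size}, \code{tested}.
#' @export
compare_corpus <- function(tab, by_class = FALSE, min_n = 5L) {
  need <- c("network", "index", "observed", "null_mean")
  if (!all(need %in% names(tab)))
    stop("tab must have columns: ", paste(need, collapse = ", "))
  if (by_class && !"class" %in% names(tab))
    stop("by_class = TRUE needs a 'class' column")
  drop <- is.na(tab$observed) | is.na(tab$null_mean)
  if (any(drop)) {
    message(sum(drop), " network/index pairs excluded (missing values)")
    tab <- tab[!drop, , drop = FALSE]
  }
  groups <- if (by_class) split(tab, list(tab$index, tab$class), drop = TRUE)
            else split(tab, tab$index)
  rows <- lapply(groups, function(gdf) {
    x <- gdf$observed; y <- gdf$null_mean
    n <- length(x)
    eff <- paired_rank_effect(x, y)
    md <- stats::median(x - y)
    if (n >= min_n) {
      wt <- wilcoxon_paired(x, y)
      data.frame(index = gdf$index[1],
                 class = if (by_class) gdf$class[1] else NA_character_,
                 n = n, median_diff = md, statistic = wt$statistic,
                 p_value = wt$p_value, effect_size = eff, tested = TRUE)
    } else {
      data.frame(index = gdf$index[1],
                 class = if (by_class) gdf$class[1] else NA_character_,
                 n = n, median_diff = md, statistic = NA_real_,
                 p_value = NA_real_, effect_size = eff, tested = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("null_comparison", "data.frame")
  out
}
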