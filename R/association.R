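#' Fisher exact test for a 2x2 table with log2 odds ratio
#'
#' The two-sided p value follows the point-probability convention (sum of
#' hypergeometric probabilities of all tables, with the observed margins,
#' no more probable than the observed one), as computed by
#' [stats::fisher.test()].  The effect estimate is the sample odds ratio
#' `(a d)/(b c)` on log2 scale, with the Haldane-Anscombe correction
#' (+0.5 on every cell) when any cell is zero; this keeps the estimate
#' closed-form and deterministic, and only its sign and magnitude are
#' interpreted downstream.  A table with an empty margin carries no
#' information: p = 1, odds ratio undefined, `testable = FALSE`.
#'
#' @param tab 2x2 matrix of nonnegative integer counts; rows = exposure
#'   (e.g. auxotroph/prototroph), columns = outcome (producer/not).
#' @return list: `log2_odds_ratio`, `p`, `testable`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(dim(tab) == c(2, 2))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must contain nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(log2_odds_ratio = NA_real_, p = 1, testable = FALSE))
  p <- fisher.test(tab)$p.value
  ctab <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (ctab[1, 1] * ctab[2, 2]) / (ctab[1, 2] * ctab[2, 1])
  list(log2_odds_ratio = log2(or), p = min(p, 1), testable = TRUE)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all variables (average ranks for ties), residualizes
#' the x- and y-ranks on the confounder ranks by least squares, and
#' reports the Pearson correlation of the residuals; with zero confounders
#' this is exactly the plain Spearman coefficient.  The p value uses the
#' t approximation with `n - 2 - k` degrees of freedom (`k` confounders).
#' Binary confounders (e.g. sex) are rank-coded like any numeric vector;
#' a constant confounder contributes nothing.  Incomplete observations
#' are dropped listwise.
#'
#' @param x,y numeric vectors.
#' @param confounders optional numeric matrix / data.frame of confounder
#'   columns (e.g. age, sex, BMI).
#' @return list: `rho`, `p`, `n`, `df`; `rho` is `NA` (with a warning)
#'   when x or y is constant after ranking.
#' @export
partial_spearman <- function(x, y, confounders = NULL) {
  if (!is.null(confounders)) {
    confounders <- as.matrix(confounders)
    stopifnot(nrow(confounders) == length(x))
  }
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y, confounders)
  x <- x[ok]; y <- y[ok]
  if (!is.null(confounders))
    confounders <- confounders[ok, , drop = FALSE]
  n <- length(x)
  k <- if (is.null(confounders)) 0L else ncol(confounders)
  if (n < k + 3) stop("too few complete observations (n = ", n, ")")

  rx <- rank(x); ry <- rank(y)
  if (length(unique(rx)) == 1 || length(unique(ry)) == 1) {
    warning("constant variable after ranking; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, df = n - 2L - k))
  }
  if (k > 0) {
    rc <- apply(confounders, 2, rank)
    fit_x <- stats::lm.fit(cbind(1, rc), rx)
    fit_y <- stats::lm.fit(cbind(1, rc), ry)
    ex <- fit_x$residuals; ey <- fit_y$residuals
  } else {
    ex <- rx - mean(rx); ey <- ry - mean(ry)
  }
  if (sd(ex) < 1e-12 || sd(ey) < 1e-12) {
    warning("variable fully explained by confounders; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, df = n - 2L - k))
  }
  rho <- cor(ex, ey)
  df <- n - 2L - k
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df)
  list(rho = rho, p = p, n = n, df = df)
}

#' Benjamini-Hochberg adjustment within families
#'
#' Step-up FDR correction applied separately within each family of tests
#' (one family per screen by default in the pipeline, mirroring per-figure
#' correction).
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @param family optional grouping vector of the same length; `NULL`
#'   treats all p values as one family.
#' @return adjusted p values in input order.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  if (is.null(family)) return(p.adjust(p, method = "BH"))
  stopifnot(length(family) == length(p))
  out <- p
  for (f in unique(family)) {
    idx <- which(family == f)
    out[idx] <- p.adjust(p[idx], method = "BH")
  }
  out
}

#' Screen amino-acid frequencies against target variables
#'
#' One partial Spearman correlation per (amino acid, target variable)
#' pair between the per-sample auxotrophy frequencies `y_jk` and each
#' target (e.g. serum metabolite levels, health markers), adjusted for the
#' given confounders, with BH correction across the whole screen family.
#'
#' @param frequencies samples x amino-acids matrix from
#'   [auxotrophy_frequency()].
#' @param targets data.frame of target variables, rownames = sample ids.
#' @param confounders optional data.frame of confounder columns (age,
#'   sex, BMI, ...), rownames = sample ids, complete for used samples.
#' @param family correction-family label; default `"metabolome_screen"`.
#' @param min_n minimal shared sample count per pair; smaller pairs are
#'   skipped with a warning.
#' @return data.frame: `family`, `amino_acid`, `target`, `estimate`
#'   (rho), `p_raw`, `p_adjusted`, `n`.
#' @export
association_screen <- function(frequencies, targets, confounders = NULL,
                               family = "metabolome_screen", min_n = 10) {
  samples <- intersect(rownames(frequencies), rownames(targets))
  if (!is.null(confounders))
    samples <- intersect(samples, rownames(confounders))
  if (length(samples) < min_n)
    stop("fewer than ", min_n, " shared samples")
  freq <- frequencies[samples, , drop = FALSE]
  targ <- targets[samples, , drop = FALSE]
  conf <- if (is.null(confounders)) NULL
          else as.matrix(confounders[samples, , drop = FALSE])

  rows <- list()
  for (aa in colnames(freq)) {
    for (tv in colnames(targ)) {
      ok <- complete.cases(freq[, aa], targ[, tv], conf)
      if (sum(ok) < min_n) {
        warning("pair (", aa, ", ", tv, ") skipped: n = ", sum(ok))
        next
      }
      res <- suppressWarnings(partial_spearman(freq[, aa], targ[, tv],
                                               conf))
      rows[[length(rows) + 1L]] <- data.frame(
        family = family, amino_acid = aa, target = tv,
        estimate = res$rho, p_raw = res$p, n = res$n,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p_raw)
  res[order(res$amino_acid, res$target), ]
}

#' Write association results as long-format TSV
#' @param res association result data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
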