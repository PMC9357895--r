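#' Log2 transform with pseudocount
#'
#' Entrywise \code{log2(x + pseudocount)}. Zeros are common after
#' missing-to-zero replacement, so a positive pseudocount (default 1 on the
#' normalized scale, mapping zeros to zero) is required.
#'
#' @param m an \code{\link{abundance_matrix}} or numeric matrix.
#' @param pseudocount positive offset.
#' @return numeric log2 matrix.
#' @export
log_transform <- function(m, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  vals <- if (inherits(m, "abundance_matrix")) m$values else m
  if (anyNA(vals))
    stop("matrix has unreplaced missing values; run replace_missing_with_zero() first")
  log2(vals + pseudocount)
}

# Inverse of the trigamma function by Newton iteration on psigamma.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NaN)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      delta <- (trigamma(y) - xi) / psigamma(y, 2)
      y <- y - delta
      if (abs(delta) < 1e-10 * y) break
    }
    y
  }, numeric(1))
}

#' Fit the variance-shrinkage prior by moment matching
#'
#' Hierarchical model: per-protein residual variances \eqn{s_g^2} with d
#' degrees of freedom scale around a prior variance \eqn{s_0^2} with prior
#' degrees of freedom \eqn{d_0}; equivalently \eqn{s_g^2} follows a scaled
#' F law. \eqn{(d_0, s_0^2)} are estimated by matching the mean and
#' variance of \eqn{\log s_g^2} to their theoretical values (digamma /
#' trigamma moments). When the spread of \eqn{\log s_g^2} does not exceed
#' what the residual degrees of freedom alone imply, \eqn{d_0 = \infty}:
#' all proteins share the variance \eqn{s_0^2}.
#'
#' @param s2 per-protein residual variances (>= 10 positive values needed).
#' @param df residual degrees of freedom (scalar, >= 1).
#' @return object of class \code{ebayes_prior}: list with \code{d0} (may be
#'   \code{Inf}) and \code{s02}.
#' @export
fit_prior <- function(s2, df) {
  if (length(df) != 1 || df < 1) stop("'df' must be a scalar >= 1")
  if (all(s2 == 0)) stop("all residual variances are zero")
  pos <- s2 > 0
  if (!all(pos)) {
    warning(sprintf("fit_prior: dropping %d zero variance(s)", sum(!pos)))
    s2 <- s2[pos]
  }
  if (length(s2) < 10) stop("need >= 10 positive variances to fit the prior")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  structure(list(d0 = d0, s02 = s02), class = "ebayes_prior")
}

#' @export
print.ebayes_prior <- function(x, ...) {
  cat(sprintf("ebayes_prior: d0 = %s, s0^2 = %.4g\n",
              format(x$d0), x$s02))
  invisible(x)
}

#' Moderated two-group t-test on log abundances
#'
#' Empirical-Bayes moderated t-test between two sample groups (day labels):
#' per-protein pooled residual variances are shrunk toward the prior,
#' \deqn{\tilde s_g^2 = (d_0 s_0^2 + d s_g^2) / (d_0 + d),}
#' and \eqn{t_g = logFC_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})} is referred
#' to a t law with \eqn{d_0 + d} degrees of freedom. With \eqn{d_0 = 0}
#' this is the ordinary pooled-variance two-sample t-test; as
#' \eqn{d_0 \to \infty} it approaches a fixed-variance z-like statistic.
#' Benjamini-Hochberg adjustment is applied across proteins.
#'
#' @param logm numeric log2 matrix (proteins x samples), e.g. from
#'   \code{\link{log_transform}}.
#' @param meta sample metadata with \code{sample_id} and \code{day}.
#' @param group1,group2 day labels of the two groups (>= 2 samples each);
#'   \code{logFC} is the group2 minus group1 mean log2 abundance.
#' @param prior \code{"fit"} (estimate via \code{\link{fit_prior}}),
#'   \code{"none"} (\eqn{d_0 = 0}: ordinary t), or an
#'   \code{\link{fit_prior}} object.
#' @param p_cutoff,lfc_cutoff strict significance cutoffs on the adjusted
#'   p-value and |logFC| for the \code{significant} flag.
#' @return data frame of class \code{differential_result}: \code{protein},
#'   \code{logFC}, \code{s2}, \code{s2_moderated}, \code{t}, \code{df},
#'   \code{p}, \code{p_adjusted}, \code{significant}; the prior used is in
#'   attribute \code{prior}.
#' @export
moderated_t_test <- function(logm, meta, group1, group2, prior = "fit",
                             p_cutoff = 0.05, lfc_cutoff = 1) {
  stopifnot(is.matrix(logm), is.numeric(logm))
  i1 <- meta$sample_id[meta$day == group1]
  i2 <- meta$sample_id[meta$day == group2]
  if (length(i1) < 2 || length(i2) < 2)
    stop("both groups need >= 2 samples")
  x1 <- logm[, i1, drop = FALSE]
  x2 <- logm[, i2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  d <- n1 + n2 - 2
  s2 <- ss / d
  if (identical(prior, "fit")) {
    prior <- fit_prior(s2, d)
  } else if (identical(prior, "none")) {
    prior <- structure(list(d0 = 0, s02 = NA_real_), class = "ebayes_prior")
  } else if (!inherits(prior, "ebayes_prior")) {
    stop("'prior' must be \"fit\", \"none\", or an ebayes_prior")
  }
  d0 <- prior$d0
  s2_mod <- if (is.infinite(d0)) rep(prior$s02, length(s2))
            else if (d0 == 0) s2
            else (d0 * prior$s02 + d * s2) / (d0 + d)
  logFC <- m2 - m1
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  t <- logFC / se
  t[se == 0 & logFC == 0] <- 0
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t), df = df_total)
  p[se == 0 & logFC == 0] <- 1
  p_adj <- benjamini_hochberg(p)
  out <- data.frame(protein = rownames(logm), logFC = logFC, s2 = s2,
                    s2_moderated = s2_mod, t = t, df = df_total, p = p,
                    p_adjusted = p_adj,
                    significant = p_adj < p_cutoff & abs(logFC) > lfc_cutoff,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("differential_result", "data.frame"),
            prior = prior, groups = c(group1, group2))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sort ascending, multiply
#' \eqn{p_{(i)}} by \eqn{m/i}, enforce monotonicity from the largest rank
#' down, cap at 1, and restore the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin((m / (m:1)) * p[o]))[ro]
  names(q) <- names(p)
  q
}

#' Volcano-ready significance table
#'
#' Per protein: log2 fold change, -log10 adjusted p-value, and a
#' significance class under strict cutoffs: \code{"ns"},
#' \code{"lfc"} (|logFC| beyond the cutoff only), \code{"padj"} (adjusted p
#' below the cutoff only), or \code{"padj_lfc"} (both). The display
#' convention colours proteins at adjusted p < 1e-4 and |logFC| > 1; pass
#' \code{p_cutoff = 0.05} for the significance-calling convention.
#'
#' @param result a \code{\link{moderated_t_test}} result.
#' @param p_cutoff adjusted p-value cutoff (strict; default 1e-4).
#' @param lfc_cutoff |logFC| cutoff (strict; default 1).
#' @return data frame: \code{protein}, \code{logFC}, \code{neg_log10_padj},
#'   \code{class}, ordered by adjusted p.
#' @export
volcano_table <- function(result, p_cutoff = 1e-4, lfc_cutoff = 1) {
  stopifnot(inherits(result, "differential_result"))
  sig_p <- result$p_adjusted < p_cutoff
  sig_fc <- abs(result$logFC) > lfc_cutoff
  cls <- ifelse(sig_p & sig_fc, "padj_lfc",
                ifelse(sig_p, "padj", ifelse(sig_fc, "lfc", "ns")))
  out <- data.frame(protein = result$protein, logFC = result$logFC,
                    neg_log10_padj = -log10(result$p_adjusted),
                    class = cls, stringsAsFactors = FALSE)
  out <- out[order(result$p_adjusted, -abs(result$logFC)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
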