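#' Association statistics linking editing to ADAR expression
#'
#' Spearman rank correlations (exact permutation p-value for small n,
#' t-approximation otherwise) and paired t tests between tumor and normal
#' editing levels. All return an `edit_assoc` object with
#' [generics::tidy()] and [generics::glance()] methods.
#'
#' @name edassoc
NULL

new_edit_assoc <- function(statistic, estimate, p_value, n, method,
                           data = NULL) {
  structure(
    list(statistic = statistic, estimate = estimate, p_value = p_value,
         n = n, method = method, data = data),
    class = "edit_assoc"
  )
}

#' @export
print.edit_assoc <- function(x, ...) {
  cat(sprintf(
    "<edit_assoc> %s: estimate = %.4g, p = %.4g, n = %d (%s)\n",
    x$statistic, x$estimate, x$p_value, x$n, x$method
  ))
  invisible(x)
}

#' @rdname edassoc
#' @param x An `edit_assoc` object.
#' @param ... Unused.
#' @method tidy edit_assoc
#' @export
tidy.edit_assoc <- function(x, ...) {
  tibble(
    statistic = x$statistic, estimate = x$estimate,
    p.value = x$p_value, n = x$n, method = x$method
  )
}

#' @rdname edassoc
#' @method glance edit_assoc
#' @export
glance.edit_assoc <- function(x, ...) tidy.edit_assoc(x)

# all permutations of 1..n as an n!-row integer matrix
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    q <- p
    q[q >= i] <- q[q >= i] + 1L
    cbind(i, q, deparse.level = 0)
  }))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Mid-ranks both variables and correlates the ranks. For `n <= exact_max`
#' the two-sided p-value is computed by full enumeration of all `n!`
#' permutations of one rank vector (valid with ties); for larger n the
#' usual t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom is used.
#'
#' @param x,y Numeric vectors of equal length, n >= 3 after removing
#'   incomplete pairs.
#' @param exact_max Largest n for which the permutation null is
#'   enumerated (default 9).
#' @return An `edit_assoc` object.
#' @export
spearman_assoc <- function(x, y, exact_max = 9) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs for a correlation")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(new_edit_assoc("spearman", NA_real_, NA_real_, n,
                          "degenerate (constant ranks)",
                          data = tibble(x = x, y = y)))
  }
  rho <- cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    s <- as.vector(matrix(ry[perms], nrow = nrow(perms)) %*% rx)
    rho_null <- (s / n - mean(rx) * mean(ry)) /
      (sd(rx) * sd(ry) * (n - 1) / n)
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- sprintf("exact permutation (%d perms)", nrow(perms))
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    method <- "t approximation"
  }
  new_edit_assoc("spearman", rho, p, n, method, data = tibble(x = x, y = y))
}

#' Correlate per-patient over-editing burden with gene expression
#'
#' Joins each patient's over-editing fraction (from
#' [patient_overediting()]) with that patient's expression of `gene` in
#' `tissue` and computes the Spearman correlation, mirroring the
#' burden-versus-ADAR1-p110 comparison.
#'
#' @param patients Tibble with `sample` and `over_fraction` columns (the
#'   `patients` element or [generics::tidy()] of an
#'   `overediting_summary`, or the summary object itself).
#' @param expression Expression tibble `gene, sample, tissue, fpkm`.
#' @param gene Gene name (default `"ADAR1-p110"`).
#' @param tissue Expression tissue (default `"tumor"`).
#' @inheritParams spearman_assoc
#' @return An `edit_assoc` object.
#' @export
burden_expression_correlation <- function(patients, expression,
                                          gene = "ADAR1-p110",
                                          tissue = "tumor", exact_max = 9) {
  if (inherits(patients, "overediting_summary")) patients <- patients$patients
  df <- patients |>
    inner_join(
      filter(expression, .data$gene == .env$gene, .data$tissue == .env$tissue),
      by = "sample"
    )
  spearman_assoc(df$over_fraction, df$fpkm, exact_max = exact_max)
}

#' Correlate editing levels at one site with gene expression
#'
#' @param levels Long editing-level tibble ([editing_level_matrix()]).
#' @param expression Expression tibble `gene, sample, tissue, fpkm`.
#' @param site One-row tibble (or list) with `chrom` and `pos` (and
#'   optionally `alt`) selecting the site.
#' @param gene,tissue,exact_max As in
#'   [burden_expression_correlation()]; levels are taken from the same
#'   `tissue`.
#' @return An `edit_assoc` object.
#' @export
site_level_correlation <- function(levels, expression, site,
                                   gene = "ADAR1-p110", tissue = "tumor",
                                   exact_max = 9) {
  lv <- levels |>
    filter(.data$chrom == site$chrom, .data$pos == site$pos,
           .data$tissue == .env$tissue)
  if ("alt" %in% names(site)) lv <- filter(lv, .data$alt == site$alt)
  df <- lv |>
    inner_join(
      filter(expression, .data$gene == .env$gene, .data$tissue == .env$tissue),
      by = "sample"
    )
  spearman_assoc(df$level, df$fpkm, exact_max = exact_max)
}

#' Paired tumor-versus-normal test
#'
#' Paired two-sided Student t test on per-sample values from the two
#' tissues. Accepts either a long tibble (`sample, tissue, level`;
#' multiple rows per sample-tissue are averaged) or two paired vectors.
#' An optional log transform (natural log of strictly positive values)
#' mirrors the convention of log-transforming skewed measurements before
#' a t test. Degenerate inputs are guarded: identical vectors give t = 0,
#' p = 1; a constant non-zero shift with zero variance gives p = 0.
#'
#' @param data Long tibble, or `NULL` when `tumor`/`normal` are given.
#' @param tumor,normal Paired numeric vectors (alternative interface).
#' @param value Name of the value column in `data` (default "level").
#' @param log_transform Log-transform values first (requires positives).
#' @return An `edit_assoc` object (`statistic = "paired_t"`, estimate =
#'   mean tumor - normal difference on the analysis scale).
#' @export
paired_tissue_test <- function(data = NULL, tumor = NULL, normal = NULL,
                               value = "level", log_transform = FALSE) {
  if (!is.null(data)) {
    wide <- data |>
      group_by(.data$sample, .data$tissue) |>
      summarise(v = mean(.data[[value]], na.rm = TRUE), .groups = "drop") |>
      pivot_wider(names_from = "tissue", values_from = "v") |>
      filter(!is.na(.data$tumor), !is.na(.data$normal))
    tumor <- wide$tumor
    normal <- wide$normal
  }
  keep <- is.finite(tumor) & is.finite(normal)
  tumor <- tumor[keep]
  normal <- normal[keep]
  n <- length(tumor)
  if (n < 2) abort("need at least 2 complete pairs for a paired test")
  if (log_transform) {
    if (any(tumor <= 0) || any(normal <= 0)) {
      abort("log transform requires strictly positive values")
    }
    tumor <- log(tumor)
    normal <- log(normal)
  }
  d <- tumor - normal
  est <- mean(d)
  if (sd(d) <= 1e-10 * (abs(est) + 1)) {
    p <- if (est == 0) 1 else 0
    tstat <- if (est == 0) 0 else sign(est) * Inf
    return(new_edit_assoc(
      "paired_t", est, p, n, "degenerate (zero-variance differences)",
      data = tibble(tumor = tumor, normal = normal)
    ))
  }
  ht <- t.test(tumor, normal, paired = TRUE)
  new_edit_assoc(
    "paired_t", est, ht$p.value, n,
    sprintf("paired t = %.3f, df = %d", unname(ht$statistic), n - 1L),
    data = tibble(tumor = tumor, normal = normal)
  )
}

#' Expression fold changes between tissues or genes
#'
#' `expression_fold_change()` is the ratio of mean expression of one gene
#' between two tissues (e.g. the ~1.8-fold tumor/normal ADAR1-p110
#' change); `expression_gene_ratio()` is the ratio of mean expression of
#' two genes within one tissue (e.g. the ~20-fold ADAR1-p110 / ADAR2
#' difference).
#'
#' @param expression Expression tibble `gene, sample, tissue, fpkm`.
#' @param gene Gene for the tissue contrast.
#' @param tissue_pair Numerator and denominator tissues.
#' @return A single numeric ratio.
#' @export
expression_fold_change <- function(expression, gene = "ADAR1-p110",
                                   tissue_pair = c("tumor", "normal")) {
  sub <- filter(expression, .data$gene == .env$gene)
  num <- mean(filter(sub, .data$tissue == tissue_pair[1])$fpkm)
  den <- mean(filter(sub, .data$tissue == tissue_pair[2])$fpkm)
  num / den
}

#' @rdname expression_fold_change
#' @param genes Numerator and denominator genes.
#' @param tissue Tissue for the gene contrast.
#' @export
expression_gene_ratio <- function(expression, genes = c("ADAR1-p110", "ADAR2"),
                                  tissue = "tumor") {
  sub <- filter(expression, .data$tissue == .env$tissue)
  num <- mean(filter(sub, .data$gene == genes[1])$fpkm)
  den <- mean(filter(sub, .data$gene == genes[2])$fpkm)
  num / den
}
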