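# Differential flux testing and Z-score fluxome normalization.
#
# All differential analyses use the Mann-Whitney U test with a raw p < 0.001
# significance cutoff and no multiplicity correction; tests are two-sided,
# with direction read from the median difference.

#' Mann-Whitney U test
#'
#' Computes the U statistic of `x` from midrank sums.  The two-sided p-value
#' is exact (full enumeration distribution of the rank-sum statistic) when
#' `length(x) + length(y) <= 20` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @param method `"auto"` (default: exact when small and tie-free, else
#'   normal), or force `"exact"`/`"normal"`.
#' @return List with `U` (for `x`), `p.value`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both input vectors must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- switch(method,
                      auto = !ties && n1 + n2 <= 20L,
                      exact = { if (ties) stop("exact method requires tie-free data",
                                               call. = FALSE); TRUE },
                      normal = FALSE)
  if (use_exact) {
    # exact enumeration distribution of U (stats::pwilcox)
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)  # continuity correction
      z <- max(z, 0)
      p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal"
  }
  list(U = U, p.value = min(p, 1), method = method)
}

#' Differential flux (or abundance) between tumor and normal samples
#'
#' One Mann-Whitney test per column of the samples x features matrix,
#' comparing the two label groups.  Significance uses the raw p < 0.001
#' cutoff without multiplicity correction; direction is the sign of the
#' tumor-minus-normal median difference.
#'
#' @param flux Samples x modules (or samples x intermediates) matrix.
#' @param labels Per-sample character vector with values `"tumor"` and
#'   `"normal"` (any two levels work; `tumor_level`/`normal_level` name them).
#' @param tumor_level,normal_level Label values defining the contrast.
#' @param alpha Significance cutoff on the raw p-value.
#' @return Data.frame with one row per column: `feature`, `median_tumor`,
#'   `median_normal`, `U`, `p.value`, `direction`, `significant`.
#' @export
differential_flux <- function(flux, labels, tumor_level = "tumor",
                              normal_level = "normal", alpha = 0.001) {
  flux <- as.matrix(flux)
  if (length(labels) != nrow(flux))
    stop("labels length (", length(labels), ") does not match sample count (",
         nrow(flux), ")", call. = FALSE)
  it <- labels == tumor_level; inorm <- labels == normal_level
  if (!any(it) || !any(inorm))
    stop("both groups must be non-empty (found ", sum(it), " '", tumor_level,
         "' and ", sum(inorm), " '", normal_level, "')", call. = FALSE)
  feats <- colnames(flux)
  if (is.null(feats)) feats <- paste0("V", seq_len(ncol(flux)))
  res <- lapply(seq_len(ncol(flux)), function(m) {
    xt <- flux[it, m]; xn <- flux[inorm, m]
    mw <- mann_whitney_u(xt, xn)
    md <- stats::median(xt) - stats::median(xn)
    data.frame(feature = feats[m],
               median_tumor = stats::median(xt),
               median_normal = stats::median(xn),
               U = mw$U, p.value = mw$p.value,
               direction = if (md > 0) "increase" else if (md < 0) "decrease" else "none",
               significant = mw$p.value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Count significant increases/decreases across cancer types
#'
#' Given one [differential_flux()] table per cancer type, tallies for every
#' feature the number of types in which it is significantly increased and
#' significantly decreased (the paper-style "x of T types" summary).
#'
#' @param results Named list of differential tables sharing one feature set.
#' @return Data.frame with `feature`, `n_types`, `n_increased`, `n_decreased`.
#' @export
summarize_across_types <- function(results) {
  if (length(results) == 0L) stop("need at least one differential table", call. = FALSE)
  feats <- results[[1]]$feature
  for (r in results)
    if (!identical(sort(r$feature), sort(feats)))
      stop("differential tables have inconsistent feature sets", call. = FALSE)
  inc <- dec <- stats::setNames(integer(length(feats)), feats)
  for (r in results) {
    r <- r[match(feats, r$feature), ]
    inc <- inc + (r$significant & r$direction == "increase")
    dec <- dec + (r$significant & r$direction == "decrease")
  }
  data.frame(feature = feats, n_types = length(results),
             n_increased = as.integer(inc), n_decreased = as.integer(dec),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Z-score fluxome profile of cancer samples against normal controls
#'
#' Standardizes each cancer sample's module fluxes against the mean and
#' standard deviation (n-1 denominator) of the matched normal controls;
#' modules with zero normal-control variance get z = 0 with a warning.
#'
#' @param flux_cancer,flux_normal Samples x modules matrices sharing the
#'   module set; `flux_normal` needs at least two samples.
#' @return Cancer-samples x modules matrix of Z-scores.
#' @export
flux_zscore <- function(flux_cancer, flux_normal) {
  flux_cancer <- as.matrix(flux_cancer); flux_normal <- as.matrix(flux_normal)
  if (nrow(flux_normal) < 2L)
    stop("need at least two normal-control samples", call. = FALSE)
  if (ncol(flux_cancer) != ncol(flux_normal))
    stop("cancer and normal matrices have different module sets", call. = FALSE)
  if (!is.null(colnames(flux_cancer)) && !is.null(colnames(flux_normal))) {
    if (!setequal(colnames(flux_cancer), colnames(flux_normal)))
      stop("cancer and normal matrices have different module sets", call. = FALSE)
    flux_normal <- flux_normal[, colnames(flux_cancer), drop = FALSE]
  }
  mu <- colMeans(flux_normal)
  sd_n <- apply(flux_normal, 2L, stats::sd)
  z <- sweep(sweep(flux_cancer, 2L, mu, `-`), 2L, ifelse(sd_n > 0, sd_n, 1), `/`)
  if (any(sd_n == 0)) {
    warning("zero normal-control sd for ", sum(sd_n == 0),
            " module(s); their z-scores set to 0")
    z[, sd_n == 0] <- 0
  }
  z
}
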