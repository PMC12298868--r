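#' Evaluate a core collection against the full population
#'
#' Per trait, a Welch two-sample t-test compares core vs full-population
#' means and a two-sided variance-ratio F-test compares variances (the core
#' is treated as an independent sample, the convention of the MD/VD
#' literature). Summary percentages over the m traits:
#' \itemize{
#'   \item MD\% = 100 x (traits with t-test p < alpha) / m
#'   \item VD\% = 100 x (traits with F-test p < alpha) / m
#'   \item CR\% = (100 / m) sum_t range_core(t) / range_full(t)
#'   \item VR\% = (100 / m) sum_t CV_core(t) / CV_full(t)
#' }
#' Traits with zero range or zero CV in the full population are excluded
#' from CR/VR with a warning (m adjusted for those ratios). The verdict is
#' \code{pass} when MD < \code{md_max} and CR > \code{cr_min}.
#'
#' @param core trait_matrix of the core accessions.
#' @param full trait_matrix of the full population (same traits).
#' @param alpha significance level (default 0.05).
#' @param md_max,cr_min verdict thresholds (defaults 20 and 80).
#' @return list of class \code{core_evaluation}: \code{md_percent},
#'   \code{vd_percent}, \code{cr_percent}, \code{vr_percent},
#'   \code{per_trait} data.frame, \code{alpha}, \code{verdict}.
#' @export
evaluate_core <- function(core, full, alpha = 0.05, md_max = 20,
                          cr_min = 80) {
  stopifnot(inherits(core, "trait_matrix"), inherits(full, "trait_matrix"))
  traits <- colnames(full$values)
  if (!identical(sort(traits), sort(colnames(core$values))))
    stop("core and full population must share the same traits")
  per <- lapply(traits, function(tr) {
    x <- core$values[, tr]; x <- x[!is.na(x)]
    y <- full$values[, tr]; y <- y[!is.na(y)]
    tt <- stats::t.test(x, y)
    ft <- stats::var.test(x, y)
    r_full <- diff(range(y))
    cv_full <- if (mean(y) != 0) stats::sd(y) / mean(y) else NA_real_
    data.frame(trait = tr,
               t_stat = unname(tt$statistic), t_p = tt$p.value,
               f_stat = unname(ft$statistic), f_p = ft$p.value,
               range_ratio = if (r_full > 0) diff(range(x)) / r_full
                             else NA_real_,
               cv_ratio = if (!is.na(cv_full) && cv_full != 0)
                 (stats::sd(x) / mean(x)) / cv_full else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  m <- length(traits)
  excl_cr <- sum(is.na(per$range_ratio))
  excl_vr <- sum(is.na(per$cv_ratio))
  if (excl_cr > 0 || excl_vr > 0)
    warning(sprintf(
      "excluded %d trait(s) from CR and %d from VR (zero range or CV in full population)",
      excl_cr, excl_vr))
  md <- 100 * sum(per$t_p < alpha) / m
  vd <- 100 * sum(per$f_p < alpha) / m
  cr <- 100 * mean(per$range_ratio, na.rm = TRUE)
  vr <- 100 * mean(per$cv_ratio, na.rm = TRUE)
  structure(list(md_percent = md, vd_percent = vd, cr_percent = cr,
                 vr_percent = vr, per_trait = per, alpha = alpha,
                 verdict = if (md < md_max && cr > cr_min) "pass" else "fail"),
            class = "core_evaluation")
}

#' @export
print.core_evaluation <- function(x, ...) {
  cat(sprintf("core evaluation: MD %.2f%%, VD %.2f%%, CR %.2f%%, VR %.2f%% [%s]\n",
              x$md_percent, x$vd_percent, x$cr_percent, x$vr_percent,
              x$verdict))
  invisible(x)
}

#' Rank strategy evaluations by representativeness
#'
#' Deterministic composite order: passing verdicts first, then ascending
#' MD, ties by descending CR, then descending VR, then descending VD.
#'
#' @param evals list of core_evaluation objects (optionally named by
#'   strategy).
#' @return data.frame in ranked order with columns strategy, md, vd, cr,
#'   vr, verdict, and the permutation \code{order} into the input list.
#' @export
rank_strategies <- function(evals) {
  stopifnot(length(evals) >= 1L)
  nm <- names(evals)
  if (is.null(nm)) nm <- sprintf("strategy%02d", seq_along(evals))
  df <- data.frame(
    strategy = nm,
    md = vapply(evals, `[[`, 0, "md_percent"),
    vd = vapply(evals, `[[`, 0, "vd_percent"),
    cr = vapply(evals, `[[`, 0, "cr_percent"),
    vr = vapply(evals, `[[`, 0, "vr_percent"),
    verdict = vapply(evals, `[[`, "", "verdict"),
    stringsAsFactors = FALSE)
  ord <- order(df$verdict != "pass", df$md, -df$cr, -df$vr, -df$vd)
  out <- df[ord, , drop = FALSE]
  out$order <- ord
  rownames(out) <- NULL
  out
}

#' Compare PCA structure of a core and its source population
#'
#' Runs \code{\link{pca_traits}} on both tables and reports per-component
#' and cumulative contributions plus the difference in cumulative
#' contribution over the leading components.
#'
#' @param core,full trait_matrix objects sharing traits.
#' @param n_components leading components for the cumulative delta
#'   (default 5).
#' @return list with \code{core}, \code{full} (pca_result),
#'   \code{cumulative_core}, \code{cumulative_full}, \code{delta}
#'   (core minus full, at \code{n_components}).
#' @export
compare_pca <- function(core, full, n_components = 5L) {
  pc_core <- pca_traits(core)
  pc_full <- pca_traits(full)
  c_use <- min(n_components, length(pc_core$eigenvalues))
  list(core = pc_core, full = pc_full,
       cumulative_core = pc_core$cumulative_percent[c_use],
       cumulative_full = pc_full$cumulative_percent[c_use],
       delta = pc_core$cumulative_percent[c_use] -
         pc_full$cumulative_percent[c_use])
}
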