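## Per-antibody metric aggregation and affinity correlation statistics.

#' Natural log of a dissociation constant in nM
#'
#' ln(K_d) in nM units is the affinity proxy (via the free-energy relation
#' dG = -RT ln K).
#'
#' @param kd_nM dissociation constant(s) in nM, > 0.
#' @export
ln_affinity <- function(kd_nM) {
  if (any(!is.finite(kd_nM) | kd_nM <= 0)) stop("K_d must be positive and finite")
  log(kd_nM)
}

CDR_LOOPS <- c("H1", "H2", "H3", "L1", "L2", "L3")

#' Build the per-antibody metric table
#'
#' Means are taken over the six CDRs. Antibodies without an affinity value are
#' retained in the table but excluded from every correlation.
#'
#' @param per_cdr data.frame with columns antibody_id, cdr (H1..L3),
#'   apo_pca_clusters, holo_pca_clusters, apo_dash_states, holo_dash_states,
#'   dres.
#' @param interactions data.frame with columns antibody_id, nonsolvent_pct,
#'   nonsolvent_nonhydrophobic_pct, hydrophobic_pct.
#' @param affinities data.frame with columns antibody_id, kd_nM (NA for
#'   missing), optional koff.
#' @return data.frame, one row per antibody, with CDR-mean sampling metrics,
#'   interaction percentages, ln_kd / ln_koff and `has_affinity`.
#' @export
build_metric_table <- function(per_cdr, interactions, affinities) {
  ids <- unique(per_cdr$antibody_id)
  rows <- lapply(ids, function(id) {
    sub <- per_cdr[per_cdr$antibody_id == id, , drop = FALSE]
    if (nrow(sub) != length(CDR_LOOPS) || !setequal(sub$cdr, CDR_LOOPS)) {
      stop("antibody ", id, ": expected one row per CDR (",
           paste(CDR_LOOPS, collapse = ", "), ")")
    }
    data.frame(antibody_id = id,
               mean_apo_pca_clusters = mean(sub$apo_pca_clusters),
               mean_holo_pca_clusters = mean(sub$holo_pca_clusters),
               mean_apo_dash_states = mean(sub$apo_dash_states),
               mean_holo_dash_states = mean(sub$holo_dash_states),
               mean_dres = mean(sub$dres),
               diff_pca_clusters = mean(sub$apo_pca_clusters - sub$holo_pca_clusters),
               diff_dash_states = mean(sub$apo_dash_states - sub$holo_dash_states))
  })
  tab <- do.call(rbind, rows)
  tab <- merge(tab, interactions, by = "antibody_id", all.x = TRUE, sort = FALSE)
  tab <- merge(tab, affinities, by = "antibody_id", all.x = TRUE, sort = FALSE)
  tab$ln_kd <- ifelse(is.finite(tab$kd_nM) & tab$kd_nM > 0, log(tab$kd_nM), NA)
  if ("koff" %in% names(tab)) {
    tab$ln_koff <- ifelse(is.finite(tab$koff) & tab$koff > 0, log(tab$koff), NA)
  }
  tab$has_affinity <- is.finite(tab$ln_kd)
  tab[order(match(tab$antibody_id, ids)), , drop = FALSE]
}

#' Squared Pearson correlation with leave-one-out influence diagnostics
#'
#' Least-squares slope/intercept and R^2 (squared Pearson r), plus a
#' leave-one-out scan: R^2 is recomputed with each point removed and the point
#' whose removal changes R^2 the most is flagged — the generalisation of
#' omitting a single anomalous panel member.
#'
#' @param x,y finite numeric vectors (n >= 3), non-zero variance. NA pairs are
#'   dropped pairwise.
#' @param x_name,y_name labels carried into the result.
#' @return object of class `correlation_result`: n, r_squared, slope,
#'   intercept, leave_one_out (per-point R^2), max_delta_point,
#'   r_squared_omitting_max.
#' @export
pearson_r2 <- function(x, y, x_name = "x", y_name = "y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance in x or y")
  fit <- stats::lm(y ~ x)
  r2 <- stats::cor(x, y)^2
  loo <- vapply(seq_len(n), function(i) {
    xi <- x[-i]; yi <- y[-i]
    if (stats::var(xi) == 0 || stats::var(yi) == 0) return(NA_real_)
    stats::cor(xi, yi)^2
  }, numeric(1))
  imax <- which.max(abs(loo - r2))
  structure(list(x_name = x_name, y_name = y_name, n = n,
                 r_squared = r2,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 leave_one_out = loo,
                 max_delta_point = imax,
                 r_squared_omitting_max = loo[imax]),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s vs %s: R^2 = %.3f (n = %d; slope %.4f, intercept %.4f)\n",
              x$y_name, x$x_name, x$r_squared, x$n, x$slope, x$intercept))
  cat(sprintf("  leave-one-out: omitting point %d gives R^2 = %.3f\n",
              x$max_delta_point, x$r_squared_omitting_max))
  invisible(x)
}

#' Percentages of CDRs per apo/holo sampling class
#'
#' @param classifications character vector over CDRs with values in
#'   more_apo / equal / more_holo (see [compare_sampling()]).
#' @return named numeric percentages (sum 100): more_apo, equal, more_holo.
#' @export
sampling_class_percentages <- function(classifications) {
  if (!length(classifications)) stop("no classifications given")
  lv <- c("more_apo", "equal", "more_holo")
  bad <- setdiff(unique(classifications), lv)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  tab <- table(factor(classifications, levels = lv))
  stats::setNames(100 * as.numeric(tab) / length(classifications), lv)
}
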