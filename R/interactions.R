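# Phage-bacterium correlation statistics, interaction-strength change
# classification, per-project trend voting and concordance scoring.

#' Spearman correlation with a small-sample exact null
#'
#' Rho is the Pearson correlation of average ranks (ties receive average
#' ranks). The two-sided p-value uses the exact permutation null for
#' n <= 9 and the t approximation (`t = rho * sqrt((n-2)/(1-rho^2))`,
#' n - 2 df) otherwise.
#'
#' @param x,y equal-length abundance vectors, n >= 4, neither constant.
#' @return list with `rho`, `p`, `n`. A constant vector yields
#'   `rho = p = NA` with a warning (the pair is skipped).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y))
    pd_stop("spearman needs equal-length vectors", "domain_error")
  n <- length(x)
  if (n < 4L) pd_stop("spearman needs n >= 4", "domain_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    pd_warn("constant vector: Spearman undefined, pair skipped")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- all_permutations(n)
    rho_null <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values (elementwise >= input, capped at 1).
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    pd_stop("p-values must lie in [0, 1]", "domain_error")
  stats::p.adjust(p_values, method = "BH")
}

#' Correlate linked phage-bacterium pairs within strata
#'
#' For every stratum (e.g. diet group), computes the Spearman correlation
#' of each linked pair across the stratum's samples, then adjusts the raw
#' p-values with Benjamini-Hochberg within that stratum's family of tests.
#'
#' @param phage_m,bacteria_m abundance matrices sharing sample ids.
#' @param pairs data.frame from [link_pairs()] (`phage_id`,
#'   `bacterium_id`; extra columns are carried through the join).
#' @param sample_info sample metadata ([validate_sample_info()]).
#' @param stratify_by metadata column defining the strata (default
#'   `"group"`); `NULL` pools all samples into one stratum.
#' @param bh_scope `"stratum"` (default) adjusts within each stratum,
#'   `"global"` over all strata jointly.
#' @param alpha significance level for the `significant` flag (default
#'   0.05, on adjusted p).
#' @return data.frame with one row per (pair, stratum): `phage_id`,
#'   `bacterium_id`, `stratum`, `n`, `rho`, `p_raw`, `p_adj`,
#'   `significant`. Strata with fewer than 4 samples are skipped with a
#'   warning; pairs undefined within a stratum (constant vector) carry NA.
#' @export
correlate_pairs <- function(phage_m, bacteria_m, pairs, sample_info,
                            stratify_by = "group", bh_scope = c("stratum", "global"),
                            alpha = 0.05) {
  bh_scope <- match.arg(bh_scope)
  shared <- intersect(colnames(phage_m), colnames(bacteria_m))
  if (!length(shared))
    pd_stop("phage and bacteria matrices share no sample ids", "schema_error")
  info <- sample_info[match(shared, sample_info$sample_id), , drop = FALSE]
  if (anyNA(info$sample_id))
    pd_stop("all shared samples must appear in the metadata", "schema_error")
  strata <- if (is.null(stratify_by)) rep("all", length(shared))
            else as.character(info[[stratify_by]])
  out <- list()
  for (s in unique(strata)) {
    ids <- shared[strata == s]
    if (length(ids) < 4L) {
      pd_warn(sprintf("stratum %s has < 4 samples, skipped", s))
      next
    }
    pm <- unclass(phage_m)[, ids, drop = FALSE]
    bm <- unclass(bacteria_m)[, ids, drop = FALSE]
    res <- lapply(seq_len(nrow(pairs)), function(k) {
      px <- pm[pairs$phage_id[k], ]
      bx <- bm[pairs$bacterium_id[k], ]
      if (stats::sd(px) == 0 || stats::sd(bx) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = length(ids)))
      spearman(px, bx)
    })
    out[[s]] <- data.frame(
      phage_id = pairs$phage_id, bacterium_id = pairs$bacterium_id,
      stratum = s, n = vapply(res, `[[`, numeric(1), "n"),
      rho = vapply(res, `[[`, numeric(1), "rho"),
      p_raw = vapply(res, `[[`, numeric(1), "p"),
      stringsAsFactors = FALSE)
    if (bh_scope == "stratum") {
      ok <- !is.na(out[[s]]$p_raw)
      out[[s]]$p_adj <- NA_real_
      out[[s]]$p_adj[ok] <- bh_adjust(out[[s]]$p_raw[ok])
    }
  }
  if (!length(out))
    return(data.frame(phage_id = character(), bacterium_id = character(),
                      stratum = character(), n = integer(), rho = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (bh_scope == "global") {
    ok <- !is.na(res$p_raw)
    res$p_adj <- NA_real_
    res$p_adj[ok] <- bh_adjust(res$p_raw[ok])
  }
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}

#' Classify the change in interaction strength between two conditions
#'
#' Compares the absolute Spearman correlations (|rho|) of one stratum under
#' control vs intervention: Wilcoxon rank-sum test on the two |rho| sets,
#' direction by the medians, gated at p < `alpha`:
#' `Increased` (median |rho| intervention > control, p < alpha),
#' `Decreased` (median |rho| intervention < control, p < alpha),
#' otherwise `non-significant` (including median ties).
#'
#' @param control_abs_rho,intervention_abs_rho nonempty |rho| sets.
#' @param alpha gate (default 0.05).
#' @return list: `median_control`, `median_intervention`, `p`, `direction`.
#' @export
classify_change <- function(control_abs_rho, intervention_abs_rho, alpha = 0.05) {
  control_abs_rho <- control_abs_rho[!is.na(control_abs_rho)]
  intervention_abs_rho <- intervention_abs_rho[!is.na(intervention_abs_rho)]
  if (!length(control_abs_rho) || !length(intervention_abs_rho))
    pd_stop("both |rho| sets must be nonempty", "domain_error")
  p <- rank_sum_p(intervention_abs_rho, control_abs_rho)
  mc <- stats::median(control_abs_rho)
  mi <- stats::median(intervention_abs_rho)
  direction <- if (!is.na(p) && p < alpha && mi > mc) "Increased"
               else if (!is.na(p) && p < alpha && mi < mc) "Decreased"
               else "non-significant"
  list(median_control = mc, median_intervention = mi, p = p,
       direction = direction)
}

#' Vote an overall abundance trend from per-project directions
#'
#' Counts the projects in which a phage's abundance increased (+1) or
#' decreased (-1) after intervention: `increasing` iff
#' `N_increase > N_decrease`, `decreasing` iff the reverse, else
#' `indeterminate` (ties, or no projects).
#'
#' @param per_project_directions vector of +1 / -1 (zeros or NAs are
#'   excluded from the vote).
#' @return list: `n_increase`, `n_decrease`, `trend`.
#' @export
vote_trend <- function(per_project_directions) {
  d <- per_project_directions[!is.na(per_project_directions) &
                                per_project_directions != 0]
  if (any(!d %in% c(-1, 1)))
    pd_stop("directions must be +1 or -1", "domain_error")
  ninc <- sum(d == 1); ndec <- sum(d == -1)
  trend <- if (ninc > ndec) "increasing"
           else if (ndec > ninc) "decreasing"
           else "indeterminate"
  list(n_increase = ninc, n_decrease = ndec, trend = trend)
}

#' Concordance of phage and host abundance shifts across projects
#'
#' Over the projects shared by both direction tables, counts concordant
#' (same-direction) and discordant (opposite-direction) changes and the
#' concordant proportion `N_concordant / (N_concordant + N_discordant)`.
#'
#' @param phage_direction_by_project named vector of +1 / -1, names =
#'   project ids.
#' @param host_direction_by_project named vector of +1 / -1.
#' @return list: `n_concordant`, `n_discordant`, `proportion_concordant`
#'   (NA with a warning when no projects are shared).
#' @export
concordance <- function(phage_direction_by_project, host_direction_by_project) {
  shared <- intersect(names(phage_direction_by_project),
                      names(host_direction_by_project))
  pd <- phage_direction_by_project[shared]
  hd <- host_direction_by_project[shared]
  ok <- !is.na(pd) & !is.na(hd) & pd != 0 & hd != 0
  pd <- pd[ok]; hd <- hd[ok]
  nc <- sum(pd == hd); ndis <- sum(pd != hd)
  if (nc + ndis == 0) {
    pd_warn("no shared projects with defined directions: concordance undefined")
    return(list(n_concordant = 0L, n_discordant = 0L,
                proportion_concordant = NA_real_))
  }
  list(n_concordant = nc, n_discordant = ndis,
       proportion_concordant = nc / (nc + ndis))
}

#' Per-project direction of a taxon's abundance change
#'
#' Sign of (median intervention abundance - median control abundance);
#' zero differences yield 0 and are excluded from downstream voting.
#'
#' @param control_values,intervention_values abundance values of the taxon
#'   in the two arms of one project.
#' @return -1, 0 or +1.
#' @export
project_direction <- function(control_values, intervention_values) {
  sign(stats::median(intervention_values) - stats::median(control_values))
}

#' Surrogate screen for diet-associated taxa
#'
#' A differential-abundance screen standing in when external
#' differential-abundance calls are not supplied: a taxon is selected when
#' its Kruskal-Wallis p across groups is < `alpha` AND its between-group
#' effect size — the largest pairwise |log10 mean difference| — exceeds
#' `effect_threshold`. Results are labeled `surrogate_screen` to
#' distinguish them from externally supplied calls, which bypass the
#' screen verbatim (labeled `supplied`).
#'
#' @param m abundance matrix (taxa x samples).
#' @param groups group label per sample (aligned with columns of `m`).
#' @param alpha Kruskal-Wallis significance level (default 0.05).
#' @param effect_threshold minimum |log10 mean difference| between any two
#'   groups (default 0.5, about a 3.2-fold mean shift).
#' @param pseudocount added to group means before log10 (default 1e-6).
#' @param supplied optional character vector of externally determined
#'   diet-associated taxon ids; when given, it is returned as-is.
#' @return data.frame: `taxon_id`, `p`, `effect`, `selected`, `source`.
#' @export
screen_differential <- function(m, groups, alpha = 0.05, effect_threshold = 0.5,
                                pseudocount = 1e-6, supplied = NULL) {
  if (!is.null(supplied))
    return(data.frame(taxon_id = supplied, p = NA_real_, effect = NA_real_,
                      selected = TRUE, source = "supplied",
                      stringsAsFactors = FALSE))
  v <- unclass(m)
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    pd_stop("screen needs >= 2 groups", "domain_error")
  res <- t(vapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ]
    p <- if (stats::sd(x) == 0) 1 else
      stats::kruskal.test(x, groups)$p.value
    mu <- tapply(x, groups, mean)
    lg <- log10(mu + pseudocount)
    c(p = p, effect = max(dist(lg)))
  }, numeric(2)))
  data.frame(taxon_id = rownames(v), p = res[, "p"], effect = res[, "effect"],
             selected = res[, "p"] < alpha & res[, "effect"] > effect_threshold,
             source = "surrogate_screen", row.names = NULL,
             stringsAsFactors = FALSE)
}
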