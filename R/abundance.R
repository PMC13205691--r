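# Normalization, relative abundance and the subsampled Bray-Curtis
# community-convergence procedure.

#' Length- and depth-normalized abundance
#'
#' `abundance = mapped_reads / (L x N) x 1e10`, where `L` is the target
#' length in bp and `N` the total number of reads in the sample. Linear in
#' `mapped_reads`; vectorized over all arguments.
#'
#' @param mapped_reads nonnegative read count(s) mapped to the target.
#' @param target_length_bp target (contig or gene) length L in bp, > 0.
#' @param total_sample_reads total reads N in the sample, > 0.
#' @return normalized abundance on the 1e10 scale (`normalized_1e10`).
#' @examples
#' normalize_abundance(100, 1000, 1e6)  # 1000
#' @export
normalize_abundance <- function(mapped_reads, target_length_bp, total_sample_reads) {
  if (any(target_length_bp <= 0) || any(total_sample_reads <= 0))
    pd_stop("target length L and total reads N must be positive", "domain_error")
  if (any(mapped_reads < 0))
    pd_stop("mapped_reads must be nonnegative", "domain_error")
  mapped_reads / (target_length_bp * total_sample_reads) * 1e10
}

#' Convert a count matrix to per-sample relative fractions
#'
#' Each sample column is divided by its column total (e.g. contig counts
#' normalized to total viral contigs per sample). An all-zero column stays
#' all-zero.
#'
#' @param m an `abundance_matrix` in `read_count` units.
#' @return an `abundance_matrix` in `relative_fraction` units.
#' @export
to_relative <- function(m) {
  if (abundance_unit(m) != "read_count")
    pd_stop(sprintf("to_relative expects read_count input, got %s",
                    abundance_unit(m)), "unit_error")
  v <- unclass(m)
  cs <- colSums(v)
  nz <- cs > 0
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2L, cs[nz], "/")
  abundance_matrix(v, "relative_fraction")
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`; 0 for identical vectors, 1 for disjoint
#' supports.
#'
#' @param x,y equal-length nonnegative vectors, not both all-zero.
#' @return distance in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y))
    pd_stop("bray_curtis needs equal-length vectors", "domain_error")
  if (any(x < 0) || any(y < 0))
    pd_stop("bray_curtis needs nonnegative vectors", "domain_error")
  tot <- sum(x) + sum(y)
  if (tot == 0)
    pd_stop("bray_curtis undefined for two all-zero vectors", "domain_error")
  sum(abs(x - y)) / tot
}

#' Subsampled Bray-Curtis community-shift procedure
#'
#' Balances unequal group sizes by random subsampling: in each iteration,
#' `per_iter_size` samples are drawn without replacement from the pre- and
#' post-intervention sides, all pre-vs-post pairwise Bray-Curtis distances
#' are computed, and their median is recorded together with a two-sided
#' Wilcoxon rank-sum p comparing the inter-group distances against the
#' within-pre-group distances of the same draw. Deterministic for a fixed
#' seed.
#'
#' @param pre,post abundance matrices (taxa x samples; `abundance_matrix`
#'   or plain matrix) for the two sides, sharing taxa rows.
#' @param n_iter number of subsampling iterations (default 100).
#' @param per_iter_size samples drawn per side per iteration; defaults to
#'   the smaller group size. Must not exceed either group size and must be
#'   >= 2.
#' @param seed integer seed (required, for reproducibility of the
#'   100-iteration procedure).
#' @param baseline comparison set for the Wilcoxon test:
#'   `"within_pre"` (default) or `"within_post"`.
#' @return data.frame with one row per iteration: `iteration`,
#'   `median_bc`, `p`; attributes `seed`, `per_iter_size`, `baseline`.
#' @export
subsampled_bc_shift <- function(pre, post, n_iter = 100L, per_iter_size = NULL,
                                seed, baseline = c("within_pre", "within_post")) {
  baseline <- match.arg(baseline)
  if (missing(seed)) pd_stop("subsampled_bc_shift requires a seed", "config_error")
  pre <- as.matrix(unclass(pre)); post <- as.matrix(unclass(post))
  if (nrow(pre) != nrow(post))
    pd_stop("pre and post must share taxa rows", "schema_error")
  np <- ncol(pre); nq <- ncol(post)
  if (np < 2L || nq < 2L)
    pd_stop("need >= 2 samples per side", "domain_error")
  per_iter_size <- per_iter_size %||% min(np, nq)
  if (per_iter_size > min(np, nq))
    pd_stop("per_iter_size exceeds a group size", "domain_error")
  if (per_iter_size < 2L)
    pd_stop("per_iter_size must be >= 2", "domain_error")

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  k <- per_iter_size
  res <- vapply(seq_len(n_iter), function(it) {
    ip <- sample.int(np, k); iq <- sample.int(nq, k)
    inter <- as.vector(outer(ip, iq, Vectorize(function(a, b)
      bray_curtis(pre[, a], post[, b]))))
    within_of <- function(m, idx) {
      cmb <- utils::combn(idx, 2L)
      vapply(seq_len(ncol(cmb)), function(j)
        bray_curtis(m[, cmb[1L, j]], m[, cmb[2L, j]]), numeric(1))
    }
    within <- if (baseline == "within_pre") within_of(pre, ip) else within_of(post, iq)
    c(stats::median(inter), rank_sum_p(inter, within))
  }, numeric(2))

  out <- data.frame(iteration = seq_len(n_iter),
                    median_bc = res[1L, ], p = res[2L, ])
  attr(out, "seed") <- as.integer(seed)
  attr(out, "per_iter_size") <- k
  attr(out, "baseline") <- baseline
  out
}
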