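# Optimal-subsample determination protocol.
#
# One reference iteration (no subsampling), n_baseline further
# no-subsampling iterations with distinct seeds (their r values against the
# reference define the baseline envelope), and one iteration per candidate
# k. Each iteration runs registration -> (optional subsampling) -> GPA ->
# PCA -> pairwise PC-score distance vector, compared to the reference
# iteration by Pearson correlation. The smallest k whose r reaches the
# baseline minimum is the optimal subsample.

#' Pairwise PC-score distance vector
#'
#' Euclidean distances between specimen score rows over all computed
#' components (equivalent to distances in Procrustes coordinate space),
#' lower triangle in the fixed column-major order of [stats::dist()].
#'
#' @param pc_scores specimens x components matrix.
#' @return Numeric vector of length `n (n - 1) / 2`.
#' @export
pc_distance_vector <- function(pc_scores) {
  if (nrow(pc_scores) < 2) dm_stop("need at least 2 specimens")
  as.vector(stats::dist(pc_scores))
}

#' Pearson correlation between two iteration distance vectors
#'
#' @param a,b numeric distance vectors of equal length (same specimen set
#'   and ordering), or `iteration_record` objects.
#' @return Pearson r.
#' @export
iteration_correlation <- function(a, b) {
  va <- if (is.list(a)) a$distance_vector else a
  vb <- if (is.list(b)) b$distance_vector else b
  if (length(va) != length(vb)) dm_stop("distance vectors differ in length")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    dm_stop("zero-variance distance vector: correlation undefined")
  # bit-identical iterations must give r = 1 exactly; stats::cor can return
  # 1 - eps even then (sqrt(s)^2 != s), so short-circuit and clamp
  if (identical(va, vb)) return(1)
  max(-1, min(1, stats::cor(va, vb)))
}

#' One iteration of the optimization protocol
#' @noRd
run_iteration <- function(reference, reference_lms, targets, params, k, seed,
                          iteration_id) {
  p <- params
  p$seed <- seed
  s <- register_sample(reference, reference_lms, targets, p, validate = FALSE)
  if (!is.null(k)) s <- subsample_registered(s, k, seed = seed)
  sp <- pca_shape(gpa(s))
  structure(list(iteration_id = iteration_id, k = k, seed = seed,
                 pc_scores = sp$pc_scores,
                 distance_vector = pc_distance_vector(sp$pc_scores),
                 r_vs_reference = NA_real_),
            class = "iteration_record")
}

#' Run the subsample-size optimization protocol
#'
#' Mirrors the published protocol: 1 reference iteration plus `n_baseline`
#' no-subsampling iterations (defining the baseline envelope) plus one
#' iteration per ladder k. Registration should be configured with
#' `stochastic_fraction < 1` so baseline iterations genuinely differ;
#' in fully deterministic mode all baseline r are exactly 1.
#'
#' @param reference,reference_lms,targets as in [register_sample()].
#' @param params an [icp_params]; per-iteration seeds are derived from
#'   `seed`, not from `params$seed`.
#' @param k_ladder candidate subsample sizes (default the published ladder
#'   25...5000), clipped to the reference vertex count.
#' @param n_baseline number of baseline iterations (default 16 as
#'   published).
#' @param seed master seed for the protocol.
#' @return An object of class `optimization_result`: `baseline_r_min`,
#'   `baseline_r_max`, `per_k` (data.frame k, r), `chosen_k`, plus all
#'   `iterations`.
#' @export
run_optimization <- function(reference, reference_lms, targets,
                             params = icp_params(stochastic_fraction = 0.5),
                             k_ladder = c(25, 50, 100, 150, 200, 250, 500,
                                          1000, 2500, 5000),
                             n_baseline = 16L, seed = 1L) {
  nv <- nrow(reference$vertices)
  k_ladder <- sort(unique(pmin(as.integer(k_ladder), nv)))
  ref_it <- run_iteration(reference, reference_lms, targets, params,
                          k = NULL, seed = derive_seed(seed, 0L),
                          iteration_id = "reference")
  iters <- list(reference = ref_it)
  base_r <- numeric(n_baseline)
  for (b in seq_len(n_baseline)) {
    it <- run_iteration(reference, reference_lms, targets, params,
                        k = NULL, seed = derive_seed(seed, b),
                        iteration_id = sprintf("baseline%02d", b))
    it$r_vs_reference <- iteration_correlation(it, ref_it)
    base_r[b] <- it$r_vs_reference
    iters[[it$iteration_id]] <- it
  }
  kr <- numeric(length(k_ladder))
  for (j in seq_along(k_ladder)) {
    it <- run_iteration(reference, reference_lms, targets, params,
                        k = k_ladder[j],
                        seed = derive_seed(seed, n_baseline + j),
                        iteration_id = sprintf("k%05d", k_ladder[j]))
    it$r_vs_reference <- iteration_correlation(it, ref_it)
    kr[j] <- it$r_vs_reference
    iters[[it$iteration_id]] <- it
  }
  res <- optimization_result(baseline_r_min = min(base_r),
                             baseline_r_max = max(base_r),
                             k = k_ladder, r = kr)
  res$baseline_r <- base_r
  res$iterations <- iters
  res$chosen_k <- choose_optimal_k(res)
  res
}

#' Construct an optimization result from per-k correlations
#'
#' Usable directly on externally obtained values (e.g. a published table of
#' per-k Pearson correlations and baseline range).
#'
#' @param baseline_r_min,baseline_r_max baseline envelope.
#' @param k,r equal-length vectors of subsample sizes and their Pearson
#'   correlations against the reference iteration.
#' @return An object of class `optimization_result`.
#' @export
optimization_result <- function(baseline_r_min, baseline_r_max, k, r) {
  if (baseline_r_min > baseline_r_max) dm_stop("baseline_r_min > baseline_r_max")
  if (length(k) != length(r)) dm_stop("k and r lengths differ")
  per_k <- data.frame(k = as.integer(k), r = as.numeric(r))
  per_k <- per_k[order(per_k$k), ]
  rownames(per_k) <- NULL
  structure(list(baseline_r_min = baseline_r_min,
                 baseline_r_max = baseline_r_max,
                 per_k = per_k, chosen_k = NA_integer_),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("optimization_result: baseline r in [%.5f, %.5f]\n",
              x$baseline_r_min, x$baseline_r_max))
  print(x$per_k, row.names = FALSE)
  ck <- choose_optimal_k(x)
  cat(if (is.na(ck)) "no acceptable k\n" else sprintf("optimal k: %d\n", ck))
  invisible(x)
}

#' Smallest subsample size within the baseline envelope
#'
#' The selection rule: the smallest k whose Pearson correlation against the
#' reference iteration reaches the baseline minimum (`r >= baseline_r_min`).
#'
#' @param result an `optimization_result`.
#' @return Integer k, or `NA` (with a message) when no ladder entry
#'   qualifies.
#' @export
choose_optimal_k <- function(result) {
  ok <- result$per_k$r >= result$baseline_r_min
  if (!any(ok)) {
    message("no acceptable k: every candidate falls below the baseline envelope")
    return(NA_integer_)
  }
  min(result$per_k$k[ok])
}
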