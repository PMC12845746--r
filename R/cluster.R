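#' Best-of-repeats K-means with squared Euclidean distance
#'
#' Lloyd iterations from `n_repeats` random initialisations; the solution with
#' the lowest total within-cluster squared Euclidean distance is returned.
#' Degenerate requests are handled in closed form: `k = 1` returns the mean
#' and the total sum of squares about it; `k = nrow(x)` puts every point in
#' its own cluster with zero dispersion.
#'
#' @param x matrix `n_vectors x n_dims`.
#' @param k number of clusters, `1 <= k <= nrow(x)`.
#' @param n_repeats random restarts.
#' @param seed integer seed.
#' @param iter_max Lloyd iteration cap per restart.
#' @return list with `centroids` (`k x n_dims`), `cluster` (assignments) and
#'   `tot_withinss`.
#' @export
kmeans_repeated <- function(x, k, n_repeats = 1000, seed = 1, iter_max = 100) {
  x <- as.matrix(x)
  k <- as.integer(k)
  if (k < 1 || k > nrow(x)) {
    abort("`k` must lie in 1..nrow(x).", class = "kicksyn_invalid_k")
  }
  if (k == 1) {
    ctr <- matrix(colMeans(x), 1)
    return(list(centroids = ctr, cluster = rep(1L, nrow(x)),
                tot_withinss = sum(sweep(x, 2, ctr[1, ])^2)))
  }
  n_distinct <- nrow(unique(x))
  if (k >= n_distinct) {
    u <- unique(x)
    assign <- apply(x, 1, function(p) {
      which.min(colSums((t(u) - p)^2))
    })
    centroids <- u[c(seq_len(n_distinct), rep(1, max(0, k - n_distinct))), ,
                   drop = FALSE]
    return(list(centroids = centroids, cluster = as.integer(assign),
                tot_withinss = 0))
  }
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(x, centers = k, iter.max = iter_max, nstart = n_repeats,
                  algorithm = "Lloyd")))
  list(centroids = unname(km$centers), cluster = as.integer(km$cluster),
       tot_withinss = km$tot.withinss)
}

#' Select the number of clusters by the Gap statistic
#'
#' `Gap(k) = mean_b log(W*_kb) - log(W_k)`, with `W_k` the best-of-repeats
#' K-means dispersion of the data and `W*_kb` the dispersion of `B` reference
#' datasets drawn uniformly on the per-dimension bounding box of the data.
#' `sd(k)` is the standard deviation of `log(W*_kb)` scaled by
#' `sqrt(1 + 1/B)`. The smallest `k` with
#' `Gap(k) >= Gap(k + 1) - sd(k + 1)` is selected; all-identical inputs
#' short-circuit to `k = 1`, and if no `k` satisfies the criterion the
#' largest evaluated `k` is returned with `converged = FALSE`.
#'
#' @param x matrix `n_vectors x n_dims`.
#' @param k_max largest cluster count evaluated (`< nrow(x)`).
#' @param B number of uniform reference draws.
#' @param seed integer seed.
#' @param n_repeats K-means restarts per dispersion evaluation.
#' @return list with `n_clusters`, `gap_curve` (tibble `k`, `log_w`, `gap`,
#'   `sd`) and `converged`.
#' @export
gap_select <- function(x, k_max = 6, B = 100, seed = 1, n_repeats = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k_max >= n) {
    abort("`k_max` must be smaller than the number of vectors.",
          class = "kicksyn_invalid_k")
  }
  if (nrow(unique(x)) == 1) {
    return(list(n_clusters = 1L, gap_curve = tibble(), converged = TRUE))
  }
  ks <- seq_len(k_max)
  log_w <- vapply(ks, function(k) {
    log(max(kmeans_repeated(x, k, n_repeats,
                            seed = derive_seed(seed, "obs", k))$tot_withinss,
            1e-300))
  }, numeric(1))
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  log_w_ref <- matrix(NA_real_, B, k_max)
  for (b in seq_len(B)) {
    ref <- with_seed(derive_seed(seed, "ref", b), {
      matrix(runif(n * ncol(x), rep(lo, each = n), rep(hi, each = n)),
             n, ncol(x))
    })
    for (k in ks) {
      log_w_ref[b, k] <- log(max(
        kmeans_repeated(ref, k, n_repeats,
                        seed = derive_seed(seed, "refk", b, k))$tot_withinss,
        1e-300))
    }
  }
  gap <- colMeans(log_w_ref) - log_w
  sd_k <- apply(log_w_ref, 2, function(v) {
    sqrt(mean((v - mean(v))^2)) * sqrt(1 + 1 / B)
  })
  ok <- which(gap[-k_max] >= gap[-1] - sd_k[-1])
  list(n_clusters = if (length(ok)) as.integer(min(ok)) else as.integer(k_max),
       gap_curve = tibble(k = ks, log_w = log_w, gap = gap, sd = sd_k),
       converged = length(ok) > 0)
}

#' Build reference synergies from one study condition
#'
#' Pools the unit-norm synergy weight vectors extracted in the reference
#' condition (by default the control group before the intervention), selects
#' the cluster count by the Gap statistic, and clusters with best-of-repeats
#' K-means. Centroids are re-normalised to unit norm after averaging.
#'
#' @param synergies an [extract_synergies()] tibble.
#' @param group,timepoint the reference condition.
#' @param config a [kick_config()] with clustering settings.
#' @param seed integer seed.
#' @return object of class `kick_refs`: `centroids`
#'   (`n_clusters x n_muscles`), `n_clusters`, `gap_curve`, `muscles`,
#'   `source`.
#' @export
reference_synergies <- function(synergies, group = "CON", timepoint = "pre",
                                config = kick_config(), seed = config$seed) {
  sel <- synergies[synergies$group == group &
                     synergies$timepoint == timepoint, ]
  if (nrow(sel) == 0) {
    abort("No synergies found for the reference condition.",
          class = "kicksyn_invalid_parameter")
  }
  vecs <- do.call(rbind, purrr::map(sel$fit, function(f) t(f$weights)))
  muscles <- rownames(sel$fit[[1]]$weights)
  if (is.null(config$n_reference_clusters)) {
    gap <- gap_select(vecs, k_max = min(config$gap_k_max, nrow(vecs) - 1L),
                      B = config$gap_B, seed = derive_seed(seed, "gap"),
                      n_repeats = config$gap_repeats)
  } else {
    gap <- list(n_clusters = config$n_reference_clusters,
                gap_curve = tibble(), converged = NA)
  }
  km <- kmeans_repeated(vecs, gap$n_clusters,
                        n_repeats = config$kmeans_repeats,
                        seed = derive_seed(seed, "kmeans"))
  centroids <- t(normalize_columns(t(km$centroids)))
  colnames(centroids) <- muscles
  structure(list(centroids = centroids, n_clusters = gap$n_clusters,
                 gap_curve = gap$gap_curve, gap_converged = gap$converged,
                 muscles = muscles,
                 source = sprintf("%s/%s", group, timepoint)),
            class = "kick_refs")
}

#' @export
print.kick_refs <- function(x, ...) {
  cat(sprintf("<kick_refs> %d reference synergies from %s (%d muscles)\n",
              x$n_clusters, x$source, length(x$muscles)))
  invisible(x)
}

#' Match one synergy set to the reference synergies
#'
#' Greedy one-to-one assignment by Pearson correlation of muscle weight
#' vectors: the highest remaining (synergy, reference) correlation at or above
#' the threshold is matched first; ties break to the lower reference index,
#' then the lower synergy index. Synergies left without a reference at the
#' threshold are unmatched.
#'
#' @param fit a `kick_synergy`.
#' @param refs a [reference_synergies()] object.
#' @param threshold minimum Pearson correlation for a match.
#' @return tibble with one row per synergy: `synergy`, `ref` (`NA` if
#'   unmatched), `r`.
#' @export
match_to_reference <- function(fit, refs, threshold = 0.6) {
  w <- fit$weights
  if (!identical(rownames(w), refs$muscles)) {
    abort("Muscle ordering differs between synergies and references.",
          class = "kicksyn_alignment")
  }
  r_mat <- suppressWarnings(cor(w, t(refs$centroids)))
  r_mat[!is.finite(r_mat)] <- -Inf
  k <- ncol(w); n_ref <- nrow(refs$centroids)
  assigned <- rep(NA_integer_, k); r_val <- rep(NA_real_, k)
  work <- r_mat
  repeat {
    best <- max(work)
    if (!is.finite(best) || best < threshold) break
    hits <- which(work == best, arr.ind = TRUE)
    hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    assigned[i] <- j; r_val[i] <- r_mat[i, j]
    work[i, ] <- -Inf; work[, j] <- -Inf
  }
  tibble(synergy = seq_len(k), ref = assigned, r = r_val)
}

#' Match every extracted synergy set of a study
#'
#' @param synergies an [extract_synergies()] tibble.
#' @param refs a [reference_synergies()] object.
#' @param threshold Pearson matching threshold.
#' @return tibble: `subject_id`, `group`, `timepoint`, `synergy`, `ref`, `r`.
#' @export
match_study <- function(synergies, refs, threshold = 0.6) {
  purrr::pmap(synergies, function(subject_id, group, timepoint, fit, ...) {
    match_to_reference(fit, refs, threshold) |>
      dplyr::mutate(subject_id = subject_id, group = group,
                    timepoint = timepoint, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Synergy census per group and timepoint
#'
#' Summarises, per group x timepoint: the mean and SD across subjects of the
#' number of extracted synergies, the occurrence count of each reference
#' synergy, and the number of unmatched synergies. Occurrence counts plus the
#' unmatched count always sum to the total number of extracted synergies.
#'
#' @param matches a [match_study()] tibble.
#' @param synergies the [extract_synergies()] tibble the matches came from.
#' @return tibble: `group`, `timepoint`, `n_subjects`, `n_syn_mean`,
#'   `n_syn_sd`, `n_total`, one `n_syn<j>` column per reference, and
#'   `n_unmatched`.
#' @export
synergy_census <- function(matches, synergies) {
  refs <- sort(unique(stats::na.omit(matches$ref)))
  per_subj <- synergies |>
    dplyr::group_by(.data$group, .data$timepoint) |>
    dplyr::summarise(n_subjects = dplyr::n_distinct(.data$subject_id),
                     n_syn_mean = mean(.data$k), n_syn_sd = sd(.data$k),
                     n_total = sum(.data$k), .groups = "drop")
  count_quos <- setNames(purrr::map(refs, function(j) {
    rlang::quo(sum(!is.na(.data$ref) & .data$ref == !!j))
  }), sprintf("n_syn%d", refs))
  counts <- matches |>
    dplyr::group_by(.data$group, .data$timepoint) |>
    dplyr::summarise(n_unmatched = sum(is.na(.data$ref)), !!!count_quos,
                     .groups = "drop")
  dplyr::left_join(per_subj, counts, by = c("group", "timepoint")) |>
    dplyr::relocate("n_unmatched", .after = dplyr::last_col())
}
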