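#' Variance accounted for by a reconstruction
#'
#' `VAF = 1 - SSE / SST` with `SSE` the sum of squared residuals and `SST`
#' the *uncentred* total sum of squares (`sum(data^2)`), the convention used
#' for global reconstruction quality in the muscle-synergy literature. A
#' mean-centred `SST` is available via `centered = TRUE`.
#'
#' @param data observed non-negative matrix.
#' @param reconstruction fitted matrix of the same shape.
#' @param centered use the mean-centred total sum of squares instead.
#' @return scalar VAF (1 for a perfect reconstruction).
#' @export
vaf <- function(data, reconstruction, centered = FALSE) {
  if (!identical(dim(data), dim(reconstruction))) {
    abort("`data` and `reconstruction` must have identical shapes.",
          class = "kicksyn_invalid_parameter")
  }
  sst <- if (centered) sum((data - mean(data))^2) else sum(data^2)
  if (sst == 0) {
    abort("VAF is undefined for all-zero data.",
          class = "kicksyn_undefined_vaf")
  }
  1 - sum((data - reconstruction)^2) / sst
}

new_kick_synergy <- function(W, H, k, vaf_value, restarts, monotone,
                             provenance = list()) {
  nrm <- sqrt(colSums(W^2))
  keep <- nrm > 0
  W[, keep] <- sweep(W[, keep, drop = FALSE], 2, nrm[keep], "/")
  H[keep, ] <- sweep(H[keep, , drop = FALSE], 1, nrm[keep], "*")
  structure(list(weights = W, activations = H, k = as.integer(k),
                 vaf = vaf_value, restarts_used = as.integer(restarts),
                 objective_monotone = monotone,
                 subject_id = provenance$subject_id %||% NA_character_,
                 group = provenance$group %||% NA_character_,
                 timepoint = provenance$timepoint %||% NA_character_),
            class = "kick_synergy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a non-negative matrix factorisation at a fixed order
#'
#' Decomposes a non-negative muscle-by-time matrix into `k` synergy weight
#' vectors and activation coefficients by Frobenius multiplicative updates.
#' Each of `n_restarts` restarts is initialised i.i.d. uniform on
#' `(0, max(data)]` and run to convergence (VAF change below `tol` per
#' 10-iteration block, up to `max_iter` iterations); the restart with the
#' highest VAF wins. Weight columns are re-normalised to unit Euclidean norm
#' with compensating scaling of the activation rows, which leaves the
#' reconstruction unchanged.
#'
#' @param data non-negative matrix (`n_muscles x n_time`), rows optionally
#'   named by muscle.
#' @param k synergy order, `1 <= k <= min(dim(data))`.
#' @param seed integer seed; restarts derive their initialisation from it.
#' @param n_restarts number of random restarts.
#' @param max_iter iteration cap per restart.
#' @param tol VAF convergence tolerance.
#' @param provenance optional list with `subject_id`, `group`, `timepoint`.
#' @return object of class `kick_synergy`: unit-norm `weights`
#'   (`n_muscles x k`), `activations` (`k x n_time`), `vaf`, `k`,
#'   `restarts_used` and an objective-monotonicity flag.
#' @export
nmf_fit <- function(data, k, seed = 1, n_restarts = 20, max_iter = 1000,
                    tol = 1e-6, provenance = list()) {
  check_nonneg_matrix(data, "data")
  k <- as.integer(k)
  if (k < 1 || k > min(dim(data))) {
    abort("`k` must lie in 1..min(dim(data)).", class = "kicksyn_invalid_order")
  }
  maxv <- max(data)
  if (maxv == 0) {
    abort("Cannot factorise an all-zero matrix.",
          class = "kicksyn_undefined_vaf")
  }
  m <- nrow(data); n <- ncol(data)
  best <- NULL
  monotone <- TRUE
  for (r in seq_len(n_restarts)) {
    init <- with_seed(derive_seed(seed, k, r), {
      list(W = matrix(runif(m * k) * maxv, m, k),
           H = matrix(runif(k * n) * maxv, k, n))
    })
    fit <- nmf_mu_cpp(data, init$W, init$H, max_iter, tol, 1e-12)
    monotone <- monotone && fit$objective_monotone
    if (is.null(best) || fit$vaf > best$vaf) best <- fit
  }
  syn <- new_kick_synergy(best$W, best$H, k, best$vaf, n_restarts, monotone,
                          provenance)
  # store the VAF recomputed from the stored (renormalised) factors
  syn$vaf <- vaf(data, syn$weights %*% syn$activations)
  rownames(syn$weights) <- rownames(data)
  syn
}

#' Select the synergy order by the VAF > threshold rule
#'
#' Sweeps candidate orders in ascending sequence, fitting each with
#' [nmf_fit()], and returns the smallest order whose best-restart VAF exceeds
#' the threshold (default 90 %). If no order qualifies, the order with the
#' highest VAF is returned and the selection is flagged non-convergent.
#'
#' @inheritParams nmf_fit
#' @param k_range candidate orders (ascending).
#' @param threshold VAF threshold; an order is selected when `vaf > threshold`.
#' @return the selected `kick_synergy`, with `converged` (logical) and
#'   `vaf_curve` (tibble `k`, `vaf` for the orders actually fitted).
#' @export
select_order <- function(data, k_range = 1:10, threshold = 0.90, seed = 1,
                         n_restarts = 20, max_iter = 1000, tol = 1e-6,
                         provenance = list()) {
  if (length(k_range) == 0) {
    abort("`k_range` must be non-empty.", class = "kicksyn_invalid_range")
  }
  k_range <- sort(unique(as.integer(k_range)))
  fits <- list(); vafs <- numeric(0)
  for (k in k_range) {
    fit <- nmf_fit(data, k, seed = seed, n_restarts = n_restarts,
                   max_iter = max_iter, tol = tol, provenance = provenance)
    fits[[as.character(k)]] <- fit
    vafs <- c(vafs, fit$vaf)
    if (fit$vaf > threshold) break
  }
  converged <- vafs[length(vafs)] > threshold
  chosen <- if (converged) fits[[length(fits)]] else fits[[which.max(vafs)]]
  chosen$converged <- converged
  chosen$vaf_curve <- tibble(k = k_range[seq_along(vafs)], vaf = vafs)
  chosen
}

#' @export
print.kick_synergy <- function(x, ...) {
  cat(sprintf("<kick_synergy> k = %d, VAF = %.3f (%d restarts)%s\n",
              x$k, x$vaf, x$restarts_used,
              if (!is.null(x$converged) && !x$converged)
                " [non-convergent selection]" else ""))
  invisible(x)
}

#' @describeIn nmf_fit tidy method: long tibble of weights and activations.
#' @param x,... broom-interface arguments.
#' @param matrix which factor to tidy, `"weights"` or `"activations"`.
#' @export
tidy.kick_synergy <- function(x, matrix = c("weights", "activations"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "weights") {
    w <- x$weights
    tibble(muscle = rep(rownames(w) %||% paste0("m", seq_len(nrow(w))),
                        ncol(w)),
           synergy = rep(seq_len(ncol(w)), each = nrow(w)),
           weight = as.vector(w))
  } else {
    h <- x$activations
    tibble(synergy = rep(seq_len(nrow(h)), each = ncol(h)),
           t = rep(seq_len(ncol(h)), nrow(h)),
           activation = as.vector(t(h)))
  }
}

#' @describeIn nmf_fit glance method: one-row fit summary.
#' @export
glance.kick_synergy <- function(x, ...) {
  tibble(k = x$k, vaf = x$vaf, restarts_used = x$restarts_used,
         converged = x$converged %||% NA,
         objective_monotone = x$objective_monotone)
}

#' Extract synergies for every envelope cycle of a study
#'
#' Runs VAF-based order selection per subject x timepoint on the preprocessed
#' envelope cycles.
#'
#' @param envelopes a [preprocess_study()] result.
#' @param config a [kick_config()] carrying the NMF settings.
#' @param seed root seed; per-recording seeds are derived from it together
#'   with subject and timepoint.
#' @return tibble of class `kick_synergies`: one row per recording with
#'   list-column `fit` (`kick_synergy`), plus `k`, `vaf`, `converged`.
#' @export
extract_synergies <- function(envelopes, config = kick_config(),
                              seed = config$seed) {
  rows <- purrr::pmap(envelopes, function(subject_id, group, timepoint,
                                          envelope, ...) {
    fit <- select_order(envelope$activity,
                        k_range = config$k_range,
                        threshold = config$vaf_threshold,
                        seed = derive_seed(seed, "nmf", subject_id, timepoint),
                        n_restarts = config$n_restarts,
                        max_iter = config$max_iter, tol = config$tol,
                        provenance = list(subject_id = subject_id,
                                          group = group,
                                          timepoint = timepoint))
    tibble(subject_id = subject_id, group = group, timepoint = timepoint,
           k = fit$k, vaf = fit$vaf, converged = fit$converged,
           fit = list(fit))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("kick_synergies", class(out))
  out
}
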