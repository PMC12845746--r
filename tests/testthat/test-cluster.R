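make_clouds <- function(n_clusters, n_per, sep_seed, spread = 0.03) {
  withr::with_seed(sep_seed, {
    ctr <- matrix(runif(n_clusters * 10), n_clusters, 10)
    ctr <- ctr / sqrt(rowSums(ctr^2))
    x <- ctr[rep(seq_len(n_clusters), each = n_per), ] +
      matrix(rnorm(n_clusters * n_per * 10, 0, spread), n_clusters * n_per)
    list(x = x, labels = rep(seq_len(n_clusters), each = n_per), ctr = ctr)
  })
}

test_that("K-means closed forms: k = 1 mean, k = n zero dispersion", {
  x <- matrix(rnorm(60), 12, 5)
  km1 <- kmeans_repeated(x, 1, seed = 1)
  expect_equal(km1$centroids[1, ], colMeans(x))
  expect_equal(km1$tot_withinss, sum(sweep(x, 2, colMeans(x))^2))
  kmn <- kmeans_repeated(x, 12, seed = 1)
  expect_equal(kmn$tot_withinss, 0)
  expect_error(kmeans_repeated(x, 13, seed = 1), class = "kicksyn_invalid_k")
})

test_that("K-means recovers well-separated clouds and dispersion shrinks with k", {
  cl <- make_clouds(2, 10, sep_seed = 5)
  km <- kmeans_repeated(cl$x, 2, n_repeats = 50, seed = 2)
  tab <- table(km$cluster, cl$labels)
  expect_equal(sort(diag(tab[order(max.col(t(tab))), ])), c(10, 10))
  wss <- sapply(1:5, function(k) {
    kmeans_repeated(cl$x, k, n_repeats = 50, seed = 3)$tot_withinss
  })
  expect_true(all(diff(wss) <= 1e-9))
})

test_that("the Gap statistic selects the generative cluster count", {
  cl <- make_clouds(3, 15, sep_seed = 7)
  g <- gap_select(cl$x, k_max = 6, B = 50, seed = 8)
  expect_equal(g$n_clusters, 3)
  expect_equal(nrow(g$gap_curve), 6)
  # single cloud
  x1 <- withr::with_seed(9, matrix(rnorm(300, 0, 0.1), 30) + 1)
  expect_equal(gap_select(x1, 5, B = 50, seed = 10)$n_clusters, 1)
  # degenerate: all points identical
  xd <- matrix(1, 20, 4)
  expect_equal(gap_select(xd, 5, B = 10, seed = 11)$n_clusters, 1)
  expect_error(gap_select(cl$x, k_max = 45, B = 10, seed = 1),
               class = "kicksyn_invalid_k")
})

fake_fit <- function(w, muscles, sid, grp, tp) {
  structure(list(weights = matrix(w, length(muscles),
                                  dimnames = list(muscles, NULL)),
                 activations = matrix(runif(ncol(matrix(w,
                                                        length(muscles))) * 100),
                                      ncol = 100),
                 k = ncol(matrix(w, length(muscles))),
                 vaf = 0.95, restarts_used = 1, objective_monotone = TRUE,
                 converged = TRUE,
                 subject_id = sid, group = grp, timepoint = tp),
            class = "kick_synergy")
}

test_that("matching recovers permutations and respects the threshold", {
  muscles <- paste0("m", 1:6)
  ctr <- rbind(c(1, 0, 0, 0.2, 0, 0),
               c(0, 1, 0, 0, 0.2, 0),
               c(0, 0, 1, 0, 0, 0.2))
  colnames(ctr) <- muscles
  refs <- structure(list(centroids = ctr, n_clusters = 3,
                         gap_curve = tibble::tibble(), muscles = muscles,
                         source = "CON/pre"),
                    class = "kick_refs")
  # identical weights in permuted order: the permutation is recovered at r = 1
  fit <- fake_fit(c(t(ctr[c(3, 1, 2), ])), muscles, "s1", "CON", "pre")
  m <- match_to_reference(fit, refs, 0.6)
  expect_equal(m$ref, c(3L, 1L, 2L))
  expect_equal(m$r, rep(1, 3), tolerance = 1e-12)
  # a weight pattern uncorrelated with every centroid stays unmatched
  ortho <- fake_fit(rep(1 / sqrt(6), 6), muscles, "s1", "CON", "pre")
  m2 <- match_to_reference(ortho, refs, 0.6)
  expect_true(is.na(m2$ref))
  # muscle-order mismatch is an alignment error
  bad <- fake_fit(c(t(ctr)), rev(muscles), "s1", "CON", "pre")
  expect_error(match_to_reference(bad, refs, 0.6),
               class = "kicksyn_alignment")
})

test_that("matching is invariant to synergy order", {
  muscles <- paste0("m", 1:6)
  withr::with_seed(21, {
    ctr <- matrix(runif(18), 3, 6)
    ctr <- ctr / sqrt(rowSums(ctr^2))
    colnames(ctr) <- muscles
    refs <- structure(list(centroids = ctr, n_clusters = 3,
                           gap_curve = tibble::tibble(), muscles = muscles,
                           source = "CON/pre"),
                      class = "kick_refs")
    w <- t(ctr) + matrix(rnorm(18, 0, 0.05), 6)
    w <- abs(w)
    fit1 <- fake_fit(c(w), muscles, "s", "CON", "pre")
    fit2 <- fake_fit(c(w[, c(2, 3, 1)]), muscles, "s", "CON", "pre")
    m1 <- match_to_reference(fit1, refs, 0.6)
    m2 <- match_to_reference(fit2, refs, 0.6)
    expect_setequal(paste(m1$ref, round(m1$r, 12)),
                    paste(m2$ref, round(m2$r, 12)))
  })
})

test_that("the synergy census conserves counts", {
  syn <- tibble::tibble(
    subject_id = rep(c("C1", "C2"), each = 2),
    group = "CON",
    timepoint = rep(c("pre", "post"), 2),
    k = c(3, 3, 2, 3))
  matches <- tibble::tibble(
    subject_id = rep(syn$subject_id, syn$k),
    group = "CON",
    timepoint = rep(syn$timepoint, syn$k),
    synergy = unlist(lapply(syn$k, seq_len)),
    ref = c(1, 2, 3, 1, 2, NA, 1, 2, 1, 2, 3),
    r = 0.9)
  cen <- synergy_census(matches, syn)
  expect_equal(cen$n_total,
               rowSums(cen[, c("n_syn1", "n_syn2", "n_syn3",
                               "n_unmatched")]))
  pre <- cen[cen$timepoint == "pre", ]
  expect_equal(pre$n_syn_mean, mean(c(3, 2)))
  # removing one match increments unmatched, decrements its reference count
  matches2 <- matches
  matches2$ref[1] <- NA
  cen2 <- synergy_census(matches2, syn)
  expect_equal(cen2$n_unmatched[cen2$timepoint == "pre"],
               cen$n_unmatched[cen$timepoint == "pre"] + 1)
  expect_equal(cen2$n_syn1[cen2$timepoint == "pre"],
               cen$n_syn1[cen$timepoint == "pre"] - 1)
})

test_that("reference clustering recovers the generating synergy structure", {
  # noisy copies of 3 ground-truth synergies across 15 subjects
  tr <- make_ground_truth(10, 3, seed = 77)
  syn_rows <- lapply(1:15, function(i) {
    w <- withr::with_seed(100 + i, {
      ww <- tr$weights + matrix(rnorm(30, 0, 0.1), 10)
      ww[ww < 0] <- 0
      sweep(ww, 2, sqrt(colSums(ww^2)), "/")
    })
    tibble::tibble(subject_id = sprintf("CON%02d", i), group = "CON",
                   timepoint = "pre", k = 3L, vaf = 0.95, converged = TRUE,
                   fit = list(fake_fit(c(w), tr$muscles,
                                       sprintf("CON%02d", i), "CON", "pre")))
  })
  syn <- dplyr::bind_rows(syn_rows)
  cfg <- kick_config(gap_B = 50, gap_repeats = 50, kmeans_repeats = 100)
  refs <- reference_synergies(syn, "CON", "pre", cfg, seed = 5)
  expect_equal(refs$n_clusters, 3)
  cosines <- best_permutation_cosines(t(refs$centroids), tr$weights)
  expect_true(all(cosines >= 0.95))
})
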