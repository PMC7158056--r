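test_that("a single anteiso-C15 precursor forces a point mass at (C29, aiai)", {
  pool <- fatty_pool(15, "anteiso", 1)
  pred <- predict_olefins(pool, c("15:anteiso" = 1))
  expect_equal(nrow(pred), 1)
  expect_equal(pred$chain_length, 29L)   # 15 + 15 - 1
  expect_equal(pred$isomer_class, "aiai")
  expect_equal(pred$p, 1)
})

test_that("two equal precursors with uniform weights give 1/4, 1/2, 1/4", {
  pool <- fatty_pool(c(14, 16), c("iso", "iso"), c(0.5, 0.5))
  pred <- predict_olefins(pool, c("14:iso" = 1, "16:iso" = 1))
  # ii -> C27, ij -> C29, jj -> C31, all isoiso
  expect_equal(pred$p[pred$chain_length == 27], 0.25)
  expect_equal(pred$p[pred$chain_length == 29], 0.50)
  expect_equal(pred$p[pred$chain_length == 31], 0.25)
})

# brute-force oracle: enumerate ordered precursor pairs
enum_predict <- function(pool, weights) {
  u <- unname(weights[pool$key]) * pool$abundance
  u <- u / sum(u)
  cells <- list()
  for (i in seq_len(nrow(pool))) for (j in seq_len(nrow(pool))) {
    L <- pool$chain_length[i] + pool$chain_length[j] - 1L
    cls <- classify_isomer(pool$branch[i], pool$branch[j])
    k <- paste0(L, ":", cls)
    cells[[k]] <- (cells[[k]] %||% 0) + u[i] * u[j]
  }
  unlist(cells)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("prediction equals ordered-pair enumeration on random models", {
  set.seed(13)
  for (rep in 1:15) {
    n_chain <- sample(2:4, 1)
    chains <- sort(sample(12:18, n_chain))
    grid <- expand.grid(chain = chains,
                        branch = c("iso", "anteiso", "straight"),
                        stringsAsFactors = FALSE)
    keep <- sort(sample(nrow(grid), sample(3:nrow(grid), 1)))
    pool <- fatty_pool(grid$chain[keep], grid$branch[keep],
                       runif(length(keep)))
    w <- setNames(runif(length(keep), 0.1, 3), pool$key)
    pred <- predict_olefins(pool, w)
    expect_equal(sum(pred$p), 1, tolerance = 1e-12)
    want <- enum_predict(pool, w)
    got <- setNames(pred$p, paste0(pred$chain_length, ":", pred$isomer_class))
    expect_setequal(names(got), names(want))
    expect_equal(got[names(want)], want, tolerance = 1e-12)
    # support obeys L = n_i + n_j - 1
    achievable <- outer(pool$chain_length, pool$chain_length, `+`) - 1L
    expect_true(all(pred$chain_length %in% achievable))
    # invariance under pool row permutation
    perm <- sample(nrow(pool))
    pool2 <- fatty_pool(pool$chain_length[perm], pool$branch[perm],
                        pool$abundance[perm])
    pred2 <- predict_olefins(pool2, w)
    got2 <- setNames(pred2$p, paste0(pred2$chain_length, ":",
                                     pred2$isomer_class))
    expect_equal(got2[names(want)], want, tolerance = 1e-12)
  }
})

test_that("missing weights and empty pools are rejected", {
  pool <- fatty_pool(c(14, 15), c("iso", "anteiso"), c(0.5, 0.5))
  expect_error(predict_olefins(pool, c("14:iso" = 1)), "missing")
  expect_error(fatty_pool(integer(), character(), numeric()))
  expect_error(predict_olefins(pool, c("14:iso" = 0, "15:anteiso" = 0)),
               "zero")
})

ref_pool <- function() fatty_pool(rep(14:17, each = 3),
                                  rep(c("iso", "anteiso", "straight"), 4),
                                  rep(1 / 12, 12))

test_that("fitting the exact expectation recovers the weights", {
  pool <- ref_pool()
  set.seed(42)
  w_true <- setNames(runif(12, 0.2, 3), pool$key)
  w_true <- w_true / sum(w_true * pool$abundance)   # identifiability anchor
  pred <- predict_olefins(pool, w_true)
  obs <- data.frame(chain_length = pred$chain_length,
                    isomer_class = pred$isomer_class,
                    count = pred$p * 1e6)
  fit <- fit_weights(pool, obs, max_iter = 20000, tol = 1e-14)
  expect_lt(max(abs(fit$weights$w - w_true[pool$key]) / w_true[pool$key]),
            1e-6)
  expect_equal(sum(fit$weights$w * pool$abundance), 1, tolerance = 1e-9)
  # log-likelihood never decreases along the EM path
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("the pool's self-convolution fits back to uniform weights", {
  pool <- ref_pool()
  w_unif <- setNames(rep(1, 12), pool$key)
  pred <- predict_olefins(pool, w_unif)
  obs <- data.frame(chain_length = pred$chain_length,
                    isomer_class = pred$isomer_class,
                    count = pred$p * 1e6)
  fit <- fit_weights(pool, obs)
  expect_lt(diff(range(fit$weights$w)), 1e-6)   # uniform up to the anchor
})

test_that("sampled data recovers weights within 10 percent", {
  pool <- ref_pool()
  set.seed(17)
  w_true <- setNames(runif(12, 0.3, 2.5), pool$key)
  w_true <- w_true / sum(w_true * pool$abundance)
  pred <- predict_olefins(pool, w_true)
  cnt <- as.vector(rmultinom(1, 1e5, pred$p))
  obs <- data.frame(chain_length = pred$chain_length,
                    isomer_class = pred$isomer_class, count = cnt)
  fit <- fit_weights(pool, obs)
  expect_lt(max(abs(fit$weights$w - w_true[pool$key]) / w_true[pool$key]),
            0.10)
})

test_that("unachievable observed cells are flagged or dropped", {
  pool <- fatty_pool(c(15, 15), c("anteiso", "iso"), c(0.7, 0.3))
  obs <- data.frame(chain_length = c(29, 25), isomer_class = c("aiai", "scsc"),
                    count = c(100, 5))
  expect_error(fit_weights(pool, obs), "unachievable")
  expect_warning(fit <- fit_weights(pool, obs, allow_slack = TRUE),
                 "dropping")
  expect_equal(fit$unachievable, "25:scsc")
  expect_error(fit_weights(pool, data.frame(chain_length = 29,
                                            isomer_class = "aiai",
                                            count = -1)), "non-negative")
})

test_that("swapping in the host's own weights changes nothing", {
  pool <- fatty_pool(c(15, 14), c("anteiso", "iso"), c(0.8, 0.2))
  w <- c("15:anteiso" = 1.1, "14:iso" = 0.6)
  sw <- swap_experiment(pool, w, w)
  expect_equal(sw$shift$total_variation, 0)
  expect_equal(sw$shift$modal_chain_shift, 0)
})

test_that("a short-iso-specific donor OleA shifts the host profile down", {
  # host pool: anteiso-C15-dominated, minor short iso species, no straight
  host <- fatty_pool(c(15, 15, 17, 13, 14),
                     c("anteiso", "iso", "anteiso", "iso", "iso"),
                     c(0.55, 0.10, 0.15, 0.15, 0.05))
  host_w <- setNames(c(1.3, 0.8, 1.0, 0.3, 0.3), host$key)
  donor_w <- setNames(c(0.15, 0.4, 0.2, 6.0, 1.0), host$key)
  sw <- swap_experiment(host, donor_w, host_w)
  mh <- marginal_distributions(sw$profile_host)
  ms <- marginal_distributions(sw$profile_swapped)
  expect_equal(as.integer(names(which.max(mh$chain))), 29L)
  expect_lt(sw$shift$modal_chain_shift, 0)
  iso_share <- function(m) sum(m$isomer[c("isoiso", "isoai", "isosc")])
  expect_gt(iso_share(ms), iso_share(mh))
  # the host pool has no straight-chain precursors: scsc stays at zero
  expect_equal(unname(ms$isomer[["scsc"]]), 0)
})
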