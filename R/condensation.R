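#' Define a fatty-acyl precursor pool
#'
#' @param chain_length Integer carbons per species (e.g. 14-17).
#' @param branch Branch state per species (`iso`, `anteiso`, `straight`).
#' @param abundance Non-negative fractions; normalized to sum to 1.
#' @return data.frame of class `fatty_pool` with a `key` column
#'   `"<chain>:<branch>"`.
#' @export
fatty_pool <- function(chain_length, branch, abundance) {
  stopifnot(length(chain_length) == length(branch),
            length(branch) == length(abundance),
            all(abundance >= 0), sum(abundance) > 0,
            all(branch %in% BRANCH_TYPES))
  key <- paste0(chain_length, ":", branch)
  if (anyDuplicated(key))
    stop("duplicate (chain_length, branch) species in pool", call. = FALSE)
  out <- data.frame(chain_length = as.integer(chain_length),
                    branch = branch,
                    abundance = abundance / sum(abundance),
                    key = key, stringsAsFactors = FALSE)
  class(out) <- c("fatty_pool", "data.frame")
  out
}

pool_weights_vector <- function(pool, weights) {
  w <- if (is.data.frame(weights))
    setNames(weights$w, paste0(weights$chain_length, ":", weights$branch))
  else weights
  missing <- setdiff(pool$key, names(w))
  if (length(missing))
    stop("weights missing for pool species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  wv <- unname(w[pool$key])
  if (any(wv < 0) || all(wv == 0))
    stop("weights must be non-negative and not all zero", call. = FALSE)
  wv
}

#' Predict the olefin product distribution of head-to-head condensation
#'
#' Two acyl precursors are drawn independently from the pool, each with
#' probability proportional to `abundance * weight`; their head-to-head
#' Claisen condensation followed by the reduction/lactonization/
#' decarboxylation steps yields an olefin of `n_i + n_j - 1` carbons whose
#' two ends keep the precursors' branch states. Unordered pairs mapping to
#' the same (chain length, isomer class) cell are summed.
#'
#' @param pool A [fatty_pool()].
#' @param weights Specificity weights: named numeric vector keyed
#'   `"<chain>:<branch>"` or data.frame with `chain_length`, `branch`, `w`.
#' @return data.frame of class `olefin_distribution` with columns
#'   `chain_length`, `isomer_class`, `p` (summing to 1).
#' @examples
#' pool <- fatty_pool(15, "anteiso", 1)
#' predict_olefins(pool, c("15:anteiso" = 1))  # point mass at (29, aiai)
#' @export
predict_olefins <- function(pool, weights) {
  stopifnot(inherits(pool, "fatty_pool"), nrow(pool) >= 1L)
  wv <- pool_weights_vector(pool, weights)
  u <- wv * pool$abundance
  if (sum(u) <= 0) stop("all effective draw probabilities are zero",
                        call. = FALSE)
  u <- u / sum(u)
  n <- nrow(pool)
  cells <- list()
  for (i in seq_len(n)) for (j in i:n) {
    p <- if (i == j) u[i]^2 else 2 * u[i] * u[j]
    if (p == 0) next
    L <- pool$chain_length[i] + pool$chain_length[j] - 1L
    cls <- classify_isomer(pool$branch[i], pool$branch[j])
    k <- paste0(L, ":", cls)
    cells[[k]] <- (cells[[k]] %||% 0) + p
  }
  ks <- strsplit(names(cells), ":", fixed = TRUE)
  out <- data.frame(chain_length = vapply(ks, function(x) as.integer(x[1]),
                                          integer(1)),
                    isomer_class = vapply(ks, `[[`, character(1), 2),
                    p = unname(unlist(cells)), stringsAsFactors = FALSE)
  out <- out[order(out$chain_length, out$isomer_class), ]
  rownames(out) <- NULL
  class(out) <- c("olefin_distribution", "data.frame")
  out
}

# category structure for a pool: which unordered precursor pairs feed each
# (chain length, isomer class) cell
pair_categories <- function(pool) {
  n <- nrow(pool)
  ii <- integer(); jj <- integer(); cat_key <- character()
  for (i in seq_len(n)) for (j in i:n) {
    ii <- c(ii, i); jj <- c(jj, j)
    cat_key <- c(cat_key,
                 paste0(pool$chain_length[i] + pool$chain_length[j] - 1L, ":",
                        classify_isomer(pool$branch[i], pool$branch[j])))
  }
  list(i = ii, j = jj, key = cat_key)
}

#' Fit OleA specificity weights to an observed olefin profile
#'
#' Maximum-likelihood weights under a multinomial model over
#' [predict_olefins()] cells, fitted by expectation-maximization with
#' latent precursor pairs (each observed olefin is allocated to the
#' precursor pairs compatible with its cell, then per-species draw
#' probabilities are re-estimated). Deterministic from the uniform start;
#' the log-likelihood is non-decreasing across iterations. Weights are
#' reported under the identifiability anchor `sum(w * f) = 1`.
#'
#' @param pool A [fatty_pool()].
#' @param observed data.frame with `chain_length`, `isomer_class` and
#'   `count` (non-negative, positive total).
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   per-species draw probabilities.
#' @param allow_slack If `TRUE`, observed cells unreachable from the pool
#'   are dropped with a warning instead of raising an error.
#' @return List of class `specificity_fit`: `weights` (data.frame
#'   `chain_length`, `branch`, `w`), `u` (draw probabilities),
#'   `loglik` (final), `loglik_trace`, `iterations`, `converged`,
#'   `unachievable` (dropped cells).
#' @export
fit_weights <- function(pool, observed, max_iter = 5000L, tol = 1e-12,
                        allow_slack = FALSE) {
  stopifnot(inherits(pool, "fatty_pool"),
            all(c("chain_length", "isomer_class", "count") %in%
                  names(observed)))
  if (any(observed$count < 0) || sum(observed$count) <= 0)
    stop("observed counts must be non-negative with positive total",
         call. = FALSE)
  pc <- pair_categories(pool)
  obs_key <- paste0(observed$chain_length, ":", observed$isomer_class)
  y <- tapply(observed$count, obs_key, sum)
  bad <- setdiff(names(y)[y > 0], unique(pc$key))
  if (length(bad)) {
    if (!allow_slack)
      stop("observed cells unachievable from the pool: ",
           paste(bad, collapse = ", "), " (set allow_slack = TRUE to drop)",
           call. = FALSE)
    warning("dropping unachievable observed cells: ",
            paste(bad, collapse = ", "))
    y <- y[!names(y) %in% bad]
  }
  y <- y[y > 0]
  N <- sum(y)
  n <- nrow(pool)
  u <- rep(1 / n, n)                       # uniform start
  loglik <- function(u) {
    q <- vapply(names(y), function(k) {
      sel <- pc$key == k
      sum(ifelse(pc$i[sel] == pc$j[sel], u[pc$i[sel]]^2,
                 2 * u[pc$i[sel]] * u[pc$j[sel]]))
    }, numeric(1))
    if (any(q <= 0)) return(-Inf)
    sum(y * log(q))                        # total prob is 1: sum(u) = 1
  }
  trace <- loglik(u)
  it <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    counts <- numeric(n)
    ok <- TRUE
    for (k in names(y)) {
      sel <- which(pc$key == k)
      contrib <- ifelse(pc$i[sel] == pc$j[sel], u[pc$i[sel]]^2,
                        2 * u[pc$i[sel]] * u[pc$j[sel]])
      qk <- sum(contrib)
      if (qk <= 0) { ok <- FALSE; break }
      alloc <- y[[k]] * contrib / qk
      for (t in seq_along(sel)) {
        counts[pc$i[sel[t]]] <- counts[pc$i[sel[t]]] + alloc[t]
        counts[pc$j[sel[t]]] <- counts[pc$j[sel[t]]] + alloc[t]
      }
    }
    if (!ok) break
    u_new <- counts / (2 * N)
    delta <- max(abs(u_new - u))
    u <- u_new
    trace <- c(trace, loglik(u))
    if (delta < tol) { converged <- TRUE; break }
  }
  # anchor sum(w * f) = sum(u) = 1 (u sums to 1 by construction)
  w <- ifelse(pool$abundance > 0, u / pool$abundance, 0)
  structure(list(
    weights = data.frame(chain_length = pool$chain_length,
                         branch = pool$branch, w = w,
                         stringsAsFactors = FALSE),
    u = setNames(u, pool$key),
    loglik = trace[length(trace)], loglik_trace = unname(trace),
    iterations = it, converged = converged,
    unachievable = if (length(bad)) bad else character()),
    class = "specificity_fit")
}

#' @export
print.specificity_fit <- function(x, ...) {
  cat(sprintf("<specificity_fit> logLik %.3f after %d EM iterations%s\n",
              x$loglik, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' In-silico oleA swap experiment
#'
#' Predicts the olefin profile of the same host precursor pool under the
#' host's own OleA specificity and under a donor's, mirroring the exchange
#' of the native oleA gene for a heterologous one. The host pool limits
#' what any OleA can make: isomer classes requiring precursor branch
#' states absent from the pool keep zero share.
#'
#' @param host_pool The host's [fatty_pool()].
#' @param donor_weights,host_weights Specificity weights covering the host
#'   pool.
#' @return List of class `swap_experiment`: `profile_host`,
#'   `profile_swapped` (olefin distributions) and `shift`
#'   (see [compare_profiles()]; `modal_chain_shift` is swapped minus host).
#' @export
swap_experiment <- function(host_pool, donor_weights, host_weights) {
  ph <- predict_olefins(host_pool, host_weights)
  pd <- predict_olefins(host_pool, donor_weights)
  structure(list(profile_host = ph, profile_swapped = pd,
                 shift = compare_profiles(ph, pd)),
            class = "swap_experiment")
}

#' @export
print.swap_experiment <- function(x, ...) {
  cat(sprintf(
    "<swap_experiment> modal chain shift %+d, total variation %.3f\n",
    x$shift$modal_chain_shift, x$shift$total_variation))
  invisible(x)
}
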