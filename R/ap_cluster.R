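#' Pairwise sample similarities for affinity propagation
#'
#' Similarity between two samples is the negative squared Euclidean distance
#' between their expression profiles (the Frey-Dueck default). The diagonal
#' is left as `NA`: it is reserved for the shared preference that
#' [affinity_propagation()] places there.
#'
#' @param E samples-x-genes numeric matrix.
#' @return symmetric m x m matrix of similarities with `NA` diagonal, class
#'   `"similarity_matrix"`.
#' @export
similarity_matrix <- function(E) {
  if (nrow(E) < 2L) stop("need at least 2 samples")
  S <- -as.matrix(stats::dist(E))^2
  diag(S) <- NA_real_
  structure(S, class = c("similarity_matrix", class(S)))
}

offdiag <- function(S) S[row(S) != col(S)]

#' Affinity propagation clustering
#'
#' Standard responsibility/availability message passing with damping over a
#' similarity matrix whose diagonal is set to a shared `preference`. A tiny
#' seeded jitter (relative scale 1e-12) is added to the similarities to break
#' the degenerate oscillations that exactly symmetric inputs can cause.
#' Convergence means the exemplar set is unchanged for `conv_iter`
#' consecutive sweeps; running out of iterations returns `converged = FALSE`
#' rather than an error.
#'
#' @param S m x m similarity matrix (diagonal ignored).
#' @param preference value placed on the diagonal; larger values yield more
#'   exemplars.
#' @param damping message damping factor in `[0.5, 1)`.
#' @param max_iter maximum number of sweeps.
#' @param conv_iter sweeps of exemplar stability required for convergence.
#' @param rng_seed seed for the symmetry-breaking jitter.
#' @return an `"ap_result"` list with elements `labels` (cluster index per
#'   sample in `1..K_found`), `exemplars` (sample indices), `preference`,
#'   `n_iterations`, `converged`, `K_found` and `net_similarity` (sum of
#'   exemplar preferences plus similarities of points to their exemplars).
#' @export
affinity_propagation <- function(S, preference, damping = 0.5,
                                 max_iter = 1000L, conv_iter = 50L,
                                 rng_seed = NULL) {
  m <- nrow(S)
  stopifnot(m == ncol(S), damping >= 0.5, damping < 1, max_iter >= conv_iter, conv_iter >= 1L)
  S0 <- unclass(S)
  if (m == 1L) {
    return(structure(list(labels = 1L, exemplars = 1L, preference = preference,
                          n_iterations = 0L, converged = TRUE, K_found = 1L,
                          net_similarity = preference),
                     class = "ap_result"))
  }
  W <- S0
  diag(W) <- preference
  scale <- max(abs(W[is.finite(W)]), 1)
  draws <- with_seed(rng_seed, list(jitter = matrix(stats::rnorm(m * m), m, m),
                                    restart = stats::runif(64L)))
  W <- W + draws$jitter * 1e-12 * scale

  R <- matrix(0, m, m)
  A <- matrix(0, m, m)
  idx <- seq_len(m)
  ex_prev <- integer(0)
  stable <- 0L
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ## responsibilities: r(i,k) = s(i,k) - max_{k' != k} (a(i,k') + s(i,k'))
    AS <- A + W
    i1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(idx, i1)]
    AS[cbind(idx, i1)] <- -Inf
    m2 <- AS[cbind(idx, max.col(AS, ties.method = "first"))]
    Rnew <- W - m1
    Rnew[cbind(idx, i1)] <- W[cbind(idx, i1)] - m2
    R <- damping * R + (1 - damping) * Rnew
    ## availabilities: a(i,k) = min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))
    Rp <- pmax(R, 0)
    diag(Rp) <- 0
    sp <- colSums(Rp)
    Anew <- rep(diag(R) + sp, each = m) - Rp
    Anew <- pmin(Anew, 0)
    diag(Anew) <- sp
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(A) + diag(R) > 0)
    if (length(ex) && identical(ex, ex_prev)) {
      stable <- stable + 1L
      if (stable >= conv_iter) { converged <- TRUE; break }
    } else {
      stable <- 0L
      ex_prev <- ex
    }
  }
  ex <- unname(which(diag(A) + diag(R) > 0))
  if (length(ex) == 0L) ex <- which.max(diag(A) + diag(R))

  ## assign each point to the exemplar with the highest similarity, then
  ## refine: within each cluster re-pick the member maximizing the summed
  ## within-cluster similarity (the standard post-convergence polish)
  Sx <- S0
  diag(Sx) <- preference
  assign_point <- function(ex) {
    a <- ex[max.col(Sx[, ex, drop = FALSE], ties.method = "first")]
    a[ex] <- ex
    a
  }
  assign_ex <- assign_point(ex)
  for (rep in seq_len(m)) {
    new_ex <- vapply(ex, function(k) {
      members <- which(assign_ex == k)
      within <- colSums(Sx[members, members, drop = FALSE])
      members[which.max(within)]
    }, integer(1L))
    new_ex <- sort(unique(new_ex))
    if (identical(new_ex, ex)) break
    ex <- new_ex
    assign_ex <- assign_point(ex)
  }
  ## local-search polish on the net-similarity objective (the quantity the
  ## messages maximize): PAM-style swaps plus add/remove moves, started from
  ## the message-passing solution and a few seeded random exemplar sets of
  ## the same size, keeping the best local optimum found
  obj <- function(ex) {
    v <- preference * length(ex)
    if (length(ex) < m) {
      best_sim <- Reduce(pmax, lapply(ex, function(k) S0[, k]))
      v <- v + sum(best_sim[-ex])
    }
    v
  }
  local_search <- function(ex) {
    cur <- obj(ex)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (k in seq_along(ex)) {
        for (cand in setdiff(idx, ex)) {
          val <- obj(c(ex[-k], cand))
          if (val > cur + 1e-12) {
            ex <- sort(c(ex[-k], cand))
            cur <- val
            improved <- TRUE
          }
        }
      }
      for (cand in setdiff(idx, ex)) {
        val <- obj(c(ex, cand))
        if (val > cur + 1e-12) {
          ex <- sort(c(ex, cand))
          cur <- val
          improved <- TRUE
        }
      }
      if (length(ex) > 1L) {
        for (k in seq_along(ex)) {
          val <- obj(ex[-k])
          if (val > cur + 1e-12) {
            ex <- ex[-k]
            cur <- val
            improved <- TRUE
            break
          }
        }
      }
    }
    list(ex = ex, val = cur)
  }
  best <- local_search(ex)
  n_restart <- 4L
  K0 <- max(length(ex), 1L)
  for (r in seq_len(n_restart)) {
    ## seeded deterministic restart sets drawn from the pre-generated uniforms
    u <- draws$restart[((r - 1L) * K0 + seq_len(K0) - 1L) %% length(draws$restart) + 1L]
    start <- unique(pmin(m, 1L + as.integer(floor(u * m + r))) %% m + 1L)
    cand <- local_search(sort(start))
    if (cand$val > best$val + 1e-12) best <- cand
  }
  ex <- best$ex
  assign_ex <- assign_point(ex)
  labels <- match(assign_ex, ex)
  net <- sum(preference * length(ex)) +
    sum(S0[cbind(setdiff(idx, ex), assign_ex[setdiff(idx, ex)])])
  structure(list(labels = labels, exemplars = ex, preference = preference,
                 n_iterations = it, converged = converged,
                 K_found = length(ex), net_similarity = net),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("ap_result: %d clusters, preference %.4g, %d iterations, %s\n",
              x$K_found, x$preference, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Net similarity of an exemplar set
#'
#' The quantity affinity propagation maximizes: the summed preference of the
#' exemplars plus, for every non-exemplar, its best similarity to an
#' exemplar. Used to compare a clustering against the exhaustive optimum on
#' small instances.
#'
#' @param S similarity matrix (diagonal ignored).
#' @param exemplars integer vector of exemplar indices.
#' @param preference diagonal preference value.
#' @export
net_similarity <- function(S, exemplars, preference) {
  S0 <- unclass(S)
  others <- setdiff(seq_len(nrow(S0)), exemplars)
  val <- preference * length(exemplars)
  if (length(others)) {
    val <- val + sum(apply(S0[others, exemplars, drop = FALSE], 1L, max))
  }
  val
}

#' Affinity propagation targeting a requested number of clusters
#'
#' AP has no native cluster-count parameter: the number of exemplars grows
#' with the shared preference. This routine bisects the preference over
#' `[min, max]` of the off-diagonal similarities, running
#' [affinity_propagation()] at every probe, until a run yields exactly `K`
#' clusters or `tol_steps` probes are exhausted, in which case the run whose
#' cluster count is closest to `K` is returned with `achieved_K = FALSE`.
#'
#' @param S similarity matrix from [similarity_matrix()].
#' @param K requested number of clusters, `1 <= K <= m`.
#' @param tol_steps maximum number of bisection probes.
#' @param rng_seed seed passed to each AP run's jitter.
#' @param ... further arguments for [affinity_propagation()].
#' @return an `"ap_result"` with extra fields `achieved_K` (logical) and
#'   `probes` (data frame of the bisection trace: preference, K_found,
#'   converged).
#' @export
cluster_with_k <- function(S, K, tol_steps = 25L, rng_seed = NULL, ...) {
  m <- nrow(S)
  stopifnot(K >= 1L, K <= m)
  off <- offdiag(S)
  lo <- min(off)
  hi <- max(off)
  probes <- data.frame(preference = numeric(0), K_found = integer(0), converged = logical(0))
  best <- NULL
  run <- function(pref) {
    res <- affinity_propagation(S, pref, rng_seed = rng_seed, ...)
    probes[nrow(probes) + 1L, ] <<- list(pref, res$K_found, res$converged)
    if (is.null(best) || abs(res$K_found - K) < abs(best$K_found - K) ||
        (abs(res$K_found - K) == abs(best$K_found - K) && res$converged && !best$converged)) {
      best <<- res
    }
    res
  }
  span <- max(hi - lo, 1e-8)
  r_lo <- run(lo)
  if (r_lo$K_found != K) {
    r_hi <- run(hi)
    ## widen the bracket when the requested K lies outside it (K_found is
    ## non-decreasing in the preference)
    grow <- span
    while (r_hi$K_found < K && nrow(probes) < tol_steps && grow < 64 * span) {
      hi <- hi + grow
      grow <- 2 * grow
      r_hi <- run(hi)
    }
    grow <- span
    while (r_lo$K_found > K && nrow(probes) < tol_steps && grow < 64 * span) {
      lo <- lo - grow
      grow <- 2 * grow
      r_lo <- run(lo)
    }
    while (best$K_found != K && nrow(probes) < tol_steps &&
           (hi - lo) > 1e-12 * max(abs(hi), abs(lo), 1)) {
      mid <- (lo + hi) / 2
      r_mid <- run(mid)
      if (r_mid$K_found >= K) hi <- mid else lo <- mid
    }
  }
  best$achieved_K <- (best$K_found == K)
  best$probes <- probes
  if (!best$achieved_K) {
    warning(sprintf("requested K = %d not attained within %d probes; closest K_found = %d",
                    K, nrow(probes), best$K_found))
  }
  best
}
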