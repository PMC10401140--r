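# A fly is a list: position = list(X = numeric(M), Y = numeric(M)),
# smell = numeric(M), mask = integer(M), obj = ObjectivePair or NULL.

new_fly <- function(X, Y, eps_smell) {
  s <- smell_concentration(X, Y, eps_smell)
  list(position = list(X = X, Y = Y), smell = s,
       mask = pruning_code(s), obj = NULL)
}

#' Flavor concentration of a fly position
#'
#' `S_m = 1 / (sqrt(X_m^2 + Y_m^2) + eps)`, the reciprocal distance of
#' each coordinate pair to the origin; `eps` guards the pole at the
#' origin so the concentration stays finite.
#'
#' @param X,Y numeric coordinate vectors of equal length M.
#' @param eps_smell small positive guard (default `1e-6`).
#' @return numeric vector of M concentrations.
#' @export
smell_concentration <- function(X, Y, eps_smell = 1e-6) {
  if (any(!is.finite(X)) || any(!is.finite(Y))) stopf("non-finite fly position")
  1 / (sqrt(X^2 + Y^2) + eps_smell)
}

#' Discretize smells into a pruning mask
#'
#' Bit m is 1 iff `S_m > 0.5` (the m-th base partition is kept); exactly
#' 0.5 maps to 0. An all-zero mask is repaired to all ones so at least
#' one base partition always survives.
#'
#' @param smells numeric vector of flavor concentrations.
#' @return integer 0/1 vector of the same length.
#' @export
pruning_code <- function(smells) {
  if (any(!is.finite(smells))) stopf("non-finite smell values")
  bits <- as.integer(smells > 0.5)
  if (!any(bits == 1L)) bits[] <- 1L
  bits
}

#' Exploration-exploitation balance factor
#'
#' `omega = alpha^((FEs - 1) / MaxFEs)`: equal to 1 at the first
#' iteration and growing monotonically toward `alpha` as the iteration
#' counter approaches its maximum.
#'
#' @param FEs current iteration, `1 <= FEs`.
#' @param MaxFEs maximum number of iterations.
#' @param alpha positive rate factor (default 13).
#' @return positive scalar.
#' @export
balance_factor <- function(FEs, MaxFEs, alpha = 13) {
  if (alpha <= 0) stopf("alpha must be positive")
  if (FEs < 1 || MaxFEs < 1) stopf("iteration counters must be >= 1")
  exp((FEs - 1) / MaxFEs * log(alpha))
}

#' Initialize the multi-subswarm fly population
#'
#' `D` subswarms of `G` flies each. Every coordinate is drawn as
#' `X_m = X_min + rand(-1, 1) * (X_max - X_min)` (and likewise for Y),
#' clamped to the bounds. The first fly of every subswarm is placed at
#' the origin, whose smell exceeds the 0.5 threshold in every component,
#' so its mask selects the full ensemble.
#'
#' @param D number of subswarms (one per latent space).
#' @param G flies per subswarm.
#' @param M base partitions per subspace (mask length).
#' @param bounds numeric `c(lo, hi)` for both X and Y (default `c(0, 2)`).
#' @param seed integer seed.
#' @param eps_smell pole guard for [smell_concentration()].
#' @return list of `D` subswarms; each is a list with `flies` (list of
#'   G flies), `subspace_index`, and `best` (NULL until evaluated).
#' @export
init_population <- function(D, G, M, bounds = c(0, 2), seed = 1L,
                            eps_smell = 1e-6) {
  if (D < 1 || G < 1) stopf("D and G must be >= 1")
  lo <- bounds[1]; hi <- bounds[2]
  with_seed(seed, {
    lapply(seq_len(D), function(d) {
      flies <- lapply(seq_len(G), function(g) {
        if (g == 1L) {
          X <- rep(0, M); Y <- rep(0, M)
        } else {
          X <- pmin(pmax(lo + runif(M, -1, 1) * (hi - lo), lo), hi)
          Y <- pmin(pmax(lo + runif(M, -1, 1) * (hi - lo), lo), hi)
        }
        new_fly(X, Y, eps_smell)
      })
      list(flies = flies, subspace_index = d, best = NULL)
    })
  })
}

#' Olfactory step from the subswarm best
#'
#' Generates an offspring by perturbing the best fly's coordinates:
#' `X_new = X_best + omega * rand(-1, 1)` per component (Y likewise),
#' clamped to the bounds; smell and mask are recomputed.
#'
#' @param best a fly (the subswarm's current best).
#' @param omega step scale from [balance_factor()].
#' @param bounds numeric `c(lo, hi)`.
#' @param seed integer seed for the perturbation draws.
#' @param eps_smell pole guard.
#' @return a new unevaluated fly.
#' @export
olfactory_step <- function(best, omega, bounds = c(0, 2), seed = 1L,
                           eps_smell = 1e-6) {
  M <- length(best$position$X)
  lo <- bounds[1]; hi <- bounds[2]
  with_seed(seed, {
    X <- pmin(pmax(best$position$X + omega * runif(M, -1, 1), lo), hi)
    Y <- pmin(pmax(best$position$Y + omega * runif(M, -1, 1), lo), hi)
    new_fly(X, Y, eps_smell)
  })
}

# Deterministic best-candidate comparison among non-dominated pairs:
# smaller dev, then smaller cp, then lower index wins.
better_tiebreak <- function(a, b) {
  if (a$dev != b$dev) return(a$dev < b$dev)
  if (a$cp != b$cp) return(a$cp < b$cp)
  FALSE
}

#' Vision-phase greedy update of a subswarm
#'
#' Each fly is replaced by its evaluated offspring iff the offspring
#' dominates it; the subswarm best is replaced iff a fly dominates the
#' current best. Among mutually non-dominated candidates for the best
#' slot, ties break by smaller Dev, then smaller Cp, then lower fly
#' index, keeping the update deterministic.
#'
#' @param sub a subswarm (list with `flies`, `best`).
#' @param offspring list of evaluated flies, parallel to `sub$flies`.
#' @return the updated subswarm.
#' @export
vision_update <- function(sub, offspring) {
  for (i in seq_along(sub$flies)) {
    par <- sub$flies[[i]]
    off <- offspring[[i]]
    if (is.null(par$obj) || dominates(off$obj, par$obj)) {
      sub$flies[[i]] <- off
    }
  }
  if (is.null(sub$best)) {
    # first evaluation: seed the best slot with fly 1 (the full-ensemble
    # fly), then let dominance take over below
    sub$best <- sub$flies[[1]]
  }
  # the best is replaced iff some fly dominates it; among several
  # dominating (possibly mutually non-dominated) challengers, ties break
  # by smaller dev, then smaller cp, then lower fly index
  challengers <- Filter(function(f) dominates(f$obj, sub$best$obj), sub$flies)
  if (length(challengers)) {
    pick <- challengers[[1]]
    for (f in challengers[-1]) {
      if (dominates(f$obj, pick$obj) ||
          (!dominates(pick$obj, f$obj) && better_tiebreak(f$obj, pick$obj)))
        pick <- f
    }
    sub$best <- pick
  }
  sub
}

#' Ring information exchange between subswarms
#'
#' The best fly of subswarm `i` migrates to subswarm `i + 1` (the last
#' wraps to the first), carrying its coordinates and mask; its
#' objectives must be re-evaluated against the destination subspace. The
#' migrant replaces the first fly of the destination subswarm; the
#' destination's own best is untouched until the migrant proves itself
#' under dominance.
#'
#' @param subswarms list of subswarms.
#' @return list of subswarms after rotation (single subswarm: no-op).
#' @export
exchange_information <- function(subswarms) {
  D <- length(subswarms)
  if (D < 2) return(subswarms)
  migrants <- lapply(subswarms, function(s) s$best)
  for (i in seq_len(D)) {
    j <- if (i == D) 1L else i + 1L
    mig <- migrants[[i]]
    if (is.null(mig)) next
    mig$obj <- NULL                       # objectives invalid in new subspace
    subswarms[[j]]$flies[[1]] <- mig
  }
  subswarms
}

#' Dynamic ensemble pruning by bi-objective fruit-fly optimization
#'
#' Searches, per latent space, for the subset of base partitions whose
#' locally weighted consensus minimizes the signed (Dev, Cp) pair.
#' `D` subswarms (one per latent space) alternate an olfactory
#' perturbation phase around each subswarm's best fly — with step scale
#' `omega` growing from 1 to `alpha` over the iterations — a vision
#' phase replacing flies and bests under Pareto dominance, and a ring
#' exchange of best flies between subswarms.
#'
#' @param ensemble a [cluster_ensemble()] grouped by subspace.
#' @param Z `LatentSpaces` or list of coordinate matrices, one per
#'   subspace.
#' @param k number of consensus clusters used in mask evaluation.
#' @param direction `+1` or `-1` (see [decide_direction()]).
#' @param max_fes iterations (default 20).
#' @param alpha balance rate factor (default 13).
#' @param n_flies total population size FD (default 9); subswarm sizes
#'   `G = FD / D`, differing by at most one when `D` does not divide FD.
#' @param bounds coordinate bounds (default `c(0, 2)`).
#' @param theta ECI adjustment factor for consensus evaluation.
#' @param eps_smell pole guard.
#' @param seed master seed.
#' @return list of class `PruningResult`: `selected` (list of per-
#'   subspace masks), `pruned_ensemble`, `archive` (non-dominated
#'   `(subspace, mask, dev, cp)` rows), `trace` (data.frame of per-
#'   iteration best objectives per subswarm), `direction`.
#' @export
prune_ensemble <- function(ensemble, Z, k, direction = 1L, max_fes = 20L,
                           alpha = 13, n_flies = 9L, bounds = c(0, 2),
                           theta = 0.4, eps_smell = 1e-6, seed = 1L) {
  spaces <- if (inherits(Z, "LatentSpaces")) Z$spaces else Z
  D <- length(spaces)
  subs_idx <- vapply(ensemble$partitions, `[[`, integer(1), "subspace_index")
  groups <- lapply(seq_len(D), function(d) ensemble$partitions[subs_idx == d])
  M_per <- vapply(groups, length, integer(1))
  if (any(M_per == 0)) stopf("every subspace needs at least one partition")
  dmats <- lapply(spaces, dist_matrix)

  # memoized mask evaluation per subspace
  caches <- lapply(seq_len(D), function(d) new.env(parent = emptyenv()))
  eval_fly <- function(fly, d) {
    key <- paste(fly$mask, collapse = "")
    cache <- caches[[d]]
    if (is.null(cache[[key]])) {
      cache[[key]] <- evaluate_mask(fly$mask, groups[[d]], spaces[[d]], k,
                                    direction, theta, dmat = dmats[[d]])
    }
    fly$obj <- cache[[key]]
    fly
  }

  # subswarm sizes G = FD / D, spread remainder over leading subswarms
  G <- rep(n_flies %/% D, D) + (seq_len(D) <= n_flies %% D)
  if (any(G == 0)) stopf("population %d too small for %d subswarms", n_flies, D)
  subswarms <- lapply(seq_len(D), function(d) {
    init_population(1, G[d], M_per[d], bounds,
                    seed = derive_seed(seed, 101L, d), eps_smell)[[1]]
  })
  for (d in seq_len(D)) {
    subswarms[[d]]$subspace_index <- d
    subswarms[[d]]$flies <- lapply(subswarms[[d]]$flies, eval_fly, d = d)
    subswarms[[d]] <- vision_update(subswarms[[d]],
                                    subswarms[[d]]$flies)
  }

  trace <- list()
  for (it in seq_len(max_fes)) {
    omega <- balance_factor(it, max_fes, alpha)
    for (d in seq_len(D)) {
      sub <- subswarms[[d]]
      offspring <- lapply(seq_along(sub$flies), function(g) {
        f <- olfactory_step(sub$best, omega, bounds,
                            seed = derive_seed(seed, it, d, g), eps_smell)
        eval_fly(f, d)
      })
      # re-evaluate any migrant whose objectives were invalidated
      for (g in seq_along(sub$flies)) {
        if (is.null(sub$flies[[g]]$obj))
          sub$flies[[g]] <- eval_fly(sub$flies[[g]], d)
      }
      subswarms[[d]] <- vision_update(sub, offspring)
      b <- subswarms[[d]]$best$obj
      trace[[length(trace) + 1L]] <-
        data.frame(iteration = it, subswarm = d, dev = b$dev, cp = b$cp)
    }
    subswarms <- exchange_information(subswarms)
  }
  # migrants from the final exchange may be unevaluated
  for (d in seq_len(D)) {
    for (g in seq_along(subswarms[[d]]$flies)) {
      if (is.null(subswarms[[d]]$flies[[g]]$obj))
        subswarms[[d]]$flies[[g]] <- eval_fly(subswarms[[d]]$flies[[g]], d)
    }
  }

  selected <- lapply(subswarms, function(s) s$best$mask)
  keep <- unlist(lapply(seq_len(D), function(d) {
    idx_d <- which(subs_idx == d)
    idx_d[selected[[d]] == 1L]
  }))
  pruned <- subset_ensemble(ensemble, sort(keep))

  bests <- lapply(seq_len(D), function(d) {
    list(subspace = d, mask = selected[[d]],
         obj = subswarms[[d]]$best$obj)
  })
  nondom <- vapply(seq_along(bests), function(i) {
    !any(vapply(seq_along(bests), function(j) {
      i != j && dominates(bests[[j]]$obj, bests[[i]]$obj)
    }, logical(1)))
  }, logical(1))
  archive <- lapply(bests[nondom], function(b) {
    list(subspace = b$subspace, mask = b$mask, dev = b$obj$dev, cp = b$obj$cp)
  })

  structure(list(selected = selected, pruned_ensemble = pruned,
                 archive = archive,
                 trace = do.call(rbind, trace), direction = direction),
            class = "PruningResult")
}

#' @export
print.PruningResult <- function(x, ...) {
  kept <- sum(unlist(x$selected))
  tot <- sum(lengths(x$selected))
  cat(sprintf("PruningResult: kept %d / %d base partitions (direction %+d)\n",
              kept, tot, x$direction))
  invisible(x)
}
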