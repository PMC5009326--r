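#' Genetic-algorithm control settings
#'
#' Small-population defaults suited to desk-scale parameter search; all are
#' overridable.
#'
#' @param pop_size population size.
#' @param n_generations number of generations.
#' @param tournament_size selection tournament size.
#' @param p_crossover per-pair uniform crossover probability.
#' @param p_mutation per-gene mutation probability.
#' @param elitism number of top individuals copied unchanged.
#' @return A list of class `ga_control`.
#' @export
ga_control <- function(pop_size = 40L, n_generations = 25L,
                       tournament_size = 3L, p_crossover = 0.7,
                       p_mutation = 0.1, elitism = 1L) {
  structure(list(pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 tournament_size = as.integer(tournament_size),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = as.integer(elitism)),
            class = "ga_control")
}

#' Genetic-algorithm tuning of the classifier parameters
#'
#' Searches a discrete space over signature lengths and filter stringency for
#' the parameter set maximizing penalized cross-validated accuracy:
#' `fitness = mean CV accuracy - lambda_len * (n1 + n2) / P`, where `P` is the
#' number of probes retained at the candidate's stringency on the full
#' dataset. The parsimony penalty prefers the shortest signature among
#' equally accurate ones. Individuals are index vectors into the supplied
#' candidate values, evolved by tournament selection, uniform crossover,
#' per-gene mutation and elitism; fitness values are cached so each distinct
#' parameter set is cross-validated once. Runs are deterministic for a fixed
#' seed.
#'
#' @param ds an [expression_dataset()].
#' @param space named list with numeric vectors `n1`, `n2` and `alpha_filter`
#'   of candidate values (a one-point space is allowed).
#' @param control a [ga_control()].
#' @param n_folds CV folds used inside the fitness.
#' @param lambda_len parsimony penalty weight; default 0.01.
#' @param weight_exponent distance weighting exponent, held fixed.
#' @param seed integer seed governing fold assignment and GA randomness.
#' @return List with `best_params` ([classifier_params()]), `best_fitness`,
#'   `cv` (the best individual's CV report), and `log` (per-generation best
#'   and mean fitness).
#' @export
ga_optimize <- function(ds, space, control = ga_control(), n_folds = 10L,
                        lambda_len = 0.01, weight_exponent = 1, seed = 1L) {
  stopifnot(inherits(ds, "expression_dataset"))
  dims <- c("n1", "n2", "alpha_filter")
  if (!all(dims %in% names(space)) ||
      any(vapply(space[dims], length, integer(1)) < 1L))
    stop("space must supply nonempty candidate vectors n1, n2, alpha_filter",
         call. = FALSE)
  space <- space[dims]
  sizes <- vapply(space, length, integer(1))

  cache <- new.env(parent = emptyenv())
  retained_count <- new.env(parent = emptyenv())
  evaluate <- function(idx) {
    key <- paste(idx, collapse = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n1 <- space$n1[idx[1L]]; n2 <- space$n2[idx[2L]]
    alpha <- space$alpha_filter[idx[3L]]
    akey <- format(alpha, digits = 15)
    if (is.null(retained_count[[akey]]))
      retained_count[[akey]] <-
        length(wilcoxon_filter(ds, alpha)$retained)
    P <- max(retained_count[[akey]], 1L)
    params <- classifier_params(n1, n2, alpha, weight_exponent)
    cv <- suppressWarnings(cross_validate(ds, params, n_folds, seed = seed))
    fit <- cv$mean_accuracy - lambda_len * (n1 + n2) / P
    cache[[key]] <- list(fitness = fit, cv = cv, params = params)
    cache[[key]]
  }

  withr_seed(seed, {
    pop <- lapply(seq_len(control$pop_size), function(i)
      vapply(sizes, function(s) sample.int(s, 1L), integer(1)))
    log <- data.frame(generation = integer(), best = numeric(),
                      mean = numeric())
    best <- NULL

    for (gen in seq_len(control$n_generations)) {
      evals <- lapply(pop, evaluate)
      fits <- vapply(evals, `[[`, numeric(1), "fitness")
      ord <- order(-fits)
      if (is.null(best) || fits[ord[1L]] > best$fitness)
        best <- evals[[ord[1L]]]
      log <- rbind(log, data.frame(generation = gen, best = max(fits),
                                   mean = mean(fits)))
      if (gen == control$n_generations) break

      tourn <- function() {
        cand <- sample.int(control$pop_size, control$tournament_size,
                           replace = TRUE)
        pop[[cand[which.max(fits[cand])]]]
      }
      nxt <- pop[ord[seq_len(min(control$elitism, control$pop_size))]]
      while (length(nxt) < control$pop_size) {
        a <- tourn(); b <- tourn()
        if (stats::runif(1) < control$p_crossover) {
          mask <- stats::runif(3L) < 0.5
          child <- ifelse(mask, a, b)
        } else child <- a
        mut <- stats::runif(3L) < control$p_mutation
        for (k in which(mut)) child[k] <- sample.int(sizes[k], 1L)
        nxt[[length(nxt) + 1L]] <- as.integer(child)
      }
      pop <- nxt
    }
    list(best_params = best$params, best_fitness = best$fitness,
         cv = best$cv, log = log)
  })
}

#' Exhaustive grid search over classifier parameters
#'
#' Evaluates the same penalized fitness as [ga_optimize()] at every point of
#' the candidate grid. Intended for small spaces and as a reference for the
#' GA on them.
#'
#' @inheritParams ga_optimize
#' @return List with `best_params`, `best_fitness` and the full `grid` of
#'   fitness values.
#' @export
grid_optimize <- function(ds, space, n_folds = 10L, lambda_len = 0.01,
                          weight_exponent = 1, seed = 1L) {
  grid <- expand.grid(n1 = space$n1, n2 = space$n2,
                      alpha_filter = space$alpha_filter)
  grid$fitness <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    params <- classifier_params(grid$n1[i], grid$n2[i], grid$alpha_filter[i],
                                weight_exponent)
    P <- max(length(wilcoxon_filter(ds, params$alpha_filter)$retained), 1L)
    cv <- suppressWarnings(cross_validate(ds, params, n_folds, seed = seed))
    grid$fitness[i] <- cv$mean_accuracy -
      lambda_len * (params$n1 + params$n2) / P
    if (is.null(best) || grid$fitness[i] > best$fitness)
      best <- list(params = params, fitness = grid$fitness[i], cv = cv)
  }
  list(best_params = best$params, best_fitness = best$fitness,
       cv = best$cv, grid = grid)
}
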