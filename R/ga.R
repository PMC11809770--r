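#' Length penalty for candidate item subsets
#'
#' The fitness of a candidate subset is its Cronbach's alpha multiplied by
#' a penalty in `[0, 1]` that discourages long forms:
#' \deqn{\mathrm{penalty}(k) = 1 - (k/K)^{\mathrm{order}}}
#' where `k` is the subset size and `K` the full pool size. The polynomial
#' order (default 3) tunes how aggressively length is penalised — higher
#' orders tolerate longer forms. `variant = "raw"` evaluates the literal
#' difference form `1 - (k - K)^order` (clamped to `[0, 1]`) for audit; it
#' is not a usable penalty and exists only so the ratio interpretation can
#' be compared against it.
#'
#' @param k Subset size(s), `0 <= k <= K`.
#' @param K Full pool size.
#' @param order Polynomial order, one of 2, 3, 4, 5.
#' @param variant `"ratio"` (default) or `"raw"`.
#' @return Penalty value(s) in `[0, 1]`.
#' @examples
#' ga_penalty(15, 46)  # ~0.965: a 15-of-46 subset keeps most of its alpha
#' @export
ga_penalty <- function(k, K, order = 3, variant = c("ratio", "raw")) {
  variant <- match.arg(variant)
  if (K <= 0) abort("Pool size K must be positive.")
  if (any(k < 0 | k > K)) abort("Subset size k must satisfy 0 <= k <= K.")
  if (!order %in% 2:5) abort("Penalty order must be one of 2, 3, 4, 5.")
  p <- if (variant == "ratio") 1 - (k / K)^order else 1 - (k - K)^order
  pmin(pmax(p, 0), 1)
}

#' Genetic-algorithm parameters
#'
#' @param population_size Number of candidate subsets per generation.
#' @param cull_fraction Fraction of the worst members removed each
#'   generation before breeding, in `(0, 1)`.
#' @param mutation_rate Per-bit flip probability; default `1 / max_items`
#'   (resolved when the pool size is known).
#' @param crossover Crossover scheme; `"uniform"` is the only scheme
#'   currently implemented.
#' @param stagnation_limit Stop after this many generations without
#'   improvement of the best fitness (default 100).
#' @param max_generations Hard safety cap on generations.
#' @param penalty_order Polynomial order of the length penalty (2-5).
#' @param penalty_variant Passed to [ga_penalty()].
#' @param max_items Pool size `K` used by the penalty; default the number
#'   of items in the data supplied to [ga_evolve()].
#' @param elitism Number of best members copied unchanged each generation.
#' @param seed Integer seed for the run.
#' @return A list of class `ga_params`.
#' @export
ga_params <- function(population_size = 200,
                      cull_fraction = 0.5,
                      mutation_rate = NULL,
                      crossover = "uniform",
                      stagnation_limit = 100,
                      max_generations = 2000,
                      penalty_order = 3,
                      penalty_variant = "ratio",
                      max_items = NULL,
                      elitism = 1,
                      seed = 1L) {
  if (cull_fraction <= 0 || cull_fraction >= 1) {
    abort("cull_fraction must lie strictly between 0 and 1.")
  }
  if (!is.null(mutation_rate) && (mutation_rate < 0 || mutation_rate > 1)) {
    abort("mutation_rate must lie in [0, 1].")
  }
  if (stagnation_limit < 1) abort("stagnation_limit must be >= 1.")
  if (!penalty_order %in% 2:5) abort("penalty_order must be one of 2, 3, 4, 5.")
  if (!identical(crossover, "uniform")) abort("Only uniform crossover is implemented.")
  structure(
    list(population_size = as.integer(population_size),
         cull_fraction = cull_fraction,
         mutation_rate = mutation_rate,
         crossover = crossover,
         stagnation_limit = as.integer(stagnation_limit),
         max_generations = as.integer(max_generations),
         penalty_order = penalty_order,
         penalty_variant = penalty_variant,
         max_items = max_items,
         elitism = as.integer(elitism),
         seed = as.integer(seed)),
    class = "ga_params"
  )
}

#' Fitness of one item subset
#'
#' Fitness is Cronbach's alpha of the subset multiplied by the length
#' penalty. Subsets must contain every core item and at least two items.
#'
#' @param data Complete data frame of responses over the full item pool.
#' @param items Character vector: the candidate subset.
#' @param core Character vector of locked-in core item ids (may be empty).
#' @param params A [ga_params()]; only the penalty settings are used.
#' @return A one-row tibble: `n_items`, `alpha`, `penalty`, `fitness`, and
#'   a list-column `items`.
#' @export
ga_fitness <- function(data, items, core = character(), params = ga_params()) {
  m <- response_matrix(data)
  if (!all(core %in% items)) {
    abort(paste0("Candidate subset is missing core item(s): ",
                 paste(setdiff(core, items), collapse = ", ")))
  }
  if (length(items) < 2L) abort("Fitness needs at least 2 items.")
  K <- params$max_items %||% ncol(m)
  C <- cov(m[, items, drop = FALSE])
  a <- alpha_from_cov(C)
  p <- ga_penalty(length(items), K, params$penalty_order, params$penalty_variant)
  tibble(n_items = length(items), alpha = a, penalty = p, fitness = a * p,
         items = list(sort(items)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fitness of a logical inclusion vector over the pool, from the
# precomputed pool covariance. Subsets with < 2 items score -Inf.
bits_fitness <- function(bits, C, K, order, variant) {
  k <- sum(bits)
  if (k < 2L) return(-Inf)
  Cs <- C[bits, bits, drop = FALSE]
  a <- (k / (k - 1)) * (1 - sum(diag(Cs)) / sum(Cs))
  a * ga_penalty(k, K, order, variant)
}

# Deterministic tie-break: higher fitness, then fewer items, then
# lexicographically earlier item-id set.
solution_key <- function(ids) paste(sort(ids), collapse = "|")
better_solution <- function(f_a, ids_a, f_b, ids_b) {
  if (f_a != f_b) return(f_a > f_b)
  if (length(ids_a) != length(ids_b)) return(length(ids_a) < length(ids_b))
  solution_key(ids_a) < solution_key(ids_b)
}

#' Evolve an item subset by genetic algorithm
#'
#' Candidate subsets are bitstrings over the non-core items (core bits are
#' always on). The population is initialised uniformly at random; each
#' generation the worst `cull_fraction` is removed, the survivors breed by
#' uniform crossover (parents sampled with linearly rank-decreasing
#' probability), children are mutated bitwise, and the best member is
#' carried over unchanged (elitism), so the best-ever fitness never
#' decreases. The run stops once the best fitness has not improved for
#' `stagnation_limit` generations. Fully reproducible from `params$seed`.
#'
#' @param data Complete data frame of responses over the full item pool.
#' @param core Character vector of core item ids locked into every subset.
#' @param params A [ga_params()].
#' @return An object of class `ga_fit` with elements `best` (one-row
#'   tibble as from [ga_fitness()] plus `generation_found`), `trace`
#'   (tibble of per-generation best-ever fitness), `params`, `core`,
#'   `pool`. `tidy()` returns the trace, `glance()` the best row.
#' @export
ga_evolve <- function(data, core = character(), params = ga_params()) {
  m <- response_matrix(data)
  pool <- colnames(m)
  unknown <- setdiff(core, pool)
  if (length(unknown) > 0L) {
    abort(paste0("Core item(s) not in data: ", paste(unknown, collapse = ", ")))
  }
  noncore <- setdiff(pool, core)
  if (length(noncore) < 1L) abort("Need at least one non-core item to search over.")
  zero_var <- pool[apply(m, 2L, var) <= 0]
  if (length(zero_var) > 0L) {
    abort(paste0("Zero-variance item(s) in pool: ",
                 paste(zero_var, collapse = ", ")))
  }
  C <- cov(m)
  K <- params$max_items %||% length(pool)
  order <- params$penalty_order
  variant <- params$penalty_variant
  core_bits <- pool %in% core
  nb <- length(noncore)
  noncore_idx <- which(!core_bits)
  mu <- params$mutation_rate %||% (1 / K)
  pop_n <- params$population_size
  n_survive <- max(2L, ceiling(pop_n * (1 - params$cull_fraction)))

  eval_pop <- function(pop) {
    apply(pop, 1L, function(bits) {
      full <- core_bits
      full[noncore_idx] <- bits
      bits_fitness(full, C, K, order, variant)
    })
  }
  ids_of <- function(bits) {
    full <- core_bits
    full[noncore_idx] <- bits
    pool[full]
  }

  with_seed(params$seed, {
    pop <- matrix(runif(pop_n * nb) < 0.5, pop_n, nb)
    fit <- eval_pop(pop)
    best_i <- best_member(fit, pop, ids_of)
    best <- list(bits = pop[best_i, ], fitness = fit[best_i],
                 ids = ids_of(pop[best_i, ]), generation = 0L)
    trace <- numeric(params$max_generations + 1L)
    trace[1L] <- best$fitness
    stagnant <- 0L
    gen <- 0L
    while (stagnant < params$stagnation_limit && gen < params$max_generations) {
      gen <- gen + 1L
      ord <- order(fit, decreasing = TRUE)
      survivors <- pop[ord[seq_len(n_survive)], , drop = FALSE]
      n_children <- pop_n - params$elitism - n_survive
      children <- NULL
      if (n_children > 0L) {
        # rank-weighted parent sampling among survivors
        w <- rev(seq_len(n_survive))
        p1 <- sample.int(n_survive, n_children, replace = TRUE, prob = w)
        p2 <- sample.int(n_survive, n_children, replace = TRUE, prob = w)
        take1 <- matrix(runif(n_children * nb) < 0.5, n_children, nb)
        children <- ifelse(take1, survivors[p1, , drop = FALSE],
                           survivors[p2, , drop = FALSE])
        flip <- matrix(runif(n_children * nb) < mu, n_children, nb)
        children <- xor(children, flip)
      }
      elite <- matrix(best$bits, params$elitism, nb, byrow = TRUE)
      pop <- rbind(elite, survivors, children)
      fit <- eval_pop(pop)
      cand_i <- best_member(fit, pop, ids_of)
      cand <- list(bits = pop[cand_i, ], fitness = fit[cand_i],
                   ids = ids_of(pop[cand_i, ]), generation = gen)
      if (better_solution(cand$fitness, cand$ids, best$fitness, best$ids)) {
        improved <- cand$fitness > best$fitness
        best <- cand
        stagnant <- if (improved) 0L else stagnant + 1L
      } else {
        stagnant <- stagnant + 1L
      }
      trace[gen + 1L] <- best$fitness
    }
    best_row <- tibble(
      n_items = length(best$ids),
      alpha = alpha_from_cov(C[best$ids, best$ids, drop = FALSE]),
      penalty = ga_penalty(length(best$ids), K, order, variant),
      generation_found = best$generation
    )
    best_row$fitness <- best_row$alpha * best_row$penalty
    best_row$items <- list(sort(best$ids))
    structure(
      list(best = best_row,
           trace = tibble(generation = 0:gen, best_fitness = trace[1:(gen + 1L)]),
           params = params, core = core, pool = pool),
      class = "ga_fit"
    )
  })
}

# Index of the population's best member under the deterministic tie-break.
best_member <- function(fit, pop, ids_of) {
  top <- which(fit == max(fit))
  if (length(top) == 1L) return(top)
  sizes <- rowSums(pop[top, , drop = FALSE])
  top <- top[sizes == min(sizes)]
  if (length(top) == 1L) return(top)
  keys <- vapply(top, function(i) solution_key(ids_of(pop[i, ])), character(1))
  top[order(keys)][1L]
}

#' @export
print.ga_fit <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "GA item selection: %d of %d items (alpha %.3f x penalty %.3f = fitness %.3f)\n",
    b$n_items, length(x$pool), b$alpha, b$penalty, b$fitness))
  cat("  items:", paste(b$items[[1]], collapse = ", "), "\n")
  cat(sprintf("  found at generation %d of %d\n", b$generation_found,
              max(x$trace$generation)))
  invisible(x)
}

#' @export
tidy.ga_fit <- function(x, ...) x$trace

#' @export
glance.ga_fit <- function(x, ...) x$best

#' @export
autoplot.ga_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$generation, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Generation", y = "Best fitness (alpha x penalty)",
                  title = "GA convergence") +
    ggplot2::theme_minimal()
}

#' Multi-start genetic algorithm with agreement check
#'
#' Runs [ga_evolve()] from `n_starts` independent random starting points
#' (seeds derived deterministically from `seed`) and reports whether all
#' runs converged on the identical item set — the standard check that the
#' search did not stall in a local optimum.
#'
#' @inheritParams ga_evolve
#' @param n_starts Number of independent runs (>= 2).
#' @param seed Master seed expanded into one seed per start.
#' @return An object of class `ga_multi` with `runs` (tibble of per-run
#'   best solutions), `agreement` (logical), `fits` (list of `ga_fit`).
#' @export
ga_multi_start <- function(data, core = character(), params = ga_params(),
                           n_starts = 6, seed = params$seed) {
  if (n_starts < 2L) abort("Multi-start needs at least 2 starts.")
  seeds <- derive_seeds(seed, n_starts)
  fits <- lapply(seq_len(n_starts), function(i) {
    p <- params
    p$seed <- seeds[i]
    ga_evolve(data, core = core, params = p)
  })
  runs <- dplyr::bind_rows(lapply(fits, function(f) f$best))
  runs$start <- seq_len(n_starts)
  runs$seed <- seeds
  keys <- vapply(runs$items, solution_key, character(1))
  structure(
    list(runs = runs, agreement = length(unique(keys)) == 1L, fits = fits),
    class = "ga_multi"
  )
}

#' @export
print.ga_multi <- function(x, ...) {
  cat(sprintf("GA multi-start: %d runs, agreement: %s\n",
              nrow(x$runs), x$agreement))
  print(dplyr::select(x$runs, "start", "n_items", "alpha", "penalty", "fitness"))
  invisible(x)
}

#' @export
tidy.ga_multi <- function(x, ...) x$runs

#' @export
glance.ga_multi <- function(x, ...) {
  tibble(n_starts = nrow(x$runs), agreement = x$agreement,
         best_fitness = max(x$runs$fitness))
}
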