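#' Multiobjective evolutionary strain search
#'
#' An elitist non-dominated-sorting evolutionary algorithm (NSGA-II style:
#' fast non-dominated sort + crowding distance) over binary gene-deletion
#' vectors. Each candidate strain is evaluated by applying its design to
#' the model and running FBA/pFBA (and FVA when productivity-range
#' objectives are requested). Feasibility constraints: a growth floor
#' relative to the wild type, optional cofactor production flux-sum bounds,
#' protected essential genes, and synthetic-lethal gene pairs that may not
#' be jointly deleted. All feasible non-dominated strains encountered are
#' accumulated in a Pareto archive.
#'
#' @name moea
NULL

OBJECTIVE_DIRECTIONS <- c(
  growth_rate = "max", product_yield = "max",
  min_productivity = "max", max_productivity = "max",
  n_knockouts = "min", chromosome_score = "max"
)

#' MOEA run configuration
#'
#' @param population_size Individuals per generation (default 100).
#' @param generations Number of generations (default 500).
#' @param mutation_rate Per-gene flip probability; `NULL` (default) uses
#'   1/g for g knockable genes.
#' @param crossover_rate Probability a parent pair is recombined (uniform
#'   crossover), default 0.9.
#' @param max_deletions Maximum simultaneous knockouts d (default 6).
#' @param objectives Ordered subset of `growth_rate`, `product_yield`,
#'   `min_productivity`, `max_productivity`, `n_knockouts`,
#'   `chromosome_score`. Default `c("growth_rate", "product_yield")`.
#' @param growth_floor_fraction Feasible strains must grow at least this
#'   fraction of the wild-type rate; default 0.90 (a 10% bound on growth
#'   reduction).
#' @param cofactor_bound_fraction Maximum relative deviation of each
#'   cofactor production flux-sum from the wild type; `NULL` (default)
#'   disables the bound, `TRUE` enables it at 0.10.
#' @param cofactor_metabolites Metabolite ids for the flux-sum bound and
#'   reports; defaults to ATP, GTP, NADH, NADPH, FADH2 ids (missing ids are
#'   ignored per model).
#' @param essential_genes Genes the search must never delete.
#' @param synthetic_lethal_pairs List of length-2 character vectors; a
#'   design may delete either gene of a pair but not both.
#' @param knockins Pathway ids pinned on for every candidate (and the WT
#'   reference).
#' @param fva_fraction Fraction of optimum for productivity-range FVA.
#' @param molar_mass_ratio Yield normalization passed to [yield_of()].
#' @param rng_seed Integer seed; runs are deterministic given the seed.
#' @return A `moea_config`.
#' @export
moea_config <- function(population_size = 100L, generations = 500L,
                        mutation_rate = NULL, crossover_rate = 0.9,
                        max_deletions = 6L,
                        objectives = c("growth_rate", "product_yield"),
                        growth_floor_fraction = 0.90,
                        cofactor_bound_fraction = NULL,
                        cofactor_metabolites = c("atp", "gtp", "nadh",
                                                 "nadph", "fadh2"),
                        essential_genes = character(),
                        synthetic_lethal_pairs = list(),
                        knockins = character(),
                        fva_fraction = 1.0,
                        molar_mass_ratio = 1,
                        rng_seed = 1L) {
  if (isTRUE(cofactor_bound_fraction)) cofactor_bound_fraction <- 0.10
  stopifnot(population_size >= 4L, generations >= 1L,
            max_deletions >= 1L,
            growth_floor_fraction > 0, growth_floor_fraction <= 1,
            is.null(mutation_rate) ||
              (mutation_rate >= 0 && mutation_rate <= 1),
            crossover_rate >= 0, crossover_rate <= 1,
            length(objectives) >= 1L,
            all(objectives %in% names(OBJECTIVE_DIRECTIONS)))
  structure(list(
    population_size = as.integer(population_size),
    generations = as.integer(generations),
    mutation_rate = mutation_rate,
    crossover_rate = crossover_rate,
    max_deletions = as.integer(max_deletions),
    objectives = objectives,
    directions = unname(OBJECTIVE_DIRECTIONS[objectives]),
    growth_floor_fraction = growth_floor_fraction,
    cofactor_bound_fraction = cofactor_bound_fraction,
    cofactor_metabolites = cofactor_metabolites,
    essential_genes = as.character(essential_genes),
    synthetic_lethal_pairs = synthetic_lethal_pairs,
    knockins = as.character(knockins),
    fva_fraction = fva_fraction,
    molar_mass_ratio = molar_mass_ratio,
    rng_seed = as.integer(rng_seed)
  ), class = "moea_config")
}

#' Pareto dominance between objective tuples
#'
#' `a` dominates `b` when it is at least as good in every objective
#' (direction-adjusted) and strictly better in at least one.
#'
#' @param a,b Numeric objective tuples of equal length.
#' @param directions Character vector of `"max"`/`"min"` per objective.
#' @return `TRUE`/`FALSE`.
#' @export
dominates <- function(a, b, directions) {
  stopifnot(length(a) == length(b), length(a) == length(directions))
  s <- ifelse(directions == "max", 1, -1)
  da <- s * a; db <- s * b
  all(da >= db) && any(da > db)
}

#' Fast non-dominated sort
#'
#' Partitions a set of objective tuples into fronts F1, F2, ...: F1 is the
#' non-dominated subset, F2 the non-dominated subset after removing F1, and
#' so on.
#'
#' @param objectives Numeric matrix, one row per individual.
#' @param directions `"max"`/`"min"` per column.
#' @return List of integer vectors of row indices, one per front.
#' @export
fast_nondominated_sort <- function(objectives, directions) {
  n <- nrow(objectives)
  if (n == 0L) return(list())
  s <- ifelse(directions == "max", 1, -1)
  M <- sweep(objectives, 2, s, `*`)
  dominated_by <- integer(n)       # count of individuals dominating i
  dominates_set <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(M[i, ] >= M[j, ]) && any(M[i, ] > M[j, ])) {
        dominates_set[[i]] <- c(dominates_set[[i]], j)
      } else if (all(M[j, ] >= M[i, ]) && any(M[j, ] > M[i, ])) {
        dominated_by[i] <- dominated_by[i] + 1L
      }
    }
  }
  fronts <- list()
  current <- which(dominated_by == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer()
    for (i in current) {
      for (j in dominates_set[[i]]) {
        dominated_by[j] <- dominated_by[j] - 1L
        if (dominated_by[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(unique(nxt))
  }
  fronts
}

#' Crowding distance within a front
#' @param objectives Numeric matrix (rows = members of one front).
#' @return Numeric vector of crowding distances (boundary points `Inf`).
#' @export
crowding_distance <- function(objectives) {
  n <- nrow(objectives)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(objectives))) {
    o <- order(objectives[, k])
    rng <- objectives[o[n], k] - objectives[o[1], k]
    d[o[1]] <- d[o[n]] <- Inf
    # sentinel (infinite) objectives of constrained candidates make the
    # range non-finite; they contribute no crowding signal on that axis
    if (is.finite(rng) && rng > 0) {
      for (i in 2:(n - 1L)) {
        d[o[i]] <- d[o[i]] +
          (objectives[o[i + 1L], k] - objectives[o[i - 1L], k]) / rng
      }
    }
  }
  d
}

#' Hypervolume of a 2-objective front (both maximized)
#'
#' Exact area dominated by the front relative to a fixed reference point.
#' Used to track archive quality across generations.
#'
#' @param objectives Matrix with 2 columns (maximization scale).
#' @param ref Reference point (length 2), must be dominated by all members.
#' @return Non-negative scalar.
#' @export
hypervolume_2d <- function(objectives, ref) {
  stopifnot(ncol(objectives) == 2L, length(ref) == 2L)
  keep <- objectives[, 1] >= ref[1] & objectives[, 2] >= ref[2]
  objectives <- objectives[keep, , drop = FALSE]
  if (nrow(objectives) == 0L) return(0)
  pts <- objectives
  # integrate over x slabs between sorted unique x-coordinates; slab height
  # is the best y among points at or beyond the slab's right edge
  ux <- sort(unique(pts[, 1]))
  hv <- 0
  for (i in seq_along(ux)) {
    x0 <- if (i == 1L) ref[1] else ux[i - 1L]
    height <- max(pts[pts[, 1] >= ux[i], 2]) - ref[2]
    if (height > 0) hv <- hv + (ux[i] - x0) * height
  }
  hv
}

# --- variation operators ----------------------------------------------------

#' Mutate a binary deletion vector
#'
#' Flips each knockable gene's deletion state independently with
#' probability `rate`, then repairs the result to at most `max_deletions`
#' by reverting randomly chosen excess deletions. Essential genes are not
#' part of the knockable universe and can never be switched off.
#'
#' @param x Logical vector over knockable genes (`TRUE` = deleted).
#' @param rate Per-gene flip probability.
#' @param max_deletions Repair cap.
#' @return Mutated logical vector.
#' @export
mutate_design <- function(x, rate, max_deletions = Inf) {
  stopifnot(rate >= 0, rate <= 1)
  flip <- stats::runif(length(x)) < rate
  x <- xor(x, flip)
  repair_deletions(x, max_deletions)
}

#' Uniform crossover of two deletion vectors
#'
#' Each gene position is swapped between the parents with probability 1/2;
#' children are repaired to the deletion cap.
#'
#' @param a,b Logical vectors of equal length.
#' @param max_deletions Repair cap.
#' @return List of two children.
#' @export
crossover_designs <- function(a, b, max_deletions = Inf) {
  stopifnot(length(a) == length(b))
  swap <- stats::runif(length(a)) < 0.5
  ca <- ifelse(swap, b, a)
  cb <- ifelse(swap, a, b)
  list(repair_deletions(ca, max_deletions), repair_deletions(cb, max_deletions))
}

repair_deletions <- function(x, max_deletions) {
  k <- sum(x)
  if (k > max_deletions) {
    on_idx <- which(x)
    revert <- on_idx[sample.int(k, k - max_deletions)]
    x[revert] <- FALSE
  }
  x
}

# --- evaluation -------------------------------------------------------------

violates_synthetic_lethal <- function(deletions, pairs) {
  for (p in pairs) if (all(p %in% deletions)) return(TRUE)
  FALSE
}

#' Evaluate a candidate strain
#'
#' Applies the design (knock-ins first), runs pFBA (and FVA when the
#' objective list requires productivity ranges), fills the metrics and
#' decides feasibility: growth floor vs. the wild type, essential-gene and
#' synthetic-lethal exclusions, and (when enabled) cofactor flux-sum
#' bounds. An infeasible LP or any violated constraint yields
#' `feasible = FALSE` with worst-sentinel objectives, so constrained
#' candidates are naturally dominated but keep the search gradient.
#'
#' @param model A `stoich_model`.
#' @param design A [strain_design()].
#' @param config A [moea_config()].
#' @param wt Optional precomputed wild-type `evaluated_strain` (the empty
#'   design under the same config); computed on the fly when missing.
#' @return An `evaluated_strain` with `design`, `objectives`, `feasible`
#'   and `metrics`.
#' @export
evaluate_strain <- function(model, design, config, wt = NULL) {
  sentinel <- ifelse(config$directions == "max", -Inf, Inf)
  names(sentinel) <- config$objectives
  bad <- function(metrics, why) {
    structure(list(design = design, objectives = sentinel, feasible = FALSE,
                   infeasibility = why, metrics = metrics),
              class = "evaluated_strain")
  }

  if (any(design$deletions %in% config$essential_genes)) {
    return(bad(NULL, "essential gene deleted"))
  }
  if (violates_synthetic_lethal(design$deletions,
                                config$synthetic_lethal_pairs)) {
    return(bad(NULL, "synthetic-lethal pair deleted"))
  }

  is_wt <- length(design$deletions) == 0L
  if (is.null(wt) && !is_wt) {
    wt <- evaluate_strain(model, strain_design(knockins = config$knockins),
                          config, wt = NULL)
    if (!wt$feasible) stop("wild-type reference is infeasible", call. = FALSE)
  }

  met <- strain_metrics(model, design,
                        cofactors = config$cofactor_metabolites,
                        molar_mass_ratio = config$molar_mass_ratio)
  if (!met$feasible) return(bad(met, "LP infeasible"))

  if (!is_wt) {
    if (met$growth_rate <
        config$growth_floor_fraction * wt$metrics$growth_rate - 1e-9) {
      return(bad(met, "growth below floor"))
    }
    if (!is.null(config$cofactor_bound_fraction)) {
      for (mid in names(wt$metrics$cofactor_production)) {
        wtv <- wt$metrics$cofactor_production[[mid]]
        sv <- met$cofactor_production[[mid]]
        if (abs(sv - wtv) > config$cofactor_bound_fraction * wtv + 1e-9) {
          return(bad(met, sprintf("cofactor bound violated (%s)", mid)))
        }
      }
    }
  }

  needs_range <- any(c("min_productivity", "max_productivity") %in%
                       config$objectives)
  prange <- if (needs_range) {
    productivity_range(model, design, config$fva_fraction,
                       config$molar_mass_ratio)
  } else c(min = NA_real_, max = NA_real_)
  met$productivity_range <- prange

  vals <- vapply(config$objectives, function(ob) switch(ob,
    growth_rate = met$growth_rate,
    product_yield = met$yield,
    min_productivity = prange[["min"]],
    max_productivity = prange[["max"]],
    n_knockouts = as.numeric(length(design$deletions)),
    chromosome_score = same_chromosome_score(
      design, custom_map = model$gene_chromosome)
  ), numeric(1))
  structure(list(design = design, objectives = vals, feasible = TRUE,
                 infeasibility = NA_character_, metrics = met),
            class = "evaluated_strain")
}

#' @export
print.evaluated_strain <- function(x, ...) {
  cat(sprintf("<evaluated_strain> %s | %s\n",
              if (x$feasible) "feasible" else
                paste0("INFEASIBLE (", x$infeasibility, ")"),
              paste(sprintf("%s=%.4g", names(x$objectives), x$objectives),
                    collapse = ", ")))
  invisible(x)
}

# --- archive ----------------------------------------------------------------

new_archive <- function(config, wt) {
  structure(list(strains = list(), config = config, wt = wt),
            class = "pareto_archive")
}

#' Objective matrix of an archive
#' @param archive A `pareto_archive`.
#' @return Numeric matrix, one row per archived strain, one column per
#'   configured objective.
#' @export
archive_objectives <- function(archive) {
  if (!length(archive$strains)) {
    return(matrix(numeric(), 0, length(archive$config$objectives),
                  dimnames = list(NULL, archive$config$objectives)))
  }
  do.call(rbind, lapply(archive$strains, `[[`, "objectives"))
}

archive_insert <- function(archive, strains) {
  cand <- c(archive$strains, strains)
  if (!length(cand)) return(archive)
  objs <- do.call(rbind, lapply(cand, `[[`, "objectives"))
  keys <- vapply(cand, function(s) design_key(s$design), character(1))
  keep <- !duplicated(keys)
  cand <- cand[keep]; objs <- objs[keep, , drop = FALSE]
  dirs <- archive$config$directions
  nd <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) {
    if (!nd[i]) next
    for (j in seq_along(cand)) {
      if (i == j || !nd[i]) next
      if (dominates(objs[j, ], objs[i, ], dirs)) { nd[i] <- FALSE; break }
    }
  }
  archive$strains <- cand[nd]
  archive
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat(sprintf("<pareto_archive> %d strain(s), objectives: %s\n",
              length(x$strains),
              paste(x$config$objectives, collapse = ", ")))
  invisible(x)
}

#' Number of strains in a Pareto archive
#' @param x A `pareto_archive`.
#' @export
length.pareto_archive <- function(x) length(x$strains)

# --- the search -------------------------------------------------------------

#' Run the multiobjective evolutionary knockout search
#'
#' Seeded and deterministic given `config$rng_seed`. The initial population
#' is the wild type plus random low-cardinality deletion sets; each
#' generation applies binary-tournament selection (rank, then crowding
#' distance), uniform crossover, per-gene mutation, evaluation (memoized by
#' deletion set), and elitist non-dominated truncation. All feasible
#' non-dominated strains ever evaluated accumulate in the returned archive.
#'
#' @param model A `stoich_model`.
#' @param config A [moea_config()].
#' @param progress Optional function called per generation with a log row
#'   (generation, archive size, hypervolume when 2 objectives).
#' @return A `pareto_archive`; attribute `"log"` holds the per-generation
#'   data frame, attribute `"n_evaluated"` the number of distinct designs
#'   evaluated.
#' @export
run_moea <- function(model, config, progress = NULL) {
  stopifnot(inherits(config, "moea_config"))
  with_seed(config$rng_seed, run_moea_impl(model, config, progress))
}

run_moea_impl <- function(model, config, progress) {
  genes <- sort(knockable_genes(model, config$essential_genes,
                                config$knockins))
  g <- length(genes)
  if (g == 0L) stop("no knockable genes", call. = FALSE)
  rate <- config$mutation_rate %||% (1 / g)

  cache <- new.env(parent = emptyenv())
  wt <- evaluate_strain(model,
                        strain_design(knockins = config$knockins), config)
  if (!wt$feasible) stop("wild-type model is infeasible", call. = FALSE)
  assign(design_key(wt$design), wt, envir = cache)

  eval_vec <- function(x) {
    d <- strain_design(deletions = genes[x], knockins = config$knockins)
    key <- design_key(d)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ev <- evaluate_strain(model, d, config, wt = wt)
    assign(key, ev, envir = cache)
    ev
  }

  pop <- vector("list", config$population_size)
  pop[[1]] <- rep(FALSE, g)
  for (i in 2:config$population_size) {
    x <- rep(FALSE, g)
    k <- sample.int(min(config$max_deletions, g, 3L) + 1L, 1L) - 1L
    if (k > 0) x[sample.int(g, k)] <- TRUE
    pop[[i]] <- x
  }
  evals <- lapply(pop, eval_vec)

  archive <- new_archive(config, wt)
  archive <- archive_insert(archive, Filter(function(e) e$feasible, evals))

  log_rows <- list()
  for (gen in seq_len(config$generations)) {
    objs <- do.call(rbind, lapply(evals, `[[`, "objectives"))
    fronts <- fast_nondominated_sort(objs, config$directions)
    rank <- integer(length(evals))
    for (fi in seq_along(fronts)) rank[fronts[[fi]]] <- fi
    crowd <- numeric(length(evals))
    for (f in fronts) {
      crowd[f] <- crowding_distance(objs[f, , drop = FALSE])
    }

    tournament <- function() {
      ij <- sample.int(length(evals), 2L)
      i <- ij[1]; j <- ij[2]
      if (rank[i] < rank[j]) i
      else if (rank[j] < rank[i]) j
      else if (crowd[i] > crowd[j]) i
      else j
    }

    children <- list()
    while (length(children) < config$population_size) {
      pa <- pop[[tournament()]]; pb <- pop[[tournament()]]
      if (stats::runif(1) < config$crossover_rate) {
        cs <- crossover_designs(pa, pb, config$max_deletions)
      } else {
        cs <- list(pa, pb)
      }
      cs <- lapply(cs, mutate_design, rate = rate,
                   max_deletions = config$max_deletions)
      children <- c(children, cs)
    }
    children <- children[seq_len(config$population_size)]
    child_evals <- lapply(children, eval_vec)
    archive <- archive_insert(archive,
                              Filter(function(e) e$feasible, child_evals))

    # elitist environmental selection over parents + children
    all_pop <- c(pop, children)
    all_evals <- c(evals, child_evals)
    objs2 <- do.call(rbind, lapply(all_evals, `[[`, "objectives"))
    fronts2 <- fast_nondominated_sort(objs2, config$directions)
    sel <- integer()
    for (f in fronts2) {
      if (length(sel) + length(f) <= config$population_size) {
        sel <- c(sel, f)
      } else {
        cd <- crowding_distance(objs2[f, , drop = FALSE])
        need <- config$population_size - length(sel)
        # crowding tie-break, then deterministic order by design key
        keys <- vapply(all_evals[f], function(e) design_key(e$design),
                       character(1))
        sel <- c(sel, f[order(-cd, keys)][seq_len(need)])
        break
      }
    }
    pop <- all_pop[sel]
    evals <- all_evals[sel]

    hv <- NA_real_
    if (length(config$objectives) == 2L && length(archive$strains)) {
      ao <- archive_objectives(archive)
      s <- ifelse(config$directions == "max", 1, -1)
      ao <- sweep(ao, 2, s, `*`)
      hv <- hypervolume_2d(ao, apply(ao, 2, min) - 1)
    }
    row <- data.frame(generation = gen, archive_size = length(archive$strains),
                      hypervolume = hv)
    log_rows[[gen]] <- row
    if (!is.null(progress)) progress(row)
  }

  attr(archive, "log") <- do.call(rbind, log_rows)
  attr(archive, "n_evaluated") <- length(ls(cache))
  archive
}

#' Exact Pareto front by exhaustive enumeration
#'
#' Evaluates every deletion subset of the knockable genes up to
#' `config$max_deletions` and returns the exact Pareto archive. Infeasible
#' at genome scale, but the definitive oracle on toy models.
#'
#' @param model A `stoich_model`.
#' @param config A [moea_config()].
#' @param max_genes Guard: refuses more knockable genes than this
#'   (default 12).
#' @return A `pareto_archive`; attribute `"n_evaluated"` counts evaluated
#'   subsets (`sum_k choose(g, k)` for k = 0..d).
#' @export
brute_force_front <- function(model, config, max_genes = 12L) {
  genes <- sort(knockable_genes(model, config$essential_genes,
                                config$knockins))
  g <- length(genes)
  if (g > max_genes) {
    stop(sprintf("%d knockable genes exceed max_genes=%d", g, max_genes),
         call. = FALSE)
  }
  wt <- evaluate_strain(model,
                        strain_design(knockins = config$knockins), config)
  if (!wt$feasible) stop("wild-type model is infeasible", call. = FALSE)
  archive <- new_archive(config, wt)
  n_eval <- 0L
  feasible <- list()
  for (k in 0:min(config$max_deletions, g)) {
    combos <- utils::combn(g, k, simplify = FALSE)
    for (cm in combos) {
      d <- strain_design(deletions = genes[cm], knockins = config$knockins)
      ev <- if (k == 0L) wt else evaluate_strain(model, d, config, wt = wt)
      n_eval <- n_eval + 1L
      if (ev$feasible) feasible[[length(feasible) + 1L]] <- ev
    }
  }
  archive <- archive_insert(archive, feasible)
  attr(archive, "n_evaluated") <- n_eval
  archive
}
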