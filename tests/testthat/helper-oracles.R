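# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: the LP oracle enumerates polytope vertices, the GPR
# oracle routes Boolean evaluation through R's own parser, and the front
# oracle is the naive O(n^2) pairwise dominance check.

# Exhaustive vertex enumeration for max/min c'x s.t. Ax = 0, lb <= x <= ub
# on bounded low-dimensional models. Returns the optimal objective value or
# NULL when no feasible vertex exists.
lp_vertex_oracle <- function(obj, A, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- qr(A)$rank
  nf <- n - r
  best <- NULL
  for (fs in utils::combn(n, r, simplify = FALSE)) {
    Af <- A[, fs, drop = FALSE]
    if (qr(Af)$rank < r) next
    fixed <- setdiff(seq_len(n), fs)
    masks <- if (nf == 0) list(integer(0)) else
      lapply(0:(2^nf - 1), function(m) as.integer(intToBits(m))[seq_len(nf)])
    for (g in masks) {
      xf <- ifelse(g == 1L, ub[fixed], lb[fixed])
      if (length(xf) && any(!is.finite(xf))) next
      rhs <- if (length(fixed)) -A[, fixed, drop = FALSE] %*% xf
             else matrix(0, nrow(A), 1)
      xs <- tryCatch(qr.solve(Af, rhs), error = function(e) NULL)
      if (is.null(xs)) next
      x <- numeric(n)
      x[fs] <- xs
      x[fixed] <- xf
      if (max(abs(A %*% x)) > 1e-7) next
      if (any(x < lb - 1e-7) || any(x > ub + 1e-7)) next
      val <- sum(obj * x)
      if (is.null(best) || (maximize && val > best) ||
          (!maximize && val < best)) best <- val
    }
  }
  best
}

# Random GPR rule trees over a gene pool (bounded depth).
random_gpr_rule <- function(genes, depth = 0L, p_leaf = 0.35) {
  if (depth >= 3L || stats::runif(1) < p_leaf) {
    return(moeko:::gpr_literal(genes[sample.int(length(genes), 1)]))
  }
  op <- c("and", "or")[sample.int(2, 1)]
  k <- sample(2:3, 1)
  moeko:::gpr_node(op, lapply(seq_len(k), function(i)
    random_gpr_rule(genes, depth + 1L, p_leaf)))
}

# Boolean evaluation through R's parser (independent of evaluate_gpr).
gpr_oracle_eval <- function(rule, states) {
  to_expr <- function(r) {
    if (r$op == "literal") return(sprintf("`%s`", r$gene))
    sep <- if (r$op == "and") " & " else " | "
    paste0("(", paste(vapply(r$args, to_expr, character(1)),
                      collapse = sep), ")")
  }
  env <- as.list(stats::setNames(as.logical(states), names(states)))
  eval(parse(text = to_expr(rule)), envir = env)
}

# Indices of the non-dominated rows of an objective matrix (naive check).
front_oracle <- function(M, directions) {
  s <- ifelse(directions == "max", 1, -1)
  Ms <- sweep(M, 2, s, `*`)
  n <- nrow(M)
  keep <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && all(Ms[j, ] >= Ms[i, ]) && any(Ms[j, ] > Ms[i, ])
    }, logical(1)))
  }, logical(1))
  which(keep)
}

# Canonical sorted unique objective tuples of an archive, for set equality.
front_tuples <- function(archive, digits = 9) {
  M <- unique(round(archive_objectives(archive), digits))
  M[do.call(order, as.data.frame(M)), , drop = FALSE]
}

# Shared small config for core-model searches in tests; overrides via `...`.
core_test_config <- function(...) {
  base <- list(population_size = 40L, generations = 25L, max_deletions = 4L,
               objectives = c("growth_rate", "product_yield"),
               growth_floor_fraction = 0.1,
               essential_genes = core_essential_genes(),
               knockins = "bcar", rng_seed = 42L)
  do.call(moea_config, utils::modifyList(base, list(...)))
}
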