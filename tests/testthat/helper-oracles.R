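# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths: the LP oracle enumerates polytope vertices
# instead of running a simplex, and the regression oracle maximises the
# quasi-log-likelihood by grid search instead of IRLS.

# Enumerate the vertices of {v : S v = 0, lb <= v <= ub} (all bounds
# finite) and return the extreme objective values. At a vertex of the
# d-dimensional feasible polytope (d = n - rank(S)), at least d variables
# sit on a bound; we try every choice of d variables and every lb/ub
# assignment, solve for the rest, and keep feasible solutions.
lp_oracle <- function(obj, S, lb, ub) {
  n <- length(obj)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  S <- as.matrix(S)
  r <- qr(S)$rank
  d <- n - r
  verts <- list()
  try_vertex <- function(fixed_idx, fixed_val) {
    free <- setdiff(seq_len(n), fixed_idx)
    rhs <- -S[, fixed_idx, drop = FALSE] %*% fixed_val
    A <- S[, free, drop = FALSE]
    sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) return()
    v <- numeric(n)
    v[fixed_idx] <- fixed_val
    v[free] <- sol
    if (max(abs(S %*% v)) > 1e-7) return()
    if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) return()
    verts[[length(verts) + 1L]] <<- pmin(pmax(v, lb), ub)
  }
  if (d == 0L) {
    try_vertex(integer(0), numeric(0))
  } else {
    sets <- utils::combn(n, d, simplify = FALSE)
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
    for (idx in sets) {
      for (g in seq_len(nrow(grid))) {
        vals <- ifelse(grid[g, ], ub[idx], lb[idx])
        try_vertex(idx, vals)
      }
    }
  }
  if (!length(verts)) {
    return(list(feasible = FALSE, max = NA_real_, min = NA_real_))
  }
  vals <- vapply(verts, function(v) sum(obj * v), numeric(1))
  list(feasible = TRUE, max = max(vals), min = min(vals))
}

# FBA/FVA oracle on a metabolic_model, via vertex enumeration.
fba_oracle <- function(model, obj = model$reactions$obj) {
  S <- as.matrix(gutflux::stoich_matrix(model))
  lp_oracle(obj, S, model$reactions$lb, model$reactions$ub)
}

fva_oracle <- function(model, reaction) {
  obj <- as.numeric(model$reactions$id == reaction)
  fba_oracle(model, obj)
}

# Quasi-log-likelihood of the fractional logit model.
quasi_loglik <- function(y, X, beta) {
  mu <- stats::plogis(as.vector(X %*% beta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# Two-stage grid maximisation for a two-coefficient fractional logit.
gridfit_fracreg2 <- function(y, X, span = 4, steps = 81L) {
  centre <- c(0, 0)
  width <- span
  for (stage in 1:4) {
    g1 <- seq(centre[1] - width, centre[1] + width, length.out = steps)
    g2 <- seq(centre[2] - width, centre[2] + width, length.out = steps)
    ll <- outer(g1, g2, Vectorize(function(a, b) {
      quasi_loglik(y, X, c(a, b))
    }))
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    centre <- c(g1[best[1]], g2[best[2]])
    width <- width * 2.5 / (steps - 1)
  }
  centre
}

# Random small metabolic networks that are always feasible: a substrate
# chain with optional branches and randomised bounds/yields. Used for the
# solver-vs-oracle equivalence sweeps.
random_toy_model <- function(seed) {
  set.seed(seed)
  uptake <- round(stats::runif(1, 2, 12), 2)
  y1 <- round(stats::runif(1, 0.5, 2), 2)
  y2 <- round(stats::runif(1, 0.5, 2), 2)
  branch <- stats::runif(1) < 0.5
  mets <- data.frame(
    id = c("a_e", "a_c", "p_e", if (branch) "q_e", "biomass_c"),
    compartment = c("e", "c", "e", if (branch) "e", "c"))
  rx <- data.frame(
    id = c("EX_a_e", "T_a", "BIOMASS", "EX_biomass_e", "SEC_p", "EX_p_e",
           if (branch) c("SEC_q", "EX_q_e")),
    lb = 0, ub = round(stats::runif(ifelse(branch, 8, 6), 3, 1000), 2),
    obj = 0)
  rx$lb[1] <- -uptake
  rx$obj[3] <- 1
  st <- rbind(
    data.frame(reaction = "EX_a_e", metabolite = "a_e", coef = -1),
    data.frame(reaction = "T_a", metabolite = c("a_e", "a_c"),
               coef = c(-1, 1)),
    data.frame(reaction = "BIOMASS", metabolite = c("a_c", "biomass_c"),
               coef = c(-1, 1)),
    data.frame(reaction = "EX_biomass_e", metabolite = "biomass_c",
               coef = -1),
    data.frame(reaction = "SEC_p", metabolite = c("a_c", "p_e"),
               coef = c(-1, y1)),
    data.frame(reaction = "EX_p_e", metabolite = "p_e", coef = -1),
    if (branch) data.frame(reaction = "SEC_q",
                           metabolite = c("a_c", "q_e"), coef = c(-1, y2)),
    if (branch) data.frame(reaction = "EX_q_e", metabolite = "q_e",
                           coef = -1))
  gutflux::metabolic_model(paste0("toy", seed), mets, rx, st)
}
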