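# Multi-omic feature selection around a seed gene and score-based Bayesian
# network structure learning. The score is a linear-Gaussian BIC (all layers
# treated as continuous); the learner is greedy hill climbing with random
# restarts over add/delete/reverse moves.

#' Two-stage correlation-threshold feature selection
#'
#' Stage 1 keeps mRNA variables whose absolute Pearson correlation with the
#' seed gene exceeds the mRNA threshold. Stage 2 keeps variables of the other
#' layers whose absolute correlation with ANY stage-1 transcript exceeds that
#' layer's threshold. The returned node set is the union plus the seed gene.
#'
#' @param layers An `omics_layers` object (`data` sample x variable matrix,
#'   `layer` named vector of layer labels).
#' @param seed_gene Seed transcript id; must be an mRNA variable.
#' @param thresholds Named correlation cutoffs in (0, 1) for `mRNA`, `miRNA`,
#'   `methylation`, `protein` (defaults 0.38, 0.45, 0.40, 0.30).
#' @param method Correlation type (default Pearson).
#' @return Data frame: `node`, `layer` (seed gene first).
#' @export
select_features <- function(layers, seed_gene,
                            thresholds = c(mRNA = 0.38, miRNA = 0.45,
                                           methylation = 0.40, protein = 0.30),
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  data <- layers$data
  lab <- layers$layer
  if (!seed_gene %in% colnames(data) || lab[[seed_gene]] != "mRNA")
    stopf("seed gene %s absent from the mRNA layer", seed_gene)
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stopf("thresholds must lie in (0, 1)")
  mrna <- setdiff(names(lab)[lab == "mRNA"], seed_gene)
  r_seed <- abs(cor(data[, mrna, drop = FALSE], data[, seed_gene],
                    method = method))
  stage1 <- mrna[r_seed[, 1] > thresholds[["mRNA"]]]
  selected <- character(0)
  if (length(stage1)) {
    for (layer in c("miRNA", "methylation", "protein")) {
      vars <- names(lab)[lab == layer]
      if (!length(vars)) next
      r <- abs(cor(data[, vars, drop = FALSE], data[, stage1, drop = FALSE],
                   method = method))
      hit <- vars[apply(r, 1, max) > thresholds[[layer]]]
      selected <- c(selected, hit)
    }
  }
  nodes <- c(seed_gene, stage1, selected)
  data.frame(node = nodes, layer = unname(lab[nodes]),
             stringsAsFactors = FALSE)
}

# Topological order of an adjacency matrix (adj[i, j] = 1 means i -> j);
# NULL when the graph is cyclic.
topo_order <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  order <- integer(0)
  avail <- rep(TRUE, n)
  for (step in seq_len(n)) {
    cand <- which(avail & indeg == 0)
    if (!length(cand)) return(NULL)
    v <- cand[1]
    order <- c(order, v)
    avail[v] <- FALSE
    indeg <- indeg - adj[v, ]
  }
  order
}

is_dag <- function(adj) !is.null(topo_order(adj))

# Gaussian log-likelihood of OLS of `node` on `parents`, maximum-likelihood
# variance; closed form avoids per-move lm() calls.
local_loglik <- function(data, node, parents) {
  y <- data[, node]
  n <- length(y)
  if (length(parents)) {
    x <- cbind(1, data[, parents, drop = FALSE])
    beta <- solve(crossprod(x), crossprod(x, y))
    rss <- sum((y - x %*% beta)^2)
  } else {
    rss <- sum((y - mean(y))^2)
  }
  sigma2 <- max(rss / n, 1e-12)
  -n / 2 * (log(2 * pi * sigma2) + 1)
}

local_bic <- function(data, node, parents) {
  n <- nrow(data)
  k <- length(parents) + 2  # coefficients + intercept + variance
  local_loglik(data, node, parents) - k / 2 * log(n)
}

#' BIC score of a directed acyclic graph
#'
#' Decomposable linear-Gaussian score: for every node, the Gaussian
#' log-likelihood of the least-squares regression of the node on its parents
#' minus `(k / 2) log n`, with `k` the number of local parameters
#' (coefficients, intercept, variance). Higher is better.
#'
#' @param data Sample x variable numeric matrix.
#' @param dag Adjacency matrix over `colnames(data)` (`dag[i, j] = 1` means
#'   an edge from variable i to variable j); must be acyclic.
#' @return List: `total` and named `local` scores.
#' @export
bic_score <- function(data, dag) {
  vars <- colnames(data)
  stopifnot(identical(rownames(dag), vars), identical(colnames(dag), vars))
  if (!is_dag(dag)) stopf("graph is cyclic")
  local <- vapply(vars, function(v)
    local_bic(data, v, vars[dag[, v] == 1]), numeric(1))
  list(total = sum(local), local = local)
}

# Random DAG: sample a node order, include each forward edge with prob p
# subject to the in-degree bound.
random_dag <- function(n, p, max_in_degree) {
  ord <- sample.int(n)
  adj <- matrix(0L, n, n)
  for (j in 2:n) {
    for (i in 1:(j - 1)) {
      if (runif(1) < p && sum(adj[, ord[j]]) < max_in_degree)
        adj[ord[i], ord[j]] <- 1L
    }
  }
  adj
}

#' Learn a Bayesian network by greedy hill climbing
#'
#' Starting from an empty graph (first restart) or seeded random DAGs, takes
#' the best score-improving add/delete/reverse move until no move improves
#' the BIC, enforcing acyclicity and a maximum in-degree at every step. Ties
#' between equal-gain moves break deterministically by lexicographic move
#' order. The best-scoring local optimum across restarts is returned.
#'
#' @param data Sample x variable numeric matrix.
#' @param layers Optional named vector of layer labels for the variables.
#' @param restarts Number of restarts (default 20).
#' @param seed Integer seed for the random restarts.
#' @param max_in_degree Maximum parents per node (default 3; bounds
#'   overfitting at small n).
#' @return An object of class `network_model`: `edges` data frame
#'   (`parent`, `child`, layer labels), `score`, `local_scores`,
#'   `adjacency`, `nodes`.
#' @export
hill_climb <- function(data, layers = NULL, restarts = 20, seed = 1,
                       max_in_degree = 3) {
  vars <- colnames(data)
  n_var <- length(vars)
  if (n_var < 2) stopf("need at least 2 variables")
  if (nrow(data) <= max_in_degree + 2)
    stopf("too few samples for the in-degree bound")

  climb <- function(adj) {
    local <- vapply(seq_len(n_var), function(v)
      local_bic(data, vars[v], vars[adj[, v] == 1]), numeric(1))
    repeat {
      best <- list(gain = 1e-9, adj = NULL, local = NULL)
      for (i in seq_len(n_var)) for (j in seq_len(n_var)) {
        if (i == j) next
        if (adj[i, j] == 0L) {
          # add i -> j
          if (sum(adj[, j]) >= max_in_degree) next
          cand <- adj; cand[i, j] <- 1L
          if (!is_dag(cand)) next
          new_j <- local_bic(data, vars[j], vars[cand[, j] == 1])
          gain <- new_j - local[j]
          if (gain > best$gain) {
            nl <- local; nl[j] <- new_j
            best <- list(gain = gain, adj = cand, local = nl)
          }
        } else {
          # delete i -> j
          cand <- adj; cand[i, j] <- 0L
          new_j <- local_bic(data, vars[j], vars[cand[, j] == 1])
          gain <- new_j - local[j]
          if (gain > best$gain) {
            nl <- local; nl[j] <- new_j
            best <- list(gain = gain, adj = cand, local = nl)
          }
          # reverse to j -> i
          if (sum(adj[, i]) < max_in_degree) {
            cand2 <- cand; cand2[j, i] <- 1L
            if (is_dag(cand2)) {
              new_i <- local_bic(data, vars[i], vars[cand2[, i] == 1])
              gain2 <- (new_j - local[j]) + (new_i - local[i])
              if (gain2 > best$gain) {
                nl <- local; nl[j] <- new_j; nl[i] <- new_i
                best <- list(gain = gain2, adj = cand2, local = nl)
              }
            }
          }
        }
      }
      if (is.null(best$adj)) break
      adj <- best$adj
      local <- best$local
    }
    list(adj = adj, local = local, total = sum(local))
  }

  best_fit <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- if (r == 1) matrix(0L, n_var, n_var)
              else random_dag(n_var, p = 0.15, max_in_degree = max_in_degree)
      fit <- climb(init)
      if (is.null(best_fit) || fit$total > best_fit$total) best_fit <- fit
    }
  })
  adj <- best_fit$adj
  dimnames(adj) <- list(vars, vars)
  idx <- which(adj == 1L, arr.ind = TRUE)
  edges <- data.frame(parent = vars[idx[, 1]], child = vars[idx[, 2]],
                      stringsAsFactors = FALSE)
  if (!is.null(layers)) {
    edges$parent_layer <- unname(layers[edges$parent])
    edges$child_layer <- unname(layers[edges$child])
  }
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, score = best_fit$total,
                 local_scores = setNames(best_fit$local, vars),
                 adjacency = adj, nodes = vars, layers = layers),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("Bayesian network: %d nodes, %d edges, BIC score %.2f\n",
              length(x$nodes), nrow(x$edges), x$score))
  if (nrow(x$edges)) {
    apply(x$edges, 1, function(e)
      cat(sprintf("  %s -> %s\n", e[["parent"]], e[["child"]])))
  }
  invisible(x)
}

#' Undirected skeleton of a learned network
#' @param model A `network_model`.
#' @return Character vector of undirected edges `"a--b"` (a < b).
#' @export
network_skeleton <- function(model) {
  if (!nrow(model$edges)) return(character(0))
  sort(unique(apply(model$edges, 1, function(e)
    paste(sort(c(e[["parent"]], e[["child"]])), collapse = "--"))))
}
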