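#' @name module-detection
#' @title Modules of ROIs with similar inter-individual variability
#'
#' @description
#' Rather than clustering temporal signals, these functions cluster regions
#' by how their task activation covaries *across participants*: two ROIs
#' belong to the same module when participants with a strong load-contrast
#' response in one tend to show a strong response in the other. The workflow
#' is: select task-responsive ROIs from the t-value table, build the
#' inter-subject Pearson correlation network, partition it with seeded
#' Louvain runs refined by single-node moves, stabilize the result by
#' consensus over many runs with permutation-null thresholding of the
#' agreement matrix, sweep the resolution parameter gamma, and pick the
#' partition most similar (by adjusted mutual information) to a reference.
NULL

#' Select task-responsive ROIs
#'
#' Keeps an ROI when the magnitude of its t-value exceeds `t_threshold` in at
#' least `ceiling(min_fraction * n_subjects)` participants. The threshold is
#' strict (`|T| > t_threshold`), so a t-value exactly at the threshold does
#' not count.
#'
#' @param tvalues Subjects x ROIs numeric matrix (or data.frame with a
#'   `subject_id` column) of t-values for the load contrast.
#' @param t_threshold Liberal significance threshold (default 1.96).
#' @param min_fraction Minimum fraction of participants (default 0.10).
#' @return Character vector of retained ROI ids (column names).
#' @export
select_rois <- function(tvalues, t_threshold = 1.96, min_fraction = 0.10) {
  T <- as_matrix_table(tvalues, "tvalues")
  if (nrow(T) == 0 || ncol(T) == 0) stopf("t-value table is empty")
  if (t_threshold <= 0) stopf("t_threshold must be positive")
  if (min_fraction <= 0 || min_fraction > 1) stopf("min_fraction must be in (0, 1]")
  need <- ceiling(min_fraction * nrow(T))
  counts <- colSums(abs(T) > t_threshold)
  cols <- colnames(T) %||% as.character(seq_len(ncol(T)))
  cols[counts >= need]
}

#' Inter-subject correlation network
#'
#' Pearson correlation across subjects of every pair of ROI activation
#' columns, with the diagonal zeroed. This is the "inter-individual
#' covariance" graph that module detection partitions.
#'
#' @param betas Subjects x ROIs activation matrix.
#' @param roi_subset Optional ROI ids (columns) to restrict to.
#' @return A list of class `bp_network`: `roi_ids`, `weights` (symmetric,
#'   entries in `[-1, 1]`, zero diagonal).
#' @export
intersubject_correlation <- function(betas, roi_subset = NULL) {
  B <- as_matrix_table(betas, "betas")
  if (!is.null(roi_subset)) {
    missing_rois <- setdiff(roi_subset, colnames(B))
    if (length(missing_rois)) stopf("unknown ROIs: %s",
                                    paste(missing_rois, collapse = ", "))
    B <- B[, roi_subset, drop = FALSE]
  }
  if (nrow(B) < 4) stopf("need at least 4 subjects")
  sds <- apply(B, 2, sd)
  if (any(sds == 0)) {
    stopf("zero-variance ROI(s): %s",
          paste(colnames(B)[sds == 0], collapse = ", "))
  }
  W <- cor(B)
  diag(W) <- 0
  structure(list(roi_ids = colnames(B), weights = W), class = "bp_network")
}

# Nonnegative weight matrix per the negative-weight policy.
network_weights <- function(net, negative = c("zero", "keep")) {
  negative <- match.arg(negative)
  W <- if (inherits(net, "bp_network")) net$weights else as.matrix(net)
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10))) {
    stopf("weight matrix must be symmetric")
  }
  if (negative == "zero") W[W < 0] <- 0
  W
}

canonical_labels <- function(memb) {
  u <- unique(memb)
  as.integer(match(memb, u))
}

#' Modularity with resolution parameter
#'
#' Newman-Girvan modularity of a partition on a nonnegative weighted graph:
#' \deqn{Q = \frac{1}{2m} \sum_{ij \in \mathrm{same}} \left( w_{ij} -
#'   \gamma \frac{k_i k_j}{2m} \right).}
#'
#' @param net A `bp_network` or symmetric weight matrix (negative entries are
#'   zeroed by the default policy).
#' @param membership Integer module label per node (covering all nodes).
#' @param gamma Resolution parameter.
#' @param negative Negative-weight policy, `"zero"` (default) or `"keep"`.
#' @return Modularity Q (scalar).
#' @export
modularity_q <- function(net, membership, gamma = 1, negative = "zero") {
  W <- network_weights(net, negative)
  n <- nrow(W)
  if (length(membership) != n) stopf("partition must cover all %d nodes", n)
  two_m <- sum(W)
  if (two_m <= 0) stopf("graph has no positive weight")
  k <- rowSums(W)
  same <- outer(membership, membership, "==")
  sum((W - gamma * outer(k, k) / two_m) * same) / two_m
}

# Greedy local moving on (possibly aggregated) graph W with self-loops on
# the diagonal. Candidate destinations are the communities node i connects
# to, plus a fresh singleton community (gain 0), which lets refinement split
# badly-placed nodes out. Returns the improved membership.
local_moving <- function(W, membership, gamma, order_nodes) {
  n <- nrow(W)
  two_m <- sum(W)
  diagw <- diag(W)
  Wo <- W; diag(Wo) <- 0
  k <- rowSums(Wo) + diagw
  sigma <- numeric(max(membership) + n)           # strength per community id
  agg <- rowsum(k, membership)
  sigma[as.integer(rownames(agg))] <- as.vector(agg)
  next_comm <- max(membership)
  improved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in order_nodes) {
      a <- membership[i]
      s <- tapply(Wo[i, ], membership, sum)       # connection to each community
      s_ids <- as.integer(names(s))
      s <- as.vector(s)
      ia <- match(a, s_ids)
      sig_a_mi <- sigma[a] - k[i]
      base <- s[ia] - gamma * k[i] * sig_a_mi / two_m
      gains <- s - gamma * k[i] * sigma[s_ids] / two_m
      gains[ia] <- -Inf                           # staying handled via base
      j <- which.max(gains)
      best_gain <- gains[j]
      to_new <- FALSE
      if (0 > best_gain) { best_gain <- 0; to_new <- TRUE }
      if (best_gain > base + 1e-12) {
        b <- if (to_new) { next_comm <- next_comm + 1L; next_comm } else s_ids[j]
        if (b > length(sigma)) sigma <- c(sigma, numeric(n))
        membership[i] <- b
        sigma[a] <- sigma[a] - k[i]
        sigma[b] <- sigma[b] + k[i]
        moved <- TRUE
        improved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(membership = membership, improved = improved_any)
}

#' Louvain community detection with refinement
#'
#' Greedy Louvain: local moving to a modularity local optimum, aggregation of
#' communities into super-nodes, repeated until no further improvement,
#' followed by a Kernighan-Lin-style single-node refinement sweep on the
#' original graph. Node visiting order is randomized from `seed`; ties are
#' broken by the first maximal-gain move encountered.
#'
#' @inheritParams modularity_q
#' @param seed Integer seed controlling node order.
#' @return A list of class `bp_partition`: `membership` (named contiguous
#'   positive integers), `gamma`, `q`, `n_modules`.
#' @export
louvain_partition <- function(net, gamma = 1, seed = 1L, negative = "zero") {
  W0 <- network_weights(net, negative)
  n <- nrow(W0)
  if (n == 0) stopf("empty graph")
  if (sum(W0) <= 0) stopf("graph has no positive weight")
  ids <- if (inherits(net, "bp_network")) net$roi_ids else
    (rownames(W0) %||% as.character(seq_len(n)))

  memb <- with_seed(seed, {
    node_map <- seq_len(n)        # original node -> current super-node
    W <- W0
    repeat {
      ord <- sample.int(nrow(W))
      res <- local_moving(W, seq_len(nrow(W)), gamma, ord)
      lm <- canonical_labels(res$membership)
      node_map <- lm[node_map]
      if (!res$improved || length(unique(lm)) == nrow(W) ||
          length(unique(lm)) == 1) break
      # aggregate: communities become nodes, internal weight -> self-loops
      W <- rowsum(t(rowsum(W, lm)), lm)
    }
    memb <- canonical_labels(node_map)
    # refinement: single-node moves on the original graph
    ord <- sample.int(n)
    canonical_labels(local_moving(W0, memb, gamma, ord)$membership)
  })
  q <- modularity_q(W0, memb, gamma)
  structure(list(membership = setNames(memb, ids), gamma = gamma, q = q,
                 n_modules = length(unique(memb))),
            class = "bp_partition")
}

#' Consensus partitioning configuration
#'
#' @param n_repetitions Louvain repetitions per consensus iteration.
#' @param null_permutations Label permutations pooled to form the null
#'   agreement threshold (the maximum over all permuted-agreement entries).
#' @param max_consensus_iterations Iteration cap before giving up.
#' @param seed Integer seed fanned out to all repetitions.
#' @return A list of class `bp_consensus_config`.
#' @export
consensus_config <- function(n_repetitions = 500, null_permutations = 100,
                             max_consensus_iterations = 20, seed = 1L) {
  if (n_repetitions < 1 || null_permutations < 1 || max_consensus_iterations < 1) {
    stopf("all counts must be >= 1")
  }
  structure(list(n_repetitions = n_repetitions,
                 null_permutations = null_permutations,
                 max_consensus_iterations = max_consensus_iterations,
                 seed = as.integer(seed)),
            class = "bp_consensus_config")
}

agreement_matrix <- function(members) {
  n <- length(members[[1]])
  A <- matrix(0, n, n)
  for (m in members) A <- A + outer(m, m, "==")
  A <- A / length(members)
  diag(A) <- 0
  A
}

#' Consensus partition of a network
#'
#' Runs [louvain_partition()] `n_repetitions` times, assembles the
#' co-assignment (agreement) matrix, zeroes entries at or below a
#' permutation-null threshold (the maximum entry of agreement matrices built
#' from label-permuted copies of the runs), re-partitions the thresholded
#' agreement graph, and iterates until the agreement matrix is binary. If no
#' entry survives the null threshold (a structureless network), the
#' best-modularity single run is returned instead of an error.
#'
#' @inheritParams louvain_partition
#' @param config A [consensus_config()].
#' @return A list: `partition` (a `bp_partition` with `q` evaluated on the
#'   input network), `agreement` (final agreement matrix of the input
#'   network's runs), `n_iterations`.
#' @export
consensus_partition <- function(net, gamma = 1,
                                config = consensus_config(),
                                negative = "zero") {
  W0 <- network_weights(net, negative)
  ids <- if (inherits(net, "bp_network")) net$roi_ids else
    (rownames(W0) %||% as.character(seq_len(nrow(W0))))
  W <- W0
  first_agreement <- NULL
  for (it in seq_len(config$max_consensus_iterations)) {
    members <- lapply(seq_len(config$n_repetitions), function(r) {
      unname(louvain_partition(W, gamma = gamma,
                               seed = child_seed(config$seed, it * 100003 + r))$membership)
    })
    uniq <- unique(members)
    if (length(uniq) == 1) {
      memb <- canonical_labels(uniq[[1]])
      part <- structure(list(membership = setNames(memb, ids), gamma = gamma,
                             q = modularity_q(W0, memb, gamma),
                             n_modules = length(unique(memb))),
                        class = "bp_partition")
      A <- agreement_matrix(members)
      return(list(partition = part,
                  agreement = first_agreement %||% A, n_iterations = it))
    }
    A <- agreement_matrix(members)
    if (it == 1) first_agreement <- A
    # permutation null: permute node labels within each run
    tau <- 0
    n <- nrow(A)
    for (p in seq_len(config$null_permutations)) {
      perm_members <- with_seed(child_seed(config$seed, 7 * it + 1000 * p), {
        lapply(members, function(m) m[sample.int(n)])
      })
      Anull <- agreement_matrix(perm_members)
      tau <- max(tau, max(Anull))
    }
    A[A <= tau] <- 0
    if (sum(A) <= 0) {
      # structureless network: no co-assignment exceeds the permutation
      # null; return the best-modularity run rather than failing
      qs <- vapply(members, function(m) modularity_q(W0, m, gamma), 0)
      memb <- canonical_labels(members[[which.max(qs)]])
      part <- structure(list(membership = setNames(memb, ids), gamma = gamma,
                             q = max(qs), n_modules = length(unique(memb))),
                        class = "bp_partition")
      return(list(partition = part, agreement = first_agreement %||% A,
                  n_iterations = it))
    }
    W <- A
  }
  stopf("consensus did not converge in %d iterations; increase n_repetitions",
        config$max_consensus_iterations)
}

entropy_nats <- function(counts, n) {
  p <- counts / n
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Adjusted mutual information between two partitions
#'
#' Chance-corrected partition similarity:
#' \deqn{\mathrm{AMI} = \frac{MI - E[MI]}{\tfrac12 (H_1 + H_2) - E[MI]},}
#' with the expected mutual information taken under the permutation
#' (hypergeometric) model and the arithmetic mean of the entropies as
#' normalizer. Label names are irrelevant; identical partitions score 1.
#'
#' @param p1,p2 `bp_partition` objects or label vectors over the same nodes.
#' @return AMI (scalar).
#' @export
adjusted_mutual_information <- function(p1, p2) {
  m1 <- if (inherits(p1, "bp_partition")) p1$membership else p1
  m2 <- if (inherits(p2, "bp_partition")) p2$membership else p2
  if (length(m1) != length(m2)) stopf("partitions must cover the same nodes")
  if (!is.null(names(m1)) && !is.null(names(m2))) {
    if (!setequal(names(m1), names(m2))) stopf("partitions must cover the same nodes")
    m2 <- m2[names(m1)]
  }
  n <- length(m1)
  t1 <- table(m1); t2 <- table(m2)
  a <- as.vector(t1); b <- as.vector(t2)
  ct <- table(m1, m2)
  # observed MI
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- ct[i, j]
    if (nij > 0) mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
  }
  h1 <- entropy_nats(a, n); h2 <- entropy_nats(b, n)
  # expected MI under the hypergeometric model
  emi <- 0
  lf <- lfactorial
  for (i in seq_along(a)) for (j in seq_along(b)) {
    lo <- max(1, a[i] + b[j] - n)
    hi <- min(a[i], b[j])
    if (hi < lo) next
    for (nij in lo:hi) {
      lp <- lf(a[i]) + lf(b[j]) + lf(n - a[i]) + lf(n - b[j]) -
        lf(n) - lf(nij) - lf(a[i] - nij) - lf(b[j] - nij) -
        lf(n - a[i] - b[j] + nij)
      emi <- emi + (nij / n) * log(n * nij / (a[i] * b[j])) * exp(lp)
    }
  }
  denom <- (h1 + h2) / 2 - emi
  if (abs(denom) < 1e-12) {
    return(if (abs(mi - emi) < 1e-12) 1 else 0)
  }
  (mi - emi) / denom
}

#' Resolution sweep with AMI-based selection and size filtering
#'
#' Computes a consensus partition for every gamma on the grid, selects the
#' gamma whose partition has the highest adjusted mutual information with a
#' reference partition, then drops modules smaller than `min_module_size`
#' (their ROIs are marked unassigned with label 0; retained modules are
#' relabelled 1..K by decreasing size).
#'
#' @inheritParams consensus_partition
#' @param gamma_grid Numeric grid of resolutions (default 1 to 1.5 by 0.05).
#' @param reference Reference partition (a `bp_partition` or label vector over
#'   the same nodes).
#' @param min_module_size Minimum ROIs per retained module (default 15).
#' @return A list: `partition` (filtered `bp_partition` with
#'   `ami_vs_reference` set; 0 labels = unassigned), `selected_gamma`,
#'   `diagnostics` (per-gamma data.frame: gamma, q, n_modules, ami),
#'   `unfiltered` (the selected partition before size filtering).
#' @export
choose_gamma <- function(net, gamma_grid = seq(1, 1.5, by = 0.05), reference,
                         min_module_size = 15, config = consensus_config(),
                         negative = "zero") {
  if (length(gamma_grid) == 0) stopf("gamma grid is empty")
  parts <- vector("list", length(gamma_grid))
  diags <- data.frame(gamma = gamma_grid, q = NA_real_,
                      n_modules = NA_integer_, ami = NA_real_)
  for (i in seq_along(gamma_grid)) {
    cp <- consensus_partition(net, gamma = gamma_grid[i], config = config,
                              negative = negative)
    parts[[i]] <- cp$partition
    diags$q[i] <- cp$partition$q
    diags$n_modules[i] <- cp$partition$n_modules
    diags$ami[i] <- adjusted_mutual_information(cp$partition, reference)
  }
  best <- which.max(diags$ami)
  sel <- parts[[best]]
  sel$ami_vs_reference <- diags$ami[best]

  memb <- sel$membership
  sizes <- table(memb)
  keep <- names(sizes)[sizes >= min_module_size]
  if (length(keep) == 0) {
    stopf("all modules smaller than min_module_size = %d", min_module_size)
  }
  filt <- memb
  filt[!(memb %in% as.integer(keep))] <- 0L
  keep_sorted <- as.integer(keep[order(-sizes[keep])])
  relab <- filt
  for (k in seq_along(keep_sorted)) relab[filt == keep_sorted[k]] <- k
  out <- sel
  out$membership <- relab
  out$n_modules <- length(keep_sorted)
  list(partition = out, selected_gamma = gamma_grid[best],
       diagnostics = diags, unfiltered = sel)
}
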