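#' Build a random network topology
#'
#' Draws the connection graph of the excitatory/inhibitory network. The
#' excitatory-to-excitatory graph is reciprocal: exactly
#' `round(p_ee * n_ex * (n_ex - 1) / 2)` unordered neuron pairs are sampled
#' uniformly without replacement and each is expanded into both directed
#' edges, so the adjacency matrix is symmetric and self-edges never occur.
#' Each possible excitatory-to-inhibitory edge is present independently with
#' probability `p_ie`, and each inhibitory-to-excitatory edge with
#' probability `p_ei`.
#'
#' Uses the current RNG state; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `net_topology`: a list with `n_ex`, `n_inh`
#'   and integer edge matrices `ee`, `ei`, `ie`, each with columns `post`
#'   and `pre` (edge direction `post <- pre`). `ei` rows are excitatory
#'   postsynaptic / inhibitory presynaptic; `ie` the reverse.
#' @export
#' @examples
#' set.seed(1)
#' topo <- build_topology(sim_params(n_ex = 40, n_inh = 10))
#' nrow(topo$ee)  # 2 * round(0.2 * 40 * 39 / 2)
build_topology <- function(params) {
  validate_sim_params(params)
  n_ex <- params$n_ex
  n_inh <- params$n_inh
  n_pairs_avail <- n_ex * (n_ex - 1) / 2
  n_pairs <- round(params$p_ee * n_pairs_avail)
  if (n_pairs > n_pairs_avail) {
    stop("invalid params: requested pair count exceeds available pairs",
         call. = FALSE)
  }
  if (n_pairs > 0) {
    pairs <- utils::combn(n_ex, 2L)           # 2 x n_pairs_avail, i < j
    take <- sample.int(n_pairs_avail, n_pairs)
    i <- pairs[1L, take]
    j <- pairs[2L, take]
    ee <- cbind(post = c(i, j), pre = c(j, i))
  } else {
    ee <- cbind(post = integer(0), pre = integer(0))
  }
  # E -> I edges, then I -> E edges, each independently Bernoulli
  ie_mask <- stats::runif(n_inh * n_ex) < params$p_ie
  ie_idx <- which(ie_mask) - 1L
  ie <- cbind(post = ie_idx %% n_inh + 1L, pre = ie_idx %/% n_inh + 1L)
  ei_mask <- stats::runif(n_ex * n_inh) < params$p_ei
  ei_idx <- which(ei_mask) - 1L
  ei <- cbind(post = ei_idx %% n_ex + 1L, pre = ei_idx %/% n_ex + 1L)
  structure(list(n_ex = n_ex, n_inh = n_inh,
                 ee = ee, ei = ei, ie = ie),
            class = "net_topology")
}

#' @export
print.net_topology <- function(x, ...) {
  cat(sprintf("<net_topology> %d E + %d I neurons\n", x$n_ex, x$n_inh))
  cat(sprintf("  E<-E: %d directed edges (reciprocal), E<-I: %d, I<-E: %d\n",
              nrow(x$ee), nrow(x$ei), nrow(x$ie)))
  invisible(x)
}

#' Excitatory adjacency matrix of a topology
#'
#' @param topo A `net_topology`.
#' @return A `n_ex` x `n_ex` 0/1 matrix, rows postsynaptic.
#' @export
ee_adjacency <- function(topo) {
  a <- matrix(0L, topo$n_ex, topo$n_ex)
  a[topo$ee] <- 1L
  a
}

#' Insert a three-neuron cell assembly into a topology
#'
#' Adds all six directed edges among the three member neurons that do not
#' already exist. Newly created edges carry zero synaptic weight when the
#' simulation resumes; pre-existing edges (and their weights) are untouched.
#' Reciprocity of the excitatory graph is preserved because edges are added
#' in both directions. Inserting the same assembly twice is a no-op the
#' second time.
#'
#' @param topo A `net_topology`.
#' @param members Integer vector of 3 distinct excitatory neuron indices.
#' @return A list with `topology` (updated) and `added_edges` (integer
#'   matrix of the newly created directed edges, columns `post`, `pre`).
#' @export
insert_assembly <- function(topo, members) {
  members <- as.integer(members)
  if (length(members) != 3L || anyDuplicated(members) ||
      any(members < 1L | members > topo$n_ex)) {
    stop("assembly members must be 3 distinct excitatory neuron indices",
         call. = FALSE)
  }
  cand <- assembly_edges(members)
  key_old <- paste(topo$ee[, 1L], topo$ee[, 2L])
  new <- cand[!(paste(cand[, 1L], cand[, 2L]) %in% key_old), , drop = FALSE]
  topo$ee <- rbind(topo$ee, new)
  list(topology = topo, added_edges = new)
}

# all 6 directed edges among a member triplet
assembly_edges <- function(members) {
  g <- expand.grid(post = members, pre = members)
  g <- g[g$post != g$pre, ]
  cbind(post = as.integer(g$post), pre = as.integer(g$pre))
}

#' Select cell-assembly member triplets
#'
#' Draws `n_assemblies` triplets of excitatory neurons, either fully at
#' random (triplets may overlap; members within one triplet are always
#' distinct) or mutually non-overlapping (every neuron used at most once,
#' requiring `3 * n_assemblies <= n_ex`).
#'
#' Uses the current RNG state.
#'
#' @param n_assemblies Number of triplets.
#' @param n_ex Number of excitatory neurons to draw from.
#' @param policy `"random"` (default) or `"non-overlapping"`.
#' @return List of integer vectors of length 3.
#' @export
select_assemblies <- function(n_assemblies, n_ex,
                              policy = c("random", "non-overlapping")) {
  policy <- match.arg(policy)
  if (n_ex < 3L) stop("need at least 3 excitatory neurons", call. = FALSE)
  if (policy == "non-overlapping") {
    if (3L * n_assemblies > n_ex) {
      stop(sprintf(
        "non-overlapping policy infeasible: 3 * %d > %d neurons",
        n_assemblies, n_ex), call. = FALSE)
    }
    picks <- sample.int(n_ex, 3L * n_assemblies)
    return(split(picks, rep(seq_len(n_assemblies), each = 3L)) |> unname())
  }
  lapply(seq_len(n_assemblies), function(i) sample.int(n_ex, 3L))
}
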